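#' Construct a knockdown screen dataset
#'
#' Bundles an aligned genotype table (lines by knockdowns, entries in
#' \[0, 1\]: 1 = dsRNA against the gene present, 0 = absent, fractional
#' values are read as knockdown probabilities) and a phenotype table
#' (lines by quantitative phenotypes) into a single validated object.
#' Rows of both tables must describe the same screen lines in the same
#' order; `kd_dataset()` aligns the phenotype rows to the genotype rows
#' by the `line_id` column.
#'
#' @param genotype A data frame: first column `line_id`, remaining columns
#'   one per knocked-down gene with values in \[0, 1\].
#' @param phenotype A data frame: first column `line_id`, remaining columns
#'   one per measured phenotype (numeric).
#' @param normalized Logical; whether the phenotype columns are already
#'   log-transformed, centered and scaled (see [normalize_phenotypes()]).
#'
#' @return An object of class `kd_dataset`: a list with elements
#'   `line_ids`, `gene_names`, `genotype` (numeric matrix), `phenotype_names`,
#'   `phenotypes` (numeric matrix) and `normalized`.
#' @seealso [load_dataset()], [normalize_phenotypes()], [simulate_screen()]
#' @export
kd_dataset <- function(genotype, phenotype, normalized = FALSE) {
  genotype <- tibble::as_tibble(genotype)
  phenotype <- tibble::as_tibble(phenotype)
  if (!"line_id" %in% names(genotype) || !"line_id" %in% names(phenotype)) {
    abort("both tables need a `line_id` column", class = "influscreen_parse_error")
  }
  gid <- as.character(genotype$line_id)
  pid <- as.character(phenotype$line_id)
  if (anyDuplicated(gid) || anyDuplicated(pid)) {
    abort("duplicated line identifiers", class = "influscreen_alignment_error")
  }
  missing_p <- setdiff(gid, pid)
  missing_g <- setdiff(pid, gid)
  if (length(missing_p) || length(missing_g)) {
    abort(
      paste0(
        "line identifiers do not match between genotype and phenotype tables; ",
        "missing from phenotypes: [", paste(head(missing_p, 5), collapse = ", "), "]; ",
        "missing from genotypes: [", paste(head(missing_g, 5), collapse = ", "), "]"
      ),
      class = "influscreen_alignment_error"
    )
  }
  phenotype <- phenotype[match(gid, pid), , drop = FALSE]

  gmat <- .numeric_matrix(genotype[-match("line_id", names(genotype))], "genotype")
  pmat <- .numeric_matrix(phenotype[-match("line_id", names(phenotype))], "phenotype")
  if (anyDuplicated(colnames(gmat))) {
    abort("duplicated gene names in genotype table", class = "influscreen_validation_error")
  }
  bad <- which(gmat < 0 | gmat > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(
      sprintf(
        "genotype values must lie in [0, 1]; first offender row %d (%s), gene %s",
        bad[1, 1], gid[bad[1, 1]], colnames(gmat)[bad[1, 2]]
      ),
      class = "influscreen_validation_error"
    )
  }
  rownames(gmat) <- rownames(pmat) <- gid
  structure(
    list(
      line_ids = gid,
      gene_names = colnames(gmat),
      genotype = gmat,
      phenotype_names = colnames(pmat),
      phenotypes = pmat,
      normalized = isTRUE(normalized)
    ),
    class = "kd_dataset"
  )
}

#' @export
print.kd_dataset <- function(x, ...) {
  cat(sprintf(
    "<kd_dataset> %d lines x %d knockdowns, %d phenotypes (%s)\n",
    length(x$line_ids), length(x$gene_names), length(x$phenotype_names),
    if (x$normalized) "normalized" else "raw"
  ))
  invisible(x)
}

.numeric_matrix <- function(df, what) {
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.character(col) || is.factor(col)) {
      suppressWarnings(num <- as.numeric(as.character(col)))
      if (anyNA(num) && !all(is.na(col))) {
        row <- which(is.na(num) & !is.na(col))[1]
        abort(
          sprintf(
            "non-numeric %s value '%s' at row %d, column '%s'",
            what, as.character(col)[row], row, names(df)[j]
          ),
          class = "influscreen_parse_error"
        )
      }
      df[[j]] <- num
    }
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(
      sprintf("missing %s value at row %d, column '%s'", what, idx[1], colnames(m)[idx[2]]),
      class = "influscreen_parse_error"
    )
  }
  m
}

#' Load a knockdown screen from delimited text files
#'
#' Reads a genotype table and a phenotype table (tab- or comma-delimited,
#' auto-detected; first column the line identifier, header row the gene or
#' phenotype names) and aligns them into a [kd_dataset()]. Row order follows
#' the genotype file. Phenotypes are returned raw; call
#' [normalize_phenotypes()] before analysis.
#'
#' @param genotype_path,phenotype_path Paths to the two delimited files.
#' @return A `kd_dataset` (not yet normalized).
#' @export
load_dataset <- function(genotype_path, phenotype_path) {
  g <- .read_delim_auto(genotype_path)
  p <- .read_delim_auto(phenotype_path)
  names(g)[1] <- "line_id"
  names(p)[1] <- "line_id"
  kd_dataset(g, p, normalized = FALSE)
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "influscreen_parse_error")
  }
  first <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
               lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Log-transform and standardize phenotype columns
#'
#' Applies the screen's phenotype normalization: each column is
#' log-transformed, mean-centered and scaled to sample standard deviation 1
#' (denominator `n - 1`). All raw values must be strictly positive.
#'
#' @param dataset A `kd_dataset` with raw phenotypes, or a bare numeric
#'   matrix / data frame of positive phenotype values.
#' @param log_base Base of the log transform (default 10).
#' @param log_transform Set to `FALSE` to only center and scale (used when
#'   the input is already on a log scale).
#' @return The same type as the input, with normalized phenotype columns;
#'   for a `kd_dataset` the `normalized` flag is set.
#' @export
normalize_phenotypes <- function(dataset, log_base = 10, log_transform = TRUE) {
  if (inherits(dataset, "kd_dataset")) {
    dataset$phenotypes <- normalize_phenotypes(dataset$phenotypes,
      log_base = log_base, log_transform = log_transform
    )
    dataset$normalized <- TRUE
    return(dataset)
  }
  m <- as.matrix(dataset)
  storage.mode(m) <- "double"
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 0) {
    abort("`log_base` must be a positive scalar", class = "influscreen_validation_error")
  }
  if (log_transform) {
    if (any(m <= 0)) {
      idx <- which(m <= 0, arr.ind = TRUE)[1, ]
      abort(
        sprintf(
          "phenotype values must be strictly positive for the log transform; offender at row %d, column '%s'",
          idx[1], colnames(m)[idx[2]] %||% as.character(idx[2])
        ),
        class = "influscreen_domain_error"
      )
    }
    m <- log(m, base = log_base)
  }
  sds <- apply(m, 2, sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    bad <- colnames(m)[sds < .Machine$double.eps^0.5] %||% which(sds < .Machine$double.eps^0.5)
    abort(
      sprintf("degenerate phenotype column(s) with zero variance: %s", paste(bad, collapse = ", ")),
      class = "influscreen_degenerate_column_error"
    )
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Pearson correlations between phenotypes
#'
#' @param dataset A `kd_dataset` or a numeric matrix of phenotypes
#'   (at least 3 rows, no zero-variance column).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
phenotype_correlations <- function(dataset) {
  m <- if (inherits(dataset, "kd_dataset")) dataset$phenotypes else as.matrix(dataset)
  if (nrow(m) < 3) {
    abort("need at least 3 lines to estimate correlations", class = "influscreen_validation_error")
  }
  sds <- apply(m, 2, sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    bad <- colnames(m)[sds < .Machine$double.eps^0.5] %||% which(sds < .Machine$double.eps^0.5)
    abort(
      sprintf("degenerate phenotype column(s) with zero variance: %s", paste(bad, collapse = ", ")),
      class = "influscreen_degenerate_column_error"
    )
  }
  stats::cor(m)
}

# internal: matrix accessors with validation
.dataset_matrices <- function(dataset, require_normalized = TRUE) {
  stopifnot(inherits(dataset, "kd_dataset"))
  if (require_normalized && !dataset$normalized) {
    abort("phenotypes are not normalized; call normalize_phenotypes() first",
      class = "influscreen_validation_error"
    )
  }
  dataset
}
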