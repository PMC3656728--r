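#' Scan every knockdown pair and collect tandem permutation nulls
#'
#' Runs the covariate-conditioned pairwise regression, the activity
#' reparametrization, the directed influence coefficients and their
#' delta-method errors for every unordered knockdown pair, and — when
#' `n_perm > 0` — replays the whole computation under *tandem
#' permutations*: each permutation draw applies one shared random row
#' permutation to the two scanned genotype columns only, leaving all
#' other knockdowns (including covariates) and the phenotypes untouched,
#' so only the scanned pair's marginal association is randomized. The
#' absolute test statistics of the permuted influence and
#' knockdown-to-phenotype coefficients form the null distributions used
#' by [adjust_significance()].
#'
#' Pairs whose design is rank deficient are reported with status
#' `non_estimable`; pairs whose main-effect matrix is ill-conditioned are
#' `singular`; pairs at a pole of the influence map are `pole`. Permuted
#' refits that are themselves non-estimable are skipped and counted; a
#' pair with more than 20% skipped draws is flagged `unreliable_null`.
#'
#' @param dataset A normalized `kd_dataset`.
#' @param decomp An `eigentrait_decomposition` with `k = 2`.
#' @param covariates A `kd_covariates` (or `NULL` for no conditioning).
#' @param n_perm Tandem permutations per pair (default 700; 0 disables).
#' @param seed Optional integer seed.
#' @param condition_number_limit,pole_tol Guards for the activity
#'   inversion and the influence map (see [activity_deltas()],
#'   [influence_coefficients()]).
#' @return An object of class `kd_pair_results`: a list with
#'   * `influences` — tibble, one row per unordered pair (`gene_a`,
#'     `gene_b`, main effects, interaction coefficients, `delta_1`,
#'     `delta_2`, `m_ab`, `m_ba`, SEs, statistics, `status`,
#'     `null_skipped`);
#'   * `pheno_models` — tibble, one row per (pair, member gene,
#'     phenotype) with the recomposed coefficient, SE and statistic;
#'   * `null_m`, `null_pheno` — permutation null matrices (draws by
#'     hypotheses), columns aligned with rows of the two tibbles;
#'   * `n_perm`, `seed`.
#' @export
scan_all_pairs <- function(dataset, decomp, covariates = NULL, n_perm = 700,
                           seed = NULL, condition_number_limit = 1e8,
                           pole_tol = 1e-8) {
  dataset <- .dataset_matrices(dataset)
  if (decomp$k != 2L) {
    abort("the influence model requires k = 2 retained eigentraits",
      class = "influscreen_unsupported_dimension_error"
    )
  }
  if (!is.null(seed)) set.seed(seed)
  G <- length(dataset$gene_names)
  pairs <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), c(1, 2), drop = FALSE]
  n <- nrow(dataset$genotype)
  n_perm <- as.integer(n_perm)
  perms <- if (n_perm > 0) {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  } else {
    matrix(0L, n, 0)
  }
  cov_sets <- .covariate_sets(covariates, 2L)
  L <- recomposition_map(decomp)

  res <- pair_engine_cpp(
    U = decomp$U[, 1:2, drop = FALSE],
    X = dataset$genotype,
    L = L,
    covs = lapply(cov_sets, as.integer),
    pairs = matrix(as.numeric(pairs), ncol = 2),
    perms = matrix(as.numeric(perms), nrow = n),
    cond_limit = condition_number_limit,
    pole_tol = pole_tol,
    rcond_tol = 1e-10
  )

  status <- c("estimable", "non_estimable", "singular", "pole")[res$status + 1L]
  skipped <- as.integer(res$null_skips)
  if (n_perm > 0) {
    unreliable <- status == "estimable" & skipped > 0.2 * n_perm
    status[unreliable] <- "unreliable_null"
  }
  genes <- dataset$gene_names
  infl <- tibble::tibble(
    gene_a = genes[pairs[, 1]], gene_b = genes[pairs[, 2]],
    beta_a1 = res$coef[, 1], beta_a2 = res$coef[, 2],
    beta_b1 = res$coef[, 3], beta_b2 = res$coef[, 4],
    gamma_1 = res$coef[, 5], gamma_2 = res$coef[, 6],
    se_gamma_1 = res$se_coef[, 5], se_gamma_2 = res$se_coef[, 6],
    delta_1 = res$delta[, 1], delta_2 = res$delta[, 2],
    m_ab = res$m[, 1], m_ba = res$m[, 2],
    se_ab = sqrt(res$var_m[, 1]), se_ba = sqrt(res$var_m[, 2]),
    stat_ab = res$m[, 1] / sqrt(res$var_m[, 1]),
    stat_ba = res$m[, 2] / sqrt(res$var_m[, 2]),
    status = status,
    null_skipped = skipped
  )

  NP <- nrow(L)
  phen <- tibble::tibble(
    pair = rep(seq_len(nrow(pairs)), each = 2L * NP),
    gene = genes[as.vector(vapply(
      seq_len(nrow(pairs)),
      function(p) rep(pairs[p, ], each = NP), integer(2L * NP)
    ))],
    partner = genes[as.vector(vapply(
      seq_len(nrow(pairs)),
      function(p) rep(rev(pairs[p, ]), each = NP), integer(2L * NP)
    ))],
    phenotype = rep(decomp$phenotype_names, times = 2L * nrow(pairs)),
    coef = as.vector(t(res$pheno)),
    se = as.vector(t(res$pheno_se)),
    status = rep(status, each = 2L * NP)
  )
  phen$stat <- phen$coef / phen$se
  # row i of phen corresponds to column i of null_pheno by construction
  phen$null_col <- seq_len(nrow(phen))

  structure(
    list(
      influences = infl,
      pheno_models = phen,
      null_m = res$null_m,
      null_pheno = res$null_pheno,
      n_perm = n_perm,
      seed = seed,
      gene_names = genes,
      pairs = pairs
    ),
    class = "kd_pair_results"
  )
}

#' @export
print.kd_pair_results <- function(x, ...) {
  cat(sprintf(
    "<kd_pair_results> %d pairs (%d estimable), %d tandem permutations\n",
    nrow(x$influences), sum(x$influences$status == "estimable"), x$n_perm
  ))
  invisible(x)
}

#' Summarize knockdown-to-phenotype effects across pair models
#'
#' Each gene's phenotype effect is estimated in every pair model it
#' appears in; the representative coefficient reported for a
#' (gene, phenotype) is the one whose standardized effect size
#' (`|coef| / SE`) is the median of the collection — an actually fitted
#' coefficient, not an interpolation; for even counts the lower median is
#' taken. Genes appearing in no estimable pair model are reported with
#' `NA` and a reason.
#'
#' @param pair_results A `kd_pair_results` from [scan_all_pairs()].
#' @return A tibble with one row per (gene, phenotype): `gene`,
#'   `phenotype`, `coef`, `se`, `stat`, `partner` (the pair model the
#'   representative came from), `n_models`, and `null_col` (the column of
#'   `pair_results$null_pheno` carrying the matching permutation null).
#' @export
summarize_phenotype_effects <- function(pair_results) {
  stopifnot(inherits(pair_results, "kd_pair_results"))
  phen <- pair_results$pheno_models
  usable <- phen[phen$status == "estimable" & is.finite(phen$stat), , drop = FALSE]
  all_genes <- pair_results$gene_names
  phenos <- unique(phen$phenotype)
  grid <- tidyr::expand_grid(gene = all_genes, phenotype = phenos)
  picked <- usable |>
    dplyr::group_by(.data$gene, .data$phenotype) |>
    dplyr::group_modify(function(df, key) {
      ord <- order(abs(df$stat))
      pick <- ord[ceiling(length(ord) / 2)] # lower median for even counts
      tibble::tibble(
        coef = df$coef[pick], se = df$se[pick], stat = df$stat[pick],
        partner = df$partner[pick], n_models = nrow(df),
        null_col = df$null_col[pick]
      )
    }) |>
    dplyr::ungroup()
  out <- dplyr::left_join(grid, picked, by = c("gene", "phenotype"))
  out$reason <- ifelse(is.na(out$coef), "no estimable pair model", NA_character_)
  out
}
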