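#' Assemble the directed genetic-interaction network
#'
#' Retains every directed knockdown-to-knockdown influence and every
#' knockdown-to-phenotype effect with adjusted p-value below the cutoff.
#' Both directions of a pair are tested independently, so a pair can
#' contribute zero, one or two directed gene edges. Edge signs follow the
#' coefficient signs: negative influences are suppressive
#' (shared-pathway-like), positive influences enhancing
#' (antagonistic-pathway-like).
#'
#' @param significance A `kd_significance` from [adjust_significance()].
#' @param cutoff Adjusted-p cutoff in (0, 1); default 0.01.
#' @param metadata Optional named list recorded on the network (seeds,
#'   permutation counts, thresholds).
#' @return An object of class `influence_network`: `gene_edges` (tibble:
#'   `source`, `target`, `m`, `se`, `stat`, `p`, `adj_p`, `sign`),
#'   `phenotype_edges` (tibble: `gene`, `phenotype`, `coef`, `se`,
#'   `stat`, `p`, `adj_p`, `sign`), `genes`, `cutoff`, `metadata`.
#' @export
build_network <- function(significance, cutoff = 0.01, metadata = list()) {
  stopifnot(inherits(significance, "kd_significance"))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1) {
    abort("`cutoff` must lie in (0, 1)", class = "influscreen_domain_error")
  }
  infl <- significance$influences
  ab <- infl[!is.na(infl$adj_p_ab) & infl$adj_p_ab < cutoff, , drop = FALSE]
  ba <- infl[!is.na(infl$adj_p_ba) & infl$adj_p_ba < cutoff, , drop = FALSE]
  gene_edges <- dplyr::bind_rows(
    tibble::tibble(
      source = ab$gene_a, target = ab$gene_b, m = ab$m_ab, se = ab$se_ab,
      stat = ab$stat_ab, p = ab$p_ab, adj_p = ab$adj_p_ab
    ),
    tibble::tibble(
      source = ba$gene_b, target = ba$gene_a, m = ba$m_ba, se = ba$se_ba,
      stat = ba$stat_ba, p = ba$p_ba, adj_p = ba$adj_p_ba
    )
  )
  gene_edges$sign <- sign(gene_edges$m)
  gene_edges <- dplyr::arrange(gene_edges, .data$adj_p, .data$source, .data$target)

  ph <- significance$phenotype_effects
  ph <- ph[!is.na(ph$adj_p) & ph$adj_p < cutoff, , drop = FALSE]
  phenotype_edges <- tibble::tibble(
    gene = ph$gene, phenotype = ph$phenotype, coef = ph$coef, se = ph$se,
    stat = ph$stat, p = ph$p, adj_p = ph$adj_p, sign = sign(ph$coef)
  )
  phenotype_edges <- dplyr::arrange(phenotype_edges, .data$adj_p, .data$gene)

  genes <- sort(unique(c(
    significance$influences$gene_a, significance$influences$gene_b
  )))
  structure(
    list(
      gene_edges = gene_edges,
      phenotype_edges = phenotype_edges,
      genes = genes,
      phenotypes = unique(significance$phenotype_effects$phenotype),
      cutoff = cutoff,
      metadata = metadata
    ),
    class = "influence_network"
  )
}

#' @export
print.influence_network <- function(x, ...) {
  cat(sprintf(
    "<influence_network> %d gene-to-gene edges, %d gene-to-phenotype edges (adjusted p < %g)\n",
    nrow(x$gene_edges), nrow(x$phenotype_edges), x$cutoff
  ))
  invisible(x)
}

#' Tidy an influence network
#'
#' @param x An `influence_network`.
#' @param ... Unused.
#' @return A tibble of all edges; gene targets and phenotype targets are
#'   distinguished by `target_type`.
#' @export
tidy.influence_network <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(
      dplyr::rename(x$gene_edges, estimate = "m"),
      target_type = "gene", .before = 1
    ),
    dplyr::mutate(
      dplyr::rename(x$phenotype_edges,
        source = "gene", target = "phenotype", estimate = "coef"
      ),
      target_type = "phenotype", .before = 1
    )
  )
}

#' @rdname tidy.influence_network
#' @export
glance.influence_network <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_gene_edges = nrow(x$gene_edges),
    n_phenotype_edges = nrow(x$phenotype_edges),
    n_negative = sum(x$gene_edges$sign < 0),
    n_positive = sum(x$gene_edges$sign > 0),
    cutoff = x$cutoff
  )
}

#' Infer pathway roles from interaction signs
#'
#' Applies the sign rules for pathway placement: knockdowns acting in the
#' same signaling process tend to show suppressive (negative)
#' interactions, knockdowns in antagonistic processes enhancing
#' (positive) ones. An unannotated gene with at least one significant
#' negative influence edge (either direction) to an annotated pathway
#' gene is a *same-pathway candidate*; one with a positive edge to an
#' annotated pathway gene is a *pathway-inhibitor candidate*; genes
#' matching both rules are *ambiguous*; a pair whose two directed edges
#' are both positive marks the gene *complex* (mutual enhancement does
#' not fit a simple inhibitor role); genes with no edges to annotated
#' genes are *unassigned*. Labels are evidence listings, not hard calls:
#' the supporting edges are returned.
#'
#' @param network An `influence_network`.
#' @param annotations A data frame with columns `gene` and `role`; roles
#'   are `"pathway"` (reference pathway member), `"inhibitor"`,
#'   `"antagonist"` or `"unannotated"`. At least one annotated pathway
#'   gene is required.
#' @return A tibble with one row per unannotated gene: `gene`, `role`
#'   (`same_pathway_candidate`, `pathway_inhibitor_candidate`,
#'   `ambiguous`, `complex`, `unassigned`), `n_negative`, `n_positive`,
#'   and `evidence` (supporting partner genes, collapsed).
#' @export
classify_pathway_roles <- function(network, annotations) {
  stopifnot(inherits(network, "influence_network"))
  annotations <- tibble::as_tibble(annotations)
  if (!all(c("gene", "role") %in% names(annotations)) ||
    !any(annotations$role == "pathway")) {
    abort("annotations must contain columns gene/role with at least one 'pathway' gene",
      class = "influscreen_validation_error"
    )
  }
  pathway_genes <- annotations$gene[annotations$role == "pathway"]
  annotated <- annotations$gene[annotations$role != "unannotated"]
  candidates <- setdiff(network$genes, annotated)
  e <- network$gene_edges
  # mutual enhancement: both directions of one unordered pair positive
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pos <- e[e$sign > 0, , drop = FALSE]
  mutual <- names(which(table(key(pos$source, pos$target)) >= 2))

  purrr::map_dfr(candidates, function(g) {
    touching <- e[(e$source == g & e$target %in% pathway_genes) |
      (e$target == g & e$source %in% pathway_genes), , drop = FALSE]
    partner <- ifelse(touching$source == g, touching$target, touching$source)
    n_neg <- sum(touching$sign < 0)
    n_pos <- sum(touching$sign > 0)
    is_mutual <- any(key(rep(g, length(partner)), partner) %in% mutual & touching$sign > 0)
    role <- if (n_neg == 0 && n_pos == 0) {
      "unassigned"
    } else if (n_neg > 0 && n_pos > 0) {
      "ambiguous"
    } else if (n_pos > 0 && is_mutual) {
      "complex"
    } else if (n_pos > 0) {
      "pathway_inhibitor_candidate"
    } else {
      "same_pathway_candidate"
    }
    tibble::tibble(
      gene = g, role = role, n_negative = n_neg, n_positive = n_pos,
      evidence = paste(
        sprintf("%s(%+.3g)", partner, touching$m),
        collapse = "; "
      )
    )
  })
}

#' Export a network to files
#'
#' Writes the edge lists as TSV, a signed adjacency matrix as CSV (rows =
#' source genes, columns = target genes then phenotypes; blanks where no
#' significant edge), a SIF file, and GraphML. The TSV round-trips
#' losslessly through [import_network()].
#'
#' @param network An `influence_network`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "adjacency", "sif", "graphml")`.
#' @return Invisibly, the named vector of written file paths.
#' @export
export_network <- function(network, dir,
                           formats = c("tsv", "adjacency", "sif", "graphml")) {
  stopifnot(inherits(network, "influence_network"))
  known <- c("tsv", "adjacency", "sif", "graphml")
  bad <- setdiff(formats, known)
  if (length(bad)) {
    abort(
      sprintf(
        "unknown format(s): %s (supported: %s)",
        paste(bad, collapse = ", "), paste(known, collapse = ", ")
      ),
      class = "influscreen_validation_error"
    )
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  if ("tsv" %in% formats) {
    f1 <- file.path(dir, "network_gene_edges.tsv")
    f2 <- file.path(dir, "network_phenotype_edges.tsv")
    readr::write_tsv(network$gene_edges, f1)
    readr::write_tsv(network$phenotype_edges, f2)
    out <- c(out, gene_edges = f1, phenotype_edges = f2)
  }
  if ("adjacency" %in% formats) {
    f <- file.path(dir, "adjacency.csv")
    genes <- network$genes
    phenos <- network$phenotypes
    adj <- matrix(NA_real_, length(genes), length(genes) + length(phenos),
      dimnames = list(genes, c(genes, phenos))
    )
    e <- network$gene_edges
    if (nrow(e)) adj[cbind(e$source, e$target)] <- e$m
    pe <- network$phenotype_edges
    if (nrow(pe)) adj[cbind(pe$gene, pe$phenotype)] <- pe$coef
    df <- tibble::as_tibble(adj, .name_repair = "minimal")
    df <- tibble::add_column(df, source = genes, .before = 1)
    readr::write_csv(df, f, na = "")
    out <- c(out, adjacency = f)
  }
  if ("sif" %in% formats) {
    f <- file.path(dir, "network.sif")
    lines <- c(
      if (nrow(network$gene_edges)) {
        sprintf(
          "%s\t%s\t%s", network$gene_edges$source,
          ifelse(network$gene_edges$sign < 0, "suppresses", "enhances"),
          network$gene_edges$target
        )
      },
      if (nrow(network$phenotype_edges)) {
        sprintf(
          "%s\t%s\t%s", network$phenotype_edges$gene,
          ifelse(network$phenotype_edges$sign < 0, "decreases", "increases"),
          network$phenotype_edges$phenotype
        )
      }
    )
    writeLines(lines %||% character(0), f)
    out <- c(out, sif = f)
  }
  if ("graphml" %in% formats) {
    f <- file.path(dir, "network.graphml")
    g <- as_igraph(network)
    igraph::write_graph(g, f, format = "graphml")
    out <- c(out, graphml = f)
  }
  invisible(out)
}

#' Convert an influence network to an igraph object
#'
#' @param network An `influence_network`.
#' @return A directed `igraph` graph; gene and phenotype nodes carry a
#'   `type` attribute, edges carry `m`, `adj_p` and `sign`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "influence_network"))
  edges <- dplyr::bind_rows(
    dplyr::select(network$gene_edges, from = "source", to = "target",
      weight = "m", adj_p = "adj_p", sign = "sign"
    ),
    dplyr::select(network$phenotype_edges, from = "gene", to = "phenotype",
      weight = "coef", adj_p = "adj_p", sign = "sign"
    )
  )
  vertices <- tibble::tibble(
    name = c(network$genes, network$phenotypes),
    type = c(
      rep("gene", length(network$genes)),
      rep("phenotype", length(network$phenotypes))
    )
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Read a network edge-list export back
#'
#' @param dir Directory written by [export_network()].
#' @param cutoff Cutoff to record on the reconstructed object.
#' @return An `influence_network` equal (up to metadata) to the exported
#'   one.
#' @export
import_network <- function(dir, cutoff = 0.01) {
  ge <- readr::read_tsv(file.path(dir, "network_gene_edges.tsv"),
    show_col_types = FALSE,
    col_types = readr::cols(
      source = readr::col_character(), target = readr::col_character(),
      .default = readr::col_double()
    )
  )
  pe <- readr::read_tsv(file.path(dir, "network_phenotype_edges.tsv"),
    show_col_types = FALSE,
    col_types = readr::cols(
      gene = readr::col_character(), phenotype = readr::col_character(),
      .default = readr::col_double()
    )
  )
  structure(
    list(
      gene_edges = ge, phenotype_edges = pe,
      genes = sort(unique(c(ge$source, ge$target))),
      phenotypes = unique(pe$phenotype),
      cutoff = cutoff, metadata = list(imported_from = dir)
    ),
    class = "influence_network"
  )
}
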