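# a hand-built kd_pair_results with controlled phenotype-model statistics
fake_pair_results <- function(stats_by_gene) {
  # stats_by_gene: named list gene -> vector of standardized effects, one
  # per pair model the gene appears in; single phenotype "p"
  rows <- list()
  pair_id <- 0L
  for (g in names(stats_by_gene)) {
    for (s in stats_by_gene[[g]]) {
      pair_id <- pair_id + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pair = pair_id, gene = g, partner = sprintf("pt%02d", pair_id),
        phenotype = "p", coef = s * 0.1, se = 0.1, status = "estimable",
        stat = s
      )
    }
  }
  phen <- dplyr::bind_rows(rows)
  phen$null_col <- seq_len(nrow(phen))
  structure(
    list(
      influences = tibble::tibble(),
      pheno_models = phen,
      null_m = matrix(0, 2, 0),
      null_pheno = matrix(0, 2, nrow(phen)),
      n_perm = 2L, seed = 1L,
      gene_names = unique(c(phen$gene, phen$partner)),
      pairs = NULL
    ),
    class = "kd_pair_results"
  )
}

test_that("the representative phenotype coefficient is the median standard effect", {
  pr <- fake_pair_results(list(
    solo = 4, odd = c(1, 5, 9), even = c(1, 2, 3, 4)
  ))
  out <- summarize_phenotype_effects(pr)
  get <- function(g) out[out$gene == g & !is.na(out$coef), ]
  expect_equal(get("solo")$stat, 4) # singleton
  expect_equal(get("odd")$stat, 5) # middle of an odd collection
  expect_equal(get("even")$stat, 2) # lower median of an even collection
  expect_equal(get("even")$n_models, 4L)
  # genes never fitted are reported missing with a reason
  missing <- out[out$gene == "pt01", ]
  expect_true(is.na(missing$coef))
  expect_match(missing$reason, "no estimable")
})

make_network <- function(edges, phenotype_edges = NULL, cutoff = 0.01) {
  ge <- tibble::tibble(
    source = character(0), target = character(0), m = numeric(0),
    se = numeric(0), stat = numeric(0), p = numeric(0),
    adj_p = numeric(0), sign = numeric(0)
  )
  if (!is.null(edges)) ge <- dplyr::bind_rows(ge, edges)
  pe <- tibble::tibble(
    gene = character(0), phenotype = character(0), coef = numeric(0),
    se = numeric(0), stat = numeric(0), p = numeric(0),
    adj_p = numeric(0), sign = numeric(0)
  )
  if (!is.null(phenotype_edges)) pe <- dplyr::bind_rows(pe, phenotype_edges)
  structure(
    list(
      gene_edges = ge, phenotype_edges = pe,
      genes = sort(unique(c(ge$source, ge$target, "u", "v", "w", "ras1", "ras2"))),
      phenotypes = "p", cutoff = cutoff, metadata = list()
    ),
    class = "influence_network"
  )
}

test_that("network assembly filters on adjusted significance, monotonically", {
  scr <- prepared_screen(G = 10, n_strong = 4, n_edges = 2, seed = 103)
  set.seed(104)
  scan <- single_locus_scan(scr$dataset, scr$decomp)
  null <- single_scan_null(scr$dataset, scr$decomp, n_perm = 120)
  cv <- select_covariates(scan, null)
  pr <- scan_all_pairs(scr$dataset, scr$decomp, cv, n_perm = 120)
  sig <- adjust_significance(pr)
  cutoffs <- c(0.2, 0.1, 0.05, 0.01, 0.005)
  counts <- vapply(
    cutoffs,
    function(cc) nrow(build_network(sig, cutoff = cc)$gene_edges),
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0)) # lowering the cutoff never adds edges

  nw <- build_network(sig, cutoff = 0.05)
  if (nrow(nw$gene_edges)) {
    expect_true(all(nw$gene_edges$adj_p < 0.05))
    expect_lt(max(abs(abs(nw$gene_edges$stat) - abs(nw$gene_edges$m) / nw$gene_edges$se)), 1e-10)
    expect_equal(nw$gene_edges$sign, sign(nw$gene_edges$m))
  }
  expect_error(build_network(sig, cutoff = 1.2), class = "influscreen_domain_error")
})

test_that("pathway roles follow the interaction sign rules", {
  ann <- tibble::tibble(gene = c("ras1", "ras2"), role = "pathway")
  edge <- function(s, t, m) {
    tibble::tibble(
      source = s, target = t, m = m, se = 0.1, stat = m / 0.1,
      p = 0.001, adj_p = 0.001, sign = sign(m)
    )
  }
  # one negative edge to a pathway gene: same-pathway candidate
  nw <- make_network(edge("u", "ras1", -0.5))
  roles <- classify_pathway_roles(nw, ann)
  expect_equal(roles$role[roles$gene == "u"], "same_pathway_candidate")
  expect_equal(roles$role[roles$gene == "w"], "unassigned")

  # one positive (enhancing) edge: inhibitor candidate; direction-agnostic
  nw2 <- make_network(edge("ras2", "v", 0.4))
  roles2 <- classify_pathway_roles(nw2, ann)
  expect_equal(roles2$role[roles2$gene == "v"], "pathway_inhibitor_candidate")

  # both rule types: ambiguous
  nw3 <- make_network(dplyr::bind_rows(
    edge("u", "ras1", -0.5), edge("ras2", "u", 0.3)
  ))
  expect_equal(
    classify_pathway_roles(nw3, ann)$role[1],
    "ambiguous"
  )

  # mutual enhancement is flagged complex, not forced into a role
  nw4 <- make_network(dplyr::bind_rows(
    edge("v", "ras1", 0.4), edge("ras1", "v", 0.5)
  ))
  expect_equal(
    classify_pathway_roles(nw4, ann)$role[classify_pathway_roles(nw4, ann)$gene == "v"],
    "complex"
  )

  expect_error(
    classify_pathway_roles(nw, tibble::tibble(gene = "x", role = "unannotated")),
    class = "influscreen_validation_error"
  )
})

test_that("network export round-trips and covers all formats", {
  ge <- tibble::tibble(
    source = c("a", "b", "c"), target = c("b", "c", "a"),
    m = c(-0.5, 0.3, 0.7), se = c(0.1, 0.1, 0.2),
    stat = c(-5, 3, 3.5), p = c(0.001, 0.004, 0.002),
    adj_p = c(0.002, 0.008, 0.004), sign = c(-1, 1, 1)
  )
  pe <- tibble::tibble(
    gene = c("a", "b"), phenotype = c("p", "p"), coef = c(0.2, -0.1),
    se = c(0.05, 0.02), stat = c(4, -5), p = c(0.001, 0.001),
    adj_p = c(0.002, 0.002), sign = c(1, -1)
  )
  nw <- structure(
    list(
      gene_edges = ge, phenotype_edges = pe, genes = c("a", "b", "c"),
      phenotypes = "p", cutoff = 0.01, metadata = list()
    ),
    class = "influence_network"
  )
  dir <- withr::local_tempdir()
  paths <- export_network(nw, dir)
  expect_true(all(file.exists(paths)))
  back <- import_network(dir)
  expect_equal(as.data.frame(back$gene_edges), as.data.frame(ge))
  expect_equal(as.data.frame(back$phenotype_edges), as.data.frame(pe))

  adj <- read.csv(paths["adjacency"], check.names = FALSE)
  expect_equal(dim(adj), c(3L, 1L + 3L + 1L)) # source col + genes + phenotype
  expect_equal(adj[adj$source == "a", "b"], -0.5)

  sif <- readLines(paths["sif"])
  expect_length(sif, 5L)
  expect_match(sif[1], "suppresses")

  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::gsize(g), 5)

  # empty networks still produce valid files with headers
  empty <- make_network(NULL)
  dire <- withr::local_tempdir()
  pe2 <- export_network(empty, dire)
  expect_true(all(file.exists(pe2)))
  expect_equal(nrow(import_network(dire)$gene_edges), 0L)

  expect_error(export_network(nw, dir, formats = "xlsx"),
    class = "influscreen_validation_error"
  )
})

test_that("tidiers summarize networks and analyses", {
  scr <- prepared_screen(G = 8, n_strong = 4, n_edges = 1, seed = 107)
  pm <- pair_scan(scr$dataset, scr$decomp, NULL, "g01", "g02")
  td <- tidy(pm)
  expect_equal(nrow(td), 6L)
  expect_true(all(c("term", "eigentrait", "estimate", "se", "stat") %in% names(td)))
  expect_equal(glance(pm)$status, "estimable")
})
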