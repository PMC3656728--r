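#' Tandem permutation null for a single knockdown pair
#'
#' Convenience wrapper around the bulk engine for one pair: applies
#' `n_perm` shared random row permutations to the two scanned genotype
#' columns only (all other knockdowns, covariates and phenotypes
#' untouched), refits the pair model for every draw, replays the
#' influence reparametrization and the phenotype recomposition, and
#' returns the absolute null test statistics. See [scan_all_pairs()] for
#' the screen-wide version whose draws are aligned across pairs for the
#' step-down adjustment.
#'
#' @inheritParams pair_scan
#' @param n_perm Number of tandem permutation draws.
#' @param seed Optional integer seed.
#' @param condition_number_limit,pole_tol See [activity_deltas()] and
#'   [influence_coefficients()].
#' @return A list of class `kd_pair_null`: `m_stats` (n_perm x 2 matrix
#'   of |stat| for m_ab and m_ba; `NA` rows are skipped draws),
#'   `pheno_stats` (n_perm x 2·NP), `skipped` (count of non-estimable
#'   draws), `reliable` (FALSE when more than 20% of draws were
#'   skipped), and `observed` (the observed [pair_influence()] row).
#' @export
tandem_pair_null <- function(dataset, decomp, covariates = NULL, gene_a, gene_b,
                             n_perm = 700, seed = NULL,
                             condition_number_limit = 1e8, pole_tol = 1e-8) {
  dataset <- .dataset_matrices(dataset)
  if (!is.null(seed)) set.seed(seed)
  ia <- .gene_index(dataset, gene_a)
  ib <- .gene_index(dataset, gene_b)
  observed <- pair_influence(
    pair_scan(dataset, decomp, covariates, ia, ib),
    condition_number_limit = condition_number_limit, pole_tol = pole_tol
  )
  if (observed$status != "estimable") {
    abort(sprintf(
      "pair %s:%s is not estimable on the observed data (status '%s')",
      observed$gene_a, observed$gene_b, observed$status
    ), class = "influscreen_validation_error")
  }
  n <- nrow(dataset$genotype)
  perms <- vapply(seq_len(as.integer(n_perm)), function(i) sample.int(n), integer(n))
  cov_sets <- .covariate_sets(covariates, 2L)
  res <- pair_engine_cpp(
    U = decomp$U[, 1:2, drop = FALSE],
    X = dataset$genotype,
    L = recomposition_map(decomp),
    covs = lapply(cov_sets, as.integer),
    pairs = matrix(as.numeric(c(ia, ib)), ncol = 2),
    perms = matrix(as.numeric(perms), nrow = n),
    cond_limit = condition_number_limit,
    pole_tol = pole_tol,
    rcond_tol = 1e-10
  )
  skipped <- as.integer(res$null_skips[1])
  structure(
    list(
      m_stats = matrix(res$null_m, ncol = 2, dimnames = list(NULL, c("m_ab", "m_ba"))),
      pheno_stats = res$null_pheno,
      skipped = skipped,
      reliable = skipped <= 0.2 * n_perm,
      observed = observed,
      n_perm = as.integer(n_perm),
      seed = seed
    ),
    class = "kd_pair_null"
  )
}

#' @export
print.kd_pair_null <- function(x, ...) {
  cat(sprintf(
    "<kd_pair_null> %s : %s, %d draws (%d skipped%s)\n",
    x$observed$gene_a, x$observed$gene_b, x$n_perm, x$skipped,
    if (!x$reliable) ", unreliable" else ""
  ))
  invisible(x)
}
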