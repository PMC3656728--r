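#' Attach permutation p-values and familywise adjustment
#'
#' Computes raw empirical p-values and free step-down maxT adjusted
#' p-values for (i) every directed influence coefficient of every
#' estimable pair and (ii) every summarized knockdown-to-phenotype
#' coefficient, from the tandem permutation nulls collected by
#' [scan_all_pairs()]. The two families are adjusted separately.
#'
#' Raw p-values by default pool the null statistics across all
#' hypotheses of the family (`pool = TRUE`); set `pool = FALSE` to
#' compare each hypothesis only against its own pair's null. The
#' step-down adjustment always uses the per-hypothesis permutation
#' matrix. Adjusted p-values are never reported below the raw p-value.
#'
#' @param pair_results A `kd_pair_results` with permutation nulls
#'   (`n_perm > 0`).
#' @param pheno_effects Optional tibble from
#'   [summarize_phenotype_effects()]; computed if omitted.
#' @param pool Pool null statistics across hypotheses for the raw
#'   p-values (default `TRUE`).
#' @return A list of class `kd_significance` with `influences` (the pair
#'   tibble plus `p_ab`, `p_ba`, `adj_p_ab`, `adj_p_ba`),
#'   `phenotype_effects` (plus `p`, `adj_p`), and `pooled`.
#' @export
adjust_significance <- function(pair_results, pheno_effects = NULL, pool = TRUE) {
  stopifnot(inherits(pair_results, "kd_pair_results"))
  if (pair_results$n_perm <= 0) {
    abort("pair_results carry no permutation null (n_perm = 0)",
      class = "influscreen_validation_error"
    )
  }
  infl <- pair_results$influences
  ok <- which(infl$status %in% c("estimable", "unreliable_null"))
  cols <- as.vector(rbind(2L * ok - 1L, 2L * ok)) # ab, ba per pair
  obs <- as.vector(rbind(infl$stat_ab[ok], infl$stat_ba[ok]))
  nullmat <- pair_results$null_m[, cols, drop = FALSE]

  infl$p_ab <- NA_real_
  infl$p_ba <- NA_real_
  infl$adj_p_ab <- NA_real_
  infl$adj_p_ba <- NA_real_
  if (length(obs)) {
    raw <- .raw_pvalues(obs, nullmat, pool)
    adj <- pmax(stepdown_adjust(obs, nullmat), raw)
    infl$p_ab[ok] <- raw[seq_along(ok) * 2L - 1L]
    infl$p_ba[ok] <- raw[seq_along(ok) * 2L]
    infl$adj_p_ab[ok] <- adj[seq_along(ok) * 2L - 1L]
    infl$adj_p_ba[ok] <- adj[seq_along(ok) * 2L]
  }

  if (is.null(pheno_effects)) pheno_effects <- summarize_phenotype_effects(pair_results)
  pheno_effects$p <- NA_real_
  pheno_effects$adj_p <- NA_real_
  pok <- which(is.finite(pheno_effects$stat))
  if (length(pok)) {
    pnull <- pair_results$null_pheno[, pheno_effects$null_col[pok], drop = FALSE]
    praw <- .raw_pvalues(pheno_effects$stat[pok], pnull, pool)
    padj <- pmax(stepdown_adjust(pheno_effects$stat[pok], pnull), praw)
    pheno_effects$p[pok] <- praw
    pheno_effects$adj_p[pok] <- padj
  }

  structure(
    list(influences = infl, phenotype_effects = pheno_effects, pooled = pool),
    class = "kd_significance"
  )
}

.raw_pvalues <- function(obs, nullmat, pool) {
  if (pool) {
    pooled <- nullmat[is.finite(nullmat)]
    vapply(obs, empirical_pvalue, numeric(1), null_stats = pooled)
  } else {
    vapply(seq_along(obs), function(i) {
      empirical_pvalue(obs[i], nullmat[, i])
    }, numeric(1))
  }
}

#' @export
print.kd_significance <- function(x, ...) {
  cat(sprintf(
    "<kd_significance> %d pair hypotheses, %d phenotype hypotheses (%s raw nulls)\n",
    2L * sum(is.finite(x$influences$p_ab)), sum(is.finite(x$phenotype_effects$p)),
    if (x$pooled) "pooled" else "per-pair"
  ))
  invisible(x)
}
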