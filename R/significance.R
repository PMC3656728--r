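#' Permutation null for the single-locus scan
#'
#' Builds the familywise null for single-locus test statistics: for each
#' of `n_perm` permutations, one shared random row permutation is applied
#' to the whole genotype matrix (preserving the genotype columns' joint
#' structure; phenotypes fixed), the full scan over genes and eigentraits
#' is rerun, and the maximum absolute test statistic is recorded. A
#' Gumbel extreme value distribution is then fitted to the maxima by
#' maximum likelihood; its upper quantiles calibrate familywise
#' thresholds (see [evd_threshold()]).
#'
#' @param dataset A normalized `kd_dataset`.
#' @param decomp An `eigentrait_decomposition` with `k` set.
#' @param n_perm Number of permutations (default 2000; at least 100, the
#'   EVD fit is unstable below that).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `kd_scan_null` with `max_stats`,
#'   `evd_params` (`location`, `scale`), `n_perm` and `seed`.
#' @export
single_scan_null <- function(dataset, decomp, n_perm = 2000, seed = NULL) {
  dataset <- .dataset_matrices(dataset)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) {
    abort("n_perm must be at least 100 for a stable EVD fit",
      class = "influscreen_validation_error"
    )
  }
  if (!is.null(seed)) set.seed(seed)
  X <- dataset$genotype
  U <- decomp$U[, seq_len(decomp$k), drop = FALSE]
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Sxx <- colSums(Xc^2)
  ok <- Sxx > n * .Machine$double.eps
  Uc <- sweep(U, 2, colMeans(U))
  Syy <- colSums(Uc^2)
  maxes <- vapply(seq_len(n_perm), function(p) {
    idx <- sample.int(n)
    Sxy <- crossprod(Xc[idx, , drop = FALSE], Uc)
    rss <- -sweep(Sxy^2 / Sxx, 2, Syy)
    stat2 <- Sxy^2 / Sxx / (pmax(rss, 0) / (n - 2)) # squared t statistic
    sqrt(max(stat2[ok, ], na.rm = TRUE))
  }, numeric(1))
  structure(
    list(
      n_perm = n_perm,
      max_stats = maxes,
      evd_params = fit_gumbel(maxes),
      seed = seed
    ),
    class = "kd_scan_null"
  )
}

#' @export
print.kd_scan_null <- function(x, ...) {
  cat(sprintf(
    "<kd_scan_null> %d permutations; Gumbel(location = %.3f, scale = %.3f)\n",
    x$n_perm, x$evd_params["location"], x$evd_params["scale"]
  ))
  invisible(x)
}

#' Fit a Gumbel extreme value distribution by maximum likelihood
#'
#' @param x Numeric sample of maxima.
#' @return Named vector `c(location, scale)`.
#' @export
fit_gumbel <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10) {
    abort("too few finite maxima for an EVD fit", class = "influscreen_validation_error")
  }
  # moment start: scale = sd * sqrt(6)/pi, location = mean - Euler-gamma * scale
  b0 <- sd(x) * sqrt(6) / pi
  m0 <- mean(x) - 0.57721566490153286 * b0
  nll <- function(par) {
    mu <- par[1]
    beta <- exp(par[2])
    z <- (x - mu) / beta
    length(x) * log(beta) + sum(z) + sum(exp(-z))
  }
  fit <- optim(c(m0, log(b0)), nll, method = "BFGS")
  c(location = fit$par[1], scale = exp(fit$par[2]))
}

#' Familywise threshold from the fitted extreme value null
#'
#' Returns the `1 - alpha` quantile of the fitted Gumbel distribution of
#' per-permutation maximum statistics: a scan statistic above it is
#' familywise significant at level `alpha`.
#'
#' @param null A `kd_scan_null`.
#' @param alpha Level in (0, 1).
#' @return Scalar threshold.
#' @export
evd_threshold <- function(null, alpha) {
  stopifnot(inherits(null, "kd_scan_null"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)", class = "influscreen_domain_error")
  }
  mu <- null$evd_params[["location"]]
  beta <- null$evd_params[["scale"]]
  mu - beta * log(-log(1 - alpha))
}

#' Empirical permutation p-value
#'
#' `p = (r + 1) / (n + 1)` where `r` counts null statistics at least as
#' extreme (in absolute value) as the observed one. The add-one rule
#' keeps p strictly positive, as appropriate for permutation tests.
#'
#' @param observed_stat Observed test statistic (its absolute value is
#'   compared).
#' @param null_stats Nonempty collection of null statistics (absolute
#'   values are taken; non-finite entries dropped).
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed_stat, null_stats) {
  ns <- abs(null_stats[is.finite(null_stats)])
  if (!length(ns)) abort("empty null distribution", class = "influscreen_validation_error")
  (sum(ns >= abs(observed_stat)) + 1) / (length(ns) + 1)
}

#' Free step-down maxT familywise adjustment
#'
#' Westfall–Young free step-down adjustment on empirical permutation
#' distributions (no EVD smoothing: empirical tails are heavier than
#' fitted EVDs and smoothing would inflate significance). Hypotheses are
#' ordered by decreasing observed `|stat|`; for each permutation,
#' successive maxima over the less-significant hypotheses are formed, and
#' each adjusted p-value is the add-one fraction of permutations whose
#' successive maximum reaches the observed statistic. Monotonicity is
#' enforced so adjusted p-values are nondecreasing in rank.
#'
#' Null columns with non-finite draws (skipped permutations for
#' non-estimable refits) are ignored within each permutation's maximum.
#'
#' @param observed_stats Numeric vector of observed statistics, one per
#'   hypothesis (absolute values are used).
#' @param null_matrix Matrix of null statistics, `n_perm` rows by
#'   `length(observed_stats)` columns (column j is hypothesis j's
#'   permutation distribution; permutation draws are aligned across
#'   columns).
#' @return Vector of adjusted p-values in (0, 1], same order as
#'   `observed_stats`.
#' @export
stepdown_adjust <- function(observed_stats, null_matrix) {
  obs <- abs(observed_stats)
  null_matrix <- as.matrix(null_matrix)
  if (ncol(null_matrix) != length(obs)) {
    abort("null matrix must have one column per hypothesis",
      class = "influscreen_validation_error"
    )
  }
  h <- length(obs)
  if (h == 0L) {
    return(numeric(0))
  }
  n_perm <- nrow(null_matrix)
  ord <- order(obs, decreasing = TRUE) # rank 1 = most significant
  A <- abs(null_matrix[, ord, drop = FALSE])
  A[!is.finite(A)] <- -Inf
  # successive maxima from the least significant hypothesis upward
  Q <- matrix(-Inf, n_perm, h)
  Q[, h] <- A[, h]
  if (h > 1) {
    for (j in (h - 1):1) Q[, j] <- pmax(Q[, j + 1], A[, j])
  }
  adj <- (colSums(Q >= rep(obs[ord], each = n_perm)) + 1) / (n_perm + 1)
  adj <- cummax(adj) # monotone in significance rank
  out <- numeric(h)
  out[ord] <- adj
  pmin(out, 1)
}
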