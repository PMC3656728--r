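#' Single-locus eigentrait scan
#'
#' For each knocked-down gene and each retained eigentrait, fits the
#' one-locus model `U_ij = b0_j + x_i b_j + e_ij` by ordinary least
#' squares, where `x_i` is the knockdown indicator (or probability) for
#' the gene in line `i` and `U_ij` the line's eigentrait value. The test
#' statistic is the effect size divided by its estimated standard error.
#'
#' Genes whose genotype column has zero variance cannot be scanned; they
#' are returned with `NA` estimates and a warning rather than an error.
#'
#' @param dataset A normalized `kd_dataset`.
#' @param decomp An `eigentrait_decomposition` with `k` set (see
#'   [select_eigentraits()]).
#' @return A tibble with one row per (gene, eigentrait): `gene`,
#'   `eigentrait`, `intercept`, `beta`, `se`, `stat`, `df`.
#' @export
single_locus_scan <- function(dataset, decomp) {
  dataset <- .dataset_matrices(dataset)
  X <- dataset$genotype
  U <- decomp$U[, seq_len(decomp$k), drop = FALSE]
  n <- nrow(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  Sxx <- colSums(Xc^2)
  degenerate <- Sxx < n * .Machine$double.eps
  if (any(degenerate)) {
    warn(sprintf(
      "zero-variance genotype column(s) excluded from scan: %s",
      paste(dataset$gene_names[degenerate], collapse = ", ")
    ))
  }
  ubar <- colMeans(U)
  Uc <- sweep(U, 2, ubar)
  Syy <- colSums(Uc^2)
  Sxy <- crossprod(Xc, Uc) # G x k
  beta <- sweep(Sxy, 1, Sxx, "/")
  rss <- -sweep(Sxy^2 / Sxx, 2, Syy) # G x k of Syy - Sxy^2/Sxx
  s2 <- pmax(rss, 0) / (n - 2)
  se <- sqrt(sweep(s2, 1, Sxx, "/"))
  stat <- beta / se
  beta[degenerate, ] <- NA_real_
  se[degenerate, ] <- NA_real_
  stat[degenerate, ] <- NA_real_
  intercept <- -sweep(outer(xbar, rep(1, ncol(U))) * beta, 2, ubar)
  G <- ncol(X)
  k <- ncol(U)
  tibble::tibble(
    gene = rep(dataset$gene_names, times = k),
    eigentrait = rep(seq_len(k), each = G),
    intercept = as.vector(intercept),
    beta = as.vector(beta),
    se = as.vector(se),
    stat = as.vector(stat),
    df = n - 2L
  )
}

#' Select strong-effect knockdowns as scan covariates
#'
#' Strong-effect knockdowns are genes whose single-locus test statistic
#' exceeds the familywise threshold derived from the permutation
#' extreme-value null at level `alpha` (see [single_scan_null()]). They
#' are carried as additive covariates, per eigentrait, in every
#' subsequent pair scan (excluding the two genes being scanned), so that
#' the strongest main effects do not inflate pair-scan residuals.
#'
#' @param scan A tibble from [single_locus_scan()].
#' @param null A `kd_scan_null` from [single_scan_null()].
#' @param alpha Familywise level in (0, 1); default 0.001.
#' @return An object of class `kd_covariates`: a list with one integer
#'   vector of gene indices per eigentrait, plus the threshold used.
#' @export
select_covariates <- function(scan, null, alpha = 0.001) {
  stopifnot(inherits(null, "kd_scan_null"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)", class = "influscreen_domain_error")
  }
  thr <- evd_threshold(null, alpha)
  genes <- unique(scan$gene)
  ks <- sort(unique(scan$eigentrait))
  sets <- lapply(ks, function(j) {
    sub <- scan[scan$eigentrait == j, ]
    sel <- sub$gene[!is.na(sub$stat) & abs(sub$stat) > thr]
    sort(match(sel, genes))
  })
  names(sets) <- paste0("eigentrait_", ks)
  structure(
    list(sets = sets, threshold = thr, alpha = alpha, gene_names = genes),
    class = "kd_covariates"
  )
}

#' @export
print.kd_covariates <- function(x, ...) {
  cat(sprintf("<kd_covariates> threshold |stat| > %.3f (alpha = %g)\n", x$threshold, x$alpha))
  for (j in seq_along(x$sets)) {
    cat(sprintf(
      "  %s: %d gene(s)%s\n", names(x$sets)[j], length(x$sets[[j]]),
      if (length(x$sets[[j]])) paste0(" [", paste(x$gene_names[x$sets[[j]]], collapse = ", "), "]") else ""
    ))
  }
  invisible(x)
}

# internal: build the pair-scan design for one eigentrait.
# Returns list(X, cols) where cols gives positions of (xa, xb, xab).
.pair_design <- function(genotype, gene_a, gene_b, cov_idx) {
  cov_idx <- setdiff(cov_idx, c(gene_a, gene_b))
  xa <- genotype[, gene_a]
  xb <- genotype[, gene_b]
  X <- cbind(
    intercept = 1,
    genotype[, cov_idx, drop = FALSE],
    xa = xa, xb = xb, xab = xa * xb
  )
  p <- ncol(X)
  list(X = X, cols = c(xa = p - 2L, xb = p - 1L, xab = p), cov_idx = cov_idx)
}

# internal: OLS with rank check; returns NULL when rank deficient
.ols_fit <- function(X, y, tol = 1e-10) {
  qrx <- qr(X, tol = tol)
  if (qrx$rank < ncol(X)) {
    return(NULL)
  }
  coefs <- qr.coef(qrx, y)
  res <- y - X %*% coefs
  XtXinv <- chol2inv(qr.R(qrx))
  list(coef = coefs, resid = drop(res), XtXinv = XtXinv, df = nrow(X) - ncol(X))
}

#' Covariate-conditioned pairwise scan for one knockdown pair
#'
#' For each retained eigentrait `j`, fits by ordinary least squares
#' `U_ij = b0_j + x_a b_aj + x_b b_bj + x_a x_b g_j + sum_c x_c b_cj + e_ij`,
#' where the sum runs over the eigentrait's strong-effect covariates
#' excluding the two scanned genes, and `g_j` is the epistatic
#' interaction coefficient. The full parameter covariance is estimated
#' per eigentrait as `s^2 (X'X)^-1`; cross-eigentrait parameter
#' covariances — needed when propagating errors through the influence
#' reparametrization — are estimated from the cross-eigentrait residual
#' covariance via `s12 (X1'X1)^-1 X1'X2 (X2'X2)^-1`, the
#' seemingly-unrelated-regressions identity for designs that coincide up
#' to covariate choice.
#'
#' @param dataset A normalized `kd_dataset`.
#' @param decomp An `eigentrait_decomposition` with `k = 2`.
#' @param covariates A `kd_covariates` from [select_covariates()] (or
#'   `NULL` for no conditioning).
#' @param gene_a,gene_b Gene names or indices; must differ.
#' @return An object of class `kd_pair_model`: per-eigentrait coefficient
#'   vectors and covariances, the 6-parameter vector
#'   `theta = (b_a1, b_a2, b_b1, b_b2, g_1, g_2)` with its 6x6 covariance
#'   `Sigma`, residual degrees of freedom, and a `status` field
#'   (`"estimable"` or `"non_estimable"`).
#' @export
pair_scan <- function(dataset, decomp, covariates = NULL, gene_a, gene_b) {
  dataset <- .dataset_matrices(dataset)
  k <- decomp$k
  if (k != 2L) {
    abort("pair_scan requires a two-eigentrait decomposition",
      class = "influscreen_unsupported_dimension_error"
    )
  }
  ia <- .gene_index(dataset, gene_a)
  ib <- .gene_index(dataset, gene_b)
  if (ia == ib) abort("gene_a and gene_b must differ", class = "influscreen_validation_error")
  cov_sets <- .covariate_sets(covariates, k)

  U <- decomp$U[, seq_len(k), drop = FALSE]
  designs <- lapply(seq_len(k), function(j) .pair_design(dataset$genotype, ia, ib, cov_sets[[j]]))
  fits <- lapply(seq_len(k), function(j) .ols_fit(designs[[j]]$X, U[, j]))

  base <- list(
    gene_a = dataset$gene_names[ia], gene_b = dataset$gene_names[ib],
    index_a = ia, index_b = ib,
    covariates = lapply(designs, function(d) dataset$gene_names[d$cov_idx])
  )
  if (any(vapply(fits, is.null, logical(1)))) {
    return(structure(
      c(base, list(status = "non_estimable", reason = "rank-deficient design")),
      class = "kd_pair_model"
    ))
  }

  s2 <- vapply(seq_len(k), function(j) sum(fits[[j]]$resid^2) / fits[[j]]$df, numeric(1))
  dfs <- vapply(fits, `[[`, numeric(1), "df")
  s12 <- sum(fits[[1]]$resid * fits[[2]]$resid) / sqrt(prod(dfs))
  cross <- s12 * fits[[1]]$XtXinv %*% crossprod(designs[[1]]$X, designs[[2]]$X) %*% fits[[2]]$XtXinv

  pos <- lapply(designs, `[[`, "cols")
  theta <- c(
    fits[[1]]$coef[pos[[1]]["xa"]], fits[[2]]$coef[pos[[2]]["xa"]],
    fits[[1]]$coef[pos[[1]]["xb"]], fits[[2]]$coef[pos[[2]]["xb"]],
    fits[[1]]$coef[pos[[1]]["xab"]], fits[[2]]$coef[pos[[2]]["xab"]]
  )
  names(theta) <- c("beta_a1", "beta_a2", "beta_b1", "beta_b2", "gamma_1", "gamma_2")
  Sigma <- matrix(0, 6, 6, dimnames = list(names(theta), names(theta)))
  et1 <- c(1, 3, 5) # theta entries from eigentrait 1
  et2 <- c(2, 4, 6)
  Sigma[et1, et1] <- s2[1] * fits[[1]]$XtXinv[pos[[1]], pos[[1]]]
  Sigma[et2, et2] <- s2[2] * fits[[2]]$XtXinv[pos[[2]], pos[[2]]]
  Sigma[et1, et2] <- cross[pos[[1]], pos[[2]]]
  Sigma[et2, et1] <- t(Sigma[et1, et2])

  structure(
    c(base, list(
      status = "estimable",
      theta = theta,
      Sigma = Sigma,
      coef = lapply(fits, `[[`, "coef"),
      sigma2 = s2,
      sigma12 = s12,
      df = dfs,
      XtXinv = lapply(fits, `[[`, "XtXinv"),
      design_cols = pos
    )),
    class = "kd_pair_model"
  )
}

#' @export
print.kd_pair_model <- function(x, ...) {
  cat(sprintf("<kd_pair_model> %s : %s (%s)\n", x$gene_a, x$gene_b, x$status))
  if (x$status == "estimable") {
    print(round(x$theta, 6))
  }
  invisible(x)
}

#' Tidy a pair model
#'
#' @param x A `kd_pair_model`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter (main effects and
#'   interaction per eigentrait) with estimate, SE and test statistic.
#' @export
tidy.kd_pair_model <- function(x, ...) {
  if (x$status != "estimable") {
    return(tibble::tibble(
      term = character(), eigentrait = integer(),
      estimate = numeric(), se = numeric(), stat = numeric()
    ))
  }
  se <- sqrt(pmax(diag(x$Sigma), 0))
  tibble::tibble(
    term = c("beta_a", "beta_a", "beta_b", "beta_b", "gamma", "gamma"),
    eigentrait = c(1L, 2L, 1L, 2L, 1L, 2L),
    estimate = unname(x$theta),
    se = unname(se),
    stat = unname(x$theta / se)
  )
}

#' @rdname tidy.kd_pair_model
#' @export
glance.kd_pair_model <- function(x, ...) {
  tibble::tibble(
    gene_a = x$gene_a, gene_b = x$gene_b, status = x$status,
    df_1 = if (x$status == "estimable") x$df[1] else NA_real_,
    df_2 = if (x$status == "estimable") x$df[2] else NA_real_,
    sigma2_1 = if (x$status == "estimable") x$sigma2[1] else NA_real_,
    sigma2_2 = if (x$status == "estimable") x$sigma2[2] else NA_real_
  )
}

.gene_index <- function(dataset, gene) {
  if (is.character(gene)) {
    i <- match(gene, dataset$gene_names)
    if (is.na(i)) abort(sprintf("unknown gene '%s'", gene), class = "influscreen_validation_error")
    return(i)
  }
  i <- as.integer(gene)
  if (i < 1L || i > length(dataset$gene_names)) {
    abort(sprintf("gene index %d out of range", i), class = "influscreen_validation_error")
  }
  i
}

.covariate_sets <- function(covariates, k) {
  if (is.null(covariates)) {
    return(rep(list(integer(0)), k))
  }
  stopifnot(inherits(covariates, "kd_covariates"))
  sets <- covariates$sets
  if (length(sets) < k) {
    abort("covariate set does not cover all retained eigentraits",
      class = "influscreen_validation_error"
    )
  }
  sets[seq_len(k)]
}
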