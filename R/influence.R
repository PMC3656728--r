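#' Activity deltas from pairwise interaction coefficients
#'
#' Recasts the two per-eigentrait epistatic interaction coefficients of a
#' knockdown pair as eigentrait-independent *activity modifications*
#' `(delta_1, delta_2)`: `delta_k` is the multiplicative change of
#' knockdown k's effective main-effect activity caused by the presence of
#' the other knockdown. They solve the linear system
#' `M %*% delta = beta_int`, where row `j` of the 2x2 matrix `M` holds
#' the two knockdowns' main effects on eigentrait `j`, i.e.
#' `M = rbind(c(beta_a1, beta_b1), c(beta_a2, beta_b2))`. The solution is
#' an exact reparametrization: `M %*% delta` reproduces the interaction
#' coefficients.
#'
#' @param beta_main 2x2 matrix of main effects, rows = eigentraits,
#'   columns = the two knockdowns `(a, b)`.
#' @param beta_int Length-2 vector of interaction coefficients
#'   `(gamma_1, gamma_2)`, one per eigentrait.
#' @param condition_number_limit Pairs whose main-effect matrix has a
#'   2-norm condition number above this (or a zero singular value) are
#'   declared singular: collinear main-effect signatures cannot identify
#'   directional activities. Default `1e8`.
#' @return A list with `delta` (length-2 vector, `NA` when singular),
#'   `status` (`"estimable"` or `"singular"`), and `condition_number`.
#' @export
activity_deltas <- function(beta_main, beta_int, condition_number_limit = 1e8) {
  M <- matrix(as.numeric(beta_main), 2, 2)
  g <- as.numeric(beta_int)
  stopifnot(length(g) == 2L)
  sv <- svd(M, nu = 0, nv = 0)$d
  kappa <- if (sv[2] <= 0) Inf else sv[1] / sv[2]
  if (!is.finite(kappa) || kappa > condition_number_limit) {
    return(list(delta = c(NA_real_, NA_real_), status = "singular", condition_number = kappa))
  }
  list(delta = drop(solve(M, g)), status = "estimable", condition_number = kappa)
}

#' Directed influence coefficients from activity deltas
#'
#' Converts the activity modifications into the directed, dimensionless
#' knockdown-to-knockdown influences that generate them:
#' `m_ab = delta_1 / (1 + delta_2)` and `m_ba = delta_2 / (1 + delta_1)`.
#' `m_ab` is the influence of knockdown *a on b*: positive values enhance
#' the partner's effect, negative values suppress it (a significant
#' negative `m_ab` means knockdown a suppressed the effects of
#' knockdown b).
#'
#' @param delta Length-2 numeric vector `(delta_1, delta_2)` (or the list
#'   returned by [activity_deltas()]).
#' @param pole_tol Denominators `|1 + delta|` below this are poles of the
#'   map; the influences are then undefined and flagged. Default `1e-8`.
#' @return A list with `m` (length-2 vector `(m_ab, m_ba)`) and `status`
#'   (`"estimable"`, `"pole"`, or the propagated input status).
#' @export
influence_coefficients <- function(delta, pole_tol = 1e-8) {
  if (is.list(delta)) {
    if (!identical(delta$status, "estimable")) {
      return(list(m = c(NA_real_, NA_real_), status = delta$status))
    }
    delta <- delta$delta
  }
  d <- as.numeric(delta)
  stopifnot(length(d) == 2L)
  if (abs(1 + d[1]) < pole_tol || abs(1 + d[2]) < pole_tol) {
    return(list(m = c(NA_real_, NA_real_), status = "pole"))
  }
  list(m = c(d[1] / (1 + d[2]), d[2] / (1 + d[1])), status = "estimable")
}

# internal: analytic gradient of (m_ab, m_ba) wrt
# theta = (beta_a1, beta_a2, beta_b1, beta_b2, gamma_1, gamma_2).
# M[j, 1] = beta_a on eigentrait j; M[j, 2] = beta_b on eigentrait j.
.influence_gradient <- function(theta) {
  M <- matrix(theta[1:4], 2, 2) # column-major: col 1 = (beta_a1, beta_a2)
  g <- theta[5:6]
  Minv <- solve(M)
  delta <- drop(Minv %*% g)
  # d delta / d M[j,k] = -delta[k] * Minv[, j]
  Jd <- matrix(0, 2, 6)
  Jd[, 1] <- -delta[1] * Minv[, 1] # beta_a1 = M[1,1]
  Jd[, 2] <- -delta[1] * Minv[, 2] # beta_a2 = M[2,1]
  Jd[, 3] <- -delta[2] * Minv[, 1] # beta_b1 = M[1,2]
  Jd[, 4] <- -delta[2] * Minv[, 2] # beta_b2 = M[2,2]
  Jd[, 5] <- Minv[, 1] # gamma_1
  Jd[, 6] <- Minv[, 2] # gamma_2
  Jm <- rbind(
    c(1 / (1 + delta[2]), -delta[1] / (1 + delta[2])^2),
    c(-delta[2] / (1 + delta[1])^2, 1 / (1 + delta[1]))
  )
  list(J = Jm %*% Jd, delta = delta)
}

#' Delta-method variance of the directed influences
#'
#' First-order propagation of the pair model's parameter uncertainty
#' through the activity reparametrization and the influence map:
#' `var(m) = J Sigma J'`, where `J` is the analytic Jacobian of
#' `(m_ab, m_ba)` with respect to the six regression parameters
#' `(beta_a1, beta_a2, beta_b1, beta_b2, gamma_1, gamma_2)` (computed in
#' closed form through the 2x2 inverse) and `Sigma` their estimated
#' covariance, including the cross-eigentrait covariances. Equivalently,
#' each variance is the sum over parameter variances times squared
#' partials plus twice the covariance cross terms.
#'
#' @param pair_model A `kd_pair_model` from [pair_scan()] (supplies
#'   `theta` and `Sigma`), or a list with those two elements.
#' @param influence Optional result of [influence_coefficients()]; used
#'   only to propagate a non-estimable status.
#' @return A list with `var_m` (length-2: `var(m_ab)`, `var(m_ba)`,
#'   negative numerical values clipped to 0 with a warning) and the
#'   Jacobian `J`.
#' @export
influence_variance <- function(pair_model, influence = NULL) {
  if (!is.null(influence) && !identical(influence$status, "estimable")) {
    return(list(var_m = c(NA_real_, NA_real_), J = NULL, status = influence$status))
  }
  theta <- pair_model$theta
  Sigma <- pair_model$Sigma
  if (is.null(theta) || is.null(Sigma)) {
    abort("pair model does not carry theta/Sigma (non-estimable?)",
      class = "influscreen_validation_error"
    )
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    abort("parameter covariance is not positive semidefinite",
      class = "influscreen_validation_error"
    )
  }
  gr <- .influence_gradient(theta)
  v <- diag(gr$J %*% Sigma %*% t(gr$J))
  if (any(v < 0)) {
    warn("negative propagated variance clipped to 0")
    v <- pmax(v, 0)
  }
  list(var_m = v, J = gr$J, status = "estimable")
}

#' Directed influences for one fitted pair model
#'
#' Convenience wrapper running [activity_deltas()],
#' [influence_coefficients()] and [influence_variance()] on a fitted
#' pair model.
#'
#' @param pair_model A `kd_pair_model`.
#' @param condition_number_limit,pole_tol See [activity_deltas()] and
#'   [influence_coefficients()].
#' @return A one-row tibble: `gene_a`, `gene_b`, `delta_1`, `delta_2`,
#'   `m_ab`, `m_ba`, `se_ab`, `se_ba`, `stat_ab`, `stat_ba`, `status`.
#' @export
pair_influence <- function(pair_model, condition_number_limit = 1e8, pole_tol = 1e-8) {
  out <- tibble::tibble(
    gene_a = pair_model$gene_a, gene_b = pair_model$gene_b,
    delta_1 = NA_real_, delta_2 = NA_real_,
    m_ab = NA_real_, m_ba = NA_real_,
    se_ab = NA_real_, se_ba = NA_real_,
    stat_ab = NA_real_, stat_ba = NA_real_,
    status = pair_model$status
  )
  if (pair_model$status != "estimable") {
    return(out)
  }
  theta <- pair_model$theta
  ad <- activity_deltas(
    rbind(theta[c(1, 3)], theta[c(2, 4)]), theta[5:6],
    condition_number_limit = condition_number_limit
  )
  if (ad$status != "estimable") {
    out$status <- ad$status
    return(out)
  }
  ic <- influence_coefficients(ad$delta, pole_tol = pole_tol)
  if (ic$status != "estimable") {
    out$delta_1 <- ad$delta[1]
    out$delta_2 <- ad$delta[2]
    out$status <- ic$status
    return(out)
  }
  iv <- influence_variance(pair_model)
  se <- sqrt(iv$var_m)
  out$delta_1 <- ad$delta[1]
  out$delta_2 <- ad$delta[2]
  out$m_ab <- ic$m[1]
  out$m_ba <- ic$m[2]
  out$se_ab <- se[1]
  out$se_ba <- se[2]
  out$stat_ab <- ic$m[1] / se[1]
  out$stat_ba <- ic$m[2] / se[2]
  out$status <- "estimable"
  out
}
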