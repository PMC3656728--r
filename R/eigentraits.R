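#' Decompose normalized phenotypes into eigentraits
#'
#' Singular value decomposition of the normalized lines-by-phenotypes
#' matrix, `P = U diag(S) V'`. The columns of `U` — the unit-norm left
#' singular vectors — are the *eigentraits*: orthogonal composite
#' phenotypes used as regression responses downstream. A deterministic
#' sign convention is applied: each right singular vector is flipped so
#' that its largest-magnitude phenotype loading is positive, with the
#' paired left vector flipped to match, so repeated decompositions of the
#' same matrix are identical.
#'
#' @param dataset A normalized `kd_dataset`, or a normalized numeric
#'   matrix (more rows than columns, finite entries).
#' @return An object of class `eigentrait_decomposition` with elements
#'   `U` (lines x phenotypes), `d` (singular values, nonincreasing),
#'   `V` (phenotype loadings), `var_frac` (`d^2 / sum(d^2)`),
#'   `phenotype_names`, and `k` (retained eigentrait count, initially all).
#' @export
decompose_phenotypes <- function(dataset) {
  m <- if (inherits(dataset, "kd_dataset")) {
    .dataset_matrices(dataset)$phenotypes
  } else {
    as.matrix(dataset)
  }
  if (!all(is.finite(m))) {
    abort("phenotype matrix has non-finite entries", class = "influscreen_validation_error")
  }
  if (nrow(m) <= ncol(m)) {
    abort("need more lines than phenotypes for the eigentrait decomposition",
      class = "influscreen_shape_error"
    )
  }
  s <- svd(m)
  # deterministic signs: largest-magnitude loading of each V column positive
  for (j in seq_along(s$d)) {
    piv <- which.max(abs(s$v[, j]))
    if (s$v[piv, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  structure(
    list(
      U = s$u,
      d = s$d,
      V = s$v,
      var_frac = s$d^2 / sum(s$d^2),
      phenotype_names = colnames(m) %||% paste0("phenotype_", seq_len(ncol(m))),
      k = ncol(m)
    ),
    class = "eigentrait_decomposition"
  )
}

#' @export
print.eigentrait_decomposition <- function(x, ...) {
  cat(sprintf(
    "<eigentrait_decomposition> %d lines, %d phenotypes, k = %d retained\n",
    nrow(x$U), length(x$d), x$k
  ))
  cat("variance fractions:", paste(sprintf("%.4f", x$var_frac), collapse = " "), "\n")
  invisible(x)
}

#' Choose how many eigentraits to retain
#'
#' Retains the leading eigentraits whose variance fraction
#' (`d^2 / sum(d^2)`) is at least `min_variance_fraction`; the leading
#' eigentrait is always kept. The directional influence model is a
#' two-eigentrait model (the activity reparametrization inverts a 2x2
#' main-effect matrix), so a retained count other than 2 raises an error
#' unless `allow_other_k = TRUE` (useful for inspecting decompositions,
#' not for running the influence pipeline).
#'
#' @param decomp An `eigentrait_decomposition`.
#' @param min_variance_fraction Variance-fraction cutoff in (0, 1),
#'   default 0.02 (eigentraits carrying less than 2% of global variance
#'   are considered uninformative).
#' @param allow_other_k Permit k other than 2.
#' @return The decomposition with `k` set.
#' @export
select_eigentraits <- function(decomp, min_variance_fraction = 0.02, allow_other_k = FALSE) {
  stopifnot(inherits(decomp, "eigentrait_decomposition"))
  if (!is.numeric(min_variance_fraction) || min_variance_fraction <= 0 || min_variance_fraction >= 1) {
    abort("`min_variance_fraction` must lie in (0, 1)", class = "influscreen_domain_error")
  }
  keep <- decomp$var_frac >= min_variance_fraction
  # leading block only: stop at first eigentrait below threshold
  k <- if (!keep[1]) 1L else {
    below <- which(!keep)
    if (length(below)) below[1] - 1L else length(keep)
  }
  k <- max(1L, k)
  if (k != 2L && !allow_other_k) {
    abort(
      sprintf(
        "retained %d eigentrait(s) at variance fraction >= %g, but the directional influence model requires exactly 2 (set allow_other_k = TRUE to keep anyway)",
        k, min_variance_fraction
      ),
      class = "influscreen_unsupported_dimension_error"
    )
  }
  decomp$k <- k
  decomp
}

#' Map eigentrait-space coefficients back to phenotype space
#'
#' Regression coefficients estimated against the unit-norm eigentraits are
#' recomposed into knockdown-to-phenotype coefficients by the linear map
#' `b = V[, 1:k] diag(S[1:k]) c`. This is the unique linear map under
#' which regressing each phenotype directly on a genotype column agrees
#' with recomposing the corresponding eigentrait regressions; being
#' linear and invertible on the retained subspace it does not alter the
#' inferred genetic interactions.
#'
#' @param coeffs A length-`k` coefficient vector, or a matrix with `k`
#'   rows (one column per quantity to recompose).
#' @param decomp An `eigentrait_decomposition` with `k` set.
#' @return A vector (or matrix) of phenotype-space coefficients, one entry
#'   per original phenotype.
#' @export
recompose_to_phenotypes <- function(coeffs, decomp) {
  stopifnot(inherits(decomp, "eigentrait_decomposition"))
  k <- decomp$k
  cmat <- if (is.matrix(coeffs)) coeffs else matrix(coeffs, ncol = 1)
  if (nrow(cmat) != k) {
    abort(
      sprintf("coefficient rows (%d) must equal retained eigentrait count k = %d", nrow(cmat), k),
      class = "influscreen_shape_error"
    )
  }
  L <- recomposition_map(decomp)
  out <- L %*% cmat
  rownames(out) <- decomp$phenotype_names
  if (is.matrix(coeffs)) out else drop(out)
}

#' Recomposition map from eigentrait to phenotype coefficients
#'
#' Returns `L = V[, 1:k] diag(S[1:k])`, the matrix such that phenotype
#' coefficients are `L %*% c` for eigentrait coefficients `c`.
#'
#' @param decomp An `eigentrait_decomposition`.
#' @return A phenotypes-by-k matrix.
#' @export
recomposition_map <- function(decomp) {
  k <- decomp$k
  decomp$V[, seq_len(k), drop = FALSE] %*% diag(decomp$d[seq_len(k)], nrow = k)
}

#' Tidy an eigentrait decomposition
#'
#' @param x An `eigentrait_decomposition`.
#' @param ... Unused.
#' @return A tibble with one row per (phenotype, eigentrait) giving the
#'   loading, the singular value and the variance fraction.
#' @export
tidy.eigentrait_decomposition <- function(x, ...) {
  np <- length(x$d)
  tibble::tibble(
    phenotype = rep(x$phenotype_names, times = np),
    eigentrait = rep(seq_len(np), each = np),
    loading = as.vector(x$V),
    singular_value = rep(x$d, each = np),
    variance_fraction = rep(x$var_frac, each = np),
    retained = rep(seq_len(np) <= x$k, each = np)
  )
}

#' @rdname tidy.eigentrait_decomposition
#' @export
glance.eigentrait_decomposition <- function(x, ...) {
  tibble::tibble(
    n_lines = nrow(x$U),
    n_phenotypes = length(x$d),
    k = x$k,
    var_frac_1 = x$var_frac[1],
    var_frac_2 = if (length(x$var_frac) >= 2) x$var_frac[2] else NA_real_
  )
}
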