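#' All-pairs double-knockdown design matrix
#'
#' One screen line per unordered pair of genes: the row for pair (a, b)
#' has 1 in columns a and b and 0 elsewhere, giving `G (G - 1) / 2` lines
#' in which every gene appears exactly `G - 1` times.
#'
#' @param G Number of genes (at least 3).
#' @param gene_names Optional character vector of length `G`.
#' @return A tibble: `line_id` then one 0/1 column per gene.
#' @export
generate_all_pairs_design <- function(G, gene_names = NULL) {
  G <- as.integer(G)
  if (is.na(G) || G < 3L) {
    abort("need at least 3 genes for an all-pairs design", class = "influscreen_domain_error")
  }
  gene_names <- gene_names %||% sprintf("g%02d", seq_len(G))
  stopifnot(length(gene_names) == G)
  pairs <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  X <- matrix(0, nrow(pairs), G, dimnames = list(NULL, gene_names))
  X[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
  X[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- 1
  tibble::tibble(
    line_id = sprintf("%s__%s", gene_names[pairs[, 1]], gene_names[pairs[, 2]]),
    tibble::as_tibble(X)
  )
}

#' Planted generative model for a double-knockdown screen
#'
#' Defines the ground truth of a simulated screen: per-gene main effects
#' on two latent eigentraits, a set of planted directed influences, the
#' loading map from eigentraits to (log-scale) phenotypes, and the
#' eigentrait-space residual noise. Defaults emulate a small
#' signal-transduction screen: a minority of knockdowns carry strong
#' pleiotropic main effects (the rest are near-silent), the first latent
#' eigentrait loads positively on all three phenotypes (cell number,
#' nuclear area, nuclear intensity) while the second separates nuclear
#' area from the other two, and influences are planted between
#' strong-effect genes, whose effect-vector angles are kept above
#' `min_angle` degrees so the activity inversion is identified.
#'
#' @param G Gene count (default 20).
#' @param n_strong Number of strong-effect genes (default 5). Strong
#'   genes are *axis dominant*, alternating between the two eigentraits:
#'   each has a major effect on one eigentrait (magnitude
#'   `U(effect_radius)`) and a minor effect on the other (major times
#'   `U(minor_ratio)`), random signs — mirroring real screens where
#'   strong knockdowns load predominantly on one composite phenotype.
#'   Axis dominance keeps single-locus scan statistics well separated
#'   from the covariate threshold (majors far above, minors far below),
#'   so strong-effect conditioning is reliable.
#' @param n_edges Number of planted directed influence edges (default 0,
#'   a null screen); edges connect distinct pairs of strong genes whose
#'   effect-vector directions differ by at least `plant_min_angle`
#'   degrees (nearly collinear signatures cannot be directionally
#'   resolved), one direction each, `|m| ~ U(m_range)` with random sign.
#' @param m_range Magnitude range for planted influences (default
#'   `c(0.5, 0.8)`).
#' @param effect_radius Magnitude range of strong-gene major-axis
#'   effects (default `c(0.9, 1.3)`).
#' @param minor_ratio Range of the minor-to-major effect ratio (default
#'   `c(0.1, 0.3)`).
#' @param plant_min_angle Minimum signature angle (degrees) between the
#'   two genes of a planted pair (default 40).
#' @param noise_sd Residual SD added per eigentrait (default 0.05).
#' @param pheno_noise_sd Optional extra residual SD added per phenotype
#'   on the log scale (default 0, keeping the log-phenotype matrix rank
#'   2 so the analysis eigentraits span the generative ones exactly).
#' @param loadings 3 x 2 matrix mapping eigentraits to log-phenotypes.
#' @param offsets Log-scale phenotype offsets (set the raw scale).
#' @param min_angle Minimum pairwise angle (degrees) between strong-gene
#'   effect vectors (default 5; exact collinearity is separately guarded
#'   by the condition-number limit at analysis time).
#' @param seed Optional integer seed.
#' @return An object of class `planted_model` with fields `G`,
#'   `gene_names`, `main_effects` (G x 2), `edges` (tibble `gene_a`,
#'   `gene_b`, `m_ab`, `m_ba`), `loadings`, `offsets`, `noise_sd`,
#'   `pheno_noise_sd`.
#' @export
planted_model <- function(G = 20, n_strong = 5, n_edges = 0,
                          m_range = c(0.5, 0.8),
                          effect_radius = c(0.9, 1.3),
                          minor_ratio = c(0.1, 0.3),
                          plant_min_angle = 40,
                          noise_sd = 0.05, pheno_noise_sd = 0,
                          loadings = NULL, offsets = c(3, 2, 2.5),
                          min_angle = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- as.integer(G)
  stopifnot(G >= 3L, n_strong <= G, noise_sd >= 0, pheno_noise_sd >= 0)
  gene_names <- sprintf("g%02d", seq_len(G))
  loadings <- loadings %||% cbind(
    c(1.0, 0.8, 0.95), # common signal across all three phenotypes
    c(-0.25, 0.9, -0.35) * 0.55 # separates nuclear area
  )
  if (n_strong == 0L) {
    if (n_edges > 0) {
      abort("cannot plant influence edges without strong-effect genes",
        class = "influscreen_domain_error"
      )
    }
    return(structure(
      list(
        G = G, gene_names = gene_names,
        main_effects = matrix(0, G, 2, dimnames = list(gene_names, c("et1", "et2"))),
        strong = character(0),
        edges = tibble::tibble(
          gene_a = character(0), gene_b = character(0),
          m_ab = numeric(0), m_ba = numeric(0)
        ),
        loadings = loadings, offsets = offsets,
        noise_sd = noise_sd, pheno_noise_sd = pheno_noise_sd
      ),
      class = "planted_model"
    ))
  }
  strong <- sort(sample.int(G, n_strong))
  # axis-dominant effect vectors, alternating major eigentrait; pairwise
  # signature directions (modulo sign) must be separated by >= min_angle
  # so every 2x2 activity inversion stays well conditioned
  axis <- rep_len(c(1L, 2L), n_strong)
  draw_effects <- function() {
    major <- runif(n_strong, effect_radius[1], effect_radius[2]) *
      sample(c(-1, 1), n_strong, replace = TRUE)
    minor <- major * runif(n_strong, minor_ratio[1], minor_ratio[2]) *
      sample(c(-1, 1), n_strong, replace = TRUE)
    B <- matrix(0, n_strong, 2)
    B[cbind(seq_len(n_strong), axis)] <- major
    B[cbind(seq_len(n_strong), 3L - axis)] <- minor
    B
  }
  pair_angles <- function(B) {
    ang <- atan2(B[, 2], B[, 1]) %% pi # direction modulo sign
    d <- abs(outer(ang, ang, "-"))
    pmin(d, pi - d)
  }
  B <- draw_effects()
  tries <- 1L
  while (min(pair_angles(B)[upper.tri(diag(n_strong))]) < min_angle * pi / 180 &&
    tries < 500L) {
    B <- draw_effects()
    tries <- tries + 1L
  }
  if (min(pair_angles(B)[upper.tri(diag(n_strong))]) < min_angle * pi / 180) {
    abort("could not place strong-gene effect vectors at the requested angular separation",
      class = "influscreen_domain_error"
    )
  }
  main <- matrix(0, G, 2, dimnames = list(gene_names, c("et1", "et2")))
  main[strong, ] <- B

  edges <- tibble::tibble(
    gene_a = character(0), gene_b = character(0),
    m_ab = numeric(0), m_ba = numeric(0)
  )
  if (n_edges > 0) {
    if (n_strong < 3) abort("need at least 3 strong genes to plant edges",
      class = "influscreen_domain_error"
    )
    cand <- t(utils::combn(seq_len(n_strong), 2))
    ang <- pair_angles(B)
    cand <- cand[ang[cand] >= plant_min_angle * pi / 180, , drop = FALSE]
    if (nrow(cand) < n_edges) {
      abort(sprintf(
        "only %d strong-gene pairs meet the %g-degree signature separation needed for planting %d edges",
        nrow(cand), plant_min_angle, n_edges
      ), class = "influscreen_domain_error")
    }
    cand <- matrix(strong[cand], ncol = 2)
    pick <- cand[sample.int(nrow(cand), n_edges), , drop = FALSE]
    mags <- runif(n_edges, m_range[1], m_range[2]) *
      sample(c(-1, 1), n_edges, replace = TRUE)
    forward <- sample(c(TRUE, FALSE), n_edges, replace = TRUE)
    edges <- tibble::tibble(
      gene_a = gene_names[pick[, 1]], gene_b = gene_names[pick[, 2]],
      m_ab = ifelse(forward, mags, 0), m_ba = ifelse(forward, 0, mags)
    )
  }
  structure(
    list(
      G = G, gene_names = gene_names, main_effects = main,
      strong = gene_names[strong], edges = edges, loadings = loadings,
      offsets = offsets, noise_sd = noise_sd, pheno_noise_sd = pheno_noise_sd
    ),
    class = "planted_model"
  )
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf(
    "<planted_model> %d genes (%d strong), %d planted edge(s), noise_sd = %g\n",
    x$G, length(x$strong), nrow(x$edges), x$noise_sd
  ))
  invisible(x)
}

#' Forward-plant interaction coefficients from directed influences
#'
#' Inverts the influence map analytically: for a planted pair with
#' influences `(m_ab, m_ba)`, the activity modifications are
#' `delta_1 = m_ab (1 + m_ba) / (1 - m_ab m_ba)` and
#' `delta_2 = m_ba (1 + m_ab) / (1 - m_ab m_ba)`, and the per-eigentrait
#' interaction coefficients follow from the exact reparametrization:
#' `gamma_j = beta_aj delta_1 + beta_bj delta_2`. Running the analysis
#' direction (activity solve, then the influence map) on the planted
#' coefficients recovers the planted influences exactly.
#'
#' @param model A `planted_model`.
#' @return A tibble with one row per planted pair: `gene_a`, `gene_b`,
#'   `delta_1`, `delta_2`, `gamma_1`, `gamma_2`.
#' @export
plant_interactions <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  e <- model$edges
  if (!nrow(e)) {
    return(tibble::tibble(
      gene_a = character(0), gene_b = character(0),
      delta_1 = numeric(0), delta_2 = numeric(0),
      gamma_1 = numeric(0), gamma_2 = numeric(0)
    ))
  }
  denom <- 1 - e$m_ab * e$m_ba
  if (any(abs(denom) < 1e-8)) {
    abort("degenerate planting: m_ab * m_ba too close to 1",
      class = "influscreen_domain_error"
    )
  }
  d1 <- e$m_ab * (1 + e$m_ba) / denom
  d2 <- e$m_ba * (1 + e$m_ab) / denom
  ba <- model$main_effects[e$gene_a, , drop = FALSE]
  bb <- model$main_effects[e$gene_b, , drop = FALSE]
  tibble::tibble(
    gene_a = e$gene_a, gene_b = e$gene_b,
    delta_1 = d1, delta_2 = d2,
    gamma_1 = ba[, 1] * d1 + bb[, 1] * d2,
    gamma_2 = ba[, 2] * d1 + bb[, 2] * d2
  )
}

#' Simulate raw screen phenotypes from a planted model
#'
#' Eigentrait values per line are the sum of the two knocked-down genes'
#' main effects, the pair's planted interaction coefficient (zero for
#' unplanted pairs) and Gaussian eigentrait-space noise. Log-phenotypes
#' are the eigentraits mapped through the loading matrix plus per-column
#' offsets (plus optional phenotype-space noise); raw phenotypes are
#' `10^log`, so the pipeline's log10 transform inverts the map exactly.
#'
#' @param design A design tibble from [generate_all_pairs_design()] (or
#'   any genotype tibble with a `line_id` column).
#' @param model A `planted_model` whose genes match the design columns.
#' @param seed Optional integer seed (noise only).
#' @return A list with `phenotypes` (tibble: `line_id`, `cell_number`,
#'   `nuclear_area`, `nuclear_intensity`), `eigentraits` (the latent
#'   noiseless-plus-noise eigentrait values) and `interactions` (the
#'   planted coefficients, from [plant_interactions()]).
#' @export
simulate_phenotypes <- function(design, model, seed = NULL) {
  stopifnot(inherits(model, "planted_model"))
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(design[setdiff(names(design), "line_id")])
  if (!setequal(colnames(X), model$gene_names)) {
    abort("design genes do not match the planted model", class = "influscreen_validation_error")
  }
  X <- X[, model$gene_names, drop = FALSE]
  n <- nrow(X)
  E <- X %*% model$main_effects # n x 2
  planted <- plant_interactions(model)
  if (nrow(planted)) {
    ia <- match(planted$gene_a, model$gene_names)
    ib <- match(planted$gene_b, model$gene_names)
    for (r in seq_len(nrow(planted))) {
      hit <- X[, ia[r]] * X[, ib[r]] # 1 only on the pair's own line
      E[, 1] <- E[, 1] + hit * planted$gamma_1[r]
      E[, 2] <- E[, 2] + hit * planted$gamma_2[r]
    }
  }
  if (model$noise_sd > 0) {
    E <- E + matrix(rnorm(2 * n, sd = model$noise_sd), n, 2)
  }
  P_log <- E %*% t(model$loadings)
  P_log <- sweep(P_log, 2, model$offsets, "+")
  if (model$pheno_noise_sd > 0) {
    P_log <- P_log + matrix(rnorm(length(P_log), sd = model$pheno_noise_sd), nrow(P_log))
  }
  pheno_names <- c("cell_number", "nuclear_area", "nuclear_intensity")
  P <- 10^P_log
  colnames(P) <- pheno_names
  list(
    phenotypes = tibble::tibble(line_id = design$line_id, tibble::as_tibble(P)),
    eigentraits = E,
    interactions = planted
  )
}

#' Simulate a complete all-pairs knockdown screen
#'
#' Convenience wrapper: builds the all-pairs design for a planted model
#' (see [planted_model()] for the generative assumptions and defaults)
#' and simulates its raw phenotypes.
#'
#' @param ... Passed to [planted_model()] (`G`, `n_edges`, `noise_sd`,
#'   `seed`, ...).
#' @param model Optionally a ready-made `planted_model` (overrides
#'   `...`).
#' @return A list with `dataset` (a raw [kd_dataset()]), `model`,
#'   `truth_edges` (planted influences), `truth_main` (tibble of planted
#'   main effects) and `interactions` (planted interaction
#'   coefficients).
#' @export
simulate_screen <- function(..., model = NULL) {
  model <- model %||% planted_model(...)
  design <- generate_all_pairs_design(model$G, model$gene_names)
  sim <- simulate_phenotypes(design, model)
  dataset <- kd_dataset(design, sim$phenotypes, normalized = FALSE)
  list(
    dataset = dataset,
    model = model,
    truth_edges = model$edges,
    truth_main = tibble::tibble(
      gene = model$gene_names,
      et1 = model$main_effects[, 1],
      et2 = model$main_effects[, 2]
    ),
    interactions = sim$interactions
  )
}

#' Write a simulated screen and its ground truth as TSV
#'
#' @param sim Result of [simulate_screen()].
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_screen <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- tibble::tibble(
    line_id = sim$dataset$line_ids,
    tibble::as_tibble(sim$dataset$genotype)
  )
  ph <- tibble::tibble(
    line_id = sim$dataset$line_ids,
    tibble::as_tibble(sim$dataset$phenotypes)
  )
  paths <- c(
    genotype = file.path(dir, "genotype.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth_edges = file.path(dir, "truth_edges.tsv"),
    truth_main = file.path(dir, "truth_main.tsv")
  )
  readr::write_tsv(gt, paths["genotype"])
  readr::write_tsv(ph, paths["phenotypes"])
  readr::write_tsv(sim$truth_edges, paths["truth_edges"])
  readr::write_tsv(sim$truth_main, paths["truth_main"])
  invisible(paths)
}
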