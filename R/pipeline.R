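#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default. Either the
#' two input paths or a simulation spec must be supplied to
#' [run_full_analysis()].
#'
#' @param genotype_path,phenotype_path Input tables (see
#'   [load_dataset()]), or `NULL` when simulating.
#' @param simulate `NULL`, or a named list of arguments to
#'   [planted_model()] (e.g. `list(G = 20, n_edges = 5)`).
#' @param log_base Phenotype log base (default 10).
#' @param min_variance_fraction Eigentrait retention cutoff (default
#'   0.02).
#' @param alpha_covariate Familywise level for strong-effect covariate
#'   selection (default 0.001).
#' @param alpha_network Adjusted-p cutoff for network edges (default
#'   0.01).
#' @param n_perm_single Permutations for the single-scan EVD null
#'   (default 2000, minimum 100).
#' @param n_perm_pair Tandem permutations per pair (default 700).
#' @param seed Integer seed controlling every random draw of the run.
#' @param condition_number_limit Singularity guard for the activity
#'   inversion (default 1e8).
#' @param pole_tol Pole guard for the influence map (default 1e-8).
#' @param pool_null Pool permutation nulls across pairs for raw p-values
#'   (default TRUE).
#' @param out_dir Optional output directory for exports and `run.log`.
#' @return A validated list of class `kd_config`.
#' @export
run_config <- function(genotype_path = NULL, phenotype_path = NULL,
                       simulate = NULL, log_base = 10,
                       min_variance_fraction = 0.02, alpha_covariate = 0.001,
                       alpha_network = 0.01, n_perm_single = 2000,
                       n_perm_pair = 700, seed = 1,
                       condition_number_limit = 1e8, pole_tol = 1e-8,
                       pool_null = TRUE, out_dir = NULL) {
  cfg <- list(
    genotype_path = genotype_path, phenotype_path = phenotype_path,
    simulate = simulate, log_base = log_base,
    min_variance_fraction = min_variance_fraction,
    alpha_covariate = alpha_covariate, alpha_network = alpha_network,
    n_perm_single = as.integer(n_perm_single),
    n_perm_pair = as.integer(n_perm_pair), seed = as.integer(seed),
    condition_number_limit = condition_number_limit, pole_tol = pole_tol,
    pool_null = isTRUE(pool_null), out_dir = out_dir
  )
  .validate_config(cfg)
  structure(cfg, class = "kd_config")
}

.validate_config <- function(cfg) {
  check_alpha <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1) {
      abort(sprintf("`%s` must lie in (0, 1)", nm), class = "influscreen_validation_error")
    }
  }
  check_alpha(cfg$alpha_covariate, "alpha_covariate")
  check_alpha(cfg$alpha_network, "alpha_network")
  check_alpha(cfg$min_variance_fraction, "min_variance_fraction")
  if (cfg$n_perm_single < 100L) {
    abort("`n_perm_single` must be at least 100", class = "influscreen_validation_error")
  }
  if (cfg$n_perm_pair < 100L) {
    abort("`n_perm_pair` must be at least 100", class = "influscreen_validation_error")
  }
  if (cfg$log_base <= 0) {
    abort("`log_base` must be positive", class = "influscreen_validation_error")
  }
  if (is.null(cfg$simulate) && (is.null(cfg$genotype_path) || is.null(cfg$phenotype_path))) {
    abort("supply genotype_path + phenotype_path, or a simulation spec",
      class = "influscreen_validation_error"
    )
  }
  invisible(cfg)
}

#' Read a configuration from YAML, with flag overrides
#'
#' Reads a YAML file whose keys match the arguments of [run_config()]
#' and applies `overrides` on top (overrides win over file values; both
#' win over defaults).
#'
#' @param path YAML file path, or `NULL` to start from defaults.
#' @param overrides Named list of values overriding the file.
#' @return A validated `kd_config`.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file not found: %s", path), class = "influscreen_parse_error")
    }
    vals <- yaml::read_yaml(path) %||% list()
  }
  vals <- modifyList(vals, overrides)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
      class = "influscreen_validation_error"
    )
  }
  do.call(run_config, vals)
}

#' Run the complete influence analysis
#'
#' Executes normalize, eigentrait decomposition, single-locus scan with
#' permutation EVD calibration, strong-effect covariate selection, the
#' all-pairs influence scan with tandem permutation nulls, phenotype
#' summarization, step-down familywise adjustment and network assembly;
#' optionally exports everything to `config$out_dir`. All randomness is
#' governed by `config$seed`; a rerun with the same configuration is
#' reproducible bit for bit.
#'
#' @param config A `kd_config` from [run_config()] or [parse_config()].
#' @return An object of class `kd_analysis`: `config`, `dataset`
#'   (normalized), `decomp`, `scan`, `scan_null`, `covariates`,
#'   `pair_results`, `significance`, `network`, `truth` (for simulated
#'   runs) and `log` (character vector of stage records).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "kd_config"))
  set.seed(config$seed)
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    log <<- c(log, line)
    inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), parent = e)
    })
  }
  say(
    "config: seed=%d n_perm_single=%d n_perm_pair=%d alpha_covariate=%g alpha_network=%g min_variance_fraction=%g",
    config$seed, config$n_perm_single, config$n_perm_pair,
    config$alpha_covariate, config$alpha_network, config$min_variance_fraction
  )

  truth <- NULL
  dataset <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- do.call(planted_model, config$simulate)
      sim <- simulate_screen(model = sim)
      truth <- sim[c("truth_edges", "truth_main", "interactions")]
      say(
        "simulated screen: G=%d, %d lines, %d planted edge(s)",
        sim$model$G, length(sim$dataset$line_ids), nrow(sim$truth_edges)
      )
      sim$dataset
    } else {
      ds <- load_dataset(config$genotype_path, config$phenotype_path)
      say(
        "loaded screen: %d lines, %d genes, %d phenotypes",
        length(ds$line_ids), length(ds$gene_names), length(ds$phenotype_names)
      )
      ds
    }
  })
  dataset <- stage("normalize", normalize_phenotypes(dataset, log_base = config$log_base))
  decomp <- stage("eigentraits", {
    d <- decompose_phenotypes(dataset)
    d <- select_eigentraits(d, config$min_variance_fraction)
    say(
      "eigentraits: variance fractions %s; retained k=%d",
      paste(sprintf("%.3f", d$var_frac), collapse = " "), d$k
    )
    d
  })
  scan <- stage("single_scan", single_locus_scan(dataset, decomp))
  scan_null <- stage("single_scan_null", single_scan_null(dataset, decomp,
    n_perm = config$n_perm_single
  ))
  covariates <- stage("covariates", {
    cv <- select_covariates(scan, scan_null, alpha = config$alpha_covariate)
    say(
      "covariates at |stat| > %.3f (alpha=%g): %s",
      cv$threshold, config$alpha_covariate,
      paste(vapply(cv$sets, length, integer(1)), collapse = "/")
    )
    cv
  })
  pair_results <- stage("pair_scan", {
    pr <- scan_all_pairs(dataset, decomp, covariates,
      n_perm = config$n_perm_pair,
      condition_number_limit = config$condition_number_limit,
      pole_tol = config$pole_tol
    )
    tab <- table(pr$influences$status)
    say(
      "pair scan: %d pairs [%s]; skipped null draws: %d",
      nrow(pr$influences),
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      sum(pr$influences$null_skipped)
    )
    pr
  })
  significance <- stage(
    "significance",
    adjust_significance(pair_results, pool = config$pool_null)
  )
  network <- stage("network", {
    nw <- build_network(significance,
      cutoff = config$alpha_network,
      metadata = list(
        seed = config$seed, n_perm_single = config$n_perm_single,
        n_perm_pair = config$n_perm_pair,
        alpha_covariate = config$alpha_covariate,
        covariate_threshold = covariates$threshold,
        pooled_null = config$pool_null
      )
    )
    say(
      "network at adjusted p < %g: %d gene edge(s), %d phenotype edge(s)",
      config$alpha_network, nrow(nw$gene_edges), nrow(nw$phenotype_edges)
    )
    nw
  })

  result <- structure(
    list(
      config = config, dataset = dataset, decomp = decomp, scan = scan,
      scan_null = scan_null, covariates = covariates,
      pair_results = pair_results, significance = significance,
      network = network, truth = truth, log = log
    ),
    class = "kd_analysis"
  )
  if (!is.null(config$out_dir)) {
    stage("export", .export_analysis(result, config$out_dir))
  }
  result
}

.export_analysis <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$scan, file.path(dir, "single_scan.tsv"))
  readr::write_tsv(result$significance$influences, file.path(dir, "influences.tsv"))
  readr::write_tsv(result$significance$phenotype_effects, file.path(dir, "phenotype_effects.tsv"))
  export_network(result$network, dir)
  cfg <- result$config
  cfg_out <- cfg[!vapply(cfg, is.null, logical(1))]
  class(cfg_out) <- NULL
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  writeLines(result$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.kd_analysis <- function(x, ...) {
  cat("<kd_analysis>\n")
  print(x$network)
  invisible(x)
}

#' Tidy / glance methods for a full analysis
#'
#' `tidy()` returns all network edges; `glance()` a one-row run summary.
#'
#' @param x A `kd_analysis`.
#' @param ... Unused.
#' @export
tidy.kd_analysis <- function(x, ...) tidy(x$network)

#' @rdname tidy.kd_analysis
#' @export
glance.kd_analysis <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$network),
    tibble::tibble(
      seed = x$config$seed,
      n_perm_single = x$config$n_perm_single,
      n_perm_pair = x$config$n_perm_pair,
      covariate_threshold = x$covariates$threshold,
      n_covariates_et1 = length(x$covariates$sets[[1]]),
      n_covariates_et2 = length(x$covariates$sets[[2]])
    )
  )
}
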