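#' Build a pipeline run configuration
#'
#' @param input `"synthetic"` or `"files"`
#' @param paths for `"files"` input: directory holding the four study CSVs
#' @param synthetic for `"synthetic"` input: a [synthetic_config()] (default
#'   config if `NULL`)
#' @param stages stages to run, a prefix-closed subset of the dependency
#'   order `read` -> `impute` -> (`decompose`, `ordinate`, `rlq`, `models`)
#' @param out_dir directory for artifacts (created if needed); `NULL` = no
#'   files written
#' @param seed integer seed recorded in the report and used for any
#'   stochastic stage
#' @param n_axes ordination / RLQ axes to keep
#' @param alpha,alpha_marginal significance thresholds reported (0.05, 0.1)
#' @param lmm_traits quantitative traits to model individually (default: all
#'   flagged `log_transform_for_lmm`)
#' @return object of class `run_config`
#' @export
run_config <- function(input = c("synthetic", "files"), paths = NULL,
                       synthetic = NULL,
                       stages = c("read", "impute", "decompose", "ordinate",
                                  "rlq", "models"),
                       out_dir = NULL, seed = 1L, n_axes = 2,
                       alpha = 0.05, alpha_marginal = 0.1,
                       lmm_traits = NULL) {
  input <- match.arg(input)
  all_stages <- c("read", "impute", "decompose", "ordinate", "rlq", "models")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!all(stages[1:min(2, length(stages))] ==
             all_stages[1:min(2, length(stages))]))
    stop("stages must start with 'read' (and 'impute' before any analysis)",
         call. = FALSE)
  if (input == "files" && is.null(paths))
    stop("input = 'files' requires 'paths'", call. = FALSE)
  if (input == "synthetic" && is.null(synthetic))
    synthetic <- synthetic_config(seed = seed)
  structure(list(
    input = input, paths = paths, synthetic = synthetic, stages = stages,
    out_dir = out_dir, seed = as.integer(seed), n_axes = n_axes,
    alpha = alpha, alpha_marginal = alpha_marginal, lmm_traits = lmm_traits
  ), class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Plain-text configuration for the command-line interface. Top-level keys
#' mirror the arguments of [run_config()]; the `synthetic` key holds
#' arguments for [synthetic_config()].
#'
#' @param path JSON file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    args <- raw$synthetic
    if (!is.null(args$age_range))
      args$age_range <- lapply(args$age_range, as.numeric)
    syn <- do.call(synthetic_config, args)
  }
  run_config(
    input = raw$input %||% "synthetic", paths = raw$paths,
    synthetic = syn,
    stages = raw$stages %||% c("read", "impute", "decompose", "ordinate",
                               "rlq", "models"),
    out_dir = raw$out_dir, seed = raw$seed %||% 1L,
    n_axes = raw$n_axes %||% 2,
    alpha = raw$alpha %||% 0.05, alpha_marginal = raw$alpha_marginal %||% 0.1,
    lmm_traits = raw$lmm_traits
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.rlq_to_list <- function(x) list(
  eigenvalues = as.numeric(x$eig),
  axis_pct = as.numeric(x$axis_pct),
  env_coef = as.data.frame(x$env_coef),
  trait_coef = as.data.frame(x$trait_coef),
  env_contrib = as.data.frame(x$env_contrib),
  trait_contrib = as.data.frame(x$trait_contrib),
  trace = x$trace
)

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order: load or simulate the
#' study, impute missing trait values, decompose community trait variation
#' (total and along the successional gradient), ordinate the individual-level
#' trait table, run the among-/within-species partial RLQs per forest type,
#' and fit the categorical-trait GLMs and individual-scale mixed models. A
#' failed stage is recorded in the report with its error message and all
#' dependent stages are skipped. Re-running an identical configuration
#' reproduces the report bit for bit.
#'
#' @param config a [run_config()] (or a JSON path accepted by
#'   [read_run_config()])
#' @return the report: a list with one element per stage (`status`,
#'   `log`, stage-specific tables) plus `config_digest` metadata. If
#'   `out_dir` is set, per-stage CSV/JSON artifacts and `report.json` are
#'   written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())
  failed <- FALSE
  study <- NULL; truth <- NULL

  stage <- function(name, fun) {
    if (failed || !(name %in% config$stages)) {
      report$stages[[name]] <<- list(status = if (failed) "skipped"
                                     else "not requested")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res)
    }
    invisible(NULL)
  }

  stage("read", function() {
    if (config$input == "synthetic") {
      set.seed(config$seed)
      g <- generate_study(config$synthetic)
      study <<- g$study; truth <<- g$truth
      if (!is.null(out)) {
        write_study(study, file.path(out, "study"))
        jsonlite::write_json(
          list(optimum = truth$optimum,
               species_means = as.data.frame(truth$species_means),
               age_center = truth$age_center,
               species_id = truth$species_id),
          file.path(out, "study", "truth.json"),
          auto_unbox = TRUE, digits = NA)
      }
    } else {
      study <<- read_study(config$paths)
    }
    list(log = list(n_plots = nrow(study$plots),
                    n_species = nrow(study$species),
                    n_individuals = nrow(study$individuals)))
  })

  stage("impute", function() {
    study <<- impute_missing_traits(study)
    lg <- attr(study, "imputation_log")
    list(log = list(n_filled = nrow(lg)))
  })

  stage("decompose", function() {
    total <- decompose_total(study)
    grad <- decompose_vs_gradient(study)
    if (!is.null(out)) {
      utils::write.csv(total, file.path(out, "decomposition_total.csv"),
                       row.names = FALSE)
      utils::write.csv(grad, file.path(out, "decomposition_gradient.csv"),
                       row.names = FALSE)
    }
    list(total = total, gradient = grad)
  })

  stage("ordinate", function() {
    hs <- ordinate_individuals(study, n_axes = config$n_axes)
    res <- list(eigenvalues = as.numeric(hs$eig),
                axis_pct = as.numeric(hs$axis_pct),
                total_inertia = hs$total_inertia)
    if (!is.null(out))
      jsonlite::write_json(res, file.path(out, "ordination.json"),
                           auto_unbox = TRUE, digits = NA)
    res
  })

  stage("rlq", function() {
    res <- list()
    for (f in unique(study$plots$forest_type)) {
      res[[f]] <- list(
        among_species = .rlq_to_list(
          partial_rlq(study, f, "among_species", n_axes = config$n_axes)),
        within_species = .rlq_to_list(
          partial_rlq(study, f, "within_species", n_axes = config$n_axes))
      )
    }
    if (!is.null(out))
      jsonlite::write_json(res, file.path(out, "rlq.json"),
                           auto_unbox = TRUE, digits = NA)
    res
  })

  stage("models", function() {
    env <- lapply(unique(study$plots$forest_type), function(f)
      cbind(forest_type = f, env_gradient_check(study, f)))
    env <- do.call(rbind, env)
    glms <- list()
    for (tn in intersect(categorical_traits(study),
                         c("phenology", "legume", "pubescence"))) {
      lev <- if (tn == "phenology") "deciduous" else "yes"
      g <- fit_categorical_trait_glm(study, tn, lev, alpha = config$alpha)
      glms[[tn]] <- list(level = g$level, terms = g$terms,
                         coefficients = as.list(g$coefficients),
                         dispersion = g$dispersion,
                         pseudo_r2 = g$pseudo_r2, separation = g$separation)
    }
    lmm_traits <- config$lmm_traits %||%
      study$traits$name[study$traits$kind == "quantitative" &
                          study$traits$log_transform_for_lmm]
    lmms <- list()
    for (tn in lmm_traits) {
      m <- fit_itv_lmm(study, tn)
      lmms[[tn]] <- list(random_structure = m$random_structure,
                         fixed = m$fixed, r2_marginal = m$r2_marginal,
                         r2_conditional = m$r2_conditional,
                         n_individuals = m$n_individuals,
                         n_species = m$n_species, singular = m$singular)
    }
    res <- list(environment = env, glm = glms, lmm = lmms)
    if (!is.null(out))
      jsonlite::write_json(res, file.path(out, "models.json"),
                           auto_unbox = TRUE, digits = NA)
    res
  })

  if (!is.null(out))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}
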