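#' Default trait set of the synthetic community
#'
#' Eleven quantitative leaf traits spanning the leaf economics spectrum plus
#' four categorical species attributes, mirroring a tropical dry forest
#' sapling survey. `les_loading` encodes the side of the leaf-economics axis
#' each quantitative trait sits on (+1 acquisitive, -1 conservative, 0
#' unrelated); `log_transform_for_lmm` marks traits generated (and modelled)
#' on the log scale.
#'
#' @return data frame with columns `name`, `kind`, `units`,
#'   `log_transform_for_lmm`, `base_mean`, `les_loading`
#' @export
default_synthetic_traits <- function() {
  q <- data.frame(
    name = c("thickness", "petiole_length", "leaf_area", "sla", "ldmc",
             "density", "lpc", "lcc", "lnc", "cn_ratio", "np_ratio"),
    kind = "quantitative",
    units = c("mm", "mm", "cm2", "m2/kg", "mg/g", "g/cm3", "mg/g", "mg/g",
              "mg/g", "ratio", "ratio"),
    log_transform_for_lmm = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                              FALSE, FALSE, FALSE, FALSE),
    base_mean = c(10, log(15), log(50), log(15), 10, 10, 10, 10, 10, 10, 10),
    les_loading = c(-1, 0, 0, 1, -1, -1, 1, -1, 1, -1, 0),
    stringsAsFactors = FALSE
  )
  cat_ <- data.frame(
    name = c("phenology", "compoundness", "pubescence", "legume"),
    kind = c("categorical", "categorical", "binary", "binary"),
    units = "class",
    log_transform_for_lmm = FALSE, base_mean = NA_real_, les_loading = 0,
    stringsAsFactors = FALSE
  )
  rbind(q, cat_)
}

# expand a scalar or partially named per-trait parameter over trait names
.per_trait <- function(x, trait_names, what) {
  if (length(x) == 1 && is.null(names(x)))
    return(stats::setNames(rep(as.numeric(x), length(trait_names)),
                           trait_names))
  out <- stats::setNames(rep(NA_real_, length(trait_names)), trait_names)
  if (is.null(names(x)))
    stop(what, " must be a scalar or a named vector", call. = FALSE)
  unknown <- setdiff(names(x), trait_names)
  if (length(unknown))
    stop(what, " names unknown: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out[names(x)] <- as.numeric(x)
  if (anyNA(out)) out[is.na(out)] <- 0
  out
}

#' Configuration of the synthetic sapling community
#'
#' Describes the world the generator simulates: two chronosequences (six
#' plots each by default, OAK spanning 12-37 y and MIX 19-67 y), a species
#' pool with correlated species-mean leaf traits (leaf-economics structure)
#' and Gaussian abundance niches along the age axis, and individual saplings
#' whose trait values respond to the successional gradient via species
#' turnover (species means shifting with niche optima) and via within-species
#' plasticity, to ontogeny (relative height), to crown illumination, and to
#' residual noise.
#'
#' All per-trait parameters act on the trait's model scale (log scale for
#' traits flagged `log_transform_for_lmm`) and accept either a scalar
#' (applied to every quantitative trait) or a named vector.
#'
#' @param seed integer seed; identical seeds give byte-identical studies
#' @param n_plots_per_type plots per forest type
#' @param age_range named list of `c(min, max)` successional ages (years) per
#'   forest type; plots are spaced evenly across each range
#' @param n_species size of the species pool (>= 2)
#' @param trait_correlation target correlation between species-mean SLA and
#'   LNC/LPC (must lie in \[0, 1); larger is infeasible)
#' @param niche_width Gaussian niche width on the age axis (years); `Inf`
#'   gives flat niches (no deterministic turnover in composition)
#' @param mean_abundance expected saplings per species per plot at the niche
#'   optimum
#' @param traits trait definition table, see [default_synthetic_traits()]
#' @param species_sd per-trait s.d. of species means around the base mean
#' @param turnover_strength per-trait shift of a species' mean per year of
#'   its niche optimum (species-sorting signal)
#' @param itv_strength per-trait within-species shift per year of plot age
#' @param ontogeny_slope per-trait shift per unit of relative height H/Hmax
#' @param cii_slope per-trait shift per unit of crown illumination index
#'   (centred at 3)
#' @param noise_sd per-trait residual s.d. (> 0)
#' @return object of class `synthetic_config` (a validated list)
#' @export
synthetic_config <- function(seed = 1L,
                             n_plots_per_type = 6L,
                             age_range = list(OAK = c(12, 37),
                                              MIX = c(19, 67)),
                             n_species = 60L,
                             trait_correlation = 0.7,
                             niche_width = 15,
                             mean_abundance = 2.5,
                             traits = default_synthetic_traits(),
                             species_sd = 1,
                             turnover_strength = 0.02,
                             itv_strength = 0.01,
                             ontogeny_slope = -0.3,
                             cii_slope = 0.05,
                             noise_sd = 0.3) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (trait_correlation < 0 || trait_correlation >= 1)
    stop("infeasible trait correlation target (must lie in [0, 1))",
         call. = FALSE)
  qn <- traits$name[traits$kind == "quantitative"]
  cfg <- list(
    seed = as.integer(seed), n_plots_per_type = as.integer(n_plots_per_type),
    age_range = age_range, n_species = as.integer(n_species),
    trait_correlation = trait_correlation, niche_width = niche_width,
    mean_abundance = mean_abundance, traits = traits,
    species_sd = .per_trait(species_sd, qn, "species_sd"),
    turnover_strength = .per_trait(turnover_strength, qn,
                                   "turnover_strength"),
    itv_strength = .per_trait(itv_strength, qn, "itv_strength"),
    ontogeny_slope = .per_trait(ontogeny_slope, qn, "ontogeny_slope"),
    cii_slope = .per_trait(cii_slope, qn, "cii_slope"),
    noise_sd = .per_trait(noise_sd, qn, "noise_sd")
  )
  if (any(cfg$noise_sd <= 0))
    stop("noise_sd must be > 0", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

.height_midpoints <- seq(1.25, 3.75, by = 0.5)

#' Generate a synthetic study with stored ground truth
#'
#' Draws a [trait_study] from the generating model described in
#' [synthetic_config()], together with a `synthetic_truth` object recording
#' every parameter needed to predict the expected turnover/ITV decomposition
#' (species niche optima, species mean trait matrix, the four per-trait
#' slopes). A single seeded random stream drives all draws, so identical
#' configurations reproduce identical studies.
#'
#' @param config a [synthetic_config()]
#' @return list with elements `study` (a [trait_study]) and `truth`
#'   (a `synthetic_truth`)
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  tr <- config$traits
  qn <- tr$name[tr$kind == "quantitative"]
  nq <- length(qn)
  nsp <- config$n_species
  types <- names(config$age_range)

  ## plots: evenly spaced chronosequences, environment monotone in age
  plots_list <- lapply(types, function(f) {
    rng <- config$age_range[[f]]
    age <- seq(rng[1], rng[2], length.out = config$n_plots_per_type)
    data.frame(
      plot_id = paste0(f, seq_along(age)), forest_type = f,
      successional_age = age, stringsAsFactors = FALSE
    )
  })
  plots <- do.call(rbind, plots_list)
  np <- nrow(plots)
  age <- plots$successional_age
  plots$canopy_openness_dry <- pmax(2, 35 - 0.30 * age + stats::rnorm(np, 0, 2))
  plots$canopy_openness_wet <- pmax(2, 28 - 0.25 * age + stats::rnorm(np, 0, 2))
  plots$air_temp_dry <- 31 - 0.04 * age + stats::rnorm(np, 0, 0.3)
  plots$air_temp_wet <- 28 - 0.03 * age + stats::rnorm(np, 0, 0.3)
  plots$soil_moisture_dry <- pmax(1, 8 + 0.08 * age + stats::rnorm(np, 0, 1))
  plots$soil_moisture_wet <- pmax(2, 20 + 0.10 * age + stats::rnorm(np, 0, 2))
  plots$adult_basal_area <- pmax(1, 5 + 0.45 * age + stats::rnorm(np, 0, 3))
  plots$soil_ph <- ifelse(plots$forest_type == "OAK", 5.0, 5.8) +
    stats::rnorm(np, 0, 0.15)
  plots$soil_clay <- pmax(2, ifelse(plots$forest_type == "OAK", 12, 30) +
                            stats::rnorm(np, 0, 3))
  age_center <- mean(age)

  ## species pool: optima, hmax, correlated trait means, categorical traits
  all_ages <- range(unlist(config$age_range))
  optimum <- stats::runif(nsp, all_ages[1], all_ages[2])
  hmax <- pmax(5, exp(stats::rnorm(nsp, log(18), 0.25)))
  les_factor <- stats::rnorm(nsp)
  rho <- config$trait_correlation
  loading <- tr$les_loading[match(qn, tr$name)]
  mu <- matrix(NA_real_, nsp, nq, dimnames = list(NULL, qn))
  for (j in seq_len(nq)) {
    lam <- loading[j] * sqrt(rho)
    z <- lam * les_factor + sqrt(1 - lam^2) * stats::rnorm(nsp)
    mu[, j] <- tr$base_mean[match(qn[j], tr$name)] +
      config$species_sd[qn[j]] * z +
      config$turnover_strength[qn[j]] * (optimum - age_center)
  }
  d_opt <- optimum - age_center
  p_dec <- stats::plogis(0.8 - 0.06 * d_opt)     # deciduous early succession
  phen_other <- stats::runif(nsp)
  phenology <- ifelse(stats::runif(nsp) < p_dec, "deciduous",
                      ifelse(phen_other < 0.75, "evergreen", "intermediate"))
  legume <- stats::runif(nsp) < stats::plogis(-0.6 - 0.05 * d_opt)
  pubescence <- stats::runif(nsp) < stats::plogis(-0.3 - 0.04 * d_opt)
  comp_draw <- stats::runif(nsp)
  compoundness <- ifelse(legume, ifelse(comp_draw < 0.7, "bipinnate",
                                        "pinnate"),
                         ifelse(comp_draw < 0.7, "simple", "pinnate"))
  species <- data.frame(
    species_id = sprintf("S%03d", seq_len(nsp)), hmax = hmax,
    legume = legume, phenology = phenology, compoundness = compoundness,
    pubescence = pubescence, stringsAsFactors = FALSE
  )

  ## abundances: Gaussian niches on age, Poisson counts
  lam_mat <- matrix(0, np, nsp)
  for (k in seq_len(np)) {
    d <- age[k] - optimum
    lam_mat[k, ] <- if (is.finite(config$niche_width))
      config$mean_abundance * exp(-d^2 / (2 * config$niche_width^2))
    else rep(config$mean_abundance, nsp)
  }
  counts <- matrix(stats::rpois(np * nsp, lam_mat), np, nsp)
  for (k in seq_len(np)) {             # every plot holds >= 1 individual
    if (sum(counts[k, ]) == 0)
      counts[k, which.min(abs(age[k] - optimum))] <- 1L
  }

  ## individuals: heights uniform over classes, CII tracking openness weakly
  open_z <- as.numeric(scale(plots$canopy_openness_dry))
  rows <- which(counts > 0, arr.ind = TRUE)
  reps <- counts[counts > 0]
  plot_i <- rep(rows[, 1], reps)
  sp_i <- rep(rows[, 2], reps)
  n_ind <- length(plot_i)
  height <- sample(.height_midpoints, n_ind, replace = TRUE)
  cii <- pmin(5L, pmax(1L, as.integer(round(
    3 + 0.8 * open_z[plot_i] + stats::rnorm(n_ind, 0, 0.9)))))
  individuals <- data.frame(
    individual_id = sprintf("I%05d", seq_len(n_ind)),
    plot_id = plots$plot_id[plot_i],
    species_id = species$species_id[sp_i],
    height_class_midpoint = height, cii = cii, stringsAsFactors = FALSE
  )
  h_rel <- height / hmax[sp_i]
  for (j in seq_len(nq)) {
    tn <- qn[j]
    eta <- mu[sp_i, j] +
      config$itv_strength[tn] * (age[plot_i] - age_center) +
      config$ontogeny_slope[tn] * h_rel +
      config$cii_slope[tn] * (cii - 3) +
      stats::rnorm(n_ind, 0, config$noise_sd[tn])
    individuals[[tn]] <- if (tr$log_transform_for_lmm[match(tn, tr$name)])
      exp(eta) else eta
  }

  study <- trait_study(
    traits = tr[, c("name", "kind", "units", "log_transform_for_lmm")],
    species = species, plots = plots, individuals = individuals
  )
  truth <- structure(list(
    config = config,
    species_id = species$species_id, optimum = optimum,
    species_means = mu, age_center = age_center
  ), class = "synthetic_truth")
  list(study = study, truth = truth)
}

#' Expected turnover/ITV decomposition under the generating model
#'
#' Independent oracle for parameter-recovery tests: evaluates the generating
#' model directly on the realized plots and individuals (expected trait value
#' per individual from the stored truth — species mean + gradient + ontogeny
#' + illumination terms; the lognormal correction `exp(sigma^2/2)` for
#' log-scale traits), aggregates expected specific and fixed
#' community-weighted means with its own arithmetic, and returns the SS
#' shares the decomposition pipeline should recover. It never calls the
#' pipeline code path.
#'
#' @param truth a `synthetic_truth` from [generate_study()]
#' @param study the matching [trait_study]
#' @param mode `"gradient"` (shares of regression-on-age explained SS) or
#'   `"total"` (shares of among-plot deviation SS)
#' @return data frame `forest_type`, `trait`, `mode`, `pct_turnover`,
#'   `pct_itv`, `pct_cov`
#' @export
truth_expected_decomposition <- function(truth, study,
                                         mode = c("gradient", "total")) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(study, "trait_study"))
  if (!identical(sort(truth$species_id), sort(study$species$species_id)))
    stop("truth does not match study (species pool differs)", call. = FALSE)
  cfg <- truth$config
  tr <- cfg$traits
  qn <- colnames(truth$species_means)
  ind <- study$individuals
  plots <- study$plots
  if (!all(ind$plot_id %in% plots$plot_id))
    stop("truth does not match study", call. = FALSE)
  sp_i <- match(ind$species_id, truth$species_id)
  plot_i <- match(ind$plot_id, plots$plot_id)
  age <- plots$successional_age
  rows <- list()
  for (tn in qn) {
    is_log <- tr$log_transform_for_lmm[match(tn, tr$name)]
    eta <- truth$species_means[sp_i, tn] +
      cfg$itv_strength[tn] * (age[plot_i] - truth$age_center) +
      cfg$ontogeny_slope[tn] * ind$h_rel +
      cfg$cii_slope[tn] * (ind$cii - 3)
    v <- if (is_log) exp(eta + cfg$noise_sd[tn]^2 / 2) else eta
    # specific = mean expected value over the plot's individuals; fixed =
    # abundance-weighted mean of each species' expected value averaged over
    # all its individuals in the forest type (own loops, not compute_cwm)
    for (f in unique(plots$forest_type)) {
      in_f <- plots$forest_type[plot_i] == f
      pl_f <- plots$plot_id[plots$forest_type == f]
      spec_cwm <- vapply(pl_f, function(p) mean(v[ind$plot_id == p]),
                         numeric(1))
      sp_mean_ft <- tapply(v[in_f], ind$species_id[in_f], mean)
      fixed_cwm <- vapply(pl_f, function(p) {
        s <- ind$species_id[ind$plot_id == p]
        mean(sp_mean_ft[s])
      }, numeric(1))
      itv_cwm <- spec_cwm - fixed_cwm
      a <- age[match(pl_f, plots$plot_id)]
      ss <- if (mode == "total") {
        c(sum((spec_cwm - mean(spec_cwm))^2),
          sum((fixed_cwm - mean(fixed_cwm))^2),
          sum((itv_cwm - mean(itv_cwm))^2))
      } else {
        expl <- function(y) {
          b <- sum((a - mean(a)) * (y - mean(y))) / sum((a - mean(a))^2)
          b^2 * sum((a - mean(a))^2)
        }
        c(expl(spec_cwm), expl(fixed_cwm), expl(itv_cwm))
      }
      pct <- if (ss[1] > 0) 100 * c(ss[2], ss[3],
                                    ss[1] - ss[2] - ss[3]) / ss[1]
             else c(NA_real_, NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        forest_type = f, trait = tn, mode = mode,
        pct_turnover = pct[1], pct_itv = pct[2], pct_cov = pct[3],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
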