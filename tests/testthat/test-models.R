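# build a minimal single-type study whose env columns we control directly
env_toy_study <- function(openness) {
  st <- toy_study()
  st$plots$canopy_openness_dry <- openness
  st
}

test_that("environment-age regressions recover a noiseless line", {
  st <- env_toy_study(-0.5 * c(10, 20, 30))
  chk <- env_gradient_check(st, "MIX", vars = "canopy_openness_dry")
  expect_equal(chk$slope, -0.5, tolerance = 1e-12)
  expect_lt(chk$p_value, 1e-10)
  # constant variable flagged, not tested
  st2 <- env_toy_study(rep(3, 3))
  chk2 <- env_gradient_check(st2, "MIX", vars = "canopy_openness_dry")
  expect_true(chk2$constant)
  expect_true(is.na(chk2$p_value))
})

test_that("p-values are uniform under the permutation null", {
  # a 6-plot study, one env variable independent of age by permutation
  st <- generate_study(small_config(seed = 61, n_plots = 6))$study
  st$plots <- st$plots[st$plots$forest_type == "MIX", ]
  st$individuals <- st$individuals[st$individuals$plot_id %in%
                                     st$plots$plot_id, ]
  set.seed(62)
  p <- replicate(999, {
    st$plots$canopy_openness_dry <- rnorm(6)   # fresh null replicate
    env_gradient_check(st, "MIX", vars = "canopy_openness_dry")$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("openness declines with age in the default synthetic world", {
  st <- generate_study(synthetic_config(seed = 63))$study
  for (f in c("MIX", "OAK")) {
    chk <- env_gradient_check(st, f)
    expect_lt(chk$slope[chk$variable == "canopy_openness_dry"], 0)
    expect_lt(chk$slope[chk$variable == "canopy_openness_wet"], 0)
  }
})

test_that("GLM backward selection drops a signal-free age term", {
  st <- toy_study()
  # equal proportions in every plot: both species present 1:1
  ind <- st$individuals
  ind$species_id <- rep(c("A", "B"), 3)
  ind$sla <- abs(ind$sla)
  st2 <- trait_study(st$traits, st$species, st$plots, ind)
  g <- fit_categorical_trait_glm(st2, "legume", "yes")
  expect_false("successional_age" %in% g$terms)
})

test_that("quasi-binomial coefficients match a from-scratch IRLS oracle", {
  # 4 plots, deciduous counts 8/10, 6/10, 4/10, 2/10, ages 10..40
  traits <- data.frame(name = c("sla", "phenology"),
                       kind = c("quantitative", "categorical"),
                       units = c("m2/kg", "class"),
                       log_transform_for_lmm = c(TRUE, FALSE))
  species <- data.frame(species_id = c("D", "E"), hmax = c(20, 20),
                        legume = FALSE,
                        phenology = c("deciduous", "evergreen"),
                        compoundness = "simple", pubescence = FALSE)
  plots <- data.frame(plot_id = paste0("P", 1:4), forest_type = "MIX",
                      successional_age = c(10, 20, 30, 40))
  k <- c(8, 6, 4, 2)
  ind <- do.call(rbind, lapply(1:4, function(i) data.frame(
    plot_id = paste0("P", i),
    species_id = rep(c("D", "E"), c(k[i], 10 - k[i])))))
  ind$individual_id <- paste0("i", seq_len(nrow(ind)))
  ind$height_class_midpoint <- 1.25
  ind$cii <- 3L
  ind$sla <- 10
  st <- trait_study(traits, species, plots, ind)
  g <- fit_categorical_trait_glm(st, "phenology", "deciduous", alpha = 1)
  # alpha = 1 blocks elimination so the full age model is compared

  # oracle: IRLS for binomial-logit iterated to 1e-10 (quasi-binomial has
  # identical coefficients; only the dispersion differs)
  X <- cbind(1, c(10, 20, 30, 40))
  y <- k / 10; n <- rep(10, 4)
  beta <- c(0, 0)
  for (it in 1:200) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- n * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta_new <- solve(t(X) %*% (W * X), t(X) %*% (W * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  expect_equal(unname(g$coefficients), drop(beta), tolerance = 1e-8)
  expect_gt(g$dispersion, 0)
})

test_that("separation and relabeling behave as documented", {
  st <- toy_study()          # species A deciduous, B evergreen
  ind <- st$individuals
  ind$species_id <- "A"      # every sapling deciduous: separation
  st2 <- trait_study(st$traits, st$species, st$plots, ind)
  expect_warning(g <- fit_categorical_trait_glm(st2, "phenology",
                                                "deciduous"),
                 "separation")
  expect_true(g$separation)

  # relabeling plots leaves fitted proportions invariant
  g1 <- fit_categorical_trait_glm(toy_study(), "phenology", "deciduous",
                                  alpha = 1)
  st3 <- toy_study()
  st3$plots$plot_id <- c("Z3", "Z1", "Z2")
  st3$individuals$plot_id <- rep(c("Z3", "Z1", "Z2"), each = 2)
  g2 <- fit_categorical_trait_glm(st3, "phenology", "deciduous", alpha = 1)
  expect_equal(sort(fitted(g1$fit)), sort(fitted(g2$fit)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("LMM with no species-level variance matches ordinary least squares", {
  # this seed reaches the variance boundary (restricted-likelihood estimate
  # of the species variance exactly 0), the degenerate hierarchy of interest
  cfg <- small_config(seed = 79, n_species = 20, species_sd = 0,
                      turnover_strength = 0, mean_abundance = 5, n_plots = 6)
  st <- generate_study(cfg)$study
  m <- fit_itv_lmm(st, "sla", select_fixed = FALSE)
  expect_equal(m$random_structure, "intercept")
  expect_true(m$singular)
  expect_equal(unname(m$variance_components["random"]), 0)
  # at the boundary the mixed model IS ordinary least squares
  ind <- st$individuals
  ft <- st$plots$forest_type[match(ind$plot_id, st$plots$plot_id)]
  ols <- lm(log(sla) ~ h_rel * factor(ft) + as.numeric(cii), data = ind)
  expect_equal(unname(m$fixed$estimate[m$fixed$term == "h_rel"]),
               unname(coef(ols)["h_rel"]), tolerance = 1e-8)
  # away from the boundary the estimated species variance stays negligible
  cfg2 <- small_config(seed = 71, n_species = 20, species_sd = 0,
                       turnover_strength = 0, mean_abundance = 5,
                       n_plots = 6)
  m2 <- fit_itv_lmm(generate_study(cfg2)$study, "sla", select_fixed = FALSE)
  expect_lt(m2$variance_components["random"] /
              m2$variance_components["residual"], 0.05)
})

test_that("LMM invariants hold and selection is deterministic", {
  st <- generate_study(small_config(seed = 72, mean_abundance = 3))$study
  m1 <- fit_itv_lmm(st, "sla")
  m2 <- fit_itv_lmm(st, "sla")
  expect_identical(m1$fixed, m2$fixed)
  expect_identical(m1$random_structure, m2$random_structure)
  expect_lte(m1$r2_marginal, m1$r2_conditional + 1e-12)
  expect_gte(m1$r2_marginal, 0)
  expect_lte(m1$r2_conditional, 1 + 1e-12)
  expect_true(all(m1$variance_components >= 0))
  # non-positive values cannot be logged
  st$individuals$sla[3] <- -1
  expect_error(fit_itv_lmm(st, "sla"), "non-positive")
})
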