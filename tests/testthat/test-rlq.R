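test_that("single-variable eigenvalue equals the squared fourth-corner covariance", {
  set.seed(201)
  for (i in 1:5) {
    L <- matrix(rpois(24, 2) + 1, 4, 6)
    env <- rnorm(4); tra <- rnorm(6)
    res <- rlq(data.frame(e = env), L, data.frame(t = tra), n_axes = 1)
    expect_equal(res$eig[1], fourth_corner_cov(env, L, tra)^2,
                 tolerance = 1e-10)
  }
})

test_that("trace identity and maximality hold on random instances", {
  set.seed(202)
  for (i in 1:10) {
    inst <- random_rlq_instance()
    res <- rlq(inst$R, inst$L, inst$Q, n_axes = 3)
    expect_equal(sum(res$eig), res$trace, tolerance = 1e-10)
    # first eigenvalue maximizes the squared cross-covariance over unit
    # coefficient pairs (Monte Carlo)
    P <- inst$L / sum(inst$L)
    X <- traitflux:::.scale_mixed(inst$R, rowSums(P))
    Y <- traitflux:::.scale_mixed(inst$Q, colSums(P))
    M <- t(X) %*% (P - outer(rowSums(P), colSums(P))) %*% Y
    for (k in 1:100) {
      u <- rnorm(ncol(X)); u <- u / sqrt(sum(u^2))
      v <- rnorm(ncol(Y)); v <- v / sqrt(sum(v^2))
      expect_lte(drop(t(u) %*% M %*% v)^2, res$eig[1] + 1e-12)
    }
  }
})

test_that("axis percentages and contributions close to 100", {
  set.seed(203)
  inst <- random_rlq_instance(n_plots = 6, n_obs = 10, p_env = 3)
  res <- rlq(inst$R, inst$L, inst$Q, n_axes = 2)
  expect_equal(sum(res$axis_pct), 100, tolerance = 1e-9)
  expect_equal(unname(colSums(res$env_contrib)), c(100, 100),
               tolerance = 1e-9)
  expect_equal(unname(colSums(res$trait_contrib)), c(100, 100),
               tolerance = 1e-9)
})

test_that("eigenvalues are invariant to rescaling an environment variable", {
  set.seed(204)
  inst <- random_rlq_instance()
  r1 <- rlq(inst$R, inst$L, inst$Q)
  inst$R[[1]] <- inst$R[[1]] * 1000
  r2 <- rlq(inst$R, inst$L, inst$Q)
  expect_equal(r1$eig, r2$eig, tolerance = 1e-10)
})

test_that("permutation null behaves at chance level without signal", {
  set.seed(205)
  inst <- random_rlq_instance(n_plots = 6, n_obs = 12)
  obs <- rlq(inst$R, inst$L, inst$Q)$eig[1]
  perm <- replicate(199, {
    rlq(inst$R, inst$L, inst$Q[sample(nrow(inst$Q)), , drop = FALSE])$eig[1]
  })
  p <- (1 + sum(perm >= obs)) / 200
  expect_gt(p, 0.01)   # no built-in signal: observed not extreme
})

test_that("L contract violations are rejected", {
  inst <- random_rlq_instance()
  L <- inst$L; L[1, ] <- 0
  expect_error(rlq(inst$R, L, inst$Q), "empty row")
  L <- inst$L; L[, 2] <- 0
  expect_error(rlq(inst$R, L, inst$Q), "empty column")
  expect_error(rlq(inst$R[-1, , drop = FALSE], inst$L, inst$Q), "align")
})

test_that("partial RLQ separates among- from within-species structure", {
  # zero ITV: within-species deviations vanish, so do the eigenvalues
  cfg <- small_config(seed = 51, itv_strength = 0, ontogeny_slope = 0,
                      cii_slope = 0, noise_sd = 1e-9)
  st <- generate_study(cfg)$study
  wi <- partial_rlq(st, "MIX", "within_species")
  expect_lt(max(wi$eig), 1e-12)

  # a single species: no between-species structure after centring.
  # Keep only the most widespread species of MIX (and the plots it occupies).
  sp_counts <- table(st$individuals$species_id[
    st$individuals$plot_id %in%
      st$plots$plot_id[st$plots$forest_type == "MIX"]])
  top <- names(sort(sp_counts, decreasing = TRUE))[1]
  ind1 <- st$individuals[st$individuals$species_id == top, ]
  ind1$h_rel <- NULL
  pl1 <- st$plots[st$plots$plot_id %in% ind1$plot_id, ]
  st1 <- trait_study(st$traits, st$species, pl1, ind1)
  am1 <- partial_rlq(st1, "MIX", "among_species")
  expect_lt(max(am1$eig), 1e-12)
})

test_that("partial analyses agree with a test-side reconstruction of the split", {
  g <- generate_study(small_config(seed = 52))
  st <- g$study
  plots <- st$plots[st$plots$forest_type == "MIX", ]
  ind <- st$individuals[st$individuals$plot_id %in% plots$plot_id, ]
  qt <- quantitative_traits(st)
  n <- nrow(ind)

  # rebuild L, P and the scaled tables exactly as documented
  L <- matrix(0, nrow(plots), n, dimnames = list(plots$plot_id, NULL))
  L[cbind(match(ind$plot_id, plots$plot_id), seq_len(n))] <- 1
  P <- L / sum(L)
  env_vars <- intersect(c("successional_age", "canopy_openness_dry",
                          "canopy_openness_wet", "air_temp_dry",
                          "air_temp_wet", "soil_moisture_dry",
                          "soil_moisture_wet", "adult_basal_area",
                          "soil_ph", "soil_clay"), names(plots))
  X <- traitflux:::.scale_mixed(plots[, env_vars], rowSums(P))
  # categorical traits at the species level, as partial_rlq builds them
  Qraw <- ind[, qt]
  sp_row <- match(ind$species_id, st$species$species_id)
  for (tn in categorical_traits(st)) {
    v <- st$species[[tn]][sp_row]
    if (is.logical(v)) v <- ifelse(v, "yes", "no")
    if (length(unique(v)) < 2) next
    Qraw[[tn]] <- factor(v)
  }
  Y <- traitflux:::.scale_mixed(Qraw, colSums(P))
  Ymean <- apply(Y, 2, function(col) ave(col, ind$species_id))
  P0 <- P - outer(rowSums(P), colSums(P))
  eig_of <- function(Ypart) {
    d <- svd(t(X) %*% P0 %*% Ypart)$d
    d^2
  }
  is_cat <- attr(Y, "variable") %in% categorical_traits(st)

  am <- partial_rlq(st, "MIX", "among_species")
  wi <- partial_rlq(st, "MIX", "within_species")
  k <- length(am$eig)
  expect_equal(am$eig, eig_of(Ymean)[seq_len(k)], tolerance = 1e-10)
  expect_equal(wi$eig,
               eig_of((Y - Ymean)[, !is_cat, drop = FALSE])[
                 seq_len(length(wi$eig))], tolerance = 1e-10)
  # among + within reconstruct the scaled raw table (machine precision);
  # categorical columns have no within-species part at all
  expect_equal(Ymean + (Y - Ymean), Y, tolerance = 1e-14)
  expect_lt(max(abs((Y - Ymean)[, is_cat])), 1e-12)
  # singleton species are flagged for the within analysis
  expect_type(attr(wi, "singleton_species"), "character")
})
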