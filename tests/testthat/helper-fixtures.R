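# Shared fixtures and independent oracles used across test files.

# small synthetic config: few species/plots/traits so property loops stay fast
small_config <- function(seed, n_species = 12, n_plots = 4,
                         traits = c("sla", "lnc", "thickness"),
                         mean_abundance = 1.5, ...) {
  tr <- default_synthetic_traits()
  tr <- tr[tr$name %in% c(traits, "phenology", "compoundness", "pubescence",
                          "legume"), ]
  synthetic_config(seed = seed, n_species = n_species,
                   n_plots_per_type = n_plots, traits = tr,
                   mean_abundance = mean_abundance, ...)
}

# canonical recovery worlds (see the methods vignette): turnover-only —
# within-species effects switched off, so specific == fixed up to noise;
# ITV-only — flat niches and identical species means, so the fixed series
# carries (almost) no signal, with linear-scale traits to keep the
# generating model exactly additive
pure_turnover_config <- function(seed) {
  small_config(seed = seed, itv_strength = 0, ontogeny_slope = 0,
               cii_slope = 0, noise_sd = 1e-9)
}

pure_itv_config <- function(seed) {
  tr <- default_synthetic_traits()
  tr <- tr[tr$name %in% c("thickness", "lnc"), ]
  # high abundance: with flat niches the only "turnover" left is the Monte
  # Carlo remnant of which plots a species happens to occupy, and it shrinks
  # as 1/sqrt(individuals per species)
  synthetic_config(seed = seed, n_species = 5, n_plots_per_type = 6,
                   niche_width = Inf, mean_abundance = 40, traits = tr,
                   turnover_strength = 0, species_sd = 0,
                   ontogeny_slope = 0, cii_slope = 0,
                   itv_strength = 0.05, noise_sd = 1e-9)
}

# brute-force Kendall tau-b by exhaustive pair enumeration (oracle)
kendall_bruteforce <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; n1 <- 0; n2 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0) n1 <- n1 + 1
    if (sy == 0) n2 <- n2 + 1
    if (sx != 0 && sy != 0) {
      if (sx == sy) C <- C + 1 else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# weighted correlation matrix (oracle for the all-quantitative ordination)
weighted_cor <- function(X, w) {
  w <- w / sum(w)
  Z <- apply(X, 2, function(x) {
    mu <- sum(w * x); (x - mu) / sqrt(sum(w * (x - mu)^2))
  })
  crossprod(Z * w, Z)
}

# fourth-corner covariance by explicit double sum over the frequency table
# (oracle for the single-variable RLQ eigenvalue)
fourth_corner_cov <- function(env, L, tra) {
  P <- L / sum(L)
  r <- rowSums(P); cc <- colSums(P)
  x <- (env - sum(r * env)) / sqrt(sum(r * (env - sum(r * env))^2))
  y <- (tra - sum(cc * tra)) / sqrt(sum(cc * (tra - sum(cc * tra))^2))
  s <- 0
  for (j in seq_along(r)) for (k in seq_along(cc))
    s <- s + (P[j, k] - r[j] * cc[k]) * x[j] * y[k]
  s
}

# random small RLQ instance (all-quantitative)
random_rlq_instance <- function(n_plots = 5, n_obs = 8, p_env = 2,
                                p_trait = 3) {
  L <- matrix(rpois(n_plots * n_obs, 2) + 1, n_plots, n_obs)
  R <- as.data.frame(matrix(rnorm(n_plots * p_env), n_plots, p_env))
  Q <- as.data.frame(matrix(rnorm(n_obs * p_trait), n_obs, p_trait))
  list(R = R, L = L, Q = Q)
}
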