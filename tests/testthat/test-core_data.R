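test_that("read/write round-trip reproduces the tables cell-for-cell", {
  st <- toy_study()
  d <- withr::local_tempdir()
  write_study(st, d)
  st2 <- read_study(d)
  expect_equal(st2$traits, st$traits)
  expect_equal(st2$species, st$species)
  expect_equal(st2$plots, st$plots)
  expect_equal(st2$individuals, st$individuals)

  # and for a generated study with missing values injected
  g <- generate_study(small_config(seed = 11))
  st3 <- g$study
  st3$individuals$sla[c(2, 5)] <- NA
  d2 <- withr::local_tempdir()
  write_study(st3, d2)
  st4 <- read_study(d2)
  expect_equal(st4$individuals, st3$individuals)
  expect_equal(st4$plots, st3$plots, tolerance = 1e-12)
})

test_that("construction and I/O errors are specific", {
  st <- toy_study()
  bad <- st$individuals
  bad$plot_id[2] <- "P99"
  expect_error(trait_study(st$traits, st$species, st$plots, bad),
               "unknown plot_id.*rows 2")
  d <- withr::local_tempdir()
  write_study(st, d)
  tr <- utils::read.csv(file.path(d, "traits.csv"))
  tr$kind <- NULL
  utils::write.csv(tr, file.path(d, "traits.csv"), row.names = FALSE)
  expect_error(read_study(d), "missing required column.*kind")

  # non-numeric entry in a quantitative column reports row and column
  write_study(st, d)
  ind <- utils::read.csv(file.path(d, "individuals.csv"))
  ind$sla <- as.character(ind$sla)
  ind$sla[3] <- "oops"
  utils::write.csv(ind, file.path(d, "individuals.csv"), row.names = FALSE)
  expect_error(read_study(d), "non-numeric.*'sla'.*3")
})

test_that("imputation follows the species-plot / species-type / type hierarchy", {
  st <- toy_study()
  ind <- st$individuals
  # add a third A individual in P1 with missing value -> mean(10, 12) = 11
  extra <- ind[1, ]
  extra$individual_id <- "i7"; extra$sla <- NA
  st2 <- trait_study(st$traits, st$species, st$plots, rbind(ind, extra))
  imp <- impute_missing_traits(st2)
  expect_equal(imp$individuals$sla[7], 11)
  lg <- attr(imp, "imputation_log")
  expect_equal(lg$rule, "species_plot")

  # species B in P1 where it was never measured -> forest-type species mean
  extra$individual_id <- "i8"; extra$species_id <- "B"
  st3 <- trait_study(st$traits, st$species, st$plots, rbind(ind, extra))
  imp3 <- impute_missing_traits(st3)
  expect_equal(imp3$individuals$sla[7], 22)  # mean(20, 22, 24)
  expect_equal(attr(imp3, "imputation_log")$rule, "species_forest_type")

  # species never measured anywhere -> forest-type grand mean
  sp <- rbind(st$species,
              data.frame(species_id = "C", hmax = 10, legume = FALSE,
                         phenology = "deciduous", compoundness = "simple",
                         pubescence = FALSE))
  extra$species_id <- "C"
  st4 <- trait_study(st$traits, sp, st$plots, rbind(ind, extra))
  imp4 <- impute_missing_traits(st4)
  expect_equal(imp4$individuals$sla[7], mean(c(10, 12, 14, 20, 22, 24)))
  expect_equal(attr(imp4, "imputation_log")$rule, "forest_type")

  # measured values never altered; imputation idempotent
  expect_equal(imp4$individuals$sla[1:6], ind$sla)
  expect_equal(impute_missing_traits(imp4)$individuals,
               imp4$individuals)

  # trait entirely unmeasured in a forest type is an error
  ind5 <- ind; ind5$sla <- NA_real_
  st5 <- trait_study(st$traits, st$species, st$plots, ind5)
  expect_error(impute_missing_traits(st5), "no measured value")
})

test_that("masked values are recovered with positive correlation", {
  g <- generate_study(synthetic_config(seed = 21, n_species = 30))
  st <- g$study
  set.seed(42)
  for (tn in c("sla", "lnc")) {
    v <- st$individuals[[tn]]
    mask <- sample(length(v), round(0.05 * length(v)))
    truth_vals <- v[mask]
    st$individuals[[tn]][mask] <- NA
    imp <- impute_missing_traits(st, traits = tn)
    expect_gt(cor(imp$individuals[[tn]][mask], truth_vals), 0)
    st$individuals[[tn]] <- v
  }
})

test_that("Sorensen similarity matches set arithmetic and its properties", {
  expect_equal(sorensen_similarity(c("s1", "s2"), c("s2", "s1")), 1)
  expect_equal(sorensen_similarity(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  expect_error(sorensen_similarity(character(0), "a"), "empty")
  set.seed(7)
  pool <- letters
  for (i in 1:25) {
    a <- sample(pool, sample(1:10, 1))
    b <- sample(pool, sample(1:10, 1))
    s <- sorensen_similarity(a, b)
    expect_identical(s, sorensen_similarity(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_identical(s == 0, length(intersect(a, b)) == 0)
  }
  ps <- plot_sorensen(toy_study(), "MIX")
  expect_equal(nrow(ps), 3)
  expect_equal(ps$similarity[ps$plot_a == "P1" & ps$plot_b == "P2"], 2 / 3)
})

test_that("Kendall tau-b matches brute-force pair counting and cor.test", {
  expect_equal(kendall_tau(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau(1:4, c(2, 1, 4, 3))$tau,
               kendall_bruteforce(1:4, c(2, 1, 4, 3)))
  set.seed(5)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    x <- sample(1:5, n, replace = TRUE)   # ties guaranteed
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    kt <- kendall_tau(x, y)
    expect_equal(kt$tau, kendall_bruteforce(x, y), tolerance = 1e-12)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    expect_equal(kt$tau, unname(ct$estimate), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  x <- c(3, 1, 4, 1, 5, 9, 2, 6); y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  expect_equal(kendall_tau(exp(x), y)$tau, kendall_tau(x, y)$tau)
  expect_equal(kendall_tau(x, 2 * y + 1)$tau, kendall_tau(x, y)$tau)
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})
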