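#' Environment-vs-age sanity checks
#'
#' Regresses every environment variable on successional age within a forest
#' type (ordinary least squares, two-sided p). Used to verify the expected
#' successional pattern — the below-canopy environment growing cooler and
#' darker — and to flag soil variables that would confound the gradient.
#'
#' @param study a [trait_study]
#' @param forest_type forest type to analyse
#' @param vars environment columns (default: every canonical one present)
#' @return data frame `variable`, `slope`, `p_value`, `signif`
#'   (`"p<0.05"`, `"p<0.1"` or `"ns"`), `constant` (flag; no test performed)
#' @export
env_gradient_check <- function(study, forest_type, vars = NULL) {
  stopifnot(inherits(study, "trait_study"))
  pl <- study$plots[study$plots$forest_type == forest_type, , drop = FALSE]
  if (nrow(pl) < 3) stop("need >= 3 plots", call. = FALSE)
  if (is.null(vars)) vars <- intersect(.tf_env_cols, names(pl))
  age <- pl$successional_age
  rows <- lapply(vars, function(v) {
    x <- pl[[v]]
    if (length(unique(x)) < 2) {
      return(data.frame(variable = v, slope = NA_real_, p_value = NA_real_,
                        signif = NA_character_, constant = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit <- .ols_line(x, age)
    data.frame(
      variable = v, slope = fit$slope, p_value = fit$p,
      signif = if (fit$p < 0.05) "p<0.05" else if (fit$p < 0.1) "p<0.1"
               else "ns",
      constant = FALSE, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Quasi-binomial model for the community proportion of a categorical trait
#'
#' For traits without recorded intraspecific variation (phenology,
#' compoundness, pubescence, legume status) the community response to
#' succession is the change in the proportion of saplings carrying a given
#' level. That proportion is modelled per plot with a quasi-binomial GLM
#' (logit link, dispersion estimated to absorb overdispersion) with
#' successional age, forest type and their interaction as candidate terms,
#' followed by backward elimination: at each step the least significant
#' droppable term (quasi-F test, threshold `alpha`) is removed, the
#' interaction always before its main effects.
#'
#' @param study a [trait_study]
#' @param trait name of a categorical/binary trait (a species column)
#' @param level target level; for binary traits `TRUE`/`"yes"`/1 are
#'   equivalent
#' @param alpha elimination threshold on the F-test p-value (default 0.05)
#' @return list of class `glm_result`: `trait`, `level`, `terms` (retained),
#'   `coefficients`, `dispersion`, `term_tests` (F-test table of the final
#'   model), `pseudo_r2` (1 - residual/null deviance), `separation` flag,
#'   `data` (per-plot counts), `fit` (the final `glm` object).
#' @export
fit_categorical_trait_glm <- function(study, trait, level = NULL,
                                      alpha = 0.05) {
  stopifnot(inherits(study, "trait_study"))
  if (!trait %in% categorical_traits(study))
    stop("'", trait, "' is not a categorical trait of this study",
         call. = FALSE)
  sp_val <- study$species[[trait]]
  if (is.logical(sp_val) || all(sp_val %in% c(0, 1))) {
    sp_val <- ifelse(sp_val == 1 | sp_val == TRUE, "yes", "no")
    if (is.null(level)) level <- "yes"
    if (isTRUE(level) || identical(level, 1)) level <- "yes"
  }
  if (is.null(level))
    stop("a target level must be given for a multi-level trait",
         call. = FALSE)
  ind <- study$individuals
  has_level <- sp_val[match(ind$species_id, study$species$species_id)] == level
  k <- tapply(has_level, ind$plot_id, sum)
  n <- tapply(has_level, ind$plot_id, length)
  pl <- study$plots[match(names(k), study$plots$plot_id), ]
  dat <- data.frame(
    plot_id = names(k), k = as.integer(k), n = as.integer(n),
    successional_age = pl$successional_age,
    forest_type = factor(pl$forest_type), stringsAsFactors = FALSE
  )
  separation <- all(dat$k == 0) || all(dat$k == dat$n)

  two_ft <- nlevels(dat$forest_type) > 1
  form <- if (two_ft)
    cbind(k, n - k) ~ successional_age * forest_type
  else cbind(k, n - k) ~ successional_age
  ctl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  fit <- stats::glm(form, family = stats::quasibinomial(), data = dat,
                    control = ctl)

  if (!separation) {
    repeat {
      d1 <- stats::drop1(fit, test = "F")
      cand <- d1[rownames(d1) != "<none>", , drop = FALSE]
      if (!nrow(cand)) break
      p <- cand[["Pr(>F)"]]
      # an NA p (perfect fit, zero dispersion) carries no evidence for the
      # term: treat as most droppable. Ties broken by dropping the
      # higher-order term first; drop1 candidates already respect marginality
      p[is.na(p)] <- Inf
      ord <- order(-p, -attr(stats::terms(fit), "order")[
        match(rownames(cand), attr(stats::terms(fit), "term.labels"))])
      worst <- ord[1]
      if (p[worst] <= alpha) break
      fit <- stats::update(fit, stats::as.formula(
        paste(". ~ . -", rownames(cand)[worst])))
      if (length(attr(stats::terms(fit), "term.labels")) == 0) break
    }
  } else {
    warning("complete separation: all plot proportions are 0 or 1; ",
            "coefficients reported without selection")
  }

  d_final <- if (length(attr(stats::terms(fit), "term.labels")))
    stats::drop1(fit, test = "F") else NULL
  structure(list(
    trait = trait, level = level,
    terms = attr(stats::terms(fit), "term.labels"),
    coefficients = stats::coef(fit),
    dispersion = summary(fit)$dispersion,
    term_tests = d_final,
    pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
    separation = separation, data = dat, fit = fit
  ), class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat("<glm_result> proportion of level '", x$level, "' of trait '",
      x$trait, "'\n", sep = "")
  cat("  retained terms:",
      if (length(x$terms)) paste(x$terms, collapse = ", ") else "(none)",
      "\n")
  print(round(x$coefficients, 4))
  cat("  dispersion:", format(x$dispersion, digits = 4),
      " pseudo-R2:", format(x$pseudo_r2, digits = 3), "\n")
  invisible(x)
}

# total random-effect variance of a (possibly random-slope) species term,
# averaged over the observed h_rel design
.ranef_variance <- function(fit, dat) {
  vc <- lme4::VarCorr(fit)$species_id
  if (is.null(vc)) return(0)
  if (nrow(vc) == 1) return(vc[1, 1])
  h <- dat$h_rel
  vc["(Intercept)", "(Intercept)"] +
    2 * vc["(Intercept)", "h_rel"] * mean(h) +
    vc["h_rel", "h_rel"] * mean(h^2)
}

#' Mixed model for intraspecific trait change with ontogeny and light
#'
#' Models the natural log of an individual sapling's mean trait value as a
#' function of relative height (H/Hmax, the ontogeny proxy), forest type,
#' their interaction, and the crown illumination index (CII, numeric), with
#' species as a random factor. Two random structures are compared by AIC on
#' restricted-likelihood fits sharing the full fixed part: random intercept
#' only, or random intercept plus random slope of H/Hmax (does the
#' ontogenetic trend differ among species?). Fixed terms are then selected
#' backward by AIC on full-likelihood fits, and the final model is refitted
#' by restricted likelihood.
#'
#' Only species with at least one individual in two different height classes
#' of the same forest type are included.
#'
#' @param study a [trait_study] (imputed)
#' @param trait quantitative trait name; values must be positive (they are
#'   log-transformed)
#' @param select_fixed if `FALSE`, keep the full fixed part (no AIC
#'   elimination)
#' @return list of class `lmm_result`: `trait`, `random_structure`
#'   (`"intercept"` or `"intercept_slope"`), `fixed` (coefficient table with
#'   Wald t p-values, df = n - p), `r2_marginal`, `r2_conditional`,
#'   `variance_components` (`fixed`, `random`, `residual`), `n_individuals`,
#'   `n_species`, `singular` flag, `fit` (the final `lmerMod`).
#' @references Marginal and conditional R2 follow the variance-components
#'   convention of Nakagawa & Schielzeth (2013), with the random-slope
#'   contribution averaged over the observed H/Hmax design.
#' @export
fit_itv_lmm <- function(study, trait, select_fixed = TRUE) {
  stopifnot(inherits(study, "trait_study"))
  if (!trait %in% quantitative_traits(study))
    stop("'", trait, "' is not a quantitative trait", call. = FALSE)
  ind <- study$individuals
  ft <- study$plots$forest_type[match(ind$plot_id, study$plots$plot_id)]

  # eligibility: >= 2 distinct height classes within one forest type
  key <- paste(ind$species_id, ft)
  n_classes <- tapply(ind$height_class_midpoint, key,
                      function(h) length(unique(h)))
  ok_sp <- unique(ind$species_id[n_classes[key] >= 2])
  sel <- ind$species_id %in% ok_sp & !is.na(ind[[trait]])
  dat <- data.frame(
    y = ind[[trait]][sel], h_rel = ind$h_rel[sel],
    cii = as.numeric(ind$cii[sel]),
    forest_type = factor(ft[sel]),
    species_id = factor(ind$species_id[sel]), stringsAsFactors = FALSE
  )
  if (any(dat$y <= 0)) {
    bad <- which(dat$y <= 0)
    stop("non-positive values of '", trait, "' cannot be log-transformed ",
         "(rows ", paste(utils::head(bad, 10), collapse = ", "), ")",
         call. = FALSE)
  }
  dat$logy <- log(dat$y)
  two_ft <- nlevels(dat$forest_type) > 1

  fixed_full <- if (two_ft) "h_rel * forest_type + cii" else "h_rel + cii"
  f_int <- stats::as.formula(paste("logy ~", fixed_full, "+ (1 | species_id)"))
  f_slp <- stats::as.formula(paste("logy ~", fixed_full,
                                   "+ (1 + h_rel | species_id)"))
  ctl <- lme4::lmerControl(check.conv.singular = "ignore",
                           calc.derivs = FALSE)
  m_int <- lme4::lmer(f_int, data = dat, REML = TRUE, control = ctl)
  m_slp <- tryCatch(
    lme4::lmer(f_slp, data = dat, REML = TRUE, control = ctl),
    error = function(e) NULL)
  use_slope <- !is.null(m_slp) &&
    stats::AIC(m_slp) < stats::AIC(m_int)
  ran_term <- if (use_slope) "(1 + h_rel | species_id)" else
    "(1 | species_id)"

  terms_now <- if (two_ft) c("h_rel", "forest_type", "cii",
                             "h_rel:forest_type")
               else c("h_rel", "cii")
  if (select_fixed) {
    refit_ml <- function(terms) {
      rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
      lme4::lmer(stats::as.formula(paste("logy ~", rhs, "+", ran_term)),
                 data = dat, REML = FALSE, control = ctl)
    }
    aic_now <- stats::AIC(refit_ml(terms_now))
    repeat {
      droppable <- terms_now[vapply(terms_now, function(tt) {
        # marginality: a main effect is droppable only if no retained
        # interaction contains it
        !any(grepl(":", terms_now) &
               vapply(strsplit(terms_now, ":"), function(p) tt %in% p,
                      logical(1)) & terms_now != tt)
      }, logical(1))]
      if (!length(droppable)) break
      # interactions first so AIC ties resolve toward the higher-order term
      droppable <- droppable[order(!grepl(":", droppable))]
      aics <- vapply(droppable, function(tt)
        stats::AIC(refit_ml(setdiff(terms_now, tt))), numeric(1))
      if (min(aics) < aic_now) {
        terms_now <- setdiff(terms_now, droppable[which.min(aics)])
        aic_now <- min(aics)
      } else break
    }
  }

  rhs <- if (length(terms_now)) paste(terms_now, collapse = " + ") else "1"
  fit <- lme4::lmer(stats::as.formula(paste("logy ~", rhs, "+", ran_term)),
                    data = dat, REML = TRUE, control = ctl)
  singular <- lme4::isSingular(fit, tol = 1e-5)

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  df <- nrow(dat) - length(beta)
  tval <- beta / se
  fixed <- data.frame(
    term = names(beta), estimate = as.numeric(beta), se = se, t = tval,
    p_value = 2 * stats::pt(-abs(tval), df), stringsAsFactors = FALSE
  )
  rownames(fixed) <- NULL

  X <- stats::model.matrix(fit)
  fx <- as.numeric(X %*% beta)
  v_f <- mean((fx - mean(fx))^2)
  v_r <- .ranef_variance(fit, dat)
  v_e <- stats::sigma(fit)^2
  structure(list(
    trait = trait,
    random_structure = if (use_slope) "intercept_slope" else "intercept",
    fixed = fixed,
    r2_marginal = v_f / (v_f + v_r + v_e),
    r2_conditional = (v_f + v_r) / (v_f + v_r + v_e),
    variance_components = c(fixed = v_f, random = v_r, residual = v_e),
    n_individuals = nrow(dat), n_species = nlevels(dat$species_id),
    singular = singular, fit = fit
  ), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result> log(", x$trait, ") on ", x$n_individuals,
      " individuals of ", x$n_species, " species\n", sep = "")
  cat("  random part:", if (x$random_structure == "intercept_slope")
    "intercept + slope of h_rel" else "intercept only",
    if (x$singular) "(singular fit)" else "", "\n")
  print(transform(x$fixed, estimate = round(estimate, 3),
                  se = round(se, 3), t = round(t, 2),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  cat("  R2 marginal:", round(x$r2_marginal, 3),
      " conditional:", round(x$r2_conditional, 3), "\n")
  invisible(x)
}
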