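#' Community-weighted mean of a trait, specific or fixed flavour
#'
#' The specific CWM of a plot uses the mean trait value of each species *in
#' that plot*; plot-to-plot change in it reflects both species turnover and
#' intraspecific shifts. The fixed CWM uses each species' mean computed
#' *across all plots of the same forest type*; it can only change through
#' turnover. Their difference isolates the intraspecific (ITV) component.
#' Weights are the relative abundances of the species in the plot (counts of
#' surveyed individuals).
#'
#' @param study a [trait_study], imputed (no missing values in `trait`)
#' @param trait name of a quantitative trait
#' @param mode `"specific"` or `"fixed"`
#' @param forest_type optional: restrict to the plots of one forest type
#' @return named numeric vector of CWM values, one per plot
#' @seealso [cwm_table()], [decompose_total()], [decompose_vs_gradient()]
#' @export
compute_cwm <- function(study, trait,
                        mode = c("specific", "fixed"),
                        forest_type = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(study, "trait_study"))
  if (!trait %in% quantitative_traits(study))
    stop("'", trait, "' is not a quantitative trait of this study",
         call. = FALSE)
  plots <- study$plots
  if (!is.null(forest_type)) plots <- plots[plots$forest_type %in% forest_type, ]
  ind <- study$individuals
  ind <- ind[ind$plot_id %in% plots$plot_id, , drop = FALSE]
  v <- ind[[trait]]
  if (anyNA(v))
    stop("trait '", trait, "' has missing values; run impute_missing_traits()",
         call. = FALSE)
  ft_of_ind <- plots$forest_type[match(ind$plot_id, plots$plot_id)]

  out <- numeric(nrow(plots))
  names(out) <- plots$plot_id
  for (k in seq_len(nrow(plots))) {
    p <- plots$plot_id[k]
    in_p <- ind$plot_id == p
    if (!any(in_p)) stop("plot '", p, "' has no individuals", call. = FALSE)
    sp <- ind$species_id[in_p]
    w <- table(sp) / sum(in_p)           # relative abundance, sums to 1
    sp_mean <- if (mode == "specific") {
      tapply(v[in_p], sp, mean)
    } else {
      in_ft <- ft_of_ind == plots$forest_type[k]
      tapply(v[in_ft], ind$species_id[in_ft], mean)[names(w)]
    }
    out[k] <- sum(w * sp_mean[names(w)])
  }
  out
}

#' Specific, fixed and intraspecific CWM for every plot and trait
#'
#' @param study a [trait_study] (imputed)
#' @param traits quantitative trait names (default: all)
#' @return data frame with columns `plot_id`, `forest_type`,
#'   `successional_age`, `trait`, `cwm_specific`, `cwm_fixed`, `cwm_itv`;
#'   `cwm_specific = cwm_fixed + cwm_itv` holds exactly by construction.
#' @export
cwm_table <- function(study, traits = quantitative_traits(study)) {
  stopifnot(inherits(study, "trait_study"))
  pieces <- lapply(traits, function(tn) {
    sp <- compute_cwm(study, tn, "specific")
    fx <- compute_cwm(study, tn, "fixed")
    data.frame(
      plot_id = study$plots$plot_id,
      forest_type = study$plots$forest_type,
      successional_age = study$plots$successional_age,
      trait = tn,
      cwm_specific = as.numeric(sp),
      cwm_fixed = as.numeric(fx),
      cwm_itv = as.numeric(sp - fx),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, pieces)
}

# among-plot sum of squared deviations from the mean
.ss_dev <- function(x) sum((x - mean(x))^2)

# OLS of y on x: slope, two-sided p (t distribution), explained SS
.ols_line <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  ss_exp <- slope^2 * sxx
  rss <- .ss_dev(y) - ss_exp
  df <- n - 2
  p <- if (df > 0 && rss > 1e-300) {
    se <- sqrt(rss / df / sxx)
    2 * stats::pt(-abs(slope / se), df)
  } else if (df > 0) 0 else NA_real_
  list(slope = slope, p = p, ss_explained = ss_exp)
}

.decomp_row <- function(forest_type, trait, ss_total, ss_turn, ss_itv,
                        slopes = NULL, degenerate = FALSE) {
  ss_cov <- ss_total - ss_turn - ss_itv
  if (degenerate || ss_total <= 0) {
    pct <- c(NA_real_, NA_real_, NA_real_)
    degenerate <- TRUE
  } else {
    pct <- 100 * c(ss_turn, ss_itv, ss_cov) / ss_total
  }
  out <- data.frame(
    forest_type = forest_type, trait = trait,
    ss_total = ss_total, ss_turnover = ss_turn, ss_itv = ss_itv,
    ss_cov = ss_cov,
    pct_turnover = pct[1], pct_itv = pct[2], pct_cov = pct[3],
    degenerate = degenerate, stringsAsFactors = FALSE
  )
  if (!is.null(slopes)) {
    out$slope_turnover <- slopes$turn$slope
    out$p_turnover <- slopes$turn$p
    out$slope_itv <- slopes$itv$slope
    out$p_itv <- slopes$itv$p
    out$slope_total <- slopes$tot$slope
    out$p_total <- slopes$tot$p
  }
  out
}

#' Partition total among-plot variation of community trait values
#'
#' Decomposes the among-plot sum of squares of the specific CWM (deviations
#' from the forest-type mean) into the part attributable to species turnover
#' (SS of the fixed CWM series), the part attributable to intraspecific
#' variation (SS of the ITV series), and their covariation (obtained by
#' subtraction; negative when turnover and ITV push community values in
#' opposite directions). Contributions are expressed as percentages of the
#' total SS and sum to 100.
#'
#' @param study a [trait_study] (imputed)
#' @param traits quantitative trait names (default: all)
#' @param forest_type forest type(s) to analyse separately (default: all
#'   present)
#' @return data frame, one row per forest type x trait, with columns
#'   `ss_total`, `ss_turnover`, `ss_itv`, `ss_cov`, `pct_*` and a
#'   `degenerate` flag (TRUE when all plots are identical so that
#'   contributions are undefined; percentages are then NA rather than NaN).
#' @export
decompose_total <- function(study, traits = quantitative_traits(study),
                            forest_type = unique(study$plots$forest_type)) {
  rows <- list()
  for (f in forest_type) {
    npl <- sum(study$plots$forest_type == f)
    if (npl < 3) stop("need >= 3 plots in forest type '", f, "'",
                      call. = FALSE)
    for (tn in traits) {
      sp <- compute_cwm(study, tn, "specific", forest_type = f)
      fx <- compute_cwm(study, tn, "fixed", forest_type = f)
      itv <- sp - fx
      rows[[length(rows) + 1L]] <- .decomp_row(
        f, tn, .ss_dev(sp), .ss_dev(fx), .ss_dev(itv),
        degenerate = .ss_dev(sp) <= 0
      )
    }
  }
  do.call(rbind, rows)
}

#' Partition community trait change along the successional gradient
#'
#' Regresses each of the three CWM series (specific, fixed, ITV) on the
#' gradient (successional age by default) by ordinary least squares. The
#' explained SS of the fixed and ITV regressions are expressed as percentages
#' of the total SS of the specific regression, giving the contributions of
#' species turnover and of intraspecific variation to the community response
#' to the gradient; covariation is the remainder. Slopes and two-sided
#' p-values of all three regressions are reported.
#'
#' @inheritParams decompose_total
#' @param gradient name of the plot column used as gradient
#' @return data frame as in [decompose_total()] plus `slope_turnover`,
#'   `p_turnover`, `slope_itv`, `p_itv`, `slope_total`, `p_total`. Here
#'   `ss_total` is the explained SS of the specific regression.
#' @export
decompose_vs_gradient <- function(study,
                                  traits = quantitative_traits(study),
                                  forest_type = unique(study$plots$forest_type),
                                  gradient = "successional_age") {
  if (!gradient %in% names(study$plots))
    stop("unknown gradient column '", gradient, "'", call. = FALSE)
  rows <- list()
  for (f in forest_type) {
    sel <- study$plots$forest_type == f
    if (sum(sel) < 3) stop("need >= 3 plots in forest type '", f, "'",
                           call. = FALSE)
    g <- study$plots[[gradient]][sel]
    if (length(unique(g)) < 2)
      stop("gradient '", gradient, "' is constant in forest type '", f, "'",
           call. = FALSE)
    for (tn in traits) {
      sp <- compute_cwm(study, tn, "specific", forest_type = f)
      fx <- compute_cwm(study, tn, "fixed", forest_type = f)
      itv <- sp - fx
      tot <- .ols_line(sp, g); turn <- .ols_line(fx, g)
      itvl <- .ols_line(itv, g)
      rows[[length(rows) + 1L]] <- .decomp_row(
        f, tn, tot$ss_explained, turn$ss_explained, itvl$ss_explained,
        slopes = list(tot = tot, turn = turn, itv = itvl),
        degenerate = tot$ss_explained <= 0
      )
    }
  }
  do.call(rbind, rows)
}
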