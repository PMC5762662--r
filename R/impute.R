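#' Fill unmeasured quantitative trait values by hierarchical means
#'
#' Field campaigns rarely measure every sapling; community-weighted means
#' nevertheless need a value for every individual retained in the abundance
#' weights. Missing quantitative values are filled with the first available
#' mean in the hierarchy
#'
#' 1. mean of the same species in the same plot,
#' 2. mean of the same species across all plots of the same forest type,
#' 3. mean of the trait across the whole forest type.
#'
#' Measured values are never altered. Unweighted arithmetic means are used at
#' every level.
#'
#' @param study a [trait_study]
#' @param traits quantitative trait names to impute (default: all)
#' @return the study with missing values filled; attribute
#'   `"imputation_log"` holds a data frame with one row per filled cell
#'   (`individual_id`, `trait`, `rule` in
#'   `c("species_plot", "species_forest_type", "forest_type")`, `value`).
#' @details Errors if a trait has no measured value at all within some forest
#'   type (nothing to extrapolate from).
#' @export
impute_missing_traits <- function(study, traits = quantitative_traits(study)) {
  stopifnot(inherits(study, "trait_study"))
  ind <- study$individuals
  ft <- study$plots$forest_type[match(ind$plot_id, study$plots$plot_id)]

  log_rows <- list()
  for (tn in traits) {
    v <- ind[[tn]]
    miss <- which(is.na(v))
    for (f in unique(ft)) {
      in_ft <- ft == f
      if (all(is.na(v[in_ft]))) {
        stop("trait '", tn, "' has no measured value in forest type '", f,
             "': cannot impute", call. = FALSE)
      }
    }
    if (!length(miss)) next
    sp_plot <- interaction(ind$species_id, ind$plot_id, drop = FALSE)
    m_sp_plot <- tapply(v, sp_plot, mean, na.rm = TRUE)
    sp_ft <- interaction(ind$species_id, ft, drop = FALSE)
    m_sp_ft <- tapply(v, sp_ft, mean, na.rm = TRUE)
    m_ft <- tapply(v, ft, mean, na.rm = TRUE)

    for (i in miss) {
      fill <- m_sp_plot[[as.character(sp_plot[i])]]
      rule <- "species_plot"
      if (is.na(fill) || is.nan(fill)) {
        fill <- m_sp_ft[[as.character(sp_ft[i])]]
        rule <- "species_forest_type"
      }
      if (is.na(fill) || is.nan(fill)) {
        fill <- m_ft[[ft[i]]]
        rule <- "forest_type"
      }
      v[i] <- fill
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        individual_id = ind$individual_id[i], trait = tn, rule = rule,
        value = fill, stringsAsFactors = FALSE
      )
    }
    ind[[tn]] <- v
  }
  study$individuals <- ind
  attr(study, "imputation_log") <-
    if (length(log_rows)) do.call(rbind, log_rows)
    else data.frame(individual_id = character(), trait = character(),
                    rule = character(), value = numeric(),
                    stringsAsFactors = FALSE)
  study
}
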