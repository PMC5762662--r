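#' @keywords internal
"_PACKAGE"

# Canonical column sets for the four study tables.  Environment columns mirror
# the microclimate / stand / soil variables measured on each plot of the
# chronosequences; a study may carry a subset (successional_age is mandatory).
.tf_env_cols <- c(
  "canopy_openness_dry", "canopy_openness_wet",
  "air_temp_dry", "air_temp_wet",
  "soil_moisture_dry", "soil_moisture_wet",
  "adult_basal_area", "soil_ph", "soil_clay"
)

.tf_traits_cols <- c("name", "kind", "units", "log_transform_for_lmm")
.tf_species_cols <- c("species_id", "hmax", "legume", "phenology",
                      "compoundness", "pubescence")
.tf_plots_req <- c("plot_id", "forest_type", "successional_age")
.tf_indiv_req <- c("individual_id", "plot_id", "species_id",
                   "height_class_midpoint", "cii")

.tf_phenology_levels <- c("deciduous", "evergreen", "intermediate")
.tf_compound_levels  <- c("simple", "pinnate", "bipinnate")

#' Construct a trait study
#'
#' Bundles the four tables of a sapling trait survey — trait definitions,
#' species attributes, plot environments and individual records — into a
#' single validated object used by all analysis stages.
#'
#' @param traits data frame with columns `name`, `kind` (one of
#'   `"quantitative"`, `"binary"`, `"categorical"`), `units`,
#'   `log_transform_for_lmm` (logical). Quantitative trait names must match
#'   columns of `individuals`; categorical/binary names must match columns of
#'   `species`.
#' @param species data frame with columns `species_id`, `hmax` (m, > 0),
#'   `legume` (logical/0-1), `phenology`, `compoundness`, `pubescence`.
#' @param plots data frame with columns `plot_id`, `forest_type` (`"MIX"` or
#'   `"OAK"`), `successional_age` (years, > 0) and any subset of the
#'   environment columns (canopy openness, air temperature and soil moisture
#'   per season, adult basal area, soil pH, soil clay).
#' @param individuals data frame with columns `individual_id`, `plot_id`,
#'   `species_id`, `height_class_midpoint` (m, midpoint of a 50-cm height
#'   class in \[1, 4\]), `cii` (crown illumination index, integer 1-5) and one
#'   numeric column per quantitative trait (NA = not measured).
#'
#' @return An object of class `trait_study`: a list with elements `traits`,
#'   `species`, `plots`, `individuals`. The individuals table gains a column
#'   `h_rel` = height / species `hmax` (relative height, the ontogeny proxy).
#'
#' @examples
#' st <- toy_study()
#' st
#' quantitative_traits(st)
#' @export
trait_study <- function(traits, species, plots, individuals) {
  traits <- as.data.frame(traits)
  species <- as.data.frame(species)
  plots <- as.data.frame(plots)
  individuals <- as.data.frame(individuals)

  .check_cols(traits, .tf_traits_cols, "traits")
  .check_cols(species, .tf_species_cols, "species")
  .check_cols(plots, .tf_plots_req, "plots")
  .check_cols(individuals, .tf_indiv_req, "individuals")

  if (anyDuplicated(traits$name))
    stop("duplicated trait names in traits table", call. = FALSE)
  if (anyDuplicated(species$species_id))
    stop("duplicated species_id in species table", call. = FALSE)
  if (anyDuplicated(plots$plot_id))
    stop("duplicated plot_id in plots table", call. = FALSE)
  if (anyDuplicated(individuals$individual_id))
    stop("duplicated individual_id in individuals table", call. = FALSE)

  bad_kind <- setdiff(traits$kind, c("quantitative", "binary", "categorical"))
  if (length(bad_kind))
    stop("unknown trait kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)

  qt <- traits$name[traits$kind == "quantitative"]
  missing_q <- setdiff(qt, names(individuals))
  if (length(missing_q))
    stop("individuals table lacks column(s) for quantitative trait(s): ",
         paste(missing_q, collapse = ", "), call. = FALSE)
  ct <- traits$name[traits$kind != "quantitative"]
  missing_c <- setdiff(ct, names(species))
  if (length(missing_c))
    stop("species table lacks column(s) for categorical trait(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)

  # referential integrity, reported with offending row numbers
  bad_plot <- which(!(individuals$plot_id %in% plots$plot_id))
  if (length(bad_plot))
    stop("individuals rows reference unknown plot_id: rows ",
         paste(bad_plot, collapse = ", "), " (ids ",
         paste(unique(individuals$plot_id[bad_plot]), collapse = ", "), ")",
         call. = FALSE)
  bad_sp <- which(!(individuals$species_id %in% species$species_id))
  if (length(bad_sp))
    stop("individuals rows reference unknown species_id: rows ",
         paste(bad_sp, collapse = ", "), " (ids ",
         paste(unique(individuals$species_id[bad_sp]), collapse = ", "), ")",
         call. = FALSE)

  if (any(!is.finite(species$hmax)) || any(species$hmax <= 0))
    stop("species hmax must be finite and > 0", call. = FALSE)
  if (any(plots$successional_age <= 0))
    stop("successional_age must be > 0", call. = FALSE)
  h <- individuals$height_class_midpoint
  if (any(!is.finite(h)) || any(h < 1) || any(h > 4))
    stop("height_class_midpoint must lie in [1, 4] m", call. = FALSE)
  cii <- individuals$cii
  if (any(!is.finite(cii)) || any(cii < 1 | cii > 5))
    stop("cii must be an integer score in 1..5", call. = FALSE)
  for (tn in qt) {
    v <- individuals[[tn]]
    if (!is.numeric(v))
      stop("quantitative trait column '", tn, "' is not numeric",
           call. = FALSE)
    if (any(is.infinite(v)))
      stop("non-finite values in quantitative trait '", tn, "'",
           call. = FALSE)
  }

  hmax <- species$hmax[match(individuals$species_id, species$species_id)]
  individuals$h_rel <- individuals$height_class_midpoint / hmax

  structure(
    list(traits = traits, species = species, plots = plots,
         individuals = individuals),
    class = "trait_study"
  )
}

#' @export
print.trait_study <- function(x, ...) {
  nq <- sum(x$traits$kind == "quantitative")
  cat("<trait_study>\n")
  cat("  plots:      ", nrow(x$plots), " (",
      paste(sprintf("%s=%d", names(table(x$plots$forest_type)),
                    as.integer(table(x$plots$forest_type))), collapse = ", "),
      ")\n", sep = "")
  cat("  species:    ", nrow(x$species), "\n", sep = "")
  cat("  individuals:", nrow(x$individuals), "\n")
  cat("  traits:     ", nrow(x$traits), " (", nq, " quantitative)\n",
      sep = "")
  invisible(x)
}

#' Names of the quantitative traits of a study
#' @param study a `trait_study`
#' @return character vector of trait names
#' @export
quantitative_traits <- function(study) {
  study$traits$name[study$traits$kind == "quantitative"]
}

#' Names of the categorical (incl. binary) traits of a study
#' @param study a `trait_study`
#' @return character vector of trait names
#' @export
categorical_traits <- function(study) {
  study$traits$name[study$traits$kind != "quantitative"]
}

.check_cols <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("table '", what, "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read a study from its four CSV tables
#'
#' Reads `traits.csv`, `species.csv`, `plots.csv` and `individuals.csv`
#' (UTF-8, comma-delimited, header row mandatory; missing values written as
#' empty fields or `NA`) and returns a cross-referenced [trait_study].
#'
#' @param dir directory containing the four files; alternatively supply the
#'   four paths explicitly.
#' @param traits,species,plots,individuals explicit file paths (override
#'   `dir`).
#' @return a [trait_study]
#' @seealso [write_study()]
#' @export
read_study <- function(dir = NULL,
                       traits = file.path(dir, "traits.csv"),
                       species = file.path(dir, "species.csv"),
                       plots = file.path(dir, "plots.csv"),
                       individuals = file.path(dir, "individuals.csv")) {
  paths <- c(traits = traits, species = species, plots = plots,
             individuals = individuals)
  for (p in paths)
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    na.strings = c("", "NA"),
                                    fileEncoding = "UTF-8")
  tr <- rd(paths["traits"])
  sp <- rd(paths["species"])
  pl <- rd(paths["plots"])
  ind <- rd(paths["individuals"])

  .check_cols(tr, .tf_traits_cols, "traits")
  qt <- tr$name[tr$kind == "quantitative"]
  for (tn in intersect(qt, names(ind))) {
    if (!is.numeric(ind[[tn]])) {
      bad <- which(!is.na(ind[[tn]]) &
                     is.na(suppressWarnings(as.numeric(ind[[tn]]))))
      stop("non-numeric value(s) in quantitative column '", tn,
           "' of individuals.csv, row(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  tr$log_transform_for_lmm <- as.logical(tr$log_transform_for_lmm)
  trait_study(tr, sp, pl, ind)
}

#' Write a study to four CSV tables
#'
#' Inverse of [read_study()]: writes `traits.csv`, `species.csv`, `plots.csv`
#' and `individuals.csv` into `dir`. Missing values are written as empty
#' fields. The derived `h_rel` column is not written (it is recomputed on
#' read).
#'
#' @param study a [trait_study]
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "trait_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  }
  ind <- study$individuals
  ind$h_rel <- NULL
  wr(study$traits, "traits.csv")
  wr(study$species, "species.csv")
  wr(study$plots, "plots.csv")
  wr(ind, "individuals.csv")
  invisible(dir)
}

#' A tiny worked example study
#'
#' Three plots of one forest type, two species, six saplings, one
#' quantitative trait. The plot-level species means are arranged so that the
#' specific community-weighted means are (11, 17, 23), the fixed means
#' (12, 17, 22) and the intraspecific component (-1, 0, +1) — a hand-checkable
#' decomposition fixture used throughout the documentation and tests.
#'
#' @param ages successional ages of the three plots
#' @return a [trait_study]
#' @export
toy_study <- function(ages = c(10, 20, 30)) {
  traits <- data.frame(
    name = c("sla", "phenology", "legume"),
    kind = c("quantitative", "categorical", "binary"),
    units = c("m2/kg", "class", "flag"),
    log_transform_for_lmm = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE
  )
  species <- data.frame(
    species_id = c("A", "B"), hmax = c(20, 25), legume = c(FALSE, TRUE),
    phenology = c("deciduous", "evergreen"),
    compoundness = c("simple", "pinnate"),
    pubescence = c(TRUE, FALSE), stringsAsFactors = FALSE
  )
  plots <- data.frame(
    plot_id = c("P1", "P2", "P3"), forest_type = "MIX",
    successional_age = ages, stringsAsFactors = FALSE
  )
  individuals <- data.frame(
    individual_id = paste0("i", 1:6),
    plot_id = c("P1", "P1", "P2", "P2", "P3", "P3"),
    species_id = c("A", "A", "A", "B", "B", "B"),
    height_class_midpoint = c(1.25, 1.75, 2.25, 2.75, 3.25, 3.75),
    cii = c(2L, 3L, 2L, 3L, 3L, 4L),
    sla = c(10, 12, 14, 20, 22, 24),
    stringsAsFactors = FALSE
  )
  trait_study(traits, species, plots, individuals)
}
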