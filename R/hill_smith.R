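# Scale a mixed quantitative/categorical table under row weights so that
# every variable contributes total inertia exactly 1:
#   - quantitative column x -> (x - mean_w) / sd_w   (weighted moments,
#     population divisor), inertia sum_i w_i z_i^2 = 1;
#   - categorical column with levels l (weighted frequencies f_l, m levels)
#     -> indicator columns (1{i in l} - f_l) / sqrt(f_l (m - 1)); summed over
#     levels the inertia is sum_l (1 - f_l)/(m - 1) = 1. For binary variables
#     this is exactly the correspondence-analysis inverse-sqrt-frequency
#     scaling.
# Returns the scaled matrix plus bookkeeping of which columns belong to which
# variable.
.scale_mixed <- function(tab, w) {
  tab <- as.data.frame(tab)
  n <- nrow(tab)
  stopifnot(length(w) == n, all(w >= 0))
  w <- w / sum(w)
  cols <- list(); var_of <- character(0)
  for (j in names(tab)) {
    x <- tab[[j]]
    if (is.numeric(x) && !is.factor(x)) {
      mu <- sum(w * x)
      sd_w <- sqrt(sum(w * (x - mu)^2))
      if (sd_w < 1e-12)
        stop("quantitative column '", j, "' has zero variance", call. = FALSE)
      cols[[j]] <- (x - mu) / sd_w
      var_of <- c(var_of, j)
    } else {
      x <- factor(x)
      lev <- levels(droplevels(x))
      if (length(lev) < 2)
        stop("categorical column '", j, "' has a single level", call. = FALSE)
      m <- length(lev)
      for (l in lev) {
        ind <- as.numeric(x == l)
        f <- sum(w * ind)
        cols[[paste(j, l, sep = ".")]] <- (ind - f) / sqrt(f * (m - 1))
        var_of <- c(var_of, j)
      }
    }
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- rownames(tab)
  attr(Z, "variable") <- var_of
  Z
}

#' Hill-Smith ordination of a mixed trait table
#'
#' Principal-components-style ordination of a table mixing quantitative and
#' categorical variables. Quantitative columns are standardized to weighted
#' mean 0 and variance 1; categorical columns are indicator-coded with
#' correspondence-analysis scaling, normalised so that every variable —
#' whatever its type — contributes total inertia 1. The weighted covariance
#' matrix of the scaled table is then eigen-decomposed.
#'
#' On an all-quantitative table this reduces exactly to PCA of the weighted
#' correlation matrix.
#'
#' @param tab data frame; numeric columns are treated as quantitative,
#'   factor/character columns as categorical
#' @param n_axes number of axes to return (default: all)
#' @param row_w non-negative row weights (default uniform); normalised to
#'   sum 1
#' @return object of class `hill_smith`: list with `eig` (eigenvalues,
#'   descending; values below 1e-10 x leading eigenvalue reported as 0),
#'   `axis_pct` (% of total inertia per axis), `row_scores`,
#'   `col_loadings` (eigenvectors, rows = scaled columns), `variable`
#'   (which input variable each scaled column belongs to), `total_inertia`
#'   (= number of variables), `row_w`.
#' @examples
#' df <- data.frame(a = rnorm(10), b = rnorm(10),
#'                  f = rep(c("x", "y"), 5))
#' hill_smith(df, n_axes = 2)
#' @export
hill_smith <- function(tab, n_axes = NULL, row_w = NULL) {
  tab <- as.data.frame(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 rows and 2 variables", call. = FALSE)
  w <- if (is.null(row_w)) rep(1 / nrow(tab), nrow(tab)) else row_w / sum(row_w)
  Z <- .scale_mixed(tab, w)
  C <- crossprod(Z * w, Z)             # t(Z) %*% diag(w) %*% Z
  es <- eigen(C, symmetric = TRUE)
  eig <- es$values
  eig[eig < 0] <- 0
  if (eig[1] > 0) eig[eig < 1e-10 * eig[1]] <- 0
  k <- if (is.null(n_axes)) length(eig) else min(n_axes, length(eig))
  vec <- es$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive on each axis
  for (a in seq_len(k)) {
    i <- which.max(abs(vec[, a]))
    if (vec[i, a] < 0) vec[, a] <- -vec[, a]
  }
  rownames(vec) <- colnames(Z)
  scores <- Z %*% vec
  colnames(scores) <- paste0("Axis", seq_len(k))
  colnames(vec) <- paste0("Axis", seq_len(k))
  structure(list(
    eig = eig, axis_pct = 100 * eig / sum(eig),
    row_scores = scores, col_loadings = vec,
    variable = attr(Z, "variable"),
    total_inertia = sum(eig), row_w = w
  ), class = "hill_smith")
}

#' @export
print.hill_smith <- function(x, ...) {
  cat("<hill_smith> total inertia", format(x$total_inertia, digits = 4),
      "\n eigenvalues:", format(utils::head(x$eig, 5), digits = 4),
      if (length(x$eig) > 5) "..." else "", "\n")
  invisible(x)
}

#' Leaf-level Hill-Smith ordination of a study
#'
#' Runs [hill_smith()] on the individual-level trait table of a study:
#' quantitative traits as measured on each sapling plus the categorical
#' traits of its species, with uniform row weights. This is the standard
#' check that the main axis of trait correlation is the leaf-economics
#' spectrum.
#'
#' @param study a [trait_study] (imputed)
#' @param n_axes axes to keep
#' @return a `hill_smith` object
#' @export
ordinate_individuals <- function(study, n_axes = 2) {
  stopifnot(inherits(study, "trait_study"))
  qt <- quantitative_traits(study)
  ct <- categorical_traits(study)
  tab <- study$individuals[, qt, drop = FALSE]
  if (anyNA(tab))
    stop("missing trait values; run impute_missing_traits() first",
         call. = FALSE)
  sp_row <- match(study$individuals$species_id, study$species$species_id)
  for (tn in ct) {
    v <- study$species[[tn]][sp_row]
    if (is.logical(v) || all(v %in% c(0, 1))) v <- ifelse(v == 1 | v == TRUE, "yes", "no")
    tab[[tn]] <- factor(v)
  }
  hill_smith(tab, n_axes = n_axes)
}
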