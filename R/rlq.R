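# Core of the three-table analysis: X (rows of L, scaled environment),
# Y (columns of L, scaled traits), P the relative-frequency version of L.
# The doubly-centred cross matrix M = X' P0 Y holds the L-weighted
# cross-covariances between environment and trait columns; its singular
# value decomposition yields axes maximizing the squared cross-covariance of
# linear combinations on either side. Eigenvalue k = squared singular value.
.rlq_core <- function(X, P, Y, n_axes, var_r, var_q) {
  r <- rowSums(P); cc <- colSums(P)
  P0 <- P - outer(r, cc)
  M <- t(X) %*% P0 %*% Y
  trace <- sum(M^2)
  sv <- svd(M)
  eig <- sv$d^2
  if (trace < 1e-300) {
    warning("rank-0 cross matrix: all eigenvalues are zero")
    eig <- rep(0, length(eig))
  }
  k <- min(n_axes, length(eig))
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (a in seq_len(k)) {            # sign: largest |env coefficient| > 0
    i <- which.max(abs(u[, a]))
    if (u[i, a] < 0) { u[, a] <- -u[, a]; v[, a] <- -v[, a] }
  }
  rownames(u) <- colnames(X); rownames(v) <- colnames(Y)
  colnames(u) <- colnames(v) <- paste0("Axis", seq_len(k))
  contrib <- function(coefs, var_of) {
    sq <- coefs^2
    agg <- rowsum(sq, var_of)                 # per input variable
    sweep(agg, 2, colSums(sq), "/") * 100
  }
  structure(list(
    eig = eig,
    axis_pct = if (sum(eig) > 0) 100 * eig / sum(eig) else rep(NA_real_, length(eig)),
    env_coef = u, trait_coef = v,
    env_contrib = contrib(u, var_r), trait_contrib = contrib(v, var_q),
    trace = trace, n_axes = k
  ), class = "rlq_result")
}

#' @export
print.rlq_result <- function(x, ...) {
  cat("<rlq_result> eigenvalues:",
      format(utils::head(x$eig, 4), digits = 4),
      if (length(x$eig) > 4) "..." else "", "\n")
  cat("  axis %:", format(utils::head(x$axis_pct, 4), digits = 4), "\n")
  cat("  total cross-covariance (trace):", format(x$trace, digits = 6), "\n")
  invisible(x)
}

#' RLQ analysis: trait-environment cross-covariance through an occurrence
#' table
#'
#' Links a plot x environment table (R), a plot x observation non-negative
#' occurrence table (L; observations are individuals or species), and an
#' observation x trait table (Q). L is converted to relative frequencies; its
#' row and column sums provide the weights under which R and Q are scaled by
#' the Hill-Smith conventions (quantitative columns standardized,
#' categorical columns indicator-coded; see [hill_smith()]). The
#' doubly-centred frequency table mediates the cross-covariance matrix
#' between the two sides, whose singular value decomposition gives axes
#' maximizing the squared cross-covariance of linear combinations of
#' environmental factors and traits.
#'
#' @param R data frame (plots x environment variables), mixed types allowed
#' @param L numeric matrix (plots x observations), non-negative, no zero
#'   row or column
#' @param Q data frame (observations x traits), mixed types allowed
#' @param n_axes axes to retain (default 2)
#' @return an `rlq_result`: `eig` (squared singular values, descending),
#'   `axis_pct` (% of total cross-covariance per axis), `env_coef` and
#'   `trait_coef` (singular-vector coefficients per scaled column),
#'   `env_contrib` / `trait_contrib` (per-variable squared-coefficient
#'   contributions, summing to 100% per axis), `trace` (total squared
#'   cross-covariance; equals `sum(eig)`).
#' @export
rlq <- function(R, L, Q, n_axes = 2) {
  L <- as.matrix(L)
  if (any(L < 0)) stop("L must be non-negative", call. = FALSE)
  if (any(rowSums(L) == 0))
    stop("L has empty row(s) (plot with no observation)", call. = FALSE)
  if (any(colSums(L) == 0))
    stop("L has empty column(s)", call. = FALSE)
  if (nrow(as.data.frame(R)) != nrow(L))
    stop("R rows must align with L rows", call. = FALSE)
  if (nrow(as.data.frame(Q)) != ncol(L))
    stop("Q rows must align with L columns", call. = FALSE)
  P <- L / sum(L)
  X <- .scale_mixed(R, rowSums(P))
  Y <- .scale_mixed(Q, colSums(P))
  .rlq_core(X, P, Y, n_axes, attr(X, "variable"), attr(Y, "variable"))
}

#' Partial RLQ: among-species vs within-species trait-environment structure
#'
#' Separates the trait-environment relationship into the component carried by
#' species turnover and the component carried by intraspecific variation.
#' The trait table Q is built at the individual level and scaled once (under
#' the individual weights of L); the scaled table is then split into
#'
#' * `among_species` — every individual's row replaced by its species' mean
#'   row (between-species structure only), and
#' * `within_species` — every row replaced by its deviation from the species
#'   mean (species effects removed).
#'
#' The two parts sum to the scaled raw table. Both partial analyses use the
#' same R (plot environment) and L (plots x individuals incidence).
#' Categorical traits are species attributes without recorded intraspecific
#' variation: they enter the among-species table (via their species-level
#' indicator values) and are excluded from the within-species table.
#'
#' @param study a [trait_study] (imputed)
#' @param forest_type single forest type to analyse
#' @param component `"among_species"`, `"within_species"` or `"raw"`
#' @param n_axes axes to retain
#' @param env_vars environment columns of the plots table to use (default:
#'   successional age plus every canonical environment column present)
#' @return an `rlq_result`; attribute `"singleton_species"` lists species
#'   represented by one individual (their within-species rows are zero).
#' @export
partial_rlq <- function(study, forest_type,
                        component = c("among_species", "within_species", "raw"),
                        n_axes = 2, env_vars = NULL) {
  component <- match.arg(component)
  stopifnot(inherits(study, "trait_study"))
  plots <- study$plots[study$plots$forest_type == forest_type, , drop = FALSE]
  if (nrow(plots) < 2) stop("need >= 2 plots", call. = FALSE)
  ind <- study$individuals[study$individuals$plot_id %in% plots$plot_id, ,
                           drop = FALSE]
  qt <- quantitative_traits(study)
  if (anyNA(ind[, qt, drop = FALSE]))
    stop("missing trait values; run impute_missing_traits() first",
         call. = FALSE)

  if (is.null(env_vars))
    env_vars <- c("successional_age", intersect(.tf_env_cols, names(plots)))
  R <- plots[, env_vars, drop = FALSE]
  keep <- vapply(R, function(x) length(unique(x)) > 1, logical(1))
  R <- R[, keep, drop = FALSE]

  n <- nrow(ind)
  L <- matrix(0, nrow(plots), n,
              dimnames = list(plots$plot_id, ind$individual_id))
  L[cbind(match(ind$plot_id, plots$plot_id), seq_len(n))] <- 1

  # raw individual-level Q: quantitative traits + species categorical traits;
  # a categorical trait with a single observed level carries no variation in
  # this forest type and is dropped
  Q <- ind[, qt, drop = FALSE]
  sp_row <- match(ind$species_id, study$species$species_id)
  for (tn in categorical_traits(study)) {
    v <- study$species[[tn]][sp_row]
    if (is.logical(v) || all(v %in% c(0, 1)))
      v <- ifelse(v == 1 | v == TRUE, "yes", "no")
    if (length(unique(v)) < 2) next
    Q[[tn]] <- factor(v)
  }

  P <- L / sum(L)
  cw <- colSums(P)
  Y <- .scale_mixed(Q, cw)
  var_q <- attr(Y, "variable")
  X <- .scale_mixed(R, rowSums(P))

  if (component != "raw") {
    # species-mean and deviation split of the scaled table (weights are
    # uniform over individuals, so plain means per species)
    sp <- ind$species_id
    Ymean <- apply(Y, 2, function(col) stats::ave(col, sp))
    if (component == "among_species") {
      Y <- Ymean
    } else {
      Y <- Y - Ymean
      is_cat <- var_q %in% categorical_traits(study)
      Y <- Y[, !is_cat, drop = FALSE]
      var_q <- var_q[!is_cat]
    }
  }
  res <- .rlq_core(X, P, Y, n_axes, attr(X, "variable"), var_q)
  singles <- names(which(table(ind$species_id) == 1))
  attr(res, "singleton_species") <- singles
  res$component <- component
  res$forest_type <- forest_type
  res
}
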