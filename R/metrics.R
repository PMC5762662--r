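#' Sørensen similarity between two species sets
#'
#' Presence/absence compositional similarity between two plots:
#' \deqn{S = 2|A \cap B| / (|A| + |B|)}
#' High species turnover along a gradient shows up as low pairwise Sørensen
#' similarity between plots of different ages.
#'
#' @param a,b character vectors of species identifiers (duplicates ignored)
#' @return similarity in \[0, 1\]; 1 for identical sets, 0 for disjoint ones
#' @examples
#' sorensen_similarity(c("a", "b", "c"), c("b", "c", "d"))  # 0.667
#' @export
sorensen_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b))
    stop("Sorensen similarity is undefined for an empty species set",
         call. = FALSE)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise Sørensen similarities among the plots of a forest type
#'
#' @param study a [trait_study]
#' @param forest_type forest type code (e.g. `"MIX"`)
#' @return data frame `plot_a`, `plot_b`, `similarity` for every unordered
#'   plot pair
#' @export
plot_sorensen <- function(study, forest_type) {
  stopifnot(inherits(study, "trait_study"))
  pl <- study$plots$plot_id[study$plots$forest_type == forest_type]
  if (length(pl) < 2) stop("need >= 2 plots", call. = FALSE)
  sets <- lapply(pl, function(p)
    unique(study$individuals$species_id[study$individuals$plot_id == p]))
  names(sets) <- pl
  cmb <- utils::combn(pl, 2)
  data.frame(
    plot_a = cmb[1, ], plot_b = cmb[2, ],
    similarity = apply(cmb, 2, function(pr)
      sorensen_similarity(sets[[pr[1]]], sets[[pr[2]]])),
    stringsAsFactors = FALSE
  )
}

#' Kendall rank correlation (tau-b) with normal-approximation p-value
#'
#' Tie-corrected Kendall correlation between two ordinal vectors, used e.g.
#' to verify that relative height (H/Hmax) and the crown illumination index
#' are nearly uncorrelated before entering both in one model.
#'
#' tau-b = (C - D) / sqrt((n0 - n1)(n0 - n2)) with C/D the concordant and
#' discordant pair counts, n0 = n(n-1)/2 and n1, n2 the tied-pair counts in
#' each vector. The two-sided p-value uses the normal approximation for the
#' statistic S = C - D with the standard tie-corrected variance.
#'
#' @param x,y numeric vectors of equal length (>= 3)
#' @return list with elements `tau`, `p_value`, `n`
#' @examples
#' kendall_tau(1:4, c(2, 1, 4, 3))
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("Kendall correlation undefined for a constant vector",
         call. = FALSE)

  # pairwise sign products, vectorised over the upper triangle
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  ut <- upper.tri(dx)
  s <- dx[ut] * dy[ut]
  S <- sum(s)

  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  # tie-corrected variance of S (Kendall 1970)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(var_s)
  p <- 2 * stats::pnorm(-abs(z))
  list(tau = tau, p_value = p, n = n)
}
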