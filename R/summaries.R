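# Posterior summaries: medians, 95% credible intervals, posterior
# probabilities of change, cross-area inequality gaps, period changes, sex
# comparisons and deprivation gradients.  Percentiles throughout use linear
# interpolation between order statistics; credible intervals are the 2.5th
# to 97.5th posterior percentiles.

#' Summarise posterior draws per unit
#'
#' @param x Numeric matrix (units x draws) or vector (draws of one unit).
#' @return data.frame with columns median, lower95, upper95 (2.5th/97.5th
#'   percentiles), one row per unit.
#' @export
summarize_draws <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) < 2) stop_invalid("need at least 2 draws")
  data.frame(median = apply(x, 1, stats::median),
             lower95 = apply(x, 1, q_interp, 0.025),
             upper95 = apply(x, 1, q_interp, 0.975))
}

year_index <- function(e0, year) {
  i <- match(as.character(year), dimnames(e0)[[2]])
  if (is.na(i)) stop_invalid("year ", year, " not present in the draws")
  i
}

#' Posterior probability that life expectancy increased
#'
#' Fraction of paired posterior draws in which e0 in `year_b` exceeds e0 in
#' `year_a`; exact ties count one half, so P(increase) + P(decrease) = 1.
#' A value near 50% means an increase is statistically indistinguishable
#' from a decrease; values near 0% or 100% indicate near-certain change.
#'
#' @param e0 An `e0_draws` array (areas x years x draws), e.g. from
#'   [posterior_life_expectancy()].
#' @param year_a,year_b Start and end years (must be in the array).
#' @return Named vector of P(increase) per area.
#' @export
posterior_prob_change <- function(e0, year_a, year_b) {
  ia <- year_index(e0, year_a); ib <- year_index(e0, year_b)
  a <- e0[, ia, , drop = FALSE]; b <- e0[, ib, , drop = FALSE]
  up <- apply(b > a, 1, mean) + 0.5 * apply(b == a, 1, mean)
  stats::setNames(as.vector(up), dimnames(e0)[[1]])
}

#' Cross-area inequality gaps in life expectancy
#'
#' Within each posterior draw, computes the maximum minus minimum and the
#' 99th minus 1st percentile of life expectancy across areas, then
#' summarises each gap over draws (median and 95% CrI). Also returns the
#' ranked-area curve: the posterior median and CrI of the life expectancy at
#' each rank position.
#'
#' @param e0 An `e0_draws` array.
#' @param year Year to evaluate.
#' @return List with `gaps` (data.frame: metric, median, lower95, upper95),
#'   `ranked` (data.frame: rank, median, lower95, upper95), `n_areas` and
#'   `few_areas` (TRUE when fewer than 100 areas make the outer percentiles
#'   unstable).
#' @export
inequality_gaps <- function(e0, year) {
  i <- year_index(e0, year)
  x <- e0[, i, ]                      # areas x draws
  if (is.null(dim(x))) stop_invalid("need at least 2 areas")
  M <- nrow(x)
  if (M < 2) stop_invalid("need at least 2 areas")
  few <- M < 100
  per_draw <- apply(x, 2, function(v) {
    p <- q_interp(v, c(0.01, 0.99))
    c(max_min = max(v) - min(v), p99_p1 = p[2] - p[1])
  })
  gaps <- cbind(metric = c("max_min", "p99_p1"),
                summarize_draws(per_draw[c("max_min", "p99_p1"), , drop = FALSE]))
  ranked <- apply(x, 2, sort)         # ranks x draws
  rk <- cbind(rank = seq_len(M), summarize_draws(ranked))
  rownames(gaps) <- rownames(rk) <- NULL
  list(gaps = gaps, ranked = rk, n_areas = M, few_areas = few)
}

#' Change in life expectancy between period boundaries
#'
#' For each area and consecutive pair of boundary years, summarises the
#' posterior draws of e0(end) - e0(start) and counts the areas whose
#' posterior-median change is negative (declining areas).
#'
#' @param e0 An `e0_draws` array.
#' @param boundaries Boundary years, default `c(2002, 2006, 2010, 2014, 2019)`.
#' @return List with `changes` (data.frame: area, period, median, lower95,
#'   upper95, prob_increase) and `declining` (data.frame: period,
#'   n_declining).
#' @export
change_by_period <- function(e0, boundaries = c(2002, 2006, 2010, 2014, 2019)) {
  idx <- vapply(boundaries, year_index, 0L, e0 = e0)
  areas <- dimnames(e0)[[1]]
  out <- list(); dec <- list()
  for (k in seq_len(length(boundaries) - 1)) {
    d <- e0[, idx[k + 1], ] - e0[, idx[k], ]    # areas x draws
    if (is.null(dim(d))) d <- matrix(d, nrow = length(areas))
    s <- summarize_draws(d)
    period <- paste0(boundaries[k], "-", boundaries[k + 1])
    out[[k]] <- cbind(data.frame(area = areas, period = period), s,
                      prob_increase = rowMeans(d > 0) + 0.5 * rowMeans(d == 0))
    dec[[k]] <- data.frame(period = period, n_declining = sum(s$median < 0))
  }
  changes <- do.call(rbind, out)
  rownames(changes) <- NULL
  list(changes = changes, declining = do.call(rbind, dec))
}

#' Compare female and male life expectancy across areas
#'
#' @param e0_female,e0_male `e0_draws` arrays on the same areas.
#' @param year Year to compare.
#' @return List with `correlation` (Pearson, across areas, of the
#'   posterior-median e0), `difference` (per-area female minus male
#'   posterior-median difference in years) and `bands` (counts of areas with
#'   male advantage, difference < 1, 1-5, and > 5 years; the bands partition
#'   the areas).
#' @export
sex_comparison <- function(e0_female, e0_male, year) {
  if (!identical(dimnames(e0_female)[[1]], dimnames(e0_male)[[1]]))
    stop_invalid("female and male draws must cover the same areas")
  mf <- apply(e0_female[, year_index(e0_female, year), , drop = FALSE], 1,
              stats::median)
  mm <- apply(e0_male[, year_index(e0_male, year), , drop = FALSE], 1,
              stats::median)
  d <- mf - mm
  bands <- c(male_advantage = sum(d < 0), under_1 = sum(d >= 0 & d < 1),
             from_1_to_5 = sum(d >= 1 & d <= 5), over_5 = sum(d > 5))
  list(correlation = stats::cor(mf, mm), difference = d, bands = bands)
}

#' Association between life expectancy and deprivation rank
#'
#' Locally weighted (tricube) linear smoothing of posterior-median life
#' expectancy against an area deprivation rank, plus the residual spread
#' around the smooth.
#'
#' @param e0_median Numeric vector of posterior-median e0 per area.
#' @param ranks Integer vector: a permutation of 1..n_areas.
#' @param span Smoothing span in (0, 1].
#' @param grid_n Number of rank positions the fitted curve is evaluated at.
#' @return List with `grid`, `fitted` (smoothed curve on the rank grid),
#'   `residual_iqr` (interquartile range of residuals at the data points)
#'   and `span`.
#' @export
deprivation_association <- function(e0_median, ranks, span = 0.75,
                                    grid_n = 101) {
  n <- length(e0_median)
  if (length(ranks) != n || !setequal(ranks, seq_len(n)))
    stop_invalid("ranks must be a permutation of 1..n_areas")
  if (!is.finite(span) || span <= 0 || span > 1)
    stop_invalid("span must be in (0, 1]")
  df <- data.frame(rank = as.numeric(ranks), e0 = e0_median)
  fit <- stats::loess(e0 ~ rank, data = df, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(1, n, length.out = grid_n)
  list(grid = grid,
       fitted = stats::predict(fit, newdata = data.frame(rank = grid)),
       residual_iqr = unname(diff(q_interp(stats::residuals(fit),
                                           c(0.25, 0.75)))),
       span = span)
}

#' Plot the ranked life-expectancy curve
#'
#' @param gaps Result of [inequality_gaps()].
#' @param ... Passed to [graphics::plot()].
#' @return The input, invisibly.
#' @export
plot_ranked_curve <- function(gaps, ...) {
  rk <- gaps$ranked
  graphics::plot(rk$rank, rk$median, type = "l", lwd = 2,
                 xlab = "area rank", ylab = "life expectancy (years)", ...)
  graphics::lines(rk$rank, rk$lower95, lty = 3)
  graphics::lines(rk$rank, rk$upper95, lty = 3)
  invisible(gaps)
}
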