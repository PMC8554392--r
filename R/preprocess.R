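#' Repair cells where deaths exceed population
#'
#' Population and mortality statistics are produced independently, so a small
#' number of age-area-year cells can report more deaths than residents. In
#' every such cell the population is set equal to the number of deaths; all
#' other cells are unchanged.
#'
#' @param data A [mortality_data()] object.
#' @return List with `data` (repaired dataset) and `n_repaired` (number of
#'   modified cells, summed over sexes).
#' @export
repair_population <- function(data) {
  stopifnot(inherits(data, "mortality_data"))
  n <- 0L
  for (s in sexes_of(data)) {
    bad <- data$deaths[[s]] > data$population[[s]]
    n <- n + sum(bad)
    data$population[[s]][bad] <- data$deaths[[s]][bad]
  }
  list(data = data, n_repaired = n)
}

#' Replace an outlier year by the mean of its neighbours
#'
#' For every sex and age group, deaths in the given area and year are
#' replaced by the mean of the counts in the adjacent years (a non-integer
#' when the neighbour sum is odd). The signed differences
#' actual - interpolated are returned so they can be added back to posterior
#' estimates after model fitting, keeping the deaths counted in the year in
#' which they occurred.
#'
#' @param data A [mortality_data()] object.
#' @param area Area id.
#' @param year Interior year (both `year - 1` and `year + 1` must be in the
#'   data).
#' @return List with `data` (interpolated dataset) and `adjustment`, an
#'   object of class `outlier_adjustment`: list(area, year, delta) where
#'   `delta` is a named list per sex of per-age signed differences.
#' @export
interpolate_outlier_year <- function(data, area, year) {
  stopifnot(inherits(data, "mortality_data"))
  m <- match(area, data$geography$area_ids)
  if (is.na(m)) stop_invalid("unknown area: ", area)
  year <- as.integer(year)
  t <- match(year, data$years)
  if (is.na(t) || t == 1L || t == length(data$years))
    stop_invalid("year must be an interior year of the dataset")
  delta <- list()
  for (s in sexes_of(data)) {
    actual <- data$deaths[[s]][, m, t]
    interp <- (data$deaths[[s]][, m, t - 1] + data$deaths[[s]][, m, t + 1]) / 2
    delta[[s]] <- actual - interp
    data$deaths[[s]][, m, t] <- interp
  }
  adj <- structure(list(area = area, year = year, delta = delta),
                   class = "outlier_adjustment")
  list(data = data, adjustment = adj)
}

#' @export
print.outlier_adjustment <- function(x, ...) {
  tot <- vapply(x$delta, sum, 0)
  cat("<outlier_adjustment> area ", x$area, ", year ", x$year,
      "; total delta: ", paste(sprintf("%s %+g", names(tot), tot),
                               collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Add interpolated-out deaths back to posterior expected deaths
#'
#' Applies an [interpolate_outlier_year()] adjustment to draws of posterior
#' expected deaths: in the adjusted area-year, expected deaths are
#' incremented by delta in every draw (floored at zero). Death rates for
#' those cells should be re-derived as adjusted deaths / population.
#'
#' @param expected Draws of expected deaths: array (ages, areas, years,
#'   draws) for one sex, with area/year dimnames.
#' @param adjustment An `outlier_adjustment`.
#' @param sex Which sex's delta to apply.
#' @return The adjusted array.
#' @export
add_back_outlier <- function(expected, adjustment, sex = "female") {
  stopifnot(inherits(adjustment, "outlier_adjustment"))
  dn <- dimnames(expected)
  m <- match(adjustment$area, dn[[2]])
  t <- match(as.character(adjustment$year), dn[[3]])
  if (is.na(m) || is.na(t))
    stop_invalid("adjustment area/year not present in the draws")
  d <- adjustment$delta[[sex]]
  if (is.null(d)) stop_invalid("no delta stored for sex ", sex)
  expected[, m, t, ] <- pmax(expected[, m, t, ] + d, 0)
  expected
}

#' Write / read an outlier adjustment as a sidecar CSV
#'
#' @param adjustment An `outlier_adjustment`.
#' @param path CSV path.
#' @param ages The [age_groups()] labels used for the rows.
#' @return `path` (write) or the adjustment (read).
#' @export
write_adjustment <- function(adjustment, path, ages = age_groups()) {
  ages <- as_age_groups(ages)
  rows <- do.call(rbind, lapply(names(adjustment$delta), function(s)
    data.frame(sex = s, age_group = ages$label, area_id = adjustment$area,
               year = adjustment$year, delta = adjustment$delta[[s]])))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjustment
#' @export
read_adjustment <- function(path, ages = age_groups()) {
  ages <- as_age_groups(ages)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  delta <- lapply(split(df, df$sex), function(d)
    d$delta[match(ages$label, d$age_group)])
  structure(list(area = df$area_id[1], year = df$year[1], delta = delta),
            class = "outlier_adjustment")
}
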