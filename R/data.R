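#' Mortality count dataset
#'
#' Container for death and population counts stratified by sex, age group,
#' small area and calendar year on a complete index grid, together with the
#' nested geography and age-group specification.
#'
#' @param deaths,population Named list with one element per sex (`"female"`,
#'   `"male"`, either or both) of numeric arrays with dim
#'   `c(n_ages, n_areas, n_years)`.
#' @param geography A [generate_geography()] object.
#' @param ages An [age_groups()] object.
#' @param years Integer vector of consecutive calendar years.
#' @return An object of class `mortality_data`.
#' @export
mortality_data <- function(deaths, population, geography, ages, years) {
  ages <- as_age_groups(ages)
  validate_geography(geography)
  years <- as.integer(years)
  if (length(years) < 1L || (length(years) > 1L && any(diff(years) != 1L)))
    stop_invalid("`years` must be consecutive calendar years")
  sexes <- names(deaths)
  if (is.null(sexes) || !all(sexes %in% c("female", "male")))
    stop_invalid("deaths/population must be named lists with elements 'female' and/or 'male'")
  if (!identical(sexes, names(population)))
    stop_invalid("deaths and population must cover the same sexes")
  dm <- c(length(ages), length(geography$area_ids), length(years))
  dn <- list(age = ages$label, area = geography$area_ids, year = as.character(years))
  for (s in sexes) {
    for (nm in c("deaths", "population")) {
      x <- get(nm)[[s]]
      if (!is.array(x) || !identical(dim(x), as.integer(dm)))
        stop_invalid(nm, "[['", s, "']] must be an array of dim (ages, areas, years)")
      if (any(!is.finite(x)) || any(x < 0))
        stop_invalid(nm, " must be finite and non-negative")
    }
    dimnames(deaths[[s]]) <- dn
    dimnames(population[[s]]) <- dn
  }
  structure(list(deaths = deaths, population = population, geography = geography,
                 ages = ages, years = years),
            class = "mortality_data")
}

#' @export
print.mortality_data <- function(x, ...) {
  cat("<mortality_data> sexes: ", paste(names(x$deaths), collapse = ", "),
      "; ", length(x$ages), " age groups x ", length(x$geography$area_ids),
      " areas x ", length(x$years), " years (", min(x$years), "-", max(x$years),
      ")\n", sep = "")
  for (s in names(x$deaths))
    cat(sprintf("  %s: %.0f deaths, %.0f person-years\n", s,
                sum(x$deaths[[s]]), sum(x$population[[s]])))
  invisible(x)
}

sexes_of <- function(data) names(data$deaths)

#' Convert a mortality dataset to long format
#'
#' @param data A [mortality_data()] object.
#' @return A data.frame with columns sex, age_group, area_id, district_id,
#'   region_id, year, deaths, population (one row per cell).
#' @export
as_long_counts <- function(data) {
  stopifnot(inherits(data, "mortality_data"))
  g <- data$geography
  out <- do.call(rbind, lapply(sexes_of(data), function(s) {
    grid <- expand.grid(age_group = data$ages$label, area_id = g$area_ids,
                        year = data$years, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid$sex <- s
    grid$deaths <- as.vector(data$deaths[[s]])
    grid$population <- as.vector(data$population[[s]])
    grid
  }))
  out$district_id <- unname(g$district_of[out$area_id])
  out$region_id <- unname(g$region_of[out$district_id])
  out[, c("sex", "age_group", "area_id", "district_id", "region_id",
          "year", "deaths", "population")]
}

#' Read stratified mortality counts from CSV
#'
#' Reads a long-format counts file (columns sex, age_group, area_id,
#' district_id, region_id, year, deaths, population), validates it, and
#' densifies it to a complete grid: combinations absent from the file get
#' 0 deaths and 0 population. Rows with missing sex are dropped and counted
#' (reported in the `n_dropped_missing_sex` attribute and a message), as is
#' done for death records without a recorded sex.
#'
#' @param path Path to a CSV file.
#' @param ages An [age_groups()] object giving the expected age labels.
#' @param quiet Suppress the dropped-record message.
#' @return A [mortality_data()] object; row order of the file is irrelevant.
#' @export
read_counts <- function(path, ages = age_groups(), quiet = FALSE) {
  if (!file.exists(path)) stop_invalid("input file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_group", "area_id", "district_id", "region_id",
            "year", "deaths", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_invalid("missing columns: ", paste(miss, collapse = ", "))
  df$row <- seq_len(nrow(df))
  drop <- is.na(df$sex) | !nzchar(trimws(as.character(df$sex)))
  n_drop <- sum(drop)
  df <- df[!drop, , drop = FALSE]
  if (n_drop > 0 && !quiet)
    message("dropped ", n_drop, " record(s) with missing sex")
  mortality_data_from_long(df, ages = ages, n_dropped_missing_sex = n_drop)
}

mortality_data_from_long <- function(df, ages = age_groups(),
                                     n_dropped_missing_sex = 0L) {
  ages <- as_age_groups(ages)
  bad_sex <- !df$sex %in% c("female", "male")
  if (any(bad_sex))
    stop_invalid("unknown sex label(s) in rows: ",
                 paste(utils::head(df$row[bad_sex], 5), collapse = ", "))
  bad_age <- !df$age_group %in% ages$label
  if (any(bad_age))
    stop_invalid("unknown age_group label(s) in rows: ",
                 paste(utils::head(df$row[bad_age], 5), collapse = ", "),
                 " (expected e.g. ", paste(utils::head(ages$label, 3), collapse = ", "), ")")
  if (any(df$deaths < 0 | df$population < 0, na.rm = TRUE) ||
      any(is.na(df$deaths) | is.na(df$population)))
    stop_invalid("negative or missing counts in rows: ",
                 paste(utils::head(df$row[is.na(df$deaths) | is.na(df$population) |
                                            df$deaths < 0 | df$population < 0], 5),
                       collapse = ", "))
  key <- paste(df$sex, df$age_group, df$area_id, df$year, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop_invalid("duplicated (sex, age_group, area_id, year) key at row(s): ",
                 paste(utils::head(df$row[dup], 5), collapse = ", "),
                 " (key ", gsub("\r", "/", key[dup][1]), ")")

  # rebuild geography from the file (areas ordered by first appearance, sorted)
  amap <- unique(df[, c("area_id", "district_id", "region_id")])
  if (anyDuplicated(amap$area_id))
    stop_invalid("area_id mapped to more than one district/region")
  amap <- amap[order(amap$region_id, amap$district_id, amap$area_id), ]
  g <- structure(list(
    area_ids = amap$area_id,
    district_of = stats::setNames(amap$district_id, amap$area_id),
    region_of = stats::setNames(
      amap$region_id[!duplicated(amap$district_id)],
      amap$district_id[!duplicated(amap$district_id)]),
    seed = NA_integer_), class = "geography")

  years <- seq(min(df$year), max(df$year))
  sexes <- intersect(c("female", "male"), unique(df$sex))
  dm <- c(length(ages), length(g$area_ids), length(years))
  deaths <- population <- list()
  for (s in sexes) {
    d <- df[df$sex == s, ]
    ia <- match(d$age_group, ages$label)
    im <- match(d$area_id, g$area_ids)
    it <- match(d$year, years)
    idx <- cbind(ia, im, it)
    D <- array(0, dm); P <- array(0, dm)
    D[idx] <- d$deaths; P[idx] <- d$population
    deaths[[s]] <- D; population[[s]] <- P
  }
  out <- mortality_data(deaths, population, g, ages, years)
  attr(out, "n_dropped_missing_sex") <- n_dropped_missing_sex
  out
}

#' Write a mortality dataset to CSV
#'
#' @param data A [mortality_data()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(data, path) {
  utils::write.csv(as_long_counts(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
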