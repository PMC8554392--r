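#' Generate a nested three-level geography
#'
#' Builds a balanced synthetic geography of small areas nested in districts
#' nested in regions, mirroring the nesting of census small areas in local
#' authority districts within regions.
#'
#' @param n_regions,n_districts_per_region,n_areas_per_district Positive
#'   integer counts.
#' @param seed Integer seed; the geography layout is deterministic given the
#'   counts, the seed is recorded for provenance.
#' @return An object of class `geography`: a list with `area_ids` (character),
#'   `district_of` (named character map area -> district) and `region_of`
#'   (named character map district -> region).
#' @examples
#' g <- generate_geography(2, 3, 4, seed = 1)
#' length(g$area_ids)  # 24
#' @export
generate_geography <- function(n_regions, n_districts_per_region,
                               n_areas_per_district, seed = 1L) {
  counts <- c(n_regions, n_districts_per_region, n_areas_per_district)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != floor(counts)))
    stop_invalid("geography counts must be positive integers")
  regions <- sprintf("R%02d", seq_len(n_regions))
  districts <- as.vector(t(outer(regions, seq_len(n_districts_per_region),
                                 function(r, j) sprintf("%s_D%02d", r, j))))
  region_of <- stats::setNames(rep(regions, each = n_districts_per_region), districts)
  areas <- as.vector(t(outer(districts, seq_len(n_areas_per_district),
                             function(d, k) sprintf("%s_A%03d", d, k))))
  district_of <- stats::setNames(rep(districts, each = n_areas_per_district), areas)
  structure(list(area_ids = areas, district_of = district_of,
                 region_of = region_of, seed = as.integer(seed)),
            class = "geography")
}

#' @export
print.geography <- function(x, ...) {
  cat("<geography> ", length(x$area_ids), " areas in ",
      length(unique(x$district_of)), " districts in ",
      length(unique(x$region_of)), " regions\n", sep = "")
  invisible(x)
}

validate_geography <- function(g) {
  stopifnot(inherits(g, "geography"))
  if (!all(g$area_ids %in% names(g$district_of)))
    stop_invalid("every area must map to a district")
  if (!all(g$district_of %in% names(g$region_of)))
    stop_invalid("every district must map to a region")
  invisible(g)
}

# integer index maps used by the sampler
geography_index <- function(g) {
  areas <- g$area_ids
  districts <- unique(unname(g$district_of))
  regions <- unique(unname(g$region_of))
  list(
    areas = areas, districts = districts, regions = regions,
    dist_of_area = match(unname(g$district_of[areas]), districts),
    reg_of_dist = match(unname(g$region_of[districts]), regions)
  )
}
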