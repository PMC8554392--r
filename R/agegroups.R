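#' Abridged age-group specification
#'
#' Defines the age grouping used throughout the package: by default the
#' 19 groups 0, 1-4, 5-9, ..., 80-84, 85+ commonly used for civil
#' registration counts. The last group is always open-ended.
#'
#' @param lower Lower bounds of the age groups in years, strictly increasing,
#'   starting at 0. Default `c(0, 1, seq(5, 85, by = 5))`.
#' @return An object of class `age_groups` with components `lower`, `width`
#'   (the width of each closed interval in years, `Inf` for the terminal
#'   group), `label` (canonical labels such as `"1-4"` and `"85+"`) and
#'   `midpoint` (interval midpoints; for the open group, lower bound + 2.5).
#' @examples
#' age_groups()
#' @export
age_groups <- function(lower = c(0, 1, seq(5, 85, by = 5))) {
  if (length(lower) < 2L || any(diff(lower) <= 0) || lower[1] != 0)
    stop_invalid("age-group lower bounds must start at 0 and be strictly increasing")
  n <- length(lower)
  width <- c(diff(lower), Inf)
  label <- character(n)
  for (i in seq_len(n)) {
    label[i] <- if (i == n) paste0(lower[i], "+")
    else if (width[i] == 1) as.character(lower[i])
    else paste0(lower[i], "-", lower[i] + width[i] - 1)
  }
  midpoint <- ifelse(is.finite(width), lower + width / 2, lower + 2.5)
  structure(list(lower = lower, width = width, label = label, midpoint = midpoint),
            class = "age_groups")
}

#' @export
print.age_groups <- function(x, ...) {
  cat("<age_groups> ", length(x$lower), " groups: ",
      paste(x$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.age_groups <- function(x) length(x$lower)

as_age_groups <- function(x) {
  if (inherits(x, "age_groups")) return(x)
  if (is.numeric(x)) return(age_groups(x))
  stop_invalid("cannot interpret `ages` as an age_groups object")
}
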