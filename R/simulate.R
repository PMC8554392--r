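#' Parameters of the synthetic mortality surface
#'
#' Defaults describe an England-like mortality schedule: a J-shaped age curve
#' (infant mortality above child mortality, monotone rise through adulthood),
#' a secular decline of about 2% per year in death rates, and cross-area
#' heterogeneity calibrated so that life expectancy at birth spans roughly
#' 70-95 years across a large set of areas — the magnitude of small-area
#' inequality the model is designed to resolve. All values are overridable.
#'
#' @param alpha Baseline log death rates per age group (length must match the
#'   age specification used downstream; default 19 groups).
#' @param beta Baseline per-year linear trend in log rates per age group.
#' @param sigma_theta_area,sigma_theta_district,sigma_theta_region SDs of
#'   area/district/region intercept deviations (log-rate units).
#' @param sigma_phi_area,sigma_phi_district,sigma_phi_region SDs of
#'   area/district/region slope deviations (log-rate units per year).
#' @param sigma_xi SD of independent age-area interaction terms.
#' @param sigma_nu SD of the per-age non-linear time random-walk increments.
#' @param sigma_omega SD of the per-area non-linear time random-walk
#'   increments.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(alpha = NULL,
                       beta = NULL,
                       sigma_theta_area = 0.28,
                       sigma_theta_district = 0.15,
                       sigma_theta_region = 0.08,
                       sigma_phi_area = 0.004,
                       sigma_phi_district = 0.002,
                       sigma_phi_region = 0.001,
                       sigma_xi = 0.10,
                       sigma_nu = 0.012,
                       sigma_omega = 0.012) {
  if (is.null(alpha)) alpha <- log(baseline_rates_england("female"))
  if (is.null(beta)) beta <- rep(-0.02, length(alpha))
  p <- list(alpha = alpha, beta = beta,
            sigma_theta_area = sigma_theta_area,
            sigma_theta_district = sigma_theta_district,
            sigma_theta_region = sigma_theta_region,
            sigma_phi_area = sigma_phi_area,
            sigma_phi_district = sigma_phi_district,
            sigma_phi_region = sigma_phi_region,
            sigma_xi = sigma_xi, sigma_nu = sigma_nu,
            sigma_omega = sigma_omega)
  sds <- unlist(p[grep("^sigma", names(p))])
  if (any(sds < 0) || any(!is.finite(sds)))
    stop_invalid("all sigma_* parameters must be finite and >= 0")
  if (length(p$beta) != length(p$alpha))
    stop_invalid("alpha and beta must have the same length")
  structure(p, class = "sim_params")
}

#' Baseline age schedule of central death rates
#'
#' A fixed schedule of central death rates (deaths per person-year) for the
#' default 19 age groups, loosely an English national schedule of the 2000s;
#' the male schedule is the female one scaled up by a constant log offset.
#' Used as the default age curve of the synthetic-data generator.
#'
#' @param sex `"female"` or `"male"`.
#' @return Numeric vector of 19 rates.
#' @export
baseline_rates_england <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  f <- c(0.0040, 0.00015, 0.00010, 0.00010, 0.00030, 0.00040, 0.00050,
         0.00060, 0.00080, 0.00120, 0.00190, 0.00300, 0.00480, 0.00760,
         0.01200, 0.02000, 0.03500, 0.06500, 0.16000)
  if (sex == "female") f else f * exp(0.45)
}

# Fixed age pyramid: share of area population in each of the 19 age groups.
population_pyramid <- function() {
  c(0.012, 0.048, 0.060, 0.058, 0.057, 0.062, 0.068, 0.067, 0.065, 0.061,
    0.066, 0.069, 0.066, 0.057, 0.050, 0.048, 0.033, 0.024, 0.029)
}

#' Generate area populations
#'
#' Area total populations are log-normally dispersed around a target median
#' and allocated across age groups by a fixed pyramid; totals are constant
#' over the year range.
#'
#' @param geography A [generate_geography()] object.
#' @param ages An [age_groups()] object (the default pyramid requires the
#'   default 19 groups; other specifications get a uniform allocation).
#' @param years Integer vector of calendar years.
#' @param median_pop Target median area population (persons), default 7985.
#' @param dispersion Log-scale SD of area totals; 0 gives identical areas.
#' @param seed Integer seed.
#' @return Numeric array of persons with dim (ages, areas, years).
#' @export
generate_population <- function(geography, ages = age_groups(), years,
                                median_pop = 7985, dispersion = 0.25,
                                seed = 1L) {
  validate_geography(geography)
  ages <- as_age_groups(ages)
  if (length(years) < 1L) stop_invalid("empty year range")
  if (!is.finite(median_pop) || median_pop <= 0)
    stop_invalid("median_pop must be > 0")
  A <- length(ages); M <- length(geography$area_ids); T <- length(years)
  pyr <- if (A == 19L) population_pyramid() else rep(1 / A, A)
  with_seed(seed, {
    totals <- median_pop * exp(dispersion * stats::rnorm(M))
    cells <- round(outer(pyr, totals))  # A x M
    array(rep(cells, T), dim = c(A, M, T),
          dimnames = list(age = ages$label, area = geography$area_ids,
                          year = as.character(years)))
  })
}

#' Generate a true log death-rate surface
#'
#' Draws the latent components of the hierarchical spatiotemporal model and
#' assembles the log-rate surface additively: age intercepts and linear
#' trends, nested area/district/region intercept and slope deviations,
#' independent age-area interactions, and per-age and per-area non-linear
#' time effects as first-order random walks (anchored at zero then centred,
#' so each walk sums to zero over time).
#'
#' @param geography A [generate_geography()] object.
#' @param ages An [age_groups()] object.
#' @param years Integer vector of calendar years.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return An object of class `rate_surface`: list with `log_rate` array
#'   (ages x areas x years), `components` (every latent draw), and the index
#'   metadata. Time is centred at the midpoint of `years`.
#' @export
generate_true_rates <- function(geography, ages = age_groups(), years,
                                params = sim_params(), seed = 1L) {
  validate_geography(geography)
  ages <- as_age_groups(ages)
  if (length(years) < 1L) stop_invalid("empty year range")
  A <- length(ages)
  if (length(params$alpha) != A)
    stop_invalid("params$alpha length must match the number of age groups")
  gi <- geography_index(geography)
  M <- length(gi$areas); D <- length(gi$districts); R <- length(gi$regions)
  T <- length(years)
  tc <- years - mean(years)

  with_seed(seed, {
    theta_area <- stats::rnorm(M, 0, params$sigma_theta_area)
    theta_district <- stats::rnorm(D, 0, params$sigma_theta_district)
    theta_region <- stats::rnorm(R, 0, params$sigma_theta_region)
    phi_area <- stats::rnorm(M, 0, params$sigma_phi_area)
    phi_district <- stats::rnorm(D, 0, params$sigma_phi_district)
    phi_region <- stats::rnorm(R, 0, params$sigma_phi_region)
    xi <- matrix(stats::rnorm(A * M, 0, params$sigma_xi), A, M)
    nu <- rw_centered(A, T, params$sigma_nu)      # A x T
    omega <- rw_centered(M, T, params$sigma_omega) # M x T

    Theta <- theta_area + theta_district[gi$dist_of_area] +
      theta_region[gi$reg_of_dist[gi$dist_of_area]]
    Phi <- phi_area + phi_district[gi$dist_of_area] +
      phi_region[gi$reg_of_dist[gi$dist_of_area]]

    log_rate <- array(0, dim = c(A, M, T),
                      dimnames = list(age = ages$label, area = gi$areas,
                                      year = as.character(years)))
    for (t in seq_len(T)) {
      log_rate[, , t] <- (params$alpha + params$beta * tc[t] + nu[, t]) +
        rep(Theta + Phi * tc[t] + omega[, t], each = A) + xi
    }
    structure(list(
      log_rate = log_rate,
      components = list(alpha = params$alpha, beta = params$beta,
                        theta_area = theta_area, theta_district = theta_district,
                        theta_region = theta_region, phi_area = phi_area,
                        phi_district = phi_district, phi_region = phi_region,
                        xi = xi, nu = nu, omega = omega),
      geography = geography, ages = ages, years = years, tc = tc,
      params = params, seed = as.integer(seed)), class = "rate_surface")
  })
}

# k independent RW1 series of length T, first element anchored at 0, then
# row-centred (each walk sums to zero over time). Returns k x T.
rw_centered <- function(k, T, sd) {
  if (T == 1L) return(matrix(0, k, 1))
  inc <- matrix(stats::rnorm(k * (T - 1), 0, sd), k, T - 1)
  walk <- cbind(0, t(apply(inc, 1, cumsum)))
  walk - rowMeans(walk)
}

#' @export
print.rate_surface <- function(x, ...) {
  cat("<rate_surface> ", paste(dim(x$log_rate), collapse = " x "),
      " (ages x areas x years), log rate range [",
      sprintf("%.2f, %.2f", min(x$log_rate), max(x$log_rate)), "]\n", sep = "")
  invisible(x)
}

#' Sample death counts from a rate surface
#'
#' Draws independent Poisson deaths per cell with mean
#' population x exp(log rate).
#'
#' @param rates A [generate_true_rates()] surface.
#' @param population Array from [generate_population()], aligned on
#'   (ages, areas, years).
#' @param sex Which sex the counts represent (`"female"` or `"male"`).
#' @param seed Integer seed.
#' @return A [mortality_data()] object for the given sex.
#' @export
sample_deaths <- function(rates, population, sex = "female", seed = 1L) {
  stopifnot(inherits(rates, "rate_surface"))
  if (!identical(dim(population), dim(rates$log_rate)))
    stop_invalid("population is not aligned with rates on (age, area, year)")
  sex <- match.arg(sex, c("female", "male"))
  mu <- population * exp(rates$log_rate)
  deaths <- with_seed(seed, array(stats::rpois(length(mu), mu), dim = dim(mu)))
  mortality_data(deaths = stats::setNames(list(deaths), sex),
                 population = stats::setNames(list(population), sex),
                 geography = rates$geography, ages = rates$ages,
                 years = rates$years)
}

#' Generate deprivation rank tables
#'
#' Produces, for each socioeconomic measure and year, a permutation of
#' 1..n_areas whose Spearman correlation with the areas' mean log death rate
#' is approximately `correlation` (rank 1 = least deprived). `correlation = 1`
#' sorts areas exactly by mean log rate.
#'
#' @param geography A [generate_geography()] object.
#' @param rates A [generate_true_rates()] surface on the same geography.
#' @param correlation Target Spearman correlation in \[-1, 1\].
#' @param measures Character vector of measure names.
#' @param years Years to produce ranks for (default: first and last year of
#'   the surface).
#' @param seed Integer seed.
#' @return A data.frame with columns measure, year, area_id, rank.
#' @export
generate_deprivation_ranks <- function(geography, rates, correlation = 0.8,
                                       measures = c("income", "employment",
                                                    "education"),
                                       years = NULL, seed = 1L) {
  if (abs(correlation) > 1) stop_invalid("|correlation| must be <= 1")
  validate_geography(geography)
  stopifnot(inherits(rates, "rate_surface"))
  if (is.null(years)) years <- range(rates$years)
  x <- rowMeans(colMeans(rates$log_rate, dims = 1))  # per-area mean log rate
  n <- length(x)
  rx <- scale(rank(x, ties.method = "first"))[, 1]
  with_seed(seed, {
    out <- do.call(rbind, lapply(measures, function(me) {
      do.call(rbind, lapply(years, function(yr) {
        if (abs(correlation) == 1) {
          rk <- rank(sign(correlation) * x, ties.method = "first")
        } else {
          y <- correlation * rx + sqrt(1 - correlation^2) * stats::rnorm(n)
          rk <- rank(y, ties.method = "first")
        }
        data.frame(measure = me, year = yr,
                   area_id = geography$area_ids, rank = as.integer(rk))
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Inject a death-count shock into one area-year
#'
#' Adds (or subtracts) deaths in a single area and year, by sex and age group
#' — a synthetic analogue of a localised mass-fatality event that makes one
#' year a trend outlier for its area.
#'
#' @param data A [mortality_data()] object.
#' @param area Area id present in the data.
#' @param year Year present in the data.
#' @param extra Named list (by sex) of numeric vectors of extra deaths per
#'   age group; a single number is spread over the 45+ age groups of all
#'   sexes present, proportionally to current deaths (remainder to the
#'   terminal group).
#' @return The modified dataset; all other cells are untouched.
#' @export
inject_shock <- function(data, area, year, extra) {
  stopifnot(inherits(data, "mortality_data"))
  m <- match(area, data$geography$area_ids)
  t <- match(as.integer(year), data$years)
  if (is.na(m) || is.na(t)) stop_invalid("area or year not present in dataset")
  A <- length(data$ages)
  if (is.numeric(extra) && length(extra) == 1L) {
    per_sex <- extra / length(sexes_of(data))
    extra <- lapply(stats::setNames(nm = sexes_of(data)), function(s) {
      cur <- data$deaths[[s]][, m, t]
      w <- ifelse(data$ages$lower >= 45, pmax(cur, 1), 0)
      e <- floor(per_sex * w / sum(w))
      e[A] <- e[A] + (per_sex - sum(e))
      e
    })
  }
  for (s in names(extra)) {
    if (!s %in% sexes_of(data)) stop_invalid("unknown sex in `extra`: ", s)
    e <- extra[[s]]
    if (length(e) != A) stop_invalid("extra[['", s, "']] must have one value per age group")
    new <- data$deaths[[s]][, m, t] + e
    if (any(new < 0)) stop_invalid("shock would make deaths negative")
    data$deaths[[s]][, m, t] <- new
  }
  data
}

#' Simulate a complete two-sex mortality dataset
#'
#' Convenience wrapper tying the generator together: one geography-wide
#' population table (split evenly between the sexes), independent female and
#' male true-rate surfaces (male baseline log rates offset upwards), and
#' Poisson death counts.
#'
#' @param geography A [generate_geography()] object.
#' @param ages,years Index specification.
#' @param params_female,params_male [sim_params()] for each sex.
#' @param median_pop Median total area population (persons, both sexes).
#' @param dispersion Log-scale SD of area totals.
#' @param seed Integer seed.
#' @return List with `data` (two-sex [mortality_data()]), `truth` (list of
#'   the two `rate_surface` objects) and `population` (the total-persons
#'   array before the sex split).
#' @export
simulate_mortality <- function(geography = generate_geography(4, 3, 10),
                               ages = age_groups(),
                               years = 2002:2019,
                               params_female = sim_params(),
                               params_male = sim_params(
                                 alpha = log(baseline_rates_england("male"))),
                               median_pop = 7985, dispersion = 0.25,
                               seed = 1L) {
  ages <- as_age_groups(ages)
  pop_total <- generate_population(geography, ages, years, median_pop,
                                   dispersion, seed = seed)
  pop_sex <- round(pop_total / 2)
  truth <- list(
    female = generate_true_rates(geography, ages, years, params_female,
                                 seed = seed + 1L),
    male = generate_true_rates(geography, ages, years, params_male,
                               seed = seed + 2L))
  d_f <- sample_deaths(truth$female, pop_sex, "female", seed = seed + 3L)
  d_m <- sample_deaths(truth$male, pop_sex, "male", seed = seed + 4L)
  data <- mortality_data(
    deaths = list(female = d_f$deaths$female, male = d_m$deaths$male),
    population = list(female = pop_sex, male = pop_sex),
    geography = geography, ages = ages, years = years)
  list(data = data, truth = truth, population = pop_total)
}
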