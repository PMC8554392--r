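# Shared fixtures and independent oracles for the test suite.

# Small synthetic dataset (repaired), together with its true rate surface.
make_small_dataset <- function(n_regions = 2, n_districts = 2, n_areas = 3,
                               years = 2010:2015, median_pop = 4000,
                               dispersion = 0.25, params = sim_params(),
                               sex = "female", seed = 1) {
  g <- generate_geography(n_regions, n_districts, n_areas, seed = seed)
  pop <- generate_population(g, years = years, median_pop = median_pop,
                             dispersion = dispersion, seed = seed + 1)
  rs <- generate_true_rates(g, years = years, params = params,
                            seed = seed + 2)
  dat <- repair_population(sample_deaths(rs, pop, sex, seed = seed + 3))$data
  list(geography = g, population = pop, rates = rs, data = dat)
}

# Tiny age specification (5 groups) with a matching rate schedule, for fits
# that need to be fast.
tiny_ages <- function() age_groups(c(0, 15, 45, 65, 85))
tiny_params <- function(...) {
  sim_params(alpha = log(c(4e-4, 8e-4, 5e-3, 2e-2, 0.15)),
             beta = rep(-0.02, 5), ...)
}

# One small cached model fit shared by several tests in a file.
local_fit_cache <- new.env(parent = emptyenv())
cached_small_fit <- function() {
  if (is.null(local_fit_cache$fit)) {
    fx <- make_small_dataset(years = 2012:2016, params = sim_params(),
                             seed = 11)
    cfg <- model_config(n_draws = 200, n_chains = 2, n_warmup = 250,
                        seed = 5)
    local_fit_cache$fit <- fit_mortality(fx$data, config = cfg)
    local_fit_cache$fx <- fx
  }
  list(fit = local_fit_cache$fit, fx = local_fit_cache$fx)
}

# Independent microsimulation oracle: inverse-CDF sampling of lifetimes from
# a piecewise-constant hazard given by central rates m on the default age
# groups (constant hazard beyond the terminal lower bound).
microsim_lifetimes <- function(m, ages = age_groups(), n = 1e5) {
  A <- length(ages)
  lower <- ages$lower
  w <- ages$width
  S <- exp(-cumsum(c(0, m[-A] * w[-A])))  # survival to each lower bound
  u <- stats::runif(n)
  i <- findInterval(1 - u, 1 - S)
  t <- numeric(n)
  cl <- i < A
  ui <- stats::runif(n)
  qi <- -expm1(-m[i[cl]] * w[i[cl]])
  t[cl] <- lower[i[cl]] - log(1 - ui[cl] * qi) / m[i[cl]]
  if (any(!cl)) t[!cl] <- lower[A] + stats::rexp(sum(!cl), m[A])
  t
}

# Survival to each age boundary implied by piecewise-constant hazards
# (closed form, for interval-probability oracles).
piecewise_survival <- function(m, ages = age_groups()) {
  A <- length(ages)
  exp(-cumsum(c(0, m[-A] * ages$width[-A])))
}
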