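test_that("geography generation is nested, sized by the product, and deterministic", {
  g <- generate_geography(1, 1, 1, seed = 3)
  expect_length(g$area_ids, 1)
  expect_length(unique(g$district_of), 1)
  expect_length(unique(g$region_of), 1)

  g2 <- generate_geography(4, 3, 10, seed = 1)
  expect_length(g2$area_ids, 120)
  expect_length(unique(g2$district_of), 12)
  expect_length(unique(g2$region_of), 4)
  # every area in exactly one district, every district in one region
  expect_true(all(g2$area_ids %in% names(g2$district_of)))
  expect_true(all(g2$district_of %in% names(g2$region_of)))

  expect_identical(generate_geography(2, 2, 2, seed = 7),
                   generate_geography(2, 2, 2, seed = 7))
  expect_error(generate_geography(0, 1, 1), "positive")
})

test_that("area populations have the target median and obey the pyramid", {
  g <- generate_geography(1, 1, 1000, seed = 1)
  pop <- generate_population(g, years = 2019, median_pop = 7985, seed = 2)
  totals <- colSums(pop[, , 1])
  expect_lt(abs(stats::median(totals) - 7985) / 7985, 0.05)
  expect_true(all(pop >= 0))

  # degenerate dispersion: all areas identical
  pop0 <- generate_population(g, years = 2019, median_pop = 5000,
                              dispersion = 0, seed = 3)
  expect_equal(max(colSums(pop0[, , 1])), min(colSums(pop0[, , 1])))

  # bit-identical rerun
  expect_identical(pop, generate_population(g, years = 2019,
                                            median_pop = 7985, seed = 2))
  expect_error(generate_population(g, years = integer(0), median_pop = 100),
               "empty")
})

test_that("true rate surfaces degenerate correctly and look like human mortality", {
  g <- generate_geography(2, 2, 3, seed = 1)
  p0 <- sim_params(sigma_theta_area = 0, sigma_theta_district = 0,
                   sigma_theta_region = 0, sigma_phi_area = 0,
                   sigma_phi_district = 0, sigma_phi_region = 0,
                   sigma_xi = 0, sigma_nu = 0, sigma_omega = 0)
  rs <- generate_true_rates(g, years = 2010:2014, params = p0, seed = 4)
  # all areas share alpha + beta * t exactly
  tc <- 2010:2014 - mean(2010:2014)
  for (t in 1:5)
    for (m in 1:12)
      expect_equal(unname(rs$log_rate[, m, t]), unname(p0$alpha + p0$beta * tc[t]))

  # default age curve: J-shaped (infant > child, monotone rise in adulthood)
  a <- sim_params()$alpha
  expect_gt(a[1], a[2])
  i35 <- which(age_groups()$lower == 35)
  expect_true(all(diff(a[i35:19]) > 0))
})

test_that("latent component variances match their hyperparameters over replicates", {
  g <- generate_geography(2, 3, 4, seed = 1)  # 24 areas, 6 districts
  p <- sim_params()
  th <- xi <- nus <- oms <- c()
  for (k in 1:200) {
    rs <- generate_true_rates(g, years = 2010:2013, params = p, seed = k)
    th <- c(th, rs$components$theta_area)
    xi <- c(xi, as.vector(rs$components$xi))
    nus <- c(nus, as.vector(t(diff(t(rs$components$nu)))))
    oms <- c(oms, as.vector(t(diff(t(rs$components$omega)))))
  }
  expect_lt(abs(stats::sd(th) / p$sigma_theta_area - 1), 0.15)
  expect_lt(abs(stats::sd(xi) / p$sigma_xi - 1), 0.15)
  expect_lt(abs(stats::sd(nus) / p$sigma_nu - 1), 0.15)
  expect_lt(abs(stats::sd(oms) / p$sigma_omega - 1), 0.15)
  # time walks sum to zero by construction
  rs <- generate_true_rates(g, years = 2010:2013, params = p, seed = 999)
  expect_equal(rowSums(rs$components$nu), rep(0, 19), tolerance = 1e-12)
  expect_equal(rowSums(rs$components$omega), rep(0, 24), tolerance = 1e-12)
})

test_that("death sampling is Poisson with the right mean and conserves totals", {
  g <- generate_geography(1, 1, 1, seed = 1)
  ag <- tiny_ages()
  rs <- generate_true_rates(g, ag, years = 2010, params = tiny_params(),
                            seed = 2)

  # zero exposure -> zero deaths
  pop0 <- array(0, dim = c(5, 1, 1))
  expect_true(all(sample_deaths(rs, pop0, seed = 3)$deaths$female == 0))

  # one large cell: rate 0.01, population 1e6 -> 10000 +- 4 sigma
  rs1 <- rs; rs1$log_rate[] <- log(0.01)
  pop1 <- array(0, dim = c(5, 1, 1)); pop1[1, 1, 1] <- 1e6
  d <- sample_deaths(rs1, pop1, seed = 4)$deaths$female[1, 1, 1]
  expect_lt(abs(d - 10000), 400)

  # Monte-Carlo: mean(deaths / population) over many cells ~ rate within 1%
  g2 <- generate_geography(1, 1, 100, seed = 5)
  rs2 <- generate_true_rates(g2, ag, years = 2010:2019,
                             params = tiny_params(sigma_theta_area = 0,
                                                  sigma_xi = 0,
                                                  sigma_omega = 0),
                             seed = 6)
  rs2$log_rate[] <- log(0.02)
  pop2 <- array(50000, dim = dim(rs2$log_rate))
  dd <- sample_deaths(rs2, pop2, seed = 7)$deaths$female
  expect_lt(abs(mean(dd / pop2) / 0.02 - 1), 0.01)

  expect_identical(sample_deaths(rs, pop1, seed = 9),
                   sample_deaths(rs, pop1, seed = 9))
  expect_error(sample_deaths(rs, array(1, dim = c(3, 1, 1))), "aligned")
})

test_that("deprivation ranks are permutations with the requested correlation", {
  g <- generate_geography(1, 1, 500, seed = 1)
  rs <- generate_true_rates(g, years = 2010, seed = 2)
  x <- rowMeans(matrix(rs$log_rate[, , 1], nrow = 19)) # not needed directly

  r1 <- generate_deprivation_ranks(g, rs, correlation = 1,
                                   measures = "income", years = 2010, seed = 3)
  area_mean <- colMeans(rs$log_rate[, , 1])
  expect_identical(order(r1$rank), order(rank(area_mean, ties.method = "first")))

  r0 <- generate_deprivation_ranks(g, rs, correlation = 0,
                                   measures = "income", years = 2010, seed = 4)
  expect_lt(abs(stats::cor(r0$rank, area_mean, method = "spearman")), 0.1)

  # permutation property at the national scale: 6791 areas span 1..6791
  g2 <- generate_geography(1, 1, 6791, seed = 5)
  rs2 <- generate_true_rates(g2, tiny_ages(), years = 2019,
                             params = tiny_params(), seed = 6)
  r2 <- generate_deprivation_ranks(g2, rs2, correlation = 0.8,
                                   measures = "income", years = 2019, seed = 7)
  expect_identical(sort(r2$rank), 1:6791)
})

test_that("injected shocks change exactly one area-year and conserve totals", {
  fx <- make_small_dataset(years = 2014:2019, seed = 21)
  dat <- fx$data
  m <- 3

  # zero injection is the identity
  zero <- list(female = rep(0, 19))
  expect_equal(inject_shock(dat, dat$geography$area_ids[m], 2016, zero), dat,
               ignore_attr = TRUE)

  # a mass-fatality event: 68 extra deaths on a ~51-death baseline gives ~119
  base <- dat
  base$deaths$female[, m, ] <- 0
  base$deaths$female[19, m, match(2016:2018, dat$years)] <- c(48, 51, 51)
  extra <- list(female = c(rep(0, 18), 68))
  shocked <- inject_shock(base, dat$geography$area_ids[m], 2017, extra)
  expect_equal(sum(shocked$deaths$female[, m, match(2017, dat$years)]), 119)
  expect_equal(sum(shocked$deaths$female), sum(base$deaths$female) + 68)
  # all other cells untouched
  other <- setdiff(seq_along(dat$years), match(2017, dat$years))
  expect_equal(shocked$deaths$female[, , other],
               base$deaths$female[, , other], ignore_attr = TRUE)
  expect_equal(shocked$deaths$female[, -m, ], base$deaths$female[, -m, ],
               ignore_attr = TRUE)

  expect_error(inject_shock(base, dat$geography$area_ids[m], 2017,
                            list(female = rep(-1000, 19))), "negative")
  expect_error(inject_shock(base, "nope", 2017, extra), "not present")
})
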