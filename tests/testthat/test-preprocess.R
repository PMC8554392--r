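test_that("population repair fixes exactly the violating cells", {
  fx <- make_small_dataset(seed = 31)
  dat <- fx$data

  # plant k violations
  set.seed(1)
  k <- 7
  idx <- cbind(sample(19, k, TRUE), sample(12, k, TRUE), sample(6, k, TRUE))
  idx <- unique(idx); k <- nrow(idx)
  dat$population$female[idx] <- 0
  dat$deaths$female[idx] <- 5
  planted <- sum(dat$deaths$female > dat$population$female)
  r <- repair_population(dat)
  expect_equal(r$n_repaired, planted)
  expect_true(all(r$data$deaths$female <= r$data$population$female))
  expect_equal(r$data$population$female[idx], rep(5, k))

  # the rule itself: (deaths 5, pop 3) -> (5, 5)
  dat$population$female[1, 1, 1] <- 3
  dat$deaths$female[1, 1, 1] <- 5
  r2 <- repair_population(dat)
  expect_equal(r2$data$population$female[1, 1, 1], 5)
  expect_equal(r2$data$deaths$female[1, 1, 1], 5)

  # idempotence: already-repaired data unchanged
  r3 <- repair_population(r$data)
  expect_equal(r3$n_repaired, 0L)
  expect_identical(r3$data, r$data)
})

test_that("outlier-year interpolation replaces counts by the neighbour mean", {
  fx <- make_small_dataset(seed = 32)
  dat <- fx$data
  area <- dat$geography$area_ids[2]
  m <- 2; t <- match(2012, dat$years)

  # neighbour totals 48 and 51 -> interpolated total 49.5
  dat$deaths$female[, m, t - 1] <- 0; dat$deaths$female[19, m, t - 1] <- 48
  dat$deaths$female[, m, t + 1] <- 0; dat$deaths$female[19, m, t + 1] <- 51
  out <- interpolate_outlier_year(dat, area, 2012)
  expect_equal(sum(out$data$deaths$female[, m, t]), 49.5)

  # delta recovers the actual counts exactly
  expect_equal(out$data$deaths$female[, m, t] + out$adjustment$delta$female,
               dat$deaths$female[, m, t])

  # fixed point: actual equal to neighbour mean -> unchanged, delta 0
  dat2 <- dat
  dat2$deaths$female[, m, t] <-
    (dat2$deaths$female[, m, t - 1] + dat2$deaths$female[, m, t + 1]) / 2
  out2 <- interpolate_outlier_year(dat2, area, 2012)
  expect_identical(out2$data$deaths$female, dat2$deaths$female)
  expect_equal(sum(abs(out2$adjustment$delta$female)), 0)

  # boundary years are rejected
  expect_error(interpolate_outlier_year(dat, area, min(dat$years)), "interior")
  expect_error(interpolate_outlier_year(dat, area, max(dat$years)), "interior")
})

test_that("shock + interpolation compose as an outlier-repair protocol", {
  fx <- make_small_dataset(seed = 33)
  dat <- fx$data
  area <- dat$geography$area_ids[5]
  t <- match(2013, dat$years)
  extra <- list(female = c(rep(0, 15), 20, 20, 14, 14))
  shocked <- inject_shock(dat, area, 2013, extra)
  out <- interpolate_outlier_year(shocked, area, 2013)

  # interpolation removes the shock up to the neighbour-mean remainder
  interp <- (dat$deaths$female[, 5, t - 1] + dat$deaths$female[, 5, t + 1]) / 2
  expect_equal(out$data$deaths$female[, 5, t], interp)
  # delta total = injected total + (baseline - neighbour mean)
  expect_equal(sum(out$adjustment$delta$female),
               68 + sum(dat$deaths$female[, 5, t]) - sum(interp))
  # all other areas and years untouched
  expect_equal(out$data$deaths$female[, -5, ], dat$deaths$female[, -5, ],
               ignore_attr = TRUE)
})

test_that("add-back restores interpolated-out deaths in every posterior draw", {
  A <- 5; M <- 3; T <- 4; nd <- 20
  dn <- list(age = tiny_ages()$label, area = paste0("a", 1:M),
             year = as.character(2010:2013), draw = NULL)
  expected <- array(stats::runif(A * M * T * nd, 5, 30), dim = c(A, M, T, nd),
                    dimnames = dn)
  delta <- c(-2, 0, 3, 40, 27)  # total +68
  adj <- structure(list(area = "a2", year = 2011,
                        delta = list(female = delta)),
                   class = "outlier_adjustment")
  adj0 <- structure(list(area = "a2", year = 2011,
                         delta = list(female = rep(0, A))),
                    class = "outlier_adjustment")

  # delta 0 is the identity
  expect_identical(add_back_outlier(expected, adj0, "female"), expected)

  out <- add_back_outlier(expected, adj, "female")
  # every draw's total for that area-year increases by the delta total
  for (i in seq_len(nd))
    expect_equal(sum(out[, 2, 2, i]) - sum(expected[, 2, 2, i]), 68)
  # conservation over years, per draw
  expect_equal(apply(out, 4, sum), apply(expected, 4, sum) + 68)
  # everything else untouched
  expect_identical(out[, -2, , ], expected[, -2, , ])
  expect_identical(out[, , -2, ], expected[, , -2, ])

  # flooring at zero
  low <- expected; low[, 2, 2, ] <- 0.5
  out2 <- add_back_outlier(low, adj, "female")
  expect_true(all(out2 >= 0))
})

test_that("interpolate-then-add-back conserves observed deaths per age", {
  fx <- make_small_dataset(seed = 34)
  dat <- fx$data
  area <- dat$geography$area_ids[1]
  t <- match(2012, dat$years)
  actual <- dat$deaths$female[, 1, t]
  out <- interpolate_outlier_year(dat, area, 2012)
  # posterior expected deaths equal to the interpolated counts exactly
  nd <- 10
  expected <- array(rep(out$data$deaths$female, nd),
                    dim = c(dim(out$data$deaths$female), nd),
                    dimnames = c(dimnames(out$data$deaths$female),
                                 list(draw = NULL)))
  back <- add_back_outlier(expected, out$adjustment, "female")
  for (i in seq_len(nd))
    expect_equal(back[, 1, t, i], actual, tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("adjustments round-trip through the sidecar CSV", {
  adj <- structure(list(area = "R01_D01_A002", year = 2017,
                        delta = list(female = stats::rnorm(19),
                                     male = stats::rnorm(19))),
                   class = "outlier_adjustment")
  f <- withr::local_tempfile(fileext = ".csv")
  write_adjustment(adj, f)
  adj2 <- read_adjustment(f)
  expect_equal(adj2$area, adj$area)
  expect_equal(adj2$year, adj$year)
  expect_equal(adj2$delta$female, adj$delta$female, tolerance = 1e-12)
  expect_equal(adj2$delta$male, adj$delta$male, tolerance = 1e-12)
})
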