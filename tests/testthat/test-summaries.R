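make_e0_cube <- function(M = 20, T = 4, nd = 200, years = 2010:2013,
                         seed = 1, base = 80) {
  set.seed(seed)
  x <- array(base + stats::rnorm(M * T * nd, 0, 1), dim = c(M, T, nd),
             dimnames = list(area = paste0("a", seq_len(M)),
                             year = as.character(years), draw = NULL))
  class(x) <- "e0_draws"
  x
}

test_that("draw summaries follow the interpolated-percentile rule", {
  s <- summarize_draws(1:1000)
  expect_equal(s$median, 500.5)
  expect_equal(s$lower95, 25.975)
  expect_equal(s$upper95, 975.025)

  sc <- summarize_draws(rep(3.5, 10))
  expect_equal(unlist(sc), c(median = 3.5, lower95 = 3.5, upper95 = 3.5))

  # independent sorting-based recomputation
  set.seed(5)
  x <- matrix(stats::rnorm(50 * 999), 50)
  s2 <- summarize_draws(x)
  manual_q <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  for (i in c(1, 17, 50)) {
    expect_equal(s2$lower95[i], manual_q(x[i, ], 0.025), tolerance = 1e-12)
    expect_equal(s2$upper95[i], manual_q(x[i, ], 0.975), tolerance = 1e-12)
    expect_equal(s2$median[i], manual_q(x[i, ], 0.5), tolerance = 1e-12)
  }
  expect_error(summarize_draws(matrix(1, 2, 1)), "2 draws")
})

test_that("posterior probability of change follows the tie-half rule", {
  e0 <- make_e0_cube()
  # identical draws in both years -> exactly 50%
  e0[, 2, ] <- e0[, 1, ]
  p <- posterior_prob_change(e0, 2010, 2011)
  expect_equal(unname(p), rep(0.5, 20))

  # every draw higher in the later year -> 100%
  e0[, 3, ] <- e0[, 1, ] + 5
  expect_equal(unname(posterior_prob_change(e0, 2010, 2012)), rep(1, 20))

  # brute-force pairwise oracle
  e0r <- make_e0_cube(seed = 9)
  p2 <- posterior_prob_change(e0r, 2010, 2013)
  for (m in c(1, 7, 20)) {
    brute <- 0
    for (i in seq_len(dim(e0r)[3])) {
      brute <- brute + (e0r[m, 4, i] > e0r[m, 1, i]) +
        0.5 * (e0r[m, 4, i] == e0r[m, 1, i])
    }
    expect_equal(unname(p2[m]), brute / dim(e0r)[3])
  }
  # symmetry under year exchange
  expect_equal(unname(posterior_prob_change(e0r, 2010, 2013) +
                        posterior_prob_change(e0r, 2013, 2010)),
               rep(1, 20))
})

test_that("inequality gaps match per-draw brute force and order correctly", {
  e0 <- make_e0_cube(M = 100, nd = 150, seed = 3)
  g <- inequality_gaps(e0, 2011)
  x <- e0[, 2, ]
  brute_mm <- apply(x, 2, function(v) max(v) - min(v))
  brute_gap <- apply(x, 2, function(v) {
    q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
    q[2] - q[1]
  })
  expect_equal(g$gaps$median[g$gaps$metric == "max_min"],
               stats::median(brute_mm), tolerance = 1e-12)
  expect_equal(g$gaps$median[g$gaps$metric == "p99_p1"],
               stats::median(brute_gap), tolerance = 1e-12)
  # gap ordering holds in every draw
  expect_true(all(brute_mm >= brute_gap))
  expect_false(g$few_areas)

  # all areas identical within each draw -> both gaps zero
  e00 <- make_e0_cube(M = 10)
  for (i in seq_len(dim(e00)[3])) e00[, , i] <- e00[1, , i][col(e00[, , i])]
  g0 <- inequality_gaps(e00, 2010)
  expect_equal(g0$gaps$median, c(0, 0), tolerance = 1e-12)

  # two areas: interpolated percentiles give 98% of the full range
  e02 <- make_e0_cube(M = 2, nd = 50, seed = 4)
  g2 <- inequality_gaps(e02, 2010)
  mm <- g2$gaps[g2$gaps$metric == "max_min", ]
  pp <- g2$gaps[g2$gaps$metric == "p99_p1", ]
  expect_equal(pp$median, 0.98 * mm$median, tolerance = 1e-10)
  expect_true(g2$few_areas)

  # ranked curve is monotone in rank
  expect_true(all(diff(g$ranked$median) >= 0))
})

test_that("period changes telescope and planted declines are counted", {
  e0 <- make_e0_cube(M = 30, T = 6, nd = 100, years = 2002:2007, seed = 6)
  ch <- change_by_period(e0, c(2002, 2004, 2007))
  expect_equal(nrow(ch$changes), 60)
  # telescoping: sum of per-period changes equals the full change, draw-wise
  full <- e0[, 6, ] - e0[, 1, ]
  parts <- (e0[, 3, ] - e0[, 1, ]) + (e0[, 6, ] - e0[, 3, ])
  expect_equal(full, parts, tolerance = 1e-12)

  # planted decline of 1 year in k areas dominates the draw noise
  k <- 5
  e0p <- make_e0_cube(M = 30, T = 2, nd = 200, years = 2002:2003, seed = 7)
  e0p[, 2, ] <- e0p[, 1, ] + 0.5 + 0.05 * matrix(stats::rnorm(30 * 200), 30)
  e0p[seq_len(k), 2, ] <- e0p[seq_len(k), 1, ] - 1
  chp <- change_by_period(e0p, c(2002, 2003))
  expect_equal(chp$declining$n_declining, k)

  # stationary null: roughly half the areas decline
  e0n <- make_e0_cube(M = 200, T = 2, nd = 300, years = 2002:2003, seed = 8)
  chn <- change_by_period(e0n, c(2002, 2003))
  expect_gt(chn$declining$n_declining, 60)
  expect_lt(chn$declining$n_declining, 140)
})

test_that("sex comparison handles affine, independent and partition cases", {
  f <- make_e0_cube(M = 50, seed = 10, base = 83)
  m <- f - 3
  sc <- sex_comparison(f, m, 2010)
  expect_equal(sc$correlation, 1, tolerance = 1e-12)
  expect_equal(unname(sc$difference), rep(3, 50), tolerance = 1e-12)
  expect_equal(unname(sc$bands),
               c(male_advantage = 0, under_1 = 0, from_1_to_5 = 50,
                 over_5 = 0), ignore_attr = TRUE)
  expect_equal(sum(sc$bands), 50)

  # independent surfaces decorrelate
  f2 <- make_e0_cube(M = 500, seed = 11)
  m2 <- make_e0_cube(M = 500, seed = 12)
  sc2 <- sex_comparison(f2, m2, 2010)
  expect_lt(abs(sc2$correlation), 0.15)
  expect_equal(sum(sc2$bands), 500)

  dimnames(m2)[[1]][1] <- "zzz"
  expect_error(sex_comparison(f2, m2, 2010), "same areas")
})

test_that("deprivation smoothing is exact on linear signal and near-OLS at span 1", {
  n <- 300
  set.seed(13)
  ranks <- sample(n)
  e0 <- 85 - 0.01 * ranks
  da <- deprivation_association(e0, ranks, span = 0.5)
  interior <- da$grid > 10 & da$grid < n - 10
  expect_lt(max(abs(da$fitted[interior] - (85 - 0.01 * da$grid[interior]))),
            1e-6)
  expect_lt(da$residual_iqr, 1e-8)

  # random permutation of e0: flat curve within noise
  e0r <- sample(e0)
  dar <- deprivation_association(e0r, ranks, span = 0.9)
  expect_lt(diff(range(dar$fitted[interior])), 3 * stats::sd(e0r))

  # span 1 approximates the global least-squares line
  e0n <- 85 - 0.01 * ranks + stats::rnorm(n, 0, 0.5)
  da1 <- deprivation_association(e0n, ranks, span = 1)
  ols <- stats::lm(e0n ~ ranks)
  pred <- stats::predict(ols, data.frame(ranks = da1$grid))
  expect_lt(stats::median(abs(da1$fitted - pred)), 0.15)

  expect_error(deprivation_association(e0, ranks, span = 0), "span")
  expect_error(deprivation_association(e0, ranks, span = 1.5), "span")
  expect_error(deprivation_association(e0, ranks[c(1, 1, 3:n)]), "permutation")
})
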