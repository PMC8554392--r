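test_that("parameter bookkeeping matches the model structure", {
  # full design: 120 areas, 19 ages, 18 years
  fx <- make_small_dataset(4, 3, 10, years = 2002:2019, seed = 41)
  spec <- build_model(fx$data, "female")
  expect_equal(spec$n_latent,
               19 + 19 + 120 + 12 + 4 + 120 + 12 + 4 + 19 * 120 + 19 * 18 +
                 120 * 18)

  # degenerate: one area, one year -> age intercepts only
  fx1 <- make_small_dataset(1, 1, 1, years = 2010, seed = 42)
  spec1 <- build_model(fx1$data, "female")
  expect_equal(spec1$n_latent, 19)
  expect_false(spec1$layout$inc_t)
  expect_false(spec1$layout$inc_m)

  # precondition: unrepaired data rejected
  bad <- fx1$data
  bad$deaths$female[1, 1, 1] <- bad$population$female[1, 1, 1] + 1
  expect_error(build_model(bad, "female"), "repair")
})

test_that("analytic gradients agree with finite differences", {
  fx <- make_small_dataset(2, 2, 2, years = 2011:2014, seed = 43)
  spec <- build_model(fx$data, "female")
  q <- arealex:::init_chain(spec, 99)
  g <- arealex:::model_lp_grad(spec, q)$grad
  eps <- 1e-6
  set.seed(7)
  idx <- sort(sample(length(q), 80))
  fd <- vapply(idx, function(i) {
    qp <- q; qp[i] <- qp[i] + eps
    qm <- q; qm[i] <- qm[i] - eps
    (arealex:::model_lp_grad(spec, qp)$lp -
       arealex:::model_lp_grad(spec, qm)$lp) / (2 * eps)
  }, 0)
  expect_lt(max(abs(fd - g[idx]) / pmax(1, abs(fd))), 1e-4)

  # also with some scales fixed
  cfgf <- model_config(fixed_sigma = c(xi = 0.1, nu = 0.01))
  specf <- build_model(fx$data, "female", cfgf)
  qf <- arealex:::init_chain(specf, 100)
  gf <- arealex:::model_lp_grad(specf, qf)$grad
  idxf <- sort(sample(length(qf), 40))
  fdf <- vapply(idxf, function(i) {
    qp <- qf; qp[i] <- qp[i] + eps
    qm <- qf; qm[i] <- qm[i] - eps
    (arealex:::model_lp_grad(specf, qp)$lp -
       arealex:::model_lp_grad(specf, qm)$lp) / (2 * eps)
  }, 0)
  expect_lt(max(abs(fdf - gf[idxf]) / pmax(1, abs(fdf))), 1e-4)
})

test_that("time random walks sum to zero in every retained draw", {
  cf <- cached_small_fit()
  f <- cf$fit$fits$female
  for (i in seq(1, nrow(f$draws), by = 23)) {
    u <- arealex:::unpack_draw(f$spec, f$draws[i, ])
    expect_equal(max(abs(rowSums(u$nu))), 0, tolerance = 1e-10)
    expect_equal(max(abs(rowSums(u$omega))), 0, tolerance = 1e-10)
  }
})

test_that("posterior rates track the data and stay positive with zero counts", {
  cf <- cached_small_fit()
  fit <- cf$fit
  lr <- posterior_log_rates(fit, "female")
  expect_true(all(is.finite(lr)))
  expect_equal(dim(lr)[4], 200)
  # rates strictly positive even where observed deaths are zero
  y <- cf$fx$data$deaths$female
  expect_true(all(exp(lr) > 0))
  # pooled empirical vs posterior-median age curve agree broadly
  med <- apply(lr, 1, stats::median)
  emp <- log((apply(y, 1, sum) + 0.5) / apply(cf$fx$data$population$female,
                                              1, sum))
  expect_gt(stats::cor(med, emp), 0.98)
})

test_that("inferred rates are invariant to a common exposure scaling", {
  ag <- tiny_ages()
  g <- generate_geography(1, 2, 3, seed = 44)
  pop <- generate_population(g, ag, 2012:2015, median_pop = 20000, seed = 45)
  rs <- generate_true_rates(g, ag, 2012:2015, params = tiny_params(),
                            seed = 46)
  dat <- repair_population(sample_deaths(rs, pop, "female", seed = 47))$data
  dat2 <- dat
  dat2$population$female <- dat$population$female * 4
  dat2$deaths$female <- dat$deaths$female * 4
  cfg <- model_config(n_draws = 200, n_chains = 1, n_warmup = 250, seed = 8)
  fit1 <- fit_mortality(dat, config = cfg)
  fit2 <- fit_mortality(dat2, config = cfg)
  m1 <- apply(posterior_log_rates(fit1, "female"), 1:3, stats::median)
  m2 <- apply(posterior_log_rates(fit2, "female"), 1:3, stats::median)
  # agreement within Monte-Carlo error, which shrinks with exposure; allow
  # a modest absolute band on the log scale
  expect_lt(stats::median(abs(m1 - m2)), 0.1)
  expect_gt(stats::cor(as.vector(m1), as.vector(m2)), 0.98)
})

test_that("expected-death draws are population times rate, cell by cell", {
  # arithmetic identity on a hand-built draw cube
  lr <- array(log(0.01), dim = c(2, 2, 1, 3),
              dimnames = list(age = c("0", "1+"), area = c("a", "b"),
                              year = "2010", draw = NULL))
  P <- array(1000, dim = c(2, 2, 1))
  ed <- posterior_expected_deaths(lr, P)
  expect_true(all(abs(ed - 10) < 1e-12))
  # zero population -> zero expected deaths
  P0 <- array(0, dim = c(2, 2, 1))
  expect_true(all(posterior_expected_deaths(lr, P0) == 0))
  expect_error(posterior_expected_deaths(lr, array(1, c(3, 2, 1))), "align")

  # brute-force recomputation on a real fit
  cf <- cached_small_fit()
  lr2 <- posterior_log_rates(cf$fit, "female")
  ed2 <- posterior_expected_deaths(lr2, cf$fx$data$population$female)
  i <- 7
  brute <- sum(cf$fx$data$population$female * exp(lr2[, , , i]))
  expect_equal(sum(ed2[, , , i]), brute, tolerance = 1e-10)
})

test_that("convergence diagnostics are calibrated on constructed chains", {
  set.seed(1)
  # iid normal draws: R-hat ~ 1
  x <- matrix(stats::rnorm(4 * 250), 250, 4)
  expect_lt(abs(rhat(x) - 1), 0.01)
  expect_gt(ess(x), 500)

  # two chains with disjoint means: R-hat >> 1.1
  y <- cbind(stats::rnorm(250, 0), stats::rnorm(250, 10))
  expect_gt(rhat(y), 1.1)

  # cross-check against an independent implementation of the formulas
  ref_rhat <- function(x) {
    n <- nrow(x) %/% 2
    sp <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
      cbind(x[1:n, j], x[(n + 1):(2 * n), j])))
    W <- mean(apply(sp, 2, stats::var))
    B <- n * stats::var(apply(sp, 2, mean))
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  z <- matrix(stats::rnorm(4 * 251), 251, 4)  # odd length exercises split
  expect_equal(rhat(z), ref_rhat(z), tolerance = 1e-8)

  # single chain: R-hat unavailable, ESS still defined
  cf <- cached_small_fit()
  d1 <- cf$fit$fits$female$diagnostics
  expect_true(is.finite(d1$max_rhat))  # two chains here
  expect_true(all(is.finite(d1$table$ess)))
})

test_that("fit methods expose coherent summaries", {
  cf <- cached_small_fit()
  fit <- cf$fit
  expect_output(print(fit), "mortality_fit")
  s <- summary(fit)
  expect_true(all(s$scales$lower95 <= s$scales$median + 1e-12))
  co <- coef(fit)
  expect_length(co$alpha, 19)
  expect_gt(co$alpha[19], co$alpha[3])  # old-age mortality above child
  res <- residuals(fit)
  expect_equal(dim(res), dim(cf$fx$data$deaths$female))
  sim <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sim, 2)
  expect_true(all(sim[[1]] >= 0))
  pr <- predict(fit, type = "rate")
  expect_true(all(pr$lower95 <= pr$median & pr$median <= pr$upper95))
})
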