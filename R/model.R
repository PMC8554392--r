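SIGMA_SLOTS <- c("alpha", "beta", "theta_area", "theta_district",
                 "theta_region", "phi_area", "phi_district", "phi_region",
                 "xi", "nu", "omega")

#' Model configuration
#'
#' Hyperprior scales, fixed-scale overrides and MCMC settings for the
#' hierarchical spatiotemporal mortality model.
#'
#' All scale parameters (SDs of random-walk increments, nested deviations and
#' interactions) get half-normal hyperpriors; `prior_scale` gives the
#' half-normal scale per component in log-rate units (per year for slope
#' components). A component named in `fixed_sigma` is not sampled but held at
#' the given value — useful for fitting with known hyperparameters.
#'
#' @param prior_scale Named numeric; any subset of
#'   `r paste0('"', paste(SIGMA_SLOTS, collapse = '", "'), '"')`.
#' @param fixed_sigma Named numeric of scales to hold fixed (same names).
#' @param n_draws Total retained posterior draws across chains (default 1000).
#' @param n_chains,n_warmup,thin MCMC settings (defaults 4, 1000, 1).
#' @param target_accept,max_depth NUTS tuning.
#' @param seed Integer seed for the sampler.
#' @param anchor_alpha_mean,anchor_alpha_sd,anchor_beta_sd Weak normal
#'   anchors on the first element of the age intercept and slope walks.
#' @param rhat_threshold,min_ess Convergence flags: largest split R-hat and
#'   smallest effective sample size tolerated before the fit is flagged.
#' @return A list of class `model_config`.
#' @export
model_config <- function(prior_scale = NULL, fixed_sigma = NULL,
                         n_draws = 1000, n_chains = 4, n_warmup = 1000,
                         thin = 1, target_accept = 0.9, max_depth = 10,
                         seed = 1L,
                         anchor_alpha_mean = -5, anchor_alpha_sd = 10,
                         anchor_beta_sd = 1,
                         rhat_threshold = 1.05, min_ess = 100) {
  ps <- c(alpha = 1, beta = 0.1, theta_area = 0.5, theta_district = 0.5,
          theta_region = 0.5, phi_area = 0.1, phi_district = 0.1,
          phi_region = 0.1, xi = 0.5, nu = 0.5, omega = 0.5)
  if (!is.null(prior_scale)) {
    bad <- setdiff(names(prior_scale), SIGMA_SLOTS)
    if (length(bad)) stop_invalid("unknown prior_scale names: ",
                                  paste(bad, collapse = ", "))
    ps[names(prior_scale)] <- prior_scale
  }
  if (any(ps <= 0)) stop_invalid("prior scales must be > 0")
  fx <- rep(NA_real_, length(SIGMA_SLOTS))
  names(fx) <- SIGMA_SLOTS
  if (!is.null(fixed_sigma)) {
    bad <- setdiff(names(fixed_sigma), SIGMA_SLOTS)
    if (length(bad)) stop_invalid("unknown fixed_sigma names: ",
                                  paste(bad, collapse = ", "))
    if (any(fixed_sigma < 0)) stop_invalid("fixed sigmas must be >= 0")
    fx[names(fixed_sigma)] <- fixed_sigma
  }
  if (n_chains < 1 || n_draws < n_chains)
    stop_invalid("need n_draws >= n_chains >= 1")
  structure(list(prior_scale = ps, fixed_sigma = fx, n_draws = n_draws,
                 n_chains = n_chains, n_warmup = n_warmup, thin = thin,
                 target_accept = target_accept, max_depth = max_depth,
                 seed = as.integer(seed),
                 anchor_alpha_mean = anchor_alpha_mean,
                 anchor_alpha_sd = anchor_alpha_sd,
                 anchor_beta_sd = anchor_beta_sd,
                 rhat_threshold = rhat_threshold, min_ess = min_ess),
            class = "model_config")
}

#' Build the model specification for one sex
#'
#' Assembles the data arrays, index maps and parameter layout of the
#' hierarchical model for log death rates:
#' age intercepts and slopes with first-order random-walk structure over age;
#' area, district and region intercept and slope deviations (zero-mean
#' Gaussians at each nesting level); independent age-area interactions; and
#' per-age and per-area non-linear time effects as first-order random walks
#' constrained to sum to zero over time. Degenerate designs are handled by
#' pinning: with a single year all slope and time-walk components are fixed
#' at zero, with a single area all area-level components are.
#'
#' @param data A repaired [mortality_data()] object (deaths <= population in
#'   every cell; see [repair_population()]).
#' @param sex Which sex to model.
#' @param config A [model_config()].
#' @return A list of class `model_spec`; its `n_latent` field counts the
#'   latent effects of the model in the natural (untransformed)
#'   parameterisation.
#' @export
build_model <- function(data, sex = "female", config = model_config()) {
  stopifnot(inherits(data, "mortality_data"))
  sex <- match.arg(sex, sexes_of(data))
  y <- data$deaths[[sex]]
  P <- data$population[[sex]]
  if (any(y > P))
    stop_invalid("dataset not repaired: deaths exceed population in ",
                 sum(y > P), " cell(s); run repair_population() first")
  gi <- geography_index(data$geography)
  A <- length(data$ages); M <- length(gi$areas)
  D <- length(gi$districts); R <- length(gi$regions)
  T <- length(data$years)
  inc_t <- T > 1; inc_m <- M > 1
  n_latent <- A + A * inc_t + (M + D + R) * inc_m +
    (M + D + R) * (inc_m && inc_t) + A * M * inc_m + A * T * inc_t +
    M * T * (inc_m && inc_t)
  sig_fixed <- !is.na(config$fixed_sigma)
  layout <- cpp_param_layout(as.integer(c(A, M, T, D, R)), sig_fixed)
  structure(list(
    sex = sex, y = round_half_even(as.vector(y)), P = as.vector(P),
    dims = c(A = A, M = M, T = T, D = D, R = R),
    tc = data$years - mean(data$years),
    dom = gi$dist_of_area - 1L, rod = gi$reg_of_dist - 1L,
    gi = gi, ages = data$ages, years = data$years,
    sig_fixed = sig_fixed,
    sig_value = ifelse(sig_fixed, config$fixed_sigma, 0),
    sig_prior = unname(config$prior_scale),
    anchors = c(config$anchor_alpha_mean, config$anchor_alpha_sd,
                config$anchor_beta_sd),
    layout = layout, n_latent = n_latent, config = config),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> sex ", x$sex, ": ", paste(x$dims[1:3], collapse = " x "),
      " cells, ", x$n_latent, " latent effects, ", x$layout$npar,
      " sampled parameters\n", sep = "")
  invisible(x)
}

# log posterior and gradient at a packed parameter vector (testing hook)
model_lp_grad <- function(spec, q) {
  cpp_lp_grad(q, spec$y, spec$P, as.integer(unname(spec$dims)), spec$tc,
              spec$dom, spec$rod, spec$sig_fixed, unname(spec$sig_value),
              spec$sig_prior, spec$anchors)
}

init_chain <- function(spec, chain_seed) {
  L <- spec$layout
  A <- spec$dims[["A"]]; M <- spec$dims[["M"]]; T <- spec$dims[["T"]]
  q <- numeric(L$npar)
  y3 <- array(spec$y, dim = c(A, M, T))
  P3 <- array(spec$P, dim = c(A, M, T))
  alpha0 <- log((apply(y3, 1, sum) + 0.5) / (apply(P3, 1, sum) + 1))
  with_seed(chain_seed, {
    q[L$o_alpha + seq_len(A)] <- alpha0 + stats::rnorm(A, 0, 0.05)
    q[seq_len(L$npar)[-(L$o_alpha + seq_len(A))]] <-
      stats::rnorm(L$npar - A, 0, 0.05)
    if (L$n_eta > 0)
      q[L$o_eta + seq_len(L$n_eta)] <- log(0.1) + stats::rnorm(L$n_eta, 0, 0.1)
  })
  q
}

#' Fit the hierarchical spatiotemporal mortality model
#'
#' Fits the Poisson log-rate model separately for each requested sex using
#' the package's built-in No-U-Turn sampler, and returns posterior draws of
#' every model parameter. Non-convergence (split R-hat or effective sample
#' size beyond the configured thresholds) is flagged in the result, never
#' silently rerun.
#'
#' @param data A repaired [mortality_data()] object.
#' @param sexes Sexes to fit (default: all present).
#' @param config A [model_config()].
#' @param verbose Print progress.
#' @return An object of class `mortality_fit` with elements `draws` (named
#'   list per sex: matrix of retained draws x parameters), `spec`,
#'   `diagnostics`, `config` and `data`.
#' @export
fit_mortality <- function(data, sexes = NULL, config = model_config(),
                          verbose = FALSE) {
  stopifnot(inherits(data, "mortality_data"))
  sexes <- sexes %||% sexes_of(data)
  iter <- ceiling(config$n_draws / config$n_chains) * config$thin
  fits <- list()
  for (s in sexes) {
    spec <- build_model(data, s, config)
    t0 <- proc.time()[3]
    chains <- lapply(seq_len(config$n_chains), function(ch) {
      cseed <- config$seed * 1009L + ch
      q0 <- init_chain(spec, cseed)
      cpp_nuts(q0, spec$y, spec$P, as.integer(unname(spec$dims)), spec$tc,
               spec$dom, spec$rod, spec$sig_fixed, unname(spec$sig_value),
               spec$sig_prior, spec$anchors,
               as.integer(config$n_warmup), as.integer(iter),
               as.integer(config$thin), config$target_accept,
               as.integer(config$max_depth), as.integer(cseed),
               TRUE)
    })
    draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
    lp <- unlist(lapply(chains, `[[`, "lp"))
    diag <- diagnose_chains(spec, chains, config)
    diag$runtime <- unname(proc.time()[3] - t0)
    if (verbose)
      message(sprintf("[%s] %d draws in %.1fs; accept %.2f; max Rhat %.3f%s",
                      s, nrow(draws), diag$runtime, diag$accept_rate,
                      diag$max_rhat,
                      if (diag$converged) "" else " [NOT CONVERGED]"))
    fits[[s]] <- list(draws = draws, lp = lp, spec = spec, diagnostics = diag)
  }
  structure(list(sexes = names(fits), fits = fits, config = config,
                 data = data), class = "mortality_fit")
}

# monitored scalars: lp, hyper-scales, age intercepts/slopes
diagnose_chains <- function(spec, chains, config) {
  L <- spec$layout
  A <- spec$dims[["A"]]
  mon <- c(L$o_alpha + seq_len(A),
           if (L$inc_t) L$o_beta + seq_len(A),
           if (L$n_eta > 0) L$o_eta + seq_len(L$n_eta))
  lab <- c(paste0("alpha[", seq_len(A), "]"),
           if (L$inc_t) paste0("beta_raw[", seq_len(A), "]"),
           if (L$n_eta > 0) paste0("log_sigma_",
                                   SIGMA_SLOTS[!spec$sig_fixed &
                                                 eta_active(spec)]))
  per_param <- function(idx) {
    m <- vapply(chains, function(ch) ch$draws[, idx], numeric(nrow(chains[[1]]$draws)))
    c(rhat = rhat(m), ess = ess(m))
  }
  lpmat <- vapply(chains, `[[`, numeric(length(chains[[1]]$lp)), "lp")
  stats <- t(vapply(mon, per_param, c(rhat = 0, ess = 0)))
  tab <- data.frame(param = lab, rhat = stats[, "rhat"], ess = stats[, "ess"])
  tab <- rbind(tab, data.frame(param = "lp", rhat = rhat(lpmat), ess = ess(lpmat)))
  n_chains <- length(chains)
  max_rhat <- if (n_chains >= 2) max(tab$rhat, na.rm = TRUE) else NA_real_
  min_ess <- min(tab$ess, na.rm = TRUE)
  list(table = tab, max_rhat = max_rhat, min_ess = min_ess,
       divergences = sum(vapply(chains, `[[`, 0L, "divergences")),
       accept_rate = mean(vapply(chains, `[[`, 0, "accept_rate")),
       converged = (is.na(max_rhat) || max_rhat <= config$rhat_threshold) &&
         min_ess >= min(config$min_ess,
                        0.5 * n_chains * nrow(chains[[1]]$draws)))
}

eta_active <- function(spec) {
  unlist(spec$layout$eta_of_slot) >= 0
}

#' Split R-hat of one scalar across chains
#'
#' Classic split-R-hat: each chain is halved, and the potential scale
#' reduction factor is computed from the between- and within-half variances.
#'
#' @param x Numeric matrix, iterations x chains (>= 2 columns after
#'   splitting, i.e. at least one chain with >= 4 iterations).
#' @return R-hat (>= 1 up to sampling noise).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2
  if (n < 2) return(NA_real_)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(n), j], x[n + seq_len(n), j])))
  W <- mean(apply(halves, 2, stats::var))
  B <- n * stats::var(colMeans(halves))
  if (W == 0) return(1)
  sqrt((W * (n - 1) / n + B / n) / W)
}

#' Effective sample size of one scalar across chains
#'
#' Multi-chain effective sample size from per-chain autocovariances with
#' Geyer's initial-monotone-positive-sequence truncation.
#'
#' @param x Numeric matrix, iterations x chains.
#' @return Estimated effective sample size.
#' @export
ess <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); C <- ncol(x)
  if (n < 4) return(NA_real_)
  acov <- vapply(seq_len(C), function(j)
    stats::acf(x[, j], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1], numeric(n))
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  var_plus <- W * (n - 1) / n
  if (C > 1) var_plus <- var_plus + stats::var(colMeans(x))
  if (var_plus == 0) return(C * n)
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer: sum consecutive pairs while positive and monotone decreasing
  tau <- 0; prev <- Inf
  for (k in seq(1, n - 1, by = 2)) {
    pair <- rho[k] + if (k + 1 <= n) rho[k + 1] else 0
    if (is.na(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
  }
  max(C * n / max(2 * tau - 1, 1e-10), 1e-10)
}

#' Convergence diagnostics of a fitted model
#'
#' @param fit A [fit_mortality()] object.
#' @return A named list per sex with the monitored-parameter table (split
#'   R-hat and effective sample size), divergence counts and an overall
#'   pass/fail flag. With a single chain, R-hat is unavailable and the check
#'   degrades to effective sample size only.
#' @export
check_convergence <- function(fit) {
  stopifnot(inherits(fit, "mortality_fit"))
  lapply(fit$fits, `[[`, "diagnostics")
}

# ---- posterior reconstruction ----

# natural-scale components of one packed draw
unpack_draw <- function(spec, q) {
  L <- spec$layout
  A <- spec$dims[["A"]]; M <- spec$dims[["M"]]; T <- spec$dims[["T"]]
  D <- spec$dims[["D"]]; R <- spec$dims[["R"]]
  sig <- ifelse(spec$sig_fixed, spec$sig_value, NA_real_)
  eo <- unlist(L$eta_of_slot)
  free <- eo >= 0
  sig[free] <- exp(q[L$o_eta + eo[free] + 1])
  sig[is.na(sig)] <- 0
  names(sig) <- SIGMA_SLOTS
  alpha <- q[L$o_alpha + seq_len(A)]
  beta <- if (L$inc_t) {
    raw <- q[L$o_beta + seq_len(A)]
    raw[1] + sig["beta"] * cumsum(c(0, raw[-1]))
  } else rep(0, A)
  if (L$inc_m) {
    theta_area <- sig["theta_area"] * q[L$o_zthm + seq_len(M)]
    theta_district <- sig["theta_district"] * q[L$o_zthd + seq_len(D)]
    theta_region <- sig["theta_region"] * q[L$o_zthr + seq_len(R)]
    xi <- matrix(sig["xi"] * q[L$o_zxi + seq_len(A * M)], A, M)
  } else {
    theta_area <- rep(0, M); theta_district <- rep(0, D)
    theta_region <- rep(0, R); xi <- matrix(0, A, M)
  }
  if (L$inc_mt) {
    phi_area <- sig["phi_area"] * q[L$o_zphm + seq_len(M)]
    phi_district <- sig["phi_district"] * q[L$o_zphd + seq_len(D)]
    phi_region <- sig["phi_region"] * q[L$o_zphr + seq_len(R)]
  } else {
    phi_area <- rep(0, M); phi_district <- rep(0, D); phi_region <- rep(0, R)
  }
  nu <- if (L$inc_t) {
    inc <- matrix(sig["nu"] * q[L$o_zdnu + seq_len(A * (T - 1))], T - 1, A)
    walk <- rbind(0, apply(inc, 2, cumsum))
    t(walk) - rowMeans(t(walk))
  } else matrix(0, A, T)
  omega <- if (L$inc_mt) {
    inc <- matrix(sig["omega"] * q[L$o_zdom + seq_len(M * (T - 1))], T - 1, M)
    walk <- rbind(0, apply(inc, 2, cumsum))
    t(walk) - rowMeans(t(walk))
  } else matrix(0, M, T)
  list(alpha = alpha, beta = beta, theta_area = theta_area,
       theta_district = theta_district, theta_region = theta_region,
       phi_area = phi_area, phi_district = phi_district,
       phi_region = phi_region, xi = xi, nu = nu, omega = omega, sigma = sig)
}

log_rate_of_draw <- function(spec, comp) {
  A <- spec$dims[["A"]]; M <- spec$dims[["M"]]; T <- spec$dims[["T"]]
  dom <- spec$dom + 1L; rod <- spec$rod + 1L
  Theta <- comp$theta_area + comp$theta_district[dom] +
    comp$theta_region[rod[dom]]
  Phi <- comp$phi_area + comp$phi_district[dom] + comp$phi_region[rod[dom]]
  out <- array(0, dim = c(A, M, T))
  for (t in seq_len(T)) {
    out[, , t] <- (comp$alpha + comp$beta * spec$tc[t] + comp$nu[, t]) +
      rep(Theta + Phi * spec$tc[t] + comp$omega[, t], each = A) + comp$xi
  }
  out
}

#' Posterior draws of log death rates
#'
#' Reconstructs the log-rate surface for every retained draw.
#'
#' @param fit A [fit_mortality()] object.
#' @param sex Sex to extract.
#' @return Array (ages x areas x years x draws) with dimnames.
#' @export
posterior_log_rates <- function(fit, sex = fit$sexes[1]) {
  stopifnot(inherits(fit, "mortality_fit"))
  f <- fit$fits[[sex]]
  if (is.null(f)) stop_invalid("no fit for sex ", sex)
  spec <- f$spec
  nd <- nrow(f$draws)
  dm <- unname(spec$dims[c("A", "M", "T")])
  out <- array(NA_real_, dim = c(dm, nd),
               dimnames = list(age = spec$ages$label, area = spec$gi$areas,
                               year = as.character(spec$years),
                               draw = NULL))
  for (i in seq_len(nd))
    out[, , , i] <- log_rate_of_draw(spec, unpack_draw(spec, f$draws[i, ]))
  out
}

#' Posterior draws of expected deaths
#'
#' Expected deaths = population x exp(log rate), per draw and cell.
#'
#' @param log_rates Array from [posterior_log_rates()]
#'   (ages x areas x years x draws).
#' @param population Aligned population array (ages x areas x years).
#' @return Array of the same shape as `log_rates`.
#' @export
posterior_expected_deaths <- function(log_rates, population) {
  d <- dim(log_rates)
  if (!identical(dim(population), d[1:3]))
    stop_invalid("population not aligned with log-rate draws")
  array(as.vector(population) * exp(as.vector(log_rates)), dim = d,
        dimnames = dimnames(log_rates))
}

# ---- methods ----

#' @export
print.mortality_fit <- function(x, ...) {
  cat("<mortality_fit> sexes: ", paste(x$sexes, collapse = ", "), "\n", sep = "")
  for (s in x$sexes) {
    d <- x$fits[[s]]$diagnostics
    cat(sprintf("  %s: %d draws, accept %.2f, divergences %d, max Rhat %s, min ESS %.0f%s\n",
                s, nrow(x$fits[[s]]$draws), d$accept_rate, d$divergences,
                ifelse(is.na(d$max_rhat), "NA", sprintf("%.3f", d$max_rhat)),
                d$min_ess, if (d$converged) "" else "  ** NOT CONVERGED **"))
  }
  invisible(x)
}

#' @export
summary.mortality_fit <- function(object, ...) {
  out <- lapply(object$sexes, function(s) {
    f <- object$fits[[s]]
    sig <- t(vapply(seq_len(nrow(f$draws)), function(i)
      unpack_draw(f$spec, f$draws[i, ])$sigma, numeric(length(SIGMA_SLOTS))))
    data.frame(sex = s, component = SIGMA_SLOTS,
               median = apply(sig, 2, stats::median),
               lower95 = apply(sig, 2, q_interp, 0.025),
               upper95 = apply(sig, 2, q_interp, 0.975))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(list(scales = out,
                 diagnostics = check_convergence(object)),
            class = "summary.mortality_fit")
}

#' @export
print.summary.mortality_fit <- function(x, ...) {
  cat("Posterior summaries of scale parameters (SD, log-rate units):\n")
  print(x$scales, digits = 3)
  for (s in names(x$diagnostics)) {
    d <- x$diagnostics[[s]]
    cat(sprintf("\n%s: max Rhat %s, min ESS %.0f, %d divergence(s), %s\n",
                s, ifelse(is.na(d$max_rhat), "NA", sprintf("%.3f", d$max_rhat)),
                d$min_ess, d$divergences,
                if (d$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' @export
coef.mortality_fit <- function(object, sex = object$sexes[1], ...) {
  f <- object$fits[[sex]]
  spec <- f$spec
  A <- spec$dims[["A"]]
  ab <- t(vapply(seq_len(nrow(f$draws)), function(i) {
    u <- unpack_draw(spec, f$draws[i, ])
    c(u$alpha, u$beta)
  }, numeric(2 * A)))
  med <- apply(ab, 2, stats::median)
  list(alpha = stats::setNames(med[seq_len(A)], spec$ages$label),
       beta = stats::setNames(med[A + seq_len(A)], spec$ages$label))
}

#' @export
predict.mortality_fit <- function(object, sex = object$sexes[1],
                                  type = c("log_rate", "rate",
                                           "expected_deaths"),
                                  summary = TRUE, ...) {
  type <- match.arg(type)
  lr <- posterior_log_rates(object, sex)
  out <- switch(type,
                log_rate = lr,
                rate = exp(lr),
                expected_deaths = posterior_expected_deaths(
                  lr, object$data$population[[sex]]))
  if (!summary) return(out)
  list(median = apply(out, 1:3, stats::median),
       lower95 = apply(out, 1:3, q_interp, 0.025),
       upper95 = apply(out, 1:3, q_interp, 0.975))
}

#' @export
fitted.mortality_fit <- function(object, sex = object$sexes[1], ...) {
  predict(object, sex = sex, type = "rate")$median
}

#' @export
residuals.mortality_fit <- function(object, sex = object$sexes[1], ...) {
  mu <- fitted(object, sex = sex) * object$data$population[[sex]]
  (object$data$deaths[[sex]] - mu) / sqrt(pmax(mu, 1e-12))
}

#' @importFrom stats simulate
#' @export
simulate.mortality_fit <- function(object, nsim = 1, seed = NULL,
                                   sex = object$sexes[1], ...) {
  f <- object$fits[[sex]]
  lr <- posterior_log_rates(object, sex)
  nd <- dim(lr)[4]
  P <- object$data$population[[sex]]
  with_seed(seed %||% object$config$seed, {
    idx <- sample.int(nd, nsim, replace = TRUE)
    lapply(idx, function(i) {
      mu <- P * exp(lr[, , , i])
      array(stats::rpois(length(mu), mu), dim = dim(mu), dimnames = dimnames(P))
    })
  })
}

#' @export
plot.mortality_fit <- function(x, sex = x$sexes[1], ...) {
  pr <- predict(x, sex = sex, type = "log_rate")
  spec <- x$fits[[sex]]$spec
  T <- spec$dims[["T"]]
  first <- apply(pr$median[, , 1, drop = FALSE], 1, mean)
  last <- apply(pr$median[, , T, drop = FALSE], 1, mean)
  graphics::matplot(spec$ages$midpoint, cbind(first, last), type = "b",
                    pch = c(1, 16), lty = 1, col = c("grey40", "black"),
                    xlab = "age (years)",
                    ylab = "posterior median log death rate",
                    main = paste0("Age-specific mortality (", sex, ")"), ...)
  graphics::legend("topleft", bty = "n", pch = c(1, 16),
                   col = c("grey40", "black"),
                   legend = paste(c("first year:", "last year:"),
                                  range(spec$years)))
  invisible(x)
}
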