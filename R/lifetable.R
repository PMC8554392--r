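# Abridged life tables from age-specific central death rates, with
# Kannisto-Thatcher extension of the open-ended old-age group.
#
# Two person-years conventions are available for the closed intervals:
#  - "cd": a0 from a Coale-Demeny-style piecewise formula in the infant
#    death rate, a_x = n/2 elsewhere; q_x = n m / (1 + (n - a) m).
#  - "constant-hazard": q and a exactly consistent with a constant hazard
#    within the interval (q = 1 - exp(-n m)); with this convention the table
#    reproduces the exact expectation of a piecewise-constant-hazard
#    survival model.

# Coale-Demeny-style a0 constants by sex (years); "total" averages the two.
a0_coale_demeny <- function(m0, sex = "total") {
  k <- switch(sex,
              female = c(thr = 0.107, lo_int = 0.053, lo_slope = 2.800, hi = 0.350),
              male = c(thr = 0.107, lo_int = 0.045, lo_slope = 2.684, hi = 0.330),
              total = c(thr = 0.107, lo_int = 0.049, lo_slope = 2.742, hi = 0.340))
  ifelse(m0 >= k["thr"], k["hi"], k["lo_int"] + k["lo_slope"] * m0)
}

# Vectorised life-table engine.
# m: matrix (cases x age groups); returns columns of the table as matrices.
lifetable_engine <- function(m, ages, ax_method = c("cd", "constant-hazard"),
                             sex = "total", radix = 1e5) {
  ax_method <- match.arg(ax_method)
  ages <- as_age_groups(ages)
  m <- as.matrix(m)
  A <- length(ages)
  if (ncol(m) != A) stop_invalid("m must have one column per age group")
  if (any(m < 0) || any(!is.finite(m))) stop_invalid("m must be finite and >= 0")
  n <- ages$width
  nc <- nrow(m)
  a <- q <- L <- matrix(NA_real_, nc, A)
  for (j in seq_len(A - 1)) {
    mj <- m[, j]; nj <- n[j]
    if (ax_method == "cd") {
      a[, j] <- if (j == 1) a0_coale_demeny(mj, sex) else nj / 2
      q[, j] <- pmin(nj * mj / (1 + (nj - a[, j]) * mj), 1)
    } else {
      tiny <- mj < 1e-12
      a[, j] <- ifelse(tiny, nj / 2, 1 / mj - nj / expm1(nj * mj))
      q[, j] <- -expm1(-nj * mj)
    }
  }
  a[, A] <- ifelse(m[, A] > 0, 1 / m[, A], 0)
  q[, A] <- 1
  l <- matrix(radix, nc, A)
  for (j in seq_len(A - 1)) l[, j + 1] <- l[, j] * (1 - q[, j])
  d <- l * q
  for (j in seq_len(A - 1)) {
    if (ax_method == "cd") {
      L[, j] <- n[j] * l[, j + 1] + a[, j] * d[, j]
    } else {
      L[, j] <- ifelse(m[, j] > 1e-12, d[, j] / m[, j], n[j] * l[, j])
    }
  }
  L[, A] <- ifelse(m[, A] > 0, l[, A] / m[, A], 0)
  Tx <- t(apply(L[, A:1, drop = FALSE], 1, cumsum))[, A:1, drop = FALSE]
  e <- ifelse(l > 0, Tx / l, 0)
  list(ages = ages, m = m, a = a, q = q, l = l, d = d, L = L, T = Tx, e = e)
}

#' Kannisto-Thatcher extension of the terminal age group
#'
#' Fits the logistic hazard mu(x) = a e^(bx) / (1 + a e^(bx)) to old-age
#' central death rates by least squares on the logit scale (logit mu is
#' linear in age), evaluated at group midpoints of the fitting ages, then
#' extrapolates group rates for 85-89, ..., 105-109 and 110+. The extended
#' rates are rescaled (iteratively, using constant-hazard person-years
#' within the extension as exposure weights) so their exposure-weighted
#' aggregate equals the observed 85+ rate.
#'
#' @param m_by_age Central death rates for all age groups (length = number
#'   of groups in `ages`, terminal group open-ended).
#' @param ages An [age_groups()] object (default 19 groups ending at 85+).
#' @param fit_ages Range of ages (years) whose groups are used in the fit;
#'   default `c(70, 84)`, i.e. groups 70-74, 75-79, 80-84.
#' @return Object of class `kt_extension`: list with `a`, `b` (hazard
#'   parameters), `m_ext` (rates for the 6 extension groups), `rescale`
#'   (the factor applied), `fallback` (TRUE when the fit is degenerate —
#'   non-positive slope or rates outside (0,1) — in which case the terminal
#'   group is left unexpanded and `m_ext` is NA).
#' @export
kt_extend <- function(m_by_age, ages = age_groups(), fit_ages = c(70, 84)) {
  ages <- as_age_groups(ages)
  r <- kt_extend_matrix(matrix(m_by_age, nrow = 1), ages, fit_ages)
  structure(list(a = r$a[1], b = r$b[1], m_ext = r$m_ext[1, ],
                 rescale = r$rescale[1], fallback = r$fallback[1],
                 fit_ages = fit_ages, ext_lower = r$ext_lower),
            class = "kt_extension")
}

#' @export
print.kt_extension <- function(x, ...) {
  if (x$fallback) {
    cat("<kt_extension> degenerate fit; terminal group left unexpanded\n")
  } else {
    cat(sprintf("<kt_extension> a = %.4g, b = %.4g; extended rates %s\n",
                x$a, x$b, paste(sprintf("%.3f", x$m_ext), collapse = ", ")))
  }
  invisible(x)
}

KT_EXT_LOWER <- seq(85, 110, by = 5)

kt_extend_matrix <- function(m, ages, fit_ages = c(70, 84)) {
  A <- length(ages)
  fit_idx <- which(ages$lower >= fit_ages[1] &
                     ages$lower + ages$width - 1 <= fit_ages[2] &
                     is.finite(ages$width))
  if (length(fit_idx) < 3)
    stop_invalid("need at least 3 closed old-age groups in fit_ages")
  x <- ages$midpoint[fit_idx]
  mf <- m[, fit_idx, drop = FALSE]
  bad <- rowSums(mf <= 0 | mf >= 1) > 0
  ylogit <- stats::qlogis(pmin(pmax(mf, 1e-300), 1 - 1e-16))
  xc <- x - mean(x)
  b <- as.vector(ylogit %*% xc) / sum(xc^2)
  loga <- rowMeans(ylogit) - b * mean(x)
  fallback <- bad | b <= 0 | !is.finite(b)
  xm <- c(KT_EXT_LOWER[-length(KT_EXT_LOWER)] + 2.5,
          KT_EXT_LOWER[length(KT_EXT_LOWER)] + 2.5)
  mu <- stats::plogis(outer(loga, rep(1, length(xm))) +
                        outer(b, xm))  # n x 6
  # rescale so the stationary-exposure aggregate matches the observed 85+ rate
  m_obs <- m[, A]
  agg <- function(me) {
    # person-years per survivor at 85 under constant hazards; aggregate
    # rate = total deaths / total person-years = 1 / e85
    l <- rep(1, nrow(me)); Ltot <- 0
    for (j in seq_len(ncol(me) - 1)) {
      ln <- l * exp(-5 * me[, j])
      Ltot <- Ltot + ifelse(me[, j] > 0, (l - ln) / me[, j], 5 * l)
      l <- ln
    }
    Ltot <- Ltot + ifelse(me[, ncol(me)] > 0, l / me[, ncol(me)], 0)
    1 / Ltot
  }
  r <- rep(1, nrow(m))
  ok <- !fallback & m_obs > 0
  if (any(ok)) {
    for (k in 1:40) {
      cur <- agg(mu[ok, , drop = FALSE] * r[ok])
      upd <- m_obs[ok] / cur
      r[ok] <- r[ok] * upd
      if (max(abs(upd - 1)) < 1e-12) break
    }
  }
  m_ext <- mu * r
  m_ext[fallback, ] <- NA_real_
  list(a = exp(loga), b = b, m_ext = m_ext, rescale = r,
       fallback = fallback, ext_lower = KT_EXT_LOWER)
}

# ages + rates after substituting the terminal group by the KT extension
kt_substitute <- function(m, ages, m_ext) {
  A <- length(ages)
  ages_ext <- age_groups(c(ages$lower[-A], KT_EXT_LOWER))
  m2 <- cbind(m[, -A, drop = FALSE], m_ext)
  list(ages = ages_ext, m = m2)
}

#' Compute an abridged life table
#'
#' Builds the full life-table columns from a vector of age-specific central
#' death rates. When `kt` is `TRUE` (or a [kt_extend()] object), the
#' open-ended 85+ group is replaced by the Kannisto-Thatcher extension
#' groups before the table is closed; if the extension fit is degenerate the
#' terminal group is left unexpanded.
#'
#' @param m Central death rates (deaths per person-year), one per age group.
#' @param ages An [age_groups()] object.
#' @param kt `FALSE` (no extension), `TRUE` (fit the extension from `m`), or
#'   a `kt_extension` object.
#' @param ax_method `"cd"` (default) or `"constant-hazard"`; see Details in
#'   the package vignette.
#' @param sex Used only by the infant a0 formula of the `"cd"` convention.
#' @param radix Survivors at age 0 (default 100 000).
#' @return A data.frame of class `life_table` with columns age_group, lower,
#'   width, m, a, q, l, d, L, T, e.
#' @examples
#' lt <- life_table(baseline_rates_england("female"))
#' life_expectancy_at_birth(lt)
#' @export
life_table <- function(m, ages = age_groups(), kt = FALSE,
                       ax_method = c("cd", "constant-hazard"),
                       sex = "total", radix = 1e5) {
  ages <- as_age_groups(ages)
  ax_method <- match.arg(ax_method)
  if (length(m) != length(ages))
    stop_invalid("m must have one rate per age group")
  kt_obj <- NULL
  if (isTRUE(kt)) kt_obj <- kt_extend(m, ages)
  else if (inherits(kt, "kt_extension")) kt_obj <- kt
  if (!is.null(kt_obj) && !kt_obj$fallback) {
    sub <- kt_substitute(matrix(m, 1), ages, matrix(kt_obj$m_ext, 1))
    ages <- sub$ages
    m <- as.vector(sub$m)
  }
  eng <- lifetable_engine(matrix(m, 1), ages, ax_method, sex, radix)
  out <- data.frame(age_group = ages$label, lower = ages$lower,
                    width = ages$width, m = m, a = as.vector(eng$a),
                    q = as.vector(eng$q), l = as.vector(eng$l),
                    d = as.vector(eng$d), L = as.vector(eng$L),
                    T = as.vector(eng$T), e = as.vector(eng$e))
  class(out) <- c("life_table", "data.frame")
  out
}

#' Life expectancy at birth from a life table
#'
#' @param table A [life_table()].
#' @return e at age 0 (= T0 / l0), in years.
#' @export
life_expectancy_at_birth <- function(table) {
  stopifnot(inherits(table, "life_table"))
  table$e[1]
}

#' Probability of dying between two exact ages
#'
#' Returns (l(x1) - l(x2)) / l(x1). Both ages must be interval boundaries of
#' the table; no sub-interval interpolation is performed. `x2 = Inf` gives
#' the probability of dying after x1, i.e. 1.
#'
#' @param table A [life_table()].
#' @param x1,x2 Exact ages in years, `x1 < x2`, each equal to the lower
#'   bound of one of the table's intervals (or `Inf` for `x2`).
#' @return A probability.
#' @export
probability_of_dying <- function(table, x1, x2) {
  stopifnot(inherits(table, "life_table"))
  if (!(x1 < x2)) stop_invalid("need x1 < x2")
  l_at <- function(x) {
    if (is.infinite(x)) return(0)
    i <- match(x, table$lower)
    if (is.na(i)) stop_invalid("age ", x, " is not an interval boundary")
    table$l[i]
  }
  l1 <- l_at(x1); l2 <- l_at(x2)
  if (l1 <= 0) return(NA_real_)
  (l1 - l2) / l1
}

#' Vectorised life expectancy at birth
#'
#' Computes e0 for many rate vectors at once — the workhorse behind
#' posterior propagation (life tables are computed for every draw, never
#' only for the posterior-median rates).
#'
#' @param m Matrix (cases x age groups) of central death rates.
#' @param ages An [age_groups()] object.
#' @param kt Apply the Kannisto-Thatcher extension (default TRUE; rows with
#'   a degenerate fit keep the unexpanded terminal group).
#' @param ax_method,sex,radix As in [life_table()].
#' @return Numeric vector of e0, one per row of `m`.
#' @export
life_expectancy <- function(m, ages = age_groups(), kt = TRUE,
                            ax_method = c("cd", "constant-hazard"),
                            sex = "total", radix = 1e5) {
  q <- lifetable_quantities(m, ages, kt, match.arg(ax_method), sex, radix)
  q$e0
}

# shared vectorised computation: e0 and survivors at all boundaries
lifetable_quantities <- function(m, ages = age_groups(), kt = TRUE,
                                 ax_method = "cd", sex = "total",
                                 radix = 1e5) {
  ages <- as_age_groups(ages)
  m <- as.matrix(m)
  A <- length(ages)
  e0 <- numeric(nrow(m))
  lower <- ages$lower
  lmat <- matrix(NA_real_, nrow(m), A)
  colnames(lmat) <- as.character(lower)
  do_rows <- function(rows, mm, aa) {
    eng <- lifetable_engine(mm, aa, ax_method, sex, radix)
    e0[rows] <<- eng$e[, 1]
    lmat[rows, ] <<- eng$l[, seq_len(A)]  # extension only adds ages >= 85
  }
  if (isTRUE(kt)) {
    ktm <- kt_extend_matrix(m, ages)
    ok <- !ktm$fallback
    if (any(ok)) {
      sub <- kt_substitute(m[ok, , drop = FALSE], ages,
                           ktm$m_ext[ok, , drop = FALSE])
      do_rows(which(ok), sub$m, sub$ages)
    }
    if (any(!ok)) do_rows(which(!ok), m[!ok, , drop = FALSE], ages)
  } else {
    do_rows(seq_len(nrow(m)), m, ages)
  }
  list(e0 = e0, l = lmat, lower = lower, radix = radix)
}

#' Posterior draws of life expectancy at birth
#'
#' Converts the posterior log-rate draws of a fitted model into life
#' expectancy at birth per area, year and draw, computing one life table per
#' draw (with Kannisto-Thatcher extension by default).
#'
#' @param fit A [fit_mortality()] object.
#' @param sex Sex to extract.
#' @param kt,ax_method Life-table settings; the `"cd"` a0 formula uses this
#'   sex's constants.
#' @param block_draws Number of draws processed per block (memory control).
#' @return Array of class `e0_draws`, dim (areas x years x draws).
#' @export
posterior_life_expectancy <- function(fit, sex = fit$sexes[1], kt = TRUE,
                                      ax_method = "cd", block_draws = 100) {
  lr <- posterior_log_rates(fit, sex)
  e0_from_log_rates(lr, fit$fits[[sex]]$spec$ages, kt, ax_method, sex)
}

#' Life expectancy draws from a log-rate draw cube
#'
#' @param log_rates Array (ages x areas x years x draws).
#' @param ages An [age_groups()] object.
#' @param kt,ax_method,sex As in [posterior_life_expectancy()].
#' @return Array of class `e0_draws`, dim (areas x years x draws).
#' @export
e0_from_log_rates <- function(log_rates, ages = age_groups(), kt = TRUE,
                              ax_method = "cd", sex = "total") {
  d <- dim(log_rates)
  A <- d[1]; M <- d[2]; T <- d[3]; nd <- d[4]
  out <- array(NA_real_, dim = c(M, T, nd),
               dimnames = c(dimnames(log_rates)[2:3], list(draw = NULL)))
  block <- max(1L, min(nd, floor(2e7 / (M * T * A))))
  for (i0 in seq(1, nd, by = block)) {
    ii <- i0:min(i0 + block - 1, nd)
    m <- exp(log_rates[, , , ii, drop = FALSE])
    mm <- t(matrix(m, nrow = A))  # (M*T*block) x A
    out[, , ii] <- life_expectancy(mm, ages, kt = kt, ax_method = ax_method,
                                   sex = sex)
  }
  class(out) <- "e0_draws"
  out
}

#' Posterior draws of the probability of dying between two ages
#'
#' @param fit A [fit_mortality()] object.
#' @param x1,x2 Exact ages (interval boundaries).
#' @param sex,kt,ax_method As in [posterior_life_expectancy()].
#' @return Array (areas x years x draws) of probabilities.
#' @export
posterior_prob_dying <- function(fit, x1, x2, sex = fit$sexes[1], kt = TRUE,
                                 ax_method = "cd") {
  lr <- posterior_log_rates(fit, sex)
  d <- dim(lr)
  A <- d[1]
  spec_ages <- fit$fits[[sex]]$spec$ages
  mm <- t(matrix(lr, nrow = A))
  q <- lifetable_quantities(exp(mm), spec_ages, kt, ax_method, sex)
  i1 <- match(x1, q$lower); i2 <- match(x2, q$lower)
  if (is.na(i1) || (is.na(i2) && !is.infinite(x2)))
    stop_invalid("x1/x2 must be interval boundaries")
  l1 <- q$l[, i1]
  l2 <- if (is.infinite(x2)) 0 else q$l[, i2]
  array((l1 - l2) / l1, dim = c(d[2], d[3], d[4]),
        dimnames = c(dimnames(lr)[2:3], list(draw = NULL)))
}
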