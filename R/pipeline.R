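# End-to-end pipeline: simulate (optional) -> preprocess -> fit -> life
# tables -> summaries, with provenance (config hash + seed) stamped into a
# manifest and structured JSON-lines logs.

#' Default pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Global seed; every stochastic stage derives its seed from it.
#' @return A nested list of class `pipeline_config`. Fields: `input` (path
#'   to a counts CSV, or NULL to simulate), `simulate` (geography sizes,
#'   years, median population, optional `shock` = list(area, year, extra)),
#'   `model` (passed to [model_config()]), `lifetable` (kt, ax_method),
#'   `summaries` (period boundaries), `outlier` (optional list(area, year)
#'   to interpolate and add back).
#' @export
pipeline_config <- function(outdir = "arealex-out", seed = 1L) {
  structure(list(
    input = NULL,
    outdir = outdir,
    seed = as.integer(seed),
    simulate = list(n_regions = 2, n_districts_per_region = 2,
                    n_areas_per_district = 5, years = 2002:2019,
                    median_pop = 7985, dispersion = 0.25, shock = NULL),
    outlier = NULL,
    model = list(n_draws = 1000, n_chains = 4, n_warmup = 1000),
    lifetable = list(kt = TRUE, ax_method = "cd"),
    summaries = list(boundaries = c(2002, 2006, 2010, 2014, 2019))),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unset fields keep their [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  cfg <- merge_in(cfg, user)
  if (!is.null(cfg$simulate$years)) cfg$simulate$years <-
      seq(min(cfg$simulate$years), max(cfg$simulate$years))
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

log_line <- function(con, stage, ...) {
  kv <- list(...)
  fields <- vapply(names(kv), function(k) {
    v <- kv[[k]]
    val <- if (is.numeric(v)) paste0(format(v, digits = 10), collapse = ",")
    else paste0('"', paste0(v, collapse = ","), '"')
    sprintf('"%s": %s', k, val)
  }, "")
  writeLines(sprintf('{"stage": "%s", "time": "%s", %s}', stage,
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     paste(fields, collapse = ", ")), con)
}

#' Run the full estimation pipeline
#'
#' Executes simulate (when no input file is given) -> preprocess (population
#' repair and optional outlier-year interpolation with posterior add-back)
#' -> model fit per sex -> life tables per draw -> summaries, writing CSV
#' artifacts, a JSON-lines log and a provenance manifest (config hash, seed,
#' file checksums) to the output directory. Any stage failure aborts with
#' the stage name; partial logs are kept.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return Invisibly, a list with the main in-memory results and the output
#'   directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(config$outdir, "log.jsonl")
  con <- file(logf, "a")
  on.exit(close(con))
  log_line(con, "start", seed = config$seed, config_hash = hash)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_line(con, name, elapsed_s = round(proc.time()[3] - t0, 2))
    r
  }

  truth <- NULL
  data <- stage("simulate", {
    if (!is.null(config$input)) {
      read_counts(config$input)
    } else {
      sc <- config$simulate
      g <- generate_geography(sc$n_regions, sc$n_districts_per_region,
                              sc$n_areas_per_district, seed = config$seed)
      sim <- simulate_mortality(g, years = sc$years,
                                median_pop = sc$median_pop,
                                dispersion = sc$dispersion,
                                seed = config$seed)
      truth <<- sim$truth
      d <- sim$data
      if (!is.null(sc$shock))
        d <- inject_shock(d, sc$shock$area, sc$shock$year, sc$shock$extra)
      write_counts(d, file.path(config$outdir, "counts.csv"))
      d
    }
  })

  adjustment <- NULL
  data <- stage("preprocess", {
    rep <- repair_population(data)
    log_line(con, "preprocess_detail", n_repaired = rep$n_repaired,
             n_dropped_missing_sex =
               attr(data, "n_dropped_missing_sex") %||% 0L)
    d <- rep$data
    if (!is.null(config$outlier)) {
      out <- interpolate_outlier_year(d, config$outlier$area,
                                      config$outlier$year)
      adjustment <<- out$adjustment
      write_adjustment(adjustment,
                       file.path(config$outdir, "outlier_adjustment.csv"),
                       d$ages)
      d <- out$data
    }
    d
  })

  mcfg <- do.call(model_config, c(config$model, list(seed = config$seed)))
  fit <- stage("fit", fit_mortality(data, config = mcfg))

  e0 <- stage("lifetable", {
    lapply(stats::setNames(nm = fit$sexes), function(s) {
      lr <- posterior_log_rates(fit, s)
      if (!is.null(adjustment)) {
        P <- data$population[[s]]
        ed <- posterior_expected_deaths(lr, P)
        ed <- add_back_outlier(ed, adjustment, s)
        lr <- log(ed / rep(pmax(P, 1e-12), dim(ed)[4]))
        lr[!is.finite(lr)] <- -20
      }
      e0_from_log_rates(lr, data$ages, kt = config$lifetable$kt,
                        ax_method = config$lifetable$ax_method, sex = s)
    })
  })

  res <- stage("summarize", {
    years <- data$years
    bounds <- intersect(config$summaries$boundaries, years)
    if (length(bounds) < 2) bounds <- range(years)
    out <- list()
    for (s in fit$sexes) {
      x <- e0[[s]]
      M <- dim(x)[1]; T <- dim(x)[2]
      st <- summarize_draws(matrix(x, M * T))
      st <- cbind(expand.grid(area_id = dimnames(x)[[1]], year = years,
                              KEEP.OUT.ATTRS = FALSE), sex = s, st)
      out$e0_summary <- rbind(out$e0_summary, st)
      pc <- posterior_prob_change(x, min(years), max(years))
      out$prob_change <- rbind(out$prob_change,
                               data.frame(sex = s, area_id = names(pc),
                                          prob_increase = unname(pc)))
      for (yr in range(years)) {
        gp <- inequality_gaps(x, yr)
        out$gaps <- rbind(out$gaps, cbind(sex = s, year = yr, gp$gaps))
      }
      ch <- change_by_period(x, bounds)
      out$changes <- rbind(out$changes, cbind(sex = s, ch$changes))
      out$declining <- rbind(out$declining, cbind(sex = s, ch$declining))
    }
    if (all(c("female", "male") %in% fit$sexes)) {
      sc <- sex_comparison(e0$female, e0$male, max(years))
      out$sex_comparison <- data.frame(
        statistic = c("correlation", names(sc$bands)),
        value = c(sc$correlation, unname(sc$bands)))
    }
    out
  })

  for (nm in names(res))
    utils::write.csv(res[[nm]], file.path(config$outdir, paste0(nm, ".csv")),
                     row.names = FALSE)

  files <- list.files(config$outdir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- data.frame(file = basename(files), md5 = unname(tools::md5sum(files)),
                         config_hash = hash, seed = config$seed,
                         package_version = as.character(utils::packageVersion("arealex")))
  utils::write.csv(manifest, file.path(config$outdir, "manifest.csv"),
                   row.names = FALSE)
  log_line(con, "done", n_files = length(files) + 1)
  invisible(list(data = data, truth = truth, fit = fit, e0 = e0,
                 summaries = res, adjustment = adjustment,
                 outdir = config$outdir, config_hash = hash))
}
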