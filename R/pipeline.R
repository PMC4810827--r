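# Orchestration of the full study design: fit one model specification to
# several webs (e.g. two periods x two regions), assess each fit by GoF,
# compare periods within each region, and emit a report bundle.

#' Read and validate a pipeline run configuration
#'
#' YAML layout:
#' \preformatted{
#' webs:
#'   offshore_1980s: {path: web1.csv, format: edge-list,
#'                    region: offshore, period: 1980s}
#'   offshore_2000s: {path: web2.csv, format: edge-list,
#'                    region: offshore, period: 2000s}
#' model: model.yaml          # optional; default seven-configuration model
#' comparisons:               # optional; default: consecutive periods
#'   - {before: offshore_1980s, after: offshore_2000s}
#' settings: {sample_size: 1000}   # optional sampler overrides
#' out_dir: results
#' seed: 1
#' }
#'
#' @param path YAML file.
#' @return validated config list (class \code{"run_config"}).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (w in names(cfg$webs)) {
    p <- cfg$webs[[w]]$path
    if (!file.exists(p) && file.exists(file.path(base, p))) {
      cfg$webs[[w]]$path <- file.path(base, p)
    }
  }
  if (!is.null(cfg$model) && !file.exists(cfg$model) &&
      file.exists(file.path(base, cfg$model))) {
    cfg$model <- file.path(base, cfg$model)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$webs) || !length(cfg$webs)) {
    stop("config must list at least one web", call. = FALSE)
  }
  for (w in names(cfg$webs)) {
    entry <- cfg$webs[[w]]
    if (is.null(entry$path) || !file.exists(entry$path)) {
      stop(sprintf("web '%s': file not found: %s", w,
                   if (is.null(entry$path)) "<missing path>" else entry$path),
           call. = FALSE)
    }
  }
  if (!is.null(cfg$model) && is.character(cfg$model) && !file.exists(cfg$model)) {
    stop(sprintf("model spec file not found: %s", cfg$model), call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "ergm_results"
  structure(cfg, class = "run_config")
}

#' Run the full fitting / GoF / regime-comparison pipeline
#'
#' For every configured web: fit the model specification, write the fit as
#' JSON and its goodness of fit as CSV. Then compare configured (or
#' inferred same-region consecutive-period) pairs of fits and write each
#' comparison as CSV, plus one combined parameter table across webs with
#' significance markers, and a log recording every setting and derived
#' seed. Stage sub-seeds are derived deterministically from the global
#' seed, so each stage is individually re-runnable.
#'
#' @param config a \code{run_config} (from \code{\link{read_run_config}})
#'   or an equivalent list.
#' @return invisibly, a list with \code{status} (0 = clean, 1 = completed
#'   with warnings such as non-converged fits), \code{fits},
#'   \code{gof_reports}, \code{comparisons}, \code{files}.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run_log.txt")
  logcon <- file(logfile, open = "wt")
  on.exit(close(logcon))
  say <- function(...) {
    writeLines(sprintf(...), logcon)
  }
  say("foodwebERGM pipeline, global seed %d", as.integer(cfg$seed))

  spec <- if (is.null(cfg$model)) {
    foodweb_model_spec()
  } else if (inherits(cfg$model, "model_spec")) {
    cfg$model
  } else {
    read_model_spec(cfg$model)
  }
  say("model: %s", paste(sprintf("%s(lambda=%g)",
                                 stat_names(spec$configurations),
                                 stat_lambdas(spec$configurations)),
                         collapse = ", "))

  status <- 0L
  files <- character(0)
  fits <- list()
  gofs <- list()
  for (w in names(cfg$webs)) {
    entry <- cfg$webs[[w]]
    fmt <- if (is.null(entry$format)) "edge-list" else entry$format
    web <- read_foodweb(entry$path, format = fmt,
                        metadata = list(region = entry$region,
                                        period = entry$period,
                                        source = entry$path))
    n <- n_species(web)
    st <- sampler_settings(n, seed = derive_seed(cfg$seed, paste0("fit_", w)))
    for (f in intersect(names(cfg$settings),
                        c("burn_in", "thinning", "sample_size"))) {
      st[[f]] <- cfg$settings[[f]]
    }
    rmst <- do.call(rm_settings, if (is.null(cfg$rm)) list() else cfg$rm)
    say("web %s: n=%d, arcs=%d, fit seed %d, burn_in=%g, thinning=%g, phase3=%d",
        w, n, n_arcs(web), st$seed, st$burn_in, st$thinning, rmst$phase3_samples)
    fit <- fit_ergm(web, spec, settings = st, rm = rmst)
    fits[[w]] <- fit
    if (!fit$converged) {
      status <- 1L
      say("web %s: fit did NOT converge (max |t| = %.3f)",
          w, max(abs(fit$convergence_t)))
    } else {
      say("web %s: converged (max |t| = %.3f, %d restarts)",
          w, max(abs(fit$convergence_t)), fit$diagnostics$restarts)
    }
    fit_path <- file.path(cfg$out_dir, paste0(w, "_fit.json"))
    write_fit_json(fit, fit_path)
    gof_st <- st
    gof_st$seed <- derive_seed(cfg$seed, paste0("gof_", w))
    gof_st$sample_size <- if (is.null(cfg$settings$gof_sample_size)) 500L else
      cfg$settings$gof_sample_size
    rep <- suppressWarnings(
      goodness_of_fit(web, fit, settings = gof_st)
    )
    gofs[[w]] <- rep
    say("web %s: GoF pass = %s (ensemble %d, seed %d)", w, format(rep$pass),
        rep$ensemble_size, gof_st$seed)
    gof_path <- file.path(cfg$out_dir, paste0(w, "_gof.csv"))
    write_gof_csv(rep, gof_path)
    files <- c(files, fit_path, gof_path)
  }

  comparisons <- cfg$comparisons
  if (is.null(comparisons)) comparisons <- infer_comparisons(cfg$webs)
  cmp_out <- list()
  for (cmp in comparisons) {
    nm <- sprintf("%s_vs_%s", cmp$before, cmp$after)
    res <- compare_fits(fits[[cmp$before]], fits[[cmp$after]])
    cmp_out[[nm]] <- res
    path <- file.path(cfg$out_dir, paste0(nm, "_comparison.csv"))
    write_comparison_csv(res, path)
    files <- c(files, path)
    say("comparison %s: %d shared configurations", nm, nrow(res$table))
  }

  tab_path <- file.path(cfg$out_dir, "parameter_table.csv")
  utils::write.csv(fits_to_table(fits), tab_path, row.names = FALSE)
  files <- c(files, tab_path, logfile)
  say("status %d", status)
  invisible(list(status = status, fits = fits, gof_reports = gofs,
                 comparisons = cmp_out, files = files))
}

# default comparison plan: within each region, consecutive periods
infer_comparisons <- function(webs) {
  regions <- vapply(webs, function(w) w$region %||% "all", "")
  out <- list()
  for (r in unique(regions)) {
    members <- names(webs)[regions == r]
    periods <- vapply(webs[members], function(w) w$period %||% "", "")
    members <- members[order(periods)]
    if (length(members) >= 2L) {
      for (k in seq_len(length(members) - 1L)) {
        out[[length(out) + 1L]] <- list(before = members[k],
                                        after = members[k + 1L])
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
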