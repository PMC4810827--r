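# Simulation-based goodness of fit: does an ensemble simulated from the
# fitted model reproduce the observed web's structure, including statistics
# the model never targeted?

#' The default 32-statistic goodness-of-fit suite
#'
#' Covers every statistic family the modelling works with plus
#' degree-distribution shape: the 10 catalogue configurations at
#' \code{lambda = 2} (arc, reciprocity, the alternating stars, two-paths
#' and triangles), raw 2- and 3-in/out-stars, raw two-path, transitive and
#' cyclic triangle counts, the 13 connected triad classes, and the in- and
#' out-degree standard deviations - 32 statistics in all. The membership is
#' a package choice (documented here so users can substitute their own 32);
#' only the count is canonical.
#'
#' @param lambda smoothing weight for the alternating members.
#' @return list of 32 \code{\link{config_stat}}.
#' @export
default_gof_suite <- function(lambda = 2) {
  nms <- c("arc", "reciprocity", "generalist", "highly_predated", "keystone",
           "tri_trophic", "apparent_competition", "exploitative_competition",
           "omnivory", "cyclic_triangle",
           "in_2_star", "in_3_star", "out_2_star", "out_3_star",
           "two_path", "transitive_triangle", "cyclic_triangle_raw",
           paste0("triad_", CONNECTED_TRIADS),
           "in_degree_sd", "out_degree_sd")
  lapply(nms, config_stat, lambda = lambda)
}

#' Goodness of fit of a fitted ERGM
#'
#' Simulates an ensemble at the fitted parameters, evaluates every suite
#' statistic on each simulated web and on the observed web, and reports the
#' t-ratio \code{(observed - ensemble mean) / ensemble sd} per statistic.
#' Modelled statistics (those in the fitted specification) are held to
#' \code{|t| <= 0.1} - the moment condition of a converged fit - while
#' non-modelled statistics pass at \code{|t| < 2}. Statistics whose
#' ensemble sd is 0 get an undefined t (\code{NA}) and are excluded from
#' the pass decision but still reported.
#'
#' @param web the observed \code{foodweb}.
#' @param fit an \code{ergm_fit} (a warning is raised if it did not
#'   converge).
#' @param suite list of \code{\link{config_stat}}; defaults to
#'   \code{\link{default_gof_suite}()}.
#' @param settings a \code{\link{sampler_settings}} for the ensemble.
#' @return object of class \code{"gof_report"}: list with \code{table}
#'   (statistic, observed, mean, sd, t, modelled, failed), \code{pass}
#'   (TRUE/FALSE, or NA when every t is undefined), \code{ensemble_size},
#'   \code{seed}.
#' @export
goodness_of_fit <- function(web, fit, suite = default_gof_suite(),
                            settings = sampler_settings(n_species(web))) {
  validate_foodweb(web)
  if (!length(suite)) stop("suite must be non-empty", call. = FALSE)
  if (!isTRUE(fit$converged)) {
    warning("fit did not converge; GoF t-ratios will reflect that", call. = FALSE)
  }
  suite <- as_stat_list(suite)
  ens <- sample_networks(fit$spec, fit$theta, n = n_species(web),
                         settings = settings, start = web,
                         keep_networks = TRUE)
  sims <- vapply(ens$networks, compute_statistics, numeric(length(suite)),
                 spec = suite)
  sims <- t(sims)  # ensemble x statistic
  observed <- compute_statistics(web, suite)
  mu <- colMeans(sims)
  sdv <- apply(sims, 2L, stats::sd)
  if (nrow(sims) < 2L) sdv <- rep(NA_real_, length(mu))
  t_ratio <- ifelse(!is.na(sdv) & sdv > 0, (observed - mu) / sdv, NA_real_)
  modelled <- stat_names(suite) %in% stat_names(fit$spec$configurations)
  failed <- ifelse(is.na(t_ratio), NA,
                   ifelse(modelled, abs(t_ratio) > 0.1, abs(t_ratio) >= 2))
  pass <- if (all(is.na(failed))) NA else !any(failed, na.rm = TRUE)
  tab <- data.frame(
    statistic = stat_names(suite),
    lambda = stat_lambdas(suite),
    observed = as.numeric(observed),
    ensemble_mean = as.numeric(mu),
    ensemble_sd = as.numeric(sdv),
    t = as.numeric(t_ratio),
    modelled = modelled,
    failed = failed,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, pass = pass,
                 ensemble_size = nrow(sims), seed = settings$seed),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("<gof_report> %d statistics, ensemble %d, pass = %s\n",
              nrow(x$table), x$ensemble_size, format(x$pass)))
  bad <- x$table[!is.na(x$table$failed) & x$table$failed, , drop = FALSE]
  if (nrow(bad)) {
    cat("failing statistics:\n")
    print(bad[, c("statistic", "observed", "ensemble_mean", "t")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a GoF report to CSV
#' @param report a \code{gof_report}.
#' @param path destination CSV (one row per statistic).
#' @return \code{path}, invisibly.
#' @export
write_gof_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
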