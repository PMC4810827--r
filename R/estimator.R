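# Monte-Carlo maximum likelihood for food-web ERGMs.
#
# Estimation follows the stochastic-approximation tradition: a short
# calibration run (phase 1) scales the updates, Robbins-Monro iterations
# (phase 2) walk theta toward the moment condition E_theta[z] = z_obs, and a
# long run at the final theta (phase 3) yields convergence t-ratios and
# standard errors from the Fisher information (the covariance of the
# sampled statistics). Between phase-3 attempts a damped Newton (Fisher
# scoring) correction re-centres theta, which sharpens the estimate far
# beyond what the raw Robbins-Monro iterates achieve.

#' Robbins-Monro estimation settings
#'
#' @param subphase_lengths iterations per subphase, as multiples of the
#'   parameter count; the gain halves between subphases.
#' @param gain0 initial gain.
#' @param phase1_samples networks used to estimate the scaling matrix.
#' @param phase3_samples networks in the final estimation sample.
#' @param t_threshold convergence criterion: converged iff all
#'   \code{|t| <= t_threshold}.
#' @param max_restarts Newton-corrected re-estimation attempts after a
#'   failed convergence check.
#' @param steps_per_iteration Metropolis proposals between successive
#'   Robbins-Monro updates; \code{NULL} means \code{10 n^2}.
#' @return list of class \code{"rm_settings"}.
#' @export
rm_settings <- function(subphase_lengths = c(2, 4, 8, 16), gain0 = 0.1,
                        phase1_samples = 100L, phase3_samples = 1000L,
                        t_threshold = 0.1, max_restarts = 3L,
                        steps_per_iteration = NULL) {
  structure(list(subphase_lengths = subphase_lengths, gain0 = gain0,
                 phase1_samples = as.integer(phase1_samples),
                 phase3_samples = as.integer(phase3_samples),
                 t_threshold = t_threshold,
                 max_restarts = as.integer(max_restarts),
                 steps_per_iteration = steps_per_iteration),
            class = "rm_settings")
}

# advance the chain `steps` proposals from adj at theta; return final state
chain_step <- function(adj, codes, lambdas, theta, steps) {
  cpp_ergm_sample(adj, codes, lambdas, theta, steps, 1, 1L, FALSE)
}

#' Fit an ERGM to a food web by Monte-Carlo maximum likelihood
#'
#' Robbins-Monro stochastic approximation with Newton-corrected restarts.
#' The moment condition at the MLE is that networks simulated at
#' \code{theta} reproduce the observed statistics; convergence is declared
#' when every statistic's t-ratio
#' \code{(mean_sim - observed) / sd_sim} is at most
#' \code{rm$t_threshold} in absolute value. Standard errors come from the
#' inverse covariance matrix of the phase-3 statistics (the Fisher
#' information of the exponential family).
#'
#' @param web observed \code{foodweb}; density must be strictly between 0
#'   and 1.
#' @param spec a \code{\link{model_spec}}.
#' @param settings a \code{\link{sampler_settings}} (burn-in/thinning used
#'   for the phase-3 sample; the seed governs the whole fit).
#' @param rm a \code{\link{rm_settings}}.
#' @return object of class \code{"ergm_fit"}: theta, standard_errors,
#'   convergence_t, significant (\code{|theta| >= 2 SE}), converged flag,
#'   observed statistics, seed and phase diagnostics. Non-convergence is
#'   reported via \code{converged = FALSE}, not an error.
#' @examples
#' \donttest{
#' web <- niche_model_web(niche_params(n = 20, connectance = 0.15, seed = 1))
#' fit <- fit_ergm(web, model_spec("arc"),
#'                 settings = sampler_settings(20, seed = 1))
#' fit$theta  # close to logit(web_density(web))
#' }
#' @export
fit_ergm <- function(web, spec, settings = sampler_settings(n_species(web)),
                     rm = rm_settings()) {
  validate_foodweb(web)
  stats <- as_stat_list(spec)
  nm <- stat_names(stats)
  codes <- as.integer(stat_codes(stats))
  lambdas <- stat_lambdas(stats)
  p <- length(stats)
  n <- n_species(web)
  dens <- web_density(web)
  if (dens <= 0 || dens >= 1) {
    stop("degenerate data: web density must be strictly between 0 and 1",
         call. = FALSE)
  }
  z_obs <- compute_statistics(web, stats)
  steps <- rm$steps_per_iteration
  if (is.null(steps)) steps <- 10 * n^2

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(settings$seed)

  # warm start: exact for the Bernoulli sub-model
  theta <- numeric(p)
  theta[nm == "arc"] <- logit(dens)

  # phase 1: diagonal scaling from a short simulation at theta0
  ph1 <- cpp_ergm_sample(web$adjacency, codes, lambdas, theta,
                         settings$burn_in, max(steps / 10, n^2),
                         rm$phase1_samples, FALSE)
  # scaling matrix: regularized statistic covariance at theta0 (a stochastic
  # Newton preconditioner; correlated statistics such as arc and the
  # alternating stars make a diagonal scaling converge poorly)
  V1 <- stats::cov(ph1$statistics)
  diag(V1) <- pmax(diag(V1), 1e-4)
  D <- V1 + diag(1e-6 + 0.01 * diag(V1), p)
  adj <- ph1$final_adjacency

  # phase 2: Robbins-Monro subphases with halving gain; the returned theta
  # is the average over the final subphase (Polyak averaging)
  run_phase2 <- function(theta, adj) {
    gains <- rm$gain0 / 2^(seq_along(rm$subphase_lengths) - 1)
    last <- NULL
    for (k in seq_along(rm$subphase_lengths)) {
      len <- ceiling(rm$subphase_lengths[k] * p)
      keep <- k == length(rm$subphase_lengths)
      if (keep) last <- matrix(0, len, p)
      for (it in seq_len(len)) {
        sim <- chain_step(adj, codes, lambdas, theta, steps)
        adj <- sim$final_adjacency
        theta <- theta - gains[k] * drop(solve(D, drop(sim$statistics) - z_obs))
        if (keep) last[it, ] <- theta
      }
    }
    list(theta = colMeans(last), adj = adj)
  }

  ph2 <- run_phase2(theta, adj)
  theta <- ph2$theta
  adj <- ph2$adj

  # phase 3 with Newton-corrected retries
  restarts <- -1L
  t_history <- list()
  best <- NULL
  repeat {
    restarts <- restarts + 1L
    ph3 <- cpp_ergm_sample(adj, codes, lambdas, theta, settings$burn_in,
                           settings$thinning, rm$phase3_samples, FALSE)
    adj <- ph3$final_adjacency
    zm <- ph3$statistics
    mu <- colMeans(zm)
    sdv <- apply(zm, 2L, stats::sd)
    t_ratio <- ifelse(sdv > 0, (mu - z_obs) / sdv, Inf * sign(mu - z_obs))
    t_history[[restarts + 1L]] <- t_ratio
    V <- stats::cov(zm)
    inv <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(best) || max(abs(t_ratio)) < max(abs(best$t_ratio))) {
      best <- list(theta = theta, t_ratio = t_ratio, inv = inv, V = V,
                   acc = ph3$acceptance_rate)
    }
    # keep polishing while attempts remain and the moment condition is not
    # comfortably inside the threshold (aiming at the boundary would leave
    # the reported t-ratios at the mercy of Monte-Carlo noise)
    if (max(abs(t_ratio)) <= 0.5 * rm$t_threshold) break
    if (restarts >= rm$max_restarts) break
    # damped Fisher-scoring correction toward the moment condition; heavier
    # damping when far off, where the local quadratic model is unreliable
    step_dir <- if (!is.null(inv)) drop(inv %*% (z_obs - mu)) else
      (z_obs - mu) / pmax(diag(V), 1e-4)
    if (max(abs(t_ratio)) > 0.5) step_dir <- 0.5 * step_dir
    nrm <- sqrt(sum(step_dir^2))
    if (nrm > 1) step_dir <- step_dir / nrm
    theta <- theta + step_dir
  }
  theta <- best$theta
  t_ratio <- best$t_ratio
  acc <- best$acc
  converged <- max(abs(t_ratio)) <= rm$t_threshold
  se_available <- !is.null(best$inv)
  se <- if (se_available) sqrt(pmax(diag(best$inv), 0)) else rep(NA_real_, p)

  theta <- stats::setNames(theta, nm)
  se <- stats::setNames(se, nm)
  structure(list(
    spec = if (inherits(spec, "model_spec")) spec else
      structure(list(configurations = stats), class = "model_spec"),
    theta = theta,
    standard_errors = se,
    convergence_t = stats::setNames(t_ratio, nm),
    significant = stats::setNames(se_available & abs(theta) >= 2 * se, nm),
    converged = converged,
    se_available = se_available,
    observed = z_obs,
    seed = settings$seed,
    web_metadata = web$metadata,
    n = n,
    diagnostics = list(
      gain_sequence = rm$gain0 / 2^(seq_along(rm$subphase_lengths) - 1),
      subphase_lengths = ceiling(rm$subphase_lengths * p),
      phase3_samples = rm$phase3_samples,
      restarts = restarts,
      t_history = t_history,
      acceptance_rate = acc,
      scaling = D
    )
  ), class = "ergm_fit")
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat(sprintf("<ergm_fit> %d configurations, %s (max |t| = %.3f, %d restarts)\n",
              length(x$theta),
              if (x$converged) "converged" else "NOT converged",
              max(abs(x$convergence_t)), x$diagnostics$restarts))
  tab <- data.frame(
    estimate = round(x$theta, 4),
    se = round(x$standard_errors, 4),
    t_conv = round(x$convergence_t, 3),
    sig = ifelse(x$significant, "*", "")
  )
  print(tab)
  invisible(x)
}

#' Exact maximum likelihood on tiny webs
#'
#' Enumeration oracle: computes the normalizing constant by summing over
#' all \code{2^(n(n-1))} loop-free digraphs (hence \code{n <= 4}) and
#' maximizes the exact likelihood by Newton iteration. When the observed
#' statistic vector lies on the boundary of its attainable range the MLE
#' diverges; estimates are then capped at +/-20 with a warning.
#'
#' @param web a \code{foodweb} with at most 4 species.
#' @param spec a \code{\link{model_spec}}.
#' @return named theta vector with attributes \code{gradient_norm} and
#'   \code{capped}.
#' @export
exact_fit_small <- function(web, spec) {
  validate_foodweb(web)
  n <- n_species(web)
  if (n > 4) stop("exact enumeration is limited to n <= 4", call. = FALSE)
  stats <- as_stat_list(spec)
  nm <- stat_names(stats)
  p <- length(stats)
  Z <- enumerate_statistics(n, stats)
  z_obs <- compute_statistics(web, stats)

  theta <- numeric(p)
  capped <- FALSE
  for (it in seq_len(200L)) {
    eta <- drop(Z %*% theta)
    eta <- eta - max(eta)
    w <- exp(eta); w <- w / sum(w)
    mu <- drop(crossprod(Z, w))
    Zc <- sweep(Z, 2L, mu)
    V <- crossprod(Zc * sqrt(w), Zc * sqrt(w))
    grad <- z_obs - mu
    if (sqrt(sum(grad^2)) <= 1e-8) break
    step <- tryCatch(solve(V + diag(1e-10, p), grad),
                     error = function(e) grad / pmax(diag(V), 1e-8))
    nrm <- sqrt(sum(step^2))
    if (nrm > 2) step <- step * 2 / nrm
    theta <- theta + step
    if (any(abs(theta) > 20)) {
      theta <- pmin(pmax(theta, -20), 20)
      capped <- TRUE
    }
  }
  if (capped) {
    warning("observed statistics on the boundary: MLE diverges, capped at +/-20",
            call. = FALSE)
  }
  structure(stats::setNames(theta, nm),
            gradient_norm = sqrt(sum((z_obs - mu)^2)),
            capped = capped)
}

# statistics of every loop-free digraph on n nodes (rows = graphs)
enumerate_statistics <- function(n, stats) {
  dyads <- which(!diag(n))
  N <- length(dyads)
  G <- 2^N
  Z <- matrix(0, G, length(stats))
  adj <- matrix(0L, n, n)
  for (g in seq_len(G) - 1L) {
    bits <- bitwAnd(bitwShiftR(g, seq_len(N) - 1L), 1L)
    adj[dyads] <- bits
    Z[g + 1L, ] <- cpp_compute_stats(adj, as.integer(stat_codes(stats)),
                                     stat_lambdas(stats))
  }
  colnames(Z) <- stat_names(stats)
  Z
}

# exact ERGM probabilities over all digraphs on n nodes (used by tests)
enumerate_probabilities <- function(n, stats, theta) {
  Z <- enumerate_statistics(n, stats)
  eta <- drop(Z %*% theta)
  eta <- eta - max(eta)
  w <- exp(eta)
  w / sum(w)
}

#' Fit and rank several candidate model specifications
#'
#' Fits every candidate, runs goodness of fit for each, and ranks by
#' (converged first, fewer GoF failures, fewer parameters). Model choice
#' remains the analyst's responsibility; the ranking is a screen, not a
#' test.
#'
#' @param web a \code{foodweb}.
#' @param candidates list of \code{\link{model_spec}}.
#' @param settings a \code{\link{sampler_settings}}.
#' @param rm a \code{\link{rm_settings}}.
#' @param gof_settings sampler settings for the GoF ensembles (defaults to
#'   \code{settings}).
#' @return list with \code{table} (one ranked row per candidate) and
#'   \code{fits}.
#' @export
compare_model_specs <- function(web, candidates,
                                settings = sampler_settings(n_species(web)),
                                rm = rm_settings(), gof_settings = settings) {
  if (length(candidates) < 1L) stop("need at least one candidate", call. = FALSE)
  fits <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    fit <- fit_ergm(web, candidates[[k]], settings = settings, rm = rm)
    gof <- goodness_of_fit(web, fit, settings = gof_settings)
    fails <- sum(gof$table$failed, na.rm = TRUE)
    fits[[k]] <- fit
    rows[[k]] <- data.frame(
      candidate = k,
      n_params = length(fit$theta),
      converged = fit$converged,
      gof_failures = fails,
      max_abs_t = max(abs(fit$convergence_t))
    )
  }
  tab <- do.call(rbind, rows)
  ord <- order(!tab$converged, tab$gof_failures, tab$n_params)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  list(table = tab, fits = fits)
}

#' Serialize a fit as JSON
#'
#' @param fit an \code{ergm_fit}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    configurations = stat_names(fit$spec$configurations),
    lambda = stat_lambdas(fit$spec$configurations),
    theta = as.list(fit$theta),
    standard_errors = as.list(fit$standard_errors),
    convergence_t = as.list(fit$convergence_t),
    significant = as.list(fit$significant),
    converged = fit$converged,
    observed = as.list(fit$observed),
    seed = fit$seed,
    diagnostics = fit$diagnostics,
    web_metadata = fit$web_metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Combine fits into a parameter table
#'
#' One row per configuration, one column per web, estimates annotated with
#' \code{*} when \code{|estimate| >= 2 SE} (the significance rule used
#' throughout).
#'
#' @param fits named list of \code{ergm_fit}.
#' @return data.frame.
#' @export
fits_to_table <- function(fits) {
  if (is.null(names(fits))) names(fits) <- paste0("web", seq_along(fits))
  all_cfg <- unique(unlist(lapply(fits, function(f) names(f$theta))))
  out <- data.frame(configuration = all_cfg, stringsAsFactors = FALSE)
  for (w in names(fits)) {
    f <- fits[[w]]
    col <- rep(NA_character_, length(all_cfg))
    idx <- match(names(f$theta), all_cfg)
    col[idx] <- sprintf("%.4f%s", f$theta, ifelse(f$significant, "*", ""))
    out[[w]] <- col
  }
  out
}
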