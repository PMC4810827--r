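# Metropolis-Hastings simulation of food webs from an ERGM.

#' Sampler settings
#'
#' Controls for the single-arc-toggle Metropolis-Hastings sampler. Defaults
#' scale with the number of ordered dyads (roughly \code{n^2}): burn-in
#' \code{50 n^2} proposals, thinning \code{10 n^2} proposals between
#' retained networks.
#'
#' @param n node count used to resolve the scaling defaults.
#' @param burn_in proposals before the first retained sample.
#' @param thinning proposals between retained samples.
#' @param sample_size number of retained networks.
#' @param seed integer seed.
#' @return list of class \code{"sampler_settings"}.
#' @export
sampler_settings <- function(n = 30L, burn_in = 50 * n^2, thinning = 10 * n^2,
                             sample_size = 100L, seed = 1L) {
  s <- list(burn_in = as.numeric(burn_in), thinning = as.numeric(thinning),
            sample_size = as.integer(sample_size), seed = as.integer(seed))
  if (any(unlist(s) <= 0)) stop("all sampler settings must be positive", call. = FALSE)
  structure(s, class = "sampler_settings")
}

empty_web <- function(n, species = NULL) {
  if (is.null(species)) species <- paste0("s", seq_len(n))
  foodweb(matrix(0L, n, n), species = species)
}

#' Simulate food webs from an ERGM
#'
#' Draws networks from \code{P(G) = exp(sum_s theta_s z_s(G)) / c} by
#' single-arc-toggle Metropolis-Hastings; the normalizing constant \code{c}
#' is never computed. The trace is deterministic given
#' \code{settings$seed}.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param theta numeric parameter vector aligned to \code{spec}.
#' @param n node count (ignored when \code{start} is given).
#' @param settings a \code{\link{sampler_settings}}.
#' @param start optional \code{foodweb} used as the initial state; defaults
#'   to the empty web.
#' @param keep_networks retain the sampled webs themselves (needed for GoF)
#'   or only their statistics.
#' @return object of class \code{"sample_ensemble"}: list with
#'   \code{statistics} (sample_size x p matrix, columns = configuration
#'   names), \code{networks} (list of \code{foodweb} or \code{NULL}),
#'   \code{acceptance_rate}, \code{final_web}, \code{degenerate} (TRUE when
#'   density was pinned at 0 or 1 for more than 90\% of retained samples; a
#'   warning is also raised), and the settings echo.
#' @examples
#' spec <- model_spec("arc")
#' ens <- sample_networks(spec, theta = 0, n = 5,
#'                        settings = sampler_settings(5, sample_size = 50))
#' mean(ens$statistics[, "arc"]) / 20  # density near 0.5
#' @export
sample_networks <- function(spec, theta, n = 30L,
                            settings = sampler_settings(n),
                            start = NULL, keep_networks = FALSE) {
  stats <- as_stat_list(spec)
  p <- length(stats)
  theta <- as.numeric(theta)
  if (length(theta) != p) stop("theta length does not match spec", call. = FALSE)
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  if (is.null(start)) start <- empty_web(n)
  validate_foodweb(start)
  n <- n_species(start)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  codes <- stat_codes(stats)
  if (anyNA(codes)) stop("spec contains non-modellable statistics", call. = FALSE)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(settings$seed)
  res <- cpp_ergm_sample(start$adjacency, as.integer(codes),
                         stat_lambdas(stats), theta,
                         settings$burn_in, settings$thinning,
                         settings$sample_size, keep_networks)
  colnames(res$statistics) <- stat_names(stats)
  nets <- NULL
  if (keep_networks) {
    nets <- lapply(res$networks, foodweb, species = start$species)
  }
  arc_col <- match("arc", stat_names(stats))
  degenerate <- FALSE
  if (!is.na(arc_col)) {
    dens <- res$statistics[, arc_col] / (n * (n - 1))
    degenerate <- mean(dens == 0 | dens == 1) > 0.9
  }
  ens <- structure(list(
    statistics = res$statistics,
    networks = nets,
    acceptance_rate = res$acceptance_rate,
    final_web = foodweb(res$final_adjacency, species = start$species),
    degenerate = degenerate,
    spec = if (inherits(spec, "model_spec")) spec else NULL,
    theta = stats::setNames(theta, stat_names(stats)),
    settings = settings
  ), class = "sample_ensemble")
  if (degenerate) {
    warning("sampler drifted to a degenerate region (density pinned at 0 or 1)",
            call. = FALSE)
  }
  ens
}

#' @export
print.sample_ensemble <- function(x, ...) {
  cat(sprintf("<sample_ensemble> %d retained networks, acceptance %.3f%s\n",
              nrow(x$statistics), x$acceptance_rate,
              if (isTRUE(x$degenerate)) " [DEGENERATE]" else ""))
  print(round(colMeans(x$statistics), 3))
  invisible(x)
}

#' Export a statistics trace to CSV
#'
#' One row per retained network, columns named after the configurations.
#'
#' @param ensemble a \code{sample_ensemble}.
#' @param path destination CSV.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(ensemble, path) {
  utils::write.csv(as.data.frame(ensemble$statistics), path, row.names = FALSE)
  invisible(path)
}
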