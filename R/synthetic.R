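# Synthetic food webs: hand-built fixtures, niche-model generation, and
# ERGM-simulated study data for parameter-recovery experiments.

#' Canonical fixture webs
#'
#' Small hand-built webs with exactly known statistics, plus a frozen
#' 30-species Baltic-scale web shipped with the package:
#' \describe{
#'   \item{chain3}{tri-trophic chain A -> B -> C}
#'   \item{omnivory3}{chain plus the omnivore shortcut A -> B, B -> C, A -> C}
#'   \item{pred_star4}{one predator P eating prey a, b, c}
#'   \item{prey_fan4}{one prey R eaten by predators x, y, z}
#'   \item{baltic_like_30}{frozen synthetic niche-model web: 30 species,
#'     180 arcs (connectance 0.207), no self-loops; committed as a data
#'     file so numbers attached to it are stable}
#' }
#'
#' @param name fixture name.
#' @return a \code{foodweb}.
#' @examples
#' triad_census(fixture_web("omnivory3"))
#' @export
fixture_web <- function(name) {
  switch(name,
    chain3 = foodweb_from_edges(c("A", "B"), c("B", "C"),
                                metadata = list(source = "fixture")),
    omnivory3 = foodweb_from_edges(c("A", "B", "A"), c("B", "C", "C"),
                                   metadata = list(source = "fixture")),
    pred_star4 = foodweb_from_edges(c("a", "b", "c"), c("P", "P", "P"),
                                    metadata = list(source = "fixture")),
    prey_fan4 = foodweb_from_edges(c("R", "R", "R"), c("x", "y", "z"),
                                   metadata = list(source = "fixture")),
    baltic_like_30 = read_foodweb(
      system.file("extdata", "baltic_like_30.csv", package = "foodwebERGM",
                  mustWork = TRUE),
      format = "edge-list",
      metadata = list(source = "synthetic niche-model fixture")),
    stop(sprintf("unknown fixture '%s'", name), call. = FALSE)
  )
}

#' Niche-model parameters
#'
#' @param n species count (\code{>= 2}).
#' @param connectance target fraction of the \code{n^2} possible links
#'   (including the later-removed cannibalistic ones), in (0, 1); webs of
#'   the scale studied here typically sit near 0.2.
#' @param seed integer seed.
#' @return list of class \code{"niche_params"}.
#' @export
niche_params <- function(n = 30L, connectance = 0.2, seed = 1L) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (connectance <= 0 || connectance >= 1) {
    stop("connectance must be in (0, 1)", call. = FALSE)
  }
  structure(list(n = as.integer(n), connectance = connectance,
                 seed = as.integer(seed)), class = "niche_params")
}

#' Generate a food web from the niche model
#'
#' Classic niche-model generator: each species draws a niche value
#' \code{u_i ~ U(0, 1)} and consumes every species whose niche value falls
#' in an interval of width \code{r_i = u_i * x_i},
#' \code{x_i ~ Beta(1, 1/(2C) - 1)}, centred at \code{c_i ~ U(r_i/2, u_i)}.
#' Consumption of prey j by consumer i yields the arc j -> i (energy flows
#' prey to predator). The construction places wide diets low in niche space
#' and yields the triangular trophic structure (fewer species higher up)
#' typical of real webs at the target connectance \code{C}. Cannibalistic
#' self-links are deleted, not redrawn.
#'
#' @param params a \code{\link{niche_params}}.
#' @return a \code{foodweb} with metadata recording the generator.
#' @export
niche_model_web <- function(params = niche_params()) {
  n <- params$n
  C <- params$connectance
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(params$seed)
  u <- stats::runif(n)
  beta_shape <- 1 / (2 * C) - 1
  x <- if (beta_shape > 0) stats::rbeta(n, 1, beta_shape) else rep(1, n)
  r <- u * x
  centre <- stats::runif(n, r / 2, pmax(u, r / 2))
  lo <- centre - r / 2
  hi <- centre + r / 2
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    prey <- which(u >= lo[i] & u <= hi[i])
    adj[prey, i] <- 1L  # prey -> consumer i
  }
  diag(adj) <- 0L  # cannibalism removed
  achieved <- sum(adj) / n^2
  if (abs(achieved - C) > 0.75 * C) {
    warning(sprintf("achieved connectance %.3f far from target %.3f",
                    achieved, C), call. = FALSE)
  }
  foodweb(adj, species = sprintf("sp%02d", seq_len(n)),
          metadata = list(source = "niche_model", connectance_target = C,
                          seed = params$seed))
}

#' Simulate a recovery study from known parameters
#'
#' Draws replicate food webs from an ERGM at a known \code{theta_true},
#' each with an independently derived sub-seed, for parameter-recovery
#' scoring. Errors (naming the parameter vector) if the generating model is
#' degenerate, i.e. the sampled webs are essentially all empty or all
#' complete.
#'
#' @param theta_true generating parameter vector aligned to \code{spec}.
#' @param spec a \code{\link{model_spec}}.
#' @param n species count.
#' @param replicates number of webs.
#' @param seed master seed; replicate r uses a sub-seed derived from it.
#' @param settings optional \code{\link{sampler_settings}} template
#'   (burn-in/thinning reused; one web retained per replicate).
#' @return list of \code{foodweb} with attribute \code{theta_true}.
#' @export
simulate_study <- function(theta_true, spec, n = 30L, replicates = 10L,
                           seed = 1L, settings = NULL) {
  stats <- as_stat_list(spec)
  if (length(theta_true) != length(stats)) {
    stop("theta_true length does not match spec", call. = FALSE)
  }
  webs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    # each replicate is a fresh chain from the empty web; equilibration from
    # a cold start needs far more proposals than the within-chain thinning,
    # hence the long default burn-in
    s <- if (is.null(settings)) {
      sampler_settings(n, burn_in = 500 * n^2)
    } else {
      settings
    }
    s$sample_size <- 1L
    s$seed <- derive_seed(seed, paste0("replicate", r))
    ens <- suppressWarnings(
      sample_networks(spec, theta_true, n = n, settings = s,
                      keep_networks = TRUE)
    )
    webs[[r]] <- ens$networks[[1L]]
  }
  dens <- vapply(webs, web_density, numeric(1))
  if (all(dens == 0) || all(dens == 1)) {
    stop(sprintf("degenerate generating model: theta = (%s) yields %s webs",
                 paste(signif(theta_true, 4), collapse = ", "),
                 if (all(dens == 0)) "empty" else "complete"), call. = FALSE)
  }
  attr(webs, "theta_true") <- stats::setNames(as.numeric(theta_true),
                                              stat_names(stats))
  webs
}
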