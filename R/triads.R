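# Descriptive motif baseline: directed triad census and z-scores against
# random-network null models. This is the classical motif analysis that the
# ERGM machinery supersedes, kept as a descriptive companion.

#' Directed triad census
#'
#' Counts all unordered node triples of a web in the 16 standard directed
#' triad isomorphism classes (MAN labelling, \code{003} ... \code{300}).
#'
#' @param web a \code{foodweb}.
#' @return object of class \code{"triad_census"}: list with \code{counts}
#'   (named numeric of length 16, summing to \code{choose(n, 3)}) and
#'   \code{n}.
#' @examples
#' triad_census(fixture_web("chain3"))  # one 021C (directed path)
#' @export
triad_census <- function(web) {
  validate_foodweb(web)
  n <- n_species(web)
  counts <- if (n < 3) stats::setNames(numeric(16), TRIAD_CLASSES) else {
    stats::setNames(cpp_triad_census(web$adjacency), TRIAD_CLASSES)
  }
  structure(list(counts = counts, n = n), class = "triad_census")
}

#' @export
print.triad_census <- function(x, ...) {
  cat("<triad_census>", x$n, "species,", sum(x$counts), "triples\n")
  print(x$counts[x$counts > 0])
  invisible(x)
}

#' Random food web with the same species and arc count
#'
#' Density-preserving null: the given number of arcs placed uniformly at
#' random over the \code{n(n-1)} loop-free ordered dyads.
#'
#' @param web template \code{foodweb} (species and arc count reused).
#' @return a random \code{foodweb}.
#' @export
null_density_preserving <- function(web) {
  n <- n_species(web)
  L <- n_arcs(web)
  dyads <- which(!diag(n))
  adj <- matrix(0L, n, n)
  adj[sample(dyads, L)] <- 1L
  foodweb(adj, species = web$species, metadata = web$metadata)
}

#' Random food web with the same in- and out-degree sequences
#'
#' Degree-preserving null by checkerboard (2x2) swap MCMC: repeatedly pick
#' two arcs \code{a->b}, \code{c->d} and rewire them to \code{a->d},
#' \code{c->b} when that creates neither loops nor multi-arcs. Both degree
#' sequences are preserved exactly.
#'
#' @param web template \code{foodweb}.
#' @param swaps number of attempted swaps; default 10x the arc count.
#' @return a random \code{foodweb}.
#' @export
null_degree_preserving <- function(web, swaps = 10L * n_arcs(web)) {
  adj <- web$adjacency
  E <- which(adj == 1L, arr.ind = TRUE)
  L <- nrow(E)
  if (L >= 2L) {
    for (s in seq_len(swaps)) {
      e <- sample.int(L, 2L)
      a <- E[e[1L], 1L]; b <- E[e[1L], 2L]
      c <- E[e[2L], 1L]; d <- E[e[2L], 2L]
      if (a == d || c == b) next
      if (adj[a, d] == 1L || adj[c, b] == 1L) next
      adj[a, b] <- 0L; adj[c, d] <- 0L
      adj[a, d] <- 1L; adj[c, b] <- 1L
      E[e[1L], 2L] <- d; E[e[2L], 2L] <- b
    }
  }
  foodweb(adj, species = web$species, metadata = web$metadata)
}

#' Motif z-scores against a random-network null model
#'
#' Compares the observed counts of the 13 connected triad classes with their
#' distribution over random networks: either arc-count-preserving
#' (\code{"density-preserving"}) or in/out-degree-sequence-preserving
#' (\code{"degree-preserving"}) nulls. A motif with \code{|z| > 2} is over-
#' or under-represented relative to the null. When a null distribution is
#' degenerate (sd = 0) the z-score is reported as \code{NA}, not an error.
#'
#' @param web a \code{foodweb}.
#' @param null \code{"density-preserving"} or \code{"degree-preserving"}.
#' @param replicates number of null networks (\code{>= 2}).
#' @param seed integer seed; the report is deterministic given the seed.
#' @return object of class \code{"motif_report"}: list with \code{table}
#'   (data.frame: motif, observed, null_mean, null_sd, z), \code{null},
#'   \code{replicates}, \code{seed}.
#' @export
motif_zscores <- function(web, null = c("density-preserving", "degree-preserving"),
                          replicates = 1000L, seed = 1L) {
  null <- match.arg(null)
  validate_foodweb(web)
  if (replicates < 2L) stop("replicates must be >= 2", call. = FALSE)
  sampler <- switch(null,
    "density-preserving" = null_density_preserving,
    "degree-preserving" = null_degree_preserving
  )
  observed <- triad_census(web)$counts[CONNECTED_TRIADS]
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  null_counts <- matrix(0, replicates, length(CONNECTED_TRIADS),
                        dimnames = list(NULL, CONNECTED_TRIADS))
  for (r in seq_len(replicates)) {
    null_counts[r, ] <- triad_census(sampler(web))$counts[CONNECTED_TRIADS]
  }
  mu <- colMeans(null_counts)
  sdv <- apply(null_counts, 2L, stats::sd)
  z <- ifelse(sdv > 0, (observed - mu) / sdv, NA_real_)
  tab <- data.frame(
    motif = CONNECTED_TRIADS,
    observed = as.numeric(observed),
    null_mean = as.numeric(mu),
    null_sd = as.numeric(sdv),
    z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, null = null, replicates = replicates,
                 seed = as.integer(seed)),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("<motif_report> null = %s, %d replicates, seed %d\n",
              x$null, x$replicates, x$seed))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
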