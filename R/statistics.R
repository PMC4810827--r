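# Configuration-statistic catalogue.
#
# Statistics are exact functions z_s(G) of a directed, binary, loop-free
# graph. Alternating ("geometrically weighted") forms use the kernel
#   g_lambda(d) = lambda * (1 - (1 - 1/lambda)^d),
# an increasing, concave transform of a partner/star count d that saturates
# at lambda, so one parameter captures a whole spectrum of star sizes
# without the degeneracy of raw k-star models.

TRIAD_CLASSES <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                   "111U", "030T", "030C", "201", "120D", "120U", "120C",
                   "210", "300")
CONNECTED_TRIADS <- setdiff(TRIAD_CLASSES, c("003", "012", "102"))

# change-statistic-capable statistics (usable in a fitted model); the code
# column is the dispatch id shared with the compiled kernels
CATALOGUE <- data.frame(
  name = c("arc", "reciprocity", "generalist", "highly_predated", "keystone",
           "tri_trophic", "apparent_competition", "exploitative_competition",
           "omnivory", "cyclic_triangle",
           "in_2_star", "in_3_star", "out_2_star", "out_3_star",
           "two_path", "transitive_triangle", "cyclic_triangle_raw"),
  code = 1:17,
  alternating = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Geometrically weighted partner kernel
#'
#' \code{g_lambda(d) = lambda (1 - (1 - 1/lambda)^d)}, the down-weighting
#' applied to a star or shared-partner count \code{d} by all alternating
#' configuration statistics. As \code{lambda} grows the kernel approaches
#' \code{d} itself (raw counting); at \code{lambda = 1} only the first
#' partner counts.
#'
#' @param d non-negative count(s).
#' @param lambda smoothing weight, \code{>= 1}.
#' @return numeric, same shape as \code{d}.
#' @export
g_lambda <- function(d, lambda) lambda * (1 - (1 - 1 / lambda)^d)

# alternating k-star weight of a single node of degree d:
# lambda^2 ((1-1/lambda)^d + d/lambda - 1) == sum_{k>=2} (-1/lambda)^(k-2) S_k(d)
alt_star_node <- function(d, lambda) {
  lambda^2 * ((1 - 1 / lambda)^d + d / lambda - 1)
}

#' Define a configuration statistic
#'
#' @param name one of the registered statistic names; see Details.
#' @param lambda smoothing weight for alternating statistics (\code{>= 1});
#'   ignored (stored as 1) for non-alternating statistics.
#'
#' @details Model-capable statistics (these have change statistics and can be
#' fitted): \code{arc}, \code{reciprocity}, \code{generalist} (alternating
#' in-star: predators with many prey), \code{highly_predated} (alternating
#' out-star: prey with many predators), \code{keystone} (mixed alternating
#' star: species with both many prey and many predators),
#' \code{tri_trophic} (alternating mixed two-path: food chains),
#' \code{apparent_competition} (two prey sharing predators),
#' \code{exploitative_competition} (two predators sharing prey),
#' \code{omnivory} (alternating transitive triangle: a chain plus the direct
#' prey-to-top-consumer shortcut), \code{cyclic_triangle}, and the raw
#' counts \code{in_2_star}, \code{in_3_star}, \code{out_2_star},
#' \code{out_3_star}, \code{two_path}, \code{transitive_triangle},
#' \code{cyclic_triangle_raw}.
#'
#' Additional descriptive statistics, valid in goodness-of-fit suites only:
#' \code{triad_<class>} for the 13 connected directed triad classes (e.g.
#' \code{triad_021C}), \code{in_degree_sd}, \code{out_degree_sd}.
#' @return object of class \code{"config_stat"}.
#' @export
config_stat <- function(name, lambda = 2) {
  if (!is.character(name) || length(name) != 1L) {
    stop("name must be a single string", call. = FALSE)
  }
  if (!name %in% all_statistic_names()) {
    stop(sprintf("unknown configuration statistic '%s'", name), call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 1) {
    stop("lambda must be a single number >= 1", call. = FALSE)
  }
  alt <- name %in% CATALOGUE$name[CATALOGUE$alternating]
  structure(list(name = name, lambda = if (alt) as.numeric(lambda) else 1),
            class = "config_stat")
}

#' @export
print.config_stat <- function(x, ...) {
  cat(sprintf("<config_stat> %s (lambda = %g)\n", x$name, x$lambda))
  invisible(x)
}

all_statistic_names <- function() {
  c(CATALOGUE$name, paste0("triad_", CONNECTED_TRIADS),
    "in_degree_sd", "out_degree_sd")
}

# normalize a spec/suite argument to a list of config_stat
as_stat_list <- function(spec, lambda = 2) {
  if (inherits(spec, "model_spec")) return(spec$configurations)
  if (inherits(spec, "config_stat")) return(list(spec))
  if (is.character(spec)) return(lapply(spec, config_stat, lambda = lambda))
  if (is.list(spec) && all(vapply(spec, inherits, TRUE, "config_stat"))) {
    return(spec)
  }
  stop("cannot interpret statistic specification", call. = FALSE)
}

stat_names <- function(stats) vapply(stats, `[[`, "", "name")
stat_lambdas <- function(stats) vapply(stats, `[[`, 0, "lambda")

# codes for the compiled kernels; NA for GoF-only statistics
stat_codes <- function(stats) {
  CATALOGUE$code[match(stat_names(stats), CATALOGUE$name)]
}

#' Define an ERGM model specification
#'
#' An ordered list of configuration statistics to be fitted jointly. Every
#' model must contain \code{arc}, the baseline tie propensity controlling
#' for density (analogous to a regression intercept).
#'
#' @param ... \code{\link{config_stat}} objects and/or statistic names
#'   (characters get \code{lambda = lambda}).
#' @param lambda default smoothing weight applied to names passed as
#'   characters.
#' @return object of class \code{"model_spec"}.
#' @examples
#' spec <- model_spec("arc", "generalist", "tri_trophic")
#' @export
model_spec <- function(..., lambda = 2) {
  parts <- list(...)
  stats <- list()
  for (p in parts) stats <- c(stats, as_stat_list(p, lambda = lambda))
  nm <- stat_names(stats)
  if (anyDuplicated(nm)) stop("duplicate configuration names", call. = FALSE)
  if (!"arc" %in% nm) stop("a model must include the 'arc' baseline", call. = FALSE)
  if (anyNA(stat_codes(stats))) {
    bad <- nm[is.na(stat_codes(stats))]
    stop(sprintf("statistic(s) %s have no change statistic and cannot be modelled",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(configurations = stats), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", length(x$configurations), "configurations:\n")
  for (s in x$configurations) {
    cat(sprintf("  %-26s lambda = %g\n", s$name, s$lambda))
  }
  invisible(x)
}

#' Read a model specification from YAML
#'
#' Expects a YAML list of mappings with keys \code{name} and (optionally)
#' \code{lambda}, e.g. \code{- name: generalist} / \code{  lambda: 2}.
#'
#' @param path YAML file.
#' @return a \code{\link{model_spec}}.
#' @export
read_model_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  stats <- lapply(raw, function(e) {
    if (is.null(e$name)) stop("model spec entry without a name", call. = FALSE)
    config_stat(e$name, lambda = if (is.null(e$lambda)) 2 else e$lambda)
  })
  do.call(model_spec, stats)
}

#' The seven-configuration food-web model
#'
#' The model specification used for the Baltic food webs: arc baseline plus
#' generalist, highly predated species, keystone species, omnivory,
#' tri-trophic chain and apparent competition.
#'
#' @param lambda smoothing weight for the alternating statistics.
#' @param exploitative also include exploitative competition.
#' @return a \code{\link{model_spec}}.
#' @export
foodweb_model_spec <- function(lambda = 2, exploitative = FALSE) {
  nms <- c("arc", "generalist", "highly_predated", "keystone", "omnivory",
           "tri_trophic", "apparent_competition")
  if (exploitative) nms <- c(nms, "exploitative_competition")
  do.call(model_spec, c(as.list(nms), list(lambda = lambda)))
}

#' Compute configuration statistics of a food web
#'
#' Exact (non-sampled) values of every statistic in \code{spec}, via dense
#' matrix algebra. Accepts a \code{\link{model_spec}}, a list of
#' \code{\link{config_stat}}, or a character vector of names.
#'
#' @param web a \code{foodweb}.
#' @param spec statistics to compute.
#' @param lambda default smoothing weight for names given as characters.
#' @return named numeric vector aligned to \code{spec}.
#' @examples
#' web <- fixture_web("chain3")
#' compute_statistics(web, model_spec("arc", "tri_trophic"))
#' @export
compute_statistics <- function(web, spec, lambda = 2) {
  validate_foodweb(web)
  stats <- as_stat_list(spec, lambda = lambda)
  X <- web$adjacency
  storage.mode(X) <- "double"
  din <- colSums(X)   # prey counts of each predator
  dout <- rowSums(X)  # predator counts of each prey
  P <- NULL; Sout <- NULL; Sin <- NULL; census <- NULL
  need <- stat_names(stats)
  if (any(need %in% c("tri_trophic", "omnivory", "cyclic_triangle",
                      "two_path", "transitive_triangle",
                      "cyclic_triangle_raw"))) P <- X %*% X
  if ("apparent_competition" %in% need) Sout <- X %*% t(X)
  if ("exploitative_competition" %in% need) Sin <- t(X) %*% X
  if (any(startsWith(need, "triad_"))) {
    census <- triad_census(web)$counts
  }
  off <- !diag(nrow(X))  # i != j mask
  vapply(stats, function(s) {
    lam <- s$lambda
    switch(s$name,
      arc = sum(X),
      reciprocity = sum(X * t(X)) / 2,
      generalist = sum(alt_star_node(din, lam)),
      highly_predated = sum(alt_star_node(dout, lam)),
      keystone = sum(g_lambda(din, lam) * g_lambda(dout, lam)),
      tri_trophic = sum(g_lambda(P[off], lam)),
      apparent_competition = sum(g_lambda(Sout[upper.tri(Sout)], lam)),
      exploitative_competition = sum(g_lambda(Sin[upper.tri(Sin)], lam)),
      omnivory = sum(g_lambda(P, lam) * X),
      cyclic_triangle = sum(g_lambda(t(P), lam) * X),
      in_2_star = sum(choose(din, 2)),
      in_3_star = sum(choose(din, 3)),
      out_2_star = sum(choose(dout, 2)),
      out_3_star = sum(choose(dout, 3)),
      two_path = sum(P[off]),
      transitive_triangle = sum(P * X),
      cyclic_triangle_raw = sum(t(P) * X) / 3,
      in_degree_sd = stats::sd(din),
      out_degree_sd = stats::sd(dout),
      {
        if (startsWith(s$name, "triad_")) {
          as.numeric(census[[sub("^triad_", "", s$name)]])
        } else {
          stop(sprintf("unknown statistic '%s'", s$name), call. = FALSE)
        }
      }
    )
  }, numeric(1), USE.NAMES = FALSE) -> values
  names(values) <- need
  values
}

#' Change statistics of a dyad
#'
#' The vector \code{delta_s(i, j) = z_s(G + ij) - z_s(G - ij)}: the change
#' in every model statistic when the arc prey \code{i} -> predator \code{j}
#' is switched on, regardless of its current state. This is the kernel of
#' both Metropolis-Hastings simulation and maximum-likelihood estimation.
#'
#' @param web a \code{foodweb}.
#' @param spec a \code{\link{model_spec}} (or coercible).
#' @param i,j species indices (1-based) or labels; \code{i != j}.
#' @return named numeric vector of changes, aligned to \code{spec}.
#' @export
change_statistics <- function(web, spec, i, j) {
  validate_foodweb(web)
  stats <- as_stat_list(spec)
  codes <- stat_codes(stats)
  if (anyNA(codes)) stop("spec contains statistics without change statistics",
                         call. = FALSE)
  if (is.character(i)) i <- match(i, web$species)
  if (is.character(j)) j <- match(j, web$species)
  if (anyNA(c(i, j))) stop("unknown species label", call. = FALSE)
  if (i == j) stop("self-loop dyad (i == j)", call. = FALSE)
  d <- cpp_change_stats(web$adjacency, as.integer(codes),
                        stat_lambdas(stats), as.integer(i), as.integer(j))
  names(d) <- stat_names(stats)
  d
}

#' Conditional log-odds of an arc
#'
#' Log-odds that arc \code{i -> j} is present given the rest of the graph,
#' under an ERGM with parameters \code{theta}: the inner product of
#' \code{theta} with the dyad's change statistics.
#'
#' @param web a \code{foodweb}.
#' @param spec a \code{\link{model_spec}}.
#' @param theta numeric parameter vector aligned to \code{spec}.
#' @param i,j species indices or labels, \code{i != j}.
#' @return a single number.
#' @export
conditional_logodds <- function(web, spec, theta, i, j) {
  stats <- as_stat_list(spec)
  if (length(theta) != length(stats)) {
    stop("theta length does not match the model specification", call. = FALSE)
  }
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  sum(theta * change_statistics(web, spec, i, j))
}
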