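#' Construct a food web
#'
#' A food web is a directed, binary, loop-free graph whose nodes are species
#' and whose arcs point in the direction of energy transfer: an arc
#' \code{i -> j} means prey \code{i} is eaten by predator \code{j}.
#' Cannibalism (self-loops) is excluded.
#'
#' @param adjacency square 0/1 matrix; entry \code{(i, j) = 1} encodes the arc
#'   prey \code{i} -> predator \code{j}. Row/column names, if present, are
#'   used as species labels.
#' @param species character vector of unique, non-empty species labels; if
#'   \code{NULL}, taken from \code{rownames(adjacency)} or generated as
#'   \code{s1, s2, ...}.
#' @param metadata free-form named list (e.g. \code{region}, \code{period},
#'   \code{source}); recorded verbatim.
#'
#' @return An object of class \code{"foodweb"}: a list with elements
#'   \code{species}, \code{adjacency} (integer matrix with dimnames) and
#'   \code{metadata}.
#' @examples
#' adj <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' adj["A", "B"] <- 1L
#' adj["B", "C"] <- 1L
#' web <- foodweb(adj)
#' n_arcs(web)
#' @export
foodweb <- function(adjacency, species = NULL, metadata = list()) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be square", call. = FALSE)
  }
  n <- nrow(adjacency)
  if (is.null(species)) {
    species <- rownames(adjacency)
    if (is.null(species)) species <- paste0("s", seq_len(n))
  }
  species <- as.character(species)
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(species, species)
  web <- structure(
    list(species = species, adjacency = adjacency, metadata = metadata),
    class = "foodweb"
  )
  validate_foodweb(web)
  web
}

#' Validate food-web invariants
#'
#' Checks the class invariants: at least two species, unique non-empty
#' labels, strictly 0/1 entries, and no self-loops (cannibalism excluded).
#'
#' @param web a \code{foodweb}.
#' @return \code{web}, invisibly; errors on violation.
#' @export
validate_foodweb <- function(web) {
  if (!inherits(web, "foodweb")) stop("not a foodweb object", call. = FALSE)
  a <- web$adjacency
  n <- length(web$species)
  if (n < 2) stop("a food web needs at least 2 species", call. = FALSE)
  if (nrow(a) != n || ncol(a) != n) stop("adjacency dimension mismatch", call. = FALSE)
  if (anyNA(a) || !all(a == 0L | a == 1L)) {
    stop("adjacency entries must be exactly 0 or 1", call. = FALSE)
  }
  if (any(diag(a) != 0L)) {
    stop("self-loops are not allowed (cannibalism excluded)", call. = FALSE)
  }
  if (anyDuplicated(web$species)) stop("duplicate species label", call. = FALSE)
  if (any(!nzchar(web$species)) || anyNA(web$species)) {
    stop("species labels must be non-empty", call. = FALSE)
  }
  invisible(web)
}

#' @export
print.foodweb <- function(x, ...) {
  n <- length(x$species)
  L <- n_arcs(x)
  cat(sprintf("<foodweb> %d species, %d arcs (connectance %.3f)\n",
              n, L, L / (n * (n - 1))))
  if (length(x$metadata)) {
    meta <- paste(names(x$metadata), unlist(lapply(x$metadata, paste, collapse = ",")),
                  sep = "=", collapse = "; ")
    cat(" metadata:", meta, "\n")
  }
  invisible(x)
}

#' Number of arcs (trophic links) in a web
#' @param web a \code{foodweb}.
#' @return integer arc count.
#' @export
n_arcs <- function(web) sum(web$adjacency)

#' Number of species in a web
#' @param web a \code{foodweb}.
#' @return integer species count.
#' @export
n_species <- function(web) length(web$species)

#' Arc density of a web
#' @param web a \code{foodweb}.
#' @return fraction of the \code{n(n-1)} possible arcs that are present.
#' @export
web_density <- function(web) {
  n <- n_species(web)
  n_arcs(web) / (n * (n - 1))
}

#' Build a food web from an edge list
#'
#' @param prey,predator character vectors of equal length: one arc per entry,
#'   energy flowing prey -> predator.
#' @param species optional label universe (to include isolated species); all
#'   prey/predator labels must be contained in it.
#' @param metadata metadata list, see \code{\link{foodweb}}.
#' @return a \code{foodweb}.
#' @export
foodweb_from_edges <- function(prey, predator, species = NULL, metadata = list()) {
  prey <- as.character(prey)
  predator <- as.character(predator)
  if (length(prey) != length(predator)) {
    stop("prey and predator vectors must have equal length", call. = FALSE)
  }
  if (any(prey == predator)) {
    bad <- which(prey == predator)[1L]
    stop(sprintf("self-loop on species '%s' (arc %d)", prey[bad], bad), call. = FALSE)
  }
  if (is.null(species)) {
    species <- sort(unique(c(prey, predator)))
  } else if (!all(c(prey, predator) %in% species)) {
    stop("edge list refers to species absent from the species vector", call. = FALSE)
  }
  n <- length(species)
  adj <- matrix(0L, n, n, dimnames = list(species, species))
  adj[cbind(match(prey, species), match(predator, species))] <- 1L
  foodweb(adj, species = species, metadata = metadata)
}

#' Edge list of a food web
#'
#' @param web a \code{foodweb}.
#' @return data.frame with character columns \code{prey} and \code{predator},
#'   one row per arc, ordered row-major by species order.
#' @export
foodweb_edges <- function(web) {
  idx <- which(web$adjacency == 1L, arr.ind = TRUE)
  df <- data.frame(
    prey = web$species[idx[, 1L]],
    predator = web$species[idx[, 2L]],
    stringsAsFactors = FALSE
  )
  df[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Read a food web from disk
#'
#' Two plain-text dialects are supported. \code{"edge-list"} is the canonical
#' format: a CSV with header \code{prey,predator} and one arc per row.
#' \code{"adjacency"} is a labelled CSV matrix whose cell \code{(r, c) = 1}
#' means arc row-species -> column-species (prey in rows, predators in
#' columns).
#'
#' @param path file to read.
#' @param format \code{"edge-list"} or \code{"adjacency"}.
#' @param species optional label universe for the edge-list format (needed to
#'   preserve isolated species).
#' @param metadata metadata to attach.
#' @return a \code{foodweb}.
#' @export
read_foodweb <- function(path, format = c("edge-list", "adjacency"),
                         species = NULL, metadata = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "edge-list") {
    df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
    if (!identical(names(df)[1:2], c("prey", "predator"))) {
      stop(sprintf("%s: expected header 'prey,predator'", path), call. = FALSE)
    }
    bad <- which(!nzchar(df$prey) | !nzchar(df$predator))
    if (length(bad)) {
      stop(sprintf("%s: malformed row at line %d", path, bad[1L] + 1L), call. = FALSE)
    }
    foodweb_from_edges(df$prey, df$predator, species = species, metadata = metadata)
  } else {
    m <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    m <- as.matrix(m)
    if (!identical(rownames(m), colnames(m))) {
      stop(sprintf("%s: adjacency row and column labels differ", path), call. = FALSE)
    }
    suppressWarnings(storage.mode(m) <- "integer")
    if (anyNA(m)) stop(sprintf("%s: non-numeric adjacency cell", path), call. = FALSE)
    foodweb(m, metadata = metadata)
  }
}

#' Write a food web to disk
#'
#' Inverse of \code{\link{read_foodweb}}: the written file round-trips to an
#' identical web (same labels and arc set).
#'
#' @param web a \code{foodweb}.
#' @param path destination file.
#' @param format \code{"edge-list"} or \code{"adjacency"}.
#' @return \code{path}, invisibly.
#' @export
write_foodweb <- function(web, path, format = c("edge-list", "adjacency")) {
  format <- match.arg(format)
  validate_foodweb(web)
  if (format == "edge-list") {
    utils::write.csv(foodweb_edges(web), path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(as.data.frame(web$adjacency), path, quote = FALSE)
  }
  invisible(path)
}

#' Convert a food web to an igraph graph
#'
#' @param web a \code{foodweb}.
#' @return a directed \code{igraph} graph with vertex names = species labels.
#' @export
as_igraph <- function(web) {
  igraph::graph_from_adjacency_matrix(web$adjacency, mode = "directed")
}
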