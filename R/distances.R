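#' Invert contact frequencies into direct spatial distances
#'
#' Following the Shrec3D idea, a contact frequency `c_ij > 0` between two
#' bins is converted into a direct distance estimate
#' `d0_ij = c_ij^(-1/gamma)`; bin pairs with zero contacts get no direct
#' edge (their distance is defined only through paths). The diagonal is
#' ignored. Direct inversion is unreliable for distal, rarely contacting
#' pairs, which is why [shortest_path_distances()] completes the metric.
#'
#' @param cm a [contact_map()].
#' @param gamma positive inversion exponent (`d` proportional to
#'   `c^(-1/gamma)`); default 1, the convention of the shortest-path
#'   reconstruction method.
#' @return a `contact_graph`: list with `graph` (sparse symmetric matrix
#'   of direct distances, 0 = no edge), `bins`, `gamma`.
#' @export
contacts_to_proximal_distances <- function(cm, gamma = 1) {
  stopifnot(inherits(cm, "contact_map"), gamma > 0)
  C <- cm$counts
  diag(C) <- 0
  if (all(C == 0)) stop("no edges: contact map has no positive off-diagonal entries")
  d0 <- matrix(0, nrow(C), ncol(C))
  pos <- C > 0
  d0[pos] <- C[pos]^(-1 / gamma)
  structure(list(graph = Matrix::Matrix(d0, sparse = TRUE),
                 bins = cm$bins, gamma = gamma),
            class = "contact_graph")
}

#' Complete direct distances with all-pairs shortest paths
#'
#' Computes, for every bin pair, the length of the shortest path through
#' the direct-distance graph (exact Dijkstra via igraph). The result is
#' a metric on each connected component: zero diagonal, symmetric,
#' triangle inequality, and never larger than the direct distance.
#' Pairs in different components (e.g. chromosomes with no
#' trans-chromosomal contacts) are at distance `Inf` and never fall into
#' any distance shell downstream.
#'
#' @param g a `contact_graph` from [contacts_to_proximal_distances()].
#' @return a numeric matrix of distances with attributes `unit`
#'   (`"contact"`), `gamma`, and `bins`.
#' @export
shortest_path_distances <- function(g) {
  stopifnot(inherits(g, "contact_graph"))
  adj <- as.matrix(g$graph)
  if (all(adj == 0)) stop("graph has no edges")
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  D <- igraph::distances(ig, algorithm = "dijkstra")
  dimnames(D) <- NULL
  diag(D) <- 0
  attr(D, "unit") <- "contact"
  attr(D, "gamma") <- g$gamma
  attr(D, "bins") <- g$bins
  D
}

#' Rescale a distance matrix to physical units
#'
#' Multiplies every finite distance by `nm_per_unit` and tags the result
#' as nanometres. The conversion factor is a free input: it depends on an
#' external calibration of the contact-to-distance relation and is not
#' derived from the data.
#'
#' @param D a distance matrix from [shortest_path_distances()].
#' @param nm_per_unit positive scale factor (nm per contact unit).
#' @return the rescaled matrix with `unit = "nm"`.
#' @export
rescale_distances <- function(D, nm_per_unit) {
  if (!is.numeric(nm_per_unit) || length(nm_per_unit) != 1L ||
      !is.finite(nm_per_unit) || nm_per_unit <= 0) {
    stop("nm_per_unit must be a positive finite scalar")
  }
  at <- attributes(D)
  out <- D * nm_per_unit
  attributes(out) <- at
  attr(out, "unit") <- "nm"
  out
}

#' Data-driven default shell width
#'
#' When no physical calibration is available, the shell thickness
#' defaults to the 5th percentile of the finite positive pairwise
#' distances, so that the first shell captures the closest few percent of
#' bin pairs regardless of the arbitrary distance unit.
#'
#' @param D a distance matrix.
#' @param prob quantile used (default 0.05).
#' @return positive scalar shell width, reported via `message()`.
#' @export
default_shell_width <- function(D, prob = 0.05) {
  v <- D[upper.tri(D)]
  v <- v[is.finite(v) & v > 0]
  if (length(v) == 0L) stop("no finite positive distances")
  dr <- as.numeric(stats::quantile(v, prob))
  message("shell width delta_r set to ", signif(dr, 4),
          " (", prob * 100, "th percentile of pairwise distances)")
  dr
}

#' Contact map to completed spatial distances in one call
#'
#' @param cm a [contact_map()].
#' @param gamma inversion exponent, see
#'   [contacts_to_proximal_distances()].
#' @param nm_per_unit optional physical calibration, see
#'   [rescale_distances()].
#' @return distance matrix as from [shortest_path_distances()].
#' @export
distances_from_contacts <- function(cm, gamma = 1, nm_per_unit = NULL) {
  D <- shortest_path_distances(contacts_to_proximal_distances(cm, gamma))
  if (!is.null(nm_per_unit)) D <- rescale_distances(D, nm_per_unit)
  D
}
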