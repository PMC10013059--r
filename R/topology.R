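#' Planar integer grid layout
#'
#' Places `width * height` oscillators on the integer grid. Coordinates are
#' 1-based and nodes are ordered row-major from (1,1): node 1 is (1,1), node 2
#' is (2,1), ..., node `width + 1` is (1,2), and so on.
#'
#' @param width,height Positive integers.
#' @return An object of class `oscomm_layout` with fields `width`, `height`
#'   and an `n x 2` integer coordinate matrix `coords`.
#' @examples
#' grid_layout(10, 10)$n # 100 oscillators
#' @export
grid_layout <- function(width, height) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L) {
    stop("grid dimensions must be positive integers")
  }
  coords <- as.matrix(expand.grid(x = seq_len(width), y = seq_len(height),
                                  KEEP.OUT.ATTRS = FALSE))
  structure(list(width = width, height = height,
                 n = width * height, coords = coords),
            class = "oscomm_layout")
}

# node index for (x, y) under the row-major convention
grid_index <- function(layout, x, y) (y - 1L) * layout$width + x

adjacency_from_edges <- function(n, edges) {
  stopifnot(is.matrix(edges) || nrow(edges) == 0L)
  if (nrow(edges) > 0L &&
      (any(edges < 1L) || any(edges > n) || any(edges[, 1] == edges[, 2]))) {
    stop("edge endpoints must be distinct indices in 1..n")
  }
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  adj <- split(as.integer(dst), factor(src, levels = seq_len(n)))
  lapply(unname(adj), sort)
}

new_topology <- function(kind, n, edges, layout = NULL, gamma = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  adj <- adjacency_from_edges(n, edges)
  degrees <- lengths(adj)
  structure(list(kind = kind, n = as.integer(n), layout = layout,
                 edges = edges, adj = adj, degrees = degrees,
                 gamma = gamma, node_costs = NULL, cost_mode = NULL,
                 base_cost = NULL,
                 n_isolated = sum(degrees == 0L)),
            class = "oscomm_topology")
}

#' @export
print.oscomm_topology <- function(x, ...) {
  cat(sprintf("%s topology: %d nodes, %d edges, mean degree %.3g\n",
              x$kind, x$n, nrow(x$edges), mean(x$degrees)))
  if (!is.null(x$gamma)) cat("  gamma:", x$gamma, "\n")
  if (x$n_isolated > 0L) cat("  isolated nodes:", x$n_isolated, "\n")
  if (!is.null(x$node_costs)) {
    cat(sprintf("  costs: %s, mean %.6g\n", x$cost_mode, mean(x$node_costs)))
  }
  invisible(x)
}

#' Connection topologies
#'
#' Generators for the four connection topologies: `topology_all_to_all()`
#' connects every distinct pair; `topology_nn4()` is the von Neumann
#' 4-nearest-neighbor lattice (axial neighbors, edge nodes omit whatever
#' connections cannot be formed); `topology_nn8()` is the Moore
#' 8-nearest-neighbor lattice (axial plus diagonal); and
#' `topology_prob_spatial()` places an edge between distinct grid nodes with
#' probability `1 / ((x2-x1)^2 + (y2-y1)^2 + gamma)`, each unordered pair
#' sampled independently once, so nearby nodes connect more often and smaller
#' `gamma` gives denser graphs.
#'
#' `topology_prob_spatial()` consumes the current R random stream: seed with
#' `set.seed()` for reproducible instances. Isolated nodes are possible (but
#' rare at `gamma = 10`); their count is recorded in the `n_isolated` field
#' and they are never silently regenerated.
#'
#' @param n Node count (>= 2) for the all-to-all topology.
#' @param layout A [grid_layout()].
#' @param gamma Non-negative density parameter of the probabilistic spatial
#'   topology.
#' @return An object of class `oscomm_topology` holding the symmetric 0/1
#'   adjacency (as edge list and adjacency list), per-node degrees, and the
#'   generating metadata.
#' @examples
#' topology_nn4(grid_layout(5, 5))
#' set.seed(1); topology_prob_spatial(grid_layout(10, 10), gamma = 10)
#' @export
topology_all_to_all <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("all-to-all topology needs n >= 2")
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  new_topology("all_to_all", n, cbind(i, j))
}

#' @rdname topology_all_to_all
#' @export
topology_nn4 <- function(layout) {
  stopifnot(inherits(layout, "oscomm_layout"))
  w <- layout$width; h <- layout$height
  x <- layout$coords[, "x"]; y <- layout$coords[, "y"]
  id <- seq_len(layout$n)
  right <- x < w
  up <- y < h
  edges <- rbind(cbind(id[right], id[right] + 1L),
                 cbind(id[up], id[up] + w))
  new_topology("nn4", layout$n, edges, layout = layout)
}

#' @rdname topology_all_to_all
#' @export
topology_nn8 <- function(layout) {
  stopifnot(inherits(layout, "oscomm_layout"))
  w <- layout$width; h <- layout$height
  x <- layout$coords[, "x"]; y <- layout$coords[, "y"]
  id <- seq_len(layout$n)
  nn4 <- topology_nn4(layout)
  ne <- x < w & y < h  # diagonal up-right
  nw <- x > 1L & y < h # diagonal up-left
  edges <- rbind(nn4$edges,
                 cbind(id[ne], id[ne] + w + 1L),
                 cbind(id[nw], id[nw] + w - 1L))
  new_topology("nn8", layout$n, edges, layout = layout)
}

# edge probability for squared grid distance d2 at density gamma
prob_spatial_edge_prob <- function(d2, gamma) 1 / (d2 + gamma)

#' @rdname topology_all_to_all
#' @export
topology_prob_spatial <- function(layout, gamma) {
  stopifnot(inherits(layout, "oscomm_layout"))
  if (!is.finite(gamma) || gamma < 0) stop("`gamma` must be non-negative")
  n <- layout$n
  if (n < 2L) stop("need at least 2 nodes")
  d2 <- stats::dist(layout$coords)^2
  p <- prob_spatial_edge_prob(as.numeric(d2), gamma)
  # dist() enumerates pairs (i, j), i > j, ordered by j then i
  j <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  keep <- stats::runif(length(p)) < p
  new_topology("probabilistic_spatial", n, cbind(j[keep], i[keep]),
               layout = layout, gamma = gamma)
}

#' Assemble a topology from an explicit edge list
#'
#' Mainly for small custom graphs (cycles, paths, test fixtures) and for
#' re-importing exported topologies.
#'
#' @param n Node count.
#' @param edges Two-column matrix of 1-based endpoints (unordered pairs).
#' @param kind Label stored on the object.
#' @param layout Optional [grid_layout()].
#' @return An `oscomm_topology`.
#' @export
topology_from_edges <- function(n, edges, kind = "custom", layout = NULL) {
  new_topology(kind, n, edges, layout = layout)
}

#' Assign per-node communication costs
#'
#' Uniform mode gives every node the base cost. Degree-adjusted mode gives
#' node i the cost `base_cost * N(i) / mu`, where `N(i)` is its degree and
#' `mu` the mean degree, so that the mean cost over nodes equals `base_cost`
#' exactly and simulations remain comparable with the uniform-cost ones. On a
#' regular graph the two modes coincide.
#'
#' @param topology An `oscomm_topology`.
#' @param base_cost Non-negative base cost (default 10).
#' @param mode `"uniform"` or `"degree_adjusted"`.
#' @return The topology with `node_costs` set.
#' @export
assign_costs <- function(topology, base_cost = 10,
                         mode = c("uniform", "degree_adjusted")) {
  stopifnot(inherits(topology, "oscomm_topology"))
  mode <- match.arg(mode)
  if (!is.finite(base_cost) || base_cost < 0) stop("`base_cost` must be >= 0")
  if (mode == "uniform") {
    topology$node_costs <- rep(as.numeric(base_cost), topology$n)
  } else {
    mu <- mean(topology$degrees)
    if (mu == 0) stop("degree-adjusted costs undefined on an edgeless graph")
    topology$node_costs <- base_cost * topology$degrees / mu
  }
  topology$cost_mode <- mode
  topology$base_cost <- as.numeric(base_cost)
  topology
}

#' Convert a topology to an igraph object
#'
#' @param topology An `oscomm_topology`.
#' @return An undirected `igraph` graph with the same node indexing
#'   (isolated nodes preserved).
#' @export
as_igraph <- function(topology) {
  stopifnot(inherits(topology, "oscomm_topology"))
  g <- igraph::make_empty_graph(n = topology$n, directed = FALSE)
  if (nrow(topology$edges) > 0L) {
    g <- igraph::add_edges(g, t(topology$edges))
  }
  g
}

#' Network summary metrics
#'
#' `clustering_coefficient()` averages the local clustering coefficient
#' (triangles through a node over pairs of its neighbors) across nodes,
#' counting nodes of degree < 2 as 0. `average_path_length()` is the mean
#' shortest-path length over unordered distinct connected pairs; on a
#' disconnected graph it warns and computes over connected pairs only,
#' attaching `attr(., "connected") = FALSE`. `mean_degree()` is the average
#' node degree.
#'
#' @param topology An `oscomm_topology`.
#' @return A single numeric value.
#' @examples
#' clustering_coefficient(topology_nn4(grid_layout(5, 5))) # 0: no triangles
#' @export
clustering_coefficient <- function(topology) {
  local_cc <- igraph::transitivity(as_igraph(topology), type = "local",
                                   isolates = "zero")
  mean(local_cc)
}

#' @rdname clustering_coefficient
#' @export
average_path_length <- function(topology) {
  g <- as_igraph(topology)
  connected <- igraph::is_connected(g)
  if (!connected) {
    warning("graph is disconnected; path length computed over connected pairs")
  }
  apl <- igraph::mean_distance(g, unconnected = TRUE)
  structure(apl, connected = connected)
}

#' @rdname clustering_coefficient
#' @export
mean_degree <- function(topology) {
  stopifnot(inherits(topology, "oscomm_topology"))
  mean(topology$degrees)
}

#' Metrics of an ensemble of probabilistic spatial topologies
#'
#' Generates `instances` independent probabilistic spatial topologies on a
#' `width x height` grid and records each instance's mean degree, average
#' clustering coefficient and average path length.
#'
#' @param width,height Grid dimensions.
#' @param gamma Density parameter.
#' @param instances Number of independent instances.
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with one row per instance and columns `instance`,
#'   `mean_degree`, `clustering`, `path_length`, `connected`, `n_isolated`.
#' @export
prob_spatial_metrics <- function(width, height, gamma, instances = 100L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(instances), function(i) {
    topo <- topology_prob_spatial(grid_layout(width, height), gamma)
    apl <- suppressWarnings(average_path_length(topo))
    data.frame(instance = i,
               mean_degree = mean_degree(topo),
               clustering = clustering_coefficient(topo),
               path_length = as.numeric(apl),
               connected = attr(apl, "connected"),
               n_isolated = topo$n_isolated)
  })
  do.call(rbind, rows)
}

#' Export / import a topology as an edge list
#'
#' `write_edge_list()` writes one edge per line as two whitespace-separated
#' 1-based node indices, plus a JSON metadata sidecar (`<file>.json`) holding
#' kind, node count, grid dimensions and gamma. `read_edge_list()` restores
#' the topology from the pair of files. `write_adjacency_mtx()` writes the
#' adjacency as a MatrixMarket sparse listing.
#'
#' @param topology An `oscomm_topology`.
#' @param file Output path (edge list); metadata goes to `<file>.json`.
#' @return Invisibly, the file path; `read_edge_list()` returns the topology.
#' @export
write_edge_list <- function(topology, file) {
  stopifnot(inherits(topology, "oscomm_topology"))
  utils::write.table(topology$edges, file, row.names = FALSE,
                     col.names = FALSE)
  meta <- list(kind = topology$kind, n = topology$n,
               width = topology$layout$width, height = topology$layout$height,
               gamma = topology$gamma)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  edges <- if (file.size(file) > 0L) {
    as.matrix(utils::read.table(file, col.names = c("i", "j")))
  } else matrix(integer(0), ncol = 2L)
  layout <- if (!is.null(meta$width)) grid_layout(meta$width, meta$height)
  topo <- new_topology(meta$kind, meta$n, edges, layout = layout,
                       gamma = meta$gamma)
  topo
}

#' @rdname write_edge_list
#' @export
write_adjacency_mtx <- function(topology, file) {
  stopifnot(inherits(topology, "oscomm_topology"))
  m <- Matrix::sparseMatrix(i = c(topology$edges[, 1], topology$edges[, 2]),
                            j = c(topology$edges[, 2], topology$edges[, 1]),
                            x = 1, dims = c(topology$n, topology$n))
  Matrix::writeMM(m, file)
  invisible(file)
}
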