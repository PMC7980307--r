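## Circuit-theory connectivity: the resistance raster is treated as a
## resistor network. Edge conductance between adjacent cells a, b is
## 1/mean(r_a, r_b); diagonal neighbours (8-connectivity) have their
## conductance divided by sqrt(2) to account for the longer step
## (average-resistance convention of raster circuit solvers).

# Build the sparse graph for a resistance surface.
# Returns list(L = Laplacian (dgCMatrix), cells = data.frame(row, col, id),
# index = matrix mapping (row,col) -> node id or NA, edges = data.frame).
resistance_graph <- function(resist, connectivity = 8) {
  stopifnot(inherits(resist, "raster_grid"), connectivity %in% c(4, 8))
  v <- resist$values
  if (any(v <= 0, na.rm = TRUE)) stop("resistance costs must be positive")
  nr <- nrow(v); nc <- ncol(v)
  index <- matrix(NA_integer_, nr, nc)
  keep <- which(!is.na(v))
  index[keep] <- seq_along(keep)
  nnode <- length(keep)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- to <- integer(0); cond <- numeric(0)
  rc <- arrayInd(keep, c(nr, nc))
  for (o in offs) {
    r2 <- rc[, 1] + o[1]; c2 <- rc[, 2] + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    i2 <- rep(NA_integer_, nnode)
    i2[ok] <- index[cbind(r2[ok], c2[ok])]
    ok <- ok & !is.na(i2)
    if (!any(ok)) next
    g <- 1 / ((v[keep[ok]] + v[cbind(r2[ok], c2[ok])]) / 2)
    if (sum(abs(o)) == 2L) g <- g / sqrt(2)
    from <- c(from, index[keep[ok]]); to <- c(to, i2[ok]); cond <- c(cond, g)
  }
  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                            x = c(cond, cond), dims = c(nnode, nnode))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  list(L = L, index = index, cells = keep,
       edges = data.frame(from = from, to = to, cond = cond))
}

node_ids <- function(graph, nodes, resist) {
  ids <- graph$index[cbind(nodes$row, nodes$col)]
  if (anyNA(ids)) {
    stop("nodes on nodata cells: ",
         paste(nodes$label[is.na(ids)], collapse = ", "))
  }
  ids
}

# connected component label per graph node
graph_components <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$L))))
  igraph::components(g)$membership
}

#' Circuit-theory resistance distances between population sites
#'
#' Effective resistance between node cells of the resistor network defined
#' by the resistance surface. Solved exactly by sparse Cholesky
#' factorization of the grounded graph Laplacian (one focal node grounded;
#' one linear solve per remaining focal node).
#'
#' @param resist resistance [raster_grid()] (positive costs, `NA` nodata).
#' @param nodes a [node_set()].
#' @param connectivity 4 or 8 (default 8, with diagonal conductance divided
#'   by sqrt(2)).
#' @return a [pairwise_matrix()] of effective resistances; pairs in
#'   different graph components get `Inf` and a warning.
#' @export
resistance_distances <- function(resist, nodes, connectivity = 8) {
  graph <- resistance_graph(resist, connectivity)
  ids <- node_ids(graph, nodes, resist)
  k <- length(ids)
  comp <- graph_components(graph)
  out <- matrix(0, k, k, dimnames = list(nodes$label, nodes$label))
  same <- outer(comp[ids], comp[ids], "==")
  if (!all(same)) warning("some node pairs are disconnected; Inf distances")
  ground <- ids[1]
  nnode <- nrow(graph$L)
  keep <- setdiff(seq_len(nnode), ground)
  Lr <- graph$L[keep, keep, drop = FALSE]
  # solve per focal node in the ground's component
  pos <- match(ids, keep)  # NA for the ground itself
  fac <- NULL
  sols <- vector("list", k)
  for (j in seq_len(k)) {
    if (is.na(pos[j]) || comp[ids[j]] != comp[ground]) next
    if (is.null(fac)) fac <- Matrix::Cholesky(Lr, LDL = FALSE, perm = TRUE)
    e <- numeric(nnode - 1L); e[pos[j]] <- 1
    sols[[j]] <- as.numeric(Matrix::solve(fac, e))
  }
  getv <- function(j, at) {
    # potential at node `at` (graph id) for unit injection at focal j,
    # ground at ids[1]; ground potential is 0
    if (at == ground) return(0)
    sols[[j]][match(at, keep)]
  }
  for (a in seq_len(k - 1)) {
    for (b in seq.int(a + 1, k)) {
      if (comp[ids[a]] != comp[ids[b]]) {
        out[a, b] <- out[b, a] <- Inf
        next
      }
      # both in ground's component by construction (ground = ids[1] only
      # guarantees its own component; recompute locally otherwise)
      if (comp[ids[a]] != comp[ground]) {
        out[a, b] <- out[b, a] <- resistance_pair_fallback(graph, ids[a], ids[b])
        next
      }
      va <- if (is.na(pos[a])) NULL else sols[[a]]
      ra <- if (is.null(va)) 0 else getv(a, ids[a])
      rb <- if (is.na(pos[b])) 0 else getv(b, ids[b])
      cross1 <- if (is.na(pos[a])) 0 else getv(a, ids[b])
      cross2 <- if (is.na(pos[b])) 0 else getv(b, ids[a])
      out[a, b] <- out[b, a] <- ra + rb - cross1 - cross2
    }
  }
  pairwise_matrix(out, "resistance")
}

# effective resistance for a pair outside the main ground's component
resistance_pair_fallback <- function(graph, i, j) {
  nnode <- nrow(graph$L)
  keep <- setdiff(seq_len(nnode), j)
  Lr <- graph$L[keep, keep, drop = FALSE]
  e <- numeric(nnode - 1L); e[match(i, keep)] <- 1
  x <- as.numeric(Matrix::solve(Lr, e))
  x[match(i, keep)]
}

#' Cumulative current-density map over focal-node pairs
#'
#' For each pair, a unit current is injected at one node and extracted at
#' the other; per-cell current is half the sum of absolute branch currents
#' incident to the cell (so focal cells carry current 1). Maps are summed
#' over the requested pairs.
#'
#' @param resist resistance [raster_grid()].
#' @param nodes a [node_set()].
#' @param pairs two-column matrix of node labels (default: all pairs).
#' @param connectivity 4 or 8.
#' @return a [raster_grid()] of summed current density (`NA` on nodata).
#' @export
current_density_map <- function(resist, nodes, pairs = NULL, connectivity = 8) {
  graph <- resistance_graph(resist, connectivity)
  ids <- node_ids(graph, nodes, resist)
  names(ids) <- nodes$label
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nodes$label, 2))
  }
  comp <- graph_components(graph)
  nnode <- nrow(graph$L)
  current <- numeric(nnode)
  for (k in seq_len(nrow(pairs))) {
    s <- ids[pairs[k, 1]]; t <- ids[pairs[k, 2]]
    if (comp[s] != comp[t]) {
      warning("skipping disconnected pair ", pairs[k, 1], "-", pairs[k, 2])
      next
    }
    keep <- setdiff(seq_len(nnode), t)  # ground the sink
    Lr <- graph$L[keep, keep, drop = FALSE]
    e <- numeric(nnode - 1L); e[match(s, keep)] <- 1
    vred <- as.numeric(Matrix::solve(Lr, e))
    v <- numeric(nnode); v[keep] <- vred
    ib <- abs((v[graph$edges$from] - v[graph$edges$to]) * graph$edges$cond)
    nodecur <- numeric(nnode)
    agg <- rowsum(c(ib, ib), c(graph$edges$from, graph$edges$to))
    nodecur[as.integer(rownames(agg))] <- agg[, 1] / 2
    # focal cells carry the full unit current (half the incident branch
    # current plus the injected/extracted half)
    nodecur[c(s, t)] <- nodecur[c(s, t)] + 0.5
    current <- current + nodecur
  }
  out <- matrix(NA_real_, resist$nrows, resist$ncols)
  out[graph$cells] <- current
  raster_grid(out, resist$cellsize, resist$xllcorner, resist$yllcorner,
              resist$nodata)
}
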