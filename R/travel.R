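# Least-cost travel time over a friction surface.
#
# Moving between adjacent cells i -> j costs d(i, j) metres times a
# combination of the two cells' friction values (min/m); the default
# combination is the arithmetic mean, a common cost-distance convention.
# d is the cell size for orthogonal moves and cell size * sqrt(2) for
# diagonal ones; an optional 16-connected neighbourhood adds knight's
# moves. nodata friction cells are impassable; cells cut off from every
# facility get +Inf.

.neighbour_offsets <- function(connectivity) {
  o8 <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
              c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  if (connectivity == 8L) return(o8)
  rbind(o8, c(-2, -1), c(-2, 1), c(-1, -2), c(-1, 2),
        c(1, -2), c(1, 2), c(2, -1), c(2, 1))
}

.combine_friction <- function(fi, fj, rule) {
  switch(rule,
    mean = (fi + fj) / 2,
    min = pmin(fi, fj),
    max = pmax(fi, fj),
    stop("unknown edge_cost rule: ", rule))
}

# Directed edge list over the passable cells of a friction grid:
# data.frame(from, to, w) with cell indices in column-major order.
.friction_edges <- function(friction, connectivity, edge_cost) {
  v <- friction$values
  nr <- nrow(v); nc <- ncol(v)
  off <- .neighbour_offsets(connectivity)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  rows <- rep.int(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  for (k in seq_len(nrow(off))) {
    r2 <- rows + off[k, 1]; c2 <- cols + off[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    i <- (cols[ok] - 1L) * nr + rows[ok]
    j <- (c2[ok] - 1L) * nr + r2[ok]
    fi <- v[i]; fj <- v[j]
    pass <- !is.na(fi) & !is.na(fj)
    i <- i[pass]; j <- j[pass]
    dist_m <- sqrt((off[k, 1] * friction$yres)^2 + (off[k, 2] * friction$xres)^2)
    from <- c(from, i); to <- c(to, j)
    w <- c(w, dist_m * .combine_friction(v[i], v[j], edge_cost))
  }
  data.frame(from = from, to = to, w = w)
}

.facility_cells <- function(friction, facilities) {
  if (is.null(facilities$row) || is.null(facilities$col))
    facilities <- snap_facilities(facilities, friction)
  idx <- (facilities$col - 1L) * nrow(friction$values) + facilities$row
  if (any(is.na(friction$values[idx])))
    stop("facility on an impassable (nodata) friction cell: ",
         paste(facilities$name[is.na(friction$values[idx])], collapse = ", "))
  idx
}

#' Least-cost travel time to the nearest facility
#'
#' Computes t(x), the minutes needed to reach the closest emergency
#' facility from every cell, as a multi-source shortest path over the
#' friction raster (Dijkstra, via igraph). All facility cells are sources
#' at time 0; every other cell gets the minimum over facilities.
#'
#' @param friction A [raster_grid()] with units `"min/m"`; `NA` cells are
#'   impassable.
#' @param facilities A [facility_set()]; snapped to cell centres if no
#'   `row`/`col` columns are present.
#' @param connectivity 8 (default) or 16 (adds knight's moves).
#' @param edge_cost How the two endpoint frictions combine: `"mean"`
#'   (default), `"min"` or `"max"`.
#' @param quiet Suppress the unreachable-cell count message.
#' @return A [raster_grid()] with units `"minutes"`; unreachable cells are
#'   `+Inf`, nodata cells `NA`.
#' @examples
#' fx <- tiny_fixture()
#' tt <- least_cost_travel_time(fx$friction, fx$facilities)
#' as.matrix(tt)[3, 4]  # orthogonal neighbour: 20 minutes
#' @export
least_cost_travel_time <- function(friction, facilities,
                                   connectivity = 8L,
                                   edge_cost = c("mean", "min", "max"),
                                   quiet = FALSE) {
  stopifnot(inherits(friction, "raster_grid"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(8L, 16L)) stop("connectivity must be 8 or 16")
  edge_cost <- match.arg(edge_cost)
  if (is.null(facilities) || nrow(facilities) == 0)
    stop("empty facility set")
  src <- .facility_cells(friction, facilities)

  n <- length(friction$values)
  edges <- .friction_edges(friction, connectivity, edge_cost)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  # undirected graph: each unordered pair appears twice in the directed
  # edge list with equal weight; keep one copy
  keep <- edges$from < edges$to
  g <- igraph::add_edges(g, rbind(edges$from[keep], edges$to[keep]))
  igraph::E(g)$weight <- edges$w[keep]
  d <- igraph::distances(g, v = src, algorithm = "dijkstra")
  tmin <- apply(d, 2, min)

  out <- matrix(tmin, nrow(friction$values), ncol(friction$values))
  out[is.na(friction$values)] <- NA_real_
  n_unreach <- sum(is.infinite(out), na.rm = TRUE)
  if (!quiet && n_unreach > 0)
    message(n_unreach, " cells are unreachable from every facility")
  raster_grid(out, xmin = friction$xmin, ymax = friction$ymax,
              xres = friction$xres, yres = friction$yres, units = "minutes")
}

#' Exhaustive shortest-path oracle for tiny grids
#'
#' Independent reference implementation of [least_cost_travel_time()]:
#' plain Bellman-Ford relaxation over the full directed edge list, no
#' graph library. Exact on any grid but quadratic in cell count, so it
#' refuses grids larger than 5x5; intended for verification only.
#'
#' @inheritParams least_cost_travel_time
#' @return A [raster_grid()] with units `"minutes"`.
#' @export
brute_force_travel_time <- function(friction, facilities,
                                    connectivity = 8L,
                                    edge_cost = c("mean", "min", "max")) {
  stopifnot(inherits(friction, "raster_grid"))
  edge_cost <- match.arg(edge_cost)
  nr <- nrow(friction$values); nc <- ncol(friction$values)
  if (nr > 5 || nc > 5)
    stop("brute_force_travel_time is a test oracle: grids larger than 5x5 are refused")
  src <- .facility_cells(friction, facilities)
  edges <- .friction_edges(friction, as.integer(connectivity), edge_cost)

  dist <- rep(Inf, nr * nc)
  dist[src] <- 0
  for (pass in seq_len(nr * nc)) {
    relaxed <- dist[edges$from] + edges$w
    upd <- relaxed < dist[edges$to]
    if (!any(upd)) break
    # process updates one by one so repeated targets keep the minimum
    for (e in which(upd)) {
      if (relaxed[e] < dist[edges$to[e]]) dist[edges$to[e]] <- relaxed[e]
    }
  }
  out <- matrix(dist, nr, nc)
  out[is.na(friction$values)] <- NA_real_
  raster_grid(out, xmin = friction$xmin, ymax = friction$ymax,
              xres = friction$xres, yres = friction$yres, units = "minutes")
}
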