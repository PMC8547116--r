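# Geographic, resistance and wind-connectivity distance matrices.
#
# All great-circle distances use a sphere of authalic radius 6371008.8 m;
# at the ~600 km scale of a coastal strip the spherical-vs-ellipsoidal
# error is far below the raster discretization error.

EARTH_RADIUS_M <- 6371008.8

gc_dist <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

#' Project population coordinates to transverse-Mercator meters
#'
#' Spherical transverse-Mercator forward projection in the UTM zone 22S
#' convention: central meridian -51 deg, scale factor 0.9996, false easting
#' 500 km, false northing 10,000 km (southern hemisphere). A point on the
#' central meridian at the equator maps to (500000, 10000000).
#'
#' @param m a [population_map] with coordinates, or a data frame with
#'   columns `pop`, `lon`, `lat`.
#' @param lon0 central meridian in degrees (default -51).
#' @return data frame of class `projected_coords` with columns `pop`, `x`,
#'   `y` in meters; warns when points lie more than 12 deg from the central
#'   meridian (projection distortion).
#' @export
project_coordinates <- function(m, lon0 = -51) {
  coords <- if (inherits(m, "population_map")) {
    if (is.null(m$coords)) stop("population map carries no coordinates")
    m$coords
  } else as.data.frame(m)
  k0 <- 0.9996; fe <- 5e5; fn <- 1e7
  if (any(abs(coords$lon - lon0) > 12))
    warning("coordinates more than 12 deg from the central meridian; ",
            "projection distortion will be large")
  lam <- (coords$lon - lon0) * pi / 180
  phi <- coords$lat * pi / 180
  B <- cos(phi) * sin(lam)
  x <- fe + k0 * EARTH_RADIUS_M * atanh(B)
  y <- fn + k0 * EARTH_RADIUS_M * atan2(tan(phi), cos(lam))
  out <- data.frame(pop = coords$pop, x = x, y = y)
  class(out) <- c("projected_coords", "data.frame")
  out
}

#' Inverse transverse-Mercator projection
#'
#' @param pc a `projected_coords` data frame from [project_coordinates()].
#' @param lon0 central meridian used for the forward projection.
#' @return data frame with columns `pop`, `lon`, `lat` in degrees.
#' @export
unproject_coordinates <- function(pc, lon0 = -51) {
  k0 <- 0.9996; fe <- 5e5; fn <- 1e7
  xp <- (pc$x - fe) / (k0 * EARTH_RADIUS_M)
  D <- (pc$y - fn) / (k0 * EARTH_RADIUS_M)
  phi <- asin(sin(D) / cosh(xp))
  lam <- atan2(sinh(xp), cos(D))
  data.frame(pop = pc$pop, lon = lon0 + lam * 180 / pi,
             lat = phi * 180 / pi)
}

#' Euclidean distance matrix between projected populations
#'
#' @param pc a `projected_coords` data frame.
#' @return symmetric [pairwise_matrix] of straight-line distances in meters.
#' @export
euclidean_distance_matrix <- function(pc) {
  if (nrow(pc) < 2L) stop("need at least 2 populations")
  d <- as.matrix(stats::dist(cbind(pc$x, pc$y)))
  pairwise_matrix(d, pc$pop, symmetric = TRUE)
}

#' Build a resistance raster from a land/water mask
#'
#' Two isolation-by-resistance models over a land/water mask (1 = land,
#' 0 = water): the *continuous* (null) model sets every cell, water
#' included, to conductance 1, so least-cost distances approximate
#' straight-line distances; the *water_bodies* model keeps land at 1 and
#' turns water cells into nodata, i.e. complete barriers.
#'
#' @param model `"continuous"` or `"water_bodies"`.
#' @param land_mask [raster_grid] with cells in `{0, 1}` (`NA` allowed and
#'   preserved as nodata).
#' @return a conductance [raster_grid].
#' @export
build_resistance_raster <- function(model = c("continuous", "water_bodies"),
                                    land_mask) {
  model <- match.arg(model)
  v <- land_mask$values
  if (!all(v %in% c(0, 1) | is.na(v)))
    stop("land_mask cells must be 0 (water) or 1 (land)")
  out <- v
  if (model == "continuous") {
    out[] <- 1
    out[is.na(v)] <- NA_real_
  } else {
    out[v == 0] <- NA_real_
  }
  raster_grid(out, land_mask$x_llcorner, land_mask$y_llcorner,
              land_mask$cell_size, land_mask$nodata_value)
}

# Map populations to raster cells, refusing (or optionally snapping away
# from) nodata cells.
node_cells <- function(r, nodes, snap = FALSE) {
  rc <- cell_of(r, nodes$lon, nodes$lat)
  vals <- r$values[rc]
  if (any(is.na(vals))) {
    bad <- which(is.na(vals))
    if (!snap)
      stop("population(s) fall on nodata cells: ",
           paste(nodes$pop[bad], collapse = ", "),
           " (use snap = TRUE to assign the nearest valid cell)")
    valid <- which(!is.na(r$values), arr.ind = TRUE)
    for (b in bad) {
      ctr <- cell_center(r, valid[, 1], valid[, 2])
      d <- gc_dist(nodes$lon[b], nodes$lat[b], ctr[, "lon"], ctr[, "lat"])
      k <- which.min(d)
      message("snapped ", nodes$pop[b], " to nearest valid cell, offset ",
              round(d[k] / 1000, 2), " km")
      rc[b, ] <- valid[k, ]
    }
  }
  rc
}

# 8-neighbour edge list over non-nodata cells of a raster.
# Returns from/to cell linear indices (column-major, as in R matrices),
# the great-circle centre-to-centre length of each edge, and the cell
# values at both ends. `directed = TRUE` emits both orientations.
neighbor_edges <- function(r, directed = FALSE) {
  nr <- r$n_rows; nc <- r$n_cols
  valid <- !is.na(r$values)
  off <- rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  if (directed) off <- rbind(off, -off)
  from_i <- integer(); from_j <- integer()
  to_i <- integer(); to_j <- integer()
  idx <- which(valid, arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    ti <- idx[, 1] + off[k, 1]; tj <- idx[, 2] + off[k, 2]
    keep <- ti >= 1L & ti <= nr & tj >= 1L & tj <= nc
    keep[keep] <- valid[cbind(ti[keep], tj[keep])]
    from_i <- c(from_i, idx[keep, 1]); from_j <- c(from_j, idx[keep, 2])
    to_i <- c(to_i, ti[keep]); to_j <- c(to_j, tj[keep])
  }
  pf <- cell_center(r, from_i, from_j)
  pt <- cell_center(r, to_i, to_j)
  data.frame(from = (from_j - 1L) * nr + from_i,
             to = (to_j - 1L) * nr + to_i,
             from_row = from_i, from_col = from_j,
             to_row = to_i, to_col = to_j,
             length = gc_dist(pf[, "lon"], pf[, "lat"],
                              pt[, "lon"], pt[, "lat"]))
}

#' Least-cost distance matrix over a conductance raster
#'
#' Builds the 8-neighbour graph over non-nodata cells, weighting each edge
#' by the great-circle distance between the two cell centres divided by the
#' mean conductance of the two cells, and returns the matrix of shortest-
#' path (Dijkstra) costs between the population cells. With a uniform
#' conductance of 1 the result approximates straight-line distance up to
#' the 8-neighbour discretization error.
#'
#' @param r conductance [raster_grid] (values > 0; `NA` = barrier).
#' @param nodes data frame with columns `pop`, `lon`, `lat`.
#' @param snap if `TRUE`, populations on nodata cells are moved to the
#'   nearest valid cell (logged); if `FALSE` (default) they raise an error.
#' @return symmetric [pairwise_matrix] of least-cost distances
#'   (meter-equivalents); pairs with no connecting path are `Inf` with a
#'   warning.
#' @export
least_cost_matrix <- function(r, nodes, snap = FALSE) {
  if (any(r$values <= 0, na.rm = TRUE))
    stop("conductance values must be strictly positive (use NA for barriers)")
  rc <- node_cells(r, nodes, snap)
  ed <- neighbor_edges(r, directed = FALSE)
  cond <- (r$values[cbind(ed$from_row, ed$from_col)] +
           r$values[cbind(ed$to_row, ed$to_col)]) / 2
  gr <- igraph::make_empty_graph(n = r$n_rows * r$n_cols, directed = FALSE)
  gr <- igraph::add_edges(gr, rbind(ed$from, ed$to))
  igraph::E(gr)$weight <- ed$length / cond
  cells <- (rc[, "col"] - 1L) * r$n_rows + rc[, "row"]
  d <- igraph::distances(gr, v = cells, to = cells,
                         algorithm = "dijkstra")
  dimnames(d) <- list(nodes$pop, nodes$pop)
  if (any(is.infinite(d)))
    warning("no connecting path for some population pairs; Inf returned")
  d <- (d + t(d)) / 2                     # exact symmetry despite fp order
  diag(d) <- 0
  pairwise_matrix(d, nodes$pop, symmetric = TRUE)
}

#' Wind field
#'
#' A time series of (speed, direction) raster pairs on a common grid.
#' Directions follow the meteorological convention: degrees clockwise from
#' north of the bearing the wind blows FROM.
#'
#' @param slices list of `list(speed = raster_grid, direction =
#'   raster_grid)` pairs.
#' @return object of class `wind_field`.
#' @export
wind_field <- function(slices) {
  if (!length(slices)) stop("need at least one wind slice")
  geo <- function(r) c(r$n_rows, r$n_cols, r$x_llcorner, r$y_llcorner,
                       r$cell_size)
  ref <- geo(slices[[1]]$speed)
  for (s in slices) {
    if (!isTRUE(all.equal(geo(s$speed), ref)) ||
        !isTRUE(all.equal(geo(s$direction), ref)))
      stop("all wind slices must share the same grid geometry")
    if (any(s$speed$values < 0, na.rm = TRUE))
      stop("wind speeds must be >= 0")
    if (any(s$direction$values < 0 | s$direction$values >= 360, na.rm = TRUE))
      stop("wind directions must lie in [0, 360)")
  }
  structure(list(slices = slices), class = "wind_field")
}

#' @export
print.wind_field <- function(x, ...) {
  r <- x$slices[[1]]$speed
  cat(sprintf("wind_field: %d time slices on a %d x %d grid\n",
              length(x$slices), r$n_rows, r$n_cols))
  invisible(x)
}

#' Directed wind-conductance edge list for one time slice
#'
#' For each ordered 8-neighbour cell pair i -> j the conductance is the
#' component of the wind vector at i along the i -> j bearing,
#' `g = max(eps, s_i * cos(theta - phi))`, where `theta` is the bearing the
#' wind blows TOWARD (meteorological direction + 180 deg) and `phi` the
#' i -> j bearing; tailwinds facilitate movement, head- and crosswinds are
#' floored at `eps`. Edge cost is centre-to-centre distance divided by
#' conductance.
#'
#' @param slice one element of a [wind_field()]'s `slices`.
#' @param eps conductance floor in m/s (default 1e-4).
#' @return data frame of directed edges with columns `from`, `to` (cell
#'   linear indices), `length` (m), `conductance` (m/s), `cost`.
#' @export
wind_conductance_graph <- function(slice, eps = 1e-4) {
  sp <- slice$speed; dr <- slice$direction
  ed <- neighbor_edges(sp, directed = TRUE)
  pf <- cell_center(sp, ed$from_row, ed$from_col)
  pt <- cell_center(sp, ed$to_row, ed$to_col)
  phi <- geosphere::bearing(pf, pt)                  # degrees from north
  theta <- dr$values[cbind(ed$from_row, ed$from_col)] + 180
  s <- sp$values[cbind(ed$from_row, ed$from_col)]
  g <- pmax(eps, s * cos((theta - phi) * pi / 180))
  ed$conductance <- g
  ed$cost <- ed$length / g
  ed
}

#' Wind-connectivity cost matrices
#'
#' Per time slice, least-cost distances between population cells over the
#' directed wind-conductance graph of [wind_conductance_graph()]; the slice
#' matrices are then arithmetically averaged over the whole time series.
#' Because tailwind and headwind differ, the average is asymmetric; a
#' symmetrized version `(M + t(M)) / 2` is returned for Mantel/MMRR use.
#'
#' @param w a [wind_field()].
#' @param nodes data frame with `pop`, `lon`, `lat`.
#' @param eps conductance floor (m/s).
#' @param snap snap populations on nodata cells to the nearest valid cell.
#' @return list with `asymmetric` and `symmetric` [pairwise_matrix] objects
#'   and `n_slices`. Pairs disconnected in some slice contribute `Inf` to
#'   the average (flagged by warning).
#' @export
wind_cost_matrix <- function(w, nodes, eps = 1e-4, snap = FALSE) {
  ref <- w$slices[[1]]$speed
  rc <- node_cells(ref, nodes, snap)
  cells <- (rc[, "col"] - 1L) * ref$n_rows + rc[, "row"]
  acc <- matrix(0, nrow(nodes), nrow(nodes))
  for (s in w$slices) {
    ed <- wind_conductance_graph(s, eps)
    gr <- igraph::make_empty_graph(n = ref$n_rows * ref$n_cols,
                                   directed = TRUE)
    gr <- igraph::add_edges(gr, rbind(ed$from, ed$to))
    igraph::E(gr)$weight <- ed$cost
    d <- igraph::distances(gr, v = cells, to = cells, mode = "out",
                           algorithm = "dijkstra")
    acc <- acc + d
  }
  avg <- acc / length(w$slices)
  diag(avg) <- 0
  if (any(is.infinite(avg)))
    warning("disconnected population pair(s) in at least one wind slice")
  dimnames(avg) <- list(nodes$pop, nodes$pop)
  sym <- (avg + t(avg)) / 2
  list(asymmetric = pairwise_matrix(avg, nodes$pop, symmetric = FALSE),
       symmetric = pairwise_matrix(sym, nodes$pop, symmetric = TRUE),
       n_slices = length(w$slices))
}
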