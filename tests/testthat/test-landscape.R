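test_that("transverse-Mercator projection matches its defining constants", {
  pc <- project_coordinates(data.frame(pop = "o", lon = -51, lat = 0))
  expect_equal(pc$x, 5e5)
  expect_equal(pc$y, 1e7)
  # forward-then-inverse is the identity
  tab <- study_populations()
  pc2 <- project_coordinates(tab[, c("pop", "lon", "lat")])
  back <- unproject_coordinates(pc2)
  expect_equal(back$lon, tab$lon, tolerance = 1e-6)
  expect_equal(back$lat, tab$lat, tolerance = 1e-6)
  expect_warning(project_coordinates(data.frame(pop = "far", lon = -70,
                                                lat = 0)), "distortion")
})

test_that("projected distances agree with the great-circle oracle", {
  tab <- study_populations()
  pc <- project_coordinates(tab[, c("pop", "lon", "lat")])
  D <- euclidean_distance_matrix(pc)
  hav <- geosphere::distHaversine(tab[tab$pop == "N2", c("lon", "lat")],
                                  tab[tab$pop == "S6", c("lon", "lat")],
                                  r = 6371008.8)
  expect_lt(abs(D["N2", "S6"] - hav) / hav, 0.005)
})

test_that("Euclidean distance matrix is a translation-invariant metric", {
  pc <- data.frame(pop = c("a", "b", "c"), x = c(0, 3, 0), y = c(0, 0, 4))
  class(pc) <- c("projected_coords", "data.frame")
  D <- euclidean_distance_matrix(pc)
  expect_equal(D["a", "b"], 3); expect_equal(D["a", "c"], 4)
  expect_equal(D["b", "c"], 5)
  pc2 <- pc; pc2$x <- pc2$x + 1e5; pc2$y <- pc2$y - 2e4
  expect_equal(unclass(euclidean_distance_matrix(pc2)), unclass(D))
  coincident <- pc; coincident$x[2] <- 0; coincident$y[2] <- 0
  expect_equal(euclidean_distance_matrix(coincident)["a", "b"], 0)
})

test_that("resistance rasters implement the two landscape models", {
  mask <- raster_grid(matrix(c(1, 0, 1, 1), 2, 2), -52, -31, 0.09)
  cont <- build_resistance_raster("continuous", mask)
  expect_true(all(cont$values == 1))
  wb <- build_resistance_raster("water_bodies", mask)
  expect_equal(sum(is.na(wb$values)), sum(mask$values == 0))
  expect_error(build_resistance_raster("continuous",
               raster_grid(matrix(2, 1, 1), 0, 0, 1)), "0 .water. or 1")
})

test_that("uniform-raster least cost equals cells-times-spacing along a row", {
  r <- raster_grid(matrix(1, 3, 8), -52, -31, 0.09)
  # nodes at the centres of cells (2,2) and (2,7): 5 cells apart
  ctr <- landgen:::cell_center(r, c(2, 2), c(2, 7))
  nodes <- data.frame(pop = c("a", "b"), lon = ctr[, "lon"],
                      lat = ctr[, "lat"])
  lc <- least_cost_matrix(r, nodes)
  step <- geosphere::distHaversine(ctr[1, ], landgen:::cell_center(r, 2, 3),
                                   r = 6371008.8)
  expect_equal(lc["a", "b"], 5 * step, tolerance = 1e-3)
})

test_that("least-cost distances equal exhaustive path enumeration", {
  set.seed(71)
  # 3x3 with a nodata centre plus random-conductance 4x4 grids
  v <- matrix(1, 3, 3); v[2, 2] <- NA
  grids <- list(raster_grid(v, -52, -31, 0.09))
  for (i in 1:3) {
    vv <- matrix(stats::runif(16, 0.2, 3), 4, 4)
    if (i == 2) vv[2, 3] <- NA
    grids[[i + 1]] <- raster_grid(vv, -52 + i, -31, 0.09)
  }
  for (r in grids) {
    nr <- r$n_rows
    corners <- c(1L, (r$n_cols - 1L) * nr + nr)   # NW and SE corner cells
    ctr <- rbind(landgen:::cell_center(r, 1, 1),
                 landgen:::cell_center(r, nr, r$n_cols))
    nodes <- data.frame(pop = c("a", "b"), lon = ctr[, "lon"],
                        lat = ctr[, "lat"])
    lc <- least_cost_matrix(r, nodes)
    oracle <- brute_force_cost(r, corners[1], corners[2])
    expect_equal(lc["a", "b"], oracle, tolerance = 1e-9)
  }
})

test_that("water-bodies costs dominate continuous costs; islands give Inf", {
  s <- scenario("stepping_stone", n_pops = 6, sizes = 5, seed = 77)
  land <- simulate_landscape(s)
  cont <- least_cost_matrix(build_resistance_raster("continuous",
                                                    land$land_mask),
                            land$nodes)
  wb <- least_cost_matrix(build_resistance_raster("water_bodies",
                                                  land$land_mask),
                          land$nodes)
  expect_true(all(wb >= cont - 1e-6))
  # population on a nodata cell errors unless snapped
  v <- matrix(1, 3, 3); v[1, 1] <- NA
  r <- raster_grid(v, -52, -31, 0.09)
  ctr <- landgen:::cell_center(r, c(1, 3), c(1, 3))
  nodes <- data.frame(pop = c("bad", "ok"), lon = ctr[, "lon"],
                      lat = ctr[, "lat"])
  expect_error(least_cost_matrix(r, nodes), "nodata cells: bad")
  expect_message(lc <- least_cost_matrix(r, nodes, snap = TRUE), "snapped")
  expect_true(is.finite(lc["bad", "ok"]))
})

test_that("wind conductance follows the tailwind cosine rule", {
  # grid centred on the equator so E-W bearings are exactly 90/270
  sp <- raster_grid(matrix(5, 1, 2), -52, -0.045, 0.09)
  mk_dir <- function(d) raster_grid(matrix(d, 1, 2), -52, -0.045, 0.09)
  # wind FROM the east (90): flow bearing 270 = toward the west neighbour;
  # the eastward edge (bearing 90) is pure headwind
  ed <- wind_conductance_graph(list(speed = sp, direction = mk_dir(90)))
  west <- ed[ed$from_col == 2 & ed$to_col == 1, ]
  east <- ed[ed$from_col == 1 & ed$to_col == 2, ]
  expect_equal(west$conductance, 5, tolerance = 1e-6)
  expect_equal(east$conductance, 1e-4)
  # wind FROM the north (0): flow toward south, perpendicular to the row
  ed2 <- wind_conductance_graph(list(speed = sp, direction = mk_dir(0)))
  expect_equal(max(ed2$conductance), 1e-4)
})

test_that("reversing the wind transposes the cost matrix", {
  r0 <- raster_grid(matrix(4, 4, 4), -52, -31, 0.09)
  mkw <- function(d) wind_field(list(list(
    speed = r0, direction = raster_grid(matrix(d, 4, 4), -52, -31, 0.09))))
  ctr <- landgen:::cell_center(r0, c(2, 3), c(1, 4))
  nodes <- data.frame(pop = c("a", "b"), lon = ctr[, "lon"],
                      lat = ctr[, "lat"])
  c1 <- wind_cost_matrix(mkw(45), nodes)
  c2 <- wind_cost_matrix(mkw(225), nodes)
  expect_equal(unclass(c1$asymmetric), t(unclass(c2$asymmetric)),
               tolerance = 1e-5)
})

test_that("wind costs average over slices and fall with tailwind speed", {
  mkw <- function(speeds) {
    slices <- lapply(speeds, function(s) list(
      speed = raster_grid(matrix(s, 1, 3), -52, -31, 0.09),
      direction = raster_grid(matrix(90, 1, 3), -52, -31, 0.09)))
    wind_field(slices)
  }
  ctr <- landgen:::cell_center(raster_grid(matrix(1, 1, 3), -52, -31, 0.09),
                               c(1, 1), c(1, 3))
  nodes <- data.frame(pop = c("a", "b"), lon = ctr[, "lon"],
                      lat = ctr[, "lat"])
  two_same <- wind_cost_matrix(mkw(c(4, 4)), nodes)
  one <- wind_cost_matrix(mkw(4), nodes)
  expect_equal(unclass(two_same$asymmetric), unclass(one$asymmetric))
  faster <- wind_cost_matrix(mkw(8), nodes)
  # westward (downwind) cost shrinks as speed rises
  expect_lt(faster$asymmetric["b", "a"], one$asymmetric["b", "a"])
  # downwind much cheaper than upwind
  expect_lt(one$asymmetric["b", "a"], one$asymmetric["a", "b"])
})
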