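test_that("climate dissimilarity is the absolute-difference metric", {
  v <- c(P1 = 1, P2 = 3, P3 = 6)
  D <- climate_dissimilarity(v)
  expect_equal(D["P1", "P2"], 2)
  expect_equal(D["P2", "P3"], 3)
  expect_equal(D["P1", "P3"], 5)
  expect_equal(unclass(climate_dissimilarity(v + 10)), unclass(D))
  expect_true(all(climate_dissimilarity(c(a = 2, b = 2, c = 2)) == 0))
})

test_that("extract_climate reads population cells and errors off-grid", {
  r <- raster_grid(matrix(1:6, 2, 3), -52, -31, 0.5)
  ctr <- landgen:::cell_center(r, c(1, 2), c(1, 3))
  nodes <- data.frame(pop = c("a", "b"), lon = ctr[, "lon"],
                      lat = ctr[, "lat"])
  expect_equal(unname(extract_climate(r, nodes)), c(r$values[1, 1],
                                                    r$values[2, 3]))
  expect_error(extract_climate(r, data.frame(pop = "x", lon = 0, lat = 0)),
               "outside raster extent")
})

test_that("Mantel statistic and permutation p behave at the extremes", {
  set.seed(5)
  X <- random_distance_matrix(10)
  mt <- mantel_test(X, X, n_perm = 199, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p_value, 1 / 200)
  expect_error(mantel_test(X, pairwise_matrix(matrix(0, 10, 10),
                                              rownames(X)), n_perm = 99),
               "zero variance")
  small <- random_distance_matrix(3)
  expect_error(mantel_test(small, small), "at least 4")
})

test_that("Mantel agrees with the vegan implementation on the statistic", {
  skip_if_not_installed("vegan")
  set.seed(6)
  X <- random_distance_matrix(12)
  Y <- random_distance_matrix(12)
  mine <- mantel_test(X, Y, n_perm = 999, seed = 3)
  ref <- vegan::mantel(as.dist(unclass(X)), as.dist(unclass(Y)),
                       permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(mine$p_value - ref$signif), 0.05)
})

test_that("MMRR recovers exact and noisy linear structure", {
  set.seed(7)
  X <- random_distance_matrix(12)
  Y <- pairwise_matrix(2 * unclass(X), rownames(X))
  fit <- mmrr(Y, list(x = X), n_perm = 99, seed = 1)
  expect_equal(fit$coefficients$beta[2], 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # noisy recovery with an irrelevant predictor
  good <- 0L; null_ok <- 0L; n_rep <- 30L
  for (i in seq_len(n_rep)) {
    set.seed(100 + i)
    X1 <- random_distance_matrix(14)
    X2 <- random_distance_matrix(14)
    E <- matrix(stats::rnorm(14^2, 0, 0.02), 14); E <- E + t(E); diag(E) <- 0
    Yv <- 2 * unclass(X1) + E
    Yn <- pairwise_matrix(Yv, rownames(X1))
    f <- mmrr(Yn, list(x1 = X1, x2 = X2), n_perm = 199, seed = i)
    b1 <- f$coefficients$beta[2]
    good <- good + (abs(b1 - 2) / 2 < 0.1 &&
                      f$coefficients$p_value[2] <= 0.05)
    null_ok <- null_ok + (f$coefficients$p_value[3] > 0.05)
  }
  expect_equal(good, n_rep)
  expect_gte(null_ok / n_rep, 0.9)
})

test_that("single-predictor MMRR R^2 equals the squared Mantel r", {
  set.seed(8)
  X <- random_distance_matrix(11)
  Y <- random_distance_matrix(11)
  r <- mantel_test(X, Y, n_perm = 9, seed = 1)$r
  f <- mmrr(Y, list(x = X), n_perm = 9, seed = 1)
  expect_equal(f$r_squared, r^2, tolerance = 1e-10)
})

test_that("matrix tests are invariant to joint relabeling and p is never 0", {
  set.seed(9)
  X <- random_distance_matrix(9)
  Y <- random_distance_matrix(9)
  perm <- sample(9)
  relab <- function(M) pairwise_matrix(unclass(M)[perm, perm],
                                       rownames(M)[perm])
  m1 <- mantel_test(X, Y, n_perm = 199, seed = 4)
  m2 <- mantel_test(relab(X), relab(Y), n_perm = 199, seed = 4)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
  f1 <- mmrr(Y, list(x = X), n_perm = 199, seed = 4)
  f2 <- mmrr(relab(Y), list(x = relab(X)), n_perm = 199, seed = 4)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_gt(m1$p_value, 0)
  expect_gt(min(f1$coefficients$p_value), 0)
})

test_that("MMRR rejects collinear or ill-posed designs", {
  set.seed(10)
  X <- random_distance_matrix(8)
  expect_error(mmrr(X, list(a = X, b = X), n_perm = 9), "collinear")
  tiny <- random_distance_matrix(4)  # 6 pairs
  expect_error(mmrr(tiny, rep(list(random_distance_matrix(4)), 5),
                    n_perm = 9), "fewer population pairs")
})

test_that("the IBD/IBE suite emits one tidy row per fitted term", {
  s <- scenario("stepping_stone", n_pops = 8, sizes = 15, n_loci = 8,
                m = 0.05, seed = 91)
  d <- simulate_dataset(s)
  f <- pairwise_fst(d$genotypes, d$map)
  geo <- euclidean_distance_matrix(project_coordinates(d$map))
  cd <- climate_dissimilarity(extract_climate(d$climate, d$nodes))
  cont <- least_cost_matrix(build_resistance_raster("continuous",
                                                    d$land_mask), d$nodes)
  rep <- ibd_ibe_suite(f, geo, resist = list(continuous = cont),
                       clim = list(gradient = cd), wind = NULL,
                       n_perm = 99, seed = 5)
  expect_setequal(unique(rep$test),
                  c("mantel_ibd", "mmrr_resistance", "mmrr_climate"))
  expect_true(all(rep$n_perm == 99))
  expect_true(all(!is.na(rep$seed)))
  # pure-IBD data: geographic signal present
  expect_lt(rep$p_value[rep$test == "mantel_ibd"], 0.05)
})
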