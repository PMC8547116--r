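test_that("migration matrices are row-stochastic for every topology", {
  for (nm in c("panmixia", "island", "stepping_stone", "barrier",
               "environment_driven")) {
    s <- scenario(nm, n_pops = 6, sizes = 5, m = 0.1, seed = 3)
    B <- landgen:::migration_matrix(s)
    expect_equal(unname(rowSums(B)), rep(1, 6), tolerance = 1e-12)
    expect_true(all(B >= 0))
  }
  expect_error(scenario("island", n_pops = 4, sizes = 5, m = 1.2, seed = 1),
               "migration rate")
  expect_error(scenario("island", n_pops = 4, sizes = 0, seed = 1),
               "sizes")
  expect_error(scenario("island", n_pops = 4, sizes = 5), "seed")
})

test_that("the barrier scenario severs exactly one chain link", {
  s <- scenario("barrier", n_pops = 6, sizes = 5, m = 0.1, seed = 3)
  B <- landgen:::migration_matrix(s)
  off <- B; diag(off) <- 0
  # 5 chain links, one severed -> 8 nonzero directed entries
  expect_equal(sum(off > 0), 8L)
})

test_that("drift fixes alleles without migration and mixes with it", {
  s0 <- scenario("island", n_pops = 4, sizes = 5, n_loci = 6,
                 allele_range = c(2, 2), m = 0, N_e = 20,
                 generations = 400, seed = 17)
  sim <- simulate_allele_frequencies(s0)
  fixed <- vapply(sim$freqs, function(P) all(P %in% c(0, 1)), logical(1))
  expect_true(all(fixed))
  # strong migration between two demes keeps frequencies together
  s1 <- scenario("island", n_pops = 2, sizes = 5, n_loci = 10,
                 allele_range = c(4, 4), m = 0.5, N_e = 200,
                 generations = 200, seed = 18)
  sim1 <- simulate_allele_frequencies(s1)
  dmean <- mean(vapply(sim1$freqs,
                       function(P) mean(abs(P[1, ] - P[2, ])), numeric(1)))
  expect_lt(dmean, 0.05)
})

test_that("genotype sampling respects sizes, missingness, and the ladder", {
  s <- scenario("stepping_stone", n_pops = 5, sizes = c(3, 5, 7, 9, 11),
                n_loci = 6, missing_rate = 0, seed = 19)
  d <- sample_genotypes(simulate_allele_frequencies(s))
  expect_equal(length(d$genotypes$individual_ids), 35L)
  expect_true(all(d$genotypes$calls %% 2 == 0))  # 2-bp ladder from 100
  expect_equal(sum(d$genotypes$calls == 0), 0L)
  s2 <- scenario("stepping_stone", n_pops = 5, sizes = 20, n_loci = 6,
                 missing_rate = 0.2, seed = 19)
  d2 <- sample_genotypes(simulate_allele_frequencies(s2))
  miss <- mean(d2$genotypes$calls[, , 1] == 0)
  expect_gt(miss, 0.1); expect_lt(miss, 0.3)
  # within-deme sampling is Hardy-Weinberg: FIS near zero at large n
  s3 <- scenario("panmixia", n_pops = 1, sizes = 400, n_loci = 10,
                 seed = 20, generations = 30)
  d3 <- sample_genotypes(simulate_allele_frequencies(s3))
  fis <- fis_bootstrap(d3$genotypes, d3$map, n_boot = 100, seed = 1)
  expect_lt(abs(fis$fis[1]), 0.05)
})

test_that("study-shaped scenario reproduces the published sampling design", {
  s <- scenario("study_shaped", seed = 21)
  expect_equal(s$n_pops, 15L)
  expect_equal(sum(s$sizes), 253L)
  expect_true(all(s$allele_range == c(7L, 17L)))
  d <- sample_genotypes(simulate_allele_frequencies(s))
  expect_equal(length(d$genotypes$individual_ids), 253L)
  expect_equal(length(d$map$population_ids), 15L)
  expect_equal(d$map$coords$lon, study_populations()$lon)
})

test_that("landscapes carry a lagoon, wind slices, and a climate surface", {
  s <- scenario("stepping_stone", n_pops = 6, sizes = 5, seed = 23)
  land <- simulate_landscape(s)
  expect_gt(sum(land$land_mask$values == 0, na.rm = TRUE), 0)
  expect_equal(length(land$wind$slices), s$geometry$n_slices)
  # barrier scenario: water band severs the water_bodies raster
  sb <- scenario("barrier", n_pops = 6, sizes = 5, m = 0.1, seed = 23)
  lb <- simulate_landscape(sb)
  wb <- build_resistance_raster("water_bodies", lb$land_mask)
  lc <- suppressWarnings(least_cost_matrix(wb, lb$nodes))
  expect_true(any(is.infinite(lc)))
  cont <- least_cost_matrix(build_resistance_raster("continuous",
                                                    lb$land_mask), lb$nodes)
  expect_true(all(is.finite(cont)))
  # zero-noise climate gradient: dissimilarity proportional to lon gap
  clim <- extract_climate(land$climate, land$nodes)
  D <- climate_dissimilarity(clim)
  gap <- abs(outer(land$nodes$lon, land$nodes$lon, "-"))
  expect_equal(unclass(D) / max(D), gap / max(gap), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("identical seeds give byte-identical synthetic datasets", {
  d1 <- simulate_dataset(scenario("wind_biased", n_pops = 6, sizes = 8,
                                  seed = 27))
  d2 <- simulate_dataset(scenario("wind_biased", n_pops = 6, sizes = 8,
                                  seed = 27))
  expect_identical(d1$genotypes$calls, d2$genotypes$calls)
  expect_identical(d1$wind$slices[[3]]$speed$values,
                   d2$wind$slices[[3]]$speed$values)
  expect_identical(d1$climate$values, d2$climate$values)
})
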