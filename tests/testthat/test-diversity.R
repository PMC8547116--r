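test_that("allele frequencies normalize over non-missing gene copies", {
  fx <- make_genotypes(list(P = list(c(100, 100), c(100, 102))))
  af <- allele_frequencies(fx$g, fx$m)
  expect_equal(unname(af$loc01$freq["P", ]), c(0.75, 0.25))
  # all-missing entries are flagged NA, not errors
  fx2 <- make_genotypes(list(P = list(c(0, 0)), Q = list(c(100, 102))))
  af2 <- allele_frequencies(fx2$g, fx2$m)
  expect_true(all(is.na(af2$loc01$freq["P", ])))
  expect_equal(af2$loc01$n_genes[["P"]], 0)
  # frequencies sum to one wherever defined (random fixtures)
  hp <- hwe_population(40, 5, c(`100` = .2, `102` = .3, `104` = .5), seed = 4)
  af3 <- allele_frequencies(hp$g, hp$m)
  for (l in af3) expect_equal(unname(rowSums(l$freq)), 1, tolerance = 1e-12)
})

test_that("observed heterozygosity hits its 0/1 bounds", {
  hom <- make_genotypes(list(P = list(c(100, 100), c(102, 102))))
  expect_equal(observed_heterozygosity(hom$g, hom$m)$per_locus[1, 1], 0)
  het <- make_genotypes(list(P = list(c(100, 102), c(100, 102))))
  expect_equal(observed_heterozygosity(het$g, het$m)$per_locus[1, 1], 1)
})

test_that("unbiased He matches hand arithmetic and dominates 1 - sum(p^2)", {
  # 2 individuals, gene copies A,A,A,B: (1 - (9+1)/16) * 4/3 = 0.5
  fx <- make_genotypes(list(P = list(c(100, 100), c(100, 102))))
  expect_equal(expected_heterozygosity(fx$g, fx$m)$per_locus[1, 1], 0.5)
  mono <- make_genotypes(list(P = list(c(100, 100), c(100, 100))))
  expect_equal(expected_heterozygosity(mono$g, mono$m)$per_locus[1, 1], 0)
  # unbiased correction factor n/(n-1) >= 1
  hp <- hwe_population(25, 4, c(`100` = .3, `102` = .3, `104` = .4), seed = 9)
  he <- expected_heterozygosity(hp$g, hp$m)$per_locus
  af <- allele_frequencies(hp$g, hp$m)
  gd <- vapply(af, function(l) 1 - sum(l$freq[1, ]^2), numeric(1))
  expect_true(all(he[1, ] >= gd - 1e-12))
  # single gene copy -> undefined
  one <- make_genotypes(list(P = list(c(100, 100))))
  one$g$calls[1, 1, ] <- c(100L, 100L)
  expect_true(is.finite(expected_heterozygosity(one$g, one$m)$per_locus[1, 1]))
})

test_that("rarefied allelic richness matches enumeration and is monotone", {
  # counts {A:2, B:2}, g = 2: enumerate C(4,2)=6 subsamples -> mean 5/3
  fx <- make_genotypes(list(P = list(c(100, 102), c(100, 102))))
  expect_equal(rarefied_allelic_richness(fx$g, fx$m, 2)$per_locus[1, 1],
               5 / 3)
  expect_equal(rarefied_allelic_richness(fx$g, fx$m, 1)$per_locus[1, 1], 1)
  # g = n_genes recovers the raw allele count; monotone in g
  hp <- hwe_population(12, 3, c(`100` = .25, `102` = .25, `104` = .5),
                       seed = 3)
  ar_full <- rarefied_allelic_richness(hp$g, hp$m, 24)
  af <- allele_frequencies(hp$g, hp$m)
  k <- vapply(af, function(l) sum(l$freq[1, ] > 0), numeric(1))
  expect_equal(unname(ar_full$per_locus[1, ]), unname(k))
  prev <- rep(0, 3)
  for (gg in c(2, 6, 12, 24)) {
    cur <- rarefied_allelic_richness(hp$g, hp$m, gg)$per_locus[1, ]
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("private alleles are counted once for the owning population", {
  same <- make_genotypes(list(A = list(c(100, 102)), B = list(c(100, 102))))
  expect_equal(unname(private_alleles(same$g, same$m)), c(0L, 0L))
  fx <- make_genotypes(list(W1 = list(c(100, 104)), W2 = list(c(100, 102))))
  pa <- private_alleles(fx$g, fx$m)
  expect_equal(pa[["W1"]], 1L)   # 104 only in W1
  expect_equal(pa[["W2"]], 1L)   # 102 only in W2
  expect_true(sum(pa) <= 3)      # bounded by total distinct alleles
})

test_that("Garza-Williamson M uses repeat-scaled ranges", {
  ladder <- make_genotypes(list(P = list(c(20, 22), c(22, 24))))
  expect_equal(garza_williamson(ladder$g, ladder$m, 2)$per_locus[1, 1], 1)
  gap <- make_genotypes(list(P = list(c(20, 24), c(20, 24))))
  expect_equal(garza_williamson(gap$g, gap$m, 2)$per_locus[1, 1], 2 / 3)
  odd <- make_genotypes(list(P = list(c(21, 24))))
  expect_error(garza_williamson(odd$g, odd$m, 2), "repeat unit")
})

test_that("Weir-Cockerham FIS is near 0 under HWE and -1 for full excess", {
  hp <- hwe_population(500, 10, c(`100` = .5, `102` = .5), seed = 11)
  fis <- fis_bootstrap(hp$g, hp$m, n_boot = 300, seed = 2)
  expect_lt(abs(fis$fis[1]), 0.05)
  expect_true(fis$ci_low[1] <= 0 && fis$ci_high[1] >= 0)
  allhet <- make_genotypes(list(P = rep(list(c(100, 102)), 20)))
  allhet2 <- allhet
  fis2 <- fis_bootstrap(allhet$g, allhet$m, n_boot = 50, seed = 1)
  expect_lt(fis2$fis[1], -0.9)
  # single locus: point estimate only
  expect_true(is.na(fis2$ci_low[1]))
  # same seed reproduces the bootstrap exactly
  hp2 <- hwe_population(60, 6, seed = 5)
  a <- fis_bootstrap(hp2$g, hp2$m, n_boot = 200, seed = 9)
  b <- fis_bootstrap(hp2$g, hp2$m, n_boot = 200, seed = 9)
  expect_identical(a, b)
})

test_that("diversity_table assembles one row per population", {
  s <- scenario("stepping_stone", n_pops = 4, sizes = 12, n_loci = 5,
                m = 0.05, generations = 60, seed = 13)
  d <- sample_genotypes(simulate_allele_frequencies(s))
  dt <- diversity_table(d$genotypes, d$map, n_boot = 100, seed = 1)
  expect_equal(nrow(dt), 4L)
  expect_true(all(dt$mean_ho >= 0 & dt$mean_ho <= 1))
  expect_true(all(dt$mean_he >= 0 & dt$mean_he <= 1))
  expect_true(all(dt$fis >= -1 & dt$fis <= 1, na.rm = TRUE))
  expect_true(all(dt$gw_mean > 0 & dt$gw_mean <= 1))
})
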