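# Per-population diversity statistics for codominant microsatellite data.
#
# All estimators work from per-(population, locus) allele counts over the
# non-missing gene copies; entries with no data are NA ("flagged absent")
# rather than errors.

# Tabulate alleles per (population, locus).
# Returns, per locus: counts matrix (pops x alleles, allele sizes as
# colnames), and het matrix (pops x alleles, number of heterozygous
# individuals carrying each allele - the W-C h ingredient).
allele_tabulate <- function(g, m) {
  pops <- m$population_ids
  lapply(seq_len(n_loci(g)), function(l) {
    a1 <- g$calls[, l, 1L]; a2 <- g$calls[, l, 2L]
    ok <- a1 != MISSING_ALLELE
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    counts <- matrix(0L, length(pops), length(alleles),
                     dimnames = list(pops, as.character(alleles)))
    het <- counts
    n_ind <- stats::setNames(integer(length(pops)), pops)
    for (p in pops) {
      idx <- pop_index(g, m, p)
      idx <- idx[ok[idx]]
      n_ind[p] <- length(idx)
      if (!length(idx)) next
      tab <- table(factor(c(a1[idx], a2[idx]), levels = alleles))
      counts[p, ] <- as.integer(tab)
      h <- a1[idx] != a2[idx]
      if (any(h)) {
        ht <- table(factor(c(a1[idx][h], a2[idx][h]), levels = alleles))
        het[p, ] <- as.integer(ht)
      }
    }
    list(alleles = alleles, counts = counts, het = het, n_ind = n_ind)
  })
}

#' Per-population allele frequencies
#'
#' Frequencies over the non-missing gene copies of each (population, locus)
#' combination. Combinations with no data are flagged rather than raising.
#'
#' @param g a [genotype_matrix].
#' @param m a [population_map].
#' @return list with one element per locus: `alleles` (sizes), `freq`
#'   (populations x alleles matrix, rows summing to 1, or `NA` rows where no
#'   data), `n_genes` (named gene-copy counts). Locus names on the list.
#' @export
allele_frequencies <- function(g, m) {
  tabs <- allele_tabulate(g, m)
  out <- lapply(tabs, function(t) {
    ng <- rowSums(t$counts)
    f <- t$counts / ifelse(ng > 0, ng, NA_real_)
    list(alleles = t$alleles, freq = f, n_genes = ng)
  })
  names(out) <- g$locus_names
  out
}

#' Observed heterozygosity
#'
#' Fraction of non-missing individuals carrying two distinct alleles, per
#' population and locus, with per-population means across loci.
#'
#' @inheritParams allele_frequencies
#' @return list with `per_locus` (populations x loci matrix) and `mean`
#'   (named per-population means over loci with data).
#' @export
observed_heterozygosity <- function(g, m) {
  pops <- m$population_ids
  ho <- matrix(NA_real_, length(pops), n_loci(g),
               dimnames = list(pops, g$locus_names))
  for (l in seq_len(n_loci(g))) {
    a1 <- g$calls[, l, 1L]; a2 <- g$calls[, l, 2L]
    ok <- a1 != MISSING_ALLELE
    for (p in pops) {
      idx <- pop_index(g, m, p); idx <- idx[ok[idx]]
      if (length(idx)) ho[p, l] <- mean(a1[idx] != a2[idx])
    }
  }
  list(per_locus = ho, mean = rowMeans(ho, na.rm = TRUE))
}

#' Unbiased expected heterozygosity
#'
#' Nei's unbiased gene diversity
#' `He = n/(n-1) * (1 - sum p_a^2)` with `n` the number of non-missing gene
#' copies; undefined (NA) where `n < 2`.
#'
#' @inheritParams allele_frequencies
#' @return list with `per_locus` (populations x loci) and `mean` per
#'   population.
#' @export
expected_heterozygosity <- function(g, m) {
  tabs <- allele_tabulate(g, m)
  pops <- m$population_ids
  he <- matrix(NA_real_, length(pops), n_loci(g),
               dimnames = list(pops, g$locus_names))
  for (l in seq_along(tabs)) {
    ng <- rowSums(tabs[[l]]$counts)
    p2 <- rowSums((tabs[[l]]$counts / ifelse(ng > 0, ng, NA_real_))^2)
    ok <- ng >= 2
    he[ok, l] <- pmin(1, pmax(0, ng[ok] / (ng[ok] - 1) * (1 - p2[ok])))
  }
  list(per_locus = he, mean = rowMeans(he, na.rm = TRUE))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of
#' `g_genes` gene copies, by hypergeometric rarefaction:
#' `AR = sum_a (1 - choose(n - n_a, g) / choose(n, g))`.
#'
#' @inheritParams allele_frequencies
#' @param g_genes rarefaction size in gene copies; default is the smallest
#'   non-zero (population, locus) gene count.
#' @return list with `per_locus` matrix, `mean` per population, and
#'   `g_genes` used. Entries with fewer than `g_genes` copies are `NA`,
#'   excluded from means with a warning.
#' @export
rarefied_allelic_richness <- function(g, m, g_genes = NULL) {
  tabs <- allele_tabulate(g, m)
  ng_all <- do.call(cbind, lapply(tabs, function(t) rowSums(t$counts)))
  if (is.null(g_genes)) {
    pos <- ng_all[ng_all > 0]
    if (!length(pos)) stop("no data to rarefy")
    g_genes <- min(pos)
  }
  if (g_genes < 1) stop("g_genes must be >= 1")
  pops <- m$population_ids
  ar <- matrix(NA_real_, length(pops), n_loci(g),
               dimnames = list(pops, g$locus_names))
  for (l in seq_along(tabs)) {
    counts <- tabs[[l]]$counts
    ng <- rowSums(counts)
    for (p in seq_along(pops)) {
      n <- ng[p]
      if (n < g_genes || n == 0) next
      cnt <- counts[p, ]
      cnt <- cnt[cnt > 0]
      # log-scale ratio of binomial coefficients for stability
      ar[p, l] <- sum(1 - exp(lchoose(n - cnt, g_genes) - lchoose(n, g_genes)))
    }
  }
  if (anyNA(ar))
    warning("rarefaction size ", g_genes,
            " exceeds some (population, locus) gene counts; ",
            "those entries are excluded from means")
  list(per_locus = ar, mean = rowMeans(ar, na.rm = TRUE), g_genes = g_genes)
}

#' Private allele counts
#'
#' Number of alleles observed in exactly one population, credited to that
#' population.
#'
#' @inheritParams allele_frequencies
#' @return named integer vector per population.
#' @export
private_alleles <- function(g, m) {
  tabs <- allele_tabulate(g, m)
  out <- stats::setNames(integer(length(m$population_ids)), m$population_ids)
  for (t in tabs) {
    present <- t$counts > 0L
    one_pop <- colSums(present) == 1L
    if (any(one_pop)) {
      owner <- apply(present[, one_pop, drop = FALSE], 2L, which.max)
      tb <- table(factor(m$population_ids[owner], levels = m$population_ids))
      out <- out + as.integer(tb)
    }
  }
  out
}

#' Garza-Williamson M
#'
#' Ratio `M = k / (r + 1)` of the number of distinct alleles `k` to the
#' allele-size range `r` expressed in repeat units; values near 1 indicate a
#' full allele ladder, low values signal bottlenecks. Allele sizes must be
#' multiples of the locus repeat unit.
#'
#' @inheritParams allele_frequencies
#' @param repeat_unit integer repeat length(s) in bp, length 1 or one per
#'   locus.
#' @return list with `per_locus` matrix and per-population `mean` over loci.
#' @export
garza_williamson <- function(g, m, repeat_unit = 2L) {
  L <- n_loci(g)
  repeat_unit <- rep_len(as.integer(repeat_unit), L)
  tabs <- allele_tabulate(g, m)
  pops <- m$population_ids
  gw <- matrix(NA_real_, length(pops), L,
               dimnames = list(pops, g$locus_names))
  for (l in seq_len(L)) {
    sizes <- tabs[[l]]$alleles
    if (length(sizes) && any(sizes %% repeat_unit[l] != 0L))
      stop("allele sizes at locus ", g$locus_names[l],
           " are not multiples of the repeat unit ", repeat_unit[l])
    ru <- sizes / repeat_unit[l]
    for (p in seq_along(pops)) {
      here <- tabs[[l]]$counts[p, ] > 0L
      if (!any(here)) next
      k <- sum(here)
      r <- max(ru[here]) - min(ru[here])
      gw[p, l] <- k / (r + 1)
    }
  }
  list(per_locus = gw, mean = rowMeans(gw, na.rm = TRUE))
}

# Weir-Cockerham single-sample variance components per (pop, locus):
# returns summed-over-alleles b and c for one population at one locus.
wc_fis_components <- function(counts, het, n_ind) {
  n <- n_ind
  if (n < 2) return(c(b = NA_real_, c = NA_real_))
  p <- counts / (2 * n)
  h <- het / n                              # freq of heterozygotes carrying a
  b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  c <- h / 2
  c(b = sum(b), c = sum(c))
}

#' Weir-Cockerham FIS with bootstrap confidence limits
#'
#' Per-population multilocus inbreeding coefficient `f` estimated as
#' `1 - sum(c) / sum(b + c)` from the Weir-Cockerham within-population
#' variance components summed over alleles and loci. Confidence limits are
#' 2.5/97.5 percentiles of `f` over loci resampled with replacement, and the
#' two-sided p-value is the bootstrap tail probability of `f` crossing 0.
#'
#' @inheritParams allele_frequencies
#' @param n_boot bootstrap replicates over loci (default 1000).
#' @param seed integer seed recorded in the result.
#' @return data frame with one row per population: `fis`, `ci_low`,
#'   `ci_high`, `p_value`, `n_loci_used`, `seed`. With a single usable locus
#'   the CI and p-value are `NA`.
#' @export
fis_bootstrap <- function(g, m, n_boot = 1000L, seed = 1L) {
  set.seed(seed)
  tabs <- allele_tabulate(g, m)
  pops <- m$population_ids
  L <- n_loci(g)
  res <- data.frame(pop = pops, fis = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_,
                    n_loci_used = 0L, seed = as.integer(seed))
  for (pi in seq_along(pops)) {
    comp <- t(vapply(seq_len(L), function(l) {
      wc_fis_components(tabs[[l]]$counts[pi, ], tabs[[l]]$het[pi, ],
                        tabs[[l]]$n_ind[pi])
    }, c(b = 0, c = 0)))
    use <- which(stats::complete.cases(comp) & rowSums(comp) > 0)
    res$n_loci_used[pi] <- length(use)
    if (!length(use)) next
    fsum <- function(idx) {
      bc <- colSums(comp[idx, , drop = FALSE])
      1 - bc["c"] / (bc["b"] + bc["c"])
    }
    res$fis[pi] <- fsum(use)
    if (length(use) >= 2) {
      boot <- vapply(seq_len(n_boot),
                     function(i) fsum(sample(use, length(use), replace = TRUE)),
                     numeric(1))
      boot <- boot[is.finite(boot)]
      qs <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
      res$ci_low[pi] <- qs[1]; res$ci_high[pi] <- qs[2]
      p_lo <- (1 + sum(boot <= 0)) / (1 + length(boot))
      p_hi <- (1 + sum(boot >= 0)) / (1 + length(boot))
      res$p_value[pi] <- min(1, 2 * min(p_lo, p_hi))
    }
  }
  res
}

#' Assemble the per-population diversity table
#'
#' One-stop summary mirroring a classical microsatellite diversity report:
#' mean Ho, mean He, rarefied allelic richness, private allele counts,
#' Garza-Williamson means and bootstrap FIS per population.
#'
#' @inheritParams fis_bootstrap
#' @param g_genes rarefaction size; see [rarefied_allelic_richness()].
#' @param repeat_unit repeat unit(s) in bp for the G-W index.
#' @return data frame, one row per population.
#' @export
diversity_table <- function(g, m, g_genes = NULL, repeat_unit = 2L,
                            n_boot = 1000L, seed = 1L) {
  ho <- observed_heterozygosity(g, m)
  he <- expected_heterozygosity(g, m)
  ar <- rarefied_allelic_richness(g, m, g_genes)
  pa <- private_alleles(g, m)
  gw <- garza_williamson(g, m, repeat_unit)
  fis <- fis_bootstrap(g, m, n_boot = n_boot, seed = seed)
  data.frame(pop = m$population_ids,
             n = as.integer(table(factor(m$assignment,
                                         levels = m$population_ids))),
             mean_ho = ho$mean, mean_he = he$mean,
             allelic_richness = ar$mean,
             private_alleles = as.integer(pa),
             gw_mean = gw$mean,
             fis = fis$fis, fis_ci_low = fis$ci_low,
             fis_ci_high = fis$ci_high, fis_p = fis$p_value,
             row.names = NULL)
}
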