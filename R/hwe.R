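# Exact tests of Hardy-Weinberg proportions and linkage-disequilibrium
# permutation tests within populations.

# log-probability kernel of a genotype table under Levene's conditional
# distribution (terms constant in the allele counts dropped):
#   H * log 2 - sum_ij log(n_ij!)
table_kernel <- function(a1, a2) {
  het <- sum(a1 != a2)
  key <- paste(pmin(a1, a2), pmax(a1, a2))
  het * log(2) - sum(lgamma(table(key) + 1))
}

# Full enumeration of Levene's distribution for a biallelic sample:
# heterozygote count h runs over the support (parity of nA), and
# P(h) \propto 2^h * n! / (nAA! h! nBB!).
levene_biallelic_pvalue <- function(nA, nB, h_obs) {
  n <- (nA + nB) / 2
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  lw <- hs * log(2) + lgamma(n + 1) -
    lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) - lgamma((nB - hs) / 2 + 1)
  w <- exp(lw - max(lw))
  p <- w / sum(w)
  sum(p[p <= p[match(h_obs, hs)] + 1e-12])
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Per (population, locus) exact probability test conditional on allele
#' counts. For biallelic samples of at most 50 individuals the full Levene
#' distribution over heterozygote counts is enumerated; otherwise the
#' p-value is estimated by Monte Carlo, drawing `n_steps` independent
#' genotype tables from the same conditional null by randomly re-pairing the
#' observed gene copies (compiled sampler). The rejection region consists of
#' tables no more probable than the observed one.
#'
#' @inheritParams allele_frequencies
#' @param n_steps Monte-Carlo draws (default 10^6).
#' @param seed integer seed recorded per test.
#' @return data frame with columns `pop`, `locus`, `p_value`, `method`
#'   (`"enumeration"` or `"mc"`), `n_steps`, `seed`. Monomorphic or
#'   too-small samples are returned with `method = "skipped"` and `NA`
#'   p-value.
#' @export
hwe_exact_test <- function(g, m, n_steps = 1e6, seed = 1L) {
  set.seed(seed)
  n_steps <- as.integer(n_steps)
  rows <- list()
  for (p in m$population_ids) {
    idx0 <- pop_index(g, m, p)
    for (l in seq_len(n_loci(g))) {
      a1 <- g$calls[idx0, l, 1L]; a2 <- g$calls[idx0, l, 2L]
      ok <- a1 != MISSING_ALLELE
      a1 <- a1[ok]; a2 <- a2[ok]
      alleles <- sort(unique(c(a1, a2)))
      row <- data.frame(pop = p, locus = g$locus_names[l],
                        p_value = NA_real_, method = "skipped",
                        n_steps = 0L, seed = as.integer(seed))
      if (length(alleles) >= 2L && length(a1) >= 2L) {
        if (length(alleles) == 2L && length(a1) <= 50L) {
          cnt <- table(factor(c(a1, a2), levels = alleles))
          row$p_value <- levene_biallelic_pvalue(cnt[1], cnt[2],
                                                 sum(a1 != a2))
          row$method <- "enumeration"
        } else {
          code1 <- match(a1, alleles) - 1L
          code2 <- match(a2, alleles) - 1L
          obs <- table_kernel(code1, code2)
          row$p_value <- hwe_mc_pvalue_cpp(as.integer(rbind(code1, code2)),
                                           n_steps, obs)
          row$method <- "mc"
          row$n_steps <- n_steps
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

# G (log-likelihood ratio) statistic of a two-column contingency table
# given as two factors of equal length.
g_statistic <- function(f1, f2) {
  O <- table(f1, f2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  keep <- O > 0
  2 * sum(O[keep] * log(O[keep] / E[keep]))
}

#' Linkage-disequilibrium permutation test
#'
#' For each population and locus pair, tests association between two-locus
#' genotypes with the G (log-likelihood-ratio) statistic of the genotype
#' contingency table. The null is built by permuting one locus's genotypes
#' across the individuals of the population, which preserves both single-
#' locus genotype distributions; `p = (1 + #(G_perm >= G_obs)) / (1 +
#' n_perm)`.
#'
#' @inheritParams allele_frequencies
#' @param n_perm permutations per test (default 1000).
#' @param seed integer seed recorded per test.
#' @return data frame with columns `pop`, `locus1`, `locus2`, `g_obs`,
#'   `p_value`, `n_perm`, `seed`; pairs skipped for lack of data (fewer than
#'   5 complete individuals or a monomorphic locus) carry `NA` p-values.
#' @export
ld_permutation_test <- function(g, m, n_perm = 1000L, seed = 1L) {
  set.seed(seed)
  L <- n_loci(g)
  rows <- list()
  for (p in m$population_ids) {
    idx0 <- pop_index(g, m, p)
    geno <- lapply(seq_len(L), function(l) {
      a1 <- g$calls[idx0, l, 1L]; a2 <- g$calls[idx0, l, 2L]
      gt <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
      gt[a1 == MISSING_ALLELE] <- NA_character_
      gt
    })
    for (l1 in seq_len(L - 1L)) for (l2 in seq.int(l1 + 1L, L)) {
      f1 <- geno[[l1]]; f2 <- geno[[l2]]
      keep <- !is.na(f1) & !is.na(f2)
      row <- data.frame(pop = p, locus1 = g$locus_names[l1],
                        locus2 = g$locus_names[l2], g_obs = NA_real_,
                        p_value = NA_real_, n_perm = 0L,
                        seed = as.integer(seed))
      f1 <- f1[keep]; f2 <- f2[keep]
      if (sum(keep) >= 5L &&
          length(unique(f1)) > 1L && length(unique(f2)) > 1L) {
        f1 <- factor(f1); f2 <- factor(f2)
        g_obs <- g_statistic(f1, f2)
        ge <- vapply(seq_len(n_perm),
                     function(i) g_statistic(f1, sample(f2)), numeric(1))
        row$g_obs <- g_obs
        row$p_value <- (1 + sum(ge >= g_obs - 1e-12)) / (1 + n_perm)
        row$n_perm <- as.integer(n_perm)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
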