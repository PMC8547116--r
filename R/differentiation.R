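# Pairwise population differentiation: Weir & Cockerham's theta from
# hierarchical variance components, and the FST/(1-FST) linearization used
# by the distance-based tests.

# W-C variance components for one locus and two populations.
# counts: 2 x n_alleles allele counts; het: 2 x n_alleles counts of
# heterozygous carriers; n: individuals with data per population.
# Returns c(a, b, c) summed over alleles.
wc_pair_components <- function(counts, het, n) {
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  p <- counts / (2 * n)                   # row-wise: pops x alleles
  h <- het / n
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = sum(a), b = sum(b), c = sum(c))
}

#' Pairwise Weir-Cockerham FST
#'
#' Multilocus theta-hat for every pair of populations, computed as the
#' ratio of summed variance components `sum(a) / sum(a + b + c)` over
#' alleles and loci (among-population, among-individual-within, and
#' within-individual components, with the unequal-sample-size corrections).
#' Missing data reduce the per-locus sample counts; loci with fewer than two
#' genotyped individuals in either population are dropped from that pair.
#' Negative estimates are returned as-is.
#'
#' @inheritParams allele_frequencies
#' @return list of class `fst_matrix` with `fst` (symmetric
#'   [pairwise_matrix] of theta-hat), and `components` (data frame of summed
#'   per-locus a, b, c per pair).
#' @export
pairwise_fst <- function(g, m) {
  pops <- m$population_ids
  if (!all(pops %in% m$assignment[g$individual_ids]))
    stop("population(s) absent from genotypes: ",
         paste(setdiff(pops, m$assignment[g$individual_ids]), collapse = ", "))
  tabs <- allele_tabulate(g, m)
  K <- length(pops)
  fst <- matrix(0, K, K, dimnames = list(pops, pops))
  comp_rows <- list()
  for (i in seq_len(K - 1L)) for (j in seq.int(i + 1L, K)) {
    A <- B <- C <- 0
    for (l in seq_along(tabs)) {
      t <- tabs[[l]]
      n <- t$n_ind[c(i, j)]
      if (any(n < 2L)) next
      cnt <- t$counts[c(i, j), , drop = FALSE]
      seen <- colSums(cnt) > 0L
      if (sum(seen) < 2L) next            # locus monomorphic in this pair
      abc <- wc_pair_components(cnt[, seen, drop = FALSE],
                                t$het[c(i, j), seen, drop = FALSE], n)
      A <- A + abc["a"]; B <- B + abc["b"]; C <- C + abc["c"]
      comp_rows[[length(comp_rows) + 1L]] <-
        data.frame(pop1 = pops[i], pop2 = pops[j],
                   locus = g$locus_names[l],
                   a = unname(abc["a"]), b = unname(abc["b"]),
                   c = unname(abc["c"]))
    }
    denom <- A + B + C
    fst[i, j] <- fst[j, i] <- if (denom > 0) A / denom else NA_real_
  }
  if (anyNA(fst))
    warning("theta-hat undefined for some pairs (no usable loci); NA returned")
  structure(list(fst = pairwise_matrix(fst, pops, symmetric = TRUE),
                 components = if (length(comp_rows))
                   do.call(rbind, comp_rows) else NULL),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Pairwise Weir-Cockerham FST\n")
  print(x$fst, ...)
  invisible(x)
}

#' Linearize an FST matrix
#'
#' Element-wise `FST / (1 - FST)`, the transform under which differentiation
#' grows linearly with distance in lattice models. Monotone for `FST < 1`;
#' negative estimates pass through un-clamped to preserve rank information.
#'
#' @param f an `fst_matrix` from [pairwise_fst()] or a symmetric
#'   [pairwise_matrix] of FST values.
#' @return a symmetric [pairwise_matrix] of linearized distances.
#' @export
linearize_fst <- function(f) {
  v <- if (inherits(f, "fst_matrix")) f$fst else f
  if (any(v >= 1, na.rm = TRUE)) {
    bad <- which(v >= 1 & upper.tri(v), arr.ind = TRUE)
    stop("FST = 1 gives infinite linearized distance for pair(s): ",
         paste(rownames(v)[bad[, 1]], colnames(v)[bad[, 2]],
               sep = "-", collapse = ", "))
  }
  out <- v / (1 - v)
  diag(out) <- 0
  pairwise_matrix(out, rownames(v), symmetric = TRUE)
}
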