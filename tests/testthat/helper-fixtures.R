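# Shared fixtures: tiny genotype sets built in code, plus independent
# oracles (exhaustive path enumeration, Levene enumeration by direct
# normalization) used to validate the fast implementations.

# genotype_matrix from a list of populations, each a list of c(a1, a2)
# calls (single locus), or from a pops x loci nested list
make_genotypes <- function(pops, loci = 1L) {
  calls <- list()
  ids <- character(); assign <- character()
  for (p in names(pops)) {
    for (i in seq_along(pops[[p]])) {
      ids <- c(ids, sprintf("%s_%02d", p, i))
      assign <- c(assign, p)
      calls[[length(calls) + 1L]] <- pops[[p]][[i]]
    }
  }
  n <- length(ids)
  arr <- array(0L, dim = c(n, loci, 2L))
  for (i in seq_len(n)) {
    v <- calls[[i]]
    arr[i, , ] <- matrix(as.integer(v), nrow = loci, ncol = 2L,
                         byrow = loci == 1L)
  }
  g <- genotype_matrix(arr, ids, sprintf("loc%02d", seq_len(loci)))
  m <- population_map(stats::setNames(assign, ids))
  list(g = g, m = m)
}

# HWE draws: one population, `n` individuals, `loci` loci, allele
# frequencies `p` (named by allele size)
hwe_population <- function(n, loci, p = c(`100` = 0.5, `102` = 0.5),
                           seed = 1) {
  set.seed(seed)
  sizes <- as.integer(names(p))
  arr <- array(0L, dim = c(n, loci, 2L))
  for (l in seq_len(loci))
    arr[, l, ] <- sample(sizes, 2L * n, replace = TRUE, prob = p)
  g <- genotype_matrix(arr, sprintf("i%03d", seq_len(n)),
                       sprintf("loc%02d", seq_len(loci)))
  m <- population_map(stats::setNames(rep("P1", n), g$individual_ids))
  list(g = g, m = m)
}

# Independent least-cost oracle: exhaustive DFS over simple paths on the
# 8-neighbour graph of a small raster, edge cost = haversine centre
# distance / mean conductance. Only feasible for grids up to ~4x4.
brute_force_cost <- function(r, from_cell, to_cell) {
  nr <- r$n_rows; nc <- r$n_cols
  ctr <- function(cell) {
    i <- (cell - 1L) %% nr + 1L; j <- (cell - 1L) %/% nr + 1L
    c(lon = r$x_llcorner + (j - 0.5) * r$cell_size,
      lat = r$y_llcorner + (nr - i + 0.5) * r$cell_size)
  }
  val <- function(cell) r$values[(cell - 1L) %% nr + 1L,
                                 (cell - 1L) %/% nr + 1L]
  nbrs <- function(cell) {
    i <- (cell - 1L) %% nr + 1L; j <- (cell - 1L) %/% nr + 1L
    out <- integer()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          !is.na(r$values[ii, jj]))
        out <- c(out, (jj - 1L) * nr + ii)
    }
    out
  }
  edge_cost <- function(a, b) {
    pa <- ctr(a); pb <- ctr(b)
    d <- geosphere::distHaversine(pa, pb, r = 6371008.8)
    d / ((val(a) + val(b)) / 2)
  }
  best <- Inf
  dfs <- function(cell, visited, acc) {
    if (acc >= best) return()
    if (cell == to_cell) { best <<- acc; return() }
    for (nb in nbrs(cell)) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        dfs(nb, visited, acc + edge_cost(cell, nb))
        visited[nb] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, nr * nc)
  visited[from_cell] <- TRUE
  dfs(from_cell, visited, 0)
  best
}

# log-transformed geographic distance matrix (zeros preserved)
log_distance <- function(geo) {
  v <- unclass(geo)
  v[v > 0] <- log(v[v > 0])
  pairwise_matrix(v, rownames(geo), symmetric = TRUE)
}

# random labelled symmetric distance matrix for permutation-test work
random_distance_matrix <- function(n, labels = sprintf("P%02d", seq_len(n))) {
  xy <- matrix(stats::runif(n * 2), n)
  D <- as.matrix(stats::dist(xy))
  dimnames(D) <- list(labels, labels)
  pairwise_matrix(D, labels, symmetric = TRUE)
}
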