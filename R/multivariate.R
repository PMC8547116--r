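# Exploratory genetic structure: DAPC (PCA -> k-means/BIC -> LDA with
# a-score PC selection) and sPCA (spatially weighted eigenanalysis with
# global/local permutation tests).

#' Individuals-by-alleles dosage matrix
#'
#' Counts of each allele carried per individual (0/1/2), one column per
#' allele per locus. Missing calls become `NA` dosages, imputed by the
#' allele's mean dosage; columns are then centred.
#'
#' @param g a [genotype_matrix].
#' @param scale also scale columns to unit variance (default `FALSE`).
#' @return list with `X` (centred numeric matrix), `imputed` (fraction of
#'   imputed entries per locus), `allele_of` / `locus_of` (column
#'   annotations).
#' @export
allele_dosage_matrix <- function(g, scale = FALSE) {
  n <- n_individuals(g)
  cols <- list(); locus_of <- character(); allele_of <- character()
  imputed <- stats::setNames(numeric(n_loci(g)), g$locus_names)
  for (l in seq_len(n_loci(g))) {
    a1 <- g$calls[, l, 1L]; a2 <- g$calls[, l, 2L]
    ok <- a1 != MISSING_ALLELE
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    imputed[l] <- mean(!ok)
    for (a in alleles) {
      d <- (a1 == a) + (a2 == a)
      d[!ok] <- NA_real_
      cols[[length(cols) + 1L]] <- d
      locus_of <- c(locus_of, g$locus_names[l])
      allele_of <- c(allele_of, as.character(a))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- paste(locus_of, allele_of, sep = ".")
  rownames(X) <- g$individual_ids
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2L, mu)
  if (scale) {
    sdv <- apply(X, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(X, 2L, sdv, "/")
  }
  list(X = X, imputed = imputed, locus_of = locus_of, allele_of = allele_of)
}

# k-means BIC on PC scores: n*log(WSS/n) + k*log(n)
kmeans_bic <- function(scores, k, nstart = 10L) {
  n <- nrow(scores)
  wss <- if (k == 1L) sum(scale(scores, scale = FALSE)^2)
         else {
           km <- stats::kmeans(scores, k, nstart = nstart, iter.max = 100L)
           km$tot.withinss
         }
  n * log(wss / n) + k * log(n)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Transforms genotypes to centred allele dosages, runs a PCA retaining all
#' components, selects the number of clusters k by k-means on the PC scores
#' with `BIC(k) = n log(WSS_k/n) + k log(n)` (minimum wins), then fits a
#' linear discriminant analysis of the clusters on a reduced number of PCs
#' chosen by the a-score (observed reassignment rate minus its expectation
#' under randomly permuted cluster labels), guarding against overfitting.
#'
#' @param g a [genotype_matrix].
#' @param m optional [population_map]; if supplied, groups can be fixed to
#'   the populations via `groups = "populations"`.
#' @param k_range candidate cluster numbers (default `1:10`, truncated to
#'   `n - 1`).
#' @param groups `"kmeans"` (default: infer clusters) or `"populations"`.
#' @param n_pca_max cap on PCs considered for the discriminant step.
#' @param n_ascore_sim permutations per candidate in the a-score.
#' @param seed integer seed.
#' @return list of class `dapc_result`: `bic` (data frame k/BIC), `best_k`,
#'   `assignments` (integer clusters or population factor), `n_pca`
#'   (retained PCs), `a_score` (data frame), `ld_scores` (individuals x
#'   discriminant functions, `NULL` when `best_k = 1`), `posterior`,
#'   `seed`.
#' @export
dapc <- function(g, m = NULL, k_range = 1:10,
                 groups = c("kmeans", "populations"),
                 n_pca_max = 50L, n_ascore_sim = 10L, seed = 1L) {
  groups <- match.arg(groups)
  set.seed(seed)
  n <- n_individuals(g)
  if (max(k_range) > n - 1L)
    stop("k_range exceeds n - 1 = ", n - 1L)
  if (2L * max(k_range) > n)
    warning("fewer than 2 individuals per candidate cluster on average")
  X <- allele_dosage_matrix(g)$X
  pc <- stats::prcomp(X, center = FALSE)
  keep <- pc$sdev > pc$sdev[1] * 1e-7
  scores <- pc$x[, keep, drop = FALSE]
  bic <- data.frame(k = k_range,
                    bic = vapply(k_range, function(k)
                      kmeans_bic(scores, k), numeric(1)))
  best_k <- bic$k[which.min(bic$bic)]
  if (groups == "populations") {
    if (is.null(m)) stop("groups = 'populations' needs a population map")
    grp <- factor(m$assignment[g$individual_ids], levels = m$population_ids)
  } else if (best_k == 1L) {
    grp <- factor(rep(1L, n))
  } else {
    grp <- factor(stats::kmeans(scores, best_k, nstart = 10L,
                                iter.max = 100L)$cluster)
  }
  if (nlevels(grp) < 2L)
    return(structure(list(bic = bic, best_k = best_k, assignments = grp,
                          n_pca = 0L, a_score = NULL, ld_scores = NULL,
                          posterior = NULL, seed = as.integer(seed)),
                     class = "dapc_result"))
  # a-score over candidate PC counts
  cap <- min(n_pca_max, ncol(scores), n - nlevels(grp) - 1L)
  cand <- unique(pmax(1L, round(seq(1L, cap, length.out = min(8L, cap)))))
  reassign <- function(np, gg) {
    fit <- MASS::lda(scores[, seq_len(np), drop = FALSE], grouping = gg)
    mean(stats::predict(fit)$class == gg)
  }
  ascore <- vapply(cand, function(np) {
    obs <- reassign(np, grp)
    null <- mean(vapply(seq_len(n_ascore_sim),
                        function(i) reassign(np, sample(grp)), numeric(1)))
    obs - null
  }, numeric(1))
  n_pca <- cand[which.max(ascore)]
  fit <- MASS::lda(scores[, seq_len(n_pca), drop = FALSE], grouping = grp)
  pred <- stats::predict(fit)
  structure(list(bic = bic, best_k = best_k, assignments = grp,
                 n_pca = n_pca,
                 a_score = data.frame(n_pca = cand, a_score = ascore),
                 ld_scores = pred$x, posterior = pred$posterior,
                 seed = as.integer(seed)),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("DAPC: best k = %d (BIC), %d PCs retained (a-score)\n",
              x$best_k, x$n_pca))
  invisible(x)
}

# connection networks on jittered individual coordinates ------------------

# binary k-nearest-neighbour adjacency (mutualized: i~j if either is a
# neighbour of the other)
knn_graph <- function(xy, k) {
  n <- nrow(xy)
  if (k >= n) stop("k must be < number of individuals")
  D <- as.matrix(stats::dist(xy))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    W[i, nb] <- 1
  }
  pmax(W, t(W))
}

# Gabriel graph: edge i-j unless some k lies inside the circle with
# diameter ij, i.e. d(i,k)^2 + d(j,k)^2 < d(i,j)^2
gabriel_graph <- function(xy) {
  n <- nrow(xy)
  D2 <- as.matrix(stats::dist(xy))^2
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    others <- setdiff(seq_len(n), c(i, j))
    if (!any(D2[i, others] + D2[j, others] < D2[i, j] - 1e-12))
      W[i, j] <- W[j, i] <- 1
  }
  W
}

distance_band_graph <- function(xy, d) {
  D <- as.matrix(stats::dist(xy))
  W <- (D > 0 & D <= d) * 1
  diag(W) <- 0
  W
}

#' Spatial principal component analysis (sPCA)
#'
#' Eigenanalysis of `(1/n) X' L X` for the centred allele-dosage matrix `X`
#' and the symmetrized row-normalized spatial weight matrix `L` of a
#' connection network built on jittered individual coordinates (individuals
#' inherit their population's coordinates plus Gaussian jitter so coincident
#' points separate). Each eigenvalue equals the product of the variance and
#' Moran's I of its axis scores: large positive eigenvalues capture global
#' (cline-like) structure, large negative ones local (repulsion-like)
#' structure.
#'
#' @param g a [genotype_matrix].
#' @param m a [population_map] with coordinates.
#' @param network `"knn"`, `"gabriel"` or `"distance"`.
#' @param k neighbours for `"knn"` (default 5).
#' @param d distance band in degrees for `"distance"`.
#' @param jitter_sd coordinate jitter standard deviation in degrees
#'   (default 0.2).
#' @param seed integer seed (jitter).
#' @return list of class `spca_result`: `eigenvalues`, `scores`, `var`,
#'   `moran` (per axis, `var * moran = eigenvalue`), `X`, `L`, `coords`
#'   (jittered), `network`, `seed`.
#' @export
spca <- function(g, m, network = c("knn", "gabriel", "distance"), k = 5L,
                 d = NULL, jitter_sd = 0.2, seed = 1L) {
  network <- match.arg(network)
  if (is.null(m$coords)) stop("population map carries no coordinates")
  set.seed(seed)
  n <- n_individuals(g)
  pc <- m$coords[match(m$assignment[g$individual_ids], m$coords$pop), ]
  xy <- cbind(lon = pc$lon + stats::rnorm(n, 0, jitter_sd),
              lat = pc$lat + stats::rnorm(n, 0, jitter_sd))
  W <- switch(network,
    knn = knn_graph(xy, k),
    gabriel = gabriel_graph(xy),
    distance = {
      if (is.null(d)) stop("network = 'distance' needs a band width d")
      distance_band_graph(xy, d)
    })
  deg <- rowSums(W)
  if (any(deg == 0))
    stop("disconnected individuals in the connection network; ",
         "increase k or d")
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected"))
  if (comp$no > 1L)
    stop("connection network has ", comp$no,
         " components; increase k or d")
  Wn <- W / deg                           # row-normalized
  L <- (Wn + t(Wn)) / 2
  X <- allele_dosage_matrix(g)$X
  C <- crossprod(X, L %*% X) / n
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  scores <- X %*% eig$vectors
  v <- colSums(scores^2) / n
  moran <- colSums(scores * (L %*% scores)) / colSums(scores^2)
  structure(list(eigenvalues = eig$values, scores = scores, var = v,
                 moran = moran, X = X, L = L, coords = xy,
                 network = network, seed = as.integer(seed)),
            class = "spca_result")
}

#' @export
print.spca_result <- function(x, ...) {
  cat(sprintf("sPCA (%s network): lambda1 = %.4f, lambda_min = %.4f\n",
              x$network, max(x$eigenvalues), min(x$eigenvalues)))
  invisible(x)
}

#' Global and local permutation tests for sPCA
#'
#' Tests for non-random spatial genetic structure by Monte Carlo: the
#' statistics are the largest positive eigenvalue (global structure) and
#' the largest absolute negative eigenvalue (local structure); the null
#' redistributes genotypes over locations by permuting the rows of the
#' dosage matrix and recomputing the eigen-decomposition. Add-one p-values.
#'
#' @param sp an `spca_result`.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return list with `global_stat`, `global_p`, `local_stat`, `local_p`,
#'   `n_perm`, `seed`.
#' @export
spca_global_local_tests <- function(sp, n_perm = 10000L, seed = 1L) {
  set.seed(seed)
  n <- nrow(sp$X)
  stat <- function(X) {
    C <- crossprod(X, sp$L %*% X) / n
    ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
    c(global = max(ev, 0), local = max(-ev, 0))
  }
  obs <- stat(sp$X)
  per <- vapply(seq_len(n_perm),
                function(i) stat(sp$X[sample.int(n), , drop = FALSE]),
                c(global = 0, local = 0))
  eps <- 1e-12
  list(global_stat = obs["global"][[1]],
       global_p = (1 + sum(per["global", ] >= obs["global"] - eps)) /
         (1 + n_perm),
       local_stat = obs["local"][[1]],
       local_p = (1 + sum(per["local", ] >= obs["local"] - eps)) /
         (1 + n_perm),
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}
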