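# Matrix-correlation inference: Mantel tests, climatic dissimilarity, and
# multiple matrix regression with randomization (MMRR).

# lower-triangle vector of a square matrix
lower_tri <- function(M) M[lower.tri(M)]

check_same_labels <- function(...) {
  mats <- list(...)
  labs <- rownames(mats[[1]])
  for (M in mats)
    if (!identical(rownames(M), labs))
      stop("pairwise matrices must share labels and label order")
  labs
}

#' Climatic dissimilarity matrix
#'
#' Pairwise absolute differences of a per-population climate value,
#' `D[i,j] = |v_i - v_j|`.
#'
#' @param values named numeric vector, one climate value per population.
#' @return symmetric [pairwise_matrix].
#' @export
climate_dissimilarity <- function(values) {
  if (is.null(names(values))) stop("values must be named by population")
  D <- abs(outer(values, values, "-"))
  pairwise_matrix(D, names(values), symmetric = TRUE)
}

#' Extract a climate value per population from a raster
#'
#' @param r climate [raster_grid].
#' @param nodes data frame with `pop`, `lon`, `lat`.
#' @return named numeric vector; errors if a population falls outside the
#'   raster extent or on a nodata cell.
#' @export
extract_climate <- function(r, nodes) {
  rc <- cell_of(r, nodes$lon, nodes$lat)
  v <- r$values[rc]
  if (anyNA(v))
    stop("population(s) on nodata climate cells: ",
         paste(nodes$pop[is.na(v)], collapse = ", "))
  stats::setNames(v, nodes$pop)
}

#' Mantel test
#'
#' Permutation test of the Pearson correlation between the lower-triangle
#' vectors of two symmetric pairwise matrices. The null distribution is
#' built by jointly permuting rows and columns of `Y`;
#' `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)` for the upper tail.
#'
#' @param X,Y symmetric [pairwise_matrix] objects with identical labels.
#' @param n_perm number of permutations (default 10000).
#' @param tail `"upper"` (default), `"lower"` or `"two"`.
#' @param seed integer seed recorded in the result.
#' @return list of class `mantel_result`: `r`, `p_value`, `n_perm`, `tail`,
#'   `seed`.
#' @export
mantel_test <- function(X, Y, n_perm = 10000L, tail = c("upper", "lower", "two"),
                        seed = 1L) {
  tail <- match.arg(tail)
  check_same_labels(X, Y)
  n <- nrow(X)
  if (n < 4L) stop("Mantel test needs at least 4 populations")
  set.seed(seed)
  x <- lower_tri(X)
  lt <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  y <- Y[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a distance matrix lower triangle")
  r_obs <- stats::cor(x, y)
  Yv <- unclass(Y)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(x, Yv[cbind(p[lt[, 1]], p[lt[, 2]])])
  }, numeric(1))
  eps <- 1e-12
  p <- switch(tail,
    upper = (1 + sum(r_perm >= r_obs - eps)) / (1 + n_perm),
    lower = (1 + sum(r_perm <= r_obs + eps)) / (1 + n_perm),
    two = (1 + sum(abs(r_perm) >= abs(r_obs) - eps)) / (1 + n_perm))
  structure(list(r = r_obs, p_value = p, n_perm = as.integer(n_perm),
                 tail = tail, seed = as.integer(seed)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s tail, %d permutations)\n",
              x$r, x$p_value, x$tail, x$n_perm))
  invisible(x)
}

#' Multiple matrix regression with randomization (MMRR)
#'
#' OLS regression of the lower triangle of a response distance matrix on the
#' lower triangles of predictor matrices (intercept included). Significance
#' of each coefficient and of the overall fit comes from randomization:
#' rows/columns of the response matrix are jointly permuted, the regression
#' is refit, and the permutation t and F statistics are compared to the
#' observed ones (two-sided on |t|, upper tail on F), with the add-one rule.
#'
#' @param Y symmetric response [pairwise_matrix].
#' @param X named list of symmetric predictor [pairwise_matrix] objects.
#' @param n_perm number of response permutations (default 10000).
#' @param seed integer seed recorded in the result.
#' @return list of class `mmrr_result`: `coefficients` (data frame with
#'   `beta`, `t`, `p_value` per term), `r_squared`, `f_statistic`,
#'   `f_p_value`, `n_perm`, `seed`.
#' @export
mmrr <- function(Y, X, n_perm = 10000L, seed = 1L) {
  if (!is.list(X)) X <- list(X1 = X)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    names(X) <- paste0("X", seq_along(X))
  do.call(check_same_labels, c(list(Y), X))
  n <- nrow(Y)
  lt <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  npair <- nrow(lt)
  p <- length(X)
  if (npair < p + 2L)
    stop("fewer population pairs than predictors + intercept")
  Xm <- cbind(`(Intercept)` = 1,
              do.call(cbind, lapply(X, lower_tri)))
  colnames(Xm) <- c("(Intercept)", names(X))
  if (p >= 2L) {
    cc <- stats::cor(Xm[, -1, drop = FALSE])
    hit <- which(abs(cc) > 0.9999 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(hit))
      stop("collinear predictors: ",
           paste(rownames(cc)[hit[, 1]], colnames(cc)[hit[, 2]],
                 sep = " ~ ", collapse = ", "))
  }
  set.seed(seed)
  # fit on standardized columns for numerical stability (predictors can
  # differ by many orders of magnitude); t, p and R^2 are scale-invariant
  # and the coefficients are transformed back afterwards
  mu_x <- colMeans(Xm[, -1, drop = FALSE])
  sd_x <- apply(Xm[, -1, drop = FALSE], 2L, stats::sd)
  if (any(sd_x == 0)) stop("constant predictor matrix")
  Xs <- cbind(1, sweep(sweep(Xm[, -1, drop = FALSE], 2L, mu_x), 2L, sd_x, "/"))
  colnames(Xs) <- colnames(Xm)
  Xm <- Xs
  if (qr(Xm)$rank < ncol(Xm))
    stop("design matrix is rank-deficient (collinear predictors)")
  XtXi <- solve(crossprod(Xm))
  M <- XtXi %*% t(Xm)                      # (p+1) x npair
  dj <- diag(XtXi)
  df <- npair - p - 1L
  y <- lower_tri(Y)
  tss <- sum((y - mean(y))^2)
  fit_stats <- function(ymat) {            # columns = response vectors
    B <- M %*% ymat
    rss <- colSums((ymat - Xm %*% B)^2)
    sigma2 <- rss / df
    tmat <- B / sqrt(outer(dj, sigma2))
    r2 <- 1 - rss / tss
    Fst <- (r2 / p) / ((1 - r2) / df)
    list(B = B, t = tmat, r2 = r2, F = Fst)
  }
  obs <- fit_stats(matrix(y, ncol = 1))
  Yv <- unclass(Y)
  perm_y <- vapply(seq_len(n_perm), function(i) {
    pp <- sample.int(n)
    Yv[cbind(pp[lt[, 1]], pp[lt[, 2]])]
  }, numeric(npair))
  per <- fit_stats(perm_y)
  eps <- 1e-12
  p_coef <- vapply(seq_len(p + 1L), function(j) {
    (1 + sum(abs(per$t[j, ]) >= abs(obs$t[j, 1]) - eps)) / (1 + n_perm)
  }, numeric(1))
  p_f <- (1 + sum(per$F >= obs$F[1] - eps)) / (1 + n_perm)
  beta_std <- drop(obs$B)
  beta <- c(beta_std[1] - sum(beta_std[-1] * mu_x / sd_x),
            beta_std[-1] / sd_x)
  structure(list(
    coefficients = data.frame(term = colnames(Xm),
                              beta = beta, t = drop(obs$t),
                              p_value = p_coef, row.names = NULL),
    r_squared = obs$r2[1], f_statistic = obs$F[1], f_p_value = p_f,
    n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "mmrr_result")
}

#' @export
print.mmrr_result <- function(x, ...) {
  cat(sprintf("MMRR: R^2 = %.4f, F p = %.4g (%d permutations)\n",
              x$r_squared, x$f_p_value, x$n_perm))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Isolation-by-distance / -resistance / -environment test suite
#'
#' Runs, with linearized FST as response: (a) the Mantel IBD test against
#' log-transformed geographic distance; (b) one single-predictor MMRR per
#' resistance model; (c) one MMRR per climate variable with geographic
#' distance as covariate; (d) an MMRR on the (symmetrized) wind cost
#' matrix. Geographic distance enters the MMRRs untransformed unless
#' `log_geo_mmrr = TRUE`.
#'
#' @param fst an `fst_matrix` from [pairwise_fst()] (or a symmetric FST
#'   [pairwise_matrix]).
#' @param geo geographic distance [pairwise_matrix] (meters).
#' @param resist named list of resistance-model cost matrices (may be
#'   empty).
#' @param clim named list of climatic dissimilarity matrices (may be
#'   empty).
#' @param wind symmetric wind cost [pairwise_matrix] or `NULL`.
#' @param n_perm permutations for every test.
#' @param seed integer seed; consecutive tests use `seed`, `seed + 1`, ...
#' @param log_geo_mmrr log-transform distance in the MMRRs too.
#' @return tidy data frame with one row per fitted term: `test`,
#'   `predictor`, `r`, `r_squared`, `beta`, `p_value`, `n_perm`, `seed`.
#' @export
ibd_ibe_suite <- function(fst, geo, resist = list(), clim = list(),
                          wind = NULL, n_perm = 10000L, seed = 1L,
                          log_geo_mmrr = FALSE) {
  lin <- linearize_fst(fst)
  rows <- list()
  add <- function(test, predictor, r = NA_real_, r2 = NA_real_,
                  beta = NA_real_, p = NA_real_, sd) {
    rows[[length(rows) + 1L]] <<-
      data.frame(test = test, predictor = predictor, r = r,
                 r_squared = r2, beta = beta, p_value = p,
                 n_perm = as.integer(n_perm), seed = as.integer(sd))
  }
  s <- as.integer(seed)
  log_geo <- pairwise_matrix_map(geo, function(v) ifelse(v > 0, log(v), 0))
  mt <- mantel_test(lin, log_geo, n_perm = n_perm, seed = s)
  add("mantel_ibd", "log_geographic_distance", r = mt$r, p = mt$p_value,
      sd = s)
  geo_mmrr <- if (log_geo_mmrr) log_geo else geo
  for (nm in names(resist)) {
    s <- s + 1L
    fit <- mmrr(lin, stats::setNames(list(resist[[nm]]), nm),
                n_perm = n_perm, seed = s)
    add("mmrr_resistance", nm, r2 = fit$r_squared,
        beta = fit$coefficients$beta[2], p = fit$coefficients$p_value[2],
        sd = s)
  }
  for (nm in names(clim)) {
    s <- s + 1L
    fit <- mmrr(lin, stats::setNames(list(clim[[nm]], geo_mmrr),
                                     c(nm, "geographic_distance")),
                n_perm = n_perm, seed = s)
    add("mmrr_climate", nm, r2 = fit$r_squared,
        beta = fit$coefficients$beta[2], p = fit$coefficients$p_value[2],
        sd = s)
    add("mmrr_climate", paste0(nm, ":geographic_distance"),
        r2 = fit$r_squared, beta = fit$coefficients$beta[3],
        p = fit$coefficients$p_value[3], sd = s)
  }
  if (!is.null(wind)) {
    s <- s + 1L
    fit <- mmrr(lin, list(wind_cost = wind), n_perm = n_perm, seed = s)
    add("mmrr_wind", "wind_cost", r2 = fit$r_squared,
        beta = fit$coefficients$beta[2], p = fit$coefficients$p_value[2],
        sd = s)
  }
  do.call(rbind, rows)
}

# apply a function element-wise, keeping labels / symmetry
pairwise_matrix_map <- function(M, f) {
  out <- f(unclass(M))
  diag(out) <- 0
  pairwise_matrix(out, rownames(M), symmetric = attr(M, "symmetric"))
}
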