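# Forward-time drift-migration simulator with paired landscape, wind and
# climate generators, so every pipeline stage can be validated against a
# known scenario.

#' Study sampling table
#'
#' Published sampling design of the motivating coastal-plant survey: 15
#' populations (inland I1-3, west-lagoon W1-3, northern coastal N1-3,
#' southern coastal S1-6), their sample sizes, decimal-degree coordinates
#' and reported multilocus FIS. Used as the geometry of the `study_shaped`
#' simulation scenario and as a realistic validation fixture.
#'
#' @return data frame with columns `pop`, `n`, `lon`, `lat`, `fis`.
#' @export
study_populations <- function() {
  data.frame(
    pop = c("I1", "I2", "I3", "W1", "W2", "W3", "N1", "N2", "N3",
            "S1", "S2", "S3", "S4", "S5", "S6"),
    n = c(4L, 10L, 9L, 27L, 4L, 23L, 10L, 23L, 37L,
          3L, 13L, 12L, 11L, 26L, 41L),
    lon = c(-55.10077, -54.85375, -54.90852, -51.20255, -51.49195,
            -52.16478, -48.76501, -49.79809, -50.42936, -50.73934,
            -50.90112, -51.42576, -52.03612, -52.54661, -52.7323),
    lat = c(-29.58307, -29.8947, -29.85478, -30.40754, -30.90082,
            -31.70757, -28.45991, -29.43227, -29.89291, -30.93746,
            -31.10909, -31.66673, -32.02393, -32.52396, -32.98765),
    fis = c(-0.16, -0.01, 0, 0.08, 0.12, 0.07, 0.34, 0.17, 0.10,
            0.35, 0.08, -0.01, -0.05, 0.27, 0.25))
}

default_geometry <- function() {
  list(lon0 = -53.5, lon1 = -47.5,      # ~600 km NE-SW-equivalent strip
       lat0 = -32.0, lat1 = -30.2,
       res = 0.09,                       # raster resolution in degrees
       wind_dir_met = 45,                # wind FROM the NE (blows to SW)
       wind_dir_sd = 60,                 # across-slice direction spread, deg
       n_slices = 16L,                   # 3-h samples over two days
       speed_range = c(0.5, 10),         # m/s along-strip speed profile
       speed_periods = 2.5,              # sinusoid periods along the strip
       climate_noise = 0)
}

#' Simulation scenario
#'
#' Bundles everything the generators need: a named migration topology,
#' population sizes and coordinates, locus/allele configuration, drift
#' population size, and landscape geometry. Scenario names:
#' `panmixia` (one gene pool), `island` (all-to-all migration),
#' `stepping_stone` (chain), `barrier` (chain with one severed link and a
#' water gap), `wind_biased` (chain with asymmetric, wind-speed-modulated
#' migration), `environment_driven` (migration decaying with environmental
#' difference), `study_shaped` (15 populations with the published sample
#' sizes and coordinates).
#'
#' @param name scenario name (see above).
#' @param n_pops number of populations (ignored for `study_shaped`).
#' @param sizes sampled individuals per population (scalar or vector).
#' @param n_loci number of microsatellite loci.
#' @param allele_range integer range of allele counts per locus; counts are
#'   drawn uniformly from it (fixed count if both ends equal).
#' @param m total migration rate out of a deme per generation.
#' @param m_up_frac `wind_biased`: upwind migration as a fraction of
#'   downwind.
#' @param barrier_leak `barrier`: migration retained across the severed
#'   link (default 0).
#' @param d_scale,tau `environment_driven`: distance decay (meters) and
#'   environmental-difference decay of migration.
#' @param N_e drift population size per deme (gene-copy draws are `2 N_e`).
#' @param generations forward generations simulated.
#' @param missing_rate fraction of genotype calls dropped as missing.
#' @param geometry list of landscape parameters; see `default_geometry` in
#'   the sources. Defaults give a 6-degree coastal strip at 0.09-degree
#'   resolution with an interior lagoon and NE spring winds.
#' @param seed mandatory integer seed; every generator draw derives from
#'   it.
#' @return object of class `scenario`.
#' @export
scenario <- function(name = c("panmixia", "island", "stepping_stone",
                              "barrier", "wind_biased",
                              "environment_driven", "study_shaped"),
                     n_pops = 15L, sizes = 20L, n_loci = 10L,
                     allele_range = c(7L, 17L), m = 0.05,
                     m_up_frac = 0.1, barrier_leak = 0,
                     d_scale = 2e5, tau = 1, N_e = 100L,
                     generations = 200L, missing_rate = 0,
                     geometry = list(), seed) {
  name <- match.arg(name)
  if (missing(seed)) stop("a seed is mandatory for every scenario")
  geo <- default_geometry()
  if (name == "wind_biased")
    # corridor/barrier wind zones with a diurnal breeze reversal: one
    # zonal cycle along the strip, near-uniform speeds, modest direction
    # noise so the zones persist across slices
    geo <- utils::modifyList(geo, list(wind_dir_sd = 15, speed_periods = 1,
                                       speed_range = c(4, 6)))
  geo <- utils::modifyList(geo, geometry)
  if (name == "study_shaped") {
    tab <- study_populations()
    n_pops <- nrow(tab)
    sizes <- tab$n
    coords <- tab[, c("pop", "lon", "lat")]
    geo$lon0 <- -55.6; geo$lon1 <- -48.2
    geo$lat0 <- -33.4; geo$lat1 <- -28.0
  } else {
    n_pops <- as.integer(n_pops)
    sizes <- rep_len(as.integer(sizes), n_pops)
    xs <- seq(geo$lon0 + 0.3, geo$lon1 - 0.3, length.out = n_pops)
    coords <- data.frame(pop = sprintf("P%02d", seq_len(n_pops)),
                         lon = xs, lat = rep(geo$lat0 + 0.25, n_pops))
  }
  if (any(sizes < 1L)) stop("population sizes must be >= 1")
  if (m < 0 || m > 1) stop("migration rate must lie in [0, 1]")
  # chain order along the main geographic axis
  pc <- project_coordinates(coords)
  ax <- stats::prcomp(cbind(pc$x, pc$y))$x[, 1]
  chain_order <- order(ax)
  # deterministic per-population environment values and wind speeds
  set.seed(as.integer(seed) + 1000L)
  env <- stats::setNames(stats::runif(n_pops, 0, 10), coords$pop)
  sp <- geo$speed_range
  wind_speed <- sp[1] + (sp[2] - sp[1]) *
    (0.5 + 0.5 * sin(2 * pi * (coords$lon - geo$lon0) /
                       (geo$lon1 - geo$lon0) * geo$speed_periods))
  structure(list(name = name, n_pops = n_pops, sizes = sizes,
                 n_loci = as.integer(n_loci),
                 allele_range = as.integer(rep_len(allele_range, 2L)),
                 m = m, m_up_frac = m_up_frac, barrier_leak = barrier_leak,
                 d_scale = d_scale, tau = tau, N_e = as.integer(N_e),
                 generations = as.integer(generations),
                 missing_rate = missing_rate, geometry = geo,
                 coords = coords, chain_order = chain_order,
                 env = env, wind_speed = stats::setNames(wind_speed,
                                                         coords$pop),
                 seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %d populations (%d individuals), %d loci, seed %d\n",
              x$name, x$n_pops, sum(x$sizes), x$n_loci, x$seed))
  invisible(x)
}

# Backward migration matrix: row i gives the origin fractions of deme i's
# gene pool each generation (rows sum to 1).
migration_matrix <- function(s) {
  K <- s$n_pops
  B <- diag(K)
  ord <- s$chain_order
  link <- function(a, b, rate) {          # deme a receives from deme b
    B[a, b] <<- B[a, b] + rate
  }
  chain_links <- function(rate_fun) {
    for (k in seq_len(K - 1L)) {
      lo <- ord[k]; hi <- ord[k + 1L]
      r <- rate_fun(k)
      link(lo, hi, r[1])                  # into lower-index-end deme
      link(hi, lo, r[2])
    }
  }
  if (s$name == "panmixia") {
    B <- matrix(1 / K, K, K)
  } else if (s$name == "island") {
    B <- matrix(s$m / (K - 1L), K, K)
    diag(B) <- 1 - s$m
  } else if (s$name %in% c("stepping_stone", "study_shaped")) {
    chain_links(function(k) c(s$m / 2, s$m / 2))
  } else if (s$name == "barrier") {
    cut <- floor(K / 2)
    chain_links(function(k)
      if (k == cut) rep(s$m / 2 * s$barrier_leak, 2) else rep(s$m / 2, 2))
  } else if (s$name == "wind_biased") {
    # dispersal follows the wind field: the backward migration rate into
    # deme i from deme j is proportional to the inverse of the j -> i
    # wind cost over the scenario's own wind field, so connectivity (and
    # hence differentiation) tracks wind, not plain distance
    land <- simulate_landscape(s)
    wc <- suppressWarnings(wind_cost_matrix(land$wind, land$nodes))
    W <- 1 / unclass(wc$symmetric)^3       # steep wind-connectivity kernel
    diag(W) <- 0
    W[!is.finite(W)] <- 0
    B <- W / rowSums(W) * s$m
    diag(B) <- 1 - s$m
  } else if (s$name == "environment_driven") {
    pc <- project_coordinates(s$coords)
    D <- as.matrix(stats::dist(cbind(pc$x, pc$y)))
    Ed <- abs(outer(s$env, s$env, "-"))
    Wt <- exp(-D / s$d_scale - Ed / s$tau)
    diag(Wt) <- 0
    B <- Wt / rowSums(Wt) * s$m
    diag(B) <- 1 - s$m
  }
  if (s$name %in% c("stepping_stone", "study_shaped", "barrier",
                    "wind_biased")) {
    out <- rowSums(B) - diag(B)
    if (any(out > 1))
      stop("total migration out of a deme exceeds 1")
    diag(B) <- 1 - out
  }
  if (any(B < 0) || any(abs(rowSums(B) - 1) > 1e-12))
    stop("invalid migration matrix (rows must be probabilities summing to 1)")
  B
}

#' Forward drift-migration simulation of allele frequencies
#'
#' Per locus, allele frequencies start from a shared ancestral Dirichlet(1)
#' draw and evolve for `generations` rounds of deterministic migration
#' (`p_i' = sum_j B_ij p_j` with the scenario's backward migration matrix
#' `B`) followed by binomial drift (multinomial resampling of `2 N_e` gene
#' copies per deme).
#'
#' @param s a [scenario()].
#' @return list of class `freq_sim`: `freqs` (per locus, populations x
#'   alleles frequency matrix at the final generation), `B` (migration
#'   matrix), `scenario`.
#' @export
simulate_allele_frequencies <- function(s) {
  B <- migration_matrix(s)
  set.seed(s$seed)
  k_locus <- if (s$allele_range[1] == s$allele_range[2])
    rep(s$allele_range[1], s$n_loci)
  else
    sample(seq.int(s$allele_range[1], s$allele_range[2]), s$n_loci,
           replace = TRUE)
  freqs <- vector("list", s$n_loci)
  for (l in seq_len(s$n_loci)) {
    anc <- stats::rgamma(k_locus[l], 1)
    anc <- anc / sum(anc)
    P <- matrix(anc, s$n_pops, k_locus[l], byrow = TRUE)
    for (gen in seq_len(s$generations)) {
      P <- B %*% P
      for (i in seq_len(s$n_pops)) {
        cnt <- stats::rmultinom(1, 2L * s$N_e, P[i, ])
        P[i, ] <- cnt / (2 * s$N_e)
      }
    }
    rownames(P) <- s$coords$pop
    freqs[[l]] <- P
  }
  structure(list(freqs = freqs, B = B, scenario = s), class = "freq_sim")
}

#' Sample diploid genotypes from simulated frequencies
#'
#' Draws two gene copies per individual and locus from the deme's final
#' allele frequencies (Hardy-Weinberg sampling within demes), assigns
#' allele sizes on a 2-bp ladder starting at 100 bp, drops calls at the
#' scenario's `missing_rate`, and attaches the scenario coordinates.
#'
#' @param sim a `freq_sim` from [simulate_allele_frequencies()].
#' @param seed integer seed for the sampling stage (defaults to the
#'   scenario seed + 1).
#' @return list with `genotypes` ([genotype_matrix]) and `map`
#'   ([population_map] with coordinates).
#' @export
sample_genotypes <- function(sim, seed = sim$scenario$seed + 1L) {
  s <- sim$scenario
  set.seed(seed)
  ids <- unlist(lapply(seq_len(s$n_pops), function(i)
    sprintf("%s_%03d", s$coords$pop[i], seq_len(s$sizes[i]))))
  n <- sum(s$sizes)
  arr <- array(0L, dim = c(n, s$n_loci, 2L))
  row0 <- cumsum(c(0L, s$sizes))
  for (l in seq_len(s$n_loci)) {
    P <- sim$freqs[[l]]
    k <- ncol(P)
    sizes_bp <- 100L + 2L * (seq_len(k) - 1L)
    for (i in seq_len(s$n_pops)) {
      ni <- s$sizes[i]
      draws <- sample.int(k, 2L * ni, replace = TRUE, prob = P[i, ])
      a <- matrix(sizes_bp[draws], ncol = 2L)
      if (s$missing_rate > 0) {
        drop <- stats::runif(ni) < s$missing_rate
        a[drop, ] <- 0L
      }
      arr[(row0[i] + 1L):row0[i + 1L], l, ] <- a
    }
  }
  g <- genotype_matrix(arr, ids, sprintf("loc%02d", seq_len(s$n_loci)))
  assign <- stats::setNames(rep(s$coords$pop, s$sizes), ids)
  m <- population_map(assign, coords = s$coords,
                      population_ids = s$coords$pop)
  list(genotypes = g, map = m)
}

#' Generate the scenario landscape: land/water mask, wind field, climate
#'
#' Builds a rectangular coastal strip with an elongated interior water body
#' (a synthetic lagoon; for the `barrier` scenario the water band cuts the
#' strip completely at the severed chain link), a time series of wind
#' slices with the scenario's mean direction, an along-strip speed profile
#' and per-slice noise, and a climate surface (linear along-strip gradient,
#' or a population-value mosaic for `environment_driven`). Cells containing
#' populations (plus one cell of buffer) are always kept as land.
#'
#' @param s a [scenario()].
#' @return list with `land_mask` (1 = land, 0 = water [raster_grid]),
#'   `wind` ([wind_field]), `climate` ([raster_grid]), `nodes` (data frame
#'   `pop`, `lon`, `lat`).
#' @export
simulate_landscape <- function(s) {
  geo <- s$geometry
  set.seed(s$seed + 2000L)
  nc <- ceiling((geo$lon1 - geo$lon0) / geo$res)
  nr <- ceiling((geo$lat1 - geo$lat0) / geo$res)
  mask <- raster_grid(matrix(1, nr, nc), geo$lon0, geo$lat0, geo$res)
  ctr_lon <- geo$lon0 + (seq_len(nc) - 0.5) * geo$res
  ctr_lat <- geo$lat0 + (nr - seq_len(nr) + 0.5) * geo$res
  lon_g <- matrix(ctr_lon, nr, nc, byrow = TRUE)
  lat_g <- matrix(ctr_lat, nr, nc)
  if (s$name == "barrier") {
    # full-height water band at the severed link
    ord <- s$chain_order
    cut <- floor(s$n_pops / 2)
    xcut <- mean(s$coords$lon[ord][c(cut, cut + 1L)])
    water <- abs(lon_g - xcut) < 1.2 * geo$res
  } else if (s$name == "study_shaped") {
    # synthetic stand-in for the big coastal lagoon: an elongated water
    # body between the west-shore and coastal populations, holding none of
    # the sampling sites
    water <- lon_g > -51.4 & lon_g < -50.95 & lat_g > -31.5 & lat_g < -30.5
  } else {
    # elongated interior lagoon along the strip axis
    lon_mid <- (geo$lon0 + geo$lon1) / 2
    lat_mid <- (geo$lat0 + geo$lat1) / 2
    water <- abs(lon_g - lon_mid) < (geo$lon1 - geo$lon0) / 6 &
      abs(lat_g - lat_mid) < (geo$lat1 - geo$lat0) / 6
  }
  v <- mask$values
  v[water] <- 0
  # keep population cells (3x3 buffer) on land
  rc <- cell_of(mask, s$coords$lon, s$coords$lat)
  for (q in seq_len(nrow(rc))) {
    ri <- pmax(1L, rc[q, 1] - 1L):pmin(nr, rc[q, 1] + 1L)
    cj <- pmax(1L, rc[q, 2] - 1L):pmin(nc, rc[q, 2] + 1L)
    if (s$name != "barrier") v[ri, cj] <- 1
  }
  mask$values <- v
  # wind slices: common meteorological direction + noise, along-strip
  # speed profile + noise
  sp <- geo$speed_range
  speed_prof <- sp[1] + (sp[2] - sp[1]) *
    (0.5 + 0.5 * sin(2 * pi * (lon_g - geo$lon0) /
                       (geo$lon1 - geo$lon0) * geo$speed_periods))
  # mean direction surface: constant for most scenarios; for wind_biased,
  # zones of along-strip flow (corridors) alternate with cross-strip flow
  # (barriers), a pattern distance alone cannot reproduce
  dir_mean <- if (s$name == "wind_biased") {
    zone <- (1 + sin(2 * pi * (lon_g - geo$lon0) /
                       (geo$lon1 - geo$lon0) * geo$speed_periods)) / 2
    geo$wind_dir_met * zone                # 45 deg corridor <-> 0 deg barrier
  } else {
    matrix(geo$wind_dir_met, nr, nc)
  }
  slices <- lapply(seq_len(geo$n_slices), function(t) {
    dir0 <- stats::rnorm(1, 0, geo$wind_dir_sd)
    # wind_biased emulates a diurnal sea-breeze cycle: alternate slices
    # reverse the flow, so corridors are travelled in both directions over
    # a day while cross-wind zones stay barriers
    flip <- if (s$name == "wind_biased" && t %% 2L == 0L) 180 else 0
    dir <- (dir_mean + dir0 + flip +
              matrix(stats::rnorm(nr * nc, 0, geo$wind_dir_sd / 2),
                     nr, nc)) %% 360
    spd <- pmax(speed_prof + matrix(stats::rnorm(nr * nc, 0, 0.3), nr, nc), 0)
    list(speed = raster_grid(spd, geo$lon0, geo$lat0, geo$res),
         direction = raster_grid(dir, geo$lon0, geo$lat0, geo$res))
  })
  # climate surface
  clim <- if (s$name == "environment_driven") {
    rcp <- cell_of(mask, s$coords$lon, s$coords$lat)
    nearest <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      d2 <- (rcp[, 1] - i)^2 + (rcp[, 2] - j)^2
      nearest[i, j] <- s$env[which.min(d2)]
    }
    nearest
  } else {
    10 + 5 * (lon_g - geo$lon0) / (geo$lon1 - geo$lon0)
  }
  if (geo$climate_noise > 0)
    clim <- clim + matrix(stats::rnorm(nr * nc, 0, geo$climate_noise), nr, nc)
  list(land_mask = mask,
       wind = wind_field(slices),
       climate = raster_grid(clim, geo$lon0, geo$lat0, geo$res),
       nodes = s$coords)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: simulates allele frequencies, samples genotypes and
#' builds the matching landscape for one scenario.
#'
#' @param s a [scenario()].
#' @return list with `genotypes`, `map`, `land_mask`, `wind`, `climate`,
#'   `nodes`, `freqs` and `scenario`.
#' @export
simulate_dataset <- function(s) {
  sim <- simulate_allele_frequencies(s)
  gs <- sample_genotypes(sim)
  land <- simulate_landscape(s)
  c(gs, land, list(freqs = sim$freqs, scenario = s))
}
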