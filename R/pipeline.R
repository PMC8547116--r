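# Config-driven orchestration of the full analysis: diversity -> FST ->
# exploratory structure -> distance/resistance/wind/climate matrices ->
# Mantel/MMRR suite -> tidy report with manifest.

#' Build a pipeline configuration
#'
#' Fills defaults mirroring the analysis' canonical settings (10,000
#' matrix-test permutations, 1000 FIS bootstrap replicates, 10^6
#' Hardy-Weinberg Monte-Carlo draws) and validates referenced paths.
#' Inputs may be file paths (GenePop, CSV, `.asc`) or in-memory package
#' objects, so the pipeline can run on simulated data without touching
#' disk.
#'
#' @param config named list (or path to a YAML file holding one) with any
#'   of: `genotypes` (GenePop path or `list(genotypes=, map=)`), `coords`
#'   (CSV path or data frame `pop/lon/lat`), `mask` (`.asc` path or
#'   [raster_grid]), `climate` (named list of `.asc` paths or rasters),
#'   `wind` (a [wind_field] or `list(speed_glob=, dir_glob=)`, slices
#'   paired by sorted filename), `out_dir`, `stages` (named logical:
#'   diversity, hwe, ld, fst, dapc, spca, matrices, mmrr), `n_perm`,
#'   `n_boot`, `hwe_steps`, `ld_perm`, `seed`, `snap`, `rarefaction`
#'   (`"auto"` or gene count), `repeat_unit`.
#' @return validated config of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(
    genotypes = NULL, coords = NULL, mask = NULL, climate = list(),
    wind = NULL, out_dir = "landgen_run",
    stages = list(),
    n_perm = 10000L, n_boot = 1000L, hwe_steps = 1e6, ld_perm = 1000L,
    seed = 1L, snap = FALSE, rarefaction = "auto", repeat_unit = 2L)
  cfg <- utils::modifyList(defaults, config)
  stage_defaults <- list(load = TRUE, diversity = TRUE, hwe = TRUE, ld = TRUE,
                         fst = TRUE, dapc = TRUE, spca = TRUE,
                         matrices = TRUE, mmrr = TRUE)
  cfg$stages <- utils::modifyList(stage_defaults, as.list(cfg$stages))
  for (f in c("genotypes", "coords", "mask")) {
    v <- cfg[[f]]
    if (is.character(v) && !file.exists(v))
      stop("config ", f, " path does not exist: ", v)
  }
  if (is.null(cfg$genotypes)) stop("config must provide genotypes")
  class(cfg) <- "run_config"
  cfg
}

load_inputs <- function(cfg) {
  gm <- if (is.character(cfg$genotypes)) read_genepop(cfg$genotypes)
        else cfg$genotypes
  g <- gm$genotypes; m <- gm$map
  if (!is.null(cfg$coords)) {
    coords <- if (is.character(cfg$coords)) read_population_coords(cfg$coords)
              else as.data.frame(cfg$coords)
    m <- population_map(m$assignment, coords = coords,
                        population_ids = m$population_ids)
  }
  mask <- if (is.null(cfg$mask)) NULL
          else if (is.character(cfg$mask)) read_ascii_raster(cfg$mask)
          else cfg$mask
  climate <- lapply(cfg$climate, function(x)
    if (is.character(x)) read_ascii_raster(x) else x)
  wind <- cfg$wind
  if (!is.null(wind) && !inherits(wind, "wind_field")) {
    sp <- sort(Sys.glob(wind$speed_glob))
    dr <- sort(Sys.glob(wind$dir_glob))
    if (length(sp) != length(dr) || !length(sp))
      stop("wind speed/direction file globs do not pair up")
    wind <- wind_field(Map(function(a, b)
      list(speed = read_ascii_raster(a), direction = read_ascii_raster(b)),
      sp, dr))
  }
  list(g = g, m = m, mask = mask, climate = climate, wind = wind)
}

#' Run the full landscape-genetics pipeline
#'
#' Executes the enabled stages in dependency order, writes one CSV per
#' result table into the output directory, and finishes with a structured
#' log and a JSON manifest carrying the package version, the seeds used by
#' every stage, per-stage status and timing, and MD5 hashes of every
#' output, so a re-run with the same config and seed is byte-identical and
#' verifiable. A failing stage is recorded and its dependents are skipped
#' with a reason; the function then signals an error after writing the
#' manifest.
#'
#' @param cfg a [run_config()] (or bare list passed through it).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  mat_dir <- file.path(cfg$out_dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  manifest <- list(package = "landgen",
                   version = as.character(utils::packageVersion("landgen")),
                   seed = cfg$seed, stages = list(), outputs = list())
  log_lines <- character()
  note <- function(stage, status, elapsed, seed, msg = "") {
    manifest$stages[[stage]] <<- list(status = status,
                                      elapsed_s = round(elapsed, 3),
                                      seed = seed, message = msg)
    log_lines <<- c(log_lines,
                    sprintf("stage=%s status=%s seed=%d elapsed=%.2fs %s",
                            stage, status, seed, elapsed, msg))
  }
  results <- new.env()
  run_stage <- function(stage, seed, deps = character(), fun) {
    if (!isTRUE(cfg$stages[[stage]])) {
      note(stage, "disabled", 0, seed); return(invisible())
    }
    failed_dep <- deps[!vapply(deps, function(d)
      identical(manifest$stages[[d]]$status, "ok"), logical(1))]
    if (length(failed_dep)) {
      note(stage, "skipped", 0, seed,
           paste("dependency not satisfied:", paste(failed_dep, collapse = ",")))
      return(invisible())
    }
    t0 <- proc.time()[3]
    ok <- tryCatch({ fun(seed); TRUE },
                   error = function(e) { note(stage, "failed",
                                              proc.time()[3] - t0, seed,
                                              conditionMessage(e)); FALSE })
    if (ok) note(stage, "ok", proc.time()[3] - t0, seed)
  }
  out_csv <- function(df, name, dir = cfg$out_dir) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  seed0 <- as.integer(cfg$seed)

  run_stage("load", seed0, fun = function(seed) {
    inp <- load_inputs(cfg)
    rep <- validate_dataset(inp$g, inp$m)
    for (f in rep$flags) log_lines <<- c(log_lines, paste("flag:", f))
    list2env(inp, results)
  })

  run_stage("diversity", seed0 + 1L, deps = "load", fun = function(seed) {
    gg <- if (identical(cfg$rarefaction, "auto")) NULL else cfg$rarefaction
    out_csv(diversity_table(results$g, results$m, g_genes = gg,
                            repeat_unit = cfg$repeat_unit,
                            n_boot = cfg$n_boot, seed = seed),
            "diversity.csv")
  })
  run_stage("hwe", seed0 + 2L, deps = "load", fun = function(seed) {
    out_csv(hwe_exact_test(results$g, results$m, n_steps = cfg$hwe_steps,
                           seed = seed), "hwe.csv")
  })
  run_stage("ld", seed0 + 3L, deps = "load", fun = function(seed) {
    out_csv(ld_permutation_test(results$g, results$m,
                                n_perm = cfg$ld_perm, seed = seed),
            "ld.csv")
  })
  run_stage("fst", seed0 + 4L, deps = "load", fun = function(seed) {
    f <- pairwise_fst(results$g, results$m)
    results$fst <- f
    write_pairwise_csv(f$fst, file.path(cfg$out_dir, "fst.csv"))
    write_pairwise_csv(linearize_fst(f),
                       file.path(cfg$out_dir, "fst_linearized.csv"))
  })
  run_stage("dapc", seed0 + 5L, deps = "load", fun = function(seed) {
    k_max <- min(10L, length(results$m$population_ids))
    dd <- dapc(results$g, results$m, k_range = seq_len(k_max), seed = seed)
    out_csv(dd$bic, "dapc_bic.csv")
    out_csv(data.frame(individual = results$g$individual_ids,
                       cluster = as.integer(dd$assignments)),
            "dapc_assignments.csv")
  })
  run_stage("spca", seed0 + 6L, deps = "load", fun = function(seed) {
    n <- n_individuals(results$g)
    k <- min(5L, n - 1L)
    sres <- NULL
    while (is.null(sres)) {                 # grow k until network connects
      sres <- tryCatch(spca(results$g, results$m, network = "knn", k = k,
                            seed = seed),
                       error = function(e) {
                         if (2L * k >= n) stop(e)
                         NULL
                       })
      if (is.null(sres)) {
        log_lines <<- c(log_lines,
                        sprintf("spca: knn k=%d disconnected, doubling", k))
        k <- min(2L * k, n - 1L)
      }
    }
    tst <- spca_global_local_tests(sres, n_perm = min(cfg$n_perm, 999L),
                                   seed = seed)
    out_csv(data.frame(axis = seq_along(sres$eigenvalues),
                       eigenvalue = sres$eigenvalues, variance = sres$var,
                       moran_i = sres$moran), "spca_eigenvalues.csv")
    out_csv(data.frame(test = c("global", "local"),
                       statistic = c(tst$global_stat, tst$local_stat),
                       p_value = c(tst$global_p, tst$local_p),
                       n_perm = tst$n_perm, seed = tst$seed),
            "spca_tests.csv")
  })
  run_stage("matrices", seed0 + 7L, deps = "load", fun = function(seed) {
    m <- results$m
    if (is.null(m$coords)) stop("matrices stage needs population coordinates")
    nodes <- m$coords
    pc <- project_coordinates(m)
    geo <- euclidean_distance_matrix(pc)
    results$geo <- geo
    write_pairwise_csv(geo, file.path(mat_dir, "geo.csv"))
    results$resist <- list()
    if (!is.null(results$mask)) {
      for (model in c("continuous", "water_bodies")) {
        r <- build_resistance_raster(model, results$mask)
        cm <- least_cost_matrix(r, nodes, snap = cfg$snap)
        results$resist[[model]] <- cm
        write_pairwise_csv(cm, file.path(mat_dir,
                                         paste0("resistance_", model, ".csv")))
      }
    }
    results$clim <- list()
    for (nm in names(results$climate)) {
      vals <- extract_climate(results$climate[[nm]], nodes)
      cd <- climate_dissimilarity(vals)
      results$clim[[nm]] <- cd
      write_pairwise_csv(cd, file.path(mat_dir, paste0("climate_", nm, ".csv")))
    }
    if (!is.null(results$wind)) {
      wc <- wind_cost_matrix(results$wind, nodes, snap = cfg$snap)
      results$wind_cost <- wc
      write_pairwise_csv(wc$asymmetric, file.path(mat_dir, "wind_cost.csv"))
      write_pairwise_csv(wc$symmetric, file.path(mat_dir, "wind_cost_sym.csv"))
    }
  })
  run_stage("mmrr", seed0 + 8L, deps = c("fst", "matrices"),
            fun = function(seed) {
    out_csv(ibd_ibe_suite(results$fst, results$geo,
                          resist = results$resist,
                          clim = results$clim,
                          wind = if (!is.null(results$wind_cost))
                            results$wind_cost$symmetric,
                          n_perm = cfg$n_perm, seed = seed),
            "mmrr_report.csv")
  })

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% c("manifest.json", "log.txt")]
  hashes <- tools::md5sum(files)
  manifest$outputs <- as.list(stats::setNames(unname(hashes),
    sub(paste0("^", cfg$out_dir, "/?"), "", files)))
  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  failed <- names(Filter(function(s) identical(s$status, "failed"),
                         manifest$stages))
  if (length(failed))
    stop("pipeline stage(s) failed: ", paste(failed, collapse = ", "))
  invisible(manifest)
}
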