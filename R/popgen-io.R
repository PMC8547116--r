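# Domain containers and file formats: diploid genotype matrices (GenePop
# dialect), population maps, pairwise matrices (CSV) and ESRI ASCII rasters.

MISSING_ALLELE <- 0L

#' Diploid genotype matrix
#'
#' Container for codominant allele-size calls: one integer pair per
#' individual and locus, with 0 as the missing sentinel. This is the object
#' every genetic statistic in the package consumes.
#'
#' @param calls integer array of dimension `n_individuals x n_loci x 2`
#'   holding allele sizes in base pairs; 0 marks a missing gene copy. Both
#'   gene copies of a call must be missing or both present.
#' @param individual_ids character vector of unique individual identifiers.
#' @param locus_names character vector of unique locus names.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individual_ids, locus_names) {
  calls <- array(as.integer(calls), dim = dim(calls))
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L)
    stop("`calls` must be an n_individuals x n_loci x 2 array")
  if (dim(calls)[1] != length(individual_ids))
    stop("individual_ids length does not match calls")
  if (dim(calls)[2] != length(locus_names))
    stop("locus_names length does not match calls")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(locus_names))
    stop("duplicate locus names")
  if (any(calls < 0L, na.rm = TRUE) || anyNA(calls))
    stop("allele sizes must be non-negative integers (0 = missing)")
  half <- xor(calls[, , 1, drop = FALSE] == MISSING_ALLELE,
              calls[, , 2, drop = FALSE] == MISSING_ALLELE)
  if (any(half))
    stop("half-missing calls: both gene copies of a call must be missing or present")
  dimnames(calls) <- list(individual_ids, locus_names, c("a1", "a2"))
  structure(list(calls = calls,
                 individual_ids = as.character(individual_ids),
                 locus_names = as.character(locus_names)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(x$calls[, , 1] == MISSING_ALLELE)
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing calls)\n",
              length(x$individual_ids), length(x$locus_names),
              100 * n_miss / (length(x$individual_ids) * length(x$locus_names))))
  invisible(x)
}

n_individuals <- function(g) length(g$individual_ids)
n_loci <- function(g) length(g$locus_names)

#' Population map
#'
#' Assignment of individuals to populations plus population coordinates in
#' decimal degrees. Coordinates may be omitted for purely genetic analyses.
#'
#' @param assignment named character vector: names are individual ids,
#'   values are population ids.
#' @param coords optional data frame with columns `pop`, `lon`, `lat`
#'   (longitude/latitude in decimal degrees, WGS-type).
#' @param population_ids optional explicit ordering of population ids;
#'   defaults to order of first appearance in `assignment`.
#' @return An object of class `population_map`.
#' @export
population_map <- function(assignment, coords = NULL, population_ids = NULL) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("`assignment` must be named by unique individual ids")
  assignment <- vapply(assignment, as.character, character(1))
  if (is.null(population_ids))
    population_ids <- unique(unname(assignment))
  population_ids <- as.character(population_ids)
  if (!all(assignment %in% population_ids))
    stop("assignment refers to populations missing from population_ids")
  if (!all(population_ids %in% assignment))
    stop("empty population(s): ",
         paste(setdiff(population_ids, assignment), collapse = ", "))
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    need <- c("pop", "lon", "lat")
    if (!all(need %in% names(coords)))
      stop("coords must have columns pop, lon, lat")
    coords$pop <- as.character(coords$pop)
    if (!all(population_ids %in% coords$pop))
      stop("coords missing populations: ",
           paste(setdiff(population_ids, coords$pop), collapse = ", "))
    coords <- coords[match(population_ids, coords$pop), need, drop = FALSE]
    rownames(coords) <- NULL
    if (any(abs(coords$lat) > 90, na.rm = TRUE))
      stop("latitudes must lie in [-90, 90]")
    if (any(abs(coords$lon) > 180, na.rm = TRUE))
      stop("longitudes must lie in [-180, 180]")
  }
  structure(list(population_ids = population_ids,
                 assignment = assignment,
                 coords = coords),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat(sprintf("population_map: %d individuals in %d populations%s\n",
              length(x$assignment), length(x$population_ids),
              if (is.null(x$coords)) " (no coordinates)" else ""))
  invisible(x)
}

# individuals of population `pop`, in genotype order
pop_index <- function(g, m, pop) {
  which(m$assignment[g$individual_ids] == pop)
}

#' Pairwise population matrix
#'
#' Square labelled matrix of pairwise quantities (FST, distances, costs).
#' Symmetric by default; wind cost matrices are asymmetric.
#'
#' @param values square numeric matrix.
#' @param labels population ids (defaults to rownames of `values`).
#' @param symmetric logical flag; if `TRUE` the matrix must equal its
#'   transpose exactly.
#' @return An object of class `pairwise_matrix` (a matrix with attributes).
#' @export
pairwise_matrix <- function(values, labels = rownames(values), symmetric = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("values must be square")
  if (is.null(labels)) stop("labels required")
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) stop("labels length mismatch")
  if (any(diag(values) != 0, na.rm = TRUE))
    stop("diagonal of a pairwise matrix must be 0")
  if (symmetric && !identical(unname(values), unname(t(values))))
    stop("matrix flagged symmetric but values[i,j] != values[j,i]")
  dimnames(values) <- list(labels, labels)
  structure(values, symmetric = symmetric, class = c("pairwise_matrix", "matrix"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix (%s), %d populations\n",
              if (attr(x, "symmetric")) "symmetric" else "asymmetric", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Georeferenced raster grid
#'
#' Row-major cell grid in geographic coordinates; row 1 is the northernmost
#' row (the ESRI ASCII convention). Nodata cells are stored as `NA`.
#'
#' @param values numeric matrix `n_rows x n_cols`; `NA` marks nodata.
#' @param x_llcorner,y_llcorner lower-left corner, decimal degrees.
#' @param cell_size cell edge, decimal degrees (> 0).
#' @param nodata_value sentinel written to/parsed from `.asc` files.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, x_llcorner, y_llcorner, cell_size,
                        nodata_value = -9999) {
  values <- as.matrix(values)
  if (cell_size <= 0) stop("cell_size must be > 0")
  structure(list(values = values,
                 n_rows = nrow(values), n_cols = ncol(values),
                 x_llcorner = x_llcorner, y_llcorner = y_llcorner,
                 cell_size = cell_size, nodata_value = nodata_value),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells of %g deg, origin (%g, %g), %d nodata\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_llcorner, x$y_llcorner,
              sum(is.na(x$values))))
  invisible(x)
}

# centre coordinates (lon, lat) of cell (row i from north, col j)
cell_center <- function(r, i, j) {
  cbind(lon = r$x_llcorner + (j - 0.5) * r$cell_size,
        lat = r$y_llcorner + (r$n_rows - i + 0.5) * r$cell_size)
}

# (row, col) of the cell containing lon/lat points; error if outside extent
cell_of <- function(r, lon, lat) {
  j <- floor((lon - r$x_llcorner) / r$cell_size) + 1L
  i <- r$n_rows - floor((lat - r$y_llcorner) / r$cell_size)
  bad <- j < 1L | j > r$n_cols | i < 1L | i > r$n_rows
  if (any(bad))
    stop("point(s) outside raster extent: ",
         paste(which(bad), collapse = ", "))
  cbind(row = as.integer(i), col = as.integer(j))
}

## ---- GenePop -------------------------------------------------------------

#' Read a GenePop genotype file
#'
#' Parses the 3-digit-per-allele GenePop dialect: a title line, one locus
#' name per line (or a single comma-separated line), `POP` separators, and
#' `id , 003005 ...` genotype rows. `000000` is a missing call. Two-digit
#' files are rejected.
#'
#' Population ids are recovered from the individual ids when every id in a
#' block shares the same `_`-prefix (the convention [write_genepop()] uses);
#' otherwise blocks are named `pop_1`, `pop_2`, ... in file order.
#'
#' @param path path to a GenePop text file.
#' @return list with elements `genotypes` ([genotype_matrix]) and
#'   `map` ([population_map], without coordinates).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("GenePop file too short: ", path)
  body <- lines[-1]                      # drop title
  is_pop <- toupper(trimws(body)) %in% c("POP")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found in ", path)
  locus_lines <- trimws(body[seq_len(first_pop - 1L)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("duplicate locus names in ", path)

  ids <- character(); pops_of <- integer()
  calls <- list()
  cur_pop <- 0L
  for (k in seq.int(first_pop, length(body))) {
    line <- body[k]
    if (toupper(trimws(line)) == "POP") { cur_pop <- cur_pop + 1L; next }
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L)
      stop("malformed genotype row (no comma) at line ", k + 1L, " of ", path)
    id <- trimws(parts[1])
    fields <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
    if (length(fields) != length(loci))
      stop("line ", k + 1L, " of ", path, ": expected ", length(loci),
           " genotype fields, found ", length(fields))
    nch <- nchar(fields)
    if (any(nch == 4L))
      stop("2-digit-per-allele coding detected at line ", k + 1L, " of ",
           path, "; only the 3-digit dialect is supported")
    if (any(nch != 6L))
      stop("malformed allele field '", fields[which(nch != 6L)[1]],
           "' at line ", k + 1L, " of ", path)
    a1 <- as.integer(substr(fields, 1L, 3L))
    a2 <- as.integer(substr(fields, 4L, 6L))
    if (anyNA(a1) || anyNA(a2))
      stop("non-numeric allele field at line ", k + 1L, " of ", path)
    miss <- a1 == 0L | a2 == 0L          # half-missing collapses to missing
    a1[miss] <- MISSING_ALLELE; a2[miss] <- MISSING_ALLELE
    ids <- c(ids, id)
    pops_of <- c(pops_of, cur_pop)
    calls[[length(calls) + 1L]] <- rbind(a1, a2)
  }
  if (anyDuplicated(ids))
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(ids); L <- length(loci)
  arr <- array(0L, dim = c(n, L, 2L))
  for (i in seq_len(n)) {
    arr[i, , 1L] <- calls[[i]][1L, ]
    arr[i, , 2L] <- calls[[i]][2L, ]
  }
  # population labels: shared id prefix before "_" if consistent per block
  pop_names <- vapply(seq_len(max(pops_of)), function(p) {
    pref <- sub("_[^_]*$", "", ids[pops_of == p])
    if (length(unique(pref)) == 1L && pref[1] != ids[pops_of == p][1])
      pref[1] else paste0("pop_", p)
  }, character(1))
  if (anyDuplicated(pop_names))
    pop_names <- paste0("pop_", seq_along(pop_names))
  g <- genotype_matrix(arr, ids, loci)
  m <- population_map(stats::setNames(pop_names[pops_of], ids),
                      population_ids = pop_names)
  list(genotypes = g, map = m)
}

#' Write a GenePop genotype file
#'
#' Emits the 3-digit-per-allele dialect. Individuals are grouped by
#' population (in `map$population_ids` order) and written as
#' `<pop>_<id> , 003005 ...` so that [read_genepop()] recovers the
#' population labels.
#'
#' @param g a [genotype_matrix].
#' @param map a [population_map] covering all individuals of `g`.
#' @param path output file path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, map, path, title = "landgen export") {
  if (any(g$calls > 999L))
    stop("allele sizes exceed 999 and cannot be 3-digit coded")
  out <- c(title, g$locus_names)
  for (p in map$population_ids) {
    out <- c(out, "POP")
    for (i in pop_index(g, map, p)) {
      fields <- sprintf("%03d%03d", g$calls[i, , 1L], g$calls[i, , 2L])
      id <- g$individual_ids[i]
      if (!startsWith(id, paste0(p, "_"))) id <- paste0(p, "_", id)
      out <- c(out, paste(id, ",", paste(fields, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

## ---- ESRI ASCII raster ---------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file with the standard 6-line header
#'   (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed
#'   by row-major values, first data row northernmost.
#' @return A [raster_grid]; nodata cells are `NA`.
#' @export
read_ascii_raster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("incomplete ESRI ASCII header in ", path)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("value count ", length(vals), " does not match ", nr, "x", nc,
         " header in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with up to 10 significant digits; `NA` cells are
#' written as the raster's nodata value.
#'
#' @param r a [raster_grid].
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- r$nodata_value
  hdr <- c(sprintf("ncols %d", r$n_cols),
           sprintf("nrows %d", r$n_rows),
           sprintf("xllcorner %.10g", r$x_llcorner),
           sprintf("yllcorner %.10g", r$y_llcorner),
           sprintf("cellsize %.10g", r$cell_size),
           sprintf("NODATA_value %.10g", r$nodata_value))
  rows <- apply(v, 1L, function(row) paste(sprintf("%.10g", row), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## ---- pairwise matrix CSV -------------------------------------------------

#' Write a pairwise matrix to CSV
#'
#' First row and column carry the population labels; asymmetric matrices are
#' marked with a leading `# asymmetric` comment line so files are
#' self-describing.
#'
#' @param x a [pairwise_matrix].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pairwise_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!attr(x, "symmetric")) writeLines("# asymmetric", con)
  utils::write.csv(as.data.frame(unclass(x)), con, row.names = TRUE)
  invisible(path)
}

#' Read a pairwise matrix from CSV
#'
#' @param path CSV written by [write_pairwise_csv()].
#' @return A [pairwise_matrix].
#' @export
read_pairwise_csv <- function(path) {
  first <- readLines(path, n = 1L)
  asym <- grepl("^#\\s*asymmetric", first)
  df <- utils::read.csv(path, row.names = 1L, comment.char = "#",
                        check.names = FALSE)
  m <- as.matrix(df)
  pairwise_matrix(m, labels = rownames(m), symmetric = !asym)
}

#' Read population coordinates from CSV
#'
#' @param path CSV with columns `pop`, `lon`, `lat`.
#' @return data frame usable as the `coords` argument of [population_map()].
#' @export
read_population_coords <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pop", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("coordinate CSV must have columns pop, lon, lat")
  df[, need]
}

## ---- validation ----------------------------------------------------------

#' Validate a genotype dataset against its population map
#'
#' Checks structural consistency and summarizes the dataset: per-population
#' sample sizes, per-locus missingness, and monomorphic or empty loci.
#' Structural violations (individuals missing from the map) raise errors;
#' data-quality findings are returned as flags.
#'
#' @param g a [genotype_matrix].
#' @param m a [population_map].
#' @return list with `pop_sizes` (named integer), `locus_missingness`
#'   (named fraction in `[0,1]`), `monomorphic_loci` (character; includes
#'   all-missing loci), and `flags` (character messages).
#' @export
validate_dataset <- function(g, m) {
  missing_ids <- setdiff(g$individual_ids, names(m$assignment))
  if (length(missing_ids))
    stop("individuals absent from population map: ",
         paste(missing_ids, collapse = ", "))
  sizes <- table(factor(m$assignment[g$individual_ids],
                        levels = m$population_ids))
  if (any(sizes == 0L))
    stop("empty population(s): ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  miss <- apply(g$calls[, , 1L, drop = FALSE] == MISSING_ALLELE, 2L, mean)
  names(miss) <- g$locus_names
  mono <- vapply(seq_len(n_loci(g)), function(l) {
    a <- c(g$calls[, l, 1L], g$calls[, l, 2L])
    length(unique(a[a != MISSING_ALLELE])) <= 1L
  }, logical(1))
  flags <- character()
  if (any(miss == 1))
    flags <- c(flags, paste0("locus with all calls missing: ",
                             paste(g$locus_names[miss == 1], collapse = ", ")))
  if (any(mono & miss < 1))
    flags <- c(flags, paste0("monomorphic locus: ",
                             paste(g$locus_names[mono & miss < 1], collapse = ", ")))
  list(pop_sizes = stats::setNames(as.integer(sizes), names(sizes)),
       locus_missingness = miss,
       monomorphic_loci = g$locus_names[mono],
       flags = flags)
}
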