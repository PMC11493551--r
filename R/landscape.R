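#' Habitat classification codes
#'
#' Integer codes used on disk and in memory for the eight broad habitat
#' classes of the simulation landscape.
#'
#' @return named integer vector mapping habitat names to codes 0-7.
#' @export
habitat_codes <- function() {
  c(ocean = 0L, road = 1L, human_habitation = 2L, grassland = 3L,
    woodland = 4L, ephemeral_flowing_water = 5L, non_flowing_water = 6L,
    other = 7L)
}

# disturbed habitats: human-made structures plus standing water created by them
DISTURBED_CODES <- c(1L, 2L, 6L)

#' Construct a landscape from a habitat vector
#'
#' A landscape couples a [build_grid()] geometry with one habitat code per
#' cell and the habitat-derived layers the simulator consumes: freshwater
#' cells (`is_water`, also the breeding sites), rehydration sites (water
#' margins plus human habitation, where moist microhabitat is available),
#' foraging habitat (grassland plus human habitation) and roads.
#'
#' @param grid a [build_grid()] object.
#' @param habitat integer vector of length `grid$n_cells` with values from
#'   [habitat_codes()].
#' @param entry_points named integer vector of cell indices where founders
#'   can be introduced; must lie on terrestrial (non-ocean, non-water) cells.
#' @return an object of class `toad_landscape`.
#' @export
landscape <- function(grid, habitat, entry_points = integer()) {
  stopifnot(inherits(grid, "hex_grid"))
  habitat <- as.integer(habitat)
  if (length(habitat) != grid$n_cells)
    stop_with("habitat vector has %d cells but the grid has %g", length(habitat), grid$n_cells)
  if (anyNA(habitat) || any(habitat < 0L) || any(habitat > 7L))
    stop_with("habitat codes must all be in 0..7")
  is_water <- habitat == 5L | habitat == 6L
  if (length(entry_points) > 0) {
    ep <- as.integer(entry_points)
    if (anyNA(ep) || any(ep < 1L) || any(ep > grid$n_cells))
      stop_with("entry points must be valid cell indices")
    bad <- habitat[ep] == 0L | is_water[ep]
    if (any(bad))
      stop_with("entry point(s) %s lie on ocean/water cells",
                paste(names(entry_points)[bad] %||% which(bad), collapse = ", "))
    entry_points <- stats::setNames(ep, names(entry_points))
  }
  # rehydration: cells next to freshwater (the margins) plus human habitation
  margin <- is_water
  if (any(is_water)) {
    nb <- hex_neighbors(grid, which(is_water))
    nbv <- nb[!is.na(nb)]
    margin[nbv] <- TRUE
  }
  margin <- margin & !is_water & habitat != 0L
  structure(
    list(grid = grid, habitat = habitat,
         is_water = is_water,
         is_breeding = is_water,
         is_rehydration = margin | habitat == 2L,
         is_foraging = habitat == 3L | habitat == 2L,
         is_road = habitat == 1L,
         entry_points = entry_points,
         cache = new.env(parent = emptyenv())),
    class = "toad_landscape")
}

#' @export
print.toad_landscape <- function(x, ...) {
  codes <- habitat_codes()
  tab <- tabulate(x$habitat + 1L, nbins = 8L)
  area_km2 <- tab * cell_area(x$grid) / 1e6
  cat(sprintf("<toad_landscape> %d x %d cells (%g x %g m)\n",
              x$grid$n_cols, x$grid$n_rows, x$grid$width_m, x$grid$height_m))
  for (i in seq_along(codes))
    if (tab[i] > 0) cat(sprintf("  %-24s %10d cells %9.3f km2\n", names(codes)[i], tab[i], area_km2[i]))
  if (length(x$entry_points))
    cat("  entry points:", paste(names(x$entry_points), collapse = ", "), "\n")
  invisible(x)
}

#' Total disturbed-habitat area
#'
#' Area of roads, human habitation and non-flowing (standing) waterbodies,
#' the human-disturbed footprint that characterises entry-point landscapes.
#'
#' @param land a [landscape()].
#' @return area in square kilometres.
#' @export
disturbed_area_km2 <- function(land) {
  sum(land$habitat %in% DISTURBED_CODES) * cell_area(land$grid) / 1e6
}

# number of connected components of the disturbed footprint (hex adjacency)
disturbed_components <- function(land) {
  cells <- which(land$habitat %in% DISTURBED_CODES)
  if (length(cells) == 0) return(0L)
  lab <- integer(length(land$habitat))
  comp <- 0L
  remaining <- cells
  in_set <- logical(length(land$habitat))
  in_set[cells] <- TRUE
  while (length(remaining) > 0) {
    comp <- comp + 1L
    frontier <- remaining[1]
    lab[frontier] <- comp
    while (length(frontier) > 0) {
      nb <- hex_neighbors(land$grid, frontier)
      nbv <- unique(nb[!is.na(nb)])
      nbv <- nbv[in_set[nbv] & lab[nbv] == 0L]
      lab[nbv] <- comp
      frontier <- nbv
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  comp
}

# lazily computed hex-graph distance fields, cached on the landscape
ensure_fields <- function(land) {
  cache <- land$cache
  if (is.null(cache$rehydration)) {
    targets <- which(land$is_rehydration | land$is_water)
    cache$rehydration <- if (length(targets)) distance_field(land$grid, targets) else NULL
    btargets <- which(land$is_breeding)
    cache$breeding <- if (length(btargets)) distance_field(land$grid, btargets) else NULL
  }
  invisible(cache)
}

disc_cells <- function(grid, center_xy, radius_m) {
  # bounding-box scan keeps this O(disc), not O(grid)
  r0 <- max(0L, floor((center_xy[2] - radius_m) / grid$row_step_m))
  r1 <- min(grid$n_rows - 1L, ceiling((center_xy[2] + radius_m) / grid$row_step_m))
  c0 <- max(0L, floor((center_xy[1] - radius_m) / grid$spacing_m) - 1L)
  c1 <- min(grid$n_cols - 1L, ceiling((center_xy[1] + radius_m) / grid$spacing_m))
  if (r1 < r0 || c1 < c0) return(integer())
  rows <- r0:r1; cols <- c0:c1
  col_g <- rep(cols, times = length(rows))
  row_g <- rep(rows, each = length(cols))
  x <- (col_g + 0.5 * (row_g %% 2L)) * grid$spacing_m
  y <- row_g * grid$row_step_m
  keep <- (x - center_xy[1])^2 + (y - center_xy[2])^2 <= radius_m^2
  as.integer(row_g[keep]) * grid$n_cols + as.integer(col_g[keep]) + 1L
}

#' Generate a synthetic entry-point landscape
#'
#' Emulates the two entry-point landscape archetypes of a tropical island
#' township at risk of amphibian invasion. `"packed"` builds a single
#' contiguous cluster of human-disturbed habitat (housing and infrastructure
#' with an embedded permanent waterbody and one access road) of
#' `cluster_area_m2` (default 4 km2) in a woodland matrix. `"fragmented"`
#' scatters several disturbed infrastructure patches and pit-lake
#' waterbodies totalling `cluster_area_m2` (default 9.7 km2) in woodland.
#' Both styles sprinkle grassland foraging patches and place a named entry
#' point inside the disturbed area, within reach of a permanent waterbody.
#'
#' @param style `"packed"` or `"fragmented"`.
#' @param grid a [build_grid()] object.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param cluster_area_m2 target disturbed-footprint area in square metres.
#'   Defaults: 4e6 (packed), 9.7e6 (fragmented).
#' @param grass_frac fraction of the arena covered by grassland patches.
#' @return a [landscape()] with entry point `site1` (packed) or `site2`
#'   (fragmented).
#' @export
generate_landscape <- function(style = c("packed", "fragmented"), grid, seed,
                               cluster_area_m2 = NULL, grass_frac = 0.05) {
  style <- match.arg(style)
  stopifnot(inherits(grid, "hex_grid"))
  if (missing(seed)) stop_with("generate_landscape() requires an explicit seed")
  cluster_area_m2 <- cluster_area_m2 %||% if (style == "packed") 4e6 else 9.7e6
  set.seed(as.integer(seed))
  codes <- habitat_codes()
  habitat <- rep.int(codes[["woodland"]], grid$n_cells)
  W <- grid$width_m; H <- grid$height_m

  place_grass <- function(habitat) {
    target <- grass_frac * W * H
    placed <- 0
    while (placed < target) {
      r <- stats::runif(1, 100, max(150, min(W, H) / 12))
      ctr <- c(stats::runif(1, 0, W), stats::runif(1, 0, H))
      cells <- disc_cells(grid, ctr, r)
      cells <- cells[habitat[cells] == codes[["woodland"]]]
      habitat[cells] <- codes[["grassland"]]
      placed <- placed + length(cells) * cell_area(grid)
    }
    habitat
  }
  habitat <- place_grass(habitat)

  if (style == "packed") {
    r_c <- sqrt(cluster_area_m2 / pi)
    if (2 * r_c > min(W, H))
      stop_with("packed cluster of %.2f km2 does not fit in a %g x %g m grid",
                cluster_area_m2 / 1e6, W, H)
    ctr <- c(W / 2, H / 2)
    habitat[disc_cells(grid, ctr, r_c)] <- codes[["human_habitation"]]
    # embedded permanent waterbody, offset from the cluster centre
    r_p <- sqrt(0.05 * cluster_area_m2 / pi)
    pond_ctr <- ctr + c(0.4 * r_c, 0)
    habitat[disc_cells(grid, pond_ctr, r_p)] <- codes[["non_flowing_water"]]
    # one access road from the cluster to the grid edge
    road_y <- ctr[2]
    road_row <- round(road_y / grid$row_step_m)
    road_cols <- 0:(floor(ctr[1] / grid$spacing_m))
    rc <- cell_index(grid, road_cols, rep(road_row, length(road_cols)))
    habitat[rc[habitat[rc] != codes[["non_flowing_water"]]]] <- codes[["road"]]
    entry <- coords_to_cell(grid, ctr[1] - 0.5 * r_c, ctr[2] + 0.2 * r_c)
    entry_points <- c(site1 = entry)
  } else {
    n_patch <- 8L; n_lake <- 4L
    a_patch <- 0.7 * cluster_area_m2 / n_patch
    a_lake <- 0.3 * cluster_area_m2 / n_lake
    r_patch <- sqrt(a_patch / pi); r_lake <- sqrt(a_lake / pi)
    n_tot <- n_patch + n_lake
    radii <- c(rep(r_patch, n_patch), rep(r_lake, n_lake))
    max_r <- max(radii)
    if (W < 4 * max_r || H < 4 * max_r)
      stop_with("fragmented patches of %.2f km2 total do not fit in a %g x %g m grid",
                cluster_area_m2 / 1e6, W, H)
    # jittered lattice placement guarantees non-overlap deterministically
    k <- ceiling(sqrt(n_tot))
    gx <- W / (k + 1); gy <- H / (k + 1)
    pos <- expand.grid(ix = seq_len(k), iy = seq_len(k))
    pos <- pos[sample.int(nrow(pos)), , drop = FALSE][seq_len(n_tot), , drop = FALSE]
    jit <- pmin(gx, gy) / 2 - max_r
    jit <- max(jit, 0)
    centers <- cbind(pos$ix * gx + stats::runif(n_tot, -jit, jit),
                     pos$iy * gy + stats::runif(n_tot, -jit, jit))
    # first lake is moved adjacent to the first infrastructure patch so the
    # entry point has breeding water within reach
    centers[n_patch + 1L, ] <- centers[1L, ] + c(r_patch + r_lake + 5 * grid$spacing_m, 0)
    kind <- c(rep(codes[["human_habitation"]], n_patch), rep(codes[["non_flowing_water"]], n_lake))
    for (i in seq_len(n_tot))
      habitat[disc_cells(grid, centers[i, ], radii[i])] <- kind[i]
    # short road stubs through each infrastructure patch
    for (i in seq_len(n_patch)) {
      row <- round(centers[i, 2] / grid$row_step_m)
      if (row < 0 || row >= grid$n_rows) next
      cols <- floor((centers[i, 1] - r_patch) / grid$spacing_m):ceiling((centers[i, 1] + r_patch) / grid$spacing_m)
      cols <- cols[cols >= 0 & cols < grid$n_cols]
      rc <- cell_index(grid, cols, rep(row, length(cols)))
      rc <- rc[habitat[rc] == codes[["human_habitation"]]]
      habitat[rc] <- codes[["road"]]
    }
    entry <- coords_to_cell(grid, centers[1, 1], centers[1, 2] + r_patch / 2)
    if (habitat[entry] %in% c(codes[["non_flowing_water"]], codes[["ocean"]]))
      entry <- coords_to_cell(grid, centers[1, 1], centers[1, 2] - r_patch / 2)
    entry_points <- c(site2 = entry)
  }
  landscape(grid, habitat, entry_points)
}

#' Read and write landscapes
#'
#' Two on-disk encodings are supported. The ESRI ASCII grid (`format =
#' "ascii"`) stores the habitat lattice with an `ncols`/`nrows`/`cellsize`
#' header and integer codes 0-7, top row first; grid geometry is recovered
#' from the header but entry points are not representable. The long CSV
#' (`format = "csv"`) stores one `col,row,habitat` row per cell (0-based
#' addresses, habitat names) after `#`-prefixed header comments carrying the
#' spacing, arena extent, entry points and the habitat code table, and
#' round-trips every field.
#'
#' @param land a [landscape()].
#' @param path file path.
#' @param format `"csv"` or `"ascii"` (default: inferred from the extension,
#'   `.asc` means ASCII).
#' @return `read_landscape()` returns a [landscape()];
#'   `write_landscape()` returns `path` invisibly.
#' @export
write_landscape <- function(land, path, format = NULL) {
  format <- format %||% if (grepl("\\.asc$", path)) "ascii" else "csv"
  g <- land$grid
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("ncols %d", g$n_cols), sprintf("nrows %d", g$n_rows),
                 "xllcorner 0", "yllcorner 0",
                 sprintf("cellsize %g", g$spacing_m), "NODATA_value -9999"), con)
    m <- matrix(land$habitat, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
    for (r in g$n_rows:1) writeLines(paste(m[r, ], collapse = " "), con)
  } else {
    codes <- habitat_codes()
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# spacing_m: %g", g$spacing_m),
                 sprintf("# width_m: %g", g$width_m),
                 sprintf("# height_m: %g", g$height_m),
                 sprintf("# habitat_codes: %s",
                         paste(sprintf("%s=%d", names(codes), codes), collapse = " ")),
                 if (length(land$entry_points))
                   sprintf("# entry_point: %s %d", names(land$entry_points), land$entry_points)),
               con)
    cr <- cell_colrow(g, seq_len(g$n_cells))
    df <- data.frame(col = cr$col, row = cr$row,
                     habitat = names(codes)[land$habitat + 1L])
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.asc$", path)) "ascii" else "csv"
  if (format == "ascii") {
    lines <- readLines(path)
    hdr <- list()
    i <- 1
    while (grepl("^[A-Za-z]", lines[i])) {
      kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
      i <- i + 1
    }
    for (k in c("ncols", "nrows", "cellsize"))
      if (is.null(hdr[[k]])) stop_with("ASCII grid header missing '%s'", k)
    nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
    data_lines <- lines[i:length(lines)]
    data_lines <- data_lines[nzchar(trimws(data_lines))]
    if (length(data_lines) != nr)
      stop_with("expected %d data rows, found %d", nr, length(data_lines))
    rows <- lapply(seq_along(data_lines), function(j) {
      v <- suppressWarnings(as.integer(strsplit(trimws(data_lines[j]), "\\s+")[[1]]))
      if (length(v) != nc || anyNA(v))
        stop_with("ragged or non-integer data at line %d of %s", i + j - 1, path)
      v
    })
    m <- do.call(rbind, rows) # first line = northernmost (largest row index)
    habitat <- as.vector(t(m[nr:1, , drop = FALSE]))
    if (any(habitat < 0L | habitat > 7L))
      stop_with("unknown habitat code(s) in %s: %s", path,
                paste(unique(habitat[habitat < 0L | habitat > 7L]), collapse = ", "))
    grid <- build_grid(nc * hdr$cellsize, nr * hdr$cellsize * sqrt(3) / 2 + 1e-9, hdr$cellsize)
    grid$n_cols <- nc; grid$n_rows <- nr; grid$n_cells <- as.double(nc) * nr
    landscape(grid, habitat)
  } else {
    lines <- readLines(path)
    hdr_lines <- grep("^#", lines, value = TRUE)
    get_num <- function(key) {
      m <- grep(sprintf("^# %s:", key), hdr_lines, value = TRUE)
      if (length(m) == 0) return(NULL)
      as.numeric(sub(sprintf("^# %s:\\s*", key), "", m[1]))
    }
    spacing <- get_num("spacing_m") %||% stop_with("CSV landscape missing '# spacing_m:' header")
    width <- get_num("width_m"); height <- get_num("height_m")
    body <- lines[!grepl("^#", lines)]
    df <- utils::read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
    for (k in c("col", "row", "habitat"))
      if (!k %in% names(df)) stop_with("CSV landscape missing column '%s'", k)
    nc <- max(df$col) + 1L; nr <- max(df$row) + 1L
    grid <- build_grid(width %||% (nc * spacing), height %||% (nr * spacing * sqrt(3) / 2 + 1e-9), spacing)
    grid$n_cols <- as.integer(nc); grid$n_rows <- as.integer(nr)
    grid$n_cells <- as.double(nc) * nr
    codes <- habitat_codes()
    hv <- if (is.numeric(df$habitat)) as.integer(df$habitat) else unname(codes[df$habitat])
    if (anyNA(hv)) {
      bad <- which(is.na(hv))[1]
      stop_with("unknown habitat code at data line %d of %s: '%s'",
                bad, path, df$habitat[bad])
    }
    habitat <- integer(grid$n_cells)
    habitat[cell_index(grid, df$col, df$row)] <- hv
    ep_lines <- grep("^# entry_point:", hdr_lines, value = TRUE)
    entry_points <- integer()
    if (length(ep_lines)) {
      parts <- strsplit(sub("^# entry_point:\\s*", "", ep_lines), "\\s+")
      entry_points <- stats::setNames(vapply(parts, function(p) as.integer(p[2]), 1L),
                                      vapply(parts, `[`, "", 1L))
    }
    landscape(grid, habitat, entry_points)
  }
}
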