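# Geographic isolation metrics and topography summaries.
#
# Scenes are flat rasters: cell-to-cell distances are Euclidean in units of
# cell_size (km). Real-geodesy buffering is out of scope; great-circle
# distances between coordinates use the haversine on a mean-radius sphere.

EARTH_RADIUS_KM <- 6371.0088

#' Construct a geographic point
#'
#' @param lat latitude in decimal degrees, in \[-90, 90\].
#' @param lon longitude in decimal degrees, in \[-180, 180\].
#' @export
geo_point <- function(lat, lon) {
  if (!is.finite(lat) || lat < -90 || lat > 90) stop("invalid latitude: ", lat)
  if (!is.finite(lon) || lon < -180 || lon > 180) stop("invalid longitude: ", lon)
  structure(list(lat = lat, lon = lon), class = "geo_point")
}

#' Great-circle distance between two points, in km
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km, as used for
#' island-centroid-to-mainland distances.
#'
#' @param a,b `geo_point` objects (see [geo_point()]).
#' @return distance in km; symmetric, non-negative, at most half the Earth's
#'   circumference.
#' @examples
#' great_circle_km(geo_point(0, 0), geo_point(0, 1))  # one equatorial degree
#' @export
great_circle_km <- function(a, b) {
  stopifnot(inherits(a, "geo_point"), inherits(b, "geo_point"))
  geosphere::distHaversine(c(a$lon, a$lat), c(b$lon, b$lat), r = EARTH_RADIUS_KM)
}

# ---- land/water scenes -------------------------------------------------

.scene_codes <- c(water = 0L, focal_island = 1L, other_island = 2L, mainland = 3L)

#' Construct a land/water scene
#'
#' A scene is an integer label grid (0 = water, 1 = focal island, 2 = other
#' island, 3 = mainland) with a cell edge length in km. Exactly one focal
#' island per scene; focal cells are land by construction.
#'
#' @param labels integer matrix of cell codes.
#' @param cell_size km per cell edge.
#' @export
geo_scene <- function(labels, cell_size) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% .scene_codes)) stop("invalid scene label code")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  structure(list(labels = labels, cell_size = cell_size), class = "geo_scene")
}

# row/col coordinates (cell centres, in cell units) of cells matching a code
.scene_cells <- function(scene, code) {
  which(scene$labels == .scene_codes[[code]], arr.ind = TRUE)
}

# minimum Euclidean centre-to-centre distance (km) between two cell sets
.min_cell_distance <- function(from, to, cell_size) {
  d2min <- Inf
  # block over 'from' to bound memory on large scenes
  step <- 2048L
  for (i0 in seq(1L, nrow(from), by = step)) {
    idx <- i0:min(i0 + step - 1L, nrow(from))
    d2 <- outer(from[idx, 1], to[, 1], "-")^2 + outer(from[idx, 2], to[, 2], "-")^2
    d2min <- min(d2min, min(d2))
  }
  sqrt(d2min) * cell_size
}

#' Shortest island-to-mainland distance in a scene
#'
#' Minimum centre-to-centre distance between any focal-island cell and any
#' mainland cell (the raster analogue of measuring between the two closest
#' shore points).
#'
#' @param scene a [geo_scene()].
#' @return distance in km.
#' @export
distance_to_mainland <- function(scene) {
  stopifnot(inherits(scene, "geo_scene"))
  focal <- .scene_cells(scene, "focal_island")
  main <- .scene_cells(scene, "mainland")
  if (nrow(focal) == 0) stop("no focal island in scene")
  if (nrow(main) == 0) stop("no mainland in scene")
  .min_cell_distance(focal, main, scene$cell_size)
}

#' UNEP Isolation Index
#'
#' Sum of the square roots of the distances (km) to the nearest
#' equivalent-or-larger island, the nearest island group or archipelago, and
#' the nearest continent. Higher values indicate greater isolation.
#'
#' @param d_equivalent_island,d_group,d_continent distances in km, >= 0.
#' @export
unep_isolation_index <- function(d_equivalent_island, d_group, d_continent) {
  d <- c(d_equivalent_island, d_group, d_continent)
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  sum(sqrt(d))
}

# cells of the focal island that touch a non-focal 4-neighbour or the border
.focal_perimeter <- function(labels) {
  f <- labels == .scene_codes[["focal_island"]]
  if (!any(f)) stop("no focal island in scene")
  nr <- nrow(f); nc <- ncol(f)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- f
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(f & !interior, arr.ind = TRUE)
}

# per-cell minimum distance (km) to the focal island perimeter
.distance_to_perimeter <- function(scene) {
  per <- .focal_perimeter(scene$labels)
  nr <- nrow(scene$labels); nc <- ncol(scene$labels)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(per))) {
    d2 <- pmin(d2, (rows - per[k, 1])^2 + (cols - per[k, 2])^2)
  }
  sqrt(d2) * scene$cell_size
}

#' Surrounding landmass proportion (SLMP)
#'
#' For each buffer distance b around the focal island perimeter, the
#' proportion of the surrounding area within b that is land (other islands or
#' mainland; the focal island itself is excluded from both numerator and
#' denominator), summed over the buffers. With the default buffers of 100,
#' 1000 and 10,000 km the value lies in \[0, 3\]: 0 for an island alone in
#' open water, 3 for an island embedded in unbroken land. Larger values mean
#' more surrounding landmass, i.e. less isolation.
#'
#' @param scene a [geo_scene()].
#' @param buffers strictly increasing positive buffer distances in km.
#' @return the SLMP value; the per-buffer proportions are attached as the
#'   `proportions` attribute.
#' @export
slmp <- function(scene, buffers = c(100, 1000, 10000)) {
  stopifnot(inherits(scene, "geo_scene"))
  if (any(buffers <= 0) || is.unsorted(buffers, strictly = TRUE)) {
    stop("buffers must be positive and strictly increasing")
  }
  dist <- .distance_to_perimeter(scene)
  lab <- scene$labels
  nonfocal <- lab != .scene_codes[["focal_island"]]
  land <- nonfocal & lab != .scene_codes[["water"]]
  props <- vapply(buffers, function(b) {
    inside <- dist <= b & nonfocal
    if (!any(inside)) return(0)
    sum(land & inside) / sum(inside)
  }, numeric(1))
  structure(sum(props), proportions = stats::setNames(props, paste0("b", buffers)))
}

# ---- elevation grids ---------------------------------------------------

#' Construct an elevation grid
#'
#' @param values numeric matrix of elevations (m above sea level).
#' @param cell_size m per cell edge.
#' @export
elevation_grid <- function(values, cell_size) {
  values <- as.matrix(values)
  if (length(values) == 0) stop("empty grid")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  structure(list(values = values, cell_size = cell_size), class = "elevation_grid")
}

# central differences in the interior, one-sided at the edges
.diff_axis <- function(z, along, h) {
  n <- dim(z)[along]
  if (n == 1) return(array(0, dim(z)))
  idx <- function(i) if (along == 1) z[i, , drop = FALSE] else z[, i, drop = FALSE]
  out <- array(0, dim(z))
  assign_rows <- function(i, v) {
    if (along == 1) out[i, ] <<- v else out[, i] <<- v
  }
  assign_rows(1, (idx(2) - idx(1)) / h)
  assign_rows(n, (idx(n) - idx(n - 1)) / h)
  if (n > 2) {
    for (i in 2:(n - 1)) assign_rows(i, (idx(i + 1) - idx(i - 1)) / (2 * h))
  }
  out
}

#' Topography summary of an elevation grid
#'
#' Computes the elevation extremes, the relief (max minus min) and a
#' per-cell magnitude-of-steepest-gradient map
#' sqrt((dz/dx)^2 + (dz/dy)^2) via central differences (one-sided at grid
#' edges), the quantity used for topographic heat maps.
#'
#' @param grid an [elevation_grid()].
#' @return list with `elevation_max`, `elevation_min`, `relief` (m) and
#'   `gradient` (matrix, m/m).
#' @export
topography_summary <- function(grid) {
  stopifnot(inherits(grid, "elevation_grid"))
  z <- grid$values
  gx <- .diff_axis(z, 2, grid$cell_size)
  gy <- .diff_axis(z, 1, grid$cell_size)
  list(elevation_max = max(z), elevation_min = min(z),
       relief = max(z) - min(z), gradient = sqrt(gx^2 + gy^2))
}

#' Aggregate archipelago members into one registry row
#'
#' Distance to mainland is the minimum over members (the nearest island
#' stands for the archipelago), area the sum of all islands, SLMP the mean of
#' non-missing member values, and elevations the extremes. The UNEP index is
#' averaged over non-missing members and GMMC is 1 if any member was
#' land-bridged.
#'
#' @param members an `island_registry` (or compatible data.frame) of the
#'   archipelago's islands.
#' @param name name for the aggregate row (defaults to the archipelago).
#' @return a one-row data.frame with the registry schema.
#' @export
archipelago_aggregate <- function(members, name = NULL) {
  if (nrow(members) == 0) stop("empty archipelago")
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  data.frame(
    island = if (is.null(name)) members$archipelago[1] else name,
    archipelago = members$archipelago[1],
    island_type = members$island_type[1],
    area_km2 = sum(members$area_km2),
    distance_km = min(members$distance_km, na.rm = TRUE),
    unep_index = mean_or_na(members$unep_index),
    slmp = mean_or_na(members$slmp),
    gmmc = if (all(is.na(members$gmmc))) NA_real_ else as.numeric(any(members$gmmc == 1, na.rm = TRUE)),
    elevation_max_m = max_or_na(members$elevation_max_m),
    elevation_min_m = if ("elevation_min_m" %in% names(members))
      min(members$elevation_min_m, na.rm = TRUE) else 0,
    stringsAsFactors = FALSE
  )
}

# ---- plain-text raster I/O (ESRI-ASCII-grid-style) ---------------------

#' Read/write plain-text rasters
#'
#' The grid format is an ESRI-ASCII-grid-style text file: a header of
#' `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize` and
#' `NODATA_value`, followed by `nrows` whitespace-separated data rows (top
#' row first). `read_ascii_grid` returns the matrix plus header fields;
#' `write_ascii_grid` is its inverse.
#'
#' @param path file path.
#' @return for `read_ascii_grid`, a list with `values` (numeric matrix,
#'   `NA` for nodata), `cellsize`, `xllcorner`, `yllcorner`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (need in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[need]])) stop("grid header lacks ", need)
  }
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != hdr$ncols * hdr$nrows) stop("grid body size mismatch")
  values <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) values[values == nodata] <- NA
  list(values = values, cellsize = hdr$cellsize,
       xllcorner = hdr[["xllcorner"]] %||% 0,
       yllcorner = hdr[["yllcorner"]] %||% 0,
       nodata = nodata %||% -9999)
}

#' @rdname read_ascii_grid
#' @param values numeric matrix to write.
#' @param cellsize cell edge length.
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param nodata value standing for missing cells.
#' @export
write_ascii_grid <- function(values, path, cellsize, xllcorner = 0,
                             yllcorner = 0, nodata = -9999) {
  values <- as.matrix(values)
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", xllcorner), paste("yllcorner", yllcorner),
           paste("cellsize", cellsize), paste("NODATA_value", nodata))
  rows <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
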