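# Missing marker used in the transcribed site table: an en dash. A plain
# hyphen and empty string are accepted on read for robustness.
.missing_markers <- c("–", "-", "", "NA")

.norm_name <- function(x) stringi::stri_trans_nfc(trimws(x))

.parse_num <- function(x, field, allow_missing = TRUE) {
  x <- trimws(x)
  miss <- is.na(x) | x %in% .missing_markers
  out <- rep(NA_real_, length(x))
  bad <- !miss & is.na(suppressWarnings(as.numeric(gsub(",", "", x))))
  if (any(bad)) {
    stop(sprintf("field '%s': unparseable value(s) in row(s) %s", field,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  out[!miss] <- as.numeric(gsub(",", "", x[!miss]))
  if (!allow_missing && any(miss)) {
    stop(sprintf("field '%s': missing value not permitted", field), call. = FALSE)
  }
  out
}

.registry_columns <- c("island", "archipelago", "island_type", "area_km2",
                       "distance_km", "unep_index", "slmp", "gmmc",
                       "elevation_max_m")

#' Load an island site registry from delimited text
#'
#' Reads a UTF-8 TSV of per-island attributes: identity, archipelago, island
#' type (`continental`, `oceanic` or `lacustrine`), area (km^2), distance to
#' the mainland (km), the UNEP Isolation Index (sum of square roots of
#' distances to the nearest equivalent-or-larger island, nearest archipelago
#' and nearest continent), the surrounding landmass proportion (SLMP), the
#' glacial-maximum mainland connection flag (GMMC, 1 = land-bridged at the
#' last glacial maximum) and maximum elevation (m). The en dash marker
#' denotes missing data and is mapped to `NA`, never to zero; downstream
#' screening rules treat missing values explicitly.
#'
#' An optional `elevation_min_m` column is honoured; when absent the minimum
#' elevation defaults to 0 m (sea level).
#'
#' @param path path to a tab-delimited UTF-8 file whose header matches the
#'   documented schema (see `islescreen_example("table1_sites.tsv")`).
#' @return a data.frame of class `island_registry`, one row per island, with
#'   site names normalised to Unicode NFC.
#' @examples
#' reg <- load_site_registry(islescreen_example("table1_sites.tsv"))
#' nrow(reg)
#' table(reg$island_type)
#' @export
load_site_registry <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", na.strings = NULL)
  missing_cols <- setdiff(.registry_columns, names(raw))
  if (length(missing_cols)) {
    stop("registry header lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  reg <- data.frame(
    island       = .norm_name(raw$island),
    archipelago  = .norm_name(raw$archipelago),
    island_type  = trimws(raw$island_type),
    area_km2     = .parse_num(raw$area_km2, "area_km2"),
    distance_km  = .parse_num(raw$distance_km, "distance_km"),
    unep_index   = .parse_num(raw$unep_index, "unep_index"),
    slmp         = .parse_num(raw$slmp, "slmp"),
    gmmc         = .parse_num(raw$gmmc, "gmmc"),
    elevation_max_m = .parse_num(raw$elevation_max_m, "elevation_max_m"),
    stringsAsFactors = FALSE
  )
  reg$elevation_min_m <- if ("elevation_min_m" %in% names(raw)) {
    .parse_num(raw$elevation_min_m, "elevation_min_m")
  } else rep(0, nrow(reg))
  validate_site_registry(reg)
  class(reg) <- c("island_registry", "data.frame")
  reg
}

#' @rdname load_site_registry
#' @param registry an `island_registry` data.frame to check.
#' @export
validate_site_registry <- function(registry) {
  if (nrow(registry) == 0) return(invisible(registry))
  dup <- duplicated(registry$island)
  if (any(dup)) {
    stop("duplicate site name(s) in row(s) ",
         paste(which(dup), collapse = ", "), ": ",
         paste(unique(registry$island[dup]), collapse = ", "))
  }
  bad_type <- !registry$island_type %in% c("continental", "oceanic", "lacustrine")
  if (any(bad_type)) {
    stop("invalid island_type in row(s) ", paste(which(bad_type), collapse = ", "))
  }
  if (any(registry$area_km2 <= 0, na.rm = TRUE)) stop("area must be > 0")
  if (any(is.na(registry$area_km2))) stop("area must be present for every site")
  if (any(registry$distance_km < 0, na.rm = TRUE)) stop("distance must be >= 0")
  if (any(registry$unep_index < 0, na.rm = TRUE)) stop("unep_index must be >= 0")
  if (any(registry$slmp < 0, na.rm = TRUE)) stop("slmp must be >= 0")
  invisible(registry)
}

#' Write a site registry back to delimited text
#'
#' Inverse of [load_site_registry()]; missing values are written as the en
#' dash marker so a written registry round-trips field-identically.
#'
#' @param registry an `island_registry`.
#' @param path output path.
#' @export
write_site_registry <- function(registry, path) {
  out <- as.data.frame(registry)
  num_cols <- c("area_km2", "distance_km", "unep_index", "slmp", "gmmc",
                "elevation_max_m", "elevation_min_m")
  for (cc in num_cols) {
    v <- format(out[[cc]], trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
    v[is.na(out[[cc]])] <- "–"
    out[[cc]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up one metric for one site
#'
#' Site names are compared after Unicode NFC normalisation, so composed and
#' decomposed spellings of names such as "Annobón" match.
#'
#' @param registry an `island_registry`.
#' @param site_name site to look up.
#' @param metric_name one of `area_km2`, `distance_km`, `unep_index`, `slmp`,
#'   `gmmc`, `elevation_max_m`, `elevation_min_m`, `island_type`,
#'   `archipelago`.
#' @return the stored value; `NA` where the table records missing data.
#' @examples
#' reg <- load_site_registry(islescreen_example("table1_sites.tsv"))
#' lookup_metric(reg, "Annobón", "area_km2")
#' lookup_metric(reg, "Mauritius", "unep_index")
#' @export
lookup_metric <- function(registry, site_name, metric_name) {
  i <- match(.norm_name(site_name), registry$island)
  if (is.na(i)) stop("unknown site: ", site_name)
  if (!metric_name %in% names(registry)) stop("unknown metric: ", metric_name)
  registry[[metric_name]][i]
}

#' Build a genome-sample manifest from per-source tables
#'
#' Concatenates per-source sample tables (each with `sample_id`, `population`
#' and optionally `site` and `species` columns) into one manifest with a
#' `source` provenance column. Sample identifiers must be globally unique
#' across sources; every sample maps to exactly one population.
#'
#' @param sources a named list of data.frames, one per sequencing source
#'   (e.g. `VGL`, `Ag1000G`, `LakeVictoria`).
#' @return a data.frame of class `sample_manifest`.
#' @seealso [load_sample_manifest()] to read the shipped synthetic fixture.
#' @export
build_sample_manifest <- function(sources) {
  if (length(sources) == 0) {
    out <- data.frame(sample_id = character(), population = character(),
                      site = character(), species = character(),
                      source = character(), stringsAsFactors = FALSE)
    class(out) <- c("sample_manifest", "data.frame")
    return(out)
  }
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    stop("sources must be a named list")
  }
  tabs <- lapply(names(sources), function(nm) {
    tab <- sources[[nm]]
    if (!all(c("sample_id", "population") %in% names(tab))) {
      stop("source '", nm, "' lacks sample_id/population columns")
    }
    data.frame(sample_id = as.character(tab$sample_id),
               population = as.character(tab$population),
               site = if ("site" %in% names(tab)) as.character(tab$site) else NA_character_,
               species = if ("species" %in% names(tab)) as.character(tab$species) else "unassigned",
               source = nm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  dup <- duplicated(out$sample_id)
  if (any(dup)) {
    stop("duplicated sample id(s) across sources: ",
         paste(unique(out$sample_id[dup]), collapse = ", "))
  }
  class(out) <- c("sample_manifest", "data.frame")
  out
}

#' Read a sample manifest from a single TSV with a source column
#'
#' @param path TSV with columns `sample_id`, `population`, `site`, `species`,
#'   `source`. The shipped fixture `manifest_sources_synthetic.tsv` carries
#'   synthetic sample identifiers with the study's true per-source totals
#'   (167 + 196 + 57 = 420 genomes).
#' @param sources optional character vector restricting to given sources.
#' @return a `sample_manifest` data.frame.
#' @export
load_sample_manifest <- function(path, sources = NULL) {
  tab <- utils::read.delim(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!is.null(sources)) tab <- tab[tab$source %in% sources, , drop = FALSE]
  split_tabs <- split(tab[, setdiff(names(tab), "source")], tab$source)
  build_sample_manifest(split_tabs)
}

#' Classify vector status from the sporozoite infection rate
#'
#' Anopheline species with sporozoite infection rates above 1% are primary
#' malaria vectors; below 1%, secondary. The boundary rate of exactly 1% is
#' classified primary (the conservative choice for vector accounting).
#'
#' @param sporozoite_rate fraction in \[0, 1\] (vectorised).
#' @return character vector of `"primary"`/`"secondary"`.
#' @examples
#' classify_vector_status(c(0.02, 0.005, 0))
#' @export
classify_vector_status <- function(sporozoite_rate) {
  if (any(is.na(sporozoite_rate))) stop("sporozoite rate must not be NA")
  if (any(sporozoite_rate < 0 | sporozoite_rate > 1)) {
    stop("sporozoite rate outside [0, 1]")
  }
  ifelse(sporozoite_rate >= 0.01, "primary", "secondary")
}

#' Load species occurrence records
#'
#' @param path TSV with columns `site`, `species`, `sporozoite_rate` (en dash
#'   for unknown) and optionally `vector_status`
#'   (`primary`/`secondary`/`other`). When `vector_status` is absent or
#'   missing it is derived from `sporozoite_rate` via
#'   [classify_vector_status()]; records with neither are classed `other`.
#' @return data.frame of species records.
#' @export
load_species_records <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", fileEncoding = "UTF-8",
                           na.strings = NULL)
  rec <- data.frame(site = .norm_name(tab$site),
                    species = trimws(tab$species),
                    sporozoite_rate = .parse_num(tab$sporozoite_rate, "sporozoite_rate"),
                    stringsAsFactors = FALSE)
  if (any(rec$sporozoite_rate < 0 | rec$sporozoite_rate > 1, na.rm = TRUE)) {
    stop("sporozoite_rate outside [0, 1]")
  }
  status <- if ("vector_status" %in% names(tab)) trimws(tab$vector_status) else
    rep(NA_character_, nrow(tab))
  status[status %in% .missing_markers] <- NA_character_
  derive <- is.na(status) & !is.na(rec$sporozoite_rate)
  status[derive] <- classify_vector_status(rec$sporozoite_rate[derive])
  status[is.na(status)] <- "other"
  bad <- !status %in% c("primary", "secondary", "other")
  if (any(bad)) stop("invalid vector_status: ", paste(unique(status[bad]), collapse = ", "))
  rec$vector_status <- status
  rec
}

#' Anopheline richness and vector-status counts for a site
#'
#' Partitions the species present at a site into primary vectors, secondary
#' vectors and other (non-vector or unknown status), and flags whether the
#' target species -- Anopheles gambiae sensu stricto and/or Anopheles
#' coluzzii -- is present.
#'
#' @param species_records data.frame as returned by [load_species_records()].
#' @param site site name.
#' @return a list with `n_total`, `n_primary`, `n_secondary`, `n_other`,
#'   `target_present`.
#' @export
richness_counts <- function(species_records, site) {
  rec <- species_records[species_records$site == .norm_name(site), , drop = FALSE]
  status <- rec$vector_status
  target <- grepl("gambiae|coluzzii", rec$species, ignore.case = TRUE)
  list(n_total = nrow(rec),
       n_primary = sum(status == "primary"),
       n_secondary = sum(status == "secondary"),
       n_other = sum(status == "other"),
       target_present = any(target))
}

#' Path to a shipped example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @export
islescreen_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "islescreen")))
  }
  path <- system.file("extdata", file, package = "islescreen")
  if (!nzchar(path)) stop("no shipped file named ", file)
  path
}
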