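# Synthetic inputs for exercising the pipeline without downloads:
# Balding-Nichols genotype data with controllable divergence, land/water
# scenes with known generating geometry, elevation grids and fixture
# bundles. All generators are pure functions of (config, seed).

#' Simulation configuration for divergent-population genotypes
#'
#' Parameters of the Balding-Nichols divergence model: per locus an
#' ancestral allele frequency p is drawn uniformly on
#' `[ancestral_maf_min, 1 - ancestral_maf_min]`; each population draws its
#' own frequency from Beta(p(1-F)/F, (1-p)(1-F)/F), whose expected
#' fixation index against the ancestral pool is exactly F (at F = 0 the
#' population frequency equals p); diploid genotypes are Binomial(2, q).
#' Per-genotype depths are Poisson(`depth_mean`) and genotypes are masked
#' missing at `missing_rate`. Positions are drawn uniformly (without
#' replacement) along the chromosome and sorted.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop diploid samples per population.
#' @param n_loci number of variant loci.
#' @param divergence_F divergence parameter F in \[0, 1): a scalar shared by
#'   all populations or one value per population.
#' @param ancestral_maf_min lower bound of the ancestral frequency draw.
#' @param missing_rate per-genotype missingness probability.
#' @param depth_mean mean sequencing depth (reads).
#' @param chromosome chromosome label for all loci.
#' @param chromosome_length chromosome length in bp.
#' @param seed integer seed; identical configs give bit-identical output.
#' @export
sim_config <- function(n_pops = 2, samples_per_pop = 30, n_loci = 5000,
                       divergence_F = 0.15, ancestral_maf_min = 0.05,
                       missing_rate = 0.02, depth_mean = 20,
                       chromosome = "3L", chromosome_length = 6000000,
                       seed = 1) {
  if (n_pops < 1 || samples_per_pop < 1 || n_loci < 1) stop("counts must be >= 1")
  if (!length(divergence_F) %in% c(1, n_pops)) {
    stop("divergence_F must have length 1 or n_pops")
  }
  if (any(divergence_F < 0 | divergence_F >= 1)) stop("divergence_F outside [0, 1)")
  if (ancestral_maf_min < 0 || ancestral_maf_min >= 0.5) {
    stop("ancestral_maf_min outside [0, 0.5)")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate outside [0, 1)")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (chromosome_length < n_loci) stop("chromosome_length must be >= n_loci")
  structure(list(n_pops = n_pops, samples_per_pop = samples_per_pop,
                 n_loci = n_loci,
                 divergence_F = rep(divergence_F, length.out = n_pops),
                 ancestral_maf_min = ancestral_maf_min,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 chromosome = chromosome,
                 chromosome_length = chromosome_length, seed = seed),
            class = "sim_config")
}

#' Expected per-site heterozygosity of the ancestral frequency draw
#'
#' For p uniform on \[a, 1-a\], E\[2p(1-p)\] = 1/2 - (1-2a)^2/6. Used to
#' derive, in closed form, the locus density that yields a target per-site
#' diversity in panmictic simulations.
#'
#' @param ancestral_maf_min the uniform draw's lower bound a.
#' @export
expected_heterozygosity <- function(ancestral_maf_min) {
  0.5 - (1 - 2 * ancestral_maf_min)^2 / 6
}

#' Simulate divergent populations under the Balding-Nichols model
#'
#' @param cfg a [sim_config()].
#' @return list with `vm` (a [variant_matrix()]) and `manifest` (data.frame
#'   of `sample_id`, `population`). Population labels are `pop1`, `pop2`,
#'   ...; sample ids `pop1_01` etc.
#' @examples
#' sim <- simulate_divergent_populations(sim_config(n_loci = 200, seed = 7))
#' hudson_fst(sim$vm,
#'            sim$manifest$sample_id[sim$manifest$population == "pop1"],
#'            sim$manifest$sample_id[sim$manifest$population == "pop2"])
#' @export
simulate_divergent_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    L <- cfg$n_loci
    p <- stats::runif(L, cfg$ancestral_maf_min, 1 - cfg$ancestral_maf_min)
    pops <- paste0("pop", seq_len(cfg$n_pops))
    geno_blocks <- vector("list", cfg$n_pops)
    for (k in seq_len(cfg$n_pops)) {
      F <- cfg$divergence_F[k]
      q <- if (F == 0) p else
        stats::rbeta(L, p * (1 - F) / F, (1 - p) * (1 - F) / F)
      g <- matrix(stats::rbinom(cfg$samples_per_pop * L, 2,
                                rep(q, each = cfg$samples_per_pop)),
                  nrow = cfg$samples_per_pop, ncol = L)
      geno_blocks[[k]] <- g
    }
    geno <- do.call(rbind, geno_blocks)
    n_samples <- nrow(geno)
    depth <- matrix(stats::rpois(n_samples * L, cfg$depth_mean), n_samples, L)
    if (cfg$missing_rate > 0) {
      geno[matrix(stats::runif(n_samples * L) < cfg$missing_rate,
                  n_samples, L)] <- NA_integer_
    }
    positions <- sort(sample.int(cfg$chromosome_length, L))
    ids <- paste0(rep(pops, each = cfg$samples_per_pop), "_",
                  sprintf("%02d", seq_len(cfg$samples_per_pop)))
    manifest <- data.frame(sample_id = ids,
                           population = rep(pops, each = cfg$samples_per_pop),
                           stringsAsFactors = FALSE)
    list(vm = variant_matrix(geno, positions, cfg$chromosome, ids, depth),
         manifest = manifest)
  })
}

# ---- synthetic geographic scenes ---------------------------------------

# continuous generating geometry, coordinates in cell units (row, col)
.scene_geometry <- function(layout, nr, nc, seed) {
  withr::with_seed(seed, {
    switch(layout,
      remote_oceanic = list(
        focal = c(r = nr / 2 + stats::runif(1, -2, 2),
                  c = nc * 0.25 + stats::runif(1, -2, 2),
                  rad = stats::runif(1, 2.5, 4)),
        mainland = list(c(r0 = 1, r1 = nr, c0 = nc - 2, c1 = nc)),
        others = list()),
      nearshore_continental = list(
        focal = c(r = nr / 2 + stats::runif(1, -2, 2),
                  c = nc * 0.72 + stats::runif(1, -1, 1),
                  rad = stats::runif(1, 2.5, 4)),
        mainland = list(c(r0 = 1, r1 = nr, c0 = nc * 0.85, c1 = nc)),
        others = lapply(1:3, function(i) {
          c(r = stats::runif(1, 5, nr - 5), c = nc * 0.78 + stats::runif(1, -2, 2),
            rad = stats::runif(1, 1, 2))
        })),
      lacustrine = list(
        focal = c(r = nr / 2 + stats::runif(1, -1, 1),
                  c = nc / 2 + stats::runif(1, -1, 1),
                  rad = stats::runif(1, 2.5, 4)),
        mainland = list(c(r0 = 1, r1 = nr, c0 = 1, c1 = 4),
                        c(r0 = 1, r1 = nr, c0 = nc - 3, c1 = nc),
                        c(r0 = 1, r1 = 4, c0 = 1, c1 = nc),
                        c(r0 = nr - 3, r1 = nr, c0 = 1, c1 = nc)),
        others = list()),
      stop("unknown layout: ", layout))
  })
}

.rasterize_geometry <- function(geom, nr, nc, refine = 1L) {
  nr2 <- nr * refine; nc2 <- nc * refine
  rows <- matrix(rep(seq_len(nr2), nc2), nr2, nc2) / refine
  cols <- matrix(rep(seq_len(nc2), each = nr2), nr2, nc2) / refine
  lab <- matrix(.scene_codes[["water"]], nr2, nc2)
  for (rect in geom$mainland) {
    lab[rows >= rect["r0"] & rows <= rect["r1"] &
          cols >= rect["c0"] & cols <= rect["c1"]] <- .scene_codes[["mainland"]]
  }
  for (isl in geom$others) {
    lab[(rows - isl["r"])^2 + (cols - isl["c"])^2 <= isl["rad"]^2] <-
      .scene_codes[["other_island"]]
  }
  f <- geom$focal
  lab[(rows - f["r"])^2 + (cols - f["c"])^2 <= f["rad"]^2] <-
    .scene_codes[["focal_island"]]
  lab
}

# analytic distance (cell units) from the focal circle to the nearest
# mainland rectangle
.analytic_distance <- function(geom) {
  f <- geom$focal
  d <- vapply(geom$mainland, function(rect) {
    dr <- max(rect["r0"] - f["r"], f["r"] - rect["r1"], 0)
    dc <- max(rect["c0"] - f["c"], f["c"] - rect["c1"], 0)
    max(sqrt(dr^2 + dc^2) - f["rad"], 0)
  }, numeric(1))
  min(d)
}

#' Simulate a land/water scene with known ground truth
#'
#' Generates a raster scene from continuous geometry (a circular focal
#' island, rectangular mainland blocks and optional circular islets) in one
#' of three layouts: `remote_oceanic` (island far from a thin mainland
#' strip, no other land nearby), `nearshore_continental` (island close to a
#' broad mainland with stepping-stone islets) and `lacustrine` (island in a
#' lake enclosed by mainland on all sides). Alongside the scene it returns
#' ground truth derived from the generating geometry: the analytic
#' island-to-mainland distance and SLMP evaluated on a 4x refined
#' rasterisation of the same geometry (resolution-independent up to cell
#' error).
#'
#' @param layout one of `"remote_oceanic"`, `"nearshore_continental"`,
#'   `"lacustrine"`.
#' @param seed integer seed for the geometry jitter.
#' @param nrow,ncol scene dimensions in cells.
#' @param cell_size km per cell edge.
#' @param buffers SLMP buffer distances (km) used for the ground truth.
#' @return list with `scene` (a [geo_scene()]) and `ground_truth` (list with
#'   `distance_km`, `slmp`, `geometry`).
#' @export
simulate_geo_scene <- function(layout, seed = 1, nrow = 60, ncol = 60,
                               cell_size = 50, buffers = c(100, 1000, 10000)) {
  geom <- .scene_geometry(layout, nrow, ncol, seed)
  scene <- geo_scene(.rasterize_geometry(geom, nrow, ncol), cell_size)
  refine <- 4L
  fine <- geo_scene(.rasterize_geometry(geom, nrow, ncol, refine),
                    cell_size / refine)
  truth <- list(distance_km = .analytic_distance(geom) * cell_size,
                slmp = as.numeric(slmp(fine, buffers)),
                geometry = geom)
  list(scene = scene, ground_truth = truth)
}

#' Synthetic single-peak elevation grid
#'
#' A cone: elevation decreases linearly with distance from the apex.
#'
#' @param nrow,ncol grid dimensions.
#' @param peak apex elevation in m.
#' @param cell_size m per cell edge.
#' @export
cone_elevation_grid <- function(nrow = 40, ncol = 40, peak = 1200,
                                cell_size = 90) {
  ar <- (nrow + 1) / 2; ac <- (ncol + 1) / 2
  d <- sqrt(outer(seq_len(nrow) - ar, seq_len(ncol) - ac, function(r, c) r^2 + c^2))
  z <- pmax(peak * (1 - d / max(d)), 0)
  elevation_grid(z, cell_size)
}

# ---- VCF writing and fixture bundles -----------------------------------

#' Write a variant matrix as VCF
#'
#' Minimal VCF v4.2 writer with GT (and DP when depths are present) used to
#' materialise simulated data; output round-trips through [read_vcf()]
#' without loss.
#'
#' @param vm a [variant_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(vm, path) {
  stopifnot(inherits(vm, "variant_matrix"))
  has_dp <- !is.null(vm$depth)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=islescreen",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vm$sample_ids), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  n_var <- ncol(vm$genotypes)
  recs <- vapply(seq_len(n_var), function(j) {
    g <- vm$genotypes[, j]
    cell <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    if (has_dp) cell <- paste0(cell, ":", vm$depth[, j])
    paste(c(vm$chromosome[j], vm$positions[j], ".", "A", "T", ".", "PASS", ".",
            if (has_dp) "GT:DP" else "GT", cell), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write a complete, mutually consistent fixture bundle
#'
#' Materialises every input the pipeline consumes: a VCF of simulated
#' genotypes, the sample manifest, the chromosome-3 heterochromatin mask
#' (1-based inclusive interval dialect), a land/water scene raster, an
#' elevation grid and a departures table.
#'
#' @param out_dir writable output directory (created if absent).
#' @param cfg a [sim_config()]; its seed also drives the scene geometry.
#' @return named character vector of the files written.
#' @export
write_fixture_bundle <- function(out_dir, cfg = sim_config()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0) stop("unwritable path: ", out_dir)
  sim <- simulate_divergent_populations(cfg)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             manifest = file.path(out_dir, "manifest.tsv"),
             mask = file.path(out_dir, "heterochromatin_mask.tsv"),
             scene = file.path(out_dir, "scene.asc"),
             elevation = file.path(out_dir, "elevation.asc"),
             departures = file.path(out_dir, "departures.tsv"))
  write_vcf(sim$vm, paths["vcf"])
  utils::write.table(sim$manifest, paths["manifest"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mask <- heterochromatin_mask()
  utils::write.table(mask, paths["mask"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sc <- simulate_geo_scene("nearshore_continental", seed = cfg$seed)
  write_ascii_grid(sc$scene$labels, paths["scene"], cellsize = sc$scene$cell_size)
  grid <- cone_elevation_grid()
  write_ascii_grid(grid$values, paths["elevation"], cellsize = grid$cell_size)
  dep <- data.frame(origin = "island_site",
                    destination_region = c("RegionA", "RegionB", "RegionA"),
                    mode = c("air", "air", "sea"), count = c(120L, 40L, 15L))
  utils::write.table(dep, paths["departures"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
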