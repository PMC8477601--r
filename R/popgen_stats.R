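# Variant processing and population-genetic statistics: SNP filtering,
# region masking, LD pruning, PCA, Hudson's FST, windowed nucleotide
# diversity and the island-vs-mainland rank-sum comparison.

#' Construct a diploid variant matrix
#'
#' Genotypes are alternate-allele counts (0/1/2, `NA` = missing) in a
#' samples x variants matrix, with optional per-genotype read depth, 1-based
#' positions and chromosome labels per variant.
#'
#' @param genotypes samples x variants integer matrix in \{0, 1, 2, NA\}.
#' @param positions 1-based variant positions, strictly increasing within a
#'   chromosome.
#' @param chromosome chromosome label per variant (recycled if length 1).
#' @param sample_ids sample identifiers (defaults to rownames).
#' @param depth optional samples x variants matrix of read depths.
#' @export
variant_matrix <- function(genotypes, positions, chromosome, sample_ids = NULL,
                           depth = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(sample_ids)) sample_ids <- rownames(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  if (length(chromosome) == 1) chromosome <- rep(chromosome, ncol(genotypes))
  if (length(positions) != ncol(genotypes) ||
      length(chromosome) != ncol(genotypes)) {
    stop("positions/chromosome length must match number of variants")
  }
  if (!all(genotypes %in% c(0L, 1L, 2L, NA))) stop("genotypes must be 0, 1, 2 or NA")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(genotypes))) stop("depth dimensions mismatch")
    if (any(depth < 0, na.rm = TRUE)) stop("depth must be >= 0")
  }
  for (chr in unique(chromosome)) {
    p <- positions[chromosome == chr]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", chr)
    }
  }
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- sample_ids
  structure(list(genotypes = genotypes, depth = depth,
                 positions = as.integer(positions),
                 chromosome = as.character(chromosome),
                 sample_ids = as.character(sample_ids)),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat("variant_matrix:", length(x$sample_ids), "samples x",
      ncol(x$genotypes), "variants on",
      length(unique(x$chromosome)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.variant_matrix <- function(x) dim(x$genotypes)

# subset a variant_matrix by variant index (logical or integer)
.vm_subset <- function(vm, keep) {
  variant_matrix(vm$genotypes[, keep, drop = FALSE],
                 vm$positions[keep], vm$chromosome[keep],
                 vm$sample_ids,
                 if (!is.null(vm$depth)) vm$depth[, keep, drop = FALSE])
}

#' Read genotypes from a VCF file
#'
#' Retains biallelic SNP records only (single-base REF and ALT); indels and
#' multiallelic records are dropped with a message. GT is decoded to
#' alternate-allele counts and DP to per-genotype depths; missing GT is
#' recorded missing.
#'
#' @param path VCF (v4.x) file, plain text or gzipped.
#' @param manifest optional `sample_manifest`; all manifest samples must be
#'   present in the VCF and the matrix is restricted to them, in manifest
#'   order.
#' @return a [variant_matrix()].
#' @export
read_vcf <- function(path, manifest = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n_rec <- nrow(vcf@fix)
  if (n_rec == 0) {
    ids <- colnames(vcf@gt)[-1]
    if (!is.null(manifest)) ids <- manifest$sample_id
    return(variant_matrix(matrix(integer(), length(ids), 0,
                                 dimnames = list(ids, NULL)),
                          integer(), character(), ids))
  }
  ref <- vcf@fix[, "REF"]
  alt <- vcf@fix[, "ALT"]
  snp <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0) {
    message("read_vcf: dropped ", n_drop, " non-biallelic-SNP record(s)")
    vcf <- vcf[snp, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- if (any(grepl("DP", vcf@gt[, "FORMAT"]))) {
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  } else NULL
  ids <- colnames(gt)
  if (!is.null(manifest)) {
    absent <- setdiff(manifest$sample_id, ids)
    if (length(absent)) {
      stop("manifest sample(s) absent from VCF: ", paste(absent, collapse = ", "))
    }
    gt <- gt[, manifest$sample_id, drop = FALSE]
    if (!is.null(dp)) dp <- dp[, manifest$sample_id, drop = FALSE]
    ids <- manifest$sample_id
  }
  # decode "0/1", "1|0", "./." etc. to alt-allele counts
  alleles <- gsub("[|]", "/", gt)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[alleles == "0/0"] <- 0L
  code[alleles %in% c("0/1", "1/0")] <- 1L
  code[alleles == "1/1"] <- 2L
  geno <- t(code)
  rownames(geno) <- ids
  variant_matrix(geno,
                 positions = as.integer(vcf@fix[, "POS"]),
                 chromosome = vcf@fix[, "CHROM"],
                 sample_ids = ids,
                 depth = if (!is.null(dp)) t(dp))
}

#' Printed heterochromatin intervals on chromosome 3
#'
#' The repeat-rich pericentromeric and telomeric regions of chromosome arms
#' 3R and 3L of the AgamP4 assembly that are masked before population
#' structure and diversity analysis. Coordinates are 1-based, both ends
#' inclusive.
#'
#' @return data.frame with `chromosome`, `start`, `end`.
#' @export
heterochromatin_mask <- function() {
  data.frame(
    chromosome = c("3R", "3R", "3L", "3L"),
    start = c(38988757L, 52161877L, 1L, 4264713L),
    end = c(41860198L, 53200684L, 1815119L, 5031692L)
  )
}

#' Read a BED-like interval file
#'
#' @param path TSV with columns chromosome, start, end (no header). This
#'   tool's native dialect is 1-based with both ends inclusive; standard
#'   0-based half-open BED is converted on read with `zero_based = TRUE`.
#' @param zero_based set TRUE when the file uses standard BED coordinates.
#' @export
read_intervals <- function(path, zero_based = FALSE) {
  tab <- utils::read.delim(path, header = FALSE, col.names = c("chromosome", "start", "end"),
                           colClasses = c("character", "integer", "integer"))
  if (zero_based) tab$start <- tab$start + 1L
  if (any(tab$start > tab$end)) stop("interval start > end")
  tab
}

# logical: is each variant inside any interval (1-based inclusive)?
.in_intervals <- function(chromosome, positions, intervals) {
  inside <- rep(FALSE, length(positions))
  for (k in seq_len(nrow(intervals))) {
    inside <- inside | (chromosome == intervals$chromosome[k] &
                          positions >= intervals$start[k] &
                          positions <= intervals$end[k])
  }
  inside
}

#' Filter variants by depth, accessibility, missingness and MAF
#'
#' Applies the standard SNP filter chain in a fixed order: (1) genotypes
#' with read depth below `min_depth` are set missing; (2) variants outside
#' the accessibility intervals are dropped (skipped when `accessibility` is
#' NULL); (3) variants with missingness above `max_missing` are dropped;
#' (4) variants with minor allele frequency below `min_maf` (computed on
#' non-missing genotypes) are dropped. A variant at exactly the MAF
#' threshold is retained (the removal rule is strictly "MAF < threshold").
#'
#' @param vm a [variant_matrix()].
#' @param accessibility optional interval data.frame (1-based inclusive) of
#'   accessible regions.
#' @param max_missing maximum tolerated missingness fraction per variant.
#' @param min_depth minimum per-genotype read depth.
#' @param min_maf minimum minor allele frequency.
#' @return the filtered [variant_matrix()]; counts of variants removed at
#'   each step are attached as attribute `filter_log`.
#' @export
filter_variants <- function(vm, accessibility = NULL, max_missing = 0.10,
                            min_depth = 8, min_maf = 0.01) {
  stopifnot(inherits(vm, "variant_matrix"))
  if (max_missing < 0 || max_missing > 1) stop("max_missing outside [0, 1]")
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf outside [0, 0.5]")
  geno <- vm$genotypes
  if (!is.null(vm$depth) && min_depth > 0) {
    geno[!is.na(vm$depth) & vm$depth < min_depth] <- NA_integer_
  }
  log <- c(accessibility = 0L, missingness = 0L, maf = 0L)
  keep <- rep(TRUE, ncol(geno))
  if (!is.null(accessibility)) {
    inside <- .in_intervals(vm$chromosome, vm$positions, accessibility)
    log["accessibility"] <- sum(keep & !inside)
    keep <- keep & inside
  }
  miss <- colMeans(is.na(geno))
  drop_miss <- keep & miss > max_missing
  log["missingness"] <- sum(drop_miss)
  keep <- keep & !drop_miss
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_maf <- keep & !is.na(maf) & maf < min_maf
  log["maf"] <- sum(drop_maf)
  keep <- keep & !drop_maf
  out <- variant_matrix(geno[, keep, drop = FALSE], vm$positions[keep],
                        vm$chromosome[keep], vm$sample_ids,
                        if (!is.null(vm$depth)) vm$depth[, keep, drop = FALSE])
  attr(out, "filter_log") <- log
  out
}

#' Restrict to chromosome-3 euchromatin
#'
#' Keeps variants on the retained chromosome arms (3R and 3L by default,
#' avoiding the polymorphic inversions on chromosomes 2 and X) that do not
#' fall inside any exclusion interval. Interval bounds are 1-based and
#' inclusive at both ends.
#'
#' @param vm a [variant_matrix()].
#' @param chromosomes chromosome labels to retain.
#' @param exclude interval data.frame of regions to mask (defaults to the
#'   printed [heterochromatin_mask()]).
#' @export
apply_region_filter <- function(vm, chromosomes = c("3R", "3L"),
                                exclude = heterochromatin_mask()) {
  stopifnot(inherits(vm, "variant_matrix"))
  keep <- vm$chromosome %in% chromosomes
  if (!is.null(exclude) && nrow(exclude) > 0) {
    keep <- keep & !.in_intervals(vm$chromosome, vm$positions, exclude)
  }
  .vm_subset(vm, keep)
}

#' Greedy LD pruning
#'
#' Slides a window of `window_snps` variants in steps of `step_snps` and,
#' within each window, greedily removes the later variant of any pair whose
#' squared genotype correlation exceeds `r2_threshold` (the earlier variant
#' is kept). Deterministic given the input variant order.
#'
#' @param vm a [variant_matrix()].
#' @param window_snps window width in variants.
#' @param step_snps step between window starts, in variants.
#' @param r2_threshold squared-correlation threshold above which a pair is
#'   considered linked.
#' @export
ld_prune <- function(vm, window_snps = 500, step_snps = 200, r2_threshold = 0.1) {
  stopifnot(inherits(vm, "variant_matrix"))
  n <- ncol(vm$genotypes)
  if (n < 2) return(vm)
  keep <- rep(TRUE, n)
  geno <- vm$genotypes
  starts <- seq(1L, n, by = step_snps)
  for (s in starts) {
    idx <- s:min(s + window_snps - 1L, n)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    g <- geno[, idx, drop = FALSE]
    # mean-impute so constant columns give NA correlation -> treated unlinked
    r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
    r2 <- r^2
    r2[is.na(r2)] <- 0
    for (j in seq_along(idx)) {
      if (!keep[idx[j]]) next
      linked <- which(r2[j, ] > r2_threshold)
      linked <- linked[linked > j & keep[idx[linked]]]
      keep[idx[linked]] <- FALSE
    }
  }
  .vm_subset(vm, keep)
}

#' PCA embedding of a genotype matrix
#'
#' Mean-centred decomposition of the (imputed) genotype matrix, the standard
#' visualisation of population structure. Missing genotypes are imputed to
#' the per-variant mean; when more than `n_snps` variants are available a
#' random subsample of exactly `n_snps` is drawn.
#'
#' @param vm a [variant_matrix()].
#' @param n_snps number of variants used (subsampled without replacement).
#' @param n_components number of principal components returned.
#' @param seed integer seed for the subsampling step.
#' @return list with `coordinates` (samples x components), and
#'   `explained_variance` (proportions, non-increasing).
#' @export
pca_embed <- function(vm, n_snps = 50000, n_components = 10, seed = 1) {
  stopifnot(inherits(vm, "variant_matrix"))
  if (nrow(vm$genotypes) < 2) stop("PCA requires at least 2 samples")
  geno <- vm$genotypes
  if (ncol(geno) > n_snps) {
    pick <- withr::with_seed(seed, sort(sample.int(ncol(geno), n_snps)))
    geno <- geno[, pick, drop = FALSE]
  }
  g <- apply(geno, 2, function(col) {
    m <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- m
    col
  })
  g <- matrix(g, nrow = nrow(geno), dimnames = dimnames(geno))
  keep <- apply(g, 2, stats::var) > 0
  g <- g[, keep, drop = FALSE]
  n_components <- min(n_components, nrow(g) - 1, ncol(g))
  fit <- stats::prcomp(g, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  list(coordinates = fit$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)])
}

# per-site alt-allele frequencies and allele counts for a sample subset
.allele_stats <- function(vm, samples) {
  idx <- match(samples, vm$sample_ids)
  if (any(is.na(idx))) {
    stop("unknown sample id(s): ", paste(samples[is.na(idx)], collapse = ", "))
  }
  g <- vm$genotypes[idx, , drop = FALSE]
  n <- 2 * colSums(!is.na(g))
  p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / n, NA_real_)
  list(p = p, n = n)
}

#' Hudson's FST estimator between two populations
#'
#' Moment estimator of the fixation index with sample-size correction.
#' Per site s, with sample allele frequencies p_a, p_b from n_a, n_b
#' observed alleles:
#' numerator N_s = (p_a - p_b)^2 - p_a(1-p_a)/(n_a-1) - p_b(1-p_b)/(n_b-1),
#' denominator D_s = p_a(1-p_b) + p_b(1-p_a).
#' The estimate is the ratio of averages sum(N_s)/sum(D_s) over sites with
#' D_s > 0; sites with D_s = 0 (both populations monomorphic for the same
#' allele) or with fewer than 2 observed alleles in either population are
#' excluded and counted. Negative estimates are reported, not clamped.
#'
#' @param vm a [variant_matrix()].
#' @param pop_a,pop_b character vectors of sample ids.
#' @param label_a,label_b population labels carried in the result.
#' @return list of class `fst_estimate` with `value`, `n_sites_used`,
#'   `n_sites_excluded`, `pop_a`, `pop_b`.
#' @export
hudson_fst <- function(vm, pop_a, pop_b, label_a = "pop_a", label_b = "pop_b") {
  stopifnot(inherits(vm, "variant_matrix"))
  a <- .allele_stats(vm, pop_a)
  b <- .allele_stats(vm, pop_b)
  usable <- a$n >= 2 & b$n >= 2
  pa <- a$p[usable]; pb <- b$p[usable]
  na <- a$n[usable]; nb <- b$n[usable]
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  used <- den > 0
  if (!any(used)) stop("no informative sites")
  structure(list(value = sum(num[used]) / sum(den[used]),
                 n_sites_used = sum(used),
                 n_sites_excluded = ncol(vm$genotypes) - sum(used),
                 pop_a = label_a, pop_b = label_b),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("Hudson FST(%s, %s) = %.4f over %d sites (%d excluded)\n",
              x$pop_a, x$pop_b, x$value, x$n_sites_used, x$n_sites_excluded))
  invisible(x)
}

#' All pairwise Hudson FST values between populations
#'
#' @param vm a [variant_matrix()].
#' @param populations named list of sample-id vectors.
#' @return data.frame with `pop_a`, `pop_b`, `fst`, `n_sites_used`.
#' @export
pairwise_fst <- function(vm, populations) {
  pops <- names(populations)
  pairs <- utils::combn(pops, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    est <- hudson_fst(vm, populations[[pairs[1, k]]], populations[[pairs[2, k]]],
                      pairs[1, k], pairs[2, k])
    data.frame(pop_a = pairs[1, k], pop_b = pairs[2, k],
               fst = est$value, n_sites_used = est$n_sites_used)
  })
  do.call(rbind, out)
}

#' Windowed nucleotide diversity
#'
#' Nucleotide diversity (pi), the average number of pairwise nucleotide
#' differences per site, computed in non-overlapping windows tiled from
#' position 1. Per segregating site the unbiased contribution is
#' 2*p*(1-p)*n/(n-1) with p the sample alternate-allele frequency and n the
#' number of non-missing alleles; sites with n < 2 contribute 0. The window
#' denominator is the window length in bases, so uncalled and monomorphic
#' positions count as invariant.
#'
#' @param vm a [variant_matrix()].
#' @param samples sample ids of the population.
#' @param window window width in bp (default 10 kb).
#' @param population label carried in the output.
#' @param chromosome_length optional named vector of chromosome lengths; by
#'   default windows extend to the last variant's window.
#' @return data.frame with `chromosome`, `start`, `end`, `pi`, `n_variants`,
#'   `population`; windows are non-overlapping and pi >= 0.
#' @export
windowed_pi <- function(vm, samples, window = 10000, population = "pop",
                        chromosome_length = NULL) {
  stopifnot(inherits(vm, "variant_matrix"))
  if (window <= 0) stop("window must be > 0")
  st <- .allele_stats(vm, samples)
  contrib <- ifelse(st$n >= 2, 2 * st$p * (1 - st$p) * st$n / (st$n - 1), 0)
  out <- list()
  for (chr in unique(vm$chromosome)) {
    on_chr <- vm$chromosome == chr
    pos <- vm$positions[on_chr]
    len <- if (!is.null(chromosome_length) && chr %in% names(chromosome_length)) {
      chromosome_length[[chr]]
    } else max(pos)
    n_win <- ceiling(len / window)
    win_of <- pmin((pos - 1L) %/% window + 1L, n_win)
    pi_sum <- vapply(seq_len(n_win), function(w) sum(contrib[on_chr][win_of == w]),
                     numeric(1))
    n_var <- tabulate(win_of, nbins = n_win)
    out[[chr]] <- data.frame(
      chromosome = chr,
      start = (seq_len(n_win) - 1L) * as.integer(window) + 1L,
      end = pmin(seq_len(n_win) * as.integer(window), as.integer(len)),
      pi = pi_sum / window,
      n_variants = n_var,
      population = population)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Wilcoxon rank-sum comparison of two diversity samples
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test, as used to compare
#' per-window nucleotide diversity between island and mainland populations.
#' Exact enumeration is used when both samples have at most 8 values and no
#' ties are present; otherwise the tie-corrected normal approximation.
#'
#' @param group1,group2 numeric vectors (e.g. per-window pi values).
#' @return list with `statistic` (rank-sum W), `p_value`, `method`.
#' @export
rank_sum_compare <- function(group1, group2) {
  if (length(group1) == 0 || length(group2) == 0) stop("empty group")
  exact <- max(length(group1), length(group2)) <= 8 &&
    !anyDuplicated(c(group1, group2))
  ht <- stats::wilcox.test(group1, group2, alternative = "two.sided",
                           exact = exact, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Spearman correlation between isolation and a genetic metric
#'
#' Rank correlation across sites between a geographic-isolation metric and a
#' genetic one (divergence or diversity), the generic form of the
#' isolation-divergence relationship. Pairs with missing values are dropped;
#' at least 3 complete pairs are required.
#'
#' @param isolation,genetic paired numeric vectors per site.
#' @return list with `rho` and `p_value` (two-sided).
#' @export
isolation_divergence_correlation <- function(isolation, genetic) {
  if (length(isolation) != length(genetic)) stop("inputs must be paired")
  ok <- stats::complete.cases(isolation, genetic)
  if (sum(ok) < 3) stop("fewer than 3 complete pairs")
  ht <- suppressWarnings(
    stats::cor.test(isolation[ok], genetic[ok], method = "spearman",
                    alternative = "two.sided"))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = sum(ok))
}
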