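# Independent brute-force oracles and small constructors used across tests.
# Oracles are deliberately written as plain loops over the definitions, not
# as calls into the package's vectorised implementations.

# Hudson FST by per-site loops over the moment formulas
oracle_hudson_fst <- function(geno_a, geno_b) {
  num_sum <- 0
  den_sum <- 0
  for (j in seq_len(ncol(geno_a))) {
    ga <- geno_a[, j]
    gb <- geno_b[, j]
    na <- 2 * sum(!is.na(ga))
    nb <- 2 * sum(!is.na(gb))
    if (na < 2 || nb < 2) next
    pa <- sum(ga, na.rm = TRUE) / na
    pb <- sum(gb, na.rm = TRUE) / nb
    d <- pa * (1 - pb) + pb * (1 - pa)
    if (d <= 0) next
    num_sum <- num_sum + (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
    den_sum <- den_sum + d
  }
  num_sum / den_sum
}

# nucleotide diversity as the literal average pairwise haplotype difference
# count divided by sequence length
oracle_pairwise_pi <- function(haplotypes, seq_length) {
  n <- nrow(haplotypes)
  pairs <- utils::combn(n, 2)
  diffs <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    diffs[k] <- sum(haplotypes[pairs[1, k], ] != haplotypes[pairs[2, k], ])
  }
  mean(diffs) / seq_length
}

# exhaustive-enumeration two-sided Mann-Whitney p-value (no ties)
oracle_rank_sum_p <- function(g1, g2) {
  n1 <- length(g1)
  all_vals <- c(g1, g2)
  u_stat <- function(idx) {
    x <- all_vals[idx]
    y <- all_vals[-idx]
    sum(outer(x, y, ">")) # U for group 1
  }
  u_obs <- sum(outer(g1, g2, ">"))
  combos <- utils::combn(length(all_vals), n1)
  u_null <- apply(combos, 2, u_stat)
  min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
}

# exhaustive pair scan for the island-to-mainland raster distance
oracle_distance <- function(scene) {
  lab <- scene$labels
  focal <- which(lab == 1L, arr.ind = TRUE)
  main <- which(lab == 3L, arr.ind = TRUE)
  best <- Inf
  for (i in seq_len(nrow(focal))) {
    for (j in seq_len(nrow(main))) {
      d <- sqrt(sum((focal[i, ] - main[j, ])^2))
      if (d < best) best <- d
    }
  }
  best * scene$cell_size
}

# rasterised brute-force SLMP: per-cell distance transform to the focal
# perimeter by explicit loops, then counting
oracle_slmp <- function(scene, buffers = c(100, 1000, 10000)) {
  lab <- scene$labels
  nr <- nrow(lab)
  nc <- ncol(lab)
  is_focal <- lab == 1L
  perim <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!is_focal[i, j]) next
      if (i == 1 || i == nr || j == 1 || j == nc ||
          !is_focal[i - 1, j] || !is_focal[i + 1, j] ||
          !is_focal[i, j - 1] || !is_focal[i, j + 1]) {
        perim[i, j] <- TRUE
      }
    }
  }
  pc <- which(perim, arr.ind = TRUE)
  total <- 0
  for (b in buffers) {
    n_in <- 0
    n_land <- 0
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        if (is_focal[i, j]) next
        dmin <- Inf
        for (k in seq_len(nrow(pc))) {
          d <- sqrt((i - pc[k, 1])^2 + (j - pc[k, 2])^2) * scene$cell_size
          if (d < dmin) dmin <- d
        }
        if (dmin <= b) {
          n_in <- n_in + 1
          if (lab[i, j] != 0L) n_land <- n_land + 1
        }
      }
    }
    total <- total + if (n_in > 0) n_land / n_in else 0
  }
  total
}

# random scene with a compact focal blob, scattered land and a mainland block
random_scene <- function(nr = 30, nc = 30, cell_size = 10, p_land = 0.1,
                         with_mainland = TRUE) {
  lab <- matrix(0L, nr, nc)
  lab[matrix(runif(nr * nc) < p_land, nr, nc)] <- 2L
  if (with_mainland) lab[, (nc - 2):nc] <- 3L
  fr <- sample(3:(nr %/% 2), 1)
  fc <- sample(3:(nc %/% 3), 1)
  lab[fr + (-1:1), fc + (-1:1)] <- 1L
  geo_scene(lab, cell_size)
}

# random small genotype table (samples x loci) with missingness
random_genotypes <- function(n_samples, n_loci, miss = 0.1) {
  g <- matrix(rbinom(n_samples * n_loci, 2, runif(n_loci, 0.1, 0.9)[rep(seq_len(n_loci), each = n_samples)]),
              n_samples, n_loci)
  g[matrix(runif(n_samples * n_loci) < miss, n_samples, n_loci)] <- NA_integer_
  g
}

# a small hand-constructed VCF: 5 records of which 2 are indels, 3 samples,
# one missing genotype; returns the file path
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "3R\t100\t.\tA\tT\t50\tPASS\t.\tGT:DP\t0/0:20\t0/1:15\t1/1:12",
    "3R\t200\t.\tAT\tA\t50\tPASS\t.\tGT:DP\t0/0:20\t0/0:20\t0/1:20",
    "3R\t300\t.\tC\tG\t50\tPASS\t.\tGT:DP\t./.:3\t0/1:9\t0/0:30",
    "3R\t400\t.\tG\tGTT\t50\tPASS\t.\tGT:DP\t0/0:20\t0/0:20\t0/0:20",
    "3L\t500\t.\tT\tC\t50\tPASS\t.\tGT:DP\t1/1:25\t0/1:14\t0/0:19"
  )
  writeLines(lines, path)
  path
}

pop_ids <- function(sim, pop) sim$manifest$sample_id[sim$manifest$population == pop]
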