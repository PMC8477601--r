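test_that("VCF reading keeps biallelic SNPs and decodes GT/DP", {
  path <- write_toy_vcf()
  expect_message(vm <- read_vcf(path), "2 non-biallelic")
  expect_equal(dim(vm), c(3, 3))
  expect_equal(vm$positions, c(100L, 300L, 500L))
  expect_equal(vm$chromosome, c("3R", "3R", "3L"))
  expect_equal(unname(vm$genotypes[, 1]), c(0L, 1L, 2L))
  expect_true(is.na(vm$genotypes["S1", 2])) # ./. recorded missing
  expect_equal(unname(vm$depth[, 1]), c(20, 15, 12))
})

test_that("VCF reading honours the manifest and flags absent samples", {
  path <- write_toy_vcf()
  man <- data.frame(sample_id = c("S3", "S1"), population = "p")
  vm <- suppressMessages(read_vcf(path, man))
  expect_equal(vm$sample_ids, c("S3", "S1"))
  bad <- data.frame(sample_id = c("S1", "S9"), population = "p")
  expect_error(suppressMessages(read_vcf(path, bad)), "S9")
})

test_that("a VCF without variants yields a valid empty matrix", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1", "S2"), collapse = "\t")), path)
  vm <- suppressWarnings(read_vcf(path))
  expect_equal(ncol(vm$genotypes), 0)
})

make_vm <- function(geno, pos, chrom, depth = NULL) {
  variant_matrix(geno, pos, chrom, depth = depth)
}

test_that("filter chain applies depth, missingness and MAF rules in order", {
  # 10 samples, 4 variants:
  # v1 clean; v2 has 2/10 genotypes missing (20% > 10%); v3 clean but 2
  # genotypes at depth 5 (become missing -> 20% missingness); v4 monomorphic
  # (MAF 0 < 1%)
  g <- cbind(rep(c(0L, 1L), 5),
             c(NA, NA, rep(1L, 8)),
             rep(c(1L, 0L), 5),
             rep(0L, 10))
  dp <- matrix(20, 10, 4)
  dp[1:2, 3] <- 5
  vm <- make_vm(g, c(100L, 200L, 300L, 400L), "3R", dp)
  out <- filter_variants(vm)
  expect_equal(out$positions, 100L)
  expect_equal(attr(out, "filter_log")[["missingness"]], 2)
  expect_equal(attr(out, "filter_log")[["maf"]], 1)
})

test_that("a variant at exactly the MAF threshold is retained", {
  # 50 diploids: 1 alt allele among 100 -> MAF exactly 0.01
  g_boundary <- c(1L, rep(0L, 49))
  g_below <- rep(0L, 50)
  g_common <- rep(c(0L, 2L), 25)
  vm <- make_vm(cbind(g_boundary, g_below, g_common),
                c(10L, 20L, 30L), "3R")
  out <- filter_variants(vm, min_depth = 0)
  expect_equal(out$positions, c(10L, 30L))
})

test_that("the accessibility mask and full-pass identity behave", {
  g <- matrix(rep(c(0L, 1L, 2L, 1L), 5), 5, 4)
  vm <- make_vm(g, c(100L, 5000L, 9000L, 20000L), "3R",
                matrix(30, 5, 4))
  acc <- data.frame(chromosome = "3R", start = 1L, end = 10000L)
  out <- filter_variants(vm, accessibility = acc)
  expect_equal(out$positions, c(100L, 5000L, 9000L))
  # identity: nothing to remove
  ident <- filter_variants(vm)
  expect_equal(ident$genotypes, vm$genotypes)
})

test_that("filtering is idempotent", {
  withr::with_seed(7, {
    g <- random_genotypes(20, 50, miss = 0.08)
    vm <- make_vm(g, sort(sample.int(1e5, 50)), "3R",
                  matrix(rpois(20 * 50, 15), 20, 50))
    once <- filter_variants(vm)
    twice <- filter_variants(once)
    expect_equal(twice$genotypes, once$genotypes)
    expect_equal(twice$positions, once$positions)
  })
})

test_that("region filter keeps chromosome-3 euchromatin with inclusive bounds", {
  g <- matrix(1L, 4, 6)
  vm <- make_vm(g, c(1000000L, 2000000L, 500L, 38988756L, 41860198L, 41860199L),
                c("3L", "3L", "2R", "3R", "3R", "3R"))
  out <- apply_region_filter(vm)
  # 3L:1,000,000 inside 3L:1-1,815,119 -> removed; 3L:2,000,000 kept;
  # 2R dropped; 3R:38,988,756 kept (one before the mask start);
  # 3R:41,860,198 removed (inclusive end); 41,860,199 kept
  expect_equal(out$positions, c(2000000L, 38988756L, 41860199L))
  expect_equal(out$chromosome, c("3L", "3R", "3R"))
})

test_that("LD pruning removes exactly one of a duplicated variant pair", {
  withr::with_seed(13, {
    base <- rbinom(40, 2, 0.4)
    g <- cbind(base, base, rbinom(40, 2, 0.5))
    vm <- make_vm(g, c(10L, 20L, 30L), "3R")
    out <- ld_prune(vm)
    expect_equal(ncol(out$genotypes), 2)
    expect_equal(out$positions[1], 10L) # the earlier copy is kept
    single <- make_vm(matrix(base, ncol = 1), 10L, "3R")
    expect_equal(ncol(ld_prune(single)$genotypes), 1)
  })
})

test_that("LD pruning retains nearly all independent variants", {
  sim <- simulate_divergent_populations(
    sim_config(n_pops = 1, samples_per_pop = 200, n_loci = 400,
               divergence_F = 0, missing_rate = 0, seed = 99))
  out <- ld_prune(sim$vm)
  expect_gte(ncol(out$genotypes) / 400, 0.95)
})

test_that("PCA embeds duplicated samples identically and orders variance", {
  withr::with_seed(17, {
    g <- random_genotypes(12, 80, miss = 0)
    g[2, ] <- g[1, ] # exact duplicate sample
    vm <- make_vm(g, sort(sample.int(1e6, 80)), "3R")
    emb <- pca_embed(vm, n_components = 5, seed = 1)
    expect_equal(emb$coordinates[1, ], emb$coordinates[2, ], tolerance = 1e-9)
    expect_true(all(diff(emb$explained_variance) <= 1e-12))
    one_sample <- make_vm(g[1, , drop = FALSE], vm$positions, "3R")
    expect_error(pca_embed(one_sample), "2 samples")
  })
})

test_that("PCA separates simulated divergent populations on PC1", {
  sim <- simulate_divergent_populations(
    sim_config(divergence_F = 0.2, n_loci = 1000, missing_rate = 0, seed = 23))
  emb <- pca_embed(sim$vm, n_components = 2, seed = 1)
  pc1 <- emb$coordinates[, 1]
  a <- pc1[sim$manifest$population == "pop1"]
  b <- pc1[sim$manifest$population == "pop2"]
  sep <- abs(mean(a) - mean(b))
  within_sd <- mean(c(sd(a), sd(b)))
  expect_gt(sep, 5 * within_sd)
})

test_that("Hudson FST is exact on fixed differences and errors without information", {
  g_a <- matrix(2L, 30, 10)
  g_b <- matrix(0L, 30, 10)
  vm <- make_vm(rbind(g_a, g_b), seq(10L, 100L, 10L), "3R")
  ids <- vm$sample_ids
  est <- hudson_fst(vm, ids[1:30], ids[31:60])
  expect_equal(est$value, 1.0)
  expect_equal(est$n_sites_used, 10)
  mono <- make_vm(matrix(0L, 10, 5), seq(5L), "3R")
  expect_error(hudson_fst(mono, mono$sample_ids[1:5], mono$sample_ids[6:10]),
               "no informative sites")
})

test_that("Hudson FST matches the per-site brute-force oracle on random tables", {
  withr::with_seed(29, {
    for (k in 1:100) {
      ga <- random_genotypes(6, 20, miss = 0.1)
      gb <- random_genotypes(8, 20, miss = 0.1)
      vm <- make_vm(rbind(ga, gb), sort(sample.int(1e5, 20)), "3R")
      ids <- vm$sample_ids
      est <- try(hudson_fst(vm, ids[1:6], ids[7:14]), silent = TRUE)
      orc <- oracle_hudson_fst(ga, gb)
      if (inherits(est, "try-error")) {
        expect_true(is.nan(orc) || !is.finite(orc))
      } else {
        expect_equal(est$value, orc, tolerance = 1e-12)
        expect_lte(est$value, 1)
      }
    }
  })
})

test_that("Hudson FST is invariant to population label swap and variant order", {
  withr::with_seed(37, {
    ga <- random_genotypes(10, 40, miss = 0.05)
    gb <- random_genotypes(10, 40, miss = 0.05)
    vm <- make_vm(rbind(ga, gb), sort(sample.int(1e6, 40)), "3R")
    ids <- vm$sample_ids
    ab <- hudson_fst(vm, ids[1:10], ids[11:20])$value
    ba <- hudson_fst(vm, ids[11:20], ids[1:10])$value
    expect_equal(ab, ba, tolerance = 1e-12)
    # FST depends on the set of sites, not their order along the chromosome
    perm <- sample(40)
    vmp <- variant_matrix(vm$genotypes[, perm], vm$positions, "3R",
                          vm$sample_ids)
    expect_equal(hudson_fst(vmp, ids[1:10], ids[11:20])$value, ab,
                 tolerance = 1e-12)
  })
})

test_that("windowed pi is zero on identical haplotypes and matches hand math", {
  g <- matrix(rep(c(0L, 2L, 0L), each = 4), 4, 3) # all samples identical
  vm <- make_vm(g, c(100L, 5000L, 9999L), "3R")
  pw <- windowed_pi(vm, vm$sample_ids)
  expect_true(all(pw$pi == 0))

  # 2 diploids (4 alleles), one site at frequency 0.5 in a 10 kb window
  g2 <- matrix(c(2L, 0L), 2, 1)
  vm2 <- make_vm(g2, 500L, "3R")
  pw2 <- windowed_pi(vm2, vm2$sample_ids)
  expect_equal(pw2$pi, 2 * 0.25 * (4 / 3) / 10000, tolerance = 1e-12)
})

test_that("windowed pi equals the enumerated pairwise-difference oracle", {
  withr::with_seed(43, {
    # 5 diploids from 10 explicit haplotypes over a 1 kb region
    haps <- matrix(rbinom(10 * 12, 1, 0.4), 10, 12)
    geno <- haps[seq(1, 9, 2), ] + haps[seq(2, 10, 2), ]
    storage.mode(geno) <- "integer"
    pos <- sort(sample.int(1000, 12))
    vm <- make_vm(geno, pos, "3R")
    pw <- windowed_pi(vm, vm$sample_ids, window = 1000)
    expect_equal(pw$pi, oracle_pairwise_pi(haps, 1000), tolerance = 1e-12)
  })
})

test_that("pi windows tile without overlap and allele relabeling is neutral", {
  withr::with_seed(47, {
    g <- random_genotypes(10, 30, miss = 0)
    pos <- sort(sample.int(45000, 30))
    vm <- make_vm(g, pos, "3R")
    pw <- windowed_pi(vm, vm$sample_ids)
    expect_true(all(pw$start == c(1, head(pw$end, -1) + 1)))
    # ref/alt swap: genotype g -> 2 - g
    vm_swap <- make_vm(2L - g, pos, "3R")
    expect_equal(windowed_pi(vm_swap, vm$sample_ids)$pi, pw$pi, tolerance = 1e-12)
  })
})

test_that("duplicating every sample changes pi only by the sampling correction", {
  withr::with_seed(53, {
    g <- random_genotypes(8, 25, miss = 0)
    pos <- sort(sample.int(10000, 25))
    vm1 <- make_vm(g, pos, "3R")
    vm2 <- make_vm(rbind(g, g), pos, "3R")
    pi1 <- sum(windowed_pi(vm1, vm1$sample_ids)$pi)
    pi2 <- sum(windowed_pi(vm2, vm2$sample_ids)$pi)
    # n/(n-1) with n=16 vs n=32 alleles: ratio (16/15)/(32/31)
    expect_equal(pi2 / pi1, (32 / 31) / (16 / 15), tolerance = 1e-9)
  })
})

test_that("rank-sum comparison reproduces exact and enumerated p-values", {
  same <- c(1.3, 2.1, 0.5, 3.2, 1.7, 2.9)
  expect_equal(rank_sum_compare(same, same)$p_value, 1.0)
  disjoint <- rank_sum_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disjoint$p_value, 0.1, tolerance = 1e-12)
  expect_equal(disjoint$method, "exact")
  withr::with_seed(59, {
    for (k in 1:5) {
      g1 <- round(runif(5, 0, 100), 3)
      g2 <- round(runif(5, 0, 100), 3)
      expect_equal(rank_sum_compare(g1, g2)$p_value, oracle_rank_sum_p(g1, g2),
                   tolerance = 1e-12)
    }
  })
  expect_error(rank_sum_compare(numeric(0), 1:3), "empty")
})

test_that("isolation-divergence correlation recovers monotone relations", {
  x <- c(5, 17, 39, 49, 87)
  expect_equal(isolation_divergence_correlation(x, x^2 + 1)$rho, 1)
  expect_equal(isolation_divergence_correlation(x, -x)$rho, -1)
  withr::with_seed(61, {
    a <- runif(20)
    b <- runif(20)
    got <- isolation_divergence_correlation(a, b)
    expect_equal(got$rho, unname(cor(rank(a), rank(b))), tolerance = 1e-12)
  })
  expect_error(isolation_divergence_correlation(c(1, 2, NA), c(1, NA, 3)),
               "3 complete pairs")
})
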