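test_that("generator is deterministic under the seed and validates its config", {
  a <- small_sim(seed = 5)$sim
  b <- small_sim(seed = 5)$sim
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$planted_outliers, b$truth$planted_outliers)
  c_ <- small_sim(seed = 6)$sim
  expect_false(identical(a$genotypes, c_$genotypes))

  expect_error(sim_config(fst = 1.2), "fst")
  expect_error(sim_config(deletion_size_range = c(40, 99999)), "50")
  expect_error(sim_config(private_alt_count = 40,
                          samples_per_population = 16), "infeasible")
  expect_error(sim_config(n_snps = 50, n_gwas_snps = 100), "infeasible")
})

test_that("Balding-Nichols moments: across-population variance tracks Fst", {
  # moment check against Var(q) = p (1 - p) F
  cfg <- sim_config(n_populations = 8, samples_per_population = 4,
                    n_snps = 10000, fst = 0.2, n_gwas_snps = 0,
                    n_planted_outliers = 0, n_rare = 0,
                    n_low_count_private = 0, n_private = 0, seed = 42)
  sim <- simulate_genotypes(cfg)
  q <- sim$truth$pop_freq
  p <- sim$truth$p_anc
  fst_hat <- mean(apply(q, 2, var)) / mean(p * (1 - p))
  expect_lt(abs(fst_hat - 0.2), 0.02)

  # F -> 0 limit: population frequencies collapse onto the ancestral one
  cfg0 <- sim_config(n_populations = 8, samples_per_population = 4,
                     n_snps = 10000, fst = 1e-4, n_gwas_snps = 0,
                     n_planted_outliers = 0, n_rare = 0,
                     n_low_count_private = 0, n_private = 0, seed = 43)
  sim0 <- simulate_genotypes(cfg0)
  fst0 <- mean(apply(sim0$truth$pop_freq, 2, var)) /
    mean(sim0$truth$p_anc * (1 - sim0$truth$p_anc))
  expect_lt(fst0, 0.01)
})

test_that("planted focal-only variants carry their exact chromosome counts", {
  s <- small_sim(seed = 9)
  sim <- s$sim
  focal <- sim$panel$sample[sim$panel$population == "FOCAL"]
  others <- setdiff(sim$panel$sample, focal)
  truth <- sim$truth$planted_sharing
  for (i in seq_len(nrow(truth))) {
    k <- truth$key[i]
    expect_identical(sum(sim$genotypes[focal, k]), truth$alt_count[i])
    expect_identical(sum(sim$genotypes[others, k]), 0L)
  }
  expect_setequal(unique(truth$class),
                  c("rare", "low_count_private", "private"))
  expect_true(all(truth$alt_count[truth$class == "rare"] == 1L))
  expect_true(all(truth$alt_count[truth$class == "private"] > 3L))
})

test_that("planted GWAS outliers realize a large focal-vs-pooled difference", {
  s <- small_sim(seed = 13)
  sim <- s$sim
  refs <- setdiff(unique(sim$panel$population), "FOCAL")
  ft <- population_frequencies(sim$genotypes, sim$panel,
                               snp_keys = sim$gwas$key,
                               groups = list(POOL = refs))
  d <- abs_freq_diff(ft, "FOCAL", "POOL")
  expect_true(all(d[sim$truth$planted_outliers] >= 0.5))
})

test_that("deletion simulator honours the validation and overlap geometry", {
  s <- small_sim(seed = 21)
  dels <- simulate_deletions(s$config, s$sim)
  sizes <- dels$calls$end - dels$calls$start
  expect_true(all(sizes > 50 & sizes < 100000))

  # same-locus calls overlap reciprocally >= 0.9 under the 2% jitter bound
  for (l in unique(dels$calls$locus)) {
    m <- dels$calls[dels$calls$locus == l, ]
    if (nrow(m) < 2) next
    pairs <- utils::combn(nrow(m), 2)
    ro <- reciprocal_overlap(m$start[pairs[1, ]], m$end[pairs[1, ]],
                             m$start[pairs[2, ]], m$end[pairs[2, ]])
    expect_true(all(ro >= 0.9))
  }

  # no carrier heterozygous SNP inside a true call; every false locus has one
  truth <- dels$truth
  for (r in seq_len(nrow(dels$calls))) {
    cl <- dels$calls[r, ]
    inside <- dels$het_sites$sample == cl$sample &
      dels$het_sites$chrom == cl$chrom &
      dels$het_sites$pos - 1 >= cl$start & dels$het_sites$pos - 1 < cl$end
    if (truth$is_false[cl$locus]) {
      expect_gte(sum(inside), 1L)
    } else {
      expect_identical(sum(inside), 0L)
    }
  }

  # with no planted false calls, validation passes everything
  cfg0 <- sim_config(n_populations = 2, n_snps = 300, n_gwas_snps = 10,
                     n_planted_outliers = 0, n_rare = 0,
                     n_low_count_private = 0, n_private = 0,
                     n_deletion_loci = 30, false_deletion_frac = 0,
                     genotyped_frac = 1, seed = 3)
  sim0 <- simulate_genotypes(cfg0)
  dels0 <- simulate_deletions(cfg0, sim0)
  merged <- merge_callsets(dels0$calls)
  val <- het_snp_validation(merged$sites, dels0$het_sites)
  expect_equal(val$summary$frac_zero_het, 1)
})

test_that("generator output survives its own writers and readers", {
  s <- small_sim(seed = 31)
  vp <- tempfile(fileext = ".vcf")
  write_vcf(s$sim$genotypes, s$sim$variants, vp)
  expect_identical(read_vcf(vp)$genotypes, s$sim$genotypes)

  dels <- simulate_deletions(s$config, s$sim)
  bp <- tempfile(fileext = ".bed")
  write_bed(dels$calls, bp)
  back <- read_bed(bp)
  expect_equal(back$start, dels$calls$start)
  expect_equal(back$sample, dels$calls$sample)
  hp <- tempfile(fileext = ".tsv")
  write_het_sites(dels$het_sites, hp)
  expect_equal(read_het_sites(hp), dels$het_sites, ignore_attr = TRUE)
})
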