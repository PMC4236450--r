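test_that("GT fields map to dosages, missing genotypes stay out of counts", {
  path <- write_vcf_text(c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\tANN_CLASS=synonymous;KNOWN\tGT\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\tANN_CLASS=nonsynonymous\tGT\t./.\t0/0",
    "chr2\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0|1\t1|1"),
    samples = c("S1", "S2"))
  x <- read_vcf(path)
  expect_identical(dim(x$genotypes), c(2L, 3L))
  expect_identical(unname(x$genotypes[, "chr1:100:A:G"]), c(1L, 2L))
  expect_true(is.na(x$genotypes["S1", "chr1:200:C:T"]))
  expect_identical(unname(x$genotypes[, "chr2:300:G:A"]), c(1L, 2L))
  expect_identical(x$variants$functional_class, c("synonymous", "nonsynonymous", "other"))
  expect_identical(x$variants$known_flag, c(TRUE, FALSE, FALSE))

  ac <- allele_count(x$genotypes, "chr1:200:C:T")
  expect_identical(ac$alt_count, 0L)
  expect_identical(ac$total_count, 2L)  # the missing sample shrinks the total
})

test_that("multiallelic records and panel/VCF sample mismatches are rejected", {
  path <- write_vcf_text(
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t1/2",
    samples = c("S1", "S2"))
  expect_error(read_vcf(path), "multiallelic")
  path2 <- write_vcf_text(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    samples = c("S1", "S2"))
  panel <- data.frame(sample = c("S1", "S3"), population = "P",
                      latitude = 0, longitude = 0)
  expect_error(read_vcf(path2, panel = panel), "S3")
})

test_that("write_vcf / read_vcf round-trips generator output exactly", {
  s <- small_sim(seed = 11)
  path <- tempfile(fileext = ".vcf")
  write_vcf(s$sim$genotypes, s$sim$variants, path)
  back <- read_vcf(path)
  expect_identical(back$genotypes, s$sim$genotypes)
  expect_identical(back$variants$key, s$sim$variants$key)
  expect_identical(back$variants$functional_class,
                   s$sim$variants$functional_class)
  expect_identical(back$variants$known_flag, s$sim$variants$known_flag)
  # and the panel TSV round-trips too
  pp <- tempfile(fileext = ".tsv")
  write_panel(s$sim$panel, pp)
  expect_equal(read_panel(pp), s$sim$panel, tolerance = 1e-12)
})

test_that("allele counts: arithmetic, bounds and the degenerate case", {
  m <- toy_matrix(c(0L, 1L, 2L))
  ac <- allele_count(m, 1)
  expect_identical(c(ac$alt_count, ac$total_count), c(3L, 6L))
  expect_equal(ac$frequency, 0.5)

  # 16 diploids with 10 alternate chromosomes: frequency 31.25%
  g16 <- toy_matrix(c(rep(2L, 5), rep(0L, 11)))
  expect_equal(allele_count(g16, 1)$frequency, 0.3125)
  # 2 of 32 chromosomes clears the 1/32 ~ 3.1% singleton bound
  g2 <- toy_matrix(c(1L, 1L, rep(0L, 14)))
  expect_equal(allele_count(g2, 1)$frequency, 0.0625)
  expect_gt(allele_count(g2, 1)$frequency, 0.03)

  all_missing <- toy_matrix(rep(NA_integer_, 3))
  ac0 <- allele_count(all_missing, 1)
  expect_true(ac0$degenerate)
  expect_identical(c(ac0$alt_count, ac0$total_count), c(0L, 0L))
  expect_error(allele_count(m, 1, samples = character(0)), "empty")

  # invariants on generator output: freq in [0,1], alt + ref = total
  s <- small_sim(seed = 2)
  ac_all <- allele_counts(s$sim$genotypes)
  expect_true(all(ac_all$frequency >= 0 & ac_all$frequency <= 1))
  expect_true(all(ac_all$alt_count +
                    (ac_all$total_count - ac_all$alt_count) ==
                    ac_all$total_count))
})

test_that("1/2/3 genotype coding is the dosage shift and refuses missingness", {
  m <- toy_matrix(c(0L, 1L, 2L))
  expect_identical(unname(code_genotypes(m)[, 1]), c(1L, 2L, 3L))
  zeros <- toy_matrix(rep(0L, 4))
  expect_true(all(code_genotypes(zeros) == 1L))
  expect_identical(code_genotypes(m) - 1L, m)
  m[1] <- NA
  expect_error(code_genotypes(m), "missing")
  expect_identical(ncol(drop_missing_variants(m)), 0L)
})

test_that("autosome filter honors whitelists and naming dialects", {
  m <- toy_matrix(rep(0L, 6), keys = c("chr1:1:A:G", "chrX:1:A:G", "chrM:1:A:G"))
  v <- data.frame(key = colnames(m), chrom = c("chr1", "chrX", "chrM"),
                  pos = 1L, ref = "A", alt = "G",
                  functional_class = "other", known_flag = FALSE)
  out <- filter_biallelic_autosomal(m, v)
  expect_identical(out$variants$chrom, "chr1")

  # plain-dialect variants against the chr-dialect whitelist still work
  v2 <- v; v2$chrom <- c("1", "X", "MT")
  expect_identical(filter_biallelic_autosomal(m, v2)$variants$chrom, "1")
  # without normalization the dialect mixture is an error, not an empty set
  expect_error(filter_biallelic_autosomal(m, v2, normalize = FALSE),
               "dialect")
  # all autosomal in the same dialect: identity
  v3 <- v; v3$chrom <- c("chr1", "chr2", "chr3")
  expect_identical(filter_biallelic_autosomal(m, v3)$genotypes, m)
})

test_that("concordance is set arithmetic on genotype-matched calls", {
  base <- data.frame(sample = "S1", chrom = "chr1", pos = c(1L, 2L, 3L, 4L),
                     ref = "A", alt = "G", genotype = c(1L, 2L, 1L, 0L))
  # calls {A,B,C}, truth {A,B,D}, site C assayed reference-homozygous
  calls <- base[1:3, ]
  truth <- base
  truth$genotype <- c(1L, 2L, 0L, 1L)
  rep <- concordance(calls, truth)
  expect_equal(rep$fdr, 1 / 3)
  expect_equal(rep$fnr, 1 / 3)
  expect_identical(rep$n_matching, 2L)

  # identity implies zero rates
  self <- concordance(truth, truth)
  expect_equal(c(self$fdr, self$fnr), c(0, 0))

  # empty callset: every truth variant missed, FDR undefined
  none <- concordance(truth[0, ], truth)
  expect_equal(none$fnr, 1)
  expect_true(is.na(none$fdr))
  expect_true(none$degenerate)

  # genotype-level matching: right site, wrong zygosity is an error both ways
  wrong <- truth[truth$genotype > 0, ]
  wrong$genotype <- 3L - wrong$genotype
  both <- concordance(wrong, truth)
  expect_equal(both$fdr, 1)
  expect_equal(both$fnr, 1)
})
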