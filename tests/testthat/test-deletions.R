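test_that("reciprocal overlap follows the min-fraction definition", {
  expect_equal(reciprocal_overlap(100, 200, 100, 200), 1)
  expect_equal(reciprocal_overlap(100, 200, 300, 400), 0)
  expect_equal(reciprocal_overlap(100, 200, 150, 250), 0.5)
  expect_equal(reciprocal_overlap(100, 200, 150, 250, same_chrom = FALSE), 0)
  # enumeration oracle on small integer intervals
  set.seed(14)
  for (i in 1:50) {
    a <- sort(sample(0:60, 2)); b <- sort(sample(0:60, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    pos <- 0:59
    o <- sum(pos >= max(a[1], b[1]) & pos < min(a[2], b[2]))
    expect_equal(reciprocal_overlap(a[1], a[2], b[1], b[2]),
                 min(o / diff(a), o / diff(b)))
  }
  expect_error(reciprocal_overlap(5, 5, 0, 10), "length")
})

test_that("size and genotyped filters apply their strict bounds", {
  calls <- data.frame(chrom = "chr1",
                      start = c(0, 0, 0, 0),
                      end = c(50, 51, 99999, 100000),
                      sample = "S1",
                      genotyped = c(TRUE, TRUE, FALSE, TRUE))
  kept <- size_filter(calls)
  expect_equal(kept$end, c(51, 99999))
  expect_equal(genotyped_filter(kept)$end, 51)
  expect_identical(nrow(genotyped_filter(kept[0, ])), 0L)
})

test_that("merging matches the brute-force oracle over many random callsets", {
  for (seed in 1:12) {
    set.seed(seed)
    calls <- random_callset(n = 250)
    got <- merge_callsets(calls, threshold = 0.8)
    want <- merge_oracle(calls, threshold = 0.8)
    # identical clusters...
    got_groups <- unname(split(seq_len(nrow(got$members)), got$members$site))
    expect_identical(got_groups[order(vapply(got_groups, min, 1L))],
                     unname(want[order(vapply(want, min, 1L))]))
    # ...and identical representatives (seed call of each cluster)
    seeds <- sort(vapply(want, min, 1L))
    expect_equal(got$sites$start,
                 sort_canonical(calls)$start[seeds])
  }
})

test_that("merging is deterministic, idempotent, and seed-consistent", {
  calls <- data.frame(chrom = "chr1",
                      start = c(100, 105, 170), end = c(200, 205, 270),
                      sample = c("A", "B", "C"))
  m <- merge_callsets(calls, threshold = 0.8)
  expect_identical(nrow(m$sites), 2L)          # 0.95 merges, 0.3 does not
  expect_identical(m$sites$n_carriers, c(2L, 1L))
  expect_identical(m$sites$carriers[1], "A,B")

  # permutation invariance
  m2 <- merge_callsets(calls[c(3, 1, 2), ], threshold = 0.8)
  expect_identical(m$sites, m2$sites)

  # idempotence: merging the representatives again changes nothing
  reps <- m$sites[, c("chrom", "start", "end")]
  reps$sample <- "merged"
  m3 <- merge_callsets(reps, threshold = 0.8)
  expect_identical(m3$sites[, c("chrom", "start", "end")],
                   m$sites[, c("chrom", "start", "end")])

  # every member overlaps its cluster seed at >= threshold (anti-chaining)
  set.seed(20)
  big <- random_callset(n = 600, span = 1e5)  # dense, chaining-prone
  mb <- merge_callsets(big, threshold = 0.8)
  for (s in mb$sites$site) {
    mem <- mb$members[mb$members$site == s, ]
    ro <- reciprocal_overlap(mb$sites$start[s], mb$sites$end[s],
                             mem$start, mem$end,
                             mem$chrom == mb$sites$chrom[s])
    expect_true(all(ro >= 0.8))
  }
})

test_that("novelty uses a strictly-greater 50% reciprocal rule", {
  sites <- data.frame(site = 1:3, chrom = "chr1",
                      start = c(100, 100, 100), end = c(200, 200, 200))
  reference <- data.frame(chrom = "chr1", start = 140, end = 240)
  out <- novelty_filter(sites[1, ], reference)
  expect_true(out$known)                      # overlap 0.6 > 0.5
  out2 <- novelty_filter(sites[1, ], data.frame(chrom = "chr2",
                                                start = 140, end = 240))
  expect_true(out2$novel)                     # different chromosome
  # exactly 0.5 stays novel
  out3 <- novelty_filter(sites[1, ], data.frame(chrom = "chr1",
                                                start = 150, end = 250))
  expect_true(out3$novel)
  # oracle comparison over random sites and references
  for (seed in 1:8) {
    set.seed(100 + seed)
    s <- random_callset(120)
    s$site <- seq_len(nrow(s))
    ref <- random_callset(80)[, c("chrom", "start", "end")]
    got <- novelty_filter(s, ref, threshold = 0.5)$known
    ro <- matrix(0, nrow(s), nrow(ref))
    for (i in seq_len(nrow(s))) {
      for (j in seq_len(nrow(ref))) {
        if (s$chrom[i] != ref$chrom[j]) next
        o <- max(0, min(s$end[i], ref$end[j]) - max(s$start[i], ref$start[j]))
        ro[i, j] <- min(o / (s$end[i] - s$start[i]),
                        o / (ref$end[j] - ref$start[j]))
      }
    }
    expect_identical(got, unname(apply(ro, 1, max) > 0.5))
  }
})

test_that("het-SNP validation counts carrier hets with half-open bounds", {
  sites <- data.frame(site = 1, chrom = "chr1", start = 1000, end = 2000,
                      carriers = "S1,S2")
  het <- data.frame(sample = c("S1", "S1", "S3", "S2", "S1"),
                    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
                    pos = c(1500, 1800, 1600, 1500, 2001))
  out <- het_snp_validation(sites, het)
  # S3 is not a carrier; chr2 does not overlap; 1-based 2001 = 0-based 2000
  # sits on the half-open boundary and is excluded
  expect_identical(out$sites$het_snp_count, 2L)
  expect_false(out$sites$validated)

  # boundary inclusion at the start: 1-based pos 1001 is 0-based 1000
  het2 <- data.frame(sample = "S1", chrom = "chr1", pos = 1001)
  expect_identical(het_snp_validation(sites, het2)$sites$het_snp_count, 1L)

  clean <- het_snp_validation(sites, het[0, ])
  expect_true(clean$sites$validated)
  expect_equal(clean$summary$frac_zero_het, 1)
})

test_that("deletion frequencies are deleted-allele counts over chromosomes", {
  expect_equal(deletion_frequency(2, 16), 0.0625)
  expect_gt(deletion_frequency(2, 16), 0.03)
  expect_equal(deletion_frequency(1, 16), 0.03125)
  expect_equal(deletion_frequency(c(1, 4), 16), c(0.03125, 0.125))
  expect_error(deletion_frequency(0, 16), "carrier")
  expect_error(deletion_frequency(40, 16), "exceeds")
})
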