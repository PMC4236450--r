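test_that("subset-polymorphism filter keeps exactly the everywhere-polymorphic variants", {
  s <- small_sim(seed = 4)
  g <- drop_missing_variants(s$sim$genotypes)
  out <- subset_polymorphic_filter(g, s$sim$panel, subset_size = 10, seed = 1)
  # recomputation from the recorded subsets agrees
  for (k in out$keep) {
    for (sub in out$subsets) {
      a <- sum(g[sub, k])
      expect_true(a > 0 && a < 2 * length(sub))
    }
  }
  # a removed variant is monomorphic in at least one subset
  removed <- setdiff(colnames(g), out$keep)[1:20]
  for (k in removed) {
    mono <- vapply(out$subsets, function(sub) {
      a <- sum(g[sub, k]); a == 0 || a == 2 * length(sub)
    }, logical(1))
    expect_true(any(mono))
  }
  # undersized populations contribute all their samples
  expect_true(all(lengths(out$subsets) == 10))
  out16 <- subset_polymorphic_filter(g, s$sim$panel, subset_size = 99)
  expect_true(all(lengths(out16$subsets) == 16))
  # determinism under the seed
  again <- subset_polymorphic_filter(g, s$sim$panel, subset_size = 10, seed = 1)
  expect_identical(again$keep, out$keep)
  expect_identical(again$subsets, out$subsets)
})

test_that("LD pruning removes duplicated columns and respects the r2 bound", {
  set.seed(8)
  base <- matrix(rbinom(32 * 20, 2, 0.5), 32, 20)
  dup <- base[, rep(1:20, each = 2)]  # adjacent duplicates, r2 = 1
  colnames(dup) <- paste0("chr1:", seq_len(40), ":A:G")
  kept <- ld_prune(dup, window = 10, step = 3)
  expect_identical(kept, colnames(dup)[seq(1, 39, by = 2)])

  # independent variants survive
  indep <- matrix(rbinom(64 * 100, 2, 0.5), 64, 100)
  colnames(indep) <- paste0("chr1:", 1:100, ":A:G")
  kept2 <- ld_prune(indep)
  # post-hoc: no kept within-window pair above the bound
  n <- length(kept2)
  for (st in seq(1, n, by = 5)) {
    idx <- st:min(st + 49, n)
    r2 <- suppressWarnings(cor(indep[, kept2[idx], drop = FALSE]))^2
    expect_true(all(r2[upper.tri(r2)] <= 0.5 | is.na(r2[upper.tri(r2)])))
  }

  # hand-built 3-variant window: r2(1,2) = 0.81 drops variant 2 only
  v1 <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 0)
  v2 <- c(0, 0, 1, 1, 2, 2, 0, 1, 1, 1)  # correlated with v1
  v3 <- c(2, 0, 2, 0, 1, 1, 1, 2, 0, 0)  # near-orthogonal
  m <- cbind(v1, v2, v3)
  colnames(m) <- paste0("chr1:", 1:3, ":A:G")
  expect_gt(cor(v1, v2)^2, 0.5)
  expect_lt(cor(v1, v3)^2, 0.5)
  expect_lt(cor(v2, v3)^2, 0.5)
  expect_identical(ld_prune(m, window = 3, step = 3),
                   colnames(m)[c(1, 3)])

  # zero-variance variants count as uncorrelated
  mz <- cbind(v1, rep(1, 10), v3)
  colnames(mz) <- paste0("chr1:", 1:3, ":A:G")
  expect_identical(ld_prune(mz, window = 3, step = 3), colnames(mz))
})

test_that("PCA scales columns, orders explained fractions, flags degeneracy", {
  s <- small_sim(seed = 19)
  g <- drop_missing_variants(s$sim$genotypes)
  coded <- code_genotypes(g)
  p <- suppressWarnings(pca_genotypes(coded))  # constant columns expected
  ef <- p$explained_fraction
  expect_true(all(diff(ef) <= 1e-12))
  expect_true(all(ef >= 0 & ef <= 1))
  expect_equal(sum(ef), 1)
  # orthogonal scores
  cross <- crossprod(p$scores[, 1:5])
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-8)

  expect_warning(p2 <- pca_genotypes(matrix(1L, 4, 3)), "constant")
  expect_true(p2$degenerate)
  expect_true(all(p2$scores == 0))
})

test_that("PC1 separates two planted populations at Fst 0.15", {
  cfg <- sim_config(n_populations = 2, samples_per_population = 16,
                    fst = 0.15, n_snps = 2000, n_gwas_snps = 10,
                    n_planted_outliers = 0, n_rare = 0,
                    n_low_count_private = 0, n_private = 0, seed = 23)
  sim <- simulate_genotypes(cfg)
  g <- sim$genotypes[, apply(sim$genotypes, 2, var) > 0]
  p <- pca_genotypes(code_genotypes(g))
  pc1 <- p$scores[, 1]
  a <- pc1[sim$panel$population == "FOCAL"]
  b <- pc1[sim$panel$population != "FOCAL"]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("genetic distance matches its formula and bounds", {
  m <- rbind(a = c(0L, 1L, 2L), b = c(2L, 1L, 0L))
  colnames(m) <- paste0("chr1:", 1:3, ":A:G")
  d <- genetic_distance(m)
  expect_equal(d["a", "b"], 2 / 3)
  expect_equal(diag(d), c(a = 0, b = 0))
  m2 <- rbind(a = c(0L, 0L), b = c(2L, 2L), c = c(0L, 0L))
  colnames(m2) <- paste0("chr1:", 1:2, ":A:G")
  d2 <- genetic_distance(m2)
  expect_equal(d2["a", "b"], 1)  # opposite homozygotes at every site
  expect_equal(d2["a", "c"], 0)  # identical samples
  expect_equal(d2, t(d2))
  # the euclidean alternative is plain dist() on the coded matrix
  expect_equal(genetic_distance(m2, method = "euclidean"),
               as.matrix(dist(m2)))
})

test_that("geographic distance is the 6371-km haversine", {
  panel <- data.frame(sample = c("a", "b", "c"),
                      population = "P",
                      latitude = c(0, 0, 0), longitude = c(0, 90, 0))
  d <- geographic_distance(panel)
  expect_equal(d["a", "b"], pi / 2 * 6371, tolerance = 1e-9) # quarter circle
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  skip_if_not_installed("geosphere")
  set.seed(12)
  p2 <- data.frame(sample = paste0("s", 1:6), population = "P",
                   latitude = runif(6, -89, 89),
                   longitude = runif(6, -179, 179))
  ref <- geosphere::distm(cbind(p2$longitude, p2$latitude),
                          fun = function(x, y)
                            geosphere::distHaversine(x, y, r = 6371000)) / 1000
  got <- geographic_distance(p2)
  expect_equal(unname(got), unname(ref), tolerance = 1e-9)
  pna <- panel; pna$latitude[2] <- NA
  expect_error(geographic_distance(pna), "b")
})

test_that("Mantel test: perfect association, invariance and cross-check", {
  set.seed(33)
  n <- 12
  x <- matrix(runif(n * n), n, n); x <- x + t(x); diag(x) <- 0
  rownames(x) <- colnames(x) <- paste0("s", 1:n)
  r <- mantel_test(x, 2 * x, n_perm = 199, seed = 1)
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 1 / 200)

  y <- matrix(runif(n * n), n, n); y <- y + t(y); diag(y) <- 0
  rownames(y) <- colnames(y) <- rownames(x)
  m <- mantel_test(x, y, n_perm = 499, seed = 2)
  expect_true(m$statistic >= -1 && m$statistic <= 1)
  expect_error(mantel_test(x, matrix(1, n, n) - diag(n)), "constant")

  skip_if_not_installed("vegan")
  ref <- vegan::mantel(as.dist(x), as.dist(y), permutations = 999)
  expect_equal(m$statistic, unname(ref$statistic), tolerance = 1e-12)
  # permutation p-values agree within Monte-Carlo noise
  expect_lt(abs(m$p_value - ref$signif), 0.1)
})

test_that("neighbor joining matches the brute-force Saitou-Nei oracle", {
  # unique 3-taxon solution
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  bl <- setNames(tr3$edge.length[tr3$edge[, 2] <= 3],
                 tr3$tip.label[tr3$edge[tr3$edge[, 2] <= 3, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 2))

  # additive matrices: exact topology and branch lengths recovered,
  # identical to the oracle's cophenetic distances
  set.seed(55)
  for (i in 1:10) {
    fx <- random_additive_matrix(6)
    got <- as.matrix(stats::cophenetic(nj_tree(fx$d)))
    want <- nj_cophenetic_oracle(fx$d)
    expect_equal(got[rownames(want), colnames(want)], want,
                 tolerance = 1e-8)
    expect_equal(got[rownames(fx$d), colnames(fx$d)], fx$d,
                 tolerance = 1e-8)
  }

  # two identical taxa form a zero-length cherry
  d4 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
               dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  tr4 <- nj_tree(d4)
  tip_edges <- tr4$edge.length[tr4$edge[, 2] %in% 1:2]
  expect_equal(tip_edges, c(0, 0))
  expect_error(nj_tree(matrix(-1, 3, 3)), "negative")

  # star-like input: equal pairwise distances give equal terminal branches
  ds <- matrix(4, 8, 8) - diag(4, 8)
  rownames(ds) <- colnames(ds) <- paste0("t", 1:8)
  trs <- nj_tree(ds)
  term <- trs$edge.length[trs$edge[, 2] <= 8]
  expect_equal(term, rep(2, 8))
})
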