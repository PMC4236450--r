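#' Ascertainment filter: polymorphic in a random subset of every population
#'
#' To compare populations of unequal depth on an equal footing, a fixed-size
#' subset of samples is drawn (without replacement) from every population
#' and only variants polymorphic - neither absent nor fixed - within every
#' subset are retained. Populations smaller than `subset_size` contribute
#' all their samples.
#'
#' @param genotypes Dosage matrix (no missing entries; see
#'   [drop_missing_variants()]).
#' @param panel Population panel.
#' @param subset_size Samples drawn per population (default 16).
#' @param seed Optional seed for the subset draw.
#' @return List: `genotypes` (filtered matrix), `keep` (retained variant
#'   keys), `subsets` (named list of the samples drawn per population).
#' @export
subset_polymorphic_filter <- function(genotypes, panel, subset_size = 16,
                                      seed = NULL) {
  pops <- unique(panel$population)
  if (length(pops) == 0L) stop("panel has no populations")
  if (!is.null(seed)) set.seed(seed)
  subsets <- lapply(pops, function(p) {
    s <- panel$sample[panel$population == p]
    if (length(s) == 0L) stop("population has no samples: ", p)
    if (length(s) > subset_size) sort(sample(s, subset_size)) else s
  })
  names(subsets) <- pops
  keep <- rep(TRUE, ncol(genotypes))
  for (s in subsets) {
    g <- genotypes[s, , drop = FALSE]
    if (anyNA(g)) stop("missing genotypes present; filter them first")
    a <- colSums(g)
    keep <- keep & a > 0L & a < 2L * nrow(g)
  }
  list(genotypes = genotypes[, keep, drop = FALSE],
       keep = colnames(genotypes)[keep], subsets = subsets)
}

#' Sliding-window LD pruning of a genotype matrix
#'
#' PLINK-style `indep-pairwise` pruning: a window of `window` variants (in
#' position order) advances by `step`; within each window, for every pair
#' of still-retained variants with squared dosage correlation above
#' `r2_max`, the later variant of the pair is removed. Zero-variance
#' variants are uncorrelated with everything by convention (r2 = 0).
#'
#' @param genotypes Dosage or 1/2/3-coded matrix, no missing entries.
#' @param window Window size in variants (default 50).
#' @param step Window shift in variants (default 5).
#' @param r2_max Squared-correlation threshold (default 0.5).
#' @return Character vector of retained variant keys, in input order.
#' @export
ld_prune <- function(genotypes, window = 50, step = 5, r2_max = 0.5) {
  if (anyNA(genotypes)) stop("missing genotypes present; filter them first")
  stopifnot(window >= 2, step >= 1)
  n <- ncol(genotypes)
  kept <- rep(TRUE, n)
  starts <- seq(1L, n, by = step)
  for (st in starts) {
    idx <- st:min(st + window - 1L, n)
    idx <- idx[kept[idx]]
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(stats::cor(genotypes[, idx, drop = FALSE]))^2
    r2[is.na(r2)] <- 0  # zero-variance columns
    # scan later variants in order: drop one if any earlier kept partner
    # in the window exceeds the threshold
    local_kept <- rep(TRUE, length(idx))
    for (jj in 2:length(idx)) {
      if (any(r2[seq_len(jj - 1L), jj][local_kept[seq_len(jj - 1L)]] > r2_max)) {
        local_kept[jj] <- FALSE
      }
    }
    kept[idx] <- local_kept
    if (st + window - 1L >= n) break
  }
  colnames(genotypes)[kept]
}

#' Principal component analysis of a coded genotype matrix
#'
#' Columns are centred and scaled to unit variance (zero-variance columns
#' are dropped with a warning), and scores are taken from the singular
#' value decomposition via [stats::prcomp()]. The explained fraction of
#' component k is its eigenvalue over the sum of all eigenvalues.
#'
#' @param coded 1/2/3-coded (or dosage) matrix, samples in rows.
#' @return Object of class `pca_result`: list with `scores` (samples x
#'   components), `explained_fraction`, `dropped` (zero-variance variant
#'   keys), `degenerate` (TRUE when no sample-axis variation exists).
#' @export
pca_genotypes <- function(coded) {
  if (nrow(coded) < 2L) stop("PCA needs at least 2 samples")
  v <- apply(coded, 2L, stats::var)
  if (all(v == 0)) {
    warning("all variants are constant across samples; degenerate PCA")
    out <- list(scores = matrix(0, nrow(coded), 1L,
                                dimnames = list(rownames(coded), "PC1")),
                explained_fraction = 0, dropped = colnames(coded),
                degenerate = TRUE)
    class(out) <- "pca_result"
    return(out)
  }
  dropped <- colnames(coded)[v == 0]
  if (length(dropped) > 0L) {
    warning(length(dropped), " zero-variance variant(s) dropped before scaling")
    coded <- coded[, v > 0, drop = FALSE]
  }
  if (ncol(coded) < 2L) stop("fewer than 2 usable (non-constant) variants")
  pr <- stats::prcomp(coded, center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2
  out <- list(scores = pr$x, explained_fraction = ev / sum(ev),
              dropped = dropped, degenerate = FALSE)
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components; PC1 %.1f%%, PC2 %.1f%% of variance%s\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$explained_fraction[1],
              100 * ifelse(length(x$explained_fraction) > 1,
                           x$explained_fraction[2], NA),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Pairwise genetic distance between individuals
#'
#' Default is the allele-sharing distance
#' `d(i, j) = mean_v |g_iv - g_jv| / 2`, i.e. the mean per-variant allele
#' difference, which is 0 for identical genomes and 1 for opposite
#' homozygotes at every site. `method = "euclidean"` gives the Euclidean
#' distance on the coded matrix as an alternative metric.
#'
#' @param genotypes Dosage or coded matrix, no missing entries.
#' @param method `"allele_sharing"` (default) or `"euclidean"`.
#' @return Symmetric distance matrix with zero diagonal, labelled by sample.
#' @export
genetic_distance <- function(genotypes,
                             method = c("allele_sharing", "euclidean")) {
  method <- match.arg(method)
  if (anyNA(genotypes)) stop("missing genotypes present; filter them first")
  d <- switch(method,
    allele_sharing = as.matrix(stats::dist(genotypes, method = "manhattan")) /
      (2 * ncol(genotypes)),
    euclidean = as.matrix(stats::dist(genotypes)))
  dimnames(d) <- list(rownames(genotypes), rownames(genotypes))
  d
}

#' Great-circle geographic distance between sampling locations
#'
#' Haversine distance on a sphere of radius 6371 km between every pair of
#' samples in the panel.
#'
#' @param panel Population panel with `latitude`/`longitude` for every
#'   sample.
#' @return Symmetric distance matrix in kilometres, labelled by sample.
#' @export
geographic_distance <- function(panel) {
  miss <- panel$sample[is.na(panel$latitude) | is.na(panel$longitude)]
  if (length(miss) > 0L) {
    stop("missing coordinates for sample(s): ", paste(miss, collapse = ", "))
  }
  lat <- panel$latitude * pi / 180
  lon <- panel$longitude * pi / 180
  n <- length(lat)
  d <- matrix(0, n, n, dimnames = list(panel$sample, panel$sample))
  for (i in seq_len(n - 1L)) {
    jj <- (i + 1L):n
    h <- sin((lat[jj] - lat[i]) / 2)^2 +
      cos(lat[i]) * cos(lat[jj]) * sin((lon[jj] - lon[i]) / 2)^2
    d[i, jj] <- d[jj, i] <- 2 * 6371 * asin(pmin(1, sqrt(h)))
  }
  d
}

#' Mantel test of association between two distance matrices
#'
#' Pearson correlation of the upper off-diagonal triangles, with a
#' permutation null obtained by jointly permuting the rows and columns of
#' the second matrix. The p-value is one-sided (positive association) with
#' the add-one correction: `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`.
#'
#' @param d1,d2 Square symmetric distance matrices over the same ids (if
#'   both carry dimnames, `d2` is aligned to `d1`'s order).
#' @param n_perm Number of permutations (default 9999, minimum 99).
#' @param seed Optional seed for the permutation stream.
#' @return Object of class `mantel_result`: list with `statistic` (r),
#'   `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL) {
  stopifnot(nrow(d1) == ncol(d1), nrow(d2) == ncol(d2),
            nrow(d1) == nrow(d2), n_perm >= 99)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2))) {
      stop("distance matrices are over different ids")
    }
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  v2 <- d2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("constant distance matrix: Mantel r is undefined")
  }
  r <- stats::cor(v1, v2)
  n <- nrow(d1)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    stats::cor(v1, d2[p, p][ut])
  }, numeric(1))
  out <- list(statistic = r,
              p_value = (sum(r_perm >= r) + 1) / (n_perm + 1),
              n_perm = n_perm)
  class(out) <- "mantel_result"
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, one-sided)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration via [ape::nj()]; negative inferred
#' branch lengths (possible on non-additive input) are clamped to zero with
#' a warning.
#'
#' @param d Symmetric non-negative distance matrix over >= 3 ids.
#' @return An unrooted `phylo` tree (write with [ape::write.tree()]).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(d < 0)) stop("negative input distances")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0),
            " negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write a distance matrix as TSV
#' @param d Distance matrix.
#' @param path File path.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(data.frame(id = rownames(d), d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
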