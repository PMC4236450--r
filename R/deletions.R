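#' Reciprocal overlap of two genomic intervals
#'
#' For intervals on the same chromosome (0-based half-open), the overlap
#' length divided by the length of the longer interval - equivalently
#' `min(o / len(a), o / len(b))`. Intervals on different chromosomes have
#' reciprocal overlap 0.
#'
#' @param a_start,a_end,b_start,b_end Interval bounds (vectors recycle).
#' @param same_chrom Logical; FALSE forces 0 (vectorized).
#' @return Numeric vector of fractions in [0, 1].
#' @examples
#' reciprocal_overlap(100, 200, 150, 250)  # 0.5
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end,
                               same_chrom = TRUE) {
  if (any(a_end <= a_start) || any(b_end <= b_start)) {
    stop("zero- or negative-length interval")
  }
  o <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  pmin(o / (a_end - a_start), o / (b_end - b_start)) * as.numeric(same_chrom)
}

#' Size-filter deletion calls
#'
#' Keeps calls strictly longer than `min_size` and strictly shorter than
#' `max_size` (defaults: > 50 bp, < 100 kbp).
#'
#' @param calls data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param min_size,max_size Exclusive size bounds in bp.
#' @return The filtered data.frame.
#' @export
size_filter <- function(calls, min_size = 50, max_size = 100000) {
  len <- calls$end - calls$start
  calls[len > min_size & len < max_size, , drop = FALSE]
}

#' Keep only calls that passed external genotyping
#'
#' Retains calls whose `genotyped` flag is TRUE - the stand-in for a
#' read-depth/split-read genotyper succeeding on the call, used as an
#' in-silico validation gate.
#'
#' @param calls data.frame with a logical `genotyped` column.
#' @return The filtered data.frame, order preserved.
#' @export
genotyped_filter <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  if (!"genotyped" %in% names(calls)) stop("calls lack a 'genotyped' column")
  calls[calls$genotyped, , drop = FALSE]
}

#' Merge per-sample deletion callsets into non-redundant sites
#'
#' Single-linkage clustering of calls under the relation "reciprocal
#' overlap >= threshold" (candidate pairs found per chromosome with
#' `IRanges`, clusters by union-find). Because single linkage can chain,
#' every cluster is then checked against its seed - the first member in
#' `(chrom, start, end, sample)` order - and members below the threshold
#' against the seed are split off and re-clustered, so the published
#' invariant "every member overlaps the representative >= threshold"
#' always holds. The representative interval of a site is its seed's,
#' which makes merging deterministic under input permutation and
#' idempotent.
#'
#' @param calls data.frame with `chrom`, `start`, `end`, `sample`
#'   (plus optional `genotype`, `genotyped`), already size-filtered;
#'   alternatively a list of such data.frames (one per sample/callset),
#'   concatenated before merging.
#' @param threshold Minimum reciprocal overlap (default 0.8, inclusive).
#' @return List: `sites` data.frame (`site`, `chrom`, `start`, `end`,
#'   `n_members`, `n_carriers`, `carriers` comma-separated,
#'   `del_alleles` = summed per-carrier genotypes when available,
#'   `genotyped` = all members genotyped) and `members` (the input calls
#'   with a `site` column).
#' @export
merge_callsets <- function(calls, threshold = 0.8) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, calls)
  }
  stopifnot(all(c("chrom", "start", "end", "sample") %in% names(calls)))
  if (nrow(calls) == 0L) {
    return(list(sites = data.frame(), members = calls))
  }
  ord <- order(calls$chrom, calls$start, calls$end, calls$sample)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  n <- nrow(calls)

  ## candidate overlapping pairs per chromosome, then the reciprocal test
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    ir <- IRanges::IRanges(start = calls$start[idx] + 1L,
                           end = calls$end[idx])  # 1-based closed for IRanges
    hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits) == 0L) next
    qi <- idx[S4Vectors::queryHits(hits)]
    si <- idx[S4Vectors::subjectHits(hits)]
    ro <- reciprocal_overlap(calls$start[qi], calls$end[qi],
                             calls$start[si], calls$end[si])
    keep <- ro >= threshold
    edges_from <- c(edges_from, qi[keep])
    edges_to <- c(edges_to, si[keep])
  }

  ## union-find over calls
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(edges_from)) {
    ri <- find(edges_from[e]); rj <- find(edges_to[e])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  cluster <- vapply(seq_len(n), find, integer(1))

  ## seed check: split members that chain away from the cluster seed
  repeat {
    changed <- FALSE
    for (cl in unique(cluster)) {
      members <- which(cluster == cl)
      seed <- min(members)
      if (length(members) == 1L) next
      ro <- reciprocal_overlap(calls$start[seed], calls$end[seed],
                               calls$start[members], calls$end[members],
                               calls$chrom[members] == calls$chrom[seed])
      bad <- members[ro < threshold]
      if (length(bad) > 0L) {
        # re-seed the violators as their own cluster(s); the next sweep
        # re-checks them against their new seed
        cluster[bad] <- min(bad)
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  site_of <- match(cluster, sort(unique(cluster)))
  calls$site <- site_of
  sites <- do.call(rbind, lapply(sort(unique(site_of)), function(s) {
    m <- which(site_of == s)
    seed <- min(m)
    carriers <- sort(unique(calls$sample[m]))
    del <- if ("genotype" %in% names(calls)) {
      sum(vapply(carriers, function(smp)
        max(calls$genotype[m][calls$sample[m] == smp]), numeric(1)))
    } else NA_real_
    data.frame(site = s, chrom = calls$chrom[seed], start = calls$start[seed],
               end = calls$end[seed], n_members = length(m),
               n_carriers = length(carriers),
               carriers = paste(carriers, collapse = ","),
               del_alleles = del,
               genotyped = if ("genotyped" %in% names(calls))
                 all(calls$genotyped[m]) else NA,
               stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL
  list(sites = sites, members = calls)
}

#' Flag merged sites as known or novel against reference callsets
#'
#' A site is known iff its reciprocal overlap with any interval of any
#' reference callset is strictly greater than `threshold` (default > 0.5);
#' otherwise novel.
#'
#' @param sites Sites data.frame from [merge_callsets()] (needs `chrom`,
#'   `start`, `end`).
#' @param reference data.frame of reference intervals (`chrom`, `start`,
#'   `end`), or a list of such data.frames.
#' @param threshold Exclusive reciprocal-overlap threshold (default 0.5).
#' @return `sites` with logical columns `known` and `novel` added.
#' @export
novelty_filter <- function(sites, reference, threshold = 0.5) {
  if (is.list(reference) && !is.data.frame(reference)) {
    reference <- do.call(rbind, reference)
  }
  known <- rep(FALSE, nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    ri <- which(reference$chrom == ch)
    if (length(ri) == 0L) next
    ir_s <- IRanges::IRanges(sites$start[si] + 1L, sites$end[si])
    ir_r <- IRanges::IRanges(reference$start[ri] + 1L, reference$end[ri])
    hits <- IRanges::findOverlaps(ir_s, ir_r)
    if (length(hits) == 0L) next
    qi <- si[S4Vectors::queryHits(hits)]
    rj <- ri[S4Vectors::subjectHits(hits)]
    ro <- reciprocal_overlap(sites$start[qi], sites$end[qi],
                             reference$start[rj], reference$end[rj])
    known[unique(qi[ro > threshold])] <- TRUE
  }
  sites$known <- known
  sites$novel <- !known
  sites
}

#' In-silico validation of deletion sites by heterozygous-SNP content
#'
#' A real deletion removes one copy of the region in its carriers, so a
#' carrier cannot be called heterozygous for a SNP inside it. For each
#' site this counts heterozygous SNPs of carrier samples falling within
#' the representative interval `[start, end)` (het positions are 1-based
#' and converted to 0-based for the containment test).
#'
#' @param sites Sites data.frame from [merge_callsets()] (needs `chrom`,
#'   `start`, `end`, `carriers`).
#' @param het_sites data.frame `sample`, `chrom`, `pos` (1-based) of
#'   heterozygous SNP calls.
#' @return List: `sites` with `het_snp_count` and `validated`
#'   (`het_snp_count == 0`) columns, and `summary` with `frac_zero_het`
#'   and `frac_one_het`.
#' @export
het_snp_validation <- function(sites, het_sites) {
  carriers <- strsplit(sites$carriers, ",", fixed = TRUE)
  counts <- integer(nrow(sites))
  pos0 <- het_sites$pos - 1L
  for (i in seq_len(nrow(sites))) {
    inside <- het_sites$chrom == sites$chrom[i] &
      pos0 >= sites$start[i] & pos0 < sites$end[i] &
      het_sites$sample %in% carriers[[i]]
    counts[i] <- sum(inside)
  }
  sites$het_snp_count <- counts
  sites$validated <- counts == 0L
  list(sites = sites,
       summary = data.frame(n_sites = nrow(sites),
                            frac_zero_het = mean(counts == 0L),
                            frac_one_het = mean(counts == 1L)))
}

#' Deleted-allele frequency of a merged site
#'
#' @param del_alleles Summed deleted-allele genotypes over the site's
#'   carriers (vectorized).
#' @param n_samples Genotyped samples in the cohort.
#' @return Frequency `del_alleles / (2 * n_samples)`.
#' @examples
#' deletion_frequency(2, 16)  # 6.25%
#' @export
deletion_frequency <- function(del_alleles, n_samples) {
  stopifnot(n_samples >= 1)
  if (any(del_alleles <= 0)) {
    stop("site without deleted alleles: a merged site must have >= 1 carrier")
  }
  if (any(del_alleles > 2 * n_samples)) {
    stop("deleted-allele count exceeds 2 x samples")
  }
  del_alleles / (2 * n_samples)
}
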