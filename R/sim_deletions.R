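#' Simulate per-sample deletion callsets with planted validation truth
#'
#' Places deletion loci in disjoint genomic slots of the synthetic genome
#' (so distinct loci can never merge), assigns each locus 1-4 carrier
#' samples in the focal cohort with a deleted-allele genotype, and emits
#' one call per carrier with breakpoints jittered by at most
#' `breakpoint_jitter` of the length - which keeps same-locus calls above
#' the 80% reciprocal-overlap merging threshold by construction.
#'
#' Validation ground truth is planted through the heterozygous-SNP site
#' list: carrier heterozygous SNPs from the genotype matrix that fall
#' inside a call of their own carrier are removed, then every false locus
#' (a `false_deletion_frac` fraction) gets one heterozygous SNP planted at
#' its midpoint for each carrier. True deletions therefore contain no
#' carrier heterozygous SNP, and every false deletion contains at least
#' one, so [het_snp_validation()] fails exactly the planted fraction.
#' A `deletion_known_frac` fraction of loci is mirrored (with small
#' breakpoint noise) in a simulated reference catalogue for
#' [novelty_filter()], alongside decoy reference intervals overlapping no
#' call.
#'
#' Draws flow from `seed` (default `config$seed + 2`) in the order: slots
#' and sizes, carriers and genotypes, per-call jitter, genotyped flags,
#' false/known locus choices, reference noise, decoys.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genotypes()] (supplies the focal samples
#'   and their heterozygous SNP sites).
#' @param seed Seed for this stream; defaults to `config$seed + 2`.
#' @return List with `calls` (data.frame `chrom,start,end,sample,genotype,
#'   genotyped` - one row per per-sample call, 0-based half-open),
#'   `het_sites` (data.frame `sample,chrom,pos` 1-based),
#'   `reference` (BED3-style data.frame of catalogue intervals) and
#'   `truth` (per-locus data.frame: interval, carriers, deleted-allele
#'   count, `is_false`, `genotyped`, `known`).
#' @export
simulate_deletions <- function(config, sim, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n_loci <- config$n_deletion_loci
  slot_w <- 250000L
  n_slot_per_chrom <- floor(config$chrom_length / slot_w)
  slots <- expand.grid(chrom = seq_len(config$n_chromosomes),
                       slot = seq_len(n_slot_per_chrom))
  n_decoy <- config$n_reference_decoys
  if (n_loci + n_decoy > nrow(slots)) {
    stop("infeasible: n_deletion_loci + n_reference_decoys exceeds the ",
         nrow(slots), " available genomic slots")
  }
  pick <- sample.int(nrow(slots), n_loci + n_decoy)
  locus_slot <- slots[pick[seq_len(n_loci)], ]
  decoy_slot <- slots[pick[n_loci + seq_len(n_decoy)], ]

  # restrict locus sizes so that jittered member calls stay strictly
  # inside the (50, 100000) bp bounds
  j0 <- config$breakpoint_jitter
  lo <- max(config$deletion_size_range[1], floor(50 / (1 - 2 * j0)) + 1L)
  hi <- min(config$deletion_size_range[2], ceiling(1e5 / (1 + 2 * j0)) - 1L)
  size <- sample(seq(lo, hi), n_loci, replace = TRUE)
  margin <- 10000L
  start <- (locus_slot$slot - 1L) * slot_w +
    vapply(size, function(s)
      margin + sample.int(slot_w - s - 2L * margin, 1L), integer(1))
  end <- start + size
  chrom <- paste0("chr", locus_slot$chrom)

  focal <- sim$panel$sample[sim$panel$population == config$focal_population]
  n_carriers <- sample(1:4, n_loci, replace = TRUE,
                       prob = c(0.5, 0.25, 0.15, 0.1))
  carriers <- lapply(n_carriers, function(k) sample(focal, k))
  genotypes <- lapply(n_carriers, function(k)
    ifelse(stats::runif(k) < 0.85, 1L, 2L))

  genotyped <- stats::runif(n_loci) < config$genotyped_frac
  n_false <- round(config$false_deletion_frac * n_loci)
  is_false <- seq_len(n_loci) %in% sample.int(n_loci, n_false)
  known <- stats::runif(n_loci) < config$deletion_known_frac

  ## per-carrier calls with jittered breakpoints
  j <- config$breakpoint_jitter
  call_rows <- lapply(seq_len(n_loci), function(i) {
    k <- n_carriers[i]
    jit <- matrix(round(stats::runif(2L * k, -j, j) * size[i]), k, 2L)
    data.frame(chrom = chrom[i], start = start[i] + jit[, 1],
               end = end[i] + jit[, 2], sample = carriers[[i]],
               genotype = genotypes[[i]], genotyped = genotyped[i],
               locus = i, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, call_rows)

  ## heterozygous-SNP site list of the focal cohort
  g <- sim$genotypes[focal, , drop = FALSE]
  het_idx <- which(g == 1L, arr.ind = TRUE)
  v <- sim$variants[het_idx[, 2], ]
  het <- data.frame(sample = focal[het_idx[, 1]], chrom = v$chrom,
                    pos = v$pos, stringsAsFactors = FALSE)
  # no carrier het SNP may fall inside any member call of its locus (the
  # representative interval is one of them), so clear the whole jitter
  # envelope of each locus for its carriers unless the locus is false
  drop <- rep(FALSE, nrow(het))
  for (i in seq_len(n_loci)) {
    pad <- ceiling(j * size[i]) + 1L
    drop <- drop | (het$sample %in% carriers[[i]] &
                      het$chrom == chrom[i] &
                      het$pos - 1L >= start[i] - pad &
                      het$pos - 1L < end[i] + pad)
  }
  het <- het[!drop, , drop = FALSE]
  planted <- do.call(rbind, lapply(which(is_false), function(i) {
    data.frame(sample = carriers[[i]], chrom = chrom[i],
               pos = as.integer((start[i] + end[i]) %/% 2L) + 1L,
               stringsAsFactors = FALSE)
  }))
  het <- rbind(het, planted)
  het <- het[order(het$chrom, het$pos, het$sample), , drop = FALSE]
  rownames(het) <- NULL

  ## reference catalogue: known loci with noise, plus decoys
  ref_rows <- lapply(which(known), function(i) {
    shift <- round(stats::runif(2, -0.1, 0.1) * size[i])
    data.frame(chrom = chrom[i], start = max(0L, start[i] + shift[1]),
               end = end[i] + shift[2], stringsAsFactors = FALSE)
  })
  decoy_size <- sample(seq(config$deletion_size_range[1],
                           config$deletion_size_range[2]),
                       n_decoy, replace = TRUE)
  decoys <- data.frame(
    chrom = paste0("chr", decoy_slot$chrom),
    start = (decoy_slot$slot - 1L) * slot_w + margin,
    end = (decoy_slot$slot - 1L) * slot_w + margin + decoy_size,
    stringsAsFactors = FALSE)
  reference <- rbind(do.call(rbind, ref_rows), decoys)
  reference <- reference[order(reference$chrom, reference$start), ,
                         drop = FALSE]
  rownames(reference) <- NULL

  truth <- data.frame(locus = seq_len(n_loci), chrom = chrom, start = start,
                      end = end, n_carriers = n_carriers,
                      carriers = vapply(carriers, paste, character(1),
                                        collapse = ","),
                      del_alleles = vapply(genotypes, sum, integer(1)),
                      is_false = is_false, genotyped = genotyped,
                      known = known, stringsAsFactors = FALSE)

  list(calls = calls[order(calls$chrom, calls$start, calls$end,
                           calls$sample), , drop = FALSE],
       het_sites = het, reference = reference, truth = truth)
}

#' Read and write deletion callsets as BED
#'
#' Callsets travel as BED4+ (`chrom start end sample`, optional `genotype`
#' and `genotyped` columns); reference catalogues as BED3. Coordinates are
#' 0-based half-open throughout, the BED convention.
#'
#' @param path File path.
#' @param header Whether the file carries a header line (default TRUE for
#'   write, auto-detected on read).
#' @return data.frame of intervals.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^(#|chrom\t|track|browser)", first)
  cols <- c("chrom", "start", "end", "sample", "genotype", "genotyped")
  x <- utils::read.delim(path, header = has_header & grepl("^chrom", first),
                         comment.char = "#", stringsAsFactors = FALSE)
  if (!"chrom" %in% names(x)) names(x) <- cols[seq_len(ncol(x))]
  x
}

#' @rdname read_bed
#' @param intervals data.frame with at least `chrom`, `start`, `end`.
#' @export
write_bed <- function(intervals, path, header = TRUE) {
  drop <- intersect("locus", names(intervals))
  x <- intervals[, setdiff(names(intervals), drop), drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

#' Write/read heterozygous-SNP site lists
#'
#' TSV with header `sample  chrom  pos` (positions 1-based, as in a VCF).
#' @param path File path.
#' @export
read_het_sites <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(pos = "integer"))
}

#' @rdname read_het_sites
#' @param het_sites data.frame `sample`, `chrom`, `pos`.
#' @export
write_het_sites <- function(het_sites, path) {
  utils::write.table(het_sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
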