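#' Configuration for the multi-population synthetic-data generator
#'
#' Bundles and validates every knob of the generator. The defaults describe
#' the cohort design the analyses in this package target: one focal
#' population of 16 diploid whole genomes compared against 14 reference
#' populations of 16 samples each, with Balding-Nichols differentiated
#' allele frequencies, a GWAS-SNP subset carrying planted large frequency
#' differences, planted focal-only (rare/private) variants with a planted
#' non-synonymous excess, and per-sample deletion callsets whose
#' heterozygous-SNP content is consistent (or deliberately inconsistent)
#' with a real deletion.
#'
#' @param n_populations Total populations, focal included (default 15).
#' @param samples_per_population Diploid samples per population (default 16).
#' @param n_snps Number of biallelic SNPs (default 10000).
#' @param fst Balding-Nichols divergence parameter, scalar or one value per
#'   population, each in (0, 1) (default 0.1).
#' @param ancestral_beta Shape parameters (a, b) of the Beta law for the
#'   ancestral allele frequency (default c(1, 1), i.e. uniform; frequencies
#'   are clamped to [0.02, 0.98] so every Balding-Nichols Beta is proper).
#' @param n_gwas_snps Variants carrying a GWAS rsid/trait annotation
#'   (default 1000).
#' @param n_planted_outliers GWAS SNPs planted at a large focal-vs-reference
#'   frequency difference (default 5).
#' @param planted_diff Target absolute frequency difference for planted
#'   outliers (default 0.5); population frequencies are set 0.2 beyond the
#'   target on each side so the realized sample difference clears it.
#' @param n_rare,n_low_count_private,n_private Planted focal-only variants
#'   at 1, 2-3, and `private_alt_count` focal alternate chromosomes
#'   (defaults 50, 10, 5).
#' @param private_alt_count Alternate chromosomes for planted private
#'   variants, must exceed 3 (default 4).
#' @param rare_nonsyn_frac,common_nonsyn_frac Probability that a planted
#'   focal-only (resp. any other) variant is labeled non-synonymous
#'   (defaults 0.6, 0.4) - the planted functional enrichment.
#' @param known_frac Probability a variant carries the known-catalogue flag
#'   (default 0.6).
#' @param n_chromosomes,chrom_length Synthetic genome: autosome count and
#'   ungapped length per autosome in bp (defaults 22, 1e7).
#' @param n_deletion_loci Deletion loci segregating in the focal cohort
#'   (default 100).
#' @param deletion_size_range Bounds (bp) for deletion sizes; must stay
#'   strictly inside (50, 100000) (default c(51, 99999)).
#' @param false_deletion_frac Fraction of loci planted as false calls that
#'   overlap carrier heterozygous SNPs (default 0.1).
#' @param breakpoint_jitter Per-call breakpoint jitter as a fraction of the
#'   deletion length; at the default 0.02 same-locus calls overlap
#'   reciprocally by at least (1 - 2j)/(1 + 2j) ~ 0.92 (default 0.02).
#' @param genotyped_frac Fraction of loci passing the external genotyper
#'   (read-depth/split-read) stand-in flag (default 0.95).
#' @param deletion_known_frac Fraction of loci present (>50% reciprocal
#'   overlap) in the simulated reference deletion catalogue (default 0.5).
#' @param n_reference_decoys Reference-catalogue intervals overlapping no
#'   call (default 50).
#' @param concordance_n_sites Assayed sites in the simulated truth genotype
#'   table (default 2000).
#' @param concordance_error_rate,concordance_miss_rate Per-site genotype
#'   error and drop-out rates of the simulated callset against truth
#'   (defaults 0.002, 0.002).
#' @param focal_bbox Sampling-location bounding box of the focal population,
#'   c(lat_min, lat_max, lon_min, lon_max) in decimal degrees; the default
#'   spans Anatolia (default c(36, 42, 26, 45)).
#' @param focal_population,reference_prefix Population labels (defaults
#'   "FOCAL", "REF").
#' @param seed Integer seed; every stochastic draw of the generator flows
#'   from it (default 1).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 15,
                       samples_per_population = 16,
                       n_snps = 10000,
                       fst = 0.1,
                       ancestral_beta = c(1, 1),
                       n_gwas_snps = 1000,
                       n_planted_outliers = 5,
                       planted_diff = 0.5,
                       n_rare = 50,
                       n_low_count_private = 10,
                       n_private = 5,
                       private_alt_count = 4,
                       rare_nonsyn_frac = 0.6,
                       common_nonsyn_frac = 0.4,
                       known_frac = 0.6,
                       n_chromosomes = 22,
                       chrom_length = 1e7,
                       n_deletion_loci = 100,
                       deletion_size_range = c(51, 99999),
                       false_deletion_frac = 0.1,
                       breakpoint_jitter = 0.02,
                       genotyped_frac = 0.95,
                       deletion_known_frac = 0.5,
                       n_reference_decoys = 50,
                       concordance_n_sites = 2000,
                       concordance_error_rate = 0.002,
                       concordance_miss_rate = 0.002,
                       focal_bbox = c(36, 42, 26, 45),
                       focal_population = "FOCAL",
                       reference_prefix = "REF",
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_populations >= 1, samples_per_population >= 1, n_snps >= 1)
    if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
    if (!length(fst) %in% c(1L, n_populations)) {
      stop("fst must be a scalar or one value per population")
    }
    stopifnot(length(ancestral_beta) == 2, all(ancestral_beta > 0))
    fracs <- c(rare_nonsyn_frac, common_nonsyn_frac, known_frac,
               false_deletion_frac, genotyped_frac, deletion_known_frac,
               concordance_error_rate, concordance_miss_rate)
    if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
    if (planted_diff <= 0 || planted_diff > 1) {
      stop("planted_diff must lie in (0, 1]")
    }
    if (deletion_size_range[1] <= 50 || deletion_size_range[2] >= 100000 ||
        deletion_size_range[1] > deletion_size_range[2]) {
      stop("deletion sizes must lie strictly within (50, 100000) bp")
    }
    if (breakpoint_jitter < 0 || breakpoint_jitter > 0.05) {
      stop("breakpoint_jitter must lie in [0, 0.05] to preserve >=80% reciprocal overlap")
    }
    if (private_alt_count <= 3) stop("private variants need > 3 alternate chromosomes")
    if (private_alt_count > 2 * samples_per_population) {
      stop("infeasible plant: private_alt_count exceeds 2 x samples_per_population")
    }
    if (n_gwas_snps + n_rare + n_low_count_private + n_private > n_snps) {
      stop("infeasible plant: more planted/annotated variants than SNPs")
    }
    if (n_planted_outliers > n_gwas_snps) {
      stop("infeasible plant: more planted outliers than GWAS SNPs")
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d populations x %d samples, %d SNPs (Fst %s)\n",
    "  %d GWAS SNPs (%d planted outliers at |df| >= %.2f)\n",
    "  planted focal-only: %d rare, %d low-count, %d private; nonsyn %g vs %g\n",
    "  %d deletion loci, false fraction %g; seed %d\n"),
    x$n_populations, x$samples_per_population, x$n_snps,
    paste(format(x$fst), collapse = "/"),
    x$n_gwas_snps, x$n_planted_outliers, x$planted_diff,
    x$n_rare, x$n_low_count_private, x$n_private,
    x$rare_nonsyn_frac, x$common_nonsyn_frac,
    x$n_deletion_loci, x$false_deletion_frac, x$seed))
  invisible(x)
}

#' Population labels of a simulation configuration
#' @param config A [sim_config()].
#' @return Character vector: focal label first, then the reference labels.
#' @export
sim_populations <- function(config) {
  c(config$focal_population,
    sprintf("%s%02d", config$reference_prefix,
            seq_len(config$n_populations - 1L)))
}
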