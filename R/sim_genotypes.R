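#' Simulate multi-population genotypes with planted ground truth
#'
#' Draws a Balding-Nichols genotype panel: an ancestral allele frequency
#' p ~ Beta(a, b) per SNP, a population frequency
#' q_k ~ Beta(p (1 - F)/F, (1 - p)(1 - F)/F) per population, and diploid
#' dosages ~ Binomial(2, q_k) per sample. On top of the neutral background
#' it plants, and records in a truth object,
#'
#' * GWAS-annotated SNPs, a few of which get a large focal-vs-reference
#'   frequency difference (outlier-scan ground truth);
#' * focal-only variants at fixed alternate-chromosome counts of 1 (rare),
#'   2-3 (low-count private) and >3 (private), absent from every reference
#'   population by construction;
#' * functional labels with a non-synonymous excess among the planted
#'   focal-only variants relative to the background.
#'
#' All draws flow from `config$seed` in the order: positions and alleles,
#' ancestral frequencies, population frequencies, planted-outlier
#' overrides, dosages, focal-only plants, functional labels, known flags,
#' GWAS annotation, panel coordinates. The same seed therefore reproduces
#' the output bit for bit.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (samples x variants dosage matrix),
#'   `variants` (variant table, see [read_vcf()]), `panel`
#'   (sample/population/coordinates), `gwas` (rsid, chrom, pos, trait,
#'   key, planted flag) and `truth` (list: `pop_freq` population-by-SNP
#'   frequency matrix, `p_anc`, `planted_outliers`, `planted_sharing`,
#'   `populations`, `focal_population`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- sim_populations(config)
  n_pop <- config$n_populations
  n_per <- config$samples_per_population
  n <- config$n_snps
  fst <- rep(config$fst, length.out = n_pop)

  ## -- variant scaffold: chromosome, position, alleles ---------------------
  chrom_idx <- sort(rep_len(seq_len(config$n_chromosomes), n))
  pos <- integer(n)
  for (c_i in unique(chrom_idx)) {
    sel <- chrom_idx == c_i
    pos[sel] <- sort(sample.int(config$chrom_length - 1L, sum(sel)))
  }
  chrom <- paste0("chr", chrom_idx)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  key <- variant_key(chrom, pos, ref, alt)

  ## -- Balding-Nichols frequencies ----------------------------------------
  p_anc <- pmin(pmax(stats::rbeta(n, config$ancestral_beta[1],
                                  config$ancestral_beta[2]), 0.02), 0.98)
  pop_freq <- matrix(NA_real_, n_pop, n, dimnames = list(pops, key))
  for (k in seq_len(n_pop)) {
    f <- fst[k]
    pop_freq[k, ] <- stats::rbeta(n, p_anc * (1 - f) / f,
                                  (1 - p_anc) * (1 - f) / f)
  }

  ## -- planted GWAS outliers: override population frequencies -------------
  gwas_idx <- sort(sample.int(n, config$n_gwas_snps))
  planted_idx <- sort(sample(gwas_idx, config$n_planted_outliers))
  hi <- min(0.5 + config$planted_diff / 2 + 0.2, 0.98)
  lo <- max(0.5 - config$planted_diff / 2 - 0.2, 0.02)
  if (length(planted_idx) > 0L) {
    up <- rep_len(c(TRUE, FALSE), length(planted_idx))  # alternate sign
    pop_freq[1L, planted_idx] <- ifelse(up, hi, lo)
    pop_freq[-1L, planted_idx] <- rep(ifelse(up, lo, hi), each = n_pop - 1L)
  }

  ## -- diploid dosages ------------------------------------------------------
  sample_ids <- as.vector(vapply(pops, function(p)
    sprintf("%s_%02d", p, seq_len(n_per)), character(n_per)))
  geno <- matrix(NA_integer_, n_pop * n_per, n,
                 dimnames = list(sample_ids, key))
  for (k in seq_len(n_pop)) {
    rows <- (k - 1L) * n_per + seq_len(n_per)
    geno[rows, ] <- matrix(stats::rbinom(n_per * n, 2L,
                                         rep(pop_freq[k, ], each = n_per)),
                           n_per, n)
  }

  ## -- planted focal-only (rare / low-count / private) variants ------------
  n_plant <- config$n_rare + config$n_low_count_private + config$n_private
  plant_class <- rep(c("rare", "low_count_private", "private"),
                     c(config$n_rare, config$n_low_count_private,
                       config$n_private))
  plant_idx <- sort(sample(setdiff(seq_len(n), gwas_idx), n_plant))
  plant_class <- sample(plant_class)  # decouple class from genome order
  target <- integer(n_plant)
  target[plant_class == "rare"] <- 1L
  lcp <- plant_class == "low_count_private"
  target[lcp] <- sample(2:3, sum(lcp), replace = TRUE)
  target[plant_class == "private"] <- as.integer(config$private_alt_count)
  focal_rows <- seq_len(n_per)
  for (i in seq_along(plant_idx)) {
    j <- plant_idx[i]
    geno[, j] <- 0L
    cnt <- target[i]
    n_hom <- max(0L, cnt - n_per)
    carriers <- sample(focal_rows, cnt - n_hom)
    dos <- rep(1L, length(carriers))
    if (n_hom > 0L) dos[seq_len(n_hom)] <- 2L
    geno[carriers, j] <- dos
    pop_freq[, j] <- 0  # truth frequencies reflect the plant
  }

  ## -- functional labels and known flags ------------------------------------
  fclass <- ifelse(stats::runif(n) < config$common_nonsyn_frac,
                   "nonsynonymous", "synonymous")
  fclass[plant_idx] <- ifelse(stats::runif(n_plant) < config$rare_nonsyn_frac,
                              "nonsynonymous", "synonymous")
  known <- stats::runif(n) < config$known_frac

  ## -- GWAS annotation -------------------------------------------------------
  traits <- c("total cholesterol", "skin pigmentation", "hair color",
              "height", "type 2 diabetes", "blood pressure", "eye color")
  rsid <- sprintf("rs%06d", seq_along(gwas_idx))
  gwas <- data.frame(rsid = rsid, chrom = chrom[gwas_idx], pos = pos[gwas_idx],
                     trait = sample(traits, length(gwas_idx), replace = TRUE),
                     key = key[gwas_idx], planted = gwas_idx %in% planted_idx,
                     stringsAsFactors = FALSE)
  id <- rep(".", n)
  id[gwas_idx] <- rsid

  variants <- data.frame(key = key, chrom = chrom, pos = pos, id = id,
                         ref = ref, alt = alt, functional_class = fclass,
                         known_flag = known, stringsAsFactors = FALSE)

  ## -- panel with sampling coordinates --------------------------------------
  bb <- config$focal_bbox
  lat <- lon <- numeric(length(sample_ids))
  lat[focal_rows] <- stats::runif(n_per, bb[1], bb[2])
  lon[focal_rows] <- stats::runif(n_per, bb[3], bb[4])
  for (k in seq_len(n_pop - 1L)) {
    rows <- k * n_per + seq_len(n_per)
    centre <- c(stats::runif(1, -50, 50), stats::runif(1, -170, 170))
    lat[rows] <- centre[1] + stats::runif(n_per, -1.5, 1.5)
    lon[rows] <- centre[2] + stats::runif(n_per, -1.5, 1.5)
  }
  panel <- data.frame(sample = sample_ids,
                      population = rep(pops, each = n_per),
                      latitude = lat, longitude = lon,
                      stringsAsFactors = FALSE)

  list(genotypes = geno, variants = variants, panel = panel, gwas = gwas,
       truth = list(pop_freq = pop_freq, p_anc = p_anc,
                    planted_outliers = key[planted_idx],
                    planted_sharing = data.frame(key = key[plant_idx],
                                                 class = plant_class,
                                                 alt_count = target,
                                                 stringsAsFactors = FALSE),
                    populations = pops,
                    focal_population = config$focal_population))
}

#' Simulate a truth genotype table and an error-bearing callset
#'
#' Emulates benchmarking WGS genotype calls against an independent assay:
#' the truth table holds the generator's own genotypes of the focal samples
#' at a random subset of assayed sites (reference-homozygous sites
#' included), and the callset is the same table degraded by a small
#' genotype-error rate and a small drop-out rate, so [concordance()]
#' recovers rates close to the planted ones.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genotypes()].
#' @param seed Seed for this stream; defaults to `config$seed + 1`.
#' @return List of data.frames `calls` and `truth` (columns `sample`,
#'   `chrom`, `pos`, `ref`, `alt`, `genotype`) plus the planted rates.
#' @export
simulate_concordance <- function(config, sim, seed = config$seed + 1L) {
  set.seed(seed)
  n_sites <- min(config$concordance_n_sites, ncol(sim$genotypes))
  site_idx <- sort(sample.int(ncol(sim$genotypes), n_sites))
  focal <- sim$panel$sample[sim$panel$population == config$focal_population]
  v <- sim$variants[site_idx, ]
  g <- sim$genotypes[focal, site_idx, drop = FALSE]
  truth <- data.frame(sample = rep(focal, times = n_sites),
                      chrom = rep(v$chrom, each = length(focal)),
                      pos = rep(v$pos, each = length(focal)),
                      ref = rep(v$ref, each = length(focal)),
                      alt = rep(v$alt, each = length(focal)),
                      genotype = as.vector(g),
                      stringsAsFactors = FALSE)
  calls <- truth
  flip <- stats::runif(nrow(calls)) < config$concordance_error_rate
  calls$genotype[flip] <- (calls$genotype[flip] +
                             sample(1:2, sum(flip), replace = TRUE)) %% 3L
  drop <- stats::runif(nrow(calls)) < config$concordance_miss_rate
  calls <- calls[!drop & calls$genotype > 0, , drop = FALSE]
  list(calls = calls, truth = truth,
       planted_error_rate = config$concordance_error_rate,
       planted_miss_rate = config$concordance_miss_rate)
}
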