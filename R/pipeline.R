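#' Assemble and validate a workflow run configuration
#'
#' The workflow is a fixed sequence of stages over one output directory:
#' `simulate` writes the synthetic study inputs (VCF, panel, GWAS list,
#' deletion callsets, reference catalogue, lengths table, truth tables),
#' and the analysis stages (`freqs`, `diffscan`, `rareprivate`,
#' `diversity`, `structure`, `deletions`, `concordance`) read those files
#' back through the package's own readers and write plain-table results.
#' Parameters mirror the function defaults; a YAML file with the same keys
#' can seed the list, and arguments override file values.
#'
#' @param outdir Run directory (created if needed).
#' @param seed Integer seed governing every stage.
#' @param yaml_path Optional YAML file of the same keys.
#' @param sim A [sim_config()] for the `simulate` stage (its `seed` is
#'   forced to `seed`).
#' @param subset_size,window,step,r2_max,n_perm Structure-stage parameters
#'   (see [subset_polymorphic_filter()], [ld_prune()], [mantel_test()]).
#' @param top_percentile Outlier-scan tail (see [outlier_scan()]).
#' @param merge_threshold,novelty_threshold Deletion-stage thresholds.
#' @param n_pcs Principal components written by the structure stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1, yaml_path = NULL, sim = NULL,
                       subset_size = 16, window = 50, step = 5,
                       r2_max = 0.5, n_perm = 999, top_percentile = 0.1,
                       merge_threshold = 0.8, novelty_threshold = 0.5,
                       n_pcs = 4) {
  cfg <- as.list(environment())
  cfg$yaml_path <- NULL
  supplied <- names(as.list(match.call()))[-1]
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    sim_keys <- intersect(names(y), names(formals(sim_config)))
    if (is.null(cfg$sim) && length(sim_keys) > 0L) {
      cfg$sim <- do.call(sim_config, y[sim_keys])
    }
    # file values fill in anything not given as an argument;
    # explicit arguments win
    for (k in setdiff(intersect(names(y), names(cfg)),
                      c("sim", supplied))) {
      cfg[[k]] <- y[[k]]
    }
  }
  if (is.null(cfg$sim)) cfg$sim <- sim_config()
  cfg$sim$seed <- cfg$seed
  stopifnot(cfg$r2_max > 0, cfg$top_percentile > 0, cfg$n_perm >= 99,
            cfg$merge_threshold > 0, cfg$merge_threshold <= 1,
            cfg$novelty_threshold >= 0, cfg$novelty_threshold < 1)
  class(cfg) <- "run_config"
  cfg
}

stage_names <- c("simulate", "freqs", "diffscan", "rareprivate", "diversity",
                 "structure", "deletions", "concordance")

#' Run one workflow stage (or all of them)
#'
#' Executes the named stage against `config$outdir`, writing plain-text
#' tables (TSV/BED/VCF/newick) under `<outdir>/<stage>/` and appending to
#' the run manifest `<outdir>/manifest.tsv` (stage, parameters, output
#' checksums - no timestamps, so a repeated run with the same seed is
#' byte-identical). Progress is logged to stderr. Analysis stages require
#' the `simulate` stage's outputs to exist.
#'
#' @param name Stage name, one of `simulate`, `freqs`, `diffscan`,
#'   `rareprivate`, `diversity`, `structure`, `deletions`, `concordance`,
#'   or `all` for the whole sequence.
#' @param config A [run_config()].
#' @return Invisibly, the list of files the stage wrote.
#' @export
run_stage <- function(name, config) {
  stopifnot(inherits(config, "run_config"))
  if (!name %in% c(stage_names, "all")) {
    stop("unknown stage '", name, "'; expected one of: ",
         paste(c(stage_names, "all"), collapse = ", "))
  }
  if (name == "all") {
    out <- lapply(stage_names, run_stage, config = config)
    return(invisible(unlist(out)))
  }
  dir.create(file.path(config$outdir, name), recursive = TRUE,
             showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  message("[", name, "] running (seed ", config$seed, ")")
  files <- switch(name,
    simulate = stage_simulate(config),
    freqs = stage_freqs(config),
    diffscan = stage_diffscan(config),
    rareprivate = stage_rareprivate(config),
    diversity = stage_diversity(config),
    structure = stage_structure(config),
    deletions = stage_deletions(config),
    concordance = stage_concordance(config))
  write_manifest(config, name, files)
  message(sprintf("[%s] done in %.1f s (%d file(s))", name,
                  proc.time()[["elapsed"]] - t0, length(files)))
  invisible(files)
}

sim_path <- function(config, file) {
  p <- file.path(config$outdir, "simulate", file)
  if (!file.exists(p)) {
    stop("missing input '", p, "': run the 'simulate' stage first")
  }
  p
}

out_path <- function(config, stage, file) file.path(config$outdir, stage, file)

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(config, stage, files) {
  params <- config[!vapply(config, is.list, logical(1))]
  params$outdir <- NULL  # keep the manifest invariant to where the run lives
  rows <- rbind(
    data.frame(stage = stage, key = paste0("param:", names(params)),
               value = vapply(params, function(v)
                 paste(format(v), collapse = ","), character(1))),
    data.frame(stage = stage, key = paste0("md5:", basename(files)),
               value = unname(tools::md5sum(files))),
    data.frame(stage = stage, key = "package_version",
               value = as.character(utils::packageVersion("wgspopgen"))))
  manifest <- file.path(config$outdir, "manifest.tsv")
  old <- if (file.exists(manifest)) {
    m <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    m[m$stage != stage, , drop = FALSE]
  } else NULL
  write_tsv(rbind(old, rows), manifest)
}

load_sim_inputs <- function(config) {
  panel <- read_panel(sim_path(config, "panel.tsv"))
  vcf <- read_vcf(sim_path(config, "genotypes.vcf"), panel = panel)
  list(panel = panel, genotypes = vcf$genotypes, variants = vcf$variants,
       focal = config$sim$focal_population,
       refs = setdiff(unique(panel$population),
                      config$sim$focal_population))
}

stage_simulate <- function(config) {
  sim <- simulate_genotypes(config$sim)
  dels <- simulate_deletions(config$sim, sim)
  conc <- simulate_concordance(config$sim, sim)
  p <- function(f) out_path(config, "simulate", f)
  files <- c(
    write_vcf(sim$genotypes, sim$variants, p("genotypes.vcf")),
    write_panel(sim$panel, p("panel.tsv")),
    write_tsv(sim$gwas[, c("rsid", "chrom", "pos", "trait", "key", "planted")],
              p("gwas_snps.tsv")),
    write_lengths(data.frame(
      chrom = paste0("chr", seq_len(config$sim$n_chromosomes)),
      length = config$sim$chrom_length), p("lengths.tsv")),
    write_bed(dels$calls, p("deletion_calls.bed")),
    write_bed(dels$reference, p("reference_deletions.bed")),
    write_het_sites(dels$het_sites, p("het_sites.tsv")),
    write_tsv(dels$truth, p("truth_deletions.tsv")),
    write_tsv(sim$truth$planted_sharing, p("truth_sharing.tsv")),
    write_tsv(data.frame(key = sim$truth$planted_outliers),
              p("truth_outliers.tsv")),
    write_genotype_table(conc$calls, p("concordance_calls.tsv")),
    write_genotype_table(conc$truth, p("concordance_truth.tsv")))
  files
}

stage_freqs <- function(config) {
  x <- load_sim_inputs(config)
  ft <- population_frequencies(x$genotypes, x$panel,
                               groups = list(REFPOOL = x$refs))
  write_tsv(ft, out_path(config, "freqs", "population_frequencies.tsv"))
}

stage_diffscan <- function(config) {
  x <- load_sim_inputs(config)
  gwas <- utils::read.delim(sim_path(config, "gwas_snps.tsv"),
                            stringsAsFactors = FALSE)
  ft <- population_frequencies(x$genotypes, x$panel, snp_keys = gwas$key,
                               groups = list(REFPOOL = x$refs))
  d <- abs_freq_diff(ft, x$focal, "REFPOOL")
  scan <- outlier_scan(d, top_percentile = config$top_percentile)
  f_focal <- ft$frequency[ft$unit == x$focal][match(names(d),
                                                    ft$key[ft$unit == x$focal])]
  f_comp <- ft$frequency[ft$unit == "REFPOOL"][match(names(d),
                                                     ft$key[ft$unit == "REFPOOL"])]
  res <- data.frame(rsid = gwas$rsid[match(names(d), gwas$key)],
                    key = names(d), f_focal = f_focal,
                    f_comparison = f_comp, abs_diff = unname(d),
                    outlier = names(d) %in% scan$outliers)
  c(write_tsv(res, out_path(config, "diffscan", "scan.tsv")),
    write_tsv(data.frame(top_percentile = config$top_percentile,
                         threshold = scan$threshold,
                         n_outliers = length(scan$outliers)),
              out_path(config, "diffscan", "threshold.tsv")),
    write_tsv(cbind(unit = x$focal, frequency_histogram(f_focal)),
              out_path(config, "diffscan", "focal_histogram.tsv")),
    write_tsv(cbind(unit = "REFPOOL", frequency_histogram(f_comp)),
              out_path(config, "diffscan", "comparison_histogram.tsv")))
}

stage_rareprivate <- function(config) {
  x <- load_sim_inputs(config)
  focal_samples <- x$panel$sample[x$panel$population == x$focal]
  other_samples <- x$panel$sample[x$panel$population != x$focal]
  fc <- allele_counts(x$genotypes, focal_samples)
  oc <- allele_counts(x$genotypes, other_samples)
  cls <- classify_sharing(fc$alt_count, fc$total_count,
                          oc$alt_count, oc$total_count)
  out <- data.frame(variant = fc$key, class = as.character(cls),
                    functional_class = x$variants$functional_class,
                    known_flag = x$variants$known_flag,
                    focal_alt = fc$alt_count, other_alt = oc$alt_count)
  tests <- lapply(c("rare_strict", "novel_rare"), function(stratum) {
    a <- sharing_stratum(cls, fc$alt_count, x$variants$known_flag, stratum)
    b <- sharing_stratum(cls, fc$alt_count, stratum = "all")
    tab <- enrichment_table(x$variants$functional_class, a, b,
                            labels = c(stratum, "all"))
    res <- chi_square_yates(tab)
    data.frame(stratum = stratum, nonsyn_stratum = tab[1, 1],
               syn_stratum = tab[1, 2], nonsyn_all = tab[2, 1],
               syn_all = tab[2, 2], chi_square = res$statistic,
               p_value = res$p_value)
  })
  c(write_tsv(out, out_path(config, "rareprivate", "classes.tsv")),
    write_tsv(do.call(rbind, tests),
              out_path(config, "rareprivate", "enrichment.tsv")))
}

stage_diversity <- function(config) {
  x <- load_sim_inputs(config)
  lengths <- read_lengths(sim_path(config, "lengths.tsv"))
  rows <- lapply(unique(x$panel$population), function(p) {
    s <- genome_pi(x$genotypes, x$panel, p, lengths)
    data.frame(population = p, sum_site_pi = s$sum_site_pi,
               n_variable_sites = s$n_variable_sites,
               ungapped_length = s$ungapped_length, genome_pi = s$genome_pi)
  })
  write_tsv(do.call(rbind, rows), out_path(config, "diversity", "pi.tsv"))
}

stage_structure <- function(config) {
  x <- load_sim_inputs(config)
  flt <- filter_biallelic_autosomal(x$genotypes, x$variants)
  g <- drop_missing_variants(flt$genotypes)
  sp <- subset_polymorphic_filter(g, x$panel,
                                  subset_size = config$subset_size,
                                  seed = config$seed)
  keep <- ld_prune(sp$genotypes, window = config$window, step = config$step,
                   r2_max = config$r2_max)
  coded <- code_genotypes(sp$genotypes[, keep, drop = FALSE])
  pca <- pca_genotypes(coded)
  n_pc <- min(config$n_pcs, ncol(pca$scores))
  scores <- data.frame(sample = rownames(pca$scores),
                       population = x$panel$population[
                         match(rownames(pca$scores), x$panel$sample)],
                       pca$scores[, seq_len(n_pc), drop = FALSE])

  focal_samples <- x$panel$sample[x$panel$population == x$focal]
  gd <- genetic_distance(coded[focal_samples, , drop = FALSE])
  tr <- nj_tree(gd)
  focal_panel <- x$panel[x$panel$population == x$focal, ]
  geo <- geographic_distance(focal_panel)
  set.seed(config$seed)
  mt <- mantel_test(gd, geo, n_perm = config$n_perm)

  p <- function(f) out_path(config, "structure", f)
  ape::write.tree(tr, p("nj_tree.nwk"))
  c(write_tsv(data.frame(step = c("autosomal_biallelic", "no_missing",
                                  "subset_polymorphic", "ld_pruned"),
                         n_snps = c(ncol(flt$genotypes), ncol(g),
                                    ncol(sp$genotypes), length(keep))),
              p("snp_filtering.tsv")),
    write_tsv(scores, p("pca_scores.tsv")),
    write_tsv(data.frame(component = seq_along(pca$explained_fraction),
                         explained_fraction = pca$explained_fraction),
              p("pca_explained.tsv")),
    write_distance_matrix(gd, p("genetic_distance.tsv")),
    write_distance_matrix(geo, p("geographic_distance.tsv")),
    p("nj_tree.nwk"),
    write_tsv(data.frame(mantel_r = mt$statistic, p_value = mt$p_value,
                         n_perm = mt$n_perm), p("mantel.tsv")))
}

stage_deletions <- function(config) {
  calls <- read_bed(sim_path(config, "deletion_calls.bed"))
  reference <- read_bed(sim_path(config, "reference_deletions.bed"))
  het <- read_het_sites(sim_path(config, "het_sites.tsv"))
  n_samples <- config$sim$samples_per_population

  calls <- size_filter(calls)
  calls <- genotyped_filter(calls)
  merged <- merge_callsets(calls, threshold = config$merge_threshold)
  sites <- novelty_filter(merged$sites, reference,
                          threshold = config$novelty_threshold)
  val <- het_snp_validation(sites[sites$novel, , drop = FALSE], het)
  sites$frequency <- deletion_frequency(sites$del_alleles, n_samples)
  p <- function(f) out_path(config, "deletions", f)
  c(write_bed(sites, p("merged_sites.bed")),
    write_bed(val$sites, p("novel_validated.bed")),
    write_tsv(data.frame(
      n_calls = nrow(calls), n_sites = nrow(sites),
      n_novel = sum(sites$novel),
      frac_novel_zero_het = val$summary$frac_zero_het,
      frac_novel_one_het = val$summary$frac_one_het,
      n_singleton = sum(sites$del_alleles == 1),
      n_multi_chromosome = sum(sites$del_alleles > 1)),
      p("summary.tsv")))
}

stage_concordance <- function(config) {
  calls <- read_genotype_table(sim_path(config, "concordance_calls.tsv"))
  truth <- read_genotype_table(sim_path(config, "concordance_truth.tsv"))
  rep <- concordance(calls, truth)
  write_tsv(data.frame(n_calls = rep$n_calls, n_truth = rep$n_truth,
                       n_matching = rep$n_matching,
                       fdr_percent = 100 * rep$fdr,
                       fnr_percent = 100 * rep$fnr),
            out_path(config, "concordance", "concordance.tsv"))
}
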