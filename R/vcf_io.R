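#' Read a multi-sample VCF into a genotype matrix and variant table
#'
#' Parses a VCF (v4.2) with per-sample `GT` fields into the pair of objects
#' the rest of the package operates on: an integer dosage matrix (samples in
#' rows, biallelic variants in columns, cells counting alternate alleles,
#' `NA` for missing genotypes) and a variant table carrying position,
#' alleles, the functional-class annotation and a known/novel flag.
#'
#' Multiallelic records are rejected: the analyses here are defined over
#' biallelic variants only, and splitting is the responsibility of upstream
#' tools (e.g. `bcftools norm`). Genotypes `./.` or `.` map to `NA` and are
#' excluded from allele counts downstream.
#'
#' @param path Path to an uncompressed or bgzipped VCF file.
#' @param panel Optional population panel (see [read_panel()]); if given,
#'   every panel sample must be present in the VCF and the matrix rows are
#'   reordered to the panel order.
#' @param class_key INFO key holding the functional class
#'   (`synonymous`/`nonsynonymous`/`other`); variants without the key get
#'   class `"other"`.
#' @param known_key INFO flag marking variants present in a reference
#'   catalogue; absent flag means novel.
#' @return A list with elements `genotypes` (integer matrix, dimnames =
#'   samples x variant keys) and `variants` (data.frame with columns `key`,
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `functional_class`, `known_flag`).
#' @export
read_vcf <- function(path, panel = NULL, class_key = "ANN_CLASS",
                     known_key = "KNOWN") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) stop("VCF '", path, "' contains no records")
  alt <- fix[, "ALT"]
  bad <- which(is.na(alt) | grepl(",", alt, fixed = TRUE))
  if (length(bad) > 0L) {
    stop("multiallelic or ALT-less record(s) at ",
         paste(fix[bad[seq_len(min(5, length(bad)))], "CHROM"],
               fix[bad[seq_len(min(5, length(bad)))], "POS"],
               sep = ":", collapse = ", "),
         " - split or drop multiallelic sites upstream")
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) stop("non-numeric POS field in VCF '", path, "'")
  info <- fix[, "INFO"]
  info[is.na(info)] <- "."
  fclass <- info_value(info, class_key)
  fclass[is.na(fclass)] <- "other"
  fclass[!fclass %in% c("synonymous", "nonsynonymous", "other")] <- "other"
  known <- info_flag(info, known_key)

  variants <- data.frame(
    key = variant_key(fix[, "CHROM"], pos, fix[, "REF"], alt),
    chrom = fix[, "CHROM"], pos = pos,
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"], alt = alt,
    functional_class = fclass, known_flag = known,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(variants$key)) {
    stop("duplicate variant records in VCF: ",
         variants$key[anyDuplicated(variants$key)])
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF '", path, "' has no GT FORMAT field")
  dos <- gt_to_dosage(gt)  # variants x samples
  geno <- t(dos)
  rownames(geno) <- colnames(gt)
  colnames(geno) <- variants$key

  if (!is.null(panel)) {
    missing <- setdiff(panel$sample, rownames(geno))
    if (length(missing) > 0L) {
      stop("panel sample(s) absent from VCF: ", paste(missing, collapse = ", "))
    }
    geno <- geno[panel$sample, , drop = FALSE]
  }
  list(genotypes = geno, variants = variants)
}

# GT strings (possibly phased) -> alt-allele dosage; anything with a "." is NA
gt_to_dosage <- function(gt) {
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  out <- map[gt]
  bad <- !is.na(gt) & !(gt %in% c(names(map), "./.", ".|.", ".")) &
    !grepl("\\.", gt)
  if (any(bad)) {
    stop("unsupported (non-biallelic?) GT value(s): ",
         paste(unique(gt[bad])[seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

info_value <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

info_flag <- function(info, key) {
  grepl(paste0("(^|;)", key, "($|;|=)"), info)
}

#' Write a genotype matrix and variant table as a VCF v4.2 file
#'
#' The inverse of [read_vcf()]: emits one biallelic record per variant with
#' `GT`-only FORMAT, the functional class under `class_key` and the known
#' flag under `known_key`. Reading the written file back reproduces the
#' sample order, variant keys and dosages exactly.
#'
#' @inheritParams read_vcf
#' @param genotypes Integer dosage matrix (samples x variants).
#' @param variants Variant table paired with `genotypes` (same order).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path, class_key = "ANN_CLASS",
                      known_key = "KNOWN") {
  stopifnot(ncol(genotypes) == nrow(variants),
            all(colnames(genotypes) == variants$key))
  gt_str <- c("0/0", "0/1", "1/1")[genotypes + 1L]
  gt_str[is.na(gt_str)] <- "./."
  dim(gt_str) <- dim(genotypes)
  info <- paste0(class_key, "=", variants$functional_class,
                 ifelse(variants$known_flag, paste0(";", known_key), ""))
  id <- if ("id" %in% names(variants)) variants$id else "."
  body <- cbind(variants$chrom, variants$pos, id, variants$ref, variants$alt,
                ".", "PASS", info, "GT", t(gt_str))
  lines <- do.call(paste, c(as.data.frame(body, stringsAsFactors = FALSE),
                            sep = "\t"))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=", class_key,
           ",Number=1,Type=String,Description=\"Functional class\">"),
    paste0("##INFO=<ID=", known_key,
           ",Number=0,Type=Flag,Description=\"Present in reference catalogue\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read and write the sample population panel
#'
#' The panel maps each sample to its population label and, optionally, to
#' the sampling location in decimal degrees. Stored as TSV with header
#' `sample  population  latitude  longitude`.
#'
#' @param path Path to the panel TSV.
#' @return A data.frame with columns `sample`, `population`, `latitude`,
#'   `longitude` (the last two possibly `NA`).
#' @export
read_panel <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "population")
  if (!all(req %in% names(p))) {
    stop("panel must have columns 'sample' and 'population'")
  }
  if (!"latitude" %in% names(p)) p$latitude <- NA_real_
  if (!"longitude" %in% names(p)) p$longitude <- NA_real_
  validate_panel(p)
  p[, c("sample", "population", "latitude", "longitude")]
}

#' @rdname read_panel
#' @param panel Panel data.frame.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_panel <- function(panel) {
  if (anyDuplicated(panel$sample)) {
    stop("duplicate sample id(s) in panel: ",
         paste(unique(panel$sample[duplicated(panel$sample)]), collapse = ", "))
  }
  lat <- panel$latitude
  lon <- panel$longitude
  if (any(!is.na(lat) & (lat < -90 | lat > 90))) {
    stop("panel latitude outside [-90, 90]")
  }
  if (any(!is.na(lon) & (lon < -180 | lon > 180))) {
    stop("panel longitude outside [-180, 180]")
  }
  invisible(panel)
}
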