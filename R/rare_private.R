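#' Classify focal-population variants by cross-population sharing
#'
#' Partitions every variant into exactly one class from the focal
#' population's point of view:
#'
#' * `monomorphic` - no alternate allele in the focal sample;
#' * `shared` - alternate allele also present in the comparison
#'   populations;
#' * `rare` - exactly one focal alternate chromosome (a singleton) and
#'   absent from every comparison population;
#' * `low_count_private` - 2-3 focal alternate chromosomes, absent
#'   elsewhere (named explicitly so the classes partition);
#' * `private` - more than 3 focal alternate chromosomes, absent
#'   elsewhere.
#'
#' @param focal_alt,focal_total Focal alternate and total chromosome
#'   counts (vectors).
#' @param other_alt,other_total Pooled counts over all comparison
#'   populations.
#' @return Factor with the five levels above, same length as the input.
#' @examples
#' classify_sharing(c(1, 4, 1, 0, 2), 32, c(0, 0, 5, 0, 0), 4000)
#' @export
classify_sharing <- function(focal_alt, focal_total, other_alt, other_total) {
  stopifnot(all(focal_alt >= 0), all(focal_alt <= focal_total),
            all(other_alt >= 0), all(other_alt <= other_total))
  n <- length(focal_alt)
  other_alt <- rep(other_alt, length.out = n)
  cls <- rep("private", n)
  cls[focal_alt >= 2 & focal_alt <= 3] <- "low_count_private"
  cls[focal_alt == 1] <- "rare"
  cls[other_alt > 0] <- "shared"
  cls[focal_alt == 0] <- "monomorphic"
  factor(cls, levels = c("monomorphic", "shared", "rare",
                         "low_count_private", "private"))
}

#' Sharing-class strata predicates
#'
#' Two readings of "rare" coexist in practice and both are exposed, named
#' in every output: `rare_strict` is a focal singleton that is also absent
#' from every comparison population, while `singleton` is a focal
#' singleton regardless of the other populations. `novel_rare` adds the
#' absence of the known-catalogue flag to `rare_strict`.
#'
#' @param classes Factor from [classify_sharing()].
#' @param focal_alt Focal alternate chromosome counts.
#' @param known_flag Logical known-catalogue flags.
#' @param stratum One of `"rare_strict"`, `"singleton"`, `"novel_rare"`,
#'   `"private"`, `"shared"`, `"all"` (all focal-polymorphic variants).
#' @return Logical vector of stratum membership.
#' @export
sharing_stratum <- function(classes, focal_alt, known_flag = NULL,
                            stratum = c("rare_strict", "singleton",
                                        "novel_rare", "private", "shared",
                                        "all")) {
  stratum <- match.arg(stratum)
  switch(stratum,
    rare_strict = classes == "rare",
    singleton = focal_alt == 1,
    novel_rare = {
      if (is.null(known_flag)) stop("novel_rare needs known_flag")
      classes == "rare" & !known_flag
    },
    private = classes == "private",
    shared = classes == "shared",
    all = focal_alt > 0)
}

#' Two-by-two functional enrichment table over two strata
#'
#' Counts non-synonymous and synonymous variants in each stratum; variants
#' of functional class `"other"` are excluded. Rows are strata, columns
#' `nonsynonymous` / `synonymous`.
#'
#' @param functional_class Character vector of functional classes.
#' @param stratum_a,stratum_b Logical membership vectors (e.g. from
#'   [sharing_stratum()]).
#' @param labels Row labels for the two strata.
#' @return 2x2 integer matrix.
#' @export
enrichment_table <- function(functional_class, stratum_a, stratum_b,
                             labels = c("a", "b")) {
  coding <- functional_class %in% c("nonsynonymous", "synonymous")
  count <- function(stratum) {
    sel <- stratum & coding
    if (!any(sel)) stop("empty stratum: no syn/nonsyn variants")
    c(sum(functional_class[sel] == "nonsynonymous"),
      sum(functional_class[sel] == "synonymous"))
  }
  tab <- rbind(count(stratum_a), count(stratum_b))
  dimnames(tab) <- list(labels, c("nonsynonymous", "synonymous"))
  if (any(colSums(tab) == 0L)) {
    stop("degenerate table: a functional class is absent from both strata")
  }
  tab
}

#' Chi-square test of a 2x2 table with Yates' continuity correction
#'
#' The closed form
#' \deqn{\chi^2 = \frac{N (|ad - bc| - N/2)^2}{(a+b)(c+d)(a+c)(b+d)}}
#' with the correction floored at zero when `|ad - bc| <= N/2`, and the
#' p-value from the 1-df chi-square survival function.
#'
#' @param table 2x2 numeric matrix with all margins positive.
#' @return Object of class `enrichment_result`: list with `table`,
#'   `statistic`, `p_value`.
#' @examples
#' chi_square_yates(rbind(c(10, 20), c(20, 10)))  # statistic 5.4
#' @export
chi_square_yates <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: the test is undefined")
  }
  a <- as.numeric(table[1, 1]); b <- as.numeric(table[1, 2])
  c_ <- as.numeric(table[2, 1]); d <- as.numeric(table[2, 2])
  n <- a + b + c_ + d
  num <- max(0, abs(a * d - b * c_) - n / 2)
  stat <- n * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  out <- list(table = table, statistic = stat,
              p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("chi-square (Yates) = %.4g, df = 1, p = %.4g\n",
              x$statistic, x$p_value))
  print(x$table)
  invisible(x)
}
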