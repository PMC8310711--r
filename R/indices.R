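# Headline statistics: refugium index, toxicity index, and the chi-square
# test of uniform element density across chromosome classes.

#' Refugium index
#'
#' RI = (%TE_obs - %TE_exp) / %TE_exp: the relative excess (RI > 0) or
#' depletion (RI < 0) of observed TE-derived bp on a chromosome (typically
#' the sex-limited chromosome) with respect to the genome-wide average
#' density of a haploid assembly.
#'
#' @param pct_te_obs observed percent TE on the chromosome(s) of interest
#'   (vectorised).
#' @param pct_te_exp genome-wide expected percent TE (> 0).
#' @return numeric vector of refugium indexes.
#' @examples
#' refugium_index(60, 10)  # 5: six-fold the genome-wide density
#' @export
refugium_index <- function(pct_te_obs, pct_te_exp) {
  if (any(pct_te_exp <= 0)) stop2("pct_te_exp must be > 0")
  (pct_te_obs - pct_te_exp) / pct_te_exp
}

#' Refugium index per chromosome from a density summary
#'
#' @param summary result of [te_bp_by_chromosome()].
#' @return the summary with an `ri` column; the genome-wide density used as
#'   the expectation is `attr(summary, "pct_te_exp")`.
#' @export
refugium_index_by_chromosome <- function(summary) {
  summary$ri <- refugium_index(summary$pct_te_obs, attr(summary, "pct_te_exp"))
  summary
}

#' Diploid intact-TE totals for the two sexes
#'
#' From per-class intact-TE counts, builds the totals carried by the
#' homogametic diploid (2 x autosomes + 2 x Z or X) and the heterogametic
#' diploid (2 x autosomes + 1 x Z or X + 1 x W or Y; 2 x autosomes + 1 x X
#' for XO). All intact-TE categories (fl-ERV + fl-LINE + fl-DNA) enter the
#' totals.
#'
#' @param census an `fl_census` (see [fl_census()]) or a named numeric vector
#'   of per-class counts (`autosome`, `Z`, `W` or `autosome`, `X`, `Y`/none).
#' @param sex_system `"ZW"`, `"XY"` or `"XO"`; defaults to the census'.
#' @return list of class `diploid_census`: `n_hom`, `n_het`, `sex_system`,
#'   `per_class` (the A/homologous/SLC counts used).
#' @examples
#' diploid_totals(c(autosome = 552, Z = 184, W = 723), "ZW")
#' @export
diploid_totals <- function(census, sex_system = NULL) {
  if (inherits(census, "fl_census")) {
    sex_system <- sex_system %||% census$sex_system
    counts <- census$by_class_total
  } else {
    counts <- census
  }
  if (is.null(sex_system)) stop2("sex_system required")
  sex_system <- match.arg(sex_system, c("ZW", "XY", "XO"))
  a <- unname(counts["autosome"])
  if (is.na(a)) a <- 0
  hom_chr <- if (sex_system == "ZW") "Z" else "X"
  slc_chr <- switch(sex_system, ZW = "W", XY = "Y", XO = NA_character_)
  z <- unname(counts[hom_chr])
  if (is.na(z)) stop2("census lacks required class ", hom_chr, " for ", sex_system)
  w <- if (is.na(slc_chr)) 0 else unname(counts[slc_chr])
  if (is.na(w)) stop2("census lacks required class ", slc_chr, " for ", sex_system)
  n_hom <- 2 * a + 2 * z
  n_het <- if (sex_system == "XO") 2 * a + z else 2 * a + z + w
  structure(list(n_hom = n_hom, n_het = n_het, sex_system = sex_system,
                 per_class = c(autosome = a, homologous = z, slc = w)),
            class = "diploid_census")
}

#' @export
print.diploid_census <- function(x, ...) {
  cat(sprintf("diploid_census (%s): n_hom = %g, n_het = %g\n",
              x$sex_system, x$n_hom, x$n_het))
  invisible(x)
}

#' Toxicity index
#'
#' TI = (2n_het - 2n_hom) / 2n_hom: the relative excess of intact TEs carried
#' by the heterogametic diploid over the homogametic diploid. TI = 0 means no
#' sex difference; TI > 0 indicates toxicity of the W or Y; TI < 0 toxicity
#' of the Z or X. Counts are integers, so the index is an exact ratio; use
#' `round(ti, 9)` to match 9-decimal report formatting.
#'
#' @param d a `diploid_census` from [diploid_totals()], or the homogametic
#'   total `n_hom` with `n_het` given separately.
#' @param n_het heterogametic diploid total when `d` is numeric.
#' @return numeric toxicity index.
#' @examples
#' toxicity_index(diploid_totals(c(autosome = 552, Z = 184, W = 723), "ZW"))
#' toxicity_index(1472, 2011)          # same: 539/1472
#' @export
toxicity_index <- function(d, n_het = NULL) {
  if (inherits(d, "diploid_census")) {
    n_hom <- d$n_hom; n_het <- d$n_het
  } else {
    n_hom <- d
    if (is.null(n_het)) stop2("n_het required when d is numeric")
  }
  if (any(n_hom <= 0)) stop2("n_hom must be > 0")
  (n_het - n_hom) / n_hom
}

#' Chi-square test of uniform element density across chromosome classes
#'
#' Compares observed per-class element counts (or bp) to expectations
#' proportional to class length, with autosomes pooled into one cell so that
#' three classes (A, Z, W or A, X, Y) give 2 degrees of freedom. A
#' per-chromosome variant (df = number of chromosomes - 1) is available via
#' `pool_autosomes = FALSE` on per-chromosome input.
#'
#' @param observed named numeric vector of observed counts or bp per class.
#' @param lengths named numeric vector of class lengths (same names).
#' @param mode `"counts"` or `"bp"` (annotation only).
#' @return list of class `uniformity_test`: `observed`, `expected`,
#'   `ratio` (obs/exp per class), `statistic`, `df`, `p_value`, `mode`.
#' @examples
#' uniformity_test(c(autosome = 0, Z = 0, W = 30),
#'                 c(autosome = 1, Z = 1, W = 1))
#' @export
uniformity_test <- function(observed, lengths, mode = c("counts", "bp")) {
  mode <- match.arg(mode)
  stopifnot(!is.null(names(observed)), !is.null(names(lengths)))
  lengths <- lengths[names(observed)]
  if (anyNA(lengths)) stop2("lengths missing for some classes")
  if (any(lengths <= 0)) stop2("class lengths must be positive")
  total <- sum(observed)
  if (total <= 0) stop2("observed total must be > 0")
  expected <- total * lengths / sum(lengths)
  if (any(expected == 0)) stop2("expected cell of zero")
  x2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- pchisq(x2, df = df, lower.tail = FALSE)
  structure(list(observed = observed, expected = expected,
                 ratio = observed / expected,
                 statistic = x2, df = df, p_value = p, mode = mode),
            class = "uniformity_test")
}

#' @export
print.uniformity_test <- function(x, ...) {
  cat(sprintf("uniformity_test (%s): X-squared = %.4g, df = %d, p = %.4g\n",
              x$mode, x$statistic, x$df, x$p_value))
  df <- data.frame(observed = x$observed, expected = x$expected,
                   `obs/exp` = x$ratio, check.names = FALSE)
  print(df)
  invisible(x)
}

#' Sex-linked chromosome index report
#'
#' One-stop summary: per-class counts, diploid totals, toxicity index,
#' per-chromosome refugium indexes and the uniformity chi-square, from a
#' full-length census and (optionally) a TE density summary.
#'
#' @param census `fl_census` object.
#' @param genome `genome_model` (for class lengths).
#' @param density optional [te_bp_by_chromosome()] result for refugium
#'   indexes.
#' @return list of class `slc_indices`.
#' @export
slc_indices <- function(census, genome, density = NULL) {
  d <- diploid_totals(census)
  ti <- toxicity_index(d)
  ch <- included_chromosomes(genome)
  class_len <- tapply(ch$length, ch$te_class, sum)
  cls <- intersect(names(census$by_class_total), names(class_len))
  ut <- uniformity_test(census$by_class_total[cls],
                        as.numeric(class_len[cls]) |> setNames(cls))
  ri <- if (!is.null(density)) refugium_index_by_chromosome(density) else NULL
  structure(list(census = census, diploid = d, toxicity_index = ti,
                 uniformity = ut, refugium = ri),
            class = "slc_indices")
}

#' @export
print.slc_indices <- function(x, ...) {
  cat("Sex-limited chromosome TE indices\n")
  cat("---------------------------------\n")
  print(x$census)
  print(x$diploid)
  cat(sprintf("toxicity index: %.9f\n", x$toxicity_index))
  print(x$uniformity)
  if (!is.null(x$refugium)) {
    cat("refugium index per chromosome:\n")
    print(x$refugium[, c("chromosome", "te_class", "pct_te_obs", "ri")])
    cat(sprintf("(genome-wide %%TE = %.4f)\n", attr(x$refugium, "pct_te_exp")))
  }
  invisible(x)
}
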