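#' Bundled worked-example census counts for six avian species
#'
#' Full-length TE counts (LINE+DNA, and fl-ERV under two detector profiles:
#' RetroTector-like `rt` and LTRharvest/LTRdigest-like `ltrhd`) for six
#' female reference-quality avian assemblies (Anna's hummingbird, emu,
#' chicken, paradise crow, kakapo, zebra finch), per chromosome group
#' (autosomes pooled, Z, W) and as printed male/female diploid totals.
#' Bundled as worked examples for [diploid_totals()] and
#' [toxicity_index()].
#'
#' @return data.frame: `species`, `group` (`autosome`, `Z`, `W`,
#'   `male_2n`, `female_2n`), `line_dna`, `rt`, `ltrhd`.
#' @export
avian_flte_counts <- function() {
  read.delim(system.file("extdata", "avian_flte_counts.tsv",
                         package = "slcTE"), stringsAsFactors = FALSE)
}

#' Reference toxicity-index values for the bundled avian censuses
#'
#' The W-chromosome toxicity indexes reported for the six species of
#' [avian_flte_counts()], under both detector profiles, printed to nine
#' decimal places.
#'
#' @return data.frame: `species`, `ti_ltrhd`, `ti_rt`.
#' @export
avian_toxicity_index <- function() {
  read.delim(system.file("extdata", "avian_toxicity_index.tsv",
                         package = "slcTE"), stringsAsFactors = FALSE)
}

#' Toxicity indexes recomputed from the bundled avian censuses
#'
#' Recomputes both profile indexes for every bundled species from the
#' intact-TE counts: the zebra finch entries from per-class A/Z/W counts
#' via [diploid_totals()] (its row set is fully internally consistent), all
#' species from the printed male/female diploid totals. Intact-TE totals
#' combine the LINE+DNA column with the profile's fl-ERV column.
#'
#' @param from `"diploid_totals"` (printed male/female 2n rows) or
#'   `"per_class"` (A/Z/W rows through [diploid_totals()]).
#' @return data.frame: `species`, `profile`, `n_hom`, `n_het`, `ti`.
#' @export
avian_ti_worked_examples <- function(from = c("diploid_totals", "per_class")) {
  from <- match.arg(from)
  counts <- avian_flte_counts()
  out <- list()
  for (sp in unique(counts$species)) {
    sub <- counts[counts$species == sp, ]
    for (profile in c("ltrhd", "rt")) {
      if (from == "diploid_totals") {
        m <- sub[sub$group == "male_2n", ]
        f <- sub[sub$group == "female_2n", ]
        n_hom <- m$line_dna + m[[profile]]
        n_het <- f$line_dna + f[[profile]]
      } else {
        per_class <- setNames(sub$line_dna + sub[[profile]], sub$group)
        d <- diploid_totals(per_class[c("autosome", "Z", "W")], "ZW")
        n_hom <- d$n_hom; n_het <- d$n_het
      }
      out[[length(out) + 1L]] <- data.frame(
        species = sp, profile = profile, n_hom = n_hom, n_het = n_het,
        ti = toxicity_index(n_hom, n_het), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
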