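# Cohort-based discovery of sex-linked SNVs in TE consensus space: variants
# present in every female genomic sample and absent in every male genomic
# sample are called W-linked; transcription is checked in RNA cohorts and
# variants seen in male RNA are discarded as false positives.

#' Presence/absence calling thresholds
#'
#' A site/allele is `present` in a sample iff depth >= `d_min` AND alt count
#' >= `c_min` AND alt frequency >= `f_pres`; `absent` iff depth >= `d_min`
#' AND alt frequency <= `f_abs`; otherwise `indeterminate`. Sites without
#' adequate coverage in any required sample are excluded rather than treated
#' as absent (the conservative reading).
#'
#' @param d_min minimum depth.
#' @param c_min minimum alternate-allele read count for presence.
#' @param f_pres minimum alternate-allele frequency for presence.
#' @param f_abs maximum alternate-allele frequency for absence.
#' @return list of class `snv_thresholds`.
#' @export
snv_thresholds <- function(d_min = 5, c_min = 3, f_pres = 0.20, f_abs = 0.05) {
  stopifnot(d_min > 0, c_min > 0, f_pres > 0, f_pres <= 1,
            f_abs >= 0, f_abs < f_pres)
  structure(list(d_min = d_min, c_min = c_min, f_pres = f_pres, f_abs = f_abs),
            class = "snv_thresholds")
}

#' Validate a sample sheet
#'
#' @param df data.frame with columns `sample`, `sex` (`male`/`female`),
#'   `assay` (`genomic`/`RNA`), and optionally `path`.
#' @return validated data.frame of class `sample_sheet`. Linkage calls need
#'   at least one female and one male genomic sample; a single male genomic
#'   sample triggers a warning (single-male cohorts are prone to
#'   false-positive W-linked SNVs).
#' @export
sample_sheet <- function(df) {
  stopifnot(all(c("sample", "sex", "assay") %in% names(df)))
  df$sample <- as.character(df$sample)
  df$sex <- match.arg(df$sex, c("male", "female"), several.ok = TRUE)
  df$assay <- match.arg(df$assay, c("genomic", "RNA"), several.ok = TRUE)
  if (anyDuplicated(df$sample)) stop2("duplicate sample identifiers")
  n_fg <- sum(df$sex == "female" & df$assay == "genomic")
  n_mg <- sum(df$sex == "male" & df$assay == "genomic")
  if (n_fg < 1 || n_mg < 1)
    stop2("need at least one female and one male genomic sample")
  if (n_mg == 1L)
    warning("only one male genomic sample: W-linked calls are prone to false positives",
            call. = FALSE)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet TSV
#'
#' Columns: sample, sex, assay, path.
#' @param path TSV file with header.
#' @return `sample_sheet` data.frame.
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(read.delim(path, stringsAsFactors = FALSE))
}

# ---- SAM --------------------------------------------------------------------

#' Parse SAM text records
#'
#' Minimal SAM reader (text dialect; headers skipped) keeping the fields the
#' pileup needs: flag, reference, 1-based position, MAPQ, CIGAR, SEQ, QUAL.
#'
#' @param path SAM file.
#' @return data.frame, one row per alignment line.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      seq = character(), qual = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t")
  bad <- which(lengths(f) < 11L)
  if (length(bad)) stop2("malformed SAM line ", bad[1])
  m <- t(vapply(f, function(x) x[1:11], character(11)))
  data.frame(qname = m[, 1], flag = as.integer(m[, 2]), rname = m[, 3],
             pos = as.integer(m[, 4]), mapq = as.integer(m[, 5]),
             cigar = m[, 6], seq = m[, 10], qual = m[, 11],
             stringsAsFactors = FALSE)
}

parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]", "", ops)),
       op = sub("[0-9]+", "", ops))
}

#' Build per-family allele pileups from alignments to a consensus library
#'
#' Counts A/C/G/T per consensus position from primary, non-duplicate, mapped
#' alignments passing mapping- and base-quality floors; CIGAR-aware column
#' placement (insertions/soft-clips consume query only, deletions reference
#' only).
#'
#' @param sam data.frame from [read_sam()] (or [naive_map()]).
#' @param library `consensus_library`.
#' @param min_mapq minimum mapping quality.
#' @param min_baseq minimum base quality (Phred+33).
#' @return object of class `consensus_pileup`: named list (per family) of
#'   4 x L count matrices (rows A,C,G,T).
#' @export
build_pileup <- function(sam, library, min_mapq = 20, min_baseq = 13) {
  fams <- names(library$sequences)
  piles <- lapply(library$sequences, function(s)
    matrix(0L, nrow = 4, ncol = nchar(s), dimnames = list(DNA_BASES, NULL)))
  if (nrow(sam)) {
    unk <- setdiff(unique(sam$rname[sam$rname != "*"]), fams)
    if (length(unk)) stop2("SAM reference(s) absent from library: ",
                           paste(unk, collapse = ", "))
    keep <- !bitwAnd(sam$flag, 0x4) &      # mapped
      !bitwAnd(sam$flag, 0x100) &          # primary
      !bitwAnd(sam$flag, 0x800) &          # not supplementary
      !bitwAnd(sam$flag, 0x400) &          # not duplicate
      sam$mapq >= min_mapq
    sam <- sam[keep, , drop = FALSE]
    for (i in seq_len(nrow(sam))) {
      fam <- sam$rname[i]
      L <- ncol(piles[[fam]])
      cg <- parse_cigar(sam$cigar[i])
      rpos <- sam$pos[i]              # 1-based ref
      qpos <- 1L
      bases <- strsplit(sam$seq[i], "")[[1]]
      quals <- utf8ToInt(sam$qual[i]) - 33L
      if (length(quals) != length(bases)) quals <- rep(60L, length(bases))
      for (j in seq_along(cg$op)) {
        len <- cg$len[j]; op <- cg$op[j]
        if (op %in% c("M", "=", "X")) {
          qs <- qpos:(qpos + len - 1L)
          rs <- rpos:(rpos + len - 1L)
          ok <- quals[qs] >= min_baseq & rs >= 1L & rs <= L
          b <- bases[qs[ok]]; r <- rs[ok]
          bi <- match(b, DNA_BASES)
          valid <- !is.na(bi)
          if (any(valid)) {
            # ref positions are unique within one alignment, so the
            # vectorised increment never collides with itself
            idx <- cbind(bi[valid], r[valid])
            piles[[fam]][idx] <- piles[[fam]][idx] + 1L
          }
          qpos <- qpos + len; rpos <- rpos + len
        } else if (op %in% c("I", "S")) {
          qpos <- qpos + len
        } else if (op %in% c("D", "N")) {
          rpos <- rpos + len
        }                                  # H, P consume nothing
      }
    }
  }
  structure(piles, class = "consensus_pileup")
}

#' Presence/absence of an allele in one sample's pileup
#'
#' @param pileup `consensus_pileup` for one sample.
#' @param family consensus family name.
#' @param position 0-based position on the consensus.
#' @param allele alternate base (A/C/G/T).
#' @param thresholds [snv_thresholds()].
#' @return one of `"present"`, `"absent"`, `"indeterminate"`.
#' @export
call_sample_presence <- function(pileup, family, position, allele,
                                 thresholds = snv_thresholds()) {
  m <- pileup[[family]]
  if (is.null(m) || position < 0 || position >= ncol(m))
    stop2("site outside consensus")
  col <- m[, position + 1L]
  depth <- sum(col)
  if (depth < thresholds$d_min) return("indeterminate")
  cnt <- col[[allele]]
  freq <- cnt / depth
  if (cnt >= thresholds$c_min && freq >= thresholds$f_pres) return("present")
  if (freq <= thresholds$f_abs) return("absent")
  "indeterminate"
}

# enumerate candidate (family, pos, alt) from female genomic pileups
candidate_alt_sites <- function(piles, sheet, library, thresholds) {
  fg <- sheet$sample[sheet$sex == "female" & sheet$assay == "genomic"]
  out <- list()
  for (fam in names(library$sequences)) {
    ref <- strsplit(library$sequences[[fam]], "")[[1]]
    tot <- Reduce(`+`, lapply(piles[fg], function(p) p[[fam]]))
    for (b in DNA_BASES) {
      pos <- which(tot[b, ] >= thresholds$c_min & ref != b)
      if (length(pos))
        out[[length(out) + 1]] <- data.frame(
          family = fam, position = pos - 1L, ref = ref[pos], alt = b,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(family = character(), position = integer(),
                      ref = character(), alt = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Call W-linked SNVs from per-sample pileups
#'
#' A variant is W-linked iff it is `present` in EVERY female genomic sample
#' and `absent` in EVERY male genomic sample; an `indeterminate` call in any
#' required sample excludes the site (conservative). Multi-allelic sites are
#' handled per alternate allele independently. Only SNVs (no indels) are
#' considered.
#'
#' @param piles named list of per-sample `consensus_pileup`s (names =
#'   sample ids).
#' @param sheet `sample_sheet`.
#' @param library `consensus_library`.
#' @param thresholds [snv_thresholds()].
#' @return data.frame of class `sexlinked_variants`: `family`, `position`
#'   (0-based), `ref`, `alt`, per-cohort tallies, `w_linked`, `transcribed`,
#'   `discarded_male_rna` (candidate sites failing the rule are kept with
#'   `w_linked = FALSE` for inspection).
#' @export
sexlinked_variants <- function(piles, sheet, library,
                               thresholds = snv_thresholds()) {
  stopifnot(inherits(sheet, "sample_sheet"))
  fg <- sheet$sample[sheet$sex == "female" & sheet$assay == "genomic"]
  mg <- sheet$sample[sheet$sex == "male" & sheet$assay == "genomic"]
  missing <- setdiff(c(fg, mg), names(piles))
  if (length(missing)) stop2("pileups missing for samples: ",
                             paste(missing, collapse = ", "))
  cand <- candidate_alt_sites(piles, sheet, library, thresholds)
  n <- nrow(cand)
  w_linked <- logical(n)
  nf_present <- integer(n); nm_absent <- integer(n); indet <- logical(n)
  for (i in seq_len(n)) {
    calls_f <- vapply(fg, function(s) call_sample_presence(
      piles[[s]], cand$family[i], cand$position[i], cand$alt[i], thresholds),
      character(1))
    calls_m <- vapply(mg, function(s) call_sample_presence(
      piles[[s]], cand$family[i], cand$position[i], cand$alt[i], thresholds),
      character(1))
    nf_present[i] <- sum(calls_f == "present")
    nm_absent[i] <- sum(calls_m == "absent")
    indet[i] <- any(c(calls_f, calls_m) == "indeterminate")
    w_linked[i] <- !indet[i] && all(calls_f == "present") && all(calls_m == "absent")
  }
  out <- cbind(cand,
               data.frame(n_female_present = nf_present,
                          n_female = length(fg),
                          n_male_absent = nm_absent,
                          n_male = length(mg),
                          indeterminate = indet,
                          w_linked = w_linked,
                          transcribed = NA,
                          discarded_male_rna = FALSE))
  class(out) <- c("sexlinked_variants", "data.frame")
  out
}

#' Check transcription of W-linked variants and remove male-RNA positives
#'
#' A W-linked variant is flagged `transcribed` iff present (same gates) in
#' at least one female RNA sample, and is discarded from the W-linked set
#' (flag `discarded_male_rna`) iff present in any male RNA sample.
#'
#' @param variants result of [sexlinked_variants()].
#' @param piles named list of per-sample pileups covering the RNA samples.
#' @param sheet `sample_sheet` (needs at least one RNA sample).
#' @param thresholds [snv_thresholds()].
#' @return updated variants.
#' @export
transcription_check <- function(variants, piles, sheet,
                                thresholds = snv_thresholds()) {
  fr <- sheet$sample[sheet$sex == "female" & sheet$assay == "RNA"]
  mr <- sheet$sample[sheet$sex == "male" & sheet$assay == "RNA"]
  if (!length(c(fr, mr))) stop2("no RNA samples in sheet")
  for (i in which(variants$w_linked)) {
    pres <- function(s) call_sample_presence(
      piles[[s]], variants$family[i], variants$position[i], variants$alt[i],
      thresholds) == "present"
    variants$transcribed[i] <- length(fr) > 0 && any(vapply(fr, pres, TRUE))
    if (length(mr) && any(vapply(mr, pres, TRUE))) {
      variants$discarded_male_rna[i] <- TRUE
      variants$w_linked[i] <- FALSE
    }
  }
  variants
}

#' Summarise W-linked SNVs per classification group
#'
#' The four standard report columns: number of W-linked SNVs, number of
#' subfamilies hit, number of transcribed SNVs, number of subfamilies with
#' transcribed SNVs — per TE classification group plus a total row.
#'
#' @param variants `sexlinked_variants` result (after
#'   [transcription_check()] if transcription columns should be filled).
#' @param classification named character vector family -> classification
#'   (e.g. a `consensus_library`'s `classification`).
#' @return data.frame: `group`, `n_snvs`, `n_subfamilies`,
#'   `n_transcribed_snvs`, `n_transcribed_subfamilies`.
#' @export
summarize_by_subfamily <- function(variants, classification) {
  v <- variants[variants$w_linked %in% TRUE, , drop = FALSE]
  grp <- function(fams) unname(classification[fams])
  groups <- sort(unique(unname(classification)))
  row_for <- function(sel, label) {
    vv <- v[sel, , drop = FALSE]
    tr <- vv$transcribed %in% TRUE
    data.frame(group = label,
               n_snvs = nrow(vv),
               n_subfamilies = length(unique(vv$family)),
               n_transcribed_snvs = sum(tr),
               n_transcribed_subfamilies = length(unique(vv$family[tr])),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(groups, function(g)
    row_for(grp(v$family) == g, g)))
  out <- rbind(out, row_for(rep(TRUE, nrow(v)), "total"))
  rownames(out) <- NULL
  out
}

#' Write variants as a consensus-space VCF-like report
#'
#' VCF-format columns with consensus families as the CHROM field; this is a
#' repeat-consensus coordinate dialect, not genomic VCF.
#'
#' @param variants `sexlinked_variants` result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##reference=TE-consensus-library (non-genomic coordinate space)",
           '##INFO=<ID=WL,Number=0,Type=Flag,Description="W-linked">',
           '##INFO=<ID=TR,Number=0,Type=Flag,Description="transcribed in female RNA">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- ifelse(variants$w_linked, "WL", ".")
  info <- ifelse(variants$transcribed %in% TRUE, paste0(info, ";TR"), info)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  variants$family, variants$position + 1L,
                  variants$ref, variants$alt,
                  ifelse(variants$discarded_male_rna, "maleRNA",
                         ifelse(variants$w_linked, "PASS", "notWlinked")),
                  info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
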