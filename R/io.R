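#' Read a FASTA file into a named character vector
#'
#' Names are the first whitespace-delimited token of each header; sequences
#' are uppercased and RNA `U` is mapped to `T`. Soft-masked (lowercase) input
#' is accepted.
#'
#' @param path FASTA file.
#' @return named character vector, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop2("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop2("duplicate FASTA names: ",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  setNames(seqs, nm)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Read a TE consensus library
#'
#' FASTA headers are expected in RepeatMasker library style
#' `family#classification` (e.g. `ERV1-like#LTR/ERV1`); a plain name gets
#' classification `Unknown`.
#'
#' @param path FASTA file of consensus sequences.
#' @return object of class `consensus_library`: list with `sequences`
#'   (named character, names = family) and `classification` (named character).
#' @export
read_consensus_library <- function(path) {
  seqs <- read_fasta(path)
  consensus_library(seqs)
}

#' Build a consensus library from sequences
#'
#' @param sequences named character vector; names may carry
#'   `family#classification`.
#' @param classification optional named character vector overriding the
#'   header-derived classification.
#' @return `consensus_library` object.
#' @export
consensus_library <- function(sequences, classification = NULL) {
  stopifnot(!is.null(names(sequences)), all(nchar(sequences) > 0))
  full <- names(sequences)
  fam <- sub("#.*$", "", full)
  cls <- ifelse(grepl("#", full), sub("^[^#]*#", "", full), "Unknown")
  if (anyDuplicated(fam))
    stop2("duplicate family names in library: ",
          paste(unique(fam[duplicated(fam)]), collapse = ", "))
  names(sequences) <- fam
  cls <- setNames(cls, fam)
  if (!is.null(classification)) cls[names(classification)] <- classification
  structure(list(sequences = sequences, classification = cls),
            class = "consensus_library")
}

#' @export
print.consensus_library <- function(x, ...) {
  cat("consensus_library:", length(x$sequences), "families\n")
  df <- data.frame(family = names(x$sequences),
                   classification = unname(x$classification),
                   length = unname(nchar(x$sequences)))
  print(utils::head(df, 10))
  if (nrow(df) > 10) cat("...\n")
  invisible(x)
}

#' Construct/validate a table of repeat hits
#'
#' The atom of landscapes and densities: one annotated TE interval.
#' Coordinates are 0-based half-open throughout the package; conversion to
#' 1-based happens only at format boundaries (`.out`, GFF3).
#'
#' @param chromosome,begin,end,strand,family,classification vectors of equal
#'   length; `begin < end`, strand in `+`/`-`.
#' @param divergence_pct optional percent divergence (>= 0, NA allowed).
#' @param fragment_link optional identifier joining split fragments of one
#'   insertion (the `.out` ID column).
#' @return data.frame of class `repeat_hits`.
#' @export
repeat_hits <- function(chromosome, begin, end, strand = "+",
                        family = NA_character_, classification = NA_character_,
                        divergence_pct = NA_real_, fragment_link = NA_character_) {
  n <- max(length(chromosome), length(begin), length(end))
  df <- data.frame(chromosome = rep_len(as.character(chromosome), n),
                   begin = rep_len(as.numeric(begin), n),
                   end = rep_len(as.numeric(end), n),
                   strand = rep_len(as.character(strand), n),
                   family = rep_len(as.character(family), n),
                   classification = rep_len(as.character(classification), n),
                   divergence_pct = rep_len(as.numeric(divergence_pct), n),
                   fragment_link = rep_len(as.character(fragment_link), n),
                   stringsAsFactors = FALSE)
  validate_repeat_hits(df)
}

validate_repeat_hits <- function(df) {
  if (nrow(df)) {
    if (any(df$begin >= df$end)) stop2("repeat hit with begin >= end")
    if (any(df$begin < 0)) stop2("negative repeat-hit coordinate")
    if (any(!df$strand %in% c("+", "-"))) stop2("strand must be + or -")
    dv <- df$divergence_pct
    if (any(!is.na(dv) & dv < 0)) stop2("divergence_pct must be >= 0")
  }
  class(df) <- c("repeat_hits", "data.frame")
  df
}

# ---- RepeatMasker .out ------------------------------------------------------

#' Parse a RepeatMasker `.out` annotation file
#'
#' Standard 15-column `.out` layout: three header lines, then whitespace-
#' delimited columns (score, div%, del%, ins%, query, qbegin, qend, qleft,
#' strand `+`/`C`, repeat, class/family, rbegin, rend, rleft, ID), with an
#' optional trailing `*` marking overlapping lower-scoring hits. 1-based
#' inclusive coordinates are converted to 0-based half-open; strand `C`
#' becomes `-`; the divergence column is kept as `divergence_pct` and the ID
#' column as `fragment_link`.
#'
#' @param path `.out` file.
#' @param keep_asterisk keep rows flagged `*` (default TRUE).
#' @return `repeat_hits` data.frame with an extra `score` column.
#' @export
parse_repeatmasker_out <- function(path, keep_asterisk = TRUE) {
  if (!file.exists(path)) stop2("no such file: ", path)
  lines <- readLines(path)
  # Skip the banner: header lines plus any blank line following them.
  body_idx <- which(grepl("^\\s*[0-9]+\\s", lines))
  if (!length(body_idx)) {
    return(cbind(repeat_hits(character(), numeric(), numeric()),
                 score = numeric()))
  }
  rows <- vector("list", length(body_idx))
  for (i in seq_along(body_idx)) {
    ln <- body_idx[i]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) == 16L && f[16] == "*") f <- f[1:15]
    if (!length(f) %in% c(14L, 15L))
      stop2("malformed .out line ", ln, ": expected 14-15 columns, got ",
            length(f))
    rows[[i]] <- f[1:14]
    # column 15 (ID) may be absent in some dialects
    rows[[i]][15] <- if (length(f) >= 15L) f[15] else NA_character_
  }
  m <- do.call(rbind, rows)
  strand <- ifelse(m[, 9] == "C", "-", m[, 9])
  if (any(!strand %in% c("+", "-")))
    stop2("malformed .out strand column (expected + or C) at line ",
          body_idx[which(!strand %in% c("+", "-"))[1]])
  qb <- suppressWarnings(as.numeric(m[, 6]))
  qe <- suppressWarnings(as.numeric(m[, 7]))
  if (anyNA(qb) || anyNA(qe))
    stop2("non-numeric coordinates in .out at line ",
          body_idx[which(is.na(qb) | is.na(qe))[1]])
  df <- repeat_hits(chromosome = m[, 5],
                    begin = qb - 1, end = qe,
                    strand = strand,
                    family = m[, 10],
                    classification = m[, 11],
                    divergence_pct = suppressWarnings(as.numeric(m[, 2])),
                    fragment_link = m[, 15])
  df$score <- suppressWarnings(as.numeric(m[, 1]))
  df
}

#' Write a RepeatMasker-style `.out` file
#'
#' Used by the simulator so that parser and downstream modules can be
#' exercised on byte-realistic annotation.
#' @param hits `repeat_hits` data.frame (optionally with `score`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(hits, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in queryding    matching        repeat            position in repeat",
    "score   div. del. ins.  sequence  begin end    (left)      repeat          class/family    begin  end    (left)  ID",
    "")
  score <- hits$score %||% rep(1000, nrow(hits))
  id <- hits$fragment_link
  id[is.na(id)] <- seq_len(nrow(hits))[is.na(id)]
  body <- sprintf("%5.0f %6.1f  0.0  0.0  %s %10d %10d (0) %s %-16s %-18s 1 %d (0) %s",
                  score,
                  ifelse(is.na(hits$divergence_pct), 0, hits$divergence_pct),
                  hits$chromosome, hits$begin + 1, hits$end,
                  ifelse(hits$strand == "-", "C", "+"),
                  hits$family, hits$classification,
                  hits$end - hits$begin, id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- BED / GFF3 -------------------------------------------------------------

hits_to_granges <- function(hits) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$chromosome,
    ranges = IRanges::IRanges(start = hits$begin + 1, end = hits$end),
    strand = hits$strand)
  S4Vectors::mcols(gr)$family <- hits$family
  S4Vectors::mcols(gr)$classification <- hits$classification
  gr
}

granges_to_hits <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  get_col <- function(nm, alt = NA_character_) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else alt
  }
  fam <- get_col("family", get_col("name", get_col("Name")))
  repeat_hits(chromosome = as.character(GenomicRanges::seqnames(gr)),
              begin = GenomicRanges::start(gr) - 1,
              end = GenomicRanges::end(gr),
              strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
              family = fam,
              classification = get_col("classification"))
}

#' Write repeat hits as BED6 or GFF3
#'
#' BED is 0-based half-open, six columns (name = family, score = 0). GFF3 is
#' 1-based inclusive with `type = dispersed_repeat` and attributes carrying
#' family and classification.
#'
#' @param hits `repeat_hits` data.frame.
#' @param path output file.
#' @param format `"BED"` or `"GFF3"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(hits, path, format = c("BED", "GFF3")) {
  format <- match.arg(toupper(format), c("BED", "GFF3"))
  gr <- hits_to_granges(hits)
  if (format == "BED") {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = ifelse(is.na(hits$family), ".", hits$family),
      score = 0L)
    rtracklayer::export(gr, path, format = "BED")
  } else {
    S4Vectors::mcols(gr)$type <- "dispersed_repeat"
    S4Vectors::mcols(gr)$source <- "slcTE"
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Read BED/GFF3 intervals back into repeat hits
#'
#' @param path interval file.
#' @param format `"BED"`, `"GFF3"`, or `"auto"` (by extension).
#' @return `repeat_hits` data.frame.
#' @export
read_intervals <- function(path, format = c("auto", "BED", "GFF3")) {
  format <- match.arg(toupper(format[1]), c("AUTO", "BED", "GFF3"))
  if (format == "AUTO") {
    ext <- toupper(sub(".*\\.", "", path))
    format <- if (ext %in% c("GFF3", "GFF")) "GFF3" else "BED"
  }
  gr <- rtracklayer::import(path, format = if (format == "BED") "BED" else "GFF3")
  granges_to_hits(gr)
}
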