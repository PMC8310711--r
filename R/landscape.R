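# Divergence landscapes: per-chromosome TE abundance binned by Kimura
# 2-parameter distance to consensus, normalised by chromosome size.

#' Transition/transversion tallies of a gapped sequence pair
#'
#' Counts transition (P) and transversion (Q) proportions over the ungapped,
#' unambiguous (A/C/G/T on both rows) columns of an aligned pair.
#'
#' @param copy_seq,consensus_seq equal-length gapped nucleotide strings
#'   (`-` or `.` as gap).
#' @return list with `P`, `Q`, `n_sites` (comparable columns).
#' @export
pair_tallies <- function(copy_seq, consensus_seq) {
  a <- strsplit(toupper(copy_seq), "")[[1]]
  b <- strsplit(toupper(consensus_seq), "")[[1]]
  if (length(a) != length(b)) stop2("aligned sequences differ in length")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop2("no comparable (ungapped, unambiguous) columns")
  diff <- a != b
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- diff & (purine[a] == purine[b])   # A<->G or C<->T
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n_sites = n)
}

#' Kimura 2-parameter distance
#'
#' K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)), with P the transition and Q
#' the transversion proportion over comparable columns. Saturated pairs where
#' the logarithm's argument is non-positive are flagged `undefined` (never
#' silently zero).
#'
#' @param copy_seq,consensus_seq equal-length gapped strings, or pass
#'   precomputed `P`/`Q`.
#' @param P,Q optional proportions overriding the sequence tallies.
#' @return list with `K` (substitutions/site, NA when undefined), `P`, `Q`,
#'   `n_sites` (NA when tallies were supplied directly), `defined` (logical).
#' @examples
#' k2p_distance(P = 0.1, Q = 0.05)$K   # ~0.17018
#' @export
k2p_distance <- function(copy_seq = NULL, consensus_seq = NULL,
                         P = NULL, Q = NULL) {
  n_sites <- NA_integer_
  if (is.null(P) || is.null(Q)) {
    t <- pair_tallies(copy_seq, consensus_seq)
    P <- t$P; Q <- t$Q; n_sites <- t$n_sites
  }
  stopifnot(P >= 0, Q >= 0, P + Q <= 1)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(K = NA_real_, P = P, Q = Q, n_sites = n_sites, defined = FALSE))
  }
  K <- -0.5 * log(w1 * sqrt(w2))
  list(K = max(K, 0), P = P, Q = Q, n_sites = n_sites, defined = TRUE)
}

#' TE density per chromosome
#'
#' Computes TE-derived bp and percent TE per chromosome, with overlapping
#' hits flattened (union of covered bases) so no base is counted twice, plus
#' the genome-wide expected density `%TE_exp` (length-weighted mean over
#' included chromosomes; unplaced excluded by default).
#'
#' @param hits `repeat_hits` data.frame.
#' @param genome `genome_model`.
#' @param filter optional predicate on the classification column (function of
#'   a character vector returning logical), e.g.
#'   `function(cl) grepl("^LTR", cl)`.
#' @param include_unplaced include unplaced records in the summary/average.
#' @param exclude_n use N-excluded chromosome lengths (needs `length_no_n`
#'   or sequences in the genome model).
#' @return data.frame of class `density_summary` with columns `chromosome`,
#'   `te_class`, `length_bp`, `te_bp`, `pct_te_obs`, and attributes
#'   `pct_te_exp` (genome-wide density) and `mode`.
#' @export
te_bp_by_chromosome <- function(hits, genome, filter = NULL,
                                include_unplaced = FALSE, exclude_n = FALSE) {
  ch <- included_chromosomes(genome, include_unplaced)
  lens <- chromosome_lengths(genome, exclude_n = exclude_n,
                             include_unplaced = include_unplaced)
  if (nrow(hits)) {
    unknown <- setdiff(unique(hits$chromosome), genome$chromosomes$name)
    if (length(unknown))
      stop2("hits reference unknown chromosome(s): ",
            paste(unknown, collapse = ", "))
    if (!is.null(filter)) hits <- hits[filter(hits$classification), , drop = FALSE]
    hits <- hits[hits$chromosome %in% ch$name, , drop = FALSE]
    too_far <- hits$end > genome$chromosomes$length[
      match(hits$chromosome, genome$chromosomes$name)]
    if (any(too_far)) stop2("hit extends past chromosome end")
  }
  te_bp <- setNames(numeric(nrow(ch)), ch$name)
  if (nrow(hits)) {
    gr <- GenomicRanges::reduce(hits_to_granges(hits), ignore.strand = TRUE)
    bp <- tapply(GenomicRanges::width(gr),
                 as.character(GenomicRanges::seqnames(gr)), sum)
    te_bp[names(bp)] <- bp
  }
  out <- data.frame(chromosome = ch$name, te_class = ch$te_class,
                    length_bp = unname(lens), te_bp = unname(te_bp),
                    pct_te_obs = 100 * unname(te_bp) / unname(lens),
                    stringsAsFactors = FALSE)
  attr(out, "pct_te_exp") <- 100 * sum(out$te_bp) / sum(out$length_bp)
  attr(out, "mode") <- if (exclude_n) "N-excluded" else "assembled"
  class(out) <- c("density_summary", "data.frame")
  out
}

#' Aggregate a density summary by chromosome class
#'
#' @param summary result of [te_bp_by_chromosome()].
#' @return data.frame with one row per chromosome class present.
#' @export
density_by_class <- function(summary) {
  agg <- aggregate(cbind(length_bp, te_bp) ~ te_class, data = summary, FUN = sum)
  agg$pct_te_obs <- 100 * agg$te_bp / agg$length_bp
  attr(agg, "pct_te_exp") <- attr(summary, "pct_te_exp")
  agg
}

#' Build a divergence-binned TE landscape
#'
#' Each hit contributes its bp to exactly one divergence bin
#' `[k*w, (k+1)*w)`; divergences at or beyond `cap` pool into the final bin.
#' Abundance is reported both as raw bp and as bp per Mb of chromosome-class
#' length.
#'
#' @param hits `repeat_hits` with `divergence_pct` filled in (from the `.out`
#'   annotation), or realign with [k2p_distance()] upstream and store
#'   `100 * K` in `divergence_pct`.
#' @param genome `genome_model`.
#' @param bin_width bin width in percent (default 1).
#' @param cap pool divergences >= `cap` percent into the last bin.
#' @param include_unplaced include unplaced chromosomes.
#' @return data.frame of class `landscape_table`: columns `te_class`,
#'   `classification`, `bin_low`, `bin_high`, `bp`, `bp_per_mb`.
#' @export
build_landscape <- function(hits, genome, bin_width = 1, cap = 50,
                            include_unplaced = FALSE) {
  if (!is.numeric(bin_width) || bin_width <= 0) stop2("bin width must be positive")
  ch <- included_chromosomes(genome, include_unplaced)
  class_len <- tapply(ch$length, ch$te_class, sum)
  bins_low <- seq(0, cap, by = bin_width)
  empty <- data.frame(te_class = character(), classification = character(),
                      bin_low = numeric(), bin_high = numeric(),
                      bp = numeric(), bp_per_mb = numeric())
  if (!nrow(hits)) {
    class(empty) <- c("landscape_table", "data.frame")
    return(empty)
  }
  hits <- hits[hits$chromosome %in% ch$name, , drop = FALSE]
  dv <- hits$divergence_pct
  if (anyNA(dv)) stop2("hits without divergence_pct; fill from .out or realignment")
  bin <- pmin(floor(dv / bin_width) * bin_width, max(bins_low))
  te_class <- ch$te_class[match(hits$chromosome, ch$name)]
  agg <- aggregate(list(bp = hits$end - hits$begin),
                   by = list(te_class = te_class,
                             classification = hits$classification,
                             bin_low = bin),
                   FUN = sum)
  agg$bin_high <- agg$bin_low + bin_width
  agg$bp_per_mb <- agg$bp / (as.numeric(class_len[agg$te_class]) / 1e6)
  agg <- agg[order(agg$te_class, agg$classification, agg$bin_low),
             c("te_class", "classification", "bin_low", "bin_high", "bp", "bp_per_mb")]
  rownames(agg) <- NULL
  class(agg) <- c("landscape_table", "data.frame")
  agg
}

#' Realign TE copies to their consensus and estimate divergence
#'
#' Affine-gap global alignment of each copy against its family consensus
#' (plain K2P on the aligned pair; ambiguous bases excluded). Intended for
#' annotations lacking a divergence column.
#'
#' @param hits `repeat_hits`.
#' @param genome `genome_model` with sequences.
#' @param library `consensus_library`.
#' @return `hits` with `divergence_pct` replaced by `100 * K` (NA where K is
#'   undefined/saturated).
#' @export
realign_divergence <- function(hits, genome, library) {
  if (is.null(genome$sequences)) stop2("genome model carries no sequences")
  out <- hits
  for (i in seq_len(nrow(hits))) {
    fam <- hits$family[i]
    if (!fam %in% names(library$sequences)) {
      out$divergence_pct[i] <- NA_real_
      next
    }
    copy <- substr(genome$sequences[[hits$chromosome[i]]],
                   hits$begin[i] + 1, hits$end[i])
    if (hits$strand[i] == "-") copy <- revcomp(copy)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(copy),
      Biostrings::DNAString(library$sequences[[fam]]),
      type = "global-local", gapOpening = 10, gapExtension = 0.5)
    k <- k2p_distance(as.character(Biostrings::alignedPattern(aln)),
                      as.character(Biostrings::alignedSubject(aln)))
    out$divergence_pct[i] <- if (k$defined) 100 * k$K else NA_real_
  }
  out
}
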