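# Structural detection of paired-LTR elements (ERV candidates): exact k-mer
# seeding of direct repeats, offset clustering, TSD-anchored boundary
# refinement, LTR-pair global alignment, and composite evidence scoring.

# integer codes 0-3 for A,C,G,T; NA elsewhere
encode_dna <- function(sequence) {
  v <- strsplit(toupper(sequence), "")[[1]]
  m <- match(v, DNA_BASES) - 1L
  m
}

# k-mer id at every start position (length n-k+1); NA where any base is non-ACGT
kmer_ids <- function(code, k) {
  n <- length(code)
  if (n < k) return(numeric(0))
  id <- numeric(n - k + 1L)
  for (j in 0:(k - 1L)) {
    id <- id * 4 + code[(1L + j):(n - k + 1L + j)]
  }
  id
}

# Direct-repeat seed pairs (p1 < p2, 1-based starts) whose k-mers match
# exactly and whose offset p2-p1 lies in [min_off, max_off].
seed_pairs <- function(ids, min_off, max_off, occ_cap = 64L) {
  ok <- which(!is.na(ids))
  if (length(ok) < 2L) return(data.frame(p1 = integer(), p2 = integer()))
  ord <- ok[order(ids[ok], ok)]
  sid <- ids[ord]
  # drop over-represented k-mers (low-complexity guard)
  r <- rle(sid)
  keep_val <- r$values[r$lengths <= occ_cap]
  keep <- sid %in% keep_val
  ord <- ord[keep]; sid <- sid[keep]
  n <- length(ord)
  res_p1 <- integer(0); res_p2 <- integer(0)
  lag <- 1L
  repeat {
    if (lag >= n) break
    i <- seq_len(n - lag)
    same <- sid[i] == sid[i + lag]
    if (!any(same)) break
    a <- ord[i][same]; b <- ord[i + lag][same]
    p1 <- pmin(a, b); p2 <- pmax(a, b)
    d <- p2 - p1
    sel <- d >= min_off & d <= max_off
    res_p1 <- c(res_p1, p1[sel]); res_p2 <- c(res_p2, p2[sel])
    lag <- lag + 1L
  }
  data.frame(p1 = res_p1, p2 = res_p2)
}

# global LTR-pair identity: matches over alignment length
ltr_pair_identity <- function(s1, s2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s1), Biostrings::DNAString(s2),
    type = "global", gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

# TSD-anchored boundary refinement: exact-seed boundaries can over- or
# under-run by a few bp when flanking bases coincide by chance; try small
# shifts of the start pair / end pair and keep the one revealing a perfect
# target-site duplication (longest TSD wins, then smallest shift).
refine_tsd <- function(seq, l1s, l1e, l2s, l2e, tsd_min, tsd_max, max_shift = 3L) {
  n <- nchar(seq)
  best <- list(tsd_len = 0L, tsd_seq = NA_character_, s = 0L, e = 0L)
  for (s in 0:max_shift) {          # shift both starts right by s
    for (e_back in 0:max_shift) {
      a <- l1s + s          # element start (1-based)
      b <- l2e - e_back     # element end (1-based, inclusive)
      for (t in seq(tsd_max, tsd_min)) {
        if (a - t < 1L || b + t > n) next
        left <- substr(seq, a - t, a - 1L)
        right <- substr(seq, b + 1L, b + t)
        if (left == right && !grepl("N", left, fixed = TRUE)) {
          cand <- list(tsd_len = t, tsd_seq = left, s = s, e = e_back)
          # longest TSD wins; smaller boundary shift breaks ties (when a
          # flanking base happens to equal the LTR edge both readings are
          # genuinely present in the sequence and the boundary is only
          # determined up to that shift)
          better <- t > best$tsd_len ||
            (t == best$tsd_len && (s + e_back) < (best$s + best$e))
          if (better) best <- cand
        }
      }
    }
  }
  best
}

#' Detect paired-LTR (ERV-like) elements in a chromosome sequence
#'
#' Finds direct repeats by exact k-mer seeding (same strand), chains seeds
#' sharing an offset into putative LTR pairs, and keeps pairs satisfying the
#' structural criteria: LTR length within bounds, element span within
#' bounds, LTR-pair global-alignment identity at least
#' `criteria$ltr_identity_min`, and (scored, not required) a flanking 4-6 bp
#' target-site duplication identical on both sides. Boundaries are refined
#' against the TSD when one is found. Overlapping candidates are resolved by
#' identity, then leftmost start.
#'
#' @param sequence chromosome nucleotide string.
#' @param criteria [fulllength_criteria()].
#' @param chromosome name recorded in the output.
#' @return data.frame of ERV candidates: element span (`begin`, `end`;
#'   0-based half-open), LTR and internal spans, `ltr_identity`, `tsd_len`,
#'   `tsd_seq`, `n_seeds`.
#' @export
detect_ltr_elements <- function(sequence, criteria = fulllength_criteria(),
                                chromosome = "seq") {
  k <- as.integer(criteria$seed_k)
  empty <- data.frame(chromosome = character(), begin = numeric(), end = numeric(),
                      ltr1_begin = numeric(), ltr1_end = numeric(),
                      ltr2_begin = numeric(), ltr2_end = numeric(),
                      internal_begin = numeric(), internal_end = numeric(),
                      ltr_identity = numeric(), tsd_len = integer(),
                      tsd_seq = character(), n_seeds = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(sequence) < criteria$elem_len_min) return(empty)
  seq <- toupper(sequence)
  ids <- kmer_ids(encode_dna(seq), k)
  min_off <- max(criteria$elem_len_min - criteria$ltr_len_max, k)
  max_off <- criteria$elem_len_max - criteria$ltr_len_min
  seeds <- seed_pairs(ids, min_off, max_off)
  if (!nrow(seeds)) return(empty)
  seeds$off <- seeds$p2 - seeds$p1
  # two-stage clustering: chain seeds along the sequence, then split each
  # positional chain by offset (diagonals within `band` of each other
  # belong to one LTR pair; indels in diverged LTRs shift the diagonal
  # only slightly, while coincidental repeats land on distant diagonals)
  band <- 20L
  pos_gap <- 400L
  seeds <- seeds[order(seeds$p1, seeds$off), ]
  pos_cl <- cumsum(c(TRUE, diff(seeds$p1) > pos_gap))
  groups <- list()
  for (pg in split(seq_len(nrow(seeds)), pos_cl)) {
    pg <- pg[order(seeds$off[pg], seeds$p1[pg])]
    off_cl <- cumsum(c(TRUE, diff(seeds$off[pg]) > band))
    groups <- c(groups, split(pg, off_cl))
  }
  evaluate_group <- function(g) {
    p1 <- seeds$p1[g]; p2 <- seeds$p2[g]
    l1s <- min(p1); l1e <- max(p1) + k - 1L    # 1-based inclusive
    l2s <- min(p2); l2e <- max(p2) + k - 1L
    w1 <- l1e - l1s + 1L; w2 <- l2e - l2s + 1L
    if (w1 < criteria$ltr_len_min || w1 > criteria$ltr_len_max) return(NULL)
    if (w2 < criteria$ltr_len_min || w2 > criteria$ltr_len_max) return(NULL)
    span <- l2e - l1s + 1L
    if (span < criteria$elem_len_min || span > criteria$elem_len_max) return(NULL)
    if (l1e >= l2s) return(NULL)                # LTRs must not touch/overlap
    tsd <- refine_tsd(seq, l1s, l1e, l2s, l2e,
                      criteria$tsd_len_min, criteria$tsd_len_max)
    if (tsd$tsd_len > 0L) {
      l1s <- l1s + tsd$s; l2s <- l2s + tsd$s
      l1e <- l1e - tsd$e; l2e <- l2e - tsd$e
      if (l1e <= l1s || l2e <= l2s || l1e >= l2s) return(NULL)
    }
    ident <- ltr_pair_identity(substr(seq, l1s, l1e), substr(seq, l2s, l2e))
    if (ident < criteria$ltr_identity_min) return(NULL)
    data.frame(
      chromosome = chromosome,
      begin = l1s - 1, end = l2e,
      ltr1_begin = l1s - 1, ltr1_end = l1e,
      ltr2_begin = l2s - 1, ltr2_end = l2e,
      internal_begin = l1e, internal_end = l2s - 1,
      ltr_identity = ident,
      tsd_len = tsd$tsd_len,
      tsd_seq = tsd$tsd_seq,
      n_seeds = length(g), stringsAsFactors = FALSE)
  }
  cand <- list()
  for (g in groups) {
    # evaluate both the full cluster and its modal-diagonal core: chance
    # repeats on a nearby diagonal can attach to a true cluster and corrupt
    # its boundaries, while real indel scatter needs the full cluster —
    # overlap resolution later keeps whichever reading aligns better
    offs <- seeds$off[g]
    modal <- as.integer(names(which.max(table(offs))))
    variants <- list(g, g[abs(offs - modal) <= 3L], g[offs == modal])
    variants <- variants[!duplicated(lapply(variants, length))]
    for (v in variants) {
      res <- evaluate_group(v)
      if (!is.null(res)) cand[[length(cand) + 1L]] <- res
    }
  }
  if (!length(cand)) return(empty)
  out <- do.call(rbind, cand)
  # resolve overlaps: best identity first, then leftmost
  out <- out[order(-out$ltr_identity, out$begin), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(out)) > i)
    if (!length(later)) next
    ov <- out$begin[later] < out$end[i] & out$end[later] > out$begin[i]
    keep[later[ov]] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$begin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score ERV candidates on internal protein evidence and filter
#'
#' Composite score (documented weights) =
#' `100 * LTR identity + 25 * TSD presence + 25 * LTR length agreement +
#' 150 * (span_gag + span_pol + span_env)`, where each span is the best
#' fraction of the domain consensus covered by a local alignment of any
#' internal ORF translation. A candidate is retained iff both LTRs are
#' present (true by construction), the score is at least
#' `criteria$erv_min_score` (>= semantics: a score exactly at the threshold
#' is retained), and at least one internal domain is at least "partly
#' complete" (`span >= criteria$partial_span_min`). `autonomous` flags
#' candidates whose pol span alone reaches `partial_span_min`.
#'
#' @param candidates result of [detect_ltr_elements()].
#' @param sequence the chromosome sequence the candidates refer to.
#' @param domains named list of domain consensus peptides
#'   (`gag`, `pol`, `env`).
#' @param criteria [fulllength_criteria()].
#' @param orf_min_bp minimum internal ORF length considered for domain
#'   evidence.
#' @return candidates with `span_gag`, `span_pol`, `span_env`, `score`,
#'   `autonomous`, filtered to retained fl-ERVs; `category` set to
#'   `"fl_ERV"`.
#' @export
score_and_filter_erv <- function(candidates, sequence, domains,
                                 criteria = fulllength_criteria(),
                                 orf_min_bp = 300) {
  need <- c("gag", "pol", "env")
  if (!all(need %in% names(domains)))
    stop2("domains must provide gag, pol and env consensi")
  if (!nrow(candidates)) {
    out <- candidates
    out$span_gag <- out$span_pol <- out$span_env <- out$score <- numeric(0)
    out$autonomous <- logical(0); out$category <- character(0)
    return(out)
  }
  seq <- toupper(sequence)
  spans <- matrix(0, nrow(candidates), 3, dimnames = list(NULL, need))
  for (i in seq_len(nrow(candidates))) {
    internal <- substr(seq, candidates$internal_begin[i] + 1,
                       candidates$internal_end[i])
    orfs <- find_orfs(internal, min_bp = orf_min_bp, both_strands = TRUE)
    if (!nrow(orfs)) next
    m <- orf_domain_matrix(orfs, domains[need])
    spans[i, ] <- apply(m, 2, max)
  }
  w1 <- candidates$ltr1_end - candidates$ltr1_begin
  w2 <- candidates$ltr2_end - candidates$ltr2_begin
  len_agree <- pmin(w1, w2) / pmax(w1, w2)
  score <- 100 * candidates$ltr_identity +
    25 * (candidates$tsd_len > 0) +
    25 * len_agree +
    150 * rowSums(spans)
  keep <- score >= criteria$erv_min_score &
    apply(spans, 1, max) >= criteria$partial_span_min
  out <- candidates[keep, , drop = FALSE]
  out$span_gag <- spans[keep, "gag"]
  out$span_pol <- spans[keep, "pol"]
  out$span_env <- spans[keep, "env"]
  out$score <- score[keep]
  out$autonomous <- out$span_pol >= criteria$partial_span_min
  out$category <- rep("fl_ERV", nrow(out))
  rownames(out) <- NULL
  out
}

#' Detect and score fl-ERVs across a genome
#'
#' Runs [detect_ltr_elements()] and [score_and_filter_erv()] on every
#' chromosome of a genome model with sequences.
#'
#' @param genome `genome_model` with sequences.
#' @param domains gag/pol/env domain consensus peptides.
#' @param criteria [fulllength_criteria()].
#' @return data.frame of retained fl-ERV calls across chromosomes.
#' @export
detect_erv_genome <- function(genome, domains, criteria = fulllength_criteria()) {
  if (is.null(genome$sequences)) stop2("genome model carries no sequences")
  res <- lapply(genome$chromosomes$name, function(chr) {
    cand <- detect_ltr_elements(genome$sequences[[chr]], criteria, chromosome = chr)
    score_and_filter_erv(cand, genome$sequences[[chr]], domains, criteria)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export full-length TE calls as GFF3
#'
#' Writes one `repeat_region` parent per call with child features
#' `five_prime_LTR`, `internal` (as `repeat_region` sub-parts) and
#' `target_site_duplication` rows where present.
#'
#' @param calls fl-ERV calls from [score_and_filter_erv()] /
#'   [detect_erv_genome()].
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_erv_gff3 <- function(calls, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(calls))) {
    id <- sprintf("flERV%04d", i)
    chrom <- calls$chromosome[i]
    row <- function(type, b, e, parent = NULL, extra = "") {
      attr <- if (is.null(parent)) sprintf("ID=%s%s", id, extra)
      else sprintf("ID=%s_%s;Parent=%s%s", id, type, id, extra)
      sprintf("%s\tslcTE\t%s\t%d\t%d\t%.1f\t+\t.\t%s",
              chrom, type, b + 1, e, calls$score[i] %||% 0, attr)
    }
    lines <- c(lines,
               row("repeat_region", calls$begin[i], calls$end[i],
                   extra = sprintf(";ltr_identity=%.3f", calls$ltr_identity[i])),
               row("five_prime_LTR", calls$ltr1_begin[i], calls$ltr1_end[i], parent = id),
               row("repeat_fragment", calls$internal_begin[i], calls$internal_end[i], parent = id),
               row("three_prime_LTR", calls$ltr2_begin[i], calls$ltr2_end[i], parent = id))
    if (!is.na(calls$tsd_len[i]) && calls$tsd_len[i] > 0) {
      lines <- c(lines,
                 row("target_site_duplication",
                     calls$begin[i] - calls$tsd_len[i], calls$begin[i], parent = id),
                 row("target_site_duplication",
                     calls$end[i], calls$end[i] + calls$tsd_len[i], parent = id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a precomputed tabular domain-hit file
#'
#' RPS-BLAST-style tab-separated columns: query, domain, query begin/end,
#' consensus begin/end, consensus length, score, e-value. `span_fraction` is
#' recomputed as aligned consensus residues over consensus length.
#'
#' @param path TSV file (with header).
#' @return data.frame with a `span_fraction` column.
#' @export
read_domain_hits <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query", "domain", "cons_begin", "cons_end", "cons_length")
  if (!all(need %in% names(df)))
    stop2("domain-hit table needs columns: ", paste(need, collapse = ", "))
  df$span_fraction <- (df$cons_end - df$cons_begin + 1) / df$cons_length
  if (any(df$span_fraction < 0 | df$span_fraction > 1))
    stop2("invalid consensus span in domain-hit table")
  df
}
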