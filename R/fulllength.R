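# Full-length (potentially transposition-competent) TE calling:
# homology-based ORF/domain-span tests for LINEs and DNA transposons, and a
# census of intact elements per chromosome class.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Full-length calling criteria
#'
#' Thresholds for the intactness tests. LINE insertions need an ORF of at
#' least `line_min_orf_bp` whose translation spans at least `line_span_min`
#' of both the endonuclease (EN) and reverse-transcriptase (RT) domain
#' consensi; DNA transposons need an ORF of at least `dna_min_orf_bp`
#' spanning `dna_span_min` of the transposase. ERV structural bounds govern
#' the paired-LTR detector, and `erv_min_score` gates the composite evidence
#' score (retained when score >= threshold). `partial_span_min` defines
#' "partly complete" for internal gag/pol/env evidence.
#'
#' @param line_min_orf_bp minimum LINE ORF length (bp).
#' @param line_span_min minimum EN and RT span fraction.
#' @param dna_min_orf_bp minimum DNA-transposon ORF length (bp).
#' @param dna_span_min minimum transposase span fraction.
#' @param erv_min_score composite-score threshold for fl-ERV retention.
#' @param ltr_len_min,ltr_len_max LTR length bounds (bp).
#' @param elem_len_min,elem_len_max full element span bounds (bp).
#' @param ltr_identity_min minimum identity of the aligned LTR pair.
#' @param tsd_len_min,tsd_len_max target-site-duplication length range (bp).
#' @param partial_span_min span fraction counting a domain as "partly
#'   complete".
#' @param seed_k exact seed k-mer length for the LTR-pair detector.
#' @param same_orf require EN and RT on the same ORF (default FALSE: the two
#'   domains may be met by one ORF or by two ORFs of the same insertion).
#' @return list of class `fl_criteria`.
#' @export
fulllength_criteria <- function(line_min_orf_bp = 600, line_span_min = 0.90,
                                dna_min_orf_bp = 1000, dna_span_min = 0.90,
                                erv_min_score = 300,
                                ltr_len_min = 100, ltr_len_max = 1000,
                                elem_len_min = 1500, elem_len_max = 15000,
                                ltr_identity_min = 0.80,
                                tsd_len_min = 4, tsd_len_max = 6,
                                partial_span_min = 0.5,
                                seed_k = 11, same_orf = FALSE) {
  cr <- list(line_min_orf_bp = line_min_orf_bp, line_span_min = line_span_min,
             dna_min_orf_bp = dna_min_orf_bp, dna_span_min = dna_span_min,
             erv_min_score = erv_min_score,
             ltr_len_min = ltr_len_min, ltr_len_max = ltr_len_max,
             elem_len_min = elem_len_min, elem_len_max = elem_len_max,
             ltr_identity_min = ltr_identity_min,
             tsd_len_min = tsd_len_min, tsd_len_max = tsd_len_max,
             partial_span_min = partial_span_min,
             seed_k = seed_k, same_orf = same_orf)
  stopifnot(all(vapply(cr[1:13], function(x) is.numeric(x) && x > 0, TRUE)),
            line_span_min <= 1, dna_span_min <= 1, partial_span_min <= 1,
            ltr_identity_min <= 1)
  structure(cr, class = "fl_criteria")
}

#' Find open reading frames
#'
#' Maximal stop-to-stop stretches in all three frames of the forward strand
#' (optionally also the reverse complement). A start codon is NOT required;
#' terminal stretches (sequence edge to first stop, last stop to edge) count.
#'
#' @param sequence nucleotide string.
#' @param min_bp minimum ORF length in bp (reported lengths are multiples
#'   of 3).
#' @param both_strands also scan the reverse complement.
#' @return data.frame: `begin`, `end` (0-based half-open on the input
#'   sequence's forward coordinates), `strand`, `frame` (0-2), `nt_length`,
#'   `peptide`.
#' @export
find_orfs <- function(sequence, min_bp = 600, both_strands = FALSE) {
  stopifnot(nchar(sequence) > 0)
  scan1 <- function(s, strand) {
    n <- nchar(s)
    res <- list()
    for (f in 0:2) {
      starts <- seq(f + 1, n - 2, by = 3)
      if (!length(starts) || utils::tail(starts, 1) + 2 > n)
        starts <- starts[starts + 2 <= n]
      if (!length(starts)) next
      codons <- substring(s, starts, starts + 2)
      is_stop <- codons %in% STOP_CODONS
      # runs of non-stop codons
      r <- rle(is_stop)
      idx_end <- cumsum(r$lengths)
      idx_start <- idx_end - r$lengths + 1
      for (j in seq_along(r$values)) {
        if (r$values[j]) next
        ncod <- r$lengths[j]
        if (3 * ncod < min_bp) next
        b <- starts[idx_start[j]] - 1          # 0-based
        e <- starts[idx_end[j]] + 2            # half-open
        pep <- as.character(Biostrings::translate(
          Biostrings::DNAString(substr(s, b + 1, e)), no.init.codon = TRUE))
        res[[length(res) + 1]] <- data.frame(
          begin = b, end = e, strand = strand, frame = f,
          nt_length = e - b, peptide = pep, stringsAsFactors = FALSE)
      }
    }
    res
  }
  out <- scan1(toupper(sequence), "+")
  if (both_strands) {
    rc <- revcomp(toupper(sequence))
    n <- nchar(sequence)
    rev_orfs <- scan1(rc, "-")
    rev_orfs <- lapply(rev_orfs, function(d) {
      b <- n - d$end; e <- n - d$begin
      d$begin <- b; d$end <- e
      d
    })
    out <- c(out, rev_orfs)
  }
  if (!length(out)) {
    return(data.frame(begin = numeric(), end = numeric(), strand = character(),
                      frame = integer(), nt_length = numeric(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Span of a peptide over a protein-domain consensus
#'
#' Local alignment (BLOSUM62, affine gaps) of a peptide against a domain
#' consensus; the span fraction is the number of consensus residues covered
#' by the alignment divided by the consensus length. Ties are broken by the
#' aligner deterministically (highest score, leftmost).
#'
#' @param peptide query peptide string.
#' @param domain_consensus domain consensus peptide string.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return list: `domain_covered` (consensus residues aligned),
#'   `consensus_length`, `span_fraction`, `score`.
#' @export
domain_span <- function(peptide, domain_consensus,
                        gap_opening = 10, gap_extension = 0.5) {
  stopifnot(nchar(peptide) > 0, nchar(domain_consensus) > 0)
  peptide <- gsub("\\*", "X", peptide)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(peptide), Biostrings::AAString(domain_consensus),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  sub_rng <- aln@subject@range
  covered <- IRanges::width(sub_rng)
  len <- nchar(domain_consensus)
  list(domain_covered = covered, consensus_length = len,
       span_fraction = covered / len, score = Biostrings::score(aln))
}

# Best span fraction of each domain over a set of ORFs; returns a matrix
# orf x domain of span fractions.
orf_domain_matrix <- function(orfs, domains) {
  m <- matrix(0, nrow = nrow(orfs), ncol = length(domains),
              dimnames = list(NULL, names(domains)))
  for (i in seq_len(nrow(orfs))) {
    for (d in names(domains)) {
      m[i, d] <- domain_span(orfs$peptide[i], domains[[d]])$span_fraction
    }
  }
  m
}

#' Full-length call for a LINE insertion
#'
#' TRUE iff the insertion carries an ORF of at least `line_min_orf_bp` and
#' its qualifying ORFs span at least `line_span_min` of both the
#' endonuclease and the reverse-transcriptase domain consensi. By default
#' the two domains may be satisfied by one ORF or by two ORFs of the same
#' insertion (`criteria$same_orf = TRUE` demands a single ORF).
#'
#' @param sequence insertion nucleotide sequence (strand-corrected: the
#'   annotated strand's forward sequence).
#' @param criteria [fulllength_criteria()].
#' @param domains named list with peptides `EN` and `RT`.
#' @return list: `full_length` (logical), `evidence` (per-ORF span table).
#' @export
call_fulllength_line <- function(sequence, criteria = fulllength_criteria(),
                                 domains) {
  if (is.null(domains$EN) || is.null(domains$RT))
    stop2("domains must provide EN and RT consensi")
  orfs <- find_orfs(sequence, min_bp = criteria$line_min_orf_bp)
  if (!nrow(orfs))
    return(list(full_length = FALSE,
                evidence = data.frame(orf = integer(), EN = numeric(), RT = numeric())))
  m <- orf_domain_matrix(orfs, domains[c("EN", "RT")])
  ok <- if (criteria$same_orf) {
    any(m[, "EN"] >= criteria$line_span_min & m[, "RT"] >= criteria$line_span_min)
  } else {
    max(m[, "EN"]) >= criteria$line_span_min &&
      max(m[, "RT"]) >= criteria$line_span_min
  }
  list(full_length = ok,
       evidence = data.frame(orf = seq_len(nrow(orfs)),
                             orf_bp = orfs$nt_length, EN = m[, "EN"], RT = m[, "RT"]))
}

#' Full-length call for a DNA-transposon insertion
#'
#' TRUE iff some ORF of at least `dna_min_orf_bp` spans at least
#' `dna_span_min` of the transposase domain consensus.
#'
#' @inheritParams call_fulllength_line
#' @param domains named list with peptide `transposase`.
#' @return list: `full_length`, `evidence`.
#' @export
call_fulllength_dna <- function(sequence, criteria = fulllength_criteria(),
                                domains) {
  if (is.null(domains$transposase)) stop2("domains must provide a transposase consensus")
  orfs <- find_orfs(sequence, min_bp = criteria$dna_min_orf_bp)
  if (!nrow(orfs))
    return(list(full_length = FALSE,
                evidence = data.frame(orf = integer(), transposase = numeric())))
  m <- orf_domain_matrix(orfs, domains["transposase"])
  list(full_length = any(m[, "transposase"] >= criteria$dna_span_min),
       evidence = data.frame(orf = seq_len(nrow(orfs)),
                             orf_bp = orfs$nt_length,
                             transposase = m[, "transposase"]))
}

#' Call full-length LINEs and DNA transposons over an annotation
#'
#' Applies the homology-based intactness tests to every LINE / DNA insertion
#' in a repeat annotation, extracting strand-corrected insertion sequences
#' from the genome.
#'
#' @param hits `repeat_hits` (e.g. from [parse_repeatmasker_out()]).
#' @param genome `genome_model` with sequences.
#' @param domains named list of domain consensus peptides
#'   (`EN`, `RT`, `transposase`).
#' @param criteria [fulllength_criteria()].
#' @return data.frame of calls: `chromosome`, `begin`, `end`, `strand`,
#'   `family`, `classification`, `category` (`fl_LINE`/`fl_DNA`).
#' @export
call_fulllength_tes <- function(hits, genome, domains,
                                criteria = fulllength_criteria()) {
  if (is.null(genome$sequences)) stop2("genome model carries no sequences")
  is_line <- grepl("^LINE", hits$classification)
  is_dna <- grepl("^DNA", hits$classification)
  keep <- which(is_line | is_dna)
  out <- list()
  for (i in keep) {
    s <- substr(genome$sequences[[hits$chromosome[i]]],
                hits$begin[i] + 1, hits$end[i])
    if (hits$strand[i] == "-") s <- revcomp(s)
    res <- if (is_line[i]) {
      call_fulllength_line(s, criteria, domains)
    } else {
      call_fulllength_dna(s, criteria, domains)
    }
    if (res$full_length) {
      out[[length(out) + 1]] <- data.frame(
        chromosome = hits$chromosome[i], begin = hits$begin[i],
        end = hits$end[i], strand = hits$strand[i], family = hits$family[i],
        classification = hits$classification[i],
        category = if (is_line[i]) "fl_LINE" else "fl_DNA",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(), begin = numeric(),
                      end = numeric(), strand = character(),
                      family = character(), classification = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Census of full-length TEs per chromosome class
#'
#' Pools counts per chromosome class (all autosomes as one class) and per
#' category (`fl_ERV`, `fl_LINE`, `fl_DNA`); LINE and DNA are additionally
#' reported jointly as `LINE+DNA`, matching how intact-TE tables are usually
#' printed.
#'
#' @param calls data.frame of full-length calls with columns `chromosome`
#'   and `category`, e.g. from [call_fulllength_tes()] and
#'   [score_and_filter_erv()] (rbind them).
#' @param genome `genome_model`.
#' @param profile free-text label of the criteria profile that produced the
#'   calls (recorded, so alternative detector profiles can be compared side
#'   by side).
#' @return object of class `fl_census`: `by_class` (class x category
#'   matrix), `by_class_total` (named vector over classes, all categories
#'   summed), `by_chromosome` (data.frame), `sex_system`, `profile`.
#' @export
fl_census <- function(calls, genome, profile = "default") {
  ch <- genome$chromosomes
  if (nrow(calls) && length(setdiff(calls$chromosome, ch$name)))
    stop2("calls reference unknown chromosomes")
  cats <- c("fl_ERV", "fl_LINE", "fl_DNA")
  classes <- unique(ch$te_class[ch$te_class != "unplaced"])
  m <- matrix(0L, nrow = length(classes), ncol = length(cats),
              dimnames = list(classes, cats))
  per_chr <- data.frame(chromosome = ch$name, te_class = ch$te_class,
                        fl_ERV = 0L, fl_LINE = 0L, fl_DNA = 0L,
                        stringsAsFactors = FALSE)
  if (nrow(calls)) {
    stopifnot(all(calls$category %in% cats))
    cls <- ch$te_class[match(calls$chromosome, ch$name)]
    tab <- table(factor(cls, levels = classes),
                 factor(calls$category, levels = cats))
    m <- m + unclass(tab)
    tab_chr <- unclass(table(factor(calls$chromosome, levels = ch$name),
                             factor(calls$category, levels = cats)))
    for (cat in cats) per_chr[[cat]] <- as.integer(tab_chr[per_chr$chromosome, cat])
  }
  structure(list(by_class = m,
                 by_class_total = rowSums(m),
                 line_dna = rowSums(m[, c("fl_LINE", "fl_DNA"), drop = FALSE]),
                 by_chromosome = per_chr,
                 sex_system = genome$sex_system,
                 profile = profile),
            class = "fl_census")
}

#' @export
print.fl_census <- function(x, ...) {
  cat("fl_census (profile: ", x$profile, ", ", x$sex_system, " system)\n", sep = "")
  m <- cbind(x$by_class, `LINE+DNA` = x$line_dna, total = x$by_class_total)
  print(m)
  invisible(x)
}
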