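# Self-contained deterministic read mapper for consensus libraries: exact
# k-mer seeding, ungapped extension, best unique hit only. A stand-in for an
# external short-read mapper in tests and simulations, not a general aligner.

#' Read a FASTQ file
#'
#' @param path FASTQ file (uncompressed text).
#' @return named character vector of reads (names = read ids); qualities are
#'   attached as the `"qual"` attribute.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop2("truncated FASTQ: ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), by = 4)]))
  reads <- toupper(lines[seq(2, length(lines), by = 4)])
  qual <- lines[seq(4, length(lines), by = 4)]
  structure(setNames(reads, ids), qual = qual)
}

#' Write reads to FASTQ
#'
#' @param reads named character vector.
#' @param path output file.
#' @param qual quality strings (default: maximal quality `I`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual = NULL) {
  if (is.null(qual)) qual <- vapply(nchar(reads), function(n)
    strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

# k-mer index of a consensus library: environment kmer -> matrix(fam_idx, pos)
build_kmer_index <- function(library, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  fams <- names(library$sequences)
  for (fi in seq_along(fams)) {
    s <- library$sequences[[fi]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kms <- substring(s, starts, starts + k - 1L)
    for (i in seq_along(kms)) {
      km <- kms[i]
      if (grepl("N", km, fixed = TRUE)) next
      hit <- c(fi, starts[i])
      if (is.null(env[[km]])) env[[km]] <- list(hit)
      else env[[km]] <- c(env[[km]], list(hit))
    }
  }
  env
}

ungapped_score <- function(read_chars, cons_chars) sum(read_chars == cons_chars)

#' Map reads to a consensus library (exact seed, ungapped extension)
#'
#' For each read (and its reverse complement) a few evenly spaced k-mer
#' seeds are looked up in a library k-mer index; each seed hit proposes an
#' ungapped placement, placements are scored by matching bases over the full
#' read, and only a single best placement is reported. Reads whose best
#' score is tied between different placements are dropped as ambiguous;
#' reads with no seed hit are unmapped. Deterministic.
#'
#' @param reads named character vector (e.g. from [read_fastq()]).
#' @param library `consensus_library`.
#' @param k seed length (read length must be >= k).
#' @param min_frac minimum fraction of matching bases to accept a placement.
#' @return SAM-records data.frame as from [read_sam()] (mapped reads only;
#'   full-length `M` CIGAR, MAPQ 60).
#' @export
naive_map <- function(reads, library, k = 31L, min_frac = 0.9) {
  stopifnot(length(reads) > 0)
  if (min(nchar(reads)) < k) stop2("read length must be >= seed length k")
  idx <- build_kmer_index(library, k)
  fams <- names(library$sequences)
  cons_chars <- lapply(library$sequences, function(s) strsplit(s, "")[[1]])
  out <- vector("list", length(reads))
  n_out <- 0L
  for (ri in seq_along(reads)) {
    rd <- reads[[ri]]
    L <- nchar(rd)
    best <- NULL; best_score <- -1L; tie <- FALSE
    for (ori in c("+", "-")) {
      s <- if (ori == "+") rd else revcomp1(rd)
      sc <- strsplit(s, "")[[1]]
      offs <- unique(pmax(1L, pmin(L - k + 1L, c(1L, (L - k) %/% 2L + 1L, L - k + 1L))))
      placements <- list()
      for (o in offs) {
        km <- substr(s, o, o + k - 1L)
        hits <- idx[[km]]
        if (is.null(hits)) next
        for (h in hits) {
          placements[[paste(h[1], h[2] - o + 1L, ori)]] <- c(h[1], h[2] - o + 1L)
        }
      }
      for (nm in names(placements)) {
        p <- placements[[nm]]
        fi <- p[1]; start <- p[2]
        cc <- cons_chars[[fi]]
        if (start < 1L || start + L - 1L > length(cc)) next
        score <- ungapped_score(sc, cc[start:(start + L - 1L)])
        if (score > best_score) {
          best_score <- score; tie <- FALSE
          best <- list(fi = fi, start = start, ori = ori, seq = s)
        } else if (score == best_score && !is.null(best) &&
                   !(best$fi == fi && best$start == start && best$ori == ori)) {
          tie <- TRUE
        }
      }
    }
    if (is.null(best) || tie || best_score < min_frac * L) next
    n_out <- n_out + 1L
    out[[n_out]] <- data.frame(
      qname = names(reads)[ri] %||% paste0("r", ri),
      flag = if (best$ori == "-") 16L else 0L,
      rname = fams[best$fi], pos = best$start, mapq = 60L,
      cigar = paste0(L, "M"), seq = best$seq, qual = strrep("I", L),
      stringsAsFactors = FALSE)
  }
  if (!n_out) {
    return(data.frame(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      seq = character(), qual = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(n_out)])
}

#' Write SAM records to a file
#'
#' @param sam data.frame as returned by [naive_map()] / [read_sam()].
#' @param library `consensus_library` for the header.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, library, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(library$sequences),
                   nchar(library$sequences)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                  sam$cigar, sam$seq, sam$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}
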