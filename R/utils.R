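#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq pnorm rbinom runif setNames aggregate
#' @importFrom utils read.delim write.table combn head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Package-wide verbosity: 0 = silent, 1 = info (default), 2 = debug.
slc_verbosity <- function() getOption("slcTE.verbosity", 1L)

slc_log <- function(..., level = 1L) {
  if (slc_verbosity() >= level) message(...)
  invisible(NULL)
}

stop2 <- function(...) stop(..., call. = FALSE)

# Deterministic substreams: one root seed, fixed offsets per stream, so adding
# a new stream never perturbs draws in existing ones. Offsets stay < 2^31.
with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 1000003L) * 2011L + as.integer(offset))
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# light-weight scalar reverse complement (hot paths; avoids XString overhead)
revcomp1 <- function(s) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
        collapse = "")
}

random_dna <- function(n, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}
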