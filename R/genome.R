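#' Chromosome-class vocabulary
#'
#' Chromosomes are partitioned into autosomes, the sex chromosomes of the
#' system in use (Z/W or X/Y) and unplaced sequence. Unplaced records are
#' tagged and excluded from index computations by default, mirroring analyses
#' restricted to assembled chromosome models.
#' @keywords internal
TE_CLASSES <- c("autosome", "Z", "W", "X", "Y", "unplaced")

#' Construct a genome model
#'
#' A genome model holds the chromosome partition used throughout the toolkit:
#' per-chromosome name, chromosome class, length, and (optionally) sequence.
#'
#' @param chromosomes data.frame with columns `name`, `te_class`
#'   (one of `r paste(TE_CLASSES, collapse = ", ")`) and `length`
#'   (bp, including assembly gaps unless you supply `length_no_n`).
#'   An optional `length_no_n` column carries N-excluded lengths.
#' @param sex_system one of `"ZW"`, `"XY"`, `"XO"`.
#' @param sequences optional named character vector of chromosome sequences;
#'   names must match `chromosomes$name` and lengths must agree.
#' @param male_assembly logical; a ZW (XY) model is allowed to lack the W (Y)
#'   when the assembly is from the homogametic sex.
#' @return An object of class `genome_model`: a list with elements
#'   `chromosomes` (validated data.frame), `sex_system`, `sequences`.
#' @examples
#' gm <- genome_model(
#'   data.frame(name = c("chr1", "chrZ", "chrW"),
#'              te_class = c("autosome", "Z", "W"),
#'              length = c(10000, 8000, 3000)),
#'   sex_system = "ZW")
#' gm
#' @export
genome_model <- function(chromosomes, sex_system = c("ZW", "XY", "XO"),
                         sequences = NULL, male_assembly = FALSE) {
  sex_system <- match.arg(sex_system)
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "te_class", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$te_class <- as.character(chromosomes$te_class)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop2("duplicate chromosome names: ",
          paste(unique(chromosomes$name[duplicated(chromosomes$name)]), collapse = ", "))
  bad <- setdiff(chromosomes$te_class, TE_CLASSES)
  if (length(bad)) stop2("unknown te_class value(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(chromosomes$length) | chromosomes$length <= 0))
    stop2("chromosome lengths must be positive")
  for (cl in c("Z", "W", "X", "Y")) {
    if (sum(chromosomes$te_class == cl) > 1L)
      stop2("at most one chromosome of class ", cl, " is allowed")
  }
  present <- unique(chromosomes$te_class)
  allowed <- switch(sex_system,
                    ZW = c("autosome", "Z", "W", "unplaced"),
                    XY = c("autosome", "X", "Y", "unplaced"),
                    XO = c("autosome", "X", "unplaced"))
  if (length(setdiff(present, allowed)))
    stop2("chromosome classes ", paste(setdiff(present, allowed), collapse = ", "),
          " are inconsistent with sex system ", sex_system)
  slc <- switch(sex_system, ZW = "W", XY = "Y", XO = NA_character_)
  if (!is.na(slc) && !(slc %in% present) && !male_assembly)
    stop2("sex system ", sex_system, " but no ", slc,
          " chromosome; pass male_assembly = TRUE for a homogametic assembly")
  if (!is.null(sequences)) {
    sequences <- setNames(toupper(as.character(sequences)), names(sequences))
    if (is.null(names(sequences)) || !all(chromosomes$name %in% names(sequences)))
      stop2("sequences must be named and cover every chromosome")
    sequences <- sequences[chromosomes$name]
    lens <- nchar(sequences)
    off <- which(lens != chromosomes$length)
    if (length(off))
      stop2("sequence length disagrees with declared length for: ",
            paste(chromosomes$name[off], collapse = ", "))
  }
  structure(list(chromosomes = chromosomes, sex_system = sex_system,
                 sequences = sequences),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  tab <- table(factor(x$chromosomes$te_class, levels = TE_CLASSES))
  cat("genome_model (", x$sex_system, " system): ",
      nrow(x$chromosomes), " chromosomes, ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp\n", sep = "")
  for (cl in names(tab)[tab > 0]) {
    sel <- x$chromosomes$te_class == cl
    cat(sprintf("  %-9s n=%d  %s bp\n", cl, sum(sel),
                format(sum(x$chromosomes$length[sel]), big.mark = ",")))
  }
  invisible(x)
}

#' Default chromosome-naming rules
#'
#' Patterns (regular expressions, case-insensitive, first match wins) mapping
#' chromosome names to classes. Covers the common `chrW` / `W` /
#' `chromosome_W` naming styles.
#' @return named character vector: pattern -> te_class.
#' @export
default_chromosome_rules <- function() {
  c("^(chr)?_?W($|[^a-z0-9])|^(chr)?W$|chromosome_?W" = "W",
    "^(chr)?Z$|chromosome_?Z" = "Z",
    "^(chr)?Y$|chromosome_?Y" = "Y",
    "^(chr)?X$|chromosome_?X" = "X",
    "^(chr)?[0-9]+[A-Za-z]?$|^chromosome_?[0-9]+$" = "autosome")
}

#' Assign chromosome classes from name patterns
#'
#' @param names character vector of chromosome names.
#' @param rules named character vector mapping regular-expression patterns to
#'   `te_class` values; earlier rules win. Unmatched names become `unplaced`.
#' @return character vector of classes, same length/order as `names`.
#' @examples
#' classify_chromosomes(c("chr1", "chrZ", "chrW", "scaffold_12"))
#' @export
classify_chromosomes <- function(names, rules = default_chromosome_rules()) {
  stopifnot(is.character(names))
  if (is.null(names(rules)) || any(names(rules) == ""))
    stop2("rules must be a named vector: pattern -> class")
  bad <- setdiff(unname(rules), TE_CLASSES)
  if (length(bad)) stop2("rules map to unknown classes: ", paste(bad, collapse = ", "))
  out <- rep("unplaced", length(names))
  decided <- rep(FALSE, length(names))
  for (i in seq_along(rules)) {
    hit <- grepl(names(rules)[i], names, ignore.case = TRUE, perl = TRUE)
    take <- hit & !decided
    out[take] <- rules[[i]]
    decided <- decided | hit
  }
  tab <- table(factor(out, levels = TE_CLASSES))
  slc_log("classify_chromosomes: ",
          paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]), collapse = " "),
          level = 2L)
  out
}

# Chromosomes included in density/index computations (assembled classes only).
included_chromosomes <- function(genome, include_unplaced = FALSE) {
  ch <- genome$chromosomes
  if (!include_unplaced) ch <- ch[ch$te_class != "unplaced", , drop = FALSE]
  ch
}

# Effective per-chromosome length: assembled length, or N-excluded when asked
# for and available.
chromosome_lengths <- function(genome, exclude_n = FALSE, include_unplaced = FALSE) {
  ch <- included_chromosomes(genome, include_unplaced)
  len <- ch$length
  if (exclude_n) {
    if (!is.null(ch$length_no_n)) {
      len <- ch$length_no_n
    } else if (!is.null(genome$sequences)) {
      len <- vapply(genome$sequences[ch$name], function(s) {
        nchar(s) - lengths(regmatches(s, gregexpr("N", s, fixed = TRUE)))
      }, numeric(1))
    } else {
      stop2("exclude_n = TRUE needs a length_no_n column or sequences")
    }
  }
  setNames(len, ch$name)
}
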