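# Per-chromosome TE expression summaries: TPM normalisation, male/female
# per-class comparisons, and a rank-sum test (exact enumeration for small
# cohorts, tie-corrected normal approximation otherwise).

#' TPM-normalise a count matrix
#'
#' TPM_i = (count_i / length_i) / sum_j(count_j / length_j) * 1e6 per
#' sample; zero-count copies get 0 and every sample column sums to 1e6
#' (when it has any counts at all).
#'
#' @param counts numeric matrix (copies x samples) or vector.
#' @param lengths per-copy lengths in bp (> 0).
#' @return matrix (or vector) of TPM values.
#' @examples
#' tpm_normalize(c(10, 10), c(100, 100))  # 5e5, 5e5
#' @export
tpm_normalize <- function(counts, lengths) {
  if (any(lengths <= 0)) stop2("lengths must be > 0")
  vec <- is.null(dim(counts))
  m <- as.matrix(counts)
  if (nrow(m) != length(lengths)) stop2("counts/lengths dimension mismatch")
  rate <- m / lengths
  tot <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  if (vec) tpm[, 1] else tpm
}

#' Read a per-copy count table
#'
#' featureCounts-style TSV: columns `copy`, `chromosome`, `length`, then one
#' column per sample. Copies with missing length are rejected.
#'
#' @param path TSV file with header.
#' @return list: `copies` data.frame (`copy`, `chromosome`, `length`),
#'   `counts` matrix (copies x samples).
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("copy", "chromosome", "length")
  if (!all(need %in% names(df)))
    stop2("count table needs columns: ", paste(need, collapse = ", "))
  if (anyNA(df$length)) stop2("copies with missing length")
  counts <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  rownames(counts) <- df$copy
  list(copies = df[, need], counts = counts)
}

#' Replicate-averaged TPM per chromosome class
#'
#' TPM-normalises per sample, removes male-sample rows on the W chromosome
#' BEFORE normalisation (these represent spurious low counts: males carry no
#' W), then averages replicates within each sex and groups per-copy values
#' by chromosome class.
#'
#' @param copies data.frame: `copy`, `chromosome`, `length`.
#' @param counts matrix copies x samples.
#' @param genome `genome_model` mapping chromosomes to classes.
#' @param sex named character vector sample -> `male`/`female`.
#' @return data.frame: `copy`, `chromosome`, `te_class`, `sex`, `tpm`
#'   (replicate-averaged per-copy TPM; one row per copy x sex, W rows absent
#'   for males).
#' @export
chromosome_class_expression <- function(copies, counts, genome, sex) {
  stopifnot(all(colnames(counts) %in% names(sex)))
  cls <- genome$chromosomes$te_class[match(copies$chromosome,
                                           genome$chromosomes$name)]
  if (anyNA(cls)) stop2("count table references unknown chromosomes")
  out <- list()
  for (sx in unique(unname(sex[colnames(counts)]))) {
    cols <- colnames(counts)[sex[colnames(counts)] == sx]
    keep <- if (sx == "male") !(cls %in% c("W", "Y")) else rep(TRUE, nrow(copies))
    tpm <- tpm_normalize(counts[keep, cols, drop = FALSE], copies$length[keep])
    out[[sx]] <- data.frame(copy = copies$copy[keep],
                            chromosome = copies$chromosome[keep],
                            te_class = cls[keep],
                            sex = sx,
                            tpm = rowMeans(tpm),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# exact two-sided rank-sum p by complete enumeration of group assignments
ranksum_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- combn(n1 + n2, n1)
  w_all <- colSums(matrix(r[combs], nrow = n1))
  mu <- n1 * (n1 + n2 + 1) / 2
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  list(statistic = w_obs - n1 * (n1 + 1) / 2, p_value = p)  # U statistic
}

# tie-corrected normal approximation (no continuity correction)
ranksum_normal <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(statistic = w - n1 * (n1 + 1) / 2, p_value = 1))
  z <- (w - mu) / sqrt(sig2)
  list(statistic = w - n1 * (n1 + 1) / 2, p_value = min(1, 2 * pnorm(-abs(z))))
}

#' Two-sided rank-sum comparison of two groups
#'
#' Wilcoxon/Mann-Whitney rank-sum test: exact enumeration of all group
#' assignments when the combined size is at most `exact_max` (ties handled
#' by permutation), tie-corrected normal approximation otherwise.
#'
#' @param group1,group2 numeric vectors (both non-empty).
#' @param exact_max largest combined size for exact enumeration.
#' @return list: `statistic` (Mann-Whitney U for group1), `p_value`,
#'   `method`.
#' @export
ranksum_compare <- function(group1, group2, exact_max = 20L) {
  if (!length(group1) || !length(group2)) stop2("both groups must be non-empty")
  if (length(group1) + length(group2) <= exact_max) {
    res <- ranksum_exact(group1, group2)
    res$method <- "exact enumeration"
  } else {
    res <- ranksum_normal(group1, group2)
    res$method <- "normal approximation (tie-corrected)"
  }
  res
}

#' Male/female expression comparison per chromosome class
#'
#' For each chromosome class, compares female and male per-copy TPM
#' distributions with [ranksum_compare()] and reports the log2 ratio of
#' mean TPM. The log2 ratio is a plain descriptive contrast, not a
#' dispersion-modelled differential-expression estimate.
#'
#' @param expr result of [chromosome_class_expression()].
#' @return data.frame: `te_class`, `n_female`, `n_male`, `mean_tpm_female`,
#'   `mean_tpm_male`, `log2_ratio`, `statistic`, `p_value`.
#' @export
compare_expression_by_class <- function(expr) {
  out <- list()
  for (cl in unique(expr$te_class)) {
    f <- expr$tpm[expr$te_class == cl & expr$sex == "female"]
    m <- expr$tpm[expr$te_class == cl & expr$sex == "male"]
    if (!length(f) || !length(m)) {
      out[[cl]] <- data.frame(te_class = cl, n_female = length(f),
                              n_male = length(m),
                              mean_tpm_female = mean(f), mean_tpm_male = mean(m),
                              log2_ratio = NA_real_, statistic = NA_real_,
                              p_value = NA_real_)
      next
    }
    rs <- ranksum_compare(f, m)
    out[[cl]] <- data.frame(te_class = cl, n_female = length(f),
                            n_male = length(m),
                            mean_tpm_female = mean(f), mean_tpm_male = mean(m),
                            log2_ratio = log2(mean(f) / mean(m)),
                            statistic = rs$statistic, p_value = rs$p_value)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
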