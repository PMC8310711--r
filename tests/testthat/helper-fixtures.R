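# Shared fixtures, built in code and cached across test files so the heavy
# simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small three-chromosome genome with planted elements (fast: ~15 s detect)
small_sim <- function() cached("small_sim", {
  plant_and_mutate(simulation_config(
    seed = 7L,
    chromosomes = data.frame(name = c("chrA1", "chrZ", "chrW"),
                             te_class = c("autosome", "Z", "W"),
                             length = c(150000, 120000, 150000)),
    fl_erv_per_class = c(autosome = 2L, Z = 1L, W = 3L),
    n_solo_ltr = 4L, n_truncated = 4L))
})

small_sim_erv_calls <- function() cached("small_sim_erv", {
  sim <- small_sim()
  detect_erv_genome(sim$genome, sim$domains)
})

# full study-conditions genome (~2 Mb, 32 fl-ERVs, 20 solo-LTRs,
# 20 truncated fragments, error-free)
study_sim <- function() cached("study_sim", {
  plant_and_mutate(simulation_config(seed = 11L))
})

study_sim_erv_calls <- function() cached("study_sim_erv", {
  sim <- study_sim()
  detect_erv_genome(sim$genome, sim$domains)
})

# 3F + 3M genomic cohort at 30x with planted W-restricted and autosomal SNVs
study_cohort <- function() cached("study_cohort", {
  simulate_snv_cohort(snv_cohort_config(seed = 5L))
})

study_cohort_piles <- function() cached("study_cohort_piles", {
  co <- study_cohort()
  lapply(co$reads, function(r) build_pileup(naive_map(r, co$library), co$library))
})

# matched cohort with autosomal variants only (specificity checks)
auto_only_cohort <- function() cached("auto_only_cohort", {
  simulate_snv_cohort(snv_cohort_config(seed = 6L, n_w_variants = 0L,
                                        n_rna_females = 0L, n_rna_males = 0L))
})

auto_only_piles <- function() cached("auto_only_piles", {
  co <- auto_only_cohort()
  lapply(co$reads, function(r) build_pileup(naive_map(r, co$library), co$library))
})

variant_key <- function(d) paste(d$family, d$position, d$alt)

# element recovered iff a call matches chromosome and both boundaries
# within `tol` bp (paired-LTR boundaries are determined only up to small
# shifts when flanking bases coincide with the LTR edges)
recovered <- function(calls, truth, tol = 3) {
  vapply(seq_len(nrow(truth)), function(i) any(
    calls$chromosome == truth$chromosome[i] &
      abs(calls$begin - truth$begin[i]) <= tol &
      abs(calls$end - truth$end[i]) <= tol), logical(1))
}

# brute-force per-column transition/transversion counter, kept deliberately
# independent of pair_tallies()
brute_pq <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  keep <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  va <- va[keep]; vb <- vb[keep]
  ts <- 0L; tv <- 0L
  for (i in seq_along(va)) {
    if (va[i] == vb[i]) next
    pair <- paste(sort(c(va[i], vb[i])), collapse = "")
    if (pair %in% c("AG", "CT")) ts <- ts + 1L else tv <- tv + 1L
  }
  list(P = ts / length(va), Q = tv / length(va), n = length(va))
}

random_pair <- function(len = 300, sub_rate = 0.15) {
  a <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  v <- strsplit(a, "")[[1]]
  mut <- runif(len) < sub_rate
  v[mut] <- vapply(v[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  list(a = a, b = paste(v, collapse = ""))
}
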