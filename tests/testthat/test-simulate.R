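test_that("library generation is deterministic and self-consistent", {
  cfg <- simulation_config(seed = 21L)
  a <- make_library(cfg)
  b <- make_library(cfg)
  expect_identical(a$library$sequences, b$library$sequences)
  expect_identical(a$domains, b$domains)
  c2 <- make_library(simulation_config(seed = 22L))
  expect_false(identical(a$library$sequences, c2$library$sequences))
  # every family passes its own intactness test when planted intact
  expect_true(call_fulllength_line(a$library$sequences[["CR1_sim"]],
                                   domains = a$domains)$full_length)
  expect_true(call_fulllength_dna(a$library$sequences[["hAT_sim"]],
                                  domains = a$domains)$full_length)
  for (fam in grep("^ERV", names(a$parts), value = TRUE)) {
    p <- a$parts[[fam]]
    g <- paste0(slcTE:::random_dna(2000), "ACTGG", p$ltr, p$internal, p$ltr,
                "ACTGG", slcTE:::random_dna(2000))
    kept <- score_and_filter_erv(detect_ltr_elements(g), g, a$domains)
    expect_equal(nrow(kept), 1L)
  }
})

test_that("planted genomes are byte-deterministic under a fixed seed", {
  cfg <- simulation_config(
    seed = 33L,
    chromosomes = data.frame(name = c("chrA1", "chrW"),
                             te_class = c("autosome", "W"),
                             length = c(60000, 60000)),
    fl_erv_per_class = c(autosome = 1L, Z = 0L, W = 1L),
    n_solo_ltr = 1L, n_truncated = 1L)
  s1 <- plant_and_mutate(cfg)
  s2 <- plant_and_mutate(cfg)
  expect_identical(s1$genome$sequences, s2$genome$sequences)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$truth$elements, s2$truth$elements)
})

test_that("truth manifest cross-validates against the emitted sequences", {
  sim <- small_sim()
  tr <- sim$truth$elements
  for (i in seq_len(nrow(tr))) {
    span <- substr(sim$genome$sequences[[tr$chromosome[i]]],
                   tr$begin[i] + 1, tr$end[i])
    expect_equal(nchar(span), tr$end[i] - tr$begin[i])
    if (tr$category[i] == "fl_ERV" && tr$target_k[i] == 0) {
      p <- sim$parts[[tr$family[i]]]
      expect_identical(span, paste0(p$ltr, p$internal, p$ltr))
    }
  }
  # .out rows coincide with the truth intervals
  expect_equal(sim$hits$begin, tr$begin)
  expect_equal(sim$hits$end, tr$end)
  # male genome lacks the W, shares the rest
  expect_identical(sim$male_sequences[["chrA1"]],
                   sim$genome$sequences[["chrA1"]])
  expect_false("chrW" %in% names(sim$male_sequences))
})

test_that("zero-density plans give TE-free output and overfull plans fail", {
  cfg0 <- simulation_config(
    seed = 1L,
    chromosomes = data.frame(name = "chrA1", te_class = "autosome",
                             length = 30000),
    fl_erv_per_class = c(autosome = 0L, Z = 0L, W = 0L),
    n_solo_ltr = 0L, n_truncated = 0L)
  s0 <- plant_and_mutate(cfg0)
  expect_equal(nrow(s0$hits), 0L)
  expect_equal(nchar(s0$genome$sequences[["chrA1"]]), 30000)
  cfg_full <- simulation_config(
    seed = 1L,
    chromosomes = data.frame(name = "chrA1", te_class = "autosome",
                             length = 30000),
    fl_erv_per_class = c(autosome = 3L, Z = 0L, W = 0L),
    n_solo_ltr = 0L, n_truncated = 0L)
  expect_error(plant_and_mutate(cfg_full), "overfull")
})

test_that("mutated copies realign to the target divergence on 5 kb elements", {
  set.seed(61)
  s <- slcTE:::random_dna(5000)
  ks <- replicate(10, {
    m <- slcTE:::mutate_k2p(s, 0.10, kappa = 2)
    k2p_distance(m$seq, s)$K
  })
  expect_true(all(ks >= 0.08 & ks <= 0.12))
  expect_equal(mean(ks), 0.10, tolerance = 0.05)
  # kappa shifts the transition share in the expected direction
  m_hi <- slcTE:::mutate_k2p(s, 0.10, kappa = 8)
  m_lo <- slcTE:::mutate_k2p(s, 0.10, kappa = 0.5)
  expect_gt(m_hi$P / max(m_hi$Q, 1e-9), m_lo$P / max(m_lo$Q, 1e-9))
})

test_that("simulated reads are exact substrings at zero error and hit target depth", {
  hap <- setNames(slcTE:::random_dna(20000), "h1")
  reads <- simulate_reads(hap, coverage = 30, read_len = 100, seed = 9,
                          both_strands = FALSE)
  expect_true(all(vapply(reads[1:50], function(r)
    grepl(r, hap, fixed = TRUE), TRUE)))
  depth <- length(reads) * 100 / 20000
  expect_lt(abs(depth - 30) / 30, 0.1)
  expect_error(simulate_reads(setNames("ACGT", "x"), read_len = 100), "length")
})

test_that("cohort simulation plants W variants only in female reads", {
  co <- study_cohort()
  piles <- study_cohort_piles()
  tw <- co$truth[co$truth$carrier == "W", ]
  for (i in seq_len(min(5, nrow(tw)))) {
    f_col <- piles$F1[[tw$family[i]]][, tw$position[i] + 1L]
    m_col <- piles$M1[[tw$family[i]]][, tw$position[i] + 1L]
    expect_gt(f_col[tw$alt[i]] / sum(f_col), 0.3)   # ~0.5: half the copies are W
    expect_equal(unname(m_col[tw$alt[i]]), 0L)
    expect_gte(sum(m_col), 5)                       # males covered, reference only
  }
  # byte-determinism of the cohort
  co2 <- simulate_snv_cohort(snv_cohort_config(seed = 5L))
  expect_identical(co$reads, co2$reads)
  expect_identical(co$truth, co2$truth)
})

test_that("simulation bundles round-trip through the on-disk formats", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  fa <- read_fasta(file.path(dir, "female_genome.fa"))
  expect_identical(unname(fa["chrW"]), unname(sim$genome$sequences[["chrW"]]))
  hits <- parse_repeatmasker_out(file.path(dir, "annotation.out"))
  expect_equal(hits$begin, sim$hits$begin)
  expect_equal(hits$end, sim$hits$end)
  lib <- read_consensus_library(file.path(dir, "library.fa"))
  expect_identical(lib$sequences, sim$library$sequences)
  expect_identical(unname(lib$classification), unname(sim$library$classification))
})
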