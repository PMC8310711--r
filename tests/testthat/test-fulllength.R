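domains_fixture <- function() cached("domains_fixture", make_library(
  simulation_config(seed = 21L))$domains)

test_that("find_orfs reports maximal stop-to-stop stretches without start codons", {
  # 30 A's: stop-free in every frame
  orfs <- find_orfs(strrep("A", 30), min_bp = 9)
  expect_equal(nrow(orfs), 3L)
  expect_true(all(orfs$nt_length %% 3 == 0))
  # stops dense in every frame leave nothing above 600 bp
  dense <- strrep("TTAA", 300)
  expect_equal(nrow(find_orfs(dense, min_bp = 600)), 0L)
})

test_that("a planted stop-free insert is recovered at exact coordinates", {
  set.seed(4)
  pep <- paste(sample(c("M", "K", "L", "G", "S", "T"), 400, replace = TRUE),
               collapse = "")
  insert <- slcTE:::peptide_to_nt(pep)          # 1200 bp stop-free
  left <- paste(rep("TAATAATAA", 40), collapse = "")
  right <- paste(rep("TAGTAGTAG", 40), collapse = "")
  seqn <- paste0(left, insert, right)
  orfs <- find_orfs(seqn, min_bp = 1200)
  in_frame <- orfs[orfs$frame == (nchar(left)) %% 3, ]
  expect_equal(nrow(in_frame), 1L)
  expect_equal(in_frame$begin, nchar(left))
  expect_equal(in_frame$end, nchar(left) + 1200)
})

test_that("domain_span measures consensus coverage under local alignment", {
  dom <- domains_fixture()$RT
  expect_equal(domain_span(dom, dom)$span_fraction, 1.0)
  half <- substr(dom, 1, nchar(dom) %/% 2)
  expect_equal(domain_span(half, dom)$span_fraction, 0.5, tolerance = 0.05)
  # 5%-mutated full-length copy still spans >= 0.9
  set.seed(8)
  v <- strsplit(dom, "")[[1]]
  mut <- sample(length(v), round(0.05 * length(v)))
  v[mut] <- sample(slcTE:::AA20, length(mut), replace = TRUE)
  expect_gte(domain_span(paste(v, collapse = ""), dom)$span_fraction, 0.9)
})

test_that("LINE calls demand both EN and RT spans on qualifying ORFs", {
  lib <- make_library(simulation_config(seed = 21L))
  doms <- lib$domains
  intact <- lib$library$sequences[["CR1_sim"]]
  expect_true(call_fulllength_line(intact, domains = doms)$full_length)
  # 5'-truncated copy missing the endonuclease
  trunc <- substr(intact, nchar(intact) - 900, nchar(intact))
  expect_false(call_fulllength_line(trunc, domains = doms)$full_length)
  # intact ORF but an RT consensus it only covers to 80% fails the 0.9 gate
  doms80 <- doms
  doms80$RT <- paste0(doms$RT, paste(rev(strsplit(substr(doms$RT, 1, 62), "")[[1]]),
                                     collapse = ""))
  res <- call_fulllength_line(intact, domains = doms80)
  expect_false(res$full_length)
  expect_lt(max(res$evidence$RT), 0.9)
  expect_error(call_fulllength_line(intact, domains = list(EN = doms$EN)),
               "RT")
})

test_that("DNA-transposon calls gate on 1 kb ORF length and transposase span", {
  lib <- make_library(simulation_config(seed = 21L))
  doms <- lib$domains
  intact <- lib$library$sequences[["hAT_sim"]]
  expect_true(call_fulllength_dna(intact, domains = doms)$full_length)
  # 900 bp ORF with full span fails the length gate
  crit_900 <- fulllength_criteria()
  pep300 <- substr(doms$transposase, 1, 300)    # 900 nt ORF
  seq900 <- paste0("TAATAA", slcTE:::peptide_to_nt(pep300), "TAATAA")
  expect_false(call_fulllength_dna(seq900, crit_900, doms)$full_length)
  # a 1.2 kb ORF covering 95% of the consensus passes both gates
  pep95 <- substr(doms$transposase, 1, ceiling(0.95 * nchar(doms$transposase)))
  seq95 <- paste0("TAATAA", slcTE:::peptide_to_nt(pep95), "TAATAA")
  expect_true(call_fulllength_dna(seq95, domains = doms)$full_length)
})

test_that("annotation-wide calling recovers planted LINE/DNA and rejects truncations", {
  cfg <- simulation_config(
    seed = 13L,
    chromosomes = data.frame(name = c("chrA1", "chrW"),
                             te_class = c("autosome", "W"),
                             length = c(120000, 120000)),
    fl_erv_per_class = c(autosome = 0L, Z = 0L, W = 0L),
    fl_line_per_class = c(autosome = 2L, Z = 0L, W = 1L),
    fl_dna_per_class = c(autosome = 1L, Z = 0L, W = 1L),
    n_solo_ltr = 0L, n_truncated = 0L, n_truncated_line = 3L)
  sim <- plant_and_mutate(cfg)
  calls <- call_fulllength_tes(sim$hits, sim$genome, sim$domains)
  tr <- sim$truth$elements
  expect_equal(sum(calls$category == "fl_LINE"), sum(tr$category == "fl_LINE"))
  expect_equal(sum(calls$category == "fl_DNA"), sum(tr$category == "fl_DNA"))
  # no truncated LINE sneaks in
  trunc <- tr[tr$category == "trunc_LINE", ]
  expect_false(any(paste(calls$chromosome, calls$begin) %in%
                     paste(trunc$chromosome, trunc$begin)))
})

test_that("census pools per class, keeps per-chromosome detail and conserves totals", {
  gm <- genome_model(data.frame(name = c("chr1", "chr2", "chrZ", "chrW"),
                                te_class = c("autosome", "autosome", "Z", "W"),
                                length = rep(1000, 4)), "ZW")
  empty <- fl_census(data.frame(chromosome = character(), category = character()),
                     gm)
  expect_true(all(empty$by_class == 0))
  calls <- data.frame(
    chromosome = c(rep("chr1", 3), rep("chr2", 2), "chrZ", rep("chrW", 4)),
    category = c("fl_ERV", "fl_ERV", "fl_LINE", "fl_ERV", "fl_DNA",
                 "fl_ERV", rep("fl_ERV", 3), "fl_LINE"))
  cen <- fl_census(calls, gm)
  expect_equal(unname(cen$by_class["autosome", "fl_ERV"]), 3L)
  expect_equal(unname(cen$by_class["W", "fl_ERV"]), 3L)
  expect_equal(unname(cen$line_dna["autosome"]), 2L)
  # class totals equal sums over member chromosomes
  agg <- aggregate(cbind(fl_ERV, fl_LINE, fl_DNA) ~ te_class,
                   data = cen$by_chromosome, FUN = sum)
  for (cl in agg$te_class) {
    expect_equal(unlist(agg[agg$te_class == cl, -1], use.names = FALSE),
                 unname(cen$by_class[cl, ]))
  }
  expect_error(fl_census(data.frame(chromosome = "nope", category = "fl_ERV"), gm),
               "unknown")
})
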