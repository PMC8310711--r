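mini_lib <- function() consensus_library(
  c(famA = "ACGTACGTAAGGCCTTAACCGGTTACGTACGTACGGTTAA",
    famB = "TTGGCCAATTGGCCAATTGGCCAATTGGCCAATTGGCCAA"))

sam_row <- function(qname, flag, rname, pos, cigar, seq,
                    mapq = 60L, qual = strrep("I", nchar(seq))) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

test_that("pileups place bases CIGAR-aware and honour quality/flag gates", {
  lib <- mini_lib()
  ref <- lib$sequences[["famA"]]
  # perfect read: depth 1, reference allele at each covered position
  sam <- sam_row("r1", 0L, "famA", 1L, "10M", substr(ref, 1, 10))
  p <- build_pileup(sam, lib)
  expect_equal(sum(p$famA), 10L)
  for (i in 1:10) {
    expect_equal(unname(p$famA[substr(ref, i, i), i]), 1L)
  }
  # one mismatch at 0-based offset 7
  rd <- substr(ref, 1, 10)
  mis <- if (substr(rd, 8, 8) == "A") "C" else "A"
  substr(rd, 8, 8) <- mis
  p2 <- build_pileup(sam_row("r2", 0L, "famA", 1L, "10M", rd), lib)
  expect_equal(unname(p2$famA[mis, 8]), 1L)
  # soft-clip and deletion shift columns correctly: 2S3M2D3M
  rd3 <- paste0("GG", substr(ref, 5, 7), substr(ref, 10, 12))
  p3 <- build_pileup(sam_row("r3", 0L, "famA", 5L, "2S3M2D3M", rd3), lib)
  expect_equal(unname(colSums(p3$famA)[5:12]), c(1, 1, 1, 0, 0, 1, 1, 1))
  # unmapped / secondary / duplicate / low-MAPQ records are ignored
  for (bad in list(c(4L, 60L), c(256L, 60L), c(1024L, 60L), c(0L, 5L))) {
    pb <- build_pileup(sam_row("rb", bad[1], "famA", 1L, "10M",
                               substr(ref, 1, 10), mapq = bad[2]), lib)
    expect_equal(sum(pb$famA), 0L)
  }
  expect_error(build_pileup(sam_row("r", 0L, "nope", 1L, "5M", "ACGTA"), lib),
               "absent")
})

test_that("presence gates implement the depth/count/frequency thresholds", {
  lib <- mini_lib()
  mk_pile <- function(depth, alt) {
    p <- list(famA = matrix(0L, 4, 40, dimnames = list(c("A", "C", "G", "T"), NULL)))
    ref_base <- substr(lib$sequences[["famA"]], 10, 10)
    alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
    p$famA[ref_base, 10] <- depth - alt
    p$famA[alt_base, 10] <- alt
    structure(p, class = "consensus_pileup")
  }
  alt_base <- setdiff(c("A", "C", "G", "T"),
                      substr(lib$sequences[["famA"]], 10, 10))[1]
  expect_equal(call_sample_presence(mk_pile(20, 8), "famA", 9, alt_base), "present")
  expect_equal(call_sample_presence(mk_pile(20, 0), "famA", 9, alt_base), "absent")
  expect_equal(call_sample_presence(mk_pile(3, 3), "famA", 9, alt_base), "indeterminate")
  expect_equal(call_sample_presence(mk_pile(20, 2), "famA", 9, alt_base), "indeterminate")
  expect_error(call_sample_presence(mk_pile(20, 8), "famA", 99, alt_base), "outside")
})

test_that("the all-female/no-male rule and its monotonicity under extra males", {
  co <- study_cohort()
  piles <- study_cohort_piles()
  v <- sexlinked_variants(piles, co$sheet, co$library)
  tw <- co$truth[co$truth$carrier == "W", ]
  called <- v[v$w_linked, ]
  expect_equal(sort(variant_key(called)), sort(variant_key(tw)))
  expect_equal(sum(!variant_key(called) %in% variant_key(tw)), 0L)
  # autosomal variants are seen but never W-linked
  ta <- co$truth[co$truth$carrier == "autosome", ]
  expect_true(all(variant_key(ta) %in% variant_key(v)))
  expect_false(any(variant_key(ta) %in% variant_key(called)))
  # adding a male sample can only shrink or preserve the W-linked set:
  # drop one male and compare
  sheet2 <- co$sheet[co$sheet$sample != "M3", ]
  class(sheet2) <- class(co$sheet)
  v2 <- sexlinked_variants(piles, sheet2, co$library)
  expect_true(all(variant_key(v[v$w_linked, ]) %in%
                    variant_key(v2[v2$w_linked, ])))
})

test_that("a variant missing from one female is not W-linked", {
  co <- study_cohort()
  piles <- study_cohort_piles()
  # erase the alt allele of one planted variant in one female's pileup
  tw <- co$truth[co$truth$carrier == "W", ][1, ]
  p <- piles
  m <- p$F1[[tw$family]]
  m[tw$alt, tw$position + 1L] <- 0L
  m[tw$ref, tw$position + 1L] <- m[tw$ref, tw$position + 1L] + 60L
  p$F1[[tw$family]] <- m
  v <- sexlinked_variants(p, co$sheet, co$library)
  expect_false(variant_key(tw) %in% variant_key(v[v$w_linked, ]))
})

test_that("transcription check flags female-RNA variants and discards male-RNA ones", {
  co <- study_cohort()
  piles <- study_cohort_piles()
  v <- sexlinked_variants(piles, co$sheet, co$library)
  v2 <- transcription_check(v, piles, co$sheet)
  tw <- co$truth[co$truth$carrier == "W", ]
  tr_truth <- tw[tw$transcribed, ]
  expect_equal(sort(variant_key(v2[v2$transcribed %in% TRUE, ])),
               sort(variant_key(tr_truth)))
  expect_equal(sum(v2$discarded_male_rna), 0L)
  # force one variant into a male RNA pileup: it must be discarded, and
  # every discarded variant was previously W-linked
  vic <- tw[1, ]
  p <- piles
  m <- p$MR1[[vic$family]]
  m[vic$alt, vic$position + 1L] <- 30L
  m[vic$ref, vic$position + 1L] <- 30L
  p$MR1[[vic$family]] <- m
  v3 <- transcription_check(v, p, co$sheet)
  expect_true(v3$discarded_male_rna[variant_key(v3) == variant_key(vic)])
  expect_false(v3$w_linked[variant_key(v3) == variant_key(vic)])
  expect_true(all(variant_key(v3[v3$discarded_male_rna, ]) %in%
                    variant_key(v[v$w_linked, ])))
})

test_that("subfamily summary counts SNVs, subfamilies and transcription", {
  cls <- c(famA = "LTR/ERV1", famB = "LTR/ERV1", famC = "LINE/CR1")
  v <- data.frame(family = c("famA", "famA", "famA", "famB", "famB"),
                  position = 1:5, ref = "A", alt = "G",
                  w_linked = TRUE,
                  transcribed = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                  discarded_male_rna = FALSE)
  s <- summarize_by_subfamily(v, cls)
  erv <- s[s$group == "LTR/ERV1", ]
  expect_equal(unlist(erv[, -1], use.names = FALSE), c(5, 2, 3, 1))
  tot <- s[s$group == "total", ]
  expect_equal(unlist(tot[, -1], use.names = FALSE), c(5, 2, 3, 1))
  empty <- summarize_by_subfamily(v[0, ], cls)
  expect_true(all(empty[, -1] == 0))
})

test_that("sample sheets enforce cohort requirements and warn on single males", {
  df <- data.frame(sample = c("F1", "M1"), sex = c("female", "male"),
                   assay = c("genomic", "genomic"))
  expect_warning(sample_sheet(df), "one male")
  expect_error(sample_sheet(df[1, , drop = FALSE]), "male")
  df3 <- data.frame(sample = c("F1", "M1", "M2"),
                    sex = c("female", "male", "male"),
                    assay = "genomic")
  expect_silent(sample_sheet(df3))
})

test_that("naive mapper places exact reads, drops foreign and ambiguous ones", {
  co <- study_cohort()
  lib <- co$library
  cons <- lib$sequences[[1]]
  rd <- substr(cons, 201, 300)
  sam <- naive_map(c(r1 = rd), lib)
  expect_equal(nrow(sam), 1L)
  expect_equal(sam$rname, names(lib$sequences)[1])
  expect_equal(sam$pos, 201L)
  # reverse-complement read maps to the same place on the minus flag
  sam_rc <- naive_map(c(r1 = slcTE:::revcomp1(rd)), lib)
  expect_equal(sam_rc$pos, 201L)
  expect_equal(sam_rc$flag, 16L)
  # a read from unrelated sequence has no seed hit (brute-force confirmed)
  set.seed(99)
  foreign <- slcTE:::random_dna(100)
  expect_equal(nrow(naive_map(c(rx = foreign), lib)), 0L)
  any_kmer_shared <- any(vapply(1:(100 - 31 + 1), function(i)
    any(vapply(lib$sequences, function(s)
      grepl(substr(foreign, i, i + 30), s, fixed = TRUE), TRUE)), TRUE))
  expect_false(any_kmer_shared)
  # a read matching two families equally is dropped as ambiguous
  lib2 <- consensus_library(c(dupA = paste0(cons, ""),
                              dupB = paste0(substr(cons, 1, 1200))))
  rd2 <- substr(cons, 301, 400)
  expect_equal(nrow(naive_map(c(ry = rd2), lib2)), 0L)
})

test_that("SAM text round-trips through write_sam/read_sam", {
  co <- study_cohort()
  lib <- co$library
  rd <- substr(lib$sequences[[2]], 101, 200)
  sam <- naive_map(c(a = rd), lib)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, lib, f)
  back <- read_sam(f)
  expect_equal(back$rname, sam$rname)
  expect_equal(back$pos, sam$pos)
  expect_equal(back$seq, sam$seq)
  # pileups built from the file equal pileups built in memory
  expect_equal(build_pileup(back, lib), build_pileup(sam, lib))
})
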