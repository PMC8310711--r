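# Deterministic synthetic-data generator: TE consensus libraries with
# planted protein domains, genomes with planted full-length elements,
# solo-LTRs and truncated fragments at controlled divergence, and
# male/female read cohorts carrying W-restricted variants — all with a
# machine-readable truth manifest.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
# one fixed sense codon per amino acid (stop-free by construction)
AA_CODON <- c(A="GCT", R="CGT", N="AAT", D="GAT", C="TGT", Q="CAA", E="GAA",
              G="GGT", H="CAT", I="ATT", L="CTT", K="AAA", M="ATG", F="TTT",
              P="CCT", S="TCT", T="ACT", W="TGG", Y="TAT", V="GTT")

random_peptide <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
peptide_to_nt <- function(p) paste(AA_CODON[strsplit(p, "")[[1]]], collapse = "")

#' Simulation configuration
#'
#' Defaults describe the study conditions the test-suite genomes emulate: a
#' ~2 Mb ZW genome (two 500 kb autosomes, 400 kb Z, 700 kb W), 32 planted
#' full-length ERVs split (10, 2, 20) across autosomes/Z/W, 20 solo-LTRs
#' and 20 truncated fragments, error-free copies (divergence 0) unless a
#' target divergence is requested, and 3 female + 3 male genomic samples at
#' 30x coverage with error-free 100 bp reads.
#'
#' @param seed integer root seed; same seed implies identical outputs.
#' @param chromosomes chromosome plan data.frame (`name`, `te_class`,
#'   `length`).
#' @param fl_erv_per_class named counts of planted full-length ERVs.
#' @param n_solo_ltr,n_truncated planted solo-LTRs / internal-only
#'   fragments (spread over chromosomes round-robin).
#' @param fl_line_per_class,fl_dna_per_class planted full-length LINEs /
#'   DNA transposons per class.
#' @param n_truncated_line planted 5'-truncated LINE copies (lack the
#'   endonuclease domain).
#' @param divergence_k target Kimura 2-parameter distance of planted copies
#'   (substitutions/site; 0 = error-free).
#' @param kappa transition/transversion rate ratio used when mutating.
#' @param spacing minimum gap between planted insertions (bp); keeping it
#'   above the maximum element span makes ground truth unambiguous.
#' @param tsd_len target-site duplication length for planted elements.
#' @param n_erv_families,ltr_len number of ERV families and their LTR
#'   length.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chromosomes = data.frame(
                                name = c("chrA1", "chrA2", "chrZ", "chrW"),
                                te_class = c("autosome", "autosome", "Z", "W"),
                                length = c(500000, 500000, 400000, 700000)),
                              fl_erv_per_class = c(autosome = 10L, Z = 2L, W = 20L),
                              n_solo_ltr = 20L, n_truncated = 20L,
                              fl_line_per_class = c(autosome = 0L, Z = 0L, W = 0L),
                              fl_dna_per_class = c(autosome = 0L, Z = 0L, W = 0L),
                              n_truncated_line = 0L,
                              divergence_k = 0, kappa = 2,
                              spacing = 16000, tsd_len = 5L,
                              n_erv_families = 2L, ltr_len = 300L) {
  stopifnot(is_count(seed), divergence_k >= 0, kappa > 0,
            all(fl_erv_per_class >= 0), n_solo_ltr >= 0, n_truncated >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a TE consensus library with planted domains
#'
#' Builds ERV families (LTR + internal region carrying stop-free gag-, pol-
#' and env-like ORFs), a LINE family whose single long ORF spans
#' endonuclease and reverse-transcriptase domains, and a DNA-transposon
#' family with an intact transposase ORF. Domain consensus peptides are
#' returned alongside, so planted intact copies pass the package's own
#' full-length criteria.
#'
#' @param config [simulation_config()].
#' @return list: `library` (`consensus_library`; ERV entries are full
#'   elements), `parts` (per-family LTR/internal components),
#'   `domains` (named peptides: EN, RT, transposase, gag, pol, env).
#' @export
make_library <- function(config = simulation_config()) {
  with_substream(config$seed, 101L, {
    domains <- list(gag = random_peptide(150), pol = random_peptide(250),
                    env = random_peptide(150), EN = random_peptide(200),
                    RT = random_peptide(250), transposase = random_peptide(360))
    parts <- list(); seqs <- character(); cls <- character()
    for (i in seq_len(config$n_erv_families)) {
      fam <- sprintf("ERV%d_sim", i)
      ltr <- random_dna(config$ltr_len)
      internal <- paste0(
        random_dna(120),
        "TAA", peptide_to_nt(domains$gag), "TAA",
        random_dna(101),                       # shift frame between genes
        "TAA", peptide_to_nt(domains$pol), "TAA",
        random_dna(103),
        "TAA", peptide_to_nt(domains$env), "TAA",
        random_dna(120))
      parts[[fam]] <- list(ltr = ltr, internal = internal)
      seqs[fam] <- paste0(ltr, internal, ltr)
      cls[fam] <- sprintf("LTR/ERV%d", (i - 1L) %% 3L + 1L)
    }
    line_orf <- paste0("TAA", peptide_to_nt(domains$EN),
                       peptide_to_nt(random_peptide(30)),
                       peptide_to_nt(domains$RT), "TAA")
    seqs["CR1_sim"] <- paste0(random_dna(150), line_orf, random_dna(150))
    cls["CR1_sim"] <- "LINE/CR1"
    parts[["CR1_sim"]] <- list(orf_offset = 150L + 3L,
                               orf_len = nchar(line_orf) - 6L)
    dna_orf <- paste0("TAA", peptide_to_nt(domains$transposase), "TAA")
    seqs["hAT_sim"] <- paste0(random_dna(120), dna_orf, random_dna(120))
    cls["hAT_sim"] <- "DNA/hAT"
    lib <- consensus_library(seqs, classification = cls)
    list(library = lib, parts = parts, domains = domains)
  })
}

# K2P forward model: site-wise expected transition (P) and transversion (Q)
# proportions for target distance K and rate ratio kappa = alpha/beta.
k2p_pq <- function(K, kappa) {
  y <- K / (2 * kappa + 4)          # beta * t
  x <- kappa * y                    # alpha * t
  Q <- (1 - exp(-8 * y)) / 2
  P <- (1 - Q - exp(-4 * (x + y))) / 2
  list(P = P, Q = Q)
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

# mutate a sequence to a target K2P distance; returns realized divergence too
mutate_k2p <- function(s, K, kappa = 2) {
  if (K <= 0) return(list(seq = s, realized_k = 0, P = 0, Q = 0))
  pq <- k2p_pq(K, kappa)
  v <- strsplit(s, "")[[1]]
  u <- runif(length(v))
  ts <- u < pq$P
  tv <- !ts & u < pq$P + pq$Q
  v[ts] <- TRANSITION[v[ts]]
  idx <- which(tv)
  if (length(idx)) {
    pick <- runif(length(idx)) < 0.5
    v[idx] <- vapply(seq_along(idx), function(j)
      TRANSVERSIONS[[substr(s, idx[j], idx[j]) ]][if (pick[j]) 1L else 2L],
      character(1))
  }
  Pr <- mean(ts); Qr <- mean(tv)
  kk <- k2p_distance(P = Pr, Q = Qr)
  list(seq = paste(v, collapse = ""),
       realized_k = if (kk$defined) kk$K else NA_real_, P = Pr, Q = Qr)
}

#' Plant TE insertions into synthetic chromosomes
#'
#' Builds the chromosome sequences of the [simulation_config()] plan with
#' full-length elements (both LTRs + TSD + intact internal ORFs), solo-LTRs
#' (one LTR + TSD, the relic of inter-LTR recombination), truncated
#' internal-only fragments, full-length LINEs/DNA transposons and
#' 5'-truncated LINEs, every copy mutated to the target divergence.
#' Insertions are interval-disjoint and spaced by at least
#' `config$spacing`.
#'
#' @param config [simulation_config()].
#' @param lib result of [make_library()] (regenerated from the config seed
#'   when omitted).
#' @return list of class `sim_genome`:
#'   `genome` (female `genome_model` with sequences),
#'   `male_sequences` (named list without the W),
#'   `hits` (RepeatMasker-style `repeat_hits` incl. realized divergence),
#'   `truth` (planted-element data.frame + expected census counts),
#'   `library`, `parts`, `domains`.
#' @export
plant_and_mutate <- function(config = simulation_config(), lib = NULL) {
  if (is.null(lib)) lib <- make_library(config)
  erv_fams <- grep("^ERV", names(lib$library$sequences), value = TRUE)
  chroms <- config$chromosomes
  # per-chromosome insertion plans
  plan <- list()
  add <- function(chrom, what, fam) {
    plan[[chrom]] <<- c(plan[[chrom]], list(list(what = what, fam = fam)))
  }
  spread <- function(n_per_class, what) {
    for (cl in names(n_per_class)) {
      members <- chroms$name[chroms$te_class == cl]
      if (!length(members) && n_per_class[[cl]] > 0)
        stop2("no chromosome of class ", cl, " in plan")
      n <- n_per_class[[cl]]
      if (n > 0) for (j in seq_len(n)) {
        fam <- if (what %in% c("fl_ERV", "solo_LTR", "fragment"))
          erv_fams[(j - 1L) %% length(erv_fams) + 1L]
        else if (what %in% c("fl_LINE", "trunc_LINE")) "CR1_sim" else "hAT_sim"
        add(members[(j - 1L) %% length(members) + 1L], what, fam)
      }
    }
  }
  spread(config$fl_erv_per_class, "fl_ERV")
  spread(config$fl_line_per_class, "fl_LINE")
  spread(config$fl_dna_per_class, "fl_DNA")
  # solo-LTRs and fragments round-robin over all chromosomes
  all_chr <- chroms$name
  for (j in seq_len(config$n_solo_ltr))
    add(all_chr[(j - 1L) %% length(all_chr) + 1L], "solo_LTR",
        erv_fams[(j - 1L) %% length(erv_fams) + 1L])
  for (j in seq_len(config$n_truncated))
    add(all_chr[(j - 1L) %% length(all_chr) + 1L], "fragment",
        erv_fams[(j - 1L) %% length(erv_fams) + 1L])
  for (j in seq_len(config$n_truncated_line))
    add(all_chr[(j - 1L) %% length(all_chr) + 1L], "trunc_LINE", "CR1_sim")

  with_substream(config$seed, 202L, {
    seqs <- list(); rows <- list(); truth <- list()
    for (ci in seq_len(nrow(chroms))) {
      chrom <- chroms$name[ci]
      target_len <- chroms$length[ci]
      ins <- plan[[chrom]] %||% list()
      pieces <- character(); cursor <- 0L  # 0-based length so far
      emit <- function(s) { pieces[[length(pieces) + 1L]] <<- s; cursor <<- cursor + nchar(s) }
      for (item in ins) {
        emit(random_dna(config$spacing))
        fam <- item$fam
        tsd <- random_dna(config$tsd_len)
        mk <- function(s) mutate_k2p(s, config$divergence_k, config$kappa)
        if (item$what == "fl_ERV") {
          p <- lib$parts[[fam]]
          m <- mk(paste0(p$ltr, p$internal, p$ltr))
          body <- m$seq
          emit(tsd)
          begin <- cursor; emit(body); end <- cursor
          emit(tsd)
          cat_out <- "fl_ERV"; div <- m$realized_k
        } else if (item$what == "solo_LTR") {
          m <- mk(lib$parts[[fam]]$ltr)
          emit(tsd); begin <- cursor; emit(m$seq); end <- cursor; emit(tsd)
          cat_out <- "solo_LTR"; div <- m$realized_k
        } else if (item$what == "fragment") {
          internal <- lib$parts[[fam]]$internal
          frag <- substr(internal, 1, min(nchar(internal), 1200L))
          m <- mk(frag)
          begin <- cursor; emit(m$seq); end <- cursor
          cat_out <- "fragment"; div <- m$realized_k
        } else if (item$what == "fl_LINE") {
          m <- mk(lib$library$sequences[["CR1_sim"]])
          emit(tsd); begin <- cursor; emit(m$seq); end <- cursor; emit(tsd)
          cat_out <- "fl_LINE"; div <- m$realized_k
        } else if (item$what == "trunc_LINE") {
          s <- lib$library$sequences[["CR1_sim"]]
          m <- mk(substr(s, nchar(s) - 900L, nchar(s)))  # 5'-truncated: no EN
          begin <- cursor; emit(m$seq); end <- cursor
          cat_out <- "trunc_LINE"; div <- m$realized_k
        } else {  # fl_DNA
          m <- mk(lib$library$sequences[["hAT_sim"]])
          emit(tsd); begin <- cursor; emit(m$seq); end <- cursor; emit(tsd)
          cat_out <- "fl_DNA"; div <- m$realized_k
        }
        truth[[length(truth) + 1L]] <- data.frame(
          chromosome = chrom, begin = begin, end = end, category = cat_out,
          family = fam, target_k = config$divergence_k,
          realized_k = div, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom, begin = begin, end = end, strand = "+",
          family = fam,
          classification = if (cat_out %in% c("fl_LINE", "trunc_LINE"))
            "LINE/CR1" else if (cat_out == "fl_DNA") "DNA/hAT"
          else unname(lib$library$classification[fam]),
          divergence_pct = round(100 * div, 1), fragment_link = NA_character_,
          stringsAsFactors = FALSE)
      }
      if (cursor > target_len)
        stop2("overfull chromosome ", chrom, ": plan needs ", cursor,
              " bp but length is ", target_len)
      emit(random_dna(target_len - cursor))
      seqs[[chrom]] <- paste(pieces, collapse = "")
    }
    hits <- if (length(rows)) {
      df <- do.call(rbind, rows)
      h <- validate_repeat_hits(df)
      h$score <- rep(1000, nrow(h))
      h
    } else cbind(repeat_hits(character(), numeric(), numeric()), score = numeric())
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chromosome = character(), begin = numeric(), end = numeric(),
                 category = character(), family = character(),
                 target_k = numeric(), realized_k = numeric())
    gm <- genome_model(chroms, sex_system = "ZW",
                       sequences = unlist(seqs)[chroms$name],
                       male_assembly = !("W" %in% chroms$te_class))
    expected <- list(fl_ERV = config$fl_erv_per_class,
                     fl_LINE = config$fl_line_per_class,
                     fl_DNA = config$fl_dna_per_class)
    structure(list(genome = gm,
                   male_sequences = seqs[chroms$name[chroms$te_class != "W"]],
                   hits = hits,
                   truth = list(elements = truth_df, expected_census = expected),
                   library = lib$library, parts = lib$parts,
                   domains = lib$domains),
              class = "sim_genome")
  })
}

#' Write a simulated genome bundle to disk
#'
#' Emits female/male FASTA, a RepeatMasker-style `.out`, the consensus
#' library FASTA, domain peptides FASTA, and a JSON truth manifest.
#'
#' @param sim result of [plant_and_mutate()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome$sequences, file.path(dir, "female_genome.fa"))
  write_fasta(unlist(sim$male_sequences), file.path(dir, "male_genome.fa"))
  write_repeatmasker_out(sim$hits, file.path(dir, "annotation.out"))
  lib_named <- setNames(sim$library$sequences,
                        paste0(names(sim$library$sequences), "#",
                               sim$library$classification))
  write_fasta(lib_named, file.path(dir, "library.fa"))
  write_fasta(unlist(sim$domains), file.path(dir, "domains.faa"))
  manifest <- list(elements = sim$truth$elements,
                   expected_census = sim$truth$expected_census)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  } else {
    saveRDS_path <- file.path(dir, "truth.tsv")
    write.table(sim$truth$elements, saveRDS_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

# ---- read cohorts -----------------------------------------------------------

#' SNV-cohort configuration
#'
#' Defaults are the cohort conditions the linkage tests emulate: 3 female +
#' 3 male genomic samples at 30x, error-free 100 bp reads, W-restricted
#' variants at frequency 1 on the W-linked copies, and autosomal variants
#' present in every sample. Haplotypes are compact TE-copy arrays (per
#' family: `n_auto_copies` autosomal copies in both sexes plus `n_w_copies`
#' W-linked copies in females only), since background sequence never
#' reaches consensus-space pileups.
#'
#' @param seed root seed.
#' @param n_females,n_males genomic samples per sex.
#' @param n_rna_females,n_rna_males RNA samples per sex.
#' @param coverage mean per-base read depth per haplotype copy set.
#' @param read_len read length (bp).
#' @param error_rate per-base substitution error rate.
#' @param n_w_variants planted W-restricted SNVs.
#' @param n_auto_variants planted autosomal SNVs (present in all samples).
#' @param transcribed_fraction fraction of ERV families whose W copies are
#'   transcribed (variants inherit the family flag).
#' @param n_families ERV families used.
#' @param n_auto_copies,n_w_copies copies per family.
#' @param flank flanking background around each copy (bp).
#' @return list of class `snv_cohort_config`.
#' @export
snv_cohort_config <- function(seed = 1L, n_females = 3L, n_males = 3L,
                              n_rna_females = 1L, n_rna_males = 1L,
                              coverage = 30, read_len = 100L, error_rate = 0,
                              n_w_variants = 30L, n_auto_variants = 30L,
                              transcribed_fraction = 0.5,
                              n_families = 4L, n_auto_copies = 2L,
                              n_w_copies = 2L, flank = 200L) {
  stopifnot(n_females >= 1, n_males >= 1, coverage > 0, read_len >= 32)
  structure(as.list(environment()), class = "snv_cohort_config")
}

#' Simulate male/female read cohorts over a TE consensus library
#'
#' Builds per-sex haplotypes (TE-copy arrays with flanks), plants
#' W-restricted variants (on W-linked copies only, hence female-only) and
#' autosomal variants (on autosomal copies, hence in every sample), and
#' samples uniform error-free (or error-injected) reads per sample.
#' Genomic samples draw from the full haplotype; RNA samples draw from
#' transcribed copies only (W copies of transcribed families in females;
#' autosomal copies of transcribed families in both sexes).
#'
#' @param config [snv_cohort_config()].
#' @return list of class `snv_cohort`: `library`, `sheet`
#'   ([sample_sheet()]), `reads` (named list sample -> character vector),
#'   `truth` (planted-variant data.frame: family, position 0-based, ref,
#'   alt, carrier, transcribed).
#' @export
simulate_snv_cohort <- function(config = snv_cohort_config()) {
  with_substream(config$seed, 303L, {
    fams <- sprintf("ERVsnv%d", seq_len(config$n_families))
    cons_len <- 2400L
    seqs <- setNames(vapply(fams, function(f) random_dna(cons_len), ""), fams)
    lib <- consensus_library(seqs, classification = setNames(
      rep("LTR/ERVL", length(fams)), fams))
    transcribed_fam <- setNames(
      seq_along(fams) <= round(config$transcribed_fraction * length(fams)), fams)

    # planted variants: positions away from copy edges so depth is full
    pick_sites <- function(n, carrier) {
      if (n == 0) return(NULL)
      fam <- fams[(seq_len(n) - 1L) %% length(fams) + 1L]
      lo <- config$read_len + 50L; hi <- cons_len - config$read_len - 50L
      pos <- integer(n); alt <- character(n); ref <- character(n)
      used <- list()
      for (i in seq_len(n)) {
        repeat {
          p <- sample(lo:hi, 1L)
          key <- paste(fam[i], p)
          if (is.null(used[[key]])) { used[[key]] <- TRUE; break }
        }
        pos[i] <- p
        ref[i] <- substr(seqs[[fam[i]]], p + 1L, p + 1L)
        alt[i] <- sample(setdiff(DNA_BASES, ref[i]), 1L)
      }
      data.frame(family = fam, position = pos, ref = ref, alt = alt,
                 carrier = carrier,
                 transcribed = unname(transcribed_fam[fam]) & carrier == "W",
                 stringsAsFactors = FALSE)
    }
    truth <- rbind(pick_sites(config$n_w_variants, "W"),
                   pick_sites(config$n_auto_variants, "autosome"))

    apply_variants <- function(s, fam, carrier) {
      v <- truth[truth$family == fam & truth$carrier == carrier, , drop = FALSE]
      if (!is.null(v) && nrow(v)) {
        ch <- strsplit(s, "")[[1]]
        ch[v$position + 1L] <- v$alt
        s <- paste(ch, collapse = "")
      }
      s
    }
    copy_array <- function(fam, carrier, n_copies) {
      s <- apply_variants(seqs[[fam]], fam, carrier)
      paste(vapply(seq_len(n_copies), function(i)
        paste0(random_dna(config$flank), s, random_dna(config$flank)), ""),
        collapse = "")
    }
    auto_hap <- paste(vapply(fams, function(f)
      copy_array(f, "autosome", config$n_auto_copies), ""), collapse = "")
    w_hap <- paste(vapply(fams, function(f)
      copy_array(f, "W", config$n_w_copies), ""), collapse = "")
    auto_tx <- paste(vapply(fams[transcribed_fam], function(f)
      copy_array(f, "autosome", config$n_auto_copies), ""), collapse = "")
    w_tx <- paste(vapply(fams[transcribed_fam], function(f)
      copy_array(f, "W", config$n_w_copies), ""), collapse = "")

    sheet <- data.frame(
      sample = c(sprintf("F%d", seq_len(config$n_females)),
                 sprintf("M%d", seq_len(config$n_males)),
                 if (config$n_rna_females) sprintf("FR%d", seq_len(config$n_rna_females)),
                 if (config$n_rna_males) sprintf("MR%d", seq_len(config$n_rna_males))),
      sex = c(rep("female", config$n_females), rep("male", config$n_males),
              rep("female", config$n_rna_females), rep("male", config$n_rna_males)),
      assay = c(rep("genomic", config$n_females + config$n_males),
                rep("RNA", config$n_rna_females + config$n_rna_males)),
      stringsAsFactors = FALSE)
    sheet <- suppressWarnings(sample_sheet(sheet))

    hap_for <- function(sex, assay) {
      if (assay == "genomic") {
        if (sex == "female") paste0(auto_hap, w_hap) else auto_hap
      } else {
        if (sex == "female") {
          if (nchar(w_tx) || nchar(auto_tx)) paste0(auto_tx, w_tx) else auto_tx
        } else auto_tx
      }
    }
    reads <- list()
    for (i in seq_len(nrow(sheet))) {
      hap <- hap_for(sheet$sex[i], sheet$assay[i])
      if (!nchar(hap)) { reads[[sheet$sample[i]]] <- character(0); next }
      n_reads <- ceiling(config$coverage * nchar(hap) / config$read_len)
      starts <- sample.int(nchar(hap) - config$read_len + 1L, n_reads, replace = TRUE)
      rd <- substring(hap, starts, starts + config$read_len - 1L)
      flip <- runif(n_reads) < 0.5
      rd[flip] <- vapply(rd[flip], revcomp1, "", USE.NAMES = FALSE)
      if (config$error_rate > 0) {
        rd <- vapply(rd, function(s) {
          ch <- strsplit(s, "")[[1]]
          err <- runif(length(ch)) < config$error_rate
          if (any(err)) ch[err] <- vapply(ch[err], function(b)
            sample(setdiff(DNA_BASES, b), 1L), "")
          paste(ch, collapse = "")
        }, "", USE.NAMES = FALSE)
      }
      reads[[sheet$sample[i]]] <- setNames(
        rd, sprintf("%s_r%06d", sheet$sample[i], seq_len(n_reads)))
    }
    structure(list(library = lib, sheet = sheet, reads = reads, truth = truth),
              class = "snv_cohort")
  })
}

#' Simulate uniform reads from arbitrary haplotype sequences
#'
#' @param haplotypes named character vector of source sequences.
#' @param coverage mean per-base depth.
#' @param read_len read length (must not exceed the shortest haplotype).
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @param both_strands sample reads from both strands.
#' @return named character vector of reads.
#' @export
simulate_reads <- function(haplotypes, coverage = 30, read_len = 100L,
                           error_rate = 0, seed = 1L, both_strands = TRUE) {
  if (read_len > min(nchar(haplotypes)))
    stop2("read length exceeds a haplotype length")
  stopifnot(coverage > 0)
  with_substream(seed, 404L, {
    out <- character(0)
    for (h in names(haplotypes)) {
      s <- haplotypes[[h]]
      n_reads <- ceiling(coverage * nchar(s) / read_len)
      starts <- sample.int(nchar(s) - read_len + 1L, n_reads, replace = TRUE)
      rd <- substring(s, starts, starts + read_len - 1L)
      if (both_strands) {
        flip <- runif(n_reads) < 0.5
        rd[flip] <- vapply(rd[flip], revcomp1, "", USE.NAMES = FALSE)
      }
      if (error_rate > 0) {
        rd <- vapply(rd, function(x) {
          ch <- strsplit(x, "")[[1]]
          err <- runif(length(ch)) < error_rate
          if (any(err)) ch[err] <- vapply(ch[err], function(b)
            sample(setdiff(DNA_BASES, b), 1L), "")
          paste(ch, collapse = "")
        }, "", USE.NAMES = FALSE)
      }
      out <- c(out, setNames(rd, sprintf("%s_r%06d", h, seq_len(n_reads))))
    }
    out
  })
}
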