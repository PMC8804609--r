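prots <- synthetic_hv1_proteins()

test_that("voltage-sensor motif scanner matches constructed examples", {
  hit <- scan_voltage_sensor("AARLWRVGRAA")
  expect_equal(hit$start, 3L)
  expect_equal(hit$matched, "RLWRVGR")
  expect_equal(hit$terminal_residue, "R")
  # fungal-like variant: third arginine replaced by lysine
  hitK <- scan_voltage_sensor("AARLWRVGKAA")
  expect_equal(hitK$terminal_residue, "K")
  # X never satisfies a constrained position
  expect_equal(nrow(scan_voltage_sensor("AAXLWRVGRAA")), 0L)
  expect_equal(nrow(scan_voltage_sensor("AARLXRVGRAA")), 0L)
  expect_equal(nrow(scan_voltage_sensor("AARLWRVGXAA")), 0L)
  expect_equal(nrow(scan_voltage_sensor("NDMETIFHELE")), 0L)
})

test_that("scanner agrees with an exhaustive window oracle on random sequences", {
  oracle <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    hits <- integer(0)
    if (n >= 7) {
      for (i in seq_len(n - 6)) {
        w <- ch[i:(i + 6)]
        if (w[1] == "R" && w[3] == "W" && w[4] == "R" && w[7] %in% c("R", "K"))
          hits <- c(hits, i)
      }
    }
    hits
  }
  # biased alphabet so motifs actually occur; includes overlapping cases
  alph <- c("R", "R", "R", "W", "K", "A", "G")
  set.seed(99)
  n_mismatch <- 0L
  for (i in 1:10000) {
    s <- paste(sample(alph, sample(7:30, 1), replace = TRUE), collapse = "")
    got <- scan_voltage_sensor(s)$start
    if (!identical(as.integer(got), as.integer(oracle(s))))
      n_mismatch <- n_mismatch + 1L
  }
  expect_equal(n_mismatch, 0L)
  # dense arginine runs produce overlapping hits
  expect_equal(scan_voltage_sensor("RRWRRRRWRR")$start, oracle("RRWRRRRWRR"))
})

test_that("selectivity-filter mapping follows the alignment to the annotated reference", {
  # self-alignment maps the annotation to itself
  self <- map_sf_position(prots$href, prots$href)
  expect_equal(self$position, 112L)
  expect_equal(self$residue, "D")
  expect_equal(self$sf_class, "Asp")
  # the insect-like query maps the reference D112 column to its E62
  call <- map_sf_position(prots$et, prots$href)
  expect_equal(call$position, 62L)
  expect_equal(call$residue, "E")
  expect_equal(call$sf_class, "Glu")
  expect_false(call$gapped)
  # aspartate variant at the same column
  callD <- map_sf_position(prots$et_sfD, prots$href)
  expect_equal(callD$sf_class, "Asp")
  expect_equal(callD$position, 62L)
  # the second packaged reference annotates its filter at position 66
  self2 <- map_sf_position(prots$npref, prots$npref)
  expect_equal(self2$position, 66L)
  expect_equal(self2$sf_class, "Asp")
  # unrelated low-complexity sequence is rejected as unalignable
  junk <- paste(rep("GA", 40), collapse = "")
  expect_error(map_sf_position(junk, prots$href), "unalignable")
  expect_error(map_sf_position("MKTLVEHAG", prots$href), "50 residues")
})

test_that("zinc-site annotation exposes the His-His-Asp arrangement", {
  self <- annotate_zinc_sites(prots$href, prots$href)
  expect_equal(self$first_site, "H")
  expect_equal(self$second_site, "H")
  q <- annotate_zinc_sites(prots$et, prots$href)
  expect_equal(q$first_site, "K")
  expect_equal(q$second_site, "D")
  expect_equal(q$positions, c(91L, 144L))
  expect_equal(q$preceding_second, c("H", "H"))
})

test_that("screening verdicts combine motif, contamination and filter rules", {
  ok <- classify_record(prots$et, prots$href)
  expect_equal(ok$verdict, "pass")
  expect_false(ok$fungal_flag)
  expect_equal(ok$sf_call$sf_class, "Glu")
  cont <- classify_record(prots$et_contaminant)
  expect_equal(cont$verdict, "flagged_contaminant")
  expect_true(cont$fungal_flag)
  none <- classify_record("MSTLLNEAGDKVHEILNKAGFDSTQPLVNEAGSKTDLIPHQVSTLGEPQR")
  expect_equal(none$verdict, "fail_motif")
})

test_that("position frequency tables sum to one and track gaps separately", {
  same <- c("MKTE", "MKTE", "MKTE")
  ft <- position_frequency_table(same)
  expect_true(all(apply(ft$freq, 2, max) == 1))
  two <- c("MKTE", "MATE")
  ft2 <- position_frequency_table(two)
  expect_equal(ft2$freq["K", 2], 0.5)
  expect_equal(ft2$freq["A", 2], 0.5)
  expect_equal(unname(colSums(ft2$freq)), rep(1, 4))
  gapped <- c("M-TE", "MKTE", "MK-E")
  ft3 <- position_frequency_table(gapped)
  expect_equal(ft3$gap_fraction, c(0, 1/3, 1/3, 0))
  expect_equal(unname(colSums(ft3$freq)), rep(1, 4), tolerance = 1e-12)
  expect_error(position_frequency_table(c("MKTE", "MKT")), "ragged")
})

test_that("the aligned S4 block keeps its sensor arginines invariant", {
  s4 <- synthetic_s4_alignment(n = 18)
  ft <- position_frequency_table(as.character(s4))
  fixed <- attr(s4, "constrained_columns")
  r_cols <- fixed[c(1, 3, 4)]
  expect_equal(unname(ft$freq["R", r_cols]), rep(1, 3))
  expect_equal(unname(ft$freq["W", fixed[2]]), 1)
  expect_equal(unname(colSums(ft$freq)), rep(1, ncol(ft$freq)),
               tolerance = 1e-12)
  # unconstrained columns do vary
  expect_true(any(apply(ft$freq[, -fixed], 2, max) < 1))
})

test_that("ORF finding translates the longest reading frame on either strand", {
  expect_equal(find_orf_translate("ATGAAATAA", min_nt = 9)$residues, "MK")
  tx <- synthetic_hv1_transcript()
  orf <- find_orf_translate(tx$sequence)
  expect_equal(nchar(orf$residues), 236L)
  expect_equal(orf$residues, prots$et$residues)
  expect_equal(orf$annotations$strand, "+")
  # strand symmetry: the reverse complement encodes the same protein
  rc <- hvgate:::revcomp(unname(tx$sequence))
  orf_rc <- find_orf_translate(rc)
  expect_equal(orf_rc$residues, orf$residues)
  expect_equal(orf_rc$annotations$strand, "-")
  expect_error(find_orf_translate("ACGTACGTACGT"), "no open reading frame")
})

test_that("in-silico PCR finds compatible primer pairs with correct product lengths", {
  # constructed template: forward primer at the 5' end, reverse-primer
  # complement at the 3' end, total 100 nt
  fwd <- "ATGGACAGCTGGAATGTGGA"
  rev_ <- "CCATGTATGTACTGCGCTGC"
  mid <- paste(rep("ACGT", 15), collapse = "")
  templ <- paste0(fwd, mid, hvgate:::revcomp(rev_))
  expect_equal(nchar(templ), 100L)
  amp <- insilico_pcr(templ, fwd, rev_)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length_bp, 100L)
  expect_equal(amp$start, 1L)
  expect_equal(amp$end, 100L)
  # swapped primers amplify nothing
  expect_equal(nrow(insilico_pcr(templ, rev_, fwd)), 0L)
  # orientation symmetry: reverse-complement template with swapped primers
  amp_rc <- insilico_pcr(hvgate:::revcomp(templ), rev_, fwd)
  expect_equal(amp_rc$length_bp, amp$length_bp)
  expect_error(insilico_pcr(templ, "ACGTACGT", rev_), "15 nt")
})

test_that("one-mismatch mode recovers a degenerate primer site", {
  fwd <- "ATGGACAGCTGGAATGTGGA"
  rev_ <- "CCATGTATGTACTGCGCTGC"
  templ <- paste0(sub("^ATGG", "ATGA", fwd),
                  paste(rep("GCTA", 10), collapse = ""),
                  hvgate:::revcomp(rev_))
  expect_equal(nrow(insilico_pcr(templ, fwd, rev_)), 0L)
  expect_equal(nrow(insilico_pcr(templ, fwd, rev_, max_mismatch = 1)), 1L)
})

test_that("hydropathy profile flags hydrophobic stretches without joining the verdict", {
  seqs <- paste0(paste(rep("G", 15), collapse = ""),
                 paste(rep("I", 25), collapse = ""),
                 paste(rep("D", 15), collapse = ""))
  kd <- kyte_doolittle(seqs)
  expect_gte(nrow(kd$segments), 1L)
  core <- kd$segments[1, ]
  expect_true(core$start > 10 && core$end < 46)
  expect_error(kyte_doolittle("MKT"), "shorter")
})

test_that("FASTA round trip preserves sequences and annotation sidecars", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "refs.fasta")
  write_fasta(prots[c("href", "npref")], path)
  back <- read_protein_fasta(path)
  expect_equal(back[[prots$href$id]]$residues, prots$href$residues)
  expect_equal(back[[prots$href$id]]$annotations$sf_position, 112)
  expect_equal(back[[prots$href$id]]$annotations$zinc_sites, c(140, 193))
  # nucleotide round trip
  tx <- synthetic_hv1_transcript()
  ntp <- file.path(dir, "tx.fasta")
  write_fasta(tx$sequence, ntp)
  nt <- read_nucleotide_fasta(ntp)
  expect_equal(unname(nt), unname(tx$sequence))
})

test_that("the packaged fixture files match the in-code generators", {
  ext <- system.file("extdata", package = "hvgate")
  refs <- read_protein_fasta(file.path(ext, "synthetic_references.fasta"))
  expect_equal(refs[[prots$href$id]]$residues, prots$href$residues)
  tx <- read_nucleotide_fasta(file.path(ext, "synthetic_transcript.fasta"))
  expect_equal(unname(tx), unname(synthetic_hv1_transcript()$sequence))
})
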