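# Synthetic sequence fixtures. These are NOT the published sequences: they
# are constructed stand-ins, built entirely in code, that reproduce the
# structural features the screening rules key on (S4 RxWRxxR motif, an
# acidic selectivity filter aligned to the reference SF column, the
# K.../His-His-Asp zinc-site arrangement, a 236-aa ORF whose transcript
# carries the published primer pair 363 bp apart). Every object and file
# derived from them is labelled "synthetic".

# Fixed filler generator: deterministic strings over an alphabet that
# excludes R and W, so no voltage-sensor motif can arise by accident.
synth_filler <- function(n, seed) {
  pool <- c("A","D","E","F","G","H","I","K","L","N","P","Q","S","T","V","Y")
  paste(with_seed(seed, sample(pool, n, replace = TRUE)), collapse = "")
}

#' Synthetic HV1-like proteins for screening tests
#'
#' Builds a deterministic, clearly synthetic homolog pair emulating the
#' geometry of an insect HV1 query and an annotated human-like reference:
#'
#' * `et`: a 236-residue query with glutamate at position 62 (the column
#'   aligned to the reference SF), lysine/aspartate zinc-site residues at 91
#'   and 144 with His142-His143 preceding the second site, and one terminal-R
#'   RxWRxxR motif at 156-162. Its first residues (MDSWNVE) are encoded by
#'   the published forward primer in [synthetic_hv1_transcript()].
#' * `href`: a 273-residue human-like reference annotated with
#'   `sf_position = 112` (Asp) and `zinc_sites = c(140, 193)` (His, His).
#' * `npref`: a 240-residue reference with `sf_position = 66` (Asp).
#' * `et_contaminant`: the query with the motif's third arginine mutated to
#'   lysine (the fungal-like variant; should be flagged).
#' * `et_sfD`: the query with Asp instead of Glu at the SF column.
#'
#' @return a named list of `hv_protein` objects.
#' @export
synthetic_hv1_proteins <- function() {
  # shared building blocks (identical residues align trivially)
  qN <- paste0("MDSWNVE", synth_filler(54, seed = 101L))        # query 1..61
  A27 <- synth_filler(27, seed = 102L)                          # SF..zn1 linker
  B50 <- synth_filler(50, seed = 103L)                          # zn1..HHD linker
  # positions 115..121 of the query (indices 24..30 of B50) are pinned to the
  # amino acids encoded by the reverse-primer footprint of the transcript
  B50 <- paste0(substr(B50, 1, 23), "SSAVHTW", substr(B50, 31, 50))
  C11 <- synth_filler(11, seed = 104L)                          # pre-motif
  MOT <- "RVWRTLR"                                              # S4 motif
  D62 <- synth_filler(62, seed = 105L)                          # shared C-term
  E12 <- synth_filler(12, seed = 106L)                          # query extra tail
  refN50 <- synth_filler(49, seed = 107L)                       # ref-only N-term

  et <- paste0(qN, "E", A27, "G", "K", B50, "HHD", C11, MOT, D62, E12)
  href <- paste0("M", refN50, qN, "D", A27, "H", B50, "LAH", C11, MOT, D62)
  npref <- paste0("MSTE", qN, "D", A27, "G", "K", B50, "HHD", C11, MOT,
                  D62, E12)

  stopifnot(nchar(et) == 236L, nchar(href) == 273L,
            substr(et, 62, 62) == "E", substr(href, 112, 112) == "D",
            substr(href, 140, 140) == "H", substr(href, 193, 193) == "H",
            substr(et, 91, 91) == "K", substr(et, 142, 144) == "HHD",
            substr(et, 156, 162) == MOT, substr(href, 205, 211) == MOT,
            substr(npref, 66, 66) == "D")

  et_contaminant <- paste0(substr(et, 1, 161), "K", substr(et, 163, 236))
  et_sfD <- paste0(substr(et, 1, 61), "D", substr(et, 63, 236))

  list(
    et = protein_record("synthetic_EtHv1_like", et,
                        annotations = list(sf_position = 62,
                                           zinc_sites = c(91, 144),
                                           synthetic = TRUE)),
    href = protein_record("synthetic_hHv1_like_ref", href,
                          annotations = list(sf_position = 112,
                                             zinc_sites = c(140, 193),
                                             synthetic = TRUE)),
    npref = protein_record("synthetic_NpHv1_like_ref", npref,
                           annotations = list(sf_position = 66,
                                              synthetic = TRUE)),
    et_contaminant = protein_record("synthetic_fungal_like", et_contaminant,
                                    annotations = list(synthetic = TRUE)),
    et_sfD = protein_record("synthetic_sfD_variant", et_sfD,
                            annotations = list(synthetic = TRUE))
  )
}

# fixed codon map (no stop codons; chosen so the first seven codons of the
# synthetic ORF spell the published forward primer, and so that the
# reverse-primer footprint can be written in synonymously)
synth_codon_map <- c(
  A = "GCA", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGA",
  H = "CAT", I = "ATT", K = "AAG", L = "CTG", M = "ATG", N = "AAT",
  P = "CCA", Q = "CAG", R = "CGT", S = "AGC", T = "ACA", V = "GTG",
  W = "TGG", Y = "TAC")

#' Synthetic HV1-like transcript carrying the published primer pair
#'
#' Encodes the synthetic 236-residue query protein of
#' [synthetic_hv1_proteins()] into a transcript-like nucleotide sequence:
#' the open reading frame starts at the forward primer
#' `ATGGACAGCTGGAATGTGGA` and the reverse-primer footprint (reverse
#' complement of `CCATGTATGTACTGCGCTGC`) is written in synonymously so that
#' the primer pair delimits a 363-bp product, as in the published tissue
#' expression assay. Untranslated regions free of ATG (5') and long ORFs
#' (3') flank the coding sequence. This is a synthetic stand-in for the
#' transcriptome-assembly accession, not the real entry.
#'
#' @return a list: `sequence` (named nucleotide string), `orf_start`,
#'   `orf_end` (1-based, stop codon included), `fwd_primer`, `rev_primer`,
#'   `protein` (the encoded `hv_protein`).
#' @export
synthetic_hv1_transcript <- function() {
  prot <- synthetic_hv1_proteins()$et
  aa <- strsplit(prot$residues, "")[[1]]
  orf <- paste0(paste(synth_codon_map[aa], collapse = ""), "TAA")
  # synonymous overwrite of the reverse-primer footprint (ORF nt 343..363):
  # AGC AGC GCA GTA CAT ACA TGG encodes S S A V H T W, matching the protein
  rev_primer <- "CCATGTATGTACTGCGCTGC"
  site <- paste0("A", revcomp(rev_primer))  # 21 nt starting at ORF nt 343
  orf <- paste0(substr(orf, 1, 342), site, substr(orf, 364, nchar(orf)))
  fwd_primer <- "ATGGACAGCTGGAATGTGGA"
  stopifnot(substr(orf, 1, 20) == fwd_primer,
            as.character(Biostrings::translate(
      Biostrings::DNAString(substr(orf, 1, nchar(orf) - 3)))) == prot$residues)
  # UTRs: 5' free of ATG; 3' opens with stops in all three frames
  utr5 <- "GATCCTGTTAACTGACTAGCTAAGTTAGCTACCTAAGCTA"
  stopifnot(!grepl("ATG", paste0(utr5, "A")))
  utr3 <- "TAATTAGTTGACTAACCTAGCTGATCCTAGTTAACTGACCTAGCATCAGCTTAGCTGACC"
  seqs <- paste0(utr5, orf, utr3)
  names(seqs) <- "synthetic_EtHv1_like_transcript"
  list(sequence = seqs,
       orf_start = nchar(utr5) + 1L,
       orf_end = nchar(utr5) + nchar(orf),
       fwd_primer = fwd_primer, rev_primer = rev_primer,
       protein = prot)
}

#' Synthetic aligned S4 block for residue-frequency tables
#'
#' A deterministic alignment of `n` S4-region sequences (21 columns centred
#' on the voltage-sensor motif) in which the three sensor-arginine columns
#' and the conserved tryptophan are invariant while unconstrained columns
#' vary, emulating the input of a sequence-logo figure.
#'
#' @param n number of sequences (default 18).
#' @param seed RNG seed for the variable columns.
#' @return a character vector of aligned sequences; attribute
#'   `constrained_columns` gives the R/W column indices.
#' @export
synthetic_s4_alignment <- function(n = 18L, seed = 7L) {
  prots <- synthetic_hv1_proteins()
  base <- substr(prots$et$residues, 150, 170)  # motif at columns 7..13
  pool <- c("A","D","E","F","G","H","I","K","L","N","P","Q","S","T","V","Y")
  fixed_cols <- c(7L, 9L, 10L, 13L)            # R, W, R, R
  out <- with_seed(seed, vapply(seq_len(n), function(i) {
    ch <- strsplit(base, "")[[1]]
    vary <- setdiff(seq_along(ch), fixed_cols)
    flip <- sample(vary, size = sample(3:6, 1))
    ch[flip] <- sample(pool, length(flip), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1)))
  names(out) <- sprintf("synthetic_s4_%02d", seq_len(n))
  structure(out, constrained_columns = fixed_cols)
}
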