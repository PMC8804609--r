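# Sequence-screening rules for mining transcriptome assemblies for HV1
# homologs: S4 voltage-sensor motif scan, selectivity-filter classification
# by pairwise alignment to an annotated reference, zinc-site annotation,
# contamination flagging, residue-frequency tables, ORF translation and
# in-silico PCR. Coordinates are 1-based inclusive throughout, matching the
# field's residue numbering (e.g. D112, H140 in the human channel).

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                "R","S","T","V","W","Y","X")

#' Protein record
#'
#' @param id sequence identifier.
#' @param residues amino-acid string (20-letter alphabet plus X); coerced to
#'   upper case.
#' @param annotations optional named list of annotated positions, e.g.
#'   `list(sf_position = 112, zinc_sites = c(140, 193))`.
#' @return an `hv_protein`.
#' @export
protein_record <- function(id, residues, annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(gsub("\\s", "", paste(residues, collapse = "")))
  if (!nzchar(residues)) stop("empty protein sequence")
  bad <- setdiff(strsplit(residues, "")[[1]], AA_LETTERS)
  if (length(bad) > 0L)
    stop("invalid residue letters: ", paste(unique(bad), collapse = ", "))
  structure(list(id = id, residues = residues, annotations = annotations),
            class = "hv_protein")
}

#' @export
print.hv_protein <- function(x, ...) {
  cat(sprintf(">%s (%d aa)\n", x$id, nchar(x$residues)))
  if (length(x$annotations))
    cat("annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

as_protein <- function(x) {
  if (inherits(x, "hv_protein")) return(x)
  if (is.character(x) && length(x) == 1L) return(protein_record("query", x))
  stop("expected an hv_protein or a single protein string")
}

#' Scan for the S4 voltage-sensor motif
#'
#' Finds all (possibly overlapping) windows matching the HV1 voltage-sensor
#' signature R-x-W-R-x-x-\[RK\]: the three sensor arginines plus the
#' conserved tryptophan, with the third arginine relaxed to lysine so that
#' fungal-like variants (Arg3 -> Lys) are captured and can be flagged as
#' contamination. `X` never matches a constrained position.
#'
#' @param record an `hv_protein` or protein string.
#' @return a data frame with one row per hit: `start` (1-based), `matched`
#'   (the 7-residue window) and `terminal_residue` (`"R"` or `"K"`). Empty
#'   when there is no hit.
#' @examples
#' scan_voltage_sensor("AARLWRVGRAA")
#' @export
scan_voltage_sensor <- function(record) {
  rec <- as_protein(record)
  s <- rec$residues
  m <- gregexpr("(?=R[A-Z]WR[A-Z][A-Z][RK])", s, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), matched = character(0),
                      terminal_residue = character(0)))
  start <- as.integer(m)
  matched <- substring(s, start, start + 6L)
  data.frame(start = start, matched = matched,
             terminal_residue = substring(matched, 7L, 7L))
}

# Global affine-gap alignment of query against an annotated reference,
# returning the per-column characters. Score floor: 20% of the reference
# self-alignment score.
align_to_reference <- function(record, reference, score_floor_frac = 0.2) {
  rec <- as_protein(record)
  ref <- as_protein(reference)
  if (nchar(rec$residues) < 50L || nchar(ref$residues) < 50L)
    stop("both sequences must be at least 50 residues for reliable mapping")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(rec$residues),
    subject = Biostrings::AAString(ref$residues),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
  self <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(ref$residues),
    subject = Biostrings::AAString(ref$residues),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
  if (Biostrings::score(aln) < score_floor_frac * Biostrings::score(self))
    stop(sprintf("unalignable: alignment score %.1f below floor (%.1f)",
                 Biostrings::score(aln),
                 score_floor_frac * Biostrings::score(self)))
  qchars <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  rchars <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(query = qchars, ref = rchars,
       qpos = cumsum(qchars != "-"), rpos = cumsum(rchars != "-"))
}

# query residue (and 1-based query position) aligned to a reference position
mapped_column <- function(aln, ref_pos) {
  col <- which(aln$rpos == ref_pos & aln$ref != "-")
  if (length(col) != 1L) stop("reference position not covered by alignment")
  list(residue = aln$query[col],
       position = if (aln$query[col] == "-") NA_integer_ else aln$qpos[col])
}

#' Map the selectivity-filter position onto a query sequence
#'
#' Globally aligns the query to an annotated reference (BLOSUM62, affine
#' gaps) and reads the query residue in the column aligned to the
#' reference's selectivity-filter position. Most HV1 carry an aspartate
#' there (D112 in the human channel); phasmatodean channels carry a
#' glutamate. A gap at the mapped column yields class `non-acidic` with a
#' `gapped` note rather than an error.
#'
#' @param record query `hv_protein` (or string).
#' @param reference an `hv_protein` whose `annotations$sf_position` is set.
#' @param score_floor_frac alignments scoring below this fraction of the
#'   reference self-score are rejected as unalignable (default 0.2).
#' @return an `hv_sf_call`: `position` (1-based query position, NA when
#'   gapped), `residue`, `sf_class` (`"Asp"`, `"Glu"` or `"non-acidic"`),
#'   `gapped`, `reference_used`.
#' @export
map_sf_position <- function(record, reference, score_floor_frac = 0.2) {
  ref <- as_protein(reference)
  sf <- ref$annotations$sf_position
  if (is.null(sf)) stop("reference carries no sf_position annotation")
  aln <- align_to_reference(record, ref, score_floor_frac)
  mc <- mapped_column(aln, sf)
  cls <- switch(mc$residue, D = "Asp", E = "Glu", "non-acidic")
  structure(list(position = mc$position, residue = mc$residue,
                 sf_class = cls, gapped = identical(mc$residue, "-"),
                 reference_used = ref$id),
            class = "hv_sf_call")
}

#' @export
print.hv_sf_call <- function(x, ...) {
  cat(sprintf("SF call: %s at position %s (%s; reference %s)%s\n",
              x$residue, ifelse(is.na(x$position), "-", x$position),
              x$sf_class, x$reference_used,
              if (x$gapped) " [gapped]" else ""))
  invisible(x)
}

#' Annotate the two zinc-coordination sites of a query sequence
#'
#' Reads the query residues aligned to the reference's two external
#' zinc-binding positions (H140 and H193 in the human channel) and, to
#' expose His-His-Asp-type arrangements on the S3-S4 linker, also the two
#' query residues immediately preceding the second site.
#'
#' @param record query `hv_protein` (or string).
#' @param reference an `hv_protein` with `annotations$zinc_sites` of length 2.
#' @param score_floor_frac see [map_sf_position()].
#' @return a list: `first_site`, `second_site` (characters; `"-"` marks a
#'   gap), `positions` (query positions, NA when gapped), and
#'   `preceding_second` (the two query residues before the second site).
#' @export
annotate_zinc_sites <- function(record, reference, score_floor_frac = 0.2) {
  ref <- as_protein(reference)
  zs <- ref$annotations$zinc_sites
  if (is.null(zs) || length(zs) != 2L)
    stop("reference must annotate two zinc_sites")
  aln <- align_to_reference(record, ref, score_floor_frac)
  m1 <- mapped_column(aln, zs[1]); m2 <- mapped_column(aln, zs[2])
  rec <- as_protein(record)
  prec <- c(NA_character_, NA_character_)
  if (!is.na(m2$position) && m2$position >= 3L)
    prec <- strsplit(substring(rec$residues, m2$position - 2L,
                               m2$position - 1L), "")[[1]]
  list(first_site = m1$residue, second_site = m2$residue,
       positions = c(m1$position, m2$position),
       preceding_second = prec)
}

#' Apply the full HV1 screening rules to one sequence
#'
#' Combines the motif scan, the fungal-contamination rule and (when a
#' reference is supplied and alignable) the selectivity-filter and
#' zinc-site annotations. Verdicts: `pass` requires at least one motif hit
#' whose terminal residue is arginine; sequences whose only hits end in
#' lysine are `flagged_contaminant` (the fungal-like Arg3 -> Lys variant);
#' `fail_motif` otherwise.
#'
#' @param record query `hv_protein` (or string).
#' @param reference optional annotated reference for SF/zinc annotation.
#' @return an `hv_screen_result`: `record_id`, `motif_hits`, `sf_call`,
#'   `zinc_sites`, `fungal_flag`, `verdict`.
#' @export
classify_record <- function(record, reference = NULL) {
  rec <- as_protein(record)
  hits <- scan_voltage_sensor(rec)
  has_R <- any(hits$terminal_residue == "R")
  only_K <- nrow(hits) > 0L && all(hits$terminal_residue == "K")
  verdict <- if (has_R) "pass"
             else if (only_K) "flagged_contaminant"
             else "fail_motif"
  sf <- NULL; zn <- NULL
  if (!is.null(reference)) {
    sf <- tryCatch(map_sf_position(rec, reference), error = function(e) NULL)
    zn <- tryCatch(annotate_zinc_sites(rec, reference), error = function(e) NULL)
  }
  structure(list(record_id = rec$id, motif_hits = hits, sf_call = sf,
                 zinc_sites = zn, fungal_flag = only_K, verdict = verdict),
            class = "hv_screen_result")
}

#' @export
print.hv_screen_result <- function(x, ...) {
  cat(sprintf("%s: %s (%d motif hit%s%s)\n", x$record_id, x$verdict,
              nrow(x$motif_hits), if (nrow(x$motif_hits) == 1L) "" else "s",
              if (x$fungal_flag) ", fungal-like terminal K" else ""))
  if (!is.null(x$sf_call)) print(x$sf_call)
  invisible(x)
}

#' Per-position residue frequencies of an aligned block
#'
#' For a set of pre-aligned sequences of equal length (optionally restricted
#' to a column range), tabulates the frequency of each residue per column.
#' Frequencies are computed over non-gap characters and sum to 1 per column;
#' the gap fraction is tracked separately. This is the numerical content of
#' a sequence logo.
#'
#' @param records character vector (or `hv_protein` list) of aligned
#'   sequences, all the same length; `-` marks gaps.
#' @param region optional `c(start, end)` column range (1-based inclusive).
#' @return an `hv_freq_table`: `freq` (residues x columns matrix),
#'   `gap_fraction` (per column), `n_sequences`.
#' @export
position_frequency_table <- function(records, region = NULL) {
  seqs <- vapply(records, function(r)
    if (inherits(r, "hv_protein")) r$residues else as.character(r),
    character(1))
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged input: aligned sequences must share one length")
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] >= 1, region[2] <= nchar(seqs[1]))
    seqs <- substring(seqs, region[1], region[2])
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  ncol_ <- ncol(mat)
  letters_ <- sort(unique(c(AA_LETTERS, as.vector(mat[mat != "-"]))))
  freq <- matrix(0, nrow = length(letters_), ncol = ncol_,
                 dimnames = list(letters_, seq_len(ncol_)))
  gap_fraction <- numeric(ncol_)
  for (j in seq_len(ncol_)) {
    col <- mat[, j]
    gap_fraction[j] <- mean(col == "-")
    col <- col[col != "-"]
    if (length(col) == 0L) next
    tab <- table(col) / length(col)
    freq[names(tab), j] <- as.numeric(tab)
  }
  structure(list(freq = freq, gap_fraction = gap_fraction,
                 n_sequences = length(seqs)),
            class = "hv_freq_table")
}

#' @export
print.hv_freq_table <- function(x, ...) {
  cat(sprintf("Residue frequency table: %d sequences x %d columns\n",
              x$n_sequences, ncol(x$freq)))
  consensus <- rownames(x$freq)[apply(x$freq, 2, which.max)]
  cat("consensus:", paste(consensus, collapse = ""), "\n")
  invisible(x)
}

# ---- nucleotide operations -------------------------------------------------

clean_nt <- function(x) {
  x <- toupper(gsub("\\s", "", paste(x, collapse = "")))
  bad <- setdiff(strsplit(x, "")[[1]], c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L)
    stop("invalid nucleotide letters: ", paste(unique(bad), collapse = ", "))
  x
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Find and translate the longest open reading frame
#'
#' Searches both strands and all three frames for open reading frames
#' starting at ATG and ending at a stop codon, and translates the longest
#' one with the standard genetic code (ties broken by earliest start on the
#' forward strand). Needed to go from transcriptome assembly nucleotide
#' entries to protein screening.
#'
#' @param nucleotide_record nucleotide string (ACGT, N allowed but an ORF may
#'   not contain it) or a named character of length 1.
#' @param min_nt minimum ORF length in nucleotides including the stop codon
#'   (default 150).
#' @return an `hv_protein` whose annotations record `strand`, `start`, `end`
#'   (1-based coordinates of the ORF, stop codon included, on the input
#'   sequence).
#' @examples
#' find_orf_translate("ATGAAATAA", min_nt = 9)  # protein "MK"
#' @export
find_orf_translate <- function(nucleotide_record, min_nt = 150L) {
  id <- if (!is.null(names(nucleotide_record))) names(nucleotide_record)[1] else "orf"
  s <- clean_nt(nucleotide_record)
  n <- nchar(s)
  best <- NULL
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3
      if (ncod < 2L) next
      codons <- substring(seqs, frame + 1L + 3L * (seq_len(ncod) - 1L),
                          frame + 3L * seq_len(ncod))
      stops <- which(codons %in% c("TAA", "TAG", "TGA"))
      starts <- which(codons == "ATG")
      if (length(stops) == 0L || length(starts) == 0L) next
      for (st in starts) {
        nxt <- stops[stops > st]
        if (length(nxt) == 0L) next
        sp <- nxt[1L]
        len_nt <- (sp - st + 1L) * 3L
        if (len_nt < min_nt) next
        cand <- list(strand = strand, frame = frame, start_codon = st,
                     stop_codon = sp, len_nt = len_nt)
        better <- is.null(best) || len_nt > best$len_nt ||
          (len_nt == best$len_nt && best$strand == "-" && strand == "+") ||
          (len_nt == best$len_nt && best$strand == strand && strand == "+" &&
             st < best$start_codon)
        if (better) best <- cand
      }
    }
  }
  if (is.null(best))
    stop(sprintf("no open reading frame of at least %d nt found", min_nt))
  seqs <- if (best$strand == "+") s else revcomp(s)
  from <- best$frame + 1L + 3L * (best$start_codon - 1L)
  to <- best$frame + 3L * best$stop_codon
  orf_nt <- substring(seqs, from, to)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf_nt)))
  aa <- sub("\\*$", "", aa)
  start <- if (best$strand == "+") from else n - to + 1L
  end <- if (best$strand == "+") to else n - from + 1L
  protein_record(id, aa,
                 annotations = list(strand = best$strand, start = start,
                                    end = end))
}

#' In-silico PCR on a nucleotide template
#'
#' Matches the forward primer on the given strand and the reverse primer as
#' its reverse complement downstream; every compatible pair yields a
#' product whose length includes both primer footprints. Exact-match
#' semantics by default (primers designed against the same transcript); an
#' optional mismatch tolerance is available.
#'
#' @param template_nt nucleotide template string.
#' @param fwd_primer,rev_primer primer sequences, at least 15 nt, written
#'   5'->3' as ordered (the reverse primer anneals to the given strand as
#'   its reverse complement).
#' @param max_mismatch mismatch tolerance per primer (default 0).
#' @return an `hv_amplicons` data frame (possibly 0-row = no amplicon, not
#'   an error): `start`, `end` (1-based inclusive template coordinates),
#'   `length_bp`, `fwd_match_pos`, `rev_match_pos`; sorted shortest first.
#' @export
insilico_pcr <- function(template_nt, fwd_primer, rev_primer,
                         max_mismatch = 0L) {
  s <- clean_nt(template_nt)
  fwd <- clean_nt(fwd_primer); rev_ <- clean_nt(rev_primer)
  if (nchar(fwd) < 15L || nchar(rev_) < 15L)
    stop("primers must be at least 15 nt")
  subj <- Biostrings::DNAString(s)
  fhits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(fwd), subj, max.mismatch = max_mismatch))
  rhits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(revcomp(rev_)), subj, max.mismatch = max_mismatch))
  out <- data.frame(start = integer(0), end = integer(0),
                    length_bp = integer(0), fwd_match_pos = integer(0),
                    rev_match_pos = integer(0))
  for (f in fhits) {
    for (r in rhits) {
      if (r >= f + nchar(fwd)) {
        end <- r + nchar(rev_) - 1L
        out <- rbind(out, data.frame(start = f, end = end,
                                     length_bp = end - f + 1L,
                                     fwd_match_pos = f, rev_match_pos = r))
      }
    }
  }
  out <- out[order(out$length_bp), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hv_amplicons", "data.frame"))
}

#' @export
print.hv_amplicons <- function(x, ...) {
  if (nrow(x) == 0L) cat("no amplicon\n")
  else {
    cat(sprintf("%d amplicon(s), shortest first:\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean hydropathy (window 19, threshold 1.6 in the classic
#' transmembrane-detection parameterisation). Provided as a descriptive
#' helper for counting candidate transmembrane segments; it plays no part in
#' the screening verdict, which rests on the motif and alignment rules.
#'
#' @param record an `hv_protein` or protein string (no X within windows
#'   contributing to segment calls; X is assigned hydropathy 0).
#' @param window odd window length (default 19).
#' @param threshold segment-call threshold on the window mean (default 1.6).
#' @return a list: `profile` (window-centre positions and mean hydropathy)
#'   and `segments` (data frame of maximal runs above threshold).
#' @export
kyte_doolittle <- function(record, window = 19L, threshold = 1.6) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2, X = 0)
  rec <- as_protein(record)
  vals <- kd[strsplit(rec$residues, "")[[1]]]
  if (length(vals) < window) stop("sequence shorter than the window")
  prof <- stats::filter(vals, rep(1 / window, window), sides = 2)
  centre <- which(!is.na(prof))
  prof <- as.numeric(prof[centre])
  above <- prof > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- data.frame(start = centre[starts[r$values]],
                     end = centre[ends[r$values]])
  list(profile = data.frame(position = centre, hydropathy = prof),
       segments = segs)
}

# ---- FASTA I/O -------------------------------------------------------------

#' Read and write FASTA with optional annotation sidecars
#'
#' Thin wrappers around Biostrings' FASTA readers returning the package's
#' record types. `read_protein_fasta()` attaches annotations from a JSON
#' sidecar (`<file>.json`, a named list keyed by record id) when present.
#'
#' @param path FASTA file path.
#' @return a list of `hv_protein` (protein reader) or a named character
#'   vector of nucleotide sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  sidecar <- paste0(path, ".json")
  ann <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
         else list()
  ids <- sub("\\s.*$", "", names(aa))
  out <- lapply(seq_along(aa), function(i) {
    a <- if (ids[i] %in% names(ann)) as.list(ann[[ids[i]]]) else list()
    protein_record(ids[i], as.character(aa[[i]]), annotations = a)
  })
  names(out) <- ids
  out
}

#' @rdname read_protein_fasta
#' @export
read_nucleotide_fasta <- function(path) {
  nt <- Biostrings::readDNAStringSet(path)
  out <- vapply(seq_along(nt), function(i) as.character(nt[[i]]), character(1))
  names(out) <- sub("\\s.*$", "", names(nt))
  out
}

#' @rdname read_protein_fasta
#' @param records named character vector or list of `hv_protein`.
#' @param annotations optional named list written to the JSON sidecar.
#' @export
write_fasta <- function(records, path, annotations = NULL) {
  if (is.list(records) && all(vapply(records, inherits, logical(1), "hv_protein"))) {
    seqs <- vapply(records, `[[`, character(1), "residues")
    names(seqs) <- vapply(records, `[[`, character(1), "id")
    ann <- lapply(records, `[[`, "annotations")
    names(ann) <- names(seqs)
    ann <- Filter(function(a) length(a) > 0, ann)
    if (is.null(annotations) && length(ann) > 0) annotations <- ann
  } else {
    seqs <- unlist(records)
  }
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  if (!is.null(annotations) && length(annotations) > 0)
    jsonlite::write_json(annotations, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
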