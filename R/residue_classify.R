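# Diagnostic-residue classification: map candidate proteins onto
# reference-numbered positions by global alignment, call the PEBP clade
# (FT/TFL1/MFT-like), predict FT inducer/repressor function from the
# exon-IV external-loop residues, and scan the segment-B motif and LYN
# triad.

#' Map a candidate protein onto reference numbering
#'
#' Global alignment (BLOSUM62, gap open 10 / extend 1) of the candidate
#' against a numbered reference; every reference position projects onto a
#' candidate position (or a gap). An alignment identity below 25% is
#' rejected as not a PEBP candidate.
#'
#' @param candidate candidate protein (length >= 100).
#' @param reference reference protein (length >= 100).
#' @param reference_id label for the numbering ("ft" or "tfl1").
#' @return list (class `residue_map`): reference_id, identity, and
#'   `mapping` data.frame (ref_pos, ref_aa, cand_pos, cand_aa; gaps are NA).
#' @export
map_to_reference <- function(candidate, reference, reference_id = "ft") {
  stopifnot(nchar(candidate) >= 100L, nchar(reference) >= 100L)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(reference), Biostrings::AAString(candidate),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
  r <- str_chars(as.character(Biostrings::alignedPattern(pa)))
  c_ <- str_chars(as.character(Biostrings::alignedSubject(pa)))
  identity <- mean(r == c_) * 100
  if (identity < 25) stop("not a PEBP candidate (alignment identity < 25%)")
  ref_pos <- cumsum(r != "-")
  cand_pos <- cumsum(c_ != "-")
  keep <- r != "-"
  mapping <- data.frame(
    ref_pos = ref_pos[keep],
    ref_aa = r[keep],
    cand_pos = ifelse(c_[keep] == "-", NA_integer_, cand_pos[keep]),
    cand_aa = ifelse(c_[keep] == "-", NA_character_, c_[keep]),
    stringsAsFactors = FALSE)
  structure(list(reference_id = reference_id, identity = identity,
                 mapping = mapping),
            class = "residue_map")
}

# residue observed at a reference position (NA for gap)
.residue_at <- function(map, ref_pos) {
  row <- map$mapping[map$mapping$ref_pos == ref_pos, ]
  if (nrow(row) == 0L) NA_character_ else row$cand_aa
}

.candidate_pos_at <- function(map, ref_pos) {
  row <- map$mapping[map$mapping$ref_pos == ref_pos, ]
  if (nrow(row) == 0L) NA_integer_ else row$cand_pos
}

#' Call the PEBP clade from mapped diagnostic residues
#'
#' The candidate is mapped against both the FT-numbered and TFL1-numbered
#' references; the higher-identity mapping provides the clade-diagnostic
#' position (85 on FT numbering, 88 on TFL1 numbering). Tyr there calls
#' FT-like, His calls TFL1-like, Trp calls MFT-like; anything else (or a
#' gap) is unclassified. The supporting position (Gln140 on FT numbering /
#' Asp144 on TFL1 numbering) is recorded as supporting or conflicting
#' evidence. Mappings whose identities differ by less than 2 points are
#' flagged `close_reference_identities`.
#'
#' @param candidate candidate protein.
#' @param refs references from [pebp_references()] (or compatible).
#' @return list: clade, evidence data.frame (position, expected, observed),
#'   maps (ft, tfl1), flags.
#' @export
call_clade <- function(candidate, refs = pebp_references()) {
  numbering <- attr(refs, "numbering")
  map_ft <- map_to_reference(candidate, refs$ft, "ft")
  map_tfl1 <- map_to_reference(candidate, refs$tfl1, "tfl1")
  flags <- character(0)
  if (abs(map_ft$identity - map_tfl1$identity) < 2) {
    flags <- c(flags, "close_reference_identities")
  }
  use <- if (map_ft$identity >= map_tfl1$identity) "ft" else "tfl1"
  map <- if (use == "ft") map_ft else map_tfl1
  num <- numbering[[use]]
  obs <- .residue_at(map, num$clade_pos)
  if (is.na(obs)) {
    clade <- "unclassified"
    reason <- "gap at clade-diagnostic position"
  } else {
    clade <- switch(obs, Y = "FT-like", H = "TFL1-like", W = "MFT-like",
                    "unclassified")
    reason <- NA_character_
  }
  support_obs <- .residue_at(map, num$support_pos)
  evidence <- data.frame(
    position = c(num$clade_pos, num$support_pos),
    numbering = use,
    expected = c("Y/H/W", num$support_aa),
    observed = c(obs, support_obs),
    stringsAsFactors = FALSE)
  if (!is.na(support_obs) && support_obs != num$support_aa) {
    flags <- c(flags, "support_residue_conflict")
  }
  list(clade = clade, evidence = evidence, reason = reason,
       maps = list(ft = map_ft, tfl1 = map_tfl1), flags = flags)
}

#' Predict FT inducer/repressor function from the external-loop residues
#'
#' For an FT-like candidate mapped on FT numbering: Tyr134 together with
#' Trp138 calls an inducer; a non-Tyr at 134 or non-Trp at 138 calls
#' repressor-like; a change at Gly137 alone (with 134/138 intact) keeps the
#' inducer call with a `G137_variant` note, since changes at that position
#' do not confer repressive activity. Glu109, Gln140 and Asn152 states are
#' recorded as annotations only. A gap at 134 or 138 is indeterminate.
#'
#' @param map FT-numbered [map_to_reference()] result.
#' @return list (class `function_call`): ft_function, notes, evidence
#'   data.frame.
#' @export
call_ft_function <- function(map) {
  stopifnot(identical(map$reference_id, "ft"))
  r134 <- .residue_at(map, 134L)
  r137 <- .residue_at(map, 137L)
  r138 <- .residue_at(map, 138L)
  notes <- character(0)
  if (is.na(r134) || is.na(r138)) {
    verdict <- "indeterminate"
  } else if (r134 == "Y" && r138 == "W") {
    verdict <- "inducer"
    if (!is.na(r137) && r137 != "G") notes <- c(notes, "G137_variant")
  } else {
    verdict <- "repressor-like"
  }
  ann_pos <- c(109L, 140L, 152L)
  ann_exp <- c("E", "Q", "N")
  evidence <- data.frame(
    position = c(134L, 137L, 138L, ann_pos),
    expected = c("Y", "G", "W", ann_exp),
    observed = c(r134, r137, r138,
                 vapply(ann_pos, function(p) .residue_at(map, p), character(1))),
    role = c("decisive", "note", "decisive", rep("annotation", 3L)),
    stringsAsFactors = FALSE)
  structure(list(ft_function = verdict, notes = notes, evidence = evidence),
            class = "function_call")
}

#' Scan the segment-B motif and the LYN triad
#'
#' Extracts the segment-B window (reference positions 128-141 on FT
#' numbering) through the residue map, counts mismatches against
#' `LGRQTVYAPGWRQN`, and reports the observed triad 3-mer (LYN expected).
#' An unmappable window is reported as absent.
#'
#' @param map FT-numbered [map_to_reference()] result.
#' @param refs references (for the numbering metadata).
#' @return list: segmentB_observed, segmentB_mismatches (NA if absent),
#'   triad (3-mer or NA), present.
#' @export
scan_motifs <- function(map, refs = pebp_references()) {
  stopifnot(identical(map$reference_id, "ft"))
  num <- attr(refs, "numbering")$ft
  win <- vapply(num$segmentB, function(p) {
    r <- .residue_at(map, p)
    if (is.na(r)) "-" else r
  }, character(1))
  present <- any(win != "-")
  expected <- str_chars(SEGMENT_B)
  mism <- if (present) sum(win != expected) else NA_integer_
  triad <- vapply(num$triad, function(p) {
    r <- .residue_at(map, p)
    if (is.na(r)) "-" else r
  }, character(1))
  triad_str <- if (all(triad == "-")) NA_character_ else paste(triad, collapse = "")
  list(segmentB_observed = paste(win, collapse = ""),
       segmentB_mismatches = mism, triad = triad_str, present = present)
}

#' Classify one candidate protein end to end
#'
#' Clade call, FT function call (FT-like candidates only; `n/a` otherwise)
#' and motif scan in one record.
#'
#' @param candidate candidate protein.
#' @param refs references from [pebp_references()].
#' @return list: clade, ft_function, notes, motif, evidence, flags.
#' @export
classify_protein <- function(candidate, refs = pebp_references()) {
  cl <- call_clade(candidate, refs)
  motif <- scan_motifs(cl$maps$ft, refs)
  if (cl$clade == "FT-like") {
    fc <- call_ft_function(cl$maps$ft)
    ft_function <- fc$ft_function
    notes <- fc$notes
    evidence <- fc$evidence
  } else {
    ft_function <- "n/a"
    notes <- character(0)
    evidence <- NULL
  }
  list(clade = cl$clade, ft_function = ft_function, notes = notes,
       motif = motif, clade_evidence = cl$evidence,
       function_evidence = evidence, flags = cl$flags)
}
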