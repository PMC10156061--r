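# Allele-pair variant calling and annotation: global allele alignment,
# substitution/deletion calling with exon/intron placement, coding-effect
# classification (synonymous / non-synonymous / stop-gained), CDS-to-protein
# position mapping, and upstream promoter repeat scanning.

#' Globally align two alleles
#'
#' Needleman-Wunsch with match +2 / mismatch -3 / gap open -5 / gap extend
#' -2. Gap runs are post-processed to their leftmost equivalent placement so
#' deletion calls are canonical. The alignment reconstructs both inputs.
#'
#' @param allele1,allele2 DNA strings (non-empty).
#' @return list (class `allele_alignment`): a1, a2 (gapped rows), score.
#' @export
align_alleles <- function(allele1, allele2) {
  if (!nzchar(allele1) || !nzchar(allele2)) stop("empty allele sequence")
  al <- align_dna_global(allele1, allele2)
  shifted <- .left_shift_gaps(al$a, al$b)
  shifted <- rev(.left_shift_gaps(shifted[[2L]], shifted[[1L]]))
  structure(list(a1 = shifted[[1L]], a2 = shifted[[2L]], score = al$score),
            class = "allele_alignment")
}

# shift every gap run in row `b` to its leftmost equivalent position
# (row `a` unchanged semantics: gaps move when the flanking bases match)
.left_shift_gaps <- function(a, b) {
  ca <- str_chars(a); cb <- str_chars(b)
  n <- length(cb)
  i <- 2L
  while (i <= n) {
    if (cb[i] == "-" && cb[i - 1L] != "-") {
      j <- i
      while (j < n && cb[j + 1L] == "-") j <- j + 1L
      # run [i..j]; shift left while the base entering from the right
      # equals the base leaving on the left
      while (i > 1L && cb[i - 1L] != "-" && ca[i - 1L] == ca[j] &&
             cb[i - 1L] == ca[j]) {
        cb[j] <- cb[i - 1L]
        cb[i - 1L] <- "-"
        i <- i - 1L; j <- j - 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(paste(ca, collapse = ""), paste(cb, collapse = ""))
}

# exon/intron region of a gene-local position, using the model's exons;
# returns list(region, cds_pos (NA for introns), index)
.locate_region <- function(model, gene_pos) {
  ex <- model$exons
  lens <- ex[, 2L] - ex[, 1L] + 1L
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  for (i in seq_len(nrow(ex))) {
    if (gene_pos >= ex[i, 1L] && gene_pos <= ex[i, 2L]) {
      return(list(region = sprintf("exon%d", i),
                  cds_pos = offsets[i] + (gene_pos - ex[i, 1L]) + 1L,
                  index = i, type = "exon"))
    }
    if (i < nrow(ex) && gene_pos > ex[i, 2L] && gene_pos < ex[i + 1L, 1L]) {
      return(list(region = sprintf("intron%d", i), cds_pos = NA_integer_,
                  index = i, type = "intron"))
    }
  }
  list(region = "flank", cds_pos = NA_integer_, index = NA_integer_,
       type = "flank")
}

#' Call variants between an aligned allele pair
#'
#' Each mismatch column becomes a substitution; each maximal gap run in
#' allele 2 becomes one deletion of that length (multi-base gaps are a
#' single event; adjacent variants are never merged). Every variant is
#' placed in its exon or intron by the gene model's intervals; exonic
#' substitutions are annotated with CDS position, protein position and
#' coding effect by comparing the two coding sequences.
#'
#' @param alignment an [align_alleles()] result.
#' @param model gene-local [gene_model()] for allele 1.
#' @return data.frame: pos_gene, pos_cds, kind, ref, alt, region, effect,
#'   aa_ref, aa_pos, aa_alt.
#' @export
call_variants <- function(alignment, model) {
  stopifnot(inherits(alignment, "allele_alignment"))
  ca <- str_chars(alignment$a1); cb <- str_chars(alignment$a2)
  a1 <- gsub("-", "", alignment$a1, fixed = TRUE)
  if (nchar(a1) != max(model$exons[, 2L]) &&
      nchar(a1) < max(model$exons[, 2L])) {
    stop("alignment inconsistent with model length")
  }
  pos1 <- cumsum(ca != "-") # allele-1 coordinate per column
  rows <- list()
  i <- 1L
  n <- length(ca)
  while (i <= n) {
    if (ca[i] != "-" && cb[i] != "-" && ca[i] != cb[i]) {
      rows[[length(rows) + 1L]] <- list(pos = pos1[i], kind = "substitution",
                                        ref = ca[i], alt = cb[i])
      i <- i + 1L
    } else if (cb[i] == "-" && ca[i] != "-") {
      j <- i
      while (j < n && cb[j + 1L] == "-" && ca[j + 1L] != "-") j <- j + 1L
      rows[[length(rows) + 1L]] <- list(
        pos = pos1[i], kind = "deletion",
        ref = paste(ca[i:j], collapse = ""), alt = "")
      i <- j + 1L
    } else if (ca[i] == "-" && cb[i] != "-") {
      j <- i
      while (j < n && ca[j + 1L] == "-" && cb[j + 1L] != "-") j <- j + 1L
      rows[[length(rows) + 1L]] <- list(
        pos = pos1[i], kind = "insertion", ref = "",
        alt = paste(cb[i:j], collapse = ""))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- data.frame(pos_gene = integer(0), pos_cds = integer(0),
                    kind = character(0), ref = character(0),
                    alt = character(0), region = character(0),
                    effect = character(0), aa_ref = character(0),
                    aa_pos = integer(0), aa_alt = character(0),
                    stringsAsFactors = FALSE)
  if (!length(rows)) return(out)
  # coding sequences of both alleles for effect annotation
  cds1 <- model$cds
  exon_subs <- list()
  located <- lapply(rows, function(r) .locate_region(model, r$pos))
  cds2 <- cds1
  for (k in seq_along(rows)) {
    r <- rows[[k]]; loc <- located[[k]]
    if (loc$type == "exon" && r$kind == "substitution") {
      cds2 <- paste0(substr(cds2, 1L, loc$cds_pos - 1L), r$alt,
                     substr(cds2, loc$cds_pos + 1L, nchar(cds2)))
    }
  }
  for (k in seq_along(rows)) {
    r <- rows[[k]]; loc <- located[[k]]
    if (loc$type != "exon") {
      eff <- "non-coding"; aa <- list(NA_character_, NA_integer_, NA_character_)
    } else if (r$kind == "substitution") {
      ann <- annotate_effect(loc$cds_pos, r$ref, r$alt, cds1, cds2)
      eff <- ann$effect
      aa <- list(ann$aa_ref, ann$aa_pos, ann$aa_alt)
    } else {
      eff <- "frameshift/indel"
      aa <- list(NA_character_, NA_integer_, NA_character_)
    }
    out[nrow(out) + 1L, ] <- list(r$pos, loc$cds_pos, r$kind, r$ref, r$alt,
                                  loc$region, eff, aa[[1L]], aa[[2L]],
                                  aa[[3L]])
  }
  out
}

#' Map a CDS nucleotide position to a protein position
#'
#' @param nt_pos 1-based CDS position(s).
#' @return ceiling(nt_pos / 3).
#' @export
map_cds_to_protein_position <- function(nt_pos) {
  if (any(nt_pos < 1L)) stop("CDS position must be >= 1")
  as.integer(ceiling(nt_pos / 3))
}

#' Annotate the coding effect of an exonic substitution
#'
#' The codons containing the position are translated in both alleles: same
#' amino acid is synonymous, a different one non-synonymous, and an
#' alternate stop codon is stop-gained.
#'
#' @param cds_pos 1-based CDS position of the substitution.
#' @param ref,alt the substituted bases (checked against the CDSs).
#' @param cds1,cds2 the two full coding sequences.
#' @return list: effect, aa_ref, aa_pos, aa_alt.
#' @export
annotate_effect <- function(cds_pos, ref, alt, cds1, cds2) {
  stopifnot(substr(cds1, cds_pos, cds_pos) == ref,
            substr(cds2, cds_pos, cds_pos) == alt)
  aa_pos <- map_cds_to_protein_position(cds_pos)
  c1 <- substr(cds1, 3L * aa_pos - 2L, 3L * aa_pos)
  c2 <- substr(cds2, 3L * aa_pos - 2L, 3L * aa_pos)
  aa1 <- translate_dna(c1); aa2 <- translate_dna(c2)
  effect <- if (aa2 == "*" && aa1 != "*") {
    "stop-gained"
  } else if (aa1 == aa2) "synonymous" else "non-synonymous"
  list(effect = effect, aa_ref = aa1, aa_pos = aa_pos, aa_alt = aa2)
}

#' Extract the upstream (putative promoter) region of a gene
#'
#' Returns up to `window` bp 5' of the start codon on the coding strand;
#' position -k of the result is k bases before the A of ATG. Truncation at
#' the scaffold edge is flagged; a gene with zero upstream bases is an
#' error.
#'
#' @param model genomic [gene_model()].
#' @param scaffold scaffold sequence (named character).
#' @param window window size in bp (default 8000).
#' @return list: seq (coding-strand upstream, 5'->3'), length, truncated.
#' @export
extract_upstream <- function(model, scaffold, window = 8000L) {
  seq <- unname(scaffold[1L])
  if (model$strand == "+") {
    atg <- min(model$exons[, 1L])
    lo <- max(1L, atg - window)
    if (atg - 1L < lo) stop("gene at scaffold edge with zero upstream")
    up <- substr(seq, lo, atg - 1L)
    truncated <- lo > atg - window
  } else {
    atg <- max(model$exons[, 2L])
    hi <- min(nchar(seq), atg + window)
    if (atg + 1L > hi) stop("gene at scaffold edge with zero upstream")
    up <- revcomp(substr(seq, atg + 1L, hi))
    truncated <- hi < atg + window
  }
  list(seq = up, length = nchar(up), truncated = truncated)
}

#' Scan an upstream window for repeat/transposon insertions
#'
#' Local alignment of each repeat-library entry against the window; hits of
#' at least `min_len` bp and `min_identity` percent identity are reported
#' with ATG-relative coordinates (near/far, both negative) and span
#' |far| - |near|.
#'
#' @param upstream result of [extract_upstream()] (or a character window).
#' @param repeat_library named character vector of repeat sequences.
#' @param min_len minimum aligned length in bp (default 200).
#' @param min_identity minimum percent identity (default 70).
#' @return data.frame: repeat_id, near, far, span, identity.
#' @export
scan_promoter_repeats <- function(upstream, repeat_library, min_len = 200L,
                                  min_identity = 70) {
  if (is.list(upstream)) upstream <- upstream$seq
  out <- data.frame(repeat_id = character(0), near = integer(0),
                    far = integer(0), span = integer(0),
                    identity = numeric(0), stringsAsFactors = FALSE)
  if (length(repeat_library) == 0L) {
    warning("empty repeat library")
    return(out)
  }
  W <- nchar(upstream)
  for (rid in names(repeat_library)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(repeat_library[[rid]]),
      Biostrings::DNAString(upstream), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    s <- Biostrings::start(Biostrings::subject(pa))
    e <- Biostrings::end(Biostrings::subject(pa))
    if (e - s + 1L < min_len) next
    p <- str_chars(as.character(Biostrings::alignedPattern(pa)))
    q <- str_chars(as.character(Biostrings::alignedSubject(pa)))
    ident <- mean(p == q) * 100
    if (ident < min_identity) next
    near <- -(W - e + 1L)
    far <- -(W - s + 1L)
    out[nrow(out) + 1L, ] <- list(rid, near, far, abs(far) - abs(near), ident)
  }
  out
}
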