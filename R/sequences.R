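# Low-level sequence helpers shared by all modules. Sequences are plain
# uppercase character strings; sets of sequences are named character vectors.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA string
#'
#' @param x character string over A/C/G/T/N.
#' @return the reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Translate a DNA string codon by codon
#'
#' Standard genetic code; stop codons render `*`; any codon containing a
#' non-ACGT character renders `X`. The trailing partial codon, if any, is
#' dropped.
#'
#' @param dna DNA string.
#' @return amino-acid string (possibly containing `*`).
#' @export
translate_dna <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# split a string into single characters
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# substring by inclusive 1-based interval
subseq_chr <- function(x, start, end) substr(x, start, end)

.mat_cache <- new.env(parent = emptyenv())

# cached nucleotide substitution matrix (explicit, to avoid the slow
# quality-based default scoring of pairwiseAlignment)
nuc_mat <- function(match = 2, mismatch = -3) {
  key <- sprintf("m%dx%d", match, mismatch)
  if (is.null(.mat_cache[[key]])) {
    .mat_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE)
  }
  .mat_cache[[key]]
}

# global DNA alignment with edit-style scoring; returns the two gapped rows
align_dna_global <- function(a, b, match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = nuc_mat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

# percent identity (0-100) of a global DNA alignment;
# identity = matches / alignment length (gap columns count against identity)
global_identity <- function(a, b) {
  al <- align_dna_global(a, b)
  mean(str_chars(al$a) == str_chars(al$b)) * 100
}

# run an expression with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) withr::with_seed(seed, expr)
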