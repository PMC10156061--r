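# Readers and writers for the plain-text formats the pipeline touches:
# FASTA/FASTQ sequence sets, GFF3 gene models, minimal VCF 4.2 + TSV variant
# reports, and a flat YAML run configuration. All emitted genomic coordinates
# are 1-based inclusive.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; names are the first whitespace-delimited token
#' of each header, with the remainder kept in the `descriptions` attribute.
#' Duplicate ids are an error.
#'
#' @param path FASTA file.
#' @param strict error on an empty file (default TRUE).
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L && strict) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (any(ids == "")) stop("malformed FASTA header (empty id)")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(set))
  names(out) <- ids
  attr(out, "descriptions") <- stats::setNames(desc, ids)
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file (sequences only) into a named character vector
#'
#' @param path FASTQ file.
#' @return named character vector of uppercased read sequences.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write gene models as GFF3
#'
#' Emits one gene, one mRNA, and paired exon/CDS features per model, with
#' 1-based inclusive coordinates. The output round-trips losslessly through
#' [read_gene_models()].
#'
#' @param models list of gene models (see [gene_model()]).
#' @param path output file.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    stopifnot(inherits(m, "gene_model"))
    ex <- m$exons
    g1 <- min(ex[, 1L]); g2 <- max(ex[, 2L])
    gid <- m$locus_id
    lines <- c(lines,
      paste(m$scaffold_id, "pebpminer", "gene", g1, g2, ".", m$strand, ".",
            sprintf("ID=%s", gid), sep = "\t"),
      paste(m$scaffold_id, "pebpminer", "mRNA", g1, g2, ".", m$strand, ".",
            sprintf("ID=%s.t1;Parent=%s", gid, gid), sep = "\t"))
    # CDS phase: cumulative coding bases before each exon in splice order
    ord <- if (m$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    lens <- ex[, 2L] - ex[, 1L] + 1L
    phase <- integer(nrow(ex))
    cum <- 0L
    for (i in ord) {
      phase[i] <- (3L - (cum %% 3L)) %% 3L
      cum <- cum + lens[i]
    }
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines,
        paste(m$scaffold_id, "pebpminer", "exon", ex[i, 1L], ex[i, 2L], ".",
              m$strand, ".",
              sprintf("ID=%s.exon%d;Parent=%s.t1", gid, i, gid), sep = "\t"),
        paste(m$scaffold_id, "pebpminer", "CDS", ex[i, 1L], ex[i, 2L], ".",
              m$strand, phase[i],
              sprintf("ID=%s.cds;Parent=%s.t1", gid, gid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file written by [write_gene_models()]
#'
#' Exon intervals, strand, scaffold and locus ids are recovered; sequence
#' fields (`cds`, `protein`) are not stored in GFF3 and come back `NA`.
#'
#' @param path GFF3 file.
#' @return list of gene models.
#' @export
read_gene_models <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(raw) == 0L) return(list())
  f <- do.call(rbind, strsplit(raw, "\t", fixed = TRUE))
  df <- data.frame(seqid = f[, 1L], type = f[, 3L],
                   start = as.integer(f[, 4L]), end = as.integer(f[, 5L]),
                   strand = f[, 7L], attr = f[, 9L],
                   stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", ]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- sub("^ID=", "", genes$attr[i])
    ex <- df[df$type == "exon" &
             grepl(sprintf("Parent=%s.t1", gid), df$attr, fixed = TRUE), ]
    ex <- ex[order(ex$start), ]
    out[[i]] <- gene_model(
      locus_id = gid, scaffold_id = genes$seqid[i], strand = genes$strand[i],
      exons = cbind(start = ex$start, end = ex$end),
      cds = NA_character_, protein = NA_character_, validate = FALSE)
  }
  out
}

#' Write variants between one named allele pair as minimal VCF 4.2 plus TSV
#'
#' Deletions are left-aligned and VCF-anchored (the REF field carries the
#' base before the deleted run). The companion TSV keeps the region and
#' coding-effect columns that VCF does not model.
#'
#' @param variants variant data frame from [call_variants()].
#' @param locus_id CHROM value (the allele-pair locus name).
#' @param path output VCF path; the TSV is written next to it with a
#'   `.tsv` extension.
#' @param allele1 allele-1 sequence, used to left-anchor deletions.
#' @export
write_variants <- function(variants, locus_id, path, allele1) {
  if (nrow(variants) > 0 &&
      any(variants$pos_gene > nchar(allele1) | variants$pos_gene < 1L)) {
    stop("variant position outside allele length")
  }
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", locus_id, nchar(allele1)),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(variants) > 0) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (v$kind == "substitution") {
        pos <- v$pos_gene; ref <- v$ref; alt <- v$alt
      } else { # deletion: anchor on the base before the deleted run
        if (v$pos_gene == 1L) stop("cannot anchor deletion at position 1")
        pos <- v$pos_gene - 1L
        anchor <- substr(allele1, pos, pos)
        ref <- paste0(anchor, v$ref)
        alt <- anchor
      }
      rows <- c(rows, paste(locus_id, pos, ".", ref, alt, ".", "PASS",
                            sprintf("REGION=%s;EFFECT=%s", v$region, v$effect),
                            sep = "\t"))
    }
  }
  writeLines(c(header, rows), path)
  tsv_path <- sub("\\.vcf$", ".tsv", path)
  if (identical(tsv_path, path)) tsv_path <- paste0(path, ".tsv")
  utils::write.table(variants, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Documented defaults for every tunable threshold in the pipeline.
#' @return named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    min_identity = 40,        # homology search, percent
    min_score = 60,           # homology search, BLOSUM62 units
    seed_k = 4L,              # protein k-mer seed length
    max_gap = 5000L,          # hit-to-locus merge distance, bp
    barcode_max_edits = 2L,   # demultiplexing, per barcode end
    identity_threshold = 0.995, # allele clustering admission
    min_fraction = 0.2,       # minimum allele amplicon fraction
    min_reads = 10L,          # minimum reads to phase a locus
    bootstrap = 100L,         # bootstrap replicates
    gamma_alpha = 1.0,        # gamma shape for distances
    upstream_window = 8000L   # promoter scan window, bp
  )
}

#' Read a flat YAML run configuration
#'
#' Unknown keys warn; missing keys take the documented defaults from
#' [default_config()]. Thresholds are range-checked.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return named list merging file values over defaults.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    stopifnot(file.exists(path))
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), c(names(cfg), "paths"))
    if (length(unknown)) {
      warning("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    for (k in intersect(names(user), names(cfg))) cfg[[k]] <- user[[k]]
    if (!is.null(user$paths)) cfg$paths <- user$paths
  }
  stopifnot(cfg$min_identity >= 0, cfg$min_identity <= 100,
            cfg$identity_threshold > 0, cfg$identity_threshold <= 1,
            cfg$min_fraction >= 0, cfg$min_fraction < 1,
            cfg$barcode_max_edits >= 0, cfg$bootstrap >= 0)
  cfg
}
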