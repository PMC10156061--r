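# Deterministic synthetic-data generation: random scaffolds, gene templates
# with the canonical four-exon PEBP structure, embedded genes, multi-assembly
# variant sets, allele pairs, and barcoded long-amplicon read pools. All
# generators are pure functions of their inputs and a seed.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# one fixed codon per amino acid used by reverse translation; V -> GTT,
# I -> ATC and A -> GCT matter for the packaged fixtures' codon contexts
REV_CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATC",
               L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

#' Generate a random scaffold sequence
#'
#' @param length scaffold length in bp (> 0).
#' @param gc GC fraction in \[0, 1\].
#' @param seed integer seed; the result is a pure function of the arguments.
#' @param id sequence name.
#' @return named character vector of length 1.
#' @export
make_scaffold <- function(length, gc = 0.4, seed = 1L, id = "scaffold1") {
  if (length <= 0L) stop("scaffold length must be positive")
  stopifnot(gc >= 0, gc <= 1)
  seq <- with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = ""))
  stats::setNames(seq, id)
}

#' Construct a gene template
#'
#' An unplaced four-exon gene: exon sequences whose concatenation is a CDS
#' (ATG start, stop end, length divisible by 3) plus the three intron
#' lengths. Default intron lengths are 150/200/250 bp. The canonical family
#' structure has exon II of 62 bp and exon III of 41 bp.
#'
#' @param name template name.
#' @param exon_seqs character vector of 4 exon DNA sequences.
#' @param intron_lengths integer vector of 3 positive intron lengths.
#' @return object of class `gene_template`.
#' @export
gene_template <- function(name, exon_seqs, intron_lengths = c(150L, 200L, 250L)) {
  stopifnot(length(exon_seqs) == 4L, length(intron_lengths) == 3L,
            all(intron_lengths >= 5L))
  cds <- paste(exon_seqs, collapse = "")
  if (nchar(cds) %% 3L != 0L) stop("template CDS length not divisible by 3")
  if (substr(cds, 1L, 3L) != "ATG") stop("template CDS must start with ATG")
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% STOP_CODONS) stop("template CDS must end with a stop codon")
  structure(list(name = name, exon_seqs = exon_seqs,
                 intron_lengths = as.integer(intron_lengths), cds = cds),
            class = "gene_template")
}

#' Reverse-translate a protein into a CDS
#'
#' Uses one fixed codon per amino acid, with optional per-residue codon
#' overrides, and appends a TGA stop.
#'
#' @param protein amino-acid string.
#' @param codon_overrides named list/vector: residue position -> codon.
#' @return DNA string of length 3 * (nchar(protein) + 1).
#' @export
reverse_translate <- function(protein, codon_overrides = NULL) {
  aa <- str_chars(protein)
  codons <- REV_CODON[aa]
  if (any(is.na(codons))) stop("unknown amino acid in protein")
  if (!is.null(codon_overrides)) {
    for (p in names(codon_overrides)) {
      i <- as.integer(p)
      cod <- toupper(codon_overrides[[p]])
      stopifnot(nchar(cod) == 3L,
                Biostrings::GENETIC_CODE[[cod]] == aa[i])
      codons[i] <- cod
    }
  }
  paste(c(codons, "TGA"), collapse = "")
}

#' Build a gene template from a protein
#'
#' Reverse-translates the protein, appends the stop codon, and splits the
#' CDS into four exons: exon I of `exon1_len` bp, the conserved 62 bp exon
#' II and 41 bp exon III, and the remainder as exon IV.
#'
#' @param name template name.
#' @param protein amino-acid string.
#' @param exon1_len exon I length in bp.
#' @param intron_lengths integer vector of 3 intron lengths.
#' @param codon_overrides per-residue codon overrides (see
#'   [reverse_translate()]).
#' @return a [gene_template()].
#' @export
template_from_protein <- function(name, protein, exon1_len = 195L,
                                  intron_lengths = c(150L, 200L, 250L),
                                  codon_overrides = NULL) {
  cds <- reverse_translate(protein, codon_overrides)
  n <- nchar(cds)
  stopifnot(exon1_len + 62L + 41L < n)
  b <- cumsum(c(exon1_len, 62L, 41L))
  exons <- c(substr(cds, 1L, b[1L]),
             substr(cds, b[1L] + 1L, b[2L]),
             substr(cds, b[2L] + 1L, b[3L]),
             substr(cds, b[3L] + 1L, n))
  gene_template(name, exons, intron_lengths)
}

#' Realize a gene template as a genomic sequence
#'
#' Fills the three introns with random sequence carrying canonical GT...AG
#' splice dinucleotides and returns the gene sequence with a gene-local
#' model (exon coordinates relative to the gene's own sequence).
#'
#' @param template a [gene_template()].
#' @param seed integer seed for the intron bodies.
#' @return list with `seq` (gene DNA), `model` (gene-local [gene_model()]),
#'   and `template`; class `synthetic_gene`.
#' @export
build_gene <- function(template, seed = 1L) {
  stopifnot(inherits(template, "gene_template"))
  introns <- with_seed(seed, vapply(template$intron_lengths, function(l) {
    paste0("GT", paste(sample(DNA_BASES, l - 4L, replace = TRUE),
                       collapse = ""), "AG")
  }, character(1)))
  parts <- c(template$exon_seqs[1L], introns[1L], template$exon_seqs[2L],
             introns[2L], template$exon_seqs[3L], introns[3L],
             template$exon_seqs[4L])
  seq <- paste(parts, collapse = "")
  lens <- nchar(parts)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  ends <- starts + lens - 1L
  exon_idx <- c(1L, 3L, 5L, 7L)
  exons <- cbind(start = starts[exon_idx], end = ends[exon_idx])
  model <- gene_model(locus_id = template$name, scaffold_id = template$name,
                      strand = "+", exons = exons, cds = template$cds,
                      introns = data.frame(donor = rep("GT", 3L),
                                           acceptor = rep("AG", 3L)))
  structure(list(seq = seq, model = model, template = template),
            class = "synthetic_gene")
}

#' Embed a gene into a scaffold
#'
#' Writes the realized gene over the scaffold at `start` (replacing the
#' scaffold bases there, so scaffold length is unchanged). On the minus
#' strand the reverse complement is written and exon coordinates are
#' reported on the forward scaffold. Splicing the returned model's exons
#' back out of the returned scaffold reproduces the template CDS exactly.
#'
#' @param scaffold named character vector of length 1.
#' @param template a [gene_template()].
#' @param start 1-based insertion position.
#' @param strand "+" or "-".
#' @param seed seed for the intron bodies.
#' @param existing list of previously embedded gene models to guard against
#'   overlap.
#' @return list(scaffold = modified scaffold, model = genomic
#'   [gene_model()], gene = the `synthetic_gene`).
#' @export
embed_gene <- function(scaffold, template, start, strand = "+", seed = 1L,
                       existing = list()) {
  g <- build_gene(template, seed)
  L <- nchar(scaffold)
  glen <- nchar(g$seq)
  if (start < 1L || start + glen - 1L > L) {
    stop("gene does not fit within scaffold at start ", start)
  }
  for (m in existing) {
    if (start <= max(m$exons[, 2L]) && start + glen - 1L >= min(m$exons[, 1L])) {
      stop("placement overlaps a previously embedded gene")
    }
  }
  insert <- if (strand == "+") g$seq else revcomp(g$seq)
  newseq <- paste0(substr(scaffold, 1L, start - 1L), insert,
                   substr(scaffold, start + glen, L))
  local_ex <- g$model$exons
  exons <- if (strand == "+") {
    cbind(start = start + local_ex[, 1L] - 1L, end = start + local_ex[, 2L] - 1L)
  } else {
    e <- cbind(start = start + glen - local_ex[, 2L],
               end = start + glen - local_ex[, 1L])
    e[order(e[, 1L]), , drop = FALSE]
  }
  model <- gene_model(locus_id = template$name, scaffold_id = names(scaffold),
                      strand = strand, exons = exons, cds = template$cds,
                      introns = g$model$introns)
  out <- stats::setNames(newseq, names(scaffold))
  attr(out, "descriptions") <- attr(scaffold, "descriptions")
  list(scaffold = out, model = model, gene = g)
}

#' Construct a variant specification
#'
#' A list of edits distinguishing two alleles. Substitutions have one-base
#' ref and alt; deletions have empty alt. Positions are 1-based: CDS
#' coordinates for `region = "exon"` rows and gene (allele-1) coordinates
#' for `region = "intron"` rows, strictly increasing within each region
#' type.
#'
#' @param pos integer positions.
#' @param kind "substitution" or "deletion".
#' @param ref reference bases (deleted run for deletions).
#' @param alt alternate base ("" for deletions).
#' @param region "exon" or "intron" hint per edit.
#' @return data.frame of class `variant_spec`.
#' @export
variant_spec <- function(pos, kind, ref, alt, region) {
  df <- data.frame(pos = as.integer(pos), kind = kind, ref = toupper(ref),
                   alt = toupper(alt), region = region,
                   stringsAsFactors = FALSE)
  stopifnot(all(df$kind %in% c("substitution", "deletion")),
            all(df$region %in% c("exon", "intron")))
  subs <- df$kind == "substitution"
  stopifnot(all(nchar(df$ref[subs]) == 1L), all(nchar(df$alt[subs]) == 1L),
            all(df$alt[!subs] == ""), all(nchar(df$ref[!subs]) >= 1L))
  for (r in unique(df$region)) {
    p <- df$pos[df$region == r]
    if (any(diff(sort(p)) == 0L)) stop("duplicate positions in variant spec")
    stopifnot(all(diff(p) > 0L))
  }
  class(df) <- c("variant_spec", "data.frame")
  df
}

# convert a CDS position to a gene-local position via the model's exons
cds_to_gene_pos <- function(model, cds_pos) {
  ex <- model$exons
  lens <- ex[, 2L] - ex[, 1L] + 1L
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  vapply(cds_pos, function(p) {
    i <- findInterval(p, offsets + 1L)
    if (i < 1L || p > offsets[i] + lens[i]) stop("CDS position out of range: ", p)
    as.integer(ex[i, 1L] + (p - offsets[i]) - 1L)
  }, integer(1))
}

# resolve a variant_spec against a gene (exon rows: CDS coords -> gene
# coords); returns data.frame with gene_pos column, sorted descending
.resolve_spec <- function(spec, model) {
  gene_pos <- spec$pos
  ex_rows <- spec$region == "exon"
  if (any(ex_rows)) {
    gene_pos[ex_rows] <- cds_to_gene_pos(model, spec$pos[ex_rows])
  }
  out <- cbind(spec, gene_pos = as.integer(gene_pos))
  # overlap check on gene coordinates
  iv <- cbind(out$gene_pos, out$gene_pos + nchar(out$ref) - 1L)
  o <- order(iv[, 1L])
  if (nrow(iv) > 1L && any(iv[o, 1L][-1L] <= iv[o, 2L][-nrow(iv)])) {
    stop("overlapping edits in variant spec")
  }
  out[order(out$gene_pos, decreasing = TRUE), , drop = FALSE]
}

# apply resolved edits (descending gene_pos) to a sequence
.apply_edits <- function(seq, edits) {
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    found <- substr(seq, e$gene_pos, e$gene_pos + nchar(e$ref) - 1L)
    if (found != e$ref) {
      stop(sprintf("ref mismatch at position %d: expected %s, found %s",
                   e$gene_pos, e$ref, found))
    }
    seq <- paste0(substr(seq, 1L, e$gene_pos - 1L), e$alt,
                  substr(seq, e$gene_pos + nchar(e$ref), nchar(seq)))
  }
  seq
}

#' Derive per-assembly scaffolds from a base scaffold
#'
#' Each named plan is a [variant_spec()] applied to the base scaffold
#' (positions are scaffold coordinates; the exon/intron hint is kept for
#' bookkeeping only). An empty spec yields an identical copy.
#'
#' @param base_scaffold named character vector of length 1.
#' @param plans named list: assembly name -> [variant_spec()] (or NULL).
#' @return named character vector of assembly sequences.
#' @export
make_assembly_set <- function(base_scaffold, plans) {
  out <- character(length(plans))
  names(out) <- names(plans)
  for (a in names(plans)) {
    spec <- plans[[a]]
    if (is.null(spec) || nrow(spec) == 0L) {
      out[[a]] <- unname(base_scaffold)
    } else {
      edits <- cbind(spec, gene_pos = spec$pos)
      iv <- cbind(edits$gene_pos, edits$gene_pos + nchar(edits$ref) - 1L)
      o <- order(iv[, 1L])
      if (nrow(iv) > 1L && any(iv[o, 1L][-1L] <= iv[o, 2L][-nrow(iv)])) {
        stop("overlapping edits in variant spec")
      }
      edits <- edits[order(edits$gene_pos, decreasing = TRUE), , drop = FALSE]
      out[[a]] <- .apply_edits(unname(base_scaffold), edits)
    }
  }
  out
}

#' Build an allele pair from a gene and a variant specification
#'
#' Allele 1 is the gene sequence itself; allele 2 is the gene with the
#' spec's edits applied. The length difference equals the total deleted
#' bases.
#'
#' @param gene a `synthetic_gene` from [build_gene()].
#' @param spec a [variant_spec()]; substitution refs must match allele 1.
#' @return named character vector c(allele1 = ..., allele2 = ...).
#' @export
make_allele_pair <- function(gene, spec) {
  stopifnot(inherits(gene, "synthetic_gene"))
  a1 <- gene$seq
  if (is.null(spec) || nrow(spec) == 0L) {
    return(c(allele1 = a1, allele2 = a1))
  }
  edits <- .resolve_spec(spec, gene$model)
  a2 <- .apply_edits(a1, edits)
  c(allele1 = a1, allele2 = a2)
}

#' Construct a sample plan for amplicon simulation
#'
#' @param sample_id sample name.
#' @param barcode_pair character c(fwd, rev) barcode sequences.
#' @param allele_weights named numeric, summing to 1.
#' @param n_reads number of reads (> 0).
#' @param error_rate total per-base error probability in \[0, 0.1); split
#'   3:1:1 between substitutions, insertions and deletions, mimicking
#'   circular-consensus-quality long reads.
#' @return list of class `sample_plan`.
#' @export
sample_plan <- function(sample_id, barcode_pair, allele_weights,
                        n_reads, error_rate = 0.005) {
  stopifnot(length(barcode_pair) == 2L, n_reads > 0L,
            abs(sum(allele_weights) - 1) < 1e-9,
            error_rate >= 0, error_rate < 0.1,
            !is.null(names(allele_weights)))
  structure(list(sample_id = sample_id, barcode_pair = barcode_pair,
                 allele_weights = allele_weights,
                 n_reads = as.integer(n_reads), error_rate = error_rate),
            class = "sample_plan")
}

#' Default asymmetric barcode set
#'
#' Deterministic 16-mer barcodes with pairwise edit distance of at least 6,
#' paired asymmetrically (distinct forward and reverse barcodes per
#' sample).
#'
#' @param n_pairs number of barcode pairs.
#' @param length barcode length (default 16).
#' @param min_dist minimum pairwise edit distance (default 6).
#' @param seed seed for the construction.
#' @return data.frame with columns fwd, rev.
#' @export
default_barcodes <- function(n_pairs = 12L, length = 16L, min_dist = 6L,
                             seed = 101L) {
  barcodes <- with_seed(seed, {
    acc <- character(0)
    while (base::length(acc) < 2L * n_pairs) {
      cand <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
      if (!base::length(acc) ||
          min(utils::adist(cand, acc)) >= min_dist) {
        acc <- c(acc, cand)
      }
    }
    acc
  })
  data.frame(fwd = barcodes[seq(1L, 2L * n_pairs, by = 2L)],
             rev = barcodes[seq(2L, 2L * n_pairs, by = 2L)],
             stringsAsFactors = FALSE)
}

# integer allele counts from weights by largest remainder (deterministic)
.weights_to_counts <- function(weights, n) {
  raw <- weights * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# per-base substitution/insertion/deletion noise
.apply_read_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  ch <- str_chars(seq)
  n <- length(ch)
  u <- stats::runif(n)
  subs <- which(u < sub_rate)
  for (i in subs) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  dels <- which(u >= sub_rate & u < sub_rate + del_rate)
  ins <- which(u >= sub_rate + del_rate & u < sub_rate + del_rate + ins_rate)
  if (length(ins)) {
    ins_base <- sample(DNA_BASES, length(ins), replace = TRUE)
    ch[ins] <- paste0(ch[ins], ins_base)
  }
  if (length(dels)) ch <- ch[-dels]
  paste(ch, collapse = "")
}

#' Simulate a barcoded amplicon read pool
#'
#' Each read is fwd_barcode + allele + reverse-complement(rev_barcode), the
#' allele chosen per the plan's weights (deterministic largest-remainder
#' counts, randomized order), with per-base substitution/insertion/deletion
#' noise at the plan's error rate (split 3:1:1) and about half the reads
#' emitted reverse-complemented. Read names encode the truth labels
#' `sample|allele|orientation|index` for downstream testing.
#'
#' @param alleles named character vector of allele sequences.
#' @param plans list of [sample_plan()]s; barcode pairs must be unique.
#' @param seed integer seed.
#' @return named character vector of reads, with a `manifest` attribute
#'   (data.frame sample_id, fwd_barcode, rev_barcode).
#' @export
simulate_amplicon_reads <- function(alleles, plans, seed = 1L) {
  pairs <- vapply(plans, function(p) paste(p$barcode_pair, collapse = "+"),
                  character(1))
  if (anyDuplicated(pairs)) stop("duplicate barcode pair across plans")
  reads <- character(0)
  with_seed(seed, {
    for (p in plans) {
      stopifnot(all(names(p$allele_weights) %in% names(alleles)))
      counts <- .weights_to_counts(p$allele_weights, p$n_reads)
      src <- sample(rep(names(p$allele_weights), counts))
      sub_r <- p$error_rate * 0.6
      ins_r <- p$error_rate * 0.2
      del_r <- p$error_rate * 0.2
      for (i in seq_along(src)) {
        insert <- alleles[[src[i]]]
        if (p$error_rate > 0) {
          insert <- .apply_read_errors(insert, sub_r, ins_r, del_r)
        }
        read <- paste0(p$barcode_pair[1L], insert, revcomp(p$barcode_pair[2L]))
        orient <- if (stats::runif(1L) < 0.5) "fwd" else "rev"
        if (orient == "rev") read <- revcomp(read)
        nm <- sprintf("%s|%s|%s|%04d", p$sample_id, src[i], orient, i)
        reads[nm] <- read
      }
    }
  })
  manifest <- data.frame(
    sample_id = vapply(plans, `[[`, character(1), "sample_id"),
    fwd_barcode = vapply(plans, function(p) p$barcode_pair[1L], character(1)),
    rev_barcode = vapply(plans, function(p) p$barcode_pair[2L], character(1)),
    stringsAsFactors = FALSE)
  attr(reads, "manifest") <- manifest
  reads
}

#' Simulate an aligned protein family with planted subfamilies
#'
#' A common random root protein is diverged into `n_clades` clade ancestors
#' (substitutions at rate `d_between`), each diverged into `n_per_clade`
#' taxa (rate `d_within`). All sequences have equal length, so the set is
#' its own alignment.
#'
#' @param n_clades,n_per_clade family shape.
#' @param length protein length.
#' @param d_between,d_within per-site substitution probabilities.
#' @param seed integer seed.
#' @return named character vector with a `groups` attribute (list clade ->
#'   taxa names).
#' @export
make_protein_family <- function(n_clades = 3L, n_per_clade = 3L, length = 120L,
                                d_between = 0.35, d_within = 0.03, seed = 1L) {
  mutate <- function(p, rate) {
    ch <- str_chars(p)
    hit <- which(stats::runif(base::length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
    paste(ch, collapse = "")
  }
  with_seed(seed, {
    root <- paste(sample(AA20, length, replace = TRUE), collapse = "")
    out <- character(0)
    groups <- list()
    for (cl in seq_len(n_clades)) {
      anc <- mutate(root, d_between)
      taxa <- sprintf("clade%d_t%d", cl, seq_len(n_per_clade))
      for (t in seq_len(n_per_clade)) out[taxa[t]] <- mutate(anc, d_within)
      groups[[sprintf("clade%d", cl)]] <- taxa
    }
    attr(out, "groups") <- groups
    out
  })
}
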