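# Long-amplicon processing: asymmetric dual-barcode demultiplexing, greedy
# identity clustering of reads into phased alleles with majority-rule
# consensus, per-allele coverages and coverage ratios, and locus zygosity
# calls.

# global-alignment identity of two reads in [0, 1]: 1 - d / max(length),
# with d the unit-cost global edit distance (each mismatch or gap column
# costs 1, so this equals matches / alignment length under unit costs)
read_identity <- function(a, b) {
  # a large length difference already bounds identity below any usable
  # threshold; skip the alignment in that case
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) / max(la, lb) > 0.05) return(0)
  d <- utils::adist(a, b)[1L, 1L]
  1 - d / max(la, lb)
}

# majority-rule column consensus of a set of reads (MAFFT multiple
# alignment unless the reads are identical); deterministic tie-breaks:
# A < C < G < T, gaps lose ties against bases
majority_consensus <- function(reads, max_reads = 30L) {
  reads <- unname(reads)
  if (length(reads) > max_reads) reads <- reads[seq_len(max_reads)]
  if (length(unique(reads)) == 1L) return(reads[1L])
  mafft <- Sys.which("mafft")
  if (mafft == "") stop("mafft not found on PATH; cannot build consensus")
  inf <- tempfile(fileext = ".fa"); outf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  write_fasta(stats::setNames(reads, sprintf("r%04d", seq_along(reads))), inf)
  system2(mafft, c("--auto", "--quiet", inf), stdout = outf, stderr = FALSE)
  aln <- toupper(as.character(Biostrings::readBStringSet(outf)))
  mat <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  cons <- apply(mat, 2L, function(col) {
    tab <- table(col)
    # bases beat gaps on ties; otherwise alphabetical
    cand <- names(tab)[tab == max(tab)]
    bases <- setdiff(cand, "-")
    if (length(bases)) sort(bases)[1L] else "-"
  })
  paste(cons[cons != "-"], collapse = "")
}

#' Demultiplex dual-barcoded amplicon reads
#'
#' Both read ends are searched for the sample's forward barcode and the
#' reverse complement of its reverse barcode, in both read orientations.
#' The best-scoring sample with both ends within `max_edits` edits and a
#' unique best total assigns the read; ties are reported ambiguous.
#' Barcodes are trimmed from the returned inserts, which are reported in
#' forward (barcode) orientation.
#'
#' @param reads named character vector of reads.
#' @param manifest data.frame with columns sample_id, fwd_barcode,
#'   rev_barcode; barcode pairs must be unique.
#' @param max_edits maximum edit distance per barcode end (default 2).
#' @return list: `assignments` data.frame (read_id, sample_id, orientation,
#'   fwd_edits, rev_edits, reason) and `inserts`, a named list sample ->
#'   character vector of trimmed inserts.
#' @export
demultiplex <- function(reads, manifest, max_edits = 2L) {
  if (nrow(manifest) == 0L) stop("empty barcode manifest")
  pairs <- paste(manifest$fwd_barcode, manifest$rev_barcode)
  if (anyDuplicated(pairs)) stop("duplicate barcode pair in manifest")
  ns <- nrow(manifest)
  fwd <- manifest$fwd_barcode
  rev_rc <- vapply(manifest$rev_barcode, revcomp, character(1))
  blf <- nchar(fwd); blr <- nchar(rev_rc)
  asg <- data.frame(read_id = names(reads), sample_id = NA_character_,
                    orientation = NA_character_, fwd_edits = NA_integer_,
                    rev_edits = NA_integer_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  inserts <- stats::setNames(vector("list", ns), manifest$sample_id)
  for (k in seq_along(reads)) {
    read_f <- reads[[k]]
    read_r <- revcomp(read_f)
    n <- nchar(read_f)
    best <- NULL; best_total <- Inf; tie <- FALSE
    for (ori in c("forward", "reverse")) {
      x <- if (ori == "forward") read_f else read_r
      wf <- substr(x, 1L, min(n, max(blf) + max_edits))
      wr <- substr(x, max(1L, n - max(blr) - max_edits + 1L), n)
      df_all <- utils::adist(fwd, wf, partial = TRUE)[, 1L]
      dr_all <- utils::adist(rev_rc, wr, partial = TRUE)[, 1L]
      for (s in seq_len(ns)) {
        total <- df_all[s] + dr_all[s]
        if (total < best_total) {
          best_total <- total
          best <- list(s = s, ori = ori, df = as.integer(df_all[s]),
                       dr = as.integer(dr_all[s]))
          tie <- FALSE
        } else if (total == best_total &&
                   (is.null(best) || s != best$s)) {
          tie <- TRUE
        }
      }
    }
    if (is.null(best) || best$df > max_edits || best$dr > max_edits) {
      asg$reason[k] <- "no-match"
      next
    }
    if (tie) {
      asg$reason[k] <- "ambiguous"
      next
    }
    s <- best$s
    x <- if (best$ori == "forward") read_f else read_r
    # trim the barcode regions off the canonical-orientation read; exact
    # barcodes sit flush at the read ends, edited ones are located by a
    # fit-barcode-in-window alignment
    if (best$df == 0L && substr(x, 1L, blf[s]) == fwd[s]) {
      f_end <- blf[s]
    } else {
      wf_len <- min(n, blf[s] + max_edits)
      paf <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(fwd[s]),
        Biostrings::DNAString(substr(x, 1L, wf_len)), type = "global-local",
        substitutionMatrix = nuc_mat(), gapOpening = 5, gapExtension = 2)
      f_end <- Biostrings::end(Biostrings::subject(paf))
    }
    if (best$dr == 0L && substr(x, n - blr[s] + 1L, n) == rev_rc[s]) {
      r_start <- n - blr[s] + 1L
    } else {
      wr_len <- min(n, blr[s] + max_edits)
      par <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(rev_rc[s]),
        Biostrings::DNAString(substr(x, n - wr_len + 1L, n)),
        type = "global-local",
        substitutionMatrix = nuc_mat(), gapOpening = 5, gapExtension = 2)
      r_start <- n - wr_len + Biostrings::start(Biostrings::subject(par))
    }
    asg$sample_id[k] <- manifest$sample_id[s]
    asg$orientation[k] <- best$ori
    asg$fwd_edits[k] <- best$df
    asg$rev_edits[k] <- best$dr
    ins <- substr(x, f_end + 1L, r_start - 1L)
    nm <- names(reads)[k]
    inserts[[manifest$sample_id[s]]] <-
      c(inserts[[manifest$sample_id[s]]], stats::setNames(ins, nm))
  }
  list(assignments = asg, inserts = inserts)
}

#' Phase one sample's amplicon inserts into allele clusters
#'
#' Greedy clustering: the longest unclustered read seeds the first cluster
#' and the read least explained by existing consensuses seeds later ones,
#' so a shorter second allele is still discovered. Because raw reads carry
#' their own errors, initial membership uses a band twice as wide as
#' `identity_threshold`; the strict threshold is then applied against the
#' per-column majority consensus, which is essentially error-free.
#' Clusters converging to the same consensus (within the admission band)
#' are merged, and two consecutive such duplicates end the search. Finally
#' every read is assigned to its best cluster consensus (at the looser
#' `assign_floor`) to obtain per-allele coverages, and clusters holding
#' less than `min_fraction` of the locus coverage are discarded as noise.
#'
#' @param inserts character vector of one sample's trimmed inserts.
#' @param identity_threshold cluster admission identity (default 0.995).
#' @param min_fraction minimum amplicon fraction to retain (default 0.2).
#' @param min_reads minimum inserts to attempt phasing (default 10).
#' @param max_clusters maximum clusters to seed (default 6).
#' @param assign_floor minimum identity for the coverage assignment pass
#'   (default 0.98).
#' @return list of clusters, each: consensus, subread_coverage,
#'   amplicon_coverage, fraction, coverage_ratio (rounded to 1 decimal).
#' @export
phase_alleles <- function(inserts, identity_threshold = 0.995,
                          min_fraction = 0.2, min_reads = 10L,
                          max_clusters = 6L, assign_floor = 0.98) {
  n <- length(inserts)
  if (n < min_reads) stop("too few reads to phase (", n, " < ", min_reads, ")")
  inserts <- unname(inserts)
  remaining <- seq_len(n)
  clusters <- list()
  # The seed read carries its own errors, so initial membership uses a
  # relative band twice as wide as the admission threshold (both reads
  # contribute an error load); the strict threshold is then applied
  # against the majority consensus, which is essentially error-free.
  # The first cluster is seeded by the longest read (full-length molecule);
  # later clusters by the read least explained by existing consensuses
  # (farthest-first), so a shorter second allele is still discovered.
  # Clusters whose consensus falls within the admission band of an
  # existing consensus are merged; two consecutive such duplicates end
  # the search.
  form_threshold <- max(0, 2 * identity_threshold - 1)
  best_sim <- rep(-Inf, n) # identity to the closest known consensus
  dup_streak <- 0L
  while (length(remaining) >= 3L && length(clusters) < max_clusters) {
    seed <- if (!length(clusters)) {
      remaining[which.max(nchar(inserts[remaining]))]
    } else {
      remaining[which.min(best_sim[remaining])]
    }
    sims <- vapply(remaining, function(i) {
      read_identity(inserts[i], inserts[seed])
    }, numeric(1))
    mem <- remaining[sims >= form_threshold]
    if (length(mem) < 5L) {
      mem <- remaining[order(sims, decreasing = TRUE)][
        seq_len(min(5L, length(remaining)))]
    }
    cons <- majority_consensus(inserts[mem])
    sims2 <- vapply(remaining, function(i) {
      read_identity(inserts[i], cons)
    }, numeric(1))
    best_sim[remaining] <- pmax(best_sim[remaining], sims2)
    mem2 <- remaining[sims2 >= identity_threshold]
    if (!length(mem2)) mem2 <- mem
    dup <- which(vapply(clusters, function(cl) {
      read_identity(cons, cl$consensus) >= identity_threshold
    }, logical(1)))
    if (length(dup)) {
      d1 <- dup[1L]
      clusters[[d1]]$core <- union(clusters[[d1]]$core, mem2)
      dup_streak <- dup_streak + 1L
    } else {
      cons2 <- if (setequal(mem2, mem)) cons else majority_consensus(inserts[mem2])
      clusters[[length(clusters) + 1L]] <- list(consensus = cons2,
                                                core = mem2)
      dup_streak <- 0L
    }
    remaining <- setdiff(remaining, union(seed, mem2))
    if (dup_streak >= 2L) break
  }
  cons_seqs <- vapply(clusters, `[[`, character(1), "consensus")
  # coverage assignment: every read to its best consensus
  counts <- integer(length(clusters))
  for (i in seq_len(n)) {
    sims <- vapply(cons_seqs, function(cs) read_identity(inserts[i], cs),
                   numeric(1))
    j <- which.max(sims)
    if (sims[j] >= assign_floor) counts[j] <- counts[j] + 1L
  }
  total <- sum(counts)
  if (total == 0L) stop("no reads assigned to any cluster")
  retained <- which(counts / total >= min_fraction)
  counts <- counts[retained]
  cons_seqs <- cons_seqs[retained]
  total_retained <- sum(counts)
  ord <- order(counts, decreasing = TRUE)
  lapply(ord, function(i) {
    frac <- counts[i] / total_retained
    list(consensus = cons_seqs[i],
         subread_coverage = counts[i],
         amplicon_coverage = counts[i],
         fraction = frac,
         coverage_ratio = round(frac, 1L))
  })
}

#' Call locus zygosity from retained allele clusters
#'
#' One retained cluster is homozygous; two are heterozygous when both
#' coverage ratios fall in \[0.2, 0.8\]; more than two retained clusters
#' are flagged as multi-allelic/contamination.
#'
#' @param clusters list from [phase_alleles()].
#' @param sample_id,locus_id identifiers carried into the call.
#' @return list (class `locus_genotype`): sample_id, locus_id, alleles,
#'   zygosity, flags.
#' @export
genotype_locus <- function(clusters, sample_id = NA_character_,
                           locus_id = NA_character_) {
  if (length(clusters) == 0L) stop("zero retained clusters")
  flags <- character(0)
  if (length(clusters) == 1L) {
    zyg <- "homozygous"
  } else if (length(clusters) == 2L) {
    fr <- vapply(clusters, `[[`, numeric(1), "fraction")
    if (all(fr >= 0.2 & fr <= 0.8)) {
      zyg <- "heterozygous"
    } else {
      zyg <- "homozygous"
      flags <- c(flags, "minor_cluster_outside_het_band")
      clusters <- clusters[which.max(fr)]
    }
  } else {
    zyg <- "flagged"
    flags <- c(flags, "multi-allelic/contamination")
  }
  structure(list(sample_id = sample_id, locus_id = locus_id,
                 alleles = clusters, zygosity = zyg, flags = flags),
            class = "locus_genotype")
}
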