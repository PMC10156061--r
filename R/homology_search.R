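# Translated homology search: six-frame translation of scaffolds, seeded
# protein local alignment against query PEBP proteins, and merging of
# per-exon hits into candidate loci.

#' Six-frame translation of a scaffold
#'
#' Standard genetic code; stops are rendered `*`; trailing partial codons
#' are dropped; codons containing N translate to `X`. Each frame records
#' the mapping back to forward-scaffold nucleotide coordinates.
#'
#' @param scaffold named character vector of length 1 (DNA).
#' @return list of 6 frames: list(scaffold_id, frame, protein) with frame
#'   in +1,+2,+3,-1,-2,-3.
#' @export
sixframe_translate <- function(scaffold) {
  seq <- toupper(unname(scaffold[1L]))
  if (grepl("[^ACGTN]", seq)) stop("non-DNA characters in scaffold")
  id <- names(scaffold)[1L]
  rc <- revcomp(seq)
  out <- list()
  for (f in 1:3) {
    out[[length(out) + 1L]] <- list(scaffold_id = id, frame = f,
                                    protein = translate_dna(substr(seq, f, nchar(seq))))
    out[[length(out) + 1L]] <- list(scaffold_id = id, frame = -f,
                                    protein = translate_dna(substr(rc, f, nchar(rc))))
  }
  for (i in seq_along(out)) class(out[[i]]) <- "translated_frame"
  attr(out, "scaffold_length") <- nchar(seq)
  out
}

#' Map a protein interval in a translated frame to scaffold coordinates
#'
#' Exact and invertible: residue i of frame +f covers nucleotides
#' f + 3(i-1) .. f + 3i - 1; minus frames are mirrored through the
#' scaffold length.
#'
#' @param frame a frame from [sixframe_translate()].
#' @param aa_start,aa_end 1-based residue interval.
#' @param scaffold_length forward scaffold length.
#' @return integer c(start, end), 1-based inclusive forward coordinates.
#' @export
frame_to_scaffold <- function(frame, aa_start, aa_end, scaffold_length) {
  f <- abs(frame$frame)
  nt1 <- as.integer(f + 3 * (aa_start - 1))
  nt2 <- as.integer(f + 3 * aa_end - 1)
  if (frame$frame > 0L) {
    c(nt1, nt2)
  } else {
    c(scaffold_length - nt2 + 1L, scaffold_length - nt1 + 1L)
  }
}

# protein local alignment (BLOSUM62, affine 11/1); returns score, identity,
# subject aligned interval
.local_align_protein <- function(query, subject) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  p <- str_chars(as.character(Biostrings::alignedPattern(pa)))
  s <- str_chars(as.character(Biostrings::alignedSubject(pa)))
  list(score = Biostrings::score(pa),
       identity = mean(p == s) * 100,
       subject_start = Biostrings::start(Biostrings::subject(pa)),
       subject_end = Biostrings::end(Biostrings::subject(pa)))
}

#' Seeded translated homology search
#'
#' Finds exact protein k-mer seeds between each query and each translated
#' frame, groups seeds into diagonal bands, extends each band by local
#' alignment (BLOSUM62, gap open 11 / extend 1), and reports hits passing
#' the score and identity thresholds in forward-scaffold coordinates.
#'
#' @param frames frames from [sixframe_translate()].
#' @param queries named character vector of query proteins.
#' @param k seed length (>= 3; default 4).
#' @param min_score minimum alignment score (default 60).
#' @param min_identity minimum percent identity (default 40).
#' @return data.frame of hits: scaffold_id, strand, start, end, query_id,
#'   score, identity.
#' @export
homology_search <- function(frames, queries, k = 4L, min_score = 60,
                            min_identity = 40) {
  if (length(queries) == 0L) stop("empty query set")
  stopifnot(k >= 3L)
  L <- attr(frames, "scaffold_length")
  hits <- list()
  for (fr in frames) {
    m <- nchar(fr$protein)
    if (m < k) next
    f_kmers <- substring(fr$protein, 1:(m - k + 1L), k:m)
    idx <- split(seq_along(f_kmers), f_kmers)
    for (qi in seq_along(queries)) {
      q <- queries[[qi]]
      n <- nchar(q)
      if (n < k) next
      q_kmers <- substring(q, 1:(n - k + 1L), k:n)
      seed_d <- integer(0); seed_j <- integer(0)
      for (i in seq_along(q_kmers)) {
        js <- idx[[q_kmers[i]]]
        if (!is.null(js)) {
          seed_d <- c(seed_d, js - i)
          seed_j <- c(seed_j, js)
        }
      }
      if (!length(seed_d)) next
      # band the diagonals: seeds of one (gap-free) exon segment share a
      # diagonal, while an intron shifts the diagonal by at least its
      # length/3, so nearby diagonals are one candidate segment and far
      # ones separate segments (e.g. the exons of one gene)
      o <- order(seed_d, seed_j)
      seed_d <- seed_d[o]; seed_j <- seed_j[o]
      grp <- cumsum(c(1L, diff(seed_d) > 5L))
      for (g in unique(grp)) {
        js <- seed_j[grp == g]
        w1 <- max(1L, min(js) - 10L)
        w2 <- min(m, max(js) + k + 10L)
        al <- .local_align_protein(q, substr(fr$protein, w1, w2))
        if (al$score < min_score || al$identity < min_identity) next
        aa1 <- w1 + al$subject_start - 1L
        aa2 <- w1 + al$subject_end - 1L
        nt <- frame_to_scaffold(fr, aa1, aa2, L)
        hits[[length(hits) + 1L]] <- data.frame(
          scaffold_id = fr$scaffold_id,
          strand = if (fr$frame > 0L) "+" else "-",
          start = nt[1L], end = nt[2L],
          query_id = names(queries)[qi],
          score = al$score, identity = al$identity,
          frame = fr$frame, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(scaffold_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      query_id = character(0), score = numeric(0),
                      identity = numeric(0), frame = integer(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$scaffold_id, out$strand, out$start), , drop = FALSE]
}

#' Merge homology hits into candidate loci
#'
#' Same-scaffold, same-strand hits within `max_gap` bp are merged into one
#' candidate locus; each locus carries its best-scoring query.
#'
#' @param hits data.frame from [homology_search()].
#' @param max_gap maximum merge distance in bp (default 5000).
#' @return data.frame: scaffold_id, strand, start, end, best_query,
#'   best_score, n_hits.
#' @export
merge_hits_to_loci <- function(hits, max_gap = 5000L) {
  if (nrow(hits) == 0L) {
    return(data.frame(scaffold_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      best_query = character(0), best_score = numeric(0),
                      n_hits = integer(0)))
  }
  hits <- hits[order(hits$scaffold_id, hits$strand, hits$start), , drop = FALSE]
  loci <- list()
  cur <- hits[1L, ]
  members <- list(hits[1L, ])
  flush <- function(cur, members) {
    mm <- do.call(rbind, members)
    best <- mm[which.max(mm$score), ]
    data.frame(scaffold_id = cur$scaffold_id, strand = cur$strand,
               start = min(mm$start), end = max(mm$end),
               best_query = best$query_id, best_score = best$score,
               n_hits = nrow(mm), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(hits))[-1L]) {
    h <- hits[i, ]
    if (h$scaffold_id == cur$scaffold_id && h$strand == cur$strand &&
        h$start - max(vapply(members, function(x) x$end, numeric(1))) <= max_gap) {
      members[[length(members) + 1L]] <- h
    } else {
      loci[[length(loci) + 1L]] <- flush(cur, members)
      cur <- h
      members <- list(h)
    }
  }
  loci[[length(loci) + 1L]] <- flush(cur, members)
  do.call(rbind, loci)
}
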