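fx <- paper_fixtures()

test_that("six-frame translation follows the genetic code and coordinates", {
  fr <- sixframe_translate(c(sc = "ATGAAATGA"))
  plus1 <- Filter(function(f) f$frame == 1, fr)[[1]]
  expect_identical(plus1$protein, "MK*")
  # 8 bp input: frame +1 holds floor(8/3) = 2 residues
  fr8 <- sixframe_translate(c(sc = "ATGAAATG"))
  expect_identical(nchar(Filter(function(f) f$frame == 1, fr8)[[1]]$protein), 2L)
  # reverse strand: revcomp("TCACTTCAT") = "ATGAAGTGA" -> "MK*" in frame -1
  frm <- sixframe_translate(c(sc = "TCACTTCAT"))
  minus1 <- Filter(function(f) f$frame == -1, frm)[[1]]
  expect_identical(minus1$protein, "MK*")
  # residue coordinates map back exactly and invertibly
  L <- 9L
  expect_identical(frame_to_scaffold(plus1, 1, 1, L), c(1L, 3L))
  expect_identical(frame_to_scaffold(minus1, 1, 1, L), c(7L, 9L))
  expect_error(sixframe_translate(c(sc = "ATGXXX")), "non-DNA")
})

test_that("planted genes are found with exon-level 100% identity hits", {
  scaf <- make_scaffold(5000, 0.4, seed = 4, id = "sc")
  emb <- embed_gene(scaf, fx$templates$mft2, start = 1201, strand = "+",
                    seed = 11)
  hits <- homology_search(sixframe_translate(emb$scaffold),
                          fx$proteins["SmMFT2_syn"])
  expect_gt(nrow(hits), 0)
  ex <- emb$model$exons
  # at least one hit covers a full exon at 100% identity
  covers <- vapply(seq_len(nrow(hits)), function(i) {
    any(hits$start[i] <= ex[, 1] & hits$end[i] >= ex[, 2]) &
      hits$identity[i] == 100
  }, logical(1))
  expect_true(any(covers))
  loci <- merge_hits_to_loci(hits)
  expect_identical(nrow(loci), 1L)
  expect_lte(loci$start, min(ex))
  expect_gte(loci$end, max(ex) - 3L) # query protein lacks the stop codon
})

test_that("shuffled scaffolds yield no hits at default thresholds", {
  scaf <- make_scaffold(5000, 0.4, seed = 4, id = "sc")
  emb <- embed_gene(scaf, fx$templates$mft2, start = 1201, seed = 11)
  base <- strsplit(emb$scaffold[[1]], "", fixed = TRUE)[[1]]
  for (s in 1:5) {
    shuf <- withr::with_seed(s, paste(sample(base), collapse = ""))
    h0 <- homology_search(sixframe_translate(c(shuf = shuf)),
                          fx$proteins["SmMFT2_syn"])
    expect_identical(nrow(h0), 0L)
  }
})

test_that("divergent homologs at 70% protein identity are still recovered", {
  scaf <- make_scaffold(5000, 0.4, seed = 4, id = "sc")
  emb <- embed_gene(scaf, fx$templates$mft2, start = 1201, seed = 11)
  fr <- sixframe_translate(emb$scaffold)
  p <- strsplit(fx$proteins[["SmMFT2_syn"]], "", fixed = TRUE)[[1]]
  q <- withr::with_seed(7, {
    idx <- sample(length(p), round(0.3 * length(p)))
    for (i in idx) p[i] <- sample(setdiff(pebpminer:::AA20, p[i]), 1)
    paste(p, collapse = "")
  })
  loci <- merge_hits_to_loci(homology_search(fr, c(q70 = q)))
  expect_identical(nrow(loci), 1L)
})

test_that("hit merging respects strand, distance, and empty input", {
  h <- data.frame(
    scaffold_id = "sc", strand = "+",
    start = c(100L, 800L, 60000L), end = c(400L, 1000L, 60500L),
    query_id = c("q1", "q1", "q2"), score = c(50, 80, 70),
    identity = c(90, 95, 99), frame = 1L, stringsAsFactors = FALSE)
  loci <- merge_hits_to_loci(h, max_gap = 10000L)
  expect_identical(nrow(loci), 2L)
  expect_identical(loci$best_query, c("q1", "q2"))
  expect_identical(loci$end[1], 1000L)
  empty <- merge_hits_to_loci(h[0, ])
  expect_identical(nrow(empty), 0L)
  expect_error(homology_search(list(), character(0)), "empty query")
})

test_that("planted-gene recall is complete across seeds", {
  found <- vapply(1:10, function(s) {
    sc <- make_scaffold(3500, 0.4, seed = s * 13, id = "s")
    e <- embed_gene(sc, fx$templates$mft2, start = 801,
                    strand = if (s %% 2) "+" else "-", seed = s)
    ll <- merge_hits_to_loci(homology_search(sixframe_translate(e$scaffold),
                                             fx$proteins["SmMFT2_syn"]))
    nrow(ll) == 1 && ll$strand == e$model$strand &&
      ll$start <= min(e$model$exons) + 5 && ll$end >= max(e$model$exons) - 5
  }, logical(1))
  expect_true(all(found))
})

test_that("reported hits are self-consistent under re-alignment", {
  scaf <- make_scaffold(4000, 0.4, seed = 21, id = "sc")
  emb <- embed_gene(scaf, fx$templates$cen1, start = 901, seed = 2)
  hits <- homology_search(sixframe_translate(emb$scaffold),
                          fx$proteins["SmCEN1_syn"])
  for (i in seq_len(nrow(hits))) {
    nt <- substr(emb$scaffold[[1]], hits$start[i], hits$end[i])
    if (hits$strand[i] == "-") nt <- revcomp(nt)
    aa <- translate_dna(nt)
    re <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(fx$proteins[["SmCEN1_syn"]]),
      Biostrings::AAString(aa), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    expect_gte(Biostrings::score(re), hits$score[i])
  }
})
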