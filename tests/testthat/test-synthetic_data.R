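fx <- paper_fixtures()

test_that("scaffold generation is seeded, GC-controlled, and validated", {
  a <- make_scaffold(1000, 0.5, seed = 7)
  b <- make_scaffold(1000, 0.5, seed = 7)
  expect_identical(a, b)
  expect_identical(nchar(a[[1]]), 1000L)
  g <- make_scaffold(500, 1.0, seed = 3)
  expect_false(grepl("[AT]", g[[1]]))
  expect_error(make_scaffold(0, 0.5, 1), "positive")
})

test_that("embedding a gene and splicing it back reproduces the template CDS", {
  tpl <- fx$templates$mft2
  for (strand in c("+", "-")) {
    scaf <- make_scaffold(3000, 0.4, seed = 11, id = "s1")
    emb <- embed_gene(scaf, tpl, start = 701, strand = strand, seed = 12)
    cds <- splice_exons(emb$scaffold[[1]], emb$model$exons, strand)
    expect_identical(cds, tpl$cds)
    expect_identical(translate_cds(cds), fx$proteins[["SmMFT2_syn"]])
  }
  scaf <- make_scaffold(1000, 0.4, seed = 1)
  expect_error(embed_gene(scaf, tpl, start = 900, strand = "+"), "fit")
  emb <- embed_gene(make_scaffold(3000, 0.4, 2), tpl, start = 101)
  expect_error(
    embed_gene(emb$scaffold, tpl, start = 500, existing = list(emb$model)),
    "overlap")
})

test_that("assembly sets apply per-assembly variant specs over a base", {
  scaf <- make_scaffold(400, 0.4, seed = 5)
  base <- scaf[[1]]
  ref <- substr(base, 100, 100)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  ref2 <- substr(base, 200, 200)
  alt2 <- setdiff(c("A", "C", "G", "T"), ref2)[1]
  vs <- variant_spec(c(100L, 200L), rep("substitution", 2),
                     c(ref, ref2), c(alt, alt2), rep("exon", 2))
  out <- make_assembly_set(scaf, list(a1 = NULL, a2 = NULL, a3 = vs))
  expect_identical(out[["a1"]], base)
  expect_identical(out[["a2"]], base)
  expect_identical(substr(out[["a3"]], 100, 100), alt)
  expect_identical(substr(out[["a3"]], 200, 200), alt2)
  expect_identical(sum(out[["a3"]] != base), 1L) # still one string, 2 edits
  expect_error(variant_spec(c(50L, 50L), rep("substitution", 2),
                            c("A", "A"), c("C", "G"), rep("exon", 2)),
               "duplicate")
})

test_that("allele pairs realize the printed length differences", {
  expect_identical(nchar(fx$alleles$mft2[["allele1"]]) -
                   nchar(fx$alleles$mft2[["allele2"]]), 5L)
  expect_identical(nchar(fx$alleles$mft2[["allele1"]]), 981L)
  expect_identical(nchar(fx$alleles$mft2[["allele2"]]), 976L)
  expect_identical(nchar(fx$alleles$cen1[["allele1"]]) -
                   nchar(fx$alleles$cen1[["allele2"]]), 12L)
  expect_identical(nchar(fx$alleles$cen1[["allele1"]]), 1027L)

  empty <- make_allele_pair(fx$genes$mft2, NULL)
  expect_identical(empty[["allele1"]], empty[["allele2"]])

  bad <- fx$specs$mft2
  bad$ref[5] <- setdiff(c("A", "C", "G", "T"), bad$ref[5])[1]
  expect_error(make_allele_pair(fx$genes$mft2, bad), "ref mismatch")
})

test_that("amplicon simulation is seeded, labeled, and weight-faithful", {
  alleles <- c(a1 = strrep("ACGT", 60), a2 = strrep("ACCT", 60))
  bc <- default_barcodes(2, seed = 5)
  p1 <- sample_plan("s1", c(bc$fwd[1], bc$rev[1]), c(a1 = 1.0), 15,
                    error_rate = 0)
  p2 <- sample_plan("s2", c(bc$fwd[2], bc$rev[2]), c(a1 = 0.5, a2 = 0.5),
                    120, error_rate = 0)
  reads <- simulate_amplicon_reads(alleles, list(p1, p2), seed = 3)
  reads_again <- simulate_amplicon_reads(alleles, list(p1, p2), seed = 3)
  expect_identical(reads, reads_again)

  lab <- strsplit(names(reads), "|", fixed = TRUE)
  smp <- vapply(lab, `[`, character(1), 1)
  src <- vapply(lab, `[`, character(1), 2)
  ori <- vapply(lab, `[`, character(1), 3)
  expect_identical(sum(smp == "s1"), 15L)
  # error-free s1 reads contain the allele insert verbatim
  r1 <- reads[smp == "s1"][1]
  x <- if (ori[smp == "s1"][1] == "rev") revcomp(r1[[1]]) else r1[[1]]
  expect_identical(substr(x, nchar(bc$fwd[1]) + 1,
                          nchar(bc$fwd[1]) + nchar(alleles[["a1"]])),
                   unname(alleles[["a1"]]))
  # 1:1 weights at n = 120: deterministic largest-remainder counts are
  # 60/60, comfortably inside the binomial 99% bounds [44, 76]
  counts <- table(src[smp == "s2"])
  expect_true(all(counts >= qbinom(0.005, 120, 0.5) &
                  counts <= qbinom(0.995, 120, 0.5)))
  expect_identical(unname(counts[["a1"]]), 60L)

  p_dup <- sample_plan("s3", c(bc$fwd[1], bc$rev[1]), c(a1 = 1.0), 5)
  expect_error(simulate_amplicon_reads(alleles, list(p1, p_dup), 1),
               "duplicate barcode pair")
})

test_that("the fixture bundle realizes the printed codon contexts and cohort", {
  cds <- fx$genes$mft2$model$cds
  expect_identical(substr(cds, 349, 351), "ATA")  # codon 117
  mutated <- paste0(substr(cds, 1, 349), "G", substr(cds, 351, nchar(cds)))
  expect_identical(substr(mutated, 349, 351), "AGA")
  expect_identical(translate_dna(substr(mutated, 349, 351)), "R")
  expect_identical(substr(cds, 61, 63), "GTT")  # codon 21
  expect_identical(substr(cds, 277, 279), "ATC") # codon 93
  expect_identical(substr(cds, 367, 369), "GCT") # codon 123

  # exactly one cohort sample carries two allele weights
  n_wts <- vapply(fx$cohort$plans, function(p) length(p$allele_weights),
                  integer(1))
  expect_identical(sum(n_wts == 2L), 1L)
  expect_identical(fx$cohort$plans[[which(n_wts == 2L)]]$sample_id, "Sa_C9")

  # allele-1 CDS translates with no internal stop
  expect_false(grepl("*", translate_cds(cds), fixed = TRUE))

  # default barcodes are mutually distant
  bc <- default_barcodes(12)
  all_bc <- c(bc$fwd, bc$rev)
  d <- utils::adist(all_bc)
  expect_true(min(d[upper.tri(d)]) >= 6)
})

test_that("random variant specs are canonical and inside their regions", {
  for (s in 1:5) {
    spec <- random_variant_spec(fx$genes$mft2, seed = s)
    expect_s3_class(spec, "variant_spec")
    dels <- spec[spec$kind == "deletion", ]
    g <- fx$genes$mft2$seq
    for (i in seq_len(nrow(dels))) {
      p <- dels$pos[i]; len <- nchar(dels$ref[i])
      expect_identical(substr(g, p, p + len - 1), dels$ref[i])
      # left-normalized: the base before differs from the run's last base
      expect_false(substr(g, p - 1, p - 1) == substr(g, p + len - 1, p + len - 1))
    }
  }
})
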