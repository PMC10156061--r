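fx <- paper_fixtures()

make_pool <- function(n1, n2 = 0, error_rate = 0, seed = 1, n_samples = 1) {
  alleles <- fx$cohort$alleles
  bc <- default_barcodes(2, seed = 44)
  w <- if (n2 > 0) {
    c(SmMFT2_allele1 = n1 / (n1 + n2), SmMFT2_allele2 = n2 / (n1 + n2))
  } else {
    c(SmMFT2_allele1 = 1.0)
  }
  plan <- sample_plan("sampleA", c(bc$fwd[1], bc$rev[1]), w, n1 + n2,
                      error_rate = error_rate)
  reads <- simulate_amplicon_reads(alleles, list(plan), seed = seed)
  list(reads = reads, manifest = attr(reads, "manifest"))
}

test_that("error-free reads demultiplex to their truth sample with 0 edits", {
  pool <- make_pool(12)
  dm <- demultiplex(pool$reads, pool$manifest)
  asg <- dm$assignments
  expect_true(all(asg$sample_id == "sampleA"))
  expect_true(all(asg$fwd_edits == 0L & asg$rev_edits == 0L))
  # reverse-complemented reads are recognized with reverse orientation
  truth_ori <- vapply(strsplit(asg$read_id, "|", fixed = TRUE), `[`,
                      character(1), 3)
  expect_identical(asg$orientation == "reverse", truth_ori == "rev")
  # trimmed inserts equal the allele verbatim
  expect_true(all(dm$inserts[["sampleA"]] ==
                  fx$cohort$alleles[["SmMFT2_allele1"]]))
})

test_that("barcode edits within the budget still assign; ties are ambiguous", {
  pool <- make_pool(4)
  manifest <- pool$manifest
  r <- pool$reads[1]
  # mutate 2 bases of the forward barcode region
  x <- r[[1]]
  ori <- strsplit(names(r), "|", fixed = TRUE)[[1]][3]
  if (ori == "rev") x <- revcomp(x)
  substr(x, 2, 2) <- if (substr(x, 2, 2) == "A") "C" else "A"
  substr(x, 5, 5) <- if (substr(x, 5, 5) == "A") "C" else "A"
  dm <- demultiplex(stats::setNames(x, "edited"), manifest)
  expect_identical(dm$assignments$sample_id, "sampleA")
  expect_identical(dm$assignments$fwd_edits, 2L)

  # two manifest entries equidistant from the read barcode tie out
  mani2 <- data.frame(sample_id = c("s1", "s2"),
                      fwd_barcode = c("AAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAT"),
                      rev_barcode = rep("GGGGGGGGCCCCCCCC", 2),
                      stringsAsFactors = FALSE)
  insert <- strrep("ACGT", 50)
  read <- paste0("AAAAAAAAAAAAAAAC", insert, revcomp("GGGGGGGGCCCCCCCC"))
  dm2 <- demultiplex(c(r1 = read), mani2)
  expect_identical(dm2$assignments$reason, "ambiguous")

  expect_error(demultiplex(c(r1 = read), mani2[0, ]), "empty")
  mani_dup <- rbind(mani2[1, ], mani2[1, ])
  expect_error(demultiplex(c(r1 = read), mani_dup), "duplicate")
})

test_that("foreign reads with no matching barcode are unassigned", {
  pool <- make_pool(4)
  junk <- make_scaffold(500, 0.5, seed = 99, id = "junk")
  dm <- demultiplex(c(pool$reads, junk), pool$manifest)
  r <- dm$assignments[dm$assignments$read_id == "junk", ]
  expect_true(is.na(r$sample_id))
  expect_identical(r$reason, "no-match")
})

test_that("a pure error-free pool phases to one exact cluster at ratio 1", {
  pool <- make_pool(30)
  dm <- demultiplex(pool$reads, pool$manifest)
  cl <- phase_alleles(dm$inserts[["sampleA"]])
  expect_length(cl, 1)
  expect_identical(cl[[1]]$consensus, unname(fx$cohort$alleles[["SmMFT2_allele1"]]))
  expect_identical(cl[[1]]$coverage_ratio, 1)
  expect_identical(cl[[1]]$amplicon_coverage, 30L)
  g <- genotype_locus(cl, "sampleA", "locus")
  expect_identical(g$zygosity, "homozygous")
})

test_that("a balanced two-allele pool phases to two 0.5 clusters", {
  pool <- make_pool(15, 15)
  dm <- demultiplex(pool$reads, pool$manifest)
  cl <- phase_alleles(dm$inserts[["sampleA"]])
  expect_length(cl, 2)
  expect_setequal(vapply(cl, `[[`, character(1), "consensus"),
                  unname(fx$cohort$alleles))
  expect_identical(vapply(cl, `[[`, numeric(1), "coverage_ratio"), c(0.5, 0.5))
  g <- genotype_locus(cl, "sampleA", "locus")
  expect_identical(g$zygosity, "heterozygous")
})

test_that("near-balanced ratios round to 0.5 and skewed minors are dropped", {
  pool <- make_pool(26, 24)
  dm <- demultiplex(pool$reads, pool$manifest)
  cl <- phase_alleles(dm$inserts[["sampleA"]])
  expect_identical(vapply(cl, `[[`, numeric(1), "coverage_ratio"), c(0.5, 0.5))

  pool2 <- make_pool(38, 2)
  dm2 <- demultiplex(pool2$reads, pool2$manifest)
  cl2 <- phase_alleles(dm2$inserts[["sampleA"]])
  expect_length(cl2, 1)
  expect_identical(cl2[[1]]$coverage_ratio, 1)

  expect_error(phase_alleles(dm2$inserts[["sampleA"]][1:5]), "too few")
})

test_that("zygosity calling flags multi-allelic cluster sets", {
  mk <- function(frac) list(consensus = "A", subread_coverage = 10L,
                            amplicon_coverage = 10L, fraction = frac,
                            coverage_ratio = round(frac, 1))
  expect_error(genotype_locus(list()), "zero")
  g3 <- genotype_locus(list(mk(0.4), mk(0.3), mk(0.3)))
  expect_identical(g3$zygosity, "flagged")
  expect_true("multi-allelic/contamination" %in% g3$flags)
})

test_that("noisy pools still recover exact allele consensuses (seeded)", {
  for (s in 1:3) {
    pool <- make_pool(30, 0, error_rate = 0.005, seed = s)
    dm <- demultiplex(pool$reads, pool$manifest)
    cl <- phase_alleles(dm$inserts[["sampleA"]])
    expect_length(cl, 1)
    expect_identical(cl[[1]]$consensus,
                     unname(fx$cohort$alleles[["SmMFT2_allele1"]]))
  }
})

test_that("error-free pools across seeds keep perfect demux truth recovery", {
  for (s in 4:6) {
    pool <- make_pool(10, 10, error_rate = 0, seed = s)
    dm <- demultiplex(pool$reads, pool$manifest)
    truth <- vapply(strsplit(dm$assignments$read_id, "|", fixed = TRUE),
                    `[`, character(1), 1)
    expect_true(all(dm$assignments$sample_id == truth))
  }
})
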