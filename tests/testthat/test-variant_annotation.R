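fx <- paper_fixtures()

test_that("allele alignment reconstructs inputs and isolates gap runs", {
  a <- fx$alleles$cen1[["allele1"]]
  same <- align_alleles(a, a)
  expect_false(grepl("-", same$a1, fixed = TRUE))
  expect_false(grepl("-", same$a2, fixed = TRUE))

  al <- align_alleles(a, fx$alleles$cen1[["allele2"]])
  expect_identical(gsub("-", "", al$a1), a)
  expect_identical(gsub("-", "", al$a2), fx$alleles$cen1[["allele2"]])
  runs <- regmatches(al$a2, gregexpr("-+", al$a2))[[1]]
  expect_identical(max(nchar(runs)), 12L)

  b <- a
  substr(b, nchar(b), nchar(b)) <- if (substr(b, nchar(b), nchar(b)) == "A")
    "C" else "A"
  alm <- align_alleles(a, b)
  expect_false(grepl("-", alm$a1, fixed = TRUE))
  expect_identical(sum(strsplit(alm$a1, "")[[1]] != strsplit(alm$a2, "")[[1]]),
                   1L)
  expect_error(align_alleles("", "ACGT"), "empty")
})

test_that("the MFT-2 allele pair yields the printed variant inventory", {
  al <- align_alleles(fx$alleles$mft2[["allele1"]], fx$alleles$mft2[["allele2"]])
  v <- call_variants(al, fx$genes$mft2$model)
  intronic <- v[grepl("intron", v$region), ]
  exonic <- v[grepl("exon", v$region), ]
  expect_identical(sum(intronic$kind == "substitution"), 2L)
  dels <- sort(nchar(intronic$ref[intronic$kind == "deletion"]))
  expect_identical(dels, c(1L, 4L))
  expect_identical(nrow(exonic), 4L)
  expect_true(all(exonic$kind == "substitution"))
  expect_true(all(exonic$effect == "non-synonymous"))
  expect_identical(exonic$pos_cds, c(61L, 277L, 350L, 367L))
  aa <- sprintf("%s%d%s", exonic$aa_ref, exonic$aa_pos, exonic$aa_alt)
  expect_identical(aa, c("V21F", "I93L", "I117R", "A123T"))
})

test_that("the CEN-1 allele pair yields two substitutions and one 12 bp deletion", {
  al <- align_alleles(fx$alleles$cen1[["allele1"]], fx$alleles$cen1[["allele2"]])
  v <- call_variants(al, fx$genes$cen1$model)
  expect_identical(nrow(v), 3L)
  expect_true(all(grepl("intron", v$region)))
  expect_identical(sum(v$kind == "substitution"), 2L)
  del <- v[v$kind == "deletion", ]
  expect_identical(nchar(del$ref), 12L)
  expect_true(all(v$effect == "non-coding"))

  idem <- call_variants(align_alleles(fx$alleles$cen1[["allele1"]],
                                      fx$alleles$cen1[["allele1"]]),
                        fx$genes$cen1$model)
  expect_identical(nrow(idem), 0L)
})

test_that("CDS positions map to protein positions by ceiling division", {
  expect_identical(map_cds_to_protein_position(c(61L, 277L, 350L, 367L)),
                   c(21L, 93L, 117L, 123L))
  expect_identical(map_cds_to_protein_position(3L), 1L)
  expect_error(map_cds_to_protein_position(0L), ">= 1")
})

test_that("effect annotation distinguishes synonymous, missense and stop-gain", {
  cds1 <- "ATGTTTGGACCTTGA"   # M F G P *
  syn <- paste0(substr(cds1, 1, 5), "C", substr(cds1, 7, 15)) # TTT -> TTC (F)
  expect_identical(annotate_effect(6L, "T", "C", cds1, syn)$effect,
                   "synonymous")
  mis <- paste0(substr(cds1, 1, 3), "C", substr(cds1, 5, 15)) # TTT -> CTT (L)
  ann <- annotate_effect(4L, "T", "C", cds1, mis)
  expect_identical(ann$effect, "non-synonymous")
  expect_identical(ann$aa_ref, "F")
  expect_identical(ann$aa_alt, "L")
  # TGG -> TGA by G-to-A
  stop_case <- annotate_effect(408L, "G", "A", fx$ft4$cds,
                               fx$ft4$cds_premature)
  expect_identical(stop_case$effect, "stop-gained")
  expect_identical(stop_case$aa_pos, 136L)
})

test_that("exonic deletions get the frameshift/indel placeholder", {
  g <- fx$genes$mft2
  a1 <- g$seq
  gp <- cds_to_gene_pos(g$model, 100L)
  a2 <- paste0(substr(a1, 1, gp - 1), substr(a1, gp + 2, nchar(a1)))
  v <- call_variants(align_alleles(a1, a2), g$model)
  del <- v[v$kind == "deletion", ]
  expect_identical(nrow(del), 1L)
  expect_identical(del$effect, "frameshift/indel")
})

test_that("upstream extraction is ATG-anchored on both strands", {
  scaf <- make_scaffold(12000, 0.4, seed = 8, id = "s")
  m <- gene_model("g", "s", "+", exons = cbind(start = 10000L, end = 10299L),
                  cds = NA_character_, validate = FALSE)
  up <- extract_upstream(m, scaf, window = 8000L)
  expect_identical(up$length, 8000L)
  expect_false(up$truncated)
  expect_identical(up$seq, substr(scaf[[1]], 2000, 9999))

  mm <- gene_model("g", "s", "-", exons = cbind(start = 2000L, end = 2299L),
                   cds = NA_character_, validate = FALSE)
  upm <- extract_upstream(mm, scaf, window = 500L)
  expect_identical(upm$seq, revcomp(substr(scaf[[1]], 2300, 2799)))

  edge <- gene_model("g", "s", "+", exons = cbind(start = 100L, end = 399L),
                     cds = NA_character_, validate = FALSE)
  upe <- extract_upstream(edge, scaf, window = 8000L)
  expect_identical(upe$length, 99L)
  expect_true(upe$truncated)
})

test_that("promoter repeat scanning reports ATG-relative spans", {
  up <- extract_upstream(fx$promoter$model, fx$promoter$scaffold)
  hits <- scan_promoter_repeats(up, fx$promoter$repeat_library)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$near, -1052L)
  expect_identical(hits$far, -3763L)
  expect_identical(hits$span, 2711L)
  expect_gte(hits$identity, 99)

  none <- scan_promoter_repeats(up, c(other = make_scaffold(800, 0.5, 123)[[1]]))
  expect_identical(nrow(none), 0L)

  # the same repeat degraded to ~65% identity falls below the threshold
  degraded <- withr::with_seed(5, {
    ch <- strsplit(fx$promoter$repeat_library[[1]], "", fixed = TRUE)[[1]]
    idx <- sample(length(ch), round(0.35 * length(ch)))
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  })
  low <- scan_promoter_repeats(up, c(deg = degraded))
  expect_identical(nrow(low), 0L)

  expect_warning(out <- scan_promoter_repeats(up, character(0)), "empty")
  expect_identical(nrow(out), 0L)
})

test_that("calling variants on generated allele pairs recovers the spec", {
  for (s in 1:15) {
    spec <- random_variant_spec(fx$genes$mft2, seed = s)
    pair <- make_allele_pair(fx$genes$mft2, spec)
    v <- call_variants(align_alleles(pair[["allele1"]], pair[["allele2"]]),
                       fx$genes$mft2$model)
    resolved <- pebpminer:::.resolve_spec(spec, fx$genes$mft2$model)
    resolved <- resolved[order(resolved$gene_pos), ]
    v <- v[order(v$pos_gene), ]
    expect_identical(v$pos_gene, resolved$gene_pos)
    expect_identical(v$kind, resolved$kind)
    expect_identical(v$ref, resolved$ref)
    expect_identical(v$alt, resolved$alt)
    # total deleted bases equal the allele length difference
    expect_identical(sum(nchar(v$ref[v$kind == "deletion"])),
                     nchar(pair[["allele1"]]) - nchar(pair[["allele2"]]))
  }
})
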