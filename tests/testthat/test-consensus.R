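fx <- paper_fixtures()

test_that("consensus is the verbatim majority sequence with variants flagged", {
  cds <- fx$genes$mft2$model$cds
  # all three agree
  r <- derive_consensus(list(a1 = cds, a2 = cds, a3 = cds), "locus1")
  expect_identical(r$consensus_cds, cds)
  expect_identical(r$agreement, 3L)
  expect_length(r$variants, 0)

  # two agree, one divergent: the pair wins and the variant is diffed
  div <- cds
  substr(div, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                   substr(cds, 100, 100))[1]
  r2 <- derive_consensus(list(a1 = cds, a2 = cds, a3 = div), "locus1")
  expect_identical(r2$consensus_cds, cds)
  expect_identical(r2$agreement, 2L)
  expect_named(r2$variants, "a3")
  expect_identical(r2$variants[["a3"]]$kind, "substitution")
  expect_identical(r2$variants[["a3"]]$pos_gene, 100L)

  # one assembly missing, other two identical
  r3 <- derive_consensus(list(a1 = cds, a2 = NA, a3 = cds), "locus1")
  expect_identical(r3$agreement, 2L)
  expect_identical(r3$consensus_cds, cds)

  expect_error(derive_consensus(list(a1 = cds), "x"), "fewer than 2")
})

test_that("consensus derivation is order-invariant and flags ties", {
  cds <- fx$genes$cen1$model$cds
  div <- cds
  substr(div, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                 substr(cds, 50, 50))[1]
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  inputs <- list(a1 = cds, a2 = div, a3 = cds)
  res <- lapply(perms, function(p) derive_consensus(inputs[p], "x"))
  expect_true(all(vapply(res, function(r) r$consensus_cds == cds, logical(1))))

  tie <- derive_consensus(list(a1 = cds, a2 = cds, a3 = div, a4 = div), "x")
  expect_true("ambiguous_consensus" %in% tie$flags)
  expect_identical(tie$consensus_cds, cds) # group containing "a1" wins

  none <- derive_consensus(list(a1 = cds, a2 = div), "x")
  expect_true("no_consensus" %in% none$flags)
  expect_identical(none$agreement, 0L)
  expect_null(none$consensus_cds)
})

test_that("a planted per-assembly variant round-trips through consensus", {
  tpl <- fx$templates$mft2
  scaf <- make_scaffold(3000, 0.4, seed = 31, id = "sc")
  emb <- embed_gene(scaf, tpl, start = 501, seed = 32)
  gp <- cds_to_gene_pos(fx$genes$mft2$model, 61L) + 500L
  ref <- substr(emb$scaffold[[1]], gp, gp)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  vs <- variant_spec(gp, "substitution", ref, alt, "exon")
  asm <- make_assembly_set(emb$scaffold, list(a1 = NULL, a2 = NULL, a3 = vs))
  per <- lapply(asm, function(s) splice_exons(s, emb$model$exons, "+"))
  r <- derive_consensus(per, "locus")
  expect_identical(r$agreement, 2L)
  expect_named(r$variants, "a3")
  expect_identical(r$variants[["a3"]]$pos_gene, 61L) # CDS coordinate
  expect_identical(r$variants[["a3"]]$ref, ref)
  expect_identical(r$variants[["a3"]]$alt, alt)
})

test_that("loci are matched across assemblies by reciprocal best identity", {
  c1 <- fx$genes$mft2$model$cds
  c2 <- fx$genes$cen1$model$cds
  sets <- list(
    asmA = c(g1 = c1, g2 = c2),
    asmB = c(x2 = c2, x1 = c1),
    asmC = c(y1 = c1))
  groups <- match_loci_across_assemblies(sets)
  sizes <- vapply(groups, length, integer(1))
  expect_setequal(sizes, c(3L, 2L))
  g3 <- groups[[which(sizes == 3L)]]
  expect_identical(unname(g3[["asmA"]]), "g1")
  expect_identical(unname(g3[["asmB"]]), "x1")
  expect_identical(unname(g3[["asmC"]]), "y1")
})

test_that("family summaries count clades per assembly", {
  cds <- fx$genes$mft2$model$cds
  mk <- function(id, present = c(TRUE, TRUE, TRUE)) {
    per <- list(a1 = if (present[1]) cds else NA,
                a2 = if (present[2]) cds else NA,
                a3 = if (present[3]) cds else NA)
    r <- derive_consensus(per, id)
    r
  }
  recs <- list(mk("ft1"), mk("ft2"), mk("mft1", c(TRUE, FALSE, TRUE)))
  calls <- c(ft1 = "FT-like", ft2 = "FT-like", mft1 = "MFT-like")
  tab <- summarize_family(recs, calls)
  expect_identical(tab["FT-like", "a1"], 2L)
  expect_identical(tab["MFT-like", "a2"], 0L)
  expect_identical(tab["MFT-like", "a3"], 1L)
  expect_identical(tab["TFL1-like", "a1"], 0L)
  expect_error(summarize_family(recs, calls[-1]), "unclassified")

  empty <- summarize_family(list(), character(0))
  expect_true(all(unlist(empty) == 0) || nrow(empty) == 3)
})
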