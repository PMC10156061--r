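# Packaged deterministic fixtures: synthetic PEBP reference proteins
# carrying the published diagnostic residue states, worked-example gene
# templates and allele pairs, a 12-sample amplicon cohort plan, and a
# promoter fixture with a planted upstream transposon fragment. Everything
# here is a pure function of fixed internal seeds; no external sequence is
# bundled or required.

SEGMENT_B <- "LGRQTVYAPGWRQN" # reference positions 128-141 (FT numbering)

#' Bundled synthetic PEBP reference proteins
#'
#' Short synthetic PEBP-like scaffolds carrying the published diagnostic
#' residue states, used for reference-numbered residue mapping: an FT-type
#' reference (Tyr85, Glu109, segment B `LGRQTVYAPGWRQN` at 128-141 with
#' Tyr134/Gly137/Trp138/Gln140, LYN triad, Asn152), a TFL1-type reference
#' (His88, Asp144 on TFL1 numbering), and an MFT-type backbone (Trp at the
#' clade-diagnostic position). Users may substitute real reference
#' sequences by file; numbering metadata travels in the `numbering`
#' attribute.
#'
#' @return named list (ft, tfl1, mft) of proteins with a `numbering`
#'   attribute.
#' @export
pebp_references <- function() {
  core <- with_seed(735L, sample(AA20, 175L, replace = TRUE))
  core[1L] <- "M"
  core[21L] <- "V"
  core[85L] <- "Y"
  core[93L] <- "I"
  core[109L] <- "E"
  core[117L] <- "I"
  core[123L] <- "A"
  core[128:141] <- str_chars(SEGMENT_B)
  core[145:147] <- c("L", "Y", "N")
  core[152L] <- "N"
  ft <- paste(core, collapse = "")
  # TFL1 numbering runs +3 relative to FT up to the segment-B region and +4
  # after it (His88 ~ FT 85, Asp144 ~ FT 140)
  tfl1_ch <- c("M", "A", "R", "S", core[2:120], "G", core[121:175])
  tfl1_ch[88L] <- "H"
  tfl1_ch[144L] <- "D"
  tfl1 <- paste(tfl1_ch, collapse = "")
  mft_ch <- core[1:170]
  mft_ch[85L] <- "W"
  mft <- paste(mft_ch, collapse = "")
  refs <- list(ft = ft, tfl1 = tfl1, mft = mft)
  attr(refs, "numbering") <- list(
    ft = list(clade_pos = 85L, support_pos = 140L, support_aa = "Q",
              diagnostics = c(85L, 109L, 134L, 137L, 138L, 140L, 152L),
              segmentB = 128:141, triad = 145:147),
    tfl1 = list(clade_pos = 88L, support_pos = 144L, support_aa = "D"))
  refs
}

#' Random variant specification for a synthetic gene
#'
#' Draws non-overlapping substitutions and deletions (1-12 bp) spaced at
#' least 12 bp apart, placing intronic edits away from splice sites, and
#' left-normalizes deletions against the allele-1 sequence so the spec is
#' in canonical (leftmost) form.
#'
#' @param gene a `synthetic_gene`.
#' @param n_exon_sub,n_intron_sub,n_intron_del edit counts.
#' @param seed integer seed.
#' @return a [variant_spec()].
#' @export
random_variant_spec <- function(gene, n_exon_sub = 2L, n_intron_sub = 2L,
                                n_intron_del = 2L, seed = 1L) {
  model <- gene$model
  seq <- gene$seq
  ex <- model$exons
  with_seed(seed, {
    lens <- ex[, 2L] - ex[, 1L] + 1L
    cds_len <- sum(lens)
    introns <- cbind(ex[-nrow(ex), 2L] + 1L, ex[-1L, 1L] - 1L)
    taken <- matrix(numeric(0), ncol = 2L) # gene-coordinate intervals used
    clear <- function(lo, hi) {
      nrow(taken) == 0L || all(hi + 12L < taken[, 1L] | lo - 12L > taken[, 2L])
    }
    rows <- list()
    add <- function(pos, kind, ref, alt, region) {
      rows[[length(rows) + 1L]] <<- data.frame(pos = pos, kind = kind,
                                               ref = ref, alt = alt,
                                               region = region)
    }
    for (i in seq_len(n_exon_sub)) {
      repeat {
        p <- sample(cds_len, 1L)
        gp <- cds_to_gene_pos(model, p)
        if (clear(gp, gp)) break
      }
      taken <- rbind(taken, c(gp, gp))
      ref <- substr(seq, gp, gp)
      add(p, "substitution", ref, sample(setdiff(DNA_BASES, ref), 1L), "exon")
    }
    for (i in seq_len(n_intron_sub)) {
      repeat {
        it <- introns[sample(nrow(introns), 1L), ]
        p <- sample((it[1L] + 4L):(it[2L] - 4L), 1L)
        if (clear(p, p)) break
      }
      taken <- rbind(taken, c(p, p))
      ref <- substr(seq, p, p)
      add(p, "substitution", ref, sample(setdiff(DNA_BASES, ref), 1L), "intron")
    }
    for (i in seq_len(n_intron_del)) {
      repeat {
        it <- introns[sample(nrow(introns), 1L), ]
        len <- sample(12L, 1L)
        lo <- it[1L] + 6L
        hi <- it[2L] - 6L - len
        if (hi < lo) next
        p <- sample(lo:hi, 1L)
        # left-normalize; reject draws whose canonical position would slide
        # out of the intron interior (the caller normalizes without bounds)
        while (p > it[1L] + 2L &&
               substr(seq, p - 1L, p - 1L) == substr(seq, p + len - 1L, p + len - 1L)) {
          p <- p - 1L
        }
        if (p >= it[1L] + 4L && clear(p, p + len - 1L)) break
      }
      taken <- rbind(taken, c(p, p + len - 1L))
      add(p, "deletion", substr(seq, p, p + len - 1L), "", "intron")
    }
    df <- do.call(rbind, rows)
    df <- df[order(df$region, df$pos), , drop = FALSE]
    variant_spec(df$pos, df$kind, df$ref, df$alt, df$region)
  })
}

# left-normalize a deletion position against a sequence, staying >= floor
.left_normalize_del <- function(seq, pos, len, floor = 2L) {
  while (pos > floor &&
         substr(seq, pos - 1L, pos - 1L) ==
         substr(seq, pos + len - 1L, pos + len - 1L)) {
    pos <- pos - 1L
  }
  pos
}

.fixture_env <- new.env(parent = emptyenv())

#' Packaged deterministic fixture bundle
#'
#' A self-contained worked-example dataset realizing the published variant
#' tables at desk scale:
#'
#' * `references`: the synthetic PEBP reference proteins
#'   ([pebp_references()]).
#' * `proteins`: classifiable fixture proteins — an inducer-type FT
#'   (Tyr134/Gly137/Trp138, LYN), a repressor-type FT (Asn134/Ser138, FHN
#'   triad), a Gly137-variant FT, a TFL1-type and an MFT-type protein.
#' * `genes`: `mft2` (981 bp gene, 513 bp CDS, 170 aa) and `cen1` (1027 bp
#'   gene, 528 bp CDS, 175 aa) synthetic genes with the canonical
#'   195/62/41/215 and 200/62/41/225 exon structures.
#' * `specs` / `alleles`: the MFT-2 allele pair (2 intronic substitutions,
#'   1 bp + 4 bp intronic deletions, and exonic substitutions at CDS
#'   61/277/350/367 in codon contexts GTT, ATC, ATA, GCT so the amino-acid
#'   changes are V21F, I93L, I117R, A123T) and the CEN-1 pair (2 intronic
#'   substitutions plus a 12 bp intronic deletion; allele lengths 1027/1015).
#' * `ft4`: a CDS whose codon 136 is TGG plus the G-to-A edited copy
#'   carrying the premature TGA stop (truncated CDS 408 bp, 135 aa).
#' * `cohort`: a 12-sample amplicon plan — 11 samples homozygous for MFT-2
#'   allele 1 and one (Sa_C9) heterozygous at weights 0.5/0.5 — with
#'   amplicon counts of tens to ~190 per sample and unique asymmetric
#'   barcode pairs.
#' * `promoter`: a scaffold with the FT-type gene embedded at position 9001
#'   and a 2712 bp transposon-like repeat planted at ATG-relative positions
#'   -1052 to -3763, plus the matching repeat library.
#'
#' @return named list (cached after first call).
#' @export
paper_fixtures <- function() {
  if (!is.null(.fixture_env$bundle)) return(.fixture_env$bundle)
  refs <- pebp_references()
  core <- str_chars(refs$ft)
  mk <- function(edits) {
    ch <- core
    for (p in names(edits)) ch[as.integer(p)] <- edits[[p]]
    paste(ch, collapse = "")
  }
  proteins <- c(
    SmFT1_syn = refs$ft,
    SmFT2_syn = mk(list(`134` = "N", `138` = "S", `145` = "F", `146` = "H")),
    SmFT3_syn = mk(list(`137` = "A")),
    SmFT4_syn = mk(list(`136` = "W")),
    SmCEN1_syn = substr(refs$tfl1, 1L, 175L),
    SmMFT2_syn = refs$mft)

  # gene templates and realized genes
  mft2_template <- template_from_protein(
    "SmMFT2_syn", proteins[["SmMFT2_syn"]], exon1_len = 195L,
    intron_lengths = c(150L, 160L, 158L),
    codon_overrides = list(`117` = "ATA"))
  cen1_template <- template_from_protein(
    "SmCEN1_syn", proteins[["SmCEN1_syn"]], exon1_len = 200L,
    intron_lengths = c(166L, 167L, 166L))
  ft1_template <- template_from_protein(
    "SmFT1_syn", proteins[["SmFT1_syn"]], exon1_len = 195L,
    intron_lengths = c(150L, 200L, 250L))
  mft2_gene <- build_gene(mft2_template, seed = 2023L)
  cen1_gene <- build_gene(cen1_template, seed = 2024L)

  # MFT-2 allele-pair spec: intronic edits on gene coordinates, exonic
  # substitutions on CDS coordinates (positions 61, 277, 350, 367)
  gseq <- mft2_gene$seq
  rot <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  ip <- c(250L, 500L) # intron 1 and intron 2 substitution sites
  d1 <- .left_normalize_del(gseq, 300L, 1L, floor = 202L)
  d4 <- .left_normalize_del(gseq, 650L, 4L, floor = 615L)
  mft2_spec <- variant_spec(
    pos = c(61L, 277L, 350L, 367L, ip[1L], d1, ip[2L], d4),
    kind = c(rep("substitution", 4L), "substitution", "deletion",
             "substitution", "deletion"),
    ref = c("G", "A", "T", "G",
            substr(gseq, ip[1L], ip[1L]), substr(gseq, d1, d1),
            substr(gseq, ip[2L], ip[2L]), substr(gseq, d4, d4 + 3L)),
    alt = c("T", "C", "G", "A",
            rot(substr(gseq, ip[1L], ip[1L])), "",
            rot(substr(gseq, ip[2L], ip[2L])), ""),
    region = c(rep("exon", 4L), rep("intron", 4L)))

  cseq <- cen1_gene$seq
  cp <- c(260L, 700L)
  d12 <- .left_normalize_del(cseq, 470L, 12L, floor = 435L)
  cen1_spec <- variant_spec(
    pos = c(cp[1L], d12, cp[2L]),
    kind = c("substitution", "deletion", "substitution"),
    ref = c(substr(cseq, cp[1L], cp[1L]), substr(cseq, d12, d12 + 11L),
            substr(cseq, cp[2L], cp[2L])),
    alt = c(rot(substr(cseq, cp[1L], cp[1L])), "",
            rot(substr(cseq, cp[2L], cp[2L]))),
    region = c("intron", "intron", "intron"))

  alleles <- list(mft2 = make_allele_pair(mft2_gene, mft2_spec),
                  cen1 = make_allele_pair(cen1_gene, cen1_spec))

  # premature-stop worked example: codon 136 TGG, G-to-A at its third base
  ft4_cds <- reverse_translate(proteins[["SmFT4_syn"]])
  stopifnot(substr(ft4_cds, 406L, 408L) == "TGG")
  ft4_premature <- paste0(substr(ft4_cds, 1L, 407L), "A",
                          substr(ft4_cds, 409L, nchar(ft4_cds)))

  # 12-sample amplicon cohort: counts on the scale of the printed screening
  # table; Sa_C9 is the single heterozygous sample
  ids <- c("Ry_C1", "Ry_C2", "Ry_C7", "An_C10", "An_C13", "An_C2",
           "Sa_C7", "Sa_C8", "Sa_C9", "Ni_C3", "Ni_C8", "Ni_C1")
  nreads <- c(169L, 140L, 186L, 139L, 169L, 120L,
              91L, 159L, 119L, 98L, 160L, 134L)
  bc <- default_barcodes(length(ids))
  plans <- lapply(seq_along(ids), function(i) {
    w <- if (ids[i] == "Sa_C9") {
      c(SmMFT2_allele1 = 0.5, SmMFT2_allele2 = 0.5)
    } else {
      c(SmMFT2_allele1 = 1.0)
    }
    sample_plan(ids[i], c(bc$fwd[i], bc$rev[i]), w, nreads[i])
  })
  manifest <- data.frame(sample_id = ids, fwd_barcode = bc$fwd,
                         rev_barcode = bc$rev, stringsAsFactors = FALSE)
  cohort_alleles <- c(SmMFT2_allele1 = unname(alleles$mft2[["allele1"]]),
                      SmMFT2_allele2 = unname(alleles$mft2[["allele2"]]))

  # promoter fixture: FT-type gene at scaffold position 9001 with a 2712 bp
  # repeat occupying ATG-relative -3763..-1052
  scaf <- make_scaffold(10500L, gc = 0.4, seed = 77L, id = "scaf_prom")
  emb <- embed_gene(scaf, ft1_template, start = 9001L, strand = "+",
                    seed = 5L)
  rep_seq <- unname(make_scaffold(2712L, gc = 0.45, seed = 99L, id = "RE1_like"))
  pscaf <- emb$scaffold
  p1 <- 9001L - 3763L
  p2 <- 9001L - 1052L
  pscaf[[1L]] <- paste0(substr(pscaf[[1L]], 1L, p1 - 1L), rep_seq,
                        substr(pscaf[[1L]], p2 + 1L, nchar(pscaf[[1L]])))
  stopifnot(nchar(pscaf[[1L]]) == 10500L)

  bundle <- list(
    references = refs,
    proteins = proteins,
    templates = list(mft2 = mft2_template, cen1 = cen1_template,
                     ft1 = ft1_template),
    genes = list(mft2 = mft2_gene, cen1 = cen1_gene),
    specs = list(mft2 = mft2_spec, cen1 = cen1_spec),
    alleles = alleles,
    ft4 = list(cds = ft4_cds, cds_premature = ft4_premature,
               stop_codon_index = 136L),
    cohort = list(plans = plans, manifest = manifest,
                  alleles = cohort_alleles, het_sample = "Sa_C9"),
    promoter = list(scaffold = pscaf, model = emb$model,
                    repeat_library = c(RE1_like = rep_seq)))
  .fixture_env$bundle <- bundle
  bundle
}
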