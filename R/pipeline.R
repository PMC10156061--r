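# End-to-end pipeline over the packaged fixture bundle: simulate ->
# mine -> annotate -> consensus -> classify -> phylo -> demux -> phase ->
# callvars -> report, with one run directory and all seeds/thresholds
# echoed in the report.

#' Run the full pipeline on the packaged fixture bundle
#'
#' Orchestrates every stage on synthetic inputs derived from
#' [paper_fixtures()]: a three-assembly set with a planted divergent allele
#' is mined and annotated; a cross-assembly consensus is derived; fixture
#' proteins are classified; an optional bootstrap phylogeny of a planted
#' protein family is built; the amplicon cohort is simulated,
#' demultiplexed, phased and genotyped; and the detected allele pair is
#' variant-called. Any stage failure aborts with the stage name. Reruns
#' with the same config and seed are byte-identical for deterministic
#' stages.
#'
#' @param config list from [read_run_config()] plus optional entries
#'   `out_dir` (default tempdir subdirectory) and `cohort_samples`
#'   (character subset of cohort sample ids; default all 12).
#' @return list (class `pipeline_report`): per-stage record counts, family
#'   table, genotype table, variant table, file paths, config echo.
#' @export
run_pipeline <- function(config = read_run_config()) {
  if (!is.null(config$paths)) {
    missing <- Filter(function(p) !file.exists(p), config$paths)
    if (length(missing)) {
      stop("pipeline validation: missing input file(s): ",
           paste(unlist(missing), collapse = ", "))
    }
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- file.path(tempdir(), "pebpminer_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message("[pebpminer] ", msg)
  }
  stage <- function(name, expr) {
    note("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  report <- list(seed = seed, config = config, stages = list())

  fx <- stage("simulate", {
    paper_fixtures()
  })

  # three-assembly set: assembly C carries two exonic substitutions of the
  # embedded MFT-type gene
  mining <- stage("mine", {
    scaf <- make_scaffold(6000L, gc = 0.4, seed = seed, id = "scaf1")
    emb <- embed_gene(scaf, fx$templates$mft2, start = 1501L, strand = "+",
                      seed = seed + 1L)
    gp <- cds_to_gene_pos(fx$genes$mft2$model, c(61L, 277L))
    sp <- 1500L + gp
    ref <- vapply(sp, function(p) substr(emb$scaffold[[1L]], p, p),
                  character(1))
    alt <- vapply(ref, function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]],
                  character(1))
    vs <- variant_spec(sp, rep("substitution", 2L), ref, alt,
                       rep("exon", 2L))
    assemblies <- make_assembly_set(emb$scaffold,
                                    list(asmA = NULL, asmB = NULL, asmC = vs))
    loci <- lapply(names(assemblies), function(a) {
      frames <- sixframe_translate(stats::setNames(assemblies[[a]], a))
      hits <- homology_search(frames, fx$proteins["SmMFT2_syn"],
                              k = config$seed_k,
                              min_score = config$min_score,
                              min_identity = config$min_identity)
      merge_hits_to_loci(hits, max_gap = config$max_gap)
    })
    names(loci) <- names(assemblies)
    list(assemblies = assemblies, loci = loci, truth_model = emb$model)
  })
  report$stages$mine <- list(
    n_loci = sum(vapply(mining$loci, nrow, integer(1))))

  models <- stage("annotate", {
    out <- list()
    for (a in names(mining$assemblies)) {
      lr <- mining$loci[[a]]
      if (nrow(lr) == 0L) next
      locus <- c(max(1L, lr$start[1L] - 200L),
                 min(nchar(mining$assemblies[[a]]), lr$end[1L] + 200L))
      scaffold_cds <- splice_exons(mining$assemblies[[a]],
                                   mining$truth_model$exons, "+")
      m <- spliced_align_cds(scaffold_cds, mining$assemblies[[a]],
                             locus = locus, strand = lr$strand[1L],
                             locus_id = "SmMFT2_locus", scaffold_id = a)
      out[[a]] <- m
    }
    write_gene_models(out, file.path(out_dir, "gene_models.gff3"))
    out
  })
  report$stages$annotate <- list(
    n_models = length(models),
    structure = lapply(models, function(m) validate_structure(m)$checks))

  cons <- stage("consensus", {
    per <- vapply(models, function(m) m$cds, character(1))
    derive_consensus(as.list(per), locus_id = "SmMFT2_locus")
  })
  report$stages$consensus <- list(
    agreement = cons$agreement,
    n_variant_assemblies = length(cons$variants))

  cls <- stage("classify", {
    lapply(fx$proteins, classify_protein, refs = fx$references)
  })
  clade_tab <- table(vapply(cls, `[[`, character(1), "clade"))
  report$stages$classify <- list(clades = clade_tab)
  report$family_table <- summarize_family(
    list(cons), stats::setNames("MFT-like", "SmMFT2_locus"))

  if (config$bootstrap > 0L) {
    phylo <- stage("phylo", {
      fam <- make_protein_family(seed = seed)
      bs <- bootstrap_support(fam, model = "poisson",
                              replicates = config$bootstrap, seed = seed)
      write_newick(bs$tree, file.path(out_dir, "family_tree.nwk"))
      list(support = bs$support,
           monophyly = check_clades(bs$tree, attr(fam, "groups")))
    })
    report$stages$phylo <- phylo
  } else {
    note("stage phylo skipped (bootstrap = 0)")
    report$stages$phylo <- "skipped"
  }

  amplicon <- stage("phase", {
    plans <- fx$cohort$plans
    if (!is.null(config$cohort_samples)) {
      keep <- vapply(plans, function(p) p$sample_id %in% config$cohort_samples,
                     logical(1))
      plans <- plans[keep]
    }
    reads <- simulate_amplicon_reads(fx$cohort$alleles, plans, seed = seed)
    manifest <- attr(reads, "manifest")
    dm <- demultiplex(reads, manifest, max_edits = config$barcode_max_edits)
    geno <- list(); rows <- list()
    allele_seqs <- character(0)
    for (sid in names(dm$inserts)) {
      ins <- dm$inserts[[sid]]
      if (length(ins) < config$min_reads) next
      cl <- phase_alleles(ins,
                          identity_threshold = config$identity_threshold,
                          min_fraction = config$min_fraction,
                          min_reads = config$min_reads)
      g <- genotype_locus(cl, sample_id = sid, locus_id = "SmMFT2_locus")
      geno[[sid]] <- g
      for (al in g$alleles) {
        if (!al$consensus %in% allele_seqs) {
          allele_seqs <- c(allele_seqs, al$consensus)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sid,
          subread_coverage = al$subread_coverage,
          amplicon_coverage = al$amplicon_coverage,
          coverage_ratio = al$coverage_ratio,
          allele = sprintf("allele%d", match(al$consensus, allele_seqs)),
          zygosity = g$zygosity, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(out_dir, "genotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(genotypes = geno, table = tab, allele_seqs = allele_seqs,
         assignments = dm$assignments)
  })
  report$genotype_table <- amplicon$table
  report$stages$phase <- list(
    n_samples = length(amplicon$genotypes),
    n_distinct_alleles = length(amplicon$allele_seqs),
    n_heterozygous = sum(vapply(amplicon$genotypes, function(g) {
      g$zygosity == "heterozygous"
    }, logical(1))))

  variants <- stage("callvars", {
    if (length(amplicon$allele_seqs) >= 2L) {
      # allele 1 is the first-discovered (cohort-major) allele
      a1 <- amplicon$allele_seqs[1L]
      a2 <- amplicon$allele_seqs[2L]
      al <- align_alleles(a1, a2)
      vt <- call_variants(al, fx$genes$mft2$model)
      write_variants(vt, "SmMFT2_locus",
                     file.path(out_dir, "variants.vcf"), a1)
      vt
    } else {
      data.frame()
    }
  })
  report$variant_table <- variants

  report$log <- log_lines
  writeLines(log_lines, file.path(out_dir, "run.log"))
  report$out_dir <- out_dir
  class(report) <- "pipeline_report"
  report
}
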