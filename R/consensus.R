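# Cross-assembly consensus calling: match loci across assemblies, derive a
# verbatim consensus where at least two assemblies agree at 100% identity,
# and flag divergent alleles as variants.

#' Derive a cross-assembly consensus CDS for one locus
#'
#' The consensus is the sequence shared verbatim by the largest subset (at
#' least two) of assemblies. Assemblies whose CDS differs from the
#' consensus are diffed against it and recorded as variants; if no two
#' assemblies agree the record is flagged `no_consensus`. The result is
#' invariant to the order of the input map. A tie between two disjoint
#' agreeing groups is resolved toward the group containing the
#' lexicographically first assembly name and flagged `ambiguous_consensus`.
#'
#' @param per_assembly_cds named character vector/list, assembly ->
#'   CDS or NA for a missing locus.
#' @param locus_id identifier for the record.
#' @return list (class `consensus_record`): locus_id, per_assembly_cds,
#'   consensus_cds, agreement, variants (assembly -> variant data frame),
#'   flags.
#' @export
derive_consensus <- function(per_assembly_cds, locus_id = "locus") {
  cds <- unlist(per_assembly_cds)
  present <- cds[!is.na(cds)]
  if (length(present) < 2L) stop("fewer than 2 assemblies provide a CDS")
  # order-invariance: group by sequence, deterministic assembly ordering
  present <- present[order(names(present))]
  groups <- split(names(present), unname(present))
  sizes <- vapply(groups, length, integer(1))
  flags <- character(0)
  consensus <- NULL
  agreement <- 0L
  variants <- list()
  if (max(sizes) >= 2L) {
    top <- which(sizes == max(sizes))
    if (length(top) > 1L) {
      flags <- c(flags, "ambiguous_consensus")
      firsts <- vapply(groups[top], function(g) sort(g)[1L], character(1))
      top <- top[order(firsts)][1L]
    }
    consensus <- names(groups)[top]
    agreement <- sizes[[top]]
    carriers <- groups[[top]]
    for (a in setdiff(names(present), carriers)) {
      al <- align_alleles(consensus, present[[a]])
      model <- gene_model(locus_id = locus_id, scaffold_id = locus_id,
                          strand = "+",
                          exons = cbind(start = 1L, end = nchar(consensus)),
                          cds = consensus, validate = FALSE)
      variants[[a]] <- call_variants(al, model)
    }
  } else {
    flags <- c(flags, "no_consensus")
  }
  structure(list(locus_id = locus_id, per_assembly_cds = cds,
                 consensus_cds = consensus, agreement = agreement,
                 variants = variants, flags = flags),
            class = "consensus_record")
}

#' Match loci across assemblies by reciprocal best identity
#'
#' CDSs from different assemblies are paired when each is the other's best
#' match at >= `min_identity` percent global identity; connected groups of
#' reciprocal best pairs form one locus.
#'
#' @param cds_sets named list: assembly -> named character vector of CDSs.
#' @param min_identity percent identity threshold (default 95).
#' @return list of locus groups, each a named character vector assembly ->
#'   local CDS name.
#' @export
match_loci_across_assemblies <- function(cds_sets, min_identity = 95) {
  assemblies <- names(cds_sets)
  nodes <- unlist(lapply(assemblies, function(a) {
    paste0(a, "::", names(cds_sets[[a]]))
  }))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  for (i in seq_along(assemblies)) {
    for (j in seq_along(assemblies)) {
      if (j <= i) next
      a <- assemblies[i]; b <- assemblies[j]
      sa <- cds_sets[[a]]; sb <- cds_sets[[b]]
      if (!length(sa) || !length(sb)) next
      idm <- matrix(0, length(sa), length(sb),
                    dimnames = list(names(sa), names(sb)))
      for (x in names(sa)) for (y in names(sb)) {
        idm[x, y] <- global_identity(sa[[x]], sb[[y]])
      }
      for (x in names(sa)) {
        y <- colnames(idm)[which.max(idm[x, ])]
        if (idm[x, y] >= min_identity &&
            rownames(idm)[which.max(idm[, y])] == x) {
          union_(which(nodes == paste0(a, "::", x)),
                 which(nodes == paste0(b, "::", y)))
        }
      }
    }
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  groups <- split(nodes, roots)
  lapply(unname(groups), function(g) {
    parts <- strsplit(g, "::", fixed = TRUE)
    stats::setNames(vapply(parts, `[`, character(1), 2L),
                    vapply(parts, `[`, character(1), 1L))
  })
}

#' Summarize clade counts per assembly
#'
#' @param records list of `consensus_record`s.
#' @param clade_calls named character vector: locus_id -> clade
#'   ("FT-like", "TFL1-like", "MFT-like").
#' @return data.frame clade x assembly count table.
#' @export
summarize_family <- function(records, clade_calls) {
  clades <- c("FT-like", "TFL1-like", "MFT-like")
  assemblies <- sort(unique(unlist(lapply(records, function(r) {
    names(r$per_assembly_cds)
  }))))
  tab <- matrix(0L, nrow = length(clades), ncol = length(assemblies),
                dimnames = list(clades, assemblies))
  for (r in records) {
    cl <- if (r$locus_id %in% names(clade_calls)) {
      clade_calls[[r$locus_id]]
    } else NA_character_
    if (is.na(cl)) stop("unclassified record: ", r$locus_id)
    if (!cl %in% clades) next # unclassified loci are not counted
    for (a in names(r$per_assembly_cds)) {
      if (!is.na(r$per_assembly_cds[[a]])) tab[cl, a] <- tab[cl, a] + 1L
    }
  }
  as.data.frame(tab)
}
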