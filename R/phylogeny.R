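# Protein distances (p, Poisson, gamma-corrected), neighbour-joining tree
# construction, bootstrap support, and clade monophyly checks. Tree
# agglomeration is delegated to the standard neighbour-joining
# implementation in ape; distances, resampling and split bookkeeping are
# computed here with pairwise-deletion gap handling.

#' Pairwise protein distance
#'
#' Columns where either row has a gap are excluded (pairwise deletion);
#' p is the proportion of differing compared sites. Models: `p` (d = p),
#' `poisson` (d = -ln(1 - p)), `gamma` (d = alpha ((1-p)^(-1/alpha) - 1)).
#'
#' @param a,b equal-length gapped protein rows.
#' @param model "p", "poisson" or "gamma".
#' @param alpha gamma shape (model = "gamma" only; default 1).
#' @return list(p, d, compared).
#' @export
pairwise_distance <- function(a, b, model = c("poisson", "p", "gamma"),
                              alpha = 1.0) {
  model <- match.arg(model)
  ca <- str_chars(a); cb <- str_chars(b)
  stopifnot(length(ca) == length(cb))
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("no comparable columns (all pairwise gaps)")
  p <- mean(ca[keep] != cb[keep])
  d <- switch(model,
    p = p,
    poisson = {
      if (p >= 1) stop("undefined Poisson distance: p = 1")
      -log(1 - p)
    },
    gamma = {
      if (p >= 1) stop("undefined gamma distance: p = 1")
      alpha * ((1 - p)^(-1 / alpha) - 1)
    })
  list(p = p, d = d, compared = sum(keep))
}

#' Distance matrix over an alignment
#'
#' @param aln named character vector of equal-length gapped rows (>= 2 taxa).
#' @param model,alpha see [pairwise_distance()].
#' @return list (class `distance_matrix`): d and p matrices, model, alpha.
#' @export
dist_matrix <- function(aln, model = c("poisson", "p", "gamma"), alpha = 1.0) {
  model <- match.arg(model)
  stopifnot(length(aln) >= 2L, length(unique(nchar(aln))) == 1L)
  n <- length(aln)
  taxa <- names(aln)
  d <- p <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pd <- pairwise_distance(aln[[i]], aln[[j]], model, alpha)
    d[i, j] <- d[j, i] <- pd$d
    p[i, j] <- p[j, i] <- pd$p
  }
  structure(list(d = d, p = p, model = model, alpha = alpha,
                 gap_handling = "pairwise-deletion"),
            class = "distance_matrix")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`); on an additive matrix the
#' result is the unique additive tree with exact branch lengths. Negative
#' branch-length estimates are clamped to zero and flagged.
#'
#' @param D `distance_matrix` or a symmetric numeric matrix.
#' @return `phylo` tree; attribute `clamped` is TRUE if any branch was
#'   negative before clamping.
#' @export
nj_tree <- function(D) {
  m <- if (inherits(D, "distance_matrix")) D$d else D
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (nrow(m) < 3L) stop("need at least 3 taxa")
  if (any(m < 0)) stop("negative distances in input")
  if (!isTRUE(all.equal(m, t(m)))) stop("asymmetric distance matrix")
  tr <- ape::nj(m)
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  if (all(m[upper.tri(m)] == 0)) attr(tr, "zero_distance_warning") <- TRUE
  tr
}

# canonical string key for the split induced by dropping an edge: the side
# not containing the alphabetically first taxon, sorted
.split_key <- function(leaves, all_taxa) {
  anchor <- sort(all_taxa)[1L]
  side <- if (anchor %in% leaves) setdiff(all_taxa, leaves) else leaves
  paste(sort(side), collapse = "|")
}

# keys of all non-trivial splits of an unrooted tree
.tree_splits <- function(tree) {
  taxa <- tree$tip.label
  ntip <- length(taxa)
  internal <- tree$edge[tree$edge[, 2L] > ntip, 2L]
  keys <- vapply(internal, function(node) {
    tips <- phangorn::Descendants(tree, node, type = "tips")[[1L]]
    .split_key(taxa[tips], taxa)
  }, character(1))
  unique(keys[vapply(strsplit(keys, "|", fixed = TRUE), function(s) {
    length(s) >= 2L && length(s) <= ntip - 2L
  }, logical(1))])
}

#' Bootstrap support for a neighbour-joining protein tree
#'
#' Alignment columns are resampled with replacement per replicate, a
#' replicate NJ tree is built under the same distance model, and the
#' support of each internal split of the original tree is the fraction of
#' replicates containing it. Deterministic given the seed.
#'
#' @param aln named character vector of equal-length gapped rows.
#' @param model,alpha distance model (see [pairwise_distance()]).
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return list: tree (`phylo` with `node.label` support on internal
#'   nodes), support (named by split key), replicates, seed.
#' @export
bootstrap_support <- function(aln, model = "poisson", alpha = 1.0,
                              replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1L)
  L <- unique(nchar(aln))
  stopifnot(length(L) == 1L)
  if (L < 2L) stop("alignment shorter than 2 columns")
  rows <- lapply(aln, str_chars)
  tree <- nj_tree(dist_matrix(aln, model, alpha))
  keys <- .tree_splits(tree)
  counts <- stats::setNames(numeric(length(keys)), keys)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- vapply(rows, function(ch) paste(ch[cols], collapse = ""),
                        character(1))
      rep_tree <- try(nj_tree(dist_matrix(rep_aln, model, alpha)),
                      silent = TRUE)
      if (inherits(rep_tree, "try-error")) next
      rep_keys <- .tree_splits(rep_tree)
      hit <- keys %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- counts / replicates
  # attach support to internal nodes as node labels
  taxa <- tree$tip.label
  ntip <- length(taxa)
  nnode <- tree$Nnode
  labels <- rep("", nnode)
  for (node in (ntip + 1L):(ntip + nnode)) {
    tips <- phangorn::Descendants(tree, node, type = "tips")[[1L]]
    key <- .split_key(taxa[tips], taxa)
    if (key %in% names(support)) {
      labels[node - ntip] <- format(support[[key]], digits = 3)
    }
  }
  tree$node.label <- labels
  list(tree = tree, support = support, replicates = replicates, seed = seed)
}

#' Check clade monophyly on an unrooted tree
#'
#' A group is monophyletic iff its leaves form one bipartition of the
#' unrooted tree; the full leaf set is monophyletic by convention. Groups
#' of fewer than 2 leaves are an error.
#'
#' @param tree `phylo` tree.
#' @param groups named list: clade -> taxa.
#' @return named logical vector.
#' @export
check_clades <- function(tree, groups) {
  taxa <- tree$tip.label
  splits <- .tree_splits(tree)
  vapply(groups, function(g) {
    if (length(g) < 2L) stop("group with fewer than 2 leaves")
    stopifnot(all(g %in% taxa))
    if (length(g) == length(taxa)) return(TRUE)
    if (length(g) == length(taxa) - 1L) return(TRUE) # complement is one leaf
    .split_key(g, taxa) %in% splits
  }, logical(1))
}

#' Multiple protein alignment via MAFFT
#'
#' Thin wrapper over the system `mafft` binary for the phylogeny path. If
#' all sequences already share one length they are returned unchanged
#' (treated as aligned).
#'
#' @param seqs named character vector of proteins.
#' @return named character vector of equal-length gapped rows.
#' @export
align_proteins <- function(seqs) {
  if (length(unique(nchar(seqs))) == 1L) return(seqs)
  mafft <- Sys.which("mafft")
  if (mafft == "") stop("mafft not found on PATH and sequences are unaligned")
  inf <- tempfile(fileext = ".fa"); outf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  write_fasta(seqs, inf)
  system2(mafft, c("--auto", "--quiet", "--anysymbol", inf),
          stdout = outf, stderr = FALSE)
  out <- read_fasta(outf)
  out[names(seqs)]
}

#' Write a tree with support values as Newick
#'
#' @param tree `phylo` tree (node labels carry bootstrap support).
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
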