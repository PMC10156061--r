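# Independent oracles used by the test suite.

# Least-squares quartet oracle: enumerate the three unrooted 4-taxon
# topologies, fit the five branch lengths by ordinary least squares, and
# return the minimum-SSE topology (as the sorted cherry containing taxon 1)
# plus its fitted lengths. Independent of the neighbour-joining path.
ls_quartet <- function(D) {
  taxa <- rownames(D)
  arrangements <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  # columns: external branches of a,b,c,d and the internal branch
  X <- rbind(
    c(1, 1, 0, 0, 0), # d(a,b)
    c(1, 0, 1, 0, 1), # d(a,c)
    c(1, 0, 0, 1, 1), # d(a,d)
    c(0, 1, 1, 0, 1), # d(b,c)
    c(0, 1, 0, 1, 1), # d(b,d)
    c(0, 0, 1, 1, 0)) # d(c,d)
  best <- NULL
  for (s in arrangements) {
    a <- s[1]; b <- s[2]; cc <- s[3]; d <- s[4]
    y <- c(D[a, b], D[a, cc], D[a, d], D[b, cc], D[b, d], D[cc, d])
    fit <- qr.solve(X, y)
    sse <- sum((X %*% fit - y)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(cherry = sort(c(taxa[a], taxa[b])), sse = sse,
                   lengths = as.numeric(fit))
    }
  }
  best
}

# the cherry (pair of taxa behind one internal edge) containing the first
# taxon of an unrooted 4-taxon phylo tree
tree_cherry <- function(tree) {
  taxa <- tree$tip.label
  ntip <- length(taxa)
  internal <- tree$edge[tree$edge[, 2] > ntip, 2]
  for (node in internal) {
    tips <- phangorn::Descendants(tree, node, type = "tips")[[1]]
    if (length(tips) == 2) {
      side <- sort(taxa[tips])
      if (taxa[1] %in% side) return(side)
      return(sort(setdiff(taxa, side)))
    }
  }
  NULL
}

# additive 4-taxon distance matrix from quartet branch lengths:
# cherry (t1,t2) | (t3,t4), external lengths l1..l4, internal m
quartet_matrix <- function(l = c(0.1, 0.2, 0.3, 0.4), m = 0.05) {
  taxa <- paste0("t", 1:4)
  D <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  D["t1", "t2"] <- D["t2", "t1"] <- l[1] + l[2]
  D["t1", "t3"] <- D["t3", "t1"] <- l[1] + m + l[3]
  D["t1", "t4"] <- D["t4", "t1"] <- l[1] + m + l[4]
  D["t2", "t3"] <- D["t3", "t2"] <- l[2] + m + l[3]
  D["t2", "t4"] <- D["t4", "t2"] <- l[2] + m + l[4]
  D["t3", "t4"] <- D["t4", "t3"] <- l[3] + l[4]
  D
}

# random unrooted tree with positive branch lengths and its additive
# (cophenetic) distance matrix
random_additive_matrix <- function(ntaxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::unroot(ape::rtree(ntaxa))
    tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.05, 0.5), 3)
    D <- stats::cophenetic(tr)
    list(tree = tr, D = D[sort(rownames(D)), sort(colnames(D))])
  })
}
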