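# Independent oracles used across the suite. Everything here is written
# against plain nested-list trees and base-R set algebra, deliberately
# avoiding the package's own tree index, DAG closure and aligner code
# paths so the two routes stay independent.

# --- nested-list gene trees -------------------------------------------

orcLeaf <- function(id) list(type = "leaf", id = id)
orcNode <- function(...) list(type = "node", children = list(...))

orcLeaves <- function(nd) {
  if (nd$type == "leaf") return(nd$id)
  unlist(lapply(nd$children, orcLeaves))
}

orcSpecies <- function(ids) as.integer(sub("\\..*$", "", ids))

orcNewick <- function(nd) {
  rec <- function(n) {
    if (n$type == "leaf") return(n$id)
    paste0("(", paste(vapply(n$children, rec, character(1)),
                      collapse = ","), ")")
  }
  paste0(rec(nd), ";")
}

# all rooted binary topologies over a fixed leaf label set
# (counts 1, 1, 3, 15, 105, 945 for 1..6 leaves)
orcAllTopologies <- function(labels) {
  if (length(labels) == 1L) return(list(orcLeaf(labels)))
  first <- labels[1L]
  rest <- labels[-1L]
  out <- list()
  for (k in seq_len(length(rest))) {
    for (pick in asplit(utils::combn(rest, k), 2L)) {
      right <- setdiff(labels, c(first, pick))
      if (!length(right)) next
      for (l in orcAllTopologies(c(first, pick))) {
        for (r in orcAllTopologies(right)) {
          out[[length(out) + 1L]] <- orcNode(l, r)
        }
      }
    }
  }
  # the split {first} | rest is generated when pick exhausts rest
  for (r in orcAllTopologies(rest)) {
    out[[length(out) + 1L]] <- orcNode(orcLeaf(first), r)
  }
  out
}

orcRandomTopology <- function(labels) {
  nodes <- lapply(labels, orcLeaf)
  while (length(nodes) > 1L) {
    ij <- sample.int(length(nodes), 2L)
    merged <- orcNode(nodes[[ij[1L]]], nodes[[ij[2L]]])
    nodes <- c(nodes[-ij], list(merged))
  }
  nodes[[1L]]
}

# brute-force species-overlap event labelling: returns, per internal
# node (in the recursion order), its event; also pairwise orthologs
orcLabelNode <- function(nd, threshold) {
  sets <- lapply(nd$children, function(ch) unique(orcSpecies(orcLeaves(ch))))
  sc <- 0
  for (i in seq_len(length(sets) - 1L)) {
    for (j in seq.int(i + 1L, length(sets))) {
      sc <- max(sc, length(intersect(sets[[i]], sets[[j]])) /
                  length(union(sets[[i]], sets[[j]])))
    }
  }
  if (sc > threshold) "duplication" else "speciation"
}

# orthologous pairs with a->b relation, by explicit leaf enumeration
orcPairs <- function(nd, threshold = 0) {
  pairs <- list()
  rec <- function(n) {
    if (n$type == "leaf") return(data.frame(id = n$id,
                                            species = orcSpecies(n$id)))
    parts <- lapply(n$children, rec)
    ev <- orcLabelNode(n, threshold)
    if (ev == "speciation") {
      for (i in seq_len(length(parts) - 1L)) {
        for (j in seq.int(i + 1L, length(parts))) {
          li <- parts[[i]]; lj <- parts[[j]]
          for (ai in seq_len(nrow(li))) for (bj in seq_len(nrow(lj))) {
            if (li$species[ai] == lj$species[bj]) next
            m <- sum(li$species == li$species[ai])
            n2 <- sum(lj$species == lj$species[bj])
            a <- li$id[ai]; b <- lj$id[bj]
            rel <- if (m == 1 && n2 == 1) "one2one"
            else if (m == 1) "one2many"
            else if (n2 == 1) "many2one" else "many2many"
            if (a > b) {
              tmp <- a; a <- b; b <- tmp
              rel <- c(one2one = "one2one", one2many = "many2one",
                       many2one = "one2many",
                       many2many = "many2many")[[rel]]
            }
            pairs[[length(pairs) + 1L]] <<-
              data.frame(a = a, b = b, relation = rel)
          }
        }
      }
    }
    do.call(rbind, parts)
  }
  rec(nd)
  if (!length(pairs)) {
    return(data.frame(a = character(), b = character(),
                      relation = character()))
  }
  out <- unique(do.call(rbind, pairs))
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-internal-node labels matched to the package by comparing the leaf
# set under each node (node identity is representation-dependent)
orcLabelsByLeafset <- function(nd, threshold = 0) {
  out <- list()
  rec <- function(n) {
    if (n$type == "leaf") return(invisible())
    key <- paste(sort(orcLeaves(n)), collapse = "|")
    out[[key]] <<- orcLabelNode(n, threshold)
    for (ch in n$children) rec(ch)
  }
  rec(nd)
  out[sort(names(out))]
}

pkgLabelsByLeafset <- function(newick, threshold = 0) {
  phy <- readGeneTree(newick)
  lab <- labelEvents(phy, threshold)
  idx <- orthomapr:::.treeIndex(phy)
  out <- list()
  for (nd in names(lab$events)) {
    tips <- idx$tipsUnder[[nd]]
    key <- paste(sort(phy$tip.label[tips]), collapse = "|")
    out[[key]] <- lab$events[[nd]]
  }
  out[sort(names(out))]
}

# --- Smith-Waterman DP oracle -----------------------------------------

orcBlosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                  envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# affine-gap local alignment; gap of length L costs open + L * ext
orcSmithWaterman <- function(a, b, open = 11, ext = 1) {
  mat <- orcBlosum62()
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(-Inf, n + 1L, m + 1L)
  Iy <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                                Ix[i, j + 1L] - ext)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                                Iy[i + 1L, j] - ext)
      s <- mat[av[i], bv[j]]
      M[i + 1L, j + 1L] <- max(0, s + max(M[i, j], Ix[i, j], Iy[i, j]))
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

orcRandomSeq <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

orcMutate <- function(seq, p) {
  aa <- strsplit(seq, "")[[1L]]
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
             "P", "Q", "R", "S", "T", "V", "W", "Y")
  hit <- which(runif(length(aa)) < p)
  for (i in hit) aa[i] <- sample(setdiff(alpha, aa[i]), 1L)
  paste(aa, collapse = "")
}

# --- DAG reachability oracle ------------------------------------------

# reflexive-transitive closure by boolean matrix powering
orcClosure <- function(dag, terms) {
  n <- length(dag@terms)
  A <- matrix(FALSE, n, n, dimnames = list(dag@terms, dag@terms))
  for (t in names(dag@parents)) for (p in dag@parents[[t]]) A[t, p] <- TRUE
  R <- A | diag(TRUE, n)
  repeat {
    R2 <- (R %*% R) > 0
    if (all(R2 == R)) break
    R <- R2
  }
  sort(unique(unlist(lapply(terms, function(t) dag@terms[R[t, ]]))))
}

orcRandomDag <- function(n, maxParents = 2L) {
  ids <- sprintf("GO:%07d", seq_len(n) + 5000L)
  parents <- list()
  for (i in seq.int(2L, n)) {
    k <- sample.int(min(maxParents, i - 1L), 1L)
    parents[[ids[i]]] <- ids[sample.int(i - 1L, k)]
  }
  newGoDag(ids, parents)
}

# --- small fixed taxonomies -------------------------------------------

# root 1 with two clades: 2 -> {4, 5}, 3 -> {6, 7}
orcTinyTaxonomy <- function() {
  newTaxonomyTree(child = c(1, 2, 3, 4, 5, 6, 7),
                  parent = c(1, 1, 1, 2, 2, 3, 3),
                  labels = c("root", "cladeA", "cladeB", "sp4", "sp5",
                             "sp6", "sp7"))
}

orcRandomTaxonomy <- function(nLeaves) {
  # star-free random rooted tree: repeatedly attach nodes
  child <- 1L; parent <- 1L
  nid <- 1L
  leaves <- c(1L)
  while (length(leaves) < nLeaves) {
    target <- sample(leaves, 1L)
    for (k in 1:2) {
      nid <- nid + 1L
      child <- c(child, nid)
      parent <- c(parent, target)
      leaves <- c(leaves, nid)
    }
    leaves <- setdiff(leaves, target)
  }
  newTaxonomyTree(child, parent)
}

# lineage via raw parent pointers (independent of taxLineage)
orcLineage <- function(tax, t) {
  path <- t
  while (tax@parent[[as.character(t)]] != t) {
    t <- tax@parent[[as.character(t)]]
    path <- c(t, path)
  }
  path
}

orcLcaPair <- function(tax, a, b) {
  la <- orcLineage(tax, a); lb <- orcLineage(tax, b)
  common <- intersect(la, lb)
  common[length(common)]
}
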