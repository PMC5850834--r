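# Species-overlap event labelling of gene trees and fine-grained
# orthology extraction with in-paralog exclusion.

#' Read a rooted gene tree from newick
#'
#' Leaf labels must be protein ids of the form \code{"<taxid>.<name>"}.
#' Singleton internal nodes (as produced by outer wrapping parentheses)
#' are collapsed. The newick nesting is interpreted as the rooted
#' topology exactly as written: event labelling is root-dependent, so no
#' silent re-rooting (midpoint or otherwise) is ever performed, and
#' database builders are responsible for storing rooted trees.
#' Multifurcating nodes, including at the root, are accepted.
#'
#' @param newick a newick string (or an \code{ape::phylo} passed through).
#' @return an \code{ape::phylo} object.
#' @export
readGeneTree <- function(newick) {
  if (inherits(newick, "phylo")) {
    phy <- newick
  } else {
    phy <- tryCatch(ape::read.tree(text = newick), error = function(e) NULL)
    if (is.null(phy)) stop("unparseable newick: ", substr(newick, 1, 60))
  }
  if (ape::Ntip(phy) > 1L) phy <- ape::collapse.singles(phy)
  if (anyDuplicated(phy$tip.label))
    stop("duplicated leaf labels in gene tree")
  phy
}

# Precomputed structural index of a phylo tree: children lists, per-node
# tip sets, parent pointers, tip species.
.treeIndex <- function(phy) {
  nt <- ape::Ntip(phy)
  nn <- nt + phy$Nnode
  children <- setNames(vector("list", nn), as.character(seq_len(nn)))
  parent <- integer(nn)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
    children[[as.character(p)]] <- c(children[[as.character(p)]], c)
    parent[c] <- p
  }
  tipsUnder <- setNames(vector("list", nn), as.character(seq_len(nn)))
  po <- if (nt == 1L) integer(0) else unique(ape::reorder.phylo(
    phy, "postorder")$edge[, 2L])
  for (i in seq_len(nt)) tipsUnder[[as.character(i)]] <- i
  for (nd in c(po[po > nt], nt + 1L)) {
    tipsUnder[[as.character(nd)]] <-
      unlist(tipsUnder[as.character(children[[as.character(nd)]])],
             use.names = FALSE)
  }
  list(ntip = nt, nnode = nn,
       internal = as.character(seq.int(nt + 1L, length.out = phy$Nnode)),
       children = children, parent = parent, tipsUnder = tipsUnder,
       species = proteinTaxid(phy$tip.label))
}

# node path from root down to node (inclusive)
.pathFromRoot <- function(idx, node) {
  path <- integer(0)
  cur <- node
  root <- idx$ntip + 1L
  while (cur != root) {
    path <- c(cur, path)
    cur <- idx$parent[cur]
  }
  c(root, path)
}

#' Label gene-tree nodes as speciation or duplication by species overlap
#'
#' Each internal node receives the label \code{duplication} when the
#' species-set overlap between its child subtrees exceeds
#' \code{overlap_threshold}, and \code{speciation} otherwise. The overlap
#' score of two children is the Jaccard index of their species sets;
#' multifurcating nodes use the maximum over all child pairs, so any
#' overlapping pair marks the node as a duplication. The default
#' threshold 0 is the strictest reading: a single shared species implies
#' a duplication.
#'
#' @param tree newick string or \code{ape::phylo} (rooted).
#' @param overlap_threshold fraction in \code{[0, 1)}.
#' @return an object of class \code{eventLabeling}: list with
#'   \code{events} (named character over internal node numbers),
#'   \code{scores} (the per-node overlap scores) and \code{threshold}.
#' @export
labelEvents <- function(tree, overlap_threshold = 0) {
  stopifnot(overlap_threshold >= 0, overlap_threshold < 1)
  phy <- readGeneTree(tree)
  if (ape::Ntip(phy) == 1L) {
    return(structure(list(events = setNames(character(0), character(0)),
                          scores = setNames(numeric(0), character(0)),
                          threshold = overlap_threshold, tree = phy),
                     class = "eventLabeling"))
  }
  idx <- .treeIndex(phy)
  events <- setNames(character(length(idx$internal)), idx$internal)
  scores <- setNames(numeric(length(idx$internal)), idx$internal)
  for (nd in idx$internal) {
    kids <- idx$children[[nd]]
    sets <- lapply(kids, function(k)
      unique(idx$species[idx$tipsUnder[[as.character(k)]]]))
    sc <- 0
    if (length(sets) >= 2L) {
      for (i in seq_len(length(sets) - 1L)) {
        for (j in seq.int(i + 1L, length(sets))) {
          jac <- length(intersect(sets[[i]], sets[[j]])) /
            length(union(sets[[i]], sets[[j]]))
          sc <- max(sc, jac)
        }
      }
    }
    scores[[nd]] <- sc
    events[[nd]] <- if (sc > overlap_threshold) "duplication" else
      "speciation"
  }
  structure(list(events = events, scores = scores,
                 threshold = overlap_threshold, tree = phy),
            class = "eventLabeling")
}

#' @export
print.eventLabeling <- function(x, ...) {
  cat(sprintf("eventLabeling: %d internal nodes (%d duplication), threshold %g\n",
              length(x$events), sum(x$events == "duplication"), x$threshold))
  invisible(x)
}

.relationType <- function(m, n) {
  if (m == 1L && n == 1L) "one2one"
  else if (m == 1L) "one2many"
  else if (n == 1L) "many2one"
  else "many2many"
}

#' Fine-grained orthologs of a seed protein
#'
#' A leaf \code{t} (different protein, different species) is an ortholog
#' of the seed iff the last common ancestor (LCA) node of seed and
#' \code{t} is labelled \code{speciation}. The relation type is derived
#' at that LCA: with \code{m} leaves of the seed's species in the child
#' subtree holding the seed and \code{n} leaves of \code{t}'s species in
#' the child subtree holding \code{t}, the relation is one2one
#' (\code{m=n=1}), one2many (\code{m=1,n>1}), many2one (\code{m>1,n=1})
#' or many2many. Same-species leaves whose LCA with the seed is a
#' duplication are in-paralogs; they are reported separately and never
#' donate annotations.
#'
#' @param tree newick string or \code{ape::phylo} (rooted).
#' @param labeling an \code{eventLabeling} from [labelEvents()]; computed
#'   at threshold 0 when omitted.
#' @param seed protein id of a leaf.
#' @return object of class \code{orthologAssignment}: list with
#'   \code{seed}, \code{orthologs} (data.frame \code{protein_id},
#'   \code{relation}) and \code{inparalogs} (character vector).
#' @export
inferOrthologs <- function(tree, labeling = NULL, seed) {
  phy <- readGeneTree(tree)
  if (is.null(labeling)) labeling <- labelEvents(phy)
  if (!(seed %in% phy$tip.label))
    stop("seed protein not found in gene tree: ", seed)
  nt <- ape::Ntip(phy)
  if (nt == 1L) {
    return(structure(list(seed = seed,
                          orthologs = data.frame(protein_id = character(),
                                                 relation = character()),
                          inparalogs = character(0)),
                     class = "orthologAssignment"))
  }
  idx <- .treeIndex(phy)
  seedTip <- match(seed, phy$tip.label)
  seedSp <- idx$species[seedTip]
  paths <- lapply(seq_len(nt), function(i) .pathFromRoot(idx, i))
  seedPath <- paths[[seedTip]]
  orth <- character(0); rel <- character(0); inpar <- character(0)
  for (t in seq_len(nt)) {
    if (t == seedTip) next
    tPath <- paths[[t]]
    k <- min(length(seedPath), length(tPath))
    common <- which(seedPath[seq_len(k)] == tPath[seq_len(k)])
    lca <- seedPath[common[length(common)]]
    ev <- labeling$events[[as.character(lca)]]
    sp <- idx$species[t]
    if (sp == seedSp) {
      if (ev == "duplication") inpar <- c(inpar, phy$tip.label[t])
      next
    }
    if (ev != "speciation") next
    seedChild <- seedPath[common[length(common)] + 1L]
    tChild <- tPath[common[length(common)] + 1L]
    m <- sum(idx$species[idx$tipsUnder[[as.character(seedChild)]]] == seedSp)
    n <- sum(idx$species[idx$tipsUnder[[as.character(tChild)]]] == sp)
    orth <- c(orth, phy$tip.label[t])
    rel <- c(rel, .relationType(m, n))
  }
  structure(list(seed = seed,
                 orthologs = data.frame(protein_id = orth, relation = rel),
                 inparalogs = inpar),
            class = "orthologAssignment")
}

#' @export
print.orthologAssignment <- function(x, ...) {
  cat(sprintf("orthologAssignment: seed %s, %d orthologs, %d in-paralogs\n",
              x$seed, nrow(x$orthologs), length(x$inparalogs)))
  invisible(x)
}

#' All ortholog pairs of a gene tree
#'
#' The unordered pairs \code{{a, b}} such that [inferOrthologs()] from
#' \code{a} reports \code{b} (symmetric by construction). The stored
#' relation is read in the a-to-b direction; it transposes under
#' exchange (one2many and many2one swap).
#'
#' @param tree newick string or \code{ape::phylo} (rooted).
#' @param labeling optional \code{eventLabeling}; threshold 0 by default.
#' @return data.frame with columns \code{a}, \code{b}, \code{relation}
#'   (a-to-b direction), one row per unordered pair with \code{a < b}.
#' @export
orthologsPairwise <- function(tree, labeling = NULL) {
  phy <- readGeneTree(tree)
  if (is.null(labeling)) labeling <- labelEvents(phy)
  nt <- ape::Ntip(phy)
  out <- list()
  if (nt >= 2L) {
    idx <- .treeIndex(phy)
    paths <- lapply(seq_len(nt), function(i) .pathFromRoot(idx, i))
    for (i in seq_len(nt - 1L)) {
      for (j in seq.int(i + 1L, nt)) {
        if (idx$species[i] == idx$species[j]) next
        pi <- paths[[i]]; pj <- paths[[j]]
        k <- min(length(pi), length(pj))
        common <- which(pi[seq_len(k)] == pj[seq_len(k)])
        lca <- pi[common[length(common)]]
        if (labeling$events[[as.character(lca)]] != "speciation") next
        ci <- pi[common[length(common)] + 1L]
        cj <- pj[common[length(common)] + 1L]
        m <- sum(idx$species[idx$tipsUnder[[as.character(ci)]]] ==
                   idx$species[i])
        n <- sum(idx$species[idx$tipsUnder[[as.character(cj)]]] ==
                   idx$species[j])
        a <- phy$tip.label[i]; b <- phy$tip.label[j]
        relAB <- .relationType(m, n)
        if (a > b) {
          tmp <- a; a <- b; b <- tmp
          relAB <- .relationType(n, m)
        }
        out[[length(out) + 1L]] <- data.frame(a = a, b = b,
                                              relation = relAB)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(), b = character(),
                      relation = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$a, res$b), , drop = FALSE]
  rownames(res) <- NULL
  res
}
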