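#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats setNames rbinom rpois runif rlnorm cor pt
#' @importFrom utils read.table write.table head combn
NULL

#' Taxonomy tree
#'
#' A rooted taxonomy over integer taxon identifiers, stored as a
#' child-to-parent pointer map. The root is encoded as its own parent
#' (NCBI \code{nodes.dmp} convention).
#'
#' @slot nodes integer vector of all taxon ids.
#' @slot parent named integer vector; \code{parent[as.character(child)]}
#'   is the parent taxid. The root maps to itself.
#' @slot root integer taxid of the single root.
#' @slot labels named character vector of node names (may be empty).
#'
#' @seealso [loadTaxonomy()], [taxLineage()], [taxLca()]
#' @exportClass TaxonomyTree
setClass("TaxonomyTree",
  representation(
    nodes = "integer",
    parent = "integer",
    root = "integer",
    labels = "character"
  )
)

setValidity("TaxonomyTree", function(object) {
  msgs <- character()
  nd <- object@nodes
  if (anyDuplicated(nd)) msgs <- c(msgs, "duplicated taxon ids")
  if (length(object@root) != 1L || !(object@root %in% nd))
    msgs <- c(msgs, "root must be a single known taxid")
  if (!all(as.character(nd) %in% names(object@parent)))
    msgs <- c(msgs, "every node needs a parent entry")
  self <- nd[object@parent[as.character(nd)] == nd]
  if (length(self) != 1L)
    msgs <- c(msgs, sprintf("exactly one self-parent root expected, found %d",
                            length(self)))
  # acyclicity: every node must reach the root
  for (n in nd) {
    seen <- integer(0)
    cur <- n
    repeat {
      if (cur %in% seen) {
        msgs <- c(msgs, sprintf("cycle detected at taxid %d", n))
        break
      }
      if (cur == object@root) break
      seen <- c(seen, cur)
      nxt <- object@parent[as.character(cur)]
      if (is.na(nxt)) {
        msgs <- c(msgs, sprintf("taxid %d has no path to root", n))
        break
      }
      cur <- nxt
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TaxonomyTree", function(object) {
  kids <- setdiff(object@nodes, object@parent)
  cat(sprintf("TaxonomyTree: %d taxa (%d leaves), root %d\n",
              length(object@nodes), length(kids), object@root))
})

#' Gene Ontology DAG
#'
#' A directed acyclic graph of GO terms. Edges point child -> parent and
#' combine \code{is_a} and \code{part_of} relationships; both propagate
#' during ancestor closure. \code{regulates} edges are not stored.
#'
#' @slot terms character vector of primary term ids ("GO:" + 7 digits).
#' @slot parents named list; \code{parents[[term]]} is the character
#'   vector of direct parents (is_a and part_of).
#' @slot namespace named character vector, term -> sub-ontology.
#' @slot altIds named character vector, alternate id -> primary id.
#' @slot obsolete character vector of obsolete term ids.
#'
#' @seealso [parseObo()], [goPropagate()]
#' @exportClass GoDag
setClass("GoDag",
  representation(
    terms = "character",
    parents = "list",
    namespace = "character",
    altIds = "character",
    obsolete = "character"
  )
)

setValidity("GoDag", function(object) {
  msgs <- character()
  if (anyDuplicated(object@terms)) msgs <- c(msgs, "duplicated term ids")
  par <- unlist(object@parents, use.names = FALSE)
  if (length(par) && !all(par %in% object@terms))
    msgs <- c(msgs, "edge points to unknown term")
  bad <- setdiff(names(object@parents), object@terms)
  if (length(bad)) msgs <- c(msgs, "edge from unknown term")
  cyc <- .dagFindCycle(object@parents, object@terms)
  if (!is.null(cyc))
    msgs <- c(msgs, paste("cycle detected:", paste(cyc, collapse = " -> ")))
  if (length(msgs)) msgs else TRUE
})

# Kahn-style topological check; returns one cycle (as a term path) or NULL.
.dagFindCycle <- function(parents, terms) {
  indeg <- setNames(integer(length(terms)), terms)
  for (ps in parents) for (p in ps) indeg[p] <- indeg[p] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in parents[[t]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(terms)) return(NULL)
  # walk from any remaining node until repetition to exhibit a cycle
  start <- names(indeg)[indeg > 0L][1L]
  path <- start
  cur <- start
  repeat {
    nxt <- intersect(parents[[cur]], names(indeg)[indeg > 0L])[1L]
    if (nxt %in% path)
      return(c(path[seq(match(nxt, path), length(path))], nxt))
    path <- c(path, nxt)
    cur <- nxt
  }
}

setMethod("show", "GoDag", function(object) {
  cat(sprintf("GoDag: %d terms, %d edges, %d alt ids, %d obsolete\n",
              length(object@terms),
              length(unlist(object@parents, use.names = FALSE)),
              length(object@altIds), length(object@obsolete)))
})

#' Orthology database bundle
#'
#' In-memory representation of the full annotation database: taxonomy,
#' protein records with sequences, orthologous-group (OG) membership at
#' nested clade levels, per-OG gene trees, and functional annotation
#' tables (GO with evidence codes, KEGG pathways, per-OG COG categories).
#'
#' Protein ids follow the \code{"<taxid>.<name>"} convention; the taxid is
#' parsed from the prefix up to the first dot.
#'
#' @slot taxonomy a [TaxonomyTree-class].
#' @slot proteins data.frame with columns \code{protein_id}, \code{taxid},
#'   \code{gene_name} (NA when unknown).
#' @slot sequences an [Biostrings::AAStringSet-class] named by protein id
#'   (may omit proteins without stored sequence).
#' @slot ogTable data.frame with columns \code{og_id}, \code{clade},
#'   \code{protein_id}.
#' @slot trees named list, og_id -> newick string over member protein ids.
#' @slot go data.frame with columns \code{protein_id}, \code{term},
#'   \code{evidence}.
#' @slot kegg data.frame with columns \code{protein_id}, \code{pathway}.
#' @slot cog data.frame with columns \code{og_id}, \code{category}.
#' @slot cladeLevels integer vector of clade taxids at which OGs exist,
#'   ordered root level first (derived from \code{ogTable}).
#'
#' @seealso [loadDatabase()], [writeDatabase()], [ogsForProtein()]
#' @exportClass OrthologDb
setClass("OrthologDb",
  representation(
    taxonomy = "TaxonomyTree",
    proteins = "data.frame",
    sequences = "AAStringSet",
    ogTable = "data.frame",
    trees = "list",
    go = "data.frame",
    kegg = "data.frame",
    cog = "data.frame",
    cladeLevels = "integer"
  )
)

setValidity("OrthologDb", function(object) {
  msgs <- databaseIntegrityErrors(object)
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "OrthologDb", function(object) {
  cat(sprintf(paste0(
    "OrthologDb: %d proteins over %d taxa; %d OGs at %d clade level(s)\n",
    "  annotations: %d GO, %d KEGG, %d COG rows; %d sequences stored\n"),
    nrow(object@proteins), length(unique(object@proteins$taxid)),
    length(unique(object@ogTable$og_id)), length(object@cladeLevels),
    nrow(object@go), nrow(object@kegg), nrow(object@cog),
    length(object@sequences)))
})
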