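# Taxonomy construction, I/O and lineage queries.

#' Construct a taxonomy tree from parent pointers
#'
#' @param child integer vector of taxon ids.
#' @param parent integer vector of the same length; the root appears as
#'   its own parent.
#' @param labels optional character vector of node names.
#' @return a [TaxonomyTree-class].
#' @export
newTaxonomyTree <- function(child, parent, labels = NULL) {
  child <- as.integer(child)
  parent <- as.integer(parent)
  stopifnot(length(child) == length(parent))
  if (anyDuplicated(child))
    stop("taxonomy structural error: taxid ",
         child[duplicated(child)][1L], " listed with more than one parent")
  root <- child[child == parent]
  if (length(root) != 1L)
    stop("taxonomy structural error: expected exactly one root ",
         "(self-parent row), found ", length(root))
  lab <- character(0)
  if (!is.null(labels)) lab <- setNames(as.character(labels), child)
  obj <- new("TaxonomyTree",
             nodes = child,
             parent = setNames(parent, child),
             root = root,
             labels = lab)
  validObject(obj)
  obj
}

#' Read a taxonomy from a 3-column TSV
#'
#' Expects rows of \code{child<TAB>parent<TAB>name} with the root encoded
#' as a self-parent row. Row order is irrelevant.
#'
#' @param path file path.
#' @return a [TaxonomyTree-class].
#' @export
loadTaxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("child", "parent", "name"),
                   colClasses = c("integer", "integer", "character"),
                   quote = "", comment.char = "")
  newTaxonomyTree(df$child, df$parent, df$name)
}

#' Write a taxonomy as a 3-column TSV
#'
#' Inverse of [loadTaxonomy()] up to row order.
#' @param tax a [TaxonomyTree-class].
#' @param path output file.
#' @export
writeTaxonomy <- function(tax, path) {
  nm <- if (length(tax@labels)) tax@labels[as.character(tax@nodes)] else
    rep("", length(tax@nodes))
  nm[is.na(nm)] <- ""
  df <- data.frame(child = tax@nodes,
                   parent = tax@parent[as.character(tax@nodes)],
                   name = nm)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.taxCheckKnown <- function(tax, taxids) {
  bad <- setdiff(taxids, tax@nodes)
  if (length(bad))
    stop("unknown taxid: ", paste(bad, collapse = ", "))
}

#' Root-to-node lineage
#'
#' @param tax a [TaxonomyTree-class].
#' @param taxid a single taxon id.
#' @return integer vector of taxids from the root down to \code{taxid}
#'   (inclusive).
#' @export
taxLineage <- function(tax, taxid) {
  .taxCheckKnown(tax, taxid)
  path <- integer(0)
  cur <- as.integer(taxid)
  while (cur != tax@root) {
    path <- c(cur, path)
    cur <- tax@parent[[as.character(cur)]]
  }
  c(tax@root, path)
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tax a [TaxonomyTree-class].
#' @param taxids non-empty vector of taxon ids.
#' @return the deepest taxid ancestral-or-equal to all inputs.
#' @export
taxLca <- function(tax, taxids) {
  taxids <- unique(as.integer(taxids))
  if (!length(taxids)) stop("taxLca needs at least one taxid")
  .taxCheckKnown(tax, taxids)
  common <- taxLineage(tax, taxids[1L])
  for (t in taxids[-1L]) {
    lin <- taxLineage(tax, t)
    common <- common[seq_len(min(length(common), length(lin)))]
    agree <- common == lin[seq_along(common)]
    common <- common[seq_len(if (all(agree)) length(common)
                             else which(!agree)[1L] - 1L)]
  }
  common[length(common)]
}

#' Is one taxon a descendant-or-self of another?
#'
#' @param tax a [TaxonomyTree-class].
#' @param taxid taxon id(s) to test (vectorised).
#' @param ancestor single candidate ancestor taxid.
#' @return logical vector.
#' @export
taxIsDescendant <- function(tax, taxid, ancestor) {
  .taxCheckKnown(tax, c(taxid, ancestor))
  vapply(as.integer(taxid),
         function(t) ancestor %in% taxLineage(tax, t),
         logical(1))
}

#' Depth of a taxon (root has depth 0)
#' @param tax a [TaxonomyTree-class].
#' @param taxid a single taxon id.
#' @return integer depth.
#' @export
taxDepth <- function(tax, taxid) length(taxLineage(tax, taxid)) - 1L

#' Leaf taxa (species) of a taxonomy
#' @param tax a [TaxonomyTree-class].
#' @return integer vector of taxids with no children.
#' @export
taxLeaves <- function(tax) {
  kids <- tax@nodes[tax@parent[as.character(tax@nodes)] != tax@nodes]
  par <- unique(tax@parent[as.character(kids)])
  sort(setdiff(tax@nodes, par))
}

#' All descendant-or-self taxa of a clade
#' @param tax a [TaxonomyTree-class].
#' @param clade a single taxid.
#' @return integer vector of taxids under \code{clade}, including itself.
#' @export
taxDescendants <- function(tax, clade) {
  .taxCheckKnown(tax, clade)
  sort(tax@nodes[vapply(tax@nodes,
                        function(t) clade %in% taxLineage(tax, t),
                        logical(1))])
}

# taxid prefix of "<taxid>.<name>" protein ids (first dot separates)
.proteinTaxid <- function(protein_id) {
  suppressWarnings(as.integer(sub("\\..*$", "", protein_id)))
}

#' Taxon id encoded in a protein identifier
#'
#' Protein ids use the \code{"<taxid>.<name>"} convention; the prefix up
#' to the first dot is the taxon id (names may contain further dots).
#'
#' @param protein_id character vector of protein ids.
#' @return integer vector of taxids.
#' @export
proteinTaxid <- function(protein_id) {
  out <- .proteinTaxid(protein_id)
  if (anyNA(out))
    stop("malformed protein id (no integer taxid prefix): ",
         protein_id[is.na(out)][1L])
  out
}
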