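# GO DAG parsing, ancestor propagation and taxon-constraint checks.

GO_ID_RE <- "^GO:[0-9]{7}$"

#' Construct a GO DAG from edge lists
#'
#' @param terms character vector of primary term ids.
#' @param parents named list mapping term -> character vector of direct
#'   parents (is_a and part_of combined).
#' @param namespace named character vector term -> sub-ontology; missing
#'   terms default to \code{"biological_process"}.
#' @param altIds named character vector, alternate id -> primary id.
#' @param obsolete character vector of obsolete term ids.
#' @return a [GoDag-class].
#' @export
newGoDag <- function(terms, parents = list(), namespace = character(),
                     altIds = character(), obsolete = character()) {
  terms <- unique(as.character(terms))
  bad <- terms[!grepl(GO_ID_RE, terms)]
  if (length(bad))
    stop("malformed GO id: ", bad[1L])
  full <- setNames(vector("list", length(terms)), terms)
  for (t in names(parents)) full[[t]] <- unique(as.character(parents[[t]]))
  ns <- setNames(rep("biological_process", length(terms)), terms)
  ns[names(namespace)] <- namespace
  obj <- new("GoDag", terms = terms, parents = full,
             namespace = ns[terms], altIds = altIds,
             obsolete = as.character(obsolete))
  validObject(obj)
  obj
}

#' Parse an OBO 1.2 ontology file (subset)
#'
#' Reads \code{[Term]} stanzas, keeping \code{id}, \code{name},
#' \code{namespace}, \code{is_a}, \code{relationship: part_of},
#' \code{alt_id} and \code{is_obsolete}. Other tags and other
#' relationship types (e.g. \code{regulates}) are ignored. Edges of
#' obsolete terms are dropped so they never participate in propagation.
#'
#' @param path path to an OBO file.
#' @return a [GoDag-class].
#' @export
parseObo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- character()
  parents <- list()
  namespace <- character()
  altIds <- character()
  obsolete <- character()
  flush <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    id <- cur$id
    terms[[length(terms) + 1L]] <<- id
    namespace[[id]] <<- cur$namespace %||% "biological_process"
    if (isTRUE(cur$obsolete)) {
      obsolete[[length(obsolete) + 1L]] <<- id
    } else if (length(cur$parents)) {
      parents[[id]] <<- unique(cur$parents)
    }
    for (a in cur$alt) altIds[[a]] <<- id
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      if (in_term) flush()
      in_term <- ln == "[Term]"
      cur <- list(parents = character(), alt = character())
      next
    }
    if (!in_term) next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) next
    key <- kv[2L]; val <- trimws(kv[3L])
    if (key == "id") cur$id <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$parents <- c(cur$parents, val)
    else if (key == "alt_id") cur$alt <- c(cur$alt, val)
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "relationship") {
      rel <- strsplit(val, "\\s+")[[1L]]
      if (length(rel) >= 2L && rel[1L] == "part_of")
        cur$parents <- c(cur$parents, rel[2L])
    }
  }
  if (in_term) flush()
  newGoDag(terms, parents, namespace, altIds, obsolete)
}

#' Resolve alternate ids to primary term ids
#'
#' @param dag a [GoDag-class].
#' @param terms character vector of term ids (primary or alternate).
#' @return character vector of primary ids; unknown ids are an error.
#' @export
goResolve <- function(dag, terms) {
  terms <- as.character(terms)
  isAlt <- terms %in% names(dag@altIds)
  terms[isAlt] <- dag@altIds[terms[isAlt]]
  bad <- setdiff(terms, dag@terms)
  if (length(bad))
    stop("unknown GO term: ", paste(bad, collapse = ", "))
  terms
}

#' Ancestors of a single term (exclusive)
#'
#' @param dag a [GoDag-class].
#' @param term a primary term id.
#' @return character vector of all ancestors via is_a/part_of.
#' @export
goAncestors <- function(dag, term) {
  seen <- character(0)
  queue <- dag@parents[[term]]
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, dag@parents[[t]])
  }
  seen
}

#' Ancestor closure of a term set
#'
#' Returns the input terms together with all of their ancestors through
#' is_a and part_of edges. Alternate ids are resolved first; obsolete
#' input terms are dropped with a warning.
#'
#' @param dag a [GoDag-class].
#' @param terms character vector of term ids.
#' @return sorted character vector (the reflexive ancestor closure).
#' @export
goPropagate <- function(dag, terms) {
  if (!length(terms)) return(character(0))
  terms <- goResolve(dag, terms)
  obs <- intersect(terms, dag@obsolete)
  if (length(obs)) {
    warning("dropping obsolete GO term(s): ", paste(obs, collapse = ", "))
    terms <- setdiff(terms, obs)
  }
  out <- unique(terms)
  for (t in unique(terms)) out <- union(out, goAncestors(dag, t))
  sort(out)
}

#' Read a taxon-constraint table
#'
#' TSV with columns \code{term}, \code{kind}
#' (\code{never_in_taxon}/\code{only_in_taxon}) and \code{taxid}.
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
loadTaxonConstraints <- function(path) {
  if (!file.exists(path)) stop("constraint file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "integer"),
                   quote = "", comment.char = "")
  names(df) <- c("term", "kind", "taxid")
  bad <- setdiff(df$kind, c("never_in_taxon", "only_in_taxon"))
  if (length(bad)) stop("unknown constraint kind: ", bad[1L])
  df
}

#' Does a term assignment violate a taxon constraint?
#'
#' A prediction of \code{term} for a protein from \code{query_taxid} is a
#' violation when a \code{never_in_taxon} constraint exists on the term
#' (or any of its ancestors, since constraints inherit down the DAG) with
#' the query inside the excluded clade, or an \code{only_in_taxon}
#' constraint exists with the query outside the required clade.
#'
#' @param dag a [GoDag-class].
#' @param term a term id (alternate ids resolved).
#' @param query_taxid the protein's taxon.
#' @param constraints data.frame from [loadTaxonConstraints()].
#' @param taxonomy a [TaxonomyTree-class].
#' @return logical scalar.
#' @export
violatesTaxonConstraint <- function(dag, term, query_taxid, constraints,
                                    taxonomy) {
  if (!nrow(constraints)) return(FALSE)
  closure <- goPropagate(dag, term)
  hits <- constraints[constraints$term %in% closure, , drop = FALSE]
  if (!nrow(hits)) return(FALSE)
  for (i in seq_len(nrow(hits))) {
    under <- taxIsDescendant(taxonomy, query_taxid, hits$taxid[i])
    if (hits$kind[i] == "never_in_taxon" && under) return(TRUE)
    if (hits$kind[i] == "only_in_taxon" && !under) return(TRUE)
  }
  FALSE
}

`%||%` <- function(a, b) if (is.null(a)) b else a
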