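# Annotation transfer engine: taxonomic scope resolution, ortholog
# selection and GO/KEGG/COG/gene-name transfer.

EXPERIMENTAL_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

#' Taxonomic scope setting
#'
#' @param mode \code{"auto"} (per-query narrowest qualifying clade
#'   level) or \code{"fixed"}.
#' @param fixed_clade taxid of the fixed level (required for
#'   \code{"fixed"}); typically the root level to disable the automatic
#'   taxonomic adjustment.
#' @return list of class \code{scopeSetting}.
#' @export
scopeSetting <- function(mode = c("auto", "fixed"), fixed_clade = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && is.null(fixed_clade))
    stop("fixed scope needs a clade taxid")
  structure(list(mode = mode, fixed_clade = fixed_clade),
            class = "scopeSetting")
}

#' Annotation transfer policy
#'
#' @param target_orthologs \code{"all"} (every ortholog in scope) or
#'   \code{"one2one"} (one-to-one relations only; higher reliability at
#'   the cost of lower coverage).
#' @param go_evidence which GO evidence classes may be transferred:
#'   \code{"experimental"} (EXP, IDA, IPI, IMP, IGI, IEP),
#'   \code{"non_electronic"} (everything except IEA) or \code{"all"}.
#' @param excluded_taxa taxids whose subtrees never donate (and are
#'   excluded from the seed search); use the query's own taxon to avoid
#'   circular annotation.
#' @param max_evalue,min_bitscore seed-search thresholds.
#' @return list of class \code{transferPolicy}.
#' @export
transferPolicy <- function(target_orthologs = c("all", "one2one"),
                           go_evidence = c("non_electronic",
                                           "experimental", "all"),
                           excluded_taxa = integer(0),
                           max_evalue = 0.001, min_bitscore = 20) {
  structure(list(target_orthologs = match.arg(target_orthologs),
                 go_evidence = match.arg(go_evidence),
                 excluded_taxa = as.integer(excluded_taxa),
                 max_evalue = max_evalue, min_bitscore = min_bitscore),
            class = "transferPolicy")
}

#' Resolve the taxonomic scope of a seed ortholog
#'
#' In \code{auto} mode, the narrowest clade level that (a) lies on the
#' seed species' lineage and (b) hosts an OG containing the seed
#' protein; when no level hosts such an OG the scope falls back to the
#' widest lineage level (ultimately the root level). In \code{fixed}
#' mode, the configured level.
#'
#' @param seed_protein seed protein id.
#' @param db an [OrthologDb-class].
#' @param setting a [scopeSetting()].
#' @return list with \code{clade} (taxid) and \code{og_id} (the OG
#'   containing the seed at that level, or NA when none exists).
#' @export
resolveScope <- function(seed_protein, db, setting = scopeSetting()) {
  seedTax <- proteinTaxid(seed_protein)
  lineage <- taxLineage(db@taxonomy, seedTax)
  levels <- db@cladeLevels[db@cladeLevels %in% c(lineage, seedTax)]
  if (!length(levels))
    stop("configuration error: no clade level covers taxon ", seedTax,
         " (the root level must cover all species)")
  ogAt <- function(clade) {
    sel <- db@ogTable$clade == clade & db@ogTable$protein_id == seed_protein
    if (any(sel)) db@ogTable$og_id[sel][1L] else NA_character_
  }
  if (setting$mode == "fixed") {
    if (!(setting$fixed_clade %in% db@cladeLevels))
      stop("fixed scope ", setting$fixed_clade, " is not a clade level")
    return(list(clade = setting$fixed_clade,
                og_id = ogAt(setting$fixed_clade)))
  }
  # deepest qualifying level first
  depths <- vapply(levels, function(x) taxDepth(db@taxonomy, x), integer(1))
  for (clade in levels[order(-depths)]) {
    og <- ogAt(clade)
    if (!is.na(og)) return(list(clade = clade, og_id = og))
  }
  list(clade = levels[which.min(depths)], og_id = NA_character_)
}

#' Filter an ortholog assignment by scope, exclusions and relation type
#'
#' @param assignment an \code{orthologAssignment} from
#'   [inferOrthologs()].
#' @param scope clade taxid; only orthologs whose species lies in the
#'   scope subtree are kept.
#' @param policy a [transferPolicy()]; applies \code{excluded_taxa}
#'   subtree removal and the \code{one2one} restriction.
#' @param taxonomy a [TaxonomyTree-class].
#' @return data.frame \code{protein_id}, \code{relation} (possibly zero
#'   rows).
#' @export
selectOrthologs <- function(assignment, scope, policy, taxonomy) {
  orth <- assignment$orthologs
  if (!nrow(orth)) return(orth)
  tax <- .proteinTaxid(orth$protein_id)
  keep <- taxIsDescendant(taxonomy, tax, scope)
  if (length(policy$excluded_taxa)) {
    banned <- unique(unlist(lapply(policy$excluded_taxa, function(x)
      taxDescendants(taxonomy, x))))
    keep <- keep & !(tax %in% banned)
  }
  if (policy$target_orthologs == "one2one")
    keep <- keep & orth$relation == "one2one"
  out <- orth[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.evidenceKeep <- function(evidence, go_evidence) {
  switch(go_evidence,
         experimental = evidence %in% EXPERIMENTAL_CODES,
         non_electronic = evidence != "IEA",
         all = rep(TRUE, length(evidence)))
}

#' Transfer GO terms from donor orthologs
#'
#' Unions the donors' GO annotations whose evidence codes pass the
#' policy's evidence filter, then ancestor-propagates the union through
#' the DAG. Terms unknown to the DAG are dropped with a warning.
#'
#' @param donors character vector of donor protein ids.
#' @param db an [OrthologDb-class].
#' @param dag a [GoDag-class].
#' @param policy a [transferPolicy()] (or a string naming the evidence
#'   class).
#' @return sorted character vector of propagated GO terms.
#' @export
transferGo <- function(donors, db, dag, policy = transferPolicy()) {
  ev <- if (is.character(policy)) policy else policy$go_evidence
  if (!length(donors)) return(character(0))
  rows <- db@go[db@go$protein_id %in% donors, , drop = FALSE]
  rows <- rows[.evidenceKeep(rows$evidence, ev), , drop = FALSE]
  terms <- unique(rows$term)
  known <- terms %in% c(dag@terms, names(dag@altIds))
  if (any(!known))
    warning("dropping GO term(s) unknown to the DAG: ",
            paste(terms[!known], collapse = ", "))
  goPropagate(dag, terms[known])
}

#' Transfer KEGG pathways from donor orthologs
#' @param donors character vector of donor protein ids.
#' @param db an [OrthologDb-class].
#' @return sorted character vector (union over donors).
#' @export
transferKegg <- function(donors, db) {
  if (!length(donors)) return(character(0))
  sort(unique(db@kegg$pathway[db@kegg$protein_id %in% donors]))
}

#' COG functional category of the scope OG
#' @param og_id OG id (or NA).
#' @param db an [OrthologDb-class].
#' @return the category letter string, \code{""} when unannotated.
#' @export
transferCog <- function(og_id, db) {
  if (is.na(og_id)) return("")
  i <- match(og_id, db@cog$og_id)
  if (is.na(i)) "" else db@cog$category[i]
}

.normalizeGeneName <- function(name) {
  toupper(sub("[._-]*[0-9]+$", "", name))
}

#' Predict a gene family name from donor orthologs
#'
#' Donor gene names are normalised (trailing copy-number digits and
#' separators stripped, upper-cased) and the most frequent normalised
#' name is returned. Ties go to the name carried by the donor
#' taxonomically closest to the seed (deepest LCA with the seed's
#' species), then to the lexicographically smallest name.
#'
#' @param donors character vector of donor protein ids.
#' @param db an [OrthologDb-class].
#' @param seed seed protein id used for the tie-break (optional).
#' @return a single name, or \code{NA} when no donor carries one.
#' @export
predictGeneName <- function(donors, db, seed = NULL) {
  names_ <- db@proteins$gene_name[match(donors, db@proteins$protein_id)]
  ok <- !is.na(names_) & nzchar(names_)
  if (!any(ok)) return(NA_character_)
  donors <- donors[ok]
  norm <- .normalizeGeneName(names_[ok])
  counts <- table(norm)
  cand <- names(counts)[counts == max(counts)]
  if (length(cand) == 1L) return(cand)
  if (!is.null(seed)) {
    seedTax <- proteinTaxid(seed)
    prox <- vapply(donors, function(d) {
      taxDepth(db@taxonomy, taxLca(db@taxonomy,
                                   c(seedTax, proteinTaxid(d))))
    }, integer(1))
    best <- max(prox[norm %in% cand])
    cand <- intersect(cand, norm[prox == best])
  }
  sort(cand)[1L]
}

.emptyResult <- function(query_id, status, seed = NULL, scope = NULL) {
  list(query_id = query_id,
       seed = seed,
       scope_clade = scope$clade %||% NA_integer_,
       og_id = scope$og_id %||% NA_character_,
       orthologs_used = data.frame(protein_id = character(),
                                   relation = character()),
       go_terms = character(0), kegg_pathways = character(0),
       cog_category = "", predicted_gene_name = NA_character_,
       status = status)
}

#' Annotate one query given its seed ortholog
#'
#' Composes scope resolution, gene-tree orthology at the scope OG,
#' ortholog selection and functional transfer. The seed ortholog itself
#' is a donor (relation \code{"seed"}) alongside its selected tree
#' orthologs, all subject to the same scope and taxon exclusions.
#' Status is \code{unmapped} (no seed), \code{seed_only} (seed found but
#' no tree ortholog survives selection; the seed still donates and the
#' scope OG's COG category is reported) or \code{annotated}.
#'
#' @param seed_row one row of a search result table (from
#'   [searchDirect()], [searchCoarse()] or [seedsFromHits()]).
#' @param db an [OrthologDb-class].
#' @param dag a [GoDag-class].
#' @param setting a [scopeSetting()].
#' @param policy a [transferPolicy()].
#' @param overlap_threshold species-overlap threshold for event
#'   labelling.
#' @return a per-query annotation result (list; see
#'   [annotationTable()] for the tabular form).
#' @export
annotateQuery <- function(seed_row, db, dag, setting = scopeSetting(),
                          policy = transferPolicy(),
                          overlap_threshold = 0) {
  qid <- seed_row$query_id
  if (is.na(seed_row$protein_id))
    return(.emptyResult(qid, "unmapped"))
  seed <- seed_row$protein_id
  scope <- resolveScope(seed, db, setting)
  selected <- data.frame(protein_id = character(), relation = character())
  if (!is.na(scope$og_id)) {
    members <- ogMembers(db, scope$og_id)
    if (length(members) >= 2L && !is.null(db@trees[[scope$og_id]])) {
      tree <- ogGeneTree(db, scope$og_id)
      labeling <- labelEvents(tree, overlap_threshold)
      assignment <- inferOrthologs(tree, labeling, seed)
      selected <- selectOrthologs(assignment, scope$clade, policy,
                                  db@taxonomy)
    }
  }
  donors <- rbind(data.frame(protein_id = seed, relation = "seed"),
                  selected)
  status <- if (nrow(selected)) "annotated" else "seed_only"
  list(query_id = qid,
       seed = seed_row,
       scope_clade = scope$clade,
       og_id = scope$og_id,
       orthologs_used = donors,
       go_terms = transferGo(donors$protein_id, db, dag, policy),
       kegg_pathways = transferKegg(donors$protein_id, db),
       cog_category = transferCog(scope$og_id, db),
       predicted_gene_name = predictGeneName(donors$protein_id, db, seed),
       status = status)
}

#' Annotate a set of query sequences end to end
#'
#' Runs the seed-ortholog search in the requested mode, then
#' [annotateQuery()] for every query. The policy's thresholds and
#' excluded taxa are applied during the search, so a seed is never drawn
#' from an excluded subtree.
#'
#' @param queries an \code{AAStringSet}, named character vector or FASTA
#'   path; ignored when \code{hits} is given.
#' @param db an [OrthologDb-class].
#' @param dag a [GoDag-class].
#' @param setting a [scopeSetting()].
#' @param policy a [transferPolicy()].
#' @param mode \code{"direct"}, \code{"coarse"} or \code{"external"}.
#' @param hits external hit table (required for \code{"external"}).
#' @param exclude_self drop search hits with target id equal to the
#'   query id.
#' @param overlap_threshold species-overlap threshold.
#' @return list of per-query results (class \code{annotationSet}).
#' @export
annotateQueries <- function(queries, db, dag, setting = scopeSetting(),
                            policy = transferPolicy(),
                            mode = c("direct", "coarse", "external"),
                            hits = NULL, exclude_self = FALSE,
                            overlap_threshold = 0) {
  mode <- match.arg(mode)
  filters <- searchFilters(max_evalue = policy$max_evalue,
                           min_bitscore = policy$min_bitscore,
                           excluded_taxa = policy$excluded_taxa,
                           exclude_self = exclude_self)
  seeds <- switch(mode,
    direct = searchDirect(queries, db, filters),
    coarse = searchCoarse(queries, db, filters),
    external = {
      if (is.null(hits)) stop("external mode needs a hit table")
      seedsFromHits(hits, db, filters)
    })
  out <- lapply(seq_len(nrow(seeds)), function(i)
    annotateQuery(seeds[i, ], db, dag, setting, policy,
                  overlap_threshold))
  structure(out, class = "annotationSet")
}

#' @export
print.annotationSet <- function(x, ...) {
  st <- vapply(x, `[[`, character(1), "status")
  cat(sprintf(
    "annotationSet: %d queries (%d annotated, %d seed_only, %d unmapped)\n",
    length(x), sum(st == "annotated"), sum(st == "seed_only"),
    sum(st == "unmapped")))
  invisible(x)
}

#' Tabular form of an annotation set
#'
#' @param results an \code{annotationSet} from [annotateQueries()] (or a
#'   plain list of [annotateQuery()] results).
#' @return data.frame, one row per query, with comma-joined sorted term
#'   lists.
#' @export
annotationTable <- function(results) {
  rows <- lapply(results, function(r) {
    rel <- r$orthologs_used$relation
    rel <- rel[rel != "seed"]
    relsum <- if (length(rel)) {
      tb <- table(rel)
      paste(sprintf("%s:%d", names(tb), as.integer(tb)), collapse = ",")
    } else ""
    data.frame(
      query = r$query_id,
      seed_ortholog = if (is.null(r$seed)) NA_character_ else
        r$seed$protein_id,
      seed_evalue = if (is.null(r$seed)) NA_real_ else r$seed$evalue,
      seed_bitscore = if (is.null(r$seed)) NA_real_ else r$seed$bitscore,
      scope_clade = r$scope_clade,
      og_id = r$og_id,
      relations = relsum,
      predicted_gene_name = r$predicted_gene_name,
      go_terms = paste(sort(r$go_terms), collapse = ","),
      kegg_pathways = paste(sort(r$kegg_pathways), collapse = ","),
      cog_category = r$cog_category,
      status = r$status)
  })
  if (!length(rows)) {
    return(data.frame(query = character(), seed_ortholog = character(),
                      seed_evalue = numeric(), seed_bitscore = numeric(),
                      scope_clade = integer(), og_id = character(),
                      relations = character(),
                      predicted_gene_name = character(),
                      go_terms = character(), kegg_pathways = character(),
                      cog_category = character(), status = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an annotation table as TSV
#'
#' One row per query; the header line is prefixed with \code{"#"}.
#'
#' @param results an \code{annotationSet} or the data.frame from
#'   [annotationTable()].
#' @param path output path.
#' @export
writeAnnotations <- function(results, path) {
  tab <- if (is.data.frame(results)) results else annotationTable(results)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(tab), collapse = "\t")), con)
  if (nrow(tab)) {
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, na = "-")
  }
  invisible(path)
}

#' Long-format GO predictions from an annotation set
#'
#' @param results an \code{annotationSet}.
#' @return data.frame \code{protein} (query id), \code{term}; one row
#'   per predicted (query, term) pair.
#' @export
annotationPredictions <- function(results) {
  rows <- lapply(results, function(r) {
    if (!length(r$go_terms)) return(NULL)
    data.frame(protein = r$query_id, term = r$go_terms)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(protein = character(), term = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
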