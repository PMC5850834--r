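# Seed-ortholog search: built-in Smith-Waterman backend, filtering, and
# parsers for external search-engine output.

# Karlin-Altschul constants used by the built-in scorer (standard
# ungapped-approximation values for BLOSUM62).
KA_LAMBDA <- 0.267
KA_K <- 0.041
AA_ALPHABET_RE <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.bitscore <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)
.evalue <- function(bits, space) space * 2^(-bits)

.rawLocalScores <- function(targets, query) {
  Biostrings::pairwiseAlignment(
    pattern = targets, subject = query, type = "local",
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
}

#' Score a pair of protein sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps
#' (open 11, extend 1). The raw score S is converted to a bit score
#' \eqn{(\lambda S - \ln K)/\ln 2} with \eqn{\lambda = 0.267},
#' \eqn{K = 0.041}, and to an E-value \eqn{m n 2^{-bits}} where m, n are
#' the two sequence lengths.
#'
#' @param a,b amino-acid strings (20-letter alphabet plus X).
#' @return list with \code{raw}, \code{bitscore}, \code{evalue}.
#' @export
alignScore <- function(a, b) {
  for (s in c(a, b)) {
    if (!nzchar(s)) stop("empty sequence")
    if (!grepl(AA_ALPHABET_RE, s)) stop("invalid amino-acid letters in sequence")
  }
  raw <- .rawLocalScores(Biostrings::AAStringSet(a), Biostrings::AAString(b))
  bits <- .bitscore(raw)
  list(raw = as.numeric(raw), bitscore = as.numeric(bits),
       evalue = .evalue(bits, nchar(a) * nchar(b)))
}

#' Search filter settings
#'
#' @param max_evalue keep hits with E-value at or below this (default
#'   0.001, the standard operating cutoff).
#' @param min_bitscore keep hits with bit score at or above this
#'   (default 20).
#' @param excluded_taxa taxids whose entire subtrees are removed from
#'   the hit list (e.g. the query's own species, to avoid circular
#'   annotation).
#' @param exclude_self drop hits whose target id equals the query id.
#' @return list of class \code{searchFilters}.
#' @export
searchFilters <- function(max_evalue = 0.001, min_bitscore = 20,
                          excluded_taxa = integer(0),
                          exclude_self = FALSE) {
  structure(list(max_evalue = max_evalue, min_bitscore = min_bitscore,
                 excluded_taxa = as.integer(excluded_taxa),
                 exclude_self = exclude_self),
            class = "searchFilters")
}

#' Apply threshold and taxon-exclusion filters to a hit table
#'
#' Removes hits with E-value above \code{max_evalue} or bit score below
#' \code{min_bitscore}; hits whose target taxid lies in an excluded
#' taxon's subtree (descendant-or-self); and, when \code{exclude_self},
#' hits of a query against its own protein id.
#'
#' @param hits data.frame with columns \code{query_id}, \code{target_id},
#'   \code{bitscore}, \code{evalue}; target ids must be protein ids when
#'   \code{excluded_taxa} is non-empty.
#' @param filters a [searchFilters()] object.
#' @param taxonomy a [TaxonomyTree-class]; required when
#'   \code{excluded_taxa} is non-empty.
#' @return the filtered hit table.
#' @export
applyFilters <- function(hits, filters = searchFilters(), taxonomy = NULL) {
  keep <- hits$evalue <= filters$max_evalue &
    hits$bitscore >= filters$min_bitscore
  if (length(filters$excluded_taxa)) {
    if (is.null(taxonomy))
      stop("excluded_taxa filtering needs a taxonomy")
    banned <- unique(unlist(lapply(filters$excluded_taxa, function(x)
      taxDescendants(taxonomy, x))))
    keep <- keep & !(.proteinTaxid(hits$target_id) %in% banned)
  }
  if (isTRUE(filters$exclude_self))
    keep <- keep & hits$target_id != hits$query_id
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# total order on hits: best bitscore, then lowest evalue, then target id
.orderHits <- function(hits) {
  hits[order(-hits$bitscore, hits$evalue, hits$target_id), , drop = FALSE]
}

.asQuerySet <- function(queries) {
  if (is.character(queries) && length(queries) == 1L &&
      file.exists(queries))
    queries <- Biostrings::readAAStringSet(queries)
  if (!methods::is(queries, "AAStringSet"))
    queries <- Biostrings::AAStringSet(queries)
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    stop("queries need unique names")
  queries
}

.checkQueryResidues <- function(queries) {
  ok <- grepl(AA_ALPHABET_RE, as.character(queries))
  if (!all(ok))
    warning("skipping query with invalid residues: ",
            paste(names(queries)[!ok], collapse = ", "))
  queries[ok]
}

.noSeedRow <- function(qid, mode, reason) {
  data.frame(query_id = qid, og_id = NA_character_,
             protein_id = NA_character_, bitscore = NA_real_,
             evalue = NA_real_, mode = mode, reason = reason)
}

#' Direct-mode seed-ortholog search
#'
#' Scores every query against every database protein with the built-in
#' local aligner and keeps, per query, the best hit passing the filters
#' (ties broken by lower E-value, then lexicographically smallest
#' protein id, so results are independent of input order). E-values use
#' an effective search space of query length times total database
#' residue count.
#'
#' @param queries an \code{AAStringSet}, a named character vector, or a
#'   FASTA path.
#' @param db an [OrthologDb-class] with stored sequences.
#' @param filters a [searchFilters()] object.
#' @return data.frame with one row per query: \code{query_id},
#'   \code{og_id} (NA in direct mode), \code{protein_id}, \code{bitscore},
#'   \code{evalue}, \code{mode}, \code{reason} (NA when a seed was found).
#' @export
searchDirect <- function(queries, db, filters = searchFilters()) {
  queries <- .checkQueryResidues(.asQuerySet(queries))
  targets <- db@sequences
  if (!length(targets)) stop("database has no stored sequences")
  space <- sum(Biostrings::width(targets))
  out <- lapply(names(queries), function(qid) {
    raw <- .rawLocalScores(targets, queries[[qid]])
    bits <- .bitscore(raw)
    hits <- data.frame(query_id = qid, target_id = names(targets),
                       bitscore = as.numeric(bits),
                       evalue = .evalue(bits,
                                        Biostrings::width(queries[qid]) *
                                          space))
    hits <- applyFilters(hits, filters, db@taxonomy)
    if (!nrow(hits)) return(.noSeedRow(qid, "direct", "no_hit_passed_filters"))
    best <- .orderHits(hits)[1L, ]
    data.frame(query_id = qid, og_id = NA_character_,
               protein_id = best$target_id, bitscore = best$bitscore,
               evalue = best$evalue, mode = "direct", reason = NA_character_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-phase (group then protein) seed-ortholog search
#'
#' Phase 1 scores each query against every root-level orthologous group,
#' where a group's score is the maximum bit score over its members
#' passing the filters (a desk-scale stand-in for a profile-HMM match;
#' externally computed HMM hits can be supplied to the annotation layer
#' instead). The best group is selected (ties by group id), then phase 2
#' re-ranks only that group's members, with E-values computed over the
#' group's residue count, and the best member becomes the seed.
#'
#' @inheritParams searchDirect
#' @return data.frame as in [searchDirect()] with \code{og_id} filled and
#'   \code{mode = "coarse_then_fine"}.
#' @export
searchCoarse <- function(queries, db, filters = searchFilters()) {
  queries <- .checkQueryResidues(.asQuerySet(queries))
  rootLevel <- db@cladeLevels[1L]
  og <- db@ogTable[db@ogTable$clade == rootLevel, , drop = FALSE]
  og <- og[og$protein_id %in% names(db@sequences), , drop = FALSE]
  if (!nrow(og)) stop("database has no root-level OGs with sequences")
  targets <- db@sequences[unique(og$protein_id)]
  space <- sum(Biostrings::width(targets))
  out <- lapply(names(queries), function(qid) {
    raw <- .rawLocalScores(targets, queries[[qid]])
    bits <- .bitscore(raw)
    hits <- data.frame(query_id = qid, target_id = names(targets),
                       bitscore = as.numeric(bits),
                       evalue = .evalue(bits,
                                        Biostrings::width(queries[qid]) *
                                          space))
    hits <- applyFilters(hits, filters, db@taxonomy)
    if (!nrow(hits))
      return(.noSeedRow(qid, "coarse_then_fine", "no_group_passed_filters"))
    hits$og_id <- og$og_id[match(hits$target_id, og$protein_id)]
    groupScore <- tapply(hits$bitscore, hits$og_id, max)
    bestOg <- sort(names(groupScore)[groupScore == max(groupScore)])[1L]
    fine <- hits[hits$og_id == bestOg, , drop = FALSE]
    ogSpace <- sum(Biostrings::width(db@sequences[ogMembers(db, bestOg)]))
    fine$evalue <- .evalue(fine$bitscore,
                           Biostrings::width(queries[qid]) * ogSpace)
    fine <- applyFilters(fine, filters, db@taxonomy)
    if (!nrow(fine))
      return(.noSeedRow(qid, "coarse_then_fine", "no_member_passed_filters"))
    best <- .orderHits(fine)[1L, ]
    data.frame(query_id = qid, og_id = bestOg,
               protein_id = best$target_id, bitscore = best$bitscore,
               evalue = best$evalue, mode = "coarse_then_fine",
               reason = NA_character_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.parseNum <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("malformed ", what, " at line ", lineno)
  v
}

#' Parse HMMER3 per-domain tabular output (domtblout)
#'
#' One hit per domain row: query from column 4, target from column 1,
#' the independent E-value (column 13), domain score (column 14) and
#' alignment coordinates on the query (columns 18-19, 1-based
#' inclusive). Comment lines (\code{#}) are ignored.
#'
#' @param path a domtblout file.
#' @return data.frame \code{query_id}, \code{target_id}, \code{evalue},
#'   \code{bitscore}, \code{qstart}, \code{qend}.
#' @export
parseDomtblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 22L)
      stop("malformed domtblout row (", length(f), " fields) at line ", i)
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = f[4L], target_id = f[1L],
      evalue = .parseNum(f[13L], "E-value", i),
      bitscore = .parseNum(f[14L], "score", i),
      qstart = as.integer(.parseNum(f[18L], "ali coord", i)),
      qend = as.integer(.parseNum(f[19L], "ali coord", i)))
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(), target_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      qstart = integer(), qend = integer()))
  }
  do.call(rbind, rows)
}

#' Parse BLAST/DIAMOND tabular format-6 output
#'
#' Standard 12-column layout (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore); comment lines are
#' ignored.
#'
#' @param path a format-6 file.
#' @return data.frame \code{query_id}, \code{target_id}, \code{evalue},
#'   \code{bitscore}, \code{qstart}, \code{qend}.
#' @export
parseTabular6 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "\t")[[1L]]
    if (length(f) != 12L)
      stop("malformed format-6 row (", length(f), " fields) at line ", i)
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = f[1L], target_id = f[2L],
      evalue = .parseNum(f[11L], "E-value", i),
      bitscore = .parseNum(f[12L], "bit score", i),
      qstart = as.integer(.parseNum(f[7L], "qstart", i)),
      qend = as.integer(.parseNum(f[8L], "qend", i)))
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(), target_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      qstart = integer(), qend = integer()))
  }
  do.call(rbind, rows)
}

#' Collapse a hit table to the best hit per query/target pair
#'
#' Keeps, per (query, target), the row with the lowest E-value (ties by
#' highest bit score).
#'
#' @param hits a hit data.frame.
#' @return the collapsed table.
#' @export
collapseHits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$query_id, hits$target_id, hits$evalue,
                     -hits$bitscore), , drop = FALSE]
  out <- hits[!duplicated(hits[, c("query_id", "target_id")]), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive per-query seed orthologs from an external hit table
#'
#' Drop-in replacement for the built-in search: applies the same filter
#' and tie-break rules to hits parsed from HMMER domtblout or
#' BLAST/DIAMOND tabular files.
#'
#' @param hits data.frame from [parseDomtblout()] or [parseTabular6()];
#'   target ids must be database protein ids.
#' @param db an [OrthologDb-class].
#' @param filters a [searchFilters()] object.
#' @return data.frame as in [searchDirect()] with \code{mode =
#'   "external"}.
#' @export
seedsFromHits <- function(hits, db, filters = searchFilters()) {
  hits <- collapseHits(hits)
  out <- lapply(unique(hits$query_id), function(qid) {
    h <- applyFilters(hits[hits$query_id == qid, , drop = FALSE],
                      filters, db@taxonomy)
    h <- h[h$target_id %in% db@proteins$protein_id, , drop = FALSE]
    if (!nrow(h)) return(.noSeedRow(qid, "external", "no_hit_passed_filters"))
    best <- .orderHits(h)[1L, ]
    data.frame(query_id = qid, og_id = NA_character_,
               protein_id = best$target_id, bitscore = best$bitscore,
               evalue = best$evalue, mode = "external",
               reason = NA_character_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a seed-ortholog table as TSV
#' @param seeds data.frame from a search function.
#' @param path output path.
#' @export
writeSeedOrthologs <- function(seeds, path) {
  write.table(seeds[, c("query_id", "protein_id", "evalue", "bitscore",
                        "mode")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
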