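# Orthology database bundle: construction, validation and I/O.

#' Construct an orthology database bundle
#'
#' Assembles and validates an [OrthologDb-class] from its component
#' tables. \code{cladeLevels} is always derived from the OG table (the
#' single source of truth), ordered from the root level down by lineage
#' depth.
#'
#' @param taxonomy a [TaxonomyTree-class].
#' @param proteins data.frame with columns \code{protein_id},
#'   \code{taxid}, \code{gene_name}; \code{taxid}/\code{gene_name} are
#'   filled from the id prefix / NA when missing.
#' @param sequences an \code{AAStringSet} named by protein id (optional).
#' @param ogTable data.frame \code{og_id}, \code{clade}, \code{protein_id}.
#' @param trees named list og_id -> newick string.
#' @param go,kegg,cog annotation data.frames (see [OrthologDb-class]).
#' @return a validated [OrthologDb-class].
#' @export
newOrthologDb <- function(taxonomy, proteins,
                          sequences = Biostrings::AAStringSet(),
                          ogTable = .emptyOgTable(), trees = list(),
                          go = .emptyGoTable(), kegg = .emptyKeggTable(),
                          cog = .emptyCogTable()) {
  if (is.null(proteins$taxid))
    proteins$taxid <- proteinTaxid(proteins$protein_id)
  if (is.null(proteins$gene_name))
    proteins$gene_name <- NA_character_
  levels <- unique(as.integer(ogTable$clade))
  levels <- levels[order(vapply(levels, function(x) taxDepth(taxonomy, x),
                                integer(1)))]
  obj <- new("OrthologDb", taxonomy = taxonomy, proteins = proteins,
             sequences = sequences, ogTable = ogTable, trees = trees,
             go = go, kegg = kegg, cog = cog,
             cladeLevels = levels)
  errs <- databaseIntegrityErrors(obj)
  if (length(errs))
    stop("database integrity error(s):\n  ", paste(errs, collapse = "\n  "))
  obj
}

.emptyOgTable <- function() data.frame(og_id = character(),
                                       clade = integer(),
                                       protein_id = character())
.emptyGoTable <- function() data.frame(protein_id = character(),
                                       term = character(),
                                       evidence = character())
.emptyKeggTable <- function() data.frame(protein_id = character(),
                                         pathway = character())
.emptyCogTable <- function() data.frame(og_id = character(),
                                        category = character())

#' Collect integrity errors for a database bundle
#'
#' All violations are gathered and returned together rather than failing
#' at the first one.
#'
#' @param db an [OrthologDb-class] (possibly not yet validated).
#' @return character vector of error messages (empty when consistent).
#' @export
databaseIntegrityErrors <- function(db) {
  msgs <- character()
  prot <- db@proteins
  if (nrow(prot)) {
    ptax <- .proteinTaxid(prot$protein_id)
    bad <- is.na(ptax) | ptax != prot$taxid
    if (any(bad))
      msgs <- c(msgs, sprintf("protein %s: id prefix does not match taxid %s",
                              prot$protein_id[bad], prot$taxid[bad]))
    unk <- !(prot$taxid %in% db@taxonomy@nodes)
    if (any(unk))
      msgs <- c(msgs, sprintf("protein %s: unknown taxid %d",
                              prot$protein_id[unk], prot$taxid[unk]))
  }
  if (length(db@sequences)) {
    seqs <- as.character(db@sequences)
    badaa <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
    if (any(badaa))
      msgs <- c(msgs, sprintf("sequence %s: invalid amino-acid letters",
                              names(db@sequences)[badaa]))
  }
  og <- db@ogTable
  if (nrow(og)) {
    miss <- !(og$protein_id %in% prot$protein_id)
    if (any(miss))
      msgs <- c(msgs, sprintf("OG %s: member %s absent from protein table",
                              og$og_id[miss], og$protein_id[miss]))
    unkc <- !(og$clade %in% db@taxonomy@nodes)
    if (any(unkc))
      msgs <- c(msgs, sprintf("OG %s: unknown clade taxid %d",
                              unique(og$og_id[unkc]), unique(og$clade[unkc])))
    for (oid in unique(og$og_id)) {
      rows <- og[og$og_id == oid, , drop = FALSE]
      clade <- rows$clade[1L]
      if (length(unique(rows$clade)) != 1L) {
        msgs <- c(msgs, sprintf("OG %s: inconsistent clade assignment", oid))
        next
      }
      if (clade %in% db@taxonomy@nodes) {
        mt <- .proteinTaxid(rows$protein_id)
        known <- mt %in% db@taxonomy@nodes
        out <- known & !vapply(mt, function(t)
          if (t %in% db@taxonomy@nodes)
            clade %in% taxLineage(db@taxonomy, t) else TRUE, logical(1))
        if (any(out))
          msgs <- c(msgs, sprintf("OG %s: member %s outside clade %d",
                                  oid, rows$protein_id[out], clade))
      }
      if (!is.null(db@trees[[oid]])) {
        lv <- tryCatch(.newickLeaves(db@trees[[oid]]),
                       error = function(e) NULL)
        if (is.null(lv)) {
          msgs <- c(msgs, sprintf("OG %s: unparseable gene tree", oid))
        } else if (!setequal(lv, rows$protein_id)) {
          msgs <- c(msgs, sprintf(
            "OG %s: gene-tree leaf set differs from member set", oid))
        }
      }
    }
    dup <- duplicated(og[, c("clade", "protein_id")])
    if (any(dup))
      msgs <- c(msgs, sprintf(
        "protein %s assigned to more than one OG at clade %d",
        og$protein_id[dup], og$clade[dup]))
  }
  extra <- setdiff(names(db@trees), og$og_id)
  if (length(extra))
    msgs <- c(msgs, sprintf("gene tree for unknown OG %s", extra))
  msgs
}

.newickLeaves <- function(newick) {
  phy <- readGeneTree(newick)
  phy$tip.label
}

#' Load a database bundle from a manifest
#'
#' The manifest is a JSON object mapping component names to file paths
#' (relative paths resolved against the manifest directory):
#' \code{taxonomy}, \code{proteins_fasta}, \code{og_table},
#' \code{gene_trees}, \code{go}, \code{kegg}, \code{cog},
#' \code{gene_names}. All components except \code{taxonomy} are optional.
#'
#' @param manifest path to a manifest JSON, or a directory containing
#'   \code{manifest.json}.
#' @return a validated [OrthologDb-class]; all integrity violations are
#'   reported together.
#' @export
loadDatabase <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  base <- dirname(manifest)
  pth <- function(key) {
    p <- m$files[[key]]
    if (is.null(p)) return(NULL)
    if (!grepl("^/", p)) p <- file.path(base, p)
    if (!file.exists(p)) stop("database file missing: ", p)
    p
  }
  tax <- loadTaxonomy(pth("taxonomy"))
  seqs <- Biostrings::AAStringSet()
  if (!is.null(pth("proteins_fasta")))
    seqs <- Biostrings::readAAStringSet(pth("proteins_fasta"))
  og <- .emptyOgTable()
  if (!is.null(pth("og_table"))) {
    og <- read.table(pth("og_table"), sep = "\t", header = TRUE,
                     colClasses = c("character", "integer", "character"),
                     quote = "", comment.char = "")
    names(og) <- c("og_id", "clade", "protein_id")
  }
  trees <- list()
  if (!is.null(pth("gene_trees"))) {
    tt <- read.table(pth("gene_trees"), sep = "\t", header = TRUE,
                     colClasses = "character", quote = "",
                     comment.char = "")
    trees <- setNames(as.list(tt[[2L]]), tt[[1L]])
  }
  go <- .emptyGoTable()
  if (!is.null(pth("go"))) {
    go <- read.table(pth("go"), sep = "\t", header = TRUE,
                     colClasses = "character", quote = "", comment.char = "")
    names(go) <- c("protein_id", "term", "evidence")
  }
  kegg <- .emptyKeggTable()
  if (!is.null(pth("kegg"))) {
    kegg <- read.table(pth("kegg"), sep = "\t", header = TRUE,
                       colClasses = "character", quote = "",
                       comment.char = "")
    names(kegg) <- c("protein_id", "pathway")
  }
  cog <- .emptyCogTable()
  if (!is.null(pth("cog"))) {
    cog <- read.table(pth("cog"), sep = "\t", header = TRUE,
                      colClasses = "character", quote = "",
                      comment.char = "")
    names(cog) <- c("og_id", "category")
  }
  ids <- unique(c(names(seqs), og$protein_id, go$protein_id,
                  kegg$protein_id))
  prot <- data.frame(protein_id = ids,
                     taxid = .proteinTaxid(ids),
                     gene_name = NA_character_)
  if (!is.null(pth("gene_names"))) {
    gn <- read.table(pth("gene_names"), sep = "\t", header = TRUE,
                     colClasses = "character", quote = "",
                     comment.char = "")
    names(gn) <- c("protein_id", "name")
    prot$gene_name <- gn$name[match(prot$protein_id, gn$protein_id)]
  }
  newOrthologDb(tax, prot, seqs, og, trees, go, kegg, cog)
}

#' Write a database bundle to a directory
#'
#' Emits the on-disk bundle formats (taxonomy TSV, 60-column-wrapped
#' FASTA, OG membership, gene-tree, GO/KEGG/COG and gene-name TSVs) plus
#' a \code{manifest.json}; [loadDatabase()] on the result reproduces the
#' bundle's logical content.
#'
#' @param db an [OrthologDb-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeDatabase <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(taxonomy = "taxonomy.tsv")
  writeTaxonomy(db@taxonomy, file.path(dir, "taxonomy.tsv"))
  if (length(db@sequences)) {
    files$proteins_fasta <- "proteins.fasta"
    Biostrings::writeXStringSet(db@sequences,
                                file.path(dir, "proteins.fasta"),
                                width = 60L)
  }
  wt <- function(df, fn) {
    write.table(df, file.path(dir, fn), sep = "\t", quote = FALSE,
                row.names = FALSE)
    fn
  }
  if (nrow(db@ogTable)) files$og_table <- wt(db@ogTable, "og_membership.tsv")
  if (length(db@trees)) {
    td <- data.frame(og_id = names(db@trees),
                     newick = unlist(db@trees, use.names = FALSE))
    files$gene_trees <- wt(td, "gene_trees.tsv")
  }
  if (nrow(db@go)) files$go <- wt(db@go, "go_annotations.tsv")
  if (nrow(db@kegg)) files$kegg <- wt(db@kegg, "kegg_annotations.tsv")
  if (nrow(db@cog)) files$cog <- wt(db@cog, "cog_annotations.tsv")
  named <- db@proteins[!is.na(db@proteins$gene_name),
                       c("protein_id", "gene_name")]
  if (nrow(named)) {
    names(named) <- c("protein_id", "name")
    files$gene_names <- wt(named, "gene_names.tsv")
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(format = "orthomapr-bundle", files = files),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Orthologous groups containing a protein
#'
#' @param db an [OrthologDb-class].
#' @param protein_id a single protein id.
#' @return data.frame with columns \code{og_id}, \code{clade},
#'   \code{depth}, ordered narrowest clade (deepest) first, root level
#'   last; at most one row per clade level. Zero rows when the protein
#'   is unassigned.
#' @export
ogsForProtein <- function(db, protein_id) {
  if (!(protein_id %in% db@proteins$protein_id))
    stop("unknown protein: ", protein_id)
  rows <- db@ogTable[db@ogTable$protein_id == protein_id,
                     c("og_id", "clade"), drop = FALSE]
  if (!nrow(rows)) {
    return(data.frame(og_id = character(), clade = integer(),
                      depth = integer()))
  }
  rows$depth <- vapply(rows$clade, function(x) taxDepth(db@taxonomy, x),
                       integer(1))
  rows <- rows[order(-rows$depth, rows$og_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Member proteins of an OG
#' @param db an [OrthologDb-class].
#' @param og_id a single OG id.
#' @return character vector of member protein ids.
#' @export
ogMembers <- function(db, og_id) {
  mem <- db@ogTable$protein_id[db@ogTable$og_id == og_id]
  if (!length(mem)) stop("unknown OG: ", og_id)
  mem
}

#' Gene tree of an OG
#' @param db an [OrthologDb-class].
#' @param og_id a single OG id.
#' @return an \code{ape::phylo} gene tree.
#' @export
ogGeneTree <- function(db, og_id) {
  nk <- db@trees[[og_id]]
  if (is.null(nk)) stop("no gene tree stored for OG ", og_id)
  readGeneTree(nk)
}

#' Clade levels of a database
#' @param db an [OrthologDb-class].
#' @return integer taxids, root level first.
#' @export
cladeLevels <- function(db) db@cladeLevels

#' Database taxonomy accessor
#' @param db an [OrthologDb-class].
#' @return the bundle's [TaxonomyTree-class].
#' @export
dbTaxonomy <- function(db) db@taxonomy

#' Database protein table accessor
#' @param db an [OrthologDb-class].
#' @return the protein data.frame.
#' @export
dbProteins <- function(db) db@proteins

#' Database sequence accessor
#' @param db an [OrthologDb-class].
#' @return the \code{AAStringSet} of stored sequences.
#' @export
dbSequences <- function(db) db@sequences

#' Per-protein functional annotation
#'
#' Collects the GO terms (with evidence codes), KEGG pathways and gene
#' name recorded for one protein.
#'
#' @param db an [OrthologDb-class].
#' @param protein_id a single protein id.
#' @return list with elements \code{go} (data.frame term/evidence),
#'   \code{kegg} (character), \code{gene_name} (character or NA).
#' @export
memberAnnotation <- function(db, protein_id) {
  list(
    go = db@go[db@go$protein_id == protein_id, c("term", "evidence"),
               drop = FALSE],
    kegg = db@kegg$pathway[db@kegg$protein_id == protein_id],
    gene_name = db@proteins$gene_name[match(protein_id,
                                            db@proteins$protein_id)]
  )
}
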