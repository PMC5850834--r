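# Synthetic orthology-database simulator with recorded ground truth:
# species tree, gene families evolved by duplication/loss, sequences,
# GO DAG and annotations with evidence codes, taxon constraints, and
# metagenomic abundance profiles.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
COG_LETTERS <- strsplit("JAKLBDYVTMNZWUOCGEFHIPQRS", "")[[1L]]

#' Simulation configuration
#'
#' Defines the study conditions of the synthetic database. Defaults
#' describe a desk-scale bundle: 20 species, 30 gene families, moderate
#' duplication (0.2/branch) and loss (0.05/branch), 3% per-site
#' substitution probability per branch, a 60-term GO DAG, and a
#' model-organism structure in which 30% of species carry mostly
#' experimental evidence codes while the rest are dominated by IEA.
#'
#' @param n_species number of species (taxonomy leaves).
#' @param branching inclusive range of children per internal taxonomy
#'   node.
#' @param n_families number of gene families (root-level OGs).
#' @param dup_rate per-branch, per-lineage duplication probability.
#' @param loss_rate per-branch, per-lineage loss probability.
#' @param seq_length protein length (residues).
#' @param subst_prob per-branch, per-site substitution probability.
#' @param n_go_terms number of GO terms in the synthetic DAG.
#' @param go_parents inclusive range of parents per non-root term.
#' @param k_root_terms GO terms drawn at each family root.
#' @param term_gain_prob per-branch probability of gaining a term.
#' @param term_loss_prob per-branch, per-term probability of loss.
#' @param model_frac fraction of species designated model organisms.
#' @param exp_prob_model,exp_prob_other probability that a (protein,
#'   term) pair receives an experimental evidence code, for model and
#'   non-model species.
#' @param tas_prob probability of the curated non-experimental code TAS
#'   (remainder is IEA).
#' @param name_prob probability that a protein carries a gene name.
#' @param n_constraints number of taxon constraints derived from the
#'   generated annotations.
#' @param n_sample_species species mixed into a metagenomic sample.
#' @param read_depth expected reads per gene at unit species abundance.
#' @param seed RNG seed; recorded in the output manifest.
#' @return list of class \code{simConfig}.
#' @export
simConfig <- function(n_species = 20, branching = c(2, 3),
                      n_families = 30, dup_rate = 0.2, loss_rate = 0.05,
                      seq_length = 120, subst_prob = 0.03,
                      n_go_terms = 60, go_parents = c(1, 2),
                      k_root_terms = 3, term_gain_prob = 0.08,
                      term_loss_prob = 0.05, model_frac = 0.3,
                      exp_prob_model = 0.7, exp_prob_other = 0.05,
                      tas_prob = 0.1, name_prob = 0.85,
                      n_constraints = 8, n_sample_species = 10,
                      read_depth = 20, seed = 1) {
  cfg <- list(n_species = n_species, branching = branching,
              n_families = n_families, dup_rate = dup_rate,
              loss_rate = loss_rate, seq_length = seq_length,
              subst_prob = subst_prob, n_go_terms = n_go_terms,
              go_parents = go_parents, k_root_terms = k_root_terms,
              term_gain_prob = term_gain_prob,
              term_loss_prob = term_loss_prob, model_frac = model_frac,
              exp_prob_model = exp_prob_model,
              exp_prob_other = exp_prob_other, tas_prob = tas_prob,
              name_prob = name_prob, n_constraints = n_constraints,
              n_sample_species = n_sample_species,
              read_depth = read_depth, seed = seed)
  probs <- c("dup_rate", "loss_rate", "subst_prob", "term_gain_prob",
             "term_loss_prob", "model_frac", "exp_prob_model",
             "exp_prob_other", "tas_prob", "name_prob")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]")
  }
  if (n_species < 2) stop("n_species must be at least 2")
  if (branching[1] < 2) stop("branching factor must be at least 2")
  structure(cfg, class = "simConfig")
}

# children map of a taxonomy: parent taxid (character) -> child taxids
.taxChildren <- function(tax) {
  kids <- tax@nodes[tax@nodes != tax@root]
  split(kids, tax@parent[as.character(kids)])
}

.simTaxonomy <- function(cfg) {
  shape <- function(n) {
    if (n == 1L) return(list())
    k <- sample(seq(cfg$branching[1L], cfg$branching[2L]), 1L)
    k <- max(2L, min(k, n))
    cuts <- if (k == 1L) integer(0) else
      sort(sample(seq_len(n - 1L), k - 1L))
    sizes <- diff(c(0L, cuts, n))
    lapply(sizes, shape)
  }
  root <- shape(cfg$n_species)
  child <- integer(0); parent <- integer(0); labels <- character(0)
  nid <- 0L
  assign_ids <- function(node, par) {
    nid <<- nid + 1L
    id <- nid
    child <<- c(child, id)
    parent <<- c(parent, if (is.null(par)) id else par)
    labels <<- c(labels,
                 if (length(node)) paste0("clade", id) else paste0("sp", id))
    for (ch in node) assign_ids(ch, id)
    id
  }
  assign_ids(root, NULL)
  newTaxonomyTree(child, parent, labels)
}

#' Simulate a random rooted species taxonomy
#'
#' @param config a [simConfig()].
#' @param seed RNG seed (defaults to the config's).
#' @return a [TaxonomyTree-class] with \code{n_species} leaves;
#'   deterministic given the seed.
#' @export
simulateTaxonomy <- function(config, seed = config$seed) {
  set.seed(seed)
  .simTaxonomy(config)
}

# --- gene families -----------------------------------------------------

# Evolve one gene family along the species tree. A lineage entering the
# branch above species node s is lost with prob loss_rate; otherwise it
# duplicates with prob dup_rate into two daughter lineages that continue
# along the same branch (so nested duplications are possible); a lineage
# reaching an internal node speciates into one lineage per child branch.
# Unifurcations left by loss are collapsed, which is exactly what makes
# species-overlap labelling fallible under loss.
.simFamilyOnce <- function(cfg, tax, fam, kids) {
  counters <- new.env(parent = emptyenv())
  arrive <- function(snode) {
    ch <- kids[[as.character(snode)]]
    if (is.null(ch)) {
      key <- as.character(snode)
      counters[[key]] <- (counters[[key]] %||% 0L) + 1L
      return(list(type = "leaf",
                  id = sprintf("%d.f%dg%d", snode, fam, counters[[key]]),
                  species = snode))
    }
    surv <- Filter(Negate(is.null), lapply(ch, branch))
    if (!length(surv)) return(NULL)
    if (length(surv) == 1L) return(surv[[1L]])
    list(type = "spec", children = surv)
  }
  branch <- function(snode) {
    if (runif(1) < cfg$loss_rate) return(NULL)
    if (runif(1) < cfg$dup_rate) {
      l <- branch(snode)
      r <- branch(snode)
      if (is.null(l)) return(r)
      if (is.null(r)) return(l)
      return(list(type = "dup", children = list(l, r)))
    }
    arrive(snode)
  }
  arrive(tax@root)
}

.familyLeaves <- function(node) {
  if (is.null(node)) return(data.frame(id = character(),
                                       species = integer()))
  if (node$type == "leaf")
    return(data.frame(id = node$id, species = node$species))
  do.call(rbind, lapply(node$children, .familyLeaves))
}

.familyNewick <- function(node) {
  rec <- function(nd) {
    if (nd$type == "leaf") return(nd$id)
    paste0("(", paste(vapply(nd$children, rec, character(1)),
                      collapse = ","), ")")
  }
  if (node$type == "leaf") paste0("(", node$id, ");")
  else paste0(rec(node), ";")
}

# Ground-truth ortholog pairs with relation types, read off the recorded
# speciation/duplication events of the simulated family tree.
.familyTruePairs <- function(node) {
  pairs <- list()
  rec <- function(nd) {
    if (nd$type == "leaf")
      return(data.frame(id = nd$id, species = nd$species))
    parts <- lapply(nd$children, rec)
    if (nd$type == "spec") {
      for (i in seq_len(length(parts) - 1L)) {
        for (j in seq.int(i + 1L, length(parts))) {
          li <- parts[[i]]; lj <- parts[[j]]
          for (ai in seq_len(nrow(li))) {
            for (bj in seq_len(nrow(lj))) {
              if (li$species[ai] == lj$species[bj]) next
              m <- sum(li$species == li$species[ai])
              n <- sum(lj$species == lj$species[bj])
              a <- li$id[ai]; b <- lj$id[bj]
              rel <- .relationType(m, n)
              if (a > b) {
                tmp <- a; a <- b; b <- tmp
                rel <- .relationType(n, m)
              }
              pairs[[length(pairs) + 1L]] <<-
                data.frame(a = a, b = b, relation = rel)
            }
          }
        }
      }
    }
    do.call(rbind, parts)
  }
  rec(node)
  if (!length(pairs)) {
    return(data.frame(a = character(), b = character(),
                      relation = character()))
  }
  out <- do.call(rbind, pairs)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.simFamily <- function(cfg, tax, fam, kids, max_redraws = 100L) {
  for (i in seq_len(max_redraws)) {
    nested <- .simFamilyOnce(cfg, tax, fam, kids)
    if (!is.null(nested) && nrow(.familyLeaves(nested)) >= 2L) {
      return(structure(list(nested = nested,
                            newick = .familyNewick(nested),
                            leaves = .familyLeaves(nested),
                            true_pairs = .familyTruePairs(nested),
                            family = fam),
                       class = "simGeneFamily"))
    }
  }
  stop("family generation kept going extinct after ", max_redraws,
       " redraws; lower loss_rate")
}

#' Simulate one gene family along a species tree
#'
#' @param config a [simConfig()].
#' @param taxonomy a [TaxonomyTree-class] (from [simulateTaxonomy()]).
#' @param family integer family index (used in protein names).
#' @param seed RNG seed.
#' @return object of class \code{simGeneFamily}: the nested event-
#'   labelled tree, its newick string, the leaf table and the recorded
#'   ground-truth ortholog pairs. Families that lose all genes (or
#'   retain fewer than two) are redrawn, up to a cap.
#' @export
simulateFamily <- function(config, taxonomy, family = 1L,
                           seed = config$seed + family) {
  set.seed(seed)
  .simFamily(config, taxonomy, family, .taxChildren(taxonomy))
}

# --- sequences ---------------------------------------------------------

.mutateSeq <- function(aa, p) {
  hit <- which(runif(length(aa)) < p)
  for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  aa
}

.simSequences <- function(nested, cfg) {
  out <- new.env(parent = emptyenv())
  rec <- function(nd, aa) {
    if (nd$type == "leaf") {
      out[[nd$id]] <- paste(aa, collapse = "")
      return(invisible())
    }
    for (ch in nd$children) rec(ch, .mutateSeq(aa, cfg$subst_prob))
  }
  root <- sample(AA20, cfg$seq_length, replace = TRUE)
  rec(nested, root)
  ids <- sort(ls(out))
  Biostrings::AAStringSet(setNames(
    vapply(ids, function(i) out[[i]], character(1)), ids))
}

#' Simulate protein sequences along a gene family tree
#'
#' The root sequence is uniform over the 20-letter alphabet; every
#' branch substitutes each site independently with the configured
#' probability (to a uniformly chosen different residue).
#'
#' @param family a \code{simGeneFamily}.
#' @param config a [simConfig()].
#' @param seed RNG seed.
#' @return an \code{AAStringSet} named by the family's protein ids.
#' @export
simulateSequences <- function(family, config, seed = config$seed) {
  set.seed(seed)
  .simSequences(family$nested, config)
}

# --- GO DAG and annotations -------------------------------------------

.simGoDag <- function(cfg) {
  ids <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  parents <- list()
  for (i in seq.int(2L, cfg$n_go_terms)) {
    np <- sample(seq(cfg$go_parents[1L], cfg$go_parents[2L]), 1L)
    np <- min(np, i - 1L)
    parents[[ids[i]]] <- ids[sample.int(i - 1L, np)]
  }
  newGoDag(ids, parents)
}

#' Simulate a random GO DAG
#'
#' A single-namespace rooted DAG: term 1 is the root, every later term
#' draws its parents uniformly among earlier terms.
#'
#' @param config a [simConfig()].
#' @param seed RNG seed.
#' @return a [GoDag-class].
#' @export
simulateGoDag <- function(config, seed = config$seed) {
  set.seed(seed)
  .simGoDag(config)
}

# Per-family term inheritance with gain/loss; returns the raw (unclosed)
# per-leaf term sets.
.simFamilyTerms <- function(nested, dag, cfg) {
  out <- new.env(parent = emptyenv())
  nonRoot <- dag@terms[-1L]
  rec <- function(nd, terms) {
    if (nd$type == "leaf") {
      out[[nd$id]] <- terms
      return(invisible())
    }
    for (ch in nd$children) {
      t2 <- terms[runif(length(terms)) >= cfg$term_loss_prob]
      if (runif(1) < cfg$term_gain_prob)
        t2 <- union(t2, sample(nonRoot, 1L))
      rec(ch, t2)
    }
  }
  k <- min(cfg$k_root_terms, length(nonRoot))
  rec(nested, sample(nonRoot, k))
  out
}

.simAnnotations <- function(families, dag, cfg, tax) {
  species <- taxLeaves(tax)
  nModel <- max(1L, round(cfg$model_frac * length(species)))
  modelSpecies <- sort(sample(species, nModel))
  goRows <- list()
  trueTerms <- list()
  for (famObj in families) {
    raw <- .simFamilyTerms(famObj$nested, dag, cfg)
    for (pid in ls(raw)) {
      closed <- goPropagate(dag, raw[[pid]])
      trueTerms[[pid]] <- closed
      if (!length(closed)) next
      sp <- .proteinTaxid(pid)
      pExp <- if (sp %in% modelSpecies) cfg$exp_prob_model else
        cfg$exp_prob_other
      u <- runif(length(closed))
      ev <- ifelse(u < pExp,
                   sample(EXPERIMENTAL_CODES, length(closed),
                          replace = TRUE),
                   ifelse(u < pExp + cfg$tas_prob, "TAS", "IEA"))
      goRows[[length(goRows) + 1L]] <-
        data.frame(protein_id = pid, term = closed, evidence = ev)
    }
  }
  go <- if (length(goRows)) do.call(rbind, goRows) else .emptyGoTable()
  rownames(go) <- NULL
  list(go = go, true_terms = trueTerms, model_species = modelSpecies)
}

#' Simulate per-protein functional annotations for gene families
#'
#' Each family root draws \code{k_root_terms} terms; terms are inherited
#' along the gene tree with per-branch gain/loss; leaf term sets are
#' ancestor-closed, and every (protein, term) pair receives an evidence
#' code (experimental codes preferentially in model-organism species,
#' TAS occasionally, IEA otherwise).
#'
#' @param families list of \code{simGeneFamily} objects.
#' @param dag a [GoDag-class].
#' @param config a [simConfig()].
#' @param taxonomy a [TaxonomyTree-class].
#' @param seed RNG seed.
#' @return list with \code{go} (annotation data.frame),
#'   \code{true_terms} (named list of closed term sets, pre evidence
#'   filtering) and \code{model_species}.
#' @export
simulateAnnotations <- function(families, dag, config, taxonomy,
                                seed = config$seed) {
  set.seed(seed)
  .simAnnotations(families, dag, config, taxonomy)
}

# Derive taxon constraints that the generated annotations obey by
# construction: only_in constraints at the LCA clade of a term's users,
# never_in constraints on root-child clades free of users.
.simConstraints <- function(trueTerms, cfg, tax, dag) {
  used <- sort(unique(unlist(trueTerms, use.names = FALSE)))
  used <- setdiff(used, dag@terms[1L])
  if (!length(used) || cfg$n_constraints == 0L) {
    return(data.frame(term = character(), kind = character(),
                      taxid = integer()))
  }
  bySpecies <- list()
  for (pid in names(trueTerms)) {
    sp <- as.character(.proteinTaxid(pid))
    bySpecies[[sp]] <- union(bySpecies[[sp]], trueTerms[[pid]])
  }
  rootKids <- .taxChildren(tax)[[as.character(tax@root)]]
  rows <- list()
  # constraints must also hold for every descendant term in the DAG:
  # only emit a constraint when all users of the term AND of all its
  # descendants satisfy it (guaranteed here because user sets of
  # descendants are subsets of the ancestor's user set under closure).
  for (term in sample(used)) {
    users <- as.integer(names(bySpecies)[vapply(bySpecies, function(ts)
      term %in% ts, logical(1))])
    if (!length(users)) next
    lcaU <- taxLca(tax, users)
    if (lcaU != tax@root) {
      rows[[length(rows) + 1L]] <-
        data.frame(term = term, kind = "only_in_taxon", taxid = lcaU)
    } else {
      free <- rootKids[!vapply(rootKids, function(k)
        any(taxIsDescendant(tax, users, k)), logical(1))]
      if (length(free)) {
        rows[[length(rows) + 1L]] <-
          data.frame(term = term, kind = "never_in_taxon",
                     taxid = free[[1L]])
      }
    }
    if (length(rows) >= cfg$n_constraints) break
  }
  if (!length(rows)) {
    return(data.frame(term = character(), kind = character(),
                      taxid = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- OGs at nested clade levels ---------------------------------------

.pruneNested <- function(node, keepIds) {
  if (node$type == "leaf")
    return(if (node$id %in% keepIds) node else NULL)
  surv <- Filter(Negate(is.null),
                 lapply(node$children, .pruneNested, keepIds = keepIds))
  if (!length(surv)) return(NULL)
  if (length(surv) == 1L) return(surv[[1L]])
  node$children <- surv
  node
}

.simCladeLevels <- function(tax) {
  internal <- setdiff(tax@nodes, taxLeaves(tax))
  depths <- vapply(internal, function(x) taxDepth(tax, x), integer(1))
  sort(internal[depths <= 2L])
}

.simOgTables <- function(families, tax) {
  levels <- .simCladeLevels(tax)
  ogRows <- list(); trees <- list(); rootOg <- character(0)
  for (famObj in families) {
    fam <- famObj$family
    for (clade in levels) {
      inClade <- famObj$leaves$id[taxIsDescendant(
        tax, famObj$leaves$species, clade)]
      if (length(inClade) < if (clade == tax@root) 2L else 2L) next
      ogId <- if (clade == tax@root) sprintf("OG%04d", fam) else
        sprintf("OG%04d.%d", fam, clade)
      ogRows[[length(ogRows) + 1L]] <-
        data.frame(og_id = ogId, clade = clade, protein_id = inClade)
      pruned <- .pruneNested(famObj$nested, inClade)
      trees[[ogId]] <- .familyNewick(pruned)
      if (clade == tax@root) rootOg[as.character(fam)] <- ogId
    }
  }
  list(ogTable = do.call(rbind, ogRows), trees = trees, rootOg = rootOg)
}

.simKeggCogNames <- function(families, ogInfo, cfg) {
  kegg <- list(); cog <- list(); nameRows <- list()
  for (famObj in families) {
    fam <- famObj$family
    npath <- sample(0:2, 1L)
    paths <- if (npath) sprintf("map%05d", sample.int(99999L, npath)) else
      character(0)
    base <- paste0(paste(sample(letters, 3L), collapse = ""),
                   sample(LETTERS, 1L))
    copyIdx <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(famObj$leaves))) {
      pid <- famObj$leaves$id[i]
      sp <- as.character(famObj$leaves$species[i])
      copyIdx[[sp]] <- (copyIdx[[sp]] %||% 0L) + 1L
      for (p in paths) {
        if (runif(1) < 0.9)
          kegg[[length(kegg) + 1L]] <-
            data.frame(protein_id = pid, pathway = p)
      }
      if (runif(1) < cfg$name_prob) {
        nm <- if (copyIdx[[sp]] > 1L)
          paste0(base, copyIdx[[sp]]) else base
        nameRows[[length(nameRows) + 1L]] <-
          data.frame(protein_id = pid, name = nm)
      }
    }
    cat_ <- paste(sample(COG_LETTERS, sample(1:2, 1L)), collapse = "")
    famOgs <- grep(sprintf("^OG%04d($|\\.)", fam),
                   names(ogInfo$trees), value = TRUE)
    for (oid in famOgs) {
      cog[[length(cog) + 1L]] <- data.frame(og_id = oid, category = cat_)
    }
  }
  list(
    kegg = if (length(kegg)) do.call(rbind, kegg) else .emptyKeggTable(),
    cog = if (length(cog)) do.call(rbind, cog) else .emptyCogTable(),
    names = if (length(nameRows)) do.call(rbind, nameRows) else
      data.frame(protein_id = character(), name = character()))
}

#' Simulate a complete orthology database bundle with ground truth
#'
#' Orchestrates taxonomy, gene families (with recorded true events and
#' ortholog pairs), sequences, GO DAG, annotations with evidence codes,
#' derived taxon constraints, OGs at nested clade levels with induced
#' gene trees, and KEGG/COG/gene-name tables. Fully deterministic given
#' the config (including its seed); the generated bundle always passes
#' database validation.
#'
#' @param config a [simConfig()].
#' @return list of class \code{simBundle} with elements \code{db} (an
#'   [OrthologDb-class]), \code{dag}, \code{constraints}, and
#'   \code{truth} (families with nested event-labelled trees, ortholog
#'   pairs per family, per-protein true closed term sets, model species,
#'   the config).
#' @export
simulateDatabase <- function(config) {
  set.seed(config$seed)
  tax <- .simTaxonomy(config)
  kids <- .taxChildren(tax)
  families <- lapply(seq_len(config$n_families), function(f)
    .simFamily(config, tax, f, kids))
  seqList <- lapply(families, function(famObj)
    .simSequences(famObj$nested, config))
  sequences <- do.call(c, seqList)
  dag <- .simGoDag(config)
  ann <- .simAnnotations(families, dag, config, tax)
  constraints <- .simConstraints(ann$true_terms, config, tax, dag)
  ogInfo <- .simOgTables(families, tax)
  extra <- .simKeggCogNames(families, ogInfo, config)
  allLeaves <- do.call(rbind, lapply(families, `[[`, "leaves"))
  proteins <- data.frame(
    protein_id = allLeaves$id,
    taxid = allLeaves$species,
    gene_name = extra$names$name[match(allLeaves$id,
                                       extra$names$protein_id)])
  db <- newOrthologDb(tax, proteins, sequences, ogInfo$ogTable,
                      ogInfo$trees, ann$go, extra$kegg, extra$cog)
  pairRows <- lapply(families, function(famObj) {
    tp <- famObj$true_pairs
    if (nrow(tp)) tp$og_id <- ogInfo$rootOg[[as.character(famObj$family)]]
    tp
  })
  truth <- list(families = families,
                ortholog_pairs = do.call(rbind, pairRows),
                true_terms = ann$true_terms,
                model_species = ann$model_species,
                config = config)
  structure(list(db = db, dag = dag, constraints = constraints,
                 truth = truth),
            class = "simBundle")
}

#' @export
print.simBundle <- function(x, ...) {
  cat(sprintf("simBundle (seed %d):\n", x$truth$config$seed))
  show(x$db)
  invisible(x)
}

#' Write a simulated bundle (database, DAG, constraints, ground truth)
#'
#' Emits the database bundle via [writeDatabase()], the GO DAG as OBO,
#' taxon constraints, ground-truth TSVs (ortholog pairs and true terms)
#' and a manifest recording the configuration and seed.
#'
#' @param bundle a \code{simBundle}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeSimBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeDatabase(bundle$db, dir)
  writeObo(bundle$dag, file.path(dir, "ontology.obo"))
  write.table(bundle$constraints, file.path(dir, "taxon_constraints.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$ortholog_pairs,
              file.path(dir, "truth_ortholog_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tt <- bundle$truth$true_terms
  ttDf <- data.frame(
    protein_id = rep(names(tt), lengths(tt)),
    term = unlist(tt, use.names = FALSE))
  write.table(ttDf, file.path(dir, "truth_terms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(generator = "orthomapr-simdb",
         config = unclass(bundle$truth$config),
         model_species = bundle$truth$model_species),
    file.path(dir, "sim_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a GO DAG as a minimal OBO 1.2 file
#' @param dag a [GoDag-class].
#' @param path output path.
#' @export
writeObo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag@terms) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("name: ", t),
                 paste0("namespace: ", dag@namespace[[t]])), con)
    for (p in dag@parents[[t]]) writeLines(paste0("is_a: ", p), con)
    if (t %in% dag@obsolete) writeLines("is_obsolete: true", con)
    for (a in names(dag@altIds)[dag@altIds == t])
      writeLines(paste0("alt_id: ", a), con)
  }
  invisible(path)
}

#' Simulate a metagenomic sample and its gold functional profile
#'
#' Draws a sample composition over a subset of species with log-normal
#' abundances, then per-gene read counts with Poisson noise proportional
#' to the species abundance. The gold profile sums read counts over
#' each GO term's truly annotated genes (the read-count construction of
#' a ground-truth profile).
#'
#' @param bundle a \code{simBundle}.
#' @param config a [simConfig()] (defaults to the bundle's).
#' @param sample_id sample label.
#' @param seed RNG seed.
#' @return list with \code{gene_abundance} (named read counts),
#'   \code{species_abundance}, and \code{gold} (a
#'   \code{functionalProfile} over the true annotations).
#' @export
simulateMetagenomeProfile <- function(bundle,
                                      config = bundle$truth$config,
                                      sample_id = "sample1",
                                      seed = config$seed) {
  set.seed(seed)
  tax <- bundle$db@taxonomy
  species <- taxLeaves(tax)
  chosen <- sort(sample(species, min(config$n_sample_species,
                                     length(species))))
  abund <- setNames(rlnorm(length(chosen)), chosen)
  prot <- bundle$db@proteins
  genes <- prot$protein_id[prot$taxid %in% chosen]
  reads <- vapply(genes, function(g) {
    sp <- as.character(prot$taxid[match(g, prot$protein_id)])
    rpois(1L, abund[[sp]] * config$read_depth)
  }, numeric(1))
  gold <- functionalProfile(reads, bundle$truth$true_terms, sample_id)
  list(gene_abundance = reads, species_abundance = abund, gold = gold)
}
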