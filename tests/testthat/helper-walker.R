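# Independent ground-truth walker: recomputes, for a held-out query
# protein, the expected seed ortholog and the expected transferred GO
# set by walking the simulator's recorded ground truth and the stored
# database tables with plain set algebra (no package transfer code).

# identity count between equal-length sequences
orcIdentity <- function(a, b) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  sum(av == bv)
}

# expected seeds: the query's true orthologs (from recorded pairs) with
# maximal sequence identity, excluding banned taxa
orcExpectedSeeds <- function(qid, bundle, banned_taxa) {
  pairs <- bundle$truth$ortholog_pairs
  partners <- c(pairs$b[pairs$a == qid], pairs$a[pairs$b == qid])
  ptax <- orcSpecies(partners)
  lin <- lapply(banned_taxa, function(x) NULL)
  keep <- !vapply(ptax, function(t)
    any(vapply(banned_taxa, function(b)
      b %in% orcLineage(bundle$db@taxonomy, t), logical(1))), logical(1))
  partners <- partners[keep]
  if (!length(partners)) return(character(0))
  seqs <- as.character(bundle$db@sequences)
  q <- seqs[[qid]]
  idents <- vapply(partners, function(p) orcIdentity(q, seqs[[p]]),
                   numeric(1))
  sort(partners[idents == max(idents)])
}

# scope: deepest clade level on the seed species' lineage hosting an OG
# that contains the seed (manual scan of the OG table)
orcExpectedScope <- function(seed, bundle) {
  tax <- bundle$db@taxonomy
  og <- bundle$db@ogTable
  lin <- orcLineage(tax, orcSpecies(seed))
  levels <- intersect(lin, unique(og$clade))
  for (clade in rev(levels)) {  # lineage is root-first; deepest last
    rows <- og[og$clade == clade & og$protein_id == seed, , drop = FALSE]
    if (nrow(rows)) return(list(clade = clade, og_id = rows$og_id[1L]))
  }
  list(clade = lin[1L], og_id = NA_character_)
}

# prune the recorded nested family tree to a leaf subset (own recursion)
orcPrune <- function(nd, keep) {
  if (nd$type == "leaf") return(if (nd$id %in% keep) nd else NULL)
  surv <- Filter(Negate(is.null), lapply(nd$children, orcPrune, keep = keep))
  if (!length(surv)) return(NULL)
  if (length(surv) == 1L) return(surv[[1L]])
  nd$children <- surv
  nd
}

orcFamilyOfProtein <- function(qid, bundle) {
  for (famObj in bundle$truth$families) {
    if (qid %in% famObj$leaves$id) return(famObj)
  }
  NULL
}

# expected transferred GO set given a seed: brute-force species-overlap
# orthologs of the seed on the scope OG's tree, scope/exclusion filters,
# seed itself as donor, evidence filter, reachability-oracle closure
orcExpectedGo <- function(seed, bundle, banned_taxa, evidence_class) {
  tax <- bundle$db@taxonomy
  scope <- orcExpectedScope(seed, bundle)
  donors <- seed
  if (!is.na(scope$og_id)) {
    members <- bundle$db@ogTable$protein_id[
      bundle$db@ogTable$og_id == scope$og_id]
    fam <- orcFamilyOfProtein(seed, bundle)
    pruned <- orcPrune(fam$nested, members)
    # nested sim nodes carry type spec/dup/leaf; relabel for the oracle
    toOrc <- function(nd) {
      if (nd$type == "leaf") return(orcLeaf(nd$id))
      do.call(orcNode, lapply(nd$children, toOrc))
    }
    pairs <- orcPairs(toOrc(pruned), threshold = 0)
    partners <- c(pairs$b[pairs$a == seed], pairs$a[pairs$b == seed])
    ptax <- orcSpecies(partners)
    inScope <- vapply(ptax, function(t)
      scope$clade %in% orcLineage(tax, t), logical(1))
    notBanned <- !vapply(ptax, function(t)
      any(vapply(banned_taxa, function(b)
        b %in% orcLineage(tax, t), logical(1))), logical(1))
    donors <- c(donors, partners[inScope & notBanned])
  }
  go <- bundle$db@go
  rows <- go[go$protein_id %in% donors, , drop = FALSE]
  keep <- switch(evidence_class,
                 experimental = rows$evidence %in%
                   c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP"),
                 non_electronic = rows$evidence != "IEA",
                 all = rep(TRUE, nrow(rows)))
  orcClosure(bundle$dag, unique(rows$term[keep]))
}
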