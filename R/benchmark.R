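# Evaluation framework: TP/FP/uncertain term classification against an
# evidence-coded gold standard, per-proteome summaries, CAFA-style
# F-max, and metagenomic functional-profile comparison.

#' Build a gold standard from evidence-coded GO annotations
#'
#' Per-protein true-positive term sets are the terms whose evidence code
#' falls in the requested class, ancestor-closed through the DAG
#' (closure is symmetric with the closure applied to predictions, so a
#' method is not penalised for predicting a parent entailed by a gold
#' term).
#'
#' @param go data.frame \code{protein_id}, \code{term}, \code{evidence}
#'   (e.g. the \code{go} table of an [OrthologDb-class], or read via
#'   [readGoldStandard()]).
#' @param dag a [GoDag-class].
#' @param evidence_class \code{"experimental"}, \code{"non_electronic"}
#'   or \code{"all"}.
#' @param closed ancestor-close the per-protein sets (default).
#' @return object of class \code{goldStandard}: list with \code{tp}
#'   (named list of term sets) and \code{taxid} (named integer vector,
#'   parsed from protein id prefixes).
#' @export
goldStandard <- function(go, dag, evidence_class = "experimental",
                         closed = TRUE) {
  rows <- go[.evidenceKeep(go$evidence, evidence_class), , drop = FALSE]
  tp <- lapply(split(rows$term, rows$protein_id), function(terms) {
    terms <- unique(terms)
    if (closed) goPropagate(dag, terms) else sort(terms)
  })
  structure(list(tp = tp,
                 taxid = setNames(proteinTaxid(names(tp)), names(tp))),
            class = "goldStandard")
}

#' Read a gold-standard TSV (protein, term, evidence)
#' @param path file path.
#' @return data.frame suitable for [goldStandard()].
#' @export
readGoldStandard <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character", quote = "", comment.char = "")
  names(df) <- c("protein_id", "term", "evidence")
  df
}

#' Classify predicted terms as TP, FP or uncertain
#'
#' A predicted term is a true positive when it lies in the protein's
#' gold (curated) set; otherwise a false positive when assigning it to
#' the protein's taxon violates a taxon constraint; otherwise uncertain.
#' Proteins absent from the gold standard are treated as having an
#' empty curated set (their predictions can still be FP or uncertain).
#'
#' @param predictions data.frame \code{protein}, \code{term}
#'   (ancestor-closed).
#' @param gold a \code{goldStandard} object.
#' @param dag a [GoDag-class].
#' @param constraints taxon-constraint data.frame (see
#'   [loadTaxonConstraints()]).
#' @param taxonomy a [TaxonomyTree-class].
#' @param protein_taxids optional named integer vector giving each
#'   predicted protein's taxon; defaults to the gold standard's taxids,
#'   then to parsing the protein id prefix.
#' @return data.frame \code{protein}, \code{term}, \code{label}; the
#'   labels partition the predicted set.
#' @export
classifyTerms <- function(predictions, gold, dag, constraints, taxonomy,
                          protein_taxids = NULL) {
  if (!nrow(predictions)) {
    return(data.frame(protein = character(), term = character(),
                      label = character()))
  }
  taxOf <- function(p) {
    if (!is.null(protein_taxids) && p %in% names(protein_taxids))
      return(protein_taxids[[p]])
    if (p %in% names(gold$taxid)) return(gold$taxid[[p]])
    .proteinTaxid(p)
  }
  fpCache <- new.env(parent = emptyenv())
  isFp <- function(term, taxid) {
    key <- paste0(term, "@", taxid)
    if (!is.null(fpCache[[key]])) return(fpCache[[key]])
    v <- violatesTaxonConstraint(dag, term, taxid, constraints, taxonomy)
    fpCache[[key]] <- v
    v
  }
  label <- character(nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    p <- predictions$protein[i]
    t <- predictions$term[i]
    label[i] <- if (t %in% gold$tp[[p]]) "TP"
    else if (isFp(t, taxOf(p))) "FP"
    else "uncertain"
  }
  data.frame(protein = predictions$protein, term = predictions$term,
             label = label)
}

#' Summarise a term classification over a proteome
#'
#' The strict TP-ratio treats every non-true assignment as false
#' (CAFA-style): \eqn{\sum TP / \sum (TP + FP + uncertain)}. The TP/FP
#' proportion ignores uncertain assignments. Per-protein coverage
#' categories: \code{tp_only} (every assignment TP), \code{no_tp} (no
#' TP assignment) and \code{mixed}; their fractions (of the proteome)
#' sum to the coverage.
#'
#' @param classification data.frame from [classifyTerms()].
#' @param proteome_size total number of proteins in the annotated
#'   proteome.
#' @return list of class \code{evalSummary}: per-protein mean TP/FP/
#'   uncertain counts, \code{tp_ratio}, \code{tp_fp_proportion},
#'   \code{coverage} and category fractions. Ratios are NA (undefined),
#'   not zero, when nothing was annotated.
#' @export
summarizeEval <- function(classification, proteome_size) {
  stopifnot(proteome_size >= 0)
  n <- nrow(classification)
  if (!n) {
    return(structure(list(mean_tp = NA_real_, mean_fp = NA_real_,
                          mean_uncertain = NA_real_, tp_ratio = NA_real_,
                          tp_fp_proportion = NA_real_, coverage = 0,
                          fraction_tp_only = 0, fraction_mixed = 0,
                          fraction_no_tp = 0,
                          n_annotated = 0L,
                          proteome_size = proteome_size),
                     class = "evalSummary"))
  }
  perProt <- split(classification$label, classification$protein)
  nAnn <- length(perProt)
  tp <- vapply(perProt, function(x) sum(x == "TP"), integer(1))
  fp <- vapply(perProt, function(x) sum(x == "FP"), integer(1))
  un <- vapply(perProt, function(x) sum(x == "uncertain"), integer(1))
  cat <- ifelse(tp == lengths(perProt), "tp_only",
                ifelse(tp == 0L, "no_tp", "mixed"))
  totTP <- sum(tp); totFP <- sum(fp); totUN <- sum(un)
  structure(list(
    mean_tp = mean(tp), mean_fp = mean(fp), mean_uncertain = mean(un),
    tp_ratio = totTP / (totTP + totFP + totUN),
    tp_fp_proportion = if (totTP + totFP > 0) totTP / (totTP + totFP)
      else NA_real_,
    coverage = nAnn / proteome_size,
    fraction_tp_only = sum(cat == "tp_only") / proteome_size,
    fraction_mixed = sum(cat == "mixed") / proteome_size,
    fraction_no_tp = sum(cat == "no_tp") / proteome_size,
    n_annotated = nAnn,
    proteome_size = proteome_size),
    class = "evalSummary")
}

#' @export
print.evalSummary <- function(x, ...) {
  cat(sprintf(paste0(
    "evalSummary: %d/%d proteins annotated (coverage %.3f)\n",
    "  mean per-protein TP %.2f, FP %.2f, uncertain %.2f\n",
    "  tp_ratio %.3f, TP/(TP+FP) %.3f\n",
    "  categories: tp_only %.3f, mixed %.3f, no_tp %.3f\n"),
    x$n_annotated, x$proteome_size, x$coverage,
    x$mean_tp, x$mean_fp, x$mean_uncertain,
    x$tp_ratio, x$tp_fp_proportion,
    x$fraction_tp_only, x$fraction_mixed, x$fraction_no_tp))
  invisible(x)
}

#' F-max of scored term predictions (partial mode)
#'
#' For each threshold t in a 0.01-step grid, precision is the mean over
#' proteins with at least one prediction at or above t of
#' \eqn{|pred_t \cap gold| / |pred_t|} (partial mode: proteins with no
#' prediction do not dilute precision) and recall is the mean over all
#' benchmark proteins with non-empty gold of
#' \eqn{|pred_t \cap gold| / |gold|}. F-max is the maximum harmonic mean
#' over the grid. Unscored predictions are treated as score 1, so a
#' binary predictor degenerates to a single operating point.
#'
#' @param predictions data.frame \code{protein}, \code{term} and
#'   optionally \code{score} in \eqn{[0,1]}.
#' @param gold a \code{goldStandard} object or a named list of term
#'   sets; proteins with empty sets are excluded from recall averaging.
#' @param thresholds numeric grid (default \code{seq(0.01, 1, 0.01)}).
#' @return list of class \code{fmaxResult} with \code{fmax},
#'   \code{threshold} (largest threshold attaining the max) and the
#'   per-threshold \code{curve} data.frame.
#' @export
fmax <- function(predictions, gold, thresholds = seq(0.01, 1, by = 0.01)) {
  goldSets <- if (inherits(gold, "goldStandard")) gold$tp else gold
  goldSets <- goldSets[lengths(goldSets) > 0L]
  if (!length(goldSets))
    stop("benchmark undefined: gold standard is empty")
  if (is.null(predictions$score)) predictions$score <- 1
  if (any(predictions$score < 0 | predictions$score > 1))
    stop("prediction scores must lie in [0, 1]")
  bench <- names(goldSets)
  predSplit <- split(predictions[, c("term", "score")],
                     predictions$protein)
  curve <- data.frame(threshold = thresholds, precision = NA_real_,
                      recall = NA_real_, f = 0)
  for (k in seq_along(thresholds)) {
    t <- thresholds[k]
    prec <- c(); rec <- numeric(0)
    for (p in union(bench, names(predSplit))) {
      ps <- predSplit[[p]]
      predT <- if (is.null(ps)) character(0) else
        unique(ps$term[ps$score >= t])
      gs <- goldSets[[p]]
      if (length(predT))
        prec <- c(prec, length(intersect(predT, gs)) / length(predT))
      if (p %in% bench)
        rec <- c(rec, length(intersect(predT, gs)) / length(gs))
    }
    pr <- if (length(prec)) mean(prec) else NA_real_
    rc <- mean(rec)
    curve$precision[k] <- pr
    curve$recall[k] <- rc
    curve$f[k] <- if (!is.na(pr) && (pr + rc) > 0)
      2 * pr * rc / (pr + rc) else 0
  }
  best <- max(curve$f)
  at <- max(curve$threshold[curve$f == best])
  structure(list(fmax = best, threshold = at, curve = curve),
            class = "fmaxResult")
}

#' @export
print.fmaxResult <- function(x, ...) {
  cat(sprintf("fmaxResult: F-max %.4f at threshold %.2f\n",
              x$fmax, x$threshold))
  invisible(x)
}

#' Build a GO functional profile from gene abundances
#'
#' The abundance of a term is the summed abundance of every gene
#' annotated with it. Term sets are expected ancestor-closed, so a
#' gene's abundance also accrues to all parents of its terms.
#'
#' @param gene_abundances named non-negative numeric vector.
#' @param gene_to_go named list mapping gene -> character vector of
#'   (closed) GO terms.
#' @param sample_id label for the sample.
#' @return object of class \code{functionalProfile}: list with
#'   \code{abundance} (named numeric) and \code{sample}.
#' @export
functionalProfile <- function(gene_abundances, gene_to_go,
                              sample_id = "sample") {
  if (any(gene_abundances < 0))
    stop("gene abundances must be non-negative")
  acc <- new.env(parent = emptyenv())
  for (g in names(gene_abundances)) {
    a <- gene_abundances[[g]]
    if (a == 0) next
    for (t in gene_to_go[[g]]) {
      acc[[t]] <- (acc[[t]] %||% 0) + a
    }
  }
  terms <- sort(ls(acc))
  structure(list(abundance = setNames(
    vapply(terms, function(t) acc[[t]], numeric(1)), terms),
    sample = sample_id),
    class = "functionalProfile")
}

#' @export
print.functionalProfile <- function(x, ...) {
  cat(sprintf("functionalProfile '%s': %d terms, total abundance %g\n",
              x$sample, length(x$abundance), sum(x$abundance)))
  invisible(x)
}

#' Write / read a functional profile as TSV (term, abundance)
#' @param profile a \code{functionalProfile}.
#' @param path file path.
#' @export
writeProfile <- function(profile, path) {
  write.table(data.frame(term = names(profile$abundance),
                         abundance = unname(profile$abundance)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfile
#' @param sample_id sample label for the profile read back.
#' @export
readProfile <- function(path, sample_id = basename(path)) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "numeric"), quote = "",
                   comment.char = "")
  structure(list(abundance = setNames(df[[2L]], df[[1L]]),
                 sample = sample_id),
            class = "functionalProfile")
}

#' Compare two functional profiles by Spearman correlation
#'
#' Vectors are built over the union of the two profiles' term keys
#' (terms absent from one profile count as abundance 0) — only terms
#' appearing in either profile enter the comparison. The correlation is
#' the tie-corrected Spearman rho; the p-value uses the large-sample
#' t-distribution approximation, or exact permutation for small
#' profiles (n of at most 8 union terms) when requested.
#'
#' @param a,b \code{functionalProfile} objects.
#' @param p_method \code{"t"} or \code{"permutation"}.
#' @return list with \code{rho}, \code{p_value} and \code{n} (union
#'   size). \code{rho} is NA when either vector is constant.
#' @export
compareProfiles <- function(a, b, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  keys <- union(names(a$abundance), names(b$abundance))
  n <- length(keys)
  if (n < 3L) stop("profile comparison needs at least 3 terms in the union")
  x <- ifelse(keys %in% names(a$abundance), a$abundance[keys], 0)
  y <- ifelse(keys %in% names(b$abundance), b$abundance[keys], 0)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- cor(rank(x), rank(y), method = "pearson")
  p <- if (p_method == "t") {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * pt(-abs(tt), df = n - 2)
  } else {
    if (n > 8L)
      stop("exact permutation p-value limited to 8 terms; use p_method='t'")
    rx <- rank(x); ry <- rank(y)
    perms <- .allPermutations(n)
    obs <- abs(rho)
    stats <- apply(perms, 1L, function(ix)
      abs(cor(rx, ry[ix], method = "pearson")))
    mean(stats >= obs - 1e-12)
  }
  list(rho = rho, p_value = p, n = n)
}

.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}
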