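# TP/FP/uncertain classification, proteome summaries, F-max and
# functional-profile comparison.

benchFixture <- function() {
  tax <- orcTinyTaxonomy()
  dag <- newGoDag(sprintf("GO:%07d", 1:6),
                  parents = list("GO:0000002" = "GO:0000001",
                                 "GO:0000003" = "GO:0000002",
                                 "GO:0000004" = "GO:0000001",
                                 "GO:0000005" = "GO:0000004",
                                 "GO:0000006" = "GO:0000001"))
  go <- data.frame(
    protein_id = c("4.p1", "4.p1", "6.q1"),
    term = c("GO:0000003", "GO:0000006", "GO:0000005"),
    evidence = c("IDA", "IEA", "EXP"))
  # clade 2 is "plants": nervous-system-like term 5 never occurs there
  cons <- data.frame(term = "GO:0000004", kind = "never_in_taxon",
                     taxid = 2L)
  list(tax = tax, dag = dag, go = go, cons = cons)
}

test_that("gold standards are evidence-filtered and ancestor-closed", {
  fx <- benchFixture()
  gold <- goldStandard(fx$go, fx$dag, "experimental")
  expect_setequal(names(gold$tp), c("4.p1", "6.q1"))
  expect_equal(gold$tp[["4.p1"]], sprintf("GO:%07d", 1:3))  # IEA dropped
  expect_equal(gold$tp[["6.q1"]], sprintf("GO:%07d", c(1, 4, 5)))
  expect_equal(unname(gold$taxid), c(4L, 6L))
  raw <- goldStandard(fx$go, fx$dag, "experimental", closed = FALSE)
  expect_equal(raw$tp[["4.p1"]], "GO:0000003")
})

test_that("classification partitions predictions; the planted taxon-excluded term is FP", {
  fx <- benchFixture()
  gold <- goldStandard(fx$go, fx$dag, "experimental")
  preds <- data.frame(
    protein = c("4.p1", "4.p1", "4.p1", "4.p1", "6.q1"),
    term = c("GO:0000003", "GO:0000002", "GO:0000005", "GO:0000006",
             "GO:0000005"))
  cls <- classifyTerms(preds, gold, fx$dag, fx$cons, fx$tax)
  expect_equal(nrow(cls), nrow(preds))               # partition
  lab <- setNames(cls$label, paste(cls$protein, cls$term))
  expect_equal(unname(lab["4.p1 GO:0000003"]), "TP")
  expect_equal(unname(lab["4.p1 GO:0000002"]), "TP")
  # the plant-protein / never-in-plants prediction (child of the
  # constrained term, so DAG inheritance applies)
  expect_equal(unname(lab["4.p1 GO:0000005"]), "FP")
  expect_equal(unname(lab["4.p1 GO:0000006"]), "uncertain")
  # same term on a non-plant protein is fine (and in its gold)
  expect_equal(unname(lab["6.q1 GO:0000005"]), "TP")
  # a protein missing from gold still gets FP/uncertain labels
  preds2 <- data.frame(protein = "4.p9", term = c("GO:0000005",
                                                  "GO:0000006"))
  cls2 <- classifyTerms(preds2, gold, fx$dag, fx$cons, fx$tax)
  expect_equal(cls2$label, c("FP", "uncertain"))
  # random triples against a three-way set-membership oracle
  set.seed(401)
  for (rep in 1:10) {
    dag <- orcRandomDag(15)
    tax <- fx$tax
    terms <- dag@terms
    goldSets <- list("4.x" = sample(terms, 4), "6.y" = sample(terms, 3))
    goldSets <- lapply(goldSets, function(t) orcClosure(dag, t))
    g <- structure(list(tp = goldSets,
                        taxid = c("4.x" = 4L, "6.y" = 6L)),
                   class = "goldStandard")
    cons <- data.frame(term = sample(terms, 2),
                       kind = sample(c("never_in_taxon", "only_in_taxon"),
                                     2, replace = TRUE),
                       taxid = sample(c(2L, 3L), 2, replace = TRUE))
    preds <- data.frame(
      protein = sample(names(goldSets), 12, replace = TRUE),
      term = sample(terms, 12, replace = TRUE))
    preds <- unique(preds)
    cls <- classifyTerms(preds, g, dag, cons, tax)
    for (i in seq_len(nrow(cls))) {
      p <- cls$protein[i]; t <- cls$term[i]
      expTP <- t %in% goldSets[[p]]
      expFP <- !expTP && {
        anc <- orcClosure(dag, t)
        any(vapply(seq_len(nrow(cons)), function(k) {
          if (!(cons$term[k] %in% anc)) return(FALSE)
          under <- cons$taxid[k] %in% orcLineage(tax, g$taxid[[p]])
          if (cons$kind[k] == "never_in_taxon") under else !under
        }, logical(1)))
      }
      expect_equal(cls$label[i],
                   if (expTP) "TP" else if (expFP) "FP" else "uncertain")
    }
  }
})

test_that("summaries: hand-computed fixture, perfect predictions, and the empty case", {
  cls <- data.frame(
    protein = c("p1", "p1", "p1", "p2", "p2", "p3", "p4", "p4", "p4"),
    term = paste0("t", 1:9),
    label = c("TP", "TP", "uncertain", "TP", "FP", "FP", "TP", "TP", "TP"))
  s <- summarizeEval(cls, proteome_size = 6)
  expect_equal(s$n_annotated, 4L)
  expect_equal(s$coverage, 4 / 6)
  expect_equal(s$mean_tp, mean(c(2, 1, 0, 3)))
  expect_equal(s$mean_fp, mean(c(0, 1, 1, 0)))
  expect_equal(s$mean_uncertain, mean(c(1, 0, 0, 0)))
  expect_equal(s$tp_ratio, 6 / 9)
  expect_equal(s$tp_fp_proportion, 6 / 8)
  expect_true(s$tp_ratio <= s$tp_fp_proportion)
  expect_equal(s$fraction_tp_only, 1 / 6)   # p4 only
  expect_equal(s$fraction_mixed, 2 / 6)     # p1, p2
  expect_equal(s$fraction_no_tp, 1 / 6)     # p3
  expect_equal(s$fraction_tp_only + s$fraction_mixed + s$fraction_no_tp,
               s$coverage)
  # all-TP predictions: tp_ratio 1 and tp_only fraction equals coverage
  allTp <- data.frame(protein = c("a", "a", "b"), term = paste0("t", 1:3),
                      label = "TP")
  s2 <- summarizeEval(allTp, proteome_size = 4)
  expect_equal(s2$tp_ratio, 1)
  expect_equal(s2$fraction_tp_only, s2$coverage)
  # no predictions: coverage 0, undefined (NA) ratios rather than zeros
  s3 <- summarizeEval(allTp[0, ], proteome_size = 4)
  expect_equal(s3$coverage, 0)
  expect_true(is.na(s3$tp_ratio))
  expect_true(is.na(s3$tp_fp_proportion))
})

test_that("F-max: closed-form cases and agreement with a finer-grid brute-force sweep", {
  gold <- list(p1 = c("GO:0000001", "GO:0000002"))
  # perfect predictor
  perf <- data.frame(protein = "p1",
                     term = c("GO:0000001", "GO:0000002"), score = 1)
  expect_equal(fmax(perf, gold)$fmax, 1)
  # single protein, gold {a,b}, predict {a}: p = 1, r = 0.5, F = 2/3
  half <- data.frame(protein = "p1", term = "GO:0000001", score = 1)
  expect_equal(fmax(half, gold)$fmax, 2 / 3)
  # unscored predictions collapse to one operating point
  unsc <- data.frame(protein = "p1", term = "GO:0000001")
  fm <- fmax(unsc, gold)
  expect_equal(fm$fmax, 2 / 3)
  expect_equal(length(unique(round(fm$curve$f, 12))), 1L)
  expect_error(fmax(perf, list(p1 = character(0))), "empty")
  # random scored instances vs a 0.001-step brute-force sweep
  set.seed(402)
  terms <- sprintf("GO:%07d", 1:12)
  for (rep in 1:8) {
    prots <- paste0("p", 1:sample(3:8, 1))
    gold <- lapply(setNames(prots, prots), function(p)
      sample(terms, sample(0:5, 1)))
    gold <- gold[lengths(gold) > 0]
    if (!length(gold)) next
    preds <- do.call(rbind, lapply(prots, function(p) {
      k <- sample(0:6, 1)
      if (!k) return(NULL)
      data.frame(protein = p, term = sample(terms, k),
                 score = round(runif(k), 2))
    }))
    if (is.null(preds)) next
    got <- fmax(preds, gold)
    # finer-grid oracle: direct sweep at 0.001 resolution
    fineF <- vapply(seq(0.001, 1, by = 0.001), function(t) {
      prec <- c(); rec <- c()
      for (p in names(gold)) {
        pt <- preds$term[preds$protein == p & preds$score >= t]
        rec <- c(rec, length(intersect(pt, gold[[p]])) / length(gold[[p]]))
      }
      for (p in unique(preds$protein)) {
        pt <- preds$term[preds$protein == p & preds$score >= t]
        if (length(pt))
          prec <- c(prec, length(intersect(pt, gold[[p]])) / length(pt))
      }
      pr <- if (length(prec)) mean(prec) else NA_real_
      rc <- mean(rec)
      if (!is.na(pr) && pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    }, numeric(1))
    expect_equal(got$fmax, max(fineF), tolerance = 1e-12)
  }
})

test_that("functional profiles sum gene abundances per term", {
  dagless <- list(g1 = c("GO:0000001", "GO:0000002"),
                  g2 = c("GO:0000002"),
                  g3 = c("GO:0000003"))
  pr <- functionalProfile(c(g1 = 5), dagless)
  expect_equal(unname(pr$abundance[c("GO:0000001", "GO:0000002")]),
               c(5, 5))
  pr2 <- functionalProfile(c(g1 = 2, g2 = 3, g3 = 0), dagless)
  expect_equal(unname(pr2$abundance["GO:0000002"]), 5)
  expect_false("GO:0000003" %in% names(pr2$abundance))
  expect_error(functionalProfile(c(g1 = -1), dagless), "non-negative")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeProfile(pr2, f)
  back <- readProfile(f)
  expect_equal(back$abundance, pr2$abundance)
})

test_that("profile comparison: rho extremes, union-of-keys restriction, oracle agreement, symmetry", {
  mk <- function(x) structure(list(abundance = x, sample = "s"),
                              class = "functionalProfile")
  a <- mk(setNames(c(1, 2, 3, 4), paste0("GO:000000", 1:4)))
  expect_equal(compareProfiles(a, a)$rho, 1)
  rev_ <- mk(setNames(c(4, 3, 2, 1), paste0("GO:000000", 1:4)))
  expect_equal(compareProfiles(a, rev_)$rho, -1)
  # disjoint supports: the union has all keys, zeros filled in
  b <- mk(setNames(c(5, 6), c("GO:0000005", "GO:0000006")))
  cmp <- compareProfiles(a, b)
  expect_equal(cmp$n, 6L)
  expect_true(cmp$rho < 0)  # a's support ranks low in b and vice versa
  # constant vector: undefined marker
  const <- mk(setNames(c(1, 1, 1, 1), names(a$abundance)))
  expect_true(is.na(compareProfiles(a, const)$rho))
  expect_error(compareProfiles(mk(c("GO:0000001" = 1)),
                               mk(c("GO:0000002" = 2))), "at least 3")
  # oracle: rank-then-Pearson, with ties, within 1e-12; symmetric
  set.seed(403)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    keys <- sprintf("GO:%07d", sample(1000, n))
    x <- mk(setNames(sample(0:10, n, replace = TRUE) + runif(n) * 0.01,
                     keys))
    y <- mk(setNames(sample(0:10, n, replace = TRUE), keys))
    got <- compareProfiles(x, y)
    xv <- x$abundance[keys]; yv <- y$abundance[keys]
    if (length(unique(yv)) == 1) next
    expect_equal(got$rho, cor(rank(xv), rank(yv)), tolerance = 1e-12)
    expect_equal(compareProfiles(y, x)$rho, got$rho)
  }
  # exact permutation p-value is available for tiny profiles
  small <- mk(setNames(c(3, 1, 2, 5, 4), sprintf("GO:%07d", 1:5)))
  small2 <- mk(setNames(c(2, 1, 3, 5, 4), sprintf("GO:%07d", 1:5)))
  pp <- compareProfiles(small, small2, p_method = "permutation")
  expect_true(pp$p_value > 0 && pp$p_value <= 1)
})
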