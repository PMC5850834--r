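# Built-in aligner, seed search modes, filters, and external-format
# parsers.

test_that("alignScore matches hand computation on self-alignment and is symmetric", {
  set.seed(201)
  s <- orcRandomSeq(50)
  got <- alignScore(s, s)
  mat <- orcBlosum62()
  aa <- strsplit(s, "")[[1]]
  raw <- sum(vapply(aa, function(x) mat[x, x], numeric(1)))
  expect_equal(got$raw, raw)
  expect_equal(got$bitscore, (0.267 * raw - log(0.041)) / log(2))
  expect_equal(got$evalue, 50 * 50 * 2^(-got$bitscore))
  a <- orcRandomSeq(30); b <- orcRandomSeq(40)
  expect_equal(alignScore(a, b)$raw, alignScore(b, a)$raw)
  expect_error(alignScore("", a), "empty")
  expect_error(alignScore("MK*L", a), "invalid")
})

test_that("raw local-alignment scores equal an independent DP oracle on short random pairs", {
  set.seed(202)
  for (rep in 1:15) {
    a <- orcRandomSeq(sample(5:30, 1))
    b <- if (rep %% 3 == 0) orcMutate(a, 0.3) else orcRandomSeq(sample(5:30, 1))
    expect_equal(alignScore(a, b)$raw, orcSmithWaterman(a, b))
  }
})

test_that("filters implement thresholds, subtree exclusion and self-exclusion, monotonically", {
  tax <- orcTinyTaxonomy()
  hits <- data.frame(
    query_id = "q",
    target_id = c("4.a", "5.b", "6.c", "7.d", "q"),
    bitscore = c(100, 50, 30, 25, 99),
    evalue = c(1e-20, 1e-6, 0.01, 1e-4, 1e-30))
  # loose filters are the identity
  loose <- searchFilters(max_evalue = 1, min_bitscore = 0)
  expect_equal(applyFilters(hits, loose, tax), hits, ignore_attr = TRUE)
  # the 0.001 operating cutoff removes the 0.01 hit
  f <- applyFilters(hits, searchFilters(max_evalue = 0.001,
                                        min_bitscore = 0), tax)
  expect_false("6.c" %in% f$target_id)
  # excluding an ancestral clade removes all species beneath it
  f2 <- applyFilters(hits, searchFilters(max_evalue = 1, min_bitscore = 0,
                                         excluded_taxa = 2L), tax)
  expect_setequal(f2$target_id, c("6.c", "7.d", "q"))
  # oracle: survivors' lineages avoid the excluded clade
  kept_tax <- orcSpecies(setdiff(f2$target_id, "q"))
  expect_false(any(vapply(kept_tax, function(t)
    2L %in% orcLineage(tax, t), logical(1))))
  # self-hit exclusion
  f3 <- applyFilters(hits, searchFilters(max_evalue = 1, min_bitscore = 0,
                                         exclude_self = TRUE), tax)
  expect_false("q" %in% f3$target_id)
  # monotone: stricter thresholds never add hits
  for (ev in c(1, 1e-3, 1e-10)) {
    a <- applyFilters(hits, searchFilters(max_evalue = ev,
                                          min_bitscore = 0), tax)
    b <- applyFilters(hits, searchFilters(max_evalue = ev / 100,
                                          min_bitscore = 0), tax)
    expect_true(all(b$target_id %in% a$target_id))
  }
})

test_that("direct search recovers the mutated source protein as seed on a simulated db", {
  cfg <- simConfig(n_species = 10, n_families = 10, seed = 41)
  b <- simulateDatabase(cfg)
  seqs <- dbSequences(b$db)
  set.seed(42)
  picks <- sample(names(seqs), 8)
  queries <- Biostrings::AAStringSet(setNames(
    vapply(picks, function(p) orcMutate(as.character(seqs[[p]]), 0.10),
           character(1)),
    paste0("q_", picks)))
  res <- searchDirect(queries, b$db)
  expect_equal(res$protein_id, picks, ignore_attr = TRUE)
  # invariant to query order and to database row order
  res2 <- searchDirect(queries[sample(length(queries))], b$db)
  expect_equal(res2$protein_id[match(res$query_id, res2$query_id)],
               res$protein_id)
  perm <- sample(nrow(dbProteins(b$db)))
  db2 <- newOrthologDb(dbTaxonomy(b$db), dbProteins(b$db)[perm, ],
                       dbSequences(b$db)[perm], b$db@ogTable,
                       b$db@trees, b$db@go, b$db@kegg, b$db@cog)
  res3 <- searchDirect(queries, db2)
  expect_equal(res3$protein_id, res$protein_id)
  # a query with nothing in common and a strict cutoff maps to nothing
  junk <- Biostrings::AAStringSet(c(junk = strrep("W", 15)))
  resj <- searchDirect(junk, b$db,
                       searchFilters(max_evalue = 1e-30))
  expect_true(is.na(resj$protein_id))
  expect_equal(resj$reason, "no_hit_passed_filters")
  # invalid residues: warning, query skipped, run continues
  mixed <- Biostrings::AAStringSet(c(good = as.character(seqs[[1]]),
                                     bad = "MKLJJJ"))
  expect_warning(resm <- searchDirect(mixed, b$db), "invalid")
  expect_equal(resm$query_id, "good")
})

test_that("coarse-then-fine picks the right group and agrees with direct mode on singleton OGs", {
  # two disjoint-sequence OGs; query copies a member of OG1
  tax <- orcTinyTaxonomy()
  seqs <- Biostrings::AAStringSet(c(
    "4.a" = strrep("MKLVHE", 20), "5.a" = strrep("MKLVHD", 20),
    "6.b" = strrep("WCPGYR", 20), "7.b" = strrep("WCPGYN", 20)))
  prot <- data.frame(protein_id = names(seqs),
                     taxid = orcSpecies(names(seqs)),
                     gene_name = NA_character_)
  og <- data.frame(og_id = c("OG1", "OG1", "OG2", "OG2"),
                   clade = 1L,
                   protein_id = names(seqs))
  db <- newOrthologDb(tax, prot, seqs, og,
                      list(OG1 = "(4.a,5.a);", OG2 = "(6.b,7.b);"))
  q <- Biostrings::AAStringSet(c(q1 = as.character(seqs[["5.a"]])))
  res <- searchCoarse(q, db)
  expect_equal(res$og_id, "OG1")
  expect_equal(res$protein_id, "5.a")
  # when every protein is its own OG the two modes coincide
  og1 <- data.frame(og_id = paste0("S", seq_along(seqs)), clade = 1L,
                    protein_id = names(seqs))
  db1 <- newOrthologDb(tax, prot, seqs, og1, list())
  qs <- Biostrings::AAStringSet(c(q1 = as.character(seqs[["5.a"]]),
                                  q2 = as.character(seqs[["6.b"]])))
  d <- searchDirect(qs, db1)
  cf <- searchCoarse(qs, db1)
  expect_equal(cf$protein_id, d$protein_id)
  expect_equal(cf$bitscore, d$bitscore)
})

test_that("external-format parsers round-trip fixtures and flag malformed rows", {
  # blast/diamond tabular format 6
  f6 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("q1", "5.a", "98.5", "100", "2", "0", "1", "100", "1", "100",
            "1e-50", "200"), collapse = "\t"),
    paste(c("q1", "6.b", "40.0", "90", "50", "3", "5", "90", "2", "88",
            "0.01", "35"), collapse = "\t")), f6)
  hits <- parseTabular6(f6)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$evalue, c(1e-50, 0.01))
  expect_equal(hits$bitscore, c(200, 35))
  expect_equal(hits$qstart, c(1L, 5L))
  writeLines("q1\tonly\tthree", f6)
  expect_error(parseTabular6(f6), "line 1")
  writeLines(character(0), f6)
  expect_equal(nrow(parseTabular6(f6)), 0L)

  # hmmer domtblout: three domains for one query; best-per-target keeps
  # the minimum-evalue domain
  fd <- withr::local_tempfile(fileext = ".domtblout")
  dom <- function(target, ieval, score, from, to)
    paste(c(target, "-", "300", "q1", "-", "250", "1e-40", "120", "0.1",
            "1", "3", "1e-10", ieval, score, "0.1", "5", "80", from, to,
            "1", "90", "0.95", "desc here"), collapse = " ")
  writeLines(c("# comment line",
               dom("5.a", "1e-20", "75.0", "10", "90"),
               dom("5.a", "1e-30", "95.0", "100", "200"),
               dom("5.a", "1e-5", "30.0", "210", "240")), fd)
  dh <- parseDomtblout(fd)
  expect_equal(nrow(dh), 3L)
  best <- collapseHits(dh)
  expect_equal(nrow(best), 1L)
  expect_equal(best$evalue, 1e-30)
  expect_equal(best$qstart, 100L)
  writeLines("too few fields", fd)
  expect_error(parseDomtblout(fd), "line 1")
})

test_that("seedsFromHits applies the same filters and tie-breaks as the built-in search", {
  cfg <- simConfig(n_species = 6, n_families = 3, seed = 43)
  b <- simulateDatabase(cfg)
  prot <- dbProteins(b$db)$protein_id
  hits <- data.frame(query_id = "q1",
                     target_id = prot[1:4],
                     bitscore = c(50, 80, 80, 20),
                     evalue = c(1e-6, 1e-9, 1e-9, 1e-3),
                     qstart = 1L, qend = 50L)
  seeds <- seedsFromHits(hits, b$db)
  # equal bitscore and evalue: lexicographically smallest protein id
  expect_equal(seeds$protein_id, sort(prot[2:3])[1])
  # order invariance
  seeds2 <- seedsFromHits(hits[sample(nrow(hits)), ], b$db)
  expect_equal(seeds2$protein_id, seeds$protein_id)
})
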