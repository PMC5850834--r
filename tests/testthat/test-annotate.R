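# Scope resolution, ortholog selection, functional transfer and the
# composed per-query annotation.

annotFixture <- function() {
  tax <- orcTinyTaxonomy()
  ids <- c("4.a1", "5.b1", "5.b2", "6.c1", "7.d1")
  prot <- data.frame(protein_id = ids, taxid = orcSpecies(ids),
                     gene_name = c("trpB", "TRPB2", "trpB", "abcA", NA))
  base <- strrep("MKLVHEQWRA", 12)
  set.seed(77)
  seqs <- Biostrings::AAStringSet(setNames(
    c(base, orcMutate(base, 0.05), orcMutate(base, 0.15),
      orcMutate(base, 0.25), orcMutate(base, 0.3)), ids))
  og <- data.frame(
    og_id = c(rep("R1", 5), rep("A1", 3)),
    clade = c(rep(1L, 5), rep(2L, 3)),
    protein_id = c(ids, "4.a1", "5.b1", "5.b2"))
  trees <- list(
    R1 = "(((4.a1,(5.b1,5.b2)),6.c1),7.d1);",
    A1 = "(4.a1,(5.b1,5.b2));")
  go <- data.frame(
    protein_id = c("5.b1", "5.b1", "5.b2", "6.c1", "7.d1"),
    term = c("GO:0000003", "GO:0000004", "GO:0000003", "GO:0000004",
             "GO:0000002"),
    evidence = c("IDA", "IEA", "TAS", "EXP", "IEA"))
  kegg <- data.frame(protein_id = c("5.b1", "5.b2", "6.c1"),
                     pathway = c("map00010", "map00010", "map00020"))
  cog <- data.frame(og_id = c("R1", "A1"), category = c("EG", "E"))
  db <- newOrthologDb(tax, prot, seqs, og, trees, go, kegg, cog)
  dag <- newGoDag(sprintf("GO:%07d", 1:4),
                  parents = list("GO:0000002" = "GO:0000001",
                                 "GO:0000003" = "GO:0000002",
                                 "GO:0000004" = "GO:0000001"))
  list(db = db, dag = dag)
}

test_that("scope resolution picks the narrowest qualifying level and falls back to root", {
  fx <- annotFixture()
  # 4.a1 is in an OG at clade 2 (its lineage) and at root
  sc <- resolveScope("4.a1", fx$db, scopeSetting("auto"))
  expect_equal(sc$clade, 2L)
  expect_equal(sc$og_id, "A1")
  # 6.c1 only has the root-level OG
  sc2 <- resolveScope("6.c1", fx$db, scopeSetting("auto"))
  expect_equal(sc2$clade, 1L)
  expect_equal(sc2$og_id, "R1")
  # fixed scope pins the level regardless
  sc3 <- resolveScope("4.a1", fx$db, scopeSetting("fixed", 1L))
  expect_equal(sc3$clade, 1L)
  expect_equal(sc3$og_id, "R1")
  expect_error(resolveScope("4.a1", fx$db, scopeSetting("fixed", 3L)),
               "not a clade level")
  # on a simulated db the chosen level equals an independent lineage scan
  cfg <- simConfig(n_species = 12, n_families = 6, seed = 51)
  b <- simulateDatabase(cfg)
  for (p in sample(dbProteins(b$db)$protein_id, 15)) {
    got <- resolveScope(p, b$db, scopeSetting("auto"))
    exp_ <- orcExpectedScope(p, b)
    expect_equal(got$clade, exp_$clade)
    expect_equal(got$og_id, exp_$og_id)
  }
})

test_that("ortholog selection honours scope subtrees, exclusions and the one2one restriction", {
  fx <- annotFixture()
  tree <- ogGeneTree(fx$db, "R1")
  oa <- inferOrthologs(tree, labelEvents(tree), "4.a1")
  pol <- transferPolicy(go_evidence = "all")
  # scope root, no exclusions: identity on the assignment
  all_ <- selectOrthologs(oa, 1L, pol, dbTaxonomy(fx$db))
  expect_equal(all_, oa$orthologs, ignore_attr = TRUE)
  # scope clade 2 keeps only species 4/5
  inA <- selectOrthologs(oa, 2L, pol, dbTaxonomy(fx$db))
  expect_true(all(orcSpecies(inA$protein_id) %in% c(4L, 5L)))
  # excluding clade 3 removes species 6 and 7
  polx <- transferPolicy(go_evidence = "all", excluded_taxa = 3L)
  ex <- selectOrthologs(oa, 1L, polx, dbTaxonomy(fx$db))
  expect_false(any(orcSpecies(ex$protein_id) %in% c(6L, 7L)))
  # one2one on a set with only one-to-many partners is empty
  pol1 <- transferPolicy(target_orthologs = "one2one", go_evidence = "all")
  one <- selectOrthologs(oa, 1L, pol1, dbTaxonomy(fx$db))
  expect_true(all(one$relation == "one2one"))
  oa5 <- inferOrthologs(tree, labelEvents(tree), "5.b1")
  # from 5.b1, the partner 4.a1 is many2one (two copies in species 5)
  m2o <- oa5$orthologs[oa5$orthologs$protein_id == "4.a1", ]
  expect_equal(m2o$relation, "many2one")
  only_m <- structure(list(seed = "x", orthologs = data.frame(
    protein_id = c("6.c1", "7.d1"),
    relation = c("many2many", "many2many")), inparalogs = character(0)),
    class = "orthologAssignment")
  expect_equal(nrow(selectOrthologs(only_m, 1L, pol1, dbTaxonomy(fx$db))), 0L)
})

test_that("GO transfer filters evidence classes, unions donors and propagates ancestors", {
  fx <- annotFixture()
  # an IEA-only donor yields nothing under experimental, closure under all
  expect_equal(transferGo("7.d1", fx$db, fx$dag, "experimental"),
               character(0))
  expect_equal(transferGo("7.d1", fx$db, fx$dag, "all"),
               c("GO:0000001", "GO:0000002"))
  # TAS passes non_electronic but not experimental
  expect_equal(transferGo("5.b2", fx$db, fx$dag, "experimental"),
               character(0))
  expect_equal(transferGo("5.b2", fx$db, fx$dag, "non_electronic"),
               sprintf("GO:%07d", 1:3))
  # union over donors equals closure of union (set-algebra oracle)
  got <- transferGo(c("5.b1", "6.c1"), fx$db, fx$dag, "all")
  expect_equal(got, orcClosure(fx$dag, c("GO:0000003", "GO:0000004")))
  # evidence-class nesting
  for (d in list("5.b1", c("5.b1", "5.b2", "6.c1", "7.d1"))) {
    e <- transferGo(d, fx$db, fx$dag, "experimental")
    n <- transferGo(d, fx$db, fx$dag, "non_electronic")
    a <- transferGo(d, fx$db, fx$dag, "all")
    expect_true(all(e %in% n) && all(n %in% a))
  }
  expect_equal(transferGo(character(0), fx$db, fx$dag, "all"),
               character(0))
  # unknown terms are dropped with a warning
  db2 <- fx$db
  db2@go$term[1] <- "GO:0099999"
  expect_warning(out <- transferGo("5.b1", db2, fx$dag, "all"), "unknown")
  expect_false("GO:0099999" %in% out)
})

test_that("KEGG union, verbatim COG and gene-name prediction rules", {
  fx <- annotFixture()
  expect_equal(transferKegg(c("5.b1", "5.b2", "6.c1"), fx$db),
               c("map00010", "map00020"))
  expect_equal(transferKegg("7.d1", fx$db), character(0))
  expect_equal(transferCog("R1", fx$db), "EG")
  expect_equal(transferCog(NA_character_, fx$db), "")
  # {"trpB", "TRPB2"} normalise to the same name
  expect_equal(predictGeneName(c("4.a1", "5.b1"), fx$db), "TRPB")
  # majority wins
  expect_equal(predictGeneName(c("4.a1", "5.b2", "6.c1"), fx$db), "TRPB")
  expect_equal(predictGeneName("7.d1", fx$db), NA_character_)
  expect_equal(predictGeneName(character(0), fx$db), NA_character_)
  # tie-break: the donor taxonomically closest to the seed
  expect_equal(predictGeneName(c("5.b1", "6.c1"), fx$db, seed = "4.a1"),
               "TRPB")
  expect_equal(predictGeneName(c("5.b1", "6.c1"), fx$db, seed = "7.d1"),
               "ABCA")
})

test_that("composed annotation: status logic, scope restriction, and policy containment", {
  fx <- annotFixture()
  q <- Biostrings::AAStringSet(c(
    qa = as.character(dbSequences(fx$db)[["4.a1"]])))
  polAll <- transferPolicy(go_evidence = "all")
  res <- annotateQueries(q, fx$db, fx$dag, policy = polAll,
                         mode = "direct", exclude_self = FALSE)
  r <- res[[1]]
  expect_equal(r$seed$protein_id, "4.a1")
  expect_equal(r$scope_clade, 2L)       # auto scope at the narrow level
  expect_equal(r$status, "annotated")
  expect_true(all(orcSpecies(r$orthologs_used$protein_id) %in% c(4L, 5L)))
  # one2one GO is contained in all-orthologs GO
  pol1 <- transferPolicy(target_orthologs = "one2one", go_evidence = "all")
  res1 <- annotateQueries(q, fx$db, fx$dag, policy = pol1, mode = "direct")
  expect_true(all(res1[[1]]$go_terms %in% r$go_terms))
  # a query unrelated to everything is unmapped
  junk <- Biostrings::AAStringSet(c(junk = strrep("W", 20)))
  resj <- annotateQueries(junk, fx$db, fx$dag, policy = polAll,
                          mode = "direct")
  expect_equal(resj[[1]]$status, "unmapped")
  expect_length(resj[[1]]$go_terms, 0)
  # output table and TSV writer
  tab <- annotationTable(c(res, resj))
  expect_equal(tab$status, c("annotated", "unmapped"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotations(c(res, resj), f)
  lines <- readLines(f)
  expect_match(lines[1], "^#query\t")
  expect_length(lines, 3)
})
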