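test_that("reaction selection follows the strict GPR policy", {
  u <- makeUniverse(
    ids = c("R1", "R2", "R3"),
    gprs = c("a or b", "a and b", NA),
    stoich = list(c(x_c = -1, y_c = 1), c(x_c = -1, z_c = 1),
                  c(y_c = -1, z_c = 1)))
  orth <- list(a = "qa")
  sel <- selectReactions(u, orth, gprPolicy(strict = TRUE))
  expect_identical(sel$id, "R1")
  expect_identical(sel$assembledGpr, "qa")
  expect_identical(sel$gprStatus, "complete")

  ## non-strict admits the incomplete complex, flagged partial
  sel <- selectReactions(u, orth, gprPolicy(strict = FALSE))
  expect_identical(sel$id, c("R1", "R2"))
  expect_identical(sel$gprStatus, c("complete", "partial"))

  ## no-GPR reactions only pass when re-admitted
  sel <- selectReactions(u, orth, gprPolicy(allowNoGpr = TRUE))
  expect_true("R3" %in% sel$id)
  expect_identical(sel$gprStatus[sel$id == "R3"], "no_gpr")
})

test_that("selection equals per-reaction truth-table evaluation on random universes", {
  set.seed(77)
  genes <- paste0("t", 1:8)
  mapped <- sample(genes, 4)
  orth <- stats::setNames(as.list(paste0("q_", mapped)), mapped)
  rules <- replicate(100, randomRule(genes, depth = 3L), simplify = FALSE)
  u <- makeUniverse(
    ids = sprintf("R%03d", 1:100),
    gprs = vapply(rules, renderGpr, character(1)),
    stoich = lapply(1:100, function(i) {
      stats::setNames(c(-1, 1), sprintf(c("in%03d_c", "out%03d_c"), i))
    }))
  sel <- selectReactions(u, orth, gprPolicy(strict = TRUE))
  oracle <- u$id[vapply(rules, function(r) ttEval(r, mapped), logical(1))]
  expect_setequal(sel$id, oracle)
})

test_that("canonical keys collapse reversed and proton-shifted variants only", {
  fwd <- c(A_c = -1, B_c = -1, C_c = 1)
  rev <- c(C_c = -1, A_c = 1, B_c = 1)
  expect_identical(canonicalKey(fwd)$key, canonicalKey(rev)$key)
  expect_true(xor(canonicalKey(fwd)$flipped, canonicalKey(rev)$flipped))

  withH <- c(A_c = -1, h_c = -1, B_c = 1)
  noH <- c(A_c = -1, B_c = 1)
  expect_identical(canonicalKey(withH)$key, canonicalKey(noH)$key)

  cyt <- c(A_c = -1, B_c = 1)
  peri <- c(A_p = -1, B_p = 1)
  expect_false(canonicalKey(cyt)$key == canonicalKey(peri)$key)
  ## opt-in collapse across a consistent compartment relabelling
  expect_identical(canonicalKey(cyt, collapseCompartments = TRUE)$key,
                   canonicalKey(peri, collapseCompartments = TRUE)$key)

  expect_error(canonicalKey(c(h_c = -1, h_p = 1)), "degenerate")
  ## different coefficients are different reactions
  expect_false(canonicalKey(c(A_c = -1, B_c = 1))$key ==
                 canonicalKey(c(A_c = -2, B_c = 1))$key)
})

test_that("deduplication merges GPRs by OR and unions provenance", {
  u <- makeUniverse(
    ids = c("R1", "R1"),
    gprs = c("a", "a"),
    stoich = list(c(x_c = -1, y_c = 1), c(x_c = -1, y_c = 1)),
    source = c("tmplA", "tmplB"))
  u$assembledGpr <- c("q1", "q1"); u$gprStatus <- "complete"
  d <- deduplicateReactions(u)
  expect_identical(nrow(d), 1L)
  expect_setequal(d$sources[[1]], c("tmplA", "tmplB"))

  ## proton variant pair: merged GPR is the disjunction of the inputs
  u <- makeUniverse(
    ids = c("Ra", "Rb"),
    gprs = c("a", "b"),
    stoich = list(c(x_c = -1, y_c = 1), c(x_c = -1, h_c = -1, y_c = 1)))
  u$assembledGpr <- c("q1", "q2"); u$gprStatus <- "complete"
  d <- deduplicateReactions(u)
  expect_identical(nrow(d), 1L)
  expect_identical(d$id, "Ra")  # smallest reaction id wins
  merged <- parseGpr(d$assembledGpr)
  for (s in allAssignments(c("q1", "q2"))) {
    expect_identical(evaluateRule(merged, s),
                     ("q1" %in% s) || ("q2" %in% s))
  }

  ## opposite irreversible directions make the representative reversible
  u <- makeUniverse(
    ids = c("Rf", "Rr"), gprs = c("a", "a"),
    stoich = list(c(x_c = -1, y_c = 1), c(y_c = -1, x_c = 1)))
  u$assembledGpr <- "q1"; u$gprStatus <- "complete"
  d <- deduplicateReactions(u)
  expect_identical(nrow(d), 1L)
  expect_true(d$reversible)
})

test_that("deduplication removes exactly the planted duplicate groups", {
  fx <- generateFixture(fixtureSpec(seed = 19, duplicateGroups = 5,
                                    duplicateTypes = c("reversibility",
                                                       "protonation")))
  orth <- stats::setNames(as.list(fx$truth$orthologPairs$query),
                          fx$truth$orthologPairs$template)
  u <- poolReactions(fx$templates)
  sel <- selectReactions(u, orth, gprPolicy(strict = TRUE))
  d <- deduplicateReactions(sel)
  expect_identical(nrow(d), nrow(sel) - fx$truth$expectedMerges)
  expect_setequal(d$id, fx$truth$expectedDraft)

  ## idempotence
  d2 <- deduplicateReactions(d)
  expect_identical(d2$id, d$id)
  expect_identical(d2$assembledGpr, d$assembledGpr)

  ## integrating the same template twice equals integrating it once
  selTwice <- selectReactions(rbind(u, u), orth, gprPolicy(strict = TRUE))
  dTwice <- deduplicateReactions(selTwice)
  expect_setequal(dTwice$id, d$id)
})

test_that("compartment copies survive deduplication by default", {
  fx <- generateFixture(fixtureSpec(seed = 29, duplicateGroups = 2,
                                    duplicateTypes = "compartment"))
  orth <- stats::setNames(as.list(fx$truth$orthologPairs$query),
                          fx$truth$orthologPairs$template)
  sel <- selectReactions(poolReactions(fx$templates), orth, gprPolicy())
  d <- deduplicateReactions(sel)
  expect_identical(fx$truth$expectedMerges, 0L)
  expect_identical(nrow(d), nrow(sel))
})

test_that("self-recovery: one template against its own proteins rebuilds it", {
  fx <- generateFixture(fixtureSpec(seed = 41, nTemplates = 1,
                                    orthologIdentity = 1,
                                    duplicateGroups = 0))
  tm <- fx$templates[[1]]
  draft <- buildDraft(list(tm), fx$queryProteome, engine = exactMatchEngine)
  expect_setequal(reactions(draft)$id, reactions(tm)$id)
  score <- assessDraft(draft,
                       reactions(tm)[reactions(tm)$id %in%
                                       reactions(draft)$id, ])
  expect_identical(score$precision, 1)
  expect_identical(score$recall, 1)
  expect_identical(score$f1, 1)
})

test_that("draft GPRs reference only query-proteome gene ids", {
  fx <- generateFixture(fixtureSpec(seed = 51))
  draft <- buildDraft(fx$templates, fx$queryProteome,
                      engine = exactMatchEngine)
  genes <- unique(unlist(lapply(reactions(draft)$gpr, function(g) {
    if (is.na(g)) character(0) else ruleGenes(parseGpr(g))
  })))
  expect_true(all(genes %in% names(fx$queryProteome)))
  ## referential integrity of the draft object itself
  expect_true(validObject(draft))
})

test_that("adding a template never removes reactions under the strict policy", {
  fx <- generateFixture(fixtureSpec(seed = 61, nTemplates = 3,
                                    duplicateGroups = 0))
  d2 <- buildDraft(fx$templates[1:2], fx$queryProteome,
                   engine = exactMatchEngine)
  d3 <- buildDraft(fx$templates, fx$queryProteome,
                   engine = exactMatchEngine)
  expect_true(all(reactions(d2)$id %in% reactions(d3)$id))
})

test_that("two disjoint single-reaction templates give a two-reaction draft", {
  mkTmpl <- function(id, gene, seq, rid) {
    rxn <- makeUniverse(rid, gene,
                        list(stats::setNames(c(-1, 1),
                                             paste0(c("in", "out"), rid, "_c"))),
                        source = id)
    TemplateModel(
      modelId = id, organism = id,
      genes = data.frame(id = gene, sequence = seq, stringsAsFactors = FALSE),
      metabolites = gemdraft:::.metaboliteTable(
        sort(names(rxn$stoichiometry[[1]]))),
      reactions = rxn)
  }
  s1 <- paste(rep("ACDEFGHIKL", 8), collapse = "")
  s2 <- paste(rep("MNPQRSTVWY", 8), collapse = "")
  t1 <- mkTmpl("tA", "gA", s1, "RA")
  t2 <- mkTmpl("tB", "gB", s2, "RB")
  query <- c(qA = s1, qB = s2)
  draft <- buildDraft(list(t1, t2), query, engine = exactMatchEngine)
  expect_setequal(reactions(draft)$id, c("RA", "RB"))
})

test_that("random template mode is reproducible under a fixed seed", {
  fx <- generateFixture(fixtureSpec(seed = 71, nTemplates = 5,
                                    duplicateGroups = 0))
  d1 <- buildDraft(fx$templates, fx$queryProteome, engine = exactMatchEngine,
                   mode = "random", k = 3, seed = 123)
  d2 <- buildDraft(fx$templates, fx$queryProteome, engine = exactMatchEngine,
                   mode = "random", k = 3, seed = 123)
  expect_identical(reactions(d1)$id, reactions(d2)$id)
  expect_identical(runInfo(d1)$templates, runInfo(d2)$templates)
  expect_identical(runInfo(d1)$seed, 123)
})

test_that("selected mode needs annotations and picks the closest templates", {
  fx <- generateFixture(fixtureSpec(seed = 81, nTemplates = 5,
                                    duplicateGroups = 0))
  expect_error(buildDraft(fx$templates, fx$queryProteome,
                          engine = exactMatchEngine, mode = "selected"),
               "requires COG annotations")
  draft <- buildDraft(fx$templates, fx$queryProteome,
                      engine = exactMatchEngine, mode = "selected", k = 3,
                      annotations = fx$annotations,
                      targetOrganism = fx$targetOrganism)
  chosenOrgs <- vapply(fx$templates[runInfo(draft)$templates], organism,
                       character(1))
  expect_setequal(unname(chosenOrgs),
                  fx$truth$expectedClosestOrder[1:3])
})
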