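test_that("a minimal one-reaction JSON model loads", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "id": "mini",
    "metabolites": [{"id": "a_c", "compartment": "c"}],
    "reactions": [{"id": "R1", "metabolites": {"a_c": -1},
                   "lower_bound": 0, "upper_bound": 1000,
                   "gene_reaction_rule": "g1"}],
    "genes": [{"id": "g1"}]
  }', path)
  m <- readTemplateJson(path)
  expect_s4_class(m, "TemplateModel")
  expect_identical(nrow(reactions(m)), 1L)
  expect_identical(nrow(modelGenes(m)), 1L)
  expect_identical(reactions(m)$gpr, "g1")
  expect_identical(metabolites(m)$baseId, "a")
})

test_that("reactions citing undeclared metabolites are an integrity error", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "id": "bad",
    "metabolites": [{"id": "a_c"}],
    "reactions": [{"id": "R1", "metabolites": {"a_c": -1, "ghost_c": 1},
                   "gene_reaction_rule": "g1"}],
    "genes": [{"id": "g1"}]
  }', path)
  expect_error(readTemplateJson(path), "integrity")
  writeLines('{"metabolites": []}', path)
  expect_error(readTemplateJson(path), "missing key")
  writeLines('{"metabolites": [', path)
  expect_error(readTemplateJson(path), "malformed JSON")
})

test_that("fixture templates round-trip through JSON field for field", {
  fx <- generateFixture(fixtureSpec(seed = 3, nTemplates = 1,
                                    reactionsPerTemplate = 25,
                                    genesPerTemplate = 18))
  tm <- fx$templates[[1]]
  path <- withr::local_tempfile(fileext = ".json")
  writeTemplateJson(tm, path)
  back <- readTemplateJson(path)
  expect_identical(modelId(back), modelId(tm))
  expect_identical(modelGenes(back), modelGenes(tm))
  expect_identical(metabolites(back)$id, metabolites(tm)$id)
  expect_identical(reactions(back)$id, reactions(tm)$id)
  expect_identical(reactions(back)$gpr, reactions(tm)$gpr)
  expect_identical(reactions(back)$reversible, reactions(tm)$reversible)
  for (i in seq_len(nrow(reactions(tm)))) {
    a <- reactions(tm)$stoichiometry[[i]]
    b <- reactions(back)$stoichiometry[[i]]
    expect_identical(sort(names(a)), sort(names(b)))
    expect_identical(unname(a[sort(names(a))]), unname(b[sort(names(a))]))
  }
  ## determinism: reading the same file twice gives identical models
  expect_identical(readTemplateJson(path), back)
})

test_that("SBML write/read round-trips stoichiometry and GPR truth tables", {
  fx <- generateFixture(fixtureSpec(seed = 5))
  draft <- buildDraft(fx$templates, fx$queryProteome,
                      engine = exactMatchEngine)
  path <- withr::local_tempfile(fileext = ".xml")
  writeDraftSbml(draft, path)
  back <- readTemplateSbml(path)
  d <- reactions(draft); b <- reactions(back)
  expect_setequal(b$id, d$id)
  idx <- match(d$id, b$id)
  expect_identical(b$reversible[idx], d$reversible)
  for (i in seq_len(nrow(d))) {
    s1 <- d$stoichiometry[[i]]
    s2 <- b$stoichiometry[[idx[i]]]
    expect_identical(sort(names(s1)), sort(names(s2)))
    expect_identical(unname(s1[sort(names(s1))]), unname(s2[sort(names(s1))]))
    r1 <- parseGpr(d$gpr[i]); r2 <- parseGpr(b$gpr[idx[i]])
    if (is.null(r1)) {
      expect_null(r2)
    } else {
      for (s in allAssignments(ruleGenes(r1))) {
        expect_identical(evaluateRule(r2, s), evaluateRule(r1, s))
      }
    }
  }
})

test_that("SBML species follow the base-id/compartment suffix convention", {
  m <- tinyModel()
  path <- withr::local_tempfile(fileext = ".xml")
  writeModelSbml(m, path)
  suppressWarnings(back <- readTemplateSbml(path))
  met <- metabolites(back)
  expect_identical(met$baseId[met$id == "glc__D_c"], "glc__D")
  expect_identical(met$compartment[met$id == "glc__D_c"], "c")
  ## fbc:and / fbc:or reconstruct the same Boolean structure
  gpr <- reactions(back)$gpr[reactions(back)$id == "HEX1"]
  r <- parseGpr(gpr)
  for (s in allAssignments(c("g1", "g2", "g3"))) {
    expect_identical(evaluateRule(r, s),
                     evaluateRule(parseGpr("(g1 and g2) or g3"), s))
  }
})

test_that("SBML reactions without gene associations load with a warning", {
  m <- tinyModel()
  path <- withr::local_tempfile(fileext = ".xml")
  writeModelSbml(m, path)
  expect_warning(back <- readTemplateSbml(path), "without FBC gene")
  expect_true(is.na(reactions(back)$gpr[reactions(back)$id == "EX_glc__D_c"]))
})

test_that("an empty draft serializes to a valid zero-reaction document", {
  draft <- new("DraftNetwork", modelId = "empty")
  path <- withr::local_tempfile(fileext = ".xml")
  writeDraftSbml(draft, path)
  suppressWarnings(back <- readTemplateSbml(path))
  expect_identical(nrow(reactions(back)), 0L)
})

test_that("written drafts pass an independent SBML validator", {
  fx <- generateFixture(fixtureSpec(seed = 45, reactionsPerTemplate = 15))
  draft <- buildDraft(fx$templates, fx$queryProteome,
                      engine = exactMatchEngine)
  expect_gt(nrow(reactions(draft)), 30)
  path <- withr::local_tempfile(fileext = ".xml")
  writeDraftSbml(draft, path)
  out <- system2("python", c("-c", shQuote(paste0(
    "import libsbml; d = libsbml.readSBML('", path, "'); ",
    "print(d.getNumErrors(libsbml.LIBSBML_SEV_ERROR))"))),
    stdout = TRUE, stderr = FALSE)
  expect_identical(tail(out, 1), "0")
})

test_that("proteome FASTA reading takes ids from the first header token", {
  path <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1 some description", "MKT", ">g2", "MDN"), path)
  seqs <- readProteomeFasta(path)
  expect_identical(names(seqs), c("g1", "g2"))
  expect_identical(as.character(seqs[["g1"]]), "MKT")

  writeLines(c(">g1", "MKT", ">g1", "MDN"), path)
  expect_error(readProteomeFasta(path), "duplicate.*g1")
  writeLines(character(0), path)
  expect_error(readProteomeFasta(path), "empty")
})

test_that("fixture proteome matches the generator's record", {
  fx <- generateFixture(fixtureSpec(seed = 21, decoyQueryGenes = 0),
                        dir = withr::local_tempdir())
  seqs <- readProteomeFasta(file.path(fx$dir, "query.faa"))
  expect_identical(length(seqs), nrow(fx$truth$orthologPairs))
  expect_identical(sum(Biostrings::width(seqs)), fx$truth$totalResidues)
})

test_that("hits tables parse typed rows and reject bad lines by number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t98.5\t80\t1e-30\t120\t100", path)
  hits <- readHitsTable(path)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$evalue, 1e-30)
  expect_identical(hits$alnLength, 80L)

  writeLines(c("q1\ts1\t98.5\t80\t1e-30\t120\t100",
               "q2\ts2\t90.0\t70\tnot-a-number\t80\t100"), path)
  expect_error(readHitsTable(path), "line 2.*e-value")
  writeLines("q1\ts1\t98.5", path)
  expect_error(readHitsTable(path), "expected 7")
})

test_that("large generated hit tables round-trip through the tabular format", {
  set.seed(8)
  hits <- randomHits(500, paste0("q", 1:40), paste0("s", 1:40))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(hits[, c("query", "subject", "identityPct", "alnLength",
                       "evalue", "bitscore", "queryLength")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  back <- readHitsTable(path)
  expect_identical(nrow(back), 500L)
  expect_equal(sum(back$bitscore), sum(hits$bitscore))
  expect_equal(sum(back$evalue), sum(hits$evalue))
})

test_that("gzip-compressed inputs are accepted", {
  fx <- generateFixture(fixtureSpec(seed = 3, nTemplates = 1))
  tm <- fx$templates[[1]]
  plain <- withr::local_tempfile(fileext = ".json")
  writeTemplateJson(tm, plain)
  gz <- withr::local_tempfile(fileext = ".json.gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(plain), con)
  close(con)
  expect_identical(readTemplateJson(gz)@reactions$id, reactions(tm)$id)
})
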