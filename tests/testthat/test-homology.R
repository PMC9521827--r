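test_that("hit filtering applies the e-value/bitscore/coverage thresholds", {
  mk <- function(evalue, bitscore, aln, qlen) {
    data.frame(query = "q1", subject = "s1", identityPct = 90,
               alnLength = aln, evalue = evalue, bitscore = bitscore,
               queryLength = qlen, stringsAsFactors = FALSE)
  }
  expect_identical(nrow(filterHits(mk(1e-30, 120, 80, 100))), 1L)
  expect_identical(nrow(filterHits(mk(1e-30, 120, 50, 100))), 0L)  # 0.50 < 0.75
  expect_identical(nrow(filterHits(mk(1e-10, 120, 80, 100))), 0L)
  expect_identical(nrow(filterHits(mk(1e-30, 49, 80, 100))), 0L)
  ## thresholds are inclusive floors/ceilings
  expect_identical(nrow(filterHits(mk(1e-20, 50, 75, 100))), 1L)
})

test_that("filtering equals the three-predicate oracle and is monotone", {
  set.seed(31)
  hits <- randomHits(1000, paste0("q", 1:30), paste0("s", 1:30))
  for (p in list(searchParams(),
                 searchParams(maxEvalue = 1e-5, minBitscore = 30,
                              minQueryCoverage = 0.5))) {
    got <- filterHits(hits, p)
    keep <- logical(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      keep[i] <- hits$evalue[i] <= p$maxEvalue &&
        hits$bitscore[i] >= p$minBitscore &&
        hits$alnLength[i] / hits$queryLength[i] >= p$minQueryCoverage
    }
    expect_identical(got, hits[keep, , drop = FALSE])
  }
  strictKept <- filterHits(hits, searchParams())
  looseKept <- filterHits(hits, searchParams(maxEvalue = 1e-10,
                                             minBitscore = 20,
                                             minQueryCoverage = 0.5))
  expect_true(all(rownames(strictKept) %in% rownames(looseKept)))
})

test_that("best hit per query uses bitscore, then e-value, then subject id", {
  hits <- data.frame(
    query = c("q1", "q1"), subject = c("s1", "s2"),
    identityPct = 90, alnLength = 80,
    evalue = c(1e-40, 1e-40), bitscore = c(90, 80),
    queryLength = 100, stringsAsFactors = FALSE)
  expect_identical(bestHitPerQuery(hits), c(q1 = "s1"))

  hits$bitscore <- c(90, 90)
  hits$evalue <- c(1e-40, 1e-50)
  expect_identical(bestHitPerQuery(hits), c(q1 = "s2"))

  hits$evalue <- c(1e-40, 1e-40)
  expect_identical(bestHitPerQuery(hits), c(q1 = "s1"))  # lexicographic
})

test_that("best-hit selection matches a sort-based oracle on tie-heavy data", {
  set.seed(17)
  hits <- randomHits(600, paste0("q", 1:20), paste0("s", 1:20),
                     tieHeavy = TRUE)
  got <- bestHitPerQuery(hits)
  ## oracle: explicit per-query scan with the stated ordering, after
  ## keeping only the best HSP per (query, subject) pair
  best <- list()
  for (i in seq_len(nrow(hits))) {
    key <- paste(hits$query[i], hits$subject[i])
    cur <- best[[key]]
    if (is.null(cur) || hits$bitscore[i] > cur$bitscore ||
        (hits$bitscore[i] == cur$bitscore && hits$evalue[i] < cur$evalue)) {
      best[[key]] <- hits[i, ]
    }
  }
  perQuery <- list()
  for (h in best) {
    cur <- perQuery[[h$query]]
    better <- is.null(cur) || h$bitscore > cur$bitscore ||
      (h$bitscore == cur$bitscore && h$evalue < cur$evalue) ||
      (h$bitscore == cur$bitscore && h$evalue == cur$evalue &&
         h$subject < cur$subject)
    if (better) perQuery[[h$query]] <- h
  }
  oracle <- vapply(perQuery, function(h) h$subject, character(1))
  expect_identical(got[sort(names(got))], oracle[sort(names(oracle))])
})

test_that("reciprocal matching requires best hits in both directions", {
  expect_identical(
    orthologPairs(reciprocalMatches(c(q1 = "t1"), c(t1 = "q1"))),
    data.frame(template = "t1", query = "q1", stringsAsFactors = FALSE))
  expect_identical(
    nrow(orthologPairs(reciprocalMatches(c(q1 = "t1"), c(t1 = "q2")))), 0L)
})

test_that("reciprocal matching equals the quadratic scan on random maps", {
  set.seed(23)
  for (rep in 1:5) {
    qs <- paste0("q", 1:50); ts <- paste0("t", 1:50)
    fwd <- stats::setNames(sample(ts, 50, replace = TRUE), qs)
    rev <- stats::setNames(sample(qs, 50, replace = TRUE), ts)
    got <- orthologPairs(reciprocalMatches(fwd, rev))
    pairs <- character(0)
    for (q in qs) {
      for (t in ts) {
        if (fwd[[q]] == t && rev[[t]] == q) pairs <- c(pairs, paste(t, q))
      }
    }
    expect_setequal(paste(got$template, got$query), pairs)
  }
})

test_that("any-reciprocal-hit mode admits non-best reciprocal pairs", {
  fwd <- data.frame(query = c("q1", "q1"), subject = c("t1", "t2"),
                    stringsAsFactors = FALSE)
  rev <- data.frame(query = c("t1", "t2"), subject = c("q1", "q9"),
                    stringsAsFactors = FALSE)
  got <- orthologPairs(reciprocalMatches(fwd, rev, anyReciprocal = TRUE))
  expect_identical(got$template, "t1")
  expect_identical(got$query, "q1")
})

test_that("exact-match engine on identical proteomes gives a perfect map", {
  set.seed(5)
  seqs <- stats::setNames(
    vapply(1:10, function(i) paste(sample(c("A", "C", "D", "E", "G"), 80,
                                          replace = TRUE), collapse = ""),
           character(1)),
    paste0("p", 1:10))
  res <- runBidirectionalSearch(seqs, seqs, engine = exactMatchEngine)
  best <- bestHitPerQuery(res$forward)
  expect_identical(best[names(seqs)],
                   stats::setNames(names(seqs), names(seqs)))
  map <- buildOrthologMap(seqs, seqs, engine = exactMatchEngine)
  expect_identical(length(map), 10L)
  expect_identical(orthologPairs(map)$template, orthologPairs(map)$query)
})

test_that("disjoint random sequences yield zero hits in both directions", {
  set.seed(6)
  a <- stats::setNames(vapply(1:5, function(i) {
    paste(sample(c("M", "K", "T", "L"), 70, replace = TRUE), collapse = "")
  }, character(1)), paste0("a", 1:5))
  b <- stats::setNames(vapply(1:5, function(i) {
    paste(sample(c("W", "Y", "F", "H"), 70, replace = TRUE), collapse = "")
  }, character(1)), paste0("b", 1:5))
  res <- runBidirectionalSearch(a, b, engine = exactMatchEngine)
  expect_identical(nrow(res$forward), 0L)
  expect_identical(nrow(res$reverse), 0L)
})

test_that("k-mer engine recovers planted orthologs from mutated proteomes", {
  fx <- generateFixture(fixtureSpec(seed = 13, mutationRate = 0.05))
  templateProteins <- do.call(c, lapply(unname(fx$templates), function(tm) {
    stats::setNames(modelGenes(tm)$sequence, modelGenes(tm)$id)
  }))
  map <- buildOrthologMap(fx$queryProteome, templateProteins,
                          engine = kmerMatchEngine(k = 12L))
  got <- orthologPairs(map)
  truth <- fx$truth$orthologPairs
  expect_true(all(paste(truth$template, truth$query) %in%
                    paste(got$template, got$query)))
  ## no decoy query gene sneaks in
  expect_false(any(grepl("^qx", got$query)))
})

test_that("multi-HSP hits collapse to the top-scoring HSP per pair", {
  hits <- data.frame(
    query = "q1", subject = "s1", identityPct = c(90, 95),
    alnLength = c(40, 80), evalue = c(1e-10, 1e-40),
    bitscore = c(60, 120), queryLength = 100, stringsAsFactors = FALSE)
  got <- filterHits(hits)
  best <- bestHitPerQuery(hits)
  expect_identical(best, c(q1 = "s1"))
  ## the surviving HSP is the high-coverage one: the pair passes filtering
  expect_identical(nrow(filterHits(hits)), 1L)
  expect_identical(filterHits(hits)$bitscore, 120)
})

test_that("the external blastp adapter finds identity self-hits", {
  set.seed(9)
  seqs <- stats::setNames(vapply(1:5, function(i) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"), 90,
                 replace = TRUE), collapse = "")
  }, character(1)), paste0("p", 1:5))
  map <- buildOrthologMap(seqs, seqs, engine = blastpEngine())
  expect_identical(length(map), 5L)
  expect_identical(orthologPairs(map)$template, orthologPairs(map)$query)
})
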