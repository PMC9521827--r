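## Bidirectional similarity searches, hit filtering at the reconstruction
## thresholds, and reciprocal best-hit ortholog mapping.

#' Homology search parameters
#'
#' Defaults are the reconstruction thresholds used throughout the package:
#' e-value at most 1e-20, bit score at least 50, and query coverage
#' (alignment length over query sequence length) at least 0.75.
#'
#' @param maxEvalue Maximum e-value (inclusive), > 0.
#' @param minBitscore Minimum bit score (inclusive floor).
#' @param minQueryCoverage Minimum query coverage in (0, 1].
#' @param scoringMatrix Substitution matrix token handed to external
#'   aligners.
#' @return A `SearchParams` list.
#' @export
searchParams <- function(maxEvalue = 1e-20, minBitscore = 50,
                         minQueryCoverage = 0.75,
                         scoringMatrix = "BLOSUM62") {
  stopifnot(maxEvalue > 0, minQueryCoverage > 0, minQueryCoverage <= 1)
  structure(list(maxEvalue = maxEvalue, minBitscore = minBitscore,
                 minQueryCoverage = minQueryCoverage,
                 scoringMatrix = scoringMatrix),
            class = "SearchParams")
}

#' Query coverage of hits
#' @param hits Hits data.frame (see [readHitsTable()]).
#' @return Numeric vector `alnLength / queryLength`.
#' @export
hitCoverage <- function(hits) hits$alnLength / hits$queryLength

#' Filter homology hits by e-value, bit score and query coverage
#'
#' Keeps hits with `evalue <= maxEvalue`, `bitscore >= minBitscore` and
#' coverage `>= minQueryCoverage`; input order is preserved. Filtering is
#' monotone: loosening any threshold never removes a kept hit.
#'
#' @param hits Hits data.frame.
#' @param params A [searchParams()] object.
#' @return Filtered hits data.frame.
#' @export
filterHits <- function(hits, params = searchParams()) {
  keep <- hits$evalue <= params$maxEvalue &
    hits$bitscore >= params$minBitscore &
    hitCoverage(hits) >= params$minQueryCoverage
  hits[keep, , drop = FALSE]
}

## Keep only the top-scoring HSP per (query, subject) pair; ranking by
## bitscore desc, then evalue asc. Summing HSPs is deliberately avoided:
## coverage of a single HSP is well-defined.
collapseHsps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query, hits$subject, -hits$bitscore, hits$evalue)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(paste(hits$query, hits$subject, sep = "\r")), ,
       drop = FALSE]
}

#' Best hit per query
#'
#' For each query, the subject with maximal bit score; ties broken by
#' smaller e-value, then lexicographically smaller subject id. Multiple
#' HSPs per (query, subject) pair are first collapsed to the top-scoring
#' one.
#'
#' @param hits Hits data.frame (already filtered).
#' @return Named character vector: query id -> best subject id.
#' @export
bestHitPerQuery <- function(hits) {
  hits <- collapseHsps(hits)
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$query, -hits$bitscore, hits$evalue, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$query), , drop = FALSE]
  stats::setNames(best$subject, best$query)
}

#' Reciprocal matches between the two search directions
#'
#' A pair (template gene `t`, query gene `q`) is an ortholog candidate iff
#' `forward[q] == t` and `reverse[t] == q` — each is the other's best hit
#' (reciprocal best hit). With `anyReciprocal = TRUE`, best-hit status is
#' not required: any pair hit in both directions qualifies (sensitivity
#' mode); `forward`/`reverse` must then be full hit tables rather than
#' best-hit maps.
#'
#' @param forward Named vector query -> template best hit (or, with
#'   `anyReciprocal`, a filtered hits data.frame query vs template).
#' @param reverse Named vector template -> query best hit (or a filtered
#'   hits data.frame template vs query).
#' @param anyReciprocal Logical; use any-reciprocal-hit semantics.
#' @return An [OrthologMap-class]; reciprocity is asserted on output.
#' @export
reciprocalMatches <- function(forward, reverse, anyReciprocal = FALSE) {
  if (anyReciprocal) {
    stopifnot(is.data.frame(forward), is.data.frame(reverse))
    fwd <- unique(paste(forward$subject, forward$query, sep = "\r"))
    rev <- unique(paste(reverse$query, reverse$subject, sep = "\r"))
    both <- intersect(fwd, rev)
    parts <- strsplit(both, "\r", fixed = TRUE)
    tpl <- vapply(parts, `[`, character(1), 1L)
    qry <- vapply(parts, `[`, character(1), 2L)
    ord <- order(tpl, qry)
    return(OrthologMap(template = tpl[ord], query = qry[ord]))
  }
  q <- names(forward)
  t <- unname(forward)
  keep <- t %in% names(reverse) & unname(reverse[t]) == q
  keep[is.na(keep)] <- FALSE
  map <- OrthologMap(template = t[keep], query = q[keep])
  p <- orthologPairs(map)
  stopifnot(all(forward[p$query] == p$template),
            all(reverse[p$template] == p$query))
  map
}

## ---- search engines -------------------------------------------------------

.asCharacterSeqs <- function(x) {
  if (is(x, "XStringSet")) stats::setNames(as.character(x), names(x))
  else x
}

#' Deterministic search engines and the external-aligner adapter
#'
#' An engine is a function `(queries, subjects, params) -> hits data.frame`
#' in the [readHitsTable()] column layout. Engines are an injection point
#' so the pipeline can run without an external aligner:
#'
#' * `exactMatchEngine` reports a hit for every query/subject pair with
#'   byte-identical sequences (full coverage, e-value 0).
#' * `kmerMatchEngine(k)` indexes subject k-mers, pairs sequences sharing
#'   at least one k-mer, and scores equal-length pairs by positional
#'   identity (two bits per matching residue, e-value `10^(-matches/2)`).
#'   Deterministic; suitable for mutated-copy test proteomes.
#' * `blastpEngine()` shells out to `makeblastdb`/`blastp` with tabular
#'   output (`-outfmt "6 std-like + qlen"`), honouring the e-value and
#'   scoring-matrix parameters.
#'
#' @param queries,subjects Named [Biostrings::AAStringSet] or named
#'   character vectors of amino-acid sequences.
#' @param params A [searchParams()] object (engines may pre-filter on
#'   e-value only; definitive filtering is [filterHits()]).
#' @return A hits data.frame.
#' @export
exactMatchEngine <- function(queries, subjects, params = searchParams()) {
  q <- .asCharacterSeqs(queries); s <- .asCharacterSeqs(subjects)
  bySeq <- split(names(s), unname(s))
  rows <- emptyHits()
  for (qi in names(q)) {
    subs <- bySeq[[q[[qi]]]]
    if (is.null(subs)) next
    n <- nchar(q[[qi]])
    rows <- rbind(rows, data.frame(
      query = qi, subject = sort(subs), identityPct = 100,
      alnLength = n, evalue = 0, bitscore = 2 * n, queryLength = n,
      stringsAsFactors = FALSE))
  }
  rows
}

#' @rdname exactMatchEngine
#' @param k K-mer length for the candidate index (default 12; long enough
#'   that unrelated random protein sequences essentially never share one).
#' @export
kmerMatchEngine <- function(k = 12L) {
  force(k)
  function(queries, subjects, params = searchParams()) {
    q <- .asCharacterSeqs(queries); s <- .asCharacterSeqs(subjects)
    kmers <- function(x) {
      n <- nchar(x)
      if (n < k) return(character(0))
      unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
    }
    index <- new.env(parent = emptyenv())
    for (si in names(s)) {
      for (km in kmers(s[[si]])) {
        index[[km]] <- c(index[[km]], si)
      }
    }
    rows <- list()
    for (qi in names(q)) {
      cand <- unique(unlist(lapply(kmers(q[[qi]]), function(km) index[[km]]),
                            use.names = FALSE))
      for (si in sort(cand)) {
        qs <- q[[qi]]; ss <- s[[si]]
        aln <- min(nchar(qs), nchar(ss))
        matches <- sum(strsplit(substr(qs, 1, aln), "")[[1]] ==
                         strsplit(substr(ss, 1, aln), "")[[1]])
        rows[[length(rows) + 1L]] <- data.frame(
          query = qi, subject = si, identityPct = 100 * matches / aln,
          alnLength = aln, evalue = 10^(-matches / 2),
          bitscore = 2 * matches, queryLength = nchar(qs),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) return(emptyHits())
    do.call(rbind, rows)
  }
}

#' @rdname exactMatchEngine
#' @param blastp,makeblastdb Paths to the external aligner binaries.
#' @export
blastpEngine <- function(blastp = "blastp", makeblastdb = "makeblastdb") {
  force(blastp); force(makeblastdb)
  function(queries, subjects, params = searchParams()) {
    q <- .asCharacterSeqs(queries); s <- .asCharacterSeqs(subjects)
    dir <- tempfile("blast")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    qf <- file.path(dir, "query.faa"); sf <- file.path(dir, "subject.faa")
    writeLines(paste0(">", names(q), "\n", unname(unlist(q))), qf)
    writeLines(paste0(">", names(s), "\n", unname(unlist(s))), sf)
    db <- file.path(dir, "db")
    st <- system2(makeblastdb, c("-in", sf, "-dbtype", "prot", "-out", db),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0) stop("makeblastdb failed with status ", st, call. = FALSE)
    outf <- file.path(dir, "hits.tsv")
    st <- system2(blastp, c("-query", qf, "-db", db,
                            "-matrix", params$scoringMatrix,
                            "-evalue", format(params$maxEvalue),
                            "-outfmt",
                            shQuote("6 qseqid sseqid pident length evalue bitscore qlen"),
                            "-out", outf),
                  stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(st, "status"))) {
      stop("blastp failed: ", paste(st, collapse = "; "), call. = FALSE)
    }
    readHitsTable(outf)
  }
}

#' Run a bidirectional similarity search
#'
#' Runs the engine in both directions (query proteome vs template
#' proteins, and back) and filters each direction's hits with
#' [filterHits()]; the coverage threshold applies to that direction's
#' query (set `coverageBothDirections = FALSE` to filter coverage in the
#' forward direction only).
#'
#' @param queryProteome,templateProteome Named sequence sets.
#' @param params A [searchParams()].
#' @param engine A search engine function (see [exactMatchEngine()]).
#' @param coverageBothDirections Logical (default `TRUE`).
#' @return List with filtered `forward` and `reverse` hits data.frames.
#' @export
runBidirectionalSearch <- function(queryProteome, templateProteome,
                                   params = searchParams(),
                                   engine = exactMatchEngine,
                                   coverageBothDirections = TRUE) {
  q <- .asCharacterSeqs(queryProteome); s <- .asCharacterSeqs(templateProteome)
  if (length(q) == 0L) stop("empty query proteome", call. = FALSE)
  if (length(s) == 0L) stop("empty template proteome", call. = FALSE)
  fwd <- filterHits(engine(q, s, params), params)
  revParams <- params
  if (!coverageBothDirections) revParams$minQueryCoverage <- 1e-9
  rev <- filterHits(engine(s, q, revParams), revParams)
  list(forward = fwd, reverse = rev)
}

#' Build the ortholog map from a bidirectional search
#'
#' Convenience composition: [runBidirectionalSearch()], best-hit selection
#' per direction, then [reciprocalMatches()].
#'
#' @inheritParams runBidirectionalSearch
#' @param anyReciprocal Use any-reciprocal-hit semantics instead of
#'   reciprocal best hit.
#' @return An [OrthologMap-class] (template -> query).
#' @export
buildOrthologMap <- function(queryProteome, templateProteome,
                             params = searchParams(),
                             engine = exactMatchEngine,
                             anyReciprocal = FALSE,
                             coverageBothDirections = TRUE) {
  hits <- runBidirectionalSearch(queryProteome, templateProteome, params,
                                 engine, coverageBothDirections)
  if (anyReciprocal) {
    return(reciprocalMatches(hits$forward, hits$reverse, anyReciprocal = TRUE))
  }
  reciprocalMatches(bestHitPerQuery(hits$forward),
                    bestHitPerQuery(hits$reverse))
}
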