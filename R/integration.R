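## Draft assembly: GPR-driven reaction selection from the pooled template
## universe, canonical-key deduplication of reversibility/protonation
## variants, and the end-to-end build.

#' Reaction selection policy
#'
#' @param strict Logical. Strict policy drops reactions whose GPR cannot be
#'   completely re-written onto the query genome (no fully mapped isozyme
#'   clause) — the behaviour used for benchmark reconstructions. Non-strict
#'   admits partially mapped clauses, flagged `"partial"`.
#' @param allowNoGpr Logical. Re-admit reactions with absent GPRs
#'   (spontaneous/boundary pseudo-reactions); excluded by default.
#' @return A `GprPolicy` list.
#' @export
gprPolicy <- function(strict = TRUE, allowNoGpr = FALSE) {
  structure(list(strict = strict, allowNoGpr = allowNoGpr),
            class = "GprPolicy")
}

#' Pool template reactions into a reaction universe
#'
#' Concatenates the reaction tables of one or more templates; reaction ids
#' may repeat across sources, and each row keeps its `sourceModel`
#' provenance.
#'
#' @param templates List of [TemplateModel-class] objects.
#' @return Reaction data.frame (the universe).
#' @export
poolReactions <- function(templates) {
  stopifnot(length(templates) >= 1L)
  do.call(rbind, lapply(templates, reactions))
}

#' Select template reactions by GPR evaluation against the ortholog map
#'
#' A reaction is selected iff [assemblePartialGpr()] returns a rule for
#' its GPR under the policy; the assembled query-genome GPR and a
#' complete/partial flag are attached. Reactions with absent GPRs pass
#' only under `allowNoGpr` (flag `"no_gpr"`).
#'
#' @param universe Reaction data.frame (see [poolReactions()]).
#' @param orthologs An [OrthologMap-class] or template->query multimap list.
#' @param policy A [gprPolicy()].
#' @return The selected subset of `universe` with extra columns
#'   `assembledGpr` and `gprStatus`.
#' @export
selectReactions <- function(universe, orthologs, policy = gprPolicy()) {
  if (is(orthologs, "OrthologMap")) orthologs <- orthologMultimap(orthologs)
  n <- nrow(universe)
  keep <- logical(n)
  assembled <- character(n)
  status <- character(n)
  for (i in seq_len(n)) {
    gpr <- universe$gpr[i]
    if (is.na(gpr) || !nzchar(trimws(gpr))) {
      if (policy$allowNoGpr) {
        keep[i] <- TRUE; assembled[i] <- NA_character_; status[i] <- "no_gpr"
      }
      next
    }
    rule <- tryCatch(parseGpr(gpr), error = function(e) {
      stop("reaction '", universe$id[i], "': ", conditionMessage(e),
           call. = FALSE)
    })
    res <- tryCatch(
      assemblePartialGpr(rule, orthologs, strict = policy$strict),
      error = function(e) {
        stop("reaction '", universe$id[i], "': ", conditionMessage(e),
             call. = FALSE)
      })
    if (is.null(res)) next
    keep[i] <- TRUE
    assembled[i] <- renderGpr(res$rule)
    status[i] <- if (res$complete) "complete" else "partial"
  }
  out <- universe[keep, , drop = FALSE]
  out$assembledGpr <- assembled[keep]
  out$gprStatus <- status[keep]
  out
}

#' Canonical key of a reaction for duplicate detection
#'
#' Template collections contain the same biochemical transformation written
#' several ways: with the two sides swapped (reversibility re-writes), with
#' or without free protons (protonation-state variants), and duplicated
#' across compartments. The canonical key normalizes the first two causes:
#' protons (metabolite base ids in `protonIds`, any compartment) are
#' stripped from both sides, each side is encoded as a sorted multiset of
#' `(base id, compartment, |coefficient|)` entries, and the
#' lexicographically smaller side encoding is put first. Two reactions are
#' duplicates iff their keys are equal.
#'
#' Compartments are part of the key by default, so a cytosolic and a
#' periplasmic copy are both kept; `collapseCompartments = TRUE` relabels
#' compartments canonically (order of first appearance in the sorted
#' encoding), collapsing copies identical up to a consistent compartment
#' relabelling.
#'
#' @param stoichiometry Named numeric vector (full metabolite id ->
#'   signed coefficient), or a single-row slice of a reaction table.
#' @param protonIds Metabolite base ids treated as free protons
#'   (default `"h"`).
#' @param collapseCompartments Logical (default `FALSE`).
#' @return List with `key` (string) and `flipped` (`TRUE` when the sides
#'   were swapped during normalization).
#' @export
canonicalKey <- function(stoichiometry, protonIds = "h",
                         collapseCompartments = FALSE) {
  s <- stoichiometry
  stopifnot(is.numeric(s), !is.null(names(s)), length(s) >= 1L)
  parts <- splitMetaboliteId(names(s))
  keep <- !(parts$baseId %in% protonIds)
  if (!any(keep)) {
    stop("degenerate reaction: only protons remain after stripping",
         call. = FALSE)
  }
  s <- s[keep]; parts <- parts[keep, , drop = FALSE]
  comp <- parts$compartment
  if (collapseCompartments) {
    ord <- order(parts$baseId, parts$compartment, abs(s))
    relabel <- stats::setNames(
      paste0("x", seq_along(unique(comp[ord]))), unique(comp[ord]))
    comp <- unname(relabel[comp])
  }
  entry <- paste0(parts$baseId, "[", comp, "]x",
                  format(abs(s), digits = 15, scientific = FALSE, trim = TRUE))
  encodeSide <- function(idx) paste(sort(entry[idx]), collapse = "+")
  neg <- encodeSide(which(s < 0))
  pos <- encodeSide(which(s > 0))
  flipped <- pos < neg
  key <- if (flipped) paste(pos, neg, sep = " <=> ") else
    paste(neg, pos, sep = " <=> ")
  list(key = key, flipped = flipped)
}

#' Deduplicate selected reactions by canonical key
#'
#' One representative per canonical key, chosen deterministically (smallest
#' reaction id, then smallest source model id). GPRs of merged duplicates
#' are combined by OR and minimized by absorption; a merged reaction is
#' flagged `"complete"` if any variant was. The representative is
#' reversible if any variant was reversible, or if two irreversible
#' variants ran in opposite directions. Provenance (`sources`,
#' `sourceReactionIds`) lists all merged variants.
#'
#' Idempotent: deduplicating an already deduplicated list changes nothing.
#'
#' @param selected Output of [selectReactions()].
#' @param protonIds,collapseCompartments Passed to [canonicalKey()].
#' @return Reaction data.frame with one row per canonical key and
#'   list-columns `sources`, `sourceReactionIds`.
#' @export
deduplicateReactions <- function(selected, protonIds = "h",
                                 collapseCompartments = FALSE) {
  n <- nrow(selected)
  if (n == 0L) {
    out <- selected
    out$sources <- list(); out$sourceReactionIds <- list()
    return(out)
  }
  keys <- character(n); flipped <- logical(n)
  for (i in seq_len(n)) {
    ck <- canonicalKey(selected$stoichiometry[[i]], protonIds,
                       collapseCompartments)
    keys[i] <- ck$key; flipped[i] <- ck$flipped
  }
  groups <- split(seq_len(n), keys)
  ## stable output order: by representative's position in the input
  repRows <- list()
  for (idx in groups) {
    sub <- selected[idx, , drop = FALSE]
    ord <- order(sub$id, sub$sourceModel)
    rep <- sub[ord[1L], , drop = FALSE]
    srcModels <- unique(sub$sourceModel[ord])
    srcIds <- unique(sub$id[ord])
    gprs <- unique(sub$assembledGpr[!is.na(sub$assembledGpr)])
    if (length(gprs) > 0) {
      clauses <- unlist(lapply(gprs, function(g) decomposeOr(parseGpr(g))),
                        recursive = FALSE)
      rep$assembledGpr <- renderGpr(clausesToRule(.minimizeClauses(clauses)))
    }
    if (!is.null(sub$gprStatus)) {
      st <- sub$gprStatus
      rep$gprStatus <- if ("complete" %in% st) "complete"
        else if ("partial" %in% st) "partial" else "no_gpr"
    }
    fl <- flipped[idx]
    rep$reversible <- any(sub$reversible) || length(unique(fl)) > 1L
    if (rep$reversible && rep$lowerBound >= 0) rep$lowerBound <- -rep$upperBound
    rep$sources <- list(srcModels)
    rep$sourceReactionIds <- list(srcIds)
    repRows[[length(repRows) + 1L]] <- list(pos = idx[ord[1L]], row = rep)
  }
  repRows <- repRows[order(vapply(repRows, `[[`, numeric(1), "pos"))]
  out <- do.call(rbind, lapply(repRows, `[[`, "row"))
  rownames(out) <- NULL
  out
}

## Metabolite closure of a reaction table, drawn from template tables.
.metaboliteClosure <- function(rxnDf, templates) {
  used <- unique(unlist(lapply(rxnDf$stoichiometry, names), use.names = FALSE))
  pool <- do.call(rbind, lapply(templates, metabolites))
  pool <- pool[!duplicated(pool$id), , drop = FALSE]
  found <- pool[pool$id %in% used, , drop = FALSE]
  missing <- setdiff(used, found$id)
  if (length(missing) > 0) {
    found <- rbind(found, .metaboliteTable(missing))
  }
  found <- found[order(found$id), , drop = FALSE]
  rownames(found) <- NULL
  found
}

## Pool template protein sequences; identical-sequence id collisions are
## collapsed, conflicting ones rejected.
poolTemplateProteins <- function(templates) {
  rows <- do.call(rbind, lapply(templates, modelGenes))
  rows <- rows[!is.na(rows$sequence), , drop = FALSE]
  rows <- rows[!duplicated(paste(rows$id, rows$sequence, sep = "\r")), ,
               drop = FALSE]
  dup <- unique(rows$id[duplicated(rows$id)])
  if (length(dup) > 0) {
    stop("conflicting sequences for pooled template gene id(s): ",
         paste(head(dup, 3), collapse = ", "), call. = FALSE)
  }
  stats::setNames(rows$sequence, rows$id)
}

#' Build a draft metabolic network from template models
#'
#' End-to-end composition of the reconstruction workflow: choose templates
#' according to `mode`, pool their reactions, run the bidirectional
#' similarity search and derive the reciprocal best-hit ortholog map,
#' select reactions by GPR evaluation, deduplicate
#' reversibility/protonation variants, and assemble the
#' [DraftNetwork-class]. The run record (`runInfo`) logs template ids,
#' parameters, seed and per-stage counts.
#'
#' Modes: `"all"` uses every template; `"selected"` uses the `k`
#' metabolically closest template organisms by COG profile (requires
#' `annotations` and `targetOrganism`, see [topKClosest()]); `"random"`
#' samples `k` templates uniformly without replacement under `seed`.
#'
#' @param templates List of [TemplateModel-class] objects.
#' @param queryProteome Named sequence set for the query organism.
#' @param params [searchParams()].
#' @param engine Search engine (see [exactMatchEngine()]).
#' @param mode `"all"`, `"selected"` or `"random"`.
#' @param k Number of templates for selected/random modes (default 3).
#' @param seed Integer seed for random mode (echoed in provenance).
#' @param policy [gprPolicy()].
#' @param annotations For selected mode: list of COG annotation
#'   data.frames (see [readCogAnnotation()]) covering the template
#'   organisms and the target.
#' @param targetOrganism For selected mode: the query organism's name in
#'   `annotations`.
#' @param draftId Identifier for the draft model.
#' @param protonIds,collapseCompartments Deduplication options.
#' @return A [DraftNetwork-class].
#' @export
buildDraft <- function(templates, queryProteome, params = searchParams(),
                       engine = exactMatchEngine,
                       mode = c("all", "selected", "random"), k = 3L,
                       seed = NULL, policy = gprPolicy(),
                       annotations = NULL, targetOrganism = NULL,
                       draftId = "draft", protonIds = "h",
                       collapseCompartments = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(templates) >= 1L)
  names(templates) <- vapply(templates, modelId, character(1))
  if (mode == "selected") {
    if (is.null(annotations) || is.null(targetOrganism)) {
      stop("mode 'selected' requires COG annotations and a target organism",
           call. = FALSE)
    }
    byOrg <- stats::setNames(names(templates),
                             vapply(templates, organism, character(1)))
    profile <- buildProfileMatrix(annotations)
    have <- intersect(rownames(profile), c(names(byOrg), targetOrganism))
    if (!(targetOrganism %in% have)) {
      stop("target organism '", targetOrganism, "' not in the annotations",
           call. = FALSE)
    }
    dist <- metabolicDistance(profile[have, , drop = FALSE])
    chosen <- topKClosest(dist, targetOrganism, k = k)
    templates <- templates[unname(byOrg[chosen])]
  } else if (mode == "random") {
    if (is.null(seed)) stop("mode 'random' requires a seed", call. = FALSE)
    if (k > length(templates)) {
      stop("k exceeds the number of available templates", call. = FALSE)
    }
    idx <- withSeed(seed, sample.int(length(templates), k))
    templates <- templates[idx]
  }
  templateProteins <- poolTemplateProteins(templates)
  if (length(templateProteins) == 0L) {
    stop("templates carry no protein sequences", call. = FALSE)
  }
  orth <- buildOrthologMap(queryProteome, templateProteins, params, engine)
  universe <- poolReactions(templates)
  selected <- selectReactions(universe, orth, policy)
  dedup <- deduplicateReactions(selected, protonIds, collapseCompartments)
  queryGenes <- unique(unlist(lapply(dedup$assembledGpr, function(g) {
    if (is.na(g)) character(0) else ruleGenes(parseGpr(g))
  }), use.names = FALSE))
  qseqs <- .asCharacterSeqs(queryProteome)
  geneDf <- data.frame(id = sort(queryGenes),
                       sequence = unname(qseqs[sort(queryGenes)]),
                       stringsAsFactors = FALSE)
  rxn <- dedup
  rxn$gpr <- rxn$assembledGpr
  new("DraftNetwork", modelId = draftId,
      organism = if (is.null(targetOrganism)) "" else targetOrganism,
      genes = geneDf,
      metabolites = .metaboliteClosure(rxn, templates),
      reactions = rxn,
      runInfo = list(
        mode = mode, k = if (mode == "all") length(templates) else k,
        seed = seed, templates = names(templates),
        params = unclass(params), policy = unclass(policy),
        orthologPairs = length(orth),
        universeSize = nrow(universe),
        selected = nrow(selected),
        merged = nrow(selected) - nrow(dedup),
        draftReactions = nrow(dedup)))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
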