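## Draft-versus-reference scoring (precision/recall/F1 over comparable
## reaction sets) and multi-model overlap/PCA summaries.

#' Comparable reaction identifiers of a model
#'
#' The reactions a draft is scored on: all reactions except boundary
#' pseudo-reactions. A reaction is excluded when its id carries an
#' `EX_`/`SK_`/`DM_` prefix (exchange, sink, demand) or when it is
#' topologically boundary — all its metabolites sit on one side of the
#' equation (which covers single-metabolite pseudo-reactions). Case is
#' preserved; `stripCopySuffix = TRUE` additionally strips `_copy<digits>`
#' suffixes found in some curated models.
#'
#' @param model A [TemplateModel-class]/[DraftNetwork-class], or a
#'   reaction data.frame.
#' @param stripCopySuffix Logical (default `FALSE`).
#' @return Character set of canonical reaction ids.
#' @export
comparableReactionSet <- function(model, stripCopySuffix = FALSE) {
  rxn <- if (is.data.frame(model)) model else reactions(model)
  if (nrow(rxn) == 0L) return(character(0))
  prefixed <- grepl("^(EX_|SK_|DM_)", rxn$id)
  boundary <- vapply(rxn$stoichiometry, function(s) {
    all(s > 0) || all(s < 0)
  }, logical(1))
  ids <- rxn$id[!(prefixed | boundary)]
  if (stripCopySuffix) ids <- sub("_copy[0-9]+$", "", ids)
  unique(ids)
}

#' Confusion counts of a draft against a reference
#'
#' TP = reactions in both, FP = draft-only, FN = reference-only. Both id
#' sets should already be canonicalized with [comparableReactionSet()].
#'
#' @param draftIds,referenceIds Character sets of reaction ids.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(draftIds, referenceIds) {
  draftIds <- unique(draftIds); referenceIds <- unique(referenceIds)
  ConfusionCounts(TP = length(intersect(draftIds, referenceIds)),
                  FP = length(setdiff(draftIds, referenceIds)),
                  FN = length(setdiff(referenceIds, draftIds)))
}

#' Precision, recall and F1 from confusion counts
#'
#' P = TP / (TP + FP), R = TP / (TP + FN), F1 = 2PR / (P + R). A
#' zero-denominator case yields 0 for that metric and sets the
#' `degenerate` flag, so a draft with no selected reactions still gets a
#' report row.
#'
#' @param counts A [ConfusionCounts-class].
#' @return List with `precision`, `recall`, `f1` (in \[0, 1\]) and
#'   `degenerate` (logical).
#' @export
scoreMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@TP; fp <- counts@FP; fn <- counts@FN
  degenerate <- FALSE
  p <- if (tp + fp == 0L) { degenerate <- TRUE; 0 } else tp / (tp + fp)
  r <- if (tp + fn == 0L) { degenerate <- TRUE; 0 } else tp / (tp + fn)
  f1 <- if (p + r == 0) { degenerate <- degenerate || tp == 0L; 0 } else
    2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, degenerate = degenerate)
}

#' Score a draft model against a reference model
#'
#' Convenience wrapper: canonicalizes both reaction sets with
#' [comparableReactionSet()], counts the confusion matrix and computes
#' the metrics.
#'
#' @param draft,reference Models (or reaction data.frames).
#' @param stripCopySuffix Passed to [comparableReactionSet()].
#' @return One-row data.frame with `TP`, `FP`, `FN`, `precision`,
#'   `recall`, `f1`.
#' @export
assessDraft <- function(draft, reference, stripCopySuffix = FALSE) {
  d <- comparableReactionSet(draft, stripCopySuffix)
  r <- comparableReactionSet(reference, stripCopySuffix)
  cc <- confusionCounts(d, r)
  m <- scoreMetrics(cc)
  data.frame(TP = cc@TP, FP = cc@FP, FN = cc@FN,
             precision = m$precision, recall = m$recall, f1 = m$f1)
}

#' Write an assessment report TSV
#'
#' One row per draft; metric floats printed to 3 decimals.
#'
#' @param rows data.frame of [assessDraft()] rows (with a `model` label
#'   column if desired).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeAssessmentReport <- function(rows, path) {
  out <- rows
  for (col in intersect(c("precision", "recall", "f1"), names(out))) {
    out[[col]] <- sprintf("%.3f", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap-region counts for labeled id sets
#'
#' For 2-7 labeled sets, counts every inclusion/exclusion region of the
#' corresponding Venn diagram: each element of the union contributes to
#' exactly one region, the one given by the sorted tuple of labels of the
#' sets containing it. All `2^n - 1` region signatures are reported
#' (possibly with count 0); counts sum to the union size.
#'
#' @param idSets Named list of character sets (2-7 entries).
#' @return data.frame with columns `region` (labels joined by `&`),
#'   `degree` and `count`.
#' @export
overlapRegions <- function(idSets) {
  n <- length(idSets)
  if (n < 2L || n > 7L) {
    stop("overlapRegions needs between 2 and 7 sets", call. = FALSE)
  }
  labels <- names(idSets)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop("idSets must have unique non-empty names", call. = FALSE)
  }
  idSets <- lapply(idSets, unique)
  elements <- unique(unlist(idSets, use.names = FALSE))
  membership <- vapply(idSets, function(s) elements %in% s,
                       logical(length(elements)))
  if (length(elements) == 1L) membership <- matrix(membership, nrow = 1L)
  sig <- apply(membership, 1L, function(row) {
    paste(sort(labels[row]), collapse = "&")
  })
  combos <- unlist(lapply(seq_len(n), function(sz) {
    utils::combn(sort(labels), sz, FUN = paste, collapse = "&",
                 simplify = FALSE)
  }), use.names = FALSE)
  counts <- table(factor(sig, levels = combos))
  data.frame(region = combos,
             degree = lengths(strsplit(combos, "&", fixed = TRUE)),
             count = as.integer(counts[combos]),
             stringsAsFactors = FALSE)
}

#' PCA of model content
#'
#' Builds the binary model-by-feature presence matrix (features: reaction
#' ids, metabolite ids, or COG ids via a gene-to-COG cross-reference) and
#' delegates to [pcaProfiles()] (zero-variance drop, z-score,
#' sign-canonicalized PCA).
#'
#' @param models List (optionally named) of models.
#' @param feature `"reaction"`, `"metabolite"` or `"cog"`.
#' @param geneCog For `feature = "cog"`: data.frame with columns `geneId`,
#'   `cogId` cross-referencing model genes to COG ids.
#' @param ... Passed to [pcaProfiles()].
#' @return As [pcaProfiles()], plus the `matrix` used.
#' @export
modelContentPca <- function(models, feature = c("reaction", "metabolite", "cog"),
                            geneCog = NULL, ...) {
  feature <- match.arg(feature)
  stopifnot(length(models) >= 3L)
  if (is.null(names(models))) {
    names(models) <- vapply(models, modelId, character(1))
  }
  featureIds <- lapply(models, function(m) {
    switch(feature,
      reaction = reactions(m)$id,
      metabolite = metabolites(m)$id,
      cog = {
        if (is.null(geneCog)) {
          stop("feature 'cog' requires a gene-to-COG cross-reference table",
               call. = FALSE)
        }
        unique(geneCog$cogId[geneCog$geneId %in% modelGenes(m)$id])
      })
  })
  cols <- sort(unique(unlist(featureIds, use.names = FALSE)))
  m <- matrix(0L, nrow = length(models), ncol = length(cols),
              dimnames = list(names(models), cols))
  for (i in seq_along(featureIds)) {
    m[i, match(unique(featureIds[[i]]), cols)] <- 1L
  }
  out <- pcaProfiles(m, ...)
  out$matrix <- m
  out
}
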