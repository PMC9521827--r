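## COG-profile based template selection: metabolic-function presence/absence
## profiles, inter-organism distances, top-k closest organisms, and PCA
## views of the profiles.

## COG functional-category letters that make up the METABOLISM general
## category.
.METABOLISM_CATEGORIES <- c("C", "E", "F", "G", "H", "I", "P", "Q")

#' Read a per-organism COG annotation table
#'
#' Tab-separated columns: protein id, COG id, functional category
#' letter(s), and optionally an e-value (extra columns ignored). A header
#' line is detected and skipped when the first field is non-COG-like text
#' such as `protein_id`. Only rows whose functional category intersects
#' the METABOLISM general category (letters C, E, F, G, H, I, P, Q) are
#' retained, since template selection is about shared metabolic functions.
#'
#' @param path TSV path (optionally gzipped).
#' @param organism Organism label attached to the table.
#' @param metabolismOnly Keep only METABOLISM-category rows (default
#'   `TRUE`).
#' @return data.frame with columns `organism`, `proteinId`, `cogId`,
#'   `category`.
#' @export
readCogAnnotation <- function(path, organism, metabolismOnly = TRUE) {
  txt <- .readTextMaybeGz(path)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) > 0 && length(fields[[1]]) >= 2L &&
      !grepl("^COG[0-9]+$", fields[[1]][2])) {
    fields <- fields[-1]  # header
  }
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0) {
    stop("COG annotation format error at line ", bad[1],
         ": expected >=3 tab-separated columns", call. = FALSE)
  }
  df <- data.frame(
    organism = organism,
    proteinId = vapply(fields, `[`, character(1), 1L),
    cogId = vapply(fields, `[`, character(1), 2L),
    category = vapply(fields, `[`, character(1), 3L),
    stringsAsFactors = FALSE)
  badCog <- !grepl("^COG[0-9]+$", df$cogId)
  if (any(badCog)) {
    stop("malformed COG id at line ", which(badCog)[1], ": ",
         df$cogId[which(badCog)[1]], call. = FALSE)
  }
  if (metabolismOnly) {
    keep <- vapply(strsplit(df$category, ""), function(ls) {
      any(ls %in% .METABOLISM_CATEGORIES)
    }, logical(1))
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Build the COG presence/absence profile matrix
#'
#' Binary matrix with one row per organism and one column per COG id
#' (sorted, deduplicated); an entry is 1 iff the organism has at least one
#' protein annotated with that COG. Organisms with zero metabolic COGs are
#' retained as all-zero rows with a warning.
#'
#' @param annotations List of annotation data.frames
#'   (see [readCogAnnotation()]), one or more organisms each.
#' @return Integer 0/1 matrix, organisms x COG ids.
#' @export
buildProfileMatrix <- function(annotations) {
  ann <- do.call(rbind, annotations)
  rownames(ann) <- NULL
  ## names on the list keep organisms visible even when every row of
  ## their table was filtered out (all-zero profile)
  named <- names(annotations)
  named <- named[!is.null(named) & nzchar(named)]
  orgs <- sort(unique(c(ann$organism, named)))
  if (length(orgs) < 2L) stop("need annotations for >=2 organisms",
                              call. = FALSE)
  cogs <- sort(unique(ann$cogId))
  m <- matrix(0L, nrow = length(orgs), ncol = length(cogs),
              dimnames = list(orgs, cogs))
  idx <- cbind(match(ann$organism, orgs), match(ann$cogId, cogs))
  m[idx] <- 1L
  zero <- rowSums(m) == 0L
  if (any(zero)) {
    warning("organism(s) with zero metabolic COGs: ",
            paste(orgs[zero], collapse = ", "), call. = FALSE)
  }
  m
}

#' Metabolic-function distance between organisms
#'
#' Pairwise distances on the COG presence/absence profiles. The default
#' metric is the Jaccard distance `1 - |A n B| / |A u B|` on presence
#' sets (computed via \code{vegan::vegdist(..., method = "jaccard",
#' binary = TRUE)}); `"hamming"` is the fraction of differing entries.
#' Pairs of all-zero profiles get distance 0 with a warning.
#'
#' @param matrix Binary profile matrix (see [buildProfileMatrix()]).
#' @param metric `"jaccard"` (default) or `"hamming"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
metabolicDistance <- function(matrix, metric = c("jaccard", "hamming")) {
  metric <- match.arg(metric)
  stopifnot(nrow(matrix) >= 2L)
  if (metric == "jaccard") {
    zero <- rowSums(matrix) == 0L
    d <- suppressWarnings(
      as.matrix(vegan::vegdist(matrix, method = "jaccard", binary = TRUE)))
    if (any(zero)) {
      warning("all-zero profile(s): pairwise distances involving them set ",
              "to 1 (0 between two all-zero profiles)", call. = FALSE)
      d[zero, ] <- 1; d[, zero] <- 1
      d[zero, zero] <- 0
    }
  } else {
    d <- as.matrix(stats::dist(matrix, method = "manhattan")) / ncol(matrix)
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(matrix), rownames(matrix))
  d
}

#' The k metabolically closest organisms to a target
#'
#' Orders organisms by distance to the target (target excluded), breaking
#' ties lexicographically, and returns the first `k` — the organisms whose
#' template models are used in "selected" reconstruction mode.
#'
#' @param distances Symmetric distance matrix with organism dimnames.
#' @param target Target organism (must be a row of `distances`).
#' @param k Number of organisms to return (default 3; must be < number of
#'   other organisms + 1).
#' @return Character vector of `k` organism names.
#' @export
topKClosest <- function(distances, target, k = 3L) {
  stopifnot(target %in% rownames(distances))
  others <- setdiff(rownames(distances), target)
  if (k > length(others)) {
    stop("k = ", k, " but only ", length(others), " other organisms",
         call. = FALSE)
  }
  d <- distances[target, others]
  others[order(d, others)][seq_len(k)]
}

#' PCA of presence/absence profiles
#'
#' Drops low-variance columns (default: zero variance), standardizes the
#' remaining columns to z-scores, and computes principal components via
#' the covariance eigendecomposition (\code{stats::prcomp}). Component
#' signs are canonicalized so each component's largest-magnitude loading
#' is positive, making scores reproducible across platforms.
#'
#' @param matrix Numeric matrix, rows = observations (organisms or
#'   models), columns = binary features. At least 3 rows.
#' @param zeroVarianceDrop Drop columns with variance <= `varThreshold`
#'   (default `TRUE`).
#' @param standardize Z-score columns (default `TRUE`).
#' @param varThreshold Variance threshold for dropping (default 0).
#' @param nComponents Number of score columns returned (default 2).
#' @return List with `scores` (rows x `nComponents`), `explainedVariance`
#'   (fraction per returned component), `allExplainedVariance`, and
#'   `rotation`.
#' @export
pcaProfiles <- function(matrix, zeroVarianceDrop = TRUE, standardize = TRUE,
                        varThreshold = 0, nComponents = 2L) {
  stopifnot(nrow(matrix) >= 3L)
  m <- matrix
  if (zeroVarianceDrop) {
    v <- apply(m, 2L, stats::var)
    m <- m[, v > varThreshold, drop = FALSE]
    if (ncol(m) == 0L) {
      stop("all columns dropped by the variance filter", call. = FALSE)
    }
  }
  p <- stats::prcomp(m, center = TRUE, scale. = standardize)
  ## canonicalize component signs: largest-|loading| positive
  for (j in seq_len(ncol(p$rotation))) {
    lead <- which.max(abs(p$rotation[, j]))
    if (p$rotation[lead, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  evar <- p$sdev^2 / sum(p$sdev^2)
  nc <- min(nComponents, ncol(p$x))
  list(scores = p$x[, seq_len(nc), drop = FALSE],
       explainedVariance = evar[seq_len(nc)],
       allExplainedVariance = evar,
       rotation = p$rotation)
}
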