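#' @import methods
#' @importFrom stats prcomp runif var
#' @importFrom utils head read.table write.table
NULL

## Reaction tables are data.frames with one row per reaction and a
## `stoichiometry` list-column of named numerics (full metabolite id ->
## signed coefficient; reactants negative, products positive). Metabolite
## tables carry id (= baseId "_" compartment), baseId, compartment, name,
## formula, charge. Gene tables carry id and sequence (NA when unknown).

.emptyGenes <- function() {
  data.frame(id = character(0), sequence = character(0),
             stringsAsFactors = FALSE)
}

.emptyMetabolites <- function() {
  data.frame(id = character(0), baseId = character(0),
             compartment = character(0), name = character(0),
             formula = character(0), charge = numeric(0),
             stringsAsFactors = FALSE)
}

.emptyReactions <- function() {
  df <- data.frame(id = character(0), name = character(0),
                   lowerBound = numeric(0), upperBound = numeric(0),
                   reversible = logical(0), gpr = character(0),
                   subsystem = character(0), sourceModel = character(0),
                   stringsAsFactors = FALSE)
  df$stoichiometry <- list()
  df
}

#' TemplateModel: a source genome-scale metabolic model
#'
#' Holds a template model's genes (optionally with protein sequences),
#' metabolites, and reactions with their GPR rule strings. GPR strings are
#' stored verbatim and parsed on demand by [parseGpr()], so a malformed
#' rule fails at evaluation time with context, not at load time.
#'
#' @slot modelId Model identifier.
#' @slot organism Organism name ("" when unknown).
#' @slot genes data.frame with columns `id`, `sequence`.
#' @slot metabolites data.frame with columns `id`, `baseId`, `compartment`,
#'   `name`, `formula`, `charge`.
#' @slot reactions data.frame with columns `id`, `name`, `lowerBound`,
#'   `upperBound`, `reversible`, `gpr`, `subsystem`, `sourceModel` and a
#'   `stoichiometry` list-column of named numeric vectors.
#' @export
setClass("TemplateModel",
  representation(modelId = "character", organism = "character",
                 genes = "data.frame", metabolites = "data.frame",
                 reactions = "data.frame"),
  prototype(modelId = NA_character_, organism = "",
            genes = .emptyGenes(), metabolites = .emptyMetabolites(),
            reactions = .emptyReactions()))

setValidity("TemplateModel", function(object) {
  msgs <- character(0)
  rxn <- object@reactions
  met <- object@metabolites
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicate reaction ids")
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicate metabolite ids")
  if (anyDuplicated(object@genes$id)) msgs <- c(msgs, "duplicate gene ids")
  if (nrow(rxn) > 0) {
    refd <- unique(unlist(lapply(rxn$stoichiometry, names), use.names = FALSE))
    missing <- setdiff(refd, met$id)
    if (length(missing) > 0) {
      msgs <- c(msgs, paste0("reactions reference undeclared metabolites: ",
                             paste(head(missing, 5), collapse = ", ")))
    }
    nmet <- vapply(rxn$stoichiometry, length, integer(1))
    if (any(nmet == 0L)) msgs <- c(msgs, "reaction with no metabolites")
    zero <- vapply(rxn$stoichiometry, function(s) any(s == 0), logical(1))
    if (any(zero)) msgs <- c(msgs, "zero stoichiometric coefficient")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Construct a TemplateModel
#' @param modelId,organism Identifiers.
#' @param genes,metabolites,reactions Component tables (see class docs).
#' @return A validated [TemplateModel-class] object.
#' @export
TemplateModel <- function(modelId, organism = "", genes = .emptyGenes(),
                          metabolites = .emptyMetabolites(),
                          reactions = .emptyReactions()) {
  new("TemplateModel", modelId = modelId, organism = organism,
      genes = genes, metabolites = metabolites, reactions = reactions)
}

#' DraftNetwork: an assembled draft metabolic network
#'
#' A [TemplateModel-class] whose reactions carry assembled query-genome
#' GPRs plus provenance: reaction-level extra columns `gprStatus`
#' (`"complete"` or `"partial"`), `sources` (list of contributing template
#' model ids) and `sourceReactionIds` (list of merged original reaction
#' ids). `runInfo` records the parameters, template ids, seed and
#' per-stage counts of the run that produced the draft.
#'
#' @slot runInfo Named list run record.
#' @export
setClass("DraftNetwork", contains = "TemplateModel",
         representation(runInfo = "list"), prototype(runInfo = list()))

#' OrthologMap: reciprocal template/query gene pairs
#'
#' @slot pairs data.frame with columns `template` and `query` gene ids;
#'   each row is a reciprocal match between the two search directions.
#' @export
setClass("OrthologMap", representation(pairs = "data.frame"),
         prototype(pairs = data.frame(template = character(0),
                                      query = character(0),
                                      stringsAsFactors = FALSE)))

setValidity("OrthologMap", function(object) {
  p <- object@pairs
  if (!all(c("template", "query") %in% names(p))) {
    return("pairs must have columns 'template' and 'query'")
  }
  if (anyDuplicated(paste(p$template, p$query, sep = "\r"))) {
    return("duplicate ortholog pairs")
  }
  TRUE
})

#' Construct an OrthologMap
#' @param template,query Parallel character vectors of gene ids.
#' @return An [OrthologMap-class].
#' @export
OrthologMap <- function(template = character(0), query = character(0)) {
  new("OrthologMap",
      pairs = data.frame(template = as.character(template),
                         query = as.character(query),
                         stringsAsFactors = FALSE))
}

#' ConfusionCounts: TP/FP/FN of a draft against a reference
#' @slot TP,FP,FN Non-negative integer counts.
#' @export
setClass("ConfusionCounts",
         representation(TP = "integer", FP = "integer", FN = "integer"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@TP, object@FP, object@FN) < 0)) "negative count" else TRUE
})

#' Construct ConfusionCounts
#' @param TP,FP,FN Non-negative counts.
#' @export
ConfusionCounts <- function(TP, FP, FN) {
  new("ConfusionCounts", TP = as.integer(TP), FP = as.integer(FP),
      FN = as.integer(FN))
}

## ---- generics + accessors -------------------------------------------------

#' Model accessors
#'
#' @param object A [TemplateModel-class] (or [DraftNetwork-class]),
#'   [OrthologMap-class] or [ConfusionCounts-class].
#' @return The corresponding component table or scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setMethod("modelId", "TemplateModel", function(object) object@modelId)

#' @rdname accessors
#' @export
setGeneric("organism", function(object) standardGeneric("organism"))
#' @rdname accessors
#' @export
setMethod("organism", "TemplateModel", function(object) object@organism)

#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setMethod("reactions", "TemplateModel", function(object) object@reactions)

#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setMethod("metabolites", "TemplateModel", function(object) object@metabolites)

#' @rdname accessors
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))
#' @rdname accessors
#' @export
setMethod("modelGenes", "TemplateModel", function(object) object@genes)

#' @rdname accessors
#' @export
setGeneric("runInfo", function(object) standardGeneric("runInfo"))
#' @rdname accessors
#' @export
setMethod("runInfo", "DraftNetwork", function(object) object@runInfo)

#' @rdname accessors
#' @export
setGeneric("orthologPairs", function(object) standardGeneric("orthologPairs"))
#' @rdname accessors
#' @export
setMethod("orthologPairs", "OrthologMap", function(object) object@pairs)

#' Template-to-query multimap view of an OrthologMap
#' @param object An [OrthologMap-class].
#' @return Named list: template gene id -> character vector of query ids.
#' @export
orthologMultimap <- function(object) {
  stopifnot(is(object, "OrthologMap"))
  p <- object@pairs
  split(p$query, factor(p$template, levels = unique(p$template)))
}

#' @rdname accessors
#' @export
setGeneric("truePositives", function(object) standardGeneric("truePositives"))
#' @rdname accessors
#' @export
setMethod("truePositives", "ConfusionCounts", function(object) object@TP)
#' @rdname accessors
#' @export
setGeneric("falsePositives", function(object) standardGeneric("falsePositives"))
#' @rdname accessors
#' @export
setMethod("falsePositives", "ConfusionCounts", function(object) object@FP)
#' @rdname accessors
#' @export
setGeneric("falseNegatives", function(object) standardGeneric("falseNegatives"))
#' @rdname accessors
#' @export
setMethod("falseNegatives", "ConfusionCounts", function(object) object@FN)

setMethod("show", "TemplateModel", function(object) {
  cat("TemplateModel", object@modelId,
      if (nzchar(object@organism)) paste0("(", object@organism, ")") else "",
      "\n")
  cat("  reactions:  ", nrow(object@reactions), "\n")
  cat("  metabolites:", nrow(object@metabolites), "\n")
  cat("  genes:      ", nrow(object@genes), "\n")
})

setMethod("show", "DraftNetwork", function(object) {
  cat("DraftNetwork", object@modelId, "\n")
  cat("  reactions:  ", nrow(object@reactions), "\n")
  cat("  metabolites:", nrow(object@metabolites), "\n")
  cat("  genes:      ", nrow(object@genes), "\n")
  st <- object@reactions$gprStatus
  if (!is.null(st)) {
    cat("  GPRs:       ", sum(st == "complete"), "complete,",
        sum(st == "partial"), "partial\n")
  }
  if (length(object@runInfo) > 0 && !is.null(object@runInfo$templates)) {
    cat("  templates:  ",
        paste(object@runInfo$templates, collapse = ", "), "\n")
  }
})

setMethod("show", "OrthologMap", function(object) {
  cat("OrthologMap with", nrow(object@pairs), "reciprocal pairs\n")
})

setMethod("length", "OrthologMap", function(x) nrow(x@pairs))

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d FN=%d\n",
              object@TP, object@FP, object@FN))
})

## Split a full metabolite id into base id and compartment on the LAST
## underscore; BiGG double-underscore base ids (e.g. "glc__D_c") survive
## intact because only the final "_c" is removed.
splitMetaboliteId <- function(id) {
  pos <- regexpr("_[^_]*$", id)
  bad <- pos <= 1L
  if (any(bad)) {
    stop("metabolite id without compartment suffix: ",
         paste(head(id[bad], 3), collapse = ", "), call. = FALSE)
  }
  data.frame(baseId = substr(id, 1L, pos - 1L),
             compartment = substr(id, pos + 1L, nchar(id)),
             stringsAsFactors = FALSE)
}
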