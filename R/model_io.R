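## Reading/writing template and draft models (COBRA JSON, SBML L3+FBC),
## proteome FASTA files and tabular homology-hit files. All paths may be
## plain or gzip-compressed.

#' @importFrom jsonlite fromJSON toJSON write_json read_json
#' @importFrom xml2 read_xml xml_ns xml_find_all xml_find_first xml_attr
#'   xml_name xml_children xml_new_root xml_add_child write_xml
NULL

.readTextMaybeGz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  paste(readLines(con, warn = FALSE), collapse = "\n")
}

.metaboliteTable <- function(ids, names = NULL, formulas = NULL,
                             charges = NULL, compartments = NULL) {
  n <- length(ids)
  parts <- splitMetaboliteId(ids)
  if (is.null(compartments)) compartments <- parts$compartment
  data.frame(id = ids, baseId = parts$baseId, compartment = compartments,
             name = if (is.null(names)) rep(NA_character_, n) else names,
             formula = if (is.null(formulas)) rep(NA_character_, n) else formulas,
             charge = if (is.null(charges)) rep(NA_real_, n) else charges,
             stringsAsFactors = FALSE)
}

#' Read a template model in COBRA/BiGG JSON format
#'
#' Expects the COBRA JSON schema: top-level keys `metabolites`, `reactions`
#' and `genes`; reactions carry `gene_reaction_rule` strings and a
#' `metabolites` map of signed coefficients (reactants negative, products
#' positive). Gene records may carry a non-standard `protein_sequence`
#' field, used for homology searches. GPR strings are stored verbatim.
#'
#' @param path Path to a `.json` (optionally `.gz`) file.
#' @return A [TemplateModel-class].
#' @export
readTemplateJson <- function(path) {
  doc <- tryCatch(fromJSON(.readTextMaybeGz(path), simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  for (key in c("metabolites", "reactions", "genes")) {
    if (is.null(doc[[key]])) {
      stop("malformed model JSON: missing key '", key, "'", call. = FALSE)
    }
  }
  g <- function(x, key, default = NA) {
    v <- x[[key]]
    if (is.null(v)) default else v
  }
  mets <- doc$metabolites
  metDf <- .metaboliteTable(
    ids = vapply(mets, function(m) as.character(m$id), character(1)),
    names = vapply(mets, function(m) as.character(g(m, "name")), character(1)),
    formulas = vapply(mets, function(m) as.character(g(m, "formula")), character(1)),
    charges = vapply(mets, function(m) as.numeric(g(m, "charge")), numeric(1)),
    compartments = {
      cc <- vapply(mets, function(m) as.character(g(m, "compartment")), character(1))
      if (all(is.na(cc))) NULL else cc
    })
  genes <- doc$genes
  geneDf <- data.frame(
    id = vapply(genes, function(x) as.character(x$id), character(1)),
    sequence = vapply(genes, function(x) as.character(g(x, "protein_sequence")),
                      character(1)),
    stringsAsFactors = FALSE)
  rxns <- doc$reactions
  n <- length(rxns)
  lb <- vapply(rxns, function(r) as.numeric(g(r, "lower_bound", -1000)), numeric(1))
  ub <- vapply(rxns, function(r) as.numeric(g(r, "upper_bound", 1000)), numeric(1))
  rxnDf <- data.frame(
    id = vapply(rxns, function(r) as.character(r$id), character(1)),
    name = vapply(rxns, function(r) as.character(g(r, "name")), character(1)),
    lowerBound = lb, upperBound = ub,
    reversible = lb < 0 & ub > 0,
    gpr = vapply(rxns, function(r) {
      v <- as.character(g(r, "gene_reaction_rule", NA_character_))
      if (!is.na(v) && !nzchar(trimws(v))) NA_character_ else v
    }, character(1)),
    subsystem = vapply(rxns, function(r) as.character(g(r, "subsystem")), character(1)),
    sourceModel = NA_character_, stringsAsFactors = FALSE)
  rxnDf$stoichiometry <- lapply(rxns, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s)) stop("reaction '", r$id, "' has no metabolites",
                         call. = FALSE)
    storage.mode(s) <- "double"
    s
  })
  modelId <- if (!is.null(doc$id)) as.character(doc$id) else
    tools::file_path_sans_ext(basename(path))
  rxnDf$sourceModel <- modelId
  refd <- unique(unlist(lapply(rxnDf$stoichiometry, names), use.names = FALSE))
  missing <- setdiff(refd, metDf$id)
  if (length(missing) > 0) {
    stop("model integrity error: reactions reference undeclared metabolites: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  TemplateModel(modelId = modelId,
                organism = if (!is.null(doc$organism)) as.character(doc$organism) else "",
                genes = geneDf, metabolites = metDf, reactions = rxnDf)
}

## ---- SBML L3 + FBC v2 -----------------------------------------------------

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sbmlSanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

## FBC association XML node -> GeneRule, using geneProduct id -> label map.
.fbcAssocToRule <- function(node, labels) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gp <- xml2::xml_attr(node, "geneProduct")
    id <- labels[[gp]]
    return(geneNode(if (is.null(id) || is.na(id)) gp else id))
  }
  kids <- xml2::xml_children(node)
  children <- lapply(kids, .fbcAssocToRule, labels = labels)
  if (nm == "and") {
    if (length(children) == 1L) children[[1L]] else andNode(children)
  } else if (nm == "or") {
    if (length(children) == 1L) children[[1L]] else orNode(children)
  } else {
    stop("unsupported FBC association element: ", nm, call. = FALSE)
  }
}

#' Read a model from SBML Level 3 with the FBC package
#'
#' Species compartments are taken from the `compartment` attribute; the
#' conventional `M_`/`R_`/`G_` SBML id prefixes are stripped. FBC
#' `geneProductAssociation` trees are converted to GPR strings (gene ids
#' taken from `fbc:label` when present). Reactions without a gene
#' association are loaded with an absent GPR and a warning is issued.
#'
#' @param path Path to an SBML `.xml` (optionally `.gz`) file.
#' @return A [TemplateModel-class].
#' @export
readTemplateSbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .SBML_NS, fbc = .FBC_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) {
    stop("not an SBML Level 3 document: ", path, call. = FALSE)
  }
  stripPrefix <- function(x, prefix) {
    ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
  }
  spNodes <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  if (length(spNodes) > 0) {
    spIds <- xml2::xml_attr(spNodes, "id")
    spComp <- xml2::xml_attr(spNodes, "compartment")
    fullIds <- stripPrefix(spIds, "M_")
    base <- ifelse(endsWith(fullIds, paste0("_", spComp)),
                   substr(fullIds, 1L, nchar(fullIds) - nchar(spComp) - 1L),
                   splitMetaboliteId(fullIds)$baseId)
    metDf <- data.frame(
      id = fullIds, baseId = base, compartment = spComp,
      name = xml2::xml_attr(spNodes, "name"),
      formula = xml2::xml_attr(spNodes, "fbc:chemicalFormula", ns = ns),
      charge = as.numeric(xml2::xml_attr(spNodes, "fbc:charge", ns = ns)),
      stringsAsFactors = FALSE)
    spLookup <- stats::setNames(fullIds, spIds)
  } else {
    metDf <- .emptyMetabolites()
    spLookup <- character(0)
  }

  gpNodes <- xml2::xml_find_all(
    model, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gpIds <- xml2::xml_attr(gpNodes, "fbc:id", ns = ns)
  gpLabels <- xml2::xml_attr(gpNodes, "fbc:label", ns = ns)
  gpLabels <- ifelse(is.na(gpLabels), stripPrefix(gpIds, "G_"), gpLabels)
  labels <- as.list(stats::setNames(gpLabels, gpIds))
  geneDf <- if (length(gpNodes) > 0) {
    data.frame(id = gpLabels, sequence = NA_character_,
               stringsAsFactors = FALSE)
  } else .emptyGenes()

  rxNodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  paramNodes <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  paramVals <- stats::setNames(as.numeric(xml2::xml_attr(paramNodes, "value")),
                               xml2::xml_attr(paramNodes, "id"))
  noGpr <- 0L
  rows <- lapply(rxNodes, function(rx) {
    rid <- stripPrefix(xml2::xml_attr(rx, "id"), "R_")
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
    getSide <- function(which, sign) {
      refs <- xml2::xml_find_all(rx, paste0("./s:", which, "/s:speciesReference"), ns)
      if (length(refs) == 0L) return(numeric(0))
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef,
                      as.character(spLookup[xml2::xml_attr(refs, "species")]))
    }
    stoich <- c(getSide("listOfReactants", -1), getSide("listOfProducts", +1))
    if (length(stoich) == 0L) {
      stop("SBML reaction '", rid, "' has no participants", call. = FALSE)
    }
    assoc <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation", ns)
    gpr <- NA_character_
    if (!inherits(assoc, "xml_missing")) {
      kids <- xml2::xml_children(assoc)
      if (length(kids) == 1L) {
        gpr <- renderGpr(.fbcAssocToRule(kids[[1L]], labels))
      }
    } else {
      noGpr <<- noGpr + 1L
    }
    lbRef <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns = ns)
    ubRef <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns = ns)
    lb <- if (!is.na(lbRef) && lbRef %in% names(paramVals)) paramVals[[lbRef]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ubRef) && ubRef %in% names(paramVals)) paramVals[[ubRef]]
          else 1000
    list(id = rid, name = xml2::xml_attr(rx, "name"), lowerBound = lb,
         upperBound = ub, reversible = rev, gpr = gpr, stoich = stoich)
  })
  rxnDf <- if (length(rows) > 0) {
    df <- data.frame(
      id = vapply(rows, `[[`, character(1), "id"),
      name = vapply(rows, function(r) as.character(r$name), character(1)),
      lowerBound = vapply(rows, `[[`, numeric(1), "lowerBound"),
      upperBound = vapply(rows, `[[`, numeric(1), "upperBound"),
      reversible = vapply(rows, `[[`, logical(1), "reversible"),
      gpr = vapply(rows, `[[`, character(1), "gpr"),
      subsystem = NA_character_, sourceModel = NA_character_,
      stringsAsFactors = FALSE)
    df$stoichiometry <- lapply(rows, `[[`, "stoich")
    df
  } else .emptyReactions()
  modelId <- xml2::xml_attr(model, "id")
  if (is.na(modelId)) modelId <- tools::file_path_sans_ext(basename(path))
  if (nrow(rxnDf) > 0) rxnDf$sourceModel <- modelId
  if (noGpr > 0L) {
    warning(noGpr, " reaction(s) without FBC gene association loaded with ",
            "absent GPR", call. = FALSE)
  }
  TemplateModel(modelId = modelId, genes = geneDf, metabolites = metDf,
                reactions = rxnDf)
}

#' Write a model as SBML Level 3 with FBC v2
#'
#' Serializes a [TemplateModel-class] or [DraftNetwork-class] as SBML
#' L3V1 + FBC v2: species per metabolite (`M_` prefix), `fbc:geneProduct`
#' per gene with the original id as `fbc:label`, flux bounds as shared
#' parameters, and each reaction's GPR as an `fbc:geneProductAssociation`.
#' Boundary (exchange/sink/demand) reactions are recognisable by their id
#' prefix, which is preserved.
#'
#' @param model A [TemplateModel-class] or [DraftNetwork-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeModelSbml <- function(model, path) {
  stopifnot(is(model, "TemplateModel"))
  rxn <- reactions(model)
  met <- metabolites(model)
  gen <- modelGenes(model)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = .SBML_NS, "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mid <- modelId(model)
  mnode <- xml2::xml_add_child(doc, "model",
                               id = .sbmlSanitize(if (is.na(mid)) "model" else mid),
                               "fbc:strict" = "false")
  comps <- sort(unique(met$compartment))
  if (length(comps) > 0) {
    lc <- xml2::xml_add_child(mnode, "listOfCompartments")
    for (cp in comps) {
      xml2::xml_add_child(lc, "compartment", id = .sbmlSanitize(cp),
                          constant = "true")
    }
  }
  if (nrow(met) > 0) {
    ls <- xml2::xml_add_child(mnode, "listOfSpecies")
    for (i in seq_len(nrow(met))) {
      attrs <- list(id = paste0("M_", .sbmlSanitize(met$id[i])),
                    compartment = .sbmlSanitize(met$compartment[i]),
                    hasOnlySubstanceUnits = "false",
                    boundaryCondition = "false", constant = "false")
      if (!is.na(met$name[i])) attrs$name <- met$name[i]
      if (!is.na(met$charge[i])) {
        attrs[["fbc:charge"]] <- format(met$charge[i], scientific = FALSE)
      }
      if (!is.na(met$formula[i])) attrs[["fbc:chemicalFormula"]] <- met$formula[i]
      do.call(xml2::xml_add_child, c(list(ls, "species"), attrs))
    }
  }
  bounds <- sort(unique(c(rxn$lowerBound, rxn$upperBound, 0)))
  boundId <- function(v) {
    paste0("B_", gsub("-", "m", gsub("\\.", "p", format(v, scientific = FALSE))))
  }
  lp <- xml2::xml_add_child(mnode, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(lp, "parameter", id = boundId(v),
                        value = format(v, scientific = FALSE, digits = 15),
                        constant = "true", sboTerm = "SBO:0000626")
  }
  if (nrow(gen) > 0) {
    lg <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (i in seq_len(nrow(gen))) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", .sbmlSanitize(gen$id[i])),
                          "fbc:label" = gen$id[i])
    }
  }
  lo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                      "fbc:type" = "maximize")
  geneRef <- function(id) paste0("G_", .sbmlSanitize(id))
  addAssoc <- function(parent, rule) {
    if (rule$kind == "GENE") {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = geneRef(rule$gene))
    } else {
      node <- xml2::xml_add_child(parent,
                                  if (rule$kind == "AND") "fbc:and" else "fbc:or")
      for (ch in rule$children) addAssoc(node, ch)
    }
  }
  lr <- xml2::xml_add_child(mnode, "listOfReactions")
  if (nrow(rxn) > 0) {
    for (i in seq_len(nrow(rxn))) {
      rnode <- xml2::xml_add_child(
        lr, "reaction", id = paste0("R_", .sbmlSanitize(rxn$id[i])),
        reversible = if (rxn$reversible[i]) "true" else "false",
        fast = "false",
        "fbc:lowerFluxBound" = boundId(rxn$lowerBound[i]),
        "fbc:upperFluxBound" = boundId(rxn$upperBound[i]))
      if (!is.na(rxn$name[i])) xml2::xml_attr(rnode, "name") <- rxn$name[i]
      s <- rxn$stoichiometry[[i]]
      react <- s[s < 0]; prod <- s[s > 0]
      if (length(react) > 0) {
        side <- xml2::xml_add_child(rnode, "listOfReactants")
        for (m in names(react)) {
          xml2::xml_add_child(side, "speciesReference",
                              species = paste0("M_", .sbmlSanitize(m)),
                              stoichiometry = format(abs(react[[m]]), digits = 15),
                              constant = "true")
        }
      }
      if (length(prod) > 0) {
        side <- xml2::xml_add_child(rnode, "listOfProducts")
        for (m in names(prod)) {
          xml2::xml_add_child(side, "speciesReference",
                              species = paste0("M_", .sbmlSanitize(m)),
                              stoichiometry = format(prod[[m]], digits = 15),
                              constant = "true")
        }
      }
      if (!is.na(rxn$gpr[i]) && nzchar(trimws(rxn$gpr[i]))) {
        rule <- parseGpr(rxn$gpr[i])
        if (!is.null(rule)) {
          assoc <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
          addAssoc(assoc, rule)
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname writeModelSbml
#' @param draft A [DraftNetwork-class].
#' @export
writeDraftSbml <- function(draft, path) {
  stopifnot(is(draft, "DraftNetwork"))
  writeModelSbml(draft, path)
}

#' Read a proteome FASTA file
#'
#' Record ids are the token before the first whitespace of each header.
#' Duplicate ids and empty files are rejected.
#'
#' @param path Amino-acid FASTA file (optionally gzipped).
#' @return A [Biostrings::AAStringSet] named by record id.
#' @export
readProteomeFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA record id(s): ", paste(head(dup, 3), collapse = ", "),
         call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Read a tabular homology-hits file
#'
#' Tab-separated, BLAST outfmt-6-like columns: query id, subject id,
#' percent identity, alignment length, e-value, bit score, query length.
#' Rows that fail numeric parsing are rejected with their line number.
#'
#' @param path Path to the hits table (optionally gzipped).
#' @return data.frame with columns `query`, `subject`, `identityPct`,
#'   `alnLength`, `evalue`, `bitscore`, `queryLength`.
#' @export
readHitsTable <- function(path) {
  txt <- .readTextMaybeGz(path)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(emptyHits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 7L)) {
    bad <- which(ncols != 7L)[1]
    stop("hits table format error at line ", bad, ": expected 7 tab-separated ",
         "columns, found ", ncols[bad], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop("hits table format error at line ", which(is.na(v))[1],
           ": non-numeric ", what, call. = FALSE)
    }
    v
  }
  data.frame(query = m[, 1], subject = m[, 2],
             identityPct = num(3, "percent identity"),
             alnLength = as.integer(num(4, "alignment length")),
             evalue = num(5, "e-value"), bitscore = num(6, "bit score"),
             queryLength = as.integer(num(7, "query length")),
             stringsAsFactors = FALSE)
}

emptyHits <- function() {
  data.frame(query = character(0), subject = character(0),
             identityPct = numeric(0), alnLength = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             queryLength = integer(0), stringsAsFactors = FALSE)
}
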