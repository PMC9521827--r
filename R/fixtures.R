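## Deterministic synthetic fixtures: template collections, query proteomes,
## COG annotation tables and a reference model, with ground truth computed
## by construction (before any pipeline code runs).

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification for a synthetic fixture
#'
#' Defines a synthetic template universe and query genome: `nTemplates`
#' template models with `reactionsPerTemplate` reactions and
#' `genesPerTemplate` genes each, GPR shapes drawn from
#' `gprShapeWeights` (every template carries at least one reaction of
#' each shape: single gene, OR-only, AND-only, mixed), `duplicateGroups`
#' planted duplicate pairs cycling through `duplicateTypes`, and a query
#' proteome containing a fraction `orthologIdentity` of each template's
#' proteins copied (optionally point-mutated at `mutationRate`) plus
#' `decoyQueryGenes` unrelated sequences. The reference model is the
#' expected draft with `referenceFpCount` reactions removed (planted
#' false positives) and `referenceFnCount` novel reactions added
#' (planted false negatives), so the fixture's target precision/recall/F1
#' are known in closed form.
#'
#' Same spec + same seed produces byte-identical fixture directories.
#'
#' @param seed Integer seed.
#' @param nTemplates,reactionsPerTemplate,genesPerTemplate Positive counts.
#' @param gprShapeWeights Named non-negative weights over
#'   `c("single", "or", "and", "mixed")`.
#' @param duplicateGroups Number of planted duplicate pairs (requires
#'   `reactionsPerTemplate >= duplicateGroups + 4`).
#' @param duplicateTypes Types cycled over planted pairs; subset of
#'   `c("reversibility", "protonation", "compartment")`. Compartment
#'   variants are planted as NON-mergeable under the default canonical
#'   key (compartments are part of the key).
#' @param orthologIdentity Fraction of template genes with a query
#'   ortholog, in \[0, 1\].
#' @param mutationRate Per-residue substitution rate for ortholog copies.
#' @param decoyQueryGenes Unrelated query sequences.
#' @param sequenceLength Protein length (>= 60 so the k-mer engine has no
#'   spurious matches at k = 12).
#' @param protonId Proton metabolite base id.
#' @param referenceFpCount,referenceFnCount Planted FP/FN sizes.
#' @return A `FixtureSpec` list.
#' @export
fixtureSpec <- function(seed = 1L, nTemplates = 3L,
                        reactionsPerTemplate = 25L, genesPerTemplate = 18L,
                        gprShapeWeights = c(single = 1, or = 1, and = 1,
                                            mixed = 1),
                        duplicateGroups = 3L,
                        duplicateTypes = c("reversibility", "protonation"),
                        orthologIdentity = 0.8, mutationRate = 0,
                        decoyQueryGenes = 5L, sequenceLength = 80L,
                        protonId = "h",
                        referenceFpCount = 5L, referenceFnCount = 5L) {
  stopifnot(nTemplates >= 1L, reactionsPerTemplate >= 4L,
            genesPerTemplate >= 3L, sequenceLength >= 60L,
            orthologIdentity >= 0, orthologIdentity <= 1,
            mutationRate >= 0, mutationRate < 1,
            all(duplicateTypes %in% c("reversibility", "protonation",
                                      "compartment")))
  stopifnot(all(names(gprShapeWeights) %in%
                  c("single", "or", "and", "mixed")),
            sum(gprShapeWeights) > 0)
  if (duplicateGroups > reactionsPerTemplate - 4L) {
    stop("inconsistent spec: duplicateGroups must be <= ",
         "reactionsPerTemplate - 4", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), nTemplates = as.integer(nTemplates),
                 reactionsPerTemplate = as.integer(reactionsPerTemplate),
                 genesPerTemplate = as.integer(genesPerTemplate),
                 gprShapeWeights = gprShapeWeights,
                 duplicateGroups = as.integer(duplicateGroups),
                 duplicateTypes = duplicateTypes,
                 orthologIdentity = orthologIdentity,
                 mutationRate = mutationRate,
                 decoyQueryGenes = as.integer(decoyQueryGenes),
                 sequenceLength = as.integer(sequenceLength),
                 protonId = protonId,
                 referenceFpCount = as.integer(referenceFpCount),
                 referenceFnCount = as.integer(referenceFnCount)),
            class = "FixtureSpec")
}

.randomSeq <- function(n) paste(sample(.AA20, n, replace = TRUE),
                                collapse = "")

#' Point-mutate amino-acid sequences
#'
#' Substitutes each residue independently with probability `rate` by a
#' residue drawn uniformly from the 20-letter alphabet (which may redraw
#' the original residue); length is preserved. Deterministic under
#' `seed`; with `seed = NULL` the current RNG stream is used.
#'
#' @param sequences Named character vector (or [Biostrings::AAStringSet]).
#' @param rate Substitution rate in \[0, 1).
#' @param seed Optional integer seed.
#' @return Named character vector of mutated sequences.
#' @export
mutateSequences <- function(sequences, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  seqs <- .asCharacterSeqs(sequences)
  doMutate <- function() {
    vapply(seqs, function(s) {
      if (rate == 0) return(s)
      chars <- strsplit(s, "")[[1]]
      hit <- stats::runif(length(chars)) < rate
      if (any(hit)) {
        chars[hit] <- sample(.AA20, sum(hit), replace = TRUE)
      }
      paste(chars, collapse = "")
    }, character(1))
  }
  if (is.null(seed)) doMutate() else withSeed(seed, doMutate())
}

## Jaccard distance by plain set arithmetic (generator-side truth).
.setJaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) 0 else 1 - length(intersect(a, b)) / u
}

#' Generate a synthetic fixture with known ground truth
#'
#' Builds the complete fixture in memory and, when `dir` is given, writes
#' it out: COBRA-JSON templates under `templates/`, the query proteome as
#' `query.faa`, per-organism COG tables under `cog/`, the reference model
#' as `reference.xml` and the ground truth as `ground_truth.json`.
#'
#' The ground truth is computed from the generator's own records — the
#' clause sets it planted, the ortholog subset it chose, the duplicate
#' pairs it inserted — not by running the reconstruction pipeline, so it
#' is an independent oracle for end-to-end tests. Its fields:
#' `orthologPairs` (template gene, query gene), `expectedSelected`
#' (reaction ids with at least one clause fully inside the planted
#' ortholog set), `plantedGroups` (duplicate pairs with type and
#' mergeable flag), `expectedDraft` (expected reaction ids after
#' deduplication), `expectedMerges`, `referenceIds`, closed-form
#' `precision`/`recall`/`f1` of the expected draft against the reference,
#' `expectedClosestOrder` (template organisms by metabolic-profile
#' distance from the query organism), and per-template bookkeeping
#' (`reactionIds`, `clauses`, `totalResidues`).
#'
#' @param spec A [fixtureSpec()].
#' @param dir Optional output directory (created if needed).
#' @return List with `templates`, `queryProteome`, `annotations`,
#'   `reference`, `truth`, `targetOrganism` and (when written) `dir`.
#' @export
generateFixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  res <- withSeed(spec$seed, .generateFixtureImpl(spec))
  if (!is.null(dir)) {
    res$dir <- writeFixture(res, dir)
  }
  res
}

.generateFixtureImpl <- function(spec) {
  Tn <- spec$nTemplates
  Rn <- spec$reactionsPerTemplate
  Gn <- spec$genesPerTemplate
  shapes <- c("single", "or", "and", "mixed")
  w <- spec$gprShapeWeights[shapes]
  w[is.na(w)] <- 0
  sharedMets <- sprintf("met%03d_c", 1:30)
  protonMet <- paste0(spec$protonId, "_c")

  templates <- vector("list", Tn)
  orthSets <- vector("list", Tn)     # per-template orthologged gene ids
  clausesByRxn <- list()             # reaction id -> list of clauses
  rxnShape <- character(0)           # reaction id -> shape
  rxnTemplate <- integer(0)          # reaction id -> template index

  mkClause <- function(genes) sort(genes)

  for (t in seq_len(Tn)) {
    geneIds <- sprintf("T%02dG%03d", t, seq_len(Gn))
    seqs <- vapply(geneIds, function(g) .randomSeq(spec$sequenceLength),
                   character(1))
    nOrth <- round(spec$orthologIdentity * Gn)
    orth <- if (nOrth > 0) sort(sample(geneIds, nOrth)) else character(0)
    orthSets[[t]] <- orth

    rxnIds <- sprintf("R%02d%03d", t, seq_len(Rn))
    stoich <- vector("list", Rn)
    gprs <- character(Rn)
    rev <- logical(Rn)
    for (j in seq_len(Rn)) {
      sig <- sprintf("u%02d%03d_c", t, j)
      nShared <- sample(2:3, 1L)
      ms <- sample(sharedMets, nShared)
      coefs <- as.numeric(sample(1:2, nShared + 1L, replace = TRUE))
      ## signature metabolite always a reactant; split shared mets
      nReact <- sample(seq_len(nShared), 1L)
      s <- stats::setNames(
        c(-coefs[1L], -coefs[seq_len(nReact) + 1L],
          if (nReact < nShared) coefs[(nReact + 2L):(nShared + 1L)]),
        c(sig, ms[seq_len(nReact)],
          if (nReact < nShared) ms[(nReact + 1L):nShared]))
      ## guarantee at least one product
      if (all(s < 0)) {
        extra <- setdiff(sharedMets, names(s))[1L]
        s[extra] <- 1
      }
      stoich[[j]] <- s
      shape <- if (j <= 4L) shapes[j] else
        sample(shapes, 1L, prob = w / sum(w))
      cl <- switch(shape,
        single = list(mkClause(sample(geneIds, 1L))),
        or = lapply(sample(geneIds, sample(2:3, 1L)), mkClause),
        and = list(mkClause(sample(geneIds, sample(2:3, 1L)))),
        mixed = {
          picks <- sample(geneIds, 3L)
          list(mkClause(picks[1:2]), mkClause(picks[3L]))
        })
      rid <- rxnIds[j]
      clausesByRxn[[rid]] <- cl
      rxnShape[rid] <- shape
      rxnTemplate[rid] <- t
      gprs[j] <- renderGpr(clausesToRule(.minimizeClauses(cl)))
      rev[j] <- stats::runif(1) < 0.3
    }
    rxnDf <- data.frame(
      id = rxnIds, name = paste("reaction", rxnIds),
      lowerBound = ifelse(rev, -1000, 0), upperBound = 1000,
      reversible = rev, gpr = gprs, subsystem = NA_character_,
      sourceModel = sprintf("tmpl%02d", t), stringsAsFactors = FALSE)
    rxnDf$stoichiometry <- stoich
    usedMets <- unique(unlist(lapply(stoich, names), use.names = FALSE))
    templates[[t]] <- TemplateModel(
      modelId = sprintf("tmpl%02d", t),
      organism = sprintf("organism%02d", t),
      genes = data.frame(id = geneIds, sequence = unname(seqs),
                         stringsAsFactors = FALSE),
      metabolites = .metaboliteTable(sort(usedMets)),
      reactions = rxnDf)
  }

  ## ---- planted duplicate groups ------------------------------------------
  plantedGroups <- list()
  if (spec$duplicateGroups > 0L) {
    if (length(orthSets[[1L]]) == 0L) {
      stop("cannot plant duplicate groups with orthologIdentity = 0",
           call. = FALSE)
    }
    for (d in seq_len(spec$duplicateGroups)) {
      type <- spec$duplicateTypes[((d - 1L) %% length(spec$duplicateTypes)) + 1L]
      baseT <- 1L
      baseJ <- 4L + d
      tmplBase <- templates[[baseT]]
      rxn <- reactions(tmplBase)
      baseId <- rxn$id[baseJ]
      ## force the base reaction satisfiable: single orthologged gene
      gBase <- sample(orthSets[[baseT]], 1L)
      rxn$gpr[baseJ] <- gBase
      clausesByRxn[[baseId]] <- list(mkClause(gBase))
      rxnShape[baseId] <- "single"
      templates[[baseT]]@reactions <- rxn

      vt <- ((d - 1L) %% Tn) + 1L
      if (length(orthSets[[vt]]) == 0L) vt <- baseT
      gVar <- sample(orthSets[[vt]], 1L)
      s <- rxn$stoichiometry[[baseJ]]
      vs <- switch(type,
        reversibility = -s,
        protonation = { s2 <- s; s2[protonMet] <- 1; s2 },
        compartment = stats::setNames(s, sub("_c$", "_p", names(s))))
      varId <- paste0(baseId, "v")
      varRow <- data.frame(
        id = varId, name = paste("reaction", varId),
        lowerBound = 0, upperBound = 1000, reversible = FALSE,
        gpr = gVar, subsystem = NA_character_,
        sourceModel = modelId(templates[[vt]]), stringsAsFactors = FALSE)
      varRow$stoichiometry <- list(vs)
      tv <- templates[[vt]]
      newRxn <- rbind(reactions(tv), varRow)
      newMets <- setdiff(names(vs), metabolites(tv)$id)
      newMetDf <- rbind(metabolites(tv), .metaboliteTable(newMets))
      newMetDf <- newMetDf[order(newMetDf$id), , drop = FALSE]
      rownames(newMetDf) <- NULL
      templates[[vt]] <- TemplateModel(
        modelId = modelId(tv), organism = organism(tv),
        genes = modelGenes(tv), metabolites = newMetDf, reactions = newRxn)
      clausesByRxn[[varId]] <- list(mkClause(gVar))
      rxnShape[varId] <- "single"
      rxnTemplate[varId] <- vt
      plantedGroups[[d]] <- list(
        members = c(baseId, varId), type = type,
        mergeable = type %in% c("reversibility", "protonation"))
    }
  }

  ## ---- query proteome -----------------------------------------------------
  orthAll <- unlist(orthSets, use.names = FALSE)
  geneSeq <- do.call(c, lapply(templates, function(tm) {
    stats::setNames(modelGenes(tm)$sequence, modelGenes(tm)$id)
  }))
  queryIds <- paste0("q_", orthAll)
  query <- stats::setNames(
    mutateSequences(geneSeq[orthAll], spec$mutationRate), queryIds)
  if (spec$decoyQueryGenes > 0L) {
    decoys <- stats::setNames(
      vapply(seq_len(spec$decoyQueryGenes),
             function(i) .randomSeq(spec$sequenceLength), character(1)),
      sprintf("qx%03d", seq_len(spec$decoyQueryGenes)))
    query <- c(query, decoys)
  }

  ## ---- ground truth -------------------------------------------------------
  orthByTemplate <- orthSets
  satisfiable <- function(rid) {
    t <- rxnTemplate[[rid]]
    any(vapply(clausesByRxn[[rid]], function(cl) {
      all(cl %in% orthByTemplate[[t]])
    }, logical(1)))
  }
  allRxnIds <- names(clausesByRxn)
  expectedSelected <- sort(allRxnIds[vapply(allRxnIds, satisfiable,
                                            logical(1))])
  dropped <- character(0)
  merges <- 0L
  for (gr in plantedGroups) {
    if (!gr$mergeable) next
    sel <- intersect(gr$members, expectedSelected)
    if (length(sel) > 1L) {
      dropped <- c(dropped, sort(sel)[-1L])
      merges <- merges + (length(sel) - 1L)
    }
  }
  expectedDraft <- setdiff(expectedSelected, dropped)

  ## ---- reference model ----------------------------------------------------
  nFp <- min(spec$referenceFpCount, max(length(expectedDraft) - 1L, 0L))
  fpIds <- if (nFp > 0) sort(sample(expectedDraft, nFp)) else character(0)
  refKeep <- setdiff(expectedDraft, fpIds)
  refRxnPool <- do.call(rbind, lapply(templates, reactions))
  refRxn <- refRxnPool[match(refKeep, refRxnPool$id), , drop = FALSE]
  if (spec$referenceFnCount > 0L) {
    fnRows <- lapply(seq_len(spec$referenceFnCount), function(i) {
      row <- data.frame(
        id = sprintf("RF%03d", i), name = sprintf("reference extra %d", i),
        lowerBound = 0, upperBound = 1000, reversible = FALSE,
        gpr = sprintf("refg%03d", i), subsystem = NA_character_,
        sourceModel = "reference", stringsAsFactors = FALSE)
      row$stoichiometry <- list(stats::setNames(
        c(-1, 1), sprintf(c("rf%03da_c", "rf%03db_c"), i)))
      row
    })
    refRxn <- rbind(refRxn, do.call(rbind, fnRows))
  }
  refRxn$sourceModel <- "reference"
  refMets <- .metaboliteTable(
    sort(unique(unlist(lapply(refRxn$stoichiometry, names),
                       use.names = FALSE))))
  refGenes <- unique(unlist(lapply(refRxn$gpr, function(g) {
    if (is.na(g)) character(0) else ruleGenes(parseGpr(g))
  }), use.names = FALSE))
  reference <- TemplateModel(
    modelId = "reference", organism = "queryorg",
    genes = data.frame(id = sort(refGenes), sequence = NA_character_,
                       stringsAsFactors = FALSE),
    metabolites = refMets, reactions = refRxn)
  tp <- length(refKeep)
  fp <- length(fpIds)
  fn <- spec$referenceFnCount
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0

  ## ---- COG annotations ----------------------------------------------------
  targetOrganism <- "queryorg"
  cogUniverse <- sprintf("COG%04d", 1:200)
  queryCogs <- cogUniverse[1:40]
  metCats <- c("C", "E", "F", "G", "H", "I", "P", "Q")
  orgCogSets <- list()
  orgCogSets[[targetOrganism]] <- queryCogs
  for (t in seq_len(Tn)) {
    shared <- queryCogs[seq_len(max(40L - 3L * (t - 1L), 5L))]
    uniq <- cogUniverse[(40L + 10L * (t - 1L) + 1L):(40L + 10L * t)]
    orgCogSets[[sprintf("organism%02d", t)]] <- c(shared, uniq)
  }
  annotations <- lapply(names(orgCogSets), function(org) {
    cogs <- orgCogSets[[org]]
    df <- data.frame(
      organism = org,
      proteinId = sprintf("%s_p%04d", org, seq_along(cogs)),
      cogId = cogs,
      category = sample(metCats, length(cogs), replace = TRUE),
      stringsAsFactors = FALSE)
    if (org == sprintf("organism%02d", Tn)) {
      ## non-metabolism rows that a correct reader must filter out
      df <- rbind(df, data.frame(
        organism = org,
        proteinId = sprintf("%s_s%04d", org, 1:5),
        cogId = sprintf("COG9%03d", 1:5),
        category = "S", stringsAsFactors = FALSE))
    }
    df
  })
  names(annotations) <- names(orgCogSets)
  tmplOrgs <- sprintf("organism%02d", seq_len(Tn))
  distToQuery <- vapply(tmplOrgs, function(org) {
    keep <- vapply(annotations[[org]]$category, function(cc) {
      any(strsplit(cc, "")[[1]] %in% metCats)
    }, logical(1))
    .setJaccard(queryCogs, unique(annotations[[org]]$cogId[keep]))
  }, numeric(1))
  expectedClosestOrder <- tmplOrgs[order(distToQuery, tmplOrgs)]

  truth <- list(
    orthologPairs = data.frame(template = orthAll,
                               query = paste0("q_", orthAll),
                               stringsAsFactors = FALSE),
    reactionIds = lapply(templates, function(tm) reactions(tm)$id),
    clauses = clausesByRxn,
    shapes = rxnShape,
    expectedSelected = expectedSelected,
    plantedGroups = plantedGroups,
    expectedMerges = merges,
    expectedDraft = expectedDraft,
    referenceIds = sort(refRxn$id),
    plantedFp = fpIds,
    precision = precision, recall = recall, f1 = f1,
    expectedClosestOrder = expectedClosestOrder,
    totalResidues = sum(nchar(query)))

  names(templates) <- vapply(templates, modelId, character(1))
  ## in-memory annotations mirror what readCogAnnotation() returns
  ## (METABOLISM rows only); the raw tables incl. non-metabolism rows are
  ## what gets written to disk, exercising the reader's filter
  annotationsMet <- lapply(annotations, function(df) {
    keep <- vapply(strsplit(df$category, ""), function(l) {
      any(l %in% metCats)
    }, logical(1))
    out <- df[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  list(templates = templates, queryProteome = query,
       annotations = annotationsMet, annotationsRaw = annotations,
       reference = reference, truth = truth,
       targetOrganism = targetOrganism)
}

#' Write a generated fixture to disk
#'
#' Layout: `templates/<id>.json` (COBRA JSON), `query.faa`,
#' `cog/<organism>.tsv`, `reference.xml` (SBML L3+FBC) and
#' `ground_truth.json`.
#'
#' @param fixture Output of [generateFixture()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(file.path(dir, "templates"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "cog"), showWarnings = FALSE)
  for (tm in fixture$templates) {
    writeTemplateJson(tm, file.path(dir, "templates",
                                    paste0(modelId(tm), ".json")))
  }
  q <- fixture$queryProteome
  writeLines(paste0(">", names(q), "\n", unname(q)),
             file.path(dir, "query.faa"))
  raw <- if (is.null(fixture$annotationsRaw)) fixture$annotations
         else fixture$annotationsRaw
  for (org in names(raw)) {
    df <- raw[[org]]
    utils::write.table(
      df[, c("proteinId", "cogId", "category")],
      file.path(dir, "cog", paste0(org, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = c("protein_id", "cog_id", "category"))
  }
  writeModelSbml(fixture$reference, file.path(dir, "reference.xml"))
  truth <- fixture$truth
  truth$clauses <- NULL  # nested ragged lists; regenerate in memory instead
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a TemplateModel as COBRA/BiGG JSON
#'
#' Inverse of [readTemplateJson()]; gene records carry the non-standard
#' `protein_sequence` field when sequences are present.
#'
#' @param model A [TemplateModel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTemplateJson <- function(model, path) {
  met <- metabolites(model)
  rxn <- reactions(model)
  gen <- modelGenes(model)
  noNa <- function(x) if (length(x) == 1L && is.na(x)) NULL else x
  doc <- list(
    id = modelId(model),
    organism = organism(model),
    metabolites = lapply(seq_len(nrow(met)), function(i) {
      Filter(Negate(is.null), list(
        id = met$id[i], name = noNa(met$name[i]),
        compartment = met$compartment[i],
        formula = noNa(met$formula[i]), charge = noNa(met$charge[i])))
    }),
    reactions = lapply(seq_len(nrow(rxn)), function(i) {
      Filter(Negate(is.null), list(
        id = rxn$id[i], name = noNa(rxn$name[i]),
        metabolites = as.list(rxn$stoichiometry[[i]]),
        lower_bound = rxn$lowerBound[i], upper_bound = rxn$upperBound[i],
        gene_reaction_rule = if (is.na(rxn$gpr[i])) "" else rxn$gpr[i],
        subsystem = noNa(rxn$subsystem[i])))
    }),
    genes = lapply(seq_len(nrow(gen)), function(i) {
      Filter(Negate(is.null), list(
        id = gen$id[i], protein_sequence = noNa(gen$sequence[i])))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read all template JSON models in a directory
#' @param dir Directory containing `*.json` template models.
#' @return Named list of [TemplateModel-class] objects.
#' @export
readTemplateDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no template JSON files in ", dir,
                                call. = FALSE)
  templates <- lapply(files, readTemplateJson)
  names(templates) <- vapply(templates, modelId, character(1))
  templates
}
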