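## Independent oracles and small generators shared across tests. The
## oracles deliberately avoid the code paths they check: rule evaluation
## goes through base R's logical eval, set problems through plain loops.

## Brute-force rule evaluation: translate the tree to an R logical
## expression and eval() it under the assignment.
ttEval <- function(rule, present) {
  expr <- function(r) {
    if (r$kind == "GENE") {
      return(if (r$gene %in% present) "TRUE" else "FALSE")
    }
    op <- if (r$kind == "AND") " & " else " | "
    paste0("(", paste(vapply(r$children, expr, character(1)),
                      collapse = op), ")")
  }
  eval(parse(text = expr(rule)))
}

## All subsets of a gene universe.
allAssignments <- function(genes) {
  n <- length(genes)
  lapply(seq_len(2^n) - 1L, function(mask) {
    genes[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
  })
}

## Random GeneRule over a gene pool.
randomRule <- function(genes, depth = 3L) {
  if (depth == 0L || runif(1) < 0.35) {
    return(geneNode(sample(genes, 1L)))
  }
  kind <- sample(c("AND", "OR"), 1L)
  kids <- lapply(seq_len(sample(2:3, 1L)), function(i) {
    randomRule(genes, depth - 1L)
  })
  if (kind == "AND") andNode(kids) else orNode(kids)
}

## DNF satisfaction: some clause fully inside the present set.
clauseSatisfied <- function(clauses, present) {
  any(vapply(clauses, function(cl) all(cl %in% present), logical(1)))
}

## Random hits table over given query/subject id pools.
randomHits <- function(n, queries, subjects, tieHeavy = FALSE) {
  qlen <- sample(50:200, n, replace = TRUE)
  aln <- pmin(qlen, sample(20:200, n, replace = TRUE))
  data.frame(
    query = sample(queries, n, replace = TRUE),
    subject = sample(subjects, n, replace = TRUE),
    identityPct = runif(n, 20, 100),
    alnLength = aln,
    evalue = 10^(if (tieHeavy) sample(c(-50, -30, -10), n, replace = TRUE)
                 else runif(n, -60, 0)),
    bitscore = if (tieHeavy) sample(c(40, 60, 90), n, replace = TRUE)
               else runif(n, 10, 200),
    queryLength = qlen,
    stringsAsFactors = FALSE)
}

## Minimal reaction data.frame in the universe layout.
makeUniverse <- function(ids, gprs, stoich, reversible = NULL,
                         source = "tmplA") {
  n <- length(ids)
  if (is.null(reversible)) reversible <- rep(FALSE, n)
  df <- data.frame(id = ids, name = ids,
                   lowerBound = ifelse(reversible, -1000, 0),
                   upperBound = 1000, reversible = reversible,
                   gpr = gprs, subsystem = NA_character_,
                   sourceModel = rep_len(source, n),
                   stringsAsFactors = FALSE)
  df$stoichiometry <- stoich
  df
}

## A tiny hand-rolled template model for IO tests.
tinyModel <- function(id = "tiny") {
  mets <- data.frame(
    id = c("glc__D_c", "g6p_c", "atp_c", "adp_c", "h_c"),
    baseId = c("glc__D", "g6p", "atp", "adp", "h"),
    compartment = "c",
    name = c("D-glucose", "G6P", "ATP", "ADP", "proton"),
    formula = c("C6H12O6", "C6H11O9P", NA, NA, "H"),
    charge = c(0, -2, -4, -3, 1),
    stringsAsFactors = FALSE)
  rxn <- data.frame(
    id = c("HEX1", "EX_glc__D_c"),
    name = c("hexokinase", "glucose exchange"),
    lowerBound = c(0, -1000), upperBound = c(1000, 1000),
    reversible = c(FALSE, TRUE),
    gpr = c("(g1 and g2) or g3", NA),
    subsystem = c("glycolysis", NA),
    sourceModel = id, stringsAsFactors = FALSE)
  rxn$stoichiometry <- list(
    c(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1),
    c(glc__D_c = -1))
  TemplateModel(
    modelId = id, organism = "tinyorg",
    genes = data.frame(id = c("g1", "g2", "g3"),
                       sequence = c("MKTAYIAKQR", "MDNAAQVLRE", "MSNQPLLRAG"),
                       stringsAsFactors = FALSE),
    metabolites = mets, reactions = rxn)
}
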