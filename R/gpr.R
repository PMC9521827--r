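## Gene-protein-reaction (GPR) Boolean rules: parsing, evaluation,
## OR-decomposition into isozyme clauses, and re-writing onto a query genome.

#' Construct a GeneRule node
#'
#' A `GeneRule` is a finite Boolean tree over gene identifiers. Leaves are
#' `GENE` nodes; internal nodes are `AND` (enzyme complex: all subunits
#' required) or `OR` (isozymes: any one suffices) with at least two children.
#'
#' @param gene Gene identifier (single string).
#' @return A `GeneRule` object.
#' @examples
#' geneNode("b0001")
#' andNode(list(geneNode("a"), geneNode("b")))
#' @export
geneNode <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  structure(list(kind = "GENE", gene = gene), class = "GeneRule")
}

#' @rdname geneNode
#' @param children List of at least two `GeneRule` children.
#' @export
andNode <- function(children) {
  stopifnot(is.list(children), length(children) >= 2L)
  structure(list(kind = "AND", children = children), class = "GeneRule")
}

#' @rdname geneNode
#' @export
orNode <- function(children) {
  stopifnot(is.list(children), length(children) >= 2L)
  structure(list(kind = "OR", children = children), class = "GeneRule")
}

#' @export
print.GeneRule <- function(x, ...) {
  cat("GeneRule:", renderGpr(x), "\n")
  invisible(x)
}

.gprTokenize <- function(text) {
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  toks
}

#' Parse a GPR rule string
#'
#' Parses the COBRA/BiGG GPR dialect: gene tokens combined with the
#' case-insensitive keywords `and` / `or` and parentheses. `AND` binds
#' tighter than `OR`. Gene tokens are any run of non-whitespace,
#' non-parenthesis characters that is not a bare keyword (BiGG gene ids
#' contain dots and dashes). Empty or whitespace-only input yields `NULL`
#' (no rule).
#'
#' @param text GPR string, possibly empty.
#' @return A `GeneRule`, or `NULL` for an empty rule.
#' @examples
#' parseGpr("(g1 and g2) or g3")
#' @export
parseGpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text)) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .gprTokenize(text)
  if (length(toks) == 0L) return(NULL)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L

  peek <- function() if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NA_character_
  advance <- function() st$pos <- st$pos + 1L
  fail <- function(msg) {
    stop(sprintf("GPR parse error at token %d ('%s'): %s",
                 st$pos, if (is.na(peek())) "<end>" else peek(), msg), call. = FALSE)
  }

  parseFactor <- function() {
    tok <- peek()
    if (is.na(tok)) fail("expected gene or '('")
    if (tok == "(") {
      advance()
      node <- parseExpr()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      advance()
      return(node)
    }
    if (tok == ")") fail("unexpected ')'")
    if (tolower(tok) %in% c("and", "or")) fail("dangling operator")
    advance()
    geneNode(tok)
  }

  parseTerm <- function() {
    parts <- list(parseFactor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      parts[[length(parts) + 1L]] <- parseFactor()
    }
    if (length(parts) == 1L) parts[[1L]] else andNode(parts)
  }

  parseExpr <- function() {
    parts <- list(parseTerm())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      parts[[length(parts) + 1L]] <- parseTerm()
    }
    if (length(parts) == 1L) parts[[1L]] else orNode(parts)
  }

  node <- parseExpr()
  if (!is.na(peek())) fail("trailing input")
  node
}

#' Render a GeneRule as a GPR string
#'
#' Lowercase operators, minimal parentheses (parentheses only around an OR
#' nested inside an AND, since AND binds tighter).
#'
#' @param rule A `GeneRule` or `NULL`.
#' @return A string; `""` for `NULL`.
#' @export
renderGpr <- function(rule) {
  if (is.null(rule)) return("")
  switch(rule$kind,
    GENE = rule$gene,
    AND = paste(vapply(rule$children, function(ch) {
      s <- renderGpr(ch)
      if (ch$kind == "OR") paste0("(", s, ")") else s
    }, character(1)), collapse = " and "),
    OR = paste(vapply(rule$children, renderGpr, character(1)),
               collapse = " or "),
    stop("unknown GeneRule kind: ", rule$kind)
  )
}

#' Evaluate a GeneRule against a set of present genes
#'
#' Standard Boolean semantics: a `GENE` leaf is true iff its id is in
#' `present`; `AND` is true iff all children are true (a complex needs all
#' its subunits); `OR` is true iff any child is true (one isozyme is
#' enough).
#'
#' @param rule A `GeneRule` (not `NULL`).
#' @param present Character vector of present gene ids.
#' @return Logical scalar.
#' @examples
#' evaluateRule(parseGpr("g1 and g2"), "g1")   # FALSE
#' evaluateRule(parseGpr("g1 or g2"), "g2")    # TRUE
#' @export
evaluateRule <- function(rule, present) {
  stopifnot(inherits(rule, "GeneRule"))
  switch(rule$kind,
    GENE = rule$gene %in% present,
    AND = all(vapply(rule$children, evaluateRule, logical(1), present = present)),
    OR = any(vapply(rule$children, evaluateRule, logical(1), present = present))
  )
}

#' Gene identifiers referenced by a rule
#' @param rule A `GeneRule` or `NULL`.
#' @return Sorted unique character vector of gene ids.
#' @export
ruleGenes <- function(rule) {
  if (is.null(rule)) return(character(0))
  collect <- function(r) {
    if (r$kind == "GENE") return(r$gene)
    unlist(lapply(r$children, collect), use.names = FALSE)
  }
  sort(unique(collect(rule)))
}

## Remove duplicate clauses and clauses that are supersets of another clause
## (absorption), yielding the unique minimal antichain representation.
.minimizeClauses <- function(clauses) {
  clauses <- lapply(clauses, function(cl) sort(unique(cl)))
  keys <- vapply(clauses, paste, character(1), collapse = "\r")
  clauses <- clauses[!duplicated(keys)]
  if (length(clauses) <= 1L) return(clauses)
  sizes <- lengths(clauses)
  ord <- order(sizes)
  clauses <- clauses[ord]
  keep <- rep(TRUE, length(clauses))
  for (i in seq_along(clauses)) {
    if (!keep[i]) next
    for (j in seq_along(clauses)) {
      if (j == i || !keep[j]) next
      if (length(clauses[[i]]) <= length(clauses[[j]]) &&
          all(clauses[[i]] %in% clauses[[j]])) {
        keep[j] <- FALSE
      }
    }
  }
  clauses <- clauses[keep]
  keys <- vapply(clauses, paste, character(1), collapse = "\r")
  clauses[order(keys)]
}

#' Decompose a GeneRule by OR into isozyme clauses
#'
#' Expands the rule into minimal disjunctive normal form: a list of gene-id
#' sets (isozyme clauses) such that the rule is true under an assignment iff
#' at least one clause has all its genes present. Clauses are deduplicated
#' and absorbed (no clause is a superset of another), making the output
#' canonical: sorted clauses of sorted gene ids.
#'
#' Expansion is capped at `maxClauses` intermediate clauses; rules that
#' exceed it fail loudly rather than being silently truncated.
#'
#' @param rule A `GeneRule` (not `NULL`).
#' @param maxClauses Clause-explosion guard (default 10000).
#' @return List of character vectors (each a clause).
#' @examples
#' decomposeOr(parseGpr("a and (b or c)"))  # list(c("a","b"), c("a","c"))
#' @export
decomposeOr <- function(rule, maxClauses = 10000L) {
  stopifnot(inherits(rule, "GeneRule"))
  expand <- function(r) {
    switch(r$kind,
      GENE = list(r$gene),
      OR = {
        out <- unlist(lapply(r$children, expand), recursive = FALSE)
        if (length(out) > maxClauses) {
          stop("DNF expansion exceeds ", maxClauses, " clauses", call. = FALSE)
        }
        out
      },
      AND = {
        acc <- list(character(0))
        for (ch in r$children) {
          chClauses <- expand(ch)
          acc <- unlist(lapply(acc, function(a) {
            lapply(chClauses, function(b) unique(c(a, b)))
          }), recursive = FALSE)
          if (length(acc) > maxClauses) {
            stop("DNF expansion exceeds ", maxClauses, " clauses", call. = FALSE)
          }
        }
        acc
      }
    )
  }
  .minimizeClauses(expand(rule))
}

## Build a GeneRule back from a clause list (OR of ANDs).
clausesToRule <- function(clauses) {
  if (length(clauses) == 0L) return(NULL)
  terms <- lapply(clauses, function(cl) {
    if (length(cl) == 1L) geneNode(cl) else andNode(lapply(cl, geneNode))
  })
  if (length(terms) == 1L) terms[[1L]] else orNode(terms)
}

#' Re-write a template GPR onto query genes via an ortholog map
#'
#' Decomposes the rule into isozyme clauses and re-writes each clause onto
#' the query genome using the template-to-query ortholog map. In strict
#' mode only clauses whose genes are all mapped survive ("complete" GPR);
#' in non-strict mode a clause with at least one mapped gene contributes
#' its mapped subset as a partial conjunction. When one template gene maps
#' to several query genes, every combination of per-gene choices yields a
#' clause. Surviving clauses are re-joined by OR and minimized by
#' absorption.
#'
#' @param rule A `GeneRule` (not `NULL`).
#' @param orthologs Named list mapping template gene id to a character
#'   vector of query gene ids (a multimap), or an [OrthologMap].
#' @param strict Logical; drop clauses with any unmapped gene (default
#'   `TRUE`).
#' @param maxClauses Clause-explosion guard.
#' @return `NULL` when no clause survives, otherwise a list with elements
#'   `rule` (the assembled `GeneRule` over query gene ids) and `complete`
#'   (`TRUE` iff at least one fully mapped clause survives; always `TRUE`
#'   in strict mode). Completeness is reaction-level metadata, kept out of
#'   the Boolean tree.
#' @examples
#' r <- parseGpr("(a and b) or c")
#' assemblePartialGpr(r, list(c = "qc"))
#' @export
assemblePartialGpr <- function(rule, orthologs, strict = TRUE,
                               maxClauses = 10000L) {
  stopifnot(inherits(rule, "GeneRule"))
  if (is(orthologs, "OrthologMap")) orthologs <- orthologMultimap(orthologs)
  stopifnot(is.list(orthologs))
  clauses <- decomposeOr(rule, maxClauses = maxClauses)
  outClauses <- list()
  anyComplete <- FALSE
  for (cl in clauses) {
    mapped <- cl[cl %in% names(orthologs)]
    complete <- length(mapped) == length(cl)
    if (strict && !complete) next
    if (length(mapped) == 0L) next
    if (complete) anyComplete <- TRUE
    choices <- orthologs[mapped]
    combos <- expand.grid(choices, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    if (nrow(combos) > maxClauses) {
      stop("ortholog expansion exceeds ", maxClauses, " clauses", call. = FALSE)
    }
    for (i in seq_len(nrow(combos))) {
      outClauses[[length(outClauses) + 1L]] <-
        unique(as.character(unlist(combos[i, ], use.names = FALSE)))
    }
  }
  if (length(outClauses) == 0L) return(NULL)
  outClauses <- .minimizeClauses(outClauses)
  list(rule = clausesToRule(outClauses), complete = anyComplete)
}
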