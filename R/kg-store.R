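# Default prefix map shared by the whole package.  Subjects/predicates are
# stored as prefixed names; the Turtle writer declares these prefixes.
kg_default_prefixes <- function() {
  c(
    kg   = "https://example.org/kgsdl/",
    rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    xsd  = "http://www.w3.org/2001/XMLSchema#"
  )
}

#' Create an empty in-memory triple store
#'
#' The store is a mutable environment holding parallel vectors of
#' subject / predicate / object / object-type plus a logical write clock.
#' All timestamps in the package are ticks of this clock, never wall-clock,
#' so campaign traces are reproducible.
#'
#' @param seed integer seed controlling the deterministic IRI minting
#'   sequence (a small LCG, not R's RNG, so minting never perturbs
#'   simulation randomness).
#' @return an object of class `kg_graph`.
#' @export
kg_new <- function(seed = 1L) {
  g <- new.env(parent = emptyenv())
  g$s <- character(0)
  g$p <- character(0)
  g$o <- character(0)
  g$otype <- character(0)   # "iri","string","double","integer","boolean","timestamp"
  g$tick <- integer(0)
  g$live <- logical(0)
  g$n <- 0L
  g$clock <- 0L
  g$index <- new.env(parent = emptyenv())       # triple key -> row
  g$last_write <- new.env(parent = emptyenv())  # subject -> last tick
  g$prefixes <- kg_default_prefixes()
  g$mint_state <- as.integer(seed) %% 2147483647L
  if (g$mint_state <= 0L) g$mint_state <- g$mint_state + 2147483646L
  g$mint_counter <- 0L
  class(g) <- "kg_graph"
  g
}

#' @export
print.kg_graph <- function(x, ...) {
  cat(sprintf("<kg_graph> %d triples, clock tick %d\n", kg_size(x), x$clock))
  invisible(x)
}

#' Number of (live) triples in a graph
#' @param g a `kg_graph`
#' @return integer count
#' @export
kg_size <- function(g) sum(g$live[seq_len(g$n)])

kg_key <- function(s, p, o, otype) paste(s, p, o, otype, sep = "\r")

# Lehmer LCG used only for IRI minting; independent of .Random.seed.
kg_mint_hex <- function(g, ndigits) {
  out <- character(ndigits)
  for (i in seq_len(ndigits)) {
    g$mint_state <- as.integer((as.double(g$mint_state) * 48271) %% 2147483647)
    out[i] <- sprintf("%x", g$mint_state %% 16L)
  }
  paste(out, collapse = "")
}

#' Mint a fresh IRI for an instance of a class
#'
#' IRIs follow `kg:<Class>_<uuid>` where the uuid-like suffix comes from a
#' seeded deterministic sequence, so provenance exports are byte-reproducible.
#'
#' @param g a `kg_graph`
#' @param class_name concept name, e.g. `"ReactionExperiment"`
#' @return prefixed IRI string
#' @export
kg_mint_iri <- function(g, class_name) {
  stopifnot(is.character(class_name), nzchar(class_name))
  g$mint_counter <- g$mint_counter + 1L
  sprintf("kg:%s_%s-%04x", class_name, kg_mint_hex(g, 12L), g$mint_counter %% 65536L)
}

kg_valid_iri <- function(x) {
  is.character(x) & nzchar(x) & grepl("^[A-Za-z][A-Za-z0-9]*:\\S+$", x) & !grepl("[\"<>{}|\\\\^`[:space:]]", x)
}

valid_otypes <- c("iri", "string", "double", "integer", "boolean", "timestamp")

#' Add triples to a graph
#'
#' Duplicate triples are ignored (set semantics).  Every call advances the
#' store-wide logical clock by one and stamps new triples with it; the
#' subject's last-write tick is updated, which is what drives the derivation
#' engine's staleness check.
#'
#' @param g a `kg_graph`
#' @param s,p character vectors of subject and predicate prefixed IRIs
#' @param o character vector of object IRIs or literal lexical forms
#' @param otype object types, one of `"iri"`, `"string"`, `"double"`,
#'   `"integer"`, `"boolean"`, `"timestamp"`
#' @return the graph, invisibly
#' @export
kg_add <- function(g, s, p, o, otype = "iri") {
  m <- max(length(s), length(p), length(o), length(otype))
  s <- rep_len(as.character(s), m); p <- rep_len(as.character(p), m)
  o <- rep_len(as.character(o), m); otype <- rep_len(as.character(otype), m)
  bad <- !kg_valid_iri(s)
  if (any(bad)) stop("malformed subject IRI in triple: ", s[which(bad)[1]], " ", p[which(bad)[1]], " ", o[which(bad)[1]])
  bad <- !kg_valid_iri(p)
  if (any(bad)) stop("malformed predicate IRI in triple: ", s[which(bad)[1]], " ", p[which(bad)[1]], " ", o[which(bad)[1]])
  bad <- !otype %in% valid_otypes
  if (any(bad)) stop("unknown literal datatype '", otype[which(bad)[1]], "' in triple about ", s[which(bad)[1]])
  bad <- otype == "iri" & !kg_valid_iri(o)
  if (any(bad)) stop("malformed object IRI in triple: ", s[which(bad)[1]], " ", p[which(bad)[1]], " ", o[which(bad)[1]])

  g$clock <- g$clock + 1L
  for (i in seq_len(m)) {
    key <- kg_key(s[i], p[i], o[i], otype[i])
    row <- g$index[[key]]
    if (!is.null(row) && g$live[row]) next
    g$n <- g$n + 1L
    if (g$n > length(g$s)) {
      newcap <- max(64L, 2L * length(g$s))
      length(g$s) <- newcap; length(g$p) <- newcap; length(g$o) <- newcap
      length(g$otype) <- newcap; length(g$tick) <- newcap; length(g$live) <- newcap
    }
    g$s[g$n] <- s[i]; g$p[g$n] <- p[i]; g$o[g$n] <- o[i]
    g$otype[g$n] <- otype[i]; g$tick[g$n] <- g$clock; g$live[g$n] <- TRUE
    g$index[[key]] <- g$n
    g$last_write[[s[i]]] <- g$clock
  }
  invisible(g)
}

#' Remove all triples matching a pattern (NULL = wildcard)
#' @param g a `kg_graph`
#' @param s,p,o pattern components; `NULL` matches anything
#' @return number of triples removed, invisibly
#' @export
kg_remove <- function(g, s = NULL, p = NULL, o = NULL) {
  idx <- kg_match_rows(g, s, p, o)
  for (row in idx) {
    g$live[row] <- FALSE
    rm(list = kg_key(g$s[row], g$p[row], g$o[row], g$otype[row]), envir = g$index)
  }
  if (length(idx)) {
    g$clock <- g$clock + 1L
    for (subj in unique(g$s[idx])) g$last_write[[subj]] <- g$clock
  }
  invisible(length(idx))
}

#' Replace the object(s) of (s, p, *) with a single new value
#' @inheritParams kg_add
#' @return the graph, invisibly
#' @export
kg_set <- function(g, s, p, o, otype = "iri") {
  kg_remove(g, s = s, p = p)
  kg_add(g, s, p, o, otype)
}

kg_match_rows <- function(g, s = NULL, p = NULL, o = NULL) {
  n <- g$n
  if (n == 0L) return(integer(0))
  keep <- g$live[seq_len(n)]
  if (!is.null(s)) keep <- keep & g$s[seq_len(n)] %in% s
  if (!is.null(p)) keep <- keep & g$p[seq_len(n)] %in% p
  if (!is.null(o)) keep <- keep & g$o[seq_len(n)] %in% o
  which(keep)
}

#' Pattern query over a graph
#'
#' `NULL` components are wildcards. Results are returned as a data frame
#' sorted lexicographically by subject, predicate, object so that query
#' output is deterministic.
#'
#' @inheritParams kg_remove
#' @return data.frame with columns `s`, `p`, `o`, `otype`, `tick`
#' @export
kg_query <- function(g, s = NULL, p = NULL, o = NULL) {
  idx <- kg_match_rows(g, s, p, o)
  out <- data.frame(
    s = g$s[idx], p = g$p[idx], o = g$o[idx],
    otype = g$otype[idx], tick = g$tick[idx],
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 1L) {
    ord <- order(out$s, out$p, out$o, method = "radix")
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Containment test for a fully ground triple
#' @inheritParams kg_add
#' @return logical
#' @export
kg_has <- function(g, s, p, o, otype = "iri") {
  row <- g$index[[kg_key(s, p, o, otype)]]
  !is.null(row) && g$live[row]
}

#' Single object lookup (s, p, ?) returning the literal value, parsed
#'
#' @param g a `kg_graph`
#' @param s,p subject/predicate
#' @param default value returned when no triple matches
#' @return parsed R value (numeric/logical/character) or `default`
#' @export
kg_value <- function(g, s, p, default = NULL) {
  hits <- kg_query(g, s = s, p = p)
  if (nrow(hits) == 0L) return(default)
  kg_parse_literal(hits$o[1], hits$otype[1])
}

#' All objects of (s, p, ?) parsed to R values
#' @inheritParams kg_value
#' @return vector (possibly empty)
#' @export
kg_values <- function(g, s, p) {
  hits <- kg_query(g, s = s, p = p)
  if (nrow(hits) == 0L) return(character(0))
  vapply(seq_len(nrow(hits)), function(i) as.character(hits$o[i]), character(1))
}

kg_parse_literal <- function(o, otype) {
  switch(otype,
    double = as.numeric(o),
    integer = as.integer(o),
    timestamp = as.integer(o),
    boolean = identical(o, "true"),
    o
  )
}

#' Format an R double as a triple-store lexical form (full precision)
#' @param x numeric
#' @return character
#' @export
kg_lex_double <- function(x) sprintf("%.17g", x)

#' Last-write tick of an entity (its subject position), 0 if never written
#' @param g a `kg_graph`
#' @param iri entity IRI
#' @return integer tick
#' @export
kg_last_write <- function(g, iri) {
  t <- g$last_write[[iri]]
  if (is.null(t)) 0L else t
}

#' Does an entity exist (appear as a subject) in the graph?
#' @inheritParams kg_last_write
#' @return logical
#' @export
kg_exists <- function(g, iri) kg_last_write(g, iri) > 0L

#' Validate ReactionExperiment status invariants over a whole graph
#'
#' Checks, for every `kg:ReactionExperiment`, that performance indicators
#' are attached iff the experiment is `Analysed`, and that lab/equipment
#' assignments are present iff status is at least `Assigned`.
#'
#' @param g a `kg_graph`
#' @return character vector of violation messages (empty when valid)
#' @export
kg_validate_experiments <- function(g) {
  exps <- kg_query(g, p = "rdf:type", o = "kg:ReactionExperiment")$s
  bad <- character(0)
  for (e in exps) {
    status <- kg_value(g, e, "kg:hasStatus", default = NA_character_)
    has_pi <- nrow(kg_query(g, s = e, p = "kg:hasPerformanceIndicator")) > 0L
    assigned <- nrow(kg_query(g, s = e, p = "kg:isAssignedTo")) > 0L
    if (is.na(status)) { bad <- c(bad, paste0(e, ": missing status")); next }
    if (has_pi != identical(status, "Analysed"))
      bad <- c(bad, paste0(e, ": indicators present iff Analysed violated (status=", status, ")"))
    if (assigned && status == "Proposed")
      bad <- c(bad, paste0(e, ": assignment present while still Proposed"))
    if (!assigned && status %in% c("Assigned", "Executed", "Analysed"))
      bad <- c(bad, paste0(e, ": status ", status, " without assignment"))
  }
  bad
}
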