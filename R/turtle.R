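# Turtle export/import for provenance graphs.
#
# The writer emits one triple per line using prefixed names and typed
# literals; the reader accepts exactly that subset (plus comments and blank
# lines).  This is deliberately the dialect the package itself produces --
# enough for round-tripping provenance, not a general W3C Turtle engine.

xsd_dtype <- c(
  string = "xsd:string", double = "xsd:double", integer = "xsd:integer",
  boolean = "xsd:boolean", timestamp = "xsd:integer"
)

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    res <- ""
    j <- 1L; n <- nchar(s)
    while (j <= n) {
      ch <- substr(s, j, j)
      if (ch == "\\" && j < n) {
        nxt <- substr(s, j + 1L, j + 1L)
        res <- paste0(res, switch(nxt, n = "\n", r = "\r", t = "\t", "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        res <- paste0(res, ch)
        j <- j + 1L
      }
    }
    out[i] <- res
  }
  out
}

ttl_term <- function(o, otype) {
  if (otype == "iri") return(o)
  dt <- xsd_dtype[[otype]]
  sprintf("\"%s\"^^%s", ttl_escape(o), dt)
}

#' Serialise a graph to a Turtle document
#'
#' @param g a `kg_graph`
#' @param path file path to write (UTF-8)
#' @return `path`, invisibly
#' @export
kg_serialize_turtle <- function(g, path) {
  hdr <- sprintf("@prefix %s: <%s> .", names(g$prefixes), unname(g$prefixes))
  df <- kg_query(g)
  lines <- hdr
  if (nrow(df) > 0L) {
    body <- sprintf("%s %s %s .", df$s, df$p,
                    mapply(ttl_term, df$o, df$otype, USE.NAMES = FALSE))
    lines <- c(hdr, "", body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Parse a Turtle document produced by [kg_serialize_turtle()]
#'
#' @param path Turtle file
#' @param seed seed for the new graph's IRI minting sequence
#' @return a `kg_graph`
#' @export
kg_parse_turtle <- function(path, seed = 1L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  g <- kg_new(seed = seed)
  prefixes <- character(0)
  rx_prefix <- "^@prefix\\s+([A-Za-z][A-Za-z0-9]*):\\s+<([^>]*)>\\s*\\.\\s*$"
  rx_lit <- "^(\\S+)\\s+(\\S+)\\s+\"(.*)\"\\^\\^(xsd:[A-Za-z]+)\\s*\\.\\s*$"
  rx_iri <- "^(\\S+)\\s+(\\S+)\\s+(\\S+)\\s*\\.\\s*$"
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    if (grepl(rx_prefix, line)) {
      m <- regmatches(line, regexec(rx_prefix, line))[[1]]
      prefixes[m[2]] <- m[3]
      next
    }
    if (grepl(rx_lit, line)) {
      m <- regmatches(line, regexec(rx_lit, line))[[1]]
      otype <- switch(m[5],
        "xsd:string" = "string", "xsd:double" = "double",
        "xsd:integer" = "integer", "xsd:boolean" = "boolean",
        stop(sprintf("line %d: unsupported datatype %s", i, m[5])))
      kg_add(g, m[2], m[3], ttl_unescape(m[4]), otype)
      next
    }
    if (grepl(rx_iri, line)) {
      m <- regmatches(line, regexec(rx_iri, line))[[1]]
      kg_add(g, m[2], m[3], m[4], "iri")
      next
    }
    stop(sprintf("Turtle parse error at line %d: %s", i, lines[i]))
  }
  if (length(prefixes)) g$prefixes <- prefixes
  g
}

#' Set-of-triples equality of two graphs
#' @param a,b `kg_graph` objects
#' @return logical
#' @export
kg_identical <- function(a, b) {
  da <- kg_query(a); db <- kg_query(b)
  if (nrow(da) != nrow(db)) return(FALSE)
  key <- function(d) sort(paste(d$s, d$p, d$o, d$otype, sep = "\r"))
  identical(key(da), key(db))
}
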