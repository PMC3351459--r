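#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules associate genes with the reaction they catalyze using the
#' conventional boolean string grammar: gene identifiers combined with
#' \code{and} (protein complexes: every subunit is required) and \code{or}
#' (isozymes: any one enzyme suffices), with parentheses for grouping.
#' \code{or} binds looser than \code{and}, so \code{"g1 and g2 or g3"} parses
#' as \code{(g1 and g2) or g3}. Keywords are case-insensitive; \code{&} and
#' \code{|} are accepted as synonyms.
#'
#' @param text a single GPR rule string.
#' @return an object of class \code{gpr}: a nested list with \code{kind}
#'   \code{"gene"} (leaf, with a \code{gene} identifier) or \code{"and"} /
#'   \code{"or"} (with a \code{children} list of two or more subtrees).
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' gpr_to_string(parse_gpr("g1 AND (g2 OR g3)"))
#' @seealso [gpr_to_string()], [gpr_genes()], [eval_gpr()]
#' @export
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("GPR rule must be a single nonempty string", call. = FALSE)

  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks$type))
    stop(sprintf("GPR parse error: unexpected token '%s' at position %d",
                 st$toks$text[st$pos], st$toks$at[st$pos]), call. = FALSE)
  tree
}

gpr_tokenize <- function(text) {
  type <- character(0); txt <- character(0); at <- integer(0)
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { type <- c(type, "lpar"); txt <- c(txt, "("); at <- c(at, i); i <- i + 1L; next }
    if (ch == ")") { type <- c(type, "rpar"); txt <- c(txt, ")"); at <- c(at, i); i <- i + 1L; next }
    if (ch == "&") { type <- c(type, "and"); txt <- c(txt, "&"); at <- c(at, i); i <- i + 1L; next }
    if (ch == "|") { type <- c(type, "or"); txt <- c(txt, "|"); at <- c(at, i); i <- i + 1L; next }
    m <- regmatches(substr(text, i, n), regexpr("^[A-Za-z0-9_.:-]+", substr(text, i, n)))
    if (length(m) == 0L)
      stop(sprintf("GPR parse error: stray character '%s' at position %d", ch, i),
           call. = FALSE)
    low <- tolower(m)
    type <- c(type, if (low == "and") "and" else if (low == "or") "or" else "gene")
    txt <- c(txt, m); at <- c(at, i)
    i <- i + nchar(m)
  }
  if (length(type) == 0L)
    stop("GPR parse error: no tokens", call. = FALSE)
  list(type = type, text = txt, at = at)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks$type)) "eof" else st$toks$type[st$pos]
}

gpr_parse_or <- function(st) {
  children <- list(gpr_parse_and(st))
  while (gpr_peek(st) == "or") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_and(st)))
  }
  gpr_node("or", children)
}

gpr_parse_and <- function(st) {
  children <- list(gpr_parse_atom(st))
  while (gpr_peek(st) == "and") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_atom(st)))
  }
  gpr_node("and", children)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (tk == "gene") {
    g <- st$toks$text[st$pos]
    st$pos <- st$pos + 1L
    return(structure(list(kind = "gene", gene = g), class = "gpr"))
  }
  if (tk == "lpar") {
    open_at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (gpr_peek(st) != "rpar")
      stop(sprintf("GPR parse error: unbalanced '(' opened at position %d", open_at),
           call. = FALSE)
    st$pos <- st$pos + 1L
    return(inner)
  }
  pos <- if (st$pos <= length(st$toks$at)) st$toks$at[st$pos] else nchar(paste(st$toks$text, collapse = " "))
  stop(sprintf("GPR parse error: expected gene or '(' at position %d", pos),
       call. = FALSE)
}

# collapse single-child wrappers; flatten nested same-operator nodes so every
# internal node has >= 2 children
gpr_node <- function(kind, children) {
  if (length(children) == 1L) return(children[[1L]])
  flat <- list()
  for (ch in children) {
    if (!is.null(ch$kind) && ch$kind == kind)
      flat <- c(flat, ch$children)
    else
      flat <- c(flat, list(ch))
  }
  structure(list(kind = kind, children = flat), class = "gpr")
}

#' Canonical string form of a GPR tree
#'
#' Produces the canonical serialization: lowercase keywords, explicit
#' parentheses around \code{or} groups nested inside \code{and}. Parsing the
#' result reproduces the same tree (\code{parse_gpr} is a left inverse).
#'
#' @param gpr a \code{gpr} object from [parse_gpr()].
#' @return a single string.
#' @export
gpr_to_string <- function(gpr) {
  stopifnot(inherits(gpr, "gpr"))
  render <- function(node, top) {
    if (node$kind == "gene") return(node$gene)
    sep <- if (node$kind == "and") " and " else " or "
    s <- paste(vapply(node$children, render, "", top = FALSE),
               collapse = sep)
    # every nested operator group is parenthesized (the cobra convention)
    if (top) s else paste0("(", s, ")")
  }
  render(gpr, TRUE)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a GPR tree
#'
#' @param gpr a \code{gpr} object.
#' @return character vector of unique gene identifiers, in first-appearance
#'   order.
#' @export
gpr_genes <- function(gpr) {
  stopifnot(inherits(gpr, "gpr"))
  walk <- function(node) {
    if (node$kind == "gene") return(node$gene)
    unlist(lapply(node$children, walk))
  }
  unique(walk(gpr))
}

#' Evaluate a GPR tree against gene expression values
#'
#' Aggregates gene-level expression into a reaction-level value: an \code{or}
#' node sums its children (isozyme capacities add) and an \code{and} node takes
#' the minimum (a complex is limited by its scarcest subunit). Genes absent
#' from \code{values} are treated as unmeasured and dropped, so missing probes
#' never create artificial bottlenecks; a tree whose genes are all unmeasured
#' evaluates to \code{NA}.
#'
#' @param gpr a \code{gpr} object.
#' @param values named numeric vector of gene expression (linear scale).
#' @return a single numeric value, or \code{NA} if no gene is measured.
#' @export
eval_gpr <- function(gpr, values) {
  stopifnot(inherits(gpr, "gpr"))
  walk <- function(node) {
    if (node$kind == "gene") {
      v <- values[node$gene]
      return(if (is.na(v)) NA_real_ else unname(v))
    }
    ch <- vapply(node$children, walk, numeric(1))
    ch <- ch[!is.na(ch)]
    if (length(ch) == 0L) return(NA_real_)
    if (node$kind == "or") sum(ch) else min(ch)
  }
  walk(gpr)
}
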