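#' Parse a Boolean gene-protein-reaction (GPR) rule
#'
#' Rules use gene identifiers combined with `and` / `or` (case-insensitive)
#' and parentheses, e.g. `"(g1 and g2) or g3"`. `and` binds tighter than
#' `or`. The result is an abstract syntax tree of nested lists: a leaf is
#' `list(op = "leaf", gene = <id>)`; internal nodes are
#' `list(op = "and"/"or", children = <list of >= 2 nodes>)`.
#'
#' @param text rule string.
#' @return rule AST.
#' @export
parse_gene_rule <- function(text) {
  tokens <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  if (!length(tokens)) stop("empty gene rule")
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  parse_or <- function() {
    kids <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance(); kids <- c(kids, list(parse_and()))
    }
    if (length(kids) == 1L) kids[[1]] else list(op = "or", children = kids)
  }
  parse_and <- function() {
    kids <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance(); kids <- c(kids, list(parse_atom()))
    }
    if (length(kids) == 1L) kids[[1]] else list(op = "and", children = kids)
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.na(tok)) stop("malformed gene rule: unexpected end in '", text, "'")
    if (tok == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")")
        stop("malformed gene rule: missing ')' in '", text, "'")
      advance()
      return(node)
    }
    if (tok %in% c(")") || tolower(tok) %in% c("and", "or"))
      stop("malformed gene rule: unexpected '", tok, "' in '", text, "'")
    advance()
    list(op = "leaf", gene = tok)
  }
  ast <- parse_or()
  if (pos <= length(tokens))
    stop("malformed gene rule: trailing tokens in '", text, "'")
  ast
}

#' Deparse a GPR rule AST back to text
#'
#' @param ast a rule AST from [parse_gene_rule()].
#' @return rule string (fully parenthesized below the top level).
#' @export
deparse_gene_rule <- function(ast) {
  if (ast$op == "leaf") return(ast$gene)
  parts <- vapply(ast$children, function(ch) {
    s <- deparse_gene_rule(ch)
    if (ch$op != "leaf") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", ast$op, " "))
}

rule_genes <- function(ast) {
  if (ast$op == "leaf") return(ast$gene)
  unique(unlist(lapply(ast$children, rule_genes)))
}

## Evaluate a rule over a samples x genes expression matrix: OR -> sum of
## children, AND -> elementwise minimum, applied recursively per sample.
eval_gene_rule <- function(ast, XG, missing = c("error", "zero")) {
  missing <- match.arg(missing)
  if (ast$op == "leaf") {
    j <- match(ast$gene, colnames(XG))
    if (is.na(j)) {
      if (missing == "error") stop("gene not in expression data: ", ast$gene)
      warning("gene not in expression data, treated as 0: ", ast$gene)
      return(rep(0, nrow(XG)))
    }
    return(XG[, j])
  }
  vals <- lapply(ast$children, eval_gene_rule, XG = XG, missing = missing)
  if (ast$op == "or") Reduce(`+`, vals) else Reduce(pmin, vals)
}

#' Map gene expression to reaction-level expression via GPR rules
#'
#' For each reaction with a gene rule, per-sample reaction expression is
#' computed by evaluating the rule on the expression matrix: `or` nodes sum
#' their children (isozymes add capacity) and `and` nodes take the
#' elementwise minimum (complex subunits limit capacity), recursively.
#' Reactions without a rule get a zero column and are flagged in the
#' `"no_rule"` attribute of the result.
#'
#' @param XG numeric samples x genes matrix with gene ids as column names.
#' @param net a [metabolic_network()] carrying gene rules.
#' @param missing what to do when a rule references a gene absent from
#'   `XG`: `"error"` (default) or `"zero"` (treat the leaf as 0 with a
#'   warning).
#' @return samples x reactions matrix (columns named by reaction id) with
#'   attribute `no_rule`, the integer indices of reactions lacking a rule.
#' @export
map_expression_to_reactions <- function(XG, net, missing = c("error", "zero")) {
  missing <- match.arg(missing)
  XG <- as.matrix(XG)
  if (is.null(colnames(XG))) stop("expression matrix must have gene ids as colnames")
  if (anyDuplicated(colnames(XG))) stop("duplicate gene ids in expression matrix")
  n <- length(net$reaction_ids)
  out <- matrix(0, nrow(XG), n, dimnames = list(rownames(XG), net$reaction_ids))
  no_rule <- integer(0)
  for (r in seq_len(n)) {
    rule <- net$gene_rules[[r]]
    if (is.null(rule)) { no_rule <- c(no_rule, r); next }
    out[, r] <- eval_gene_rule(rule, XG, missing = missing)
  }
  attr(out, "no_rule") <- no_rule
  out
}
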