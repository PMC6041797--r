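#' Construct a metabolic network
#'
#' A metabolic network holds the exchange stoichiometric matrix `S` over the
#' *internal* (balanceable) metabolites only, together with per-reaction
#' reversibility flags, flux bounds, optional subsystem labels and optional
#' gene-protein-reaction (GPR) rules. `S` has one row per internal metabolite
#' and one column per reaction; `S[m, r]` is the stoichiometric coefficient
#' with which reaction `r` produces (positive) or consumes (negative)
#' metabolite `m`. External metabolites cannot be balanced and are excluded
#' at construction time.
#'
#' @param reaction_ids character vector of unique reaction identifiers.
#' @param metabolite_ids character vector of unique internal metabolite ids.
#' @param S numeric matrix, `length(metabolite_ids)` rows by
#'   `length(reaction_ids)` columns.
#' @param reversible logical vector per reaction.
#' @param lb,ub numeric flux bounds per reaction (used by [fba()]). Defaults:
#'   0 (irreversible) or -1000 for `lb`, 1000 for `ub`.
#' @param subsystem optional character vector of subsystem labels (`NA` where
#'   unassigned).
#' @param gene_rules optional list of GPR rule ASTs (see [parse_gene_rule()]),
#'   `NULL` entries where no rule is attached.
#'
#' @return An object of class `"metabolic_network"`.
#' @export
metabolic_network <- function(reaction_ids, metabolite_ids, S,
                              reversible = rep(FALSE, length(reaction_ids)),
                              lb = NULL, ub = NULL,
                              subsystem = NULL, gene_rules = NULL) {
  reaction_ids <- as.character(reaction_ids)
  metabolite_ids <- as.character(metabolite_ids)
  S <- as.matrix(S)
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction ids: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "))
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "))
  if (length(reaction_ids) == 0L) stop("empty network: no reactions")
  if (nrow(S) != length(metabolite_ids) || ncol(S) != length(reaction_ids))
    stop("S must be ", length(metabolite_ids), " x ", length(reaction_ids))
  reversible <- as.logical(reversible)
  if (length(reversible) != length(reaction_ids))
    stop("reversible must have one entry per reaction")
  if (is.null(lb)) lb <- ifelse(reversible, -1000, 0)
  if (is.null(ub)) ub <- rep(1000, length(reaction_ids))
  if (length(lb) != length(reaction_ids) || length(ub) != length(reaction_ids))
    stop("bounds must have one entry per reaction")
  if (any(lb > ub)) stop("lower bound exceeds upper bound for reaction(s): ",
                         paste(reaction_ids[lb > ub], collapse = ", "))
  if (any(!reversible & lb < 0))
    stop("irreversible reactions must have lb >= 0: ",
         paste(reaction_ids[!reversible & lb < 0], collapse = ", "))
  if (is.null(subsystem)) subsystem <- rep(NA_character_, length(reaction_ids))
  if (is.null(gene_rules)) gene_rules <- vector("list", length(reaction_ids))
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  structure(list(
    reaction_ids = reaction_ids,
    metabolite_ids = metabolite_ids,
    S = S,
    reversible = reversible,
    lb = as.numeric(lb),
    ub = as.numeric(ub),
    subsystem = as.character(subsystem),
    gene_rules = gene_rules
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network: ", length(x$reaction_ids), " reactions, ",
      length(x$metabolite_ids), " internal metabolites\n", sep = "")
  cat("  reversible: ", sum(x$reversible), "; with gene rule: ",
      sum(!vapply(x$gene_rules, is.null, logical(1))), "\n", sep = "")
  subs <- unique(x$subsystem[!is.na(x$subsystem)])
  if (length(subs))
    cat("  subsystems: ", paste(subs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.metabolic_network <- function(x) dim(x$S)

## ---- reaction equation parsing ("2 A + B -> C", "<->" reversible) ----

parse_equation <- function(eq, line = NA) {
  rev <- grepl("<->", eq, fixed = TRUE)
  arrow <- if (rev) "<->" else "->"
  if (!grepl(arrow, eq, fixed = TRUE))
    stop("malformed equation", if (!is.na(line)) paste0(" at line ", line),
         ": ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(s) {
    s <- trimws(s)
    if (s == "") return(list(mets = character(0), coef = numeric(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    coef <- numeric(length(terms)); mets <- character(length(terms))
    for (i in seq_along(terms)) {
      parts <- strsplit(terms[i], "[[:space:]]+")[[1]]
      if (length(parts) == 2L && !is.na(suppressWarnings(as.numeric(parts[1])))) {
        coef[i] <- as.numeric(parts[1]); mets[i] <- parts[2]
      } else if (length(parts) == 1L) {
        coef[i] <- 1; mets[i] <- parts[1]
      } else stop("malformed term", if (!is.na(line)) paste0(" at line ", line),
                  ": '", terms[i], "'")
    }
    list(mets = mets, coef = coef)
  }
  list(lhs = parse_side(sides[1]), rhs = parse_side(sides[2]), reversible = rev)
}

#' Read a metabolic network from the tabular (TSV) dialect
#'
#' The dialect has a header line and the tab-separated columns
#' `reaction_id`, `equation`, `reversible`, `lb`, `ub`, `subsystem`,
#' `gene_rule` (the last four optional / allowed empty). Equations use
#' `2 A + B -> C` syntax with `<->` marking reversible reactions; an empty
#' side (`-> A` or `B ->`) denotes exchange with the environment. Metabolites
#' may also be declared external explicitly with a leading comment line
#' `# external: m1 m2 ...`; external metabolites are dropped from the rows of
#' `S`. Missing bounds default to `lb = 0` (irreversible) or `-1000`
#' (reversible) and `ub = 1000`.
#'
#' @param path path to a TSV file.
#' @return A [metabolic_network()].
#' @export
read_network_tsv <- function(path) {
  lines <- readLines(path)
  external <- character(0)
  ext_lines <- grep("^#[[:space:]]*external:", lines)
  for (i in ext_lines)
    external <- c(external, strsplit(trimws(sub("^#[[:space:]]*external:", "",
                                                lines[i])), "[[:space:],]+")[[1]])
  lines_keep <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines_keep) < 2L) stop("empty network file: ", path)
  header <- strsplit(lines_keep[1], "\t", fixed = TRUE)[[1]]
  need <- c("reaction_id", "equation")
  if (!all(need %in% header))
    stop("TSV header must contain columns 'reaction_id' and 'equation'")
  col <- function(fields, name) {
    i <- match(name, header)
    if (is.na(i) || i > length(fields)) NA_character_ else fields[i]
  }
  n <- length(lines_keep) - 1L
  rid <- character(n); revf <- logical(n)
  lb <- rep(NA_real_, n); ub <- rep(NA_real_, n)
  subsys <- rep(NA_character_, n); rules <- vector("list", n)
  parsed <- vector("list", n)
  for (k in seq_len(n)) {
    ln <- k + 1L
    fields <- strsplit(lines_keep[ln], "\t", fixed = TRUE)[[1]]
    rid[k] <- col(fields, "reaction_id")
    eq <- col(fields, "equation")
    if (is.na(rid[k]) || is.na(eq))
      stop("malformed line ", ln, ": missing reaction_id or equation")
    parsed[[k]] <- parse_equation(eq, line = ln)
    rv <- col(fields, "reversible")
    revf[k] <- parsed[[k]]$reversible ||
      (!is.na(rv) && tolower(trimws(rv)) %in% c("true", "1", "yes"))
    v <- col(fields, "lb"); if (!is.na(v) && nzchar(trimws(v))) lb[k] <- as.numeric(v)
    v <- col(fields, "ub"); if (!is.na(v) && nzchar(trimws(v))) ub[k] <- as.numeric(v)
    v <- col(fields, "subsystem")
    if (!is.na(v) && nzchar(trimws(v))) subsys[k] <- trimws(v)
    v <- col(fields, "gene_rule")
    if (!is.na(v) && nzchar(trimws(v))) rules[[k]] <- parse_gene_rule(v)
  }
  mets <- unique(unlist(lapply(parsed, function(p) c(p$lhs$mets, p$rhs$mets))))
  internal <- setdiff(mets, external)
  S <- matrix(0, length(internal), n, dimnames = list(internal, rid))
  for (k in seq_len(n)) {
    p <- parsed[[k]]
    for (i in seq_along(p$lhs$mets)) {
      m <- p$lhs$mets[i]
      if (m %in% internal) S[m, k] <- S[m, k] - p$lhs$coef[i]
    }
    for (i in seq_along(p$rhs$mets)) {
      m <- p$rhs$mets[i]
      if (m %in% internal) S[m, k] <- S[m, k] + p$rhs$coef[i]
    }
  }
  lb[is.na(lb)] <- ifelse(revf[is.na(lb)], -1000, 0)
  ub[is.na(ub)] <- 1000
  metabolic_network(rid, internal, S, revf, lb, ub, subsys, rules)
}

#' Write a metabolic network in the TSV dialect
#'
#' Inverse of [read_network_tsv()] for networks whose stoichiometry is
#' expressible in the equation syntax (any network built by this package).
#' Metabolites that appear in no row of `S` cannot occur, so all written
#' metabolites are internal and no `# external:` line is emitted.
#'
#' @param net a [metabolic_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  fmt_side <- function(mets, coef) {
    if (!length(mets)) return("")
    paste(ifelse(coef == 1, mets, paste(format(coef, trim = TRUE), mets)),
          collapse = " + ")
  }
  rows <- character(length(net$reaction_ids))
  for (k in seq_along(net$reaction_ids)) {
    col <- net$S[, k]
    lhs <- which(col < 0); rhs <- which(col > 0)
    eq <- paste(fmt_side(net$metabolite_ids[lhs], -col[lhs]),
                if (net$reversible[k]) "<->" else "->",
                fmt_side(net$metabolite_ids[rhs], col[rhs]))
    rule <- net$gene_rules[[k]]
    rows[k] <- paste(net$reaction_ids[k], trimws(eq),
                     tolower(net$reversible[k]),
                     format(net$lb[k], trim = TRUE),
                     format(net$ub[k], trim = TRUE),
                     ifelse(is.na(net$subsystem[k]), "", net$subsystem[k]),
                     if (is.null(rule)) "" else deparse_gene_rule(rule),
                     sep = "\t")
  }
  writeLines(c(paste("reaction_id", "equation", "reversible", "lb", "ub",
                     "subsystem", "gene_rule", sep = "\t"), rows), path)
  invisible(path)
}

#' Split reversible reactions into forward/backward irreversible pairs
#'
#' Every reversible reaction `r` becomes two irreversible columns with
#' stoichiometry `S[, r]` and `-S[, r]`. The returned mapping allows net
#' fluxes in the original space to be recovered as forward minus backward.
#'
#' @param net a [metabolic_network()].
#' @return A list with elements `network` (the split, all-irreversible
#'   network) and `mapping` (data frame with columns `reaction` (original
#'   index), `forward`, `backward` (split-space column indices; `backward`
#'   is `NA` for originally irreversible reactions)).
#' @export
split_reversible <- function(net) {
  n <- length(net$reaction_ids)
  fwd <- integer(n); bwd <- rep(NA_integer_, n)
  cols <- list(); ids <- character(0); k <- 0L
  for (r in seq_len(n)) {
    k <- k + 1L; fwd[r] <- k
    cols[[k]] <- net$S[, r, drop = TRUE]
    ids[k] <- net$reaction_ids[r]
    if (net$reversible[r]) {
      k <- k + 1L; bwd[r] <- k
      cols[[k]] <- -net$S[, r, drop = TRUE]
      ids[k] <- paste0(net$reaction_ids[r], "_rev")
    }
  }
  Ssp <- do.call(cbind, cols)
  if (is.null(dim(Ssp))) Ssp <- matrix(Ssp, nrow = length(net$metabolite_ids))
  split_net <- metabolic_network(ids, net$metabolite_ids, Ssp,
                                 reversible = rep(FALSE, k),
                                 lb = rep(0, k),
                                 ub = rep(1000, k))
  list(network = split_net,
       mapping = data.frame(reaction = seq_len(n), forward = fwd,
                            backward = bwd))
}

#' Recombine a split-space flux vector into net fluxes
#'
#' @param v_split numeric vector in the split (all-irreversible) space.
#' @param mapping the mapping returned by [split_reversible()].
#' @return numeric vector of net fluxes (forward minus backward) in the
#'   original reaction order.
#' @export
recombine_fluxes <- function(v_split, mapping) {
  v <- v_split[mapping$forward]
  has_b <- !is.na(mapping$backward)
  v[has_b] <- v[has_b] - v_split[mapping$backward[has_b]]
  unname(v)
}

#' Select reaction columns by subsystem label or explicit ids
#'
#' @param net a [metabolic_network()].
#' @param selector either a single subsystem label or a character vector of
#'   reaction ids.
#' @return sorted integer indices into `net$reaction_ids`.
#' @export
subsystem_columns <- function(net, selector) {
  if (length(selector) == 1L && selector %in% net$subsystem) {
    idx <- which(net$subsystem == selector)
  } else if (all(selector %in% net$reaction_ids)) {
    idx <- match(selector, net$reaction_ids)
  } else {
    bad <- setdiff(selector, net$reaction_ids)
    stop("selector matches no subsystem label or reaction ids (unknown: ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  if (!length(idx)) stop("empty subsystem selection")
  sort(unique(idx))
}
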