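#' Read a metabolic network from an SBML file
#'
#' Supports SBML Level 2 and Level 3 core, with optional `fbc`
#' gene-product associations and flux bounds. Species flagged
#' `boundaryCondition="true"` are external and excluded from the rows of
#' `S`. Reaction order is document order. Reversibility comes from the
#' `reversible` attribute; bounds from `fbc` bound parameters when
#' present, otherwise the defaults `lb = 0` (irreversible) / `-1000`
#' (reversible) and `ub = 1000`.
#'
#' @param path path to an SBML file.
#' @return a [metabolic_network()].
#' @export
read_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure: ",
                                           conditionMessage(e)))
  ln <- function(node, name)
    xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
  species <- ln(doc, "species")
  if (!length(species)) stop("empty network: no species in ", path)
  sp_id <- xml2::xml_attr(species, "id")
  boundary <- tolower(ifelse(is.na(xml2::xml_attr(species, "boundaryCondition")),
                             "false", xml2::xml_attr(species, "boundaryCondition")))
  internal <- sp_id[boundary != "true"]

  ## fbc bound parameters (id -> value)
  params <- ln(doc, "parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                             xml2::xml_attr(params, "id"))

  reactions <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (!length(reactions)) stop("empty network: no reactions in ", path)
  rid <- xml2::xml_attr(reactions, "id")
  n <- length(rid)
  revf <- logical(n); lb <- rep(NA_real_, n); ub <- rep(NA_real_, n)
  rules <- vector("list", n)
  S <- matrix(0, length(internal), n, dimnames = list(internal, rid))
  for (k in seq_len(n)) {
    rx <- reactions[[k]]
    revf[k] <- tolower(ifelse(is.na(xml2::xml_attr(rx, "reversible")), "true",
                              xml2::xml_attr(rx, "reversible"))) == "true"
    add_side <- function(list_name, sgn) {
      side <- xml2::xml_find_first(rx, paste0("./*[local-name()='",
                                              list_name, "']"))
      if (inherits(side, "xml_missing")) return(invisible())
      refs <- xml2::xml_find_all(side, "./*[local-name()='speciesReference']")
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (sid %in% internal) S[sid, k] <<- S[sid, k] + sgn * st
      }
    }
    add_side("listOfReactants", -1)
    add_side("listOfProducts", +1)
    lbid <- xml2::xml_attr(rx, "lowerFluxBound")
    ubid <- xml2::xml_attr(rx, "upperFluxBound")
    if (!is.na(lbid) && lbid %in% names(par_val)) lb[k] <- par_val[lbid]
    if (!is.na(ubid) && ubid %in% names(par_val)) ub[k] <- par_val[ubid]
    gpa <- xml2::xml_find_first(rx, "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) rules[[k]] <- parse_fbc_assoc(kids[[1]])
    }
  }
  if (anyDuplicated(rid)) stop("duplicate reaction ids in SBML")
  lb[is.na(lb)] <- ifelse(revf[is.na(lb)], -1000, 0)
  ub[is.na(ub)] <- 1000
  metabolic_network(rid, internal, S, revf, lb, ub, gene_rules = rules)
}

parse_fbc_assoc <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    if (is.na(g)) g <- xml2::xml_attr(node, "fbc:geneProduct")
    return(list(op = "leaf", gene = g))
  }
  kids <- lapply(xml2::xml_children(node), parse_fbc_assoc)
  if (nm == "and") list(op = "and", children = kids)
  else if (nm == "or") list(op = "or", children = kids)
  else stop("unsupported gene association element: ", nm)
}

#' Write a minimal SBML Level 3 document for a network
#'
#' Fixture-grade writer (round-trip support for [read_network_sbml()]):
#' emits core species/reactions with `boundaryCondition` flags for the
#' supplied external species, fbc flux-bound parameters and fbc
#' gene-product associations.
#'
#' @param net a [metabolic_network()].
#' @param path output path.
#' @param external character vector of external species ids to add as
#'   boundary species on otherwise unbalanced reaction sides.
#' @return `path`, invisibly.
#' @export
write_network_sbml <- function(net, path, external = character(0)) {
  esc <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '<model id="net"><listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "<listOfSpecies>")
  for (m in net$metabolite_ids)
    lines <- c(lines, paste0('<species id="', esc(m),
                             '" compartment="c" boundaryCondition="false" ',
                             'hasOnlySubstanceUnits="false" constant="false"/>'))
  for (m in external)
    lines <- c(lines, paste0('<species id="', esc(m),
                             '" compartment="c" boundaryCondition="true" ',
                             'hasOnlySubstanceUnits="false" constant="false"/>'))
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>")
  for (k in seq_along(net$reaction_ids)) {
    lines <- c(lines,
      paste0('<parameter id="lb_', k, '" value="', net$lb[k], '" constant="true"/>'),
      paste0('<parameter id="ub_', k, '" value="', net$ub[k], '" constant="true"/>'))
  }
  lines <- c(lines, "</listOfParameters>", "<listOfReactions>")
  assoc_xml <- function(ast) {
    if (ast$op == "leaf")
      return(paste0('<fbc:geneProductRef fbc:geneProduct="', esc(ast$gene), '"/>'))
    kids <- paste(vapply(ast$children, assoc_xml, character(1)), collapse = "")
    paste0("<fbc:", ast$op, ">", kids, "</fbc:", ast$op, ">")
  }
  for (k in seq_along(net$reaction_ids)) {
    col <- net$S[, k]
    side <- function(idx, coefs, tag) {
      if (!length(idx)) return("")
      refs <- paste0('<speciesReference species="',
                     esc(net$metabolite_ids[idx]), '" stoichiometry="',
                     coefs, '" constant="true"/>', collapse = "")
      paste0("<", tag, ">", refs, "</", tag, ">")
    }
    lhs <- which(col < 0); rhs <- which(col > 0)
    rule <- net$gene_rules[[k]]
    lines <- c(lines, paste0(
      '<reaction id="', esc(net$reaction_ids[k]), '" reversible="',
      tolower(net$reversible[k]), '" fast="false" fbc:lowerFluxBound="lb_',
      k, '" fbc:upperFluxBound="ub_', k, '">',
      side(lhs, -col[lhs], "listOfReactants"),
      side(rhs, col[rhs], "listOfProducts"),
      if (!is.null(rule))
        paste0("<fbc:geneProductAssociation>", assoc_xml(rule),
               "</fbc:geneProductAssociation>") else "",
      "</reaction>"))
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
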