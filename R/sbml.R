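#' Write / read a stoichiometric model as SBML level 3
#'
#' Writes an SBML level-3 document with FBC-style flux bounds (per-reaction
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameters and an fbc objective)
#' and gene-association strings in the classic `GENE_ASSOCIATION:` reaction
#' notes convention. Exchange-reaction tags and uptake kinetics are carried
#' in model-level notes so that a written model round-trips.
#'
#' @param model a `stoich_model`.
#' @param path output file path (`.xml`).
#' @return `write_sbml_model` returns `path` invisibly; `read_sbml_model`
#'   returns a `stoich_model`.
#' @export
write_sbml_model <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false")
  m <- xml2::xml_add_child(doc, "model", id = "toy_model", "fbc:strict" = "true")

  notes <- xml2::xml_add_child(m, "notes")
  body <- xml2::xml_add_child(notes, "body",
                              xmlns = "http://www.w3.org/1999/xhtml")
  kv <- function(x) paste(names(x), unlist(x), sep = "=", collapse = ";")
  xml2::xml_add_child(body, "p", paste0("EXCHANGES: ", kv(model$exchanges)))
  xml2::xml_add_child(body, "p", paste0("KINETICS: ", kv(model$uptake_kinetics)))

  comps <- xml2::xml_add_child(m, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  sp <- xml2::xml_add_child(m, "listOfSpecies")
  for (met in model$metabolites) {
    xml2::xml_add_child(sp, "species", id = met, compartment = "c",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  pars <- xml2::xml_add_child(m, "listOfParameters")
  for (r in model$reactions) {
    xml2::xml_add_child(pars, "parameter", id = paste0("lb_", r),
                        value = format(model$lb[[r]], digits = 17),
                        constant = "true")
    xml2::xml_add_child(pars, "parameter", id = paste0("ub_", r),
                        value = format(model$ub[[r]], digits = 17),
                        constant = "true")
  }
  rxns <- xml2::xml_add_child(m, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(rxns, "reaction", id = r,
                              reversible = tolower(model$lb[[r]] < 0),
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("lb_", r),
                              "fbc:upperFluxBound" = paste0("ub_", r))
    if (nzchar(model$gpr[[r]])) {
      nts <- xml2::xml_add_child(rn, "notes")
      bd <- xml2::xml_add_child(nts, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(bd, "p", paste0("GENE_ASSOCIATION: ", model$gpr[[r]]))
    }
    s <- model$S[, r]
    rea <- which(s < 0); pro <- which(s > 0)
    if (length(rea)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in rea) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = model$metabolites[i],
                            stoichiometry = format(-s[i], digits = 17),
                            constant = "true")
      }
    }
    if (length(pro)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in pro) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = model$metabolites[i],
                            stoichiometry = format(s[i], digits = 17),
                            constant = "true")
      }
    }
  }
  lo <- xml2::xml_add_child(m, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = model$objective,
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_sbml_model
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
          x = "http://www.w3.org/1999/xhtml")
  mets <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), "id")
  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rids <- xml2::xml_attr(rxn_nodes, "id")
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  gpr <- stats::setNames(rep("", length(rids)), rids)
  for (k in seq_along(rxn_nodes)) {
    rn <- rxn_nodes[[k]]
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)) {
      S[xml2::xml_attr(sr, "species"), rids[k]] <-
        S[xml2::xml_attr(sr, "species"), rids[k]] -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)) {
      S[xml2::xml_attr(sr, "species"), rids[k]] <-
        S[xml2::xml_attr(sr, "species"), rids[k]] +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    note <- xml2::xml_text(xml2::xml_find_first(
      rn, "./s:notes/x:body/x:p[starts-with(text(), 'GENE_ASSOCIATION')]", ns))
    if (!is.na(note)) gpr[rids[k]] <- trimws(sub("^GENE_ASSOCIATION:", "", note))
  }
  lb <- pars[paste0("lb_", rids)]
  ub <- pars[paste0("ub_", rids)]
  objective <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns), "reaction")
  parse_kv <- function(tag) {
    p <- xml2::xml_text(xml2::xml_find_first(
      doc, sprintf(".//s:model/s:notes/x:body/x:p[starts-with(text(), '%s')]", tag),
      ns))
    if (is.na(p)) return(list())
    p <- trimws(sub(paste0("^", tag, ":"), "", p))
    if (!nzchar(p)) return(list())
    kvs <- strsplit(strsplit(p, ";")[[1]], "=")
    stats::setNames(lapply(kvs, function(x) {
      v <- x[2]
      if (grepl("^[0-9.eE+-]+$", v)) as.numeric(v) else v
    }), vapply(kvs, `[`, character(1), 1))
  }
  stoichiometric_model(S, lb, ub, gpr, objective,
                       exchanges = parse_kv("EXCHANGES"),
                       uptake_kinetics = parse_kv("KINETICS"))
}

#' Write / read regulatory rule sets as TSV
#'
#' Columns `gene`, `phase`, `reaction`, `action`, `factor`; the model label
#' is kept in a `# model_label:` header comment.
#'
#' @param rules a `regulatory_rules` object.
#' @param path file path.
#' @return `write_regulatory_rules` returns `path` invisibly;
#'   `read_regulatory_rules` returns the `regulatory_rules`.
#' @export
write_regulatory_rules <- function(rules, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# model_label: ", attr(rules, "model_label") %||% "M1"), con)
  utils::write.table(as.data.frame(rules), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_regulatory_rules
#' @export
read_regulatory_rules <- function(path) {
  first <- readLines(path, n = 1)
  label <- if (grepl("^# model_label:", first)) {
    trimws(sub("^# model_label:", "", first))
  } else "M1"
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  regulatory_rules(df, model_label = label)
}
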