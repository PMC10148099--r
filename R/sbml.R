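# SBML Level 3 + fbc version 2 reader/writer. Covers the subset of SBML
# used by COBRA-style genome-scale models: compartments, species (with
# boundaryCondition), reactions with stoichiometry, fbc flux bounds via
# global parameters, fbc gene-product associations, and COBRA-convention
# subsystem annotations in reaction notes (<p>SUBSYSTEM: ...</p>).

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

#' Read a metabolic model from SBML
#'
#' Supports SBML Level 3 with the fbc (v2) extension. Flux bounds are taken
#' from fbc `lowerFluxBound`/`upperFluxBound` parameter references; if a
#' reaction carries none, kinetic-law parameters named
#' `LOWER_BOUND`/`UPPER_BOUND` are used; failing both, defaults of
#' (-1000, 1000) for reversible and (0, 1000) for irreversible reactions
#' are applied with a warning. Species flagged `boundaryCondition="true"`
#' are dropped from all stoichiometries (they are not mass-balanced).
#' Subsystems are read from COBRA-style `SUBSYSTEM:` notes and gene rules
#' from fbc gene-product associations (fallback: `GENE_ASSOCIATION:`
#' notes).
#'
#' @param path SBML file path.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("not parseable as XML: ", path, " (", conditionMessage(e), ")")
  })
  ns <- c(sbml = SBML_CORE_NS, fbc = SBML_FBC_NS, xhtml = XHTML_NS)
  model_node <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(model_node, "xml_missing")) {
    stop("format error: no <model> element in ", path)
  }
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  comp_nodes <- xml2::xml_find_all(model_node,
                                   "./sbml:listOfCompartments/sbml:compartment", ns)
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp_nodes <- xml2::xml_find_all(model_node,
                                 "./sbml:listOfSpecies/sbml:species", ns)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  mets <- data.frame(
    id = sp_id,
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")), sp_id,
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = vapply(sp_nodes, sbml_attr, "", local = "chemicalFormula"),
    stringsAsFactors = FALSE)
  boundary_ids <- sp_id[sp_boundary]
  mets <- mets[!sp_boundary, , drop = FALSE]

  params <- xml2::xml_find_all(model_node,
                               "./sbml:listOfParameters/sbml:parameter", ns)
  par_val <- stats::setNames(sbml_num(xml2::xml_attr(params, "value")),
                             xml2::xml_attr(params, "id"))

  gp_nodes <- xml2::xml_find_all(model_node,
                                 ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_ids <- vapply(gp_nodes, sbml_attr, "", local = "id")
  gp_labels <- vapply(gp_nodes, sbml_attr, "", local = "label")
  gp_label <- stats::setNames(ifelse(is.na(gp_labels), gp_ids, gp_labels),
                              gp_ids)

  rxn_nodes <- xml2::xml_find_all(model_node,
                                  "./sbml:listOfReactions/sbml:reaction", ns)
  if (!length(rxn_nodes)) stop("format error: no reactions in ", path)
  n <- length(rxn_nodes)
  ids <- character(n); nms <- character(n)
  lbs <- numeric(n); ubs <- numeric(n)
  rules <- character(n); subsystems <- character(n)
  sto <- vector("list", n)
  for (k in seq_len(n)) {
    node <- rxn_nodes[[k]]
    rid <- xml2::xml_attr(node, "id")
    ids[k] <- rid
    nm <- xml2::xml_attr(node, "name")
    nms[k] <- if (is.na(nm)) rid else nm
    reversible <- xml2::xml_attr(node, "reversible") %in% "true"

    coefs <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        node, paste0("./sbml:", side, "/sbml:speciesReference"), ns)
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      st <- sbml_num(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      for (i in seq_along(sp)) {
        coefs[sp[i]] <- (if (sp[i] %in% names(coefs)) coefs[[sp[i]]] else 0) +
          st[i]
      }
    }
    had_species <- length(coefs) > 0
    coefs <- coefs[!(names(coefs) %in% boundary_ids)]
    coefs <- coefs[coefs != 0]
    if (!length(coefs)) {
      if (!had_species) {
        stop("format error: reaction ", rid, " has no stoichiometry")
      }
      # every species was a boundary metabolite: the reaction constrains
      # nothing once boundary species are dropped
      warning("reaction ", rid,
              " touches only boundary species; dropping it")
      sto[k] <- list(NULL)
      ids[k] <- NA_character_
      next
    }
    sto[[k]] <- coefs

    # bounds: fbc parameter references, then kinetic-law fallback, then defaults
    lb_ref <- sbml_attr(node, "lowerFluxBound")
    ub_ref <- sbml_attr(node, "upperFluxBound")
    if (!is.na(lb_ref) || !is.na(ub_ref)) {
      for (ref in c(lb_ref, ub_ref)) {
        if (!is.na(ref) && !(ref %in% names(par_val))) {
          stop("format error: reaction ", rid, " references flux-bound ",
               "parameter '", ref, "' that is not defined")
        }
      }
      lbs[k] <- if (is.na(lb_ref)) -Inf else par_val[[lb_ref]]
      ubs[k] <- if (is.na(ub_ref)) Inf else par_val[[ub_ref]]
    } else {
      kl <- xml2::xml_find_all(
        node, ".//sbml:kineticLaw//sbml:localParameter | .//sbml:kineticLaw//sbml:parameter", ns)
      kl_ids <- xml2::xml_attr(kl, "id")
      kl_vals <- sbml_num(xml2::xml_attr(kl, "value"))
      if ("LOWER_BOUND" %in% kl_ids || "UPPER_BOUND" %in% kl_ids) {
        lbs[k] <- if ("LOWER_BOUND" %in% kl_ids) {
          kl_vals[match("LOWER_BOUND", kl_ids)]
        } else if (reversible) -1000 else 0
        ubs[k] <- if ("UPPER_BOUND" %in% kl_ids) {
          kl_vals[match("UPPER_BOUND", kl_ids)]
        } else 1000
      } else {
        warning("reaction ", rid, ": no flux bounds found; using defaults")
        lbs[k] <- if (reversible) -1000 else 0
        ubs[k] <- 1000
      }
    }

    rules[k] <- sbml_read_gpr(node, ns, gp_label)
    subsystems[k] <- sbml_note_field(node, ns, "SUBSYSTEM")
    if (!nzchar(rules[k])) {
      ga <- sbml_note_field(node, ns, "GENE_ASSOCIATION")
      if (nzchar(ga)) rules[k] <- ga
    }
  }
  keep_rxn <- !is.na(ids)
  rxns <- data.frame(id = ids[keep_rxn], name = nms[keep_rxn],
                     lower_bound = lbs[keep_rxn],
                     upper_bound = ubs[keep_rxn],
                     gene_rule = rules[keep_rxn],
                     subsystem = subsystems[keep_rxn],
                     stringsAsFactors = FALSE)
  genes <- unname(gp_label)
  rule_leaves <- unique(unlist(lapply(rxns$gene_rule, rule_genes),
                               use.names = FALSE))
  genes <- unique(c(genes, rule_leaves))
  metabolic_model(model_id, mets, rxns,
                  stats::setNames(sto[keep_rxn], rxns$id),
                  genes = genes, compartments = compartments)
}

# fetch an attribute that may or may not carry a namespace prefix
# (e.g. fbc:lowerFluxBound); matches on the local name
sbml_attr <- function(node, local) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == local | endsWith(names(at), paste0(":", local)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

sbml_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x %in% c("INF", "inf")] <- Inf
  out[x %in% c("-INF", "-inf")] <- -Inf
  out
}

sbml_read_gpr <- function(rxn_node, ns, gp_label) {
  assoc <- xml2::xml_find_first(rxn_node, "./fbc:geneProductAssociation", ns)
  if (inherits(assoc, "xml_missing")) return("")
  kids <- xml2::xml_children(assoc)
  if (!length(kids)) return("")
  tree <- sbml_gpr_tree(kids[[1]], gp_label)
  rule_to_string(tree)
}

sbml_gpr_tree <- function(node, gp_label) {
  tag <- xml2::xml_name(node)
  if (tag == "geneProductRef") {
    gp <- sbml_attr(node, "geneProduct")
    lab <- if (gp %in% names(gp_label)) gp_label[[gp]] else gp
    return(lab)
  }
  if (tag %in% c("and", "or")) {
    args <- lapply(xml2::xml_children(node), sbml_gpr_tree, gp_label = gp_label)
    return(list(op = tag, args = args))
  }
  stop("format error: unsupported gene-association element <", tag, ">")
}

sbml_note_field <- function(node, ns, field) {
  ps <- xml2::xml_find_all(node, "./sbml:notes//xhtml:p", ns)
  if (!length(ps)) ps <- xml2::xml_find_all(node, "./sbml:notes//p", ns)
  for (p in ps) {
    txt <- trimws(xml2::xml_text(p))
    pre <- paste0(field, ":")
    if (startsWith(txt, pre)) {
      return(trimws(substring(txt, nchar(pre) + 1)))
    }
  }
  ""
}

#' Write a metabolic model to SBML
#'
#' Emits SBML Level 3 Version 1 with the fbc v2 extension: flux bounds as
#' global constant parameters, gene rules as fbc gene-product associations
#' (no element is written for empty rules), and subsystems as COBRA-style
#' `SUBSYSTEM:` notes. [read_sbml()] inverts the output.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  num <- function(v) {
    if (is.infinite(v)) (if (v > 0) "INF" else "-INF")
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
  gene_sid <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_CORE_NS, '" xmlns:fbc="', SBML_FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(model$id), '" fbc:strict="true">'),
    '    <listOfCompartments>',
    vapply(model$compartments, function(cp) {
      paste0('      <compartment id="', esc(cp),
             '" constant="true" size="1"/>')
    }, ""),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    vapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      frm <- if (!is.na(m$formula) && nzchar(m$formula)) {
        paste0(' fbc:chemicalFormula="', esc(m$formula), '"')
      } else ""
      paste0('      <species id="', esc(m$id), '" name="', esc(m$name),
             '" compartment="', esc(m$compartment),
             '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
             ' constant="false"', frm, '/>')
    }, ""),
    '    </listOfSpecies>',
    '    <listOfParameters>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    out <- c(out,
      paste0('      <parameter id="', esc(r$id), '_lb" value="',
             num(r$lower_bound), '" constant="true"/>'),
      paste0('      <parameter id="', esc(r$id), '_ub" value="',
             num(r$upper_bound), '" constant="true"/>'))
  }
  out <- c(out, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    sto <- model$stoichiometry[[r$id]]
    rev <- if (r$lower_bound < 0) "true" else "false"
    out <- c(out, paste0(
      '      <reaction id="', esc(r$id), '" name="', esc(r$name),
      '" reversible="', rev, '" fast="false" fbc:lowerFluxBound="',
      esc(r$id), '_lb" fbc:upperFluxBound="', esc(r$id), '_ub">'))
    if (nzchar(r$subsystem)) {
      out <- c(out,
        '        <notes>',
        paste0('          <body xmlns="', XHTML_NS, '">'),
        paste0('            <p>SUBSYSTEM: ', esc(r$subsystem), '</p>'),
        '          </body>',
        '        </notes>')
    }
    reac <- sto[sto < 0]; prod <- sto[sto > 0]
    if (length(reac)) {
      out <- c(out, '        <listOfReactants>',
        vapply(seq_along(reac), function(j) {
          paste0('          <speciesReference species="', esc(names(reac)[j]),
                 '" stoichiometry="', num(-reac[[j]]), '" constant="true"/>')
        }, ""),
        '        </listOfReactants>')
    }
    if (length(prod)) {
      out <- c(out, '        <listOfProducts>',
        vapply(seq_along(prod), function(j) {
          paste0('          <speciesReference species="', esc(names(prod)[j]),
                 '" stoichiometry="', num(prod[[j]]), '" constant="true"/>')
        }, ""),
        '        </listOfProducts>')
    }
    if (nzchar(r$gene_rule)) {
      tree <- parse_gene_rule(r$gene_rule)
      out <- c(out, '        <fbc:geneProductAssociation>',
               sbml_gpr_xml(tree, gene_sid, indent = 10),
               '        </fbc:geneProductAssociation>')
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>')
  if (length(model$genes)) {
    out <- c(out, '    <fbc:listOfGeneProducts>',
      vapply(model$genes, function(g) {
        paste0('      <fbc:geneProduct fbc:id="', gene_sid(g),
               '" fbc:label="', esc(g), '"/>')
      }, ""),
      '    </fbc:listOfGeneProducts>')
  }
  out <- c(out, '  </model>', '</sbml>')
  con <- tryCatch(file(path, "w", encoding = "UTF-8"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

sbml_gpr_xml <- function(node, gene_sid, indent) {
  pad <- strrep(" ", indent)
  if (is.character(node)) {
    return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="',
                  gene_sid(node), '"/>'))
  }
  c(paste0(pad, "<fbc:", node$op, ">"),
    unlist(lapply(node$args, sbml_gpr_xml, gene_sid = gene_sid,
                  indent = indent + 2)),
    paste0(pad, "</fbc:", node$op, ">"))
}
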