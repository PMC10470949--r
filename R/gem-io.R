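## Model I/O: a small JSON dialect (read/write) and an SBML Level 3 +
## FBC v2 reader (read-only).  The JSON dialect is
##   {"id", "metabolites": [{"id","name","compartment"}],
##    "reactions": [{"id","name","stoichiometry": {mid: coef},
##                   "lb","ub","gpr": "rule string","subsystem"}],
##    "genes": [...], "objective"}

#' Read a metabolic model from file
#'
#' @param path Path to the model file.
#' @param format `"json"` (native dialect) or `"sbml"` (Level 3 with the
#'   FBC v2 gene-product associations; subsystems from a `groups`
#'   partonomy or a notes fallback).  Default guesses from the file
#'   extension.
#' @param subsystem_key For SBML input, where subsystem labels live:
#'   `"groups"` (default; `groups:group` members) or `"notes"` (a
#'   `SUBSYSTEM: ...` line inside each reaction's notes).
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       subsystem_key = c("groups", "notes")) {
  format <- match.arg(format)
  subsystem_key <- match.arg(subsystem_key)
  if (!file.exists(path)) {
    stop_hf(sprintf("model file not found: %s", path), "hepaflux_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  model <- switch(format,
    json = read_model_json(path),
    sbml = read_model_sbml(path, subsystem_key)
  )
  validate_model(model)
  model
}

#' Write a metabolic model to the JSON dialect
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rxns <- lapply(unname(model$reactions), function(r) {
    out <- list(
      id = r$id, name = r$name,
      stoichiometry = as.list(r$stoichiometry),
      lb = r$lb, ub = r$ub,
      gpr = gpr_to_string(r$gpr)
    )
    if (!is.null(r$subsystem) && !is.na(r$subsystem)) out$subsystem <- r$subsystem
    out
  })
  obj <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      as.list(model$metabolites[i, c("id", "name", "compartment")])
    }),
    reactions = rxns,
    genes = as.list(model$genes),
    objective = model$objective
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_model_json <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) {
      stop_hf(sprintf("malformed JSON model '%s': %s", path, conditionMessage(e)),
              "hepaflux_parse_error")
    }
  )
  for (field in c("id", "metabolites", "reactions", "objective")) {
    if (is.null(obj[[field]])) {
      stop_hf(sprintf("JSON model missing required field '%s'", field),
              "hepaflux_parse_error")
    }
  }
  mets <- do.call(rbind, lapply(obj$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "", stringsAsFactors = FALSE)
  }))
  rxns <- lapply(obj$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoichiometry)) {
      stop_hf("JSON reaction missing 'id' or 'stoichiometry'", "hepaflux_parse_error")
    }
    st <- unlist(r$stoichiometry)
    reaction(
      id = r$id, name = r$name %||% r$id,
      stoichiometry = st,
      lb = r$lb %||% 0, ub = r$ub %||% 1000,
      gpr = if (!is.null(r$gpr) && nzchar(r$gpr)) r$gpr else NULL,
      subsystem = r$subsystem %||% NA_character_
    )
  })
  genes <- unlist(obj$genes) %||% NULL
  metabolic_model(
    id = obj$id, metabolites = mets, reactions = rxns,
    genes = genes, objective = obj$objective, validate = FALSE
  )
}

## --- SBML (Level 3, FBC v2, groups) ---------------------------------

xml_local <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

## Attribute lookup robust to namespace prefixes (fbc:geneProduct etc.).
xml_attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | grepl(paste0(":", name, "$"), names(at)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

read_model_sbml <- function(path, subsystem_key = "groups") {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop_hf(sprintf("malformed SBML '%s': %s", path, conditionMessage(e)),
              "hepaflux_parse_error")
    }
  )
  model_node <- xml_local(doc, "model")
  if (length(model_node) == 0) {
    stop_hf("SBML file has no <model> element", "hepaflux_parse_error")
  }
  model_node <- model_node[[1]]
  model_id <- xml_attr_any(model_node, "id") %||% "sbml_model"

  ## numeric flux-bound parameters
  params <- xml_local(model_node, "parameter")
  pval <- stats::setNames(
    as.numeric(vapply(params, xml_attr_any, character(1), "value")),
    vapply(params, xml_attr_any, character(1), "id")
  )

  ## gene products: id -> label
  gps <- xml_local(model_node, "geneProduct")
  gp_label <- stats::setNames(
    vapply(gps, function(g) {
      lab <- xml_attr_any(g, "label")
      if (is.na(lab)) xml_attr_any(g, "id") else lab
    }, character(1)),
    vapply(gps, xml_attr_any, character(1), "id")
  )

  species <- xml_local(model_node, "species")
  mets <- do.call(rbind, lapply(species, function(s) {
    data.frame(
      id = xml_attr_any(s, "id"),
      name = {
        nm <- xml_attr_any(s, "name"); if (is.na(nm)) xml_attr_any(s, "id") else nm
      },
      compartment = xml_attr_any(s, "compartment"),
      stringsAsFactors = FALSE
    )
  }))

  ## subsystems from groups
  sub_of <- character(0)
  if (subsystem_key == "groups") {
    for (grp in xml_local(model_node, "group")) {
      gname <- xml_attr_any(grp, "name")
      if (is.na(gname)) gname <- xml_attr_any(grp, "id")
      for (mem in xml_local(grp, "member")) {
        ref <- xml_attr_any(mem, "idRef")
        if (!is.na(ref)) sub_of[ref] <- gname
      }
    }
  }

  rxn_nodes <- xml2::xml_find_all(
    model_node, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']"
  )
  rxns <- lapply(rxn_nodes, function(rn) {
    rid <- xml_attr_any(rn, "id")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(
      rn, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']"
    )) {
      coef <- as.numeric(xml_attr_any(sr, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      sp <- xml_attr_any(sr, "species")
      st[sp] <- (if (sp %in% names(st)) st[sp] else 0) - coef
    }
    for (sr in xml2::xml_find_all(
      rn, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']"
    )) {
      coef <- as.numeric(xml_attr_any(sr, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      sp <- xml_attr_any(sr, "species")
      st[sp] <- (if (sp %in% names(st)) st[sp] else 0) + coef
    }
    lb_ref <- xml_attr_any(rn, "lowerFluxBound")
    ub_ref <- xml_attr_any(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]] else -1000
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else 1000
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) NULL else {
      sbml_gpa_to_gpr(xml2::xml_children(gpa)[[1]], gp_label)
    }
    subsystem <- if (rid %in% names(sub_of)) {
      sub_of[[rid]]
    } else if (subsystem_key == "notes") {
      notes <- xml2::xml_find_first(rn, "./*[local-name()='notes']")
      if (inherits(notes, "xml_missing")) NA_character_ else {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexec("SUBSYSTEM:\\s*([^\n<]+)", txt))[[1]]
        if (length(m) == 2) trimws(m[2]) else NA_character_
      }
    } else NA_character_
    reaction(
      id = rid,
      name = { nm <- xml_attr_any(rn, "name"); if (is.na(nm)) rid else nm },
      stoichiometry = st, lb = lb, ub = ub, gpr = gpr, subsystem = subsystem
    )
  })

  ## active objective
  fobj <- xml2::xml_find_first(
    model_node,
    ".//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']"
  )
  objective <- if (inherits(fobj, "xml_missing")) {
    stop_hf("SBML model has no flux objective", "hepaflux_parse_error")
  } else {
    xml_attr_any(fobj, "reaction")
  }

  metabolic_model(
    id = model_id, metabolites = mets, reactions = rxns,
    genes = unname(gp_label), objective = objective, validate = FALSE
  )
}

## fbc:and / fbc:or / fbc:geneProductRef -> gpr tree
sbml_gpa_to_gpr <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml_attr_any(node, "geneProduct")
    lab <- if (ref %in% names(gp_label)) gp_label[[ref]] else ref
    return(gpr_gene(lab))
  }
  if (nm %in% c("and", "or")) {
    children <- lapply(xml2::xml_children(node), sbml_gpa_to_gpr, gp_label = gp_label)
    return(gpr_node(nm, children))
  }
  stop_hf(sprintf("unsupported gene association element '%s'", nm),
          "hepaflux_parse_error")
}
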