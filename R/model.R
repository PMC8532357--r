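#' Construct a genome-scale metabolic model object
#'
#' A `metabolic_model` bundles the metabolite list, the reaction list
#' (stoichiometry, flux bounds, gene-protein-reaction associations,
#' subsystems) and the identity of the biomass pseudo-reaction. It is the
#' constraint network from which the steady-state flux polytope
#' \eqn{\{v : Sv = 0,\ lb \le v \le ub\}} is built.
#'
#' Units are fixed package-wide: fluxes in mmol gDW\eqn{^{-1}} h\eqn{^{-1}},
#' time in hours, biomass in gDW/L, concentrations in mmol/L.
#'
#' @param model_id Character scalar identifying the model.
#' @param metabolites Tibble with columns `id`, `name`, `compartment`.
#' @param reactions Tibble with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_association`, `subsystem` and a list-column
#'   `stoichiometry` of named numeric vectors (names are metabolite ids,
#'   values are signed coefficients; negative = consumed).
#' @param biomass_reaction_id Id of the biomass pseudo-reaction, or `NA`.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(model_id, metabolites, reactions,
                            biomass_reaction_id = NA_character_) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  model <- structure(
    list(
      model_id = as.character(model_id),
      metabolites = metabolites,
      reactions = reactions,
      biomass_reaction_id = biomass_reaction_id
    ),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique reaction and metabolite ids,
#' every stoichiometry entry references an existing metabolite, all
#' coefficients nonzero, at least one entry per reaction, and
#' `lower_bound <= upper_bound` everywhere.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly. Errors with a descriptive message on the
#'   first violated invariant.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  mets <- model$metabolites
  if (anyDuplicated(rx$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "))
  }
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (any(rx$lower_bound > rx$upper_bound)) {
    bad <- rx$id[rx$lower_bound > rx$upper_bound]
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(bad, collapse = ", "))
  }
  for (i in seq_len(nrow(rx))) {
    st <- rx$stoichiometry[[i]]
    if (length(st) < 1) {
      stop("reaction ", rx$id[i], " has empty stoichiometry")
    }
    if (any(st == 0)) {
      stop("reaction ", rx$id[i], " has zero stoichiometric coefficient(s)")
    }
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown) > 0) {
      stop("reaction ", rx$id[i], " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!is.na(model$biomass_reaction_id) &&
      !model$biomass_reaction_id %in% rx$id) {
    stop("biomass_reaction_id '", model$biomass_reaction_id,
         "' is not a reaction of the model")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  s <- model_summary(x)
  cat("<metabolic_model> ", x$model_id, "\n", sep = "")
  cat("  metabolites: ", s$n_metabolites,
      "   reactions: ", s$n_reactions,
      "   genes: ", s$n_genes, "\n", sep = "")
  cat("  biomass reaction: ",
      ifelse(is.na(x$biomass_reaction_id), "<none>", x$biomass_reaction_id),
      "\n", sep = "")
  invisible(x)
}

# Gene names are extracted from raw boolean GPR strings; tokens that are not
# boolean keywords or parentheses are gene names.
extract_genes <- function(gpr) {
  gpr <- gpr[!is.na(gpr) & nzchar(gpr)]
  if (length(gpr) == 0) return(character(0))
  tokens <- unlist(strsplit(gpr, "[()\\s]+", perl = TRUE))
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!tolower(tokens) %in% c("and", "or")]
  unique(tokens)
}

#' Summarize a metabolic model
#'
#' @param model A `metabolic_model`.
#' @return A one-row tibble with `n_metabolites`, `n_reactions`, `n_genes`
#'   (unique gene names appearing in any gene association).
#' @export
model_summary <- function(model) {
  validate_model(model)
  tibble::tibble(
    model_id = model$model_id,
    n_metabolites = nrow(model$metabolites),
    n_reactions = nrow(model$reactions),
    n_genes = length(extract_genes(model$reactions$gene_association))
  )
}

#' Build the stoichiometric system of a model
#'
#' Assembles the m x n stoichiometric matrix S (rows metabolites, columns
#' reactions, in declaration order) together with the bound vectors. S[i, j]
#' is the signed coefficient of metabolite i in reaction j; the steady-state
#' flux polytope is \eqn{\{v : Sv = 0, lb \le v \le ub\}}.
#'
#' @param model A `metabolic_model`.
#' @return An object of class `stoichiometric_system`: a list with `S`
#'   (dense matrix with dimnames), `lb`, `ub`, `reaction_ids`,
#'   `metabolite_ids`.
#' @export
build_stoichiometric_system <- function(model) {
  validate_model(model)
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- unname(st)
  }
  structure(
    list(
      S = S,
      lb = stats::setNames(model$reactions$lower_bound, rxn_ids),
      ub = stats::setNames(model$reactions$upper_bound, rxn_ids),
      reaction_ids = rxn_ids,
      metabolite_ids = met_ids
    ),
    class = "stoichiometric_system"
  )
}

#' Find exchange reactions
#'
#' Exchange (boundary) reactions are detected purely structurally: a
#' reaction whose stoichiometry touches exactly one metabolite, regardless
#' of orientation or naming. By convention positive flux is secretion and
#' negative flux is uptake.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of exchange reaction ids (possibly empty).
#' @export
find_exchange_reactions <- function(model) {
  validate_model(model)
  n_mets <- vapply(model$reactions$stoichiometry, length, integer(1))
  model$reactions$id[n_mets == 1L]
}

#' Read a metabolic model from file
#'
#' Supports SBML Level 3 (with the fbc package for flux bounds and
#' gene-product associations, and the groups package for subsystems) and the
#' package's internal JSON format. Reactions lacking explicit bounds receive
#' the conventional defaults: reversible (-1000, 1000), irreversible
#' (0, 1000) mmol gDW\eqn{^{-1}} h\eqn{^{-1}}.
#'
#' @param path Path to the model file.
#' @param format `"sbml"` or `"internal-json"`.
#' @return A `metabolic_model`.
#' @export
read_model <- function(path, format = c("sbml", "internal-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file does not exist: ", path)
  switch(format,
         "sbml" = read_model_sbml(path),
         "internal-json" = read_model_json(path))
}

#' Write a metabolic model to file
#'
#' The internal JSON format round-trips every field. The SBML writer targets
#' toy-scale networks (it emits SBML L3v1 with fbc v2 bounds/GPRs and a
#' groups-based subsystem annotation); writing full genome-scale models is
#' out of scope.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @param format `"internal-json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("internal-json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  switch(format,
         "internal-json" = write_model_json(model, path),
         "sbml" = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- purrr::map_dfr(x$metabolites, tibble::as_tibble)
  rxns <- purrr::map_dfr(x$reactions, function(r) {
    tibble::tibble(
      id = r$id, name = r$name,
      lower_bound = as.numeric(r$lower_bound),
      upper_bound = as.numeric(r$upper_bound),
      gene_association = r$gene_association %||% "",
      subsystem = r$subsystem %||% "",
      stoichiometry = list(unlist(r$stoichiometry))
    )
  })
  metabolic_model(x$model_id, mets, rxns,
                  x$biomass_reaction_id %||% NA_character_)
}

write_model_json <- function(model, path) {
  x <- list(
    model_id = model$model_id,
    biomass_reaction_id = model$biomass_reaction_id,
    metabolites = purrr::pmap(model$metabolites, list),
    reactions = purrr::pmap(model$reactions, function(id, name, lower_bound,
                                                      upper_bound,
                                                      gene_association,
                                                      subsystem,
                                                      stoichiometry) {
      list(id = id, name = name, lower_bound = lower_bound,
           upper_bound = upper_bound, gene_association = gene_association,
           subsystem = subsystem, stoichiometry = as.list(stoichiometry))
    })
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

sbml_ns <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  groups = "http://www.sbml.org/sbml/level3/version1/groups/version1"
)

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("failed to parse SBML file '", path, "': ", conditionMessage(e))
  })
  ns <- sbml_ns
  # namespaced attribute lookup: try the prefixed form, then the bare name
  xattr <- function(node, name) {
    a <- xml2::xml_attr(node, name)
    if (all(is.na(a))) a <- xml2::xml_attr(node, sub("^.*:", "", name))
    a
  }
  model_node <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(model_node, "xml_missing")) {
    stop("no <model> element found in ", path)
  }
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "sbml_model"

  sp <- xml2::xml_find_all(model_node, ".//sbml:listOfSpecies/sbml:species", ns)
  mets <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id")),
    compartment = dplyr::coalesce(xml2::xml_attr(sp, "compartment"), "c")
  )

  pars <- xml2::xml_find_all(model_node,
                             ".//sbml:listOfParameters/sbml:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  gps <- xml2::xml_find_all(model_node,
                            ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(
    dplyr::coalesce(xml2::xml_attr(gps, "label"), xml2::xml_attr(gps, "id")),
    xml2::xml_attr(gps, "id"))

  rxn_nodes <- xml2::xml_find_all(model_node,
                                  ".//sbml:listOfReactions/sbml:reaction", ns)
  if (length(rxn_nodes) == 0) stop("no reactions found in ", path)

  parse_gpr <- function(node) {
    assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    if (inherits(assoc, "xml_missing")) return("")
    render <- function(nd) {
      nm <- xml2::xml_name(nd)
      if (nm == "geneProductRef") {
        ref <- xml2::xml_attr(nd, "geneProduct")
        return(gp_label[[ref]] %||% ref)
      }
      kids <- xml2::xml_children(nd)
      parts <- vapply(kids, render, character(1))
      op <- if (nm == "and") " and " else " or "
      paste0("(", paste(parts, collapse = op), ")")
    }
    kids <- xml2::xml_children(assoc)
    if (length(kids) == 0) return("")
    out <- render(kids[[1]])
    sub("^\\((.*)\\)$", "\\1", out)
  }

  get_stoich <- function(node) {
    reac <- xml2::xml_find_all(node,
      "./sbml:listOfReactants/sbml:speciesReference", ns)
    prod <- xml2::xml_find_all(node,
      "./sbml:listOfProducts/sbml:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      xml2::xml_attr(reac, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      xml2::xml_attr(prod, "species"))
    )
    # a metabolite on both sides collapses to its net coefficient
    if (anyDuplicated(names(st))) {
      st <- tapply(st, names(st), sum)
      st <- stats::setNames(as.numeric(st), names(st))
    }
    st[st != 0]
  }

  rxns <- purrr::map_dfr(rxn_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb_ref <- xattr(node, "fbc:lowerFluxBound")
    ub_ref <- xattr(node, "fbc:upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) {
      par_val[[lb_ref]]
    } else if (reversible) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) {
      par_val[[ub_ref]]
    } else 1000
    tibble::tibble(
      id = id,
      name = dplyr::coalesce(xml2::xml_attr(node, "name"), id),
      lower_bound = lb, upper_bound = ub,
      gene_association = parse_gpr(node),
      subsystem = "",
      stoichiometry = list(get_stoich(node))
    )
  })
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction id(s) in SBML file: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }

  # subsystems via the groups package, when present
  grp_nodes <- xml2::xml_find_all(model_node,
                                  ".//groups:listOfGroups/groups:group", ns)
  for (g in grp_nodes) {
    gname <- xattr(g, "groups:name")
    if (is.na(gname)) gname <- xattr(g, "groups:id")
    members <- xattr(
      xml2::xml_find_all(g, ".//groups:member", ns), "groups:idRef")
    hit <- rxns$id %in% members
    rxns$subsystem[hit] <- ifelse(
      nzchar(rxns$subsystem[hit]),
      paste(rxns$subsystem[hit], gname, sep = "; "), gname)
  }

  # biomass reaction: fbc objective when present, else id heuristic
  obj <- xml2::xml_find_first(
    model_node, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  biomass_id <- if (!inherits(obj, "xml_missing")) {
    xattr(obj, "fbc:reaction")
  } else {
    hit <- grep("biomass", rxns$id, ignore.case = TRUE, value = TRUE)
    if (length(hit) > 0) hit[[1]] else NA_character_
  }

  metabolic_model(model_id, mets, rxns, biomass_id)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  rx <- model$reactions
  genes <- extract_genes(rx$gene_association)
  gp_id <- stats::setNames(paste0("G_", seq_along(genes)), genes)

  bounds <- sort(unique(c(rx$lower_bound, rx$upper_bound)))
  pid <- function(v) paste0("fb_", match(v, bounds))

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', sbml_ns[["sbml"]], '" xmlns:fbc="',
           sbml_ns[["fbc"]], '" xmlns:groups="', sbml_ns[["groups"]],
           '" level="3" version="1" fbc:required="false"',
           ' groups:required="false">'),
    paste0('<model id="', esc(model$model_id), '" fbc:strict="true">'),
    '<listOfCompartments>',
    paste0('<compartment id="', esc(unique(model$metabolites$compartment)),
           '" constant="true"/>'),
    '</listOfCompartments>',
    '<listOfSpecies>',
    sprintf(
      '<species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(model$metabolites$id), esc(model$metabolites$name),
      esc(model$metabolites$compartment)),
    '</listOfSpecies>',
    '<listOfParameters>',
    sprintf('<parameter id="fb_%d" value="%s" constant="true"/>',
            seq_along(bounds),
            vapply(bounds, format, character(1), digits = 17)),
    '</listOfParameters>'
  )

  if (length(genes) > 0) {
    lines <- c(lines, '<fbc:listOfGeneProducts>',
               sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                       unname(gp_id), esc(genes)),
               '</fbc:listOfGeneProducts>')
  }

  gpr_xml <- function(gpr) {
    if (is.na(gpr) || !nzchar(gpr)) return(character(0))
    toks <- extract_genes(gpr)
    refs <- sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>',
                    gp_id[toks])
    has_and <- grepl("\\band\\b", gpr, ignore.case = TRUE)
    if (length(toks) == 1) {
      body <- refs
    } else if (has_and && !grepl("\\bor\\b", gpr, ignore.case = TRUE)) {
      body <- c("<fbc:and>", refs, "</fbc:and>")
    } else {
      body <- c("<fbc:or>", refs, "</fbc:or>")
    }
    c("<fbc:geneProductAssociation>", body, "</fbc:geneProductAssociation>")
  }

  lines <- c(lines, '<listOfReactions>')
  for (i in seq_len(nrow(rx))) {
    st <- rx$stoichiometry[[i]]
    reac <- st[st < 0]
    prod <- st[st > 0]
    lines <- c(lines, sprintf(
      '<reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(rx$id[i]), esc(rx$name[i]),
      tolower(rx$lower_bound[i] < 0), pid(rx$lower_bound[i]),
      pid(rx$upper_bound[i])))
    if (length(reac) > 0) {
      lines <- c(lines, '<listOfReactants>',
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(names(reac)), format(-unname(reac), digits = 17)),
                 '</listOfReactants>')
    }
    if (length(prod) > 0) {
      lines <- c(lines, '<listOfProducts>',
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(names(prod)), format(unname(prod), digits = 17)),
                 '</listOfProducts>')
    }
    lines <- c(lines, gpr_xml(rx$gene_association[i]), '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>')

  subsys <- unique(rx$subsystem[nzchar(rx$subsystem)])
  if (length(subsys) > 0) {
    lines <- c(lines, '<groups:listOfGroups>')
    for (k in seq_along(subsys)) {
      members <- rx$id[rx$subsystem == subsys[k]]
      lines <- c(lines,
        sprintf('<groups:group groups:id="grp_%d" groups:name="%s" groups:kind="partition">',
                k, esc(subsys[k])),
        '<groups:listOfMembers>',
        sprintf('<groups:member groups:idRef="%s"/>', esc(members)),
        '</groups:listOfMembers>', '</groups:group>')
    }
    lines <- c(lines, '</groups:listOfGroups>')
  }

  if (!is.na(model$biomass_reaction_id)) {
    lines <- c(lines,
      '<fbc:listOfObjectives fbc:activeObjective="obj">',
      '<fbc:objective fbc:id="obj" fbc:type="maximize">',
      '<fbc:listOfFluxObjectives>',
      sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
              esc(model$biomass_reaction_id)),
      '</fbc:listOfFluxObjectives>', '</fbc:objective>',
      '</fbc:listOfObjectives>')
  }

  lines <- c(lines, '</model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
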