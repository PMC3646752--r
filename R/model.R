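#' Load a machinery model document
#'
#' Reads a structured YAML model document (components, subsystems,
#' compartments, metabolite registry, reactions) into a
#' [MachineryModel-class], cross-referencing every reaction's catalysts,
#' subsystem, compartment and metabolites. Dangling references raise an
#' error naming each unresolved id.
#'
#' @param path path to a model YAML document; defaults to the packaged
#'   yeast secretory machinery model.
#' @return a [MachineryModel-class].
#' @seealso [yeastModel()], [validateModel()]
#' @export
loadModel <- function(path = system.file("extdata",
                                         "yeast_machinery_model.yaml",
                                         package = "secflux")) {
  if (!file.exists(path)) stop(sprintf("model document not found: %s", path))
  doc <- yaml::read_yaml(path)
  comps <- do.call(rbind, lapply(doc$components, function(cp)
    data.frame(component_id = cp$component_id, name = cp$name,
               kind = cp$kind,
               subsystems = paste(unlist(cp$subsystems), collapse = ","),
               stringsAsFactors = FALSE)))
  subs <- do.call(rbind, lapply(doc$subsystems, function(s)
    data.frame(subsystem_id = s$subsystem_id, name = s$name,
               compartment = s$compartment, stringsAsFactors = FALSE)))
  compartments <- unlist(doc$compartments)
  mets <- c(unlist(doc$metabolites$external),
            unlist(doc$metabolites$internal))
  reactions <- doc$reactions
  names(reactions) <- vapply(reactions, `[[`, "", "reaction_id")

  complexes <- list()
  for (r in reactions)
    if (identical(r$category, "complex_formation"))
      complexes[[r$complex_id]] <- unlist(r$members)

  diagnostics <- character()
  compIds <- comps$component_id
  for (r in reactions) {
    rid <- r$reaction_id
    if (!is.null(r$subsystem_id) && !is.na(r$subsystem_id) &&
        !(r$subsystem_id %in% subs$subsystem_id))
      diagnostics <- c(diagnostics,
        sprintf("%s: unknown subsystem '%s'", rid, r$subsystem_id))
    if (!is.null(r$compartment_id) &&
        !(r$compartment_id %in% compartments))
      diagnostics <- c(diagnostics,
        sprintf("%s: unknown compartment '%s'", rid, r$compartment_id))
    for (cat in unlist(r$catalysts))
      if (!(cat %in% compIds) && !(cat %in% names(complexes)))
        diagnostics <- c(diagnostics,
          sprintf("%s: unknown catalyst '%s'", rid, cat))
    for (m in names(r$metabolite_stoichiometry)) {
      if (!(m %in% mets))
        diagnostics <- c(diagnostics,
          sprintf("%s: unknown metabolite '%s'", rid, m))
      v <- r$metabolite_stoichiometry[[m]]
      if (!is.numeric(v) || !is.finite(v))
        diagnostics <- c(diagnostics,
          sprintf("%s: non-finite coefficient for '%s'", rid, m))
    }
    if (identical(r$category, "exchange") &&
        length(r$metabolite_stoichiometry) != 1L)
      diagnostics <- c(diagnostics,
        sprintf("%s: exchange reactions carry exactly one metabolite", rid))
    if (identical(r$category, "template") &&
        (is.null(r$applicability) || identical(r$applicability, "")))
      diagnostics <- c(diagnostics,
        sprintf("%s: template reaction without applicability", rid))
    if (identical(r$category, "complex_formation"))
      for (m in unlist(r$members))
        if (!(m %in% compIds))
          diagnostics <- c(diagnostics,
            sprintf("%s: unknown complex member '%s'", rid, m))
  }
  if (length(diagnostics))
    stop("model load errors:\n  ", paste(diagnostics, collapse = "\n  "))

  new("MachineryModel", components = comps, subsystems = subs,
      compartments = compartments, reactions = reactions,
      complexes = complexes, metabolites = mets, source = path)
}

#' The packaged yeast secretory machinery model
#'
#' Convenience loader (cached per session) for the curated yeast model
#' shipped with the package: 163 components, 16 subsystems, 8 compartments
#' and 137 reactions.
#'
#' @return a [MachineryModel-class].
#' @examples
#' m <- yeastModel()
#' validateModel(m)$n_components  # 163
#' @export
yeastModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- loadModel()
    cache
  }
})

#' Validate a machinery model and report its census
#'
#' Recomputes, by enumeration over the loaded reactions and components
#' (never from cached fields), the counts a model summary table reports:
#' reactions per category, components by kind, subsystems, compartments,
#' and components never referenced as catalysts or complex members
#' (orphans).
#'
#' @param model a [MachineryModel-class].
#' @return list with `n_components`, `n_protein`, `n_rna`, `n_subsystems`,
#'   `n_compartments`, `n_reactions`, `reaction_categories` (named
#'   integer), `orphan_components` (character).
#' @export
validateModel <- function(model) {
  stopifnot(is(model, "MachineryModel"))
  cats <- vapply(model@reactions, `[[`, "", "category")
  used <- unique(c(
    unlist(lapply(model@reactions, function(r) unlist(r$catalysts))),
    unlist(model@complexes)))
  used <- setdiff(used, names(model@complexes))
  orphans <- setdiff(model@components$component_id, used)
  list(
    n_components = nrow(model@components),
    n_protein = sum(model@components$kind == "protein"),
    n_rna = sum(model@components$kind == "RNA"),
    n_subsystems = nrow(model@subsystems),
    n_compartments = length(model@compartments),
    n_reactions = length(model@reactions),
    reaction_categories = c(
      template = sum(cats == "template"),
      complex_formation = sum(cats == "complex_formation"),
      biosynthesis = sum(cats == "biosynthesis"),
      exchange = sum(cats == "exchange")),
    orphan_components = orphans)
}

#' Export the component-subsystem bipartite network
#'
#' One edge per (component, subsystem) membership, with node attributes
#' (kind, degree, and any supplied per-component weight such as specific
#' activity), in a form loadable by Cytoscape-style tools.
#'
#' @param model a [MachineryModel-class].
#' @param node_weights optional named numeric (component_id -> weight, e.g.
#'   SA). Weights for unknown components raise a warning and are omitted.
#' @param path optional: if given, writes `<path>_edges.tsv` and
#'   `<path>_nodes.tsv`.
#' @return list with `edges` (data.frame `component_id`, `subsystem_id`)
#'   and `nodes` (data.frame `node_id`, `type`, `degree`, `weight`).
#' @export
exportNetwork <- function(model, node_weights = NULL, path = NULL) {
  stopifnot(is(model, "MachineryModel"))
  comps <- model@components
  edges <- do.call(rbind, lapply(seq_len(nrow(comps)), function(i) {
    ss <- strsplit(comps$subsystems[i], ",", fixed = TRUE)[[1]]
    data.frame(component_id = comps$component_id[i], subsystem_id = ss,
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  deg <- table(edges$component_id)
  sdeg <- table(edges$subsystem_id)
  nodes <- rbind(
    data.frame(node_id = comps$component_id, type = "component",
               degree = as.integer(deg[comps$component_id]),
               stringsAsFactors = FALSE),
    data.frame(node_id = model@subsystems$subsystem_id, type = "subsystem",
               degree = as.integer(sdeg[model@subsystems$subsystem_id]),
               stringsAsFactors = FALSE))
  nodes$degree[is.na(nodes$degree)] <- 0L
  nodes$weight <- NA_real_
  if (!is.null(node_weights)) {
    unknown <- setdiff(names(node_weights), comps$component_id)
    if (length(unknown)) {
      warning(sprintf("weight(s) for unknown component(s) omitted: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
      node_weights <- node_weights[setdiff(names(node_weights), unknown)]
    }
    idx <- match(names(node_weights), nodes$node_id)
    nodes$weight[idx] <- unname(node_weights)
  }
  if (!is.null(path)) {
    utils::write.table(edges, paste0(path, "_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(nodes, paste0(path, "_nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(edges = edges, nodes = nodes)
}
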