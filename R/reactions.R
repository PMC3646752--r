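#' Options for protein-specific reaction generation
#'
#' @param f_misfold fraction of molecules misfolding into the ERAD branch
#'   (0..1). Default 0: no degradation flux.
#' @param alp_proteins protein ids routed to the vacuole via the direct
#'   AP-3 (ALP) pathway instead of the default CPY (endosomal) route.
#' @return list of options for [generateReactions()] / [generateAll()].
#' @export
reactionOptions <- function(f_misfold = 0, alp_proteins = character()) {
  .assertScalarNumber(f_misfold, "f_misfold", min = 0)
  if (f_misfold > 1) stop("'f_misfold' must be <= 1")
  list(f_misfold = f_misfold, alp_proteins = alp_proteins)
}

## per-record generation core; rec is a single-row records data.frame
.generateOne <- function(rec, model, options) {
  b <- .booleanize(rec)
  ## routing view of the record: unknown destinations take the full
  ## secreted-protein itinerary
  loc <- if (b$localization == "unknown") "extracellular" else b$localization
  route <- if (rec$protein_id %in% options$alp_proteins) "ALP" else "CPY"
  f <- options$f_misfold
  eradBranch <- if (f > 0) {
    if (rec$tm_domains > 0) "M"
    else if (b$n_glyc && !b$gpi) "L"
    else "C"
  } else ""
  env <- .featureEnv(b, rec, list(route = route, f_misfold = f,
                                  erad_branch = eradBranch))
  env$loc <- loc

  subOrder <- model@subsystems$subsystem_id
  steps <- list()
  for (r in model@reactions) {
    if (!(r$category %in% c("template", "biosynthesis"))) next
    if (!isTRUE(.evalModelExpr(r$applicability, env))) next
    mult <- .evalModelExpr(r$scale %||% "1", env)
    if (!is.finite(mult) || mult <= 0) next
    sm <- r$metabolite_stoichiometry
    steps[[length(steps) + 1L]] <- data.frame(
      reaction_id = r$reaction_id,
      subsystem_id = r$subsystem_id,
      compartment_id = r$compartment_id,
      metabolite = if (length(sm)) names(sm) else NA_character_,
      coefficient = if (length(sm)) unlist(sm) * mult else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(steps))
    return(data.frame(reaction_id = character(), subsystem_id = character(),
                      compartment_id = character(), metabolite = character(),
                      coefficient = numeric(), step_index = integer()))
  out <- do.call(rbind, steps)
  rownames(out) <- NULL
  ## route order: subsystems S1 -> S16, then document order within
  ord <- order(match(out$subsystem_id, subOrder),
               match(out$reaction_id, names(model@reactions)))
  out <- out[ord, , drop = FALSE]
  out$step_index <- match(out$reaction_id, unique(out$reaction_id))
  out
}

#' Instantiate the reaction list of one client protein
#'
#' The virtual secretory machinery: from a validated feature record and the
#' machinery model, emits the ordered list of modification and transport
#' reactions the protein traverses, with metabolite stoichiometry scaled by
#' the record's feature counts (glycosylation sites, disulfide bonds, TM
#' domains). Records that are not machinery clients (no signal peptide and
#' no transmembrane domain) are refused.
#'
#' @param rec one feature record: a single-row data.frame (or 1-record
#'   [PSIM-class]).
#' @param model a [MachineryModel-class].
#' @param options see [reactionOptions()].
#' @return a [ReactionListSet-class] holding the single list.
#' @examples
#' m <- yeastModel()
#' er <- data.frame(protein_id = "ERres", signal_peptide = TRUE,
#'   n_glyc_sites = 0L, o_glyc_sites = 0L, disulfide_bonds = 0L,
#'   gpi_anchor = FALSE, tm_domains = 0L, localization = "ER")
#' unique(reactionSteps(generateReactions(er, m))$subsystem_id)
#' @export
generateReactions <- function(rec, model, options = reactionOptions()) {
  if (is(rec, "PSIM")) rec <- rec@records
  stopifnot(is(model, "MachineryModel"), nrow(rec) == 1L)
  if (!rec$signal_peptide && rec$tm_domains == 0)
    stop(sprintf(paste0("'%s' is not a secretory machinery client: no ",
                        "signal peptide and no transmembrane domain"),
                 rec$protein_id))
  st <- .generateOne(rec, model, options)
  st <- cbind(protein_id = rec$protein_id, st)
  cls <- classifyProteins(rec, enumerateClasses())
  pr <- data.frame(protein_id = rec$protein_id, class_id = cls$class_id,
                   category = cls$category, client = TRUE,
                   n_steps = length(unique(st$reaction_id)))
  new("ReactionListSet", steps = st, proteins = pr, options = options)
}

#' Instantiate reaction lists for a whole proteome
#'
#' Runs the virtual machinery over every record of a PSIM. Clients (signal
#' peptide, or a signal anchor in a transmembrane domain) get one ordered
#' reaction list each; non-clients are tallied separately, never dropped
#' silently.
#'
#' @param psim a [PSIM-class].
#' @param catalog a [ClassCatalog-class] used to annotate each list with
#'   its secretory class.
#' @param model a [MachineryModel-class].
#' @param options see [reactionOptions()].
#' @return a [ReactionListSet-class].
#' @export
generateAll <- function(psim, catalog = enumerateClasses(),
                        model = yeastModel(),
                        options = reactionOptions()) {
  stopifnot(is(psim, "PSIM"), is(model, "MachineryModel"))
  rec <- psim@records
  asg <- classifyProteins(psim, catalog)
  stepList <- vector("list", nrow(rec))
  nsteps <- integer(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!asg$client[i]) next
    st <- .generateOne(rec[i, ], model, options)
    nsteps[i] <- length(unique(st$reaction_id))
    if (nrow(st)) stepList[[i]] <- cbind(protein_id = rec$protein_id[i], st)
  }
  steps <- do.call(rbind, stepList[!vapply(stepList, is.null, TRUE)])
  if (is.null(steps))
    steps <- data.frame(protein_id = character(), reaction_id = character(),
                        subsystem_id = character(),
                        compartment_id = character(),
                        metabolite = character(), coefficient = numeric(),
                        step_index = integer())
  rownames(steps) <- NULL
  pr <- data.frame(protein_id = asg$protein_id, class_id = asg$class_id,
                   category = asg$category, client = asg$client,
                   n_steps = nsteps, stringsAsFactors = FALSE)
  new("ReactionListSet", steps = steps, proteins = pr, options = options)
}

#' Serialize reaction lists to TSV
#'
#' One row per (protein, step, metabolite coefficient), in route order.
#'
#' @param lists a [ReactionListSet-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeReactionLists <- function(lists, path) {
  stopifnot(is(lists, "ReactionListSet"))
  cols <- c("protein_id", "step_index", "reaction_id", "subsystem_id",
            "metabolite", "coefficient")
  utils::write.table(lists@steps[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
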