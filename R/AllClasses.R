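#' @import methods
NULL

.LOCALIZATIONS <- c("ER", "Golgi", "membrane", "vacuole", "extracellular",
                    "unknown")

.PSIM_FEATURES <- c("signal_peptide", "n_glyc_sites", "o_glyc_sites",
                    "disulfide_bonds", "gpi_anchor", "tm_domains",
                    "localization")

.SIGNATURE_SLOTS <- c("signal_peptide", "n_glyc", "o_glyc", "disulfide",
                      "gpi", "tm", "localization")

#' PSIM: Protein Specific Information Matrix
#'
#' An ordered collection of per-protein secretory feature records: presence of
#' an N-terminal signal peptide, numbers of N- and O-linked glycosylation
#' sites, number of disulfide bonds, GPI anchoring, number of transmembrane
#' domains, and final localization. Counts are kept quantitative; presence /
#' absence booleanization happens only at classification time.
#'
#' @slot records data.frame with one row per protein. Mandatory columns:
#'   `protein_id` (unique character), `signal_peptide` (logical),
#'   `n_glyc_sites`, `o_glyc_sites`, `disulfide_bonds`, `tm_domains`
#'   (non-negative integers), `gpi_anchor` (logical), `localization`
#'   (one of ER, Golgi, membrane, vacuole, extracellular, unknown).
#'   Optional: `abundance` (molecules per cell), `sequence_length`
#'   (residues). Extra columns (e.g. the eighth column of human-style
#'   tables) are preserved as opaque pass-through attributes.
#' @slot parseReport data.frame of rows dropped or flagged at read time
#'   (columns `row`, `protein_id`, `problem`).
#'
#' @seealso [readPSIM()], [writePSIM()], [summarizeFeatures()]
#' @export
setClass("PSIM",
  representation(records = "data.frame", parseReport = "data.frame"),
  prototype(records = data.frame(), parseReport = data.frame())
)

setValidity("PSIM", function(object) {
  rec <- object@records
  if (nrow(rec) == 0L) return(TRUE)
  msgs <- character()
  need <- c("protein_id", .PSIM_FEATURES)
  miss <- setdiff(need, names(rec))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(rec$protein_id))
    msgs <- c(msgs, "protein_id values must be unique")
  for (cc in c("n_glyc_sites", "o_glyc_sites", "disulfide_bonds",
               "tm_domains")) {
    v <- rec[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v)))
      msgs <- c(msgs, sprintf("%s must be non-negative integers", cc))
  }
  for (cc in c("signal_peptide", "gpi_anchor"))
    if (!is.logical(rec[[cc]]) || any(is.na(rec[[cc]])))
      msgs <- c(msgs, sprintf("%s must be TRUE/FALSE", cc))
  if (!all(rec$localization %in% .LOCALIZATIONS))
    msgs <- c(msgs, sprintf("localization must be one of: %s",
                            paste(.LOCALIZATIONS, collapse = ", ")))
  if ("abundance" %in% names(rec) &&
      any(rec$abundance < 0, na.rm = TRUE))
    msgs <- c(msgs, "abundance must be >= 0")
  if ("sequence_length" %in% names(rec) &&
      any(rec$sequence_length < 1, na.rm = TRUE))
    msgs <- c(msgs, "sequence_length must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' ClassCatalog: enumerated theoretical secretory classes
#'
#' The combinatorial catalog of secretory classes: every feasible combination
#' of booleanized secretory features plus final localization, split into the
#' SP+ category (N-terminal signal peptide) and the SP- category (signal
#' anchor in a transmembrane domain), with one unknown-localization catch-all
#' class per category. Under the default feasibility configuration the
#' catalog holds 186 classes: 104 regular SP+, 80 regular SP-, 2 catch-alls.
#'
#' @slot classes data.frame with columns `class_id` (integer, 0-based),
#'   `category` ("SP_plus"/"SP_minus"), `signal_peptide`, `n_glyc`, `o_glyc`,
#'   `disulfide`, `gpi`, `tm` (logical signature slots), `localization`,
#'   `catch_all` (logical).
#' @slot config the feasibility rule set (see [constraintConfig()]) that
#'   produced the catalog.
#' @export
setClass("ClassCatalog",
  representation(classes = "data.frame", config = "list"),
  prototype(classes = data.frame(), config = list())
)

setValidity("ClassCatalog", function(object) {
  cl <- object@classes
  if (nrow(cl) == 0L) return(TRUE)
  need <- c("class_id", "category", .SIGNATURE_SLOTS, "catch_all")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  sig <- do.call(paste, c(cl[.SIGNATURE_SLOTS], list(sep = "|")))
  if (anyDuplicated(sig)) return("duplicate class signatures")
  bad <- (cl$category == "SP_plus") != cl$signal_peptide
  if (any(bad)) return("category must be SP_plus iff signal_peptide is TRUE")
  TRUE
})

#' MachineryModel: the secretory machinery network
#'
#' A machine-readable reconstruction of the secretory machinery: molecular
#' components grouped into functional subsystems, membrane compartments, a
#' metabolite registry, and reactions in four categories (template,
#' complex formation, biosynthesis, exchange). The packaged yeast model
#' (see [yeastModel()]) holds 163 components (162 proteins + the SCR1 RNA),
#' 16 subsystems, 8 compartments and 137 reactions (56/26/30/25 by
#' category).
#'
#' @slot components data.frame: `component_id`, `name`, `kind`
#'   ("protein"/"RNA"), `subsystems` (comma-separated subsystem ids).
#' @slot subsystems data.frame: `subsystem_id` (S1..S16), `name`.
#' @slot compartments character vector of compartment ids.
#' @slot reactions list of reaction records (id, category, subsystem,
#'   compartment, metabolite stoichiometry, catalysts, applicability and
#'   scale expressions, note).
#' @slot complexes named list: complex id -> character vector of member
#'   component ids (defined by the complex-formation reactions).
#' @slot metabolites character vector: the metabolite registry.
#' @slot source path of the model document the object was loaded from.
#' @export
setClass("MachineryModel",
  representation(components = "data.frame", subsystems = "data.frame",
                 compartments = "character", reactions = "list",
                 complexes = "list", metabolites = "character",
                 source = "character"),
  prototype(components = data.frame(), subsystems = data.frame(),
            compartments = character(), reactions = list(),
            complexes = list(), metabolites = character(), source = NA_character_)
)

#' ReactionListSet: instantiated protein-specific reaction lists
#'
#' The output of the virtual secretory machinery: for each client protein,
#' the ordered list of machinery reactions it traverses (subsystem order
#' S1 -> S16) with feature-scaled metabolite stoichiometry.
#'
#' @slot steps data.frame with one row per (protein, step, metabolite
#'   coefficient): `protein_id`, `step_index`, `reaction_id`, `subsystem_id`,
#'   `compartment_id`, `metabolite` (NA for metabolite-free steps),
#'   `coefficient` (positive = consumed, negative = produced).
#' @slot proteins data.frame with one row per input protein: `protein_id`,
#'   `class_id`, `category`, `client` (logical), `n_steps`.
#' @slot options list of generation options used (misfold fraction,
#'   vacuolar-route overrides, ...).
#' @export
setClass("ReactionListSet",
  representation(steps = "data.frame", proteins = "data.frame",
                 options = "list"),
  prototype(steps = data.frame(), proteins = data.frame(), options = list())
)

#' DemandReport: steady-state metabolite consumption
#'
#' Metabolite consumption rates of the machinery at steady state
#' (molecules per cell per hour), with groupings by machinery subsystem and
#' by client compartment x membrane class (luminal, single-pass TM,
#' multi-pass TM, GPI-anchored).
#'
#' @slot totals data.frame: `metabolite`, `consumption` (gross draw,
#'   cell^-1 h^-1), `net` (consumption minus production of pathway
#'   intermediates).
#' @slot bySubsystem data.frame: `subsystem_id`, `metabolite`, `consumption`.
#' @slot byCompartment data.frame: `compartment`, `membrane_class`,
#'   `metabolite`, `consumption`.
#' @slot reactionRates named numeric: steady-state rate v_j of every
#'   instantiated reaction (cell^-1 h^-1).
#' @slot mu specific growth rate (h^-1) used.
#' @export
setClass("DemandReport",
  representation(totals = "data.frame", bySubsystem = "data.frame",
                 byCompartment = "data.frame", reactionRates = "numeric",
                 mu = "numeric"),
  prototype(totals = data.frame(), bySubsystem = data.frame(),
            byCompartment = data.frame(), reactionRates = numeric(),
            mu = NA_real_)
)

#' ActivityReport: specific activity of machinery components
#'
#' Per-component specific activity (SA): catalytic cycles per cell per hour
#' at steady state, i.e. the summed rate of the reactions a component
#' catalyzes (directly or through a complex) divided by the component's own
#' abundance.
#'
#' @slot activities data.frame: `component_id`, `abundance`, `catalyzed_flux`,
#'   `SA`, `log10SA`, `n_reactions`, `status` ("ok", "zero_abundance",
#'   "no_reactions", "undefined").
#' @slot fit named numeric: `mean` and `sd` of log10(SA) over defined,
#'   positive SA values (NA until [saDistribution()] is called with >= 2
#'   values).
#' @export
setClass("ActivityReport",
  representation(activities = "data.frame", fit = "numeric"),
  prototype(activities = data.frame(), fit = c(mean = NA_real_, sd = NA_real_))
)

## ---- show methods -------------------------------------------------------

setMethod("show", "PSIM", function(object) {
  cat(sprintf("PSIM with %d protein record(s)\n", nrow(object@records)))
  if (nrow(object@records)) {
    loc <- table(object@records$localization)
    cat("  localization:",
        paste(sprintf("%s=%d", names(loc), as.integer(loc)), collapse = ", "),
        "\n")
  }
  if (nrow(object@parseReport))
    cat(sprintf("  %d row(s) flagged at parse time\n",
                nrow(object@parseReport)))
})

setMethod("show", "ClassCatalog", function(object) {
  cl <- object@classes
  cat(sprintf("ClassCatalog with %d secretory class(es)\n", nrow(cl)))
  if (nrow(cl)) {
    reg <- cl[!cl$catch_all, ]
    cat(sprintf("  regular SP+: %d, regular SP-: %d, catch-alls: %d\n",
                sum(reg$category == "SP_plus"),
                sum(reg$category == "SP_minus"), sum(cl$catch_all)))
  }
})

setMethod("show", "MachineryModel", function(object) {
  cats <- vapply(object@reactions, `[[`, "", "category")
  cat(sprintf(paste0("MachineryModel: %d components, %d subsystems, ",
                     "%d compartments, %d reactions\n"),
              nrow(object@components), nrow(object@subsystems),
              length(object@compartments), length(object@reactions)))
  if (length(cats)) {
    tb <- table(factor(cats, levels = c("template", "complex_formation",
                                        "biosynthesis", "exchange")))
    cat("  reactions:",
        paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
        "\n")
  }
})

setMethod("show", "ReactionListSet", function(object) {
  pr <- object@proteins
  cat(sprintf("ReactionListSet: %d protein(s), %d client(s), %d step(s)\n",
              nrow(pr), sum(pr$client), sum(pr$n_steps)))
})

setMethod("show", "DemandReport", function(object) {
  cat(sprintf("DemandReport (mu = %g h^-1): %d metabolite(s)\n",
              object@mu, nrow(object@totals)))
  if (nrow(object@totals)) {
    top <- utils::head(object@totals[order(-object@totals$consumption), ], 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %-12s %.4g cell^-1 h^-1\n",
                  top$metabolite[i], top$consumption[i]))
  }
})

setMethod("show", "ActivityReport", function(object) {
  a <- object@activities
  ok <- a$status == "ok" & is.finite(a$log10SA)
  cat(sprintf("ActivityReport: %d component(s), %d with defined SA\n",
              nrow(a), sum(ok)))
  if (!is.na(object@fit["mean"]))
    cat(sprintf("  log10(SA) fit: mean = %.3f, sd = %.3f\n",
                object@fit["mean"], object@fit["sd"]))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for secflux containers
#'
#' Small accessor functions in place of direct slot access.
#'
#' @param x a [PSIM-class], [ClassCatalog-class], [MachineryModel-class],
#'   [ReactionListSet-class], [DemandReport-class] or
#'   [ActivityReport-class] object, as appropriate.
#' @return A data.frame (or list / numeric, as documented per accessor).
#' @name accessors
NULL

#' @rdname accessors
#' @export
records <- function(x) {
  stopifnot(is(x, "PSIM"))
  x@records
}

#' @rdname accessors
#' @export
parseReport <- function(x) {
  stopifnot(is(x, "PSIM"))
  x@parseReport
}

#' @rdname accessors
#' @export
catalogClasses <- function(x) {
  stopifnot(is(x, "ClassCatalog"))
  x@classes
}

#' @rdname accessors
#' @export
modelComponents <- function(x) {
  stopifnot(is(x, "MachineryModel"))
  x@components
}

#' @rdname accessors
#' @export
modelSubsystems <- function(x) {
  stopifnot(is(x, "MachineryModel"))
  x@subsystems
}

#' @rdname accessors
#' @export
modelCompartments <- function(x) {
  stopifnot(is(x, "MachineryModel"))
  x@compartments
}

#' @rdname accessors
#' @export
modelReactions <- function(x) {
  stopifnot(is(x, "MachineryModel"))
  x@reactions
}

#' @rdname accessors
#' @export
modelComplexes <- function(x) {
  stopifnot(is(x, "MachineryModel"))
  x@complexes
}

#' @rdname accessors
#' @export
modelMetabolites <- function(x) {
  stopifnot(is(x, "MachineryModel"))
  x@metabolites
}

#' @rdname accessors
#' @export
reactionSteps <- function(x) {
  stopifnot(is(x, "ReactionListSet"))
  x@steps
}

#' @rdname accessors
#' @export
reactionProteins <- function(x) {
  stopifnot(is(x, "ReactionListSet"))
  x@proteins
}

#' @rdname accessors
#' @export
demandTotals <- function(x) {
  stopifnot(is(x, "DemandReport"))
  x@totals
}

#' @rdname accessors
#' @export
demandBySubsystem <- function(x) {
  stopifnot(is(x, "DemandReport"))
  x@bySubsystem
}

#' @rdname accessors
#' @export
demandByCompartment <- function(x) {
  stopifnot(is(x, "DemandReport"))
  x@byCompartment
}

#' @rdname accessors
#' @export
demandReactionRates <- function(x) {
  stopifnot(is(x, "DemandReport"))
  x@reactionRates
}

#' @rdname accessors
#' @export
activities <- function(x) {
  stopifnot(is(x, "ActivityReport"))
  x@activities
}

#' Number of records / classes in a container
#' @param x a PSIM or ClassCatalog
#' @return integer count
#' @export
setMethod("length", "PSIM", function(x) nrow(x@records))

#' @rdname length-PSIM-method
#' @export
setMethod("length", "ClassCatalog", function(x) nrow(x@classes))
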