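#' Amino acid biosynthesis cost table
#'
#' Per-residue biosynthetic costs in ATP and NADPH equivalents, shipped as
#' an editable TSV (textbook-derived values with per-entry source notes),
#' plus the polymerization cost per peptide bond: 4 ATP equivalents
#' (2 ATP for tRNA charging, 1 GTP for ribosome binding, 1 GTP for
#' elongation).
#'
#' @param path TSV with columns `aa` (one-letter code), `atp`, `nadph`;
#'   defaults to the packaged table.
#' @param bond_cost ATP equivalents per peptide bond (default 4).
#' @return list with `costs` (data.frame, 20 rows) and `bond_cost`.
#' @export
aaCostTable <- function(path = system.file("extdata", "aa_costs.tsv",
                                           package = "secflux"),
                        bond_cost = 4) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("aa", "atp", "nadph") %in% names(tb)))
    stop("cost table needs columns: aa, atp, nadph")
  if (nrow(tb) != 20L || anyDuplicated(tb$aa))
    stop("cost table must have exactly one entry per amino acid (20)")
  list(costs = tb, bond_cost = bond_cost)
}

#' A zero-cost amino-acid table (polymerization cost only)
#'
#' Convenience for isolating the translational polymerization term of the
#' synthesis-cost calculation: all 20 biosynthesis costs are zero.
#'
#' @param bond_cost ATP equivalents per peptide bond (default 4).
#' @return list as in [aaCostTable()].
#' @export
zeroCostTable <- function(bond_cost = 4) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  list(costs = data.frame(aa = aas, atp = 0, nadph = 0),
       bond_cost = bond_cost)
}

#' Steady-state context for demand calculations
#'
#' @param mu specific growth rate (h^-1); required, must be > 0. (The
#'   choice is organism- and condition-specific; 0.35 h^-1 is a typical
#'   value for exponential growth of yeast on glucose, offered here only
#'   as an illustration.)
#' @param abundances named numeric: protein_id -> steady-state abundance
#'   (molecules per cell).
#' @param default_abundance abundance assumed for proteins missing from
#'   the table; default 1 molecule per cell, keeping unmeasured clients in
#'   the model with a negligible contribution.
#' @return list context consumed by [reactionRates()] and
#'   [metaboliteDemand()].
#' @export
costContext <- function(mu, abundances = numeric(), default_abundance = 1) {
  .assertScalarNumber(mu, "mu")
  if (mu <= 0) stop("'mu' must be > 0")
  if (length(abundances) && (is.null(names(abundances)) ||
                             any(abundances < 0, na.rm = TRUE)))
    stop("'abundances' must be a named, non-negative numeric vector")
  .assertScalarNumber(default_abundance, "default_abundance", min = 0)
  list(mu = mu, abundances = abundances,
       default_abundance = default_abundance)
}

#' Steady-state processing rate of a protein
#'
#' At steady state the machinery must process each client at the rate its
#' pool is diluted by growth: v_p = mu * P_p (molecules per cell per hour).
#'
#' @param abundance steady-state abundance P_p (molecules per cell),
#'   vectorized.
#' @param mu specific growth rate (h^-1).
#' @return numeric vector of processing rates.
#' @examples
#' processingRate(1000, 0.1)  # 100
#' @export
processingRate <- function(abundance, mu) {
  if (any(abundance < 0, na.rm = TRUE)) stop("'abundance' must be >= 0")
  .assertScalarNumber(mu, "mu", min = 0)
  mu * abundance
}

.proteinRates <- function(protein_ids, context) {
  ab <- context$abundances[protein_ids]
  ab[is.na(ab)] <- context$default_abundance
  stats::setNames(processingRate(as.numeric(ab), context$mu), protein_ids)
}

#' Steady-state rate of each machinery reaction
#'
#' The rate of reaction j is the summed processing rate of every client
#' whose reaction list contains j: v_j = sum_p S_jp * v_p, with S_jp the
#' 0/1 membership of reaction j in list p.
#'
#' @param lists a [ReactionListSet-class].
#' @param context a [costContext()].
#' @return named numeric: reaction_id -> v_j (cell^-1 h^-1).
#' @export
reactionRates <- function(lists, context) {
  stopifnot(is(lists, "ReactionListSet"))
  st <- lists@steps
  if (nrow(st) == 0L) return(stats::setNames(numeric(), character()))
  memb <- unique(st[, c("protein_id", "reaction_id")])
  vp <- .proteinRates(unique(memb$protein_id), context)
  agg <- stats::aggregate(list(v = vp[memb$protein_id]),
                          by = list(reaction_id = memb$reaction_id), sum)
  stats::setNames(agg$v, agg$reaction_id)
}

#' Steady-state metabolite demand of the machinery
#'
#' Propagates client processing rates through the instantiated
#' (feature-scaled) reaction stoichiometry: the consumption rate of
#' metabolite x is r_x = sum over lists and steps of C_x * v_p
#' (cell^-1 h^-1). Reported as gross consumption (positive coefficients
#' only, the boundary draw) and net (consumption minus production of
#' pathway intermediates), grouped by machinery subsystem and, when the
#' feature records are supplied, by client compartment x membrane class
#' (luminal, single-pass TM, multi-pass TM, GPI-anchored).
#'
#' @param lists a [ReactionListSet-class].
#' @param model a [MachineryModel-class] (metabolite registry check).
#' @param context a [costContext()].
#' @param psim optional [PSIM-class]; enables the compartment x membrane
#'   class grouping.
#' @return a [DemandReport-class].
#' @export
metaboliteDemand <- function(lists, model, context, psim = NULL) {
  stopifnot(is(lists, "ReactionListSet"), is(model, "MachineryModel"))
  st <- lists@steps
  st <- st[!is.na(st$metabolite), , drop = FALSE]
  if (nrow(st)) {
    unknown <- setdiff(unique(st$metabolite), model@metabolites)
    if (length(unknown))
      stop(sprintf("metabolite(s) absent from the model registry: %s",
                   paste(unknown, collapse = ", ")))
  }
  vj <- reactionRates(lists, context)
  empty <- data.frame(metabolite = character(), consumption = numeric(),
                      net = numeric())
  if (nrow(st) == 0L)
    return(new("DemandReport", totals = empty,
               bySubsystem = data.frame(), byCompartment = data.frame(),
               reactionRates = vj, mu = context$mu))
  vp <- .proteinRates(unique(st$protein_id), context)
  st$rate <- st$coefficient * vp[st$protein_id]
  cons <- pmax(st$rate, 0)
  totals <- stats::aggregate(
    cbind(consumption = cons, net = st$rate),
    by = list(metabolite = st$metabolite), sum)
  totals <- totals[order(totals$metabolite), ]
  rownames(totals) <- NULL
  bySub <- stats::aggregate(
    list(consumption = cons),
    by = list(subsystem_id = st$subsystem_id, metabolite = st$metabolite),
    sum)
  bySub <- bySub[order(match(bySub$subsystem_id,
                             model@subsystems$subsystem_id),
                       bySub$metabolite), ]
  rownames(bySub) <- NULL
  byComp <- data.frame()
  if (!is.null(psim)) {
    rec <- if (is(psim, "PSIM")) psim@records else psim
    idx <- match(st$protein_id, rec$protein_id)
    mclass <- ifelse(rec$gpi_anchor[idx], "GPI-anchored",
              ifelse(rec$tm_domains[idx] == 0, "luminal",
              ifelse(rec$tm_domains[idx] == 1, "single-pass TM",
                     "multi-pass TM")))
    byComp <- stats::aggregate(
      list(consumption = cons),
      by = list(compartment = rec$localization[idx],
                membrane_class = mclass, metabolite = st$metabolite),
      sum)
    byComp <- byComp[order(byComp$compartment, byComp$membrane_class,
                           byComp$metabolite), ]
    rownames(byComp) <- NULL
  }
  new("DemandReport", totals = totals, bySubsystem = bySub,
      byCompartment = byComp, reactionRates = vj, mu = context$mu)
}

#' Protein synthesis cost in ATP and NADPH equivalents
#'
#' Sums per-residue biosynthesis costs with the translational
#' polymerization cost: cost = sum_aa n_aa * c_aa + bond_cost * (L - 1),
#' where L is the sequence length and bond_cost (default 4 ATP
#' equivalents per peptide bond) covers tRNA charging (2 ATP) plus
#' ribosome binding and elongation (1 GTP each).
#'
#' @param x an amino-acid sequence (character string or
#'   [Biostrings::AAString]), or a named integer vector of residue counts.
#' @param cost_table a cost table from [aaCostTable()] or
#'   [zeroCostTable()].
#' @return named numeric: `atp` and `nadph` equivalents.
#' @examples
#' synthesisCost("GA", zeroCostTable())["atp"]  # 4: one peptide bond
#' @export
synthesisCost <- function(x, cost_table = aaCostTable()) {
  costs <- cost_table$costs
  if (is.numeric(x)) {
    counts <- x
    bad <- setdiff(names(counts), costs$aa)
    if (length(bad))
      stop(sprintf("unknown residue(s) in counts: %s",
                   paste(bad, collapse = ", ")))
    len <- sum(counts)
  } else {
    s <- as.character(x)
    if (length(s) != 1L || nchar(s) == 0L)
      stop("'x' must be one non-empty sequence")
    resv <- strsplit(toupper(s), "")[[1]]
    bad <- which(!(resv %in% costs$aa))
    if (length(bad))
      stop(sprintf("unknown residue '%s' at position %d",
                   resv[bad[1]], bad[1]))
    counts <- table(resv)
    len <- length(resv)
  }
  if (len < 1) stop("sequence must contain at least one residue")
  idx <- match(names(counts), costs$aa)
  atp <- sum(as.numeric(counts) * costs$atp[idx]) +
    cost_table$bond_cost * (len - 1)
  nadph <- sum(as.numeric(counts) * costs$nadph[idx])
  c(atp = atp, nadph = nadph)
}

#' Read an abundance table
#'
#' TSV with columns `protein_id` and `molecules_per_cell`.
#'
#' @param path TSV path.
#' @return named numeric vector.
#' @export
readAbundances <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "molecules_per_cell") %in% names(tb)))
    stop("abundance table needs columns: protein_id, molecules_per_cell")
  stats::setNames(tb$molecules_per_cell, tb$protein_id)
}

#' Write a demand report as tidy TSV
#'
#' @param report a [DemandReport-class].
#' @param path output TSV (totals); per-subsystem rows are appended with a
#'   `subsystem_id` column when present.
#' @return `path`, invisibly.
#' @export
writeDemandReport <- function(report, path) {
  stopifnot(is(report, "DemandReport"))
  tot <- report@totals
  tot$subsystem_id <- "all"
  sub <- report@bySubsystem
  if (nrow(sub)) {
    sub$net <- NA_real_
    sub <- sub[, c("metabolite", "consumption", "net", "subsystem_id")]
    tot <- rbind(tot, sub)
  }
  utils::write.table(tot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
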