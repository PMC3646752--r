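#' Specific activity of machinery components
#'
#' The specific activity (SA) of a machinery component is the number of
#' catalytic cycles it performs per cell per hour at steady state: the
#' summed rate of the reactions it catalyzes, weighted by its catalytic
#' stoichiometry (default 1 per participation), divided by its own
#' abundance: SA_i = sum_j v_j * sigma_ij / C_i. A component participating
#' through a complex inherits the flux of the reactions the complex
#' catalyzes; a reaction is counted once per component even when it
#' appears in several subsystems.
#'
#' Components with zero abundance but nonzero catalyzed flux are flagged
#' `undefined`, never silently dropped; components with no catalyzed
#' reactions are flagged `no_reactions`.
#'
#' @param model a [MachineryModel-class].
#' @param reaction_rates named numeric v_j from [reactionRates()].
#' @param component_abundances named numeric: component_id -> C_i
#'   (molecules per cell).
#' @return an [ActivityReport-class].
#' @examples
#' m <- yeastModel()
#' v <- c(T14_CHAPERONE_FOLDING = 100)
#' rep <- specificActivity(m, v, c(KAR2 = 50, LHS1 = 50, SIL1 = 50,
#'                                 SCJ1 = 50, JEM1 = 50))
#' activities(rep)[activities(rep)$component_id == "KAR2", "SA"]  # 2
#' @export
specificActivity <- function(model, reaction_rates, component_abundances) {
  stopifnot(is(model, "MachineryModel"))
  unknown <- setdiff(names(component_abundances),
                     model@components$component_id)
  if (length(unknown))
    stop(sprintf("abundance(s) for unknown component(s): %s",
                 paste(unknown, collapse = ", ")))
  ## map each reaction to the atomic components catalyzing it
  flux <- stats::setNames(numeric(nrow(model@components)),
                          model@components$component_id)
  nrx <- stats::setNames(integer(nrow(model@components)),
                         model@components$component_id)
  for (rid in names(reaction_rates)) {
    r <- model@reactions[[rid]]
    if (is.null(r)) next
    cats <- unlist(r$catalysts)
    if (!length(cats)) next
    sigma <- r$sigma %||% 1
    members <- unique(unlist(lapply(cats, function(cc)
      if (cc %in% names(model@complexes)) model@complexes[[cc]] else cc)))
    flux[members] <- flux[members] + reaction_rates[[rid]] * sigma
    nrx[members] <- nrx[members] + 1L
  }
  ids <- model@components$component_id
  ab <- component_abundances[ids]
  a <- data.frame(component_id = ids, abundance = as.numeric(ab),
                  catalyzed_flux = as.numeric(flux[ids]),
                  n_reactions = as.integer(nrx[ids]),
                  stringsAsFactors = FALSE)
  a$SA <- NA_real_
  a$status <- "ok"
  a$status[a$n_reactions == 0L] <- "no_reactions"
  noAb <- is.na(a$abundance) | a$abundance == 0
  a$status[noAb & a$catalyzed_flux > 0] <- "undefined"
  a$status[noAb & a$catalyzed_flux <= 0 &
             a$status == "ok"] <- "zero_abundance"
  ok <- a$status == "ok"
  a$SA[ok] <- a$catalyzed_flux[ok] / a$abundance[ok]
  a$log10SA <- ifelse(!is.na(a$SA) & a$SA > 0, log10(a$SA), NA_real_)
  new("ActivityReport", activities = a,
      fit = c(mean = NA_real_, sd = NA_real_))
}

#' Distribution of log10 specific activity
#'
#' Histogram bins and a normal summary (mean, sd) of log10(SA) over
#' components with defined, positive SA. Requires at least two such
#' values.
#'
#' @param report an [ActivityReport-class].
#' @param bins number of histogram bins (deterministic equal-width edges).
#' @return list with `mean`, `sd`, `n`, `breaks`, `counts`, and the
#'   updated report (`report`) carrying the fit.
#' @export
saDistribution <- function(report, bins = 20) {
  stopifnot(is(report, "ActivityReport"))
  x <- report@activities$log10SA
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    stop("need at least 2 positive SA values to summarize a distribution")
  m <- mean(x)
  s <- stats::sd(x)
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE)))
  report@fit <- c(mean = m, sd = s)
  list(mean = m, sd = s, n = length(x), breaks = breaks, counts = counts,
       report = report)
}

#' Components above a specific-activity threshold
#'
#' Returns the components whose log10(SA) exceeds a threshold, sorted by
#' descending SA (ties broken by component id) — the natural shortlist of
#' high-turnover machinery parts.
#'
#' @param report an [ActivityReport-class].
#' @param threshold_log10 keep components with log10(SA) > this value
#'   (e.g. 3 for more than 1000 cycles per cell per hour).
#' @return data.frame subset of `activities(report)`, ordered.
#' @export
rankComponents <- function(report, threshold_log10 = 3) {
  stopifnot(is(report, "ActivityReport"))
  a <- report@activities
  a <- a[!is.na(a$log10SA) & a$log10SA > threshold_log10, , drop = FALSE]
  a <- a[order(-a$SA, a$component_id), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Write an activity report as TSV
#'
#' @param report an [ActivityReport-class].
#' @param model a [MachineryModel-class] (adds subsystem memberships).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeActivityReport <- function(report, model, path) {
  a <- report@activities
  a$subsystems <- model@components$subsystems[
    match(a$component_id, model@components$component_id)]
  utils::write.table(a, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
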