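#' Default feasibility configuration for class enumeration
#'
#' The decision tree that generates the theoretical secretory classes is
#' encoded as a list of enumeration blocks. Each block fixes or frees the
#' six boolean signature slots and lists the admissible localizations; the
#' catalog is the union of the blocks' cartesian products plus (optionally)
#' one unknown-localization catch-all class per category.
#'
#' The default rule set factorizes as: SP+ category = 2^3 (N-/O-glyc,
#' disulfide free) x three membrane states (GPI-anchored with 3 admissible
#' localizations; non-GPI membrane-spanning with 5; non-GPI soluble with 5)
#' = 8 x 13 = 104 regular classes. SP- category = TM forced present (the
#' signal anchor is the ER-entry signal), GPI free, 2^3 x 2 x 5 = 80
#' regular classes. Plus 2 catch-alls = 186.
#'
#' @param gpi_localizations admissible final localizations for GPI-anchored
#'   classes (the least certain default; membrane, extracellular and
#'   vacuole are admitted).
#' @param catch_alls logical: append one unknown-localization catch-all
#'   class per category.
#' @return list of blocks understood by [enumerateClasses()]. Each block
#'   has entries `signal_peptide`, `n_glyc`, `o_glyc`, `disulfide`, `gpi`,
#'   `tm` (logical vectors of admissible values) and `localization`
#'   (character vector).
#' @export
constraintConfig <- function(gpi_localizations = c("membrane",
                                                   "extracellular",
                                                   "vacuole"),
                             catch_alls = TRUE) {
  known <- setdiff(.LOCALIZATIONS, "unknown")
  free <- c(FALSE, TRUE)
  blocks <- list(
    ## SP+ / GPI-anchored (membrane state: GPI; TM slot booleanizes FALSE)
    list(signal_peptide = TRUE, n_glyc = free, o_glyc = free,
         disulfide = free, gpi = TRUE, tm = FALSE,
         localization = gpi_localizations),
    ## SP+ / non-GPI membrane-spanning
    list(signal_peptide = TRUE, n_glyc = free, o_glyc = free,
         disulfide = free, gpi = FALSE, tm = TRUE, localization = known),
    ## SP+ / non-GPI soluble
    list(signal_peptide = TRUE, n_glyc = free, o_glyc = free,
         disulfide = free, gpi = FALSE, tm = FALSE, localization = known),
    ## SP- : signal anchor in a TM domain; TM forced present, GPI free
    list(signal_peptide = FALSE, n_glyc = free, o_glyc = free,
         disulfide = free, gpi = free, tm = TRUE, localization = known)
  )
  list(blocks = blocks, catch_alls = catch_alls)
}

#' Enumerate the theoretical secretory classes
#'
#' Expands the feasibility configuration into the full catalog of secretory
#' classes. Ordering is deterministic: SP+ category first, then
#' lexicographic over the signature slots in the order signal peptide,
#' N-glyc, O-glyc, disulfide, GPI, TM, localization (localizations in the
#' order ER, Golgi, membrane, vacuole, extracellular); catch-all classes
#' come last. Class ids are 0-based.
#'
#' @param config a configuration from [constraintConfig()] (default yields
#'   186 classes).
#' @return a [ClassCatalog-class].
#' @examples
#' length(enumerateClasses())  # 186
#' @export
enumerateClasses <- function(config = constraintConfig()) {
  if (!is.list(config) || is.null(config$blocks))
    stop("configuration error: 'config' must have a 'blocks' list")
  rows <- list()
  for (b in config$blocks) {
    for (slot in c("signal_peptide", "n_glyc", "o_glyc", "disulfide",
                   "gpi", "tm"))
      if (length(b[[slot]]) == 0L)
        stop(sprintf("configuration error: slot '%s' admits no value", slot))
    if (length(b$localization) == 0L)
      stop("configuration error: no admissible localization")
    if (any(!b$localization %in% .LOCALIZATIONS))
      stop("configuration error: unknown localization token")
    g <- expand.grid(signal_peptide = b$signal_peptide, n_glyc = b$n_glyc,
                     o_glyc = b$o_glyc, disulfide = b$disulfide,
                     gpi = b$gpi, tm = b$tm,
                     localization = b$localization,
                     stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- g
  }
  cl <- do.call(rbind, rows)
  sig <- do.call(paste, c(cl[.SIGNATURE_SLOTS], list(sep = "|")))
  if (anyDuplicated(sig)) {
    dup <- duplicated(sig)
    cl <- cl[!dup, , drop = FALSE]
  }
  locOrd <- match(cl$localization, .LOCALIZATIONS)
  ord <- order(!cl$signal_peptide,        # SP+ first
               cl$n_glyc, cl$o_glyc, cl$disulfide, cl$gpi, cl$tm, locOrd)
  cl <- cl[ord, , drop = FALSE]
  cl$catch_all <- FALSE
  if (isTRUE(config$catch_alls)) {
    ca <- data.frame(signal_peptide = c(TRUE, FALSE), n_glyc = FALSE,
                     o_glyc = FALSE, disulfide = FALSE, gpi = FALSE,
                     tm = c(FALSE, TRUE), localization = "unknown",
                     catch_all = TRUE, stringsAsFactors = FALSE)
    cl <- rbind(cl, ca)
  }
  cl$category <- ifelse(cl$signal_peptide, "SP_plus", "SP_minus")
  cl$class_id <- seq_len(nrow(cl)) - 1L
  cl <- cl[, c("class_id", "category", .SIGNATURE_SLOTS, "catch_all")]
  rownames(cl) <- NULL
  new("ClassCatalog", classes = cl, config = config)
}

#' Assign feature records to secretory classes
#'
#' Booleanizes each record's features and looks up its secretory class.
#' Records with a signal peptide join the SP+ category; records without
#' one but with at least one transmembrane domain enter the ER via the
#' signal anchor in their TM segment (SP- category); records with neither
#' are not clients of the machinery and receive `NA`. Unknown localization
#' maps to the category's catch-all class. For GPI-anchored records the TM
#' slot booleanizes to absent (the GPI membrane state dominates).
#'
#' @param psim a [PSIM-class] (or a single-row records data.frame).
#' @param catalog a [ClassCatalog-class].
#' @return data.frame with columns `protein_id`, `class_id` (NA for
#'   non-clients), `category` (NA for non-clients), `client` (logical) and
#'   `note` (diagnostic for catch-all or out-of-catalog assignments).
#' @examples
#' cat186 <- enumerateClasses()
#' p <- PSIM(data.frame(protein_id = c("CWP2", "PMA1", "CYT1"),
#'   signal_peptide = c(TRUE, FALSE, FALSE),
#'   n_glyc_sites = c(0L, 4L, 0L), o_glyc_sites = c(4L, 0L, 0L),
#'   disulfide_bonds = 0L, gpi_anchor = c(TRUE, FALSE, FALSE),
#'   tm_domains = c(0L, 10L, 0L),
#'   localization = c("extracellular", "membrane", "unknown")))
#' classifyProteins(p, cat186)
#' @export
classifyProteins <- function(psim, catalog) {
  stopifnot(is(catalog, "ClassCatalog"))
  rec <- if (is(psim, "PSIM")) psim@records else psim
  cl <- catalog@classes
  sigKey <- do.call(paste, c(cl[.SIGNATURE_SLOTS], list(sep = "|")))
  n <- if (is.null(rec) || !nrow(rec)) 0L else nrow(rec)
  out <- data.frame(protein_id = character(n),
                    class_id = rep(NA_integer_, n),
                    category = rep(NA_character_, n),
                    client = rep(FALSE, n),
                    note = rep(NA_character_, n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  out$protein_id <- rec$protein_id
  for (i in seq_len(n)) {
    b <- .booleanize(rec[i, ])
    if (!b$signal_peptide && rec$tm_domains[i] == 0) next  # NOT_CLIENT
    category <- if (b$signal_peptide) "SP_plus" else "SP_minus"
    out$client[i] <- TRUE
    out$category[i] <- category
    if (b$localization == "unknown") {
      hit <- which(cl$catch_all & cl$category == category)
      out$class_id[i] <- cl$class_id[hit]
      out$note[i] <- "unknown localization: catch-all class"
      next
    }
    key <- paste(b$signal_peptide, b$n_glyc, b$o_glyc, b$disulfide, b$gpi,
                 b$tm, b$localization, sep = "|")
    hit <- which(sigKey == key & !cl$catch_all)
    if (length(hit) == 1L) {
      out$class_id[i] <- cl$class_id[hit]
    } else {
      ## feasible record with no regular class under this configuration
      ## (e.g. GPI-anchored with a localization outside the admissible set)
      hit <- which(cl$catch_all & cl$category == category)
      out$class_id[i] <- cl$class_id[hit]
      out$note[i] <- "no regular class for signature: catch-all class"
    }
  }
  out
}

#' Per-class population report
#'
#' Counts how many proteins of a PSIM fall into each secretory class,
#' with the member protein ids; non-clients are tallied separately.
#'
#' @param psim a [PSIM-class].
#' @param catalog a [ClassCatalog-class].
#' @return list with `counts` (data.frame `class_id`, `category`, `count`,
#'   restricted to populated classes), `members` (named list class_id ->
#'   protein ids), `non_clients` (character vector of protein ids) and
#'   `n_clients`.
#' @export
populationReport <- function(psim, catalog) {
  asg <- classifyProteins(psim, catalog)
  cli <- asg[asg$client, , drop = FALSE]
  if (nrow(cli) == 0L)
    return(list(counts = data.frame(class_id = integer(),
                                    category = character(),
                                    count = integer()),
                members = list(),
                non_clients = asg$protein_id[!asg$client],
                n_clients = 0L))
  tb <- table(cli$class_id)
  counts <- data.frame(class_id = as.integer(names(tb)),
                       count = as.integer(tb))
  counts$category <- catalog@classes$category[
    match(counts$class_id, catalog@classes$class_id)]
  counts <- counts[order(counts$class_id), c("class_id", "category", "count")]
  rownames(counts) <- NULL
  members <- split(cli$protein_id, cli$class_id)
  list(counts = counts, members = members,
       non_clients = asg$protein_id[!asg$client],
       n_clients = nrow(cli))
}

#' Export a class catalog as TSV
#'
#' One row per class: class id, the seven signature columns ('+'/'-' for
#' booleans), localization, category and catch-all flag.
#'
#' @param catalog a [ClassCatalog-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "ClassCatalog"))
  cl <- catalog@classes
  out <- data.frame(class_id = cl$class_id, category = cl$category)
  for (s in setdiff(.SIGNATURE_SLOTS, "localization"))
    out[[s]] <- ifelse(cl[[s]], "+", "-")
  out$localization <- cl$localization
  out$catch_all <- ifelse(cl$catch_all, "yes", "no")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
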