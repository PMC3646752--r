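#' Construct a PSIM from a data.frame of feature records
#'
#' Builds a validated [PSIM-class] from in-memory records. Counts stay
#' quantitative (the number of predicted sites / bonds / domains);
#' booleanization to presence/absence happens only when records are
#' assigned to secretory classes.
#'
#' @param records data.frame with the columns documented in [PSIM-class].
#'   A `localization` value of `"cell wall"` is mapped to `"extracellular"`
#'   (cell-wall proteins are treated as extracellular); unrecognized tokens
#'   map to `"unknown"` with a warning.
#' @param parseReport optional data.frame of row-level diagnostics.
#' @return a [PSIM-class] object.
#' @examples
#' p <- PSIM(data.frame(protein_id = "CWP2", signal_peptide = TRUE,
#'   n_glyc_sites = 0L, o_glyc_sites = 4L, disulfide_bonds = 0L,
#'   gpi_anchor = TRUE, tm_domains = 0L, localization = "cell wall"))
#' records(p)$localization  # "extracellular"
#' @export
PSIM <- function(records,
                 parseReport = data.frame(row = integer(),
                                          protein_id = character(),
                                          problem = character())) {
  if (nrow(records)) {
    records$localization <- .normalizeLocalization(records$localization)
    flag <- records$gpi_anchor & !records$signal_peptide
    if (any(flag)) {
      ## GPI attachment requires ER entry via a signal peptide in this model
      parseReport <- rbind(parseReport, data.frame(
        row = which(flag), protein_id = records$protein_id[flag],
        problem = "gpi_anchor without signal_peptide (flagged)"))
    }
    rownames(records) <- NULL
  }
  new("PSIM", records = records, parseReport = parseReport)
}

.normalizeLocalization <- function(loc) {
  loc <- as.character(loc)
  loc[loc == "cell wall"] <- "extracellular"
  bad <- !(loc %in% .LOCALIZATIONS)
  if (any(bad)) {
    warning(sprintf("unrecognized localization token(s) mapped to 'unknown': %s",
                    paste(unique(loc[bad]), collapse = ", ")), call. = FALSE)
    loc[bad] <- "unknown"
  }
  loc
}

.DEFAULT_SCHEMA <- c(protein_id = "protein_id",
                     signal_peptide = "signal_peptide",
                     n_glyc_sites = "n_glyc_sites",
                     o_glyc_sites = "o_glyc_sites",
                     disulfide_bonds = "disulfide_bonds",
                     gpi_anchor = "gpi_anchor",
                     tm_domains = "tm_domains",
                     localization = "localization")

#' Read a PSIM feature table from TSV
#'
#' Parses a tab-separated feature table (UTF-8, header row required, '.'
#' decimal) into a validated [PSIM-class]. Every input row is either
#' accepted or recorded in the parse report with its row number and the
#' reason; nothing is dropped silently. Boolean columns accept
#' TRUE/FALSE, 1/0, yes/no and '+'/'-'. Extra columns beyond the seven
#' feature columns (e.g. the eighth column of human-style tables) are
#' preserved as pass-through attributes; classification uses only the
#' shared seven.
#'
#' @param path path to the TSV file.
#' @param schema named character vector mapping canonical column names
#'   (`protein_id`, `signal_peptide`, `n_glyc_sites`, `o_glyc_sites`,
#'   `disulfide_bonds`, `gpi_anchor`, `tm_domains`, `localization`,
#'   optionally `abundance`, `sequence_length`) to the file's header names.
#' @return a [PSIM-class]; rows that failed validation are listed in
#'   `parseReport(x)`.
#' @export
readPSIM <- function(path, schema = .DEFAULT_SCHEMA) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  schema <- c(schema,
              .DEFAULT_SCHEMA[setdiff(names(.DEFAULT_SCHEMA), names(schema))])
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  miss <- schema[!(schema %in% names(raw)) &
                   names(schema) %in% names(.DEFAULT_SCHEMA)]
  if (length(miss))
    stop(sprintf("schema error: column(s) not found in header: %s",
                 paste(miss, collapse = ", ")))

  n <- nrow(raw)
  problems <- data.frame(row = integer(), protein_id = character(),
                         problem = character())
  note <- function(i, id, why)
    problems <<- rbind(problems,
                       data.frame(row = i, protein_id = id, problem = why))

  parseBool <- function(x) {
    x <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[x %in% c("true", "t", "1", "yes", "y", "+")] <- TRUE
    out[x %in% c("false", "f", "0", "no", "n", "-")] <- FALSE
    out
  }
  parseCount <- function(x) {
    suppressWarnings(v <- as.numeric(x))
    v[!is.na(v) & (v < 0 | v != floor(v))] <- NaN  # NaN marks domain error
    v
  }

  if (n == 0L) return(PSIM(data.frame()))

  rec <- data.frame(
    protein_id = trimws(raw[[schema[["protein_id"]]]]),
    signal_peptide = parseBool(raw[[schema[["signal_peptide"]]]]),
    n_glyc_sites = parseCount(raw[[schema[["n_glyc_sites"]]]]),
    o_glyc_sites = parseCount(raw[[schema[["o_glyc_sites"]]]]),
    disulfide_bonds = parseCount(raw[[schema[["disulfide_bonds"]]]]),
    gpi_anchor = parseBool(raw[[schema[["gpi_anchor"]]]]),
    tm_domains = parseCount(raw[[schema[["tm_domains"]]]]),
    localization = trimws(raw[[schema[["localization"]]]]),
    stringsAsFactors = FALSE)
  for (opt in c("abundance", "sequence_length")) {
    col <- if (opt %in% names(schema)) schema[[opt]] else opt
    if (col %in% names(raw))
      rec[[opt]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  extras <- setdiff(names(raw), schema)
  for (e in extras) rec[[paste0("x_", e)]] <- raw[[e]]

  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    id <- rec$protein_id[i]
    if (is.na(id) || id == "") { note(i, "?", "missing protein_id"); ok[i] <- FALSE; next }
    for (cc in c("signal_peptide", "gpi_anchor"))
      if (is.na(rec[[cc]][i])) { note(i, id, sprintf("row %d: %s not interpretable as boolean", i, cc)); ok[i] <- FALSE }
    for (cc in c("n_glyc_sites", "o_glyc_sites", "disulfide_bonds", "tm_domains")) {
      v <- rec[[cc]][i]
      if (is.na(v) || is.nan(v)) { note(i, id, sprintf("row %d: %s is not a non-negative integer", i, cc)); ok[i] <- FALSE }
    }
  }
  dup <- duplicated(rec$protein_id) & ok
  if (any(dup)) {
    for (i in which(dup)) note(i, rec$protein_id[i],
                               sprintf("row %d: duplicate protein_id", i))
    ok[dup] <- FALSE
  }
  kept <- rec[ok, , drop = FALSE]
  if (nrow(kept)) {
    for (cc in c("n_glyc_sites", "o_glyc_sites", "disulfide_bonds", "tm_domains"))
      kept[[cc]] <- as.integer(kept[[cc]])
  }
  PSIM(kept, parseReport = problems)
}

#' Write a PSIM to TSV
#'
#' Serializes a [PSIM-class] to the tab-separated dialect [readPSIM()]
#' consumes; `readPSIM(writePSIM(p, f))` reproduces `p` field-for-field.
#' An empty PSIM yields a header-only file.
#'
#' @param psim a [PSIM-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePSIM <- function(psim, path) {
  stopifnot(is(psim, "PSIM"))
  validObject(psim)
  rec <- psim@records
  if (nrow(rec) == 0L)
    rec <- data.frame(matrix(character(), ncol = 8,
                             dimnames = list(NULL, names(.DEFAULT_SCHEMA))))
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize feature presence and localization distribution
#'
#' Counts, for each secretory feature, how many records carry it (counts
#' booleanized as > 0), plus the distribution of records over the six
#' localization tokens.
#'
#' @param psim a [PSIM-class].
#' @return list with elements `n` (record count), `present` (named integer:
#'   records with the feature present), `absent` (complement), and
#'   `localization` (named integer over all six tokens).
#' @export
summarizeFeatures <- function(psim) {
  stopifnot(is(psim, "PSIM"))
  rec <- psim@records
  n <- nrow(rec)
  feats <- c(signal_peptide = "signal_peptide", n_glyc = "n_glyc_sites",
             o_glyc = "o_glyc_sites", disulfide = "disulfide_bonds",
             gpi = "gpi_anchor", tm = "tm_domains")
  present <- vapply(feats, function(cc) {
    if (n == 0L) 0L
    else if (is.logical(rec[[cc]])) sum(rec[[cc]])
    else sum(rec[[cc]] > 0)
  }, integer(1))
  loc <- vapply(.LOCALIZATIONS, function(l)
    if (n == 0L) 0L else sum(rec$localization == l), integer(1))
  list(n = n, present = present, absent = n - present, localization = loc)
}
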