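#' Configuration for the synthetic proteome generator
#'
#' Defines the statistical structure of a synthetic secretory proteome:
#' Bernoulli priors for the boolean features, Poisson means for site /
#' bond / domain counts, a categorical localization distribution, a
#' log-normal abundance model and a log-normal sequence-length model.
#' The defaults emulate a yeast-like secretory proteome; the abundance
#' model (log10-mean 2, log10-sd 1) spans the 1-1e5 molecules-per-cell
#' range observed between rare chaperone cofactors and the most abundant
#' cell-wall proteins.
#'
#' @param n_proteins number of proteins to generate.
#' @param seed mandatory RNG seed (integer).
#' @param p_signal_peptide Bernoulli prior for an N-terminal signal
#'   peptide.
#' @param p_gpi conditional Bernoulli prior for GPI anchoring given a
#'   signal peptide (GPI attachment requires ER entry via the signal
#'   peptide, so SP- records are never GPI-anchored).
#' @param lambda_n,lambda_o,lambda_ds,lambda_tm Poisson means for
#'   N-glycosylation sites, O-sites, disulfide bonds and TM domains.
#' @param p_localization named probabilities over the six localization
#'   tokens; must sum to 1.
#' @param log10_abundance_mean,log10_abundance_sd abundance model.
#' @param log_length_mean,log_length_sd natural-log sequence-length model
#'   (lengths are rounded and floored at 30 residues).
#' @return validated config list for [generateProteome()].
#' @export
proteomeConfig <- function(n_proteins, seed,
                           p_signal_peptide = 0.3,
                           p_gpi = 0.08,
                           lambda_n = 1.2, lambda_o = 0.8,
                           lambda_ds = 0.7, lambda_tm = 1.0,
                           p_localization = c(ER = 0.12, Golgi = 0.08,
                                              membrane = 0.35,
                                              vacuole = 0.10,
                                              extracellular = 0.25,
                                              unknown = 0.10),
                           log10_abundance_mean = 2,
                           log10_abundance_sd = 1,
                           log_length_mean = log(400),
                           log_length_sd = 0.45) {
  if (missing(seed)) stop("config error: 'seed' is mandatory")
  .assertScalarNumber(n_proteins, "n_proteins", min = 0)
  for (p in c(p_signal_peptide, p_gpi))
    if (p < 0 || p > 1) stop("config error: probabilities must be in [0,1]")
  for (l in c(lambda_n, lambda_o, lambda_ds, lambda_tm))
    if (l < 0) stop("config error: Poisson means must be >= 0")
  if (!setequal(names(p_localization), .LOCALIZATIONS) ||
      any(p_localization < 0) ||
      abs(sum(p_localization) - 1) > 1e-8)
    stop("config error: p_localization must cover the six tokens and sum to 1")
  as.list(environment())
}

#' Generate a synthetic secretory proteome
#'
#' Draws a feature table (PSIM), a steady-state abundance table and random
#' amino-acid sequences under the configured priors, deterministically for
#' a given seed. A truth ledger records, for every protein, the intended
#' secretory category and class signature, plus the expected number of
#' reaction steps recounted independently (a direct scan of the model
#' document's predicates, separate from the instantiation path) so that
#' downstream stages can be checked against generator bookkeeping.
#'
#' @param config a [proteomeConfig()].
#' @param model a [MachineryModel-class] used for the truth ledger's
#'   expected step counts (default: packaged yeast model).
#' @return list with `psim` ([PSIM-class]), `abundances` (named numeric),
#'   `sequences` ([Biostrings::AAStringSet]) and `truth` (data.frame).
#' @export
generateProteome <- function(config, model = yeastModel()) {
  set.seed(config$seed)
  n <- as.integer(config$n_proteins)
  if (n == 0L) {
    return(list(psim = PSIM(data.frame()), abundances = numeric(),
                sequences = Biostrings::AAStringSet(),
                truth = data.frame()))
  }
  sp <- stats::runif(n) < config$p_signal_peptide
  gpi <- sp & (stats::runif(n) < config$p_gpi)
  rec <- data.frame(
    protein_id = sprintf("SYN%04d", seq_len(n)),
    signal_peptide = sp,
    n_glyc_sites = stats::rpois(n, config$lambda_n),
    o_glyc_sites = stats::rpois(n, config$lambda_o),
    disulfide_bonds = stats::rpois(n, config$lambda_ds),
    gpi_anchor = gpi,
    tm_domains = stats::rpois(n, config$lambda_tm),
    localization = sample(names(config$p_localization), n, replace = TRUE,
                          prob = config$p_localization),
    stringsAsFactors = FALSE)
  ## GPI-anchored records get a feasible destination under the default
  ## feasibility rules (membrane / extracellular / vacuole)
  fix <- gpi & !(rec$localization %in% c("membrane", "extracellular",
                                         "vacuole", "unknown"))
  if (any(fix))
    rec$localization[fix] <- sample(c("membrane", "extracellular",
                                      "vacuole"), sum(fix), replace = TRUE)
  abund <- 10^stats::rnorm(n, config$log10_abundance_mean,
                           config$log10_abundance_sd)
  len <- pmax(30L, as.integer(round(
    exp(stats::rnorm(n, config$log_length_mean, config$log_length_sd)))))
  rec$abundance <- abund
  rec$sequence_length <- len
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(len, function(L)
    paste(sample(aas, L, replace = TRUE), collapse = ""), character(1))
  sequences <- Biostrings::AAStringSet(stats::setNames(seqs, rec$protein_id))
  truth <- .truthLedger(rec, model)
  list(psim = PSIM(rec), abundances = stats::setNames(abund, rec$protein_id),
       sequences = sequences, truth = truth)
}

## Independent bookkeeping of intended class and step count: a plain scan
## over the model document's applicability/scale fields, written separately
## from the instantiation path in reactions.R.
.truthLedger <- function(rec, model) {
  n <- nrow(rec)
  out <- data.frame(protein_id = rec$protein_id,
                    client = rec$signal_peptide | rec$tm_domains > 0,
                    category = ifelse(rec$signal_peptide, "SP_plus",
                                      "SP_minus"),
                    stringsAsFactors = FALSE)
  out$category[!out$client] <- NA_character_
  sig <- character(n)
  expected <- integer(n)
  for (i in seq_len(n)) {
    if (!out$client[i]) { sig[i] <- NA_character_; next }
    g <- rec$gpi_anchor[i]
    sig[i] <- paste(c("-", "+")[1 + c(rec$signal_peptide[i],
                                      rec$n_glyc_sites[i] > 0,
                                      rec$o_glyc_sites[i] > 0,
                                      rec$disulfide_bonds[i] > 0,
                                      g,
                                      rec$tm_domains[i] > 0 &&
                                        !(g && rec$signal_peptide[i]))],
                    collapse = "")
    env <- list2env(list(
      sp = rec$signal_peptide[i], n = as.numeric(rec$n_glyc_sites[i]),
      o = as.numeric(rec$o_glyc_sites[i]),
      ds = as.numeric(rec$disulfide_bonds[i]),
      tm = as.numeric(rec$tm_domains[i]), g = as.numeric(g), gpi = g,
      loc = if (rec$localization[i] == "unknown") "extracellular"
            else rec$localization[i],
      route = "CPY", f = 0, erad_branch = ""), parent = baseenv())
    cnt <- 0L
    for (r in model@reactions) {
      if (!(r$category %in% c("template", "biosynthesis"))) next
      app <- r$applicability
      if (!is.null(app) && !identical(app, "") &&
          !isTRUE(eval(parse(text = app)[[1]], env))) next
      sc <- r$scale
      mult <- if (is.null(sc)) 1 else eval(parse(text = sc)[[1]], env)
      if (is.finite(mult) && mult > 0) cnt <- cnt + 1L
    }
    expected[i] <- cnt
  }
  out$signature <- sig
  out$localization <- rec$localization
  out$expected_steps <- expected
  out
}

#' A fixed, hand-auditable five-protein micro-proteome
#'
#' Five archetypal secretory clients covering the main routes through the
#' machinery: a short GPI-anchored O-mannosylated cell-wall protein (the
#' most abundant protein class in yeast), a signal-peptide-lacking
#' multi-pass plasma-membrane proton pump, an N-glycosylated vacuolar
#' protease travelling the endosomal (CPY) route, a small secreted
#' pheromone-like protein, and an ER-resident chaperone that never leaves
#' the ER. Abundances are unit (1 molecule per cell) so that, at mu = 1
#' h^-1, every per-event coefficient is directly legible in the demand
#' report. The packaged expected-demand table
#' (`extdata/worked_example_expected.tsv`) was computed independently of
#' this package's instantiation code and is asserted in the test suite.
#'
#' @return list with `psim`, `abundances`, `context` (mu = 1), and
#'   `expected` (data.frame metabolite / consumption read from the
#'   packaged table).
#' @export
workedExample <- function() {
  rec <- data.frame(
    protein_id = c("CellWallGPI", "ProtonPumpTM", "VacuolarProtease",
                   "SecretedPheromone", "ERChaperone"),
    signal_peptide = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    n_glyc_sites = c(0L, 4L, 4L, 3L, 0L),
    o_glyc_sites = c(4L, 0L, 0L, 0L, 0L),
    disulfide_bonds = c(0L, 0L, 1L, 0L, 0L),
    gpi_anchor = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    tm_domains = c(0L, 10L, 0L, 0L, 0L),
    localization = c("extracellular", "membrane", "vacuole",
                     "extracellular", "ER"),
    stringsAsFactors = FALSE)
  ab <- stats::setNames(rep(1, 5), rec$protein_id)
  expected_path <- system.file("extdata", "worked_example_expected.tsv",
                               package = "secflux")
  expected <- if (nzchar(expected_path))
    utils::read.delim(expected_path, stringsAsFactors = FALSE)
  else data.frame()
  list(psim = PSIM(rec), abundances = ab,
       context = costContext(mu = 1, abundances = ab),
       expected = expected)
}
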