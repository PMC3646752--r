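## shared fixture builders (all in code, no stored binaries)

makeRecord <- function(protein_id = "P1", signal_peptide = TRUE,
                       n_glyc_sites = 0L, o_glyc_sites = 0L,
                       disulfide_bonds = 0L, gpi_anchor = FALSE,
                       tm_domains = 0L, localization = "extracellular") {
  data.frame(protein_id = protein_id, signal_peptide = signal_peptide,
             n_glyc_sites = n_glyc_sites, o_glyc_sites = o_glyc_sites,
             disulfide_bonds = disulfide_bonds, gpi_anchor = gpi_anchor,
             tm_domains = tm_domains, localization = localization,
             stringsAsFactors = FALSE)
}

writeTempTSV <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## one random record per catalog signature constraints, seeded by caller
randomRecords <- function(n) {
  data.frame(
    protein_id = sprintf("R%04d", seq_len(n)),
    signal_peptide = sample(c(TRUE, FALSE), n, replace = TRUE),
    n_glyc_sites = rpois(n, 1),
    o_glyc_sites = rpois(n, 1),
    disulfide_bonds = rpois(n, 1),
    gpi_anchor = FALSE,
    tm_domains = rpois(n, 1),
    localization = sample(c("ER", "Golgi", "membrane", "vacuole",
                            "extracellular", "unknown"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

localYeastModel <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- yeastModel()
    m
  }
})
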