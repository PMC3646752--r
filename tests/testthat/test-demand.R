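m <- localYeastModel()
cat186 <- enumerateClasses()

test_that("processing rate is the growth-dilution product", {
  expect_equal(processingRate(1000, 0.1), 100)
  expect_equal(processingRate(0, 0.5), 0)
  expect_error(processingRate(-1, 0.1), ">= 0")
  ## the default-abundance convention: unmeasured proteins count 1 per cell
  ctx <- costContext(mu = 0.4, abundances = c(KNOWN = 10))
  lists <- generateAll(PSIM(makeRecord("MISSING")), cat186, m)
  vj <- reactionRates(lists, ctx)
  expect_equal(unname(vj["T14_CHAPERONE_FOLDING"]), 0.4)
})

test_that("reaction rates add over proteins sharing a reaction", {
  rec <- rbind(makeRecord("A", localization = "ER"),
               makeRecord("B", localization = "ER"))
  lists <- generateAll(PSIM(rec), cat186, m)
  ctx <- costContext(mu = 1, abundances = c(A = 2, B = 3))
  vj <- reactionRates(lists, ctx)
  expect_equal(unname(vj["T14_CHAPERONE_FOLDING"]), 5)

  single <- generateAll(PSIM(makeRecord("A", localization = "ER")),
                        cat186, m)
  v1 <- reactionRates(single, costContext(mu = 1, abundances = c(A = 5)))
  expect_equal(unname(v1["T14_CHAPERONE_FOLDING"]), 5)
})

test_that("rates and demands match a naive double loop on a synthetic proteome", {
  gen <- generateProteome(proteomeConfig(200, seed = 17), model = m)
  lists <- generateAll(gen$psim, cat186, m)
  ctx <- costContext(mu = 0.35, abundances = gen$abundances)
  vj <- reactionRates(lists, ctx)

  ## brute-force oracle: loop over (protein, step) pairs
  st <- reactionSteps(lists)
  vp <- ctx$mu * gen$abundances
  oracle <- new.env()
  memb <- unique(st[, c("protein_id", "reaction_id")])
  for (k in seq_len(nrow(memb))) {
    rid <- memb$reaction_id[k]
    assign(rid, (if (exists(rid, oracle)) get(rid, oracle) else 0) +
             vp[[memb$protein_id[k]]], oracle)
  }
  for (rid in names(vj))
    expect_equal(vj[[rid]], get(rid, oracle), tolerance = 1e-9)

  ## metabolite demand vs triple loop over (protein, step, metabolite)
  dem <- metaboliteDemand(lists, m, ctx, psim = gen$psim)
  stm <- st[!is.na(st$metabolite), ]
  expected <- tapply(pmax(stm$coefficient * vp[stm$protein_id], 0),
                     stm$metabolite, sum)
  tot <- demandTotals(dem)
  for (i in seq_len(nrow(tot)))
    expect_equal(tot$consumption[i], unname(expected[[tot$metabolite[i]]]),
                 tolerance = 1e-9)
})

test_that("demand is linear: homogeneous in mu and in abundances", {
  gen <- generateProteome(proteomeConfig(60, seed = 23), model = m)
  lists <- generateAll(gen$psim, cat186, m)
  d1 <- demandTotals(metaboliteDemand(
    lists, m, costContext(0.2, gen$abundances)))
  d2 <- demandTotals(metaboliteDemand(
    lists, m, costContext(0.4, gen$abundances)))
  expect_equal(d2$consumption, 2 * d1$consumption, tolerance = 1e-12)
  d3 <- demandTotals(metaboliteDemand(
    lists, m, costContext(0.2, gen$abundances * 3)))
  expect_equal(d3$consumption, 3 * d1$consumption, tolerance = 1e-12)
})

test_that("grouped demands conserve the global totals", {
  gen <- generateProteome(proteomeConfig(80, seed = 31), model = m)
  lists <- generateAll(gen$psim, cat186, m)
  dem <- metaboliteDemand(lists, m, costContext(0.35, gen$abundances),
                          psim = gen$psim)
  tot <- demandTotals(dem)
  bySub <- demandBySubsystem(dem)
  byComp <- demandByCompartment(dem)
  for (met in tot$metabolite) {
    expect_equal(sum(bySub$consumption[bySub$metabolite == met]),
                 tot$consumption[tot$metabolite == met], tolerance = 1e-9)
    expect_equal(sum(byComp$consumption[byComp$metabolite == met]),
                 tot$consumption[tot$metabolite == met], tolerance = 1e-9)
  }
})

test_that("a single disulfide chain propagates to FADH2 demand exactly", {
  rec <- makeRecord("DS", disulfide_bonds = 1L, localization = "ER")
  lists <- generateAll(PSIM(rec), cat186, m)
  dem <- metaboliteDemand(lists, m,
                          costContext(mu = 1, abundances = c(DS = 10)))
  tot <- demandTotals(dem)
  expect_equal(tot$consumption[tot$metabolite == "FADH2"], 10)
})

test_that("lipid-linked intermediates balance to zero net demand", {
  gen <- generateProteome(proteomeConfig(40, seed = 57), model = m)
  lists <- generateAll(gen$psim, cat186, m)
  dem <- metaboliteDemand(lists, m, costContext(0.35, gen$abundances))
  tot <- demandTotals(dem)
  for (met in c("Dol-P-Man", "Dol-P-Glc", "LLO", "GPI-anchor")) {
    row <- tot[tot$metabolite == met, ]
    if (nrow(row)) expect_equal(row$net, 0, tolerance = 1e-9)
  }
})

test_that("glycan precursor draw equals per-site stoichiometry times sites", {
  rec <- makeRecord("G", n_glyc_sites = 5L, localization = "vacuole")
  lists <- generateAll(PSIM(rec), cat186, m)
  dem <- metaboliteDemand(lists, m,
                          costContext(mu = 1, abundances = c(G = 1)))
  tot <- demandTotals(dem)
  grab <- function(met) tot$consumption[tot$metabolite == met]
  ## core glycan Glc3Man9GlcNAc2: 2 GlcNAc + 9 Man + 3 Glc per site
  expect_equal(grab("UDP-GlcNAc"), 2 * 5)
  expect_equal(grab("UDP-Glc"), 3 * 5 + 5)    # + calnexin reglucosylation
  expect_equal(grab("Dol-P-Man"), 4 * 5)      # lumenal mannoses
  expect_equal(grab("farnesyl-PP"), 5)        # one carrier per glycan
})

test_that("synthesis cost implements residue costs plus bond cost", {
  ## dipeptide under a zero-cost table isolates one peptide bond: 4 ATP
  expect_equal(unname(synthesisCost("GA", zeroCostTable())["atp"]), 4)
  ## a single residue forms no bonds
  expect_equal(unname(synthesisCost("W", zeroCostTable())["atp"]), 0)
  ## length-10 homopolymer at 2 ATP/residue: 10*2 + 9*4 = 56
  tbl <- zeroCostTable()
  tbl$costs$atp[tbl$costs$aa == "A"] <- 2
  expect_equal(unname(synthesisCost(strrep("A", 10), tbl)["atp"]), 56)
  ## NADPH side is independent of bond cost
  tbl$costs$nadph[tbl$costs$aa == "A"] <- 3
  expect_equal(unname(synthesisCost(strrep("A", 10), tbl)["nadph"]), 30)
  ## unknown residues are rejected with their position
  expect_error(synthesisCost("GAXZ", zeroCostTable()), "position 3")
  ## counts interface agrees with the string interface
  expect_equal(synthesisCost(c(A = 10), tbl), synthesisCost(strrep("A", 10), tbl))
  ## the packaged cost table has 20 entries
  expect_equal(nrow(aaCostTable()$costs), 20L)
})
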