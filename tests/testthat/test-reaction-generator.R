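m <- localYeastModel()
cat186 <- enumerateClasses()

test_that("a featureless ER-resident gets only translocation and folding", {
  er <- makeRecord("ERmin", localization = "ER")
  st <- reactionSteps(generateReactions(er, m))
  expect_setequal(unique(st$subsystem_id), c("S1", "S4"))
  expect_false(any(grepl("COPII", st$reaction_id)))
  expect_false(any(grepl("GLYCAN", st$reaction_id)))
})

test_that("a GPI cell-wall protein takes the full secreted GPI route", {
  cwp <- makeRecord("Cwp2like", gpi_anchor = TRUE, o_glyc_sites = 4L,
                    localization = "extracellular")
  st <- reactionSteps(generateReactions(cwp, m))
  ids <- unique(st$reaction_id)
  expect_true("T19_GPI_ANCHOR_ATTACHMENT" %in% ids)
  expect_true("T13_O_MANNOSYLATION" %in% ids)
  expect_true(any(st$subsystem_id == "S5"))   # anchor biosynthesis
  expect_true(any(st$subsystem_id == "S14"))  # HDSV to the surface
  expect_false(any(st$subsystem_id %in% c("S13", "S15", "S16")))
  ## itinerary terminates extracellularly
  expect_equal(st$compartment_id[nrow(st)], "extracellular")
})

test_that("per-site stoichiometry scales linearly with zero intercept", {
  base <- makeRecord("N1", n_glyc_sites = 1L, localization = "vacuole")
  tri <- makeRecord("N3", n_glyc_sites = 3L, localization = "vacuole")
  st1 <- reactionSteps(generateReactions(base, m))
  st3 <- reactionSteps(generateReactions(tri, m))
  pick <- function(st, rid, met) st$coefficient[st$reaction_id == rid &
                                                  st$metabolite == met]
  ## hand-multiplied template coefficients: LLO transfer draws n LLO units
  expect_equal(pick(st3, "T09_N_GLYCAN_TRANSFER", "LLO"), 3)
  expect_equal(pick(st3, "T09_N_GLYCAN_TRANSFER", "LLO"),
               3 * pick(st1, "T09_N_GLYCAN_TRANSFER", "LLO"))
  ## dolichol-pathway precursor draw scales with the site count
  expect_equal(pick(st3, "B06_LLO_MAN2_3", "GDP-Man"),
               3 * pick(st1, "B06_LLO_MAN2_3", "GDP-Man"))
  expect_equal(pick(st3, "B06_LLO_MAN2_3", "GDP-Man"), 6)  # 2 per site

  ## disulfide: one FADH2 equivalent per bond
  ds <- makeRecord("DS4", disulfide_bonds = 4L)
  stds <- reactionSteps(generateReactions(ds, m))
  expect_equal(pick(stds, "T16_DISULFIDE_OXIDATION", "FADH2"), 4)

  ## zero intercept: absent feature, no step
  none <- makeRecord("N0", n_glyc_sites = 0L, localization = "vacuole")
  st0 <- reactionSteps(generateReactions(none, m))
  expect_false("T09_N_GLYCAN_TRANSFER" %in% st0$reaction_id)
  expect_false(any(st0$subsystem_id == "S2"))
})

test_that("non-clients are refused with a reason", {
  sol <- makeRecord("Cyt", signal_peptide = FALSE, tm_domains = 0L)
  expect_error(generateReactions(sol, m), "not a secretory machinery client")
})

test_that("generation is pure and deterministic", {
  rec <- makeRecord("Dup", n_glyc_sites = 2L, localization = "membrane")
  a <- generateReactions(rec, m)
  b <- generateReactions(rec, m)
  expect_identical(reactionSteps(a), reactionSteps(b))
  ## byte-identical serialization
  fa <- tempfile(); fb <- tempfile()
  writeReactionLists(a, fa); writeReactionLists(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("adding a feature only ever adds steps (monotonicity)", {
  base <- makeRecord("Mono", o_glyc_sites = 1L,
                     localization = "extracellular")
  plus <- base
  plus$gpi_anchor <- TRUE
  ids0 <- unique(reactionSteps(generateReactions(base, m))$reaction_id)
  ids1 <- unique(reactionSteps(generateReactions(plus, m))$reaction_id)
  expect_true(all(ids0 %in% ids1))
  expect_gt(length(ids1), length(ids0))
})

test_that("routes are sound over 1000 random records", {
  set.seed(99)
  rec <- randomRecords(1000)
  client <- rec$signal_peptide | rec$tm_domains > 0
  psim <- PSIM(rec)
  lists <- generateAll(psim, cat186, m)
  st <- reactionSteps(lists)
  bySub <- split(st$subsystem_id, st$protein_id)
  for (i in which(client)) {
    id <- rec$protein_id[i]
    subs <- unique(bySub[[id]])
    loc <- rec$localization[i]
    if (loc == "ER") {
      expect_false("S10" %in% subs, label = sprintf("%s: ER, no COPII", id))
    } else {
      expect_true("S10" %in% subs, label = sprintf("%s: COPII present", id))
      expect_true("S12" %in% subs, label = sprintf("%s: Golgi present", id))
    }
    if (loc == "vacuole") {
      expect_true("S15" %in% subs, label = sprintf("%s: CPY route", id))
      expect_false(any(c("S13", "S14") %in% subs),
                   label = sprintf("%s: no surface vesicles", id))
    }
    if (loc %in% c("membrane", "extracellular"))
      expect_false(any(c("S15", "S16") %in% subs),
                   label = sprintf("%s: no vacuolar route", id))
  }
  ## non-clients got no lists
  expect_equal(sort(reactionProteins(lists)$protein_id[
    !reactionProteins(lists)$client]), sort(rec$protein_id[!client]))
})

test_that("steps are ordered along the route S1 -> S16", {
  rec <- makeRecord("Ord", n_glyc_sites = 2L, disulfide_bonds = 1L,
                    gpi_anchor = TRUE, localization = "membrane")
  st <- reactionSteps(generateReactions(rec, m))
  subIdx <- as.integer(sub("S", "", st$subsystem_id))
  expect_true(all(diff(subIdx) >= 0))
})

test_that("the ALP override routes a vacuolar protein via AP-3", {
  rec <- makeRecord("AlpLike", localization = "vacuole")
  st <- reactionSteps(generateReactions(
    rec, m, reactionOptions(alp_proteins = "AlpLike")))
  expect_true(any(st$subsystem_id == "S16"))
  expect_false(any(st$subsystem_id == "S15"))
})

test_that("the ERAD branch engages with a nonzero misfolded fraction", {
  rec <- makeRecord("Mis", n_glyc_sites = 2L, localization = "vacuole")
  st0 <- reactionSteps(generateReactions(rec, m))
  expect_false(any(st0$subsystem_id %in% c("S7", "S8", "S9")))
  stf <- reactionSteps(generateReactions(rec, m,
                                         reactionOptions(f_misfold = 0.1)))
  ## luminal glycosylated substrate: ERADL, scaled by f
  expect_true(any(stf$subsystem_id == "S8"))
  expect_false(any(stf$subsystem_id %in% c("S7", "S9")))
  ub <- stf$coefficient[stf$reaction_id == "T25_ERADL_UBIQUITINATION" &
                          stf$metabolite == "UB"]
  expect_equal(ub, 0.1)
})

test_that("whole-proteome totals match an independent recount", {
  gen <- generateProteome(proteomeConfig(50, seed = 3), model = m)
  lists <- generateAll(gen$psim, cat186, m)
  pr <- reactionProteins(lists)
  st <- reactionSteps(lists)
  recount <- vapply(split(st$reaction_id, st$protein_id),
                    function(x) length(unique(x)), integer(1))
  for (i in which(pr$client))
    expect_equal(pr$n_steps[i], unname(recount[pr$protein_id[i]]))
  expect_equal(sum(pr$n_steps), sum(recount))

  ## empty proteome, empty collection
  lists0 <- generateAll(PSIM(data.frame()), cat186, m)
  expect_equal(nrow(reactionSteps(lists0)), 0L)
})
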