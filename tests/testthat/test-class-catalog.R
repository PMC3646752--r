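cat186 <- enumerateClasses()

test_that("default configuration yields the published class combinatorics", {
  cl <- catalogClasses(cat186)
  expect_equal(nrow(cl), 186L)
  reg <- cl[!cl$catch_all, ]
  expect_equal(sum(reg$category == "SP_plus"), 104L)
  expect_equal(sum(reg$category == "SP_minus"), 80L)
  expect_equal(sum(cl$catch_all), 2L)
  ## category is determined by the signal-peptide slot
  expect_true(all((cl$category == "SP_plus") == cl$signal_peptide))
  ## ids are 0-based and dense
  expect_equal(cl$class_id, 0:185)
})

test_that("an unconstrained single-localization config gives 2^6 classes", {
  cfg <- list(blocks = list(list(
    signal_peptide = c(FALSE, TRUE), n_glyc = c(FALSE, TRUE),
    o_glyc = c(FALSE, TRUE), disulfide = c(FALSE, TRUE),
    gpi = c(FALSE, TRUE), tm = c(FALSE, TRUE),
    localization = "membrane")), catch_alls = FALSE)
  expect_equal(length(enumerateClasses(cfg)), 64L)
})

test_that("contradictory configurations raise a configuration error", {
  cfg <- list(blocks = list(list(
    signal_peptide = logical(0), n_glyc = TRUE, o_glyc = TRUE,
    disulfide = TRUE, gpi = TRUE, tm = TRUE, localization = "ER")),
    catch_alls = FALSE)
  expect_error(enumerateClasses(cfg), "configuration error")
  cfg2 <- list(blocks = list(list(
    signal_peptide = TRUE, n_glyc = TRUE, o_glyc = TRUE,
    disulfide = TRUE, gpi = TRUE, tm = TRUE, localization = character(0))),
    catch_alls = FALSE)
  expect_error(enumerateClasses(cfg2), "configuration error")
})

test_that("enumeration is stable under re-enumeration", {
  again <- enumerateClasses()
  expect_identical(catalogClasses(cat186), catalogClasses(again))
})

test_that("classification follows the ER-entry rules", {
  ## GPI-anchored cell-wall mannoprotein: SP+ class with gpi signature
  cwp <- makeRecord("Cwp2like", gpi_anchor = TRUE, o_glyc_sites = 4L,
                    localization = "extracellular")
  asg <- classifyProteins(PSIM(cwp), cat186)
  expect_true(asg$client)
  cl <- catalogClasses(cat186)
  hit <- cl[cl$class_id == asg$class_id, ]
  expect_equal(hit$category, "SP_plus")
  expect_true(hit$gpi)
  expect_true(hit$o_glyc)

  ## multi-pass plasma-membrane pump without signal peptide: SP- with tm
  pma <- makeRecord("Pma1like", signal_peptide = FALSE, tm_domains = 10L,
                    localization = "membrane")
  asg2 <- classifyProteins(PSIM(pma), cat186)
  hit2 <- cl[cl$class_id == asg2$class_id, ]
  expect_equal(hit2$category, "SP_minus")
  expect_true(hit2$tm)

  ## no signal peptide, no TM domain: not a machinery client
  sol <- makeRecord("Cytosolic", signal_peptide = FALSE, tm_domains = 0L)
  asg3 <- classifyProteins(PSIM(sol), cat186)
  expect_false(asg3$client)
  expect_true(is.na(asg3$class_id))

  ## unknown localization falls into the category catch-all
  unk <- makeRecord("Unk", localization = "unknown")
  asg4 <- classifyProteins(PSIM(unk), cat186)
  expect_true(cl$catch_all[cl$class_id == asg4$class_id])
})

test_that("classify matches signatures slot-for-slot on random records", {
  set.seed(7)
  rec <- randomRecords(300)
  ## sprinkle GPI-anchored SP+ records with feasible destinations
  g <- which(rec$signal_peptide)[1:40]
  rec$gpi_anchor[g] <- TRUE
  rec$localization[g] <- sample(c("membrane", "extracellular", "vacuole"),
                                40, replace = TRUE)
  asg <- classifyProteins(PSIM(rec), cat186)
  cl <- catalogClasses(cat186)
  for (i in which(asg$client & is.na(asg$note))) {
    sig <- cl[cl$class_id == asg$class_id[i], ]
    expect_equal(sig$signal_peptide, rec$signal_peptide[i])
    expect_equal(sig$n_glyc, rec$n_glyc_sites[i] > 0)
    expect_equal(sig$o_glyc, rec$o_glyc_sites[i] > 0)
    expect_equal(sig$disulfide, rec$disulfide_bonds[i] > 0)
    expect_equal(sig$gpi, rec$gpi_anchor[i])
    expect_equal(sig$tm, rec$tm_domains[i] > 0 &&
                   !(rec$gpi_anchor[i] && rec$signal_peptide[i]))
    expect_equal(sig$localization, rec$localization[i])
  }
})

test_that("every catalog class is reachable by a constructed record", {
  cl <- catalogClasses(cat186)
  for (i in seq_len(nrow(cl))) {
    rec <- makeRecord(
      sprintf("RC%d", i),
      signal_peptide = cl$signal_peptide[i],
      n_glyc_sites = as.integer(cl$n_glyc[i]),
      o_glyc_sites = as.integer(cl$o_glyc[i]),
      disulfide_bonds = as.integer(cl$disulfide[i]),
      gpi_anchor = cl$gpi[i],
      ## SP- records need the signal anchor even in GPI classes
      tm_domains = as.integer(cl$tm[i] || !cl$signal_peptide[i]),
      localization = cl$localization[i])
    asg <- classifyProteins(rec, cat186)
    expect_equal(asg$class_id, cl$class_id[i],
                 label = sprintf("class %d reachable", cl$class_id[i]))
  }
})

test_that("population report counts are exact against generator truth", {
  gen <- generateProteome(proteomeConfig(250, seed = 5),
                          model = localYeastModel())
  rep <- populationReport(gen$psim, cat186)
  expect_equal(rep$n_clients + length(rep$non_clients), 250L)
  expect_equal(sum(rep$counts$count), rep$n_clients)
  expect_setequal(rep$non_clients,
                  gen$truth$protein_id[!gen$truth$client])

  ## three identical SP+ records collapse into one class of count 3
  tri <- do.call(rbind, lapply(1:3, function(i)
    makeRecord(paste0("T", i), n_glyc_sites = 1L)))
  rep3 <- populationReport(PSIM(tri), cat186)
  expect_equal(nrow(rep3$counts), 1L)
  expect_equal(rep3$counts$count, 3L)

  ## empty input, empty report
  rep0 <- populationReport(PSIM(data.frame()), cat186)
  expect_equal(nrow(rep0$counts), 0L)
  expect_equal(rep0$n_clients, 0L)
})

test_that("catalog TSV export has one row per class", {
  f <- tempfile(fileext = ".tsv")
  writeCatalog(cat186, f)
  tb <- utils::read.delim(f)
  expect_equal(nrow(tb), 186L)
  expect_true(all(tb$signal_peptide %in% c("+", "-")))
})
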