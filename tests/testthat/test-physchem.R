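test_that("hydrophobicity is the mean of embedded scale values", {
  kd <- hydropathyScale("kyte_doolittle")
  expect_equal(hydrophobicity("III", kd), 4.5)
  expect_equal(hydrophobicity("IR", kd), 0)
  # C=2.5, A=1.8, S=-0.8, S=-0.8 -> 2.7/4
  expect_equal(hydrophobicity("CASS", kd), 0.675)
  expect_true(is.na(hydrophobicity("", kd)))
  expect_error(hydrophobicity("CAXS", kd), "X.*position 3")
})

test_that("both scales carry published values, oriented high = hydrophobic", {
  kd <- hydropathyScale("kyte_doolittle")
  expect_equal(unname(kd@values["I"]), 4.5)
  expect_equal(unname(kd@values["R"]), -4.5)
  expect_length(kd@values, 20L)
  ww <- hydropathyScale("wimley_white_interface")
  expect_length(ww@values, 20L)
  # raw interface free energies are sign-flipped at load
  expect_equal(unname(ww@raw["W"]), -1.85)
  expect_equal(unname(ww@values["W"]), 1.85)
  expect_equal(unname(ww@values["E"]), -2.02)
})

test_that("hydrophobic and hydrophilic homopolymers rank concordantly on both scales", {
  phobic <- c("IIIII", "LLLLL", "FFFFF")
  philic <- c("RRRRR", "KKKKK", "DDDDD")
  for (s in c("kyte_doolittle", "wimley_white_interface")) {
    sc <- hydropathyScale(s)
    expect_true(min(hydrophobicity(phobic, sc)) >
                  max(hydrophobicity(philic, sc)), info = s)
  }
})

test_that("hydrophobicity is permutation-invariant and monotone in extremes", {
  kd <- hydropathyScale("kyte_doolittle")
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(names(kd@values), 12, replace = TRUE), collapse = "")
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(hydrophobicity(s, kd), hydrophobicity(perm, kd))
    hi <- names(which.max(kd@values)); lo <- names(which.min(kd@values))
    expect_gte(hydrophobicity(paste0(s, hi), kd), hydrophobicity(s, kd))
    expect_lte(hydrophobicity(paste0(s, lo), kd), hydrophobicity(s, kd))
  }
})

test_that("midRegion trims flanks and degenerates to empty", {
  expect_equal(midRegion("CASSLGQAYEQYF", 3, 3), "SLGQAYE")
  expect_equal(midRegion("CASF", 3, 3), "")
  x <- c("CASSLGQAYEQYF", "CAVRF")
  expect_equal(midRegion(x, 0, 0), x)
})

test_that("scoreRepertoire composes midRegion and hydrophobicity per clone", {
  spec <- data.frame(chain = "TRB", cdr3_aa = "CASSLGQAYEQYF",
                     condition = "case", n = 1)
  rep <- makeToyRepertoire(spec)
  m <- scoreRepertoire(rep)
  expect_equal(nrow(m), 1L)
  expect_equal(m$mid_sequence, "SLGQAYE")
  expect_equal(m$hydro_mid, hydrophobicity("SLGQAYE"))
  expect_equal(m$hydro_full, hydrophobicity("CASSLGQAYEQYF"))
  expect_equal(m$mid_length, m$length_aa - 6L)
})

test_that("vectorised scoring equals an independent per-residue summation", {
  sim <- generateRepertoire(simConfig(seed = 5, nCells = 200))
  m <- suppressMessages(scoreRepertoire(sim$repertoire))
  kd <- hydropathyScale("kyte_doolittle")
  for (i in seq_len(nrow(m))) {
    acc <- 0
    letters <- strsplit(m$cdr3_aa[i], "")[[1]]
    for (l in letters) acc <- acc + kd@values[[l]]
    expect_equal(m$hydro_full[i], acc / length(letters), tolerance = 1e-12)
  }
  expect_equal(nrow(m), nrow(clones(sim$repertoire)))
})

test_that("length distributions are per-condition frequencies that sum to 1", {
  # mid-lengths 5, 5, 8 (full lengths 11, 11, 14), cell counts 1, 1, 4
  spec <- data.frame(
    chain = "TRB",
    cdr3_aa = c("CASSLGQAYEQ", "CASSWWQAYEQ", "CASSLGQAYEQYFH"),
    condition = "case", n = c(1, 1, 4)
  )
  rep <- makeToyRepertoire(spec)
  by_clone <- lengthDistribution(rep, by = "clone", region = "mid")
  expect_equal(by_clone$frequency[by_clone$length == 5], 2 / 3)
  expect_equal(by_clone$frequency[by_clone$length == 8], 1 / 3)
  by_cell <- lengthDistribution(rep, by = "cell", region = "mid")
  expect_equal(by_cell$frequency[by_cell$length == 5], 2 / 6)
  expect_equal(by_cell$frequency[by_cell$length == 8], 4 / 6)
  sim <- generateRepertoire(simConfig(seed = 2, nCells = 300))
  ld <- lengthDistribution(sim$repertoire, by = "cell", region = "full")
  sums <- tapply(ld$frequency, ld$condition, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
})

test_that("empty mid regions are missing data, not zeros", {
  spec <- data.frame(chain = "TRB", cdr3_aa = c("CASSF", "CASSLGQAYEQYF"),
                     condition = "case", n = 1)
  rep <- makeToyRepertoire(spec)
  expect_message(m <- scoreRepertoire(rep), "1 clone")
  expect_true(is.na(m$hydro_mid[m$cdr3_aa == "CASSF"]))
})
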