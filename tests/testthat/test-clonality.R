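toy_two_condition <- function() {
  # case: clone A 2 cells of 100; control: clone A 1 cell of 200
  spec <- data.frame(
    chain = "TRB",
    cdr3_aa = c("CASSAAAAYEQYF", rep("CASSFILLERQYF", 1),
                "CASSAAAAYEQYF", rep("CASSFILLERQYF", 1)),
    condition = c("case", "case", "control", "control"),
    n = c(2, 98, 1, 199)
  )
  makeToyRepertoire(spec)
}

test_that("expansion index is the case:control frequency ratio x 100", {
  rep <- toy_two_condition()
  e0 <- expansionIndex(rep, "case", "control", pseudo = 0)
  a <- e0[e0$cdr3_aa == "CASSAAAAYEQYF", ]
  expect_equal(a$freq_case, 0.02)
  expect_equal(a$freq_control, 0.005)
  expect_equal(a$index, 400)
  expect_equal(a$index_raw, 400)
  expect_error(expansionIndex(rep, "case", "nope"), "nope")
})

test_that("pseudocount keeps the index defined for one-condition clones", {
  # clone only in case: freq_case 0.01 of 100 cells, absent from 100
  # control cells; with pseudo 1 the control frequency becomes 1/100
  spec <- data.frame(
    chain = "TRB",
    cdr3_aa = c("CASSBBBBYEQYF", "CASSFILLERQYF", "CASSFILLERQYF"),
    condition = c("case", "case", "control"),
    n = c(1, 99, 100)
  )
  rep <- makeToyRepertoire(spec)
  e <- expansionIndex(rep, "case", "control", pseudo = 1)
  b <- e[e$cdr3_aa == "CASSBBBBYEQYF", ]
  expect_equal(b$index, 100 * (0.01 + 0.01) / 0.01)
  expect_true(is.na(b$index_raw))
})

test_that("equal frequencies give index 100 for any pseudocount", {
  spec <- data.frame(
    chain = "TRB", cdr3_aa = c("CASSAAAAYEQYF", "CASSFILLERQYF"),
    condition = rep(c("case", "control"), each = 2),
    n = c(5, 95, 5, 95)
  )
  spec <- rbind(spec[1:2, ], spec[1:2, ])
  spec$condition <- c("case", "case", "control", "control")
  rep <- makeToyRepertoire(spec)
  for (p in c(0, 1, 5)) {
    e <- expansionIndex(rep, "case", "control", pseudo = p)
    expect_equal(e$index[e$cdr3_aa == "CASSAAAAYEQYF"], 100)
  }
})

test_that("pseudo-free index is antisymmetric under condition swap", {
  sim <- generateRepertoire(simConfig(seed = 21, nCells = 400))
  fwd <- expansionIndex(sim$repertoire, "cardiotox", "no_irae", pseudo = 0)
  rev <- expansionIndex(sim$repertoire, "no_irae", "cardiotox", pseudo = 0)
  m <- merge(fwd, rev, by = "cdr3_aa")
  both <- m[m$n_case.x > 0 & m$n_control.x > 0, ]
  expect_gt(nrow(both), 0)
  expect_equal(both$index_raw.x * both$index_raw.y,
               rep(10000, nrow(both)))
})

test_that("Berger-Parker dominance behaves as max count over total", {
  expect_equal(bergerParker(c(5, 3, 2)), 0.5)
  expect_equal(bergerParker(7), 1)
  expect_equal(bergerParker(c(1, 1, 1, 1)), 0.25)
  set.seed(4)
  x <- rpois(50, 3) + 1
  expect_equal(bergerParker(x), bergerParker(17 * x))  # scale invariance
  expect_error(bergerParker(c(0, 0)), "positive")
  dom <- dominancePerSample(generateRepertoire(
    simConfig(seed = 3, nCells = 200))$repertoire)
  expect_true(all(dom$berger_parker > 0 & dom$berger_parker <= 1))
})

test_that("hydroVsExpansion recovers a perfect monotone association", {
  metrics <- data.frame(chain = "TRB", cdr3_aa = c("A", "B", "C"),
                        hydro_mid = c(0.1, 0.2, 0.3))
  expansion <- data.frame(chain = "TRB", cdr3_aa = c("A", "B", "C"),
                          n_case = 1:3)
  out <- hydroVsExpansion(metrics, expansion)
  expect_equal(out$rho, 1)
  expect_equal(out$n, 3)
  # fewer than 3 clones: undefined, flagged
  out2 <- hydroVsExpansion(metrics[1:2, ], expansion[1:2, ])
  expect_true(is.na(out2$rho))
  expect_match(out2$note, "fewer than 3")
})

test_that("sharing matrix flags multi-subset and cross-lineage clones", {
  spec <- data.frame(
    chain = "TRB",
    cdr3_aa = c("CASSAAAAYEQYF", "CASSAAAAYEQYF", "CASSCCCCYEQYF"),
    condition = "case",
    subset = c("CD8 GZMK+", "CD4 Treg", "CD8 GZMK+"),
    n = c(3, 1, 2)
  )
  rep <- makeToyRepertoire(spec)
  sh <- sharingMatrix(rep, "subset")
  expect_true(sh$shared[["CASSAAAAYEQYF"]])
  expect_true(sh$cross_lineage[["CASSAAAAYEQYF"]])
  expect_false(sh$shared[["CASSCCCCYEQYF"]])
  expect_equal(sh$n_shared, 1L)
  # row sums conserve clone totals
  cl <- clones(rep)
  expect_equal(unname(rowSums(sh$matrix)[cl$cdr3_aa]), cl$n_cells)
})
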