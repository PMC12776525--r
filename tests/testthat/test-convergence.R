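test_that("translation follows the standard genetic code and rejects stops", {
  expect_equal(translateCDR3("TGT"), "C")
  expect_equal(translateCDR3("TGC"), "C")        # synonymous codon
  expect_equal(translateCDR3(c("TGTGCC", "AAAAGA")), c("CA", "KR"))
  expect_error(translateCDR3("TGAGCC"), "stop codon TGA at codon 1")
  expect_error(translateCDR3("TGTG"), "not a multiple of 3")
  expect_error(translateCDR3("TGN"), "non-ACGT")
})

test_that("translation agrees with an independent codon-table oracle", {
  set.seed(77)
  sense <- setdiff(
    apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                      c("T", "C", "A", "G")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  n_codons <- sample(3:8, 10000, replace = TRUE)
  seqs <- vapply(n_codons, function(k)
    paste(sample(sense, k, replace = TRUE), collapse = ""), character(1))
  mine <- translateCDR3(seqs)
  oracle <- vapply(seqs, function(s)
    paste(seqinr::translate(strsplit(s, "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
  expect_identical(mine, oracle)
})

test_that("CrE classes count distinct nucleotide variants per amino-acid clone", {
  spec <- data.frame(
    chain = "TRB",
    cdr3_aa = c("CASSAAAAYEQYF", "CASSAAAAYEQYF", "CASSCCCCYEQYF"),
    nt = c(aa2nt("CASSAAAAYEQYF"),
           sub("TGT", "TGC", aa2nt("CASSAAAAYEQYF")),
           aa2nt("CASSCCCCYEQYF")),
    condition = "case", n = c(2, 1, 1)
  )
  cv <- classifyConvergence(makeToyRepertoire(spec))
  r <- cv$records
  expect_equal(as.character(r$cre_class[r$cdr3_aa == "CASSAAAAYEQYF"]), "CrE-2")
  expect_equal(as.character(r$cre_class[r$cdr3_aa == "CASSCCCCYEQYF"]), "CrE-1")
  s <- cv$summary
  expect_equal(sum(s$pct_clones), 100)
  expect_equal(sum(s$pct_cells), 100)
})

test_that("a variant-free repertoire is 100 percent CrE-1", {
  sim <- generateRepertoire(simConfig(seed = 8, nCells = 300,
                                      convergenceRate = 0))
  cv <- classifyConvergence(sim$repertoire)
  expect_true(all(cv$records$cre_class == "CrE-1"))
})

test_that("classification matches brute force and is order-invariant", {
  sim <- generateRepertoire(simConfig(seed = 12, nCells = 400))
  rep <- sim$repertoire
  cv <- classifyConvergence(rep, scope = "condition")
  rec <- contigs(rep)
  rec <- rec[rec$chain == "TRB", ]
  key <- paste(rec$condition, rec$cdr3_aa)
  oracle <- tapply(rec$cdr3_nt, key, function(x) length(unique(x)))
  got <- setNames(cv$records$n_nt_variants,
                  paste(cv$records$condition, cv$records$cdr3_aa))
  expect_equal(got[names(oracle)], c(oracle))
  # conservation over classes
  expect_equal(sum(cv$records$n_cells), nrow(rec))
  # row order of the input must not matter
  set.seed(1)
  shuf <- contigs(rep)[sample(nrow(contigs(rep))), ]
  rep2 <- buildClones(shuf[, 1:7],
                      unique(shuf[, c("barcode", "sample_id", "subset")]),
                      sampleInfo(rep))
  cv2 <- classifyConvergence(rep2, scope = "condition")
  expect_identical(cv$records, cv2$records)
})

test_that("per-class hydrophobicity means reduce to hand-set values", {
  conv <- data.frame(chain = "TRB", cdr3_aa = c("A", "B", "C"),
                     cre_class = factor(c("CrE-1", "CrE-2", "CrE-3"),
                                        levels = c("CrE-1", "CrE-2", "CrE-3")))
  metrics <- data.frame(chain = "TRB", cdr3_aa = c("A", "B", "C"),
                        mid_length = 7L, hydro_mid = c(0.5, 1.5, 2.5))
  out <- convergenceVsPhyschem(conv, metrics)
  expect_equal(out$table$mean_hydro_mid[order(out$table$cre_class)],
               c(0.5, 1.5, 2.5))
  expect_equal(out$tests$n, 3L)
  expect_true(is.finite(out$tests$H) || out$tests$flag != "")
})

test_that("multi-V convergent clones are detected, single-V ones excluded", {
  base <- aa2nt("CASSLGQAYEQYF")
  spec <- data.frame(
    chain = "TRB",
    cdr3_aa = c("CASSLGQAYEQYF", "CASSLGQAYEQYF",
                "CASSDDDDYEQYF", "CASSDDDDYEQYF"),
    nt = c(base, sub("TGT", "TGC", base),
           aa2nt("CASSDDDDYEQYF"),
           sub("TGT", "TGC", aa2nt("CASSDDDDYEQYF"))),
    v_gene = c("TRBV19", "TRBV6-5", "TRBV19", "TRBV19"),
    condition = "case", n = 1
  )
  vg <- vGeneConvergence(makeToyRepertoire(spec))
  expect_equal(vg$cdr3_aa, "CASSLGQAYEQYF")
  expect_equal(vg$n_v_genes, 2L)
  expect_match(vg$v_genes, "TRBV19;TRBV6-5")
})

test_that("alpha partners of expanded beta clones are tabulated by cell", {
  rec <- data.frame(
    barcode = c("c1", "c2", "c3", "c1", "c2", "c3", "c4"),
    chain = c("TRB", "TRB", "TRB", "TRA", "TRA", "TRA", "TRB"),
    v_gene = "V", j_gene = "J",
    cdr3_nt = aa2nt(c("CASSLGQAYEQYF", "CASSLGQAYEQYF", "CASSLGQAYEQYF",
                      "CAVRDNQFYF", "CAVRDNQFYF", "CAVSSNQFYF",
                      "CASSWWWWYEQYF")),
    cdr3_aa = c("CASSLGQAYEQYF", "CASSLGQAYEQYF", "CASSLGQAYEQYF",
                "CAVRDNQFYF", "CAVRDNQFYF", "CAVSSNQFYF", "CASSWWWWYEQYF"),
    umis = 2L, stringsAsFactors = FALSE
  )
  cells <- data.frame(barcode = paste0("c", 1:4), sample_id = "s1",
                      subset = "CD8 GZMK+")
  samples <- data.frame(sample_id = "s1", condition = "case")
  rep <- buildClones(rec, cells, samples)
  pr <- alphaBetaPairing(rep, expandedMin = 2L)
  p <- pr$pairs
  expect_equal(nrow(p), 2L)
  expect_equal(p$n_cells[p$alpha == "CAVRDNQFYF"], 2L)
  expect_equal(p$n_cells[p$alpha == "CAVSSNQFYF"], 1L)
  expect_equal(pr$n_unpaired, 1L)   # c4 is beta-only
})

test_that("planted beta-alpha length coupling yields a positive association", {
  sim <- generateRepertoire(simConfig(seed = 31, nCells = 1500,
                                      pairingCoupling = 0.8))
  pr <- alphaBetaPairing(sim$repertoire)
  expect_gt(pr$length_assoc$rho, 0)
  expect_lt(pr$length_assoc$p, 0.05)
})
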