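# Seeded V(D)J repertoire simulator. Clone skeletons are V stub + random
# in-frame junctional insertion + J stub (stop codons rejected), clone
# sizes follow a discrete power law, and four effects are planted so every
# downstream statistic has a known truth: (i) a hydrophobicity tilt of the
# case clone pool and of case clone sizes (exp(beta * hydro_mid) weights),
# (ii) condition-specific CDR3 length mixtures, (iii) synonymous
# nucleotide convergence onto expanded clones (with optional alternative
# V stubs encoding the same amino acids), and (iv) beta-alpha mid-length
# coupling of paired chains. Germline stubs are short invented sequences
# beginning TGTGC ("CA...") and ending in J motifs whose last codon is F,
# so generated CDR3s look canonical; they are package constants, not
# downloads.

.TRB_V <- c(
  "TRBV19"   = "TGTGCCAGCAGT",        # CASS
  "TRBV6-5"  = "TGCGCAAGTAGT",        # CASS via synonymous codons
  "TRBV28"   = "TGTGCCAGC",           # CAS
  "TRBV12-3" = "TGTGCCACCAGC"         # CATS
)
.TRB_J <- c(
  "TRBJ2-7" = "TACGAGCAGTACTTT",      # YEQYF
  "TRBJ2-1" = "AATGAGCAGTTCTTT",      # NEQFF
  "TRBJ1-2" = "AACTATGGCTACACCTTC",   # NYGYTF
  "TRBJ2-5" = "CAAGAGACCCAGTACTTC"    # QETQYF
)
.TRA_V <- c(
  "TRAV12-1" = "TGTGTGGTG",           # CVV
  "TRAV8-4"  = "TGTGCCGTG"            # CAV
)
.TRA_J <- c(
  "TRAJ49" = "AACCAGTTCTATTTT",       # NQFYF
  "TRAJ33" = "GATAGCAACTATCAGTTC"     # DSNYQF
)

#' Simulation configuration for the repertoire generator
#'
#' Collects every generator parameter with the defaults that define the
#' simulated study conditions. Defaults: 2000 cells per condition in 3
#' samples each; case CDR3 beta lengths a 50/50 mixture of 12 and 15
#' residues versus a 14/15 control mixture (the short/long bimodality of
#' the case repertoire); clone sizes from a discrete power law with
#' exponent 2.5; a hydrophobicity-expansion coupling of beta = 0.5 acting
#' on the case condition only; 25 percent of expanded clones receive
#' synonymous nucleotide variants (30 percent of those through an
#' alternative V stub); beta-alpha mid-length coupling 0.6 with 90
#' percent of cells alpha-paired.
#'
#' @param seed integer RNG seed (drives everything)
#' @param nCells cells per condition
#' @param conditions named character vector \code{c(case = ..., control
#'   = ...)}
#' @param nSamples samples per condition
#' @param lengthModes named list (one entry per condition label) of
#'   two-column matrices \code{cbind(length_aa, weight)}; weights must sum
#'   to 1
#' @param cloneSizeExponent power-law exponent of the clone-size law
#' @param maxCloneSize truncation of the clone-size law
#' @param hydroCouplingBeta log-weight per unit mid-region Kyte-Doolittle
#'   hydrophobicity applied to case clone selection and case clone sizes
#' @param convergenceRate probability an expanded clone (2+ cells)
#'   receives synonymously recoded nucleotide variants
#' @param multiVProb probability a planted variant uses an alternative V
#'   stub encoding the same amino acids, where the pool offers one
#' @param subsetLabels,subsetProps phenotypic subset labels and their
#'   mixing proportions
#' @param subsetFidelity probability a cell takes its clone's primary
#'   subset label
#' @param pairingCoupling slope tying alpha target mid-length to beta
#'   mid-length
#' @param pairedFraction fraction of cells carrying a TRA partner contig
#' @param sharedCloneFraction fraction of the case clone pool reusing
#'   control skeletons (creates cross-condition shared clones)
#' @param trimN,trimC mid-region trims used for the planted couplings
#' @return a named list of class \code{SimulationConfig}
#' @export
simConfig <- function(seed = 1L,
                      nCells = 2000L,
                      conditions = c(case = "cardiotox", control = "no_irae"),
                      nSamples = 3L,
                      lengthModes = NULL,
                      cloneSizeExponent = 2.5,
                      maxCloneSize = 500L,
                      hydroCouplingBeta = 0.5,
                      convergenceRate = 0.25,
                      multiVProb = 0.3,
                      subsetLabels = c("CD8 GZMK+", "CD8 PRF1+",
                                       "CD4 Treg", "CD4 Tcm"),
                      subsetProps = c(0.35, 0.25, 0.2, 0.2),
                      subsetFidelity = 0.8,
                      pairingCoupling = 0.6,
                      pairedFraction = 0.9,
                      sharedCloneFraction = 0.05,
                      trimN = 3L, trimC = 3L) {
  if (is.null(lengthModes)) {
    lengthModes <- list(
      cbind(c(12, 15), c(0.5, 0.5)),
      cbind(c(14, 15), c(0.5, 0.5))
    )
    names(lengthModes) <- conditions[c("case", "control")]
  }
  for (lm in lengthModes)
    if (abs(sum(lm[, 2]) - 1) > 1e-8)
      stop("length-mode weights must sum to 1")
  stopifnot(length(subsetLabels) == length(subsetProps),
            abs(sum(subsetProps) - 1) < 1e-8,
            convergenceRate >= 0, convergenceRate <= 1,
            pairedFraction >= 0, pairedFraction <= 1,
            sharedCloneFraction >= 0, sharedCloneFraction <= 1)
  cfg <- list(seed = as.integer(seed), nCells = as.integer(nCells),
              conditions = conditions, nSamples = as.integer(nSamples),
              lengthModes = lengthModes,
              cloneSizeExponent = cloneSizeExponent,
              maxCloneSize = as.integer(maxCloneSize),
              hydroCouplingBeta = hydroCouplingBeta,
              convergenceRate = convergenceRate, multiVProb = multiVProb,
              subsetLabels = subsetLabels, subsetProps = subsetProps,
              subsetFidelity = subsetFidelity,
              pairingCoupling = pairingCoupling,
              pairedFraction = pairedFraction,
              sharedCloneFraction = sharedCloneFraction,
              trimN = as.integer(trimN), trimC = as.integer(trimC))
  class(cfg) <- "SimulationConfig"
  cfg
}

# Batch skeleton generation. All germline stubs are whole codons, so the
# junctional insertion is codon-aligned; drawing insert codons uniformly
# from the 61 stop-free codons guarantees a productive junction with no
# rejection loop. Returns a data.frame(v, j, nt, aa), one row per target
# length. Errors if some target length is reachable by no (V, J) pair.
.skeleton_batch <- function(target_lens, vpool, jpool, max_insert = 18L) {
  stopifnot(all(nchar(vpool) %% 3 == 0), all(nchar(jpool) %% 3 == 0))
  sense <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
  v_aa <- translateCDR3(unname(vpool))
  j_aa <- translateCDR3(unname(jpool))
  feas_all <- expand.grid(v = seq_along(vpool), j = seq_along(jpool))
  n <- length(target_lens)
  vi <- integer(n); ji <- integer(n)
  for (L in unique(target_lens)) {
    ins <- 3L * L - nchar(vpool)[feas_all$v] - nchar(jpool)[feas_all$j]
    feas <- which(ins >= 0 & ins <= max_insert)
    if (!length(feas))
      stop(sprintf("no V/J stub pair can reach CDR3 length %d aa", L))
    at <- which(target_lens == L)
    pick <- feas[sample.int(length(feas), length(at), replace = TRUE)]
    vi[at] <- feas_all$v[pick]
    ji[at] <- feas_all$j[pick]
  }
  n_cod <- target_lens - nchar(vpool)[vi] %/% 3L - nchar(jpool)[ji] %/% 3L
  cods <- sample(sense, sum(n_cod), replace = TRUE)
  grp <- rep.int(seq_len(n), n_cod)
  ins_nt <- character(n); ins_aa <- character(n)
  if (length(cods)) {
    by_clone <- split(cods, factor(grp, levels = seq_len(n)))
    ins_nt <- vapply(by_clone, paste, character(1), collapse = "")
    ins_aa <- vapply(by_clone, function(x)
      paste(.GENETIC_CODE[x], collapse = ""), character(1))
  }
  data.frame(
    v = names(vpool)[vi], j = names(jpool)[ji],
    nt = paste0(unname(vpool)[vi], ins_nt, unname(jpool)[ji]),
    aa = paste0(v_aa[vi], ins_aa, j_aa[ji]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# synonymously recode nt (preserving its translation), differing from all
# sequences in `avoid`; optionally force a given prefix (alternative V stub)
.recode_syn <- function(nt, avoid, prefix_nt = NULL) {
  aa <- strsplit(translateCDR3(nt), "")[[1L]]
  for (try in 1:25) {
    cods <- vapply(aa, function(a) {
      opts <- .CODONS_BY_AA[[a]]
      opts[sample.int(length(opts), 1L)]
    }, character(1))
    out <- paste(cods, collapse = "")
    if (!is.null(prefix_nt))
      out <- paste0(prefix_nt, substr(out, nchar(prefix_nt) + 1L, nchar(out)))
    if (!(out %in% avoid)) return(out)
  }
  NULL
}

.rpowerlaw <- function(n, alpha, kmax) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}

#' Generate a synthetic single-cell TCR repertoire with known truth
#'
#' Runs the full generative model of \code{\link{simConfig}} and returns
#' both the assembled \code{\linkS4class{TCRRepertoire}} (paired TRB/TRA
#' contigs, per-barcode subsets, per-condition samples) and a ground-truth
#' ledger recording every planted beta clone: its condition, amino-acid
#' CDR3, cell count, nucleotide variants, V genes, whether convergence
#' used multiple V stubs, its primary subset and its mid-region
#' hydrophobicity. Output is a deterministic function of the config
#' (including its seed).
#'
#' @param config a \code{\link{simConfig}} list
#' @return list with elements \code{repertoire}
#'   (\code{\linkS4class{TCRRepertoire}}), \code{truth} (data.frame of
#'   planted beta clones), \code{config}
#' @examples
#' sim <- generateRepertoire(simConfig(seed = 7, nCells = 200))
#' sim$repertoire
#' @export
generateRepertoire <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  kd <- hydropathyScale("kyte_doolittle")
  case_lab <- config$conditions[["case"]]
  ctrl_lab <- config$conditions[["control"]]

  draw_pool <- function(cond_lab, n_slots) {
    lm <- config$lengthModes[[cond_lab]]
    lens <- lm[, 1][sample.int(nrow(lm), n_slots, replace = TRUE,
                               prob = lm[, 2])]
    .skeleton_batch(lens, .TRB_V, .TRB_J)
  }

  K <- max(20L, ceiling(config$nCells / 3))
  beta <- config$hydroCouplingBeta

  # control pool: uniform selection
  ctrl_pool <- draw_pool(ctrl_lab, K)
  ctrl_pool$h <- hydrophobicity(
    midRegion(ctrl_pool$aa, config$trimN, config$trimC), kd)
  ctrl_pool$h[is.na(ctrl_pool$h)] <- 0

  # case pool: candidates thinned toward hydrophobic mid regions, plus a
  # shared slice of the control pool (also tilt-weighted)
  n_shared <- round(config$sharedCloneFraction * K)
  n_fresh <- K - n_shared
  cand <- draw_pool(case_lab, 2L * n_fresh)
  cand$h <- hydrophobicity(midRegion(cand$aa, config$trimN, config$trimC), kd)
  cand$h[is.na(cand$h)] <- 0
  w <- exp(beta * (cand$h - max(cand$h)))
  sel <- sample.int(nrow(cand), n_fresh, prob = w)
  case_pool <- cand[sel, , drop = FALSE]
  if (n_shared > 0) {
    ws <- exp(beta * (ctrl_pool$h - max(ctrl_pool$h)))
    case_pool <- rbind(case_pool,
                       ctrl_pool[sample.int(K, n_shared, prob = ws), ,
                                 drop = FALSE])
  }

  assign_sizes <- function(pool, tilt) {
    s <- .rpowerlaw(nrow(pool), config$cloneSizeExponent, config$maxCloneSize)
    w <- s * exp(tilt * pool$h)
    counts <- as.integer(stats::rmultinom(1L, config$nCells, w))
    pool$size <- counts
    pool[pool$size > 0L, , drop = FALSE]
  }
  case_pool <- assign_sizes(case_pool, beta)
  ctrl_pool <- assign_sizes(ctrl_pool, 0)
  case_pool$condition <- case_lab
  ctrl_pool$condition <- ctrl_lab
  pool <- rbind(case_pool, ctrl_pool)

  # merge accidental same-condition aa collisions so truth matches the
  # clone definition (amino-acid identity); keep per-variant (nt, v)
  # pairs parallel so each emitted nucleotide variant carries its V gene
  key <- paste(pool$condition, pool$aa, sep = "\r")
  if (anyDuplicated(key)) {
    idx_by_key <- split(seq_len(nrow(pool)), key)
    first <- vapply(idx_by_key, `[`, integer(1), 1L)
    merged <- pool[first, , drop = FALSE]
    merged$size <- vapply(idx_by_key, function(i)
      as.integer(sum(pool$size[i])), integer(1))
    merged$nts <- lapply(idx_by_key, function(i) {
      keep <- !duplicated(pool$nt[i])
      pool$nt[i][keep]
    })
    merged$var_v <- lapply(idx_by_key, function(i) {
      keep <- !duplicated(pool$nt[i])
      pool$v[i][keep]
    })
    pool <- merged
  } else {
    pool$nts <- as.list(pool$nt)
    pool$var_v <- as.list(pool$v)
  }

  # plant synonymous convergence on expanded clones
  pool$multi_v <- FALSE
  syn_alt <- c("TRBV19" = "TRBV6-5", "TRBV6-5" = "TRBV19")
  for (i in seq_len(nrow(pool))) {
    if (pool$size[i] < 2L) next
    if (stats::runif(1) > config$convergenceRate) next
    n_extra <- 1L + stats::rbinom(1L, 1L, 0.3)
    n_extra <- min(n_extra, pool$size[i] - 1L)  # each variant needs a cell
    for (e in seq_len(n_extra)) {
      v0 <- pool$var_v[[i]][1L]
      use_alt <- stats::runif(1) < config$multiVProb && v0 %in% names(syn_alt)
      prefix <- if (use_alt) .TRB_V[[syn_alt[[v0]]]] else NULL
      var <- .recode_syn(pool$nts[[i]][1L], avoid = pool$nts[[i]],
                         prefix_nt = prefix)
      if (is.null(var)) next
      pool$nts[[i]] <- c(pool$nts[[i]], var)
      pool$var_v[[i]] <- c(pool$var_v[[i]],
                           if (use_alt) syn_alt[[v0]] else v0)
      if (use_alt) pool$multi_v[i] <- TRUE
    }
  }

  # subsets and alpha partners per clone
  pool$primary_subset <- sample(config$subsetLabels, nrow(pool),
                                replace = TRUE, prob = config$subsetProps)
  mean_b <- mean(nchar(pool$aa))
  n_partner <- 1L + stats::rbinom(nrow(pool), 1L, 0.3)
  len_b <- rep.int(nchar(pool$aa), n_partner)
  la <- round(13 + config$pairingCoupling * (len_b - mean_b) +
                stats::rnorm(length(len_b)))
  la <- pmin(pmax(la, 9L), 15L)
  alpha_all <- .skeleton_batch(la, .TRA_V, .TRA_J)
  pool$alphas <- split(alpha_all, rep.int(seq_len(nrow(pool)), n_partner))

  # expand clones to cells, fully vectorised over the whole repertoire
  n_i <- pool$size
  N <- sum(n_i)
  ci <- rep.int(seq_len(nrow(pool)), n_i)          # clone index per cell
  first <- cumsum(n_i) - n_i + 1L                  # first cell of each clone
  bcs <- sprintf("bc%07d", seq_len(N))
  # nucleotide variant per cell: each extra variant takes one cell right
  # after the founder cell; the remainder carry the founder sequence
  nt_cell <- vapply(pool$nts, `[`, character(1), 1L)[ci]
  v_cell <- vapply(pool$var_v, `[`, character(1), 1L)[ci]
  for (i in which(lengths(pool$nts) > 1L)) {
    k <- seq_len(length(pool$nts[[i]]) - 1L)
    nt_cell[first[i] + k] <- pool$nts[[i]][-1L]
    v_cell[first[i] + k] <- pool$var_v[[i]][-1L]
  }
  keep_primary <- stats::runif(N) < config$subsetFidelity
  subs <- ifelse(keep_primary, pool$primary_subset[ci],
                 sample(config$subsetLabels, N, replace = TRUE,
                        prob = config$subsetProps))
  samp <- sprintf("%s_s%d", pool$condition[ci],
                  sample.int(config$nSamples, N, replace = TRUE))
  trb <- data.frame(
    barcode = bcs, chain = "TRB", v_gene = v_cell, j_gene = pool$j[ci],
    cdr3_nt = nt_cell, cdr3_aa = pool$aa[ci],
    umis = 1L + stats::rgeom(N, 0.4), stringsAsFactors = FALSE
  )
  # alpha partner per cell: partner 1 unless the clone has two partners
  # and the 25 percent secondary draw fires; pairedFraction of cells
  # carry the alpha contig at all
  a_first <- cumsum(n_partner) - n_partner + 1L    # partner-1 row per clone
  has_a <- stats::runif(N) < config$pairedFraction
  pick2 <- n_partner[ci] == 2L & stats::rbinom(N, 1L, 0.25) == 1L
  arow <- a_first[ci] + as.integer(pick2)
  tra <- data.frame(
    barcode = bcs[has_a], chain = "TRA",
    v_gene = alpha_all$v[arow[has_a]],
    j_gene = alpha_all$j[arow[has_a]],
    cdr3_nt = alpha_all$nt[arow[has_a]],
    cdr3_aa = alpha_all$aa[arow[has_a]],
    umis = 1L + stats::rgeom(sum(has_a), 0.4), stringsAsFactors = FALSE
  )
  records <- rbind(trb, tra)
  cells <- data.frame(barcode = bcs, sample_id = samp, subset = subs,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c(sprintf("%s_s%d", case_lab, seq_len(config$nSamples)),
                  sprintf("%s_s%d", ctrl_lab, seq_len(config$nSamples))),
    condition = rep(c(case_lab, ctrl_lab), each = config$nSamples),
    stringsAsFactors = FALSE
  )
  rep_obj <- buildClones(dedupePerBarcode(records), cells, samples)

  truth <- data.frame(
    condition = pool$condition,
    cdr3_aa = pool$aa,
    size = pool$size,
    n_nt_variants = vapply(pool$nts, length, integer(1)),
    nt_variants = vapply(pool$nts, function(x)
      paste(sort(x), collapse = ";"), character(1)),
    n_v_genes = vapply(pool$var_v, function(x)
      length(unique(x)), integer(1)),
    v_genes = vapply(pool$var_v, function(x)
      paste(sort(unique(x)), collapse = ";"), character(1)),
    multi_v = pool$multi_v,
    primary_subset = pool$primary_subset,
    hydro_mid = pool$h,
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$condition, truth$cdr3_aa), , drop = FALSE]
  rownames(truth) <- NULL
  list(repertoire = rep_obj, truth = truth, config = config)
}

#' Write small on-disk fixtures from the generator
#'
#' Emits a compact (about 200-cell) repertoire as both dialects — a
#' 10x-style contig CSV and an AIRR Rearrangement TSV — together with the
#' per-barcode cell metadata, sample metadata and the ground-truth ledger
#' as JSON. One clone is deterministically planted with exactly three
#' nucleotide variants (a CrE-3 event) and no other clone exceeds two, so
#' the convergence analysis has an unambiguous known answer. Regenerating
#' with the same config yields byte-identical files.
#'
#' @param outDir output directory (created if needed)
#' @param config a \code{\link{simConfig}}; the default is the shipped
#'   fixture configuration (seed 42, 90 cells per condition)
#' @return invisibly, the named vector of file paths written
#' @export
makeFixtures <- function(outDir,
                         config = simConfig(seed = 42L, nCells = 90L,
                                            convergenceRate = 0,
                                            sharedCloneFraction = 0.1)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- generateRepertoire(config)
  rep_obj <- sim$repertoire
  rec <- rep_obj@contigs
  truth <- sim$truth

  # plant exactly one CrE-3 clone: give the largest beta clone (3+ cells)
  # two synonymous variants; config disables all random convergence
  set.seed(config$seed + 1L)
  cl <- rep_obj@clones
  syn_alt <- c("TRBV19" = "TRBV6-5", "TRBV6-5" = "TRBV19")
  # only condition-pure clones, so the planted event sits in one condition
  pure <- names(which(table(truth$cdr3_aa) == 1L))
  big <- which(cl$chain == "TRB" & cl$n_cells >= 3L & cl$cdr3_aa %in% pure)
  if (!length(big)) stop("fixture config produced no clone with 3+ cells")
  # prefer a clone whose V stub has a synonymous alternative, so the
  # fixture also carries one planted multi-V convergent clone
  altable <- big[cl$v_genes[big] %in% names(syn_alt)]
  big <- if (length(altable)) altable[which.max(cl$n_cells[altable])]
         else big[which.max(cl$n_cells[big])]
  aa <- cl$cdr3_aa[big]
  rows <- which(rec$chain == "TRB" & rec$cdr3_aa == aa)
  base_nt <- rec$cdr3_nt[rows[1L]]
  base_v <- rec$v_gene[rows[1L]]
  use_alt <- base_v %in% names(syn_alt)
  v1 <- .recode_syn(base_nt, avoid = base_nt,
                    prefix_nt = if (use_alt) .TRB_V[[syn_alt[[base_v]]]]
                                else NULL)
  if (is.null(v1)) stop("could not synonymously recode the fixture clone")
  v2 <- .recode_syn(base_nt, avoid = c(base_nt, v1))
  if (is.null(v2)) stop("could not synonymously recode the fixture clone")
  rec$cdr3_nt[rows[2L]] <- v1
  if (use_alt) rec$v_gene[rows[2L]] <- syn_alt[[base_v]]
  rec$cdr3_nt[rows[3L]] <- v2
  rec$v_gene[rows[3L]] <- base_v
  ti <- which(truth$cdr3_aa == aa)
  truth$n_nt_variants[ti] <- 3L
  truth$nt_variants[ti] <- paste(sort(c(base_nt, v1, v2)), collapse = ";")
  if (use_alt) {
    truth$multi_v[ti] <- TRUE
    truth$n_v_genes[ti] <- 2L
    truth$v_genes[ti] <- paste(sort(c(base_v, syn_alt[[base_v]])),
                               collapse = ";")
  }

  cells <- unique(rec[, c("barcode", "sample_id", "subset")])
  samples <- rep_obj@samples
  rec_io <- rec[, c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt",
                    "cdr3_aa", "umis")]
  paths <- c(
    tenx = file.path(outDir, "contigs_tenx.csv"),
    airr = file.path(outDir, "contigs_airr.tsv"),
    cells = file.path(outDir, "cells.csv"),
    samples = file.path(outDir, "samples.csv"),
    truth = file.path(outDir, "truth.json")
  )
  writeContigs(rec_io, paths[["tenx"]], "tenx_csv")
  writeContigs(rec_io, paths[["airr"]], "airr_tsv")
  utils::write.csv(cells, paths[["cells"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(samples, paths[["samples"]], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(planted_cre3_cdr3_aa = aa, truth = truth,
         config = config[setdiff(names(config), "lengthModes")]),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
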