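# End-to-end report assembly: every table the analysis produces, written
# as TSVs plus one JSON summary that echoes the full parameter set, so a
# run is reproducible from its own output.

#' Per-condition mid-region hydrophobicity comparison
#'
#' Collects mid-region hydrophobicity values per condition — one value per
#' clone (default) or repeated per cell — and compares case against
#' control with a two-sample Kolmogorov-Smirnov test. Clone weighting is
#' the default because cells of one clone share a single CDR3 and are not
#' independent observations.
#'
#' @param rep a \code{\linkS4class{TCRRepertoire}}
#' @param caseLabel,controlLabel condition labels
#' @param weight \code{"clone"} or \code{"cell"}
#' @param scale,trimN,trimC scoring parameters
#' @param chain chain to analyse (default \code{"TRB"})
#' @return list: \code{values} (per-condition numeric vectors),
#'   \code{test} (a \code{\link{compareGroups}} KS result),
#'   \code{mean_case}, \code{mean_control}
#' @export
hydroByCondition <- function(rep, caseLabel, controlLabel,
                             weight = c("clone", "cell"),
                             scale = hydropathyScale("kyte_doolittle"),
                             trimN = 3L, trimC = 3L, chain = "TRB") {
  weight <- match.arg(weight)
  cc <- cloneCounts(rep, by = "condition", chain = chain)
  cc <- cc[cc$group %in% c(caseLabel, controlLabel), , drop = FALSE]
  h <- hydrophobicity(
    {m <- midRegion(cc$cdr3_aa, trimN, trimC); ifelse(nchar(m) > 0, m, NA)},
    scale)
  keep <- !is.na(h)
  cc <- cc[keep, , drop = FALSE]; h <- h[keep]
  reps <- if (weight == "cell") cc$n_cells else rep(1L, nrow(cc))
  vals <- split(rep(h, reps), rep(cc$group, reps))
  test <- compareGroups(vals[[caseLabel]], vals[[controlLabel]], "ks")
  list(values = vals, test = test,
       mean_case = mean(vals[[caseLabel]]),
       mean_control = mean(vals[[controlLabel]]))
}

#' Assemble the full physicochemical repertoire report
#'
#' Runs every analysis stage on a built repertoire and writes a
#' machine-readable bundle to \code{outDir}: per-clone hydrophobicity
#' metrics on each requested scale, length distributions, expansion
#' indices, per-sample dominance, convergence records and class
#' percentages, the subset sharing matrix (long format), multi-V
#' convergent clones, alpha-beta pairing, and a JSON summary holding the
#' headline statistics together with a verbatim echo of all parameters.
#' Per-comparison p-values are reported as in the underlying tests;
#' Benjamini-Hochberg adjusted q-values over the summary's comparisons
#' are added as a clearly labelled extension. Output is a deterministic
#' function of the repertoire and config: no timestamps, stable ordering.
#'
#' @param rep a \code{\linkS4class{TCRRepertoire}}
#' @param caseLabel,controlLabel condition labels to contrast
#' @param outDir output directory (created if needed)
#' @param scales character vector of built-in scale names
#' @param trimN,trimC mid-region trims
#' @param pseudo expansion-index pseudocount
#' @param bins copy-number bin upper edges
#' @param expandedMin cells needed to call a clone expanded
#' @param chain chain for the headline statistics
#' @param seed echoed into the parameter log (the analysis itself is
#'   deterministic)
#' @return invisibly, the summary list (also written as
#'   \code{summary.json})
#' @export
hydroReport <- function(rep, caseLabel, controlLabel, outDir,
                        scales = c("kyte_doolittle",
                                   "wimley_white_interface"),
                        trimN = 3L, trimC = 3L, pseudo = 1,
                        bins = c(1, 2, 5, 10, Inf), expandedMin = 2L,
                        chain = "TRB", seed = NA_integer_) {
  stopifnot(is(rep, "TCRRepertoire"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.table(
    x, file.path(outDir, f), sep = "\t", row.names = FALSE, quote = FALSE)

  metrics_all <- do.call(rbind, lapply(scales, function(s)
    suppressMessages(scoreRepertoire(rep, hydropathyScale(s), trimN, trimC))))
  wr(metrics_all, "metrics.tsv")
  metrics <- metrics_all[metrics_all$scale == scales[1L] &
                           metrics_all$chain == chain, , drop = FALSE]

  ld <- lengthDistribution(rep, by = "cell", region = "mid", chain = chain,
                           trimN = trimN, trimC = trimC)
  wr(ld, "length_distribution.tsv")

  exp_tab <- expansionIndex(rep, caseLabel, controlLabel, pseudo, chain)
  wr(exp_tab, "expansion.tsv")

  dom <- dominancePerSample(rep, chain)
  wr(dom, "dominance.tsv")

  conv <- classifyConvergence(rep, scope = "condition", chain = chain)
  wr(conv$records, "convergence_records.tsv")
  wr(conv$summary, "convergence_summary.tsv")

  shar <- sharingMatrix(rep, "subset", chain)
  shar_long <- data.frame(
    cdr3_aa = rep(rownames(shar$matrix), ncol(shar$matrix)),
    group = rep(colnames(shar$matrix), each = nrow(shar$matrix)),
    n_cells = as.vector(shar$matrix)
  )
  shar_long <- shar_long[shar_long$n_cells > 0, , drop = FALSE]
  wr(shar_long, "sharing_long.tsv")

  vg <- vGeneConvergence(rep, chain)
  wr(vg, "vgene_convergence.tsv")

  pairing <- alphaBetaPairing(rep, expandedMin,
                              hydropathyScale(scales[1L]), trimN, trimC)
  wr(pairing$pairs, "pairing.tsv")

  hyd <- hydroByCondition(rep, caseLabel, controlLabel, "clone",
                          hydropathyScale(scales[1L]), trimN, trimC, chain)
  hve <- hydroVsExpansion(metrics, exp_tab, bins)
  roc_labels <- exp_tab$n_case >= expandedMin
  roc_scores <- metrics$hydro_mid[match(exp_tab$cdr3_aa, metrics$cdr3_aa)]
  ok <- !is.na(roc_scores)
  roc <- if (length(unique(roc_labels[ok])) == 2)
    rocFromScores(roc_labels[ok], roc_scores[ok]) else NULL

  p_raw <- c(ks_case_vs_control = hyd$test$p,
             spearman_expansion = hve$p,
             roc_expanded = if (is.null(roc)) NA else roc$p)
  q_bh <- stats::p.adjust(p_raw, method = "BH")

  summary <- list(
    parameters = list(case = caseLabel, control = controlLabel,
                      scales = scales, trim_n = trimN, trim_c = trimC,
                      pseudo = pseudo, bins = bins,
                      expanded_min = expandedMin, chain = chain,
                      seed = seed),
    n_cells = nrow(rep@contigs[rep@contigs$chain == chain, ]),
    n_clones = nrow(rep@clones[rep@clones$chain == chain, ]),
    hydrophobicity = list(
      mean_mid_case = hyd$mean_case, mean_mid_control = hyd$mean_control,
      ks_D = unname(hyd$test$statistic), ks_p = hyd$test$p),
    expansion = list(
      spearman_rho = hve$rho, spearman_p = hve$p, spearman_ci = hve$ci,
      n_clones = hve$n,
      berger_parker_mean_case = mean(dom$berger_parker[dom$condition ==
                                                         caseLabel]),
      berger_parker_mean_control = mean(dom$berger_parker[dom$condition ==
                                                            controlLabel])),
    convergence = stats::setNames(
      lapply(split(conv$summary, conv$summary$condition), function(d)
        stats::setNames(as.list(d$pct_clones), d$cre_class)),
      unique(conv$summary$condition)),
    sharing = list(n_shared = shar$n_shared,
                   n_cross_lineage = shar$n_cross_lineage),
    roc = if (is.null(roc)) NULL else
      list(auroc = roc$auroc, p = roc$p, n_pos = roc$n_pos,
           n_neg = roc$n_neg),
    q_values_bh = as.list(q_bh)   # multiple-testing extension, BH
  )
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
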