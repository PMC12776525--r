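#' @import methods
NULL

#' TCRRepertoire: a single-cell TCR repertoire with its clonotype table
#'
#' Container tying together (i) the retained, deduplicated productive V(D)J
#' contig records, (ii) the amino-acid-defined clonotype table derived from
#' them, and (iii) per-sample metadata. Clones are keyed by
#' \code{(chain, cdr3_aa)}: cells sharing an identical CDR3 amino-acid
#' sequence on a chain belong to one clone, whatever their nucleotide
#' rearrangement or V gene. Build objects with \code{\link{buildClones}};
#' do not fill slots by hand.
#'
#' @slot contigs data.frame of retained contig records, one row per cell and
#'   chain, with columns \code{barcode}, \code{chain}, \code{v_gene},
#'   \code{j_gene}, \code{cdr3_nt}, \code{cdr3_aa}, \code{umis},
#'   \code{sample_id}, \code{condition}, \code{subset}.
#' @slot clones data.frame of clonotypes with columns \code{chain},
#'   \code{cdr3_aa}, \code{n_cells}, \code{n_nt_variants}; nucleotide
#'   variants and V genes are kept as \code{;}-joined sorted strings in
#'   \code{nt_variants} and \code{v_genes}.
#' @slot samples data.frame mapping \code{sample_id} to \code{condition}
#'   (plus any covariates supplied at build time).
#'
#' @seealso \code{\link{buildClones}}, \code{\link{contigs}},
#'   \code{\link{clones}}, \code{\link{sampleInfo}}, \code{\link{cloneCounts}}
#' @exportClass TCRRepertoire
setClass("TCRRepertoire",
  representation(
    contigs = "data.frame",
    clones  = "data.frame",
    samples = "data.frame"
  )
)

setValidity("TCRRepertoire", function(object) {
  msg <- character()
  need_contig <- c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt",
                   "cdr3_aa", "umis", "sample_id", "condition", "subset")
  miss <- setdiff(need_contig, names(object@contigs))
  if (length(miss))
    msg <- c(msg, paste0("contigs lack column(s): ", paste(miss, collapse = ", ")))
  need_clone <- c("chain", "cdr3_aa", "n_cells", "n_nt_variants",
                  "nt_variants", "v_genes")
  miss <- setdiff(need_clone, names(object@clones))
  if (length(miss))
    msg <- c(msg, paste0("clones lack column(s): ", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    # conservation: cells per chain identical before and after clone building
    for (ch in unique(object@contigs$chain)) {
      n_rec <- sum(object@contigs$chain == ch)
      n_cl  <- sum(object@clones$n_cells[object@clones$chain == ch])
      if (n_rec != n_cl)
        msg <- c(msg, sprintf("chain %s: %d contig records but %d cells in clones",
                              ch, n_rec, n_cl))
    }
    key_rec <- paste(object@contigs$chain, object@contigs$cdr3_aa)
    key_cl  <- paste(object@clones$chain, object@clones$cdr3_aa)
    if (anyDuplicated(key_cl))
      msg <- c(msg, "duplicate (chain, cdr3_aa) clone keys")
    if (!all(key_rec %in% key_cl))
      msg <- c(msg, "contig record without a matching clone")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TCRRepertoire compact summary of cells, clones and conditions
#' @param object a \code{TCRRepertoire}
#' @export
setMethod("show", "TCRRepertoire", function(object) {
  cat("TCRRepertoire\n")
  for (ch in sort(unique(object@contigs$chain))) {
    cat(sprintf("  %s: %d cells, %d clones\n", ch,
                sum(object@contigs$chain == ch),
                sum(object@clones$chain == ch)))
  }
  tab <- table(object@samples$condition)
  cat(sprintf("  %d samples (%s)\n", nrow(object@samples),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

#' @rdname contigs
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname clones
#' @export
setGeneric("clones", function(x) standardGeneric("clones"))

#' @rdname sampleInfo
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' Contig records of a repertoire
#'
#' @param x a \code{\linkS4class{TCRRepertoire}}
#' @return data.frame of retained per-cell contig records
#' @export
setMethod("contigs", "TCRRepertoire", function(x) x@contigs)

#' Clonotype table of a repertoire
#'
#' @param x a \code{\linkS4class{TCRRepertoire}}
#' @return data.frame with one row per (chain, cdr3_aa) clone
#' @export
setMethod("clones", "TCRRepertoire", function(x) x@clones)

#' Sample-level metadata of a repertoire
#'
#' @param x a \code{\linkS4class{TCRRepertoire}}
#' @return data.frame mapping sample_id to condition and covariates
#' @export
setMethod("sampleInfo", "TCRRepertoire", function(x) x@samples)

#' Per-clone cell counts split by a grouping variable
#'
#' Long-format counts of cells per clone within samples, conditions or
#' phenotypic subsets, recomputed from the contig records so that row sums
#' always conserve clone totals.
#'
#' @param x a \code{\linkS4class{TCRRepertoire}}
#' @param by one of \code{"sample"}, \code{"condition"}, \code{"subset"}
#' @param chain optional chain filter (\code{"TRA"} or \code{"TRB"})
#' @return data.frame with columns \code{chain}, \code{cdr3_aa},
#'   \code{group}, \code{n_cells}
#' @examples
#' rep <- generateRepertoire(simConfig(seed = 1, nCells = 120))$repertoire
#' head(cloneCounts(rep, by = "condition", chain = "TRB"))
#' @export
cloneCounts <- function(x, by = c("sample", "condition", "subset"),
                        chain = NULL) {
  stopifnot(is(x, "TCRRepertoire"))
  by <- match.arg(by)
  rec <- x@contigs
  if (!is.null(chain)) rec <- rec[rec$chain %in% chain, , drop = FALSE]
  col <- switch(by, sample = "sample_id", condition = "condition",
                subset = "subset")
  agg <- stats::aggregate(
    list(n_cells = rec$barcode),
    by = list(chain = rec$chain, cdr3_aa = rec$cdr3_aa, group = rec[[col]]),
    FUN = length
  )
  agg <- agg[order(agg$chain, agg$cdr3_aa, agg$group), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
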