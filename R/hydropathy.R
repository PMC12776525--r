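# Residue hydropathy tables. Both scales are stored so that HIGHER = MORE
# HYDROPHOBIC. Kyte-Doolittle values are the published residue hydropathies
# (I = 4.5 ... R = -4.5). The Wimley-White membrane-interface transfer free
# energies (kcal/mol, water -> POPC interface; charged Asp/Glu/Lys/Arg,
# neutral His) are negated at load for the same orientation; the published
# raw values are kept alongside.
.KD_VALUES <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

.WW_INTERFACE_RAW <- c(
  A =  0.17, R =  0.81, N =  0.42, D =  1.23, C = -0.24,
  Q =  0.58, E =  2.02, G =  0.01, H =  0.17, I = -0.31,
  L = -0.56, K =  0.99, M = -0.23, F = -1.13, P =  0.45,
  S =  0.13, T =  0.14, W = -1.85, Y = -0.94, V =  0.07
)

#' HydropathyScale: a per-residue hydrophobicity table
#'
#' Twenty standard amino-acid letters mapped to numeric hydropathy values,
#' oriented so that higher always means more hydrophobic. For the
#' Wimley-White interface scale this means the published transfer free
#' energies are sign-flipped at load; the raw published values are retained
#' in \code{raw}.
#'
#' @slot name scale identifier
#' @slot values named numeric vector, one value per amino-acid letter,
#'   higher = more hydrophobic
#' @slot raw the published values before any reorientation
#' @exportClass HydropathyScale
setClass("HydropathyScale",
  representation(name = "character", values = "numeric", raw = "numeric")
)

setValidity("HydropathyScale", function(object) {
  aa <- sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (!identical(sort(names(object@values)), aa))
    return("values must name exactly the 20 standard amino acids")
  if (!identical(sort(names(object@raw)), aa))
    return("raw must name exactly the 20 standard amino acids")
  TRUE
})

#' @describeIn HydropathyScale print the scale and its orientation
#' @param object a \code{HydropathyScale}
#' @export
setMethod("show", "HydropathyScale", function(object) {
  cat(sprintf("HydropathyScale '%s' (higher = more hydrophobic)\n", object@name))
  print(round(object@values[order(-object@values)], 2))
})

#' Built-in or user-supplied hydropathy scales
#'
#' Returns one of the two embedded scales, or loads a custom two-column
#' (letter, value) whitespace/tab-delimited text file. Embedded scales:
#' \describe{
#'   \item{kyte_doolittle}{the classic residue hydropathy index
#'     (I = 4.5, V = 4.2, ..., R = -4.5), used for headline statistics.}
#'   \item{wimley_white_interface}{membrane-interface transfer free
#'     energies, negated so higher = more hydrophobic (W = 1.85,
#'     F = 1.13, ..., E = -2.02).}
#' }
#' Custom files are taken as already oriented (higher = more hydrophobic).
#'
#' @param name \code{"kyte_doolittle"} or \code{"wimley_white_interface"},
#'   or an arbitrary label when \code{file} is given
#' @param file optional path to a two-column text file (letter, value)
#' @return a \code{\linkS4class{HydropathyScale}}
#' @examples
#' hydropathyScale("kyte_doolittle")
#' @export
hydropathyScale <- function(name = c("kyte_doolittle", "wimley_white_interface"),
                            file = NULL) {
  if (!is.null(file)) {
    tab <- utils::read.table(file, header = FALSE, col.names = c("aa", "value"),
                             stringsAsFactors = FALSE)
    v <- stats::setNames(tab$value, tab$aa)
    return(new("HydropathyScale", name = as.character(name)[1L],
               values = v, raw = v))
  }
  name <- match.arg(name)
  if (name == "kyte_doolittle")
    new("HydropathyScale", name = name, values = .KD_VALUES, raw = .KD_VALUES)
  else
    new("HydropathyScale", name = name, values = -.WW_INTERFACE_RAW,
        raw = .WW_INTERFACE_RAW)
}

#' Mid-hypervariable region of a CDR3 amino-acid sequence
#'
#' Trims conserved flanking residues to isolate the junction-encoded loop
#' apex: \code{trimN} residues from the N terminus (the conserved
#' cysteine-anchored "CAS..." motif) and \code{trimC} from the C terminus
#' (the residues proximal to the J-encoded "F/W-G-x-G" motif). Sequences no
#' longer than \code{trimN + trimC} give the empty string. Vectorised.
#'
#' @param cdr3_aa character vector of CDR3 amino-acid sequences
#' @param trimN,trimC non-negative trim widths (default 3 and 3)
#' @return character vector of mid-region sequences
#' @examples
#' midRegion("CASSLGQAYEQYF")      # "SLGQAYE"
#' midRegion("CASF")               # ""
#' @export
midRegion <- function(cdr3_aa, trimN = 3L, trimC = 3L) {
  stopifnot(trimN >= 0, trimC >= 0)
  n <- nchar(cdr3_aa)
  out <- substr(cdr3_aa, trimN + 1L, n - trimC)
  out[n <= trimN + trimC] <- ""
  out
}

#' Mean hydrophobicity of amino-acid sequences
#'
#' Arithmetic mean of per-residue scale values over each sequence. The empty
#' string is missing data (\code{NA}), never zero: a zero is a valid mean on
#' these scales and would silently bias group comparisons. Unknown letters
#' are an error naming the letter and its position.
#'
#' @param seq character vector of amino-acid sequences
#' @param scale a \code{\linkS4class{HydropathyScale}} (default
#'   Kyte-Doolittle)
#' @return numeric vector of mean hydropathies (\code{NA} for empty strings)
#' @examples
#' hydrophobicity("CASS")                     # 0.675 on Kyte-Doolittle
#' hydrophobicity("IR")                       # 0
#' @export
hydrophobicity <- function(seq, scale = hydropathyScale("kyte_doolittle")) {
  stopifnot(is(scale, "HydropathyScale"))
  vals <- scale@values
  vapply(seq, function(s) {
    if (is.na(s) || !nchar(s)) return(NA_real_)
    letters <- strsplit(s, "")[[1L]]
    bad <- which(!(letters %in% names(vals)))
    if (length(bad))
      stop(sprintf("unknown amino-acid letter '%s' at position %d in '%s'",
                   letters[bad[1L]], bad[1L], s))
    mean(vals[letters])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score every clone of a repertoire for CDR3 hydrophobicity
#'
#' Computes, per clone, the full-CDR3 and mid-hypervariable-region mean
#' hydrophobicity together with length summaries. Clones whose mid region is
#' empty after trimming carry \code{NA} for \code{hydro_mid} and are to be
#' excluded from mid-region statistics; a message reports how many.
#'
#' @param rep a \code{\linkS4class{TCRRepertoire}}
#' @param scale a \code{\linkS4class{HydropathyScale}}
#' @param trimN,trimC mid-region trim widths (see \code{\link{midRegion}})
#' @return data.frame with one row per clone: \code{chain}, \code{cdr3_aa},
#'   \code{n_cells}, \code{length_aa}, \code{mid_sequence},
#'   \code{mid_length}, \code{hydro_full}, \code{hydro_mid}, \code{scale}
#' @examples
#' rep <- generateRepertoire(simConfig(seed = 1, nCells = 150))$repertoire
#' head(scoreRepertoire(rep))
#' @export
scoreRepertoire <- function(rep, scale = hydropathyScale("kyte_doolittle"),
                            trimN = 3L, trimC = 3L) {
  stopifnot(is(rep, "TCRRepertoire"))
  cl <- rep@clones
  mid <- midRegion(cl$cdr3_aa, trimN, trimC)
  out <- data.frame(
    chain        = cl$chain,
    cdr3_aa      = cl$cdr3_aa,
    n_cells      = cl$n_cells,
    length_aa    = nchar(cl$cdr3_aa),
    mid_sequence = mid,
    mid_length   = nchar(mid),
    hydro_full   = hydrophobicity(cl$cdr3_aa, scale),
    hydro_mid    = hydrophobicity(ifelse(nchar(mid) > 0, mid, NA), scale),
    scale        = scale@name,
    stringsAsFactors = FALSE
  )
  n_empty <- sum(out$mid_length == 0L)
  if (n_empty > 0)
    message(sprintf("%d clone(s) with empty mid region excluded from mid-region statistics",
                    n_empty))
  out
}

#' CDR3 length distribution per condition
#'
#' Normalised frequency of full or mid-region CDR3 amino-acid lengths within
#' each condition. Clone weighting counts each clonotype once; cell
#' weighting counts clones by their cell numbers, which is what reveals the
#' short/long bimodality of expanded repertoires.
#'
#' @param rep a \code{\linkS4class{TCRRepertoire}}
#' @param by \code{"clone"} or \code{"cell"} weighting
#' @param region \code{"full"} or \code{"mid"}
#' @param chain optional chain filter
#' @param trimN,trimC mid-region trims when \code{region = "mid"}
#' @return data.frame with columns \code{condition}, \code{length},
#'   \code{frequency}; frequencies sum to 1 within each condition
#' @export
lengthDistribution <- function(rep, by = c("clone", "cell"),
                               region = c("full", "mid"), chain = NULL,
                               trimN = 3L, trimC = 3L) {
  stopifnot(is(rep, "TCRRepertoire"))
  by <- match.arg(by); region <- match.arg(region)
  cc <- cloneCounts(rep, by = "condition", chain = chain)
  seqs <- if (region == "full") cc$cdr3_aa else midRegion(cc$cdr3_aa, trimN, trimC)
  cc$length <- nchar(seqs)
  w <- if (by == "cell") cc$n_cells else rep(1L, nrow(cc))
  agg <- stats::aggregate(list(weight = w),
                          by = list(condition = cc$group, length = cc$length),
                          FUN = sum)
  tot <- stats::ave(agg$weight, agg$condition, FUN = sum)
  agg$frequency <- agg$weight / tot
  agg <- agg[order(agg$condition, agg$length), c("condition", "length", "frequency")]
  rownames(agg) <- NULL
  agg
}
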