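#' @import methods
#' @importFrom stats cor median pt rbinom rnorm runif sd setNames var
#' @importFrom utils head read.table write.table modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Position-specific frequency matrix (PSFM)
#'
#' A PSFM describes a DNA binding motif as per-position letter
#' frequencies over the alphabet \{A, C, G, T\}, together with
#' background letter frequencies used to weight columns by their
#' information content.
#'
#' @slot name single string, motif identifier.
#' @slot profile 4 x l numeric matrix; rows named A, C, G, T; every
#'   column sums to 1.
#' @slot background named numeric(4) of background letter frequencies
#'   (default uniform 0.25), summing to 1.
#'
#' @seealso [PSFM()], [readPSFM()], [columnInformation()],
#'   [similarityScore()]
#' @exportClass PSFM
setClass("PSFM", representation(
  name = "character",
  profile = "matrix",
  background = "numeric"
))

setValidity("PSFM", function(object) {
  p <- object@profile
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single string")
  if (!is.numeric(p) || nrow(p) != 4L || !identical(rownames(p), DNA_BASES))
    msg <- c(msg, "'profile' must be a numeric 4 x l matrix with rows A,C,G,T")
  else {
    if (ncol(p) < 1L) msg <- c(msg, "PSFM must have at least one column")
    if (any(p < 0) || any(p > 1)) msg <- c(msg, "frequencies must lie in [0, 1]")
    cs <- colSums(p)
    if (any(abs(cs - 1) > 1e-9))
      msg <- c(msg, "every profile column must sum to 1 (tolerance 1e-9)")
  }
  q <- object@background
  if (length(q) != 4L || is.null(names(q)) || !identical(names(q), DNA_BASES))
    msg <- c(msg, "'background' must be numeric(4) named A,C,G,T")
  else {
    if (any(q < 0)) msg <- c(msg, "background frequencies must be nonnegative")
    if (abs(sum(q) - 1) > 1e-9) msg <- c(msg, "background must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PSFM
#'
#' @param profile 4 x l matrix of per-position letter frequencies or
#'   counts (rows A, C, G, T in that order, or named). Count matrices
#'   are normalized column-wise.
#' @param name motif identifier.
#' @param background background letter frequencies; defaults to the
#'   uniform 0.25 per base.
#' @param pseudocount nonnegative value added to every entry of a count
#'   matrix before normalization (default 0).
#'
#' @return a [PSFM-class] object.
#' @examples
#' m <- PSFM(rbind(A = c(7, 0), C = c(1, 0), G = c(1, 10), T = c(1, 0)),
#'           name = "toy")
#' consensusString(m)
#' @export
PSFM <- function(profile, name = "motif", background = NULL,
                 pseudocount = 0) {
  profile <- as.matrix(profile)
  if (nrow(profile) != 4L)
    stop("PSFM profile must have 4 rows (A, C, G, T)")
  if (is.null(rownames(profile))) rownames(profile) <- DNA_BASES
  profile <- profile[DNA_BASES, , drop = FALSE]
  if (any(!is.finite(profile)) || any(profile < 0))
    stop("PSFM entries must be finite and nonnegative")
  profile <- profile + pseudocount
  cs <- colSums(profile)
  if (any(cs == 0))
    stop("PSFM column with zero total at position(s): ",
         paste(which(cs == 0), collapse = ", "))
  profile <- sweep(profile, 2L, cs, "/")
  if (is.null(background)) {
    background <- setNames(rep(0.25, 4L), DNA_BASES)
  } else {
    if (is.null(names(background))) names(background) <- DNA_BASES
    background <- background[DNA_BASES]
    background <- background / sum(background)
  }
  new("PSFM", name = name, profile = profile, background = background)
}

#' @describeIn PSFM number of motif positions.
#' @param x a PSFM.
#' @export
setMethod("length", "PSFM", function(x) ncol(x@profile))

#' @rdname PSFM-accessors
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))

#' PSFM accessors
#'
#' @param x a [PSFM-class].
#' @return `motifName()` the identifier; `profileMatrix()` the 4 x l
#'   frequency matrix; `background()` the named background frequencies.
#' @name PSFM-accessors
#' @export
setMethod("motifName", "PSFM", function(x) x@name)

#' @rdname PSFM-accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname PSFM-accessors
#' @export
setMethod("profileMatrix", "PSFM", function(x) x@profile)

#' @rdname PSFM-accessors
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname PSFM-accessors
#' @export
setMethod("background", "PSFM", function(x) x@background)

setMethod("show", "PSFM", function(object) {
  cat("PSFM object '", object@name, "' (", length(object),
      " positions)\n", sep = "")
  cat("consensus:", consensusString(object), "\n")
  print(round(object@profile, 3))
})

#' @describeIn similarityScore majority-letter consensus of a PSFM
#'   (ties reported as IUPAC-style slash groups are collapsed to the
#'   first of the tied letters in alphabetical order).
#' @export
setMethod("consensusString", "PSFM", function(x) {
  paste(DNA_BASES[apply(x@profile, 2L, which.max)], collapse = "")
})

#' Motif enrichment statistics
#'
#' Holds the matched-window counts and derived binomial-approximation
#' statistics comparing a sample region set against a background set:
#' expected count `E = N_c * L_s / L_c`, fold enrichment `F = N_s / E`
#' and Z-score `Z = (N_s - E) / sqrt(E)`.
#'
#' @slot motif motif identifier.
#' @slot nSample matched-window count in the sample set (N_s).
#' @slot lSample effective (unmasked) sample length in bp (L_s).
#' @slot nBackground matched-window count in the background set (N_c).
#' @slot lBackground effective background length in bp (L_c).
#' @slot expected expected sample count E.
#' @slot foldEnrichment F; `NA` when N_c = 0.
#' @slot zScore Z; `NA` when N_c = 0.
#' @slot lowExpected TRUE when E < 10, where the normal approximation
#'   to the binomial is dubious.
#' @seealso [enrichmentStats()]
#' @exportClass EnrichmentResult
setClass("EnrichmentResult", representation(
  motif = "character",
  nSample = "numeric",
  lSample = "numeric",
  nBackground = "numeric",
  lBackground = "numeric",
  expected = "numeric",
  foldEnrichment = "numeric",
  zScore = "numeric",
  lowExpected = "logical"
))

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult", if (nzchar(object@motif)) sprintf("'%s'", object@motif), "\n")
  cat(sprintf("  sample:     N_s = %g in L_s = %g bp\n",
              object@nSample, object@lSample))
  cat(sprintf("  background: N_c = %g in L_c = %g bp\n",
              object@nBackground, object@lBackground))
  cat(sprintf("  E = %.4g, fold enrichment F = %.4g, Z = %.4g\n",
              object@expected, object@foldEnrichment, object@zScore))
  if (object@lowExpected)
    cat("  warning: E < 10; normal approximation to the binomial is dubious\n")
})

#' @rdname EnrichmentResult-accessors
#' @export
setGeneric("foldEnrichment", function(x) standardGeneric("foldEnrichment"))

#' EnrichmentResult accessors
#'
#' @param x an [EnrichmentResult-class].
#' @name EnrichmentResult-accessors
#' @export
setMethod("foldEnrichment", "EnrichmentResult", function(x) x@foldEnrichment)

#' @rdname EnrichmentResult-accessors
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("zScore", "EnrichmentResult", function(x) x@zScore)

#' @rdname EnrichmentResult-accessors
#' @export
setGeneric("expectedCount", function(x) standardGeneric("expectedCount"))

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("expectedCount", "EnrichmentResult", function(x) x@expected)

#' Convert an EnrichmentResult to a one-row data.frame
#'
#' @param x an [EnrichmentResult-class].
#' @param row.names,optional,... passed through for generic
#'   compatibility; ignored.
#' @export
as.data.frame.EnrichmentResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(motif = x@motif, n_sample = x@nSample, l_sample = x@lSample,
             n_background = x@nBackground, l_background = x@lBackground,
             expected = x@expected, fold_enrichment = x@foldEnrichment,
             z_score = x@zScore, low_expected = x@lowExpected,
             stringsAsFactors = FALSE)
}
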