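#' @importFrom Biostrings consensusString reverseComplement readBStringSet
#'   writeXStringSet BStringSet BString subseq
NULL

#' Per-column information content of a PSFM
#'
#' For column j with letter frequencies P_ij and background Q_i,
#' \deqn{I_j = \sum_{i \in \{A,C,G,T\}} P_{ij} \log_2(P_{ij}/Q_i)}
#' with the convention that terms with P_ij = 0 contribute 0. With a
#' uniform background, I_j is the column's information content in bits:
#' 0 for a uniform column, 2 for a deterministic one.
#'
#' @param psfm a [PSFM-class].
#' @param base logarithm base (default 2, bits). The similarity score
#'   [similarityScore()] is invariant to this choice because the base
#'   factors out of its numerator and denominator.
#' @return numeric vector of length `length(psfm)`.
#' @examples
#' columnInformation(PSFM(cbind(c(1, 0, 0, 0), rep(0.25, 4))))
#' @export
columnInformation <- function(psfm, base = 2) {
  stopifnot(is(psfm, "PSFM"))
  q <- psfm@background
  if (any(q == 0))
    stop("background frequencies must be strictly positive")
  p <- psfm@profile
  term <- p * log(p / q, base = base)
  term[p == 0] <- 0    # 0 * log(0) := 0
  colSums(term)
}

# Numerator weight matrix W[i, j] = I_j (2 P_ij - 1) and the (scalar)
# denominator sum_j I_j (2 P_j^max - 1). Shared by similarityScore and
# the window scanner.
.similarity_weights <- function(psfm, base = 2) {
  info <- columnInformation(psfm, base = base)
  p <- psfm@profile
  w <- sweep(2 * p - 1, 2L, info, "*")
  denom <- sum(info * (2 * apply(p, 2L, max) - 1))
  if (denom == 0)
    stop("uninformative PSFM: all columns uniform relative to background")
  list(weights = w, denom = denom)
}

#' Information-weighted similarity between a PSFM and a sequence
#'
#' For a sequence of the motif's length selecting letter i(j) at each
#' position j,
#' \deqn{S = \frac{\sum_j I_j (2 P_{i(j),j} - 1)}{\sum_j I_j (2 P^{max}_j - 1)}}
#' S equals 1 exactly when the sequence picks a maximum-frequency
#' letter at every informative column; it can be negative for strongly
#' anti-consensus sequences and never exceeds 1.
#'
#' @param psfm a [PSFM-class].
#' @param sequences character vector of DNA strings, each of length
#'   `length(psfm)`; case-insensitive. Sequences containing letters
#'   outside A/C/G/T (e.g. N) are unscorable and get `NA`.
#' @param base log base for the information weights; S is invariant to
#'   it (kept as an argument so the invariance can be checked).
#' @return numeric vector of similarities, one per sequence.
#' @examples
#' m <- PSFM(rbind(A = c(0.7, 0), C = c(0.1, 0), G = c(0.1, 1), T = c(0.1, 0)))
#' similarityScore(m, c("AG", "CG"))
#' @export
similarityScore <- function(psfm, sequences, base = 2) {
  stopifnot(is(psfm, "PSFM"))
  l <- length(psfm)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) && any(nchar(sequences) != l))
    stop("every sequence must have the motif length (", l, " bp)")
  sw <- .similarity_weights(psfm, base = base)
  vapply(sequences, function(s) {
    idx <- match(strsplit(s, "", fixed = TRUE)[[1L]], DNA_BASES)
    if (anyNA(idx)) return(NA_real_)
    sum(sw$weights[cbind(idx, seq_len(l))]) / sw$denom
  }, numeric(1), USE.NAMES = FALSE)
}

#' @describeIn similarityScore reverse complement of a PSFM: columns
#'   reversed and complementary letters swapped, so scanning the minus
#'   strand of a sequence equals scanning its reverse complement with
#'   the original matrix.
#' @param x a PSFM.
#' @param ... ignored.
#' @export
setMethod("reverseComplement", "PSFM", function(x, ...) {
  p <- x@profile[c("T", "G", "C", "A"), rev(seq_len(ncol(x@profile))),
                 drop = FALSE]
  rownames(p) <- DNA_BASES
  q <- x@background[c("T", "G", "C", "A")]
  names(q) <- DNA_BASES
  new("PSFM", name = x@name, profile = p, background = q)
})

#' Build a PSFM from a degenerate consensus string
#'
#' Utility for reconstructing matrices from a published consensus when
#' the numeric PSFM itself is not available. Fixed letters receive
#' frequency `1 - 3 * noise`; two-fold degenerate IUPAC letters
#' (R, Y, S, W, K, M) split `1 - 2 * noise` equally between their two
#' bases; `N` is uniform.
#'
#' @param consensus string over A,C,G,T,R,Y,S,W,K,M,N.
#' @param name motif identifier.
#' @param noise per-column frequency assigned to each non-consensus
#'   letter (default 0.02).
#' @return a [PSFM-class].
#' @examples
#' consensusPSFM("AGRGGAAG", name = "PU.1-short")
#' @export
consensusPSFM <- function(consensus, name = consensus, noise = 0.02) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                N = DNA_BASES)
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  bad <- setdiff(letters, names(iupac))
  if (length(bad))
    stop("unsupported consensus letter(s): ", paste(bad, collapse = ", "))
  prof <- vapply(letters, function(ch) {
    hits <- iupac[[ch]]
    col <- setNames(rep(noise, 4L), DNA_BASES)
    col[hits] <- (1 - noise * (4 - length(hits))) / length(hits)
    col
  }, numeric(4))
  PSFM(prof, name = name)
}

#' Read a PSFM from a matrix file
#'
#' Two dialects are supported. `"transfac"`: a TRANSFAC-style count
#' matrix with header lines (`ID`/`NA`/`P0  A  C  G  T`), numbered rows
#' `01  7  1  1  1 [consensus]`, terminated by `//`; counts are
#' normalized to frequencies per column. `"plain_matrix"`: one
#' whitespace-delimited row of four frequencies (A C G T order) per
#' position, `#` comments allowed.
#'
#' The background is uniform (0.25 per base) unless supplied.
#'
#' @param path file path.
#' @param dialect `"transfac"` or `"plain_matrix"`.
#' @param name motif identifier; for TRANSFAC input defaults to the
#'   `ID`/`NA` field.
#' @param background optional background frequencies.
#' @return a [PSFM-class].
#' @export
readPSFM <- function(path, dialect = c("transfac", "plain_matrix"),
                     name = NULL, background = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "transfac") {
    id <- NULL
    rows <- list()
    for (ln in lines) {
      ln <- trimws(ln)
      if (!nzchar(ln) || ln == "//" || ln == "XX") next
      tok <- strsplit(ln, "\\s+")[[1L]]
      key <- toupper(tok[1L])
      if (key %in% c("ID", "NA", "AC") && length(tok) >= 2L) {
        if (is.null(id)) id <- tok[2L]
      } else if (grepl("^P0$|^PO$", key, ignore.case = TRUE)) {
        next
      } else if (grepl("^[0-9]+$", tok[1L])) {
        if (length(tok) < 5L)
          stop("malformed TRANSFAC matrix row: ", ln)
        rows[[length(rows) + 1L]] <- as.numeric(tok[2:5])
      }
    }
    if (!length(rows)) stop("no matrix rows found in ", path)
    counts <- t(do.call(rbind, rows))
    rownames(counts) <- DNA_BASES
    if (any(counts < 0)) stop("negative matrix entries in ", path)
    if (is.null(name)) name <- if (is.null(id)) basename(path) else id
    PSFM(counts, name = name, background = background)
  } else {
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!length(lines)) stop("no matrix rows found in ", path)
    rows <- lapply(lines, function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]))
    if (any(lengths(rows) != 4L))
      stop("plain_matrix rows must have exactly 4 values (A C G T)")
    freq <- t(do.call(rbind, rows))
    rownames(freq) <- DNA_BASES
    if (any(is.na(freq)) || any(freq < 0)) stop("invalid matrix entries in ", path)
    if (is.null(name)) name <- basename(path)
    PSFM(freq, name = name, background = background)
  }
}

#' Built-in motif reconstructions
#'
#' Consensus-derived reconstructions of the three motifs used
#' throughout the package examples and tests: the extended "long" PU.1
#' element (A/G)AAAG(A/G)GGAAGTG, the canonical "short" PU.1 element
#' AG(A/G)GGAAG, and the retinoic acid response element half site
#' (RAREh) AGGTCA. The numeric matrices are reconstructions built from
#' the published consensus strings (see [consensusPSFM()]), not
#' database matrices; substitute your own PSFMs via [readPSFM()] for
#' real analyses. Shipped as TRANSFAC-format files under
#' `inst/extdata/` and parsed at call time.
#'
#' @return a named list of [PSFM-class] objects with elements
#'   `long`, `short` and `rareh`.
#' @examples
#' lapply(defaultMotifs(), consensusString)
#' @export
defaultMotifs <- function() {
  dir <- system.file("extdata", package = "CistromeKit")
  list(
    long = readPSFM(file.path(dir, "pu1_long_reconstruction.transfac")),
    short = readPSFM(file.path(dir, "pu1_short_reconstruction.transfac")),
    rareh = readPSFM(file.path(dir, "rareh_reconstruction.transfac"))
  )
}
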