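#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   mcols mcols<- findOverlaps countOverlaps strand<- start<- end<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors Rle queryHits subjectHits runValue runLength
#' @importFrom IRanges RleList
#' @importFrom GenomeInfoDb seqlengths seqlevels
NULL

#' Read genome sequences from FASTA
#'
#' Sequences are returned with case preserved: lowercase bases denote
#' soft-masked (repeat) sequence and `N` hard-masked sequence, both of
#' which the scanner treats as unscorable and excludes from effective
#' lengths. Record names are the first whitespace-delimited token of
#' each header.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::BStringSet] (BString, not DNAString, so
#'   that masking case survives).
#' @export
readSequences <- function(path) {
  seqs <- readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

#' @rdname readSequences
#' @param seqs named character vector or BStringSet.
#' @export
writeSequences <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- BStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read peak/region files into a GRanges
#'
#' Internally all regions are GRanges (1-based, closed intervals, the
#' Bioconductor convention); readers own every coordinate conversion.
#'
#' Dialects:
#' \describe{
#'   \item{bed}{headerless, >= 3 columns, 0-based half-open; column 4
#'     (if present) is the region name, column 5 a score stored as
#'     `fold`.}
#'   \item{peak_table}{tab-delimited with a header row (MACS-style);
#'     coordinates 1-based inclusive; an optional summit column gives
#'     the summit as an offset from the region start; an optional fold
#'     column carries the peak fold enrichment. Extra columns are
#'     tolerated; column names are configurable via `columns`.}
#' }
#'
#' @param path input file.
#' @param dialect `"bed"` or `"peak_table"`.
#' @param columns named list mapping the roles `chrom`, `start`, `end`,
#'   `summit`, `fold`, `name` to header names of the peak_table dialect
#'   (case-insensitive).
#' @return [GenomicRanges::GRanges] with metadata columns `name`,
#'   `summit` (absolute 1-based position or NA) and `fold` (or NA).
#'   Row order of the input is preserved.
#' @export
readRegions <- function(path, dialect = c("bed", "peak_table"),
                        columns = list()) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, comment.char = "#",
                     quote = "")
    if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
    start1 <- as.numeric(df[[2L]]) + 1  # 0-based half-open -> 1-based closed
    end1 <- as.numeric(df[[3L]])
    bad <- which(end1 < start1)
    if (length(bad))
      stop("end <= start after conversion at row(s): ",
           paste(head(bad, 5L), collapse = ", "))
    gr <- GRanges(df[[1L]], IRanges(start1, end1))
    mcols(gr)$name <- if (ncol(df) >= 4L) as.character(df[[4L]]) else NA_character_
    mcols(gr)$summit <- NA_real_
    mcols(gr)$fold <- if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5L]])) else NA_real_
    gr
  } else {
    cols <- modifyList(list(chrom = "chr", start = "start", end = "end",
                            summit = "summit", fold = "fold", name = "name"),
                       columns)
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, comment.char = "",
                     quote = "", check.names = FALSE)
    hd <- tolower(names(df))
    pick <- function(role) {
      i <- match(tolower(cols[[role]]), hd)
      if (is.na(i)) NULL else df[[i]]
    }
    chrom <- pick("chrom"); st <- pick("start"); en <- pick("end")
    if (is.null(chrom) || is.null(st) || is.null(en))
      stop("peak_table needs columns '", cols$chrom, "', '", cols$start,
           "', '", cols$end, "' (configurable via 'columns')")
    start1 <- as.numeric(st)   # already 1-based inclusive
    end1 <- as.numeric(en)
    bad <- which(end1 < start1)
    if (length(bad))
      stop("end <= start after conversion at row(s): ",
           paste(head(bad, 5L), collapse = ", "))
    gr <- GRanges(as.character(chrom), IRanges(start1, end1))
    nm <- pick("name")
    mcols(gr)$name <- if (is.null(nm)) NA_character_ else as.character(nm)
    smt <- pick("summit")
    mcols(gr)$summit <- if (is.null(smt)) NA_real_ else start1 + as.numeric(smt)
    fd <- pick("fold")
    mcols(gr)$fold <- if (is.null(fd)) NA_real_ else as.numeric(fd)
    if (!all(is.na(mcols(gr)$summit))) {
      out <- which(!is.na(mcols(gr)$summit) &
                   (mcols(gr)$summit < start1 | mcols(gr)$summit > end1))
      if (length(out))
        stop("summit outside its region at row(s): ",
             paste(head(out, 5L), collapse = ", "))
    }
    gr
  }
}

#' Write regions to BED or peak_table
#'
#' Inverse of [readRegions()]: `readRegions(writeRegions(x, p, d), d)`
#' reproduces `x`'s coordinates bit-for-bit. The bed dialect writes
#' name/score columns when present but cannot carry summits; the
#' peak_table dialect preserves summit (as offset from start) and fold
#' enrichment rounded to 2 decimals.
#'
#' @param regions GRanges as produced by [readRegions()].
#' @param path output file.
#' @param dialect `"bed"` or `"peak_table"`.
#' @export
writeRegions <- function(regions, path, dialect = c("bed", "peak_table")) {
  dialect <- match.arg(dialect)
  m <- mcols(regions)
  nm <- if (!is.null(m$name)) as.character(m$name) else rep(NA_character_, length(regions))
  if (dialect == "bed") {
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L,  # back to 0-based half-open
                     end = end(regions),
                     stringsAsFactors = FALSE)
    if (any(!is.na(nm))) {
      df$name <- ifelse(is.na(nm), ".", nm)
      if (!is.null(m$fold) && any(!is.na(m$fold)))
        df$score <- ifelse(is.na(m$fold), 0, m$fold)
    }
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    summit <- if (!is.null(m$summit)) m$summit else rep(NA_real_, length(regions))
    fold <- if (!is.null(m$fold)) m$fold else rep(NA_real_, length(regions))
    df <- data.frame(chr = as.character(seqnames(regions)),
                     start = start(regions),
                     end = end(regions),
                     name = ifelse(is.na(nm), ".", nm),
                     summit = summit - start(regions),
                     fold = round(fold, 2L),
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read gene models
#'
#' Accepts UCSC refFlat (11 columns: geneName, transcript, chrom,
#' strand, txStart, txEnd, ... with 0-based txStart) or a simplified
#' 5-column variant (name, chrom, strand, txStart, txEnd, same
#' convention), or BED6. Each record is one gene model; the
#' transcription start site (TSS) is the 5' end in gene orientation and
#' the transcription end site (TES) the 3' end.
#'
#' @param path input file.
#' @param format `"refflat"` or `"bed"`.
#' @return [GenomicRanges::GRanges] with strand set and a `name`
#'   metadata column. Use [tssPosition()] / [tesPosition()] for the
#'   strand-aware sites.
#' @export
readGeneModels <- function(path, format = c("refflat", "bed")) {
  format <- match.arg(format)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#", quote = "")
  if (format == "refflat") {
    if (ncol(df) >= 6L) {
      name <- as.character(df[[1L]]); chrom <- as.character(df[[3L]])
      strand <- as.character(df[[4L]])
      txs <- as.numeric(df[[5L]]); txe <- as.numeric(df[[6L]])
    } else if (ncol(df) == 5L) {
      name <- as.character(df[[1L]]); chrom <- as.character(df[[2L]])
      strand <- as.character(df[[3L]])
      txs <- as.numeric(df[[4L]]); txe <- as.numeric(df[[5L]])
    } else stop("refFlat file needs 5 or >= 6 columns: ", path)
  } else {
    if (ncol(df) < 6L) stop("BED gene file needs 6 columns (strand): ", path)
    chrom <- as.character(df[[1L]]); txs <- as.numeric(df[[2L]])
    txe <- as.numeric(df[[3L]]); name <- as.character(df[[4L]])
    strand <- as.character(df[[6L]])
  }
  if (!all(strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'; offending row(s): ",
         paste(head(which(!strand %in% c("+", "-")), 5L), collapse = ", "))
  if (any(txe <= txs)) stop("gene with tx_end <= tx_start in ", path)
  gr <- GRanges(chrom, IRanges(txs + 1, txe), strand = strand)
  mcols(gr)$name <- name
  gr
}

#' @rdname readGeneModels
#' @param genes gene GRanges.
#' @export
writeGeneModels <- function(genes, path) {
  df <- data.frame(name = mcols(genes)$name,
                   chrom = as.character(seqnames(genes)),
                   strand = as.character(strand(genes)),
                   tx_start = start(genes) - 1L,
                   tx_end = end(genes),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand-aware transcription start/end sites
#'
#' @param genes gene GRanges with strand.
#' @return 1-based positions: TSS is `start` on `+` and `end` on `-`;
#'   TES is the opposite end.
#' @export
tssPosition <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' @rdname tssPosition
#' @export
tesPosition <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", start(genes), end(genes))
}

#' Read a per-base score track
#'
#' Conservation-style tracks (e.g. phastCons) as bedGraph or fixed-step
#' wiggle, expanded per base. Positions not covered by the file are
#' missing (`NA`), not zero; the profiler treats them as such.
#'
#' @param path input file.
#' @param dialect `"bedgraph"` or `"fixedstep_wig"`.
#' @param chromLengths optional named vector of chromosome lengths; if
#'   absent, each chromosome's track extends to its last covered base.
#' @return an RleList, one numeric Rle per chromosome with
#'   `NA` at missing positions; query with [trackValues()].
#' @export
readScoreTrack <- function(path, dialect = c("bedgraph", "fixedstep_wig"),
                           chromLengths = NULL) {
  dialect <- match.arg(dialect)
  fmt <- if (dialect == "bedgraph") "bedGraph" else "wig"
  gr <- rtracklayer::import(path, format = fmt)
  if (dialect == "bedgraph") {
    self <- findOverlaps(gr, gr)
    if (any(queryHits(self) != subjectHits(self)))
      stop("overlapping bedGraph intervals in ", path)
  }
  scoreTrack(gr, chromLengths = chromLengths)
}

#' Build a score track from a scored GRanges
#'
#' @param gr GRanges with a numeric `score` metadata column.
#' @param chromLengths optional named chromosome lengths.
#' @return an RleList with NA at uncovered positions.
#' @export
scoreTrack <- function(gr, chromLengths = NULL) {
  stopifnot(!is.null(mcols(gr)$score))
  if (any(!is.finite(mcols(gr)$score))) stop("track scores must be finite")
  chroms <- unique(as.character(seqnames(gr)))
  if (!is.null(chromLengths)) chroms <- union(chroms, names(chromLengths))
  out <- lapply(setNames(chroms, chroms), function(ch) {
    sel <- as.character(seqnames(gr)) == ch
    len <- if (!is.null(chromLengths) && ch %in% names(chromLengths))
      chromLengths[[ch]] else if (any(sel)) max(end(gr)[sel]) else 0L
    v <- rep(NA_real_, len)
    if (any(sel)) {
      s <- start(gr)[sel]; e <- pmin(end(gr)[sel], len)
      sc <- mcols(gr)$score[sel]
      for (k in seq_along(s)) if (e[k] >= s[k]) v[s[k]:e[k]] <- sc[k]
    }
    Rle(v)
  })
  as(out, "RleList")
}

#' @rdname readScoreTrack
#' @param track an RleList score track.
#' @export
writeScoreTrack <- function(track, path) {
  pieces <- lapply(names(track), function(ch) {
    r <- track[[ch]]
    rl <- cumsum(c(0L, S4Vectors::runLength(r)))
    val <- runValue(r)
    keep <- !is.na(val)
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = rl[which(keep)],      # 0-based
               end = rl[which(keep) + 1L], score = val[keep],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Query a score track at 1-based positions
#'
#' @param track RleList from [readScoreTrack()]/[scoreTrack()].
#' @param chrom chromosome name.
#' @param positions 1-based positions; out-of-range or uncovered
#'   positions give `NA`.
#' @return numeric vector.
#' @export
trackValues <- function(track, chrom, positions) {
  if (!chrom %in% names(track)) return(rep(NA_real_, length(positions)))
  r <- track[[chrom]]
  ok <- positions >= 1 & positions <= length(r)
  out <- rep(NA_real_, length(positions))
  if (any(ok)) out[ok] <- as.numeric(r[positions[ok]])
  out
}

#' Read a chrom.sizes file
#'
#' @param path two-column (name, length) text file.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Read tag (read 5' end) positions from BED
#'
#' Each record contributes one single-bp position: the 5' end in read
#' orientation (start for `+`/unstranded, end for `-`).
#'
#' @param path BED file.
#' @return GRanges of width-1 positions.
#' @export
readTags <- function(path) {
  gr <- readRegions(path, dialect = "bed")
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#", quote = "")
  strnd <- if (ncol(df) >= 6L) as.character(df[[6L]]) else rep("+", nrow(df))
  pos <- ifelse(strnd == "-", end(gr), start(gr))
  out <- GRanges(seqnames(gr), IRanges(pos, pos), strand = strnd)
  out
}

#' @rdname readTags
#' @param tags width-1 GRanges of tag positions.
#' @export
writeTags <- function(tags, path) {
  df <- data.frame(chrom = as.character(seqnames(tags)),
                   start = start(tags) - 1L, end = start(tags),
                   name = ".", score = 0,
                   strand = ifelse(as.character(strand(tags)) == "-", "-", "+"),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
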