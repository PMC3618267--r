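ANNOTATION_CATEGORIES <- c("promoter", "gene_body", "upstream_enhancer",
                           "downstream_enhancer", "distal_intergenic")

# Gene-oriented offsets of an anchor from a gene's TSS and TES: positive
# means downstream of the site in gene orientation.
.oriented_offsets <- function(anchor, genes) {
  minus <- as.character(strand(genes)) == "-"
  tss <- tssPosition(genes)
  tes <- tesPosition(genes)
  d <- ifelse(minus, tss - anchor, anchor - tss)
  t <- ifelse(minus, tes - anchor, anchor - tes)
  list(d = d, t = t)
}

#' Classify one genomic anchor against gene models
#'
#' Region classes relative to a gene, in gene orientation (distances in
#' bp from the TSS, negative = upstream):
#' promoter `[-2000, +1000]` around the TSS (closed on both ends);
#' gene body `(TSS+1000, TES]`; upstream enhancer `[-50000, -2000)`;
#' downstream enhancer `(TES, TES+50000]`; anchors farther than 50 kb
#' from every TSS and TES are distal intergenic. When several genes
#' yield classes, the highest-priority class wins
#' (promoter > gene body > upstream enhancer > downstream enhancer);
#' ties within a class are broken by smallest |distance to TSS|, then
#' lexicographic gene name.
#'
#' @param chrom chromosome of the anchor.
#' @param anchor 1-based anchor position (typically a peak summit).
#' @param genes gene GRanges from [readGeneModels()].
#' @return a list with `category`, `gene` (name or NA), `gene_strand`
#'   and `distance` (signed gene-oriented bp to the TSS, NA for distal
#'   intergenic).
#' @export
classifyAnchor <- function(chrom, anchor, genes) {
  same <- as.character(seqnames(genes)) == chrom
  if (!any(same))
    return(list(category = "distal_intergenic", gene = NA_character_,
                gene_strand = NA_character_, distance = NA_real_))
  g <- genes[same]
  off <- .oriented_offsets(anchor, g)
  d <- off$d; t <- off$t
  cat_idx <- rep(NA_integer_, length(g))
  cat_idx[t > 0 & t <= 50000] <- 4L                  # downstream enhancer
  cat_idx[d >= -50000 & d < -2000] <- 3L             # upstream enhancer
  cat_idx[d > 1000 & t <= 0] <- 2L                   # gene body
  cat_idx[d >= -2000 & d <= 1000] <- 1L              # proximal promoter
  if (all(is.na(cat_idx)))
    return(list(category = "distal_intergenic", gene = NA_character_,
                gene_strand = NA_character_, distance = NA_real_))
  best <- min(cat_idx, na.rm = TRUE)
  cand <- which(!is.na(cat_idx) & cat_idx == best)
  nm <- mcols(g)$name[cand]
  ord <- order(abs(d[cand]), nm)
  pick <- cand[ord[1L]]
  list(category = ANNOTATION_CATEGORIES[best],
       gene = mcols(g)$name[pick],
       gene_strand = as.character(strand(g))[pick],
       distance = d[pick])
}

#' Annotate peaks with genomic-region classes
#'
#' Each peak is anchored at its summit (midpoint fallback when the
#' summit is absent) and assigned exactly one class by
#' [classifyAnchor()]'s boundary and priority rules, so the classes
#' partition the peak set.
#'
#' @param peaks GRanges with optional `summit`/`name` metadata columns.
#' @param genes gene GRanges; an empty gene set annotates everything as
#'   distal intergenic, with a warning.
#' @return a list with
#'   \describe{
#'     \item{annotations}{data.frame, one row per peak: `peak`, `name`,
#'       `chrom`, `anchor`, `category` (factor), `gene`, `gene_strand`,
#'       `distance_to_tss`;}
#'     \item{distribution}{data.frame of `category`, `count`, `percent`
#'       (counts sum to the peak count, percents to 100).}
#'   }
#' @export
annotatePeaks <- function(peaks, genes) {
  if (length(peaks) == 0L) stop("empty peak set")
  if (length(genes) == 0L)
    warning("empty gene set: all peaks annotated as distal_intergenic")
  summit <- mcols(peaks)$summit
  if (is.null(summit)) summit <- rep(NA_real_, length(peaks))
  anchor <- ifelse(is.na(summit),
                   floor((start(peaks) + end(peaks)) / 2), summit)
  rows <- lapply(seq_along(peaks), function(i) {
    cl <- classifyAnchor(as.character(seqnames(peaks)[i]), anchor[i], genes)
    data.frame(peak = i,
               name = if (!is.null(mcols(peaks)$name))
                 as.character(mcols(peaks)$name[i]) else NA_character_,
               chrom = as.character(seqnames(peaks)[i]),
               anchor = anchor[i],
               category = cl$category,
               gene = cl$gene,
               gene_strand = cl$gene_strand,
               distance_to_tss = cl$distance,
               stringsAsFactors = FALSE)
  })
  anno <- do.call(rbind, rows)
  anno$category <- factor(anno$category, levels = ANNOTATION_CATEGORIES)
  counts <- table(anno$category)
  dist <- data.frame(category = names(counts),
                     count = as.integer(counts),
                     percent = as.numeric(counts) / length(peaks) * 100,
                     stringsAsFactors = FALSE)
  list(annotations = anno, distribution = dist)
}

#' Per-gene proximal/distal targeting summary
#'
#' A gene is proximally targeted when at least one linked peak is in
#' its promoter class, and distally targeted when at least one linked
#' peak falls in its gene body or either enhancer class. Distal
#' intergenic peaks are linked to no gene and do not contribute.
#'
#' @param annotations the `annotations` data.frame from
#'   [annotatePeaks()].
#' @return a list with `perGene` (data.frame: `gene`, `has_proximal`,
#'   `has_distal`) and the counts `nProximalOnly`, `nDistalOnly`,
#'   `nBoth`, `nTargeted`.
#' @export
geneTargetSummary <- function(annotations) {
  linked <- annotations[!is.na(annotations$gene), , drop = FALSE]
  if (nrow(linked) == 0L) {
    per <- data.frame(gene = character(0), has_proximal = logical(0),
                      has_distal = logical(0), stringsAsFactors = FALSE)
    return(list(perGene = per, nProximalOnly = 0L, nDistalOnly = 0L,
                nBoth = 0L, nTargeted = 0L))
  }
  prox <- tapply(linked$category == "promoter", linked$gene, any)
  dist <- tapply(linked$category %in%
                   c("gene_body", "upstream_enhancer", "downstream_enhancer"),
                 linked$gene, any)
  per <- data.frame(gene = names(prox),
                    has_proximal = as.logical(prox),
                    has_distal = as.logical(dist[names(prox)]),
                    stringsAsFactors = FALSE)
  list(perGene = per,
       nProximalOnly = sum(per$has_proximal & !per$has_distal),
       nDistalOnly = sum(!per$has_proximal & per$has_distal),
       nBoth = sum(per$has_proximal & per$has_distal),
       nTargeted = nrow(per))
}
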