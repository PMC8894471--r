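# Genomic-context classification of TSSs: coding vs non-coding,
# silencer-bound vs free, cross-condition set comparison, and the
# pie/Venn summary tables.

genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$contig, IRanges::IRanges(genes$start, genes$end))
}

tss_granges <- function(tss) {
  GenomicRanges::GRanges(tss$contig, IRanges::IRanges(tss$position, width = 1L))
}

#' Classify TSSs as coding or non-coding
#'
#' A TSS is "coding" iff its base lies within any gene interval on either
#' strand (strand-agnostic: spurious intragenic starts on the antisense
#' strand still sit in coding DNA). Set `same_strand_only = TRUE` to require
#' the gene to be on the TSS strand.
#'
#' @param tss A `tss_set` (or any data.frame with contig/position/strand).
#' @param genes Gene model `data.frame`.
#' @param same_strand_only Restrict to same-strand genes.
#' @return Character vector `"coding"` / `"non-coding"` per TSS.
#' @export
classify_tss_location <- function(tss, genes, same_strand_only = FALSE) {
  if (!nrow(tss)) return(character(0))
  if (!nrow(genes)) return(rep("non-coding", nrow(tss)))
  g <- genes_granges(genes)
  if (same_strand_only) BiocGenerics::strand(g) <- genes$strand
  q <- tss_granges(tss)
  if (same_strand_only) BiocGenerics::strand(q) <- tss$strand
  hit <- IRanges::overlapsAny(q, g,
                              ignore.strand = !same_strand_only)
  ifelse(hit, "coding", "non-coding")
}

#' Membership of TSSs in a labelled region set
#'
#' @param tss A `tss_set`.
#' @param regions Region set `data.frame` (1-based inclusive ends).
#' @return Logical vector per TSS.
#' @export
assign_region_membership <- function(tss, regions) {
  if (!nrow(tss)) return(logical(0))
  if (is.null(regions) || !nrow(regions)) return(rep(FALSE, nrow(tss)))
  r <- GenomicRanges::GRanges(regions$contig,
                              IRanges::IRanges(regions$start, regions$end))
  IRanges::overlapsAny(tss_granges(tss), r, ignore.strand = TRUE)
}

#' Compare two TSS sets at exact coordinates
#'
#' Matching is exact on (contig, position, strand); a `tolerance_bp` merge
#' window is available but off by default, mirroring duplicate removal by
#' exact pooling.
#'
#' @param a,b `tss_set`s.
#' @param tolerance_bp Positions within this many bases (same strand) are
#'   considered shared (default 0 = exact).
#' @return A `venn_partition` list: `only_a`, `only_b`, `shared`, `labels`.
#' @export
compare_tss_sets <- function(a, b, tolerance_bp = 0L) {
  key <- function(s) paste(s$contig, s$position, s$strand)
  if (tolerance_bp == 0L) {
    shared <- sum(key(a) %in% key(b))
    only_a <- nrow(a) - shared
    only_b <- nrow(b) - sum(key(b) %in% key(a))
  } else {
    ga <- tss_granges(a); BiocGenerics::strand(ga) <- a$strand
    gb <- tss_granges(b); BiocGenerics::strand(gb) <- b$strand
    ha <- IRanges::overlapsAny(ga, gb, maxgap = tolerance_bp)
    hb <- IRanges::overlapsAny(gb, ga, maxgap = tolerance_bp)
    shared <- sum(ha); only_a <- sum(!ha); only_b <- sum(!hb)
  }
  structure(list(only_a = only_a, only_b = only_b, shared = shared,
                 labels = c(attr(a, "condition") %||% "A",
                            attr(b, "condition") %||% "B")),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn> %s only: %d | shared: %d | %s only: %d\n",
              x$labels[1L], x$only_a, x$shared, x$labels[2L], x$only_b))
  invisible(x)
}

#' Cross-tabulate TSSs by silencer occupancy and coding context
#'
#' The four-way partition {bound, free} x {coding, non-coding} underlying
#' the occupancy pie charts.
#'
#' @param tss A `tss_set`.
#' @param genes Gene model `data.frame`.
#' @param regions Silencer-bound region set.
#' @param condition Condition label for the summary.
#' @return `data.frame` with `bound`, `coding`, `count`, `percent`; counts
#'   sum to `nrow(tss)`.
#' @export
context_summary <- function(tss, genes, regions, condition = attr(tss, "condition")) {
  coding <- classify_tss_location(tss, genes) == "coding"
  bound <- assign_region_membership(tss, regions)
  cells <- expand.grid(bound = c(TRUE, FALSE), coding = c(TRUE, FALSE))
  count <- mapply(function(b, c) sum(bound == b & coding == c),
                  cells$bound, cells$coding)
  out <- data.frame(condition = condition %||% "unnamed",
                    bound = cells$bound, coding = cells$coding, count = count,
                    percent = if (nrow(tss)) 100 * count / nrow(tss) else 0)
  out
}
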