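# Differential transcript / TSS activity between two conditions.
#
# The test is an exact conditional rate test: conditioning two Poisson
# counts on their sum turns the two-condition comparison into a binomial
# test of a successes in a+b trials against pi = M_A / (M_A + M_B), where
# M_A and M_B are the pooled condition library sizes. Two-sidedness is by
# minimum likelihood: outcomes no more probable than the observed one are
# summed. Replicates are pooled within condition; fold changes use a 0.5
# pseudocount per pooled count and total-count normalization.

#' Exact conditional rate test for two pooled counts
#'
#' @param a,b Pooled counts in conditions A and B (vectors recycle).
#' @param M_A,M_B Library sizes (total assigned counts) per condition.
#' @return Two-sided p-value(s); `a + b = 0` gives p = 1 by convention.
#' @export
exact_rate_test <- function(a, b, M_A, M_B) {
  if (any(M_A <= 0) || any(M_B <= 0)) stop_fmt("library sizes must be positive")
  n <- length(a)
  b <- rep_len(b, n); M_A <- rep_len(M_A, n); M_B <- rep_len(M_B, n)
  pi <- M_A / (M_A + M_B)
  vapply(seq_len(n), function(i) {
    tot <- a[i] + b[i]
    if (tot == 0) return(1)
    d <- dbinom(0:tot, tot, pi[i])
    # relative tolerance guards against ties broken by floating point
    min(1, sum(d[d <= d[a[i] + 1L] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `fdr_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and
#' mapped back to input order.
#'
#' @param p Vector of p-values.
#' @return Vector of BH-adjusted FDR values in input order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Count reads per gene by 5'-end, same-strand assignment
#'
#' A read is assigned to a gene iff its 5' base (interval start on `+`, end
#' on `-`) lies within the gene on the same strand; its 5' base lies in at
#' most one gene when genes do not overlap.
#'
#' @param reads `GRanges` of read intervals (or BED6 `data.frame`).
#' @param genes Gene model `data.frame`.
#' @return List: `counts` (named integer per gene), `n_total` (all reads),
#'   `n_assigned`.
#' @export
count_gene_reads <- function(reads, genes) {
  gr <- reads_as_granges(reads)
  strand <- as.character(BiocGenerics::strand(gr))
  five <- ifelse(strand == "+", BiocGenerics::start(gr), BiocGenerics::end(gr))
  q <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr)),
                              IRanges::IRanges(five, width = 1L),
                              strand = strand)
  g <- genes_granges(genes)
  BiocGenerics::strand(g) <- genes$strand
  hits <- GenomicRanges::findOverlaps(q, g, ignore.strand = FALSE)
  # 5' base in at most one gene for disjoint genes; keep first otherwise
  hits <- hits[!duplicated(S4Vectors::queryHits(hits))]
  counts <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(genes))
  names(counts) <- genes$gene_id
  list(counts = counts, n_total = length(gr), n_assigned = length(hits))
}

#' Build a gene count table for two conditions
#'
#' Library size per sample is the total read count (assigned plus
#' unassigned).
#'
#' @param reads_a,reads_b Lists of per-replicate read `GRanges` for
#'   conditions A and B.
#' @param genes Gene model `data.frame`.
#' @param labels Condition labels.
#' @return A `count_table` list: `features`, `counts` (feature x sample),
#'   `lib_sizes`, `condition` (factor per sample).
#' @export
gene_count_table <- function(reads_a, reads_b, genes,
                             labels = c("A", "B")) {
  samples <- c(reads_a, reads_b)
  cond <- factor(rep(labels, c(length(reads_a), length(reads_b))),
                 levels = labels)
  per <- lapply(samples, count_gene_reads, genes = genes)
  counts <- do.call(cbind, lapply(per, `[[`, "counts"))
  colnames(counts) <- paste0(cond, ".", sequence(c(length(reads_a), length(reads_b))))
  features <- data.frame(id = genes$gene_id, kind = "gene",
                         contig = genes$contig, start = genes$start,
                         end = genes$end, strand = genes$strand,
                         stringsAsFactors = FALSE)
  structure(list(features = features, counts = counts,
                 lib_sizes = vapply(per, `[[`, numeric(1), "n_total"),
                 condition = cond),
            class = "count_table")
}

#' Pooled per-TSS count table for two conditions
#'
#' The feature set is the deduplicated union of both TSS sets; the
#' per-sample count is the 5'-end coverage at the TSS base on its strand,
#' and the library size is the sample's total 5'-end count.
#'
#' @param tss_a,tss_b `tss_set`s for the two conditions.
#' @param cov_a,cov_b Lists of per-replicate stranded track pairs.
#' @param labels Condition labels.
#' @return A `count_table` with one row per pooled TSS.
#' @export
pooled_tss_counts <- function(tss_a, tss_b, cov_a, cov_b,
                              labels = c("A", "B")) {
  pooled <- union_tss(list(tss_a, tss_b))
  samples <- c(cov_a, cov_b)
  cond <- factor(rep(labels, c(length(cov_a), length(cov_b))), levels = labels)
  counts <- vapply(samples, function(pair) {
    ifelse(pooled$strand == "+",
           pair$fwd$values[pooled$position],
           pair$rev$values[pooled$position])
  }, numeric(nrow(pooled)))
  counts <- matrix(counts, nrow = nrow(pooled))
  colnames(counts) <- paste0(cond, ".", sequence(c(length(cov_a), length(cov_b))))
  features <- data.frame(id = paste0("tss_", pooled$position, pooled$strand),
                         kind = "tss", contig = pooled$contig,
                         start = pooled$position, end = pooled$position,
                         strand = pooled$strand, stringsAsFactors = FALSE)
  structure(list(features = features, counts = counts,
                 lib_sizes = vapply(samples, function(pair)
                   sum(pair$fwd$values) + sum(pair$rev$values), numeric(1)),
                 condition = cond),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d %s features x %d samples (%s)\n",
              nrow(x$counts), x$features$kind[1L] %||% "?", ncol(x$counts),
              paste(levels(x$condition), collapse = " vs ")))
  invisible(x)
}

#' Differential-activity (volcano) table
#'
#' Replicates are pooled within condition; each feature gets a normalized
#' log2 fold change `log2(((a+0.5)/M_A) / ((b+0.5)/M_B))`, an exact
#' conditional rate test p-value and a BH-adjusted FDR. Rows are sorted by
#' p-value.
#'
#' @param table A `count_table`.
#' @param bound Optional logical per feature: silencer-bound context flag.
#' @return `data.frame` with feature columns, pooled counts `count_a`,
#'   `count_b`, `log2fc`, `p_value`, `fdr` and `bound`.
#' @export
volcano_table <- function(table, bound = NULL) {
  idx_a <- table$condition == levels(table$condition)[1L]
  a <- rowSums(table$counts[, idx_a, drop = FALSE])
  b <- rowSums(table$counts[, !idx_a, drop = FALSE])
  M_A <- sum(table$lib_sizes[idx_a])
  M_B <- sum(table$lib_sizes[!idx_a])
  log2fc <- log2(((a + 0.5) / M_A) / ((b + 0.5) / M_B))
  p <- exact_rate_test(a, b, M_A, M_B)
  out <- cbind(table$features,
               data.frame(count_a = a, count_b = b, log2fc = log2fc,
                          p_value = p, fdr = bh_adjust(p),
                          bound = if (is.null(bound)) NA else bound))
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}
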