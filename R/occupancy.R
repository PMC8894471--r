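# Silencer occupancy-shape analysis: 10-bp binning with genome-mean
# background subtraction, start-codon-anchored aggregate (metagene)
# profiles, and the percent-of-max signal vs non-coding-fraction curve.

#' Bin a signal track and subtract the genome-mean background
#'
#' Bin `k` covers bases `[(k-1)w + 1, kw]`; a short terminal bin is averaged
#' over its actual bases. The background is the mean over all bin values and
#' is subtracted from each bin, so centered values may be negative.
#'
#' @param track A `coverage_track`.
#' @param bin_width Bin width in bases (default 10).
#' @return A `binned_signal` list: `bin_width`, `bin_start`, `bin_end`,
#'   `bin_values`, `background`, `centered`.
#' @export
bin_and_center <- function(track, bin_width = 10L) {
  if (bin_width < 1L) stop_fmt("bin_width must be >= 1")
  L <- length(track$values)
  n_bins <- ceiling(L / bin_width)
  grp <- rep(seq_len(n_bins), each = bin_width, length.out = L)
  sums <- unname(rowsum(track$values, grp)[, 1L])
  sizes <- tabulate(grp, nbins = n_bins)
  vals <- sums / sizes
  bg <- mean(vals)
  structure(list(contig = track$contig, bin_width = as.integer(bin_width),
                 bin_start = (seq_len(n_bins) - 1L) * bin_width + 1L,
                 bin_end = pmin(seq_len(n_bins) * bin_width, L),
                 bin_values = vals, background = bg, centered = vals - bg),
            class = "binned_signal")
}

#' @export
print.binned_signal <- function(x, ...) {
  cat(sprintf("<binned_signal> %d bins of %d bp, background %.3f\n",
              length(x$bin_values), x$bin_width, x$background))
  invisible(x)
}

# Distance from each bin center to its nearest start codon, signed along the
# owning gene's strand (negative = upstream of the start codon). Ties go to
# the lower-coordinate gene.
bin_start_codon_distance <- function(binned, genes) {
  if (!nrow(genes)) stop_fmt("metagene profile requires gene models")
  centers <- (binned$bin_start + binned$bin_end) / 2
  ord <- order(genes$start_codon_pos, genes$start)
  cp <- genes$start_codon_pos[ord]
  st <- genes$strand[ord]
  i <- findInterval(centers, cp)                    # last codon <= center
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(cp))
  d_lo <- abs(centers - cp[lo]); d_hi <- abs(centers - cp[hi])
  use_lo <- (i >= 1L) & (d_lo <= d_hi | i + 1L > length(cp))  # tie -> lower coordinate
  pick <- ifelse(use_lo, lo, hi)
  signed <- ifelse(st[pick] == "+", centers - cp[pick], cp[pick] - centers)
  list(distance = signed, gene_index = ord[pick])
}

#' Start-codon-anchored aggregate occupancy profile
#'
#' Each bin (by its center) is assigned to its nearest gene start codon; the
#' distance is signed along that gene's strand (negative = upstream). The
#' centered signal is summed per distance range over `[-span, +span]`.
#'
#' @param binned A `binned_signal`.
#' @param genes Gene model `data.frame`.
#' @param span Profile half-width in bases (default 1000).
#' @param step Distance-bin width in bases (default 100).
#' @param use_centered Sum background-subtracted values (default); `FALSE`
#'   sums raw bin values.
#' @return `data.frame` with `dist_lo`, `dist_hi` (range `[lo, hi)`) and
#'   `signal`.
#' @export
metagene_profile <- function(binned, genes, span = 1000L, step = 100L,
                             use_centered = TRUE) {
  d <- bin_start_codon_distance(binned, genes)$distance
  vals <- if (use_centered) binned$centered else binned$bin_values
  breaks <- seq(-span, span, by = step)
  idx <- findInterval(d, breaks, rightmost.closed = TRUE)
  ok <- d >= -span & d <= span
  nb <- length(breaks) - 1L
  sig <- vapply(seq_len(nb), function(k) sum(vals[ok & idx == k]), numeric(1))
  data.frame(dist_lo = breaks[-length(breaks)], dist_hi = breaks[-1L],
             signal = as.numeric(sig), row.names = NULL)
}

#' Fraction of positive occupancy signal near start codons
#'
#' Convenience summary for comparing occupancy shapes: the share of total
#' positive centered signal carried by bins whose centers lie within
#' `± window` of their nearest start codon.
#'
#' @param binned A `binned_signal`.
#' @param genes Gene model `data.frame`.
#' @param window Distance window in bases (default 100).
#' @return Fraction in `[0, 1]`.
#' @export
start_proximal_signal_fraction <- function(binned, genes, window = 100L) {
  d <- bin_start_codon_distance(binned, genes)$distance
  pos <- pmax(binned$centered, 0)
  if (sum(pos) == 0) return(0)
  sum(pos[abs(d) <= window]) / sum(pos)
}

#' Percent-of-max occupancy vs non-coding fraction curve
#'
#' Bins are expressed as a percentage of the maximum centered bin value and
#' partitioned into `n_levels` equal percent intervals over `[0, 100]`
#' (bins with negative centered signal fall in the lowest level). Per
#' level, the fraction of bins whose center base lies outside all genes is
#' reported.
#'
#' @param binned A `binned_signal`.
#' @param genes Gene model `data.frame`.
#' @param n_levels Number of percent-of-max levels (default 20).
#' @return `data.frame` with `pct_lo`, `pct_hi`, `n_bins`,
#'   `fraction_noncoding` (NA for empty levels).
#' @export
signal_vs_noncoding_curve <- function(binned, genes, n_levels = 20L) {
  mx <- max(binned$centered)
  if (mx <= 0) stop_fmt("maximum centered signal is not positive")
  pct <- pmax(100 * binned$centered / mx, 0)
  breaks <- seq(0, 100, length.out = n_levels + 1L)
  lev <- cut(pct, breaks, include.lowest = TRUE, labels = FALSE)
  center_base <- floor((binned$bin_start + binned$bin_end) / 2)
  coding <- rep(FALSE, length(center_base))
  if (nrow(genes)) {
    q <- GenomicRanges::GRanges(binned$contig,
                                IRanges::IRanges(center_base, width = 1L))
    coding <- IRanges::overlapsAny(q, genes_granges(genes), ignore.strand = TRUE)
  }
  n_bins <- tabulate(lev, nbins = n_levels)
  frac <- vapply(seq_len(n_levels), function(k) {
    sel <- lev == k
    if (!any(sel)) NA_real_ else mean(!coding[sel])
  }, numeric(1))
  data.frame(pct_lo = breaks[-length(breaks)], pct_hi = breaks[-1L],
             n_bins = n_bins, fraction_noncoding = frac)
}
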