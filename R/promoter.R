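# Promoter -10 element annotation, spacer/discriminator statistics,
# position-frequency matrices with information content, and initiating
# nucleotide (iNTP) usage.

MINUS10_CONSENSUS <- "TATAAT"

# Sense-strand context upstream of a TSS, `width` bases, ending at the base
# immediately upstream of the +1. NULL when the window runs off the contig.
sense_upstream <- function(genome, position, strand, width) {
  if (strand == "+") {
    if (position - width < 1L) return(NULL)
    substr(genome$residues, position - width, position - 1L)
  } else {
    if (position + width > genome$length) return(NULL)
    revcomp(substr(genome$residues, position + 1L, position + width))
  }
}

hamming6 <- function(hex, consensus = MINUS10_CONSENSUS) {
  a <- strsplit(hex, "", fixed = TRUE)[[1L]]
  b <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  sum(a != b)
}

#' Assign promoter -10 elements to TSSs
#'
#' For each TSS, every hexamer whose 3' base lies `d` bases upstream of the
#' +1 (for `d` in `spacer_range`; the spacer counts the bases strictly
#' between the hexamer and the +1) is scored by Hamming distance to the
#' TATAAT consensus on the sense strand. The minimum-mismatch placement
#' wins; ties prefer `d = 7`, then the smaller `|d - 7|`, then the smaller
#' `d`. A TSS too close to the contig edge for a full search window is
#' skipped (counted in attribute `n_skipped`).
#'
#' @param tss A `tss_set`.
#' @param genome A `genome_seq`.
#' @param spacer_range Inclusive spacer search range (default 5:9).
#' @param max_mismatch_for_call Mismatch bound for `has_element`.
#' @return `data.frame` of promoter calls: TSS key columns plus
#'   `element_start`, `element_end`, `element_seq`, `mismatches`, `spacer`,
#'   `discriminator_seq`, `discriminator_at`, `has_element`.
#' @export
annotate_minus10 <- function(tss, genome, spacer_range = c(5L, 9L),
                             max_mismatch_for_call = 2L) {
  dmin <- as.integer(min(spacer_range)); dmax <- as.integer(max(spacer_range))
  width <- dmax + 6L
  ds <- dmin:dmax
  # rank candidates once: mismatches, then the tie-break order over d
  d_order <- ds[order(ds != 7L, abs(ds - 7L), ds)]
  n_skipped <- 0L
  rows <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    p <- tss$position[i]; s <- tss$strand[i]
    ctx <- sense_upstream(genome, p, s, width)
    if (is.null(ctx)) { n_skipped <- n_skipped + 1L; next }
    best_d <- NA_integer_; best_mm <- Inf; best_hex <- NA_character_
    for (d in d_order) {
      # ctx index for offset -k is width - k + 1; hexamer spans -(d+6)..-(d+1)
      hex <- substr(ctx, width - d - 5L, width - d)
      mm <- hamming6(hex)
      if (mm < best_mm) { best_mm <- mm; best_d <- d; best_hex <- hex }
    }
    disc <- substr(ctx, width - best_d + 1L, width)
    el <- if (s == "+") c(p - best_d - 6L, p - best_d - 1L)
          else c(p + best_d + 1L, p + best_d + 6L)
    rows[[i]] <- data.frame(
      contig = tss$contig[i], position = p, strand = s,
      element_start = el[1L], element_end = el[2L], element_seq = best_hex,
      mismatches = best_mm, spacer = best_d, discriminator_seq = disc,
      discriminator_at = if (best_d > 0)
        mean(strsplit(disc, "")[[1L]] %in% c("A", "T")) else NA_real_,
      has_element = best_mm <= max_mismatch_for_call,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  if (n_skipped > 0L)
    warning(sprintf("%d TSS(s) skipped: no full upstream window", n_skipped))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Spacer-length distribution of promoter calls
#'
#' @param calls Output of [annotate_minus10()].
#' @param only_with_element Restrict to calls with `has_element` (default).
#' @return Named numeric vector: percentage of calls per spacer distance;
#'   sums to 100.
#' @export
spacer_distribution <- function(calls, only_with_element = TRUE) {
  if (only_with_element) calls <- calls[calls$has_element, , drop = FALSE]
  if (!nrow(calls)) stop_fmt("spacer_distribution: no promoter calls")
  tab <- table(calls$spacer)
  setNames(100 * as.numeric(tab) / sum(tab), names(tab))
}

#' Percentage of TSSs positioned downstream of a -10 element
#'
#' @param calls Output of [annotate_minus10()].
#' @return Percentage of calls with `has_element`.
#' @export
fraction_with_element <- function(calls) {
  if (!nrow(calls)) stop_fmt("fraction_with_element: no promoter calls")
  100 * mean(calls$has_element)
}

#' TSS-anchored position frequency matrix with information content
#'
#' Sense-strand sequences (reverse-complemented for `-` strand TSSs) are
#' stacked with the +1 base at window offset `+1`; offsets are ...,-2,-1,+1
#' (there is no offset 0). Per-position base frequencies and information
#' content `IC_j = 2 + sum_b f_bj log2 f_bj` are computed; N bases are
#' excluded from the column counts. No small-sample correction is applied
#' by default (TSS sets here number in the hundreds to thousands).
#'
#' @param tss A `tss_set`.
#' @param genome A `genome_seq`.
#' @param upstream Bases upstream of the +1 to include (default 45).
#' @param downstream Bases from the +1 onward to include (default 1, the +1
#'   itself).
#' @param small_sample_correction Subtract the e_n = 3/(2 ln2 n_j) bias
#'   correction from each column's IC (clamped at 0).
#' @return A `pfm` object: list with `offsets`, `freqs` (4 x W matrix, rows
#'   A,C,G,T), `counts` (sequences per column) and `ic` (bits).
#' @export
build_pfm <- function(tss, genome, upstream = 45L, downstream = 1L,
                      small_sample_correction = FALSE) {
  W <- upstream + downstream
  offsets <- c(seq(-upstream, -1L), seq_len(downstream))
  seqs <- character(0)
  n_dropped <- 0L
  for (i in seq_len(nrow(tss))) {
    p <- tss$position[i]; s <- tss$strand[i]
    seq_i <- if (s == "+") {
      if (p - upstream < 1L || p + downstream - 1L > genome$length) NULL
      else substr(genome$residues, p - upstream, p + downstream - 1L)
    } else {
      if (p - downstream + 1L < 1L || p + upstream > genome$length) NULL
      else revcomp(substr(genome$residues, p - downstream + 1L, p + upstream))
    }
    if (is.null(seq_i)) n_dropped <- n_dropped + 1L else seqs <- c(seqs, seq_i)
  }
  if (!length(seqs)) stop_fmt("build_pfm: no usable sequences")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(ncol(mat)), function(j)
    as.numeric(table(factor(mat[, j], levels = bases))), numeric(4))
  dimnames(counts) <- list(bases, offsets)
  n_j <- colSums(counts)
  freqs <- sweep(counts, 2L, pmax(n_j, 1L), "/")
  ic <- apply(freqs, 2L, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  if (small_sample_correction)
    ic <- pmax(ic - 3 / (2 * log(2) * pmax(n_j, 1L)), 0)
  structure(list(offsets = offsets, freqs = freqs, counts = n_j, ic = ic,
                 n_dropped = n_dropped),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> offsets %d..%d (n = %d), total IC %.1f bits\n",
              min(x$offsets), max(x$offsets), max(x$counts), sum(x$ic)))
  invisible(x)
}

#' Write a PFM as TSV (rows = offsets; columns A, C, G, T, n, IC)
#'
#' @param pfm A `pfm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(offset = pfm$offsets, t(pfm$freqs), n = pfm$counts,
                   ic = pfm$ic, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Initiating-nucleotide (iNTP) usage at TSSs
#'
#' Tallies the sense-strand base at the +1 position (complemented for `-`
#' strand TSSs); the iNTP is the NTP matching that base, so T is reported as
#' U. TSSs over N are excluded (attribute `n_excluded`).
#'
#' @param tss A `tss_set`.
#' @param genome A `genome_seq`.
#' @return Named numeric vector of fractions over A, G, C, U; sums to 1.
#' @export
intp_usage <- function(tss, genome) {
  base <- vapply(seq_len(nrow(tss)), function(i)
    substr(genome$residues, tss$position[i], tss$position[i]), character(1))
  sense <- ifelse(tss$strand == "+", base, complement_base(base))
  keep <- sense != "N"
  sense <- chartr("T", "U", sense[keep])
  tab <- table(factor(sense, levels = c("A", "G", "C", "U")))
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  attr(out, "n_excluded") <- sum(!keep)
  out
}
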