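# TSS calling from replicate 5'-end coverage: a position is a TSS when its
# depth rises more than `fold_threshold`-fold over the previous base (in the
# direction of transcription) in every replicate.

# Dense "previous depth" on one strand; prev(p) = p-1 on "+", p+1 on "-"
# (the upstream base in the direction of transcription).
#
# zero_policy:
#   adjacent - the immediately previous base (zero-depth exclusion then
#              applies to both the called and the previous base);
#   skip     - zero-depth positions are dropped from the coverage series
#              first, so "previous" is the nearest upstream nonzero base
#              (suited to sparse 5'-end tracks).
prev_depth_dense <- function(values, strand, zero_policy) {
  L <- length(values)
  vp <- if (strand == "-") rev(values) else values  # transcription order
  if (zero_policy == "adjacent") {
    prev <- c(NA_real_, vp[-L])
  } else {
    nz <- which(vp > 0)
    idx <- findInterval(seq_len(L) - 1L, nz)
    prev <- ifelse(idx >= 1L, vp[nz[pmax(idx, 1L)]], NA_real_)
  }
  if (strand == "-") rev(prev) else prev
}

step_calls_one <- function(values, strand, fold_threshold, zero_policy) {
  prev <- prev_depth_dense(values, strand, zero_policy)
  which(!is.na(prev) & prev > 0 & values > 0 &
        values > fold_threshold * prev)
}

#' Call TSSs from replicate stranded 5'-end coverage
#'
#' A position is called on a strand iff, in every replicate, its depth is
#' strictly greater than `fold_threshold` times the depth of the previous
#' base in the direction of transcription (p-1 on `+`, p+1 on `-`), with
#' zero-depth positions excluded according to `zero_policy`. Genome-terminal
#' bases (no previous base) are never called.
#'
#' @param replicates List (>= 2) of stranded track pairs, each a list with
#'   `fwd` and `rev` `coverage_track`s of equal length.
#' @param fold_threshold Required fold increase (strict; default 3).
#' @param zero_policy `"adjacent"`: the immediately previous base must be
#'   nonzero (conservative, both-sided zero exclusion). `"skip"`: zero-depth
#'   positions are removed from the series first, so the step is measured
#'   against the nearest upstream nonzero base; use this for sparse 5'-end
#'   spike coverage. Called bases must be nonzero under both policies.
#' @return A `tss_set` `data.frame`: columns `contig`, `position`, `strand`,
#'   `depth.<i>` and `fold.<i>` per replicate; attribute `condition`.
#' @export
call_tss <- function(replicates, fold_threshold = 3,
                     zero_policy = c("adjacent", "skip")) {
  zero_policy <- match.arg(zero_policy)
  if (length(replicates) < 2L)
    stop_fmt("call_tss requires >= 2 replicates, got %d", length(replicates))
  lens <- unlist(lapply(replicates, function(r)
    c(length(r$fwd$values), length(r$rev$values))))
  if (length(unique(lens)) != 1L) stop_fmt("replicate tracks differ in length")
  contig <- replicates[[1L]]$fwd$contig

  one_strand <- function(strand) {
    key <- if (strand == "+") "fwd" else "rev"
    hits <- lapply(replicates, function(r)
      step_calls_one(r[[key]]$values, strand, fold_threshold, zero_policy))
    pos <- sort(Reduce(intersect, hits))
    if (!length(pos)) return(NULL)
    depths <- vapply(replicates, function(r) r[[key]]$values[pos],
                     numeric(length(pos)))
    folds <- vapply(replicates, function(r) {
      prev <- prev_depth_dense(r[[key]]$values, strand, zero_policy)
      r[[key]]$values[pos] / prev[pos]
    }, numeric(length(pos)))
    cbind(data.frame(contig = contig, position = pos, strand = strand,
                     stringsAsFactors = FALSE),
          matrix(depths, nrow = length(pos)), matrix(folds, nrow = length(pos)))
  }
  out <- rbind(one_strand("+"), one_strand("-"))
  nr <- length(replicates)
  if (is.null(out)) {
    out <- data.frame(contig = character(0), position = integer(0),
                      strand = character(0))
    for (i in seq_len(nr)) out[[paste0("depth.", i)]] <- numeric(0)
    for (i in seq_len(nr)) out[[paste0("fold.", i)]] <- numeric(0)
  } else {
    names(out)[4:(3 + 2 * nr)] <- c(paste0("depth.", seq_len(nr)),
                                    paste0("fold.", seq_len(nr)))
    out <- out[order(out$position, out$strand), ]
    rownames(out) <- NULL
  }
  tss_set(out, condition = "unnamed")
}

#' Construct / validate a TSS set
#'
#' @param df `data.frame` with at least `contig`, `position`, `strand`;
#'   duplicates by (contig, position, strand) are an error.
#' @param condition Condition label.
#' @return The sorted `data.frame` with class `tss_set`.
#' @export
tss_set <- function(df, condition = "unnamed") {
  key <- paste(df$contig, df$position, df$strand)
  if (anyDuplicated(key)) stop_fmt("duplicate TSS keys in set")
  df <- df[order(df$position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "condition") <- condition
  class(df) <- c("tss_set", "data.frame")
  df
}

#' Union of TSS sets with per-condition provenance
#'
#' Key-wise union on (contig, position, strand); a logical `in_<condition>`
#' column per input set records provenance.
#'
#' @param sets List of `tss_set`s (same genome).
#' @return A `tss_set` with provenance columns.
#' @export
union_tss <- function(sets) {
  labs <- vapply(seq_along(sets), function(i)
    attr(sets[[i]], "condition") %||% paste0("set", i), character(1))
  keys <- lapply(sets, function(s) paste(s$contig, s$position, s$strand))
  all_key <- unique(unlist(keys))
  first <- do.call(rbind, lapply(sets, function(s)
    data.frame(contig = s$contig, position = s$position, strand = s$strand,
               stringsAsFactors = FALSE)))
  first <- first[!duplicated(paste(first$contig, first$position, first$strand)), ]
  for (i in seq_along(sets))
    first[[paste0("in_", labs[i])]] <-
      paste(first$contig, first$position, first$strand) %in% keys[[i]]
  tss_set(first, condition = paste(labs, collapse = "+"))
}

#' Export a TSS set to TSV
#'
#' @param tss A `tss_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss <- function(tss, path) {
  write.table(as.data.frame(tss), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a TSS set from TSV
#'
#' @param path TSV written by [write_tss()].
#' @param condition Condition label.
#' @return A `tss_set`.
#' @export
read_tss <- function(path, condition = basename(path)) {
  tss_set(read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
          condition = condition)
}
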