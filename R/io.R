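# Readers and writers for the standard formats the pipeline touches:
# FASTA genomes, GFF3/BED6 gene annotation, bedGraph coverage (one file per
# strand), BED6 read intervals, and reduction of reads to 5'-end coverage.

#' Read a genome sequence from FASTA
#'
#' Returns the first record (single-contig bacterial genomes). Residues are
#' upper-cased and must be in {A,C,G,T,N}.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_seq` object: list with `name`, `length` and `residues`
#'   (a single character string, 1-based addressing via [substr()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_fmt("not valid FASTA: %s", conditionMessage(e)))
  if (length(set) == 0L) stop_fmt("FASTA format error: no records in %s", path)
  res <- toupper(as.character(set[[1L]]))
  bad <- regexpr("[^ACGTN]", res)
  if (bad > 0L)
    stop_fmt("FASTA format error: non-IUPAC character '%s' at base %d",
             substr(res, bad, bad), bad)
  genome_seq(names(set)[1L], res)
}

#' Construct a genome_seq object
#'
#' @param name Contig name.
#' @param residues Upper-case A/C/G/T/N string.
#' @return A `genome_seq` object.
#' @export
genome_seq <- function(name, residues) {
  structure(list(name = sub("\\s.*", "", name), length = nchar(residues),
                 residues = residues),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d bp\n", x$name, x$length))
  invisible(x)
}

#' Write a genome_seq to FASTA
#'
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(genome$residues)
  names(seqs) <- genome$name
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3 or BED6
#'
#' GFF3 `gene`/`CDS` features or BED6 lines become gene models with a
#' start-codon position derived from strand: the interval start on `+`, the
#' interval end on `-`. BED half-open 0-based coordinates are converted to
#' 1-based inclusive.
#'
#' @param path Annotation file.
#' @param dialect `"gff3"` or `"bed6"` (default guessed from extension).
#' @return `data.frame` with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `start_codon_pos`.
#' @export
read_annotation <- function(path, dialect = c("auto", "gff3", "bed6")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed6"
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "bed")
  if (dialect == "gff3") {
    keep <- as.character(gr$type) %in% c("gene", "CDS")
    if (any(keep)) gr <- gr[keep]
    ids <- gr$ID %||% gr$Name %||% paste0("gene", seq_along(gr))
    ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  } else {
    ids <- gr$name %||% paste0("gene", seq_along(gr))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop_fmt("annotation record %d has no strand", which(strand == "*")[1L])
  gm <- data.frame(
    gene_id = as.character(ids),
    contig  = as.character(GenomicRanges::seqnames(gr)),
    start   = BiocGenerics::start(gr),
    end     = BiocGenerics::end(gr),
    strand  = strand,
    stringsAsFactors = FALSE)
  if (any(gm$end < gm$start)) stop_fmt("annotation has end < start")
  gm$start_codon_pos <- ifelse(gm$strand == "+", gm$start, gm$end)
  gm
}

#' Write gene models to GFF3
#'
#' @param genes Gene model `data.frame` (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$contig,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

new_track <- function(contig, strand, values) {
  if (any(values < 0)) stop_fmt("coverage values must be non-negative")
  structure(list(contig = contig, strand = strand, values = as.numeric(values)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s(%s): %d bp, total %.1f\n",
              x$contig, x$strand, length(x$values), sum(x$values)))
  invisible(x)
}

bedgraph_to_dense <- function(path, genome_length, contig, strand) {
  if (file.size(path) == 0L)
    return(new_track(contig, strand, numeric(genome_length)))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L)
    return(new_track(contig, strand, numeric(genome_length)))
  if (any(BiocGenerics::end(gr) > genome_length))
    stop_fmt("bedGraph interval exceeds genome length %d", genome_length)
  if (any(gr$score < 0)) stop_fmt("bedGraph has negative value")
  # overlapping intervals sum
  cov <- IRanges::coverage(IRanges::ranges(gr), weight = gr$score,
                           width = genome_length)
  new_track(contig, strand, as.numeric(cov))
}

#' Read strand-separated coverage from a pair of bedGraph files
#'
#' bedGraph intervals are 0-based half-open; bases covered by no interval
#' read as 0; overlapping intervals sum.
#'
#' @param path_fwd,path_rev bedGraph files for the + and - strand.
#' @param genome_length Genome length in bases.
#' @param contig Contig name for the resulting tracks.
#' @return List with elements `fwd` and `rev`, each a `coverage_track` dense
#'   over `[1, genome_length]`.
#' @export
read_coverage <- function(path_fwd, path_rev, genome_length, contig = "genome") {
  list(fwd = bedgraph_to_dense(path_fwd, genome_length, contig, "+"),
       rev = bedgraph_to_dense(path_rev, genome_length, contig, "-"))
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed into intervals; zero runs are omitted.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(track$contig,
                               IRanges::IRanges(starts[keep], ends[keep]),
                               score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a stranded track pair as .fwd.bedgraph / .rev.bedgraph
#'
#' @param pair List with `fwd` and `rev` coverage tracks.
#' @param prefix Path prefix; the two suffixes are appended.
#' @return Character vector of the two paths, invisibly.
#' @export
write_coverage_pair <- function(pair, prefix) {
  paths <- paste0(prefix, c(".fwd.bedgraph", ".rev.bedgraph"))
  write_coverage(pair$fwd, paths[1L])
  write_coverage(pair$rev, paths[2L])
  invisible(paths)
}

reads_as_granges <- function(reads) {
  if (methods::is(reads, "GRanges")) return(reads)
  # data.frame in BED6 convention: chrom, start (0-based), end, name, score, strand
  GenomicRanges::GRanges(reads[[1L]],
                         IRanges::IRanges(reads[[2L]] + 1L, reads[[3L]]),
                         strand = reads[[6L]])
}

#' Reduce read intervals to 5'-end coverage
#'
#' Each + strand read increments the forward track at its leftmost base;
#' each - strand read increments the reverse track at its rightmost base.
#'
#' @param reads BED6 `data.frame` (0-based half-open) or a `GRanges`.
#' @param genome_length Genome length in bases.
#' @param contig Contig name for the tracks.
#' @return List with `fwd` and `rev` integer `coverage_track`s.
#' @export
fiveprime_coverage <- function(reads, genome_length, contig = "genome") {
  gr <- reads_as_granges(reads)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop_fmt("read without strand at record %d",
                                   which(strand == "*")[1L])
  fwd <- tabulate(BiocGenerics::start(gr)[strand == "+"], nbins = genome_length)
  rev <- tabulate(BiocGenerics::end(gr)[strand == "-"], nbins = genome_length)
  list(fwd = new_track(contig, "+", fwd), rev = new_track(contig, "-", rev))
}

#' Read a BED file as a labelled region set
#'
#' @param path BED file (>= 3 columns).
#' @param label Label for the set (default: file name).
#' @return `data.frame` with `contig`, `start`, `end` (1-based inclusive) and
#'   attribute `label`.
#' @export
read_regions <- function(path, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "bed")
  region_set(data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                        start = BiocGenerics::start(gr),
                        end = BiocGenerics::end(gr),
                        stringsAsFactors = FALSE), label)
}

#' Construct a region set
#'
#' @param df `data.frame` with `contig`, `start`, `end` (1-based inclusive).
#' @param label Text label.
#' @return The `data.frame`, sorted, with attribute `label`.
#' @export
region_set <- function(df, label = "regions") {
  if (nrow(df) && any(df$end < df$start)) stop_fmt("region with end < start")
  df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "label") <- label
  df
}

#' Write a region set to BED
#'
#' @param regions Region set `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  gr <- GenomicRanges::GRanges(regions$contig,
                               IRanges::IRanges(regions$start, regions$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write read intervals to BED6
#'
#' @param reads `GRanges` of reads.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  if (is.null(reads$name)) reads$name <- paste0("read", seq_along(reads))
  if (is.null(reads$score)) reads$score <- 0L
  rtracklayer::export(reads, path, format = "bed")
  invisible(path)
}
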