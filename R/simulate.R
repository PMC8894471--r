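# Synthetic-data generator: seeded genomes with AT-rich islands, genes,
# planted intergenic/intragenic promoters, silencer occupancy in narrow
# (Rok-like) and broad (H-NS-like) modes, and overdispersed replicate
# coverage, plus a ground-truth manifest for recovery tests.

#' Simulation configuration
#'
#' Defaults describe a small bacterial chromosome: moderately AT-rich
#' background, a handful of horizontally-acquired AT-rich islands, densely
#' packed non-overlapping genes, canonical promoters whose -10 element
#' (consensus TATAAT) sits 6-8 bp upstream of the +1 base, AT-rich
#' discriminators, and negative-binomial (overdispersed) 5'-end counts.
#'
#' @param genome_length Genome length in bases.
#' @param gc_background G+C fraction of the background sequence.
#' @param islands List of `c(length, at_fraction)` pairs describing AT-rich
#'   islands to embed, non-overlapping.
#' @param n_genes Number of non-overlapping genes to place.
#' @param gene_length_range Two-element range of gene lengths (bases).
#' @param n_intergenic_promoters Number of promoters planted in intergenic
#'   space, upstream of gene start codons.
#' @param n_intragenic_promoters_per_island_kb Density of spurious promoters
#'   planted inside island-overlapping gene bodies, per kb of island.
#' @param spacer_distribution Named numeric vector mapping spacer length
#'   (bases strictly between the -10 hexamer 3' base and the +1) to
#'   probability; must sum to 1.
#' @param discriminator_at A+T fraction of planted discriminator sequences.
#' @param minus10_mismatch_rate Per-base probability that a planted hexamer
#'   base deviates from TATAAT.
#' @param tss_strength_range Range of expected 5'-end counts at planted TSSs.
#' @param background_rate Mean noise count per base per replicate.
#' @param nb_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param n_replicates Number of cappable-seq replicates.
#' @param seed Integer seed (mandatory).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000L,
                       gc_background = 0.44,
                       islands = list(c(12000, 0.70), c(12000, 0.70),
                                      c(12000, 0.70), c(12000, 0.70)),
                       n_genes = 180L,
                       gene_length_range = c(600L, 1500L),
                       n_intergenic_promoters = 60L,
                       n_intragenic_promoters_per_island_kb = 1.0,
                       spacer_distribution = c("6" = 0.15, "7" = 0.60, "8" = 0.25),
                       discriminator_at = 0.75,
                       minus10_mismatch_rate = 0.02,
                       tss_strength_range = c(30, 300),
                       background_rate = 0.2,
                       nb_dispersion = 0.1,
                       n_replicates = 2L,
                       seed) {
  if (missing(seed) || is.null(seed)) stop_fmt("sim_config: seed is mandatory")
  cfg <- list(genome_length = as.integer(genome_length),
              gc_background = gc_background, islands = islands,
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              n_intergenic_promoters = as.integer(n_intergenic_promoters),
              n_intragenic_promoters_per_island_kb = n_intragenic_promoters_per_island_kb,
              spacer_distribution = spacer_distribution,
              discriminator_at = discriminator_at,
              minus10_mismatch_rate = minus10_mismatch_rate,
              tss_strength_range = tss_strength_range,
              background_rate = background_rate,
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genome_length > 0, cfg$n_genes >= 0, cfg$n_replicates >= 1)
  fr <- c(cfg$gc_background, cfg$discriminator_at, cfg$minus10_mismatch_rate)
  if (any(fr < 0 | fr > 1)) stop_fmt("sim_config: fractions must lie in [0,1]")
  sd <- cfg$spacer_distribution
  if (abs(sum(sd) - 1) > 1e-8) stop_fmt("sim_config: spacer probabilities must sum to 1")
  if (is.null(names(sd)) || anyNA(as.integer(names(sd))))
    stop_fmt("sim_config: spacer_distribution must be named by integer distance")
  if (cfg$background_rate < 0 || cfg$nb_dispersion < 0)
    stop_fmt("sim_config: rates must be non-negative")
  invisible(cfg)
}

# NB with dispersion phi: var = mu + phi*mu^2; phi = 0 falls back to Poisson.
rnb <- function(n, mu, dispersion) {
  if (length(mu) == 1L) mu <- rep(mu, n)
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

sample_bases <- function(n, at_fraction) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c(at_fraction / 2, at_fraction / 2,
                  (1 - at_fraction) / 2, (1 - at_fraction) / 2))
}

# Writes sense-strand promoter sequence (hexamer, discriminator, +1 base)
# into a character vector of residues; returns list(residues, record).
plant_promoter <- function(res, pos, strand, spacer, cfg) {
  hex <- strsplit("TATAAT", "")[[1L]]
  mut <- runif(6) < cfg$minus10_mismatch_rate
  if (any(mut)) {
    for (i in which(mut)) hex[i] <- sample(setdiff(c("A", "C", "G", "T"), hex[i]), 1L)
  }
  disc <- sample_bases(spacer, cfg$discriminator_at)
  plus1 <- sample(c("A", "G", "C", "T"), 1L, prob = c(0.5, 0.3, 0.1, 0.1))
  sense <- c(hex, disc, plus1)
  if (strand == "+") {
    coords <- (pos - spacer - 6L):pos
    res[coords] <- sense
    el <- c(pos - spacer - 6L, pos - spacer - 1L)
  } else {
    coords <- (pos + spacer + 6L):pos       # sense 5'->3' descends the genome
    res[coords] <- complement_base(sense)
    el <- c(pos + spacer + 1L, pos + spacer + 6L)
  }
  list(res = res,
       rec = data.frame(position = pos, strand = strand,
                        element_start = el[1L], element_end = el[2L],
                        element_seq = paste(hex, collapse = ""),
                        spacer = spacer,
                        discriminator_seq = paste(disc, collapse = ""),
                        stringsAsFactors = FALSE))
}

#' Simulate a genome with islands, genes and planted promoters
#'
#' Background bases are i.i.d. at the configured GC; AT-rich islands are
#' embedded non-overlapping; genes are placed without overlap; intergenic
#' promoters are planted 20-150 bp upstream of gene start codons (within
#' intergenic space, on the gene's strand) and intragenic promoters only
#' inside island-overlapping gene bodies. Each planted promoter writes its
#' -10 hexamer (TATAAT with per-base mismatch rate), a spacer-length
#' discriminator with the configured A+T composition, and records the TSS at
#' the base after the discriminator.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_truth` list: `genome` (`genome_seq`), `genes` (gene model
#'   `data.frame`), `islands` (region set), `tss_truth` (`data.frame` with
#'   position, strand, strength, context, planted element coordinates,
#'   spacer, discriminator sequence) and `config`.
#' @export
simulate_genome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "genome"))
  L <- cfg$genome_length
  res <- sample_bases(L, 1 - cfg$gc_background)

  # islands: one per equal-width slot, random offset
  n_isl <- length(cfg$islands)
  islands <- data.frame(contig = character(0), start = integer(0), end = integer(0))
  if (n_isl > 0) {
    slot <- L %/% n_isl
    starts <- ends <- integer(n_isl)
    for (i in seq_len(n_isl)) {
      len <- as.integer(cfg$islands[[i]][1L])
      atf <- cfg$islands[[i]][2L]
      if (len > slot - 200L) stop_fmt("island %d does not fit its genome slot", i)
      s <- (i - 1L) * slot + sample.int(slot - len - 100L, 1L) + 50L
      e <- s + len - 1L
      res[s:e] <- sample_bases(len, atf)
      starts[i] <- s; ends[i] <- e
    }
    islands <- data.frame(contig = "synthetic", start = starts, end = ends)
  }
  islands <- region_set(islands, "AT-rich islands")

  # genes: one per equal-width slot, random length/offset/strand
  genes <- data.frame()
  if (cfg$n_genes > 0) {
    slot <- L %/% cfg$n_genes
    glen <- sample(seq(cfg$gene_length_range[1L], cfg$gene_length_range[2L]),
                   cfg$n_genes, replace = TRUE)
    glen <- pmin(glen, slot - 100L)
    if (any(glen < 60L)) stop_fmt("genes do not fit: increase genome_length or reduce n_genes")
    off <- vapply(slot - glen - 20L, function(m) sample.int(m, 1L), integer(1))
    gs <- (seq_len(cfg$n_genes) - 1L) * slot + off + 10L
    ge <- gs + glen - 1L
    gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
                        contig = "synthetic", start = gs, end = ge,
                        strand = gstrand,
                        start_codon_pos = ifelse(gstrand == "+", gs, ge),
                        stringsAsFactors = FALSE)
  }

  spacers <- as.integer(names(cfg$spacer_distribution))
  draw_spacer <- function()
    spacers[sample.int(length(spacers), 1L, prob = cfg$spacer_distribution)]
  in_any <- function(p, df) nrow(df) && any(p >= df$start & p <= df$end)
  occupied <- integer(0)   # planted promoter footprints, kept >= 60 bp apart
  recs <- list()

  # intergenic promoters: upstream of a gene's start codon, on its strand
  n_placed <- 0L
  attempts <- 0L
  while (n_placed < cfg$n_intergenic_promoters) {
    attempts <- attempts + 1L
    if (attempts > cfg$n_intergenic_promoters * 200L)
      stop_fmt("could not place %d intergenic promoters (placed %d)",
               cfg$n_intergenic_promoters, n_placed)
    g <- genes[sample.int(nrow(genes), 1L), ]
    u <- sample(20:150, 1L)
    pos <- if (g$strand == "+") g$start - u else g$end + u
    sp <- draw_spacer()
    win <- if (g$strand == "+") c(pos - sp - 6L, pos) else c(pos, pos + sp + 6L)
    if (win[1L] < 50L || win[2L] > L - 50L) next
    if (in_any(win[1L], genes) || in_any(win[2L], genes) || in_any(pos, genes)) next
    if (length(occupied) && min(abs(occupied - pos)) < 60L) next
    pl <- plant_promoter(res, pos, g$strand, sp, cfg)
    res <- pl$res
    pl$rec$context <- "intergenic"
    recs[[length(recs) + 1L]] <- pl$rec
    occupied <- c(occupied, pos)
    n_placed <- n_placed + 1L
  }

  # intragenic promoters: inside island-overlapping gene bodies only
  n_intra <- 0L
  if (nrow(islands) && cfg$n_intragenic_promoters_per_island_kb > 0) {
    total_kb <- sum(islands$end - islands$start + 1L) / 1000
    n_intra <- as.integer(round(cfg$n_intragenic_promoters_per_island_kb * total_kb))
  }
  if (n_intra > 0L) {
    # candidate intervals: gene ∩ island
    cand <- list()
    for (i in seq_len(nrow(islands))) {
      ov <- genes[genes$end >= islands$start[i] & genes$start <= islands$end[i], ]
      if (nrow(ov)) {
        ov$cs <- pmax(ov$start, islands$start[i])
        ov$ce <- pmin(ov$end, islands$end[i])
        cand[[length(cand) + 1L]] <- ov
      }
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || !nrow(cand))
      stop_fmt("no island-overlapping genes available for intragenic promoters")
    placed <- 0L; attempts <- 0L
    while (placed < n_intra) {
      attempts <- attempts + 1L
      if (attempts > n_intra * 200L)
        stop_fmt("could not place %d intragenic promoters (placed %d)", n_intra, placed)
      k <- sample.int(nrow(cand), 1L)
      lo <- cand$cs[k] + 20L; hi <- cand$ce[k] - 20L
      if (hi <= lo) next
      pos <- sample(lo:hi, 1L)
      strand <- sample(c("+", "-"), 1L)
      sp <- draw_spacer()
      win <- if (strand == "+") c(pos - sp - 6L, pos) else c(pos, pos + sp + 6L)
      if (win[1L] < cand$cs[k] || win[2L] > cand$ce[k]) next
      if (length(occupied) && min(abs(occupied - pos)) < 60L) next
      pl <- plant_promoter(res, pos, strand, sp, cfg)
      res <- pl$res
      pl$rec$context <- "intragenic"
      recs[[length(recs) + 1L]] <- pl$rec
      occupied <- c(occupied, pos)
      placed <- placed + 1L
    }
  }

  truth <- do.call(rbind, recs)
  truth$strength <- runif(nrow(truth), cfg$tss_strength_range[1L],
                          cfg$tss_strength_range[2L])
  truth <- truth[order(truth$position, truth$strand), ]
  rownames(truth) <- NULL
  truth <- truth[, c("position", "strand", "strength", "context",
                     "element_start", "element_end", "element_seq", "spacer",
                     "discriminator_seq")]

  structure(list(genome = genome_seq("synthetic", paste(res, collapse = "")),
                 genes = genes, islands = islands, tss_truth = truth,
                 config = cfg),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d bp genome, %d genes, %d islands, %d planted TSSs (%d intragenic)\n",
              x$genome$length, nrow(x$genes), nrow(x$islands),
              nrow(x$tss_truth), sum(x$tss_truth$context == "intragenic")))
  invisible(x)
}

#' Simulate replicate cappable-seq 5'-end coverage
#'
#' At each truth TSS the per-replicate count is negative binomial with mean
#' equal to the planted strength; every other base is negative binomial with
#' mean `background_rate`. Replicates are independent given the seed stream.
#'
#' @param truth A `sim_truth` from [simulate_genome()].
#' @param cfg Configuration (defaults to `truth$config`).
#' @param silenced Optional logical vector over `truth$tss_truth` rows; those
#'   TSSs have their mean divided by `repression_factor` (silencer present).
#' @param repression_factor Fold repression applied to silenced TSSs.
#' @param stream Name of the random substream (vary to get a second
#'   independent condition from the same seed).
#' @return List of `n_replicates` elements, each a list with `fwd` and `rev`
#'   `coverage_track`s.
#' @export
simulate_cappable <- function(truth, cfg = truth$config, silenced = NULL,
                              repression_factor = 1, stream = "cappable") {
  set.seed(stage_seed(cfg$seed, stream))
  L <- truth$genome$length
  tt <- truth$tss_truth
  mu <- tt$strength
  if (!is.null(silenced)) mu[silenced] <- mu[silenced] / repression_factor
  lapply(seq_len(cfg$n_replicates), function(r) {
    fwd <- rnb(L, cfg$background_rate, cfg$nb_dispersion)
    rev <- rnb(L, cfg$background_rate, cfg$nb_dispersion)
    sig <- rnb(nrow(tt), mu, cfg$nb_dispersion)
    ip <- tt$strand == "+"
    fwd[tt$position[ip]] <- fwd[tt$position[ip]] + sig[ip]
    rev[tt$position[!ip]] <- rev[tt$position[!ip]] + sig[!ip]
    list(fwd = new_track(truth$genome$name, "+", fwd),
         rev = new_track(truth$genome$name, "-", rev))
  })
}

#' Simulate ChIP occupancy for a narrow or broad silencer
#'
#' `narrow` (Rok-like) places Gaussian bumps of s.d. `peak_width / 2` on
#' intergenic promoter TSSs; `broad` (H-NS-like) raises a plateau of height
#' `peak_height` across each full AT-rich island. Both sit on a uniform
#' baseline and are additive over features. The track is unstranded.
#'
#' @param truth A `sim_truth`.
#' @param mode `"narrow"` or `"broad"`.
#' @param peak_height Peak/plateau height above baseline.
#' @param peak_width Characteristic width in bases (narrow mode).
#' @param baseline Uniform baseline signal.
#' @return A `coverage_track` with strand `"*"`.
#' @export
simulate_chip <- function(truth, mode = c("narrow", "broad"),
                          peak_height = 50, peak_width = 100, baseline = 1) {
  mode <- match.arg(mode)
  L <- truth$genome$length
  sig <- rep(baseline, L)
  if (peak_height > 0) {
    if (mode == "broad") {
      for (i in seq_len(nrow(truth$islands)))
        sig[truth$islands$start[i]:truth$islands$end[i]] <-
          sig[truth$islands$start[i]:truth$islands$end[i]] + peak_height
    } else {
      sd <- peak_width / 2
      centers <- truth$tss_truth$position[truth$tss_truth$context == "intergenic"]
      half <- as.integer(ceiling(4 * sd))
      for (p in centers) {
        lo <- max(1L, p - half); hi <- min(L, p + half)
        x <- lo:hi
        sig[x] <- sig[x] + peak_height * exp(-0.5 * ((x - p) / sd)^2)
      }
    }
  }
  new_track(truth$genome$name, "*", sig)
}

#' Silencer-bound regions implied by an occupancy mode
#'
#' Broad mode: the AT-rich islands themselves. Narrow mode: windows of
#' `± peak_width` around intergenic promoter TSSs.
#'
#' @param truth A `sim_truth`.
#' @param mode `"narrow"` or `"broad"`.
#' @param peak_width Window half-width for narrow mode.
#' @return A region set `data.frame`.
#' @export
bound_regions <- function(truth, mode = c("narrow", "broad"), peak_width = 100) {
  mode <- match.arg(mode)
  if (mode == "broad") return(truth$islands)
  p <- truth$tss_truth$position[truth$tss_truth$context == "intergenic"]
  region_set(data.frame(contig = truth$genome$name,
                        start = pmax(1L, p - as.integer(peak_width)),
                        end = pmin(truth$genome$length, p + as.integer(peak_width))),
             "silencer-bound (narrow)")
}

#' Simulate RNA-seq read intervals for two conditions
#'
#' Per-gene read counts are negative binomial around a per-gene expression
#' mean; in the "silencer present" condition, silenced genes have their mean
#' divided by `repression_factor`. Reads are placed uniformly within the
#' gene on the sense strand.
#'
#' @param truth A `sim_truth`.
#' @param silenced_genes Character vector of silenced `gene_id`s.
#' @param repression_factor Fold repression in the silencer-present condition.
#' @param cfg Configuration (defaults to `truth$config`).
#' @param mean_reads_range Range of expected reads per gene per replicate.
#' @param read_length Read interval length (bases).
#' @return List with `silencer_present` and `silencer_absent`, each a list of
#'   `n_replicates` `GRanges` of read intervals.
#' @export
simulate_rnaseq <- function(truth, silenced_genes = character(0),
                            repression_factor = 1, cfg = truth$config,
                            mean_reads_range = c(100, 500), read_length = 75L) {
  set.seed(stage_seed(cfg$seed, "rnaseq"))
  genes <- truth$genes
  base_mu <- runif(nrow(genes), mean_reads_range[1L], mean_reads_range[2L])
  sil <- genes$gene_id %in% silenced_genes
  make_cond <- function(mu) {
    lapply(seq_len(cfg$n_replicates), function(r) {
      counts <- rnb(nrow(genes), mu, cfg$nb_dispersion)
      idx <- rep.int(seq_len(nrow(genes)), counts)
      span <- pmax(genes$end - genes$start + 1L - read_length, 1L)
      starts <- genes$start[idx] + floor(runif(length(idx)) * span[idx])
      GenomicRanges::GRanges(genes$contig[idx],
                             IRanges::IRanges(starts, width = read_length),
                             strand = genes$strand[idx])
    })
  }
  mu_present <- base_mu / ifelse(sil, repression_factor, 1)
  list(silencer_present = make_cond(mu_present),
       silencer_absent = make_cond(base_mu))
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA, GFF3, island/bound-region BEDs, per-replicate stranded
#' bedGraph tracks and a TSV truth manifest.
#'
#' @param truth A `sim_truth`.
#' @param reps Output of [simulate_cappable()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(truth, reps, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(prefix, ...))
  out <- list(fasta = write_fasta(truth$genome, p(".genome.fa")),
              gff = write_annotation(truth$genes, p(".genes.gff3")),
              islands = write_regions(truth$islands, p(".islands.bed")),
              truth = p(".truth.tsv"))
  write.table(truth$tss_truth, out$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (r in seq_along(reps))
    out[[paste0("rep", r)]] <- write_coverage_pair(reps[[r]], p(sprintf(".rep%d", r)))
  invisible(out)
}
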