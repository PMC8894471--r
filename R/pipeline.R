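# End-to-end orchestration: simulate -> call TSSs -> annotate promoters ->
# classify contexts -> occupancy shape -> differential activity -> report.
# All randomness flows from one top-level seed through named per-stage
# substreams, so identical config + seed gives identical results.

#' Demo pipeline configurations
#'
#' Two shipped profiles: `"bsubtilis-like"` (narrow, promoter-centred
#' silencer occupancy; tight spacer distribution; AT-rich discriminators)
#' and `"ecoli-like"` (broad, island-wide occupancy; wider spacer spread;
#' indifferent discriminator composition).
#'
#' @param profile Profile name.
#' @return A nested configuration list (see [run_end_to_end()]).
#' @export
demo_config <- function(profile = c("bsubtilis-like", "ecoli-like")) {
  profile <- match.arg(profile)
  base <- list(
    sim = list(genome_length = 200000L, n_genes = 180L,
               n_intergenic_promoters = 60L,
               n_intragenic_promoters_per_island_kb = 1.0,
               background_rate = 0.2, nb_dispersion = 0.1, n_replicates = 2L),
    fold_threshold = 3, zero_policy = "skip",
    spacer_range = c(5L, 9L), max_mismatch = 2L,
    repression_factor = 8,      # transcript-abundance fold (RNA-seq)
    tss_repression_factor = 25, # promoter occlusion: silenced TSSs drop
                                # below detection, as for silent promoters
    chip = list(peak_height = 50, peak_width = 100, baseline = 1))
  if (profile == "bsubtilis-like") {
    base$occupancy_mode <- "narrow"
    base$sim$spacer_distribution <- c("6" = 0.15, "7" = 0.60, "8" = 0.25)
    base$sim$discriminator_at <- 0.80
  } else {
    base$occupancy_mode <- "broad"
    base$sim$spacer_distribution <-
      c("5" = 0.05, "6" = 0.25, "7" = 0.40, "8" = 0.25, "9" = 0.05)
    base$sim$discriminator_at <- 0.55
  }
  base$profile <- profile
  base
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim$spacer_distribution))
    cfg$sim$spacer_distribution <- unlist(cfg$sim$spacer_distribution)
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  if (!is.null(config$sim$spacer_distribution))
    config$sim$spacer_distribution <- as.list(config$sim$spacer_distribution)
  yaml::write_yaml(config, path)
  invisible(path)
}

run_stage <- function(stage, manifest, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e)
    stop_fmt("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  manifest$log[[stage]] <- list(stage = stage,
                                seconds = round(proc.time()[["elapsed"]] - t0, 2))
  list(res = res, manifest = manifest)
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Simulates a genome and two cappable-seq conditions (silencer present,
#' with TSSs inside silencer-bound regions repressed, and silencer absent),
#' calls and compares TSSs, annotates promoters, classifies genomic
#' contexts, analyses silencer occupancy shape, and tests differential
#' gene and TSS activity.
#'
#' @param config Configuration list (see [demo_config()]) or a YAML path.
#' @param seed Integer top-level seed.
#' @param out_dir Optional output directory for TSV/BED/bedGraph artefacts
#'   and a JSON summary.
#' @return A `run_manifest` list: `config`, `summary` (named statistics),
#'   `venn`, `context`, `spacer_distribution`, `intp`, tables, and `log`.
#' @export
run_end_to_end <- function(config, seed, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  manifest <- list(config = config, seed = seed, log = list(), files = list())

  sim_args <- config$sim
  if (!is.null(sim_args$spacer_distribution))
    sim_args$spacer_distribution <-
      setNames(as.numeric(sim_args$spacer_distribution),
               names(sim_args$spacer_distribution))
  sim_args$seed <- stage_seed(seed, "simulate")
  cfg <- do.call(sim_config, sim_args)

  st <- run_stage("simulate", manifest, function() simulate_genome(cfg))
  truth <- st$res; manifest <- st$manifest

  mode <- config$occupancy_mode %||% "narrow"
  chip_cfg <- config$chip %||% list()
  bound <- bound_regions(truth, mode,
                         peak_width = chip_cfg$peak_width %||% 100)
  silenced_tss <- assign_region_membership(
    data.frame(contig = truth$genome$name,
               position = truth$tss_truth$position,
               strand = truth$tss_truth$strand), bound)

  st <- run_stage("cappable", manifest, function() list(
    present = simulate_cappable(truth, cfg, silenced = silenced_tss,
                                repression_factor = config$tss_repression_factor %||%
                                  config$repression_factor %||% 8,
                                stream = "cappable_present"),
    absent = simulate_cappable(truth, cfg, stream = "cappable_absent")))
  cov <- st$res; manifest <- st$manifest

  fold <- config$fold_threshold %||% 3
  policy <- config$zero_policy %||% "skip"
  st <- run_stage("call_tss", manifest, function() {
    a <- call_tss(cov$present, fold, policy)
    attr(a, "condition") <- "silencer_present"
    b <- call_tss(cov$absent, fold, policy)
    attr(b, "condition") <- "silencer_absent"
    list(present = a, absent = b, union = union_tss(list(a, b)))
  })
  tss <- st$res; manifest <- st$manifest
  venn <- compare_tss_sets(tss$present, tss$absent)

  st <- run_stage("annotate_promoters", manifest, function() {
    calls <- annotate_minus10(tss$union, truth$genome,
                              spacer_range = config$spacer_range %||% c(5L, 9L),
                              max_mismatch_for_call = config$max_mismatch %||% 2L)
    list(calls = calls,
         spacer = spacer_distribution(calls),
         with_element_pct = fraction_with_element(calls),
         pfm = build_pfm(tss$union, truth$genome),
         intp = intp_usage(tss$union, truth$genome))
  })
  prom <- st$res; manifest <- st$manifest

  st <- run_stage("classify", manifest, function() rbind(
    context_summary(tss$present, truth$genes, bound, "silencer_present"),
    context_summary(tss$absent, truth$genes, bound, "silencer_absent")))
  context <- st$res; manifest <- st$manifest

  st <- run_stage("occupancy", manifest, function() {
    chip <- simulate_chip(truth, mode,
                          peak_height = chip_cfg$peak_height %||% 50,
                          peak_width = chip_cfg$peak_width %||% 100,
                          baseline = chip_cfg$baseline %||% 1)
    binned <- bin_and_center(chip)
    list(binned = binned,
         profile = metagene_profile(binned, truth$genes),
         curve = signal_vs_noncoding_curve(binned, truth$genes),
         start_prox_frac = start_proximal_signal_fraction(binned, truth$genes))
  })
  occ <- st$res; manifest <- st$manifest

  st <- run_stage("differential", manifest, function() {
    sil_genes <- truth$genes$gene_id[
      assign_region_membership(
        data.frame(contig = truth$genes$contig,
                   position = truth$genes$start_codon_pos,
                   strand = truth$genes$strand), bound)]
    reads <- simulate_rnaseq(truth, silenced_genes = sil_genes,
                             repression_factor = config$repression_factor %||% 8,
                             cfg = cfg)
    gt <- gene_count_table(reads$silencer_present, reads$silencer_absent,
                           truth$genes,
                           labels = c("silencer_present", "silencer_absent"))
    gene_bound <- gt$features$id %in% sil_genes
    tt <- pooled_tss_counts(tss$present, tss$absent, cov$present, cov$absent,
                            labels = c("silencer_present", "silencer_absent"))
    tss_bound <- assign_region_membership(
      data.frame(contig = tt$features$contig, position = tt$features$start,
                 strand = tt$features$strand), bound)
    list(genes = volcano_table(gt, gene_bound),
         tss = volcano_table(tt, tss_bound),
         silenced_genes = sil_genes)
  })
  diff <- st$res; manifest <- st$manifest

  spac <- prom$spacer
  manifest$summary <- c(
    n_tss_present = nrow(tss$present), n_tss_absent = nrow(tss$absent),
    n_tss_union = nrow(tss$union),
    venn_only_present = venn$only_a, venn_shared = venn$shared,
    venn_only_absent = venn$only_b,
    pct_with_minus10 = unname(prom$with_element_pct),
    spacer_mode = as.integer(names(spac)[which.max(spac)]),
    intp_pct_A = unname(100 * prom$intp["A"]),
    intp_pct_G = unname(100 * prom$intp["G"]),
    start_proximal_signal_fraction = occ$start_prox_frac,
    n_genes_silenced = length(diff$silenced_genes))
  manifest$venn <- venn
  manifest$context <- context
  manifest$spacer_distribution <- spac
  manifest$intp <- prom$intp
  manifest$promoter_calls <- prom$calls
  manifest$pfm <- prom$pfm
  manifest$occupancy <- occ[c("profile", "curve")]
  manifest$diff_genes <- diff$genes
  manifest$diff_tss <- diff$tss
  manifest$truth <- truth

  if (!is.null(out_dir)) manifest <- write_manifest(manifest, tss, out_dir)
  class(manifest) <- "run_manifest"
  manifest
}

write_manifest <- function(manifest, tss, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  truth <- manifest$truth
  manifest$files$genome <- write_fasta(truth$genome, p("genome.fa"))
  manifest$files$genes <- write_annotation(truth$genes, p("genes.gff3"))
  manifest$files$islands <- write_regions(truth$islands, p("islands.bed"))
  manifest$files$tss_present <- write_tss(tss$present, p("tss_present.tsv"))
  manifest$files$tss_absent <- write_tss(tss$absent, p("tss_absent.tsv"))
  for (nm in c("promoter_calls", "context", "diff_genes", "diff_tss")) {
    manifest$files[[nm]] <- p(paste0(nm, ".tsv"))
    write.table(manifest[[nm]], manifest$files[[nm]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  manifest$files$profile <- p("metagene_profile.tsv")
  write.table(manifest$occupancy$profile, manifest$files$profile,
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$files$curve <- p("signal_noncoding_curve.tsv")
  write.table(manifest$occupancy$curve, manifest$files$curve,
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$files$pfm <- write_pfm(manifest$pfm, p("pfm.tsv"))
  manifest$files$summary <- p("summary.json")
  jsonlite::write_json(
    list(seed = manifest$seed, summary = as.list(manifest$summary),
         digests = as.list(tools::md5sum(unlist(manifest$files[
           names(manifest$files) != "summary"])))),
    manifest$files$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  s <- x$summary
  for (nm in names(s)) cat(sprintf("  %-32s %s\n", nm, format(s[[nm]])))
  invisible(x)
}
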