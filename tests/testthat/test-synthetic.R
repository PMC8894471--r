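test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 101)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(t1$genome$residues, t2$genome$residues)
  expect_identical(t1$tss_truth, t2$tss_truth)
  c1 <- simulate_cappable(t1, cfg)
  c2 <- simulate_cappable(t2, cfg)
  expect_identical(c1[[1]]$fwd$values, c2[[1]]$fwd$values)
  expect_identical(c1[[2]]$rev$values, c2[[2]]$rev$values)
})

test_that("island AT composition matches the configured fraction", {
  cfg <- small_cfg(seed = 5, genome_length = 80000L,
                   islands = list(c(8000, 0.72), c(8000, 0.72)),
                   n_genes = 70L)
  truth <- simulate_genome(cfg)
  for (i in seq_len(nrow(truth$islands))) {
    isl <- substr(truth$genome$residues, truth$islands$start[i],
                  truth$islands$end[i])
    at <- mean(strsplit(isl, "")[[1]] %in% c("A", "T"))
    expect_lt(abs(at - 0.72), 0.03)
  }
})

test_that("planted promoters are self-consistent: hexamer, spacer, discriminator", {
  truth <- simulate_genome(small_cfg(seed = 31))
  tt <- truth$tss_truth
  g <- truth$genome
  for (i in seq_len(nrow(tt))) {
    el <- substr(g$residues, tt$element_start[i], tt$element_end[i])
    if (tt$strand[i] == "-") el <- captss:::revcomp(el)
    expect_identical(el, tt$element_seq[i])
    # spacer = bases strictly between hexamer 3' end and the TSS
    if (tt$strand[i] == "+") {
      expect_equal(tt$position[i] - tt$element_end[i] - 1L, tt$spacer[i])
      disc <- substr(g$residues, tt$element_end[i] + 1L, tt$position[i] - 1L)
    } else {
      expect_equal(tt$element_start[i] - tt$position[i] - 1L, tt$spacer[i])
      disc <- captss:::revcomp(substr(g$residues, tt$position[i] + 1L,
                                      tt$element_start[i] - 1L))
    }
    expect_identical(disc, tt$discriminator_seq[i])
  }
  expect_true(all(tt$spacer %in% 6:8))
})

test_that("forced exact consensus at spacer 7 when mismatch rate is zero", {
  cfg <- small_cfg(seed = 13, minus10_mismatch_rate = 0,
                   spacer_distribution = c("7" = 1.0))
  truth <- simulate_genome(cfg)
  expect_true(all(truth$tss_truth$element_seq == "TATAAT"))
  expect_true(all(truth$tss_truth$spacer == 7L))
})

test_that("no islands means no intragenic promoters", {
  cfg <- small_cfg(seed = 17, islands = list(),
                   n_intragenic_promoters_per_island_kb = 2.0)
  truth <- simulate_genome(cfg)
  expect_equal(sum(truth$tss_truth$context == "intragenic"), 0L)
})

test_that("cappable coverage: background-only tracks match the configured rate", {
  cfg <- small_cfg(seed = 23, n_intergenic_promoters = 1L,
                   islands = list(), background_rate = 0.3)
  truth <- simulate_genome(cfg)
  reps <- simulate_cappable(truth, cfg)
  vals <- reps[[1]]$fwd$values[-truth$tss_truth$position]
  # NB mean within 3 standard errors (var = mu + phi mu^2)
  se <- sqrt((0.3 + 0.1 * 0.09) / length(vals))
  expect_lt(abs(mean(vals) - 0.3), 3 * se)
})

test_that("cappable signal appears only at planted TSSs when background is zero", {
  cfg <- small_cfg(seed = 29, background_rate = 0)
  truth <- simulate_genome(cfg)
  reps <- simulate_cappable(truth, cfg)
  tt <- truth$tss_truth
  for (r in reps) {
    expect_true(all(which(r$fwd$values > 0) %in% tt$position[tt$strand == "+"]))
    expect_true(all(which(r$rev$values > 0) %in% tt$position[tt$strand == "-"]))
  }
})

test_that("ChIP modes have the planted shapes", {
  truth <- simulate_genome(small_cfg(seed = 37))
  broad <- simulate_chip(truth, "broad", peak_height = 40, baseline = 1)
  isl <- truth$islands
  inside <- unlist(Map(seq, isl$start, isl$end))
  expect_true(all(broad$values[inside] >= 41))
  expect_true(all(broad$values[-inside] == 1))

  narrow <- simulate_chip(truth, "narrow", peak_height = 40, peak_width = 100)
  above <- narrow$values - 1
  centers <- truth$tss_truth$position[truth$tss_truth$context == "intergenic"]
  near <- unique(unlist(lapply(centers, function(p)
    max(1, p - 100):min(truth$genome$length, p + 100))))
  # a +-peak_width window around a Gaussian of s.d. peak_width/2 holds ~95%
  expect_gt(sum(above[near]) / sum(above), 0.5)

  flat <- simulate_chip(truth, "narrow", peak_height = 0, baseline = 2)
  expect_true(all(flat$values == 2))
})

test_that("RNA-seq repression scales silenced gene counts by the planted factor", {
  cfg <- small_cfg(seed = 41, nb_dispersion = 0.02, n_replicates = 4L)
  truth <- simulate_genome(cfg)
  sil <- truth$genes$gene_id[1:10]
  rn <- simulate_rnaseq(truth, silenced_genes = sil, repression_factor = 8,
                        cfg = cfg, mean_reads_range = c(400, 600))
  ca <- Reduce(`+`, lapply(rn$silencer_present, function(r)
    count_gene_reads(r, truth$genes)$counts))
  cb <- Reduce(`+`, lapply(rn$silencer_absent, function(r)
    count_gene_reads(r, truth$genes)$counts))
  ratio <- cb[sil] / pmax(ca[sil], 1)
  expect_lt(abs(median(ratio) - 8), 1.5)
  # unsilenced genes are exchangeable between conditions
  other <- setdiff(truth$genes$gene_id, sil)
  expect_lt(abs(median(cb[other] / ca[other]) - 1), 0.2)
})
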