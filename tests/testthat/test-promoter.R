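# Builds a + strand TSS context: random padding, TATAAT-like hexamer, a
# spacer of given length, with the TSS at `pos`.
context_genome <- function(hex, spacer, pad = 40, tail = 10, seed = 1) {
  set.seed(seed)
  bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  res <- paste0(bases(pad), hex, bases(spacer), "G", bases(tail))
  list(genome = genome_seq("chr", res), pos = pad + 6 + spacer + 1)
}

test_that("an exact consensus hexamer is found at its planted spacer", {
  cg <- context_genome("TATAAT", 7, seed = 3)
  ts <- tss_set(data.frame(contig = "chr", position = cg$pos, strand = "+"))
  call <- annotate_minus10(ts, cg$genome)
  expect_equal(call$spacer, 7L)
  expect_equal(call$mismatches, 0L)
  expect_true(call$has_element)
  expect_equal(call$element_seq, "TATAAT")
  expect_equal(nchar(call$discriminator_seq), 7L)
  # element coordinates point at the planted hexamer
  expect_equal(substr(cg$genome$residues, call$element_start, call$element_end),
               "TATAAT")
})

test_that("minus-strand annotation mirrors the sense geometry", {
  cg <- context_genome("TATAAT", 6, seed = 11)
  L <- cg$genome$length
  rc <- genome_seq("chr", captss:::revcomp(cg$genome$residues))
  ts <- tss_set(data.frame(contig = "chr", position = L - cg$pos + 1,
                           strand = "-"))
  call <- annotate_minus10(ts, rc)
  expect_equal(call$spacer, 6L)
  expect_equal(call$mismatches, 0L)
})

test_that("mismatch ties prefer spacer 7, then closeness to 7, then the smaller spacer", {
  # uniform context: every placement scores the same -> the 7 bp spacer wins
  g <- genome_seq("chr", strrep("A", 60))      # AAAAAA vs TATAAT = 3 mm anywhere
  ts <- tss_set(data.frame(contig = "chr", position = 40L, strand = "+"))
  call <- annotate_minus10(ts, g)
  expect_equal(call$spacer, 7L)
  expect_equal(call$mismatches, 3L)
  expect_false(call$has_element)

  # planted exact hexamer at d = 6 beats the uniform alternatives outright
  res <- paste0(strrep("C", 40), "TATAAT", strrep("C", 6), "G", strrep("C", 10))
  g2 <- genome_seq("chr", res)
  ts2 <- tss_set(data.frame(contig = "chr", position = 53L, strand = "+"))
  call2 <- annotate_minus10(ts2, g2)
  expect_equal(call2$spacer, 6L)
  expect_equal(call2$mismatches, 0L)
})

test_that("annotation equals the exhaustive enumeration oracle on random contexts", {
  set.seed(404)
  n_bad <- 0
  for (i in 1:200) {
    res <- paste(sample(c("A", "C", "G", "T"), 80, TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    g <- genome_seq("chr", res)
    pos <- 60L
    ts <- tss_set(data.frame(contig = "chr", position = pos, strand = "+"))
    got <- annotate_minus10(ts, g)
    ctx <- substr(res, pos - 15, pos - 1)
    want <- brute_minus10(ctx)
    if (got$spacer != want$d || got$mismatches != want$mm) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("TSSs too close to the contig edge are skipped with a warning", {
  g <- random_genome(100, seed = 5)
  ts <- tss_set(data.frame(contig = "chr", position = c(5L, 60L),
                           strand = "+"))
  expect_warning(calls <- annotate_minus10(ts, g), "skipped")
  expect_equal(nrow(calls), 1L)
  expect_equal(attr(calls, "n_skipped"), 1L)
})

test_that("spacer distribution sums to 100 and reflects the calls", {
  calls <- data.frame(spacer = c(7, 7, 6, 8), has_element = TRUE)
  d <- spacer_distribution(calls)
  expect_equal(sum(d), 100)
  expect_equal(unname(d["7"]), 50)
  expect_error(spacer_distribution(calls[0, ]), "no promoter")

  calls2 <- data.frame(spacer = c(6, 8), has_element = TRUE)
  expect_equal(unname(spacer_distribution(calls2)[c("6", "8")]), c(50, 50))
})

test_that("fraction_with_element covers the all and none cases", {
  expect_equal(fraction_with_element(data.frame(has_element = rep(TRUE, 5))), 100)
  expect_equal(fraction_with_element(data.frame(has_element = rep(FALSE, 3))), 0)
})

test_that("PFM information content matches closed forms", {
  # identical sequences: IC = 2 everywhere
  g <- genome_seq("chr", strrep("ACGTACGTACGT", 20))
  ts <- tss_set(data.frame(contig = "chr", position = c(60L, 108L, 156L),
                           strand = "+"))  # 48 apart: same phase, identical windows
  pfm <- build_pfm(ts, g, upstream = 10, downstream = 1)
  expect_true(all(abs(pfm$ic - 2) < 1e-12))
  expect_true(all(abs(colSums(pfm$freqs) - 1) < 1e-9))

  # hand-built frequency columns: uniform -> 0 bits; 50/50 two bases -> 1 bit
  seqs <- c("AA", "CC", "GA", "TC")   # col1 uniform, col2 A/C half-half
  mat <- do.call(rbind, strsplit(seqs, ""))
  g2 <- genome_seq("chr", paste0(paste(t(mat)[, 1], collapse = ""), "AAAA"))
  # construct via four single-TSS windows over a genome holding the seqs
  res <- paste(apply(mat, 1, paste, collapse = ""), collapse = "")
  g2 <- genome_seq("chr", res)
  ts2 <- tss_set(data.frame(contig = "chr", position = seq(2, 8, by = 2),
                            strand = "+"))
  pfm2 <- build_pfm(ts2, g2, upstream = 1, downstream = 1)
  expect_equal(unname(pfm2$ic[1]), 0)        # A,C,G,T uniform
  expect_equal(unname(pfm2$ic[2]), 1)        # A/C at 50/50
  expect_true(all(pfm2$ic >= 0 & pfm2$ic <= 2))
})

test_that("PFM window drops off-contig sequences and counts them", {
  g <- random_genome(100, seed = 9)
  ts <- tss_set(data.frame(contig = "chr", position = c(3L, 60L), strand = "+"))
  pfm <- build_pfm(ts, g, upstream = 20, downstream = 1)
  expect_equal(pfm$n_dropped, 1L)
  expect_equal(unname(pfm$counts[1]), 1)
})

test_that("iNTP usage reads the sense +1 base and complements minus-strand TSSs", {
  g <- genome_seq("chr", "AAAAGAAAAACAAAA")
  plus <- tss_set(data.frame(contig = "chr", position = 5L, strand = "+"))
  expect_equal(unname(intp_usage(plus, g)["G"]), 1)
  minus <- tss_set(data.frame(contig = "chr", position = 11L, strand = "-"))
  expect_equal(unname(intp_usage(minus, g)["G"]), 1)   # C complements to G
  both <- tss_set(data.frame(contig = "chr", position = c(5L, 11L, 2L),
                             strand = c("+", "-", "+")))
  u <- intp_usage(both, g)
  expect_equal(sum(u), 1)
  expect_equal(unname(u["A"]), 1 / 3)
})
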