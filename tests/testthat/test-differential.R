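test_that("gene read counting assigns by 5' base on the same strand", {
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "chr",
                      start = c(100L, 210L), end = c(200L, 300L),
                      strand = c("+", "+"), start_codon_pos = c(100L, 210L))
  reads <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(c(150, 150, 190, 50), end = c(220, 220, 260, 99)),
    strand = c("+", "-", "+", "+"))
  got <- count_gene_reads(reads, genes)
  # read 1: 5' base 150 in g1; read 2 antisense; read 3 spans g1/g2 but its
  # 5' base is in g1 only; read 4 outside
  expect_equal(unname(got$counts), c(2L, 0L))
  expect_equal(got$n_total, 4L)
  expect_equal(got$n_assigned, 2L)

  # minus-strand gene: 5' base is the interval end
  genes2 <- data.frame(gene_id = "gm", contig = "chr", start = 100L,
                       end = 200L, strand = "-", start_codon_pos = 200L)
  reads2 <- GenomicRanges::GRanges("chr", IRanges::IRanges(150, 250),
                                   strand = "-")
  expect_equal(unname(count_gene_reads(reads2, genes2)$counts), 0L)  # 5' at 250
  reads3 <- GenomicRanges::GRanges("chr", IRanges::IRanges(90, 150),
                                   strand = "-")
  expect_equal(unname(count_gene_reads(reads3, genes2)$counts), 1L)
})

test_that("pooled TSS counts deduplicate features and read coverage at the +1", {
  a <- tss_set(data.frame(contig = "chr", position = c(100L, 200L), strand = "+"),
               condition = "A")
  b <- tss_set(data.frame(contig = "chr", position = c(200L, 300L), strand = "-"),
               condition = "B")
  mk <- function(fwd_at, rev_at) {
    fwd <- numeric(500); fwd[fwd_at] <- 7
    rev <- numeric(500); rev[rev_at] <- 2
    make_pair(fwd, rev)
  }
  cov_a <- list(mk(c(100, 200), integer(0)), mk(c(100, 200), integer(0)))
  cov_b <- list(mk(integer(0), c(200, 300)), mk(integer(0), c(200, 300)))
  ct <- pooled_tss_counts(a, b, cov_a, cov_b)
  expect_equal(nrow(ct$counts), 4L)     # 200+ and 200- are distinct features
  # a TSS seen only in A has zero counts in the B samples
  row_100 <- which(ct$features$start == 100)
  expect_equal(unname(ct$counts[row_100, ]), c(7, 7, 0, 0))
  expect_true(all(ct$counts <= matrix(ct$lib_sizes, nrow(ct$counts),
                                      ncol(ct$counts), byrow = TRUE)))
})

test_that("exact rate test matches hand-derived and enumerated values", {
  # symmetric observation is modal: p = 1
  expect_equal(exact_rate_test(5, 5, 1e6, 1e6), 1)
  # one-sided extreme with equal libraries: 2 * 0.5^10
  expect_equal(exact_rate_test(10, 0, 1e6, 1e6), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(exact_rate_test(0, 0, 10, 10), 1)

  # full equivalence with the enumeration oracle, unequal libraries included
  for (M in list(c(1e6, 1e6), c(2e6, 1e6), c(1e6, 3e6))) {
    for (n in c(1, 7, 20)) {
      for (a in 0:n) {
        expect_equal(exact_rate_test(a, n - a, M[1], M[2]),
                     brute_exact_p(a, n - a, M[1], M[2]),
                     tolerance = 1e-12,
                     info = sprintf("a=%d n=%d M=%g/%g", a, n, M[1], M[2]))
      }
    }
  }
})

test_that("exact rate test agrees with the base binomial test", {
  set.seed(99)
  for (i in 1:50) {
    a <- rpois(1, 40); b <- rpois(1, 25)
    M <- c(2.1e6, 1.7e6)
    want <- stats::binom.test(a, a + b, p = M[1] / sum(M))$p.value
    expect_equal(exact_rate_test(a, b, M[1], M[2]), want, tolerance = 1e-9)
  }
})

test_that("BH adjustment follows the step-up rule and is order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # monotone non-decreasing in sorted-p order
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= -1e-15))
})

test_that("volcano table: symmetric counts give zero fold change and sane columns", {
  ct <- structure(list(
    features = data.frame(id = c("f1", "f2"), kind = "gene", contig = "chr",
                          start = c(1L, 10L), end = c(5L, 20L), strand = "+"),
    counts = matrix(c(10, 3, 10, 3, 10, 50, 10, 50), nrow = 2,
                    dimnames = list(NULL, c("A.1", "A.2", "B.1", "B.2"))),
    lib_sizes = c(100, 100, 100, 100),
    condition = factor(c("A", "A", "B", "B"))), class = "count_table")
  v <- volcano_table(ct, bound = c(TRUE, FALSE))
  f1 <- v[v$id == "f1", ]
  expect_equal(f1$log2fc, 0)
  expect_equal(f1$p_value, 1)
  f2 <- v[v$id == "f2", ]
  expect_equal(f2$log2fc, log2(6.5 / 100.5))
  expect_true(all(v$fdr >= v$p_value - 1e-15))
  expect_true(!is.unsorted(v$p_value))
})

test_that("null features in bound and free regions behave exchangeably", {
  set.seed(404)
  n <- 400
  counts <- matrix(rpois(4 * n, 30), ncol = 4,
                   dimnames = list(NULL, c("A.1", "A.2", "B.1", "B.2")))
  ct <- structure(list(
    features = data.frame(id = paste0("f", 1:n), kind = "gene", contig = "chr",
                          start = 1:n, end = 1:n, strand = "+"),
    counts = counts, lib_sizes = colSums(counts),
    condition = factor(c("A", "A", "B", "B"))), class = "count_table")
  bound <- rep(c(TRUE, FALSE), n / 2)
  v <- volcano_table(ct, bound)
  ks <- suppressWarnings(stats::ks.test(v$p_value[v$bound], v$p_value[!v$bound]))
  expect_gt(ks$p.value, 0.01)
})
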