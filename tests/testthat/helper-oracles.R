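# Fixture builders and independent brute-force oracles. The oracles
# deliberately re-derive each rule with naive per-case code so that the
# vectorized implementations are checked against a second, simpler path.

make_pair <- function(fwd, rev = numeric(length(fwd)), contig = "chr") {
  list(fwd = captss:::new_track(contig, "+", fwd),
       rev = captss:::new_track(contig, "-", rev))
}

random_genome <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome_seq("chr", paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

# Brute-force TSS caller: re-evaluates the step rule at every base with a
# plain loop; "skip" walks upstream base by base to find the previous
# nonzero position.
brute_step_calls <- function(values, strand, fold, policy) {
  L <- length(values)
  dir <- if (strand == "+") -1L else 1L
  hits <- integer(0)
  for (p in seq_len(L)) {
    if (values[p] <= 0) next
    q <- p + dir
    if (policy == "skip") while (q >= 1L && q <= L && values[q] == 0) q <- q + dir
    if (q < 1L || q > L) next
    if (values[q] > 0 && values[p] > fold * values[q]) hits <- c(hits, p)
  }
  hits
}

brute_call_tss <- function(replicates, fold, policy) {
  res <- list()
  for (strand in c("+", "-")) {
    key <- if (strand == "+") "fwd" else "rev"
    per_rep <- lapply(replicates, function(r)
      brute_step_calls(r[[key]]$values, strand, fold, policy))
    pos <- sort(Reduce(intersect, per_rep))
    if (length(pos))
      res[[strand]] <- data.frame(position = pos, strand = strand)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(position = integer(0), strand = character(0))
  else { out <- out[order(out$position, out$strand), ]; rownames(out) <- NULL; out }
}

# Brute-force -10 assignment: enumerate every (placement, spacer) pair and
# apply the tie-break by explicit sorting.
brute_minus10 <- function(ctx_sense, spacer_range = 5:9) {
  cons <- c("T", "A", "T", "A", "A", "T")
  U <- nchar(ctx_sense)
  ch <- strsplit(ctx_sense, "")[[1]]
  cand <- data.frame()
  for (d in spacer_range) {
    idx <- (U - d - 5):(U - d)
    mm <- sum(ch[idx] != cons)
    cand <- rbind(cand, data.frame(d = d, mm = mm))
  }
  cand <- cand[order(cand$mm, cand$d != 7, abs(cand$d - 7), cand$d), ]
  cand[1, ]
}

# Brute-force two-sided exact conditional test: pmf from explicit
# choose() products, outcomes no more probable than observed are summed.
brute_exact_p <- function(a, b, M_A, M_B) {
  n <- a + b
  if (n == 0) return(1)
  pi <- M_A / (M_A + M_B)
  pmf <- vapply(0:n, function(k) choose(n, k) * pi^k * (1 - pi)^(n - k), 0)
  min(1, sum(pmf[pmf <= pmf[a + 1] * (1 + 1e-7)]))
}

small_cfg <- function(seed, ...) {
  args <- list(genome_length = 50000L, n_genes = 45L,
               islands = list(c(5000, 0.70), c(5000, 0.70)),
               n_intergenic_promoters = 15L,
               n_intragenic_promoters_per_island_kb = 1.0,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}
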