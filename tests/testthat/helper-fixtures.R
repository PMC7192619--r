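# Shared fixture builders; everything is constructed in code.

make_counts <- function(transcript_id, position, sample_id, a, g, c = 0L, t = 0L) {
  validate_counts(data.frame(
    transcript_id = transcript_id, position = position, sample_id = sample_id,
    a_count = a, c_count = c, g_count = g, t_count = t,
    stringsAsFactors = FALSE))
}

make_sites <- function(transcript_id, position, in_vivo_level = NA_real_) {
  validate_sites(data.frame(
    transcript_id = transcript_id, position = position, ref_base = "A",
    in_vivo_level = in_vivo_level, stringsAsFactors = FALSE))
}

# expand per-site level/coverage vectors for one sample into a count table
counts_for_sample <- function(sample_id, g, ag, transcript = NULL) {
  n <- length(g)
  if (is.null(transcript)) transcript <- sprintf("tx%d", seq_len(n))
  make_counts(transcript, rep(1L, n), rep(sample_id, n), a = ag - g, g = g)
}

table1_fixture <- function() {
  path <- system.file("extdata", "sqkv1a_table1.tsv", package = "axonedit")
  read_results_table(path)
}

# brute-force BH step-up: adj_i = min over j >= i (in sorted order) of p(j)*m/j
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}
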