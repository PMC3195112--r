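# Independent brute-force oracles, written against the plain textbook
# definitions with loops and no shared code with the package internals.

bf_contingency <- function(x, y) {
  a <- 0L; b <- 0L; c <- 0L; d <- 0L
  for (i in seq_along(x)) {
    if (x[i] == 1 && y[i] == 1) a <- a + 1L
    else if (x[i] == 1) b <- b + 1L
    else if (y[i] == 1) c <- c + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = c, d = d, n = length(x))
}

bf_similarity <- function(x, y, coefficient) {
  ct <- bf_contingency(x, y)
  with(ct, switch(coefficient,
    tanimoto = if (a + b + c == 0) 0 else a / (a + b + c),
    cosine = if ((a + b) * (a + c) == 0) 0 else a / sqrt((a + b) * (a + c)),
    forbes = if ((a + b) * (a + c) == 0) 0 else n * a / ((a + b) * (a + c)),
    russell_rao = a / n,
    simple_match = (a + d) / n
  ))
}

# rank molecule ids by decreasing similarity to ref_bits, ties by ascending id
bf_rank <- function(fps, ids, ref_bits, coefficient) {
  sims <- vapply(fps, function(f) bf_similarity(ref_bits, f, coefficient), 0)
  ids[order(-sims, ids)]
}

bf_top_set <- function(fps, ids, ref_bits, coefficient, fraction) {
  k <- max(1L, floor(fraction * length(ids)))
  bf_rank(fps, ids, ref_bits, coefficient)[seq_len(k)]
}

# tally how many of the sets contain each id
bf_counts <- function(sets, ids) {
  vapply(ids, function(id) sum(vapply(sets, function(s) id %in% s, TRUE)), 0L)
}

bf_overlap_histogram <- function(counts, n) {
  vapply(seq_len(n), function(s) sum(counts == s), 0L)
}

bf_precision <- function(counts, is_active, n) {
  vapply(seq_len(n), function(s) {
    in_bucket <- counts == s
    if (sum(in_bucket) == 0) NA_real_ else 100 * sum(is_active & in_bucket) / sum(in_bucket)
  }, 0)
}

bf_intersection_size <- function(sets, k) {
  common <- sets[[1L]]
  for (i in seq_len(k)[-1L]) common <- common[common %in% sets[[i]]]
  length(unique(common))
}

# extract raw bit rows of one database view as a list of vectors
db_bits_list <- function(db, view) {
  B <- fp_from_hex(db[[paste0("fp", view)]], n_bits(db))
  lapply(seq_len(nrow(B)), function(i) B[i, ])
}
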