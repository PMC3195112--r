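# Binary fingerprints: 0/1 bit vectors of fixed length, the contingency table
# between two of them, and the five similarity coefficients built on it.

COEFFICIENTS <- c("tanimoto", "cosine", "forbes", "russell_rao", "simple_match")

# 256 x 8 lookup: row b+1 holds the bits of byte b, most significant first
.byte_bits <- local({
  m <- matrix(0L, 256L, 8L)
  for (b in 0:255) m[b + 1L, ] <- as.integer(intToBits(b))[8:1]
  m
})
.hex_bytes <- sprintf("%02x", 0:255)

#' Names of the supported similarity coefficients
#'
#' @return Character vector: `"tanimoto"`, `"cosine"`, `"forbes"`,
#'   `"russell_rao"`, `"simple_match"`.
#' @export
similarity_coefficients <- function() COEFFICIENTS

.check_bits <- function(x, arg = "x") {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || !all(x %in% c(0, 1))) {
    abort(sprintf("`%s` must be a vector of 0/1 bits with length >= 1.", arg))
  }
  as.integer(x)
}

#' Contingency counts between two binary fingerprints
#'
#' Counts the four cells of the 2x2 table underlying all binary similarity
#' coefficients: `a` positions on in both fingerprints, `b` on in `x` only,
#' `c` on in `y` only, `d` off in both.
#'
#' @param x,y Equal-length 0/1 vectors.
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`, `n_bits`.
#' @examples
#' contingency_counts(c(1, 0, 1, 1, 0), c(1, 0, 0, 1, 1))
#' @export
contingency_counts <- function(x, y) {
  x <- .check_bits(x, "x")
  y <- .check_bits(y, "y")
  if (length(x) != length(y)) {
    abort(sprintf("Fingerprint lengths differ: %d vs %d.", length(x), length(y)))
  }
  a <- sum(x & y)
  tibble::tibble(
    a = a, b = sum(x) - a, c = sum(y) - a,
    d = length(x) - sum(x) - sum(y) + a, n_bits = length(x)
  )
}

#' Similarity from contingency counts
#'
#' Applies one of the five coefficients to contingency counts. Degenerate
#' denominators never raise: Tanimoto of two all-zero fingerprints is 0, and
#' Cosine/Forbes are 0 whenever either fingerprint has no on bits, so empty
#' fingerprints rank last rather than crash a batch search.
#'
#' Formulas (with `n = n_bits`): Tanimoto `a/(a+b+c)`; Cosine
#' `a/sqrt((a+b)(a+c))`; Forbes `n*a/((a+b)(a+c))`; Russell-Rao `a/n`;
#' Simple Match `(a+d)/n`.
#'
#' @param counts Data frame with columns `a`, `b`, `c`, `d`, `n_bits`
#'   (one or more rows), as from [contingency_counts()].
#' @param coefficient One of [similarity_coefficients()].
#' @return Numeric vector, one score per row of `counts`. All coefficients lie
#'   in `[0, 1]` except Forbes, which lies in `[0, n_bits]`; scores are meant
#'   for ranking only.
#' @export
similarity_from_counts <- function(counts, coefficient = "tanimoto") {
  coefficient <- match.arg(coefficient, COEFFICIENTS)
  a <- counts$a; b <- counts$b; c <- counts$c; d <- counts$d; n <- counts$n_bits
  if (any(a < 0 | b < 0 | c < 0 | d < 0) || any(a + b + c + d != n)) {
    abort("Invalid contingency counts: cells must be >= 0 and sum to `n_bits`.")
  }
  switch(coefficient,
    tanimoto = ifelse(a + b + c == 0, 0, a / (a + b + c)),
    cosine = ifelse((a + b) * (a + c) == 0, 0, a / sqrt((a + b) * (a + c))),
    forbes = ifelse((a + b) * (a + c) == 0, 0, n * a / ((a + b) * (a + c))),
    russell_rao = a / n,
    simple_match = (a + d) / n
  )
}

#' Similarity between two fingerprints
#'
#' @inheritParams contingency_counts
#' @inheritParams similarity_from_counts
#' @return A single similarity score.
#' @examples
#' fp_similarity(c(1, 0, 1), c(1, 1, 0), "tanimoto")
#' @export
fp_similarity <- function(x, y, coefficient = "tanimoto") {
  similarity_from_counts(contingency_counts(x, y), coefficient)
}

# --- hex serialization ------------------------------------------------------
# Convention: bit position 0 is the most significant bit of the first byte;
# lengths that are not a multiple of 8 are padded with trailing zero bits in
# the low bits of the last byte. The explicit length disambiguates the pad.

#' Serialize fingerprints to lowercase hex
#'
#' @param bits A 0/1 vector, or a matrix with one fingerprint per row.
#' @return Character vector of hex strings, `ceiling(L/8)` bytes each, bit 0
#'   stored in the most significant position of the first byte.
#' @seealso [fp_from_hex()]
#' @export
fp_to_hex <- function(bits) {
  if (!is.matrix(bits)) bits <- matrix(.check_bits(bits), nrow = 1L)
  L <- ncol(bits)
  pad <- (8L - L %% 8L) %% 8L
  if (pad > 0L) bits <- cbind(bits, matrix(0L, nrow(bits), pad))
  k <- ncol(bits) / 8L
  pow <- 2L^(7:0)
  out <- matrix("", nrow(bits), k)
  for (j in seq_len(k)) {
    vals <- as.integer(bits[, (8L * (j - 1L) + 1L):(8L * j), drop = FALSE] %*% pow)
    out[, j] <- .hex_bytes[vals + 1L]
  }
  do.call(paste0, asplit(out, 2L))
}

#' Parse hex-serialized fingerprints
#'
#' @param hex Character vector of lowercase hex strings.
#' @param n_bits Fingerprint length `L`; trailing pad bits beyond `L` are
#'   dropped (and must be zero).
#' @return An integer matrix with one fingerprint of `n_bits` columns per
#'   element of `hex`.
#' @export
fp_from_hex <- function(hex, n_bits) {
  n_bytes <- ceiling(n_bits / 8)
  bad <- which(nchar(hex) != 2L * n_bytes | grepl("[^0-9a-f]", hex))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Invalid hex fingerprint at position %d: expected %d lowercase hex chars, got \"%s\".",
      bad[1L], 2L * n_bytes, hex[bad[1L]]
    ))
  }
  big <- paste(hex, collapse = "")
  starts <- seq(1L, nchar(big), by = 2L)
  bytes <- match(substring(big, starts, starts + 1L), .hex_bytes) - 1L
  bits <- .byte_bits[bytes + 1L, , drop = FALSE]
  m <- matrix(t(bits), nrow = length(hex), byrow = TRUE)
  if (ncol(m) > n_bits && any(m[, (n_bits + 1L):ncol(m)] != 0L)) {
    abort("Nonzero pad bits beyond the declared fingerprint length.")
  }
  m[, seq_len(n_bits), drop = FALSE]
}
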