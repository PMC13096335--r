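# Independent brute-force oracles. Deliberately written position by
# position, without reusing any package internals, so that agreement with
# the vectorized implementations is a meaningful check.

# zero-padded moving average, double loop
ma_oracle <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in (i - h):(i + h)) {
      if (j >= 1 && j <= n) s <- s + x[j]
    }
    out[i] <- s / w
  }
  out
}

# plateau-tolerant weak local maxima, position by position (0-based)
locmax_oracle <- function(x) {
  n <- length(x)
  hits <- integer(0)
  for (i in seq_len(n)) {
    left_ok <- i == 1 || x[i] >= x[i - 1]
    right_ok <- i == n || x[i] >= x[i + 1]
    if (left_ok && right_ok) hits <- c(hits, i - 1L)
  }
  hits
}

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

.revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# character-by-character IUPAC scan; N in the sequence only matches motif N
iupac_oracle <- function(sequence, pattern, both_strands = TRUE) {
  match_at <- function(seq_chars, pat_chars, off) {
    for (k in seq_along(pat_chars)) {
      if (!(seq_chars[off + k] %in% .iupac_sets[[pat_chars[k]]])) {
        return(FALSE)
      }
    }
    TRUE
  }
  pat <- strsplit(pattern, "")[[1]]
  scan_one <- function(s) {
    chars <- strsplit(s, "")[[1]]
    hits <- integer(0)
    if (length(chars) >= length(pat)) {
      for (off in 0:(length(chars) - length(pat))) {
        if (match_at(chars, pat, off)) hits <- c(hits, off)
      }
    }
    hits
  }
  plus <- scan_one(sequence)
  out <- data.frame(offset = plus, strand = rep("+", length(plus)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rc_hits <- scan_one(.revcomp_chr(sequence))
    minus <- nchar(sequence) - rc_hits - length(pat)
    out <- rbind(out, data.frame(offset = minus,
                                 strand = rep("-", length(minus)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

# exact one-sided signed-rank p by enumeration of all sign assignments
# (tie-free differences only)
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  total <- 0L
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    W <- sum(r[signs == 1L])
    total <- total + 1L
    if (W >= W_obs) count <- count + 1L
  }
  list(W = W_obs, p = count / total)
}
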