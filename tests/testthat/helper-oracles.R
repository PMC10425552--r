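# brute-force Fisher exact p: enumerate all 2x2 tables with the observed
# margins and sum the hypergeometric probabilities no larger than the
# observed table's
fisher_enum_p <- function(x11, x12, x21, x22) {
  m <- x11 + x12; n <- x21 + x22; k <- x11 + x21
  kk <- max(0, k - n):min(k, m)
  probs <- dhyper(kk, m, n, k)
  p_obs <- dhyper(x11, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney U with tie correction and normal approximation with
# continuity correction, written out from the textbook formulas
mw_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  N <- n1 + n2
  mu <- n1 * n2 / 2
  v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
  list(U = U, p = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5))
}
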