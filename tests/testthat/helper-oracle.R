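# Independent brute-force oracle: computes each index by looping over the
# edges of a concrete igraph with the defining formula written out inline.
# Deliberately does not touch irr_kernels()/kernel_sum(), so it can serve as
# a cross-check of the package's computation paths.
oracle_index <- function(g, id) {
  d <- igraph::degree(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  total <- 0
  for (e in seq_len(nrow(ends))) {
    a <- d[ends[e, 1]]
    b <- d[ends[e, 2]]
    total <- total + switch(
      id,
      IRDIF = abs(a / b - b / a),
      AL    = abs(a - b),
      IRL   = abs(log(a) - log(b)),
      IRLU  = abs(a - b) / min(a, b),
      IRLF  = abs(a - b) / sqrt(a * b),
      IRF   = (a - b)^2,
      IRLA  = 2 * abs(a - b) / (a + b),
      IRD1  = log(1 + abs(a - b)),
      IRA   = (1 / sqrt(a) - 1 / sqrt(b))^2,
      IRGA  = 2 * log((a + b) / (2 * sqrt(a * b))),
      IRB   = (sqrt(a) - sqrt(b))^2,
      IRRt  = abs(a - b) / 2,
      stop("oracle: unknown index ", id)
    )
  }
  total
}

# Relative comparison helper with a sensible floor for near-zero values.
rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), 1e-12)
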