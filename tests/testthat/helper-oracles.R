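# Independent oracles and fixture builders used across the suite.

# circular resultant length |sum w exp(2i theta)| / sum w, computed
# directly from angles and weights (independent of the tensor path)
resultant_length <- function(theta, w = rep(1, length(theta))) {
  if (sum(w) == 0) return(0)
  Mod(sum(w * exp(2i * theta))) / sum(w)
}

# exact hypergeometric tail by explicit enumeration over all tables with
# the observed margins, probabilities from stats::dhyper (a code path
# independent of the package's log-binomial implementation)
hyper_oracle <- function(a, b, c, d, alternative = "greater") {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  p <- dhyper(xs, m, n, k)
  switch(alternative,
         greater   = sum(p[xs >= a]),
         less      = sum(p[xs <= a]),
         two_sided = sum(p[p <= p[xs == a] * (1 + 1e-7)]))
}

# sinusoidal stripe image: fibers run perpendicular to `axis`
stripe_image <- function(n = 128, period = 8, axis = c("row", "col")) {
  axis <- match.arg(axis)
  idx <- if (axis == "row") matrix(seq_len(n), n, n) else matrix(seq_len(n), n, n, byrow = TRUE)
  100 + 50 * sin(2 * pi * idx / period)
}

# superposition of four equal-amplitude plane waves at 0/45/90/135
# degrees: the orientation content is balanced under 90-degree rotation,
# so the mean nematic tensor vanishes at any patch scale
composite4_image <- function(n = 256, period = 8) {
  r <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  100 + 25 * (sin(2 * pi * cc / period) + sin(2 * pi * r / period) +
              sin(2 * pi * (cc + r) / (period * sqrt(2))) +
              sin(2 * pi * (cc - r) / (period * sqrt(2))))
}

# binary disk mask
disk_mask <- function(n, cy, cx, radius) {
  R <- matrix(seq_len(n), n, n)
  C <- matrix(seq_len(n), n, n, byrow = TRUE)
  m <- ((R - cy)^2 + (C - cx)^2 <= radius^2) * 1L
  storage.mode(m) <- "integer"
  m
}

# match segmented nuclei to planted truth cells by nearest centroid;
# returns the truth row index per label
match_truth <- function(nuclei, truth) {
  labs <- sort(unique(nuclei[nuclei > 0]))
  cy <- tapply(row(nuclei)[nuclei > 0], nuclei[nuclei > 0], mean)
  cx <- tapply(col(nuclei)[nuclei > 0], nuclei[nuclei > 0], mean)
  vapply(seq_along(labs), function(i) {
    which.min((truth$row - cy[i])^2 + (truth$col - cx[i])^2)
  }, 0L)
}
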