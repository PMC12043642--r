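# Shared fixture builders; everything is generated in code at test time.

# One planted propagating contraction on the default 30 mm / 900 s map.
fixture_stmap <- function(velocity = 1.0, span = 0.9, origin = 0.02,
                          onsets = 100, noise_sd = 0, amplitude = 0.5,
                          seed = 1, ...) {
  tcs <- lapply(onsets, function(o)
    true_contraction(o, origin, span, velocity, amplitude_frac = amplitude))
  simulate_stmap(contractions = tcs, noise_sd = noise_sd, seed = seed, ...)
}

# Direct (non-separable) replicate-padded correlation, the smoothing oracle.
direct_filter2d <- function(x, k) {
  h <- nrow(k)
  ctr <- floor((h + 1) / 2)
  nr <- nrow(x); nc <- ncol(x)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, nr, nc)
  for (u in seq_len(h)) for (v in seq_len(h)) {
    out <- out + k[u, v] *
      x[clamp(seq_len(nr) + u - ctr, nr), clamp(seq_len(nc) + v - ctr, nc),
        drop = FALSE]
  }
  out
}

# Exact-area rectangle blob (thickness x ceiling(area/thickness), partial
# last column) stamped into a mask.
stamp_blob <- function(mask, r0, c0, area, thickness) {
  len <- ceiling(area / thickness)
  mask[r0:(r0 + thickness - 1L), c0:(c0 + len - 2L)] <- TRUE
  rem <- area - thickness * (len - 1L)
  if (rem > 0) mask[r0:(r0 + rem - 1L), c0 + len - 1L] <- TRUE
  mask
}
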