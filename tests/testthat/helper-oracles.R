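# Shared fixtures and independent oracles.

# brute-force dense 2-D convolution, scalar loops (the reference the
# GEMM-based kernel and the zero-offset deformable path are checked against)
conv_ref <- function(x, w, b = numeric(dim(w)[4]), stride = 1,
                     pad = (dim(w)[1] - 1) %/% 2) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  k <- dim(w)[1]; Co <- dim(w)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Co))
  for (yo in 1:Ho) for (xo in 1:Wo) for (o in 1:Co) {
    s <- b[o]
    for (i in 1:k) for (j in 1:k) for (c in 1:C) {
      yi <- (yo - 1) * stride + i - 1 - pad
      xi <- (xo - 1) * stride + j - 1 - pad
      if (yi >= 0 && yi < H && xi >= 0 && xi < W)
        s <- s + w[i, j, c, o] * x[yi + 1, xi + 1, c]
    }
    out[yo, xo, o] <- s
  }
  out
}

# central finite differences of a scalar function over an array argument
fd_grad <- function(arr, f, eps = 1e-5) {
  g <- arr * 0
  for (i in seq_along(arr)) {
    a1 <- arr; a1[i] <- a1[i] + eps
    a2 <- arr; a2[i] <- a2[i] - eps
    g[i] <- (f(a1) - f(a2)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-9, max(abs(a)), max(abs(b)))
}

# a small deterministic image batch
toy_batch <- function(n = 2, size = 32, seed = 1) {
  with_seed(seed, array(runif(size * size * 3 * n), c(size, size, 3, n)))
}

# small in-memory labeled-image set, shared across training-path tests
toy_dataset <- function(per_class = 6, size = 64, seed = 5) {
  counts <- rep(as.integer(per_class), 5)
  generate_lesion_set(counts, pmax(2L, counts %/% 3L), seed = seed,
                      size = size)
}
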