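#' @useDynLib sevgrade, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom median
#' @importFrom utils read.csv write.csv head
NULL

# ---- seeded evaluation -------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stream seed from a global seed and a label
#'
#' Splitmix-style fan-out so one run seed deterministically yields
#' independent sub-seeds for data generation, augmentation, weight
#' initialisation and batching. All arithmetic stays below 2^31.
#'
#' @param seed integer global seed.
#' @param key character label of the consumer stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- 17
  for (code in utf8ToInt(as.character(key))) h <- (h * 131 + code) %% m
  s <- (abs(as.numeric(seed)) %% m)
  for (i in 1:3) s <- (s * 16807 + h) %% m
  as.integer(max(1, s))
}

# ---- array helpers -----------------------------------------------------

# promote a single H x W x C image to an H x W x C x 1 batch
as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# stack a list of H x W x C arrays into H x W x C x N
stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

#' Bilinear sample of a 2-D grid at real-valued coordinates
#'
#' Interpolates the four neighbours of each `(y, x)`; coordinates outside
#' `[0, H-1] x [0, W-1]` draw zeros (zero padding), matching the sampling
#' rule used inside the deformable convolution. Coordinates are 0-based
#' with origin at the top-left pixel centre.
#'
#' @param map numeric matrix (rows = y).
#' @param y,x numeric vectors of coordinates.
#' @return numeric vector of sampled values.
#' @export
bilinear_sample <- function(map, y, x) {
  stopifnot(is.matrix(map), length(y) == length(x), all(is.finite(y)),
            all(is.finite(x)))
  cpp_bilinear_sample(map, as.numeric(y), as.numeric(x))
}

# interpolation matrix mapping a length-n_in axis to n_out (half-pixel
# centre alignment, edges clamped); resize is then A %*% X %*% t(B)
resize_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    A[, 1] <- 1
    return(A)
  }
  src <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  f <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    A[i, lo[i] + 1] <- A[i, lo[i] + 1] + (1 - f[i])
    A[i, hi[i] + 1] <- A[i, hi[i] + 1] + f[i]
  }
  A
}

#' Bilinear resize of an image or feature map
#'
#' @param x array `H x W x C` or `H x W x C x N`.
#' @param out_h,out_w target spatial size.
#' @return resized array with the same trailing dimensions.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  single <- length(d) == 3L
  x <- as_batch(x)
  d <- dim(x)
  A <- resize_matrix(d[1], out_h)
  B <- resize_matrix(d[2], out_w)
  out <- array(0, c(out_h, out_w, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    out[, , c, n] <- A %*% x[, , c, n] %*% t(B)
  if (single) dim(out) <- c(out_h, out_w, d[3])
  out
}

# adjoint of resize_bilinear for backprop (A^T G B)
resize_bilinear_bw <- function(gy, in_h, in_w) {
  d <- dim(gy)
  A <- resize_matrix(in_h, d[1])
  B <- resize_matrix(in_w, d[2])
  gx <- array(0, c(in_h, in_w, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    gx[, , c, n] <- t(A) %*% gy[, , c, n] %*% B
  gx
}

# mirror an out-of-range 0-based index back into [0, n-1]
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - i, i)
}

# numerically stable softplus and its derivative
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
sigmoid <- function(z) 1 / (1 + exp(-z))
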