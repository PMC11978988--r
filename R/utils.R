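# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discrete Fourier sample frequencies
#'
#' Frequencies (cycles per unit) associated with the unshifted output of
#' [stats::fft()] for `n` samples spaced `d` apart, in standard FFT order
#' (DC first, negative frequencies in the second half).
#'
#' @param n number of samples.
#' @param d sample spacing (e.g. object-side pixel size in micrometres).
#' @return numeric vector of length `n`.
#' @keywords internal
#' @noRd
fft_freq <- function(n, d = 1) {
  i <- seq_len(n) - 1L
  i[i >= ceiling(n / 2)] <- i[i >= ceiling(n / 2)] - n
  i / (n * d)
}

# Swap quadrants so the zero frequency sits at index (n %/% 2 + 1).
fft_shift <- function(x) {
  if (is.matrix(x)) {
    nr <- nrow(x); nc <- ncol(x)
    x[c(seq.int(nr %/% 2 + 1L, nr), seq_len(nr %/% 2)),
      c(seq.int(nc %/% 2 + 1L, nc), seq_len(nc %/% 2)), drop = FALSE]
  } else {
    n <- length(x)
    x[c(seq.int(n %/% 2 + 1L, n), seq_len(n %/% 2))]
  }
}

ifft_shift <- function(x) {
  if (is.matrix(x)) {
    nr <- nrow(x); nc <- ncol(x)
    x[c(seq.int(nr - nr %/% 2 + 1L, nr), seq_len(nr - nr %/% 2)),
      c(seq.int(nc - nc %/% 2 + 1L, nc), seq_len(nc - nc %/% 2)), drop = FALSE]
  } else {
    n <- length(x)
    x[c(seq.int(n - n %/% 2 + 1L, n), seq_len(n - n %/% 2))]
  }
}

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Object-plane coordinate of each pixel index (1-based), centred so that the
# origin coincides with the FFT centre pixel (index n %/% 2 + 1).
pixel_coords <- function(n, pixel) (seq_len(n) - (n %/% 2 + 1L)) * pixel

# Sum weights w into an nr x nc matrix at integer (row, col) positions.
accumulate_matrix <- function(rows, cols, w, nr, nc) {
  keep <- rows >= 1L & rows <= nr & cols >= 1L & cols <= nc
  m <- numeric(nr * nc)
  if (any(keep)) {
    idx <- (cols[keep] - 1L) * nr + rows[keep]
    s <- rowsum(w[keep], idx)
    m[as.integer(rownames(s))] <- s
  }
  matrix(m, nr, nc)
}

# Deterministic per-stage RNG substream: hash the stage name into an offset
# so stages draw from independent streams of one global seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Quantize doubles to the nearest IEEE float32 value (used by TIFF export so
# that write -> read round trips are bit-stable).
as_float32 <- function(x) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(x), con, size = 4L)
  r <- rawConnectionValue(con)
  close(con)
  y <- readBin(r, what = "numeric", n = length(x), size = 4L)
  if (is.matrix(x)) dim(y) <- dim(x)
  y
}
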