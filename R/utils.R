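#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomized routines in the package draw from named sub-streams so
#' that adding a new random component never shifts the draws of existing
#' ones. The mapping is a simple deterministic hash of the stream name
#' folded into the master seed, kept within the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param name character stream name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name),
            length(name) == 1L)
  codes <- utf8ToInt(name)
  h <- 0
  for (i in seq_along(codes)) {
    h <- (h * 131 + codes[i] * i) %% 2147483647
  }
  as.integer((abs(master) %% 2147483647 * 48271 + h) %% 2147483647)
}

# clamp numeric values into [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# row-wise Euclidean norms of a matrix
.row_norms <- function(x) sqrt(rowSums(x^2))

# full pairwise Euclidean distance matrix between rows of x and rows of y
.cross_dist <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  sqrt(pmax(d2, 0))
}

# within-sample pairwise distances; the diagonal is exactly zero rather
# than the square root of floating-point residue
.self_dist <- function(x) {
  d <- .cross_dist(x, x)
  diag(d) <- 0
  d
}

.stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
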