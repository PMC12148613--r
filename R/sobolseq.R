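# Sobol' low-discrepancy sequence (Gray-code construction, Joe-Kuo
# direction numbers for the first 20 dimensions).  Used as the quasi-random
# sampler option for global sensitivity analysis; the Latin-hypercube sampler
# handles high-dimensional designs.

.sobol_dirtab <- list(
  # each entry: list(a = polynomial coefficient, m = initial direction nums)
  list(a = 0, m = c(1)),
  list(a = 1, m = c(1, 3)),
  list(a = 1, m = c(1, 3, 1)),
  list(a = 2, m = c(1, 1, 1)),
  list(a = 1, m = c(1, 1, 3, 3)),
  list(a = 4, m = c(1, 3, 5, 13)),
  list(a = 2, m = c(1, 1, 5, 5, 17)),
  list(a = 4, m = c(1, 1, 5, 5, 5)),
  list(a = 7, m = c(1, 1, 7, 11, 19)),
  list(a = 11, m = c(1, 1, 5, 1, 1)),
  list(a = 13, m = c(1, 1, 1, 3, 11)),
  list(a = 14, m = c(1, 3, 5, 5, 31)),
  list(a = 1, m = c(1, 3, 3, 9, 7, 49)),
  list(a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(a = 16, m = c(1, 3, 1, 13, 27, 49)),
  list(a = 19, m = c(1, 1, 1, 15, 7, 5)),
  list(a = 22, m = c(1, 3, 1, 15, 13, 25)),
  list(a = 25, m = c(1, 1, 5, 5, 19, 61)),
  list(a = 1, m = c(1, 3, 7, 11, 23, 15, 103)))

#' Sobol' quasi-random sequence
#'
#' Generates \code{n} points of the (unscrambled) Sobol' sequence in
#' \code{dim} dimensions, optionally discarding the first \code{skip} points
#' and then leaping over \code{leap} points between successive draws (the
#' stride is therefore \code{leap + 1}, matching the convention of common
#' quasi-random toolboxes; an even leap keeps the stride odd, which
#' preserves the sequence's equidistribution).
#'
#' @param n Number of points to return.
#' @param dim Dimension (at most 20).
#' @param skip Points discarded from the start of the sequence (default 0).
#' @param leap Points omitted between successive draws (default 0).
#' @return An \code{n x dim} matrix in [0, 1).
#' @export
sobol_sequence <- function(n, dim, skip = 0, leap = 0) {
  if (dim > length(.sobol_dirtab) + 1)
    stop("dimension ", dim, " exceeds the sequence capacity of ",
         length(.sobol_dirtab) + 1)
  leap <- leap + 1  # stride
  n_total <- skip + n * leap
  nbits <- max(ceiling(log2(n_total + 1)), 1)
  # direction integers V[bit, dim] scaled to 2^nbits
  V <- matrix(0, nrow = nbits, ncol = dim)
  V[, 1] <- bitwShiftL(1L, nbits - seq_len(nbits))  # van der Corput
  if (dim > 1) for (j in 2:dim) {
    e <- .sobol_dirtab[[j - 1]]
    s <- length(e$m)
    m <- as.integer(e$m)
    if (nbits > s) for (i in (s + 1):nbits) {
      newm <- bitwXor(m[i - s], bitwShiftL(m[i - s], s))
      if (s >= 2) for (k in 1:(s - 1))
        if (bitwAnd(bitwShiftR(e$a, s - 1 - k), 1L) == 1L)
          newm <- bitwXor(newm, bitwShiftL(m[i - k], k))
      m <- c(m, newm)
    }
    V[, j] <- bitwShiftL(m[seq_len(nbits)], nbits - seq_len(nbits))
  }
  X <- integer(dim)
  out <- matrix(0, nrow = n, ncol = dim)
  keep <- 0L
  # Gray-code order: point i uses direction of lowest zero bit of i-1;
  # index 0 is the origin (all zeros)
  idx <- seq.int(skip, n_total - 1)
  take <- (idx - skip) %% leap == 0
  for (i in seq_len(n_total)) {
    if (i - 1 >= skip && take[i - skip]) {
      keep <- keep + 1L
      out[keep, ] <- X / 2^nbits
      if (keep == n) break
    }
    c0 <- 1L
    ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c0 <- c0 + 1L }
    X <- bitwXor(X, V[c0, ])
  }
  out
}
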