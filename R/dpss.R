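#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal commuting matrix (Percival &
#' Walden formulation), which is numerically stable and exact to machine
#' precision for the short windows used here (<= 256 samples). Tapers are
#' normalized to unit energy; even-order tapers are sign-fixed to have a
#' positive mean.
#'
#' @param n window length, samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (k < 2*nw for good concentration).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  if (k >= 2 * nw) warning("k >= 2*nw: highest tapers poorly concentrated")
  w <- nw / n
  i <- seq_len(n) - 1
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  h <- e$vectors[, seq_len(k), drop = FALSE]
  h <- sweep(h, 2, sqrt(colSums(h^2)), "/")
  for (j in seq_len(k)) if (sum(h[, j]) < 0) h[, j] <- -h[, j]
  h
}
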