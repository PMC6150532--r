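#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the symmetric tridiagonal eigenproblem whose
#' eigenvectors are the tapers (the standard commuting-matrix construction).
#' Tapers are normalized to unit energy; results are cached per (n, k, nw).
#'
#' @param n taper length in samples.
#' @param k number of tapers (default 5).
#' @param nw time-bandwidth product (default 3).
#' @return `n` x `k` matrix, one taper per column, ordered by decreasing
#'   spectral concentration.
#' @export
dpss_tapers <- local({
  cache <- new.env(parent = emptyenv())
  function(n, k = 5, nw = 3) {
    key <- paste(n, k, nw, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (k >= 2 * nw) {
      warning("k >= 2*nw: trailing tapers are poorly concentrated")
    }
    w <- nw / n
    t <- 0:(n - 1)
    diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
    diag_off <- (t[-1] * (n - t[-1])) / 2
    m <- diag(diag_main)
    m[cbind(1:(n - 1), 2:n)] <- diag_off
    m[cbind(2:n, 1:(n - 1))] <- diag_off
    eg <- eigen(m, symmetric = TRUE)
    h <- eg$vectors[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      h[, j] <- h[, j] / sqrt(sum(h[, j]^2))
      s <- sum(h[, j])
      if (abs(s) > 1e-10) {
        if (s < 0) h[, j] <- -h[, j]          # symmetric: positive mean
      } else if (h[2, j] < 0) {
        h[, j] <- -h[, j]                     # antisymmetric: positive rise
      }
    }
    cache[[key]] <- h
    h
  }
})
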