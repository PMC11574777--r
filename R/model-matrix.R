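# Full second-order model matrix on normalized dose codes.
# X01: n x k matrix with entries in [0, 1] (coded levels {0,1,2} / 2).
# Column order: intercept, k linear, k quadratic, k(k-1)/2 pairwise
# interactions in (i < j) row-major order. This ordering is relied on by
# fit_quadratic_surface() and the coefficient accessors.
quad_model_matrix <- function(X01) {
  X01 <- as.matrix(X01)
  n <- nrow(X01); k <- ncol(X01)
  p <- 1L + 2L * k + (k * (k - 1L)) %/% 2L
  M <- matrix(0, n, p)
  M[, 1L] <- 1
  M[, 2L:(k + 1L)] <- X01
  M[, (k + 2L):(2L * k + 1L)] <- X01 * X01
  col <- 2L * k + 1L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      col <- col + 1L
      M[, col] <- X01[, i] * X01[, j]
    }
  }
  M
}

# Names matching quad_model_matrix() columns, given drug names.
quad_term_names <- function(drugs) {
  k <- length(drugs)
  pairs <- character(0)
  if (k >= 2L)
    for (i in seq_len(k - 1L))
      for (j in (i + 1L):k)
        pairs <- c(pairs, paste0(drugs[i], ":", drugs[j]))
  c("(Intercept)", drugs, paste0(drugs, "^2"), pairs)
}

# coded levels {0,1,2} -> numeric regression inputs {0, 0.5, 1}
codes_to_numeric <- function(codes) as.matrix(codes) / 2
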