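# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's vectorized prediction path: scoring is done by explicit scalar
# loops over the polynomial terms.

# a design object holding the full 3^k factorial (for small-k exact fits)
make_grid_design <- function(k, drugs = sprintf("d%d", seq_len(k))) {
  codes <- as.matrix(expand.grid(rep(list(0:2), k)))
  dimnames(codes) <- NULL
  storage.mode(codes) <- "integer"
  colnames(codes) <- drugs
  structure(list(codes = codes, portion = rep("three_level", nrow(codes)),
                 drugs = drugs, k = as.integer(k)),
            class = "qpop_design")
}

# two-drug reference surface used across fitting/prediction tests:
# y = 1 - 0.3 x1 - 0.2 x2 + 0.05 x1^2 + 0 x2^2 - 0.15 x1 x2
toy_truth2 <- function() {
  qpopr:::new_qpop_surface(c("A", "B"), beta0 = 1,
                           beta_lin = c(-0.3, -0.2),
                           beta_quad = c(0.05, 0),
                           beta_int = -0.15)
}

# scalar brute-force scorer: predicted NCV of one coded level vector
brute_score_one <- function(surface, lv) {
  k <- surface$k
  x <- lv / 2
  y <- surface$beta0
  for (i in seq_len(k))
    y <- y + surface$beta_lin[[i]] * x[i] + surface$beta_quad[[i]] * x[i]^2
  idx <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      idx <- idx + 1L
      y <- y + surface$beta_int[[idx]] * x[i] * x[j]
    }
  }
  unname(y)
}

# brute-force full ranking: score every vector, sort by (score, lexicographic)
brute_ranking <- function(surface) {
  k <- surface$k
  grid <- as.matrix(expand.grid(rep(list(0:2), k)))
  scores <- apply(grid, 1L, function(lv) brute_score_one(surface, lv))
  ord <- do.call(order, c(list(scores),
                          lapply(seq_len(k), function(j) grid[, j])))
  list(codes = unname(grid[ord, , drop = FALSE]), scores = scores[ord])
}

# random surface with coefficients of plausible magnitude
random_surface <- function(k, seed) {
  set.seed(seed)
  qpopr:::new_qpop_surface(
    sprintf("d%d", seq_len(k)),
    beta0 = 1,
    beta_lin = stats::runif(k, -0.6, -0.1),
    beta_quad = stats::rnorm(k, 0, 0.05),
    beta_int = stats::rnorm((k * (k - 1L)) %/% 2L, 0, 0.1))
}

# plate with exactly the supplied per-role signal vectors
make_plate <- function(design_signals, neg, pos = numeric(0),
                       design_rows = seq_along(design_signals)) {
  n_d <- length(design_signals); n_n <- length(neg); n_p <- length(pos)
  qpop_plate(data.frame(
    well = sprintf("W%03d", seq_len(n_d + n_n + n_p)),
    signal = c(design_signals, neg, pos),
    role = rep(c("design", "negative_control", "positive_control"),
               c(n_d, n_n, n_p)),
    design_row = c(design_rows, rep(NA_integer_, n_n + n_p)),
    replicate = 1L,
    stringsAsFactors = FALSE))
}

# k-drug panel + config for small synthetic scenarios (no named synergies)
small_config <- function(k, ...) {
  drugs <- sprintf("d%d", seq_len(k))
  doses <- cbind(0, seq_len(k) * 1e-7, seq_len(k) * 2e-7)
  qpop_sim_config(panel = qpop_panel(drugs, doses),
                  synergy_pairs = list(),
                  regimens = list(drugs[1:2]), regimen_probs = 1, ...)
}

# full-enumeration Fisher oracle: sum of hypergeometric probabilities not
# exceeding that of the observed table (fixed margins)
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(a, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# pair-counting AUC oracle: P(score_resp < score_non) + 0.5 P(equal)
auc_oracle <- function(scores, labels) {
  labels <- collapse_clinical(labels)
  resp <- scores[labels == "response"]
  non <- scores[labels == "no_response"]
  tot <- 0
  for (a in resp) for (b in non) tot <- tot + (a < b) + 0.5 * (a == b)
  tot / (length(resp) * length(non))
}
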