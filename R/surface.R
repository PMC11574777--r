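# Patient-specific quadratic response surface.
#
# The fitted model is the full second-order polynomial on normalized dose
# codes x_i in {0, 0.5, 1} (coded levels {0,1,2} / 2):
#
#   yhat(x) = b0 + sum_i b_i x_i + sum_i b_ii x_i^2 + sum_{i<j} b_ij x_i x_j
#
# where y is normalized cell viability. Negative linear coefficients mean
# single-agent efficacy; negative interaction coefficients mean synergy.
# Coefficients are estimated by ordinary least squares from the OACD runs
# (155 runs >= 91 terms at k = 12); adjusted R^2 summarizes model robustness.

new_qpop_surface <- function(drugs, beta0, beta_lin, beta_quad, beta_int,
                             adj_r2 = NA_real_, r2 = NA_real_,
                             n_obs = NA_integer_, sigma = NA_real_) {
  k <- length(drugs)
  stopifnot(length(beta_lin) == k, length(beta_quad) == k,
            length(beta_int) == (k * (k - 1L)) %/% 2L)
  pair_names <- quad_term_names(drugs)[-(1:(2 * k + 1))]
  structure(list(drugs = drugs, k = k,
                 beta0 = as.numeric(beta0),
                 beta_lin = stats::setNames(as.numeric(beta_lin), drugs),
                 beta_quad = stats::setNames(as.numeric(beta_quad), drugs),
                 beta_int = stats::setNames(as.numeric(beta_int), pair_names),
                 adj_r2 = adj_r2, r2 = r2,
                 n_obs = as.integer(n_obs), sigma = sigma),
            class = "qpop_surface")
}

#' Fit the quadratic response surface to normalized plate data
#'
#' Ordinary least-squares fit of the full second-order model (intercept, k
#' linear, k quadratic and k(k-1)/2 pairwise interaction terms — 91 terms for
#' k = 12) on the numeric dose codes {0, 0.5, 1}. The design must make the
#' model identifiable: at least as many observations as coefficients and a
#' full-rank model matrix, both checked before fitting.
#'
#' @param design a \code{\link{qpop_design}}.
#' @param response a \code{qpop_ncv} table (matched to design rows by
#'   \code{design_row}) or a numeric vector of NCV values, one per design
#'   row in order.
#' @return An object of class \code{qpop_surface} with elements
#'   \code{beta0}, \code{beta_lin}, \code{beta_quad}, \code{beta_int}
#'   (named by drug / drug pair), \code{adj_r2}, \code{r2}, \code{n_obs},
#'   \code{sigma}.
#' @export
fit_quadratic_surface <- function(design, response) {
  stopifnot(inherits(design, "qpop_design"))
  n <- nrow(design$codes)
  if (inherits(response, "qpop_ncv") || is.data.frame(response)) {
    if (!all(c("design_row", "ncv") %in% names(response)))
      stop("response table needs columns 'design_row' and 'ncv'")
    m <- match(seq_len(n), response$design_row)
    if (anyNA(m))
      stop("response lacks NCV for design row(s): ",
           paste(which(is.na(m)), collapse = ", "))
    y <- as.numeric(response$ncv[m])
  } else {
    y <- as.numeric(response)
    if (length(y) != n)
      stop("response length ", length(y), " != design rows ", n)
  }
  if (any(!is.finite(y))) stop("non-finite NCV values in response")
  k <- design$k
  p <- 1L + 2L * k + (k * (k - 1L)) %/% 2L
  if (n < p)
    stop("unidentifiable fit: ", n, " observations for ", p, " coefficients")
  M <- quad_model_matrix(codes_to_numeric(design$codes))
  qrM <- qr(M)
  if (qrM$rank < p)
    stop("model matrix is rank-deficient (rank ", qrM$rank, " < ", p,
         "); check the design for duplicated or collinear runs")
  beta <- qr.coef(qrM, y)
  fitted <- drop(M %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  # p - 1 non-intercept terms
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  sigma <- sqrt(rss / (n - p))
  new_qpop_surface(design$drugs,
                   beta0 = beta[1L],
                   beta_lin = beta[2L:(k + 1L)],
                   beta_quad = beta[(k + 2L):(2L * k + 1L)],
                   beta_int = beta[(2L * k + 2L):p],
                   adj_r2 = adj_r2, r2 = r2, n_obs = n, sigma = sigma)
}

# flat coefficient vector in quad_model_matrix() column order
.surface_beta <- function(model) {
  c(model$beta0, model$beta_lin, model$beta_quad, model$beta_int)
}

# predict over an n x k matrix of numeric codes in [0,1], without forming
# the full model matrix (the interaction block would dominate memory at
# 3^12 rows)
.predict_x01 <- function(model, X01) {
  k <- model$k
  y <- model$beta0 +
    drop(X01 %*% model$beta_lin) +
    drop((X01 * X01) %*% model$beta_quad)
  idx <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      idx <- idx + 1L
      b <- model$beta_int[[idx]]
      if (b != 0) y <- y + b * (X01[, i] * X01[, j])
    }
  }
  y
}

#' Predict NCV for coded dose-level combinations
#'
#' Evaluates the fitted quadratic surface at coded levels (0 = absent,
#' 1 = low, 2 = high dose). Deterministic; the all-zero vector returns the
#' untreated baseline (the intercept).
#'
#' @param model a \code{qpop_surface}.
#' @param levels integer vector of length k with entries in {0,1,2}, or a
#'   matrix with k columns (one combination per row).
#' @return predicted NCV value(s), unclipped.
#' @export
predict_ncv <- function(model, levels) {
  stopifnot(inherits(model, "qpop_surface"))
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  levels <- as.matrix(levels)
  if (ncol(levels) != model$k)
    stop("'levels' must have k = ", model$k, " entries per combination")
  if (!all(levels %in% 0:2))
    stop("coded levels must be 0, 1 or 2")
  drop(.predict_x01(model, levels / 2))
}

#' @export
print.qpop_surface <- function(x, ...) {
  cat("qpop_surface:", x$k, "drugs,",
      1 + 2 * x$k + x$k * (x$k - 1) / 2, "coefficients\n")
  if (!is.na(x$adj_r2))
    cat(sprintf("  fit: n_obs = %d, R^2 = %.4f, adj R^2 = %.4f\n",
                x$n_obs, x$r2, x$adj_r2))
  cat("  untreated baseline (intercept):", format(x$beta0, digits = 4), "\n")
  invisible(x)
}

#' Serialize / restore a fitted surface as JSON
#'
#' Coefficients are keyed by drug name and drug pair so serialized models are
#' self-describing and portable across sessions.
#'
#' @param model a \code{qpop_surface}.
#' @param path output path.
#' @return \code{path} (write) or the restored \code{qpop_surface} (read).
#' @export
write_surface_json <- function(model, path) {
  stopifnot(inherits(model, "qpop_surface"))
  jsonlite::write_json(list(
    drugs = model$drugs,
    intercept = model$beta0,
    linear = as.list(model$beta_lin),
    quadratic = as.list(model$beta_quad),
    interaction = as.list(model$beta_int),
    diagnostics = list(adj_r2 = model$adj_r2, r2 = model$r2,
                       n_obs = model$n_obs, sigma = model$sigma)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_surface_json
#' @export
read_surface_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$diagnostics
  new_qpop_surface(obj$drugs, obj$intercept,
                   unlist(obj$linear), unlist(obj$quadratic),
                   unlist(obj$interaction),
                   adj_r2 = .null_na(d$adj_r2), r2 = .null_na(d$r2),
                   n_obs = if (is.null(d$n_obs) || is.na(d$n_obs))
                     NA_integer_ else as.integer(d$n_obs),
                   sigma = .null_na(d$sigma))
}

.null_na <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) NA_real_ else as.numeric(x)
}
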