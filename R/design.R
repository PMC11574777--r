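# Orthogonal-array composite design (OACD) construction.
#
# The design concatenates (i) a two-level fractional factorial at the extreme
# levels {absent, high} = coded {0, 2}, of resolution >= IV, with (ii) a
# three-level orthogonal array (9-run for k <= 4, 27-run for 5 <= k <= 13)
# adding the center level, so that the full quadratic response-surface model
# (1 + 2k + k(k-1)/2 terms) is estimable from few runs. For the 12-drug panel
# this gives 128 + 27 = 155 test combinations and a 91-term model.

# Stored generator sets for the two-level portion. Each generator is a set of
# base-column indices whose product defines one added column. All base words
# have odd length >= 3 and are distinct, which forces every word of the
# defining relation to have even length >= 4, i.e. resolution >= IV; this is
# re-verified computationally on every build rather than assumed. The
# specific sets (and the three-level column assignments below) were screened
# so that the combined design's quadratic model matrix has full column rank.
.ff_table <- list(
  `5`  = list(base = 4L, gens = list(c(1L, 2L, 3L, 4L))),  # resolution V
  `6`  = list(base = 4L, gens = list(c(1L, 2L, 3L), c(1L, 2L, 4L))),
  `7`  = list(base = 4L, gens = list(c(1L, 2L, 3L), c(1L, 2L, 4L),
                                     c(1L, 3L, 4L))),
  `8`  = list(base = 5L, gens = list(c(1L, 2L, 3L), c(1L, 4L, 5L),
                                     c(1L, 2L, 3L, 4L, 5L))),
  `9`  = list(base = 6L, gens = list(c(1L, 3L, 4L, 5L, 6L), c(2L, 3L, 4L),
                                     c(2L, 3L, 5L))),
  `10` = list(base = 6L, gens = list(c(1L, 2L, 3L), c(1L, 4L, 5L),
                                     c(2L, 4L, 6L), c(3L, 5L, 6L))),
  `11` = list(base = 7L, gens = list(c(1L, 3L, 4L, 6L, 7L),
                                     c(2L, 3L, 5L, 6L, 7L),
                                     c(1L, 2L, 6L),
                                     c(1L, 2L, 4L, 5L, 7L))),
  `12` = list(base = 7L, gens = list(c(3L, 4L, 6L), c(2L, 4L, 5L),
                                     c(1L, 4L, 5L, 6L, 7L),
                                     c(1L, 2L, 3L, 4L, 6L),
                                     c(1L, 2L, 5L, 6L, 7L))),
  `13` = list(base = 8L, gens = list(c(1L, 4L, 5L, 6L, 8L),
                                     c(1L, 2L, 5L, 6L, 7L),
                                     c(2L, 4L, 8L), c(3L, 6L, 7L),
                                     c(1L, 2L, 3L, 4L, 6L, 7L, 8L))),
  `14` = list(base = 7L, gens = list(c(1L, 2L, 3L), c(1L, 2L, 4L),
                                     c(1L, 3L, 4L), c(2L, 3L, 4L),
                                     c(1L, 2L, 5L), c(1L, 3L, 5L),
                                     c(2L, 3L, 5L))),
  `15` = list(base = 7L, gens = list(c(1L, 2L, 3L), c(1L, 2L, 4L),
                                     c(1L, 3L, 4L), c(2L, 3L, 4L),
                                     c(1L, 2L, 5L), c(1L, 3L, 5L),
                                     c(2L, 3L, 5L), c(2L, 4L, 5L))),
  `16` = list(base = 7L, gens = list(c(1L, 2L, 3L), c(1L, 2L, 4L),
                                     c(1L, 3L, 4L), c(2L, 3L, 4L),
                                     c(1L, 2L, 5L), c(1L, 3L, 5L),
                                     c(2L, 3L, 5L), c(2L, 4L, 5L),
                                     c(3L, 4L, 5L)))
)

# Assignment of 27-run array columns to drugs, where the default 1..k
# assignment left the combined quadratic model matrix rank-deficient.
.oa27_columns <- list(
  `9`  = c(1L, 2L, 7L, 12L, 3L, 13L, 5L, 11L, 10L),
  `11` = c(8L, 5L, 6L, 13L, 1L, 3L, 2L, 10L, 11L, 9L, 4L),
  `12` = c(12L, 8L, 7L, 6L, 9L, 3L, 13L, 2L, 5L, 1L, 10L, 4L),
  `13` = c(4L, 3L, 10L, 12L, 9L, 1L, 13L, 2L, 6L, 11L, 8L, 5L, 7L)
)

# full two-level factorial in -1/+1 coding, standard (Yates) column order
.ff_base <- function(m) {
  n <- 2L^m
  M <- matrix(0L, n, m)
  for (j in seq_len(m))
    M[, j] <- rep(rep(c(-1L, 1L), each = 2L^(j - 1L)), length.out = n)
  M
}

#' Two-level fractional-factorial portion of the OACD
#'
#' Builds a two-level design at the extreme coded levels {0, 2} (drug absent /
#' highest tested dose). For k <= 4 a full factorial is returned; for
#' 5 <= k <= 16 a stored resolution->=IV fractional factorial is used
#' (for k = 12: a 2^(12-5) = 128-run fraction). Resolution >= IV — no main
#' effect aliased with any two-factor interaction — is verified
#' computationally on every call, never assumed.
#'
#' @param k number of drugs (factors), 2 <= k <= 16.
#' @return integer matrix (runs x k) with entries in {0, 2} and attribute
#'   \code{portion = "two_level"}.
#' @export
#' @examples
#' nrow(build_two_level_fraction(12))  # 128
build_two_level_fraction <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 16L)
    stop("no two-level design available for k = ", k,
         " (supported: 2 <= k <= 16)")
  if (k <= 4L) {
    X <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), k)))
    dimnames(X) <- NULL
  } else {
    cfg <- .ff_table[[as.character(k)]]
    B <- .ff_base(cfg$base)
    G <- vapply(cfg$gens,
                function(g) as.integer(apply(B[, g, drop = FALSE], 1L, prod)),
                integer(nrow(B)))
    X <- cbind(B, G)
  }
  if (!.is_resolution_iv(X))
    stop("internal error: stored generator set for k = ", k,
         " failed the resolution-IV alias check")  # nocov
  codes <- X + 1L  # -1/+1 -> 0/2
  storage.mode(codes) <- "integer"
  attr(codes, "portion") <- "two_level"
  codes
}

# TRUE iff: all columns distinct/orthogonal and no main effect is aliased
# with any two-factor interaction (exhaustive check over all k*k*(k-1)/2
# main-by-interaction inner products on the -1/+1 matrix).
.is_resolution_iv <- function(X) {
  k <- ncol(X); n <- nrow(X)
  XtX <- crossprod(X)
  if (any(abs(XtX[upper.tri(XtX)]) > 0)) return(FALSE)  # res >= III + distinct
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      fi <- X[, i] * X[, j]
      if (any(abs(crossprod(X, fi)) == n)) return(FALSE)
    }
  }
  TRUE
}

# the two standard three-level orthogonal arrays, built over GF(3):
# 9 runs x 4 columns (strength 2) and 27 runs x 13 columns (strength 2)
.oa9 <- function() {
  g <- as.matrix(expand.grid(a = 0:2, b = 0:2))
  co <- list(c(1, 0), c(0, 1), c(1, 1), c(1, 2))
  X <- vapply(co, function(v) as.integer((g %*% v) %% 3), integer(9))
  dimnames(X) <- NULL
  X
}

.oa27 <- function() {
  g <- as.matrix(expand.grid(a = 0:2, b = 0:2, c = 0:2))
  co <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, 2, 0),
             c(1, 0, 1), c(1, 0, 2), c(0, 1, 1), c(0, 1, 2), c(1, 1, 1),
             c(1, 1, 2), c(1, 2, 1), c(1, 2, 2))
  X <- vapply(co, function(v) as.integer((g %*% v) %% 3), integer(27))
  dimnames(X) <- NULL
  X
}

#' Three-level orthogonal-array portion of the OACD
#'
#' Returns the smallest standard three-level orthogonal array accommodating k
#' columns: the 9-run array for k <= 4, the 27-run array for 5 <= k <= 13.
#' Every column carries each level n/3 times and every column pair carries
#' each of the 9 level pairs n/9 times (strength 2); this balance is verified
#' on every call.
#'
#' @param k number of drugs (factors), 2 <= k <= 13.
#' @return integer matrix (9 or 27 rows x k) with entries in {0, 1, 2} and
#'   attribute \code{portion = "three_level"}.
#' @export
#' @examples
#' nrow(build_three_level_oa(12))  # 27
build_three_level_oa <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 13L)
    stop("no three-level orthogonal array available for k = ", k,
         " (supported: 2 <= k <= 13)")
  if (k <= 4L) {
    X <- .oa9()[, seq_len(k), drop = FALSE]
  } else {
    cols <- .oa27_columns[[as.character(k)]]
    if (is.null(cols)) cols <- seq_len(k)
    X <- .oa27()[, cols, drop = FALSE]
  }
  if (!.is_balanced_oa(X))
    stop("internal error: three-level array for k = ", k,
         " failed the strength-2 balance check")  # nocov
  attr(X, "portion") <- "three_level"
  X
}

# strength-2 balance: levels equifrequent per column, pairs equifrequent per
# column pair
.is_balanced_oa <- function(X) {
  n <- nrow(X); k <- ncol(X)
  for (j in seq_len(k))
    if (!all(tabulate(X[, j] + 1L, 3L) == n / 3)) return(FALSE)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        tab <- table(factor(X[, i], 0:2), factor(X[, j], 0:2))
        if (!all(tab == n / 9)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Generate the orthogonal-array composite design
#'
#' Concatenates the two-level fractional-factorial portion (extreme levels)
#' with the three-level orthogonal-array portion (adds the center level) and
#' verifies that the full quadratic model is estimable: the
#' (1 + 2k + k(k-1)/2)-column second-order model matrix of the combined
#' design has full column rank. For k = 12 the design has 128 + 27 = 155
#' rows and supports the 91-term model. Output is deterministic for fixed k.
#'
#' @param k number of drugs, 2 <= k <= 13.
#' @param drugs optional character vector of k drug names used as column
#'   names (defaults to \code{drug01 ... drugk}).
#' @return An object of class \code{qpop_design}: list with \code{codes}
#'   (rows x k integer matrix, entries {0,1,2}), \code{portion} (per-row
#'   \code{"two_level"}/\code{"three_level"}), \code{drugs} and \code{k}.
#' @export
#' @examples
#' d <- generate_oacd(3)
#' nrow(d$codes)  # 8 + 9 = 17
generate_oacd <- function(k, drugs = NULL) {
  two <- build_two_level_fraction(k)
  three <- build_three_level_oa(k)
  codes <- rbind(two, three)
  portion <- rep(c("two_level", "three_level"), c(nrow(two), nrow(three)))
  if (is.null(drugs)) drugs <- sprintf("drug%02d", seq_len(k))
  if (length(drugs) != k) stop("'drugs' must have length k = ", k)
  colnames(codes) <- drugs
  p <- 1L + 2L * k + (k * (k - 1L)) %/% 2L
  rk <- qr(quad_model_matrix(codes_to_numeric(codes)))$rank
  if (rk < p)
    stop("combined design is rank-deficient for the quadratic model (rank ",
         rk, " < ", p, ")")  # nocov
  structure(list(codes = codes, portion = portion, drugs = drugs,
                 k = as.integer(k)),
            class = "qpop_design")
}

#' @export
print.qpop_design <- function(x, ...) {
  cat("qpop_design: OACD with", nrow(x$codes), "runs x", x$k, "drugs (",
      sum(x$portion == "two_level"), "two-level +",
      sum(x$portion == "three_level"), "three-level )\n")
  invisible(x)
}

#' Map coded design levels to concentrations
#'
#' Coded level 0 maps to concentration 0 (drug absent), level 1 to the low
#' and level 2 to the high tested concentration of each drug. Dose caps
#' (high dose <= min(10% Cmax, IC10)) are re-validated.
#'
#' @param design a \code{\link{qpop_design}}.
#' @param panel a \code{\link{qpop_panel}} with the same number of drugs.
#' @return numeric matrix (rows x k) of molar concentrations, with the
#'   panel's drug names as column names.
#' @export
map_levels_to_doses <- function(design, panel) {
  stopifnot(inherits(design, "qpop_design"), inherits(panel, "qpop_panel"))
  if (design$k != panel$k)
    stop("design has ", design$k, " columns but panel has ", panel$k,
         " drugs")
  cap <- pmin(0.10 * panel$cmax, panel$ic10, na.rm = TRUE)
  cap[is.na(panel$cmax) & is.na(panel$ic10)] <- NA_real_
  bad <- which(!is.na(cap) & panel$doses[, 3] > cap * (1 + 1e-12))
  if (length(bad))
    stop("dose cap violation: drug(s) ",
         paste(panel$drugs[bad], collapse = ", "),
         " exceed min(10% Cmax, IC10)")
  conc <- vapply(seq_len(panel$k),
                 function(j) panel$doses[j, design$codes[, j] + 1L],
                 numeric(nrow(design$codes)))
  colnames(conc) <- panel$drugs
  conc
}

#' Export / import a design as delimited text
#'
#' The CSV holds one test combination per row: \code{row}, \code{portion},
#' one coded-level column per drug, and (when a panel is supplied) one
#' mapped-concentration column per drug. A JSON sidecar
#' (\code{<path>.json}) records k, drug names, portion sizes and the dose
#' table so a design file is self-describing.
#'
#' @param design a \code{\link{qpop_design}}.
#' @param path output CSV path.
#' @param panel optional \code{\link{qpop_panel}}; adds concentration columns
#'   and dose metadata.
#' @return \code{path}, invisibly.
#' @export
write_design_csv <- function(design, path, panel = NULL) {
  stopifnot(inherits(design, "qpop_design"))
  df <- data.frame(row = seq_len(nrow(design$codes)),
                   portion = design$portion,
                   design$codes, check.names = FALSE)
  meta <- list(k = design$k, drugs = design$drugs,
               n_two_level = sum(design$portion == "two_level"),
               n_three_level = sum(design$portion == "three_level"))
  if (!is.null(panel)) {
    conc <- map_levels_to_doses(design, panel)
    colnames(conc) <- paste0(panel$drugs, "_conc")
    df <- cbind(df, conc)
    meta$doses <- as.data.frame(panel$doses)
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_design_csv
#' @return for \code{read_design_csv}: the reconstructed
#'   \code{\link{qpop_design}}.
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".json")
  drugs <- if (file.exists(meta_path)) {
    unlist(jsonlite::read_json(meta_path)$drugs)
  } else {
    setdiff(names(df), c("row", "portion"))
  }
  drugs <- drugs[drugs %in% names(df)]
  codes <- as.matrix(df[, drugs, drop = FALSE])
  storage.mode(codes) <- "integer"
  if (!all(codes %in% 0:2)) stop("design file contains codes outside {0,1,2}")
  structure(list(codes = codes, portion = as.character(df$portion),
                 drugs = drugs, k = length(drugs)),
            class = "qpop_design")
}
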