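#' Define a drug panel
#'
#' A drug panel is the fixed set of drugs screened on every plate, each at
#' three dose levels: level 0 is always "drug absent" (concentration 0), and
#' levels 1 and 2 are the low and high tested concentrations. The high
#' concentration is capped at 10% of the maximum serum concentration
#' (\code{cmax}) or at the IC10, whichever is lower, so that ex vivo dosing
#' stays clinically achievable and no drug dominates the screen.
#'
#' @param drugs character vector of drug identifiers (length k >= 2).
#' @param doses numeric matrix (k x 3) of molar concentrations, one row per
#'   drug, strictly increasing within each row, first column all zero.
#' @param cmax optional numeric vector of per-drug maximum serum
#'   concentrations (molar); \code{NA} where unknown.
#' @param ic10 optional numeric vector of per-drug IC10 concentrations
#'   (molar); \code{NA} where unknown.
#'
#' @return An object of class \code{qpop_panel}: a list with elements
#'   \code{drugs}, \code{doses}, \code{cmax}, \code{ic10} and \code{k}.
#' @export
#' @examples
#' qpop_panel(c("drugA", "drugB"),
#'            doses = rbind(c(0, 1e-7, 2e-7), c(0, 5e-8, 1e-7)))
qpop_panel <- function(drugs, doses, cmax = NULL, ic10 = NULL) {
  drugs <- as.character(drugs)
  k <- length(drugs)
  if (k < 2L) stop("a drug panel needs at least 2 drugs")
  if (anyDuplicated(drugs)) stop("duplicate drug names in panel")
  doses <- as.matrix(doses)
  if (!is.numeric(doses) || nrow(doses) != k || ncol(doses) != 3L)
    stop("'doses' must be a numeric k x 3 matrix (k = ", k, ")")
  if (any(doses[, 1] != 0))
    stop("dose level 0 must be concentration 0 (drug absent) for every drug")
  if (any(doses[, 2] <= 0) || any(doses[, 3] <= doses[, 2]))
    stop("doses must be strictly increasing within each drug")
  if (is.null(cmax)) cmax <- rep(NA_real_, k)
  if (is.null(ic10)) ic10 <- rep(NA_real_, k)
  if (length(cmax) != k || length(ic10) != k)
    stop("'cmax' and 'ic10' must have one entry per drug")
  cap <- pmin(0.10 * cmax, ic10, na.rm = TRUE)
  cap[is.na(cmax) & is.na(ic10)] <- NA_real_
  bad <- which(!is.na(cap) & doses[, 3] > cap * (1 + 1e-12))
  if (length(bad))
    stop("top dose exceeds 10% Cmax / IC10 cap for drug(s): ",
         paste(drugs[bad], collapse = ", "))
  rownames(doses) <- drugs
  colnames(doses) <- c("level0", "level1", "level2")
  structure(list(drugs = drugs, doses = doses,
                 cmax = stats::setNames(as.numeric(cmax), drugs),
                 ic10 = stats::setNames(as.numeric(ic10), drugs),
                 k = k),
            class = "qpop_panel")
}

#' Read a drug panel from a YAML configuration file
#'
#' The file holds a top-level \code{drugs:} sequence; each entry has
#' \code{name}, \code{doses} (the two nonzero concentrations, ascending,
#' molar) and optionally \code{cmax} and \code{ic10}.
#'
#' @param path path to the YAML file.
#' @return A \code{\link{qpop_panel}}.
#' @export
read_panel_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$drugs)) stop("panel YAML must contain a 'drugs' sequence")
  nm <- vapply(cfg$drugs, function(d) as.character(d$name), "")
  dose <- t(vapply(cfg$drugs, function(d) {
    dd <- as.numeric(d$doses)
    if (length(dd) == 3L && dd[1] == 0) dd else c(0, dd[1:2])
  }, numeric(3)))
  getf <- function(field)
    vapply(cfg$drugs, function(d)
      if (is.null(d[[field]])) NA_real_ else as.numeric(d[[field]]), 0)
  qpop_panel(nm, dose, cmax = getf("cmax"), ic10 = getf("ic10"))
}

#' Write a drug panel to a YAML configuration file
#'
#' @param panel a \code{\link{qpop_panel}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_panel_yaml <- function(panel, path) {
  stopifnot(inherits(panel, "qpop_panel"))
  entries <- lapply(seq_len(panel$k), function(i) {
    e <- list(name = panel$drugs[i],
              doses = as.numeric(panel$doses[i, 2:3]))
    if (!is.na(panel$cmax[i])) e$cmax <- as.numeric(panel$cmax[i])
    if (!is.na(panel$ic10[i])) e$ic10 <- as.numeric(panel$ic10[i])
    e
  })
  yaml::write_yaml(list(drugs = entries), path)
  invisible(path)
}

#' @export
print.qpop_panel <- function(x, ...) {
  cat("qpop_panel:", x$k, "drugs at 3 levels (0 = absent)\n")
  print(data.frame(drug = x$drugs,
                   low = x$doses[, 2], high = x$doses[, 3],
                   cmax = x$cmax, ic10 = x$ic10, row.names = NULL))
  invisible(x)
}
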