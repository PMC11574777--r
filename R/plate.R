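# Plate ingestion, control normalization and assay quality control.
#
# Raw well signals (relative luminescence units from a viability assay) are
# normalized to the mean of the untreated negative-control wells on the same
# plate, giving normalized cell viability (NCV): 1 = no effect, 0 = complete
# kill. Assay quality is summarized by the Z'-factor and the strictly
# standardized mean difference (SSMD) of the positive/negative control
# separation; runs with Z' < 0.7 are excluded from downstream modelling.

.plate_roles <- c("design", "negative_control", "positive_control")

#' Construct a plate readout object
#'
#' @param wells data.frame with columns \code{well} (unique id),
#'   \code{signal} (raw RLU, finite and >= 0), \code{role} (one of
#'   \code{"design"}, \code{"negative_control"}, \code{"positive_control"}),
#'   \code{design_row} (integer row of the design for design wells, NA for
#'   controls) and optionally \code{replicate}.
#' @param n_design_rows optional expected number of design rows; when given,
#'   every design row 1..n must be covered by at least one well.
#' @return An object of class \code{qpop_plate} (the validated data.frame).
#' @export
qpop_plate <- function(wells, n_design_rows = NULL) {
  req <- c("well", "signal", "role", "design_row")
  miss <- setdiff(req, names(wells))
  if (length(miss)) stop("plate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  wells$well <- as.character(wells$well)
  if (anyDuplicated(wells$well))
    stop("duplicate well id(s): ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "))
  if (!all(wells$role %in% .plate_roles))
    stop("unknown well role(s): ",
         paste(unique(setdiff(wells$role, .plate_roles)), collapse = ", "))
  if (any(!is.finite(wells$signal)) || any(wells$signal < 0))
    stop("well signals must be finite and >= 0 (offending wells: ",
         paste(wells$well[!is.finite(wells$signal) | wells$signal < 0],
               collapse = ", "), ")")
  des <- wells$role == "design"
  if (any(des & (is.na(wells$design_row) | wells$design_row < 1)))
    stop("design wells must carry a positive design_row")
  if (sum(wells$role == "negative_control") < 2L)
    stop("at least 2 negative-control wells are required")
  if (!is.null(n_design_rows)) {
    covered <- sort(unique(wells$design_row[des]))
    missing_rows <- setdiff(seq_len(n_design_rows), covered)
    if (length(missing_rows))
      stop("design row(s) with no well: ",
           paste(missing_rows, collapse = ", "))
  }
  if (is.null(wells$replicate)) wells$replicate <- 1L
  class(wells) <- c("qpop_plate", "data.frame")
  wells
}

#' Read a plate from readout and layout files
#'
#' The readout file is delimited text with columns \code{well, signal}; the
#' layout file maps wells to roles with columns
#' \code{well, role, design_row, replicate} (design_row/replicate empty for
#' control wells). Every readout well must appear in the layout.
#'
#' @param readout_file,layout_file paths to delimited text files (comma- or
#'   tab-separated, autodetected from the extension: .tsv/.txt = tab).
#' @param n_design_rows optional coverage check, see \code{\link{qpop_plate}}.
#' @return A \code{\link{qpop_plate}}.
#' @export
read_plate <- function(readout_file, layout_file, n_design_rows = NULL) {
  readout <- .read_delim_auto(readout_file)
  layout <- .read_delim_auto(layout_file)
  if (!all(c("well", "signal") %in% names(readout)))
    stop("readout file needs columns 'well' and 'signal'")
  if (!all(c("well", "role") %in% names(layout)))
    stop("layout file needs columns 'well' and 'role'")
  readout$well <- as.character(readout$well)
  layout$well <- as.character(layout$well)
  orphan <- setdiff(readout$well, layout$well)
  if (length(orphan))
    stop("layout has no entry for well(s): ", paste(orphan, collapse = ", "))
  m <- match(readout$well, layout$well)
  wells <- data.frame(
    well = readout$well,
    signal = as.numeric(readout$signal),
    role = as.character(layout$role[m]),
    design_row = if ("design_row" %in% names(layout))
      as.integer(layout$design_row[m]) else NA_integer_,
    replicate = if ("replicate" %in% names(layout))
      as.integer(layout$replicate[m]) else 1L,
    stringsAsFactors = FALSE)
  qpop_plate(wells, n_design_rows = n_design_rows)
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

#' Normalize design wells to untreated negative controls
#'
#' Each well signal is divided by the mean negative-control signal of the
#' plate; replicate wells of the same design row are then averaged. NCV
#' values above 1 (growth relative to control) are retained, not clipped.
#'
#' @param plate a \code{\link{qpop_plate}}.
#' @return An object of class \code{qpop_ncv}: data.frame with columns
#'   \code{design_row}, \code{ncv} (mean over replicates),
#'   \code{replicate_sd} (sample SD, NA for a single well) and
#'   \code{n_wells}, sorted by design row.
#' @export
normalize_to_controls <- function(plate) {
  stopifnot(inherits(plate, "qpop_plate"))
  neg <- plate$signal[plate$role == "negative_control"]
  mu_neg <- mean(neg)
  if (!is.finite(mu_neg) || mu_neg <= .Machine$double.eps * max(1, max(neg)))
    stop("negative-control mean is zero or near zero; normalization undefined")
  des <- plate[plate$role == "design", , drop = FALSE]
  ncv_w <- des$signal / mu_neg
  agg <- split(ncv_w, des$design_row)
  out <- data.frame(
    design_row = as.integer(names(agg)),
    ncv = vapply(agg, mean, 0),
    replicate_sd = vapply(agg, function(v)
      if (length(v) > 1L) stats::sd(v) else NA_real_, 0),
    n_wells = vapply(agg, length, 0L),
    row.names = NULL)
  out <- out[order(out$design_row), , drop = FALSE]
  class(out) <- c("qpop_ncv", "data.frame")
  out
}

#' Z'-factor of the control separation
#'
#' Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|, computed on raw
#' signals with sample (n-1) standard deviations. Values near 1 indicate a
#' robust assay window; Z' <= 0 an unusable one.
#'
#' @param plate a \code{\link{qpop_plate}} with >= 2 positive-control and
#'   >= 2 negative-control wells.
#' @return a single numeric Z' value (always <= 1).
#' @export
compute_zprime <- function(plate) {
  cs <- .control_stats(plate)
  if (cs$mu_pos == cs$mu_neg)
    stop("Z' undefined: positive and negative control means are equal")
  1 - 3 * (cs$sd_pos + cs$sd_neg) / abs(cs$mu_pos - cs$mu_neg)
}

#' Strictly standardized mean difference of the control separation
#'
#' SSMD = (mean_neg - mean_pos) / sqrt(sd_neg^2 + sd_pos^2) on raw signals.
#'
#' @inheritParams compute_zprime
#' @return a single numeric SSMD value.
#' @export
compute_ssmd <- function(plate) {
  cs <- .control_stats(plate)
  denom <- sqrt(cs$sd_neg^2 + cs$sd_pos^2)
  if (denom == 0)
    stop("SSMD undefined: both control groups have zero variance")
  (cs$mu_neg - cs$mu_pos) / denom
}

.control_stats <- function(plate) {
  stopifnot(inherits(plate, "qpop_plate"))
  pos <- plate$signal[plate$role == "positive_control"]
  neg <- plate$signal[plate$role == "negative_control"]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need >= 2 positive-control and >= 2 negative-control wells")
  list(mu_pos = mean(pos), mu_neg = mean(neg),
       sd_pos = stats::sd(pos), sd_neg = stats::sd(neg))
}

#' Plate quality metrics and gate
#'
#' \code{qc_metrics} computes Z' and SSMD and applies the exclusion gate;
#' \code{qc_gate} applies the gate to precomputed metrics. A run passes when
#' Z' >= threshold (the boundary value passes: exclusion is Z' strictly below
#' the cutoff). Failing runs are flagged excluded and carry no downstream
#' model.
#'
#' @param plate a \code{\link{qpop_plate}}.
#' @param threshold Z' exclusion cutoff (default 0.7).
#' @return \code{qc_metrics}: an object of class \code{qpop_qc} — list with
#'   \code{zprime}, \code{ssmd}, \code{threshold}, \code{passed}.
#' @export
qc_metrics <- function(plate, threshold = 0.7) {
  z <- compute_zprime(plate)
  cs <- .control_stats(plate)
  # zero variance in both control groups with separated means: a perfect
  # assay window; report SSMD as +Inf rather than refusing the plate
  s <- if (cs$sd_neg == 0 && cs$sd_pos == 0) Inf else compute_ssmd(plate)
  structure(list(zprime = z, ssmd = s, threshold = threshold,
                 passed = qc_gate(z, threshold)),
            class = "qpop_qc")
}

#' @rdname qc_metrics
#' @param zprime a Z' value (or a \code{qpop_qc} object).
#' @return \code{qc_gate}: logical, TRUE when the run passes.
#' @export
qc_gate <- function(zprime, threshold = 0.7) {
  if (inherits(zprime, "qpop_qc")) zprime <- zprime$zprime
  if (!is.finite(zprime)) stop("Z' must be finite")
  zprime >= threshold
}

#' @export
print.qpop_qc <- function(x, ...) {
  cat(sprintf("plate QC: Z' = %.4f, SSMD = %.2f -> %s (threshold %.2f)\n",
              x$zprime, x$ssmd,
              if (x$passed) "pass" else "EXCLUDED", x$threshold))
  invisible(x)
}

#' Write / read an NCV table as delimited text
#'
#' @param ncv a \code{qpop_ncv} table from \code{\link{normalize_to_controls}}.
#' @param path output CSV path.
#' @return \code{path} (write) or the \code{qpop_ncv} table (read).
#' @export
write_ncv_csv <- function(ncv, path) {
  utils::write.csv(as.data.frame(ncv), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ncv_csv
#' @export
read_ncv_csv <- function(path) {
  out <- utils::read.csv(path)
  if (!all(c("design_row", "ncv") %in% names(out)))
    stop("NCV file needs columns 'design_row' and 'ncv'")
  class(out) <- c("qpop_ncv", "data.frame")
  out
}
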