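# Per-patient analysis orchestration and cohort-level concordance
# evaluation: plate -> QC gate -> surface fit -> exhaustive ranking ->
# patient report, and reports + clinical table -> concordance report.

#' Run the full per-patient analysis
#'
#' Normalizes the plate to its negative controls, applies the Z' quality
#' gate, fits the quadratic surface, enumerates and ranks all combinations,
#' and assembles the patient report: QC block, model diagnostics, predicted
#' single-drug NCVs per level, top-N two- and three-drug combinations, and
#' the pairwise-interaction matrix. A QC failure is a structured outcome
#' (status \code{"excluded"}, no model), not an error.
#'
#' @param plate a \code{\link{qpop_plate}}, or the path to a readout file
#'   (then \code{layout} must be given).
#' @param design a \code{\link{qpop_design}} or path to a design CSV.
#' @param layout layout file path when \code{plate} is a readout path.
#' @param panel optional \code{\link{qpop_panel}} for dose annotation
#'   (validated against the design).
#' @param patient patient identifier carried into the report.
#' @param qc_threshold Z' exclusion cutoff (default 0.7).
#' @param top_n rows per combination order in the report (default 10).
#' @param rank enumerate and rank all 3^k combinations (default TRUE). Set
#'   FALSE to skip enumeration (no top lists / top-pair input) when only the
#'   fitted model and regimen scoring are needed, e.g. for large simulated
#'   cohorts.
#' @param keep_ranking keep the full ranking object in the report (default
#'   TRUE; set FALSE to drop the 3^k table and retain only the top lists).
#' @return An object of class \code{qpop_report}: list with \code{patient},
#'   \code{status} (\code{"ok"} or \code{"excluded"}), \code{qc},
#'   and — when QC passes — \code{model}, \code{ncv}, \code{single_drug}
#'   (per drug, per level predicted NCV), \code{top2}, \code{top3},
#'   \code{interaction_matrix}, \code{ranking} (optional).
#' @export
run_qpop <- function(plate, design, layout = NULL, panel = NULL,
                     patient = "patient", qc_threshold = 0.7, top_n = 10L,
                     rank = TRUE, keep_ranking = TRUE) {
  if (is.character(design)) design <- read_design_csv(design)
  stopifnot(inherits(design, "qpop_design"))
  if (is.character(plate)) {
    if (is.null(layout))
      stop("'layout' file is required when 'plate' is a readout path")
    plate <- read_plate(plate, layout, n_design_rows = nrow(design$codes))
  }
  stopifnot(inherits(plate, "qpop_plate"))
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "qpop_panel"))
    if (!identical(panel$drugs, design$drugs))
      stop("panel drugs do not match design drugs")
  }
  qc <- qc_metrics(plate, threshold = qc_threshold)
  if (!qc$passed) {
    return(structure(list(patient = patient, status = "excluded", qc = qc,
                          drugs = design$drugs),
                     class = "qpop_report"))
  }
  ncv <- normalize_to_controls(plate)
  model <- fit_quadratic_surface(design, ncv)
  single <- vapply(1:2, function(lv) {
    x <- matrix(0L, design$k, design$k)
    diag(x) <- lv
    predict_ncv(model, x)
  }, numeric(design$k))
  dimnames(single) <- list(design$drugs, c("level1", "level2"))
  rep_obj <- list(patient = patient, status = "ok", qc = qc,
                  model = model, ncv = ncv,
                  single_drug = single,
                  interaction_matrix = pairwise_interaction_matrix(model),
                  drugs = design$drugs)
  if (rank) {
    ranking <- enumerate_and_rank(model)
    rep_obj$top2 <- top_combinations(ranking, 2L, top_n)
    rep_obj$top3 <- top_combinations(ranking, 3L, top_n)
    if (keep_ranking) rep_obj$ranking <- ranking
  }
  structure(rep_obj, class = "qpop_report")
}

#' @export
print.qpop_report <- function(x, ...) {
  cat("qpop_report for", x$patient, "- status:", x$status, "\n")
  print(x$qc)
  if (x$status == "ok") {
    cat(sprintf("  model: adj R^2 = %.4f (n_obs = %d)\n",
                x$model$adj_r2, x$model$n_obs))
    if (!is.null(x$top2))
      cat("  top 2-drug combination:", x$top2$combination[1],
          sprintf("(predicted NCV %.3f)\n", x$top2$predicted_ncv[1]))
  }
  invisible(x)
}

#' Evaluate cohort-level concordance
#'
#' Scores each passing patient report at the administered regimen (every
#' regimen drug at its highest tested level), classifies at the NCV cutoff,
#' and compares against clinical outcomes: overall and per-subgroup confusion
#' summaries, Fisher's exact test of the 2x2 table, ROC analysis of the raw
#' scores, and the cohort top-pair frequency table. Patients whose report
#' failed QC, whose regimen contains out-of-panel drugs, or whose outcome is
#' missing are excluded and logged per reason — never silently dropped.
#'
#' @param reports list of \code{\link{run_qpop}} reports (full rankings
#'   retained if the top-pair table is wanted).
#' @param clinical data.frame with columns \code{patient}, \code{regimen}
#'   (semicolon-separated drug names), \code{clinical_response}
#'   (CR/CRi/PR/NR), and optionally \code{nd_rr} and \code{eln_risk}; or the
#'   path to such a CSV.
#' @param cutoff NCV classification threshold (default 0.65).
#' @param top_n depth of the per-patient top-pair extraction (default 10).
#' @param ci_method see \code{\link{proportion_ci}}.
#' @return An object of class \code{qpop_concordance}: list with
#'   \code{records} (per-patient data.frame), \code{confusion},
#'   \code{fisher_p}, \code{roc}, \code{subgroups} (confusion per ND/RR
#'   tag), \code{top_pairs}, \code{exclusions} (patient, reason) and
#'   \code{accounting} (patients_in = evaluated + excluded).
#' @export
evaluate_cohort <- function(reports, clinical, cutoff = 0.65, top_n = 10L,
                            ci_method = "clopper_pearson") {
  if (is.character(clinical)) clinical <- utils::read.csv(clinical)
  req <- c("patient", "regimen", "clinical_response")
  if (!all(req %in% names(clinical)))
    stop("clinical table needs columns: ", paste(req, collapse = ", "))
  rep_ids <- vapply(reports, function(r) r$patient, "")
  if (anyDuplicated(rep_ids)) stop("duplicate patient ids among reports")
  excl <- list()
  note <- function(patient, reason)
    excl[[length(excl) + 1L]] <<- data.frame(patient = patient,
                                             reason = reason)
  rows <- list()
  for (i in seq_len(nrow(clinical))) {
    pid <- as.character(clinical$patient[i])
    ri <- match(pid, rep_ids)
    if (is.na(ri)) { note(pid, "no_report"); next }
    rep_i <- reports[[ri]]
    if (rep_i$status != "ok") { note(pid, "qc_failed"); next }
    regimen <- strsplit(as.character(clinical$regimen[i]), ";")[[1]]
    regimen <- trimws(regimen[nzchar(trimws(regimen))])
    if (!length(regimen)) { note(pid, "empty_regimen"); next }
    if (length(setdiff(regimen, rep_i$drugs))) {
      note(pid, "out_of_panel"); next
    }
    outc <- as.character(clinical$clinical_response[i])
    if (is.na(outc) || !nzchar(outc)) { note(pid, "missing_outcome"); next }
    score <- predict_regimen_ncv(rep_i$model, regimen)
    rows[[length(rows) + 1L]] <- data.frame(
      patient = pid,
      regimen = paste(regimen, collapse = ";"),
      predicted_ncv = score,
      predicted_label = classify_prediction(score, cutoff),
      clinical_label = collapse_clinical(outc),
      nd_rr = if ("nd_rr" %in% names(clinical))
        as.character(clinical$nd_rr[i]) else NA_character_,
      eln_risk = if ("eln_risk" %in% names(clinical))
        as.character(clinical$eln_risk[i]) else NA_character_,
      stringsAsFactors = FALSE)
  }
  orphan <- setdiff(rep_ids, as.character(clinical$patient))
  for (pid in orphan) note(pid, "no_clinical_record")
  records <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(records)) stop("no evaluable patients after exclusions")
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient = character(0), reason = character(0))
  confusion <- confusion_summary(records$predicted_label,
                                 records$clinical_label,
                                 ci_method = ci_method)
  tab <- matrix(c(confusion$tp, confusion$fn, confusion$fp, confusion$tn),
                2L, 2L)
  fisher_p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    NA_real_ else fisher_exact_2x2(tab)
  roc <- if (length(unique(records$clinical_label)) == 2L)
    roc_analysis(records$predicted_ncv, records$clinical_label) else NULL
  subgroups <- list()
  if (!all(is.na(records$nd_rr))) {
    for (g in unique(stats::na.omit(records$nd_rr))) {
      sel <- records$nd_rr == g
      subgroups[[g]] <- confusion_summary(records$predicted_label[sel],
                                          records$clinical_label[sel],
                                          ci_method = ci_method)
    }
  }
  evaluated_ids <- records$patient
  with_ranking <- vapply(reports, function(r)
    r$status == "ok" && !is.null(r$ranking) && r$patient %in% evaluated_ids,
    TRUE)
  top_pairs <- if (any(with_ranking))
    top_pair_frequency(lapply(reports[with_ranking], `[[`, "ranking"),
                       top_n = top_n) else NULL
  structure(list(records = records, confusion = confusion,
                 fisher_p = fisher_p, roc = roc, subgroups = subgroups,
                 top_pairs = top_pairs, exclusions = exclusions,
                 accounting = list(
                   patients_in = nrow(clinical) + length(orphan),
                   evaluated = nrow(records),
                   excluded = nrow(exclusions),
                   excluded_by_reason = table(exclusions$reason)),
                 cutoff = cutoff),
            class = "qpop_concordance")
}

#' @export
print.qpop_concordance <- function(x, ...) {
  acc <- x$accounting
  cat("qpop_concordance:", acc$evaluated, "evaluated /", acc$excluded,
      "excluded of", acc$patients_in, "patients (cutoff",
      format(x$cutoff), ")\n")
  print(x$confusion)
  if (!is.na(x$fisher_p))
    cat(sprintf("  Fisher exact p = %.4f\n", x$fisher_p))
  if (!is.null(x$roc)) cat(sprintf("  ROC AUC = %.3f\n", x$roc$auc))
  invisible(x)
}

#' Write a patient report as JSON
#'
#' Machine-readable serialization of the report: QC block, diagnostics,
#' single-drug table, top combination lists and the interaction matrix (the
#' full ranking is not embedded; export it with
#' \code{\link{write_ranking_csv}}).
#'
#' @param report a \code{qpop_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "qpop_report"))
  obj <- list(patient = report$patient, status = report$status,
              qc = list(zprime = report$qc$zprime, ssmd = report$qc$ssmd,
                        threshold = report$qc$threshold,
                        passed = report$qc$passed))
  if (report$status == "ok") {
    obj$diagnostics <- list(adj_r2 = report$model$adj_r2,
                            r2 = report$model$r2,
                            n_obs = report$model$n_obs)
    obj$single_drug <- as.data.frame(report$single_drug)
    obj$single_drug$drug <- rownames(report$single_drug)
    if (!is.null(report$top2)) obj$top2 <- report$top2
    if (!is.null(report$top3)) obj$top3 <- report$top3
    obj$interaction_matrix <- report$interaction_matrix
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(path)
}

#' Write a patient report as markdown
#'
#' Human-readable companion to \code{\link{write_report_json}}.
#'
#' @inheritParams write_report_json
#' @export
write_report_markdown <- function(report, path) {
  stopifnot(inherits(report, "qpop_report"))
  ln <- c(paste("# Drug sensitivity report:", report$patient), "",
          sprintf("QC: Z' = %.4f, SSMD = %.2f -> %s", report$qc$zprime,
                  report$qc$ssmd,
                  if (report$qc$passed) "pass" else "EXCLUDED"))
  if (report$status == "ok") {
    fmt_top <- function(tab, label) {
      c("", paste0("## Top ", label, " combinations"), "",
        sprintf("%2d. %s  (predicted NCV %.3f)",
                seq_len(nrow(tab)), tab$combination, tab$predicted_ncv))
    }
    ln <- c(ln,
            sprintf("Model: adj R^2 = %.4f on %d runs",
                    report$model$adj_r2, report$model$n_obs))
    if (!is.null(report$top2)) ln <- c(ln, fmt_top(report$top2, "two-drug"))
    if (!is.null(report$top3)) ln <- c(ln, fmt_top(report$top3, "three-drug"))
  } else {
    ln <- c(ln, "", "Run excluded by QC gate; no model or rankings.")
  }
  writeLines(ln, path)
  invisible(path)
}
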