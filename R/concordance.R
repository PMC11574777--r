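# Predicted-vs-clinical concordance statistics.
#
# Predicted regimen NCV scores are dichotomized at the 0.65 cutoff
# (score < 0.65 = predicted responder; the boundary is assigned to
# non-response, since responders are defined strictly below the cutoff).
# Clinical outcomes CR / CRi / PR collapse to "response", NR to
# "no_response". Concordance is summarized by a 2x2 confusion table with
# sensitivity / specificity / PPV / NPV / accuracy and 95% binomial
# intervals, Fisher's exact test, and ROC / Youden analysis of the raw
# scores.

#' Classify a predicted NCV score
#'
#' @param predicted_ncv numeric score(s).
#' @param cutoff NCV classification threshold (default 0.65).
#' @return character vector: \code{"responder"} where score < cutoff,
#'   \code{"non_responder"} otherwise (scores exactly at the cutoff are
#'   non-responders).
#' @export
classify_prediction <- function(predicted_ncv, cutoff = 0.65) {
  if (any(!is.finite(predicted_ncv))) stop("scores must be finite")
  ifelse(predicted_ncv < cutoff, "responder", "non_responder")
}

#' Collapse clinical outcome categories to binary response
#'
#' @param outcome character vector of outcome categories; CR, CRi and PR
#'   count as clinical response, NR as no response. Already-binary values
#'   (\code{"response"}/\code{"no_response"}) pass through.
#' @return character vector of \code{"response"} / \code{"no_response"}.
#' @export
collapse_clinical <- function(outcome) {
  outcome <- as.character(outcome)
  up <- toupper(outcome)
  out <- rep(NA_character_, length(outcome))
  out[up %in% c("CR", "CRI", "PR", "RESPONSE")] <- "response"
  out[up %in% c("NR", "NO_RESPONSE")] <- "no_response"
  if (anyNA(out))
    stop("unknown clinical outcome value(s): ",
         paste(unique(outcome[is.na(out)]), collapse = ", "))
  out
}

#' Confusion summary of predicted vs clinical response
#'
#' Builds the 2x2 table (TP = predicted responder with clinical response) and
#' its derived proportions, each with a 95% binomial confidence interval.
#' A metric whose denominator class is empty is reported as NA (undefined),
#' never as 0.
#'
#' @param predicted character vector of \code{"responder"} /
#'   \code{"non_responder"} (from \code{\link{classify_prediction}}), or
#'   numeric predicted NCV scores (classified at \code{cutoff}).
#' @param clinical clinical outcomes (see \code{\link{collapse_clinical}}).
#' @param cutoff threshold used when \code{predicted} is numeric.
#' @param ci_method confidence-interval method, see
#'   \code{\link{proportion_ci}}.
#' @return An object of class \code{qpop_confusion}: list with counts
#'   \code{tp, fp, fn, tn}, a \code{metrics} data.frame (estimate, x, n,
#'   ci_low, ci_high for sensitivity, specificity, ppv, npv, accuracy) and
#'   \code{n}.
#' @export
confusion_summary <- function(predicted, clinical, cutoff = 0.65,
                              ci_method = c("clopper_pearson", "wilson_cc")) {
  ci_method <- match.arg(ci_method)
  if (is.numeric(predicted)) predicted <- classify_prediction(predicted, cutoff)
  if (!all(predicted %in% c("responder", "non_responder")))
    stop("'predicted' must be 'responder'/'non_responder' or numeric scores")
  clinical <- collapse_clinical(clinical)
  if (length(predicted) != length(clinical))
    stop("'predicted' and 'clinical' lengths differ")
  tp <- sum(predicted == "responder" & clinical == "response")
  fp <- sum(predicted == "responder" & clinical == "no_response")
  fn <- sum(predicted == "non_responder" & clinical == "response")
  tn <- sum(predicted == "non_responder" & clinical == "no_response")
  met <- function(x, n) {
    if (n == 0L) return(c(NA_real_, NA_real_, NA_real_))
    c(x / n, proportion_ci(x, n, method = ci_method))
  }
  rows <- rbind(sensitivity = c(tp, tp + fn, met(tp, tp + fn)),
                specificity = c(tn, tn + fp, met(tn, tn + fp)),
                ppv         = c(tp, tp + fp, met(tp, tp + fp)),
                npv         = c(tn, tn + fn, met(tn, tn + fn)),
                accuracy    = c(tp + tn, tp + fp + fn + tn,
                                met(tp + tn, tp + fp + fn + tn)))
  metrics <- data.frame(metric = rownames(rows), x = rows[, 1], n = rows[, 2],
                        estimate = rows[, 3], ci_low = rows[, 4],
                        ci_high = rows[, 5], row.names = NULL)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 metrics = metrics, n = tp + fp + fn + tn,
                 ci_method = ci_method),
            class = "qpop_confusion")
}

#' @export
print.qpop_confusion <- function(x, ...) {
  cat("confusion (n =", x$n, "): TP", x$tp, "FP", x$fp,
      "FN", x$fn, "TN", x$tn, "\n")
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %5.1f%%  (%d/%d, 95%% CI %.1f-%.1f%%)\n",
                m$metric[i], 100 * m$estimate[i], m$x[i], m$n[i],
                100 * m$ci_low[i], 100 * m$ci_high[i]))
  invisible(x)
}

#' Binomial proportion confidence interval
#'
#' Exact Clopper-Pearson (beta-quantile form) or continuity-corrected Wilson
#' interval. Both are provided because published concordance intervals are
#' not always derived from a single method.
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials (>= 1).
#' @param method \code{"clopper_pearson"} (default) or \code{"wilson_cc"}.
#' @param conf confidence level (default 0.95).
#' @return numeric length-2 vector \code{c(low, high)}.
#' @export
proportion_ci <- function(x, n, method = c("clopper_pearson", "wilson_cc"),
                          conf = 0.95) {
  method <- match.arg(method)
  if (n < 1L || x < 0L || x > n) stop("need 0 <= x <= n, n >= 1")
  a <- 1 - conf
  if (method == "clopper_pearson") {
    low <- if (x == 0L) 0 else stats::qbeta(a / 2, x, n - x + 1)
    high <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - a / 2)
    p <- x / n; q <- 1 - p
    low <- if (x == 0L) 0 else
      max(0, (2 * n * p + z^2 - 1 -
                z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * q + 1))) /
            (2 * (n + z^2)))
    high <- if (x == n) 1 else
      min(1, (2 * n * p + z^2 + 1 +
                z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * q - 1))) /
            (2 * (n + z^2)))
  }
  c(low = low, high = high)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table. Degenerate
#' margins (an empty row or column) carry no evidence of association and
#' return p = 1 with a warning.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (sum(table) < 1) stop("table total must be >= 1")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate margins: p = 1")
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' ROC analysis of predicted NCV scores
#'
#' Lower score = more responder-like (the orientation of the viability
#' scale). AUC is computed from the rank (Mann-Whitney) statistic with
#' tie-averaging, equivalent to the trapezoidal area under the ROC curve.
#' Candidate thresholds are the midpoints between adjacent distinct scores
#' (plus one below and one above the range); the optimal cutoff maximizes
#' Youden's J = sensitivity + specificity - 1, with the lowest maximizing
#' threshold reported on ties.
#'
#' @param scores numeric predicted NCV scores.
#' @param labels clinical outcomes (see \code{\link{collapse_clinical}});
#'   both classes must be present.
#' @return list with \code{auc}, \code{points} (data.frame of threshold,
#'   sensitivity, specificity, youden), \code{optimal_cutoff},
#'   \code{youden_max}, \code{n_response}, \code{n_no_response}.
#' @export
roc_analysis <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  labels <- collapse_clinical(labels)
  resp <- scores[labels == "response"]
  non <- scores[labels == "no_response"]
  if (!length(resp) || !length(non))
    stop("both clinical classes must be present for ROC analysis")
  r <- rank(scores)
  u <- sum(r[labels == "no_response"]) - length(non) * (length(non) + 1) / 2
  auc <- u / (length(resp) * length(non))
  s <- sort(unique(scores))
  thr <- if (length(s) == 1L) c(s - 0.5, s + 0.5)
         else c(s[1] - diff(range(s)) / 2,
                (s[-length(s)] + s[-1]) / 2,
                s[length(s)] + diff(range(s)) / 2)
  sens <- vapply(thr, function(t) mean(resp < t), 0)
  spec <- vapply(thr, function(t) mean(non >= t), 0)
  pts <- data.frame(threshold = thr, sensitivity = sens, specificity = spec,
                    youden = sens + spec - 1)
  best <- which.max(pts$youden)  # lowest threshold on ties
  list(auc = auc, points = pts,
       optimal_cutoff = pts$threshold[best],
       youden_max = pts$youden[best],
       n_response = length(resp), n_no_response = length(non))
}

#' Frequency of drug pairs among per-patient top combinations
#'
#' For each patient ranking, the top \code{top_n} two-drug combinations are
#' extracted; the table counts, per unordered drug pair, the number of
#' patients whose top list contains that pair (a patient contributes at most
#' once per pair). Sorted by descending count, ties alphabetical — the
#' cohort-level "most frequently suggested doublet" summary.
#'
#' @param rankings list of \code{qpop_ranking} objects from a common panel.
#' @param top_n top-list depth per patient (default 10).
#' @return data.frame with columns \code{drug_a}, \code{drug_b},
#'   \code{pair}, \code{patients}.
#' @export
top_pair_frequency <- function(rankings, top_n = 10L) {
  stopifnot(length(rankings) >= 1L,
            all(vapply(rankings, inherits, TRUE, "qpop_ranking")))
  drugs <- rankings[[1L]]$drugs
  for (r in rankings)
    if (!identical(r$drugs, drugs))
      stop("all rankings must come from the same panel")
  counts <- new.env(parent = emptyenv())
  for (r in rankings) {
    top2 <- top_combinations(r, order = 2L, n = top_n)
    codes <- as.matrix(top2[, drugs, drop = FALSE])
    pairs <- unique(apply(codes, 1L, function(row) {
      on <- sort(drugs[row > 0])
      paste(on, collapse = " + ")
    }))
    for (p in pairs)
      assign(p, (if (exists(p, counts)) get(p, counts) else 0L) + 1L, counts)
  }
  pair <- ls(counts)
  if (!length(pair))
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      pair = character(0), patients = integer(0)))
  patients <- vapply(pair, get, 0L, envir = counts)
  halves <- strsplit(pair, " \\+ ")
  out <- data.frame(drug_a = vapply(halves, `[`, "", 1L),
                    drug_b = vapply(halves, `[`, "", 2L),
                    pair = pair, patients = as.integer(patients),
                    row.names = NULL)
  out[order(-out$patients, out$pair), , drop = FALSE]
}

#' Paired comparison of two combinations across patients
#'
#' Two-sided paired t-test of predicted NCV scores for combination A vs
#' combination B on the same patients, run separately per subgroup (e.g.
#' newly diagnosed vs relapsed/refractory, or ELN risk). Zero-variance
#' differences are flagged degenerate (p = NA); identical vectors give mean
#' difference 0 and p = 1.
#'
#' @param scores_a,scores_b numeric vectors of per-patient predicted NCV for
#'   the two combinations, same patients in the same order.
#' @param grouping subgroup tag per patient (default: one overall group).
#' @return data.frame with one row per subgroup: \code{group}, \code{n},
#'   \code{mean_diff} (A - B), \code{t}, \code{p}, \code{degenerate}.
#' @export
paired_combo_comparison <- function(scores_a, scores_b,
                                    grouping = rep("all", length(scores_a))) {
  if (length(scores_a) != length(scores_b))
    stop("paired score vectors must have equal length")
  if (length(grouping) != length(scores_a))
    stop("'grouping' must have one tag per patient")
  groups <- unique(as.character(grouping))
  out <- lapply(groups, function(g) {
    sel <- grouping == g
    a <- scores_a[sel]; b <- scores_b[sel]
    n <- length(a)
    if (n < 2L)
      return(data.frame(group = g, n = n, mean_diff = mean(a - b),
                        t = NA_real_, p = NA_real_, degenerate = TRUE))
    d <- a - b
    if (stats::sd(d) <= 1e-12 * (1 + abs(mean(d)))) {
      if (all(abs(d) <= 1e-12))
        return(data.frame(group = g, n = n, mean_diff = 0,
                          t = NA_real_, p = 1, degenerate = FALSE))
      return(data.frame(group = g, n = n, mean_diff = mean(d),
                        t = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(group = g, n = n, mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  })
  do.call(rbind, out)
}
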