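# Exhaustive enumeration and ranking of all dose-level combinations, and
# the surface summaries derived from the ranking: top-N lists per
# combination order, the pairwise-interaction (polygonogram) matrix and
# regimen-level predicted NCV.

#' Enumerate and rank all 3^k dose-level combinations
#'
#' Scores every coded level vector in {0,1,2}^k under the fitted surface and
#' sorts ascending by predicted NCV, so rank 1 is the combination with the
#' greatest predicted cell-killing capability. Ties are broken by
#' lexicographic order of the level vector (first drug most significant),
#' making the ranking deterministic and stable under re-runs. For a 12-drug
#' panel this is the full list of 531,441 combinations.
#'
#' @param model a \code{qpop_surface}.
#' @param max_k refusal bound on panel size (enumeration is 3^k; default 13).
#' @return An object of class \code{qpop_ranking}: list with \code{codes}
#'   (3^k x k integer matrix, sorted), \code{predicted_ncv} (sorted
#'   ascending), \code{n_active} (non-zero drugs per combination),
#'   \code{drugs}, \code{k}.
#' @export
enumerate_and_rank <- function(model, max_k = 13L) {
  stopifnot(inherits(model, "qpop_surface"))
  k <- model$k
  if (k > max_k)
    stop("refusing to enumerate 3^", k,
         " combinations (bound is 3^", max_k, ")")
  grid <- as.matrix(expand.grid(rep(list(0:2), k), KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  pred <- .predict_x01(model, grid / 2)
  # ascending NCV; lexicographic tie-break, leftmost drug most significant
  ord <- do.call(order, c(list(pred),
                          lapply(seq_len(k), function(j) grid[, j])))
  codes <- grid[ord, , drop = FALSE]
  colnames(codes) <- model$drugs
  structure(list(codes = codes,
                 predicted_ncv = pred[ord],
                 n_active = as.integer(rowSums(codes > 0L)),
                 drugs = model$drugs, k = k),
            class = "qpop_ranking")
}

#' @export
print.qpop_ranking <- function(x, n = 5L, ...) {
  cat("qpop_ranking:", nrow(x$codes), "combinations of", x$k, "drugs\n")
  print(utils::head(ranking_table(x), n))
  invisible(x)
}

#' Ranking as a data.frame
#'
#' @param ranking a \code{qpop_ranking}.
#' @param top_n optional truncation to the first rows.
#' @return data.frame with \code{rank}, one coded-level column per drug,
#'   \code{n_active}, \code{combination} (human-readable
#'   \code{"drug@level"} list) and \code{predicted_ncv}.
#' @export
ranking_table <- function(ranking, top_n = NULL) {
  stopifnot(inherits(ranking, "qpop_ranking"))
  idx <- seq_len(if (is.null(top_n)) nrow(ranking$codes)
                 else min(top_n, nrow(ranking$codes)))
  codes <- ranking$codes[idx, , drop = FALSE]
  lab <- apply(codes, 1L, function(r) {
    on <- which(r > 0L)
    if (!length(on)) return("(untreated)")
    paste(paste0(ranking$drugs[on], "@", r[on]), collapse = " + ")
  })
  data.frame(rank = idx, codes,
             n_active = ranking$n_active[idx],
             combination = lab,
             predicted_ncv = ranking$predicted_ncv[idx],
             check.names = FALSE, row.names = NULL)
}

#' Top combinations of a given order
#'
#' Filters the ranking to combinations with exactly \code{order} active
#' (non-zero) drugs and returns the first \code{n} in rank order — e.g. the
#' top-10 two-drug combinations of a patient report. May return fewer than
#' \code{n} rows.
#'
#' @param ranking a \code{qpop_ranking}.
#' @param order number of active drugs (>= 1).
#' @param n maximum rows returned (default 10).
#' @return data.frame as in \code{\link{ranking_table}} (rank is the global
#'   rank in the full list).
#' @export
top_combinations <- function(ranking, order, n = 10L) {
  stopifnot(inherits(ranking, "qpop_ranking"), order >= 1L)
  sel <- which(ranking$n_active == as.integer(order))
  sel <- sel[seq_len(min(n, length(sel)))]
  tab <- ranking_table(ranking)
  tab[sel, , drop = FALSE]
}

#' Pairwise drug-interaction (polygonogram) matrix
#'
#' For each unordered drug pair (i, j): the minimum predicted NCV over the
#' four two-drug assignments with drugs i and j at coded levels {1,2} and
#' every other drug absent — the best achievable kill using only that pair.
#' The diagonal holds the best single-drug predicted NCV (minimum over the
#' drug's two tested levels, others absent). Lower scores indicate stronger
#' predicted pair activity; rendering as a polygonogram is left to plotting
#' layers.
#'
#' @param model a \code{qpop_surface}.
#' @return symmetric k x k numeric matrix with drug names on both dimensions.
#' @export
pairwise_interaction_matrix <- function(model) {
  stopifnot(inherits(model, "qpop_surface"))
  k <- model$k
  M <- matrix(NA_real_, k, k, dimnames = list(model$drugs, model$drugs))
  for (i in seq_len(k)) {
    x <- matrix(0L, 2L, k); x[, i] <- 1:2
    M[i, i] <- min(predict_ncv(model, x))
  }
  if (k >= 2L) {
    combos <- as.matrix(expand.grid(a = 1:2, b = 1:2))
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        x <- matrix(0L, 4L, k)
        x[, i] <- combos[, "a"]; x[, j] <- combos[, "b"]
        M[i, j] <- M[j, i] <- min(predict_ncv(model, x))
      }
    }
  }
  M
}

#' Predicted NCV of an administered regimen
#'
#' Scores a clinical regimen on the patient's surface with every regimen drug
#' at its highest tested level (code 2) and all other drugs absent. This is
#' the score compared against the 0.65 NCV cutoff for predicted
#' responder / non-responder classification.
#'
#' @param model a \code{qpop_surface}.
#' @param regimen character vector of drug names (non-empty, all in the
#'   panel).
#' @return predicted NCV of the regimen (single numeric).
#' @export
predict_regimen_ncv <- function(model, regimen) {
  stopifnot(inherits(model, "qpop_surface"))
  regimen <- unique(as.character(regimen))
  if (!length(regimen)) stop("regimen must contain at least one drug")
  unknown <- setdiff(regimen, model$drugs)
  if (length(unknown))
    stop("regimen drug(s) not in panel: ", paste(unknown, collapse = ", "))
  lv <- integer(model$k)
  lv[match(regimen, model$drugs)] <- 2L
  predict_ncv(model, lv)
}

#' Export a ranking as delimited text
#'
#' @param ranking a \code{qpop_ranking}.
#' @param path output CSV path.
#' @param top_n optional truncation (e.g. 100 for a report attachment).
#' @return \code{path}, invisibly.
#' @export
write_ranking_csv <- function(ranking, path, top_n = NULL) {
  utils::write.csv(ranking_table(ranking, top_n = top_n), path,
                   row.names = FALSE)
  invisible(path)
}
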