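# Concordance statistics: classification, confusion summaries, intervals,
# Fisher's exact test, ROC analysis, paired comparisons, top-pair counts.

test_that("the NCV cutoff classifies with the boundary as non-response", {
  expect_equal(classify_prediction(0.40), "responder")
  expect_equal(classify_prediction(0.80), "non_responder")
  expect_equal(classify_prediction(0.65), "non_responder")  # strict '< 0.65'
  expect_equal(classify_prediction(c(0.1, 0.9)),
               c("responder", "non_responder"))
  expect_error(classify_prediction(NA_real_), "finite")
})

test_that("clinical categories collapse with CR/CRi/PR as response", {
  expect_equal(collapse_clinical(c("CR", "CRi", "PR", "NR")),
               c("response", "response", "response", "no_response"))
  expect_error(collapse_clinical("maybe"), "maybe")
})

test_that("confusion metrics equal brute-force recomputation on random cohorts", {
  set.seed(88)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    pred <- sample(c("responder", "non_responder"), n, replace = TRUE)
    clin <- sample(c("CR", "CRi", "PR", "NR"), n, replace = TRUE)
    cs <- confusion_summary(pred, clin)
    is_resp <- collapse_clinical(clin) == "response"
    tp <- sum(pred == "responder" & is_resp)
    fp <- sum(pred == "responder" & !is_resp)
    fn <- sum(pred == "non_responder" & is_resp)
    tn <- sum(pred == "non_responder" & !is_resp)
    expect_equal(c(cs$tp, cs$fp, cs$fn, cs$tn), c(tp, fp, fn, tn))
    m <- cs$metrics
    expect_equal(m$estimate[m$metric == "accuracy"], (tp + tn) / n)
    if (tp + fn > 0)
      expect_equal(m$estimate[m$metric == "sensitivity"], tp / (tp + fn))
    if (tn + fp > 0)
      expect_equal(m$estimate[m$metric == "specificity"], tn / (tn + fp))
  }
})

test_that("empty denominator classes give undefined metrics, not zero", {
  cs <- confusion_summary(rep("responder", 5), rep("CR", 5))
  m <- cs$metrics
  expect_true(is.na(m$estimate[m$metric == "specificity"]))
  expect_true(is.na(m$estimate[m$metric == "npv"]))
  expect_equal(m$estimate[m$metric == "sensitivity"], 1)
})

test_that("binomial intervals match their defining equations", {
  cp <- proportion_ci(4, 5, method = "clopper_pearson")
  expect_equal(unname(cp), c(0.2836, 0.9949), tolerance = 1e-4)
  # Clopper-Pearson bounds solve the tail equations
  expect_equal(1 - pbinom(4 - 1, 5, cp[["low"]]), 0.025, tolerance = 1e-9)
  expect_equal(pbinom(4, 5, cp[["high"]]), 0.025, tolerance = 1e-9)
  expect_equal(cp[["high"]], 0.975^(1 / 5), tolerance = 1e-9)  # closed form
  wc <- proportion_ci(15, 18, method = "wilson_cc")
  expect_equal(unname(wc), c(0.577, 0.956), tolerance = 1e-3)
  # boundary conventions
  expect_equal(proportion_ci(5, 5)[["high"]], 1)
  expect_equal(proportion_ci(5, 5, method = "wilson_cc")[["high"]], 1)
  expect_equal(proportion_ci(0, 8)[["low"]], 0)
  expect_error(proportion_ci(6, 5), "x <= n")
})

test_that("Fisher p-values agree with full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(rbind(c(4, 1), c(0, 6))), 5 / 330,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(rbind(c(2, 0), c(0, 2))), 1 / 3,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  expect_warning(p <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4))),
                 "degenerate")
  expect_equal(p, 1)
  set.seed(17)
  for (rep in 1:50) {
    repeat {
      tab <- matrix(rpois(4, 4), 2)
      if (sum(tab) >= 1 && sum(tab) <= 40 &&
          all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    expect_equal(fisher_exact_2x2(tab), fisher_oracle(tab),
                 tolerance = 1e-8)
  }
})

test_that("ROC analysis matches its worked examples", {
  r <- roc_analysis(c(0.2, 0.3, 0.7, 0.8), c("CR", "CR", "NR", "NR"))
  expect_equal(r$auc, 1)
  expect_equal(r$optimal_cutoff, 0.5)
  expect_equal(r$youden_max, 1)
  expect_equal(roc_analysis(rep(0.5, 6),
                            c("CR", "CR", "CR", "NR", "NR", "NR"))$auc, 0.5)
  expect_equal(roc_analysis(c(0.2, 0.7, 0.3, 0.8),
                            c("CR", "CR", "NR", "NR"))$auc, 0.75)
  expect_error(roc_analysis(c(0.2, 0.3), c("CR", "CR")), "both")
})

test_that("AUC equals the pairwise Mann-Whitney probability on random data", {
  set.seed(5150)
  for (rep in 1:25) {
    n <- sample(6:25, 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    labels <- sample(c("CR", "NR"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_analysis(scores, labels)$auc,
                 auc_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  scores <- runif(40)
  labels <- sample(c("CR", "NR"), 40, replace = TRUE)
  ours <- roc_analysis(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(
    pROC::roc(response = collapse_clinical(labels) == "no_response",
              predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("raising the cutoff never shrinks the predicted-responder count", {
  set.seed(23)
  scores <- runif(60)
  counts <- vapply(seq(0, 1, by = 0.05), function(ct)
    sum(classify_prediction(scores, cutoff = ct) == "responder"), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("top-pair counts reflect construction of the cohort rankings", {
  # three patients whose surfaces share one dominant synergistic pair
  rks <- lapply(1:3, function(s) {
    m <- random_surface(4, seed = 400 + s)
    m$beta_int[["d1:d2"]] <- -1.5  # dominant negative interaction
    enumerate_and_rank(m)
  })
  tab <- top_pair_frequency(rks, top_n = 10)
  expect_equal(tab$pair[1], "d1 + d2")
  expect_equal(tab$patients[1], 3L)
  # a pair absent from every top-10 does not appear
  absent <- lapply(1:3, function(s) {
    m <- random_surface(4, seed = 500 + s)
    m$beta_lin[] <- c(-0.9, -0.8, -0.01, -0.01)
    m$beta_int[] <- 0
    enumerate_and_rank(m)
  })
  tab2 <- top_pair_frequency(absent, top_n = 3)
  expect_false("d3 + d4" %in% tab2$pair)
})

test_that("paired comparisons handle exact ties, shifts and power", {
  a <- c(0.3, 0.5, 0.7, 0.4, 0.6)
  same <- paired_combo_comparison(a, a)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)
  expect_false(same$degenerate)
  shift <- paired_combo_comparison(a, a + 0.1)
  expect_true(shift$degenerate)  # zero-variance nonzero differences
  expect_true(is.na(shift$p))
  # power: shift -0.15 at sd 0.05, n = 20 rejects essentially always
  set.seed(2024)
  rej <- vapply(seq_len(1000), function(s) {
    b <- runif(20, 0.4, 0.8)
    a <- b - 0.15 + rnorm(20, 0, 0.05)
    paired_combo_comparison(a, b)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.99)
  # per-subgroup rows
  g <- rep(c("ND", "RR"), c(12, 8))
  set.seed(1)
  res <- paired_combo_comparison(runif(20), runif(20), grouping = g)
  expect_setequal(res$group, c("ND", "RR"))
  expect_equal(res$n[res$group == "ND"], 12)
})
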