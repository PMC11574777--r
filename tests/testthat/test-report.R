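# Per-patient orchestration and cohort evaluation.

test_that("a noiseless run reports the truth's best combinations", {
  cfg <- small_config(3, seed = 19, noise_sd = 0)
  design <- generate_oacd(3, cfg$panel$drugs)
  truth <- sample_truth_surface(cfg)
  plate <- simulate_plate(truth, design, cfg)
  rep1 <- run_qpop(plate, design, patient = "PX")
  expect_equal(rep1$status, "ok")
  # oracle: brute-force argmin over exactly-2-active assignments
  oracle <- brute_ranking(truth)
  two <- rowSums(oracle$codes > 0) == 2
  expect_equal(unname(unlist(rep1$top2[1, cfg$panel$drugs])),
               oracle$codes[which(two)[1], ])
  expect_equal(rep1$top2$predicted_ncv[1], oracle$scores[which(two)[1]],
               tolerance = 1e-9)
  expect_equal(rep1$model$adj_r2, 1, tolerance = 1e-10)
})

test_that("QC failure produces a structured excluded report", {
  # controls with overlapping distributions: Z' well below 0.7
  pl <- make_plate(design_signals = c(0.5, 0.6, 0.7),
                   neg = c(0.8, 1.0, 1.2), pos = c(0.1, 0.35, 0.6),
                   design_rows = 1:3)
  design <- make_grid_design(2)  # unused beyond validation
  design$codes <- design$codes[1:3, ]; design$portion <- design$portion[1:3]
  rep_x <- run_qpop(pl, structure(list(codes = design$codes,
                                       portion = design$portion,
                                       drugs = design$drugs, k = 2L),
                                  class = "qpop_design"),
                    patient = "bad")
  expect_equal(rep_x$status, "excluded")
  expect_false(rep_x$qc$passed)
  expect_null(rep_x$model)
  expect_null(rep_x$top2)
})

test_that("identical inputs give identical reports and serializations", {
  cfg <- small_config(3, seed = 4)
  design <- generate_oacd(3, cfg$panel$drugs)
  plate <- simulate_plate(sample_truth_surface(cfg), design, cfg)
  r1 <- run_qpop(plate, design, patient = "P1")
  r2 <- run_qpop(plate, design, patient = "P1")
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(f1, f2)), add = TRUE)
  write_report_json(r1, f1); write_report_json(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::read_json(f1)
  expect_equal(parsed$status, "ok")
  expect_equal(parsed$patient, "P1")
})

test_that("file-based and in-memory invocations agree", {
  cfg <- small_config(3, seed = 14)
  design <- generate_oacd(3, cfg$panel$drugs)
  plate <- simulate_plate(sample_truth_surface(cfg), design, cfg)
  rd <- tempfile(fileext = ".csv"); ly <- tempfile(fileext = ".csv")
  dz <- tempfile(fileext = ".csv")
  on.exit(unlink(c(rd, ly, dz, paste0(dz, ".json"))), add = TRUE)
  write_plate_csv(plate, rd, ly)
  write_design_csv(design, dz)
  r_file <- run_qpop(rd, dz, layout = ly, patient = "P1")
  r_mem <- run_qpop(plate, design, patient = "P1")
  expect_equal(r_file$model$beta_lin, r_mem$model$beta_lin)
  expect_equal(r_file$top2, r_mem$top2)
})

test_that("cohort evaluation logs every exclusion with its reason", {
  cfg <- small_config(3, seed = 2, cohort_size = 8, noise_sd = 0,
                      label_flip_eps = 0)
  coh <- simulate_cohort(cfg)
  reports <- lapply(seq_len(8), function(i)
    run_qpop(coh$plates[[i]], coh$design,
             patient = coh$patients$patient[i], rank = FALSE))
  clin <- coh$patients
  clin$regimen[3] <- "d1;unlisted_drug"      # out-of-panel regimen
  clin$clinical_response[5] <- ""            # missing outcome
  # and one clinical record with no report at all
  clin <- rbind(clin[, ], clin[1, ])
  clin$patient[9] <- "P999"
  ev <- evaluate_cohort(reports, clin)
  expect_setequal(ev$exclusions$patient[ev$exclusions$reason == "out_of_panel"],
                  coh$patients$patient[3])
  expect_setequal(
    ev$exclusions$patient[ev$exclusions$reason == "missing_outcome"],
    coh$patients$patient[5])
  expect_true("P999" %in%
                ev$exclusions$patient[ev$exclusions$reason == "no_report"])
  expect_equal(ev$accounting$evaluated + ev$accounting$excluded,
               ev$accounting$patients_in)
  expect_equal(ev$accounting$evaluated, 6)
})

test_that("QC-failed patients are excluded from concordance, never scored", {
  cfg <- small_config(3, seed = 3, cohort_size = 4, noise_sd = 0,
                      label_flip_eps = 0)
  coh <- simulate_cohort(cfg)
  reports <- lapply(seq_len(4), function(i)
    run_qpop(coh$plates[[i]], coh$design,
             patient = coh$patients$patient[i], rank = FALSE))
  # sabotage one plate's controls so its QC fails: positive controls with a
  # huge spread collapse the assay window
  bad <- coh$plates[[2]]
  n_pos <- sum(bad$role == "positive_control")
  mu_neg <- mean(bad$signal[bad$role == "negative_control"])
  bad$signal[bad$role == "positive_control"] <-
    rep(c(0.1, 0.9) * mu_neg, length.out = n_pos)
  reports[[2]] <- run_qpop(bad, coh$design,
                           patient = coh$patients$patient[2], rank = FALSE)
  expect_equal(reports[[2]]$status, "excluded")
  ev <- evaluate_cohort(reports, coh$patients)
  expect_true(coh$patients$patient[2] %in%
                ev$exclusions$patient[ev$exclusions$reason == "qc_failed"])
  expect_false(coh$patients$patient[2] %in% ev$records$patient)
})

test_that("markdown reports render for both passing and excluded runs", {
  cfg <- small_config(3, seed = 4)
  design <- generate_oacd(3, cfg$panel$drugs)
  plate <- simulate_plate(sample_truth_surface(cfg), design, cfg)
  r1 <- run_qpop(plate, design, patient = "P1")
  md <- tempfile(fileext = ".md")
  on.exit(unlink(md), add = TRUE)
  write_report_markdown(r1, md)
  txt <- readLines(md)
  expect_true(any(grepl("^# Drug sensitivity report", txt)))
  expect_true(any(grepl("two-drug", txt)))
})
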