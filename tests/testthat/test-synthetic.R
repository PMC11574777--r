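# Synthetic-data generator: determinism, construction guarantees,
# round-trip identities and calibration.

test_that("truth surfaces are deterministic with baseline exactly 1", {
  cfg <- qpop_sim_config(seed = 77)
  t1 <- sample_truth_surface(cfg)
  t2 <- sample_truth_surface(cfg)
  expect_identical(t1, t2)
  expect_identical(t1$beta0, 1)
  expect_true(all(t1$beta_lin < 0))
  t3 <- sample_truth_surface(qpop_sim_config(seed = 78))
  expect_false(identical(t1$beta_lin, t3$beta_lin))
})

test_that("configured synergy strengths land in the interaction terms", {
  cfg <- qpop_sim_config(seed = 5)
  truth <- sample_truth_surface(cfg)
  s <- attr(truth, "calibration_scale")
  expect_true(is.numeric(s) && s > 0 && s <= 1)
  for (sp in cfg$synergy_pairs) {
    nm <- intersect(c(paste(sp$pair, collapse = ":"),
                      paste(rev(sp$pair), collapse = ":")),
                    names(truth$beta_int))
    expect_length(nm, 1)
    # pre-calibration value = strength + jitter (4 sd bound)
    expect_lt(abs(truth$beta_int[[nm]] / s - sp$beta), 4 * cfg$jitter_sd)
  }
})

test_that("truth viability stays at or above the floor on design rows", {
  for (seed in 1:5) {
    cfg <- qpop_sim_config(seed = seed)
    truth <- sample_truth_surface(cfg)
    design <- generate_oacd(12, cfg$panel$drugs)
    expect_gte(min(predict_ncv(truth, design$codes)),
               cfg$viability_floor - 1e-12)
  }
})

test_that("zero-noise plates reproduce the truth surface exactly", {
  cfg <- qpop_sim_config(seed = 13, noise_sd = 0)
  design <- generate_oacd(12, cfg$panel$drugs)
  truth <- sample_truth_surface(cfg)
  plate <- simulate_plate(truth, design, cfg)
  ncv <- normalize_to_controls(plate)
  expect_equal(ncv$ncv, unname(predict_ncv(truth, design$codes)),
               tolerance = 1e-12)
  expect_equal(compute_zprime(plate), 1)
  fit <- fit_quadratic_surface(design, ncv)
  expect_equal(qpopr:::.surface_beta(fit), qpopr:::.surface_beta(truth),
               tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
})

test_that("fitted coefficients are unbiased under plate noise", {
  # at noise sd 0.01 the Monte-Carlo mean of an unbiased estimator stays
  # well inside 0.01 per coefficient with 30 seeds (the linear terms carry
  # sampling-sd multipliers up to ~14 sigma on this design)
  cfg <- qpop_sim_config(seed = 1, noise_sd = 0.01)
  design <- generate_oacd(12, cfg$panel$drugs)
  set.seed(314)
  bias <- 0
  nseeds <- 30
  for (s in seq_len(nseeds)) {
    truth <- qpopr:::.draw_truth(cfg, design)
    plate <- qpopr:::.sim_plate(truth, design, cfg)
    fit <- fit_quadratic_surface(design, normalize_to_controls(plate))
    bias <- bias + (qpopr:::.surface_beta(fit) - qpopr:::.surface_beta(truth))
  }
  expect_lt(mean(abs(bias / nseeds)), 0.01)
})

test_that("end-to-end zero-noise pipeline reproduces the truth ranking (k=3)", {
  cfg <- small_config(3, seed = 41, noise_sd = 0)
  design <- generate_oacd(3, cfg$panel$drugs)
  truth <- sample_truth_surface(cfg)
  fit <- fit_quadratic_surface(
    design, normalize_to_controls(simulate_plate(truth, design, cfg)))
  got <- enumerate_and_rank(fit)
  want <- brute_ranking(truth)
  expect_equal(unname(got$codes), want$codes)
  expect_equal(got$predicted_ncv, want$scores, tolerance = 1e-9)
})

test_that("cohorts are reproducible and internally consistent", {
  cfg <- qpop_sim_config(seed = 8, cohort_size = 6)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$plates, c2$plates)
  expect_equal(nrow(c1$patients), 6)
  # labels follow the 0.65 rule XOR flip
  responds <- collapse_clinical(c1$patients$clinical_response) == "response"
  expect_equal(responds,
               xor(c1$patients$true_ncv < 0.65, c1$patients$label_flipped))
})

test_that("with no label noise and no plate noise, concordance is perfect", {
  cfg <- qpop_sim_config(seed = 9, cohort_size = 15, noise_sd = 0,
                         label_flip_eps = 0)
  coh <- simulate_cohort(cfg)
  reports <- lapply(seq_len(15), function(i)
    run_qpop(coh$plates[[i]], coh$design,
             patient = coh$patients$patient[i], rank = FALSE))
  ev <- evaluate_cohort(reports, coh$patients)
  m <- ev$confusion$metrics
  expect_equal(m$estimate[m$metric == "accuracy"], 1)
})

test_that("label-flip noise calibrates overall accuracy to 1 - eps", {
  # with zero plate noise the fitted surface equals the truth, so
  # disagreement arises only from flipped labels: accuracy -> 1 - eps
  cfg <- qpop_sim_config(seed = 10, cohort_size = 400, noise_sd = 0,
                         label_flip_eps = 0.1)
  coh <- simulate_cohort(cfg)
  reports <- lapply(seq_len(400), function(i)
    run_qpop(coh$plates[[i]], coh$design,
             patient = coh$patients$patient[i], rank = FALSE))
  ev <- evaluate_cohort(reports, coh$patients)
  m <- ev$confusion$metrics
  expect_equal(m$estimate[m$metric == "accuracy"], 0.9, tolerance = 0.045)
})

test_that("serial resistance raises the drug's single-agent NCV run by run", {
  cfg <- qpop_sim_config(seed = 6, noise_sd = 0.02)
  sr <- simulate_serial_resistance(cfg, n_runs = 3, drug = "midostaurin")
  single <- function(model) {
    lv <- integer(12); lv[match("midostaurin", model$drugs)] <- 2L
    predict_ncv(model, lv)
  }
  true_ncvs <- vapply(sr$truths, single, 0)
  expect_true(all(diff(true_ncvs) > 0))
  # zero drift leaves predictions identical
  sr0 <- simulate_serial_resistance(
    qpop_sim_config(seed = 6, noise_sd = 0.02, resistance_drift = 0),
    n_runs = 3)
  expect_equal(vapply(sr0$truths, single, 0),
               rep(single(sr0$truths[[1]]), 3))
})

test_that("fitted serial NCVs recover the resistance trend in most runs", {
  # single-drug predictions are extrapolations with leverage h ~ 14.5 on
  # this design, so the fitted trend is reliable when the per-run
  # prediction error sd (noise_sd * sqrt(h)) is well below the 0.1 drift
  # step; noise sd 0.008 puts the per-pair z at ~2.3
  cfg_base <- qpop_sim_config(seed = 1, noise_sd = 0.008)
  design <- generate_oacd(12, cfg_base$panel$drugs)
  mono <- vapply(seq_len(200), function(s) {
    cfg <- qpop_sim_config(seed = s, noise_sd = 0.008)
    sr <- simulate_serial_resistance(cfg, n_runs = 3, drug = "midostaurin")
    fitted_ncv <- vapply(seq_len(3), function(r) {
      fit <- fit_quadratic_surface(
        design, normalize_to_controls(sr$plates[[r]]))
      lv <- integer(12); lv[match("midostaurin", fit$drugs)] <- 2L
      predict_ncv(fit, lv)
    }, 0)
    all(diff(fitted_ncv) > 0)
  }, TRUE)
  expect_gte(mean(mono), 0.95)
})
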