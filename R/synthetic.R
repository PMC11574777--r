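# Synthetic data generation: ground-truth surfaces, simulated plates,
# cohorts with clinical labels, and serial resistance drift.
#
# The generator emulates the statistical structure the analysis assumes —
# viability responses that follow a quadratic surface in normalized dose,
# additive Gaussian noise truncated at zero signal, negative/positive control
# wells, and clinical labels tied to the true regimen NCV through the same
# 0.65 rule the classifier uses (optionally corrupted by label-flip noise).
# It makes every pipeline stage testable without patient data; it does not
# attempt biologically mechanistic simulation.
#
# Truth surfaces are calibrated to the bounded viability readout: after
# drawing single-drug effects, a weak antagonistic interaction background
# (overlapping cytotoxic mechanisms saturate rather than stack) and the
# configured synergy pairs, all drug-effect terms are rescaled, if needed, so
# that the lowest predicted NCV over the design rows equals the viability
# floor (default 0.10). A truth surface therefore never predicts negative
# viability at any tested combination, which keeps the zero-noise
# simulate -> normalize -> fit round trip exact. The applied scale is kept
# in attr(surface, "calibration_scale").

#' Default 12-drug screening panel (synthetic)
#'
#' A synthetic stand-in for a clinical AML combination panel: 12 approved
#' chemotherapy / targeted agents with plausible molar dose ranges. The high
#' tested dose is set at 10% of Cmax and the low dose at 5% of Cmax. Drug
#' identities carry no computational meaning.
#'
#' @return a \code{\link{qpop_panel}} with 12 drugs.
#' @export
default_panel <- function() {
  drugs <- c("azacytidine", "venetoclax", "cytarabine", "fludarabine",
             "midostaurin", "gilteritinib", "daunorubicin", "idarubicin",
             "cladribine", "etoposide", "sorafenib", "dexamethasone")
  cmax <- c(4e-6, 5e-6, 2e-5, 2e-6, 5e-6, 8e-7,
            1e-6, 2e-7, 2e-7, 3e-5, 1e-5, 4e-7)
  doses <- cbind(0, 0.05 * cmax, 0.10 * cmax)
  qpop_panel(drugs, doses, cmax = cmax)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic generator with its default. All
#' randomness is governed by \code{seed}; identical config + seed gives
#' identical output.
#'
#' @param panel the drug panel (default \code{\link{default_panel}}).
#' @param seed integer RNG seed.
#' @param noise_sd additive Gaussian noise SD on treated wells, NCV units
#'   (default 0.05).
#' @param control_noise_frac control-well noise SD as a fraction of
#'   \code{noise_sd} (default 0.4: control wells are homogeneous, undosed
#'   conditions with lower well-to-well variability than treated wells).
#' @param synergy_pairs list of \code{list(pair = c(drugA, drugB),
#'   beta = strength)} fixing named interaction coefficients before floor
#'   calibration (negative = synergy); other pairs get the antagonistic
#'   background.
#' @param effect_range range of the top-dose single-drug kill fraction
#'   (default 0.10-0.40: the strongest single agent reduces viability by up
#'   to 40% at its highest tested dose).
#' @param curvature_range range of the half-dose effect as a fraction of the
#'   top-dose effect (default 0.4-0.6; 0.5 = linear dose response, away from
#'   0.5 = curvature, giving small quadratic terms).
#' @param saturation strength of the antagonistic interaction background:
#'   the background mean is \code{saturation * sum(effects) / npairs}
#'   (default 1.2).
#' @param int_sd SD of the background interaction terms (default 0.02).
#' @param jitter_sd SD of the jitter added to fixed synergy strengths
#'   (default 0.01).
#' @param viability_floor lowest truth NCV allowed at any design row
#'   (default 0.10).
#' @param replicates design wells per design row (default 3, mirroring a
#'   triplicate assay; replicate NCVs are averaged before fitting).
#' @param n_neg,n_pos negative / positive control wells per plate
#'   (default 16 each).
#' @param control_scale raw signal of an untreated well, RLU (default 1e4).
#' @param pos_level mean NCV of the cytotoxic positive control (default
#'   0.02).
#' @param label_flip_eps probability a clinical label contradicts the
#'   true-surface prediction (default 0.1, in [0, 0.5]).
#' @param cohort_size number of patients (default 29).
#' @param regimens list of candidate regimens (character vectors of panel
#'   drugs); \code{regimen_probs} their sampling weights.
#' @param regimen_probs numeric weights, same length as \code{regimens}.
#' @param nd_prop proportion of newly diagnosed (vs relapsed/refractory)
#'   patients (default 20/29).
#' @param eln_probs sampling weights of ELN risk tags
#'   favorable/intermediate/adverse.
#' @param resistance_drift per-run additive increment of the resistant
#'   drug's linear coefficient toward 0 (default 0.1).
#' @param resistance_start linear coefficient of the resistant drug at the
#'   first serial run, before floor calibration (default -0.5).
#' @return list of class \code{qpop_sim_config}.
#' @export
qpop_sim_config <- function(panel = default_panel(),
                            seed = 1L,
                            noise_sd = 0.05,
                            control_noise_frac = 0.4,
                            synergy_pairs = list(
                              list(pair = c("fludarabine", "cytarabine"),
                                   beta = -0.20),
                              list(pair = c("fludarabine", "venetoclax"),
                                   beta = -0.15),
                              list(pair = c("azacytidine", "venetoclax"),
                                   beta = -0.12)),
                            effect_range = c(0.10, 0.40),
                            curvature_range = c(0.4, 0.6),
                            saturation = 1.2,
                            int_sd = 0.02,
                            jitter_sd = 0.01,
                            viability_floor = 0.10,
                            replicates = 3L,
                            n_neg = 16L,
                            n_pos = 16L,
                            control_scale = 1e4,
                            pos_level = 0.02,
                            label_flip_eps = 0.1,
                            cohort_size = 29L,
                            regimens = list(
                              c("azacytidine", "venetoclax"),
                              c("cytarabine", "daunorubicin"),
                              c("fludarabine", "cytarabine"),
                              c("cytarabine", "daunorubicin", "midostaurin"),
                              c("venetoclax", "cytarabine")),
                            regimen_probs = c(0.38, 0.25, 0.15, 0.12, 0.10),
                            nd_prop = 20 / 29,
                            eln_probs = c(favorable = 0.3,
                                          intermediate = 0.4,
                                          adverse = 0.3),
                            resistance_drift = 0.1,
                            resistance_start = -0.5) {
  stopifnot(inherits(panel, "qpop_panel"),
            noise_sd >= 0, control_noise_frac >= 0,
            label_flip_eps >= 0, label_flip_eps <= 0.5,
            length(effect_range) == 2L, effect_range[1] > 0,
            diff(effect_range) >= 0,
            viability_floor >= 0, viability_floor < 1,
            replicates >= 1L, n_neg >= 2L, n_pos >= 2L,
            control_scale > 0,
            length(regimen_probs) == length(regimens))
  for (rg in regimens)
    if (length(setdiff(rg, panel$drugs)))
      stop("regimen drug(s) outside the panel: ",
           paste(setdiff(rg, panel$drugs), collapse = ", "))
  for (sp in synergy_pairs)
    if (length(setdiff(sp$pair, panel$drugs)))
      stop("synergy pair drug(s) outside the panel: ",
           paste(setdiff(sp$pair, panel$drugs), collapse = ", "))
  structure(list(panel = panel, seed = as.integer(seed),
                 noise_sd = noise_sd,
                 control_noise_frac = control_noise_frac,
                 synergy_pairs = synergy_pairs,
                 effect_range = effect_range,
                 curvature_range = curvature_range,
                 saturation = saturation,
                 int_sd = int_sd, jitter_sd = jitter_sd,
                 viability_floor = viability_floor,
                 replicates = as.integer(replicates),
                 n_neg = as.integer(n_neg), n_pos = as.integer(n_pos),
                 control_scale = control_scale, pos_level = pos_level,
                 label_flip_eps = label_flip_eps,
                 cohort_size = as.integer(cohort_size),
                 regimens = regimens,
                 regimen_probs = regimen_probs / sum(regimen_probs),
                 nd_prop = nd_prop, eln_probs = eln_probs,
                 resistance_drift = resistance_drift,
                 resistance_start = resistance_start),
            class = "qpop_sim_config")
}

# rescale all drug-effect terms so the minimum predicted NCV over the design
# rows equals the viability floor (no-op when already above it); the
# prediction is 1 + s * effect(x), so scaling preserves the combination
# ranking
.calibrate_floor <- function(truth, design, floor_) {
  mn <- min(predict_ncv(truth, design$codes))
  s <- if (mn < floor_) (1 - floor_) / (1 - mn) else 1
  truth$beta_lin <- s * truth$beta_lin
  truth$beta_quad <- s * truth$beta_quad
  truth$beta_int <- s * truth$beta_int
  attr(truth, "calibration_scale") <- s
  truth
}

# draw one truth surface from the current RNG stream
.draw_truth <- function(config, design) {
  panel <- config$panel
  k <- panel$k
  # top-dose kill fraction e and half-dose fraction h per drug;
  # beta_lin + beta_quad = -e and 0.5*beta_lin + 0.25*beta_quad = -h*e
  e2 <- stats::runif(k, config$effect_range[1], config$effect_range[2])
  h <- stats::runif(k, config$curvature_range[1], config$curvature_range[2])
  b_lin <- -e2 * (4 * h - 1)
  b_quad <- 2 * e2 * (2 * h - 1)
  npair <- (k * (k - 1L)) %/% 2L
  mu0 <- config$saturation * sum(e2) / npair
  b_int <- stats::rnorm(npair, mu0, config$int_sd)
  pair_names <- quad_term_names(panel$drugs)[-(1:(2 * k + 1))]
  for (sp in config$synergy_pairs) {
    idx <- which(pair_names == paste(sp$pair, collapse = ":") |
                   pair_names == paste(rev(sp$pair), collapse = ":"))
    b_int[idx] <- sp$beta + stats::rnorm(1, 0, config$jitter_sd)
  }
  truth <- new_qpop_surface(panel$drugs, beta0 = 1, beta_lin = b_lin,
                            beta_quad = b_quad, beta_int = b_int)
  .calibrate_floor(truth, design, config$viability_floor)
}

#' Sample a ground-truth response surface
#'
#' The untreated baseline is exactly 1 (NCV of the negative control); linear
#' coefficients are negative (single-agent efficacy), quadratic terms small
#' (dose-response curvature), and interactions are a weak antagonistic
#' background except for the configured synergy pairs, whose strengths
#' receive only a small jitter. The surface is then calibrated to the
#' viability floor (see \code{\link{qpop_sim_config}}). Deterministic per
#' seed.
#'
#' @param config a \code{\link{qpop_sim_config}}.
#' @return a \code{qpop_surface} (ground truth: no fit diagnostics), with
#'   attribute \code{calibration_scale}.
#' @export
sample_truth_surface <- function(config) {
  stopifnot(inherits(config, "qpop_sim_config"))
  design <- generate_oacd(config$panel$k, drugs = config$panel$drugs)
  set.seed(config$seed)
  .draw_truth(config, design)
}

# simulate one plate from the current RNG stream
.sim_plate <- function(truth, design, config) {
  n <- nrow(design$codes)
  y <- predict_ncv(truth, design$codes)
  reps <- config$replicates
  ncv_wells <- rep(y, each = reps) +
    stats::rnorm(n * reps, 0, config$noise_sd)
  csd <- config$control_noise_frac * config$noise_sd
  neg <- 1 + stats::rnorm(config$n_neg, 0, csd)
  pos <- config$pos_level + stats::rnorm(config$n_pos, 0, csd)
  signal <- config$control_scale * pmax(0, c(ncv_wells, neg, pos))
  total <- length(signal)
  well <- if (total <= 384L) {
    i <- seq_len(total) - 1L
    paste0(LETTERS[i %/% 24L + 1L], sprintf("%02d", i %% 24L + 1L))
  } else sprintf("W%04d", seq_len(total))
  wells <- data.frame(
    well = well,
    signal = signal,
    role = rep(c("design", "negative_control", "positive_control"),
               c(n * reps, config$n_neg, config$n_pos)),
    design_row = c(rep(seq_len(n), each = reps),
                   rep(NA_integer_, config$n_neg + config$n_pos)),
    replicate = c(rep(seq_len(reps), n),
                  rep(1L, config$n_neg + config$n_pos)),
    stringsAsFactors = FALSE)
  qpop_plate(wells, n_design_rows = n)
}

#' Simulate a plate readout from a ground-truth surface
#'
#' Raw design-well signal = control_scale * max(0, truth NCV + noise);
#' negative controls read near control_scale, positive (cytotoxic) controls
#' near zero. With \code{noise_sd = 0}, normalization recovers the truth
#' surface exactly at every design row and Z' = 1.
#'
#' @param truth a \code{qpop_surface} (typically from
#'   \code{\link{sample_truth_surface}}).
#' @param design a \code{\link{qpop_design}} over the same drugs.
#' @param config a \code{\link{qpop_sim_config}}.
#' @param seed optional seed override (defaults to \code{config$seed}).
#' @return a \code{\link{qpop_plate}}.
#' @export
simulate_plate <- function(truth, design, config, seed = config$seed) {
  stopifnot(inherits(truth, "qpop_surface"), inherits(design, "qpop_design"),
            inherits(config, "qpop_sim_config"))
  if (!identical(truth$drugs, design$drugs))
    stop("truth surface and design cover different drugs")
  set.seed(seed)
  .sim_plate(truth, design, config)
}

#' Simulate a patient cohort
#'
#' Each patient receives an independent ground-truth surface, one simulated
#' plate, an administered regimen sampled from the configured pool, and a
#' clinical label equal to the true-surface prediction
#' (true regimen NCV < 0.65) XOR-flipped with probability
#' \code{label_flip_eps}. Responders are assigned a CR/CRi/PR category;
#' non-responders NR. Disease stage (ND vs R/R) and ELN risk tags are drawn
#' with the configured proportions, independently of the surfaces.
#'
#' @param config a \code{\link{qpop_sim_config}}.
#' @return An object of class \code{qpop_cohort}: list with \code{design},
#'   \code{panel}, \code{patients} (data.frame: patient, regimen
#'   (semicolon-separated), clinical_response, nd_rr, eln_risk, true_ncv,
#'   true_responder, label_flipped), \code{plates} (list of
#'   \code{qpop_plate}), \code{truths} (list of \code{qpop_surface}) and
#'   \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "qpop_sim_config"))
  panel <- config$panel
  design <- generate_oacd(panel$k, drugs = panel$drugs)
  set.seed(config$seed)
  n <- config$cohort_size
  truths <- vector("list", n)
  plates <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    truths[[i]] <- .draw_truth(config, design)
    plates[[i]] <- .sim_plate(truths[[i]], design, config)
    regimen <- config$regimens[[
      sample.int(length(config$regimens), 1L, prob = config$regimen_probs)]]
    true_ncv <- predict_regimen_ncv(truths[[i]], regimen)
    true_resp <- true_ncv < 0.65
    flipped <- stats::runif(1) < config$label_flip_eps
    responds <- xor(true_resp, flipped)
    clinical <- if (responds)
      sample(c("CR", "CRi", "PR"), 1L, prob = c(0.7, 0.2, 0.1)) else "NR"
    rows[[i]] <- data.frame(
      patient = sprintf("P%04d", i),
      regimen = paste(regimen, collapse = ";"),
      clinical_response = clinical,
      nd_rr = if (stats::runif(1) < config$nd_prop) "ND" else "RR",
      eln_risk = sample(names(config$eln_probs), 1L,
                        prob = config$eln_probs),
      true_ncv = true_ncv,
      true_responder = true_resp,
      label_flipped = flipped,
      stringsAsFactors = FALSE)
  }
  structure(list(design = design, panel = panel,
                 patients = do.call(rbind, rows),
                 plates = plates, truths = truths, config = config),
            class = "qpop_cohort")
}

#' @export
print.qpop_cohort <- function(x, ...) {
  cat("qpop_cohort:", nrow(x$patients), "patients,",
      x$panel$k, "drugs,", nrow(x$design$codes), "design rows per plate\n")
  invisible(x)
}

#' Simulate serial runs with acquired resistance
#'
#' One patient, several consecutive runs: at the first run the named drug's
#' linear coefficient is set to \code{resistance_start} and the surface is
#' calibrated to the viability floor; each subsequent run adds
#' \code{resistance_drift} to that (calibrated) linear coefficient, capped
#' at 0, holding everything else fixed. The predicted single-drug NCV at top
#' dose therefore increases strictly across runs (until the cap), emulating
#' diminishing ex vivo sensitivity under acquired resistance (e.g. a FLT3
#' inhibitor under rising mutation allelic burden).
#'
#' @param config a \code{\link{qpop_sim_config}} with
#'   \code{resistance_drift > 0}.
#' @param n_runs number of consecutive runs (default 3).
#' @param drug resistant drug name (default \code{"midostaurin"}).
#' @return list with \code{truths} and \code{plates} (length n_runs),
#'   \code{design}, \code{drug}.
#' @export
simulate_serial_resistance <- function(config, n_runs = 3L,
                                       drug = "midostaurin") {
  stopifnot(inherits(config, "qpop_sim_config"), n_runs >= 1L)
  if (!drug %in% config$panel$drugs)
    stop("drug '", drug, "' is not in the panel")
  if (config$resistance_drift < 0) stop("resistance_drift must be >= 0")
  design <- generate_oacd(config$panel$k, drugs = config$panel$drugs)
  set.seed(config$seed)
  base <- .draw_truth(config, design)
  base$beta_lin[drug] <- config$resistance_start
  base <- .calibrate_floor(base, design, config$viability_floor)
  start <- base$beta_lin[[drug]]
  truths <- vector("list", n_runs)
  plates <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    tr <- base
    tr$beta_lin[drug] <- min(0, start + (r - 1L) * config$resistance_drift)
    truths[[r]] <- tr
    plates[[r]] <- .sim_plate(tr, design, config)
  }
  list(truths = truths, plates = plates, design = design, drug = drug)
}

#' Write a simulated plate in the pipeline's file formats
#'
#' Emits the readout (well, signal) and layout (well, role, design_row,
#' replicate) tables consumed by \code{\link{read_plate}}.
#'
#' @param plate a \code{\link{qpop_plate}}.
#' @param readout_path,layout_path output CSV paths.
#' @return invisible NULL.
#' @export
write_plate_csv <- function(plate, readout_path, layout_path) {
  stopifnot(inherits(plate, "qpop_plate"))
  utils::write.csv(plate[, c("well", "signal")], readout_path,
                   row.names = FALSE)
  utils::write.csv(plate[, c("well", "role", "design_row", "replicate")],
                   layout_path, row.names = FALSE)
  invisible(NULL)
}

#' Write a cohort's clinical table in the pipeline's file format
#'
#' @param cohort a \code{qpop_cohort} (or its \code{patients} data.frame).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_clinical_csv <- function(cohort, path) {
  df <- if (inherits(cohort, "qpop_cohort")) cohort$patients else cohort
  utils::write.csv(
    df[, intersect(c("patient", "regimen", "clinical_response", "nd_rr",
                     "eln_risk"), names(df))],
    path, row.names = FALSE)
  invisible(path)
}
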