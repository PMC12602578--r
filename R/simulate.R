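#' Simulation design for a synthetic multi-scanner radiomic cohort
#'
#' Captures the study conditions the generator emulates: several scanner
#' batches with per-(batch, feature) additive and multiplicative effects, a
#' per-patient global uptake factor on PET intensity features (the nuisance a
#' tumor-to-liver ratio cancels), a class-informative signal on a feature
#' subset, clinical covariates with a logistic link to outcome, and
#' segmentation replicates for ICC filtering.
#'
#' Scales: each feature has a positive base level `base_j` (log-normal across
#' features, constant across samples); `batch_shift_sd`, `noise_sd` and
#' `replicate_noise_sd` are coefficients of variation — SDs expressed as
#' multiples of `base_j` — while `batch_scale_sd` and `uptake_sd` are SDs of
#' log-normal multiplicative factors. All within-batch sample-to-sample
#' variation comes from the residual noise, so switching every noise source
#' off makes samples identical. `effect_size` is the standardized mean
#' difference between pCR and non-pCR samples on each informative feature
#' (in units of the within-class SD `noise_sd * base_j`; when `noise_sd = 0`
#' the effect falls back to `effect_size * base_j`).
#'
#' @param n_per_batch named integer vector, samples per scanner batch.
#' @param n_features_ct,n_features_pet feature counts per modality.
#' @param n_informative number of class-informative features. The signal is
#'   placed on PET intensity (non-shape) features — the premise of uptake
#'   normalization is that the discriminative metabolic signal rides on PET
#'   uptake features — spilling over to CT non-shape features only when
#'   `n_informative` exceeds the PET intensity count.
#' @param effect_size standardized pCR vs non-pCR mean difference.
#' @param batch_shift_sd SD of additive per-(batch, feature) shifts, as a
#'   multiple of the feature's base level.
#' @param batch_scale_sd SD of log per-(batch, feature) multiplicative factors.
#' @param uptake_sd SD of the log per-patient uptake factor applied to all
#'   PET intensity (non-shape) tumor and liver features.
#' @param noise_sd residual SD as a multiple of the feature's base level.
#' @param pcr_prevalence target marginal probability of pCR, in (0, 1).
#' @param clinical_or named odds ratios linking ER, PR, HER2 to pCR.
#' @param liver_noise_frac multiplier on `noise_sd` for the liver features:
#'   the liver VOI is a large homogeneous normal-tissue region, so its
#'   features carry much less residual noise than tumor features.
#' @param replicate_noise_sd SD of the segmentation-replicate perturbation,
#'   as a multiple of the feature's base level.
#' @param high_rep_noise_frac fraction of features given inflated replicate
#'   noise (poorly reproducible features the ICC filter should catch).
#' @param high_rep_noise_mult multiplier on `replicate_noise_sd` for those.
#' @param shape_frac fraction of features per modality flagged shape/volume.
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#'
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(n_per_batch = c(scanner1 = 50, scanner2 = 50,
                                              scanner3 = 50),
                              n_features_ct = 100, n_features_pet = 100,
                              n_informative = 20, effect_size = 0.8,
                              batch_shift_sd = 0.5, batch_scale_sd = 0.2,
                              uptake_sd = 0.3, noise_sd = 0.5,
                              pcr_prevalence = 0.35,
                              clinical_or = c(ER = 2.5, PR = 2, HER2 = 2),
                              liver_noise_frac = 0.2,
                              replicate_noise_sd = 0.2,
                              high_rep_noise_frac = 0.1,
                              high_rep_noise_mult = 10,
                              shape_frac = 0.1, seed = 7L) {
  design <- list(n_per_batch = n_per_batch, n_features_ct = n_features_ct,
                 n_features_pet = n_features_pet,
                 n_informative = n_informative, effect_size = effect_size,
                 batch_shift_sd = batch_shift_sd,
                 batch_scale_sd = batch_scale_sd, uptake_sd = uptake_sd,
                 noise_sd = noise_sd, pcr_prevalence = pcr_prevalence,
                 clinical_or = clinical_or,
                 liver_noise_frac = liver_noise_frac,
                 replicate_noise_sd = replicate_noise_sd,
                 high_rep_noise_frac = high_rep_noise_frac,
                 high_rep_noise_mult = high_rep_noise_mult,
                 shape_frac = shape_frac, seed = as.integer(seed))
  class(design) <- "simulation_design"
  validate_design(design)
  design
}

validate_design <- function(d) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid simulation design: '", field, "' ", msg,
                  call. = FALSE)
  }
  chk(length(d$n_per_batch) >= 1 && all(d$n_per_batch >= 1),
      "n_per_batch", "must be positive counts")
  chk(!is.null(names(d$n_per_batch)) && !anyDuplicated(names(d$n_per_batch)),
      "n_per_batch", "must have unique batch names")
  chk(d$n_features_ct >= 1, "n_features_ct", "must be positive")
  chk(d$n_features_pet >= 1, "n_features_pet", "must be positive")
  chk(d$n_informative >= 0 &&
        d$n_informative <= d$n_features_ct + d$n_features_pet,
      "n_informative", "must be in [0, n_features_ct + n_features_pet]")
  chk(d$pcr_prevalence > 0 && d$pcr_prevalence < 1,
      "pcr_prevalence", "must be strictly in (0, 1)")
  for (f in c("effect_size", "batch_shift_sd", "batch_scale_sd", "uptake_sd",
              "noise_sd", "replicate_noise_sd", "liver_noise_frac"))
    chk(is.numeric(d[[f]]) && length(d[[f]]) == 1 && d[[f]] >= 0, f,
        "must be a single non-negative number")
  chk(all(c("ER", "PR", "HER2") %in% names(d$clinical_or)) &&
        all(d$clinical_or > 0),
      "clinical_or", "must name positive odds ratios for ER, PR, HER2")
  chk(d$high_rep_noise_frac >= 0 && d$high_rep_noise_frac < 1,
      "high_rep_noise_frac", "must be in [0, 1)")
  chk(d$shape_frac >= 0 && d$shape_frac < 1, "shape_frac",
      "must be in [0, 1)")
  invisible(TRUE)
}

# intercept making the marginal pCR prevalence match the target, given three
# independent Bernoulli(1/2) covariates with the design's odds ratios
solve_intercept <- function(prevalence, log_or) {
  grid <- as.matrix(expand.grid(ER = 0:1, PR = 0:1, HER2 = 0:1))
  lp <- drop(grid %*% log_or)
  f <- function(b0) mean(stats::plogis(b0 + lp)) - prevalence
  stats::uniroot(f, c(-30, 30))$root
}

#' Simulate a synthetic multi-scanner cohort with known ground truth
#'
#' Generates tumor CT + PET feature tables, matched liver PET features, and
#' three segmentation-replicate tables, under the model
#' `value = (base + effect * informative * pCR + batch_shift) * batch_scale *
#' uptake^is_pet_intensity + noise`, with positive per-feature base levels so
#' tumor-to-liver ratios are well defined. PET shape/volume features are
#' geometric and receive no uptake factor. Outcome is drawn with a logistic
#' dependence on ER/PR/HER2. Dividing a PET tumor feature by its liver
#' counterpart cancels the patient's uptake factor exactly when
#' `noise_sd = 0`.
#'
#' @param design a [simulation_design()].
#' @return a `synthetic_cohort` list with elements `tumor_table`,
#'   `liver_table`, `replicates` (tables `rep_1a`, `rep_1b`, `rep_2`), and
#'   `truth` (informative feature ids, per-patient uptake factors, per-batch
#'   shift/scale matrices, per-feature base levels, class effects,
#'   high-replicate-noise feature ids, logistic intercept), plus the design.
#' @export
simulate_cohort <- function(design) {
  validate_design(design)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(design$seed)

  n <- sum(design$n_per_batch)
  batches <- rep(names(design$n_per_batch), design$n_per_batch)
  sample_id <- sprintf("S%03d", seq_len(n))

  ## clinical covariates and outcome
  clin <- data.frame(ER = stats::rbinom(n, 1, 0.5),
                     PR = stats::rbinom(n, 1, 0.5),
                     HER2 = stats::rbinom(n, 1, 0.5))
  log_or <- log(design$clinical_or[c("ER", "PR", "HER2")])
  b0 <- solve_intercept(design$pcr_prevalence, log_or)
  p_pcr <- stats::plogis(b0 + as.matrix(clin) %*% log_or)
  pcr <- stats::rbinom(n, 1, p_pcr)
  outcome <- ifelse(pcr == 1, "pCR", "non-pCR")

  ## feature metadata; the first shape_frac features per modality are
  ## geometric (shape/volume)
  p_ct <- design$n_features_ct
  p_pet <- design$n_features_pet
  p <- p_ct + p_pet
  modality <- rep(c("CT", "PET"), c(p_ct, p_pet))
  feature_id <- c(sprintf("ct_f%03d", seq_len(p_ct)),
                  sprintf("pet_f%03d", seq_len(p_pet)))
  n_shape_ct <- floor(design$shape_frac * p_ct)
  n_shape_pet <- floor(design$shape_frac * p_pet)
  is_shape <- c(seq_len(p_ct) <= n_shape_ct, seq_len(p_pet) <= n_shape_pet)
  feature_id[is_shape] <- sub("_f", "_shape", feature_id[is_shape])
  family <- ifelse(is_shape, "shape", "firstorder")
  fmeta <- data.frame(feature_id = feature_id, modality = modality,
                      family = family, is_shape = as.integer(is_shape))

  ## positive per-feature base levels
  base <- exp(stats::runif(p, 1, 3))

  ## informative features: PET intensity first (the metabolic signal), CT
  ## non-shape as spill-over; the class effect is expressed in units of the
  ## within-class SD (noise_sd * base), so the standardized mean difference
  ## equals effect_size
  pet_int_idx <- which(modality == "PET" & !is_shape)
  ct_int_idx <- which(modality == "CT" & !is_shape)
  n_pet_inf <- min(design$n_informative, length(pet_int_idx))
  informative <- sample(pet_int_idx, n_pet_inf)
  if (design$n_informative > n_pet_inf)
    informative <- c(informative,
                     sample(ct_int_idx, design$n_informative - n_pet_inf))
  informative <- sort(informative)
  eff_unit <- if (design$noise_sd > 0) design$noise_sd * base else base
  effect <- numeric(p)
  effect[informative] <- design$effect_size * eff_unit[informative]

  ## batch effects
  nb <- length(design$n_per_batch)
  shift <- matrix(stats::rnorm(nb * p, 0, design$batch_shift_sd), nb, p,
                  dimnames = list(names(design$n_per_batch), feature_id))
  shift <- sweep(shift, 2, base, `*`)
  scale <- matrix(exp(stats::rnorm(nb * p, 0, design$batch_scale_sd)), nb, p,
                  dimnames = list(names(design$n_per_batch), feature_id))

  ## per-patient uptake factor on PET intensity features
  uptake <- exp(stats::rnorm(n, 0, design$uptake_sd))
  pet_intensity <- modality == "PET" & !is_shape

  bidx <- match(batches, names(design$n_per_batch))
  signal <- matrix(base, n, p, byrow = TRUE) +
    outer(pcr, effect) +
    shift[bidx, , drop = FALSE]
  upfac <- matrix(1, n, p)
  upfac[, pet_intensity] <- uptake
  noise <- matrix(stats::rnorm(n * p), n, p) *
    matrix(design$noise_sd * base, n, p, byrow = TRUE)
  vals <- signal * scale[bidx, , drop = FALSE] * upfac + noise
  dimnames(vals) <- list(sample_id, feature_id)

  smeta <- data.frame(sample_id = sample_id, batch = batches,
                      outcome = outcome, clin)
  tumor <- feature_table(vals, smeta, fmeta, feature_type = "raw")

  ## liver PET features: one per PET intensity tumor feature, no class
  ## effect, same uptake factor, milder feature-to-feature spread
  liv_idx <- which(pet_intensity)
  p_liv <- length(liv_idx)
  base_liv <- exp(stats::runif(p_liv, 1.5, 2.5))
  shift_liv <- matrix(stats::rnorm(nb * p_liv, 0, design$batch_shift_sd),
                      nb, p_liv) * matrix(base_liv, nb, p_liv, byrow = TRUE)
  scale_liv <- matrix(exp(stats::rnorm(nb * p_liv, 0, design$batch_scale_sd)),
                      nb, p_liv)
  noise_liv <- matrix(stats::rnorm(n * p_liv), n, p_liv) *
    matrix(design$liver_noise_frac * design$noise_sd * base_liv, n, p_liv,
           byrow = TRUE)
  vals_liv <- (matrix(base_liv, n, p_liv, byrow = TRUE) +
                 shift_liv[bidx, , drop = FALSE]) *
    scale_liv[bidx, , drop = FALSE] * uptake + noise_liv
  dimnames(vals_liv) <- list(sample_id, feature_id[liv_idx])
  fmeta_liv <- fmeta[liv_idx, , drop = FALSE]
  rownames(fmeta_liv) <- NULL
  liver <- feature_table(vals_liv, smeta, fmeta_liv, feature_type = "liver")

  ## segmentation replicates: tumor plus independent perturbations, with a
  ## subset of features made poorly reproducible
  n_noisy <- floor(design$high_rep_noise_frac * p)
  noisy_feats <- sort(sample(seq_len(p), n_noisy))
  rep_sd <- rep(design$replicate_noise_sd, p)
  rep_sd[noisy_feats] <- rep_sd[noisy_feats] * design$high_rep_noise_mult
  rep_sd_abs <- rep_sd * base
  one_rep <- function(tag) {
    pert <- matrix(stats::rnorm(n * p), n, p) *
      matrix(rep_sd_abs, n, p, byrow = TRUE)
    feature_table(vals + pert, smeta, fmeta, feature_type = tag)
  }
  replicates <- list(rep_1a = one_rep("rep_1a"), rep_1b = one_rep("rep_1b"),
                     rep_2 = one_rep("rep_2"))

  truth <- list(informative = feature_id[informative],
                uptake = stats::setNames(uptake, sample_id),
                batch_shift = shift, batch_scale = scale,
                base = stats::setNames(base, feature_id),
                class_effect = stats::setNames(effect, feature_id),
                high_rep_noise = feature_id[noisy_feats],
                intercept = b0, log_or = log_or)

  structure(list(tumor_table = tumor, liver_table = liver,
                 replicates = replicates, truth = truth, design = design),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$tumor_table$values), " samples, ",
      ncol(x$tumor_table$values), " tumor features (",
      length(x$truth$informative), " informative), ",
      ncol(x$liver_table$values), " liver features\n", sep = "")
  invisible(x)
}

#' Monte-Carlo Bayes AUC of the oracle score for a design
#'
#' The recovery ceiling for the pipeline: the AUC attained by the oracle
#' linear discriminant that knows the informative features, their class
#' effects and the within-class variance (batch and uptake nuisances, which
#' the pipeline removes, are not simulated here). Estimated by Monte Carlo on
#' the clean signal scale with the score `sum_j effect_j * x_j / var_j`. For
#' a single informative feature with standardized effect d this converges to
#' `pnorm(d / sqrt(2))`, the two-Gaussian AUC.
#'
#' @param design a [simulation_design()].
#' @param n_mc Monte-Carlo draws per class (default 1e5).
#' @return estimated AUC in `[0.5, 1]` (0.5 exactly when `effect_size = 0`
#'   or `n_informative = 0`).
#' @export
bayes_auc <- function(design, n_mc = 1e5) {
  validate_design(design)
  if (design$n_informative == 0 || design$effect_size == 0) return(0.5)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(design$seed)

  # on the clean scale each informative feature is Gaussian with mean shift
  # effect_size * sigma_j, so after the score's 1/sigma_j^2 weighting the
  # per-feature base levels drop out; unit-scale draws suffice
  k <- design$n_informative
  d <- design$effect_size
  s_neg <- drop(matrix(stats::rnorm(n_mc * k), n_mc, k) %*% rep(d, k))
  s_pos <- drop(matrix(stats::rnorm(n_mc * k), n_mc, k) %*% rep(d, k)) +
    k * d^2
  r <- rank(c(s_pos, s_neg))
  (sum(r[seq_len(n_mc)]) - n_mc * (n_mc + 1) / 2) / (n_mc^2)
}

#' Write a synthetic cohort to CSV/JSON files
#'
#' Writes `tumor*.csv`, `liver*.csv`, `replicate_{1a,1b,2}*.csv` per the
#' [write_feature_table()] convention, plus `samples.csv` and `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(cohort$tumor_table, file.path(dir, "tumor"))
  write_feature_table(cohort$liver_table, file.path(dir, "liver"))
  write_feature_table(cohort$replicates$rep_1a, file.path(dir, "replicate_1a"))
  write_feature_table(cohort$replicates$rep_1b, file.path(dir, "replicate_1b"))
  write_feature_table(cohort$replicates$rep_2, file.path(dir, "replicate_2"))
  utils::write.csv(cohort$tumor_table$sample_meta,
                   file.path(dir, "samples.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth$batch_shift <- as.data.frame(truth$batch_shift)
  truth$batch_scale <- as.data.frame(truth$batch_scale)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}
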