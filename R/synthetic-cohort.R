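#' Parameters for a synthetic NPDR cohort table
#'
#' Describes an eye-level cohort of nonproliferative diabetic retinopathy
#' (NPDR) patients with stage-dependent covariate distributions. Defaults
#' emulate a 35-patient / ~58-eye macular ischemia cohort: stage mix
#' 19/24/15 (mild/moderate/severe), mean age 61.8 (SD 12.1) years, overall
#' HbA1c near 7.6% (SD ~1.5), visual acuity near 81 ETDRS letters, diabetes
#' duration near 18 years, 63% men, 83% on insulin. Image-derived metrics
#' (FAZ surface/perimeter/grade, nonperfusion index, deep-plexus
#' nonperfused area) are drawn from stage-dependent normals so downstream
#' group comparisons have a known direction of effect.
#'
#' Per-stage entries are length-3 vectors ordered mild, moderate, severe.
#'
#' @param n_patients number of patients.
#' @param second_eye_prob probability that a patient contributes both eyes
#'   (default 23/35, giving 58 expected eyes from 35 patients).
#' @param stage_proportions length-3 nonnegative weights (mild, moderate,
#'   severe) summing to 1.
#' @param age,hba1c,bcva,duration,faz_area,npi,dcp_area,disruption lists
#'   with `mean` (scalar for age, per-stage length-3 otherwise) and `sd`.
#' @param perimeter_shape perimeter inflation over the circle of equal area
#'   (1 = perfect circle); log-normal jitter with `perimeter_log_sd`.
#' @param perimeter_log_sd see above.
#' @param smoking_prev per-stage smoking prevalence.
#' @param male_prob,insulin_prob,oral_med_prob,type2_prob patient-level
#'   Bernoulli probabilities.
#' @param seed RNG seed.
#' @return a validated `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 35L,
                          second_eye_prob = 23 / 35,
                          stage_proportions = c(19, 24, 15) / 58,
                          age = list(mean = 61.8, sd = 12.1),
                          hba1c = list(mean = c(7.0, 7.6, 8.3), sd = 1.4),
                          bcva = list(mean = c(85, 81, 76), sd = 12),
                          duration = list(mean = c(15, 18, 22), sd = 9),
                          faz_area = list(mean = c(0.32, 0.42, 0.56), sd = 0.12),
                          npi = list(mean = c(0.24, 0.29, 0.35), sd = 0.06),
                          dcp_area = list(mean = c(0.45, 0.65, 0.95), sd = 0.25),
                          disruption = list(mean = c(0.06, 0.30, 0.60), sd = 0.15),
                          perimeter_shape = 1.15,
                          perimeter_log_sd = 0.05,
                          smoking_prev = c(0.45, 0.55, 0.65),
                          male_prob = 22 / 35,
                          insulin_prob = 29 / 35,
                          oral_med_prob = 22 / 35,
                          type2_prob = 30 / 35,
                          seed = 1L) {
  if (n_patients < 1) stop_param("`n_patients` must be at least 1")
  if (length(stage_proportions) != 3L || any(stage_proportions < 0)) {
    stop_param("`stage_proportions` must be 3 nonnegative values")
  }
  if (abs(sum(stage_proportions) - 1) > 1e-9) {
    stop_param("`stage_proportions` must sum to 1 (within 1e-9)")
  }
  check_fraction(second_eye_prob, "second_eye_prob")
  for (nm in c("age", "hba1c", "bcva", "duration", "faz_area", "npi",
               "dcp_area", "disruption")) {
    x <- get(nm)
    if (!is.list(x) || is.null(x$mean) || is.null(x$sd) || any(x$sd < 0)) {
      stop_param("`", nm, "` must be list(mean=, sd=) with nonnegative sd")
    }
  }
  if (length(smoking_prev) != 3L || any(smoking_prev < 0 | smoking_prev > 1)) {
    stop_param("`smoking_prev` must be 3 probabilities")
  }
  structure(list(
    n_patients = as.integer(n_patients), second_eye_prob = second_eye_prob,
    stage_proportions = stage_proportions, age = age, hba1c = hba1c,
    bcva = bcva, duration = duration, faz_area = faz_area, npi = npi,
    dcp_area = dcp_area, disruption = disruption,
    perimeter_shape = perimeter_shape, perimeter_log_sd = perimeter_log_sd,
    smoking_prev = smoking_prev, male_prob = male_prob,
    insulin_prob = insulin_prob, oral_med_prob = oral_med_prob,
    type2_prob = type2_prob, seed = as.integer(seed)
  ), class = "cohort_params")
}

#' Stage levels used throughout the package
#' @export
npdr_stages <- function() c("mild", "moderate", "severe")

stage_mean <- function(dist, stage_idx) {
  m <- dist$mean
  if (length(m) == 1L) rep(m, length(stage_idx)) else m[stage_idx]
}

#' Generate a synthetic eye-level cohort table
#'
#' One row per eye; fellow eyes share `patient_id` and the patient-level
#' covariates (age, sex, HbA1c, diabetes duration, smoking, insulin, oral
#' medication, diabetes type), which are drawn from the distributions of
#' the patient's worse-stage eye. Eye-level stage labels are sampled from
#' `stage_proportions`; eye-level metrics from the per-stage distributions.
#' Reproducible under the seed in `params`.
#'
#' @param params a [cohort_params()] object.
#' @return a data.frame with columns `patient_id`, `eye_id`, `eye_side`,
#'   `stage` (ordered factor mild < moderate < severe), `age`, `sex_male`,
#'   `type2_diabetes`, `hba1c_percent`, `diabetes_duration_years`,
#'   `smoking`, `insulin`, `oral_medication`, `bcva_letters`,
#'   `faz_surface_mm2`, `faz_perimeter_mm`, `faz_grade`, `npi`,
#'   `dcp_area_mm2`.
#' @examples
#' head(generate_cohort(cohort_params(seed = 42)))
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) {
    params <- do.call(cohort_params, as.list(params))
  }
  p <- params
  with_seed(p$seed, {
    n_eyes_per <- 1L + rbinom(p$n_patients, 1L, p$second_eye_prob)
    n_eyes <- sum(n_eyes_per)
    pat <- rep(seq_len(p$n_patients), n_eyes_per)
    side <- unlist(lapply(n_eyes_per, function(k) c("OD", "OS")[seq_len(k)]),
                   use.names = FALSE)
    stage_idx <- sample.int(3L, n_eyes, replace = TRUE,
                            prob = p$stage_proportions)
    # patient-level covariates follow the worse eye
    worst <- tapply(stage_idx, pat, max)
    age <- round(pmax(18, rnorm(p$n_patients, p$age$mean, p$age$sd)))
    hba1c <- round(pmax(4.5, rnorm(p$n_patients, stage_mean(p$hba1c, worst),
                                   p$hba1c$sd)), 1)
    dur <- round(pmax(1, rnorm(p$n_patients, stage_mean(p$duration, worst),
                               p$duration$sd)), 1)
    smoking <- rbinom(p$n_patients, 1L, p$smoking_prev[worst])
    sex_male <- rbinom(p$n_patients, 1L, p$male_prob)
    insulin <- rbinom(p$n_patients, 1L, p$insulin_prob)
    oral <- rbinom(p$n_patients, 1L, p$oral_med_prob)
    type2 <- rbinom(p$n_patients, 1L, p$type2_prob)

    bcva <- round(pmin(100, pmax(5, rnorm(n_eyes, stage_mean(p$bcva, stage_idx),
                                          p$bcva$sd))))
    faz_area <- pmax(0.05, rnorm(n_eyes, stage_mean(p$faz_area, stage_idx),
                                 p$faz_area$sd))
    perim <- p$perimeter_shape * 2 * sqrt(pi * faz_area) *
      exp(rnorm(n_eyes, 0, p$perimeter_log_sd))
    disrupt <- pmin(1, pmax(0, rnorm(n_eyes, stage_mean(p$disruption, stage_idx),
                                     p$disruption$sd)))
    npi <- pmin(1, pmax(0, rnorm(n_eyes, stage_mean(p$npi, stage_idx),
                                 p$npi$sd)))
    dcp <- pmax(0, rnorm(n_eyes, stage_mean(p$dcp_area, stage_idx),
                         p$dcp_area$sd))

    data.frame(
      patient_id = sprintf("P%03d", pat),
      eye_id = sprintf("P%03d_%s", pat, side),
      eye_side = side,
      stage = factor(npdr_stages()[stage_idx], levels = npdr_stages(),
                     ordered = TRUE),
      age = age[pat],
      sex_male = sex_male[pat],
      type2_diabetes = type2[pat],
      hba1c_percent = hba1c[pat],
      diabetes_duration_years = dur[pat],
      smoking = smoking[pat],
      insulin = insulin[pat],
      oral_medication = oral[pat],
      bcva_letters = bcva,
      faz_surface_mm2 = faz_area,
      faz_perimeter_mm = perim,
      faz_grade = grade_faz(disrupt),
      npi = npi,
      dcp_area_mm2 = dcp,
      stringsAsFactors = FALSE
    )
  })
}

#' Cohort descriptive statistics
#'
#' Eye-level stage counts and percentages, patient-level counts and
#' percentages for the binary covariates, and mean/SD summaries of the
#' quantitative covariates — the descriptives reported ahead of group
#' comparisons (qualitative variables as number and percentage,
#' quantitative as mean and standard deviation).
#'
#' @param table an eye-level cohort data.frame (see [generate_cohort()]).
#' @return a `cohort_descriptives` list with `n_eyes`, `n_patients`,
#'   `stage` (count + pct per stage), `patient_binary` (count + pct for
#'   sex/insulin/oral medication/smoking/type 2), and `quantitative`
#'   (mean + sd for age, HbA1c, duration, BCVA).
#' @export
cohort_descriptives <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_param("`table` must be a non-empty cohort data.frame")
  }
  n_eyes <- nrow(table)
  stages <- factor(as.character(table$stage), levels = npdr_stages())
  stage_n <- as.integer(table(stages))
  stage_df <- data.frame(stage = npdr_stages(), n = stage_n,
                         pct = 100 * stage_n / n_eyes)
  pt <- table[!duplicated(table$patient_id), , drop = FALSE]
  n_pat <- nrow(pt)
  bin_vars <- intersect(c("sex_male", "insulin", "oral_medication",
                          "smoking", "type2_diabetes"), names(pt))
  bins <- do.call(rbind, lapply(bin_vars, function(v) {
    k <- sum(pt[[v]] == 1, na.rm = TRUE)
    data.frame(variable = v, n = k, pct = 100 * k / n_pat)
  }))
  quant_vars <- intersect(c("age", "hba1c_percent", "diabetes_duration_years"),
                          names(pt))
  quants <- do.call(rbind, lapply(quant_vars, function(v) {
    data.frame(variable = v, mean = mean(pt[[v]], na.rm = TRUE),
               sd = sd(pt[[v]], na.rm = TRUE))
  }))
  if ("bcva_letters" %in% names(table)) {
    quants <- rbind(quants, data.frame(variable = "bcva_letters",
                                       mean = mean(table$bcva_letters, na.rm = TRUE),
                                       sd = sd(table$bcva_letters, na.rm = TRUE)))
  }
  structure(list(n_eyes = n_eyes, n_patients = n_pat, stage = stage_df,
                 patient_binary = bins, quantitative = quants),
            class = "cohort_descriptives")
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  cat(sprintf("Cohort: %d eyes of %d patients\n", x$n_eyes, x$n_patients))
  cat("Stage distribution (eyes):\n")
  print(transform(x$stage, pct = round(pct, 1)), row.names = FALSE)
  if (!is.null(x$patient_binary) && nrow(x$patient_binary)) {
    cat("Patient-level factors:\n")
    print(transform(x$patient_binary, pct = round(pct, 1)), row.names = FALSE)
  }
  invisible(x)
}
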