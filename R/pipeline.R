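#' Cohort-level statistical analysis of OCTA ischemia metrics
#'
#' Runs the full statistical workflow over an eye-level table: cohort
#' descriptives; Kruskal-Wallis comparisons of the five image metrics (FAZ
#' grade, surface, perimeter, superficial-plexus nonperfusion index,
#' deep-plexus central nonperfused area) across NPDR stages; Fisher exact
#' comparisons of the qualitative factors; univariate screens of each FAZ
#' parameter and the NPI; and a backward-elimination covariance model per
#' outcome. Eyes are treated as independent observations (no
#' intraclass-correlation correction).
#'
#' @param table eye-level cohort data.frame (see [generate_cohort()] for
#'   the column contract).
#' @param config a [run_config()].
#' @return a `report` list: `meta` (config, config hash, seed, package
#'   version, eye/patient counts), `descriptives`, `group_comparisons`
#'   (data.frame), `categorical_comparisons` (data.frame), `screens`
#'   (one data.frame per outcome), `models` (retained terms + elimination
#'   trace per outcome).
#' @export
analyze_cohort <- function(table, config = run_config()) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_validation("empty cohort: nothing to analyze")
  }
  if (!all(c("stage", "patient_id") %in% names(table))) {
    stop_validation("cohort table must have `patient_id` and `stage` columns")
  }
  desc <- cohort_descriptives(table)

  metric_vars <- intersect(c("faz_grade", "faz_surface_mm2", "faz_perimeter_mm",
                             "npi", "dcp_area_mm2"), names(table))
  comparisons <- do.call(rbind, lapply(metric_vars, function(v) {
    cg <- compare_groups(table, v)
    data.frame(variable = v, test = cg$test, statistic = cg$statistic,
               df = cg$df, p_value = cg$p_value)
  }))

  cat_vars <- intersect(c("sex_male", "smoking", "insulin", "oral_medication",
                          "type2_diabetes"), names(table))
  categorical <- do.call(rbind, lapply(cat_vars, function(v) {
    cg <- suppressWarnings(compare_groups_categorical(table, v))
    data.frame(variable = v, test = cg$test, p_value = cg$p_value)
  }))

  outcomes <- intersect(c("faz_grade", "faz_surface_mm2", "faz_perimeter_mm",
                          "npi"), names(table))
  screens <- lapply(outcomes, function(oc) univariate_screen(table, oc))
  names(screens) <- outcomes
  models <- lapply(outcomes, function(oc) {
    fit <- suppressWarnings(
      fit_multivariate(table, oc, entry_p = config$entry_p,
                       stay_p = config$stay_p)
    )
    list(outcome = oc, transformation = fit$transformation,
         n_used = fit$n_used, candidates = fit$candidates,
         retained = fit$retained, trace = fit$trace)
  })
  names(models) <- outcomes

  list(
    meta = list(config = unclass(config), config_hash = config_hash(config),
                seed = config$seed,
                package_version = as.character(utils::packageVersion("octaquant")),
                n_eyes = desc$n_eyes, n_patients = desc$n_patients),
    descriptives = list(stage = desc$stage,
                        patient_binary = desc$patient_binary,
                        quantitative = desc$quantitative),
    group_comparisons = comparisons,
    categorical_comparisons = categorical,
    screens = screens,
    models = models
  )
}

#' End-to-end pipeline: images + contours + cohort table to report
#'
#' For each eye listed in the cohort CSV, reads the superficial-plexus
#' image (`<eye_id>_scp.png`), the traced FAZ contour (`<eye_id>.json` or
#' `.txt`), and optionally the deep-plexus image (`<eye_id>_dcp.png`);
#' computes NPI, FAZ surface/perimeter/grade (graded against the
#' above-threshold vessel mask of the superficial image) and the deep
#' central nonperfused area; merges the metrics into the table; and runs
#' [analyze_cohort()]. Eyes with a missing image or contour are excluded
#' and listed in the report.
#'
#' @param images_dir directory of PNG angiograms.
#' @param contours_dir directory of traced contours.
#' @param cohort_csv eye-level covariate CSV; must contain `eye_id`,
#'   `patient_id` and `stage` columns.
#' @param config a [run_config()].
#' @param out_dir if non-NULL, the report is written there via
#'   [write_report()].
#' @return the report list, with an `excluded` element naming skipped eyes.
#' @export
run_pipeline <- function(images_dir, contours_dir, cohort_csv,
                         config = run_config(), out_dir = NULL) {
  if (!file.exists(cohort_csv)) stop_io("cohort CSV not found: ", cohort_csv)
  tab <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop_validation("empty cohort: nothing to analyze")
  if (!all(c("eye_id", "patient_id", "stage") %in% names(tab))) {
    stop_validation("cohort CSV must have eye_id, patient_id and stage columns")
  }
  tab$stage <- factor(tab$stage, levels = npdr_stages(), ordered = TRUE)

  excluded <- character()
  mets <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    id <- tab$eye_id[i]
    scp_path <- file.path(images_dir, paste0(id, "_scp.png"))
    ctr_path <- Filter(file.exists,
                       file.path(contours_dir, paste0(id, c(".json", ".txt"))))
    if (!file.exists(scp_path) || length(ctr_path) == 0L) {
      excluded <- c(excluded, id)
      next
    }
    scp <- read_angiogram(scp_path, plexus = "superficial",
                          field_mm = config$field_mm, eye_id = id)
    contour <- read_contour(ctr_path[[1L]])
    arcade <- scp$pixels >= config$npi_threshold
    fm <- faz_metrics(contour, scp$scale, arcade_mask = arcade,
                      questionable_epsilon = config$questionable_epsilon)
    npi <- compute_npi(scp, threshold = config$npi_threshold,
                       inclusive = config$inclusive_threshold)$npi
    dcp_path <- file.path(images_dir, paste0(id, "_dcp.png"))
    dcp_area <- if (file.exists(dcp_path)) {
      dcp <- read_angiogram(dcp_path, plexus = "deep",
                            field_mm = config$field_mm, eye_id = id)
      suppressWarnings(
        measure_central_nonperfused_area(dcp, threshold = config$npi_threshold,
                                         inclusive = config$inclusive_threshold)$area_mm2
      )
    } else NA_real_
    mets[[i]] <- data.frame(eye_id = id, faz_surface_mm2 = fm$surface_mm2,
                            faz_perimeter_mm = fm$perimeter_mm,
                            faz_grade = fm$grade, npi = npi,
                            dcp_area_mm2 = dcp_area)
  }
  metrics <- do.call(rbind, mets)
  if (is.null(metrics) || nrow(metrics) == 0L) {
    stop_validation("no eye had both an image and a contour; nothing to analyze")
  }
  drop_cols <- intersect(names(tab), setdiff(names(metrics), "eye_id"))
  tab <- merge(tab[, setdiff(names(tab), drop_cols), drop = FALSE],
               metrics, by = "eye_id")
  report <- analyze_cohort(tab, config)
  report$excluded <- excluded
  report$metrics = metrics
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}
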