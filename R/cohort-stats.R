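#' Three-group comparison of a continuous variable (Kruskal-Wallis)
#'
#' Nonparametric ANOVA across the NPDR stage groups: tie-corrected
#' Kruskal-Wallis H with its chi-square p-value on k - 1 degrees of
#' freedom, alongside per-group n / mean / SD descriptives (the form in
#' which group results are reported).
#'
#' @param table eye-level cohort data.frame.
#' @param variable name of the numeric column to compare.
#' @param group name of the grouping column (default `"stage"`).
#' @return a `group_comparison` list: `variable`, `test`, `statistic`,
#'   `df`, `p_value`, and `groups` (data.frame of n, mean, sd per group).
#' @examples
#' co <- generate_cohort(cohort_params(seed = 3))
#' compare_groups(co, "npi")
#' @export
compare_groups <- function(table, variable, group = "stage") {
  x <- table[[variable]]
  g <- table[[group]]
  if (is.null(x) || is.null(g)) stop_param("column not found in table")
  if (!is.numeric(x)) stop_param("`", variable, "` must be numeric")
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- if (is.factor(g)) g[keep] else factor(g[keep])
  counts <- table(g)
  if (any(counts == 0L)) {
    warning("empty group(s) excluded: ",
            paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)
  }
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop_param("need at least 2 non-empty groups")
  desc <- do.call(rbind, lapply(levels(g), function(lv) {
    xi <- x[g == lv]
    data.frame(group = lv, n = length(xi), mean = mean(xi), sd = sd(xi))
  }))
  if (length(unique(x)) == 1L) {
    warning("all values tied: H = 0, p = 1", call. = FALSE)
    stat <- 0; p <- 1; df <- nlevels(g) - 1L
  } else {
    kw <- kruskal.test(x, g)
    stat <- unname(kw$statistic); p <- kw$p.value; df <- unname(kw$parameter)
  }
  structure(list(variable = variable, test = "Kruskal-Wallis",
                 statistic = stat, df = df, p_value = p, groups = desc),
            class = "group_comparison")
}

#' Three-group comparison of a categorical variable (Fisher exact)
#'
#' Builds the stage-by-level contingency table and tests it with the
#' Fisher exact test; all-zero rows or columns are dropped with a warning,
#' and a variable with a single observed level returns p = 1.
#'
#' @inheritParams compare_groups
#' @return a `group_comparison` list with the contingency `counts` table.
#' @export
compare_groups_categorical <- function(table, variable, group = "stage") {
  x <- table[[variable]]
  g <- table[[group]]
  if (is.null(x) || is.null(g)) stop_param("column not found in table")
  keep <- !is.na(x) & !is.na(g)
  xf <- if (is.factor(x)) x[keep] else factor(x[keep])
  gf <- if (is.factor(g)) droplevels(g[keep]) else factor(g[keep])
  tab <- table(xf, gf)
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("all-zero rows/columns dropped from contingency table",
            call. = FALSE)
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("degenerate contingency table (single level): p = 1",
            call. = FALSE)
    p <- 1
  } else {
    p <- fisher.test(tab, workspace = 2e7)$p.value
  }
  structure(list(variable = variable, test = "Fisher exact",
                 statistic = NA_real_, df = NA_integer_, p_value = p,
                 counts = tab),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s", x$variable, x$test))
  if (!is.na(x$statistic)) cat(sprintf(" H = %.4g (df = %d)", x$statistic, x$df))
  cat(sprintf(", p = %.4g\n", x$p_value))
  if (!is.null(x$groups)) print(x$groups, row.names = FALSE)
  invisible(x)
}

is_binary <- function(v) {
  u <- unique(v[!is.na(v)])
  length(u) == 2L
}

#' Univariate screen of an outcome against candidate covariates
#'
#' Spearman rank correlation (tie-corrected) for quantitative covariates
#' and the two-sided Mann-Whitney rank-sum test for binary factors — the
#' univariate step feeding the multivariate covariance model.
#'
#' @param table eye-level cohort data.frame.
#' @param outcome name of the numeric outcome column (e.g. `"npi"`,
#'   `"faz_surface_mm2"`, `"faz_perimeter_mm"`, `"faz_grade"`).
#' @param covariates covariate column names; defaults to the standard
#'   clinical set present in the table.
#' @return data.frame with `covariate`, `type` (`"spearman"` or
#'   `"mann_whitney"`), `statistic` (rho or U), `p_value`, ordered as
#'   given (this order also breaks ties during backward elimination).
#' @export
univariate_screen <- function(table, outcome, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(
      c("age", "sex_male", "type2_diabetes", "hba1c_percent",
        "diabetes_duration_years", "smoking", "insulin", "oral_medication",
        "bcva_letters"),
      setdiff(names(table), outcome)
    )
  }
  y <- table[[outcome]]
  if (is.null(y) || !is.numeric(y)) stop_param("`outcome` must name a numeric column")
  rows <- lapply(covariates, function(cv) {
    v <- table[[cv]]
    if (is.null(v)) stop_param("covariate `", cv, "` not found")
    keep <- !is.na(v) & !is.na(y)
    v <- v[keep]; yi <- y[keep]
    if (length(unique(v)) < 2L) {
      warning("constant covariate `", cv, "` skipped", call. = FALSE)
      return(NULL)
    }
    if (is_binary(v)) {
      lv <- sort(unique(v))
      wt <- suppressWarnings(wilcox.test(yi[v == lv[2L]], yi[v == lv[1L]],
                                         alternative = "two.sided"))
      data.frame(covariate = cv, type = "mann_whitney",
                 statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      ct <- suppressWarnings(cor.test(v, yi, method = "spearman",
                                      alternative = "two.sided"))
      data.frame(covariate = cv, type = "spearman",
                 statistic = unname(ct$estimate), p_value = ct$p.value)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(covariate = character(), type = character(),
                                      statistic = numeric(), p_value = numeric())
  rownames(out) <- NULL
  out
}

#' Multivariate covariance model with backward elimination
#'
#' Ordinary least-squares analysis of covariance for one outcome: the
#' candidate covariates (by default those passing the univariate screen at
#' `entry_p`) enter a linear model; the covariate with the largest
#' p-value at or above `stay_p` is removed and the model refit until every
#' retained covariate is independently significant. Ties in exit p-values
#' are broken by removing the later covariate in the declared candidate
#' order, so the elimination trace is deterministic. The outcome is
#' log-transformed when `log_transform = "auto"` finds non-normal
#' residuals (Shapiro-Wilk p < 0.05 on the full-model fit) and all outcome
#' values are positive.
#'
#' @param table eye-level cohort data.frame.
#' @param outcome numeric outcome column name.
#' @param candidates covariate names to consider; `NULL` runs
#'   [univariate_screen()] and takes covariates with p < `entry_p`, in
#'   screen order.
#' @param entry_p univariate entry threshold (default 0.20).
#' @param stay_p retention threshold in the multivariate model
#'   (default 0.05).
#' @param log_transform `"auto"`, `"on"` or `"off"`.
#' @return a `model_fit` list: `outcome`, `transformation` (`"log"` or
#'   `"identity"`), `retained` (term/estimate/se/p data.frame),
#'   `trace` (dropped covariate + exit p, in drop order), `candidates`,
#'   `n_used`, `screen` (the univariate screen when it was run).
#' @export
fit_multivariate <- function(table, outcome, candidates = NULL,
                             entry_p = 0.20, stay_p = 0.05,
                             log_transform = c("auto", "on", "off")) {
  log_transform <- match.arg(log_transform)
  screen <- NULL
  if (is.null(candidates)) {
    screen <- univariate_screen(table, outcome)
    candidates <- screen$covariate[screen$p_value < entry_p]
  }
  candidates <- as.character(candidates)
  y <- table[[outcome]]
  if (is.null(y) || !is.numeric(y)) stop_param("`outcome` must name a numeric column")

  dat <- table[, c(outcome, candidates), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n_used <- nrow(dat)
  if (length(candidates) > 0L && n_used <= length(candidates) + 2L) {
    stop_param("too few complete cases (", n_used, ") for ",
               length(candidates), " candidate covariates")
  }

  fit_lm <- function(yv, terms) {
    df <- dat[, terms, drop = FALSE]
    df$.y <- yv
    if (length(terms) == 0L) return(lm(.y ~ 1, data = df))
    lm(reformulate(terms, response = ".y"), data = df)
  }

  yv <- dat[[outcome]]
  use_log <- switch(log_transform,
    on = TRUE,
    off = FALSE,
    auto = {
      ok <- all(yv > 0)
      if (ok && length(candidates) > 0L) {
        res <- residuals(fit_lm(yv, candidates))
        length(res) >= 4L && shapiro.test(res)$p.value < 0.05
      } else if (ok) {
        length(yv) >= 4L && shapiro.test(yv)$p.value < 0.05
      } else FALSE
    })
  if (use_log && any(yv <= 0)) {
    warning("log transform requested but outcome has non-positive values; ",
            "using identity", call. = FALSE)
    use_log <- FALSE
  }
  if (use_log) yv <- log(yv)

  terms <- candidates
  trace <- data.frame(dropped = character(), exit_p = numeric())
  repeat {
    fit <- fit_lm(yv, terms)
    co <- summary(fit)$coefficients
    # collinear covariates are silently NA in lm; drop them first, by name
    alias <- setdiff(terms, rownames(co))
    if (length(alias) > 0L) {
      warning("collinear covariate dropped: ", alias[1L], call. = FALSE)
      trace <- rbind(trace, data.frame(dropped = alias[1L], exit_p = NA_real_))
      terms <- setdiff(terms, alias[1L])
      next
    }
    if (length(terms) == 0L) break
    pv <- setNames(co[terms, "Pr(>|t|)"], terms)
    pv[is.na(pv)] <- 1  # degenerate fits (zero residual variance)
    if (all(pv < stay_p)) break
    # largest p leaves; ties broken by later position in candidate order
    worst_p <- max(pv)
    tied <- terms[pv >= worst_p - .Machine$double.eps^0.5 & pv >= stay_p]
    drop_term <- tied[which.max(match(tied, candidates))]
    trace <- rbind(trace, data.frame(dropped = drop_term,
                                     exit_p = unname(pv[drop_term])))
    terms <- setdiff(terms, drop_term)
  }

  fit <- fit_lm(yv, terms)
  co <- summary(fit)$coefficients
  retained <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                         se = co[, "Std. Error"], p_value = co[, "Pr(>|t|)"])
  rownames(retained) <- NULL
  structure(list(outcome = outcome,
                 transformation = if (use_log) "log" else "identity",
                 retained = retained, trace = trace,
                 candidates = candidates, n_used = n_used,
                 screen = screen, fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Covariance model for %s (%s scale), n = %d\n",
              x$outcome, x$transformation, x$n_used))
  cat(sprintf("Candidates: %s\n",
              if (length(x$candidates)) paste(x$candidates, collapse = ", ")
              else "(none passed entry)"))
  print(transform(x$retained, estimate = signif(estimate, 4),
                  se = signif(se, 4), p_value = signif(p_value, 4)),
        row.names = FALSE)
  if (nrow(x$trace)) {
    cat("Eliminated (in order): ",
        paste(sprintf("%s (p=%.3g)", x$trace$dropped, x$trace$exit_p),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
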