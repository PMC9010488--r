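#' Reference cohort medians and interquartile intervals
#'
#' Per-group, per-muscle medians and interquartile intervals (25th-75th
#' percentile) of the three CrCEST outcomes in adults: healthy controls
#' (n = 22) and Friedreich's ataxia (n = 10). These parameterise the phantom
#' defaults and the synthetic cohort generator.
#'
#' @return Tibble with `group`, `muscle`, `outcome` (`resting_pct`,
#'   `delta_pct`, `tau_s`), `median`, `q25`, `q75`.
#' @export
crcest_reference_medians <- function() {
  tibble::tribble(
    ~group,    ~muscle, ~outcome,      ~median, ~q25, ~q75,
    "control", "LG",  "resting_pct",   6.2,   5.3,  8.2,
    "control", "MG",  "resting_pct",   5.9,   5.4,  7.5,
    "control", "Sol", "resting_pct",   6.6,   6.0,  7.0,
    "FRDA",    "LG",  "resting_pct",   5.9,   4.9,  6.4,
    "FRDA",    "MG",  "resting_pct",   6.3,   5.7,  7.0,
    "FRDA",    "Sol", "resting_pct",   7.0,   6.1,  7.4,
    "control", "LG",  "delta_pct",     8.9,   6.0, 10.4,
    "control", "MG",  "delta_pct",     5.0,   4.5,  5.8,
    "control", "Sol", "delta_pct",     3.4,   2.8,  4.7,
    "FRDA",    "LG",  "delta_pct",     5.2,   2.9,  9.1,
    "FRDA",    "MG",  "delta_pct",     3.5,   1.2,  5.5,
    "FRDA",    "Sol", "delta_pct",     3.9,   1.7,  6.6,
    "control", "LG",  "tau_s",       138,    85,  226,
    "control", "MG",  "tau_s",       184,    90,  263,
    "control", "Sol", "tau_s",       254,   184,  309,
    "FRDA",    "LG",  "tau_s",       274,   221,  309,
    "FRDA",    "MG",  "tau_s",       269,   240,  342,
    "FRDA",    "Sol", "tau_s",       210,   149,  266
  )
}

#' Null version of the reference medians
#'
#' Replaces the disease rows by the control rows so a cohort generated from
#' it carries no disease effect on any outcome; used for CI-coverage and
#' interaction null-calibration checks.
#'
#' @param medians Reference tibble, see [crcest_reference_medians()].
#' @return Tibble of the same shape with identical distributions per group.
#' @export
null_reference_medians <- function(medians = crcest_reference_medians()) {
  ctrl <- medians[medians$group == "control", ]
  frda <- ctrl
  frda$group <- "FRDA"
  dplyr::bind_rows(ctrl, frda)
}

#' Simulate a CrCEST study cohort
#'
#' Generates one row per (subject, muscle) with the three imaging outcomes
#' and the clinical covariates used by the model suites. Outcomes are centred
#' on the per-(group, muscle) medians of `medians`; their spread reproduces
#' the interquartile intervals. `tau_s` and `delta_pct` are generated
#' log-normally (positive, right-skewed, as observed), `resting_pct`
#' normally. Between-subject correlation across a subject's three muscles is
#' induced by a subject-level random intercept with intraclass correlation
#' `icc`. Fitted-status flags are set from the 24/1000 s plausibility bounds.
#'
#' @param n_control,n_frda Subjects per group.
#' @param medians Outcome parameter tibble, see [crcest_reference_medians()].
#' @param icc Intraclass correlation of the subject random effect.
#' @param sd_scale Multiplier on all outcome spreads.
#' @param seed Integer seed.
#' @return A cohort tibble (one row per subject x muscle).
#' @export
simulate_cohort <- function(n_control = 22, n_frda = 10,
                            medians = crcest_reference_medians(),
                            icc = 0.65, sd_scale = 1, seed = 1L) {
  set.seed(seed)
  n <- n_control + n_frda
  subjects <- tibble::tibble(
    subject = sprintf("S%03d", seq_len(n)),
    disease = factor(rep(c("control", "FRDA"), c(n_control, n_frda)),
                     levels = c("control", "FRDA"))
  )
  is_frda <- subjects$disease == "FRDA"
  subjects$sex <- factor(
    ifelse(runif(n) < ifelse(is_frda, 0.36, 0.44), "F", "M"),
    levels = c("F", "M"))
  subjects$age <- pmin(pmax(round(exp(rnorm(n, log(ifelse(is_frda, 27, 29)), 0.22))), 18), 65)
  subjects$BMI <- rnorm(n, ifelse(is_frda, 26.9, 24.4), 3.5)
  subjects$waist_cm <- rnorm(n, ifelse(is_frda, 99, 93), 10)
  subjects$total_activity <- exp(rnorm(n, log(ifelse(is_frda, 11.1, 19.2)),
                                       ifelse(is_frda, 0.8, 0.45)))
  subjects$height_cm <- rnorm(n, ifelse(subjects$sex == "M", 176, 163), 7)
  subjects$leg_lean_mass <- pmax(rnorm(n, ifelse(subjects$sex == "M", 9.5, 7.0), 1.4), 3)
  subjects$leg_fat_mass <- pmax(rnorm(n, ifelse(is_frda, 4.2, 3.4), 1.3), 0.5)

  grid <- tidyr::expand_grid(subjects,
                             muscle = factor(muscle_levels(),
                                             levels = muscle_levels()))
  params <- medians
  params$sd <- (params$q75 - params$q25) / 1.349 * sd_scale
  params$sdlog <- log(params$q75 / params$q25) / 1.349 * sd_scale

  draw <- function(outcome, lognormal) {
    p <- params[params$outcome == outcome, ]
    key <- match(paste(as.character(grid$disease), as.character(grid$muscle)),
                 paste(p$group, p$muscle))
    if (lognormal) {
      s <- p$sdlog[key]
      b <- rnorm(n, 0, 1)[match(grid$subject, subjects$subject)]
      exp(log(p$median[key]) + s * (sqrt(icc) * b + sqrt(1 - icc) * rnorm(nrow(grid))))
    } else {
      s <- p$sd[key]
      b <- rnorm(n, 0, 1)[match(grid$subject, subjects$subject)]
      p$median[key] + s * (sqrt(icc) * b + sqrt(1 - icc) * rnorm(nrow(grid)))
    }
  }
  grid$resting_pct <- draw("resting_pct", lognormal = FALSE)
  grid$delta_pct <- draw("delta_pct", lognormal = TRUE)
  grid$tau_s <- draw("tau_s", lognormal = TRUE)
  grid$status <- ifelse(grid$tau_s < 24, "excluded_low",
                        ifelse(grid$tau_s > 1000, "excluded_high", "ok"))
  grid
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @return The Shapiro-Wilk p-value.
#' @export
test_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    abort("Normality testing needs at least 3 observations.",
          class = "crcest_data_error")
  }
  if (diff(range(values)) == 0) {
    abort("Normality test undefined for constant input.",
          class = "crcest_data_error")
  }
  shapiro.test(values)$p.value
}

#' Two-group rank comparison (Kruskal-Wallis)
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return Tibble with `statistic` (chi-squared) and `p.value`. When every
#'   value is tied across both groups the statistic is 0 and p = 1.
#' @export
compare_groups_rank <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("Both groups must be non-empty.", class = "crcest_data_error")
  }
  pooled <- c(values_a, values_b)
  if (diff(range(pooled)) == 0) {
    return(tibble::tibble(statistic = 0, p.value = 1))
  }
  kt <- kruskal.test(list(values_a, values_b))
  tibble::tibble(statistic = unname(kt$statistic), p.value = kt$p.value)
}

# fixed-effect formulas of the declared model suites
suite_terms <- function(outcome, model) {
  base <- c("age", "sex", "disease")
  if (outcome == "resting_pct") {
    extra <- switch(as.character(model),
      "1" = character(),
      "2" = "BMI",
      "3" = c("height_cm", "leg_lean_mass"),
      "4" = c("height_cm", "leg_fat_mass"),
      abort("resting models are 1-4.", class = "crcest_schema_error"))
    c(base, "muscle", extra)
  } else if (outcome %in% c("delta_pct", "tau_s")) {
    c(base, "disease:muscle", "muscle")
  } else {
    abort(sprintf("Unknown outcome '%s'.", outcome), class = "crcest_schema_error")
  }
}

per_muscle_terms <- function(outcome, model) {
  base <- c("age", "sex", "disease")
  extra <- if (outcome == "delta_pct") {
    switch(as.character(model), "1" = character(), "2" = "total_activity",
           "3" = "waist_cm",
           abort("delta models are 1-3.", class = "crcest_schema_error"))
  } else if (outcome == "tau_s") {
    switch(as.character(model), "1" = character(),
           "2" = c("delta_pct", "resting_pct"), "3" = "total_activity",
           abort("tau models are 1-3.", class = "crcest_schema_error"))
  } else {
    abort("Per-muscle suites are defined for delta_pct and tau_s.",
          class = "crcest_schema_error")
  }
  c(base, extra)
}

check_columns <- function(table, terms, outcome) {
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing <- setdiff(c(outcome, vars), names(table))
  if (length(missing)) {
    abort(sprintf("Missing column(s) for this model: %s",
                  paste(missing, collapse = ", ")),
          class = "crcest_data_error")
  }
}

prepare_table <- function(table, outcome) {
  table$muscle <- factor(as.character(table$muscle), levels = muscle_levels())
  table$disease <- factor(as.character(table$disease),
                          levels = c("control", "FRDA"))
  if (outcome == "tau_s" && "status" %in% names(table)) {
    table <- table[table$status == "ok", ]  # plausibility exclusions
  }
  table
}

# Wald-z fixed-effect table for a lmerMod fit
lmer_fixef_table <- function(fit, level = 0.95) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- est / se
  q <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    conf.low = unname(est - q * se), conf.high = unname(est + q * se),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' Mixed-effects model of a CrCEST outcome
#'
#' Fits the declared suites with a per-subject random intercept (REML).
#' Resting CrCEST models 1-4 adjust for age, sex, disease status and muscle
#' group (LG as reference) plus, per model, BMI or height with leg lean or
#' fat mass. For `delta_pct` and `tau_s` the mixed model is the
#' disease x muscle interaction screen. Implausible tau rows
#' (`status != "ok"`) are excluded from tau models. Fixed-effect p-values and
#' confidence intervals use the Wald z approximation. A singular
#' random-effect fit raises a `crcest_singular_fit` warning.
#'
#' @param table Cohort tibble (one row per subject x muscle).
#' @param outcome `"resting_pct"`, `"delta_pct"` or `"tau_s"`.
#' @param model Model number within the outcome's suite.
#' @return A `crcest_model_result` tibble (term, estimate, CI, p, labels);
#'   the `lmerMod` fit is in the `"fit"` attribute.
#' @export
fit_mixed_model <- function(table, outcome = "resting_pct", model = 1) {
  terms <- suite_terms(outcome, model)
  check_columns(table, terms, outcome)
  table <- prepare_table(table, outcome)
  fml <- as.formula(paste(outcome, "~", paste(terms, collapse = " + "),
                          "+ (1 | subject)"))
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = table, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage"))
  dropped <- attr(lme4::getME(fit, "X"), "col.dropped")
  if (lme4::isSingular(fit) || !is.null(dropped)) {
    warn(paste("Degenerate mixed-model fit (singular random effect or",
               "rank-deficient design); estimates may be unreliable."),
         class = "crcest_singular_fit")
  }
  out <- lmer_fixef_table(fit)
  out$outcome <- outcome
  out$model <- paste0("Model ", model)
  out$muscle_scope <- "all"
  out$n_subjects <- length(unique(table$subject))
  out$n_observations <- nrow(table)
  structure(out, class = c("crcest_model_result", class(out)), fit = fit)
}

#' Disease x muscle interaction test
#'
#' Likelihood-ratio test of the disease-by-muscle interaction block against
#' the additive mixed model (both fitted by maximum likelihood), answering
#' whether the effect of disease status on the outcome differs between
#' muscle groups.
#'
#' @param table Cohort tibble with both disease groups and >= 2 muscles.
#' @param outcome Outcome column name.
#' @return The interaction p-value.
#' @export
detect_interaction <- function(table, outcome = "tau_s") {
  table <- prepare_table(table, outcome)
  if (length(unique(as.character(table$muscle))) < 2) {
    abort("Interaction testing needs at least 2 muscle groups.",
          class = "crcest_data_error")
  }
  if (length(unique(as.character(table$disease))) < 2) {
    abort("Interaction testing needs both disease groups.",
          class = "crcest_data_error")
  }
  f0 <- as.formula(paste(outcome, "~ age + sex + disease + muscle + (1 | subject)"))
  f1 <- as.formula(paste(outcome, "~ age + sex + disease * muscle + (1 | subject)"))
  quiet_lmer <- function(f) suppressMessages(suppressWarnings(
    lme4::lmer(f, data = table, REML = FALSE)))
  m0 <- quiet_lmer(f0)
  m1 <- quiet_lmer(f1)
  lrt <- suppressMessages(anova(m0, m1))
  lrt$`Pr(>Chisq)`[2]
}

#' Per-muscle linear regression suites
#'
#' When a disease x muscle interaction is present, ordinary least-squares
#' models are built for each muscle group separately. Delta-CrCEST models:
#' age + sex + disease (1), + total physical activity (2), + waist
#' circumference (3). tauCr models: age + sex + disease (1), + delta-CrCEST
#' and resting CrCEST (2), + total physical activity (3). Implausible tau
#' rows are excluded. A rank-deficient design raises a
#' `crcest_rank_deficient` warning naming the aliased terms.
#'
#' @param table Cohort tibble.
#' @param outcome `"delta_pct"` or `"tau_s"`.
#' @param models Which models of the suite to fit.
#' @param muscles Muscles to fit (default all three).
#' @return A `crcest_model_result` tibble over (muscle, model, term).
#' @export
fit_linear_models_per_muscle <- function(table, outcome = "tau_s",
                                         models = 1:3,
                                         muscles = muscle_levels()) {
  table <- prepare_table(table, outcome)
  purrr::map_dfr(muscles, function(m) {
    sub <- table[as.character(table$muscle) == m, ]
    purrr::map_dfr(models, function(k) {
      terms <- per_muscle_terms(outcome, k)
      check_columns(sub, terms, outcome)
      fml <- as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
      fit <- lm(fml, data = sub)
      if (any(is.na(coef(fit)))) {
        warn(sprintf("Rank-deficient design in %s model %d: %s dropped.", m, k,
                     paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
             class = "crcest_rank_deficient")
      }
      ci <- suppressWarnings(confint(fit))
      sm <- summary(fit)$coefficients
      kept <- rownames(sm)
      tibble::tibble(
        term = kept,
        estimate = sm[, 1], std_error = sm[, 2],
        conf.low = ci[kept, 1], conf.high = ci[kept, 2],
        p.value = sm[, 4],
        outcome = outcome, model = paste0("Model ", k), muscle_scope = m,
        n_subjects = nrow(sub), n_observations = nrow(sub))
    })
  }) -> out
  structure(out, class = c("crcest_model_result", class(out)))
}

#' Cohort summary: medians and interquartile intervals
#'
#' @param table Cohort tibble.
#' @param outcomes Outcome columns to summarise.
#' @return Tibble with `disease`, `muscle`, `outcome`, `n`, `median`, `q25`,
#'   `q75` and a `formatted` "median (q25-q75)" string.
#' @export
summarize_cohort <- function(table,
                             outcomes = c("resting_pct", "delta_pct", "tau_s")) {
  long <- tidyr::pivot_longer(table[, c("disease", "muscle", outcomes)],
                              dplyr::all_of(outcomes),
                              names_to = "outcome", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$disease, .data$muscle, .data$outcome),
    n = sum(!is.na(.data$value)),
    median = median(.data$value, na.rm = TRUE),
    q25 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
    q75 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
    .groups = "drop")
  out$formatted <- sprintf("%.1f (%.1f-%.1f)", out$median, out$q25, out$q75)
  out
}

#' Run the full model suite on a cohort table
#'
#' Reproduces the study's statistical layer: the univariate summary, the
#' resting CrCEST mixed models (1-4), the disease x muscle interaction screen
#' for delta-CrCEST and tauCr, and the per-muscle linear model suites for
#' both.
#'
#' @param table Cohort tibble.
#' @return List: `summary`, `resting_models`, `interaction` (tibble of
#'   p-values), `delta_models`, `tau_models`.
#' @export
cohort_model_suite <- function(table) {
  resting <- purrr::map_dfr(1:4, function(k)
    suppressWarnings(fit_mixed_model(table, "resting_pct", k)))
  inter <- tibble::tibble(
    outcome = c("delta_pct", "tau_s"),
    p.value = c(detect_interaction(table, "delta_pct"),
                detect_interaction(table, "tau_s")))
  list(
    summary = summarize_cohort(table),
    resting_models = resting,
    interaction = inter,
    delta_models = fit_linear_models_per_muscle(table, "delta_pct"),
    tau_models = fit_linear_models_per_muscle(table, "tau_s")
  )
}
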