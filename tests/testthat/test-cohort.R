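test_that("normality test behaves on normal, skewed and degenerate input", {
  set.seed(21)
  p_norm <- replicate(100, test_normality(rnorm(500)))
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(100, test_normality(rexp(500)))
  expect_gte(mean(p_exp < 0.05), 0.95)
  expect_error(test_normality(c(1, 2)), class = "crcest_data_error")
  expect_error(test_normality(rep(3, 10)), class = "crcest_data_error")
})

test_that("rank comparison matches exhaustive rank arithmetic", {
  # {1,2,3} vs {4,5,6}: ranks 1..6, H = 12/(N(N+1)) * sum(R^2/n) - 3(N+1)
  res <- compare_groups_rank(c(1, 2, 3), c(4, 5, 6))
  H <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(res$statistic, H)
  # identical groups
  res0 <- compare_groups_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  # all tied
  tied <- compare_groups_rank(rep(2, 4), rep(2, 5))
  expect_equal(tied$p.value, 1)
  expect_error(compare_groups_rank(numeric(0), 1:3),
               class = "crcest_data_error")
})

test_that("rank test is invariant to monotone transforms and has power", {
  set.seed(22)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(compare_groups_rank(a, b)$statistic,
               compare_groups_rank(exp(a), exp(b))$statistic)
  hits <- replicate(50, {
    x <- rnorm(20); y <- rnorm(20, mean = 3)
    compare_groups_rank(x, y)$p.value < 0.001
  })
  expect_gte(mean(hits), 0.99)
})

test_that("synthetic cohorts have the declared shape and status flags", {
  tab <- simulate_cohort(seed = 5)
  expect_equal(nrow(tab), 32 * 3)
  expect_equal(length(unique(tab$subject)), 32)
  expect_true(all(table(tab$subject) <= 3))
  expect_identical(tab, simulate_cohort(seed = 5))
  expect_true(all(tab$status[tab$tau_s > 1000] == "excluded_high"))
  expect_true(all(tab$status[tab$tau_s < 24] == "excluded_low"))
  med <- summarize_cohort(tab)
  expect_equal(nrow(med), 2 * 3 * 3)
})

test_that("summary medians and quartiles match a sort-based oracle", {
  s <- summarize_cohort(tibble::tibble(
    disease = "control", muscle = "LG",
    resting_pct = c(1, 2, 3, 4, 5), delta_pct = 1:5, tau_s = 1:5))
  expect_equal(s$median, rep(3, 3))
  expect_equal(s$q25, rep(2, 3))
  expect_equal(s$q75, rep(4, 3))
  # type-7 interpolation oracle on an even-length sample
  set.seed(9)
  x <- rnorm(10)
  xs <- sort(x)
  h <- function(p) { i <- (10 - 1) * p + 1
    xs[floor(i)] + (i - floor(i)) * (xs[floor(i) + 1] - xs[floor(i)]) }
  s2 <- summarize_cohort(tibble::tibble(
    disease = "a", muscle = "LG", resting_pct = x, delta_pct = x, tau_s = x))
  expect_equal(s2$median[1], h(0.5))
  expect_equal(s2$q25[1], h(0.25))
  expect_equal(s2$q75[1], h(0.75))
})

test_that("mixed model recovers an injected soleus offset", {
  med <- null_reference_medians()
  med$median[med$outcome == "resting_pct"] <-
    rep(c(6.0, 6.0, 6.5), 2)   # Sol = LG + 0.50 in both groups
  hits <- vapply(1:100, function(r) {
    tab <- simulate_cohort(medians = med, seed = 300 + r)
    m <- suppressWarnings(fit_mixed_model(tab, "resting_pct", 1))
    row <- m[m$term == "muscleSol", ]
    row$conf.low <= 0.5 && row$conf.high >= 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("mixed-model output is labelled and bracketed correctly", {
  tab <- simulate_cohort(seed = 33)
  m <- suppressWarnings(fit_mixed_model(tab, "resting_pct", 2))
  expect_true(all(m$conf.low <= m$estimate & m$estimate <= m$conf.high))
  expect_true("BMI" %in% m$term)
  expect_equal(unique(m$model), "Model 2")
  expect_equal(unique(m$n_subjects), 32)
  expect_lte(unique(m$n_observations), 3 * 32)
  # LG is the reference level: no LG coefficient, MG and Sol present
  expect_false(any(grepl("muscleLG", m$term)))
  expect_true(all(c("muscleMG", "muscleSol") %in% m$term))
  # tau models drop implausible rows
  tab2 <- tab
  tab2$status[1:5] <- "excluded_high"
  m2 <- suppressWarnings(fit_mixed_model(tab2, "tau_s", 1))
  expect_equal(unique(m2$n_observations), nrow(tab) - 5)
})

test_that("degenerate single-subject groups raise a singular-fit diagnostic", {
  tab <- simulate_cohort(n_control = 1, n_frda = 1, seed = 4)
  expect_warning(fit_mixed_model(tab, "resting_pct", 1),
                 class = "crcest_singular_fit")
})

test_that("interaction screen needs both factors and detects strong effects", {
  tab <- simulate_cohort(seed = 44)
  expect_error(detect_interaction(tab[tab$muscle == "LG", ], "tau_s"),
               class = "crcest_data_error")
  expect_error(detect_interaction(tab[tab$disease == "control", ], "tau_s"),
               class = "crcest_data_error")
  # a blatant muscle-specific disease effect is found at one seed
  med <- null_reference_medians()
  med$median[med$outcome == "tau_s" & med$group == "FRDA" &
               med$muscle == "LG"] <- 600
  tab2 <- simulate_cohort(medians = med, seed = 44)
  expect_lt(detect_interaction(tab2, "tau_s"), 0.01)
})

test_that("per-muscle linear suites recover disease effects and flag defects", {
  # injected LG disease effect equal to the observed median gap (+136 s)
  hits <- vapply(1:100, function(r) {
    tab <- simulate_cohort(seed = 600 + r)
    m <- fit_linear_models_per_muscle(tab, "tau_s", models = 1,
                                      muscles = "LG")
    row <- m[m$term == "diseaseFRDA", ]
    gap <- 274 - 138
    row$conf.low <= gap && row$conf.high >= gap
  }, logical(1))
  expect_gte(mean(hits), 0.90)

  tab <- simulate_cohort(seed = 61)
  # missing covariate column is reported by name
  expect_error(
    fit_linear_models_per_muscle(dplyr::select(tab, -total_activity),
                                 "tau_s", models = 3),
    "total_activity", class = "crcest_data_error")
  # perfectly collinear covariate pair triggers the rank-deficiency path
  tab$waist_cm <- 2 * tab$age
  expect_warning(fit_linear_models_per_muscle(tab, "delta_pct", models = 3,
                                              muscles = "LG"),
                 class = "crcest_rank_deficient")
})

test_that("null covariate-free cohorts keep the FRDA coefficient near zero", {
  hits <- vapply(1:60, function(r) {
    tab <- simulate_cohort(medians = null_reference_medians(),
                           seed = 700 + r)
    m <- fit_linear_models_per_muscle(tab, "delta_pct", models = 1,
                                      muscles = "LG")
    row <- m[m$term == "diseaseFRDA", ]
    row$conf.low <= 0 && row$conf.high >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("the whole model suite runs and is shaped like the result tables", {
  tab <- simulate_cohort(seed = 77)
  suite <- suppressWarnings(cohort_model_suite(tab))
  expect_named(suite, c("summary", "resting_models", "interaction",
                        "delta_models", "tau_models"))
  expect_equal(sort(unique(suite$resting_models$model)),
               paste("Model", 1:4))
  expect_equal(nrow(suite$interaction), 2)
  # per-muscle suites: one block per (muscle, model)
  expect_equal(
    nrow(dplyr::distinct(tibble::as_tibble(suite$tau_models),
                         muscle_scope, model)), 9)
  expect_s3_class(autoplot(suite$tau_models), "ggplot")
})
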