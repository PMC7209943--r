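# Prevalences, the sex-comparison family, age quartiles and grids, and
# the parent phase summary.

make_table <- function(df) survey_table(df)

test_that("question_prevalences does exact per-question arithmetic", {
  df <- data.frame(id = paste0("r", 1:4), age = 30, sex = "M", country = "IL",
                   q1 = c(1L, 1L, 1L, 2L),          # 3 never + 1 rarely
                   q2 = c(1L, 1L, 1L, 1L),          # all never
                   q3 = c(0L, -1L, 1L, 4L))         # 2 informative
  prev <- question_prevalences(make_table(df))
  expect_equal(prev$percent_engaging[prev$question == "q1"], 25)
  expect_equal(prev$pct_rarely[prev$question == "q1"], 25)
  expect_equal(prev$percent_engaging[prev$question == "q2"], 0)
  expect_equal(prev$n_informative[prev$question == "q3"], 2)
  expect_equal(prev$percent_engaging[prev$question == "q3"], 50)
  # complement identity holds after rounding
  expect_equal(prev$percent_engaging, 100 - prev$pct_never)
})

test_that("prevalence percentages are recomputable by direct tally", {
  tab <- simulate_survey(survey_sim_config(n_per_group = 150,
                                           missing_rate = 0.1, seed = 21))
  cleaned <- clean_survey(tab)$table
  prev <- question_prevalences(cleaned)
  for (q in survey_questions(cleaned)) {
    expect_equal(prev$percent_engaging[prev$question == q],
                 oracle_percent_engaging(cleaned[[q]]))
  }
  # per-category percentages sum to 100 within rounding slack
  sums <- rowSums(prev[, c("pct_never", "pct_rarely", "pct_occasionally",
                           "pct_often")])
  expect_true(all(abs(sums - 100) <= 0.03))
})

test_that("a question with zero informative answers is flagged", {
  df <- data.frame(id = c("r1", "r2"), age = 30, sex = "W", country = "IL",
                   q1 = c(0L, -1L), q2 = c(1L, 2L))
  prev <- question_prevalences(make_table(df))
  expect_true(prev$flag_empty[prev$question == "q1"])
  expect_true(is.na(prev$percent_engaging[prev$question == "q1"]))
})

test_that("sex_comparison_family tests the declared family and corrects within it", {
  tab <- simulate_survey(survey_sim_config(
    n_per_group = 120, n_questions = 12,
    effect_sizes = c(2, rep(0, 11)), missing_rate = 0.05, seed = 31))
  cleaned <- clean_survey(tab)$table
  fam <- sex_comparison_family(cleaned, questions = paste0("q", 1:10),
                               n_perm = 1999, seed = 5)
  expect_equal(nrow(fam), 10)
  expect_equal(fam$question, paste0("q", 1:10))
  expect_true(all(fam$p_fdr >= fam$p_boot - 1e-15))
  expect_true(all(fam$p_fdr <= 1))
  expect_equal(fam$p_fdr, oracle_bh(fam$p_boot), tolerance = 1e-12)
  # the planted effect is detected
  expect_lt(fam$p_fdr[1], 0.05)
  expect_equal(fam$statistic[1],
               cvm_statistic(cleaned$q1[cleaned$sex == "M" &
                                          is_informative(cleaned$q1)],
                             cleaned$q1[cleaned$sex == "W" &
                                          is_informative(cleaned$q1)]))
  # deterministic as a family
  fam2 <- sex_comparison_family(cleaned, questions = paste0("q", 1:10),
                                n_perm = 1999, seed = 5)
  expect_identical(fam, fam2)
})

test_that("unreported sex is dropped and empty groups are excluded with warning", {
  df <- data.frame(id = paste0("r", 1:6), age = 30,
                   sex = c("M", "M", "W", "W", "unreported", "unreported"),
                   country = "IL",
                   q1 = c(1L, 2L, 3L, 4L, 1L, 1L),
                   q2 = c(1L, 2L, 0L, -1L, 2L, 3L))  # women uninformative
  tab <- make_table(df)
  expect_warning(fam <- sex_comparison_family(tab, questions = c("q1", "q2"),
                                              n_perm = 99, seed = 1),
                 "empty sex group")
  expect_equal(fam$n_men[fam$question == "q1"], 2)
  expect_equal(fam$n_women[fam$question == "q1"], 2)
  expect_true(is.na(fam$statistic[fam$question == "q2"]))
  expect_false(is.na(fam$p_fdr[fam$question == "q1"]))
})

test_that("age quartiles split evenly and keep tied ages together", {
  df <- data.frame(id = paste0("r", 1:8), age = 1:8, sex = "M", country = "X",
                   q1 = 1L)
  aq <- assign_age_quartiles(make_table(df))
  expect_equal(unname(table(aq$labels)), rep(2L, 4), ignore_attr = TRUE)
  expect_equal(aq$ranges$age_min, c(1, 3, 5, 7))
  expect_equal(aq$ranges$age_max, c(2, 4, 6, 8))

  df2 <- data.frame(id = paste0("r", 1:6), age = c(20, 20, 20, 30, 40, 50),
                    sex = "M", country = "X", q1 = 1L)
  aq2 <- assign_age_quartiles(make_table(df2))
  expect_true(all(aq2$labels[df2$age == 20] == "Q1"))

  df3 <- data.frame(id = c("r1", "r2"), age = c(20, 30), sex = "M",
                    country = "X", q1 = 1L)
  expect_error(assign_age_quartiles(make_table(df3)), "distinct ages")
})

test_that("quartile labels exhaust respondents with reported age", {
  tab <- simulate_survey(survey_sim_config(n_per_group = 101, seed = 8))
  aq <- assign_age_quartiles(tab)
  expect_equal(sum(!is.na(aq$labels)), nrow(tab))
  sizes <- as.vector(table(aq$labels))
  expect_lte(max(sizes) - min(sizes), 2 * max(table(tab$age)))
})

test_that("age_comparison_grid runs the declared contrast families", {
  tab <- simulate_survey(survey_sim_config(n_per_group = 150, seed = 13))
  grid <- age_comparison_grid(tab, "q1", n_perm = 499, seed = 3)
  expect_equal(nrow(grid), 22)
  expect_equal(sum(grid$family == "pairwise_overall"), 6)
  expect_equal(sum(grid$family == "pairwise_M"), 6)
  expect_equal(sum(grid$family == "pairwise_W"), 6)
  expect_equal(sum(grid$family == "sex_by_quartile"), 4)
  # FDR applied within each family, never across
  for (fam in unique(grid$family)) {
    sel <- grid$family == fam & !is.na(grid$p_boot)
    expect_equal(grid$p_fdr[sel], oracle_bh(grid$p_boot[sel]),
                 tolerance = 1e-12)
  }
})

test_that("a self-comparison gives statistic 0 and p = 1", {
  v <- c(1, 1, 2, 3, 4, 4)
  expect_identical(cvm_statistic(v, v), 0)
  res <- permutation_test(v, v, n_perm = 200, seed = 1)
  expect_identical(res$p_boot, 1)
})

test_that("parent_phase_summary tallies parents and phase ages", {
  df <- data.frame(id = paste0("r", 1:7), age = 40, sex = "W", country = "IL",
                   q1 = 1L,
                   parent = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                   child_phase_noticed = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                           NA, NA),
                   child_phase_age = c(4L, 5L, NA, NA, NA, NA, NA))
  res <- parent_phase_summary(make_table(df))
  expect_equal(res$n_parents, 5)
  expect_equal(res$percent_noticed, 40)
  expect_equal(res$percent_not_noticed, 60)
  expect_equal(sum(res$age_freq), 2)

  # all-"no" parents
  df$child_phase_noticed <- ifelse(df$parent, FALSE, NA)
  res0 <- parent_phase_summary(make_table(df))
  expect_equal(res0$percent_noticed, 0)

  # no parents at all
  df$parent <- FALSE
  resn <- parent_phase_summary(make_table(df))
  expect_equal(resn$n_parents, 0)
})

test_that("a zero-effect cohort rarely yields any corrected rejection", {
  # Under the global null, BH controls family-wise error at about alpha,
  # so ~95% of replicate cohorts should show no adjusted p below 0.05;
  # assert within 3 binomial s.e. of that proportion.
  n_reps <- 150
  any_rej <- with_seed_for_tests(314, vapply(seq_len(n_reps), function(i) {
    tab <- simulate_survey(survey_sim_config(
      n_per_group = 80, n_questions = 10, effect_sizes = 0,
      missing_rate = 0, multi_answer_rate = 0))
    fam <- sex_comparison_family(tab, questions = paste0("q", 1:10),
                                 n_perm = 499)
    any(fam$p_fdr < 0.05)
  }, logical(1)))
  clean_rate <- mean(!any_rej)
  expect_gte(clean_rate, 0.95 - 3 * sqrt(0.95 * 0.05 / n_reps))
})
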