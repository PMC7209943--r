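# Cohort-level questionnaire analyses: per-question prevalences, the
# 10-question sex-comparison family, age-quartile comparison grids and the
# parent-reported child phase summary.

#' Per-question answer prevalences
#'
#' Tallies, for each ordinal question, the percentage of respondents in
#' each category and the percentage engaging in the behaviour at all
#' (any answer other than "never").  Denominators are per-question
#' informative counts: blank, "n.a." and deleted cells are excluded, so a
#' respondent who skipped a question does not dilute its percentages.
#' Percentages are rounded half-up to 2 decimals, and
#' `percent_engaging = 100 - pct_never` exactly.
#'
#' @param table a cleaned [survey_table()].
#' @param questions question columns to tally (default: all).
#' @return a data.frame with one row per question: `question`,
#'   `n_informative`, `pct_never`, `pct_rarely`, `pct_occasionally`,
#'   `pct_often`, `percent_engaging`, `flag_empty` (TRUE when a question
#'   has zero informative answers and its percentages are undefined).
#' @export
question_prevalences <- function(table, questions = NULL) {
  stopifnot(inherits(table, "survey_table"))
  if (is.null(questions)) questions <- survey_questions(table)
  rows <- lapply(questions, function(q) {
    v <- table[[q]]
    inf <- v[is_informative(v)]
    n_inf <- length(inf)
    if (n_inf == 0) {
      return(data.frame(question = q, n_informative = 0L,
                        pct_never = NA_real_, pct_rarely = NA_real_,
                        pct_occasionally = NA_real_, pct_often = NA_real_,
                        percent_engaging = NA_real_, flag_empty = TRUE))
    }
    counts <- tabulate(inf, nbins = 4)
    pct <- round_half_up(100 * counts / n_inf, 2)
    data.frame(question = q, n_informative = n_inf,
               pct_never = pct[1], pct_rarely = pct[2],
               pct_occasionally = pct[3], pct_often = pct[4],
               percent_engaging = 100 - pct[1], flag_empty = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sex-comparison test family
#'
#' Runs, for each question in the declared family, the two-sample CvM
#' permutation test between men's and women's informative ratings
#' (respondents with unreported sex are dropped), then applies the
#' Benjamini-Hochberg FDR correction across exactly that family.  A
#' question with an empty sex group is excluded from the family with a
#' warning and returned with `NA` results.
#'
#' @param table a cleaned [survey_table()].
#' @param questions the family of question columns (default `q1..q10`,
#'   the self/other-sniffing items).
#' @param n_perm permutations per question.
#' @param seed integer seed; each question gets a derived child seed so
#'   the family is reproducible as a whole.
#' @param variant CvM normalization, see [cvm_statistic()].
#' @return a data.frame with one row per question: `question`, `n_men`,
#'   `n_women`, `statistic`, `p_boot`, `p_fdr`, `n_perm`, `seed`.
#' @export
sex_comparison_family <- function(table, questions = paste0("q", 1:10),
                                  n_perm = 10000, seed = NULL,
                                  variant = "anderson") {
  stopifnot(inherits(table, "survey_table"))
  questions <- intersect(questions, survey_questions(table))
  rows <- lapply(seq_along(questions), function(i) {
    q <- questions[i]
    v <- table[[q]]
    men <- v[table$sex == "M" & is_informative(v)]
    women <- v[table$sex == "W" & is_informative(v)]
    s <- child_seed(seed, i)
    if (length(men) == 0 || length(women) == 0) {
      warning(sprintf("question %s has an empty sex group; excluded from family", q),
              call. = FALSE)
      return(data.frame(question = q, n_men = length(men),
                        n_women = length(women), statistic = NA_real_,
                        p_boot = NA_real_, p_fdr = NA_real_,
                        n_perm = n_perm,
                        seed = if (is.null(s)) NA_real_ else s))
    }
    res <- permutation_test(men, women, n_perm = n_perm, seed = s,
                            variant = variant)
    data.frame(question = q, n_men = res$n_a, n_women = res$n_b,
               statistic = res$statistic, p_boot = res$p_boot,
               p_fdr = NA_real_, n_perm = n_perm,
               seed = if (is.null(s)) NA_real_ else s)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_boot)
  out$p_fdr[ok] <- bh_fdr(out$p_boot[ok])
  rownames(out) <- NULL
  out
}

#' Assign age quartiles
#'
#' Ranks respondents by age and splits them into four contiguous groups,
#' Q1 (youngest) to Q4 (oldest), as equal in size as ties permit: all
#' respondents sharing an age value receive the quartile of the lowest
#' rank among them, so equal ages are never split across quartiles.
#'
#' @param table a [survey_table()]; rows with missing age get an `NA`
#'   label.
#' @return an object of class `age_quartiles`: list with `labels` (factor
#'   `Q1..Q4` aligned with the table rows), `ranges` (realized min/max age
#'   per quartile), `counts` (quartile-by-sex table) and `n`.
#' @examples
#' tab <- simulate_survey(survey_sim_config(n_per_group = 50, seed = 2))
#' assign_age_quartiles(tab)$ranges
#' @export
assign_age_quartiles <- function(table) {
  stopifnot(inherits(table, "survey_table"))
  age <- table$age
  has_age <- !is.na(age)
  if (length(unique(age[has_age])) < 4) {
    stop("need at least 4 distinct ages to form quartiles")
  }
  n <- sum(has_age)
  r <- rank(age[has_age], ties.method = "min")
  q <- ceiling(r * 4 / n)
  labels <- factor(rep(NA_character_, nrow(table)),
                   levels = paste0("Q", 1:4))
  labels[has_age] <- paste0("Q", q)

  ranges <- do.call(rbind, lapply(1:4, function(i) {
    a <- age[has_age][q == i]
    data.frame(quartile = paste0("Q", i), n = length(a),
               age_min = if (length(a)) min(a) else NA_real_,
               age_max = if (length(a)) max(a) else NA_real_)
  }))
  counts <- table(quartile = labels, sex = table$sex)
  structure(list(labels = labels, ranges = ranges, counts = counts, n = n),
            class = "age_quartiles")
}

#' @export
print.age_quartiles <- function(x, ...) {
  cat(sprintf("Age quartiles over %d respondents with reported age:\n", x$n))
  for (i in seq_len(nrow(x$ranges))) {
    cat(sprintf("  %s: n = %3d, ages %g-%g\n", x$ranges$quartile[i],
                x$ranges$n[i], x$ranges$age_min[i], x$ranges$age_max[i]))
  }
  invisible(x)
}

#' Age-quartile comparison grid for one question
#'
#' For a single question, runs all 6 pairwise quartile contrasts three
#' times (overall, within men, within women; 18 tests) plus the 4
#' per-quartile between-sex contrasts (22 tests total).  FDR correction is
#' applied within each declared family: the 6 pairwise contrasts of each
#' scope form one family each, and the 4 sex contrasts form another.
#' Contrasts with an empty cell are skipped with a warning and returned
#' with `NA` results outside every family.
#'
#' @param table a cleaned [survey_table()].
#' @param question the question column to contrast.
#' @param n_perm permutations per contrast.
#' @param seed integer seed (child seeds derived per contrast).
#' @param quartiles an [assign_age_quartiles()] result; computed from
#'   `table` when `NULL`.
#' @param variant CvM normalization.
#' @return a data.frame with one row per contrast: `family`, `scope`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `statistic`, `p_boot`, `p_fdr`.
#' @export
age_comparison_grid <- function(table, question, n_perm = 10000, seed = NULL,
                                quartiles = NULL, variant = "anderson") {
  stopifnot(inherits(table, "survey_table"),
            question %in% survey_questions(table))
  if (is.null(quartiles)) quartiles <- assign_age_quartiles(table)
  lab <- quartiles$labels
  v <- table[[question]]
  qlev <- paste0("Q", 1:4)
  pairs <- utils::combn(qlev, 2)

  pick <- function(quart, sex = NULL) {
    sel <- !is.na(lab) & lab == quart & is_informative(v)
    if (!is.null(sex)) sel <- sel & table$sex == sex
    v[sel]
  }

  rows <- list()
  idx <- 0
  run_contrast <- function(a, b, family, scope, ga, gb) {
    idx <<- idx + 1
    s <- child_seed(seed, idx)
    if (length(a) == 0 || length(b) == 0) {
      warning(sprintf("empty cell in contrast %s %s vs %s; skipped",
                      scope, ga, gb), call. = FALSE)
      return(data.frame(family = family, scope = scope, group_a = ga,
                        group_b = gb, n_a = length(a), n_b = length(b),
                        statistic = NA_real_, p_boot = NA_real_,
                        p_fdr = NA_real_))
    }
    res <- permutation_test(a, b, n_perm = n_perm, seed = s, variant = variant)
    data.frame(family = family, scope = scope, group_a = ga, group_b = gb,
               n_a = res$n_a, n_b = res$n_b, statistic = res$statistic,
               p_boot = res$p_boot, p_fdr = NA_real_)
  }

  for (scope in c("overall", "M", "W")) {
    sex <- if (scope == "overall") NULL else scope
    fam <- paste0("pairwise_", scope)
    for (j in seq_len(ncol(pairs))) {
      rows[[length(rows) + 1]] <-
        run_contrast(pick(pairs[1, j], sex), pick(pairs[2, j], sex),
                     fam, scope, pairs[1, j], pairs[2, j])
    }
  }
  for (quart in qlev) {
    rows[[length(rows) + 1]] <-
      run_contrast(pick(quart, "M"), pick(quart, "W"),
                   "sex_by_quartile", quart, "M", "W")
  }

  out <- do.call(rbind, rows)
  for (fam in unique(out$family)) {
    sel <- out$family == fam & !is.na(out$p_boot)
    if (any(sel)) out$p_fdr[sel] <- bh_fdr(out$p_boot[sel])
  }
  rownames(out) <- NULL
  out
}

#' Parent-reported child phase summary
#'
#' Among respondents flagged as parents, summarizes the share reporting a
#' phase of increased hand-sniffing in their children and the distribution
#' of the child's age at which the phase was noticed.
#'
#' @param table a [survey_table()] with `parent`, `child_phase_noticed`
#'   and optionally `child_phase_age` columns.
#' @return a list with `n_parents`, `n_informative` (parents answering the
#'   phase question), `percent_noticed`, `percent_not_noticed` (both
#'   rounded half-up to 2 decimals) and `age_freq` (counts of reported
#'   phase by child age).  Empty when there are no parents.
#' @export
parent_phase_summary <- function(table) {
  stopifnot(inherits(table, "survey_table"))
  if (!"parent" %in% names(table) || !any(table$parent %in% TRUE)) {
    return(list(n_parents = 0L, n_informative = 0L,
                percent_noticed = NA_real_, percent_not_noticed = NA_real_,
                age_freq = integer(0)))
  }
  parents <- table[table$parent %in% TRUE, , drop = FALSE]
  noticed <- parents$child_phase_noticed
  inf <- !is.na(noticed)
  pct <- round_half_up(100 * sum(noticed[inf]) / sum(inf), 2)
  age_freq <- integer(0)
  if ("child_phase_age" %in% names(parents)) {
    ages <- parents$child_phase_age[inf & noticed %in% TRUE]
    ages <- ages[!is.na(ages)]
    if (length(ages)) age_freq <- table(child_age = ages)
  }
  list(n_parents = nrow(parents), n_informative = sum(inf),
       percent_noticed = pct,
       percent_not_noticed = round_half_up(100 - pct, 2),
       age_freq = age_freq)
}
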