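# Three-session controllability comparison: Shapiro-Wilk normality
# gating, Bonferroni corrected paired t tests across sessions and
# intensity bands, Wilcoxon signed-rank tests, and summary tables/plots.

SESSIONS_DEFAULT <- c("Pregaming", "Postgaming", "FollowUp")

#' Assemble an assessment report table
#'
#' Validates and classes a long outcome table for the statistics
#' pipeline: one row per subject, session, outcome kind and intensity
#' band.
#'
#' @param df Data frame with columns `subject`, `session`, `outcome`,
#'   `band`, `value`.
#' @param sessions Ordered session labels (defines the factor order).
#' @return An `assessment_report`.
#' @export
assessment_report <- function(df, sessions = SESSIONS_DEFAULT) {
  need <- c("subject", "session", "outcome", "band", "value")
  if (!all(need %in% names(df)))
    stop("report needs columns subject, session, outcome, band, value")
  if (anyDuplicated(df[c("subject", "session", "outcome", "band")]))
    stop("report must have one row per subject x session x outcome x band")
  df$session <- factor(as.character(df$session), levels = sessions, ordered = TRUE)
  if (anyNA(df$session)) stop("unknown session label in report")
  class(df) <- unique(c("assessment_report", class(df)))
  df
}

#' Shapiro-Wilk normality gate
#'
#' Tests whether a sample is compatible with a normal distribution at
#' the 5% level; the decision gates parametric versus nonparametric
#' comparison. A constant sample is degenerate and reported as
#' non-normal with a diagnostic rather than an error.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param alpha Gate level (default 0.05).
#' @return List with `normal` (logical), `statistic` (Shapiro-Wilk W),
#'   `p_value`, and `note`.
#' @export
check_normality <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("normality check requires at least 3 values (input error)")
  if (stats::sd(values) == 0) {
    return(list(
      normal = FALSE, statistic = NA_real_, p_value = NA_real_,
      note = "degenerate: zero variance"
    ))
  }
  sw <- stats::shapiro.test(values)
  list(
    normal = unname(sw$p.value) >= alpha,
    statistic = unname(sw$statistic),
    p_value = unname(sw$p.value),
    note = "Shapiro-Wilk"
  )
}

report_subset <- function(report, outcome_kind) {
  out <- report[report$outcome == outcome_kind, , drop = FALSE]
  if (nrow(out) == 0L) stop("report has no rows for outcome ", outcome_kind)
  out
}

# Per-subject mean value of one outcome for each level of `by`
# ("session" or "band"), averaging over the other factor. Returns a wide
# data frame: one row per subject, one column per level. Errors on
# missing cells, naming the gap.
subject_means <- function(report, outcome_kind, by) {
  df <- report_subset(report, outcome_kind)
  lev <- as.character(df[[by]])
  m <- tapply(df$value, list(as.character(df$subject), lev), mean)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf(
      "incomplete report: subject %s missing %s %s (input error)",
      rownames(m)[bad[1, 1]], by, colnames(m)[bad[1, 2]]
    ))
  }
  wide <- as.data.frame(m)
  wide$subject <- rownames(m)
  wide
}

pairs_of <- function(levels) {
  utils::combn(levels, 2, simplify = FALSE)
}

comparison_row <- function(outcome, family, contrast, test, statistic,
                           p_raw, p_adj, direction) {
  data.frame(
    outcome = outcome, family = family, contrast = contrast, test = test,
    statistic = statistic, p_raw = p_raw, p_adjusted = p_adj,
    direction = direction, stringsAsFactors = FALSE
  )
}

run_paired_family <- function(wide, levels, outcome, family, test) {
  prs <- pairs_of(levels)
  res <- lapply(prs, function(pr) {
    a <- wide[[pr[1]]]
    b <- wide[[pr[2]]]
    d <- b - a
    dir <- if (mean(d) < 0) "decrease" else if (mean(d) > 0) "increase" else "none"
    if (test == "paired t") {
      if (stats::sd(d) == 0) {
        stat <- 0
        p <- 1
      } else {
        tt <- stats::t.test(b, a, paired = TRUE)
        stat <- unname(tt$statistic)
        p <- tt$p.value
      }
    } else {
      wx <- wilcoxon_paired(a, b)
      stat <- wx$statistic
      p <- wx$p_value
    }
    comparison_row(outcome, family, paste(pr[1], "vs", pr[2]), test, stat, p, NA, dir)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- pmin(1, res$p_raw * nrow(res))  # Bonferroni within the family
  res
}

#' Bonferroni corrected paired t-tests across sessions and bands
#'
#' The parametric comparison used for the precision outcome: paired
#' t-tests on per-subject means for each of the three session pairs
#' (averaging over bands) and each of the three intensity-band pairs
#' (averaging over sessions), Bonferroni corrected within each family
#' of three contrasts.
#'
#' @param report An `assessment_report`.
#' @param outcome_kind Outcome to compare (default
#'   `"precision_deviation"`).
#' @return Data frame of comparison results: `outcome`, `family`
#'   (`sessions` or `bands`), `contrast`, `test`, `statistic`, `p_raw`,
#'   `p_adjusted`, `direction` (sign of the second-minus-first change).
#' @export
compare_precision <- function(report, outcome_kind = "precision_deviation") {
  df <- report_subset(report, outcome_kind)
  sess <- levels(droplevels(df$session))
  res <- run_paired_family(
    subject_means(df, outcome_kind, "session"), sess, outcome_kind, "sessions", "paired t"
  )
  bands <- unique(as.character(df$band))
  if (length(bands) > 1L) {
    band_order <- intersect(c("low", "middle", "high"), bands)
    res <- rbind(res, run_paired_family(
      subject_means(df, outcome_kind, "band"), band_order, outcome_kind, "bands", "paired t"
    ))
  }
  res
}

# Paired Wilcoxon signed-rank: exact distribution for n <= 25 when there
# are no zero differences or rank ties, normal approximation (with
# continuity correction) otherwise. All-zero differences are degenerate
# and reported as p = 1.
wilcoxon_paired <- function(a, b, exact_max_n = 25L) {
  d <- b - a
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(list(statistic = 0, p_value = 1, method = "degenerate (all differences zero)"))
  }
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- length(d) <= exact_max_n && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)
  )
  list(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Wilcoxon signed-rank comparisons across sessions
#'
#' The nonparametric route, used for the separation percentage and the
#' endurance r² score: related-samples Wilcoxon signed-rank tests on
#' per-subject paired values for each requested session pair, Bonferroni
#' corrected when more than one pair is tested. Uses the exact signed-
#' rank distribution for n <= 25 (no ties), the normal approximation
#' otherwise.
#'
#' @param report An `assessment_report`.
#' @param outcome_kind Outcome to compare (e.g. `"separation_active"`,
#'   `"endurance_r2"`).
#' @param contrasts List of session pairs to test; default all pairs
#'   present.
#' @return Data frame of comparison results (see [compare_precision()]).
#' @export
compare_nonparametric <- function(report, outcome_kind, contrasts = NULL) {
  df <- report_subset(report, outcome_kind)
  sess <- levels(droplevels(df$session))
  wide <- subject_means(df, outcome_kind, "session")
  if (is.null(contrasts)) contrasts <- pairs_of(sess)
  res <- lapply(contrasts, function(pr) {
    a <- wide[[pr[1]]]
    b <- wide[[pr[2]]]
    d <- b - a
    dir <- if (mean(d) < 0) "decrease" else if (mean(d) > 0) "increase" else "none"
    wx <- wilcoxon_paired(a, b)
    comparison_row(outcome_kind, "sessions", paste(pr[1], "vs", pr[2]),
                   "Wilcoxon signed-rank", wx$statistic, wx$p_value, NA, dir)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- pmin(1, res$p_raw * nrow(res))
  res
}

#' Route outcomes to parametric or nonparametric comparison
#'
#' For each outcome kind in the report, runs the Shapiro-Wilk gate on
#' the paired differences of per-subject session means (first versus
#' last session) and routes to the Bonferroni corrected paired t-test
#' when all gates pass, or to the Wilcoxon signed-rank test otherwise.
#' Every routing decision is recorded.
#'
#' @param report An `assessment_report`.
#' @param alpha Gate level for the normality check.
#' @return List of class `analysis_plan`: `routing` (data frame
#'   `outcome`, `shapiro_w`, `shapiro_p`, `normal`, `test`) and
#'   `results` (combined comparison table).
#' @export
route_tests <- function(report, alpha = 0.05) {
  outcomes <- unique(report$outcome)
  routing <- list()
  results <- list()
  for (oc in outcomes) {
    df <- report_subset(report, oc)
    sess <- levels(droplevels(df$session))
    wide <- subject_means(df, oc, "session")
    diffs <- wide[[sess[length(sess)]]] - wide[[sess[1]]]
    gate <- check_normality(diffs, alpha)
    test <- if (isTRUE(gate$normal)) "paired t" else "Wilcoxon signed-rank"
    routing[[oc]] <- data.frame(
      outcome = oc, shapiro_w = gate$statistic, shapiro_p = gate$p_value,
      normal = gate$normal, test = test, stringsAsFactors = FALSE
    )
    results[[oc]] <- if (test == "paired t") {
      compare_precision(report, oc)
    } else {
      compare_nonparametric(report, oc)
    }
  }
  structure(
    list(routing = do.call(rbind, routing), results = do.call(rbind, results)),
    class = "analysis_plan"
  )
}

#' @export
print.analysis_plan <- function(x, ...) {
  cat("Routing decisions:\n")
  print(x$routing, row.names = FALSE)
  cat("\nComparisons:\n")
  print(x$results, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summary table of an assessment report
#'
#' Mean, sample standard deviation (n - 1 denominator; absent for
#' n = 1), and n per session, outcome, and intensity band.
#'
#' @param report An `assessment_report`.
#' @return Data frame with columns `outcome`, `band`, `session`,
#'   `mean`, `sd`, `n`.
#' @export
summarize_report <- function(report) {
  key <- interaction(report$outcome, report$band, report$session, drop = TRUE)
  parts <- split(report, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    data.frame(
      outcome = g$outcome[1], band = g$band[1], session = g$session[1],
      mean = mean(g$value),
      sd = if (nrow(g) > 1L) stats::sd(g$value) else NA_real_,
      n = nrow(g)
    )
  }))
  out <- out[order(out$outcome, out$band, out$session), ]
  rownames(out) <- NULL
  out
}

#' Plot mean outcome by intensity band and session
#'
#' Bar-and-errorbar figure (mean ± SD) of one outcome across intensity
#' bands, grouped by session — the standard view of the precision
#' deviation and opposing-activation results.
#'
#' @param report An `assessment_report`.
#' @param outcome_kind Outcome to plot.
#' @param ylab Y axis label.
#' @return A ggplot object.
#' @export
plot_bands_by_session <- function(report, outcome_kind = "precision_deviation",
                                  ylab = "mean deviation (% MVC)") {
  df <- summarize_report(report_subset(report, outcome_kind))
  df$band <- factor(df$band, levels = intersect(c("low", "middle", "high", "all"), df$band))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$mean, fill = .data$session)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = "intensity band", y = ylab, fill = "session") +
    ggplot2::theme_minimal()
}

#' Plot per-subject endurance scores, first versus last session
#'
#' Paired line plot of each subject's best r², Pregaming versus
#' Follow-Up: the per-subject view behind the endurance improvement
#' comparison.
#'
#' @param report An `assessment_report` containing `endurance_r2` rows.
#' @return A ggplot object.
#' @export
plot_endurance_pairs <- function(report) {
  df <- report_subset(report, "endurance_r2")
  sess <- levels(droplevels(df$session))
  keep <- df$session %in% c(sess[1], sess[length(sess)])
  df <- df[keep, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$session, y = .data$value, group = .data$subject
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = expression(best ~ r^2)) +
    ggplot2::theme_minimal()
}
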