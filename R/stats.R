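#' Outcome variables and their improvement direction
#'
#' The six trial-level outcome variables of the study design and the sign
#' convention for improvement: improvement is a positive score, so a
#' decrease is an improvement for gait time, FoG time and APA duration,
#' while an increase is an improvement for APA amplitude. The reactive
#' displacement amplitudes (COP/COM RMS) carry direction `decrease`
#' (higher RMS reads as worse performance).
#'
#' @return Data frame with columns `variable` and `improvement_direction`.
#' @export
outcome_variables <- function() {
  data.frame(
    variable = c("gait_time", "fog_time", "apa_duration", "apa_amplitude",
                 "cop_ap_rms", "com_ap_rms"),
    improvement_direction = c("decrease", "decrease", "decrease", "increase",
                              "decrease", "decrease"),
    stringsAsFactors = FALSE)
}

#' Percent change of an ON condition relative to OFF
#'
#' `(on - off) / off`, dimensionless. The OFF value must be nonzero;
#' a zero baseline makes the percent change undefined and raises an
#' error (callers exclude the variable for that subject and log it).
#'
#' @param on_value value under stimulation (scalar or vector).
#' @param off_value baseline (OFF) value; same length as `on_value`.
#' @return `(on_value - off_value) / off_value`.
#' @examples
#' percent_change(1.0, 2.0) # -0.5
#' @export
percent_change <- function(on_value, off_value) {
  if (any(!is.finite(on_value)) || any(!is.finite(off_value)))
    stop("percent change requires finite values", call. = FALSE)
  if (any(off_value == 0))
    stop("undefined baseline: OFF value is 0", call. = FALSE)
  (on_value - off_value) / off_value
}

#' Signed improvement score of a percent change
#'
#' Maps a percent change onto the study's sign convention, in which
#' improvement is always positive: the score is `pct` for variables
#' whose improvement direction is `increase` and `-pct` for those whose
#' improvement direction is `decrease`.
#'
#' @param variable variable name, one of [outcome_variables()].
#' @param pct percent change as returned by [percent_change()].
#' @return Signed improvement score (positive = improvement).
#' @examples
#' improvement_score("fog_time", -0.4) # +0.4: FoG time shortened
#' @export
improvement_score <- function(variable, pct) {
  vars <- outcome_variables()
  i <- match(variable, vars$variable)
  if (any(is.na(i)))
    stop("unknown outcome variable: ",
         paste(variable[is.na(i)], collapse = ", "), call. = FALSE)
  if (any(!is.finite(pct)))
    stop("`pct` must be finite", call. = FALSE)
  ifelse(vars$improvement_direction[i] == "increase", pct, -pct)
}

#' One-sample Student's t test against zero
#'
#' `t = mean / (sd / sqrt(n))` with `n - 1` degrees of freedom and, by
#' default, a two-sided p value (the conservative choice when sidedness
#' is unstated). Degenerate samples (fewer than 2 values, or zero
#' standard deviation) raise an error rather than returning a spurious
#' statistic.
#'
#' @param values numeric vector of per-subject values (e.g. percent
#'   changes).
#' @param mu null-hypothesis mean (default 0).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05; significance is declared at p <= alpha).
#' @return Object of class `ttest_result`: list with `t`, `df`, `p`,
#'   `n`, `mean`, `sd`, `significant`.
#' @export
one_sample_t <- function(values, mu = 0,
                         alternative = c("two.sided", "less", "greater"),
                         alpha = 0.05) {
  alternative <- match.arg(alternative)
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    stop("`values` must all be finite", call. = FALSE)
  n <- length(values)
  if (n < 2L)
    stop("degenerate sample: need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0)
    stop("degenerate sample: zero standard deviation", call. = FALSE)
  m <- mean(values)
  tval <- (m - mu) / (s / sqrt(n))
  df <- n - 1L
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tval), df),
              less = stats::pt(tval, df),
              greater = stats::pt(tval, df, lower.tail = FALSE))
  structure(list(t = tval, df = df, p = p, n = n, mean = m, sd = s,
                 significant = p <= alpha),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<ttest_result> t(%d) = %.4f, p = %.4g%s (n = %d, mean = %.4g)\n",
              x$df, x$t, x$p, if (x$significant) " *" else "", x$n, x$mean))
  invisible(x)
}

#' Aggregate trial metrics into study-level outcome statistics
#'
#' Takes a long table of trial-level metrics (one row per trial and
#' variable), averages trials within each subject-by-condition cell,
#' computes the percent change of each ON condition relative to OFF per
#' subject and variable, attaches the signed improvement score, and runs
#' a one-sample t test of the percent changes against zero for each
#' variable and ON condition.
#'
#' Subjects missing an OFF mean for a variable are dropped pairwise for
#' that variable (with a message), as are subjects whose OFF mean is 0
#' (undefined percent-change baseline -- e.g. subjects with no freezing
#' episodes have `fog_time = 0` in OFF and are excluded from the FoG
#' percent change). Variable/condition cells whose percent changes are
#' degenerate (fewer than 2 subjects, or zero spread) carry `NA`
#' statistics and an explanatory note instead of a t test.
#'
#' @param trials data frame with columns `subject`, `condition`,
#'   `variable`, `value` (one row per trial metric).
#' @param baseline baseline condition label (default `"OFF"`).
#' @param on_conditions ON condition labels (default `c("HZ60", "HZ300")`).
#' @param alpha significance level (default 0.05).
#' @param p_adjust multiple-testing correction across the tests,
#'   passed to [stats::p.adjust()]; the study convention is none.
#' @return Object of class `study_summary`: list with `summary`
#'   (subject x condition x variable trial means and counts),
#'   `percent_change` (per subject, ON condition and variable), and
#'   `ttests` (per variable and ON condition).
#' @export
summarize_study <- function(trials, baseline = "OFF",
                            on_conditions = c("HZ60", "HZ300"),
                            alpha = 0.05, p_adjust = "none") {
  need <- c("subject", "condition", "variable", "value")
  if (!is.data.frame(trials) || !all(need %in% names(trials)))
    stop("`trials` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!nrow(trials)) stop("`trials` is empty", call. = FALSE)
  if (any(!is.finite(trials$value)))
    stop("`trials$value` must be finite", call. = FALSE)

  trials$subject <- as.character(trials$subject)
  trials$condition <- as.character(trials$condition)
  trials$variable <- as.character(trials$variable)

  means <- stats::aggregate(value ~ subject + condition + variable,
                            data = trials, FUN = mean)
  names(means)[names(means) == "value"] <- "mean"
  counts <- stats::aggregate(value ~ subject + condition + variable,
                             data = trials, FUN = length)
  means$n_trials <- counts$value
  means <- means[order(means$subject, means$variable,
                       match(means$condition, c(baseline, on_conditions))), ]
  rownames(means) <- NULL

  pct <- list()
  for (v in sort(unique(means$variable))) {
    mv <- means[means$variable == v, ]
    for (s in sort(unique(mv$subject))) {
      off <- mv$mean[mv$subject == s & mv$condition == baseline]
      if (!length(off)) {
        message(sprintf("subject %s has no %s data for %s; excluded", s, baseline, v))
        next
      }
      if (off == 0) {
        message(sprintf("subject %s has %s %s = 0; percent change undefined, excluded",
                        s, baseline, v))
        next
      }
      for (cc in on_conditions) {
        on <- mv$mean[mv$subject == s & mv$condition == cc]
        if (!length(on)) next
        p <- percent_change(on, off)
        pct[[length(pct) + 1L]] <- data.frame(
          subject = s, condition = cc, variable = v,
          pct_change = p, improvement = improvement_score(v, p),
          stringsAsFactors = FALSE)
      }
    }
  }
  pct <- if (length(pct)) do.call(rbind, pct) else
    data.frame(subject = character(0), condition = character(0),
               variable = character(0), pct_change = numeric(0),
               improvement = numeric(0), stringsAsFactors = FALSE)
  rownames(pct) <- NULL

  tt <- list()
  for (v in sort(unique(pct$variable))) {
    for (cc in on_conditions) {
      vals <- pct$pct_change[pct$variable == v & pct$condition == cc]
      if (!length(vals)) next
      row <- data.frame(variable = v, condition = cc, n = length(vals),
                        mean_pct = mean(vals), t = NA_real_, df = NA_integer_,
                        p = NA_real_, significant = NA, note = "",
                        stringsAsFactors = FALSE)
      res <- tryCatch(one_sample_t(vals, alpha = alpha), error = function(e) e)
      if (inherits(res, "error")) {
        row$note <- conditionMessage(res)
      } else {
        row$t <- res$t; row$df <- res$df; row$p <- res$p
      }
      tt[[length(tt) + 1L]] <- row
    }
  }
  tt <- if (length(tt)) do.call(rbind, tt) else
    data.frame(variable = character(0), condition = character(0),
               n = integer(0), mean_pct = numeric(0), t = numeric(0),
               df = integer(0), p = numeric(0), significant = logical(0),
               note = character(0), stringsAsFactors = FALSE)
  if (nrow(tt)) {
    tt$p_adjusted <- stats::p.adjust(tt$p, method = p_adjust)
    tt$significant <- !is.na(tt$p_adjusted) & tt$p_adjusted <= alpha
  }
  rownames(tt) <- NULL

  structure(list(summary = means, percent_change = pct, ttests = tt),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> %d subject-condition-variable cells, %d percent-change rows\n",
              nrow(x$summary), nrow(x$percent_change)))
  if (nrow(x$ttests)) {
    cat("t tests of percent change vs 0:\n")
    print(x$ttests[, c("variable", "condition", "n", "mean_pct", "t", "df", "p", "significant")],
          digits = 4)
  }
  invisible(x)
}
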