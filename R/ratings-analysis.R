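# Analysis of listener ratings: per-condition aggregation, mixed-effects
# modelling with post-hoc contrasts, Spearman correlations of flow
# against FTO parameters, rank-sum comparisons with exact small-sample
# enumeration, and the matched-subset interval search.

#' Average ratings per participant, scheme and attribute
#'
#' Arithmetic mean over each participant's repetitions of a scheme (eight
#' in the full design), per attribute. Missing cells are reported as `NA`
#' with a warning.
#'
#' @param records rating data frame with columns `participant`, `gender`,
#'   `scheme`, `attribute`, `value`.
#' @return data frame with `participant`, `gender`, `scheme`,
#'   `attribute`, `value` (cell mean) and `n` (cell count).
#' @export
average_per_condition <- function(records) {
  stopifnot(all(c("participant", "scheme", "attribute", "value") %in%
                names(records)))
  gender_of <- unique(records[, c("participant", "gender")])
  agg <- stats::aggregate(value ~ participant + scheme + attribute,
                          data = records, FUN = mean)
  cnt <- stats::aggregate(value ~ participant + scheme + attribute,
                          data = records, FUN = length)
  names(cnt)[names(cnt) == "value"] <- "n"
  out <- merge(agg, cnt, by = c("participant", "scheme", "attribute"))
  full <- expand.grid(participant = unique(records$participant),
                      scheme = unique(records$scheme),
                      attribute = unique(records$attribute),
                      stringsAsFactors = FALSE)
  out <- merge(full, out, all.x = TRUE,
               by = c("participant", "scheme", "attribute"))
  if (anyNA(out$value)) {
    warning(sum(is.na(out$value)), " empty participant x scheme x ",
            "attribute cell(s); reported as NA")
    out$n[is.na(out$n)] <- 0
  }
  out <- merge(out, gender_of, by = "participant")
  out <- out[order(out$participant, out$attribute, out$scheme),
             c("participant", "gender", "scheme", "attribute", "value", "n")]
  rownames(out) <- NULL
  out
}

#' Mixed-effects model of condition-averaged ratings
#'
#' Fits, for one attribute, the linear mixed model
#' `value ~ scheme * gender + (1 | participant)` on the per-participant
#' condition means, reports Type III F tests with Satterthwaite
#' denominator degrees of freedom for scheme, gender and their
#' interaction, and least-squares-means pairwise contrasts between
#' schemes (t, 95% CI, p; no multiplicity correction by default, Holm
#' optionally).
#'
#' @param cell_means output of [average_per_condition()].
#' @param attribute which attribute to model.
#' @param p_adjust `"none"` (default) or `"holm"` for the pairwise
#'   contrasts.
#' @return list with `model` (the `lmerModLmerTest` fit), `anova` (data
#'   frame: effect, F, df, p), `contrasts` (data frame of pairwise scheme
#'   contrasts), `singular` (logical diagnostic).
#' @export
mixed_model_ratings <- function(cell_means,
                                attribute = c("flow", "naturalness",
                                              "ease_of_following"),
                                p_adjust = c("none", "holm")) {
  attribute <- match.arg(attribute)
  p_adjust <- match.arg(p_adjust)
  d <- cell_means[cell_means$attribute == attribute, , drop = FALSE]
  if (anyNA(d$value)) stop("cell means contain NA; design too unbalanced")
  d$scheme <- factor(d$scheme, levels = c("conLow", "conNHQ", "NHQ", "HIN"))
  d$gender <- factor(d$gender)
  d$participant <- factor(d$participant)
  m <- lmerTest::lmer(value ~ scheme * gender + (1 | participant),
                      data = d)
  singular <- lme4::isSingular(m)
  an <- stats::anova(m, type = 3)
  an_df <- data.frame(effect = rownames(an), F = an[["F value"]],
                      df1 = an[["NumDF"]], df2 = an[["DenDF"]],
                      p = an[["Pr(>F)"]])
  rownames(an_df) <- NULL
  ls <- lmerTest::ls_means(m, which = "scheme", pairwise = TRUE)
  ct <- data.frame(contrast = rownames(ls), estimate = ls[, "Estimate"],
                   se = ls[, "Std. Error"], df = ls[, "df"],
                   t = ls[, "t value"], lower = ls[, "lower"],
                   upper = ls[, "upper"], p = ls[, "Pr(>|t|)"])
  rownames(ct) <- NULL
  if (p_adjust == "holm") ct$p <- stats::p.adjust(ct$p, method = "holm")
  list(model = m, anova = an_df, contrasts = ct, singular = singular,
       attribute = attribute, ddf_method = "Satterthwaite")
}

#' Spearman correlation between flow ratings and an FTO parameter
#'
#' Restricted to the two variable-FTO schemes (NHQ and HIN) and the flow
#' attribute, across all conversations and participants. Ties get
#' mid-ranks; the p-value is the two-sided asymptotic one.
#'
#' @param records rating data frame carrying `realized_fto_median_ms` and
#'   `realized_fto_iqr_ms`.
#' @param parameter `"median"` or `"iqr"`.
#' @return list with `rho`, `p`, `n`.
#' @export
correlate_flow_vs_fto <- function(records, parameter = c("median", "iqr")) {
  parameter <- match.arg(parameter)
  d <- records[records$scheme %in% c("NHQ", "HIN") &
               records$attribute == "flow", , drop = FALSE]
  if (nrow(d) < 5) stop("need at least 5 flow records from NHQ/HIN")
  x <- if (parameter == "median") d$realized_fto_median_ms
       else d$realized_fto_iqr_ms
  ct <- suppressWarnings(stats::cor.test(d$value, x, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test on pooled mid-ranks. The statistic is the
#' normal-approximation z with tie correction and a 0.5 continuity
#' correction, `z = (W - n_A (N + 1) / 2 -/+ 0.5) / sd(W)`. For pooled
#' sizes up to `exact_max_n` the p-value is computed by exhaustive
#' enumeration of all group assignments instead of the normal
#' approximation. Two degenerate identical groups give `z = 0`, `p = 1`.
#'
#' @param values_a,values_b numeric vectors (each of size >= 3).
#' @param exact_max_n enumerate exactly when `n_A + n_B` is at most this
#'   (default 12).
#' @return list with `statistic` (z), `p`, `W` (rank sum of group A),
#'   `n_a`, `n_b`, `method`.
#' @export
compare_groups_ranksum <- function(values_a, values_b, exact_max_n = 12) {
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (n_a < 3 || n_b < 3) stop("both groups need at least 3 values")
  pooled <- c(values_a, values_b)
  n <- n_a + n_b
  r <- rank(pooled)
  w <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  if (length(unique(pooled)) == 1)
    return(list(statistic = 0, p = 1, W = w, n_a = n_a, n_b = n_b,
                method = "degenerate"))
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  v <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  d <- w - mu
  z <- sign(d) * max(0, abs(d) - 0.5) / sqrt(v)
  if (n <= exact_max_n) {
    sets <- utils::combn(n, n_a)
    ws <- colSums(matrix(r[sets], nrow = n_a))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = z, p = p, W = w, n_a = n_a, n_b = n_b, method = method)
}

#' Matched-subset search over an FTO parameter
#'
#' Slides a window of `window_width_ms` in `step_ms` steps over the range
#' of the matched FTO parameter (median or IQR) of the NHQ/HIN flow
#' records, keeps windows in which (a) a rank-sum test finds no
#' significant group difference in the matched parameter (p > `alpha`)
#' and (b) the NHQ and HIN counts differ by at most `max_count_diff`, and
#' returns the qualifying window containing the most conversations (ties
#' broken towards the lower edge). For the selected subset it then
#' reports the rank-sum contrast on the flow ratings and on the unmatched
#' parameter, with group means of both parameters.
#'
#' @param records rating data frame (flow rows of the NHQ/HIN schemes are
#'   selected internally).
#' @param match_on `"median"` or `"iqr"`.
#' @param window_width_ms window width (default 80 ms).
#' @param step_ms grid step (default 5 ms).
#' @param alpha significance level of the matching test (default 0.05).
#' @param max_count_diff maximum |n_NHQ - n_HIN| (default 20).
#' @return a `subset_result`: `parameter_matched`, `interval` (ms),
#'   `n_total`, `n_NHQ`, `n_HIN`, `match_test`, `contrast_test`,
#'   `unmatched_test`, `group_means`, `flow_means`; `n_total = 0` with
#'   `NA` interval when no window qualifies.
#' @export
find_matched_subset <- function(records, match_on = c("median", "iqr"),
                                window_width_ms = 80, step_ms = 5,
                                alpha = 0.05, max_count_diff = 20) {
  match_on <- match.arg(match_on)
  d <- records[records$scheme %in% c("NHQ", "HIN") &
               records$attribute == "flow", , drop = FALSE]
  if (!nrow(d)) stop("no NHQ/HIN flow records")
  x <- if (match_on == "median") d$realized_fto_median_ms
       else d$realized_fto_iqr_ms
  other <- if (match_on == "median") d$realized_fto_iqr_ms
           else d$realized_fto_median_ms
  is_nhq <- d$scheme == "NHQ"

  starts <- seq(min(x), max(max(x) - window_width_ms, min(x)), by = step_ms)
  best <- NULL
  for (s in starts) {
    sel <- x >= s & x <= s + window_width_ms
    nn <- sum(sel & is_nhq)
    nh <- sum(sel & !is_nhq)
    if (nn < 3 || nh < 3 || abs(nn - nh) > max_count_diff) next
    mt <- compare_groups_ranksum(x[sel & is_nhq], x[sel & !is_nhq])
    if (mt$p <= alpha) next
    if (is.null(best) || nn + nh > best$n_total) {
      best <- list(start = s, n_total = nn + nh, n_nhq = nn, n_hin = nh,
                   match_test = mt)
    }
  }
  if (is.null(best)) {
    return(structure(list(parameter_matched = match_on,
                          interval = c(NA_real_, NA_real_), n_total = 0,
                          n_NHQ = 0, n_HIN = 0, match_test = NULL,
                          contrast_test = NULL, unmatched_test = NULL,
                          group_means = NULL, flow_means = NULL),
                     class = "subset_result"))
  }
  sel <- x >= best$start & x <= best$start + window_width_ms
  contrast <- compare_groups_ranksum(d$value[sel & is_nhq],
                                     d$value[sel & !is_nhq])
  unmatched <- compare_groups_ranksum(other[sel & is_nhq],
                                      other[sel & !is_nhq])
  structure(list(
    parameter_matched = match_on,
    interval = c(best$start, best$start + window_width_ms),
    n_total = best$n_total, n_NHQ = best$n_nhq, n_HIN = best$n_hin,
    match_test = best$match_test, contrast_test = contrast,
    unmatched_test = unmatched,
    group_means = data.frame(
      scheme = c("NHQ", "HIN"),
      matched_param = c(mean(x[sel & is_nhq]), mean(x[sel & !is_nhq])),
      unmatched_param = c(mean(other[sel & is_nhq]),
                          mean(other[sel & !is_nhq]))),
    flow_means = data.frame(
      scheme = c("NHQ", "HIN"),
      flow = c(mean(d$value[sel & is_nhq]), mean(d$value[sel & !is_nhq])))),
    class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  if (x$n_total == 0) {
    cat("<subset_result: no qualifying window>\n")
    return(invisible(x))
  }
  cat(sprintf(
    paste0("<subset_result matched on FTO %s: interval %.0f-%.0f ms, ",
           "n = %d (NHQ %d / HIN %d)>\n"),
    x$parameter_matched, x$interval[1], x$interval[2], x$n_total, x$n_NHQ,
    x$n_HIN))
  cat(sprintf("  match test:    z = %.2f, p = %.3f\n",
              x$match_test$statistic, x$match_test$p))
  cat(sprintf("  flow contrast: z = %.2f, p = %.3f\n",
              x$contrast_test$statistic, x$contrast_test$p))
  invisible(x)
}
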