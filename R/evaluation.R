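# Performance metrics and the statistical tests used downstream:
# concordance index, Kaplan-Meier curves, log-rank and Wilcoxon rank-sum.

#' Concordance index
#'
#' `C = (1/N_effect) * sum over events i, sum over j in R(t_i), I[r_i > r_j]`
#' where the comparable pairs run over every event patient `i` and every
#' `j != i` with `t_j >= t_i` (so two events at the same time contribute a
#' pair in both directions, matching the double sum literally).
#' `ties = "strict"` scores a tied risk pair 0 (the printed indicator);
#' `"half"` gives tied risks 0.5 credit for cross-tool comparability.
#'
#' @param risks Numeric risk scores or a `risk_table`.
#' @param time Positive times.
#' @param event 0/1 event indicators.
#' @param ties `"strict"` (default) or `"half"`.
#' @return List: `value` in \[0,1\], `n_effective` (comparable pairs).
#' @export
c_index <- function(risks, time, event, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  r <- if (is.data.frame(risks)) risks$risk else risks
  stopifnot(length(r) == length(time), length(time) == length(event))
  if (sum(event) == 0) stopf("no events: no comparable pairs")
  conc <- 0
  tied <- 0
  n_eff <- 0
  for (i in which(event == 1)) {
    j <- which(time >= time[i])
    j <- j[j != i]
    if (length(j) == 0) next
    conc <- conc + sum(r[i] > r[j])
    tied <- tied + sum(r[i] == r[j])
    n_eff <- n_eff + length(j)
  }
  if (n_eff == 0) stopf("no comparable pairs")
  value <- if (ties == "strict") conc / n_eff else (conc + 0.5 * tied) / n_eff
  list(value = value, n_effective = as.integer(n_eff))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate; censored times reduce the at-risk count
#' without introducing a step.
#'
#' @param time Positive times.
#' @param event 0/1 event indicators.
#' @return data.frame `survival_curve`: `time` (ascending distinct
#'   observed times), `surv`, `n_risk`, `n_event`, `n_censor`.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(data.frame(time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       n_censor = fit$n.censor),
            class = c("survival_curve", "data.frame"))
}

#' Log-rank test across two or more groups
#'
#' Unweighted (Mantel-Haenszel) log-rank with hypergeometric tie
#' handling at each distinct event time; chi-square with g-1 degrees of
#' freedom.
#'
#' @param time Positive times.
#' @param event 0/1 event indicators.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List: `statistic`, `df`, `p_value`, `stars`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stopf("need at least 2 non-empty groups")
  if (sum(event) == 0) stopf("no events: log-rank undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = droplevels(group)))
  df <- nlevels(droplevels(group)) - 1
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), df = df, p_value = p,
       stars = significance_stars(p))
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Mid-ranks for ties; exact enumeration for small tie-free samples
#' (both n <= 20), normal approximation with continuity correction
#' otherwise.
#'
#' @param a,b Numeric samples (both non-empty).
#' @return List: `statistic` (U for sample `a`), `p_value`, `stars`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       stars = significance_stars(wt$p.value))
}
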