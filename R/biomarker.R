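# Downstream biomarker statistics: Mann-Whitney U, ROC-AUC by the rank
# formula, two-group log-rank test with O/E accumulation, Pike and Cox
# hazard-ratio estimators, and maximally selected rank cutpoints.

#' Mann-Whitney U test
#'
#' U is oriented to the first group (number of (a, b) pairs with a > b,
#' ties counted half). Exact p-values (via the Wilcoxon distribution) are
#' used when both groups have at most 8 values and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b Numeric vectors (>= 1 value each; tests downstream require
#'   3).
#' @return List: `U`, `p` (two-sided), `exact` (logical).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  r1 <- sum(r[seq_len(n1)])
  U <- r1 - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && n1 <= 8 && n2 <= 8) {
    pl <- stats::pwilcox(U, n1, n2)
    pu <- 1 - stats::pwilcox(U - 1, n1, n2)
    return(list(U = U, p = min(1, 2 * min(pl, pu)), exact = TRUE))
  }
  n <- n1 + n2
  tie_tab <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                              (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (U - n1 * n2 / 2)
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' ROC area under the curve
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(tie)`, computed by the rank
#' formula (identical to `U / (n1 * n2)` of the Mann-Whitney test of
#' positives vs negatives).
#'
#' @param scores Numeric predictor.
#' @param labels Logical or 0/1 vector; TRUE/1 is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# O/E/V accumulation over distinct event times for a two-group comparison;
# O1/E1/V refer to the first group.
.logrank_oe <- function(time, event, g1) {
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  O <- sum(event == 1)
  list(O1 = O1, E1 = E1, O2 = O - O1, E2 = O - E1, V = V, O = O)
}

.two_groups <- function(group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  g
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected accumulation over event times;
#' `chi2 = (O1 - E1)^2 / V`, two-sided p from chi-square with 1 df. O and
#' E are reported for both groups (group 1 = first factor level).
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (0/1).
#' @param group Two-level grouping vector.
#' @return List: `chi2`, `p`, `O` and `E` (length-2, per group), `V`.
#' @export
logrank_test <- function(time, event, group) {
  g <- .two_groups(group)
  stopifnot(length(time) == length(event), length(time) == length(g))
  g1 <- g == levels(g)[1]
  if (sum(event[g1]) < 1 || sum(event[!g1]) < 1)
    stop("both groups need at least one event")
  oe <- .logrank_oe(time, event, g1)
  if (oe$V <= 0) stop("zero log-rank variance")
  chi2 <- (oe$O1 - oe$E1)^2 / oe$V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       O = stats::setNames(c(oe$O1, oe$O2), levels(g)),
       E = stats::setNames(c(oe$E1, oe$E2), levels(g)), V = oe$V)
}

# Newton solver for a single-covariate Cox partial likelihood (Breslow
# ties). Returns the coefficient and its standard error.
cox_newton <- function(time, event, x, max_iter = 25, tol = 1e-8) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  beta <- 0
  for (it in seq_len(max_iter)) {
    eta <- exp(beta * x)
    # reverse cumulative sums over the risk set
    s0 <- rev(cumsum(rev(eta)))
    s1 <- rev(cumsum(rev(eta * x)))
    s2 <- rev(cumsum(rev(eta * x^2)))
    ev <- event == 1
    U <- sum(x[ev] - s1[ev] / s0[ev])
    I <- sum(s2[ev] / s0[ev] - (s1[ev] / s0[ev])^2)
    if (I <= 0) break
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  list(beta = beta, se = 1 / sqrt(I))
}

#' Two-group hazard ratio
#'
#' Default is the Pike estimator `HR = (O1 / E1) / (O2 / E2)` from the
#' log-rank O/E table, with a log-scale confidence interval using
#' variance `1 / V`. `method = "cox"` fits a single-covariate Cox model
#' by Newton iteration instead.
#'
#' @param time,event,group As in [logrank_test()]; the HR is group 1 (first
#'   factor level) versus group 2. With `method = "cox"`, `group` may also
#'   be a continuous covariate, in which case the HR is per unit of the
#'   covariate.
#' @param method `"pike"` (default) or `"cox"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `hr`, `ci` (length 2), `log_hr`, `se`, `method`.
#' @export
hazard_ratio <- function(time, event, group, method = c("pike", "cox"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  continuous <- is.numeric(group) && length(unique(group)) > 2
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "pike") {
    if (continuous) stop("pike estimator needs a two-level group")
    g <- .two_groups(group)
    g1 <- g == levels(g)[1]
    oe <- .logrank_oe(time, event, g1)
    if (oe$E1 <= 0 || oe$E2 <= 0) stop("zero expected events")
    if (oe$O1 == 0 || oe$O2 == 0) stop("a group has no events")
    hr <- (oe$O1 / oe$E1) / (oe$O2 / oe$E2)
    se <- 1 / sqrt(oe$V)
  } else {
    x <- if (continuous) as.numeric(group) else {
      g <- .two_groups(group)
      as.numeric(g == levels(g)[1])
    }
    fit <- cox_newton(time, event, x)
    hr <- exp(fit$beta)
    se <- fit$se
  }
  list(hr = hr, ci = c(exp(log(hr) - z * se), exp(log(hr) + z * se)),
       log_hr = log(hr), se = se, method = method)
}

#' Maximally selected rank cutpoint
#'
#' Evaluates the standardized log-rank statistic
#' `z = (O1 - E1) / sqrt(V)` (group 1 = biomarker <= cutpoint) at every
#' candidate cutpoint between the `q_low` and `q_high` biomarker quantiles
#' and returns the cutpoint maximizing `|z|`. The reported Kaplan-Meier
#' p-value at the selected cutpoint is the naive log-rank p; it is NOT
#' adjusted for the cutpoint selection and is flagged as such.
#'
#' @param table data.frame with `time`, `event`, `biomarker` (>= 20
#'   subjects, >= 5 events).
#' @param q_low,q_high Quantile window for candidates (defaults 0.1, 0.9).
#' @return List: `cutoff`, `statistic` (max `|z|`), `candidates`
#'   (data.frame cutpoint/z), `p_naive`, `p_selection_adjusted` (FALSE).
#' @export
maxstat_cutoff <- function(table, q_low = 0.1, q_high = 0.9) {
  stopifnot(all(c("time", "event", "biomarker") %in% names(table)))
  if (nrow(table) < 20) stop("need at least 20 subjects")
  if (sum(table$event) < 5) stop("need at least 5 events")
  x <- table$biomarker
  if (length(unique(x)) < 2) stop("all biomarker values identical")
  qs <- stats::quantile(x, c(q_low, q_high))
  cand <- sort(unique(x))
  cand <- cand[cand >= qs[1] & cand <= qs[2] & cand < max(x)]
  if (length(cand) == 0) stop("no candidate cutpoints in quantile window")
  zs <- vapply(cand, function(ct) {
    g1 <- x <= ct
    oe <- .logrank_oe(table$time, table$event, g1)
    if (oe$V <= 0) return(0)
    (oe$O1 - oe$E1) / sqrt(oe$V)
  }, numeric(1))
  best <- which.max(abs(zs))
  cut <- cand[best]
  grp <- factor(ifelse(x <= cut, "low", "high"), levels = c("low", "high"))
  p_naive <- tryCatch(logrank_test(table$time, table$event, grp)$p,
                      error = function(e) NA_real_)
  list(cutoff = cut, statistic = abs(zs[best]),
       candidates = data.frame(cutpoint = cand, z = zs),
       p_naive = p_naive, p_selection_adjusted = FALSE)
}
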