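# Survival and enrichment statistics.
#
# Kaplan-Meier estimation, the two-group log-rank test and Cox proportional
# hazards delegate to the survival package (Efron tie handling, Wald
# confidence intervals); Harrell's concordance index, the exact upper-tail
# hypergeometric enrichment and the Mann-Whitney test follow the explicit
# conventions below. Conventions:
#   * KM median: smallest event time t with S(t) <= 0.5; undefined (NA)
#     when S never reaches 0.5;
#   * log-rank: standard 1-df chi-square, no continuity correction;
#   * concordance: a pair is comparable when the strictly shorter time is
#     an observed event; score ties count 1/2.

#' Assemble survival records
#'
#' @param patient_id character ids.
#' @param time follow-up in months, strictly positive.
#' @param event logical/0-1: death observed.
#' @param group optional group label per patient.
#' @param ... further per-patient covariate vectors (named).
#' @return data.frame of survival records.
#' @export
survival_records <- function(patient_id, time, event, group = NULL, ...) {
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be finite and positive")
  }
  df <- data.frame(patient_id = as.character(patient_id), time = time,
                   event = as.logical(event), stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- group
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

#' Kaplan-Meier curve and median survival
#'
#' Product-limit estimator; the median is the smallest event time at which
#' the estimate drops to 0.5 or below, `NA` when it never does.
#'
#' @param records data.frame with `time` and `event` (see
#'   [survival_records()]).
#' @return list: `time`, `surv` (step function values at the observed
#'   times), `n_risk`, `n_event`, `median`.
#' @export
km_curve <- function(records) {
  if (nrow(records) < 1) stop("no records")
  if (any(records$time <= 0)) stop("non-positive survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  drop_idx <- which(fit$n.event > 0 & fit$surv <= 0.5 + 1e-12)
  med <- if (length(drop_idx)) fit$time[drop_idx[1]] else NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med)
}

#' Two-group log-rank test
#'
#' @param records data.frame with `time`, `event` and a two-level `group`.
#' @return list: `statistic` (1-df chi-square), `p`.
#' @export
log_rank <- function(records) {
  g <- factor(records$group)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop("log-rank needs two non-empty groups")
  }
  if (sum(records$event) == 0) {
    warning("no events in either group; log-rank P set to 1")
    return(list(statistic = 0, p = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = records, rho = 0)
  list(statistic = unname(sd_$chisq),
       p = pchisq(unname(sd_$chisq), df = 1, lower.tail = FALSE))
}

#' Univariate or bivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling; hazard ratios
#' with Wald 95% confidence intervals on the log scale. Monotone-likelihood
#' (complete separation) or non-convergence is flagged rather than hidden.
#'
#' @param records data.frame with `time`, `event` and the covariates.
#' @param covariates one or two covariate column names (binary or
#'   categorical; first level is the reference).
#' @return data.frame, one row per model term: `term`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `flagged`.
#' @export
cox_fit <- function(records, covariates) {
  if (!length(covariates) %in% 1:2) {
    stop("only univariate and bivariate fits are supported")
  }
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov)) {
    stop("covariate(s) absent: ", paste(missing_cov, collapse = ", "))
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w),
                ignore.case = TRUE)) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)
  co <- s$coefficients
  data.frame(
    term = rownames(co),
    hr = unname(exp(co[, "coef"])),
    ci_low = unname(exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"])),
    ci_high = unname(exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"])),
    p = unname(co[, "Pr(>|z|)"]),
    flagged = flagged,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the higher risk score
#' belongs to the patient who fails first. A pair is comparable when the
#' strictly shorter time carries an observed event; score ties contribute
#' 1/2.
#'
#' @param records data.frame with `time` and `event`.
#' @param scores numeric risk score per record (higher = higher risk).
#' @return concordance in `[0, 1]`, `NA` (with a warning) when no pair is
#'   comparable.
#' @export
concordance_index <- function(records, scores) {
  if (length(scores) != nrow(records)) stop("one score per record required")
  t_ <- records$time; e <- records$event
  n <- length(t_)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (!e[i]) next
    later <- t_ > t_[i] # strictly longer times: i fails first
    if (!any(later)) next
    den <- den + sum(later)
    num <- num + sum(scores[i] > scores[later]) +
      0.5 * sum(scores[i] == scores[later])
  }
  if (den == 0) {
    warning("no comparable pairs; concordance undefined")
    return(NA_real_)
  }
  num / den
}

#' Exact upper-tail hypergeometric enrichment
#'
#' Probability of observing `k` or more annotated patients in a subset of
#' size `n`, when `K` of the `N` cohort patients carry the annotation:
#' `P = C(N,n)^-1 * sum_{i=k}^{n} C(K,i) C(N-K, n-i)` (impossible summands
#' are zero).
#'
#' @param N cohort size.
#' @param K annotated patients in the cohort.
#' @param n subset size.
#' @param k annotated patients in the subset.
#' @return the upper-tail P value.
#' @export
hypergeometric_enrichment <- function(N, K, n, k) {
  if (!(K <= N && n <= N && k >= 0 && k <= min(n, K))) {
    stop("invalid enrichment input: need 0 <= k <= min(n, K), n <= N, K <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact two-sided P for combined sample sizes up to 20 without ties;
#' otherwise the normal approximation with tie correction (no continuity
#' correction).
#'
#' @param values_a,values_b non-empty numeric samples.
#' @return list: `u` (U statistic of the first sample), `p` (two-sided).
#' @export
mann_whitney <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (length(values_a) + length(values_b)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = FALSE)
  )
  list(u = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Enrichment of a clinical annotation in a probelet split
#'
#' Splits the patients into "high" and "low" subsets by the sign of their
#' probelet coefficient (or by a quantile), and reports, per annotation
#' level and subset, the exact hypergeometric upper-tail P; plus, for
#' two-level annotations, the Mann-Whitney P comparing coefficients across
#' the levels.
#'
#' @param probelet numeric coefficient vector, one entry per patient.
#' @param clinical data.frame with `patient_id` and the annotation column;
#'   row order must match the probelet.
#' @param annotation annotation column name.
#' @param split `"sign"` (default; > 0 is high) or `"quantile"`.
#' @param q quantile for `split = "quantile"`.
#' @return list: `table` (per level x subset hypergeometric results),
#'   `mann_whitney_p` (NA unless the annotation has exactly two levels).
#' @export
annotate_probelet <- function(probelet, clinical, annotation,
                              split = c("sign", "quantile"), q = 0.5) {
  split <- match.arg(split)
  if (!annotation %in% names(clinical)) {
    stop("annotation '", annotation, "' absent from the clinical table")
  }
  if (length(probelet) != nrow(clinical)) {
    stop("probelet length != clinical row count")
  }
  ann <- clinical[[annotation]]
  ok <- !is.na(ann)
  x <- probelet[ok]; ann <- factor(ann[ok])
  thr <- if (split == "sign") 0 else quantile(x, q)
  high <- x > thr
  N <- length(x)
  rows <- list()
  for (lev in levels(ann)) {
    K <- sum(ann == lev)
    for (sub in c("high", "low")) {
      inset <- if (sub == "high") high else !high
      n <- sum(inset)
      k <- sum(inset & ann == lev)
      p <- if (n == 0) 1 else hypergeometric_enrichment(N, K, n, k)
      rows[[length(rows) + 1L]] <- data.frame(
        level = lev, subset = sub, N = N, K = K, n = n, k = k, p_hyper = p,
        stringsAsFactors = FALSE)
    }
  }
  mw <- NA_real_
  if (nlevels(ann) == 2) {
    a <- x[ann == levels(ann)[1]]
    b <- x[ann == levels(ann)[2]]
    if (length(a) && length(b)) {
      mw <- if (length(unique(x)) == 1) 1 else mann_whitney(a, b)$p
    }
  }
  list(table = do.call(rbind, rows), mann_whitney_p = mw)
}

#' Two-group survival report
#'
#' Bundles the statistics reported for a low/high classification: per-group
#' size, events and KM median; the log-rank test; the univariate Cox hazard
#' ratio of high versus low; and the concordance index of the supplied risk
#' scores (the high-group indicator when none are given).
#'
#' @param records data.frame with `time`, `event` and two-level `group`.
#' @param scores optional numeric risk score per record.
#' @return list: `groups` (data.frame), `logrank` (list), `cox`
#'   (data.frame), `concordance`.
#' @export
survival_report <- function(records, scores = NULL) {
  g <- factor(records$group, levels = c("low", "high"))
  if (anyNA(g)) g <- factor(records$group)
  groups <- do.call(rbind, lapply(levels(g), function(lev) {
    r <- records[g == lev, , drop = FALSE]
    data.frame(group = lev, n = nrow(r), events = sum(r$event),
               km_median = if (nrow(r)) km_curve(r)$median else NA_real_,
               stringsAsFactors = FALSE)
  }))
  lr <- log_rank(records)
  records$group <- g
  cx <- cox_fit(records, "group")
  if (is.null(scores)) scores <- as.numeric(g == levels(g)[2])
  ci <- concordance_index(records, scores)
  list(groups = groups, logrank = lr, cox = cx, concordance = ci)
}
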