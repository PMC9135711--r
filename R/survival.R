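#' Average z-score signature over target genes
#'
#' For every target gene present in the cohort expression table, expression
#' is z-scored across patients (sample standard deviation, n - 1); the
#' per-patient signature is the mean z over target genes. Genes with zero
#' variance are dropped with a warning; if no target gene with variance
#' remains the call errors.
#'
#' @param cohort a `reglink_cohort` or any list with `expression`
#'   (genes x patients matrix).
#' @param target_genes character vector of signature genes.
#' @return named per-patient average z-score.
#' @export
cohort_signature <- function(cohort, target_genes) {
  expr <- cohort$expression
  if (ncol(expr) < 2L) stopf("cohort needs >= 2 patients")
  present <- intersect(target_genes, rownames(expr))
  if (length(present) == 0L) {
    stopf("none of the target genes is in the expression table")
  }
  if (length(present) < length(unique(target_genes))) {
    warnf("%d target gene(s) absent from the expression table",
          length(unique(target_genes)) - length(present))
  }
  x <- expr[present, , drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  if (any(sdv == 0)) {
    if (all(sdv == 0)) stopf("all target genes have zero variance across patients")
    warnf("dropping %d zero-variance target gene(s)", sum(sdv == 0))
    x <- x[sdv > 0, , drop = FALSE]
    mu <- mu[sdv > 0]; sdv <- sdv[sdv > 0]
  }
  z <- (x - mu) / sdv
  colMeans(z)
}

#' Stratify patients by signature score
#'
#' The default rule labels a patient `high` iff the score exceeds the cohort
#' median; ties at the median go to `low`. Tertile splitting labels the top
#' tertile `high` and the bottom `low` (middle `mid`); a fixed `threshold`
#' rule is also available. Errors if a rule leaves a stratum empty.
#'
#' @param scores named per-patient scores.
#' @param rule `"median"`, `"tertile"` or `"threshold"`.
#' @param threshold cut point for `rule = "threshold"`.
#' @return named character labels.
#' @export
stratify <- function(scores, rule = c("median", "tertile", "threshold"),
                     threshold = 0) {
  rule <- match.arg(rule)
  if (length(scores) < 2L) stopf("need >= 2 patients to stratify")
  if (length(unique(scores)) == 1L) {
    stopf("all scores identical: stratification undefined")
  }
  labels <- switch(rule,
    median = ifelse(scores > median(scores), "high", "low"),
    tertile = {
      q <- quantile(scores, c(1 / 3, 2 / 3))
      ifelse(scores > q[2], "high", ifelse(scores > q[1], "mid", "low"))
    },
    threshold = ifelse(scores > threshold, "high", "low"))
  if (length(unique(labels[labels != "mid"])) < 2L) {
    stopf("stratification left a stratum empty")
  }
  setNames(labels, names(scores))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per stratum and the two-group log-rank
#' statistic with hypergeometric variance: at each distinct event time,
#' `O - E` accumulates the observed minus expected events in the first
#' stratum and `V` the hypergeometric variance; the statistic
#' `(O - E)^2 / V` is referred to a chi-squared distribution with 1 df
#' (two-sided p). If neither stratum has an event, p is `NA` (sentinel).
#'
#' @param cohort a `reglink_cohort` or any list with `clinical`
#'   (data.frame: patient, time, event).
#' @param labels named two-level stratum labels covering the patients
#'   (patients labeled `mid` are excluded).
#' @return list with `curves` (data.frame: stratum, time, n_risk, n_event,
#'   surv), `chisq`, `p`, `observed`, `expected` (first stratum).
#' @export
km_logrank <- function(cohort, labels) {
  cl <- cohort$clinical
  assert_columns(cl, c("patient", "time", "event"), "clinical table")
  labels <- labels[cl$patient]
  use <- !is.na(labels) & labels != "mid"
  cl <- cl[use, , drop = FALSE]
  labels <- labels[use]
  strata <- sort(unique(labels))
  if (length(strata) != 2L) stopf("log-rank needs exactly two strata")

  curves <- lapply(strata, function(s) {
    tt <- cl$time[labels == s]; ev <- cl$event[labels == s]
    times <- sort(unique(tt[ev == 1]))
    if (length(times) == 0L) {
      return(data.frame(stratum = character(), time = numeric(),
                        n_risk = integer(), n_event = integer(),
                        surv = numeric()))
    }
    n_risk <- vapply(times, function(u) sum(tt >= u), integer(1))
    n_event <- vapply(times, function(u) sum(tt == u & ev == 1), integer(1))
    data.frame(stratum = s, time = times, n_risk = n_risk, n_event = n_event,
               surv = cumprod(1 - n_event / n_risk), stringsAsFactors = FALSE)
  })
  curves <- do.call(rbind, curves)

  ev_times <- sort(unique(cl$time[cl$event == 1]))
  if (length(ev_times) == 0L) {
    return(list(curves = curves, chisq = NA_real_, p = NA_real_,
                observed = 0, expected = 0))
  }
  O <- E <- V <- 0
  g1 <- labels == strata[1]
  for (u in ev_times) {
    at_risk <- cl$time >= u
    n_j <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d_j <- sum(cl$time == u & cl$event == 1)
    d1 <- sum(cl$time == u & cl$event == 1 & g1)
    O <- O + d1
    E <- E + d_j * n1 / n_j
    if (n_j > 1) {
      V <- V + d_j * (n1 / n_j) * (1 - n1 / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  chisq <- if (V > 0) (O - E)^2 / V else NA_real_
  p <- if (is.na(chisq)) NA_real_ else pchisq(chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, chisq = chisq, p = p, observed = O, expected = E)
}

#' Complication rate of a cohort
#'
#' Percentage of patients with at least one complication, reported with
#' one-decimal half-up rounding (35 of 89 reads 39.3).
#'
#' @param cohort a `reglink_cohort` or any list with `clinical` containing a
#'   binary `complication` column.
#' @return percentage in `[0, 100]`, rounded to one decimal.
#' @export
complication_rate <- function(cohort) {
  cl <- cohort$clinical
  assert_columns(cl, "complication", "clinical table")
  if (nrow(cl) == 0L) stopf("cohort is empty")
  round_half_up(100 * sum(cl$complication == 1) / nrow(cl), 1)
}
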