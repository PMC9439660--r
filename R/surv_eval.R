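# Survival estimation and discrimination metrics. Kaplan-Meier, log-rank
# and Cox regression are delegated to the survival package; Harrell's C,
# IPCW time-dependent ROC, calibration and continuous NRI are implemented
# here with the orientation convention: higher score = higher risk.

check_surv_input <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(time < 0)) stop("negative survival times")
  if (!all(event %in% c(0, 1))) stop("`event` must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with Greenwood-based confidence band.
#'
#' @param time,event Follow-up times (>= 0) and 0/1 event indicators.
#' @param conf_level Confidence level for the band.
#' @return A `survival_curve` data.frame: `time`, `surv`, `n_risk`,
#'   `n_event`, `lower`, `upper`, starting at S(0) = 1.
#' @export
km_curve <- function(time, event, conf_level = 0.95) {
  check_surv_input(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.int = conf_level)
  out <- data.frame(time = c(0, fit$time), surv = c(1, fit$surv),
                    n_risk = c(length(time), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    lower = c(1, fit$lower), upper = c(1, fit$upper))
  class(out) <- c("survival_curve", "data.frame")
  out
}

# Survival probability at time t from a survival_curve (step function).
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  curve$surv[pmax(idx, 1)]
}

#' Two-group log-rank test
#'
#' @param time,event Survival data.
#' @param group Two-level grouping vector.
#' @return List `statistic` (chi-square, 1 df), `p_value`, `n` per group.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  g <- factor(group)
  if (nlevels(g) != 2) stop("`group` must have exactly 2 non-empty levels")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = as.numeric(table(g)))
}

#' Cox proportional-hazards regression
#'
#' Efron tie handling, Newton optimization to a tight gradient tolerance,
#' Wald confidence intervals. `mode = "uni"` fits each covariate in a
#' separate model; `mode = "multi"` fits them jointly.
#'
#' @param time,event Survival data.
#' @param covariates data.frame (or matrix) of covariates.
#' @param mode "uni" or "multi".
#' @param conf_level Confidence level.
#' @return A `cox_result`: data.frame `table` (term, beta, HR, lower,
#'   upper, p), `loglik`, `n`, `n_events`.
#' @export
cox_fit <- function(time, event, covariates, mode = c("multi", "uni"),
                    conf_level = 0.95) {
  mode <- match.arg(mode)
  check_surv_input(time, event)
  covariates <- as.data.frame(covariates)
  if (sum(event) < ncol(covariates) + 1)
    stop("too few events for the number of covariates")
  fit_one <- function(df) {
    f <- survival::coxph(survival::Surv(time, event) ~ ., data = df,
                         ties = "efron",
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 50))
    if (any(is.na(stats::coef(f))) || any(sqrt(diag(f$var)) > 1e3))
      stop("Cox model did not converge (possible separation); check covariates")
    f
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- list(); ll <- NULL
  if (mode == "multi") {
    f <- fit_one(covariates)
    b <- stats::coef(f); se <- sqrt(diag(f$var)); ll <- f$loglik[2]
    rows <- list(data.frame(term = names(b), beta = as.numeric(b),
                            hr = exp(b), lower = exp(b - z * se),
                            upper = exp(b + z * se),
                            p = 2 * stats::pnorm(-abs(b / se))))
  } else {
    for (v in names(covariates)) {
      f <- fit_one(covariates[, v, drop = FALSE])
      b <- stats::coef(f); se <- sqrt(diag(f$var))
      rows[[v]] <- data.frame(term = v, beta = as.numeric(b), hr = exp(b),
                              lower = exp(b - z * se), upper = exp(b + z * se),
                              p = 2 * stats::pnorm(-abs(b / se)))
    }
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  structure(list(table = tab, loglik = ll, n = length(time),
                 n_events = sum(event), mode = mode),
            class = "cox_result")
}

#' Harrell's concordance index
#'
#' Fraction of usable (event-anchored) subject pairs whose risk ordering
#' matches the observed event ordering; score ties count 0.5. Higher
#' score must mean higher risk.
#'
#' @param time,event Survival data.
#' @param score Risk score (higher = higher risk).
#' @param ci "none" or "bootstrap" (seeded percentile interval).
#' @param n_boot,conf_level,seed Bootstrap settings.
#' @return List `c_index`, `n_pairs` (comparable pairs), and `lower`,
#'   `upper` when a CI is requested.
#' @export
harrell_c <- function(time, event, score, ci = c("none", "bootstrap"),
                      n_boot = 1000, conf_level = 0.95, seed = 1) {
  ci <- match.arg(ci)
  check_surv_input(time, event)
  stopifnot(length(score) == length(time))
  cstat <- function(tt, ev, ss) {
    # pair (i, j) comparable iff the earlier time is an observed event
    dt <- outer(tt, tt, "<")
    comp <- dt & matrix(ev == 1, length(tt), length(tt))
    if (!any(comp)) return(NA_real_)
    ds <- outer(ss, ss, ">")
    ts <- outer(ss, ss, "==")
    (sum(ds & comp) + 0.5 * sum(ts & comp)) / sum(comp)
  }
  c0 <- cstat(time, event, score)
  if (is.na(c0)) stop("no comparable pairs")
  out <- list(c_index = c0,
              n_pairs = sum(outer(time, time, "<") &
                              matrix(event == 1, length(time), length(time))))
  if (ci == "bootstrap") {
    bs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(time), replace = TRUE)
      cstat(time[idx], event[idx], score[idx])
    }, numeric(1)))
    qs <- stats::quantile(bs, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                          na.rm = TRUE)
    out$lower <- qs[[1]]; out$upper <- qs[[2]]
  }
  out
}

# KM estimate of the censoring distribution G(t) (event indicator flipped),
# evaluated just before each requested time.
censor_km <- function(time, event) {
  km_curve(time, 1 - event)
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls, IPCW)
#'
#' Cases are subjects with an observed event by the horizon, weighted by
#' the inverse censoring survival at their event time; controls are
#' subjects still at risk past the horizon, weighted by the inverse
#' censoring survival at the horizon.
#'
#' @param time,event Survival data.
#' @param score Risk score (higher = higher risk).
#' @param horizon Evaluation time.
#' @return AUC scalar.
#' @export
td_roc_auc <- function(time, event, score, horizon) {
  check_surv_input(time, event)
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon)
  if (!length(cases)) stop("no cases by the horizon")
  if (!length(controls)) stop("no controls past the horizon")
  G <- censor_km(time, event)
  # G evaluated just before t (left limit)
  g_at <- function(t) pmax(km_surv_at(G, t - 1e-9), 1e-6)
  w_case <- 1 / g_at(time[cases])
  w_ctrl <- rep(1 / g_at(horizon), length(controls))
  sc <- score[cases]; sn <- score[controls]
  gt <- outer(sc, sn, ">"); eq <- outer(sc, sn, "==")
  wmat <- outer(w_case, w_ctrl)
  sum(wmat * (gt + 0.5 * eq)) / sum(wmat)
}

#' Calibration of predicted risk at a horizon
#'
#' Bins subjects by predicted risk (quartiles by default) and compares
#' the mean predicted risk in each bin with the Kaplan-Meier observed
#' risk 1 - S(t) of the bin. Empty bins (from tied predictions) are
#' merged with a neighbour, with a warning.
#'
#' @param predicted Predicted event risk by `horizon`, in \[0, 1\].
#' @param time,event Survival data.
#' @param horizon Evaluation time.
#' @param n_bins Number of risk bins (default 4, quartiles).
#' @return data.frame: `bin`, `n`, `mean_predicted`, `observed`.
#' @export
calibration_curve <- function(predicted, time, event, horizon, n_bins = 4) {
  check_surv_input(time, event)
  if (any(predicted < 0 | predicted > 1)) stop("`predicted` must be in [0, 1]")
  brk <- unique(stats::quantile(predicted, seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < n_bins + 1)
    warning("tied predictions: some bins merged with their neighbour")
  if (length(brk) == 1) brk <- c(brk - 1e-9, brk + 1e-9)
  bin <- cut(predicted, brk, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    idx <- which(bin == b)
    if (!length(idx)) return(NULL)
    km <- km_curve(time[idx], event[idx])
    data.frame(bin = b, n = length(idx),
               mean_predicted = mean(predicted[idx]),
               observed = 1 - km_surv_at(km, horizon))
  }))
  rownames(out) <- NULL
  out
}

#' Continuous net reclassification improvement
#'
#' Category-free NRI of a new score against an old one at a horizon:
#' P(up|event) - P(down|event) + P(down|nonevent) - P(up|nonevent),
#' with event status at the horizon weighted by inverse-probability-of-
#' censoring weights. "Up" means the new score exceeds the old one, so
#' the two scores must live on a common (risk) scale.
#'
#' @param score_new,score_old Risk scores for the same subjects.
#' @param time,event Survival data.
#' @param horizon Evaluation time (must be within follow-up).
#' @param n_boot Bootstrap replicates for the CI (0 disables).
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level.
#' @return List `nri`, `nri_events`, `nri_nonevents`, and `lower`,
#'   `upper` when bootstrapped.
#' @export
nri <- function(score_new, score_old, time, event, horizon,
                n_boot = 1000, seed = 1, conf_level = 0.95) {
  check_surv_input(time, event)
  stopifnot(length(score_new) == length(time),
            length(score_old) == length(time))
  if (horizon > max(time)) stop("horizon beyond observed follow-up")
  nri_one <- function(sn, so, tt, ev) {
    cases <- which(tt <= horizon & ev == 1)
    ctrls <- which(tt > horizon)
    if (!length(cases) || !length(ctrls)) return(c(NA, NA, NA))
    G <- censor_km(tt, ev)
    g_at <- function(t) pmax(km_surv_at(G, t - 1e-9), 1e-6)
    wc <- 1 / g_at(tt[cases]); wn <- rep(1 / g_at(horizon), length(ctrls))
    up_c <- sn[cases] > so[cases]; dn_c <- sn[cases] < so[cases]
    up_n <- sn[ctrls] > so[ctrls]; dn_n <- sn[ctrls] < so[ctrls]
    ev_part <- sum(wc * (up_c - dn_c)) / sum(wc)
    ne_part <- sum(wn * (dn_n - up_n)) / sum(wn)
    c(ev_part + ne_part, ev_part, ne_part)
  }
  est <- nri_one(score_new, score_old, time, event)
  out <- list(nri = est[1], nri_events = est[2], nri_nonevents = est[3])
  if (n_boot > 0) {
    bs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(time), replace = TRUE)
      nri_one(score_new[idx], score_old[idx], time[idx], event[idx])[1]
    }, numeric(1)))
    qs <- stats::quantile(bs, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                          na.rm = TRUE)
    out$lower <- qs[[1]]; out$upper <- qs[[2]]
  }
  out
}

#' Predicted event risk by a horizon from a Cox linear predictor
#'
#' Breslow baseline cumulative hazard with the linear predictor as
#' offset; predicted risk is 1 - exp(-H0(t) exp(lp - mean(lp))).
#'
#' @param time,event Survival data used to estimate the baseline.
#' @param lp Linear predictor (risk score) of the same subjects.
#' @param horizon Evaluation time.
#' @param lp_new Optional linear predictor of new subjects (defaults to
#'   `lp`).
#' @return Predicted risks in \[0, 1\].
#' @export
cox_baseline_risk <- function(time, event, lp, horizon, lp_new = lp) {
  check_surv_input(time, event)
  lpc <- lp - mean(lp)
  o <- order(time)
  ts <- time[o]; ev <- event[o]; r <- exp(lpc[o])
  denom <- rev(cumsum(rev(r)))          # sum of exp(lp) over the risk set
  et <- unique(ts[ev == 1 & ts <= horizon])
  H0 <- sum(vapply(et, function(t0) {
    i <- which(ts == t0)
    sum(ev[i]) / denom[i[1]]
  }, numeric(1)))
  pmin(pmax(1 - exp(-H0 * exp(lp_new - mean(lp))), 0), 1)
}
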