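# Prognostic scoring: LASSO penalized Cox feature selection over the
# signature catalogue, the linear histological / combined scores, the
# maximally selected log-rank cutpoint, and risk-group stratification.

#' Fit a LASSO-penalized Cox model over slide signatures
#'
#' Columns are standardized internally; coefficients are returned on the
#' original scale. The penalty is chosen by K-fold cross-validated
#' partial-likelihood deviance with seeded fold assignment (lambda.min by
#' default). `lambda = 0` fits the unpenalized Cox partial likelihood
#' (Efron ties).
#'
#' @param X Numeric matrix (subjects x features) with column names.
#' @param time,event Survival data (>= 2 events required).
#' @param seed Fold-assignment seed.
#' @param n_folds CV folds (default 10).
#' @param lambda Optional fixed penalty; NULL = cross-validate.
#' @param lambda_rule "min" or "1se".
#' @return A `lasso_cox_fit`: named `beta` (original scale; zeros kept),
#'   `lambda`, `lambda_path`, `cv_curve`, `n_nonzero`, `dropped`
#'   (constant columns removed before fitting).
#' @export
fit_lasso_cox <- function(X, time, event, seed = 1, n_folds = 10,
                          lambda = NULL, lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  check_surv_input(time, event)
  if (sum(event) < 2) stop("need at least 2 events to fit a Cox model")
  const <- apply(X, 2, function(v) stats::sd(v) < 1e-12)
  if (any(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(X)[const], collapse = ", ")))
  }
  Xf <- X[, !const, drop = FALSE]
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  y <- survival::Surv(time, event)

  if (!is.null(lambda) && lambda == 0) {
    f <- survival::coxph(y ~ Xf, ties = "efron",
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 100))
    beta[colnames(Xf)] <- as.numeric(stats::coef(f))
    fit <- list(beta = beta, lambda = 0, lambda_path = NULL,
                cv_curve = NULL, dropped = colnames(X)[const])
  } else if (!is.null(lambda)) {
    g <- glmnet::glmnet(Xf, y, family = "cox", standardize = TRUE)
    b <- as.numeric(stats::coef(g, s = lambda, exact = TRUE, x = Xf, y = y))
    beta[colnames(Xf)] <- b
    fit <- list(beta = beta, lambda = lambda, lambda_path = g$lambda,
                cv_curve = NULL, dropped = colnames(X)[const])
  } else {
    foldid <- with_seed(seed,
      sample(rep_len(seq_len(n_folds), nrow(Xf))))
    cv <- glmnet::cv.glmnet(Xf, y, family = "cox", foldid = foldid,
                            type.measure = "deviance", standardize = TRUE)
    lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    b <- as.numeric(stats::coef(cv, s = lam))
    beta[colnames(Xf)] <- b
    fit <- list(beta = beta, lambda = lam, lambda_path = cv$lambda,
                cv_curve = cv$cvm, dropped = colnames(X)[const])
  }
  fit$n_nonzero <- sum(fit$beta != 0)
  structure(fit, class = "lasso_cox_fit")
}

#' Compute a linear risk score from a fitted model
#'
#' The histological / combined score is the sum of products of feature
#' values and fitted coefficients, score = sum_j beta_j x_j.
#'
#' @param fit A `lasso_cox_fit` (or any list with a named `beta`).
#' @param x Named vector, `signature_vector`, matrix or data.frame whose
#'   columns cover the fit's feature names.
#' @return Numeric score(s).
#' @export
compute_score <- function(fit, x) {
  beta <- fit$beta
  if (inherits(x, "signature_vector")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  missing <- setdiff(names(beta), colnames(x))
  if (length(missing))
    stop(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
  as.numeric(x[, names(beta), drop = FALSE] %*% beta)
}

# Log-rank chi-square statistics for splitting at each candidate cutoff,
# vectorized across candidates (hypergeometric variance, tied times
# grouped).
logrank_stats_at <- function(scores, time, event, candidates) {
  o <- order(time)
  t_s <- time[o]; d_s <- event[o]; s_s <- scores[o]
  n <- length(t_s); C <- length(candidates)
  Z <- outer(s_s, candidates, ">") * 1
  # at-risk count in group 1 at each sorted index (risk set = j >= i)
  M <- apply(Z[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  U <- numeric(C); V <- numeric(C)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && t_s[j + 1] == t_s[i]) j <- j + 1L
    dtot <- sum(d_s[i:j])
    if (dtot > 0) {
      nr <- n - i + 1L
      n1 <- M[i, ]
      d1 <- colSums(Z[(i:j)[d_s[i:j] == 1], , drop = FALSE])
      U <- U + (d1 - dtot * n1 / nr)
      if (nr > 1)
        V <- V + dtot * (n1 / nr) * (1 - n1 / nr) * (nr - dtot) / (nr - 1)
    }
    i <- j + 1L
  }
  ifelse(V > 0, U^2 / V, 0)
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates the two-group log-rank statistic at every candidate cutoff
#' (midpoints between sorted unique scores, restricted to the quantile
#' bounds and to splits with at least two events on each side) and
#' returns the maximizer; ties go to the smaller cutoff. An optional
#' permutation calibration (scores permuted against outcomes) yields a
#' p-value for the selected statistic.
#'
#' @param scores Risk scores.
#' @param time,event Survival data.
#' @param quantile_bounds Candidate range as score quantiles.
#' @param n_perm Permutation replicates for the p-value (0 disables).
#' @param seed Permutation seed.
#' @return List `cutoff`, `statistic` (chi-square at the cutoff),
#'   `candidates`, `statistics`, and `p_value` when permuted.
#' @export
optimal_cutoff <- function(scores, time, event, quantile_bounds = c(0.10, 0.90),
                           n_perm = 0, seed = 1) {
  check_surv_input(time, event)
  stopifnot(length(scores) == length(time))
  us <- sort(unique(scores))
  if (length(us) < 2) stop("no admissible candidate cutoff: all scores equal")
  mids <- (us[-1] + us[-length(us)]) / 2
  qb <- stats::quantile(scores, quantile_bounds)
  cand <- mids[mids >= qb[1] & mids <= qb[2]]
  # admissibility: >= 2 events on each side
  cand <- cand[vapply(cand, function(cc)
    sum(event[scores > cc]) >= 2 && sum(event[scores <= cc]) >= 2, logical(1))]
  if (!length(cand)) stop("no admissible candidate cutoff")
  stat <- logrank_stats_at(scores, time, event, cand)
  best <- which.max(stat)
  out <- list(cutoff = cand[best], statistic = stat[best],
              candidates = cand, statistics = stat)
  if (n_perm > 0) {
    obs <- stat[best]
    perm_max <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      sp <- sample(scores)
      max(logrank_stats_at(sp, time, event, cand))
    }, numeric(1)))
    out$p_value <- (1 + sum(perm_max >= obs)) / (n_perm + 1)
  }
  out
}

#' Stratify subjects into risk groups at a cutoff
#'
#' High risk iff score > cutoff (strictly); a score exactly at the
#' cutoff is low risk.
#'
#' @param scores Numeric risk scores (finite).
#' @param cutoff Scalar cutoff.
#' @return data.frame `score`, `group` (factor low/high), with the
#'   cutoff and group counts as attributes.
#' @export
stratify <- function(scores, cutoff) {
  stopifnot(all(is.finite(scores)) || length(scores) == 0)
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  out <- data.frame(score = scores, group = group)
  attr(out, "cutoff") <- cutoff
  attr(out, "counts") <- table(group)
  out
}
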