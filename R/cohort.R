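# Survival cohort simulation. Event times follow a Weibull proportional-
# hazards model whose log-hazard is a known sparse linear function of the
# slide signature vector, with independent uniform censoring tuned to a
# target censoring fraction — so LASSO-Cox selection and every
# discrimination metric can be checked against a known oracle.

#' Specify a synthetic survival cohort
#'
#' @param n_patients Cohort size.
#' @param beta_true Named sparse coefficient vector over signature names
#'   (>= 1 nonzero entry). Defaults to the five planted coefficients of
#'   the package's default cohort.
#' @param baseline Weibull baseline, `list(shape, scale)`; shape 1 is the
#'   exponential limit. Scale is in months.
#' @param censor_rate Target censored fraction in \[0, 1).
#' @param seed Integer seed.
#' @param prevalences Bernoulli prevalences of the binary clinical
#'   markers.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        beta_true = default_beta_true(),
                        baseline = list(shape = 1, scale = 60),
                        censor_rate = 0.3, seed = 7,
                        prevalences = c(sex_male = 0.85, afp_high = 0.40,
                                        alt_high = 0.35, tumor_multiple = 0.15)) {
  stopifnot(n_patients >= 1, censor_rate >= 0, censor_rate < 1,
            baseline$shape > 0, baseline$scale > 0)
  if (sum(beta_true != 0) < 1) stop("beta_true needs >= 1 nonzero entry")
  if (is.null(names(beta_true))) stop("beta_true must be named")
  structure(list(n_patients = as.integer(n_patients), beta_true = beta_true,
                 baseline = baseline, censor_rate = censor_rate,
                 seed = as.integer(seed), prevalences = prevalences),
            class = "cohort_spec")
}

#' Default planted coefficients
#'
#' Five nonzero coefficients over the signature catalogue: tumor,
#' fibrosis and lymphocyte area proportions plus tumor-region GLCM
#' contrast and lymphocyte blob density. Magnitudes are fixed so that
#' the oracle linear predictor's concordance on the default cohort is
#' approximately 0.88.
#'
#' @return Named numeric vector.
#' @export
default_beta_true <- function() {
  c(prop_TR = 14.7, prop_FI = 16.5, prop_LA = -19.7,
    TR.glcm_contrast = 3.56, LA.blob_density = -0.324)
}

# Class-conditional tile feature statistics (mean, sd per feature) from a
# small set of rendered calibration tiles.
calibrate_class_features <- function(seed, n_tiles = 12, side = 96,
                                     recipes = default_recipes()) {
  cls <- hcc_classes()
  mu <- sd <- matrix(0, length(cls), .N_TILE_FEATURES,
                     dimnames = list(cls, tile_feature_names()))
  for (ci in seq_along(cls)) {
    f <- t(vapply(seq_len(n_tiles), function(i) {
      tl <- render_tile(recipes[[cls[ci]]], side,
                        substream_seed(seed, 900000L + ci * 1000L + i))
      tile_features(tl$pixels)
    }, numeric(.N_TILE_FEATURES)))
    mu[ci, ] <- colMeans(f)
    sd[ci, ] <- apply(f, 2, stats::sd)
  }
  list(mu = mu, sd = sd)
}

#' Generate a cohort's signature matrix statistically
#'
#' Emulates the imaging pipeline's per-slide output: compositions drawn
#' from a Dirichlet, class feature blocks drawn around class-conditional
#' means calibrated from rendered tiles, with independent per-slide
#' feature jitter standing in for slide-to-slide staining and texture
#' heterogeneity.
#'
#' @param n Number of slides.
#' @param seed Integer seed.
#' @param alpha Dirichlet concentration over the six classes.
#' @param jitter Slide-level feature sd as a multiple of the tile-level sd.
#' @return Matrix n x 138 with `signature_names()` columns.
#' @export
synthetic_signatures <- function(n, seed,
                                 alpha = c(TR = 8, NLT = 6, PA = 2,
                                           FI = 3, HNA = 2, LA = 2),
                                 jitter = 0.85) {
  cal <- calibrate_class_features(seed)
  with_seed(seed, {
    g <- matrix(stats::rgamma(n * 6, shape = alpha), n, 6, byrow = TRUE)
    comps <- g / rowSums(g)
    props <- pmax(comps + matrix(stats::rnorm(n * 6, 0, 0.01), n, 6), 1e-6)
    props <- props / rowSums(props)
    blocks <- do.call(cbind, lapply(seq_along(hcc_classes()), function(ci) {
      mu <- matrix(cal$mu[ci, ], n, .N_TILE_FEATURES, byrow = TRUE)
      noise <- matrix(stats::rnorm(n * .N_TILE_FEATURES), n) *
        matrix(cal$sd[ci, ] * jitter, n, .N_TILE_FEATURES, byrow = TRUE)
      mu + noise
    }))
    X <- cbind(props, blocks, matrix(1, n, 6))
    colnames(X) <- signature_names()
    X
  })
}

#' Simulate survival outcomes over a cohort of slide signatures
#'
#' Event times are Weibull with log-hazard `beta_true . x` (proportional
#' hazards); censoring is independent uniform on (0, u) with u tuned so
#' the realized censored fraction matches `spec$censor_rate`. Clinical
#' covariates are independent draws (age ~ N(54, 8), binary markers ~
#' Bernoulli at the configured prevalences, tumor size log-normal).
#'
#' @param spec A `cohort_spec`.
#' @param signatures Matrix of signatures (n x p with column names), a
#'   list of `signature_vector`s, or NULL to generate with
#'   `synthetic_signatures(spec$n_patients, spec$seed)`.
#' @param horizon Optional maximum censoring horizon; an error is raised
#'   if the target censor rate cannot be reached within it.
#' @return data.frame (`cohort_table`): patient_id, slide_id, time,
#'   event, lp (true linear predictor) and clinical covariates; the
#'   signature matrix and `beta_true` are attached as attributes.
#' @export
simulate_cohort <- function(spec, signatures = NULL, horizon = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(signatures))
    signatures <- synthetic_signatures(spec$n_patients, spec$seed)
  if (is.list(signatures) && inherits(signatures[[1]], "signature_vector"))
    signatures <- t(vapply(signatures, function(s) s$values,
                           numeric(length(signatures[[1]]$values))))
  X <- as.matrix(signatures)
  n <- nrow(X)
  missing <- setdiff(names(spec$beta_true), colnames(X))
  if (length(missing))
    stop(sprintf("beta_true names not in signatures: %s",
                 paste(missing, collapse = ", ")))
  lp <- as.numeric(X[, names(spec$beta_true), drop = FALSE] %*% spec$beta_true)
  lp <- lp - mean(lp)

  with_seed(substream_seed(spec$seed, 31L), {
    u <- stats::runif(n)
    shape <- spec$baseline$shape; scale <- spec$baseline$scale
    T_event <- scale * (-log(u) * exp(-lp))^(1 / shape)

    if (spec$censor_rate == 0) {
      time <- T_event; event <- rep(1L, n)
    } else {
      p_cens <- function(uu) mean(pmin(T_event, uu)) / uu
      hi <- if (is.null(horizon)) max(T_event) * 100 else horizon
      if (p_cens(hi) > spec$censor_rate + 1e-9) {
        if (!is.null(horizon))
          stop(sprintf(
            "censor rate %.2f unachievable within horizon %.1f (minimum %.2f)",
            spec$censor_rate, horizon, p_cens(hi)))
        # extremely heavy tails: extend until achievable
        while (p_cens(hi) > spec$censor_rate) hi <- hi * 10
      }
      u_star <- stats::uniroot(function(uu) p_cens(uu) - spec$censor_rate,
                               lower = min(T_event) / 2, upper = hi,
                               tol = 1e-8)$root
      C <- stats::runif(n, 0, u_star)
      event <- as.integer(T_event <= C)
      time <- pmin(T_event, C)
    }

    prev <- spec$prevalences
    covars <- data.frame(
      age = stats::rnorm(n, 54, 8),
      sex_male = stats::rbinom(n, 1, prev[["sex_male"]]),
      afp_high = stats::rbinom(n, 1, prev[["afp_high"]]),
      alt_high = stats::rbinom(n, 1, prev[["alt_high"]]),
      tumor_multiple = stats::rbinom(n, 1, prev[["tumor_multiple"]]),
      tumor_size = exp(stats::rnorm(n, log(4), 0.4)))

    out <- cbind(data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                            slide_id = sprintf("S%04d", seq_len(n)),
                            time = time, event = event, lp = lp),
                 covars)
    attr(out, "signatures") <- X
    attr(out, "beta_true") <- spec$beta_true
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' The default acceptance-scale synthetic cohort
#'
#' n slides with Dirichlet-varied compositions, the five default planted
#' coefficients, Weibull shape-1 baseline and 30% uniform censoring.
#'
#' @param n Cohort size (default 600).
#' @param seed Integer seed (default 7).
#' @return A `cohort_table` (see `simulate_cohort`).
#' @export
default_cohort <- function(n = 600, seed = 7) {
  simulate_cohort(cohort_spec(n_patients = n, seed = seed))
}
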