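# End-to-end orchestration: synthetic slides -> tissue masks -> tile
# classifier -> classification maps -> signatures -> survival cohort ->
# LASSO-Cox score -> cutpoint -> discrimination report, with a manifest
# of checksums and timings for reproducibility.

#' Pipeline run configuration
#'
#' @param out_dir Output directory.
#' @param n_slides Number of synthetic slides in the demo cohort.
#' @param slide_size Slide side in px.
#' @param n_cells Voronoi cells per slide (fewer = larger regions).
#' @param tile_side Tile side in px.
#' @param min_coverage Tile tissue-coverage threshold.
#' @param n_tiles_train Training tiles per class for the classifier.
#' @param backend Classifier backend ("ranger" or "nnet").
#' @param top_k Representative tiles per class.
#' @param n_folds CV folds for the LASSO-Cox penalty.
#' @param lambda_rule "min" or "1se".
#' @param cutpoint_bounds Quantile bounds for the cutpoint search.
#' @param horizons Evaluation horizons (months).
#' @param censor_rate Target censoring fraction.
#' @param seed Global seed; all stage seeds derive from it.
#' @param normalize Apply stain standardization to a shared template.
#' @param write_images Write slide PNGs (off by default to keep runs light).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("histoscore_run_"),
                       n_slides = 24, slide_size = 480, n_cells = 10,
                       tile_side = 96, min_coverage = 0.5,
                       n_tiles_train = 80, backend = "ranger", top_k = 10,
                       n_folds = 5, lambda_rule = "min",
                       cutpoint_bounds = c(0.10, 0.90),
                       horizons = c(12, 36, 60), censor_rate = 0.3,
                       seed = 1, normalize = TRUE, write_images = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Save / load a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML path.
#' @return `load_config` returns a `run_config`; round-trips unchanged.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes generation -> preprocessing -> classifier training -> slide
#' mapping -> signature extraction -> survival simulation -> LASSO-Cox
#' scoring -> cutpoint/stratification -> discrimination metrics, writing
#' all artifacts under `config$out_dir`. Fails fast with the stage name
#' on error.
#'
#' @param config A `run_config`.
#' @return A `run_manifest`: config hash, artifact checksums, stage
#'   timings, package version. The report and scored cohort are written
#'   to the output directory.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    res
  }
  seed <- config$seed

  slides <- tick("synthgen", {
    stage_msg("synthgen", "%d slides at %d px", config$n_slides,
              config$slide_size)
    alpha <- c(8, 6, 2, 3, 2, 2)
    with_seed(substream_seed(seed, 11L), {
      comps <- t(vapply(seq_len(config$n_slides), function(i) {
        g <- stats::rgamma(6, alpha); g / sum(g)
      }, numeric(6)))
      lapply(seq_len(config$n_slides), function(i)
        compose_slide(comps[i, ], config$slide_size,
                      seed = substream_seed(seed, 1000L + i),
                      n_cells = config$n_cells))
    })
  })

  model <- tick("classifier", {
    stage_msg("classifier", "training %s on %d tiles/class", config$backend,
              config$n_tiles_train)
    batch <- synth_tile_batch(config$n_tiles_train, side = config$tile_side,
                              seed = substream_seed(seed, 21L))
    sp <- split_dataset(batch, seed = substream_seed(seed, 22L))
    train_classifier(sp$train, sp$val,
                     classifier_config(backend = config$backend,
                                       seed = substream_seed(seed, 23L)))
  })

  sigs <- tick("slidemap_signatures", {
    masks <- lapply(slides, function(s) tissue_mask(s$image))
    template <- if (config$normalize)
      estimate_template(slides[[1]]$image, masks[[1]]) else NULL
    lapply(seq_along(slides), function(i) {
      sid <- sprintf("S%04d", i)
      img <- slides[[i]]$image
      if (!is.null(template))
        img <- reinhard_normalize(img, masks[[i]], template)
      mp <- smooth_map(build_map(img, masks[[i]], model,
                                 min_coverage = config$min_coverage,
                                 slide_id = sid))
      tk <- top_k_tiles(mp, k = config$top_k)
      acc <- function(r, c) {
        side <- config$tile_side
        img[r * side + seq_len(side), c * side + seq_len(side), , drop = FALSE]
      }
      if (config$write_images)
        write_slide(slides[[i]], file.path(config$out_dir, sid))
      write_map_csv(mp, file.path(config$out_dir, paste0(sid, "_map.csv")))
      slide_signature(mp, tk, acc)
    })
  })

  cohort <- tick("cohort", {
    spec <- cohort_spec(n_patients = length(sigs),
                        censor_rate = config$censor_rate,
                        seed = substream_seed(seed, 41L))
    co <- simulate_cohort(spec, sigs)
    write_cohort(co, file.path(config$out_dir, "cohort.csv"))
    co
  })

  scored <- tick("risk_model", {
    X <- attr(cohort, "signatures")
    fit <- fit_lasso_cox(X, cohort$time, cohort$event,
                         seed = substream_seed(seed, 51L),
                         n_folds = config$n_folds,
                         lambda_rule = config$lambda_rule)
    hs <- compute_score(fit, X)
    cut <- tryCatch(
      optimal_cutoff(hs, cohort$time, cohort$event,
                     quantile_bounds = config$cutpoint_bounds),
      error = function(e) list(cutoff = stats::median(hs), statistic = NA))
    groups <- stratify(hs, cut$cutoff)
    save_fit(fit, file.path(config$out_dir, "fit.json"), cutoff = cut$cutoff)
    co2 <- cbind(as.data.frame(cohort), hs = hs, group = groups$group)
    write_cohort(co2, file.path(config$out_dir, "cohort_scored.csv"))
    list(fit = fit, hs = hs, cutoff = cut, groups = groups, cohort = co2)
  })

  report <- tick("surv_eval", {
    co <- scored$cohort
    hs <- scored$hs
    hc <- harrell_c(co$time, co$event, hs)
    aucs <- sapply(config$horizons, function(h)
      tryCatch(td_roc_auc(co$time, co$event, hs, h),
               error = function(e) NA_real_))
    names(aucs) <- paste0("t", config$horizons)
    lr <- if (nlevels(droplevels(co$group)) == 2)
      logrank_test(co$time, co$event, co$group) else NULL
    h1 <- config$horizons[1]
    cal <- tryCatch({
      risk <- cox_baseline_risk(co$time, co$event, hs, h1)
      calibration_curve(risk, co$time, co$event, h1)
    }, error = function(e) NULL)
    rep <- list(n = nrow(co), n_events = sum(co$event),
                c_index = hc$c_index, auc_at = as.list(aucs),
                cutoff = scored$cutoff$cutoff,
                n_high = sum(co$group == "high"),
                n_low = sum(co$group == "low"),
                logrank_p = if (!is.null(lr)) lr$p_value else NA,
                n_selected = scored$fit$n_nonzero,
                calibration = cal)
    write_report(rep, file.path(config$out_dir, "report.json"))
    rep
  })

  cfg_path <- file.path(config$out_dir, "config.yaml")
  save_config(config, cfg_path)
  # config hash ignores out_dir so identical runs in different directories
  # hash identically
  norm_cfg <- tempfile(fileext = ".yaml")
  cfg_no_dir <- unclass(config); cfg_no_dir$out_dir <- NULL
  yaml::write_yaml(cfg_no_dir, norm_cfg)
  files <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                        file.path(config$out_dir,
                                  c("manifest.json", "config.yaml"))))
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  manifest <- list(
    config_hash = unname(tools::md5sum(norm_cfg)),
    checksums = as.list(sums),
    timings = as.list(timings),
    package_version = as.character(utils::packageVersion("histoscore")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  class(manifest) <- "run_manifest"
  manifest
}
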