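# End-to-end experiment orchestration at phantom scale: cohort synthesis,
# degradation to pseudo-clinical CT, threshold segmentation, template
# fitting (similarity ICP + LAD and/or SSM), morphometry, and error
# summarization as mean absolute error in percent of the gold-standard
# sample range.

#' Experiment configuration
#'
#' Defaults mirror the validation design: an 18-specimen cohort, fitting at
#' grayscale thresholds bracketing the capsule boundary, 50 ICP/LAD
#' iterations and a LAD neighbourhood of 5 mm.
#'
#' @param cohort_size number of phantom specimens (default 18).
#' @param presets degradation presets to run; any of `"cbct"`, `"mdct"`,
#'   `"poor_mdct"`, or `"none"` for undegraded volumes.
#' @param thresholds grayscale segmentation thresholds (default 160/170/180).
#' @param methods subset of `"lad"`, `"full_ssm"`, `"loo_ssm"`.
#' @param lad_d LAD neighbourhood radius (mm).
#' @param iters LAD / SSM iteration budget.
#' @param icp_iters similarity-ICP iteration budget (default 200; the
#'   closed-form inner step is cheap and the stage early-stops at its
#'   convergence tolerance, typically near 100 iterations).
#' @param seed integer master seed; every random stage derives from it.
#' @param source_spacing voxel pitch of the micro-CT-like source volumes
#'   (mm).
#' @param landmark_sigma std. dev. of the landmark placement jitter
#'   emulating manual clicks (mm).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort_size = 18,
                              presets = "mdct",
                              thresholds = c(160, 170, 180),
                              methods = "lad",
                              lad_d = 5, iters = 50, icp_iters = 200,
                              seed = 1L,
                              source_spacing = 0.15,
                              landmark_sigma = 0.25) {
  stopifnot(cohort_size >= 2,
            all(presets %in% c("none", "cbct", "mdct", "poor_mdct")),
            all(methods %in% c("lad", "full_ssm", "loo_ssm")))
  structure(list(cohort_size = cohort_size, presets = presets,
                 thresholds = thresholds, methods = methods,
                 lad_d = lad_d, iters = iters, icp_iters = icp_iters,
                 seed = as.integer(seed),
                 source_spacing = source_spacing,
                 landmark_sigma = landmark_sigma),
            class = "experiment_config")
}

#' Build the registration template
#'
#' The template is a phantom specimen generated from the default (mean)
#' parameters in canonical pose, annotated once with its landmark triad and
#' the traced outer-wall contour; the contour anchors are carried through
#' every subsequent deformation of the template.
#'
#' @param params template phantom parameters.
#' @return list with `mesh`, `landmarks`, `anchors`, `contour`, `side`,
#'   `truth`.
#' @export
build_template <- function(params = phantom_params()) {
  spec <- generate_specimen(params)
  tr <- trace_outer_wall(spec$mesh, spec$truth$landmarks$apex,
                         spec$truth$round_window, spec$truth$coiling_axis)
  list(mesh = spec$mesh, landmarks = spec$truth$landmarks,
       anchors = tr$anchors, contour = tr$contour,
       side = spec$params$side, truth = spec$truth)
}

#' Measure a fitted template surface
#'
#' Rebuilds the outer-wall contour from the template anchors on a fitted
#' mesh of the same topology and computes the three measurements.
#'
#' @param mesh fitted `trimesh` (template topology).
#' @param template a [build_template()] result.
#' @export
measure_fitted <- function(mesh, template) {
  ct <- contour_from_anchors(template$anchors, mesh)
  measurement_report(ct)
}

.metrics <- c("non_planarity", "reach", "duct_length")

# Fit one specimen's cloud with every requested method; returns a list of
# per-method measurement reports plus the unfitted-template baseline.
.fit_and_measure <- function(template, cloud, landmarks_data, side_data,
                             cfg, models = NULL) {
  reflect <- if (side_data != template$side) "force" else "never"
  init <- landmark_similarity(template$landmarks, landmarks_data,
                              reflect = reflect)
  roi <- template_roi(apply_transform(init, template$mesh$vertices), dilate = 2)
  cloud <- crop_cloud(cloud, roi)
  if (nrow(cloud$points) < 3) stop("empty cloud after ROI crop")
  icp_iters <- if (is.null(cfg$icp_iters)) 200 else cfg$icp_iters
  icp_tf <- icp_similarity(template$mesh, cloud, init, iters = icp_iters,
                           anchors = list(src = template$landmarks,
                                          dst = landmarks_data))
  aligned <- apply_transform(icp_tf, template$mesh)
  out <- list(unfitted = measure_fitted(aligned, template))
  for (m in cfg$methods) {
    fitted <- switch(m,
      lad = lad_fit(aligned, cloud,
                    lad_config(d = cfg$lad_d, iters = cfg$iters))$mesh,
      full_ssm = ssm_fit(models$full, cloud, icp_tf, iters = cfg$iters)$mesh,
      loo_ssm = ssm_fit(models$loo, cloud, icp_tf, iters = cfg$iters)$mesh)
    out[[m]] <- measure_fitted(fitted, template)
  }
  out
}

# Mirror a specimen's vertex set into the template chirality for SSM
# training (any fixed mirror works; Procrustes absorbs the orientation).
.training_vertices <- function(spec, template_side) {
  V <- spec$mesh$vertices
  if (spec$truth$side != template_side) V <- V %*% diag(c(-1, 1, 1))
  V
}

#' Run the end-to-end validation experiment
#'
#' Synthesizes a phantom cohort, renders micro-CT-like volumes, degrades
#' them per preset, segments at each threshold, fits the template with each
#' requested method, measures the fitted surfaces, and summarizes errors
#' against the analytic gold standard.  Stage failures are recorded per
#' specimen and never abort the cohort.
#'
#' @param cfg an [experiment_config()].
#' @param cohort optional pre-built cohort (list of `otic_specimen`), e.g.
#'   to share specimens across configurations.
#' @param template optional pre-built template from [build_template()].
#' @return list with `results` (per-specimen long data frame), `summary`
#'   (mean absolute error and percent-of-range per metric x method x preset
#'   x threshold), `truth` (gold-standard table), `failures`.
#' @export
run_experiment <- function(cfg = experiment_config(), cohort = NULL,
                           template = NULL) {
  if (is.null(template)) template <- build_template()
  if (is.null(cohort)) cohort <- sample_cohort(cfg$cohort_size, cfg$seed)
  n <- length(cohort)
  truth <- data.frame(specimen = seq_len(n),
                      t(sapply(cohort, function(s)
                        unlist(s$truth[.metrics]))))
  names(truth)[-1] <- .metrics
  # SSM training uses the cohort's true meshes in native correspondence
  models_full <- NULL
  need_ssm <- any(c("full_ssm", "loo_ssm") %in% cfg$methods)
  train <- NULL
  if (need_ssm) {
    train <- lapply(cohort, .training_vertices, template_side = template$side)
    models_full <- build_ssm(train, template$mesh$vertices,
                             faces = template$mesh$faces)
  }
  rows <- list(); failures <- list()
  set.seed(cfg$seed + 7777L)
  lm_jitter <- lapply(seq_len(n), function(i)
    matrix(rnorm(9, 0, cfg$landmark_sigma), 3, 3))
  for (i in seq_len(n)) {
    spec <- cohort[[i]]
    micro <- phantom_volume(spec, spacing = cfg$source_spacing)
    lm_data <- spec$truth$landmarks
    for (k in seq_along(lm_data))
      lm_data[[k]] <- lm_data[[k]] + lm_jitter[[i]][k, ]
    models <- NULL
    if (need_ssm) {
      models <- list(full = models_full)
      if ("loo_ssm" %in% cfg$methods)
        models$loo <- build_ssm(train[-i], template$mesh$vertices,
                                faces = template$mesh$faces)
    }
    for (preset in cfg$presets) {
      vol <- if (preset == "none") micro else
        degrade_volume(micro, degrade_config(preset,
                                             rng_seed = cfg$seed * 1000L + i))
      for (thr in cfg$thresholds) {
        res <- tryCatch(
          .fit_and_measure(template,
                           extract_threshold_cloud(vol, thr),
                           lm_data, spec$truth$side, cfg, models),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <-
            list(specimen = i, preset = preset, threshold = thr,
                 message = conditionMessage(res))
          next
        }
        for (m in names(res))
          for (metric in .metrics)
            rows[[length(rows) + 1]] <- data.frame(
              specimen = i, preset = preset, threshold = thr, method = m,
              metric = metric, value = res[[m]][[metric]],
              truth = spec$truth[[metric]])
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- NULL
  if (!is.null(results)) {
    results$abs_error <- abs(results$value - results$truth)
    rng <- sapply(.metrics, function(m) diff(range(truth[[m]])))
    agg <- aggregate(abs_error ~ metric + method + preset + threshold,
                     results, mean)
    agg$gold_range <- rng[agg$metric]
    agg$pct_of_range <- ifelse(agg$gold_range > 0,
                               100 * agg$abs_error / agg$gold_range, NA_real_)
    agg$undefined_pct <- agg$gold_range <= 0
    summary <- agg
  }
  list(results = results, summary = summary, truth = truth,
       failures = failures, template = template, config = cfg)
}

#' Parameter sensitivity sweep
#'
#' Re-runs the pipeline on the least and most non-planar cohort members
#' while varying one parameter: the segmentation `threshold`, the LAD
#' neighbourhood `d`, the iteration budget `iters`, or the `template`.
#'
#' @param base_cfg an [experiment_config()] (its first preset/threshold are
#'   used for the stages not being varied).
#' @param vary one of `"threshold"`, `"d"`, `"iters"`, `"template"`.
#' @param values vector of values (for `"template"`, a list of
#'   [phantom_params()] objects).
#' @param cohort optional pre-built cohort.
#' @return long data frame of measurements and errors per varied value.
#' @export
sensitivity_sweep <- function(base_cfg, vary = c("threshold", "d", "iters",
                                                 "template"),
                              values, cohort = NULL) {
  vary <- match.arg(vary)
  if (!length(values)) stop("no values to sweep")
  if (is.null(cohort)) cohort <- sample_cohort(base_cfg$cohort_size,
                                               base_cfg$seed)
  np <- sapply(cohort, function(s) s$truth$non_planarity)
  pick <- c(which.min(np), which.max(np))
  sub <- cohort[pick]
  out <- list()
  for (v in seq_along(values)) {
    cfg <- base_cfg
    cfg$cohort_size <- length(sub)
    template <- NULL
    if (vary == "threshold") cfg$thresholds <- values[[v]]
    else cfg$thresholds <- base_cfg$thresholds[1]
    if (vary == "d") cfg$lad_d <- values[[v]]
    if (vary == "iters") cfg$iters <- values[[v]]
    if (vary == "template") template <- build_template(values[[v]])
    cfg$presets <- base_cfg$presets[1]
    run <- run_experiment(cfg, cohort = sub, template = template)
    if (!is.null(run$results)) {
      run$results$vary <- vary
      run$results$value_varied <- if (vary == "template") v else values[[v]]
      run$results$which_specimen <- c("least_nonplanar",
                                      "most_nonplanar")[run$results$specimen]
      out[[v]] <- run$results
    }
  }
  do.call(rbind, out)
}
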