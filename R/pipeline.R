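# End-to-end orchestration: segment -> contours -> spectra -> metrics ->
# cohort statistics, with a validated config, per-case artifacts and a run
# log. Entry at any stage (image, mask, or contour pair) is supported, and
# every stage can be re-entered from its serialized artifact.

#' Default pipeline configuration
#'
#' Nested list covering every tunable of the chain. Unknown keys are
#' rejected by [validate_config()]; the fully-resolved config is echoed
#' into every output directory.
#'
#' @param ... named overrides of top-level sections (`segmentation`,
#'   `contours`, `multifractal`, `stats`), each a named list of overrides
#'   within the section.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    segmentation = list(
      stain_vectors = hdab_stain_vectors(),
      tissue_od_min = 0.10,
      dab_threshold = NULL,
      dab_od_min = 0.15,
      min_object_px = 64L,
      fill_small_holes_px = 64L
    ),
    contours = list(largest_component_only = FALSE),
    multifractal = unclass(mf_config()),
    stats = list(endpoint = "TTR", dichotomize = "median",
                 treatment_col = "adjuvant")
  )
  ov <- list(...)
  for (sec in names(ov)) {
    if (!sec %in% names(cfg)) stop("unknown config section '", sec, "'")
    for (key in names(ov[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key '", sec, ".", key, "'")
      cfg[[sec]][[key]] <- ov[[sec]][[key]]
    }
  }
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg list or `pipeline_config`.
#' @return the validated config (classed), or an error naming the offending
#'   key.
#' @export
validate_config <- function(cfg) {
  ref <- list(
    segmentation = c("stain_vectors", "tissue_od_min", "dab_threshold",
                     "dab_od_min", "min_object_px", "fill_small_holes_px"),
    contours = "largest_component_only",
    multifractal = names(unclass(mf_config())),
    stats = c("endpoint", "dichotomize", "treatment_col"))
  bad_sec <- setdiff(names(cfg), names(ref))
  if (length(bad_sec)) stop("unknown config section(s): ",
                            paste(bad_sec, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), ref[[sec]])
    if (length(bad)) stop("unknown config key(s) in '", sec, "': ",
                          paste(bad, collapse = ", "))
  }
  sv <- cfg$segmentation$stain_vectors
  if (is.list(sv))  # YAML/JSON configs carry the matrix as a list of rows
    cfg$segmentation$stain_vectors <- do.call(rbind, lapply(sv, as.numeric))
  mf <- cfg$multifractal
  stopifnot(mf$min_box_px >= 1, mf$max_box_fraction > 0,
            mf$max_box_fraction <= 1, mf$q_min < mf$q_max, mf$q_step > 0,
            mf$min_density >= 0, mf$max_density <= 1,
            mf$min_density < mf$max_density, mf$n_offsets >= 1)
  stopifnot(cfg$stats$endpoint %in% c("TTR", "CSS"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file (.yaml/.yml/.json); keys override defaults.
#' @return `pipeline_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "'"))
  do.call(pipeline_config, raw)
}

#' Write the fully-resolved configuration
#'
#' @param cfg `pipeline_config`.
#' @param path output path (.yaml or .json).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$segmentation$stain_vectors <-
    unname(apply(x$segmentation$stain_vectors, 1, as.numeric, simplify = FALSE))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
    stop("unsupported config format '.", ext, "'"))
  invisible(path)
}

.mf_config_from <- function(cfg) {
  do.call(mf_config, cfg$multifractal)
}

#' Run the per-case pipeline from any entry stage
#'
#' Accepts a section image (or image path), a binary tumor mask, or a
#' contour pair, and runs all remaining stages: segmentation, contour
#' extraction (both variants), multifractal spectra and the four metrics.
#' When `out_dir` is given, all artifacts are written: tumor mask PNG, the
#' two contour PNGs (`_outline`/`_internal` suffixes), one spectrum CSV per
#' variant, a one-row `metrics.csv`, and a JSON run log recording the
#' resolved config (with its MD5 hash) and seed.
#'
#' @param input `section_image`, image file path, `binary_mask`, or a list
#'   with elements `outline` and `internal` (`contour_image`s).
#' @param config `pipeline_config`.
#' @param out_dir optional artifact directory (created if missing).
#' @return list with `metrics` (one-row data.frame), `spectra` (list per
#'   variant), `mask`, `contours`.
#' @export
run_case <- function(input, config = pipeline_config(), out_dir = NULL) {
  config <- validate_config(config)
  mask <- NULL; contours <- NULL
  if (is.character(input)) input <- read_section_image(input)
  if (inherits(input, "section_image")) {
    seg <- config$segmentation
    mask <- segment_tumor(input, stain_vectors = seg$stain_vectors,
                          tissue_od_min = seg$tissue_od_min,
                          dab_threshold = seg$dab_threshold,
                          dab_od_min = seg$dab_od_min,
                          min_object_px = seg$min_object_px,
                          fill_small_holes_px = seg$fill_small_holes_px)
  } else if (inherits(input, "binary_mask")) {
    mask <- input
  } else if (is.list(input) && all(c("outline", "internal") %in% names(input))) {
    contours <- input
  } else {
    stop("run_case input must be a section image, an image path, a binary ",
         "mask, or a list(outline=, internal=) of contour images")
  }
  if (is.null(contours))
    contours <- extract_contours(
      mask, largest_component_only = config$contours$largest_component_only)
  mfc <- .mf_config_from(config)
  metrics <- compute_case_metrics(contours$outline, contours$internal, mfc)
  spectra <- list()
  for (v in c("outline", "internal")) {
    ci <- contours[[v]]
    spectra[[v]] <- if (ci$empty) NULL else mf_spectrum(ci, mfc)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cid <- contours$outline$case_id
    if (!is.null(mask))
      write_mask_image(mask, file.path(out_dir, paste0(cid, "_mask.png")))
    write_mask_image(contours$outline,
                     file.path(out_dir, paste0(cid, "_outline.png")))
    write_mask_image(contours$internal,
                     file.path(out_dir, paste0(cid, "_internal.png")))
    for (v in names(spectra)) {
      if (!is.null(spectra[[v]]))
        write.csv(as.data.frame(spectra[[v]]),
                  file.path(out_dir, sprintf("%s_spectrum_%s.csv", cid, v)),
                  row.names = FALSE)
    }
    write.csv(metrics, file.path(out_dir, paste0(cid, "_metrics.csv")),
              row.names = FALSE)
    cfg_path <- file.path(out_dir, paste0(cid, "_config.json"))
    write_config(config, cfg_path)
    log <- list(case_id = cid, seed = config$multifractal$seed,
                config_md5 = unname(tools::md5sum(cfg_path)),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                qc_flags = metrics$qc_flags)
    jsonlite::write_json(log, file.path(out_dir, paste0(cid, "_runlog.json")),
                         auto_unbox = TRUE)
  }
  list(metrics = metrics, spectra = spectra, mask = mask,
       contours = contours)
}

#' Run a batch of cases, continuing past per-case failures
#'
#' @param inputs named list (or vector of paths) of per-case inputs as
#'   accepted by [run_case()].
#' @param config `pipeline_config`.
#' @param out_dir optional artifact directory shared by the batch; the
#'   combined metrics table is written as `metrics.csv`.
#' @return list with `metrics` (data.frame, one row per successful case)
#'   and `failures` (named character vector of error messages).
#' @export
run_batch <- function(inputs, config = pipeline_config(), out_dir = NULL) {
  rows <- list(); failures <- character(0)
  for (i in seq_along(inputs)) {
    nm <- if (!is.null(names(inputs)) && nzchar(names(inputs)[i]))
      names(inputs)[i]
    else if (is.character(inputs[[i]])) basename(inputs[[i]])
    else sprintf("case_%d", i)
    res <- tryCatch(run_case(inputs[[i]], config, out_dir = out_dir),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
    } else {
      rows[[nm]] <- res$metrics
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0))
  rownames(metrics) <- NULL
  if (!is.null(out_dir) && nrow(metrics)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  }
  list(metrics = metrics, failures = failures)
}

#' Cohort-level biomarker evaluation report
#'
#' Joins per-case multifractal metrics to the clinical table by `case_id`
#' and emits the three standard analyses: (a) metric-by-covariate
#' comparisons (Mann-Whitney / Kruskal-Wallis for categorical covariates,
#' Spearman for continuous ones), (b) the prognostic analysis in the
#' surgery-alone arm (Kaplan-Meier + log-rank, univariate Cox on the
#' median-dichotomized marker, and a multivariate Cox with the standard
#' covariate set), and (c) the marker-by-treatment interaction test on the
#' full cohort.
#'
#' @param metrics data.frame with `case_id` and metric columns (from
#'   [run_batch()] or [compute_case_metrics()]).
#' @param cohort clinical data.frame with `case_id`, covariates and
#'   survival columns.
#' @param marker metric column evaluated as the biomarker.
#' @param endpoint `"TTR"` or `"CSS"`.
#' @param arm `"all"` or `"surgery-only"` for the prognostic analysis (b).
#' @param multivariate_covariates covariates added to the marker in the
#'   multivariate Cox model (only those present and non-constant are
#'   used).
#' @return object of class `cohort_report` with elements `associations`,
#'   `km`, `cox_univariate`, `cox_multivariate`, `interaction`,
#'   `marker`, `n_joined`.
#' @export
run_cohort <- function(metrics, cohort, marker = "f_alpha_max",
                       endpoint = c("TTR", "CSS"),
                       arm = c("surgery-only", "all"),
                       multivariate_covariates = c("stage", "sex",
                                                   "age_ge_66", "mmr",
                                                   "site", "tbc")) {
  endpoint <- match.arg(endpoint)
  arm <- match.arg(arm)
  stopifnot("case_id" %in% names(metrics), "case_id" %in% names(cohort))
  if (!marker %in% names(metrics))
    stop("marker column '", marker, "' not found in metrics table")
  d <- merge(cohort, metrics[, c("case_id", marker)], by = "case_id")
  if (nrow(d) < 4L)
    stop("metrics/cohort join yields fewer than 4 cases (", nrow(d), ")")
  mv <- d[[marker]]
  d$marker_group <- dichotomize_median(mv)
  if ("age_years" %in% names(d))
    d$age_ge_66 <- factor(ifelse(d$age_years >= 66, "ge66", "lt66"),
                          levels = c("lt66", "ge66"))

  cat_covs <- intersect(c("sex", "site", "mmr", "stage", "adjuvant",
                          "grade", "tbc"), names(d))
  num_covs <- intersect(c("age_years", "budding_count"), names(d))
  assoc <- do.call(rbind, c(
    lapply(cat_covs, function(cv) {
      res <- tryCatch(group_compare(mv, d[[cv]]), error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(covariate = cv, test = res$method, estimate = NA_real_,
                 p_value = res$p, stringsAsFactors = FALSE)
    }),
    lapply(num_covs, function(cv) {
      res <- tryCatch(spearman_corr(mv, d[[cv]]), error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(covariate = cv, test = "spearman", estimate = res$rho,
                 p_value = res$p, stringsAsFactors = FALSE)
    })))

  db <- if (arm == "surgery-only" && "adjuvant" %in% names(d))
    d[d$adjuvant == "no", ] else d
  sv <- .surv_cols(db, endpoint)
  km <- km_logrank(sv$time, sv$event, db$marker_group, endpoint)
  uni <- cox_model(db, endpoint, covariates = "marker_group")
  mcovs <- intersect(multivariate_covariates, names(db))
  mcovs <- mcovs[vapply(mcovs, function(cv)
    length(unique(db[[cv]][!is.na(db[[cv]])])) >= 2L, logical(1))]
  multi <- tryCatch(
    cox_model(db, endpoint, covariates = c("marker_group", mcovs)),
    error = function(e) e)
  inter <- if ("adjuvant" %in% names(d))
    tryCatch(interaction_test(d, d$marker_group, endpoint,
                              treatment_col = "adjuvant"),
             error = function(e) e)
  else NULL
  structure(list(associations = assoc, km = km, cox_univariate = uni,
                 cox_multivariate = multi, interaction = inter,
                 marker = marker, endpoint = endpoint, arm = arm,
                 n_joined = nrow(d)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> marker '%s', endpoint %s, %d joined cases\n",
              x$marker, x$endpoint, x$n_joined))
  cat("\n-- metric vs covariates --\n")
  a <- x$associations
  if (!is.null(a)) {
    a$p_value <- signif(a$p_value, 3)
    print(a, row.names = FALSE)
  }
  cat(sprintf("\n-- prognosis (%s arm), log-rank p = %.4g --\n",
              x$arm, x$km$p))
  print(x$cox_univariate)
  if (inherits(x$cox_multivariate, "survival_result")) {
    cat("\n-- multivariate --\n"); print(x$cox_multivariate)
  }
  if (inherits(x$interaction, "interaction_result")) {
    cat("\n-- treatment interaction --\n"); print(x$interaction)
  }
  invisible(x)
}
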