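# Cohort-level statistics for multifractal biomarkers: median
# dichotomization, nonparametric group comparisons, Kaplan-Meier/log-rank,
# Cox proportional hazards (uni- and multivariate, Efron ties) and the
# marker-by-treatment interaction test. Thin, validated wrappers over the
# survival package and stats; alpha = 0.05 two-sided throughout, no
# multiple-testing correction.

#' Median dichotomization into metric-high / metric-low
#'
#' Values at or below the median are labeled `"low"`, values above
#' `"high"` (ties at the median go to low, a deterministic convention);
#' missing values stay missing.
#'
#' @param values numeric vector.
#' @return factor with levels `c("low", "high")` and attribute
#'   `"median"`.
#' @export
dichotomize_median <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  med <- median(values[ok])
  if (all(values[ok] == values[ok][1]))
    stop("degenerate split: all values identical")
  lab <- ifelse(values > med, "high", "low")
  out <- factor(lab, levels = c("low", "high"))
  attr(out, "median") <- med
  out
}

#' Spearman rank correlation with two-tailed p
#'
#' Average ranks for ties; asymptotic two-tailed p (the tie-robust choice).
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant vector: correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE,
                    alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Nonparametric comparison of a metric across groups
#'
#' Two groups: Mann-Whitney U (two-sided, tie-corrected normal
#' approximation); three or more: Kruskal-Wallis.
#'
#' @param values numeric vector.
#' @param groups grouping vector (coerced to factor; missing pairs
#'   dropped).
#' @return list with `p`, `method`, `statistic`, `n`.
#' @export
group_compare <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  if (any(table(groups) < 1L)) stop("empty group")
  if (k == 2L) {
    tt <- suppressWarnings(
      stats::wilcox.test(values ~ groups, alternative = "two.sided"))
    list(p = tt$p.value, method = "mann-whitney",
         statistic = unname(tt$statistic), n = length(values))
  } else {
    tt <- stats::kruskal.test(values ~ groups)
    list(p = tt$p.value, method = "kruskal-wallis",
         statistic = unname(tt$statistic), n = length(values))
  }
}

.surv_cols <- function(cohort, endpoint = c("TTR", "CSS")) {
  endpoint <- match.arg(endpoint)
  cols <- if (endpoint == "TTR") c("ttr_months", "ttr_event")
          else c("css_months", "css_event")
  if (!all(cols %in% names(cohort)))
    stop("cohort table lacks columns ", paste(cols, collapse = ", "))
  list(time = cohort[[cols[1]]], event = cohort[[cols[2]]],
       endpoint = endpoint)
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' @param times event/censoring times (months).
#' @param events 0/1 event indicators.
#' @param group_labels grouping vector.
#' @param endpoint label carried into the result (`"TTR"` or `"CSS"`).
#' @return list with `fit` (a `survfit` object), `chisq`, `df`, `p`,
#'   `endpoint`.
#' @export
km_logrank <- function(times, events, group_labels, endpoint = "TTR") {
  stopifnot(length(times) == length(events),
            length(times) == length(group_labels))
  ok <- !is.na(times) & !is.na(events) & !is.na(group_labels)
  d <- data.frame(time = times[ok], event = events[ok],
                  group = droplevels(factor(group_labels[ok])))
  if (nlevels(d$group) < 2L) stop("log-rank needs >= 2 non-empty groups")
  if (any(d$time < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd$n) - 1L
  list(fit = fit, chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       endpoint = endpoint)
}

#' Cox proportional-hazards model on a cohort table
#'
#' Efron handling of ties; Wald 95 percent confidence intervals and p per
#' coefficient. Cases with missing values in any model column are dropped
#' listwise and the population actually used is reported.
#'
#' @param cohort data.frame with survival columns (`ttr_months`/`ttr_event`
#'   or `css_months`/`css_event`) and the covariates.
#' @param endpoint `"TTR"` or `"CSS"`.
#' @param covariates character vector of covariate column names.
#' @return object of class `survival_result`: data.frame `table`
#'   (term, hazard_ratio, ci95_lower, ci95_upper, p_value), `n_used`,
#'   `n_events`, `endpoint`, and the underlying `fit`.
#' @export
cox_model <- function(cohort, endpoint = c("TTR", "CSS"), covariates) {
  endpoint <- match.arg(endpoint)
  stopifnot(length(covariates) >= 1L,
            all(covariates %in% names(cohort)))
  sv <- .surv_cols(cohort, endpoint)
  d <- cohort[, covariates, drop = FALSE]
  d$.time <- sv$time; d$.event <- sv$event
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 4L) stop("fewer than 4 complete cases")
  if (sum(d$.event) < 1L) stop("no events in the modeling population")
  for (cv in covariates) {
    v <- d[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("constant covariate '", cv, "' in the modeling population")
    if (is.character(v)) d[[cv]] <- factor(v)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15))
    stop("Cox fit did not converge (possible separation); coefficients: ",
         paste(sprintf("%.2f", coef(fit)), collapse = ", "))
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
    ci95_lower = unname(s$conf.int[, "lower .95"]),
    ci95_upper = unname(s$conf.int[, "upper .95"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  structure(list(table = tab, n_used = nrow(d), n_events = sum(d$.event),
                 endpoint = endpoint, fit = fit),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("<survival_result> %s: n = %d, events = %d\n",
              x$endpoint, x$n_used, x$n_events))
  tab <- x$table
  tab[, 2:5] <- lapply(tab[, 2:5], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Marker-by-treatment interaction test (Cox model with product term)
#'
#' Fits `Surv ~ marker + treatment + marker:treatment` and reports the Wald
#' p-value of the product term (a likelihood-ratio p is included as a
#' secondary diagnostic), together with the treatment hazard ratio within
#' each marker stratum. A significant product term indicates
#' treatment-response prediction rather than pure prognosis.
#'
#' @param cohort data.frame with survival columns and a treatment column.
#' @param marker_labels per-case factor/vector with levels low/high (or
#'   0/1), aligned with `cohort` rows.
#' @param endpoint `"TTR"` or `"CSS"`.
#' @param treatment_col name of the treatment column (values yes/no or
#'   1/0).
#' @return object of class `interaction_result`: `coefficient` (product
#'   term log-HR), `p_value` (Wald), `p_value_lr`, `stratum_hr`
#'   (data.frame of treatment HRs within marker-low and marker-high),
#'   `n_used`, `endpoint`.
#' @export
interaction_test <- function(cohort, marker_labels,
                             endpoint = c("TTR", "CSS"),
                             treatment_col = "adjuvant") {
  endpoint <- match.arg(endpoint)
  stopifnot(treatment_col %in% names(cohort),
            length(marker_labels) == nrow(cohort))
  sv <- .surv_cols(cohort, endpoint)
  trt <- cohort[[treatment_col]]
  if (!is.numeric(trt)) trt <- as.integer(trt %in% c("yes", "1", "TRUE"))
  mk <- marker_labels
  if (!is.numeric(mk)) mk <- as.integer(as.character(mk) %in% c("high", "1"))
  d <- data.frame(time = sv$time, event = sv$event, marker = mk, trt = trt)
  d <- d[stats::complete.cases(d), ]
  cells <- table(factor(d$marker, levels = 0:1),
                 factor(d$trt, levels = 0:1))
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty marker x treatment cell: marker-%s / treatment-%s",
                 c("low", "high")[empty[1]], c("no", "yes")[empty[2]]))
  }
  fit <- survival::coxph(
    survival::Surv(time, event) ~ marker * trt, data = d, ties = "efron")
  fit0 <- survival::coxph(
    survival::Surv(time, event) ~ marker + trt, data = d, ties = "efron")
  s <- summary(fit)
  ix <- grep(":", rownames(s$coefficients))
  p_lr <- stats::pchisq(2 * (fit$loglik[2] - fit0$loglik[2]), df = 1,
                        lower.tail = FALSE)
  stratum <- do.call(rbind, lapply(c(0L, 1L), function(g) {
    sub <- d[d$marker == g, ]
    f <- survival::coxph(survival::Surv(time, event) ~ trt, data = sub,
                         ties = "efron")
    ss <- summary(f)
    data.frame(stratum = c("marker-low", "marker-high")[g + 1L],
               treatment_hr = unname(ss$coefficients[1, "exp(coef)"]),
               ci95_lower = unname(ss$conf.int[1, "lower .95"]),
               ci95_upper = unname(ss$conf.int[1, "upper .95"]),
               p_value = unname(ss$coefficients[1, "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  }))
  structure(list(coefficient = unname(coef(fit)[ix]),
                 p_value = unname(s$coefficients[ix, "Pr(>|z|)"]),
                 p_value_lr = p_lr,
                 stratum_hr = stratum,
                 n_used = nrow(d), endpoint = endpoint, fit = fit),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(
    "<interaction_result> %s: product-term coef %.3f (Wald p = %.4g, LR p = %.4g), n = %d\n",
    x$endpoint, x$coefficient, x$p_value, x$p_value_lr, x$n_used))
  tab <- x$stratum_hr
  tab[, 2:5] <- lapply(tab[, 2:5], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
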