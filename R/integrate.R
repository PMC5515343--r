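#' Integrate per-platform calls into a per-patient any-defect flag
#'
#' A DNA defect is annotated when the exome burden is moderate or high,
#' OR the methylation category is occult_tumor, OR the copy-number
#' category is evidence_of_tumor (triplets) / likely_evidence (pairs).
#' Field effects, small copy-number evidence, low burden, and RNA
#' mutation positivity do not trigger the flag. Missing platforms (NA) do
#' not contribute; a patient with no platform at all gets `any_defect =
#' NA` and is excluded downstream (count reported via message).
#'
#' @param patient_id character vector.
#' @param methylation_category values in occult_tumor / field_effect /
#'   normal (NA = platform missing).
#' @param cn_category values in evidence_of_tumor / small_evidence /
#'   likely_evidence / normal.
#' @param exome_category values in high / moderate / low / none.
#' @param rna_positive logical (recorded, never contributes).
#' @return a `defect_profile` data.frame with per-platform columns,
#'   `n_platforms`, and `any_defect`.
#' @export
integrate_defects <- function(patient_id, methylation_category = NA,
                              cn_category = NA, exome_category = NA,
                              rna_positive = NA) {
  n <- length(patient_id)
  rec <- function(x) rep_len(x, n)
  meth <- rec(as.character(methylation_category))
  cn <- rec(as.character(cn_category))
  ex <- rec(as.character(exome_category))
  chk <- function(x, levels, what) {
    bad <- setdiff(stats::na.omit(unique(x)), levels)
    if (length(bad)) fs_stopf("invalid %s value(s): %s", what,
                              paste(bad, collapse = ", "))
  }
  chk(meth, c("occult_tumor", "field_effect", "normal"), "methylation")
  chk(cn, c("evidence_of_tumor", "small_evidence", "likely_evidence",
            "normal"), "cn")
  chk(ex, c("high", "moderate", "low", "none"), "exome")
  hit <- cbind(meth = meth == "occult_tumor",
               cn = cn %in% c("evidence_of_tumor", "likely_evidence") &
                 !is.na(cn),
               exome = ex %in% c("moderate", "high") & !is.na(ex))
  hit[, "cn"][is.na(cn)] <- NA
  hit[, "exome"][is.na(ex)] <- NA
  n_platforms <- rowSums(!is.na(cbind(meth, cn, ex)))
  any_defect <- apply(hit, 1, function(h)
    if (all(is.na(h))) NA else any(h, na.rm = TRUE))
  if (any(n_platforms == 0))
    message(sprintf("integrate_defects: %d patient(s) with no platform excluded",
                    sum(n_platforms == 0)))
  out <- data.frame(patient_id = patient_id,
                    methylation_category = meth, cn_category = cn,
                    exome_category = ex,
                    rna_mutation_positive = rec(as.logical(rna_positive)),
                    n_platforms = n_platforms, any_defect = any_defect,
                    stringsAsFactors = FALSE)
  class(out) <- c("defect_profile", "data.frame")
  out
}

censor_records <- function(records, censor_at) {
  over <- records$time_years > censor_at
  records$event[over] <- FALSE
  records$time_years[over] <- censor_at
  records
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group after administrative
#' censoring at `censor_at` years (events beyond that time become
#' censored observations at the cut), with the two-group (or k-group)
#' log-rank chi-square.
#'
#' @param records a `clinical_table` data.frame (needs `time_years`,
#'   `event`).
#' @param groups per-patient group labels.
#' @param censor_at censoring horizon in years (default 10; `Inf`
#'   disables).
#' @return a `km_result`: list with `curves` (data.frame: group, time,
#'   n_risk, n_event, survival), `logrank_chisq`, `logrank_p`, `n`,
#'   `censor_at`.
#' @export
km_fit <- function(records, groups, censor_at = 10) {
  stopifnot(length(groups) == nrow(records))
  groups <- as.character(groups)
  if (any(table(groups) == 0) || any(is.na(groups)))
    fs_stopf("empty or missing group label")
  rec <- censor_records(records, censor_at)
  if (!any(rec$event)) fs_stopf("no events before the censoring horizon")
  sf <- survival::survfit(survival::Surv(time_years, event) ~ group,
                          data = data.frame(time_years = rec$time_years,
                                            event = rec$event,
                                            group = groups))
  strata_lab <- if (is.null(sf$strata)) unique(groups)
  else sub("^group=", "", names(sf$strata))
  grp <- if (is.null(sf$strata)) rep(strata_lab, length(sf$time))
  else rep(strata_lab, sf$strata)
  curves <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, survival = sf$surv,
                       stringsAsFactors = FALSE)
  lr_chisq <- NA_real_; lr_p <- NA_real_
  if (length(unique(groups)) > 1) {
    sd <- survival::survdiff(survival::Surv(rec$time_years, rec$event) ~ groups)
    lr_chisq <- sd$chisq
    lr_p <- stats::pchisq(sd$chisq, df = length(unique(groups)) - 1,
                          lower.tail = FALSE)
  }
  out <- list(curves = curves, logrank_chisq = lr_chisq, logrank_p = lr_p,
              n = nrow(rec), censor_at = censor_at)
  class(out) <- "km_result"
  out
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result: %d subjects, censored at %s y, log-rank p = %s>\n",
              x$n, format(x$censor_at),
              if (is.na(x$logrank_p)) "NA" else format.pval(x$logrank_p)))
  invisible(x)
}

#' @export
plot.km_result <- function(x, ...) {
  groups <- unique(x$curves$group)
  graphics::plot(NA, xlim = c(0, max(x$curves$time)), ylim = c(0, 1),
                 xlab = "Years", ylab = "Overall survival", ...)
  for (i in seq_along(groups)) {
    cv <- x$curves[x$curves$group == groups[i], ]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$survival)), col = i,
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = groups, col = seq_along(groups),
                   lty = 1, bty = "n")
  invisible(x)
}

cox_reference_levels <- c(subtype = "inactive", node_status = "negative",
                          tumor_subtype = "LumA", stage = "I",
                          t_size = "T1", age_decade = "<40")

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood fit of overall survival on the requested
#' covariates, after administrative censoring. Categorical covariates are
#' expanded against fixed reference levels (inactive subtype,
#' node-negative, LumA, stage I, T1, age <40, no defect). Patients with a
#' missing covariate are complete-case excluded (count reported);
#' the fit errors when events are fewer than estimated parameters.
#'
#' @param records `clinical_table` data.frame, possibly augmented with
#'   `subtype` and `any_defect` columns.
#' @param covariates character vector drawn from subtype, node_status,
#'   tumor_subtype, stage, t_size, age_decade, any_defect.
#' @param er_filter restrict to ER-positive patients.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param censor_at censoring horizon in years (default 10).
#' @return a `cox_result`: list with `terms` (data.frame: term,
#'   hazard_ratio, ci_low, ci_high, p), `n`, `n_events`, `n_excluded`,
#'   and the underlying `survival::coxph` fit.
#' @export
cox_fit <- function(records,
                    covariates = c("subtype", "node_status", "tumor_subtype",
                                   "stage", "t_size", "age_decade",
                                   "any_defect"),
                    er_filter = FALSE, ties = c("efron", "breslow"),
                    censor_at = 10) {
  ties <- match.arg(ties)
  rec <- as.data.frame(records)
  missing_cov <- setdiff(covariates, names(rec))
  if (length(missing_cov))
    fs_stopf("missing covariate column(s): %s",
             paste(missing_cov, collapse = ", "))
  if (er_filter) rec <- rec[!is.na(rec$er_status) &
                              rec$er_status == "positive", , drop = FALSE]
  cc <- stats::complete.cases(rec[, c("time_years", "event", covariates)])
  if (any(!cc))
    message(sprintf("cox_fit: %d patient(s) complete-case excluded", sum(!cc)))
  rec <- rec[cc, , drop = FALSE]
  rec <- censor_records(rec, censor_at)
  for (v in intersect(covariates, names(cox_reference_levels))) {
    lv <- unique(as.character(rec[[v]]))
    ref <- cox_reference_levels[[v]]
    rec[[v]] <- factor(as.character(rec[[v]]),
                       levels = c(ref, sort(setdiff(lv, ref))))
    rec[[v]] <- droplevels(rec[[v]])
  }
  if ("any_defect" %in% covariates)
    rec$any_defect <- factor(as.character(rec$any_defect),
                             levels = c("FALSE", "TRUE"))
  constant <- vapply(covariates, function(v) {
    x <- rec[[v]]
    length(unique(if (is.factor(x)) droplevels(x) else x)) < 2
  }, logical(1))
  if (any(constant)) {
    message(sprintf("cox_fit: dropping constant covariate(s): %s",
                    paste(covariates[constant], collapse = ", ")))
    covariates <- covariates[!constant]
    if (!length(covariates)) fs_stopf("no non-constant covariates left")
  }
  for (v in covariates) if (is.factor(rec[[v]])) rec[[v]] <- droplevels(rec[[v]])
  n_par <- sum(vapply(covariates, function(v)
    if (is.factor(rec[[v]])) max(1L, nlevels(rec[[v]]) - 1L) else 1L,
    integer(1)))
  n_events <- sum(rec$event)
  if (n_events == 0) fs_stopf("no events; cannot fit")
  if (n_events < n_par)
    fs_stopf(paste0("only %d events for %d parameters; drop covariates ",
                    "or pool levels"), n_events, n_par)
  fml <- stats::as.formula(paste("survival::Surv(time_years, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = rec, ties = ties)
  if (any(!is.finite(fit$coefficients)))
    fs_stopf("Cox fit failed to converge (%d iterations)", fit$iter)
  s <- summary(fit)
  terms <- data.frame(term = rownames(s$coefficients),
                      hazard_ratio = s$conf.int[, "exp(coef)"],
                      ci_low = s$conf.int[, "lower .95"],
                      ci_high = s$conf.int[, "upper .95"],
                      p = s$coefficients[, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  out <- list(terms = terms, n = nrow(rec), n_events = n_events,
              n_excluded = sum(!cc), fit = fit, ties = ties,
              covariates = covariates)
  class(out) <- "cox_result"
  out
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result: %d subjects, %d events, ties=%s>\n",
              x$n, x$n_events, x$ties))
  print(transform(x$terms,
                  hazard_ratio = signif(hazard_ratio, 3),
                  ci_low = signif(ci_low, 3), ci_high = signif(ci_high, 3),
                  p = signif(p, 2)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.cox_result <- function(object, ...) summary(object$fit, ...)

#' Sensitivity analysis excluding late-stage patients
#'
#' Refits the Cox model after removing patients whose raw stage is in
#' `exclude` (default stage IV, identified from `stage_raw` when present,
#' otherwise from the collapsed `stage` factor) and reports both fits.
#'
#' @param records as for [cox_fit()].
#' @param exclude raw stage values to drop (default `"IV"`).
#' @param ... passed to [cox_fit()].
#' @return list with `primary` and `filtered` `cox_result`s and
#'   `n_removed`.
#' @export
sensitivity_exclude_stage <- function(records, exclude = "IV", ...) {
  rec <- as.data.frame(records)
  raw <- if ("stage_raw" %in% names(rec)) as.character(rec$stage_raw)
  else as.character(rec$stage)
  drop <- !is.na(raw) & raw %in% exclude
  primary <- cox_fit(records, ...)
  filtered <- if (any(drop)) cox_fit(rec[!drop, , drop = FALSE], ...)
  else primary
  list(primary = primary, filtered = filtered, n_removed = sum(drop))
}

#' Association battery between expression subtype and clinical features
#'
#' For each categorical covariate, a chi-square test when all expected
#' cell counts reach 5, otherwise Fisher's exact test (2x2 tables; larger
#' sparse tables fall back to simulation-free chi-square with a
#' warning); patient age uses a pooled-variance two-sided t-test on
#' decade midpoints (or an `age_years` column when present). The test
#' used is reported per row.
#'
#' @param records `clinical_table` data.frame (optionally with
#'   `any_defect`).
#' @param subtype per-patient active/inactive labels.
#' @return data.frame: variable, test, statistic, p_value, n.
#' @export
association_tests <- function(records, subtype) {
  rec <- as.data.frame(records)
  stopifnot(length(subtype) == nrow(rec))
  subtype <- factor(subtype)
  vars <- intersect(c("node_status", "tumor_subtype", "stage", "t_size",
                      "any_defect"), names(rec))
  rows <- lapply(vars, function(v) {
    x <- factor(as.character(rec[[v]]))
    keep <- !is.na(x) & !is.na(subtype)
    tab <- table(subtype[keep], droplevels(x[keep]))
    if (min(dim(tab)) < 2)
      return(data.frame(variable = v, test = "none", statistic = NA_real_,
                        p_value = NA_real_, n = sum(keep)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= 5)) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, test = "chi-square",
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 n = sum(keep))
    } else if (all(dim(tab) == 2)) {
      ft <- stats::fisher.test(tab)
      data.frame(variable = v, test = "fisher", statistic = NA_real_,
                 p_value = ft$p.value, n = sum(keep))
    } else {
      fs_warnf("sparse %s table larger than 2x2; chi-square approximate", v)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, test = "chi-square (sparse)",
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 n = sum(keep))
    }
  })
  age <- if ("age_years" %in% names(rec)) rec$age_years
  else c(35, 45, 55, 65, 75)[as.integer(rec$age_decade)]
  keep <- !is.na(age) & !is.na(subtype)
  age_row <- tryCatch({
    tt <- stats::t.test(age[keep] ~ subtype[keep], var.equal = TRUE)
    data.frame(variable = "age", test = "pooled t-test",
               statistic = unname(tt$statistic), p_value = tt$p.value,
               n = sum(keep))
  }, error = function(e)
    data.frame(variable = "age", test = "pooled t-test (degenerate)",
               statistic = NA_real_, p_value = NA_real_, n = sum(keep)))
  rows <- c(rows, list(age_row))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
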