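# Cohort-level association between coupling strength and apnoea rate: a
# linear mixed-effects model with fixed effects PAC, data length, ventilation
# mode and postmenstrual age, and a random intercept per infant. Reported per
# the study design: the PAC slope's t statistic on residual degrees of
# freedom, its two-sided p, and the partial correlation rho = t/sqrt(t^2+dof).

VENT_LEVELS <- c("self-ventilating", "low-flow", "high-flow")

#' Partial correlation from a t statistic
#'
#' @param t t statistic of a regression slope.
#' @param dof residual degrees of freedom.
#' @return `t / sqrt(t^2 + dof)`.
#' @examples
#' partial_corr_from_t(-2.37, 98)  # -0.23
#' @export
partial_corr_from_t <- function(t, dof) t / sqrt(t^2 + dof)

#' Build the per-recording cohort table
#'
#' One row per recording: coupling (mean coherence over the
#' statistically significant delta+theta cells of channels FCz and Cz,
#' pooled), apnoea rate per hour, data length, ventilation mode, PMA and
#' infant id. Recordings whose mask leaves no cell are excluded with a
#' message.
#'
#' @param results named list (by recording id) of [pac_spectrum()] results.
#' @param mask a group-level [fdr_mask()] (or logical array matching the
#'   grids).
#' @param records named list of classified [breath_record()]s.
#' @param metas named list of [recording_meta()]s.
#' @param bands bands pooled for the PAC summary (default delta + theta).
#' @param channels channels pooled (default FCz and Cz).
#' @return a `data.frame` cohort table (see [gen_cohort()] for the columns).
#' @export
build_cohort <- function(results, mask, records, metas,
                         bands = list(delta = c(0.5, 4), theta = c(4, 8)),
                         channels = c("FCz", "Cz")) {
  ids <- names(results)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("`results` must be a named list with unique recording ids")
  }
  if (inherits(mask, "significance_mask")) mask <- mask$mask
  rows <- lapply(ids, function(id) {
    res <- results[[id]]
    meta <- metas[[id]]
    rec <- records[[id]]
    pooled <- range(unlist(bands))
    ba <- band_average(res, list(pooled = pooled), mask = mask,
                       channels = intersect(channels, res$channels))
    pac <- mean(ba, na.rm = TRUE)
    if (!is.finite(pac)) {
      message("recording ", id, ": empty significance mask, excluded")
      return(NULL)
    }
    data.frame(
      recording_id = id, infant_id = meta$infant_id, pac = pac,
      apnoea_rate = apnoea_rate(rec, meta$vitals_hours),
      data_length_hours = min(rec$analysed_hours, meta$vitals_hours),
      ventilation_mode = meta$ventilation_mode, pma_weeks = meta$pma_weeks,
      caffeine = meta$caffeine, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Fit the coupling-apnoea linear mixed-effects model
#'
#' `apnoea_rate ~ pac + data_length_hours + ventilation_mode + pma_weeks +
#' (1 | infant_id)`, with self-ventilating as the reference ventilation
#' level. The PAC slope is reported with its t statistic on residual degrees
#' of freedom (`n_rows - n_fixed_parameters`), two-sided p, and partial
#' correlation. A singular random-effect fit falls back to ordinary least
#' squares with a flag; so does a cohort with fewer than 2 repeatedly
#' measured infants.
#'
#' @param table a cohort `data.frame` ([build_cohort()] or [gen_cohort()]).
#' @param min_rows minimum rows required.
#' @return an object of class `lmm_result`: `slope`, `se`, `t_statistic`,
#'   `dof`, `p_value`, `partial_correlation`, `ci` (95% Wald), `covariates`
#'   (fixed-effect table), `n_rows`, `n_infants`, `random_effect_used`,
#'   `model`.
#' @export
fit_lmm <- function(table, min_rows = 20) {
  need <- c("pac", "apnoea_rate", "data_length_hours", "ventilation_mode",
            "pma_weeks", "infant_id")
  if (!all(need %in% names(table))) {
    stop("cohort table lacks columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  }
  table <- table[stats::complete.cases(table[, need]), ]
  if (nrow(table) < min_rows) stop("need at least ", min_rows, " rows")
  table$ventilation_mode <- factor(table$ventilation_mode,
                                   levels = VENT_LEVELS)
  table$ventilation_mode <- droplevels(table$ventilation_mode)

  repeats <- sum(table(table$infant_id) > 1)
  use_re <- repeats >= 2
  fit <- NULL
  if (use_re) {
    fit <- suppressMessages(lme4::lmer(
      apnoea_rate ~ pac + data_length_hours + ventilation_mode + pma_weeks +
        (1 | infant_id),
      data = table, REML = TRUE
    ))
    if (lme4::isSingular(fit, tol = 1e-5)) use_re <- FALSE
  } else {
    warning("fewer than 2 infants with repeated recordings; ",
            "fitting fixed effects only")
  }
  if (!use_re) {
    fit <- stats::lm(
      apnoea_rate ~ pac + data_length_hours + ventilation_mode + pma_weeks,
      data = table
    )
  }
  co <- if (use_re) summary(fit)$coefficients else summary(fit)$coefficients
  est <- co["pac", "Estimate"]
  se <- co["pac", "Std. Error"]
  dof <- nrow(table) - nrow(co)
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df = dof)
  rho <- partial_corr_from_t(tval, dof)
  ci <- est + c(-1, 1) * stats::qt(0.975, dof) * se
  # normality check: residual quantiles against the theoretical normal ones
  r <- sort(as.numeric(stats::residuals(fit)))
  qq <- data.frame(
    theoretical = stats::qnorm(stats::ppoints(length(r))) * stats::sd(r),
    sample = r
  )
  structure(
    list(slope = est, se = se, t_statistic = tval, dof = dof, p_value = p,
         partial_correlation = rho, ci = ci,
         covariates = co[, c("Estimate", "Std. Error"), drop = FALSE],
         n_rows = nrow(table), n_infants = length(unique(table$infant_id)),
         random_effect_used = use_re, qq = qq, model = fit),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf(
    "<lmm_result> PAC slope %.3f (SE %.3f), t(%d) = %.2f, p = %.3g, rho = %.2f\n",
    x$slope, x$se, x$dof, x$t_statistic, x$p_value, x$partial_correlation
  ))
  cat(sprintf("  %d recordings, %d infants, random intercept %s\n",
              x$n_rows, x$n_infants,
              if (x$random_effect_used) "by infant" else "not used (fallback)"))
  invisible(x)
}

#' Covariate-adjusted response for visualisation
#'
#' Adjusts the apnoea rate for the non-PAC fixed effects by refitting the
#' model without the random effect: each adjusted response is the fitted
#' value with all covariates held at their means plus the residual, so the
#' adjusted scatter shows the partial PAC relationship. A best-fit line on
#' the adjusted data is returned.
#'
#' @param table the cohort table used for the fit.
#' @param result the [fit_lmm()] result (used for column checking only; the
#'   adjustment model is refit without the random effect, matching the
#'   visualisation procedure).
#' @return a list: `data` (data.frame `recording_id`, `pac`,
#'   `adjusted_apnoea_rate`), `line` (`intercept`, `slope`).
#' @export
adjusted_response <- function(table, result) {
  stopifnot(inherits(result, "lmm_result"))
  table <- table[stats::complete.cases(
    table[, c("pac", "apnoea_rate", "data_length_hours", "ventilation_mode",
              "pma_weeks")]
  ), ]
  table$ventilation_mode <- factor(table$ventilation_mode,
                                   levels = VENT_LEVELS)
  table$ventilation_mode <- droplevels(table$ventilation_mode)
  fit <- stats::lm(
    apnoea_rate ~ pac + data_length_hours + ventilation_mode + pma_weeks,
    data = table
  )
  newd <- table
  newd$data_length_hours <- mean(table$data_length_hours)
  newd$pma_weeks <- mean(table$pma_weeks)
  # hold the categorical covariate at its reference level
  newd$ventilation_mode <- factor(levels(table$ventilation_mode)[1],
                                  levels = levels(table$ventilation_mode))
  adj <- stats::predict(fit, newdata = newd) + stats::residuals(fit)
  line <- stats::lm(adj ~ table$pac)
  list(
    data = data.frame(recording_id = table$recording_id, pac = table$pac,
                      adjusted_apnoea_rate = as.numeric(adj)),
    line = c(intercept = unname(stats::coef(line)[1]),
             slope = unname(stats::coef(line)[2]))
  )
}
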