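#' Kaplan-Meier curve of time to treatment discontinuation
#'
#' Product-limit estimator over the episode table, optionally stratified by
#' index drug. Steps occur only at event (discontinuation) times;
#' right-censored episodes leave the risk set without a step; `S(0) = 1`.
#'
#' @param episodes Episodes data.frame (`time_to_discontinuation`, `event`,
#'   optionally `index_drug`).
#' @param by_drug Stratify by `index_drug`?
#' @return Data.frame with columns `index_drug` (if stratified), `day`,
#'   `survival`, `n_risk`, `n_event`, including the `day = 0` row.
#' @export
km_curve <- function(episodes, by_drug = FALSE) {
  if (!nrow(episodes)) stop("no episodes", call. = FALSE)
  one <- function(df, label) {
    fit <- survival::survfit(
      survival::Surv(df$time_to_discontinuation, df$event) ~ 1)
    out <- data.frame(day = c(0, fit$time),
                      survival = c(1, fit$surv),
                      n_risk = c(fit$n, fit$n.risk),
                      n_event = c(0, fit$n.event))
    if (!is.null(label)) out <- cbind(index_drug = label, out)
    out
  }
  if (!by_drug) return(one(episodes, NULL))
  parts <- lapply(split(episodes, episodes$index_drug),
                  function(df) one(df, df$index_drug[1]))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Covariate vectors for the comparative models
#'
#' Builds the adjustment set used by [cox_hr()] and [restart_logit()]:
#' gender, standardized drug strength at initiation, and co-medication use.
#' Strength at initiation is the start dose from [dose_summary()] divided by
#' the modal start dose of the same drug, making it dimensionless and
#' comparable across products (raw mg are not). Episodes excluded from the
#' dose analysis (single purchase) fall back to the strength of their only
#' purchase. The co-medication flag is month-1 combination status from
#' [comed_status()].
#'
#' @param episodes Episodes data.frame from [build_episodes()].
#' @param patients Patient table with `patient_id`, `gender`.
#' @param doses Output of [dose_table()] (columns `patient_id`,
#'   `start_dose_mg`).
#' @param comed Output of [comed_table()] (columns `patient_id`, `month1`).
#' @return Data.frame `patient_id`, `gender`, `start_strength_std`,
#'   `comed_flag` with no missing values.
#' @export
build_covariates <- function(episodes, patients, doses, comed) {
  cv <- data.frame(patient_id = episodes$patient_id,
                   index_drug = episodes$index_drug,
                   stringsAsFactors = FALSE)
  g <- patients$gender[match(cv$patient_id, patients$patient_id)]
  g[is.na(g)] <- "unknown"
  cv$gender <- factor(g, levels = c("M", "F", "unknown"))
  start <- doses$start_dose_mg[match(cv$patient_id, doses$patient_id)]
  fallback <- doses$fallback_start_mg[match(cv$patient_id, doses$patient_id)]
  start[is.na(start)] <- fallback[is.na(start)]
  modal <- tapply(start, cv$index_drug, function(x) {
    ux <- sort(unique(x))
    ux[which.max(tabulate(match(x, ux)))]
  })
  cv$start_strength_std <- start / as.numeric(modal[cv$index_drug])
  cm <- comed$month1[match(cv$patient_id, comed$patient_id)]
  cv$comed_flag <- !is.na(cm) & cm == "combined"
  cv
}

#' Cox proportional-hazards comparison of drug cohorts
#'
#' Fits a Cox partial-likelihood model of time to discontinuation on index-
#' drug indicators (reference drug omitted) plus the configured covariates,
#' with the Efron approximation for tied event times (day-granular dispensing
#' data tie heavily). Hazard ratios use two-sided Wald confidence intervals at
#' level `1 - alpha`.
#'
#' @param episodes Episodes data.frame.
#' @param covariates Data.frame from [build_covariates()], or `NULL` for an
#'   unadjusted fit.
#' @param reference_drug Drug whose hazard is the denominator (HR = 1).
#' @param alpha Two-sided test level (default 0.05).
#' @return Object of class `hazard_result`: data.frame `term`, `hr`, `lo`,
#'   `hi`, `p`, with attributes `reference`, `n`, `n_event`, `converged`.
#' @export
cox_hr <- function(episodes, covariates = NULL, reference_drug,
                   alpha = 0.05) {
  drugs <- unique(episodes$index_drug)
  if (length(drugs) < 2) stop("need at least two drug cohorts", call. = FALSE)
  if (!reference_drug %in% drugs) {
    stop("reference drug absent from the episodes", call. = FALSE)
  }
  if (!any(episodes$event == 1L)) stop("no events", call. = FALSE)
  df <- data.frame(
    time = episodes$time_to_discontinuation,
    event = episodes$event,
    drug = stats::relevel(factor(episodes$index_drug), ref = reference_drug)
  )
  form <- time_event_formula("drug")
  if (!is.null(covariates)) {
    m <- match(episodes$patient_id, covariates$patient_id)
    df$gender <- droplevels(covariates$gender[m])
    df$start_strength_std <- covariates$start_strength_std[m]
    df$comed_flag <- covariates$comed_flag[m]
    terms <- c("drug",
               if (nlevels(df$gender) > 1) "gender",
               if (stats::var(df$start_strength_std) > 0) "start_strength_std",
               if (length(unique(df$comed_flag)) > 1) "comed_flag")
    form <- time_event_formula(terms)
  }
  fit <- survival::coxph(form, data = df, ties = "efron")
  converged <- is.null(fit$info) && all(is.finite(stats::coef(fit))) &&
    all(abs(stats::coef(fit)) < 10)
  if (!converged) {
    warning("Cox fit did not converge cleanly (possible separation or no ",
            "events in a stratum); inspect coefficients", call. = FALSE)
  }
  s <- summary(fit, conf.int = 1 - alpha)
  keep <- startsWith(rownames(s$coefficients), "drug")
  z <- stats::qnorm(1 - alpha / 2)
  co <- s$coefficients[keep, , drop = FALSE]
  res <- data.frame(
    term = sub("^drug", "", rownames(co)),
    hr = exp(co[, "coef"]),
    lo = exp(co[, "coef"] - z * co[, "se(coef)"]),
    hi = exp(co[, "coef"] + z * co[, "se(coef)"]),
    p = co[, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(res, class = c("hazard_result", "data.frame"),
            reference = reference_drug, n = fit$n, n_event = fit$nevent,
            converged = converged)
}

time_event_formula <- function(terms) {
  stats::as.formula(paste("survival::Surv(time, event) ~",
                          paste(terms, collapse = " + ")))
}

#' Logistic model of restarting after discontinuation
#'
#' Maximum-likelihood logistic regression of the restart indicator (index-drug
#' repurchase within three months of discontinuation) on drug indicators plus
#' the same covariates as [cox_hr()], restricted to sequel-eligible
#' discontinuers. Odds ratios carry two-sided Wald confidence intervals.
#' Quasi-separation (fitted probabilities at 0/1 or runaway coefficients) is
#' flagged with a warning, never silently returned.
#'
#' @param sequels Output of [classify_sequel()] joined to episodes: needs
#'   `patient_id`, `eligible`, `sequel_class`, `index_drug`.
#' @param covariates Data.frame from [build_covariates()], or `NULL`.
#' @param reference_drug Reference cohort (OR = 1).
#' @param alpha Two-sided level.
#' @return Object of class `odds_result`: data.frame `term`, `or`, `lo`,
#'   `hi`, `p` with attributes `reference`, `n`, `converged`.
#' @export
restart_logit <- function(sequels, covariates = NULL, reference_drug,
                          alpha = 0.05) {
  el <- sequels[sequels$eligible, , drop = FALSE]
  if (!nrow(el)) stop("no sequel-eligible discontinuers", call. = FALSE)
  df <- data.frame(
    restart = as.integer(el$sequel_class == "restart"),
    drug = stats::relevel(factor(el$index_drug), ref = reference_drug)
  )
  terms <- "drug"
  if (!is.null(covariates)) {
    m <- match(el$patient_id, covariates$patient_id)
    df$gender <- droplevels(covariates$gender[m])
    df$start_strength_std <- covariates$start_strength_std[m]
    df$comed_flag <- covariates$comed_flag[m]
    terms <- c("drug",
               if (nlevels(df$gender) > 1) "gender",
               if (stats::var(df$start_strength_std) > 0) "start_strength_std",
               if (length(unique(df$comed_flag)) > 1) "comed_flag")
  }
  form <- stats::as.formula(paste("restart ~", paste(terms, collapse = " + ")))
  fit <- stats::glm(form, data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  eps <- 1e-8
  sep <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    any(abs(stats::coef(fit)[-1]) > 10)
  if (sep) {
    warning("possible (quasi-)separation in the restart model: fitted ",
            "probabilities at 0/1 or runaway coefficients", call. = FALSE)
  }
  co <- summary(fit)$coefficients
  keep <- startsWith(rownames(co), "drug")
  z <- stats::qnorm(1 - alpha / 2)
  res <- data.frame(
    term = sub("^drug", "", rownames(co)[keep]),
    or = exp(co[keep, "Estimate"]),
    lo = exp(co[keep, "Estimate"] - z * co[keep, "Std. Error"]),
    hi = exp(co[keep, "Estimate"] + z * co[keep, "Std. Error"]),
    p = co[keep, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(res, class = c("odds_result", "data.frame"),
            reference = reference_drug, n = nrow(df), converged = !sep)
}

#' @export
print.hazard_result <- function(x, ...) {
  cat("Cox PH hazard ratios vs", attr(x, "reference"),
      sprintf("(n = %d, events = %d)\n", attr(x, "n"), attr(x, "n_event")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
print.odds_result <- function(x, ...) {
  cat("Restart odds ratios vs", attr(x, "reference"),
      sprintf("(n = %d)\n", attr(x, "n")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
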