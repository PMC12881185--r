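# Survival validation of the signature: Kaplan-Meier curves, log-rank
# comparison of high vs low groups, Cox proportional-hazards fits with
# Efron tie handling, and the global Schoenfeld residual test.

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @return list of class "KMCurve": time, nRisk, nEvent, nCensor, surv,
#'   median (NA when the curve never crosses 0.5).
#' @export
kmEstimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (any(times < 0)) stop("negative times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(sf)$table["median"])
  structure(list(time = sf$time, nRisk = sf$n.risk, nEvent = sf$n.event,
                 nCensor = sf$n.censor, surv = sf$surv, median = med),
            class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, %d events, median %s\n",
              length(x$time), sum(x$nEvent),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-sided log-rank test between two groups
#'
#' Standard (O-E)^2/V chi-square statistic with one degree of freedom.
#' When no events occurred at all the test is undefined; the statistic is
#' reported as 0 with p = 1 and a warning.
#'
#' @param times,events as in [kmEstimate()].
#' @param groups two-level grouping (e.g. "high"/"low").
#' @return list: statistic, df, p.value.
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2L)
    stop("need exactly two nonempty groups")
  if (sum(events) == 0) {
    warning("no events observed; log-rank test undefined, p = 1")
    return(list(statistic = 0, df = 1L, p.value = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(statistic = unname(sd$chisq), df = 1L,
       p.value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling (configurable).
#' Categorical covariates are dummy-coded against their first (or stated)
#' reference level. Zero-variance covariates carry no information: they are
#' reported with HR 1 and an infinite-variance warning rather than passed
#' to the solver. Monotone likelihood (perfect separation) is flagged with
#' a warning; coefficients are reported as returned, not clipped.
#'
#' @param times,events as in [kmEstimate()].
#' @param covariates data.frame of covariates (numeric or categorical),
#'   e.g. the LRPS plus tumor type, mutation type and stage.
#' @param ties "efron" (default) or "breslow".
#' @param refLevels optional named list: reference level per categorical
#'   covariate.
#' @return list of class "CoxFit": table (term, coef, hr, lower, upper,
#'   se, p), n, nEvents, schoenfeldGlobalP, model (the underlying coxph
#'   fit, NULL when no covariate carried information).
#' @export
coxFit <- function(times, events, covariates, ties = c("efron", "breslow"),
                   refLevels = NULL) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(times))
  for (nm in names(refLevels)) {
    covariates[[nm]] <- stats::relevel(factor(covariates[[nm]]),
                                       ref = refLevels[[nm]])
  }
  constant <- vapply(covariates, function(col) length(unique(col)) < 2L,
                     logical(1))
  degenerate <- names(covariates)[constant]
  if (length(degenerate))
    warning("covariate(s) constant across samples (no information, ",
            "infinite variance): ", paste(degenerate, collapse = ", "),
            "; reported with HR 1")
  active <- covariates[, !constant, drop = FALSE]
  if (sum(events) < ncol(active))
    warning("fewer events than covariates; estimates will be unstable")
  model <- NULL
  tab <- NULL
  if (ncol(active) > 0L) {
    dat <- cbind(data.frame(.time = times, .event = events), active)
    fml <- as.formula(paste("survival::Surv(.time, .event) ~",
                            paste(sprintf("`%s`", names(active)),
                                  collapse = " + ")))
    model <- withCallingHandlers(
      survival::coxph(fml, data = dat, ties = ties),
      warning = function(w) {
        if (grepl("infinite|did not converge|beta may be infinite",
                  conditionMessage(w)))
          warning("possible monotone likelihood (perfect separation): ",
                  conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    sm <- summary(model)
    ci <- sm$conf.int
    tab <- data.frame(term = rownames(sm$coefficients),
                      coef = sm$coefficients[, "coef"],
                      hr = sm$coefficients[, "exp(coef)"],
                      lower = ci[, "lower .95"],
                      upper = ci[, "upper .95"],
                      se = sm$coefficients[, "se(coef)"],
                      p = sm$coefficients[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(degenerate)) {
    degTab <- data.frame(term = degenerate, coef = 0, hr = 1,
                         lower = NA_real_, upper = NA_real_,
                         se = Inf, p = NA_real_,
                         stringsAsFactors = FALSE)
    tab <- rbind(tab, degTab)
  }
  zp <- if (!is.null(model) && sum(events) >= 2)
    tryCatch(schoenfeldGlobalTest(model), error = function(e) NA_real_)
  else NA_real_
  structure(list(table = tab, n = length(times), nEvents = sum(events),
                 schoenfeldGlobalP = zp, model = model),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d\n", x$n, x$nEvents))
  if (!is.null(x$table)) {
    tb <- x$table
    for (i in seq_len(nrow(tb)))
      cat(sprintf("  %-24s HR %.4g (95%% CI %.4g-%.4g), p = %.3g\n",
                  tb$term[i], tb$hr[i], tb$lower[i], tb$upper[i], tb$p[i]))
  }
  cat(sprintf("  global Schoenfeld p = %.3g (PH %s)\n",
              x$schoenfeldGlobalP,
              if (is.na(x$schoenfeldGlobalP)) "untested"
              else if (x$schoenfeldGlobalP > 0.05) "upheld" else "questionable"))
  invisible(x)
}

#' Global Schoenfeld residual test of proportional hazards
#'
#' Regresses the scaled Schoenfeld residuals on a transform of time
#' (Kaplan-Meier transform by default) and returns the global chi-square
#' p-value. Proportional hazards are considered upheld when p > 0.05. With
#' a single covariate the global p equals the covariate-specific p.
#'
#' @param fit a "CoxFit" from [coxFit()] or a \code{coxph} model.
#' @param transform time transform: "km" (default), "identity" or "rank".
#' @return the global test p-value (numeric).
#' @export
schoenfeldGlobalTest <- function(fit, transform = c("km", "identity",
                                                    "rank")) {
  transform <- match.arg(transform)
  model <- if (inherits(fit, "CoxFit")) fit$model else fit
  if (is.null(model) || !inherits(model, "coxph"))
    stop("need a fitted Cox model")
  if (model$nevent < 2L) stop("need at least 2 events")
  zp <- survival::cox.zph(model, transform = transform, global = TRUE)
  unname(zp$table["GLOBAL", "p"])
}
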