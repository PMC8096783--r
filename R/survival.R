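# Survival evaluation: Kaplan-Meier estimation, log-rank comparison and
# univariate/bivariate Cox proportional-hazards regression, as used to
# assess the prognostic performance of the dECIF variable. Fitting is
# delegated to the survival package (Efron ties by default); results are
# re-shaped into the HR / 95% CI / p reporting layout.

#' Kaplan--Meier estimate per group, with reverse-KM median follow-up
#'
#' @param clinical tibble with `os_time` (months), `os_event` (0/1).
#' @param group optional vector (or column name in `clinical`) defining
#'   groups; `NULL` fits a single curve.
#' @return list: `table` (tibble `group`, `time`, `n_risk`, `n_event`,
#'   `surv`), `median_followup` (months, reverse Kaplan--Meier), `fit`
#'   (the underlying `survfit` object).
#' @export
km_estimate <- function(clinical, group = NULL) {
  if (any(clinical$os_time < 0)) stop("negative survival time")
  g <- resolve_group(clinical, group)
  df <- data.frame(time = clinical$os_time, event = clinical$os_event)
  fit <- if (is.null(g)) {
    survival::survfit(survival::Surv(time, event) ~ 1, data = df)
  } else {
    df$g <- g
    survival::survfit(survival::Surv(time, event) ~ g, data = df)
  }
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(g)) rep("all", length(s$time)) else {
    sub("^g=", "", as.character(s$strata))
  }
  rev_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1, data = df)
  list(
    table = tibble::tibble(group = grp, time = s$time, n_risk = s$n.risk,
                           n_event = s$n.event, surv = s$surv),
    median_followup = unname(summary(rev_fit)$table["median"]),
    fit = fit
  )
}

resolve_group <- function(clinical, group) {
  if (is.null(group)) return(NULL)
  if (is.character(group) && length(group) == 1 && group %in% names(clinical)) {
    return(clinical[[group]])
  }
  if (length(group) != nrow(clinical)) stop("group length must match records")
  group
}

#' Log-rank test comparing survival curves across groups
#'
#' @param clinical tibble with `os_time`, `os_event`.
#' @param group grouping vector or column name (>= 2 groups).
#' @return list: `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(clinical, group) {
  g <- factor(resolve_group(clinical, group))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (sum(clinical$os_event) == 0) stop("no events")
  df <- data.frame(time = clinical$os_time, event = clinical$os_event, g = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  list(chi_square = unname(sd$chisq), df = length(sd$n) - 1,
       p_value = unname(1 - stats::pchisq(sd$chisq, length(sd$n) - 1)))
}

#' Cox proportional-hazards regression (univariate or adjusted)
#'
#' Fits `Surv(os_time, os_event) ~ terms` by partial likelihood (Efron tie
#' handling by default) and reports, for every non-reference level of each
#' categorical term and for every continuous term, the hazard ratio with
#' its Wald confidence interval and p-value. Categorical terms are
#' releveled so the stated reference (the putative better category) is the
#' baseline. A monotone partial likelihood (infinite HR) is flagged and its
#' interval reported as unbounded.
#'
#' @param clinical tibble with `os_time`, `os_event` and the term columns.
#' @param terms character vector of covariate column names; two terms give
#'   the bivariate adjusted model.
#' @param reference_map named list/vector: reference level per categorical
#'   term.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param confidence confidence level (default 0.95).
#' @return tibble: `term`, `hr`, `ci_low`, `ci_high`, `p_value`,
#'   `reference_category`, `n`, `n_events`, `adjusted_for`, `flag`.
#' @export
cox_fit <- function(clinical, terms, reference_map = NULL, ties = "efron",
                    confidence = 0.95) {
  if (sum(clinical$os_event) == 0) stop("no events: Cox model undefined")
  miss <- setdiff(terms, names(clinical))
  if (length(miss) > 0) stop("term(s) not in clinical table: ",
                             paste(miss, collapse = ", "))
  df <- as.data.frame(clinical[, c("os_time", "os_event", terms)])
  refs <- list()
  for (tm in terms) {
    v <- df[[tm]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      v <- factor(v)
      ref <- reference_map[[tm]] %||% levels(v)[1]
      if (!ref %in% levels(v)) stop("reference level '", ref,
                                    "' absent from term ", tm)
      df[[tm]] <- stats::relevel(v, ref = ref)
      refs[[tm]] <- ref
    } else {
      refs[[tm]] <- NA_character_
    }
  }
  fml <- stats::as.formula(paste("survival::Surv(os_time, os_event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  sm <- summary(fit, conf.int = confidence)
  cf <- sm$coefficients
  ci <- sm$conf.int
  term_of <- function(nm) terms[which.max(vapply(terms, function(t) startsWith(nm, t), TRUE))]
  out <- lapply(rownames(cf), function(nm) {
    beta <- cf[nm, "coef"]; se <- cf[nm, "se(coef)"]
    unbounded <- !is.finite(beta) || abs(beta) > 15 || se > 1e3
    tibble::tibble(
      term = nm,
      hr = exp(beta),
      ci_low = if (unbounded) 0 else ci[nm, 3],
      ci_high = if (unbounded) Inf else ci[nm, 4],
      p_value = cf[nm, "Pr(>|z|)"],
      reference_category = refs[[term_of(nm)]],
      n = sm$n, n_events = sm$nevent,
      adjusted_for = paste(setdiff(terms, term_of(nm)), collapse = ","),
      flag = if (unbounded) "monotone_likelihood" else ""
    )
  })
  do.call(rbind, out)
}
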