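# Kaplan-Meier, logrank and two-group Cox comparison of CNA-derived groups.
#
# The default endpoint is cancer-specific: deaths of tumour disease (DOTD)
# are events, deaths because of other reasons (DBOR) are censored at their
# time. An all-cause switch pools both death categories.

surv_endpoint <- function(clinical, cause_filter = c("DOTD_only", "all")) {
  cause_filter <- match.arg(cause_filter)
  if (is.null(clinical$surv_time) || is.null(clinical$event))
    stop_data("clinical table lacks surv_time/event columns")
  if (any(clinical$surv_time < 0)) stop_data("negative survival time")
  ev <- as.logical(clinical$event)
  if (cause_filter == "DOTD_only" && !is.null(clinical$death_cause))
    ev <- ev & clinical$death_cause == "DOTD"
  survival::Surv(clinical$surv_time, ev)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate over one set of clinical records; ties are handled
#' by simultaneous decrement.
#'
#' @param clinical clinical records with `surv_time`, `event` and (for the
#'   cancer-specific endpoint) `death_cause`.
#' @param cause_filter `"DOTD_only"` (default, cancer-specific) or `"all"`.
#' @return `data.frame` with class `survival_curve`: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(clinical, cause_filter = c("DOTD_only", "all")) {
  if (nrow(clinical) == 0) stop_data("no clinical records")
  s <- surv_endpoint(clinical, cause_filter)
  fit <- survival::survfit(s ~ 1, conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Logrank test between two groups
#'
#' Standard 1-df logrank chi-square; two-sided p.
#'
#' @param clinical clinical records.
#' @param group logical or two-level vector aligned with `clinical` rows.
#' @inheritParams km_curve
#' @return list with `chisq`, `p_value`, and per-group observed/expected
#'   event counts.
#' @export
logrank_test <- function(clinical, group,
                         cause_filter = c("DOTD_only", "all")) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop_data("logrank needs exactly two non-empty groups")
  if (any(tapply(clinical$surv_time, group, sum) == 0))
    stop_data("a group has zero total observation time")
  s <- surv_endpoint(clinical, cause_filter)
  sd <- survival::survdiff(s ~ group)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p_value = p,
       observed = as.vector(sd$obs), expected = as.vector(sd$exp))
}

#' Two-group Cox proportional-hazards comparison
#'
#' Partial-likelihood estimate (Breslow tie handling) of the hazard ratio
#' of `group == TRUE` vs `FALSE`, with a Wald 95% CI and the logrank p.
#' Degenerate separation — all events confined to one group — makes the
#' partial-likelihood maximum diverge; the result is flagged
#' `estimable = FALSE` with an `NA` hazard ratio rather than a spuriously
#' huge number.
#'
#' @inheritParams logrank_test
#' @return list with `hazard_ratio`, `ci_low`, `ci_high`, `logrank_p`,
#'   `estimable`, `n`, `events`, and the group `labels`.
#' @export
cox_two_group <- function(clinical, group,
                          cause_filter = c("DOTD_only", "all")) {
  cause_filter <- match.arg(cause_filter)
  gf <- as.factor(group)
  if (nlevels(droplevels(gf)) != 2) stop_data("need exactly two groups")
  s <- surv_endpoint(clinical, cause_filter)
  ev <- s[, "status"] == 1
  if (sum(ev) == 0)
    return(list(hazard_ratio = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, logrank_p = NA_real_,
                estimable = FALSE, n = nrow(clinical), events = 0L,
                labels = levels(gf),
                reason = "zero events"))
  ev_by_group <- tapply(ev, gf, sum)
  lr <- logrank_test(clinical, gf, cause_filter)
  if (any(ev_by_group == 0))
    return(list(hazard_ratio = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, logrank_p = lr$p_value,
                estimable = FALSE, n = nrow(clinical),
                events = sum(ev), labels = levels(gf),
                reason = paste0("all events in group '",
                                names(which(ev_by_group > 0)),
                                "'; hazard ratio diverges")))
  fit <- survival::coxph(s ~ gf, ties = "breslow")
  beta <- unname(coef(fit)[1])
  se <- sqrt(unname(fit$var[1, 1]))
  list(hazard_ratio = exp(beta),
       ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
       se_log_hr = se, logrank_p = lr$p_value, estimable = TRUE,
       n = nrow(clinical), events = sum(ev), labels = levels(gf))
}

#' Survival comparison of assigned patient groups
#'
#' Pools CNA patient groups into two arms (default: low-burden `A` and `Z`
#' vs G3-burdened `B`-`F`) and runs [cox_two_group()].
#'
#' @param clinical clinical records.
#' @param groups output of [assign_patient_groups()].
#' @param arm1 group labels forming the reference arm.
#' @param arm2 group labels forming the comparison arm.
#' @inheritParams km_curve
#' @return as [cox_two_group()], plus the arm definition.
#' @export
compare_group_survival <- function(clinical, groups,
                                   arm1 = c("A", "Z"),
                                   arm2 = c("B", "C", "D", "E", "F"),
                                   cause_filter = c("DOTD_only", "all")) {
  g <- groups$group[match(clinical$sample_id, groups$sample_id)]
  keep <- g %in% c(arm1, arm2)
  cl <- clinical[keep, , drop = FALSE]
  arm <- factor(ifelse(g[keep] %in% arm2, "burdened", "reference"),
                levels = c("reference", "burdened"))
  res <- cox_two_group(cl, arm, cause_filter)
  res$arm1 <- arm1; res$arm2 <- arm2
  res
}
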