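# Progression-free-interval analysis: stage reclassification,
# median-follow-up censoring, Kaplan-Meier/logrank, Cox PH models.

#' Parse AJCC-style stage labels
#'
#' Accepts roman or arabic stage labels with optional substage letters
#' ("Stage IIIA", "stage 2b", "IV", "0"); returns the integer stage 0-4 or
#' `NA` for unparseable labels.
#'
#' @param x character vector of stage labels.
#' @return Integer vector in 0..4 (or `NA`).
#' @export
#' @examples
#' parse_stage(c("Stage IIIA", "Stage IV", "stage 0", "II", "N/A"))
parse_stage <- function(x) {
  s <- toupper(trimws(gsub("(?i)stage", "", x, perl = TRUE)))
  s <- gsub("[ABC]+$", "", s)
  s <- trimws(s)
  out <- rep(NA_integer_, length(x))
  out[s == "0"] <- 0L
  out[s %in% c("I", "1")] <- 1L
  out[s %in% c("II", "2")] <- 2L
  out[s %in% c("III", "3")] <- 3L
  out[s %in% c("IV", "4")] <- 4L
  out
}

#' Prepare survival records for one tumor type
#'
#' Applies the stage rule (stages 0-2 reclassified `low`, stage 3 `high`,
#' stage-4 rows excluded; unparseable labels flagged with a missing
#' `stage_class`) and administrative censoring at the within-tumor-type
#' median follow-up time: records with event/censoring time beyond the
#' median follow-up are truncated to it with the event indicator set to 0.
#' Idempotent: re-applying changes nothing.
#'
#' @param records clinical data.frame with `PFI.time`, `PFI`, `stage`,
#'   `last_followup` columns (one tumor type).
#' @param time,event,stage,follow_up column names.
#' @return Filtered/recoded data.frame with `stage_class` and the follow-up
#'   cutoff in attribute `followup_cutoff`.
#' @export
prepare_survival <- function(records, time = "PFI.time", event = "PFI",
                             stage = "stage", follow_up = "last_followup") {
  assert_cols(records, c(time, event, stage, follow_up), "clinical table")
  st <- parse_stage(records[[stage]])
  cutoff <- stats::median(records[[follow_up]], na.rm = TRUE)
  out <- records[is.na(st) | st != 4L, , drop = FALSE]
  st <- st[is.na(st) | st != 4L]
  out$stage_class <- ifelse(is.na(st), NA_character_,
                            ifelse(st <= 2L, "low", "high"))
  late <- out[[time]] > cutoff
  out[[event]][late] <- 0L
  out[[time]][late] <- cutoff
  rownames(out) <- NULL
  attr(out, "followup_cutoff") <- cutoff
  out
}

#' Kaplan-Meier curves and logrank test
#'
#' Product-limit estimates per group with Greenwood variance (via
#' [survival::survfit()]), a risk table at requested times, and the
#' two-or-more-group logrank chi-square and p-value.
#'
#' @param time,event,group aligned vectors; every group must be non-empty.
#' @param risk_times times for the risk table (default: quartiles of
#'   observed time).
#' @return list: `fit` (survfit), `risk_table`, `chisq`, `df`, `p`.
#' @export
km_logrank <- function(time, event, group, risk_times = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  if (any(table(group) == 0)) stop("a group has zero subjects", call. = FALSE)
  d <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (sum(event) == 0) {
    chisq <- 0; df <- nlevels(group) - 1; pval <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    chisq <- sd$chisq
    df <- length(sd$n) - 1
    pval <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  risk_times <- risk_times %||% unname(stats::quantile(time, c(0, .25, .5, .75)))
  sm <- summary(fit, times = risk_times, extend = TRUE)
  risk_table <- data.frame(group = sm$strata, time = sm$time,
                           n_risk = sm$n.risk, n_event = sm$n.event,
                           surv = sm$surv, stringsAsFactors = FALSE)
  list(fit = fit, risk_table = risk_table, chisq = chisq, df = df, p = pval)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Newton-Raphson, Efron tie correction,
#' convergence tolerance 1e-9, at most 50 iterations) and reports, per
#' covariate, the hazard ratio with Wald 95% CI and p-value. Monotone
#' likelihood (complete separation) is reported as non-convergence with no
#' estimate for the affected term.
#'
#' @param data data.frame containing the time/event columns and covariates.
#' @param covariates character vector of covariate column names; the first
#'   is typically the binary signature class.
#' @param time,event column names (defaults `PFI.time`, `PFI`).
#' @return data.frame: `term`, `hr`, `lower95`, `upper95`, `p`, `converged`;
#'   attributes `n`, `n_event`, `fit`.
#' @export
cox_fit <- function(data, covariates, time = "PFI.time", event = "PFI") {
  assert_cols(data, c(time, event, covariates), "survival table")
  d <- data[stats::complete.cases(data[, c(time, event, covariates)]), ,
            drop = FALSE]
  f <- stats::as.formula(paste0("survival::Surv(`", time, "`, `", event,
                                "`) ~ ", paste(covariates, collapse = " + ")))
  n_event <- sum(d[[event]])
  warned_inf <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = d, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        warned_inf <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  sane <- is.finite(co[, "se(coef)"]) & abs(co[, "coef"]) < 15 & !warned_inf
  out <- data.frame(term = rownames(co),
                    hr = ifelse(sane, exp(co[, "coef"]), NA_real_),
                    lower95 = ifelse(sane, ci[, 3], NA_real_),
                    upper95 = ifelse(sane, ci[, 4], NA_real_),
                    p = ifelse(sane, co[, "Pr(>|z|)"], NA_real_),
                    converged = sane, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- nrow(d)
  attr(out, "n_event") <- n_event
  attr(out, "fit") <- fit
  out
}
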