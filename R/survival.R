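# Survival validation: median-expression stratification, Kaplan-Meier
# product-limit curves and the two-group log-rank test (a local
# reimplementation of the usual web-portal comparison), via the survival
# package.

#' Split patients into high/low expression groups at the median
#'
#' `high` is strictly above the median, `low` at or below (ties go to
#' low); a different quantile can be supplied. Patients lacking survival
#' data must be excluded before calling.
#'
#' @param values Named numeric vector: one expression value per patient.
#' @param quantile Split quantile (default 0.5, the median).
#' @return Named character vector of `"high"` / `"low"` labels.
#' @export
median_split <- function(values, quantile = 0.5) {
  if (length(values) < 4) stop("need >= 4 patients, got ", length(values))
  if (length(unique(values)) == 1)
    stop("all expression values equal: no split exists")
  cut <- stats::quantile(values, quantile, names = FALSE)
  labs <- ifelse(values > cut, "high", "low")
  if (all(labs == "low") || all(labs == "high"))
    stop("degenerate split: all patients on one side of the cutoff")
  labs
}

#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times;
#' censored subjects leave the risk set after their time.
#'
#' @param times Non-negative follow-up times.
#' @param events 0 (censored) / 1 (death) indicators.
#' @return List of class `km_curve`: `time` (distinct event times,
#'   sorted), `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% 0:1)) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep],
                 n_risk = fit$n.risk[keep],
                 n_event = fit$n.event[keep],
                 surv = fit$surv[keep]),
            class = "km_curve")
}

#' Restricted mean survival (area under the KM curve)
#'
#' Integrated up to the largest observed time; used to orient which
#' group fares worse.
#' @param times,events As in [km_estimate()].
#' @keywords internal
km_area <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tt <- c(0, fit$time); ss <- c(1, fit$surv)
  sum(diff(tt) * ss[-length(ss)])
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank with the hypergeometric
#' variance at each distinct event time; chi-square on 1 df.
#'
#' @param group_a,group_b Lists with elements `times` and `events`.
#' @return List of class `logrank_result`: `chi_square`, `df`, `p`,
#'   `n_a`, `n_b`.
#' @export
logrank_test <- function(group_a, group_b) {
  na <- length(group_a$times); nb <- length(group_b$times)
  if (!na || !nb) stop("both groups must be non-empty")
  if (sum(group_a$events) + sum(group_b$events) == 0)
    stop("zero total events: log-rank test undefined")
  times <- c(group_a$times, group_b$times)
  events <- c(group_a$events, group_b$events)
  grp <- rep(c("a", "b"), c(na, nb))
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ grp)
  chi <- unname(sd_$chisq)
  structure(list(chi_square = chi, df = 1,
                 p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 n_a = na, n_b = nb),
            class = "logrank_result")
}

#' Screen candidate lncRNAs by median-split survival
#'
#' For each candidate: average its tumor expression per patient, drop
#' patients without follow-up, median-split, log-rank. A candidate is
#' flagged when the high-expression group has worse survival (smaller
#' restricted mean) and p < `p_max`. Candidates that cannot be tested
#' (absent from the matrix, degenerate split, no events) yield an
#' untestable row rather than an error.
#'
#' @param candidates Character vector of lncRNA ids.
#' @param expr Log-scale lncRNA [expression_matrix()].
#' @param clinical A [clinical_table()] with survival columns on tumor
#'   samples.
#' @param p_max Flagging threshold (default 0.05).
#' @param quantile Split quantile passed to [median_split()].
#' @return Data.frame with columns `lncrna_id`, `testable`, `n_high`,
#'   `n_low`, `chi_square`, `p`, `high_worse`, `flagged`.
#' @export
survival_screen <- function(candidates, expr, clinical, p_max = 0.05,
                            quantile = 0.5) {
  x <- unclass_mat(expr)
  cl <- clinical[clinical$condition == "tumor" &
                   !is.na(clinical$survival_time), , drop = FALSE]
  cl <- cl[cl$sample_id %in% colnames(x), , drop = FALSE]
  row_for <- function(id, ...) {
    d <- list(lncrna_id = id, testable = FALSE, n_high = NA_integer_,
              n_low = NA_integer_, chi_square = NA_real_, p = NA_real_,
              high_worse = NA, flagged = FALSE)
    d[names(list(...))] <- list(...)
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  if (!length(candidates))
    return(data.frame(lncrna_id = character(), testable = logical(),
                      n_high = integer(), n_low = integer(),
                      chi_square = numeric(), p = numeric(),
                      high_worse = logical(), flagged = logical()))
  out <- lapply(candidates, function(id) {
    if (!id %in% rownames(x)) return(row_for(id))
    vals <- tapply(x[id, cl$sample_id], cl$patient_id, mean)
    surv <- cl[!duplicated(cl$patient_id), ]
    surv <- surv[match(names(vals), surv$patient_id), ]
    labs <- tryCatch(median_split(vals, quantile), error = function(e) NULL)
    if (is.null(labs)) return(row_for(id))
    hi <- labs == "high"
    if (sum(surv$event) == 0) return(row_for(id))
    lr <- tryCatch(
      logrank_test(list(times = surv$survival_time[hi],
                        events = surv$event[hi]),
                   list(times = surv$survival_time[!hi],
                        events = surv$event[!hi])),
      error = function(e) NULL)
    if (is.null(lr)) return(row_for(id))
    worse <- km_area(surv$survival_time[hi], surv$event[hi]) <
      km_area(surv$survival_time[!hi], surv$event[!hi])
    row_for(id, testable = TRUE, n_high = sum(hi), n_low = sum(!hi),
            chi_square = lr$chi_square, p = lr$p, high_worse = worse,
            flagged = worse && lr$p < p_max)
  })
  do.call(rbind, out)
}
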