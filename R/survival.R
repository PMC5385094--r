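#' Kaplan-Meier product-limit estimate
#'
#' `S(t)` is the product over distinct event times `t_i <= t` of
#' `(1 - d_i / n_i)`, with tied events aggregated per distinct time.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored), aligned with
#'   `times`.
#' @return A data.frame of class `survival_curve` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events) || length(times) == 0)
    stop("`times` and `events` must be non-empty and aligned", call. = FALSE)
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' k-sample log-rank test
#'
#' Chi-square statistic on `k - 1` degrees of freedom from the
#' observed-minus-expected event counts per group, using the hypergeometric
#' variance at each distinct event time.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Categorical vector aligned with `times`; >= 2 non-empty
#'   groups.
#' @return A list with `statistic`, `df`, `p_value`, and `n_per_group`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (length(times) != length(events) || length(times) != length(groups))
    stop("`times`, `events`, `groups` must align", call. = FALSE)
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2)
    stop("need >= 2 non-empty groups", call. = FALSE)
  groups <- droplevels(groups)
  for (g in levels(groups))
    if (all(times[groups == g] == 0))
      stop("group '", g, "' has all follow-up times 0", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(statistic = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       n_per_group = as.vector(table(groups)))
}

#' Administrative censoring at a horizon
#'
#' Subjects with follow-up strictly beyond `horizon` are censored at the
#' horizon; subjects at or before the horizon are unchanged (an event exactly
#' at the horizon stays an event). Used to restrict comparisons to, e.g.,
#' 5-year survival.
#'
#' @param times,events As in [km_estimate()].
#' @param horizon Positive censoring horizon (same units as `times`).
#' @return A list with truncated `times` and `events`.
#' @export
censor_at <- function(times, events, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0)
    stop("`horizon` must be a single positive number", call. = FALSE)
  over <- times > horizon
  list(times = ifelse(over, horizon, times),
       events = ifelse(over, 0L, as.integer(events)))
}

#' Compare survival across clusters
#'
#' Applies optional administrative censoring at `horizon`, computes one
#' Kaplan-Meier curve per cluster, and a global k-sample log-rank test.
#'
#' @param labels Cluster labels named by sample id.
#' @param clinical Clinical data.frame with a `sample_id` column and
#'   `<endpoint>_time` / `<endpoint>_event` columns.
#' @param endpoint Endpoint name, e.g. `"os"` or `"recurrence"`.
#' @param horizon Optional positive horizon for [censor_at()]; `NULL` skips
#'   truncation. The 5-year convention is 60 (months).
#' @return A list of class `cluster_survival` with `curves` (per-cluster
#'   `survival_curve`s), `test` (from [logrank_test()]), `endpoint`,
#'   `horizon`, and `n_dropped` (samples missing time or event).
#' @export
cluster_survival <- function(labels, clinical, endpoint = "os",
                             horizon = NULL) {
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c("sample_id", tcol, ecol) %in% names(clinical)))
    stop("clinical table lacks sample_id / ", tcol, " / ", ecol, call. = FALSE)
  idx <- match(names(labels), clinical$sample_id)
  if (anyNA(idx))
    stop("labelled sample(s) absent from the clinical table: ",
         paste(utils::head(names(labels)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  times <- clinical[[tcol]][idx]
  events <- clinical[[ecol]][idx]
  keep <- !is.na(times) & !is.na(events)
  n_dropped <- sum(!keep)
  times <- times[keep]; events <- events[keep]; lab <- labels[keep]
  if (!is.null(horizon)) {
    ce <- censor_at(times, events, horizon)
    times <- ce$times; events <- ce$events
  }
  curves <- lapply(split(seq_along(lab), lab),
                   function(i) km_estimate(times[i], events[i]))
  structure(list(curves = curves,
                 test = logrank_test(times, events, lab),
                 endpoint = endpoint, horizon = horizon,
                 n_dropped = n_dropped),
            class = "cluster_survival")
}

#' @export
print.cluster_survival <- function(x, ...) {
  cat(sprintf("Survival by cluster, endpoint '%s'%s\n", x$endpoint,
              if (is.null(x$horizon)) ""
              else sprintf(" (censored at %g)", x$horizon)))
  cat(sprintf("  log-rank: chi-square = %.4g, df = %d, p = %.4g\n",
              x$test$statistic, x$test$df, x$test$p_value))
  cat("  group sizes: ", paste(x$test$n_per_group, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Plot cluster survival curves
#'
#' Step curves per cluster with the log-rank p-value in the title.
#'
#' @param x A `cluster_survival`.
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.cluster_survival <- function(x, ...) {
  xmax <- max(vapply(x$curves, function(cv) max(cv$time), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "time", ylab = "survival probability",
                 main = sprintf("%s endpoint (log-rank p = %.3g)",
                                x$endpoint, x$test$p_value))
  for (i in seq_along(x$curves)) {
    cv <- x$curves[[i]]
    graphics::lines(c(0, cv$time), c(1, cv$surv), type = "s", col = i)
  }
  graphics::legend("bottomleft",
                   legend = paste0("cluster ", names(x$curves)),
                   col = seq_along(x$curves), lty = 1, cex = 0.8)
  invisible(x)
}
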