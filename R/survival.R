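#' Kaplan-Meier product-limit estimate
#'
#' Estimates the overall-survival step function S(t) from right-censored
#' times via `survival::survfit`. Ties are handled by the standard
#' aggregated-counts convention (all deaths at a time processed together;
#' subjects censored at t remain at risk at t). Censored-only data yield
#' S identically 1.
#'
#' @param os_months Nonnegative survival/censoring times (months).
#' @param os_event 0/1 event indicator (1 = death observed).
#' @return Object of class `"km_curve"`: data.frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `std_err` (Greenwood), plus a
#'   `median` attribute (`NA` if S never falls to 0.5).
#' @export
km_estimate <- function(os_months, os_event) {
  if (!length(os_months)) stop("need >=1 sample")
  if (any(os_months < 0, na.rm = TRUE)) stop("negative survival time")
  keep <- !is.na(os_months) & !is.na(os_event)
  fit <- survival::survfit(survival::Surv(os_months[keep], os_event[keep]) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    n_censor = fit$n.censor, surv = fit$surv,
                    std_err = fit$std.err)
  attr(out, "median") <- unname(summary(fit)$table["median"])
  attr(out, "n") <- sum(keep)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median survival of a Kaplan-Meier curve
#' @param km A `km_curve` from [km_estimate()].
#' @return Median survival time in months, `NA` if not reached.
#' @export
km_median <- function(km) attr(km, "median")

#' k-group log-rank test
#'
#' Standard log-rank comparison of survival distributions across k >= 2
#' groups (via `survival::survdiff`): at each event time, expected events
#' per group are proportional to at-risk counts, and the chi-square
#' statistic with k-1 degrees of freedom aggregates observed-minus-expected
#' over time. All-censored data give statistic 0 and P 1.
#'
#' @param os_months,os_event Survival times and 0/1 event indicators.
#' @param groups Group label per sample (k >= 2 distinct, each nonempty).
#' @return Object of class `"logrank_result"`: list with `groups` (labels),
#'   `n`, `observed`, `expected` (per group), `statistic`, `df`, `p_value`.
#' @export
logrank <- function(os_months, os_event, groups) {
  n <- length(os_months)
  if (length(os_event) != n || length(groups) != n)
    stop("survival and group vectors must align")
  keep <- !is.na(os_months) & !is.na(os_event) & !is.na(groups)
  os_months <- os_months[keep]; os_event <- os_event[keep]
  groups <- as.character(groups[keep])
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need >=2 nonempty groups, got ", length(lev))
  sizes <- table(groups)
  if (any(sizes < 5))
    warning("group(s) with <5 samples: ",
            paste(names(sizes)[sizes < 5], collapse = ", "))
  if (sum(os_event) == 0) {
    res <- list(groups = lev, n = as.integer(sizes[lev]),
                observed = stats::setNames(rep(0, length(lev)), lev),
                expected = stats::setNames(rep(0, length(lev)), lev),
                statistic = 0, df = length(lev) - 1L, p_value = 1)
    class(res) <- "logrank_result"
    return(res)
  }
  g <- factor(groups, levels = lev)
  sd <- survival::survdiff(survival::Surv(os_months, os_event) ~ g)
  stat <- unname(sd$chisq)
  df <- length(lev) - 1L
  res <- list(groups = lev, n = as.integer(sizes[lev]),
              observed = stats::setNames(as.numeric(sd$obs), lev),
              expected = stats::setNames(as.numeric(sd$exp), lev),
              statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test:", length(x$groups), "groups, chi-square =",
      format(x$statistic, digits = 4), "on", x$df, "df, P =",
      format(x$p_value, digits = 4), "\n")
  print(data.frame(group = x$groups, n = x$n,
                   observed = x$observed, expected = x$expected,
                   row.names = NULL))
  invisible(x)
}

#' Survival comparison across stratification groups
#'
#' Runs a log-rank test over the groups of a stratification assignment,
#' either the omnibus k-group test or, when `pair` names two labels (e.g.
#' the two most diverse WRE corners `WRdL_EH` vs `WRdH_EL`), the two-group
#' test restricted to those samples. Per-group Kaplan-Meier curves are
#' returned alongside.
#'
#' @param clinical A [clinical_table()] with `os_months` and `os_event`.
#' @param assignment A `strata_assignment`.
#' @param pair Optional character(2): restrict to these two labels.
#' @return List: `logrank` (a `logrank_result`) and `curves` (named list of
#'   `km_curve`, one per group).
#' @export
compare_strata_survival <- function(clinical, assignment, pair = NULL) {
  labels <- assignment$labels
  idx <- match(names(labels), clinical$sample)
  if (any(is.na(idx)))
    stop("assignment covers sample(s) absent from the clinical table: ",
         paste(utils::head(names(labels)[is.na(idx)], 5), collapse = ", "))
  time <- clinical$os_months[idx]
  event <- clinical$os_event[idx]
  grp <- unname(labels)
  if (!is.null(pair)) {
    if (length(pair) != 2 || pair[1] == pair[2])
      stop("'pair' must name two distinct labels")
    absent <- setdiff(pair, grp)
    if (length(absent))
      stop("label(s) absent from assignment: ", paste(absent, collapse = ", "))
    keep <- grp %in% pair
    time <- time[keep]; event <- event[keep]; grp <- grp[keep]
  }
  lr <- logrank(time, event, grp)
  curves <- lapply(stats::setNames(lr$groups, lr$groups), function(g)
    km_estimate(time[grp == g], event[grp == g]))
  list(logrank = lr, curves = curves)
}

#' Write Kaplan-Meier curves to TSV
#' @param curves Named list of `km_curve` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_curves <- function(curves, path) {
  rows <- do.call(rbind, lapply(names(curves), function(g) {
    k <- curves[[g]]
    data.frame(group = g, time = k$time, n_risk = k$n_risk,
               n_event = k$n_event, surv = k$surv, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
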