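SCHEMES <- c("W", "R", "E", "WE", "RE", "WR", "WRE")

#' Median dichotomization
#'
#' Splits a per-sample score at the cohort median: `high` iff value >
#' median, ties at the median labeled `low` (deterministic tie rule). The
#' split is always computed within one cohort; medians are never pooled
#' across cohorts.
#'
#' @param values Named numeric vector (names = sample IDs).
#' @return List with `labels` (named character, `"low"`/`"high"`) and
#'   `cutoff` (the median).
#' @examples
#' median_split(c(a = 1, b = 2, c = 3, d = 4))$labels
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("need >=2 samples to dichotomize")
  if (any(!is.finite(values))) stop("non-finite signature values")
  if (max(values) == min(values))
    stop("all values identical; median dichotomy is degenerate")
  cut <- stats::median(values)
  labels <- ifelse(values > cut, "high", "low")
  names(labels) <- names(values)
  list(labels = labels, cutoff = cut)
}

# canonical low/high letter for composite label strings
.lh <- function(lab) ifelse(lab == "high", "H", "L")

new_strata_assignment <- function(scheme, labels, cutoffs) {
  structure(
    list(scheme = scheme, labels = labels,
         indication = indication_of(labels, scheme), cutoffs = cutoffs),
    class = "strata_assignment")
}

#' Single-signature stratification
#'
#' Median split of one signature into a `low`/`high` two-group assignment.
#'
#' @param sig A `signature_table` from [compute_wre()].
#' @param scheme `"W"`, `"R"` or `"E"`.
#' @return A `strata_assignment`: list with `scheme`, per-sample `labels`,
#'   `indication` (low/high/intermediate m6A-indication) and `cutoffs`.
#' @export
single_stratify <- function(sig, scheme = c("W", "R", "E")) {
  scheme <- match.arg(scheme)
  v <- stats::setNames(sig[[scheme]], sig$sample)
  ms <- median_split(v)
  new_strata_assignment(scheme, ms$labels, stats::setNames(ms$cutoff, scheme))
}

#' Double stratification (WE, RE or WR)
#'
#' Cross-classifies two binary signature labels into the four canonical
#' groups, e.g. scheme WE yields `WL_EL`, `WL_EH`, `WH_EL`, `WH_EH`
#' (writer-low-eraser-low etc.).
#'
#' @param a,b Named character vectors of `"low"`/`"high"` labels over the
#'   same sample set, in the scheme's letter order (e.g. W then E for WE).
#' @param scheme `"WE"`, `"RE"` or `"WR"`.
#' @param cutoffs Optional named numeric cutoffs to carry along.
#' @return A `strata_assignment` with four-level labels.
#' @export
double_stratify <- function(a, b, scheme = c("WE", "RE", "WR"), cutoffs = NULL) {
  scheme <- match.arg(scheme)
  if (!setequal(names(a), names(b)) || length(a) != length(b)) {
    diff <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    stop("sample sets differ between the two label vectors: ",
         paste(utils::head(diff, 5), collapse = ", "))
  }
  b <- b[names(a)]
  letters2 <- strsplit(scheme, "")[[1]]
  labels <- paste0(letters2[1], .lh(a), "_", letters2[2], .lh(b))
  names(labels) <- names(a)
  new_strata_assignment(scheme, labels, cutoffs)
}

#' Triple (WRE) stratification
#'
#' Groups samples by how many of the writer and reader signatures are high
#' (0 = double-low `dL`, 1 = single-high `sH`, 2 = double-high `dH`),
#' crossed with the eraser level, giving the six groups `WRdL_EL`,
#' `WRdL_EH`, `WRsH_EL`, `WRsH_EH`, `WRdH_EL`, `WRdH_EH`.
#'
#' @param w,r,e Named character `"low"`/`"high"` label vectors over the same
#'   sample set.
#' @param cutoffs Optional named numeric cutoffs to carry along.
#' @return A `strata_assignment` with six-level labels.
#' @export
triple_stratify <- function(w, r, e, cutoffs = NULL) {
  if (!setequal(names(w), names(r)) || !setequal(names(w), names(e)) ||
      length(unique(c(length(w), length(r), length(e)))) != 1) {
    all_n <- list(names(w), names(r), names(e))
    diff <- unique(unlist(lapply(all_n, function(x) setdiff(unlist(all_n), x))))
    stop("sample sets differ across w/r/e labels: ",
         paste(utils::head(diff, 5), collapse = ", "))
  }
  r <- r[names(w)]; e <- e[names(w)]
  n_high <- (w == "high") + (r == "high")
  wr <- c("dL", "sH", "dH")[n_high + 1]
  labels <- paste0("WR", wr, "_E", .lh(e))
  names(labels) <- names(w)
  new_strata_assignment("WRE", labels, cutoffs)
}

# per-scheme label -> m6A-indication lookup. Low m6A-indication strata are
# those expected to carry little m6A (writers/readers low and/or erasers
# high); high m6A-indication the converse; everything else intermediate.
INDICATION_MAP <- list(
  W   = c(low = "low", high = "high"),
  R   = c(low = "low", high = "high"),
  E   = c(low = "high", high = "low"),
  WE  = c(WL_EL = "intermediate", WL_EH = "low",
          WH_EL = "high", WH_EH = "intermediate"),
  RE  = c(RL_EL = "intermediate", RL_EH = "low",
          RH_EL = "high", RH_EH = "intermediate"),
  WR  = c(WL_RL = "low", WL_RH = "intermediate",
          WH_RL = "intermediate", WH_RH = "high"),
  WRE = c(WRdL_EL = "intermediate", WRdL_EH = "low",
          WRsH_EL = "intermediate", WRsH_EH = "intermediate",
          WRdH_EL = "high", WRdH_EH = "intermediate")
)

#' m6A-indication of a stratum label
#'
#' Maps stratum labels to the m6A-indication classes: `W` low, `R` low,
#' `E` high, `WL_EH`, `RL_EH`, `WL_RL` and `WRdL_EH` are *low*
#' m6A-indications; `W` high, `R` high, `E` low, `WH_EL`, `RH_EL`, `WH_RH`
#' and `WRdH_EL` are *high*; all other composite groups are
#' *intermediate*.
#'
#' @param label Character vector of stratum labels.
#' @param scheme One of `"W"`, `"R"`, `"E"`, `"WE"`, `"RE"`, `"WR"`, `"WRE"`.
#' @return Character vector in `{"low", "high", "intermediate"}`.
#' @export
indication_of <- function(label, scheme) {
  scheme <- match.arg(scheme, SCHEMES)
  map <- INDICATION_MAP[[scheme]]
  unknown <- setdiff(unique(label), names(map))
  if (length(unknown))
    stop("unknown label(s) for scheme ", scheme, ": ",
         paste(unknown, collapse = ", "))
  stats::setNames(unname(map[label]), names(label))
}

#' Stratify a cohort under all seven schemes
#'
#' Computes the median splits of W, R and E once and derives the single
#' (W/R/E), double (WE/RE/WR) and triple (WRE) stratifications from them.
#'
#' @param sig A `signature_table` from [compute_wre()].
#' @param schemes Subset of the seven scheme names to return.
#' @return Named list of `strata_assignment` objects.
#' @export
stratify_all <- function(sig, schemes = SCHEMES) {
  schemes <- match.arg(schemes, SCHEMES, several.ok = TRUE)
  splits <- lapply(c(W = "W", R = "R", E = "E"), function(s)
    median_split(stats::setNames(sig[[s]], sig$sample)))
  cuts <- vapply(splits, `[[`, numeric(1), "cutoff")
  out <- list()
  for (s in schemes) {
    out[[s]] <- switch(s,
      W = , R = , E =
        new_strata_assignment(s, splits[[s]]$labels, cuts[s]),
      WE = double_stratify(splits$W$labels, splits$E$labels, "WE", cuts[c("W", "E")]),
      RE = double_stratify(splits$R$labels, splits$E$labels, "RE", cuts[c("R", "E")]),
      WR = double_stratify(splits$W$labels, splits$R$labels, "WR", cuts[c("W", "R")]),
      WRE = triple_stratify(splits$W$labels, splits$R$labels, splits$E$labels, cuts)
    )
  }
  out
}

#' Write stratification assignments to TSV
#' @param assignments A `strata_assignment` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strata <- function(assignments, path) {
  if (inherits(assignments, "strata_assignment")) assignments <- list(assignments)
  rows <- do.call(rbind, lapply(assignments, function(a)
    data.frame(sample = names(a$labels), scheme = a$scheme,
               label = unname(a$labels), indication = unname(a$indication),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimum-log-rank-P cutoff scan
#'
#' Searches the observed signature values for the threshold that best
#' separates overall survival: every unique value leaving both resulting
#' groups at least `min_group_frac` of the cohort is tried as a cutoff
#' (`high` iff value > cutoff, matching [median_split()]'s tie rule), and
#' the two-group log-rank P is recorded. The full scan curve is returned so
#' alternative selection rules can be applied; note the minimum P is an
#' optimized quantity and should be interpreted (or corrected) accordingly
#' — `p_bonferroni` multiplies it by the number of candidates tried.
#'
#' @param values Named numeric signature vector.
#' @param os_months,os_event Survival time (months) and 0/1 event indicator,
#'   aligned with `values`.
#' @param min_group_frac Minimum fraction of samples in each group
#'   (default 0.1).
#' @return List: `cutoff`, `p_value` (at the selected cutoff),
#'   `p_bonferroni`, `labels`, and `scan` (data.frame `cutoff`, `n_low`,
#'   `n_high`, `p_value`).
#' @export
best_cutoff_scan <- function(values, os_months, os_event, min_group_frac = 0.1) {
  n <- length(values)
  if (n < 20) stop("need >=20 samples with survival data for a cutoff scan")
  if (length(os_months) != n || length(os_event) != n)
    stop("survival vectors must align with the signature vector")
  floor_n <- max(1, ceiling(min_group_frac * n))
  cand <- sort(unique(values))
  ok <- vapply(cand, function(cut) {
    nl <- sum(values <= cut)
    nl >= floor_n && (n - nl) >= floor_n
  }, logical(1))
  cand <- cand[ok]
  if (!length(cand))
    stop("no cutoff leaves both groups >= ", floor_n,
         " samples; lower min_group_frac")
  scan <- do.call(rbind, lapply(cand, function(cut) {
    g <- ifelse(values > cut, "high", "low")
    lr <- logrank(os_months, os_event, g)
    data.frame(cutoff = cut, n_low = sum(g == "low"), n_high = sum(g == "high"),
               p_value = lr$p_value)
  }))
  best <- which.min(scan$p_value)
  labels <- ifelse(values > scan$cutoff[best], "high", "low")
  names(labels) <- names(values)
  list(cutoff = scan$cutoff[best], p_value = scan$p_value[best],
       p_bonferroni = min(1, scan$p_value[best] * nrow(scan)),
       labels = labels, scan = scan)
}
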