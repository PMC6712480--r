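#' Genes mutated above a frequency threshold in both cohorts
#'
#' Keeps genes whose mutated-sample fraction is strictly greater than
#' `threshold` in *both* cohorts (the screen used to reduce a mutation
#' landscape to recurrently mutated genes), sorted lexicographically.
#'
#' @param mut_a,mut_b [mutation_table()]s for the two cohorts.
#' @param threshold Fraction in `[0, 1)`; default 0.01 (1 percent).
#' @return Character vector of gene symbols.
#' @export
filter_genes_by_frequency <- function(mut_a, mut_b, threshold = 0.01) {
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)")
  freq <- function(mut) {
    m <- mut$matrix
    if (nrow(m) == 0) stop("empty cohort")
    colSums(m) / nrow(m)
  }
  fa <- freq(mut_a); fb <- freq(mut_b)
  genes <- intersect(names(fa)[fa > threshold], names(fb)[fb > threshold])
  sort(genes)
}

#' Mutation-frequency fold change, low vs high m6A-indication
#'
#' For each gene and each stratification scheme, computes the smoothed
#' ratio of mutation frequencies between the low- and the high-indication
#' group: `FC = ((m_low + a) / (n_low + 2a)) / ((m_high + a) / (n_high + 2a))`
#' with Haldane-Anscombe smoothing `a = 0.5`, so FC stays finite when one
#' group carries no mutation. Intermediate-indication samples are excluded.
#' FC > 1 means the gene is mutated more often under low m6A-indication.
#'
#' @param mut A [mutation_table()].
#' @param assignments Named list of `strata_assignment`s (see
#'   [stratify_all()]).
#' @param genes Genes to evaluate; defaults to all genes in `mut`.
#' @param alpha Smoothing constant (default 0.5).
#' @return Numeric matrix of class `"foldchange_matrix"`, genes x schemes.
#' @export
foldchange_low_vs_high <- function(mut, assignments, genes = NULL, alpha = 0.5) {
  if (inherits(assignments, "strata_assignment"))
    assignments <- stats::setNames(list(assignments), assignments$scheme)
  if (is.null(genes)) genes <- colnames(mut$matrix)
  genes <- toupper(genes)
  m <- matrix(0L, nrow(mut$matrix), length(genes),
              dimnames = list(rownames(mut$matrix), genes))
  present <- intersect(genes, colnames(mut$matrix))
  m[, present] <- mut$matrix[, present]
  fc <- matrix(NA_real_, length(genes), length(assignments),
               dimnames = list(genes, names(assignments)))
  for (s in names(assignments)) {
    a <- assignments[[s]]
    low <- names(a$labels)[a$indication == "low"]
    high <- names(a$labels)[a$indication == "high"]
    low <- intersect(low, rownames(m)); high <- intersect(high, rownames(m))
    if (!length(low) || !length(high))
      stop("scheme ", s, " has an empty low- or high-indication group")
    f_low <- (colSums(m[low, , drop = FALSE]) + alpha) / (length(low) + 2 * alpha)
    f_high <- (colSums(m[high, , drop = FALSE]) + alpha) / (length(high) + 2 * alpha)
    fc[, s] <- f_low / f_high
  }
  class(fc) <- c("foldchange_matrix", class(fc))
  fc
}

#' Intersect fold-change matrices across two cohorts
#'
#' Calls each (gene, scheme) cell `UP` when FC > 1 in both cohorts (mutation
#' rate upregulated under low m6A-indication), `DN` when FC < 1 in both,
#' `discordant` otherwise. The per-gene consensus is `UP` (`DN`) when at
#' least `consensus_frac` of the schemes are concordantly UP (DN).
#'
#' @param fc_a,fc_b `foldchange_matrix` objects sharing genes and schemes.
#' @param consensus_frac Fraction of schemes required for a consensus call
#'   (default 4/7).
#' @return List: `calls` (character matrix genes x schemes) and `consensus`
#'   (named character vector per gene).
#' @export
cross_cohort_intersect <- function(fc_a, fc_b, consensus_frac = 4 / 7) {
  genes <- intersect(rownames(fc_a), rownames(fc_b))
  if (!length(genes)) stop("fold-change matrices share no genes")
  schemes <- intersect(colnames(fc_a), colnames(fc_b))
  if (!length(schemes)) stop("fold-change matrices share no schemes")
  a <- fc_a[genes, schemes, drop = FALSE]
  b <- fc_b[genes, schemes, drop = FALSE]
  calls <- matrix("discordant", length(genes), length(schemes),
                  dimnames = list(genes, schemes))
  calls[a > 1 & b > 1] <- "UP"
  calls[a < 1 & b < 1] <- "DN"
  need <- consensus_frac * length(schemes)
  consensus <- apply(calls, 1, function(x) {
    if (sum(x == "UP") >= need) "UP"
    else if (sum(x == "DN") >= need) "DN"
    else "discordant"
  })
  list(calls = calls, consensus = consensus)
}

#' Frequency of one exact variant per indication group
#'
#' Fraction of samples in each m6A-indication group (low / high /
#' intermediate, when present) carrying the exact (gene, protein_change)
#' variant. An absent variant yields zero frequencies, not an error.
#'
#' @param mut A [mutation_table()].
#' @param gene Gene symbol.
#' @param protein_change Exact variant string, e.g. `"p.D254Y"`.
#' @param assignment A `strata_assignment`.
#' @return Data frame: `group`, `n`, `carriers`, `frequency`.
#' @export
variant_frequency <- function(mut, gene, protein_change, assignment) {
  carriers <- variant_carriers(mut, gene, protein_change)
  ind <- assignment$indication
  groups <- intersect(c("low", "high", "intermediate"), unique(ind))
  do.call(rbind, lapply(groups, function(g) {
    s <- names(ind)[ind == g]
    k <- sum(s %in% carriers)
    data.frame(group = g, n = length(s), carriers = k,
               frequency = if (length(s)) k / length(s) else 0,
               stringsAsFactors = FALSE)
  }))
}

check_margins <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin; test undefined")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table entries must be nonnegative integers")
}

new_contingency_result <- function(variable, table, test, statistic, p,
                                   low_expected = FALSE) {
  structure(list(variable = variable, table = table, test = test,
                 statistic = statistic, p_value = p,
                 low_expected = low_expected),
            class = "contingency_result")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric point
#' probabilities of all tables no more probable than the observed one (the
#' sum-of-small-P convention, with a relative tolerance for ties).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param variable Label carried into the result.
#' @return A `contingency_result`: `variable`, `table`, `test`,
#'   `statistic` (`NA`, exact test), `p_value`.
#' @examples
#' fisher_exact_2x2(matrix(c(7, 3, 8, 6), 2))$p_value  # 0.6785
#' @export
fisher_exact_2x2 <- function(table, variable = "2x2") {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  check_margins(table)
  p <- stats::fisher.test(table)$p.value
  new_contingency_result(variable, table, "fisher_2x2", NA_real_, min(1, p))
}

#' Pearson chi-square test for an r x c table
#'
#' Without continuity correction; degrees of freedom (r-1)(c-1). When any
#' expected count is below 5 the result carries a `low_expected` flag (the
#' asymptotic P may be unreliable; consider [exact_mc()]).
#'
#' @param table r x c matrix of nonnegative integer counts (r, c >= 2).
#' @param variable Label carried into the result.
#' @return A `contingency_result` with `statistic` and `p_value`.
#' @export
chi_square <- function(table, variable = "rxc") {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("need an r x c table, r,c >= 2")
  check_margins(table)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_contingency_result(variable, table, "chi_square",
                         unname(ct$statistic), ct$p.value,
                         low_expected = any(ct$expected < 5))
}

#' Monte-Carlo exact test for an r x c table
#'
#' Estimates the exact conditional P by sampling margin-preserving random
#' tables and counting those with point probability no larger than the
#' observed table's (the r x c generalization of the two-sided Fisher
#' convention). Reproducible given `seed`.
#'
#' @param table r x c matrix of nonnegative integer counts.
#' @param n_draws Number of Monte-Carlo tables (>= 1000).
#' @param seed Integer seed.
#' @param variable Label carried into the result.
#' @return A `contingency_result` (statistic `NA`).
#' @export
exact_mc <- function(table, n_draws = 10000, seed = 1, variable = "rxc") {
  table <- as.matrix(table)
  if (n_draws < 1000) stop("n_draws must be >= 1000")
  check_margins(table)
  p <- with_seed(seed, stats::fisher.test(table, simulate.p.value = TRUE,
                                          B = n_draws)$p.value)
  new_contingency_result(variable, table, "exact_mc", NA_real_, p)
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(x$variable, " [", x$test, "] P = ", format(x$p_value, digits = 4),
      if (isTRUE(x$low_expected)) "  (expected count < 5)", "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Clinical-index association with the m6A-indication dichotomy
#'
#' For each clinical variable, builds the observed low- vs high-indication
#' contingency table (rows = variable categories, columns = indication
#' groups; `"n/a"` rows excluded per variable, not per sample; age
#' dichotomized at 60 years into `<=60` / `>60`), then dispatches a
#' two-sided Fisher exact test for 2x2 tables and a chi-square test
#' otherwise. When a larger table has an expected count below 5 and
#' `use_exact_mc` is set, the Monte-Carlo exact test is used instead.
#'
#' @param clinical A [clinical_table()].
#' @param assignment A `strata_assignment` with nonempty low and high
#'   indication groups.
#' @param variables Variables to test; default all categorical indexes
#'   present plus dichotomized age.
#' @param use_exact_mc Replace low-expected-count chi-square by [exact_mc()].
#' @param seed Seed for [exact_mc()].
#' @return Named list of `contingency_result`, one per variable.
#' @export
clinical_association <- function(clinical, assignment, variables = NULL,
                                 use_exact_mc = FALSE, seed = 1) {
  ind <- assignment$indication
  groups <- list(low = names(ind)[ind == "low"],
                 high = names(ind)[ind == "high"])
  if (!length(groups$low) || !length(groups$high))
    stop("assignment lacks a nonempty low or high indication group")
  if (is.null(variables)) {
    variables <- intersect(c("gender", "age", "lauren", "t_stage", "n_stage",
                             "m_stage", "stage", "msi", "ebv"),
                           c(names(clinical), "age"))
    if (!"age_years" %in% names(clinical)) variables <- setdiff(variables, "age")
  }
  value_of <- function(var, samples) {
    idx <- match(samples, clinical$sample)
    if (var == "age") {
      if (!"age_years" %in% names(clinical)) stop("variable absent: age_years")
      age <- clinical$age_years[idx]
      ifelse(is.na(age), NA_TOKEN, ifelse(age <= 60, "<=60", ">60"))
    } else {
      if (!var %in% names(clinical)) stop("variable absent: ", var)
      as.character(clinical[[var]][idx])
    }
  }
  out <- list()
  for (var in variables) {
    vals <- lapply(groups, function(s) value_of(var, s))
    lev <- if (var == "age") c("<=60", ">60") else CLINICAL_LEVELS[[var]]
    counts <- vapply(vals, function(v) table(factor(v[v != NA_TOKEN & !is.na(v)],
                                                    levels = lev)),
                     numeric(length(lev)))
    if (any(colSums(counts) == 0))
      stop("variable '", var, "' is all-missing in the ",
           names(groups)[colSums(counts) == 0][1], "-indication group")
    tab <- counts[rowSums(counts) > 0, , drop = FALSE]
    res <- if (nrow(tab) < 2) {
      new_contingency_result(var, tab, "degenerate", NA_real_, NA_real_)
    } else if (nrow(tab) == 2 && ncol(tab) == 2) {
      fisher_exact_2x2(tab, variable = var)
    } else {
      cs <- chi_square(tab, variable = var)
      if (use_exact_mc && cs$low_expected)
        exact_mc(tab, seed = seed, variable = var)
      else cs
    }
    out[[var]] <- res
  }
  out
}

#' Welch two-sample comparison of group means
#'
#' Welch (unequal variance) two-sided t-test of a numeric per-sample
#' quantity (e.g. TMB or per-sample mutation count) between two groups.
#'
#' @param values Numeric vector.
#' @param labels Two-level grouping vector aligned with `values`.
#' @return List: `t`, `df`, `p_value`, `mean_diff` (first level minus
#'   second, levels sorted), `n` (per group).
#' @export
group_mean_compare <- function(values, labels) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("need exactly 2 groups, got ", length(lev))
  x <- values[labels == lev[1]]; y <- values[labels == lev[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("need >=2 non-missing values per group")
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(x) - mean(y),
       n = stats::setNames(c(length(x), length(y)), lev))
}

#' Write contingency results to TSV
#'
#' One row per result, the observed table serialized alongside the P value
#' as `r1c1,r1c2,...;r2c1,...`.
#'
#' @param results List of `contingency_result` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contingency <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r)
    data.frame(variable = r$variable, test = r$test,
               statistic = r$statistic, p_value = r$p_value,
               low_expected = isTRUE(r$low_expected),
               table = paste(apply(r$table, 1, paste, collapse = ","),
                             collapse = ";"),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
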