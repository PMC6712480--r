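# row-wise means/SDs split by a logical column mask; returns list(m1,m0,s1,s0)
.group_moments <- function(x, is_high) {
  n1 <- sum(is_high); n0 <- sum(!is_high)
  x1 <- x[, is_high, drop = FALSE]; x0 <- x[, !is_high, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  list(m1 = m1, m0 = m0, s1 = sqrt(v1), s0 = sqrt(v0), n1 = n1, n0 = n0)
}

#' Per-gene differential expression between two strata
#'
#' Welch two-sided t-test of every gene between the high and the low group
#' (difference reported as high minus low). Genes constant in both groups
#' yield an `NA` statistic with a `degenerate` flag rather than an error.
#'
#' @param expr An [expression_matrix()].
#' @param labels Named `"low"`/`"high"` vector over the samples of `expr`.
#' @param p_threshold DEG flag threshold on the two-sided P (default 0.05).
#' @return Data frame: `gene`, `mean_diff`, `t`, `df`, `p_value`, `deg`
#'   (logical), `degenerate`.
#' @export
diff_expr <- function(expr, labels, p_threshold = 0.05) {
  labels <- labels[colnames(expr)]
  if (any(is.na(labels))) stop("labels must cover every sample in expr")
  is_high <- labels == "high"
  if (sum(is_high) < 2 || sum(!is_high) < 2)
    stop("need >=2 samples per group")
  g <- .group_moments(unclass(expr), is_high)
  se2 <- g$s1^2 / g$n1 + g$s0^2 / g$n0
  t_stat <- (g$m1 - g$m0) / sqrt(se2)
  df <- se2^2 / ((g$s1^2 / g$n1)^2 / (g$n1 - 1) + (g$s0^2 / g$n0)^2 / (g$n0 - 1))
  degenerate <- se2 == 0
  t_stat[degenerate] <- NA_real_
  p <- 2 * stats::pt(-abs(t_stat), df)
  data.frame(gene = rownames(expr), mean_diff = g$m1 - g$m0, t = t_stat,
             df = df, p_value = p,
             deg = !degenerate & p < p_threshold, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Three-set Venn region counts
#'
#' Counts the seven intersection regions of three gene sets (e.g. the DEG
#' sets of the W, R and E stratifications). Region counts sum to the size
#' of the union.
#'
#' @param set_w,set_r,set_e Character vectors.
#' @param names Labels for the three sets.
#' @return Named integer vector over the regions `W_only`, `R_only`,
#'   `E_only`, `W_R`, `W_E`, `R_E`, `W_R_E` (with `names` substituted).
#' @export
venn_counts <- function(set_w, set_r, set_e, names = c("W", "R", "E")) {
  u <- unique(c(set_w, set_r, set_e))
  inw <- u %in% set_w; inr <- u %in% set_r; ine <- u %in% set_e
  key <- inw + 2 * inr + 4 * ine
  reg <- c(paste0(names[1], "_only"), paste0(names[2], "_only"),
           paste0(names[1], "_", names[2]), paste0(names[3], "_only"),
           paste0(names[1], "_", names[3]), paste0(names[2], "_", names[3]),
           paste0(names[1], "_", names[2], "_", names[3]))
  counts <- vapply(1:7, function(k) sum(key == k), integer(1))
  stats::setNames(counts, reg)
}

# signal-to-noise ratio with the classic SD floor: each group SD is raised
# to at least 0.2 * |group mean| (and to 0.2 when the mean is 0)
.s2n <- function(x, is_high) {
  g <- .group_moments(x, is_high)
  floor_sd <- function(s, m) pmax(s, ifelse(m == 0, 0.2, 0.2 * abs(m)))
  (g$m1 - g$m0) / (floor_sd(g$s1, g$m1) + floor_sd(g$s0, g$m0))
}

#' Rank genes for enrichment analysis
#'
#' Orders all genes by a differential metric between the high and low
#' group, descending: signal-to-noise ratio (default; group SDs floored at
#' 0.2 x |group mean| to avoid division blow-ups) or the Welch t statistic.
#' Ties are broken lexicographically by gene symbol so the ranking is
#' deterministic.
#'
#' @param expr An [expression_matrix()].
#' @param labels Named `"low"`/`"high"` vector over the samples of `expr`.
#' @param metric `"s2n"` or `"t"`.
#' @return Named numeric vector of scores, sorted descending, names = genes.
#' @export
rank_genes <- function(expr, labels, metric = c("s2n", "t")) {
  metric <- match.arg(metric)
  labels <- labels[colnames(expr)]
  if (any(is.na(labels))) stop("labels must cover every sample in expr")
  is_high <- labels == "high"
  if (sum(is_high) < 3 || sum(!is_high) < 3)
    stop("need >=3 samples per group")
  x <- unclass(expr)
  scores <- if (metric == "s2n") .s2n(x, is_high) else {
    d <- diff_expr(expr, labels)
    stats::setNames(ifelse(is.na(d$t), 0, d$t), d$gene)
  }
  names(scores) <- rownames(x)
  scores[order(-scores, names(scores))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running-sum statistic over a ranked gene list: at each hit
#' (gene in the set) the sum increases by `|score|^p` normalized over the
#' hits, at each miss it decreases by `1 / (N - Nh)`; the enrichment score
#' ES is the maximum-magnitude deviation of the running sum from zero.
#' `p = 1` (default) weights hits by their scores; `p = 0` reduces to the
#' standard KS statistic.
#'
#' @param scores Named numeric vector sorted in ranking order (as from
#'   [rank_genes()]).
#' @param gene_set Character vector; must intersect the ranked list.
#' @param p Weighting exponent (default 1).
#' @param profile If `TRUE`, also return the full running-sum profile.
#' @return List: `es`, `peak` (rank position of the extreme), `hits`
#'   (positions of set members), and if requested `profile` (length-N
#'   running sum).
#' @export
enrichment_score <- function(scores, gene_set, p = 1, profile = FALSE) {
  n <- length(scores)
  hits <- which(names(scores) %in% toupper(gene_set))
  if (!length(hits))
    stop("gene set has no overlap with the ranked list")
  nh <- length(hits)
  w <- abs(scores[hits])^p
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else rep(1 / nh, nh)
  miss_dec <- if (n > nh) 1 / (n - nh) else 0
  # running sum evaluated only at hit positions: value just before the i-th
  # hit is cum_inc[i-1] - miss_dec * (misses so far); just after, add inc[i]
  cum_inc <- cumsum(inc)
  misses_before <- hits - seq_len(nh)
  at_hit <- cum_inc - miss_dec * misses_before
  before_hit <- c(0, cum_inc[-nh]) - miss_dec * misses_before
  hi <- max(at_hit); lo <- min(before_hit)
  es <- if (hi >= -lo) hi else lo
  peak <- if (hi >= -lo) hits[which.max(at_hit)] else hits[which.min(before_hit)] - 1L
  out <- list(es = unname(es), peak = as.integer(peak), hits = hits)
  if (profile) {
    step <- rep(-miss_dec, n)
    step[hits] <- inc
    out$profile <- cumsum(step)
  }
  out
}

#' Leading-edge genes of an enrichment result
#' @param scores Ranked scores (as passed to [enrichment_score()]).
#' @param es_result Result of [enrichment_score()].
#' @return Character vector of set genes at or before the ES peak (after it
#'   for negative ES).
#' @export
leading_edge <- function(scores, es_result) {
  h <- es_result$hits
  if (es_result$es >= 0) names(scores)[h[h <= es_result$peak]]
  else names(scores)[h[h > es_result$peak]]
}

#' Gene set enrichment analysis with phenotype permutation
#'
#' Categorical (two-phenotype) GSEA: genes are ranked by the
#' signal-to-noise ratio between the high and low group, each set's
#' weighted-KS enrichment score is computed, and significance is assessed
#' by permuting the phenotype labels and re-ranking. For each set,
#' `NES = ES / mean(|permuted ES| of the same sign)`, the nominal P is the
#' fraction of same-sign permuted ES at least as extreme as the observed
#' one, and the FDR q pools signed NES values across all sets in the
#' original method's fashion. Fully reproducible given `seed`.
#'
#' @param expr An [expression_matrix()].
#' @param labels Named `"low"`/`"high"` vector over the samples of `expr`.
#' @param gene_sets Named list of gene symbol vectors (see [read_gmt()]);
#'   sets with no overlap with `expr` are dropped with a warning.
#' @param n_perm Number of label permutations (>= 100; 1000 typical).
#' @param seed Integer seed.
#' @param p Hit-weighting exponent (default 1).
#' @param metric Ranking metric, see [rank_genes()].
#' @return Data frame of class `"enrichment_result"`: `set`, `size`
#'   (overlap with `expr`), `es`, `nes`, `p_value`, `fdr`, `leading_edge`
#'   (comma-separated), `n_perm`.
#' @export
gsea <- function(expr, labels, gene_sets, n_perm = 1000, seed = 1, p = 1,
                 metric = c("s2n", "t")) {
  metric <- match.arg(metric)
  if (n_perm < 100) stop("n_perm must be >= 100")
  labels <- labels[colnames(expr)]
  if (any(is.na(labels))) stop("labels must cover every sample in expr")
  if (sum(labels == "high") < 3 || sum(labels == "low") < 3)
    stop("need >=3 samples per group to permute meaningfully")
  keep <- vapply(gene_sets, function(s) any(toupper(s) %in% rownames(expr)),
                 logical(1))
  if (!all(keep)) {
    warning("dropping set(s) with no overlap: ",
            paste(names(gene_sets)[!keep], collapse = ", "))
    gene_sets <- gene_sets[keep]
  }
  if (!length(gene_sets)) stop("no gene set overlaps the expression matrix")

  obs_scores <- rank_genes(expr, labels, metric)
  obs_es <- vapply(gene_sets, function(s)
    enrichment_score(obs_scores, s, p)$es, numeric(1))

  n_high <- sum(labels == "high")
  samples <- colnames(expr)
  perm_es <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(i) {
      pl <- stats::setNames(rep("low", length(samples)), samples)
      pl[sample(samples, n_high)] <- "high"
      ps <- rank_genes(expr, pl, metric)
      vapply(gene_sets, function(s) enrichment_score(ps, s, p)$es, numeric(1))
    }, numeric(length(gene_sets)))
  })
  perm_es <- matrix(perm_es, nrow = length(gene_sets))

  nes <- p_nom <- numeric(length(gene_sets))
  perm_nes <- perm_es
  for (i in seq_along(gene_sets)) {
    pe <- perm_es[i, ]
    pos <- pe[pe >= 0]; neg <- pe[pe < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    perm_nes[i, ] <- ifelse(pe >= 0, pe / mpos, pe / mneg)
    if (obs_es[i] >= 0) {
      nes[i] <- if (is.na(mpos)) NA_real_ else obs_es[i] / mpos
      p_nom[i] <- if (length(pos)) mean(pos >= obs_es[i]) else 0
    } else {
      nes[i] <- if (is.na(mneg)) NA_real_ else obs_es[i] / mneg
      p_nom[i] <- if (length(neg)) mean(neg <= obs_es[i]) else 0
    }
  }
  all_perm_nes <- perm_nes[is.finite(perm_nes)]
  fdr <- vapply(seq_along(gene_sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num_all <- mean(all_perm_nes >= 0)
      num <- if (num_all > 0) mean(all_perm_nes[all_perm_nes >= 0] >= nes[i]) else 0
      den_set <- nes[!is.na(nes) & nes >= 0]
      den <- mean(den_set >= nes[i])
    } else {
      num_all <- mean(all_perm_nes < 0)
      num <- if (num_all > 0) mean(all_perm_nes[all_perm_nes < 0] <= nes[i]) else 0
      den_set <- nes[!is.na(nes) & nes < 0]
      den <- mean(den_set <= nes[i])
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  le <- vapply(seq_along(gene_sets), function(i) {
    esr <- enrichment_score(obs_scores, gene_sets[[i]], p)
    paste(leading_edge(obs_scores, esr), collapse = ",")
  }, character(1))
  size <- vapply(gene_sets, function(s)
    sum(toupper(s) %in% rownames(expr)), integer(1))

  out <- data.frame(set = names(gene_sets), size = size, es = obs_es,
                    nes = nes, p_value = p_nom, fdr = fdr,
                    leading_edge = le, n_perm = n_perm,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write enrichment results to TSV
#' @param res An `enrichment_result` from [gsea()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
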