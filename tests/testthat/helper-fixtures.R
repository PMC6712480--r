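# shared fixture builders; all fixtures are generated in code

# minimal expression matrix containing the seven regulators plus extras
toy_expression <- function(n_samples = 6, extra_genes = 3, seed = 42) {
  genes <- c(unlist(m6a_regulators(), use.names = FALSE),
             if (extra_genes > 0) sprintf("G%03d", seq_len(extra_genes)))
  m <- with_seed(seed, matrix(stats::rlnorm(length(genes) * n_samples, 3, 0.4),
                              nrow = length(genes),
                              dimnames = list(genes, sprintf("S%02d", seq_len(n_samples)))))
  expression_matrix(m)
}

toy_clinical <- function(n = 6, seed = 42) {
  with_seed(seed, clinical_table(data.frame(
    sample = sprintf("S%02d", seq_len(n)),
    os_months = round(stats::rexp(n, 1 / 24), 1),
    os_event = stats::rbinom(n, 1, 0.7),
    gender = sample(c("Male", "Female"), n, replace = TRUE),
    age_years = sample(40:80, n, replace = TRUE),
    stringsAsFactors = FALSE)))
}

# two-group expression dataset with optional mean-shifted (spiked) genes
spiked_expr <- function(n_genes = 60, n_per_group = 20, spiked = character(),
                        shift = 2, seed = 1) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(2 * n_per_group))
  labels <- stats::setNames(rep(c("low", "high"), each = n_per_group), samples)
  m <- with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * 2 * n_per_group, 8), n_genes,
                dimnames = list(genes, samples))
    x[spiked, labels == "high"] <- x[spiked, labels == "high"] + shift
    x - min(x) + 0.01  # keep nonnegative
  })
  list(expr = expression_matrix(m), labels = labels)
}

# named low/high label vector
lh_labels <- function(x, samples = names(x)) {
  stats::setNames(ifelse(x, "high", "low"), samples)
}

# independent O/E/V log-rank oracle for two groups (aggregated ties)
logrank_oracle_2g <- function(time, event, group) {
  lev <- sort(unique(group))
  stopifnot(length(lev) == 2)
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & group == lev[1])
    d_t <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == lev[1])
    o_minus_e <- o_minus_e + d1 - d_t * n1 / n_t
    if (n_t > 1)
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# enumeration oracle for the two-sided Fisher 2x2 P (sum of point probs
# no larger than the observed, computed from factorials directly)
fisher_oracle_2x2 <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p_obs <- logp[ks == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# step-by-step weighted-KS running-sum oracle
es_oracle <- function(scores, gene_set, p = 1) {
  hit <- names(scores) %in% toupper(gene_set)
  nh <- sum(hit); n <- length(scores)
  w <- abs(scores)^p
  run <- numeric(n); cur <- 0
  sw <- sum(w[hit])
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) w[i] / sw else -1 / (n - nh)
    run[i] <- cur
  }
  run[which.max(abs(run))]
}
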