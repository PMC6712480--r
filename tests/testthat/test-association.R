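make_mut <- function(freqs, n, prefix = "S", seed = 1) {
  with_seed(seed, {
    samples <- sprintf("%s%03d", prefix, seq_len(n))
    recs <- do.call(rbind, lapply(names(freqs), function(g) {
      hit <- stats::rbinom(n, 1, freqs[[g]]) == 1
      if (!any(hit)) return(NULL)
      data.frame(sample = samples[hit], gene = g,
                 protein_change = sprintf("p.X%dY", which(hit)))
    }))
    mutation_table(if (is.null(recs))
      data.frame(sample = character(), gene = character(),
                 protein_change = character()) else recs, samples = samples)
  })
}

test_that("frequency filter keeps genes above threshold in both cohorts", {
  a <- mutation_table(data.frame(sample = c("A1", "A2"), gene = c("CDH1", "CDH1"),
                                 protein_change = ""), samples = sprintf("A%d", 1:78))
  b <- mutation_table(data.frame(sample = sprintf("B%d", 1:5), gene = "CDH1",
                                 protein_change = ""), samples = sprintf("B%d", 1:289))
  expect_identical(filter_genes_by_frequency(a, b, 0.01), "CDH1")  # 2/78 & 5/289

  b1 <- mutation_table(data.frame(sample = "B1", gene = "CDH1", protein_change = ""),
                       samples = sprintf("B%d", 1:289))
  expect_identical(filter_genes_by_frequency(a, b1, 0.01), character(0))  # 1/289 fails
  expect_error(filter_genes_by_frequency(a, b, 1.5), "threshold")
})

test_that("frequency filter equals a brute-force recount on random cohorts", {
  fa <- c(G1 = 0.05, G2 = 0.008, G3 = 0.2, G4 = 0.015)
  fb <- c(G1 = 0.03, G2 = 0.05, G3 = 0.004, G4 = 0.02)
  a <- make_mut(fa, 150, "A", seed = 2); b <- make_mut(fb, 200, "B", seed = 3)
  got <- filter_genes_by_frequency(a, b, 0.01)
  brute <- sort(Reduce(intersect, lapply(list(a, b), function(m) {
    cnt <- vapply(colnames(m$matrix), function(g)
      length(unique(m$records$sample[m$records$gene == g])), integer(1))
    names(cnt)[cnt / nrow(m$matrix) > 0.01]
  })))
  expect_identical(got, brute)
})

test_that("smoothed fold change matches the plug-in formula", {
  labels <- lh_labels(rep(c(TRUE, FALSE), each = 10), sprintf("S%03d", 1:20))
  assign <- list(W = m6Asig:::new_strata_assignment("W", labels, NULL))
  # gene mutated in 5/10 low (here: label 'low' = W-low = low indication)
  recs <- data.frame(sample = c(sprintf("S%03d", 11:15), "S001"),
                     gene = "CDH1", protein_change = "")
  mut <- mutation_table(recs, samples = sprintf("S%03d", 1:20))
  fc <- foldchange_low_vs_high(mut, assign)
  expect_equal(unname(fc["CDH1", "W"]), (5.5 / 11) / (1.5 / 11), tolerance = 1e-12)

  # identical frequencies in both groups -> FC exactly 1
  recs2 <- data.frame(sample = c("S001", "S011"), gene = "TP53", protein_change = "")
  mut2 <- mutation_table(recs2, samples = sprintf("S%03d", 1:20))
  fc2 <- foldchange_low_vs_high(mut2, assign)
  expect_equal(unname(fc2["TP53", "W"]), 1)
  expect_true(all(fc2 > 0))
})

test_that("cross-cohort intersection applies the UP/DN truth table and consensus", {
  fc_a <- matrix(c(1.5, 1.5, 0.5), 3, 1, dimnames = list(c("G1", "G2", "G3"), "W"))
  fc_b <- matrix(c(2.0, 0.8, 0.7), 3, 1, dimnames = list(c("G1", "G2", "G3"), "W"))
  class(fc_a) <- class(fc_b) <- c("foldchange_matrix", "matrix")
  cc <- cross_cohort_intersect(fc_a, fc_b, consensus_frac = 1)
  expect_identical(unname(cc$calls[, "W"]), c("UP", "discordant", "DN"))
  expect_identical(unname(cc$consensus), c("UP", "discordant", "DN"))

  # randomized matrices vs an exhaustive truth-table oracle
  schemes <- c("W", "R", "E")
  a <- with_seed(9, matrix(stats::runif(30, 0.3, 3), 10, 3,
                           dimnames = list(sprintf("G%d", 1:10), schemes)))
  b <- with_seed(10, matrix(stats::runif(30, 0.3, 3), 10, 3,
                            dimnames = list(sprintf("G%d", 1:10), schemes)))
  cc2 <- cross_cohort_intersect(a, b, consensus_frac = 2 / 3)
  for (g in rownames(a)) for (s in schemes) {
    want <- if (a[g, s] > 1 && b[g, s] > 1) "UP"
            else if (a[g, s] < 1 && b[g, s] < 1) "DN" else "discordant"
    expect_identical(cc2$calls[g, s], want)
  }
  expect_error(cross_cohort_intersect(a, b[, character(0), drop = FALSE]),
               "scheme")
})

test_that("spiked drivers show FC > 1 across most schemes in the generator", {
  ok <- vapply(1:30, function(s) {
    co <- generate_cohort(simulation_params(n_samples = 600, seed = 400 + s,
                                            n_background_genes = 0,
                                            n_passenger_genes = 0))
    strata <- stratify_all(compute_wre(co$expression))
    fc <- foldchange_low_vs_high(co$mutations, strata, genes = "CDH1")
    sum(fc["CDH1", ] > 1) >= 6
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("variant frequencies match a brute-force recount", {
  labels <- lh_labels(rep(c(FALSE, TRUE), 10), sprintf("S%03d", 1:20))
  assign <- m6Asig:::new_strata_assignment("W", labels, NULL)
  carriers <- sprintf("S%03d", c(1, 3, 5, 2))
  recs <- data.frame(sample = carriers, gene = "CDH1",
                     protein_change = c(rep("p.D254Y", 3), "p.A5T"))
  mut <- mutation_table(recs, samples = sprintf("S%03d", 1:20))
  vf <- variant_frequency(mut, "CDH1", "p.D254Y", assign)
  low <- names(labels)[assign$indication == "low"]
  expect_equal(vf$frequency[vf$group == "low"],
               sum(sprintf("S%03d", c(1, 3, 5)) %in% low) / length(low))
  # absent variant -> all-zero frequencies
  vf0 <- variant_frequency(mut, "CDH1", "p.Q999*", assign)
  expect_true(all(vf0$frequency == 0))
})

test_that("Fisher exact reproduces the published clinical-index P values", {
  expect_equal(round(fisher_exact_2x2(matrix(c(7, 3, 8, 6), 2))$p_value, 4), 0.6785)
  expect_equal(round(fisher_exact_2x2(matrix(c(11, 18, 4, 26), 2))$p_value, 4), 0.0391)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("Fisher exact equals the enumeration oracle and is transposition-invariant", {
  tabs <- with_seed(12, replicate(50, matrix(stats::rpois(4, 6) + 1, 2), simplify = FALSE))
  for (tab in tabs) {
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_oracle_2x2(tab), tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(t(tab))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p_value, p, tolerance = 1e-12)
  }
})

test_that("chi-square matches the closed 2x2 formula and a summation oracle", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  got <- chi_square(tab)
  n <- sum(tab)
  closed <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  expect_equal(got$statistic, closed, tolerance = 1e-10)

  # observed == expected -> statistic 0, P 1
  even <- matrix(c(10, 10, 20, 20), 2)
  expect_equal(chi_square(even)$statistic, 0, tolerance = 1e-12)
  expect_equal(chi_square(even)$p_value, 1)

  # 3x2 vs independent summation oracle
  t32 <- with_seed(13, matrix(stats::rpois(6, 15) + 5, 3, 2))
  got32 <- chi_square(t32)
  expected <- outer(rowSums(t32), colSums(t32)) / sum(t32)
  expect_equal(got32$statistic, sum((t32 - expected)^2 / expected),
               tolerance = 1e-10)
  expect_identical(got32$low_expected, any(expected < 5))
})

test_that("Monte-Carlo exact test is seeded-reproducible and agrees with Fisher", {
  tab <- matrix(c(8, 3, 4, 9), 2)
  p1 <- exact_mc(tab, n_draws = 20000, seed = 7)$p_value
  p2 <- exact_mc(tab, n_draws = 20000, seed = 7)$p_value
  expect_identical(p1, p2)
  exact <- fisher_exact_2x2(tab)$p_value
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(p1 - exact), 3 * se + 1e-4)
  # table equal to expectation -> P near 1
  expect_gt(exact_mc(matrix(c(10, 10, 10, 10), 2), seed = 1)$p_value, 0.9)
  expect_error(exact_mc(tab, n_draws = 10), "1000")
})

test_that("clinical association rebuilds the published tables and dispatches tests", {
  # cohort whose WRE corners carry exactly the printed age/M-status counts
  n_low <- 29; n_high <- 30
  samples <- sprintf("P%03d", 1:(n_low + n_high))
  labels <- stats::setNames(rep(c("WRdL_EH", "WRdH_EL"), c(n_low, n_high)), samples)
  assign <- m6Asig:::new_strata_assignment("WRE", labels, NULL)
  clin <- clinical_table(data.frame(
    sample = samples,
    os_months = 10, os_event = 0,
    age_years = c(rep(50, 11), rep(70, 18), rep(50, 4), rep(70, 26)),
    m_stage = c(rep("m0", 27), rep("m1", 2), rep("m0", 26), rep("m1", 2),
                rep("n/a", 2)),
    lauren = c(rep(c("Diffuse", "Intestinal", "Others"), c(13, 13, 3)),
               rep(c("Diffuse", "Intestinal", "Others"), c(2, 26, 2))),
    stringsAsFactors = FALSE))
  res <- clinical_association(clin, assign, variables = c("age", "m_stage", "lauren"))
  expect_equal(round(res$age$p_value, 4), 0.0391)
  expect_equal(round(res$m_stage$p_value, 4), 1.0000)
  expect_identical(res$age$test, "fisher_2x2")
  expect_identical(res$lauren$test, "chi_square")  # 3x2 falls through to chi-square
  expect_identical(dim(res$lauren$table), c(3L, 2L))

  # n/a excluded per variable: M-status table keeps 27/2 vs 26/2
  expect_equal(unname(res$m_stage$table), matrix(c(27, 2, 26, 2), 2))

  # a variable that is all-missing in one group errors
  clin2 <- clin; clin2$lauren[labels == "WRdL_EH"] <- "n/a"
  expect_error(clinical_association(clin2, assign, variables = "lauren"),
               "all-missing")
})

test_that("Welch comparison matches the hand formula and detects shifts", {
  x <- c(1.1, 2.3, 3.1, 4.7); y <- c(2.0, 2.2, 2.9)
  got <- group_mean_compare(c(x, y), rep(c("a", "b"), c(4, 3)))
  vx <- stats::var(x) / 4; vy <- stats::var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 3 + vy^2 / 2)
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_equal(got$df, df_hand, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_hand), df_hand), tolerance = 1e-10)

  # identical groups -> t 0, P 1
  same <- group_mean_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # N(0,1) vs N(1,1) at n = 100 is nearly always detected
  hits <- vapply(1:100, function(s) with_seed(s, {
    group_mean_compare(c(stats::rnorm(100), stats::rnorm(100, 1)),
                       rep(c("a", "b"), each = 100))$p_value < 0.001
  }), logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(group_mean_compare(1:3, c("a", "b", "b")), ">=2")
})

test_that("generator reproduces the diffuse-excess direction in low-indication strata", {
  co <- generate_cohort(simulation_params(n_samples = 600, seed = 77,
                                          n_background_genes = 0))
  strata <- stratify_all(compute_wre(co$expression))
  res <- clinical_association(co$clinical, strata$WRE, variables = "lauren")
  tab <- res$lauren$table
  expect_gt(tab["Diffuse", "low"] / sum(tab[, "low"]),
            tab["Diffuse", "high"] / sum(tab[, "high"]))
})
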