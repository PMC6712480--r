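test_that("median split labels and tie rule follow the printed convention", {
  ms <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(ms$cutoff, 2.5)
  expect_identical(unname(ms$labels), c("low", "low", "high", "high"))

  # tie at the median goes low
  ms2 <- median_split(c(a = 1, b = 2, c = 2, d = 3))
  expect_equal(ms2$cutoff, 2)
  expect_identical(unname(ms2$labels), c("low", "low", "low", "high"))

  # odd n with distinct values: exactly (n-1)/2 high
  v <- with_seed(5, stats::setNames(sample(1000, 101), sprintf("s%d", 1:101)))
  expect_identical(sum(median_split(v)$labels == "high"), 50L)

  expect_error(median_split(c(a = 1, b = 1)), "identical")
})

test_that("double stratification crosses labels canonically and partitions the cohort", {
  a <- lh_labels(c(s1 = TRUE, s2 = TRUE, s3 = FALSE, s4 = FALSE))
  b <- lh_labels(c(s1 = FALSE, s2 = TRUE, s3 = FALSE, s4 = TRUE))
  we <- double_stratify(a, b, "WE")
  expect_identical(unname(we$labels),
                   c("WH_EL", "WH_EH", "WL_EL", "WL_EH"))
  expect_identical(we$indication[["s1"]], "high")  # W high, E low
  expect_identical(we$indication[["s4"]], "low")

  # group sizes sum to n for random labels
  big <- with_seed(8, list(a = lh_labels(stats::runif(200) > 0.5,
                                         sprintf("p%d", 1:200)),
                           b = lh_labels(stats::runif(200) > 0.5,
                                         sprintf("p%d", 1:200))))
  wr <- double_stratify(big$a, big$b, "WR")
  expect_identical(sum(table(wr$labels)), 200L)

  expect_error(double_stratify(a, b[1:3], "WE"), "sample sets differ")
})

test_that("triple stratification matches the 8-row truth table", {
  combos <- expand.grid(w = c("low", "high"), r = c("low", "high"),
                        e = c("low", "high"), stringsAsFactors = FALSE)
  samples <- sprintf("c%d", 1:8)
  tr <- triple_stratify(stats::setNames(combos$w, samples),
                        stats::setNames(combos$r, samples),
                        stats::setNames(combos$e, samples))
  # brute-force oracle over the 8 corners
  oracle <- apply(combos, 1, function(row) {
    nh <- sum(row[c("w", "r")] == "high")
    paste0("WR", c("dL", "sH", "dH")[nh + 1], "_E",
           ifelse(row["e"] == "high", "H", "L"))
  })
  expect_identical(unname(tr$labels), oracle)
  # the two single-high corners land in the same group
  expect_identical(tr$labels[[which(combos$w == "high" & combos$r == "low" & combos$e == "low")]],
                   tr$labels[[which(combos$w == "low" & combos$r == "high" & combos$e == "low")]])

  # random labels partition into six groups summing to n
  rnd <- with_seed(3, lapply(1:3, function(i)
    lh_labels(stats::runif(200) > 0.5, sprintf("p%d", 1:200))))
  tr2 <- triple_stratify(rnd[[1]], rnd[[2]], rnd[[3]])
  expect_identical(sum(table(tr2$labels)), 200L)
  expect_true(all(tr2$labels %in% c("WRdL_EL", "WRdL_EH", "WRsH_EL",
                                    "WRsH_EH", "WRdH_EL", "WRdH_EH")))
})

test_that("exactly 7 labels map to low and 7 to high m6A-indication", {
  all_labels <- list(W = c("low", "high"), R = c("low", "high"),
                     E = c("low", "high"),
                     WE = c("WL_EL", "WL_EH", "WH_EL", "WH_EH"),
                     RE = c("RL_EL", "RL_EH", "RH_EL", "RH_EH"),
                     WR = c("WL_RL", "WL_RH", "WH_RL", "WH_RH"),
                     WRE = c("WRdL_EL", "WRdL_EH", "WRsH_EL", "WRsH_EH",
                             "WRdH_EL", "WRdH_EH"))
  ind <- unlist(lapply(names(all_labels), function(s)
    indication_of(all_labels[[s]], s)))
  expect_identical(sum(ind == "low"), 7L)
  expect_identical(sum(ind == "high"), 7L)
  # the enumerated members of each class
  expect_identical(indication_of("WRdH_EL", "WRE"), "high")
  expect_identical(indication_of("WRdL_EH", "WRE"), "low")
  expect_identical(indication_of("WH_EH", "WE"), "intermediate")
  expect_identical(indication_of("high", "E"), "low")  # eraser inverts
  expect_error(indication_of("bogus", "WE"), "unknown label")
})

test_that("indication of the WRE corners matches the truth-table corners exactly", {
  combos <- expand.grid(w = c("low", "high"), r = c("low", "high"),
                        e = c("low", "high"), stringsAsFactors = FALSE)
  samples <- sprintf("c%d", 1:8)
  tr <- triple_stratify(stats::setNames(combos$w, samples),
                        stats::setNames(combos$r, samples),
                        stats::setNames(combos$e, samples))
  is_low <- combos$w == "low" & combos$r == "low" & combos$e == "high"
  is_high <- combos$w == "high" & combos$r == "high" & combos$e == "low"
  expect_identical(unname(tr$indication),
                   ifelse(is_low, "low", ifelse(is_high, "high", "intermediate")))
})

test_that("stratification is invariant to sample order", {
  sig <- compute_wre(toy_expression(30, seed = 17))
  strata <- stratify_all(sig)
  perm <- with_seed(2, sample(nrow(sig)))
  sig_p <- sig[perm, ]
  strata_p <- stratify_all(sig_p)
  for (s in names(strata))
    expect_identical(strata_p[[s]]$labels[names(strata[[s]]$labels)],
                     strata[[s]]$labels)
})

test_that("cutoff scan finds a hazard-separating threshold and honors group floors", {
  hits <- vapply(1:100, function(s) with_seed(s, {
    n <- 120
    sig <- stats::runif(n, 0, 2)
    haz <- ifelse(sig < 1, 3, 1) / 20
    time <- stats::rexp(n, haz)
    res <- best_cutoff_scan(stats::setNames(sig, sprintf("p%d", 1:n)),
                            time, rep(1, n))
    res$cutoff >= 0.8 && res$cutoff <= 1.2
  }), logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("scan-count Bonferroni correction controls the null minimum P", {
  null_ok <- vapply(1:100, function(s) with_seed(1000 + s, {
    n <- 100
    sig <- stats::runif(n)
    time <- stats::rexp(n, 1 / 20)
    res <- best_cutoff_scan(stats::setNames(sig, sprintf("p%d", 1:n)),
                            time, rep(1, n))
    res$p_bonferroni > 0.05
  }), logical(1))
  expect_gte(mean(null_ok), 0.90)
})

test_that("degenerate or tiny survival inputs are rejected by the scan", {
  expect_error(best_cutoff_scan(stats::setNames(rep(1, 20), sprintf("p%d", 1:20)),
                                stats::rexp(20), rep(1, 20)),
               "no cutoff")
  expect_error(best_cutoff_scan(stats::setNames(stats::runif(10), sprintf("p%d", 1:10)),
                                stats::rexp(10), rep(1, 10)),
               ">=20")
})
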