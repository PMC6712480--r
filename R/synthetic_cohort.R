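#' Simulation parameters for a synthetic GC cohort
#'
#' Bundles and validates the parameters of [generate_cohort()]. The
#' defaults describe the cohort structure the analysis assumes: a single
#' latent m6A factor on which the writer and reader regulator blocks load
#' positively and the eraser block negatively (so corr(W,R) > 0 and
#' corr(W,E) < 0 by construction), proportional-hazards survival favoring
#' high-m6A patients, driver-mutation odds multiplied in low-m6A patients,
#' and clinical covariates (Lauren subtype, T/N/M, stage, TMB, MSI)
#' shifted by the latent level; EBV is an independent Bernoulli label.
#'
#' @param n_samples Cohort size (default 600).
#' @param regulator_means Named positive means (linear units) for the seven
#'   regulators.
#' @param within_block_rho Correlation between genes of the same block
#'   (default 0.7).
#' @param wr_rho Cross-correlation between writer- and reader-block genes
#'   (default 0.55, positive).
#' @param we_rho Cross-correlation between writer/reader- and eraser-block
#'   genes (default -0.4, negative).
#' @param log_sd Log-scale standard deviation of regulator expression.
#' @param n_background_genes Background genes beyond the regulators.
#' @param n_responsive_genes How many background genes load (negatively) on
#'   the latent factor; these form the spiked "oncogenic" gene set.
#' @param responsive_loading Latent loading of the responsive genes
#'   (default -0.6; negative = anti-correlated with m6A).
#' @param hazard_scale Baseline mean survival in months (exponential).
#' @param hr_low_vs_high Hazard ratio of the lowest latent tertile vs the
#'   rest (default 2.5; > 1 means low m6A fares worse).
#' @param censor_rate Target fraction of censored patients (uniform
#'   censoring window calibrated to the baseline hazard).
#' @param driver_genes Data frame `gene`, `baseline_prob`,
#'   `odds_multiplier`: per-gene mutation probability and the odds
#'   multiplier applied to below-median-latent (low m6A) patients.
#' @param n_passenger_genes Latent-independent mutated genes (frequencies
#'   drawn once per cohort from 0.005-0.08).
#' @param clinical_effects Named list of logit shifts per unit latent:
#'   `lauren_shift` (diffuse excess at low m6A), `stage_shift` (T/N/M/stage
#'   progression at low m6A), `msi_shift` (MSI-H excess at high m6A).
#' @param tmb_shift Log-TMB increase per unit latent (positive: TMB higher
#'   at high m6A, i.e. at low eraser expression).
#' @param seed Root seed; all stages draw from named substreams of it.
#' @return Validated list of class `"simulation_params"`.
#' @export
simulation_params <- function(n_samples = 600,
                              regulator_means = c(METTL3 = 50, METTL14 = 40,
                                                  YTHDF1 = 60, YTHDF2 = 55,
                                                  YTHDF3 = 45, ALKBH5 = 30,
                                                  FTO = 35),
                              within_block_rho = 0.7,
                              wr_rho = 0.55,
                              we_rho = -0.4,
                              log_sd = 0.5,
                              n_background_genes = 100,
                              n_responsive_genes = min(30, n_background_genes),
                              responsive_loading = -0.6,
                              hazard_scale = 30,
                              hr_low_vs_high = 2.5,
                              censor_rate = 0.3,
                              driver_genes = data.frame(
                                gene = c("CDH1", "TP53", "RHOA", "MUC6",
                                         "AR", "GLI3", "SETBP1"),
                                baseline_prob = c(0.30, 0.45, 0.20, 0.15,
                                                  0.15, 0.15, 0.12),
                                odds_multiplier = rep(3, 7),
                                stringsAsFactors = FALSE),
                              n_passenger_genes = 30,
                              clinical_effects = list(lauren_shift = 0.8,
                                                      stage_shift = 0.6,
                                                      msi_shift = 0.6),
                              tmb_shift = 0.4,
                              seed = 1) {
  stopifnot(n_samples >= 2, hazard_scale > 0, hr_low_vs_high > 0,
            censor_rate >= 0, censor_rate < 1, log_sd > 0,
            n_background_genes >= 0,
            n_responsive_genes <= n_background_genes,
            abs(responsive_loading) < 1)
  reg <- unlist(m6a_regulators())
  if (!setequal(names(regulator_means), unname(reg)))
    stop("regulator_means must name exactly the seven canonical regulators")
  if (any(regulator_means <= 0)) stop("regulator_means must be positive")
  if (wr_rho < 0 || wr_rho >= 1) stop("wr_rho must be in [0, 1)")
  if (we_rho > 0) stop("we_rho must be <= 0 (erasers oppose writers/readers)")
  if (within_block_rho < 0 || within_block_rho >= 1)
    stop("within_block_rho must be in [0, 1)")
  # latent loadings implied by the block parameters
  if (wr_rho == 0 && we_rho != 0)
    stop("we_rho != 0 requires wr_rho > 0 (single-latent-factor construction)")
  a_wr <- sqrt(wr_rho)
  a_e <- if (wr_rho > 0) abs(we_rho) / a_wr else 0
  if (a_wr^2 > within_block_rho || a_e^2 > within_block_rho)
    stop(sprintf(paste0("block correlations are not jointly attainable: ",
                        "latent loadings (W/R: %.3f, E: %.3f) squared exceed ",
                        "within_block_rho = %.3f; raise within_block_rho or ",
                        "shrink wr_rho/we_rho"), a_wr, a_e, within_block_rho))
  if (!all(c("gene", "baseline_prob", "odds_multiplier") %in% names(driver_genes)))
    stop("driver_genes needs columns gene, baseline_prob, odds_multiplier")
  if (any(driver_genes$baseline_prob <= 0 | driver_genes$baseline_prob >= 1))
    stop("driver baseline_prob must be in (0, 1)")
  p <- as.list(environment())
  p$loadings <- list(a_wr = a_wr, a_e = a_e,
                     b_wr = sqrt(within_block_rho - a_wr^2),
                     b_e = sqrt(within_block_rho - a_e^2),
                     c = sqrt(1 - within_block_rho))
  # implied 7x7 regulator correlation must be positive definite
  cm <- implied_regulator_correlation(p)
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("implied regulator correlation matrix is not positive definite ",
         "(within_block_rho = ", within_block_rho, ", wr_rho = ", wr_rho,
         ", we_rho = ", we_rho, ")")
  class(p) <- "simulation_params"
  p
}

#' Regulator correlation matrix implied by simulation parameters
#' @param params A [simulation_params()] (or the argument list thereof).
#' @return 7x7 correlation matrix over the regulator genes.
#' @export
implied_regulator_correlation <- function(params) {
  reg <- m6a_regulators()
  genes <- unlist(reg, use.names = FALSE)
  block <- rep(c("W", "R", "E"), times = lengths(reg))
  a <- ifelse(block == "E", -params$loadings$a_e, params$loadings$a_wr)
  cm <- outer(a, a)
  same_block <- outer(block, block, "==")
  cm[same_block] <- params$within_block_rho
  diag(cm) <- 1
  dimnames(cm) <- list(genes, genes)
  cm
}

# uniform-censoring window giving the target censoring fraction under the
# baseline exponential hazard: solves E[S(C)] = censor_rate for C~U(0,w)
censor_window <- function(lambda, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  f <- function(w) (1 - exp(-lambda * w)) / (lambda * w) - censor_rate
  stats::uniroot(f, c(1e-8, 1e8), tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort (expression + clinical + mutations + gene sets) with
#' the statistical structure described in [simulation_params()], plus a
#' hidden truth record, so every pipeline stage can be tested against
#' known ground truth. Regeneration with identical parameters (including
#' the seed) is bit-identical; the expression, survival, mutation and
#' clinical stages draw from independent named substreams of the root seed.
#'
#' @param params A [simulation_params()].
#' @return Object of class `"synthetic_cohort"`: list with `expression`
#'   ([expression_matrix()]), `clinical` ([clinical_table()]), `mutations`
#'   ([mutation_table()]), `gene_sets` (incl. the spiked set
#'   `ONCOGENIC_SPIKED`), `truth` (per-sample latent level, tertile and
#'   true hazard; attributes `spiked_drivers`, `spiked_set`) and `params`.
#' @export
generate_cohort <- function(params = simulation_params()) {
  if (!inherits(params, "simulation_params"))
    stop("params must come from simulation_params()")
  n <- params$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  ld <- params$loadings
  reg <- m6a_regulators()

  ## expression substream: latent factor, regulator blocks, background genes
  expr_parts <- with_seed(substream_seed(params$seed, "expression"), {
    z <- stats::rnorm(n)
    u <- list(W = stats::rnorm(n), R = stats::rnorm(n), E = stats::rnorm(n))
    gene_std <- function(block) {
      a <- if (block == "E") -ld$a_e else ld$a_wr
      b <- if (block == "E") ld$b_e else ld$b_wr
      a * z + b * u[[block]] + ld$c * stats::rnorm(n)
    }
    rows <- lapply(c(W = "W", R = "R", E = "E"), function(bl) {
      genes <- reg[[c(W = "writers", R = "readers", E = "erasers")[bl]]]
      t(vapply(genes, function(g)
        params$regulator_means[g] * exp(params$log_sd * gene_std(bl)),
        numeric(n)))
    })
    m <- do.call(rbind, rows)
    nb <- params$n_background_genes
    bg <- NULL
    spiked_set <- character()
    if (nb > 0) {
      nr <- params$n_responsive_genes
      bg_names <- sprintf("BG%04d", seq_len(nb))
      lam <- params$responsive_loading
      bg <- t(vapply(seq_len(nb), function(i) {
        std <- if (i <= nr) lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
               else stats::rnorm(n)
        20 * exp(params$log_sd * std)
      }, numeric(n)))
      rownames(bg) <- bg_names
      spiked_set <- bg_names[seq_len(nr)]
    }
    full <- rbind(m, bg)
    colnames(full) <- samples
    list(expr = full, z = z, spiked_set = spiked_set)
  })
  z <- expr_parts$z

  ## survival substream: exponential with tertile-dependent hazard
  tert <- cut(z, stats::quantile(z, c(0, 1 / 3, 2 / 3, 1)),
              labels = c("low", "mid", "high"), include.lowest = TRUE)
  lambda0 <- 1 / params$hazard_scale
  hazard <- lambda0 * ifelse(tert == "low", params$hr_low_vs_high, 1)
  surv <- with_seed(substream_seed(params$seed, "survival"), {
    t_true <- stats::rexp(n, rate = hazard)
    w <- censor_window(lambda0, params$censor_rate)
    c_time <- if (is.finite(w)) stats::runif(n, 0, w) else rep(Inf, n)
    list(os_months = round(pmin(t_true, c_time), 2),
         os_event = as.numeric(t_true <= c_time))
  })

  ## mutation substream: drivers boosted in below-median-latent samples
  lowz <- z < stats::median(z)
  muts <- with_seed(substream_seed(params$seed, "mutations"), {
    dg <- params$driver_genes
    recs <- list()
    for (i in seq_len(nrow(dg))) {
      odds <- dg$baseline_prob[i] / (1 - dg$baseline_prob[i]) *
        ifelse(lowz, dg$odds_multiplier[i], 1)
      hit <- stats::rbinom(n, 1, odds / (1 + odds)) == 1
      if (!any(hit)) next
      pc <- if (toupper(dg$gene[i]) == "CDH1")
        ifelse(stats::runif(sum(hit)) < 0.5, "p.D254Y",
               sprintf("p.M%dV", which(hit)))
      else sprintf("p.M%dV", which(hit))
      recs[[dg$gene[i]]] <- data.frame(sample = samples[hit],
                                       gene = dg$gene[i], protein_change = pc,
                                       stringsAsFactors = FALSE)
    }
    np <- params$n_passenger_genes
    if (np > 0) {
      pp <- stats::runif(np, 0.005, 0.08)
      for (i in seq_len(np)) {
        hit <- stats::rbinom(n, 1, pp[i]) == 1
        if (!any(hit)) next
        g <- sprintf("PSG%03d", i)
        recs[[g]] <- data.frame(sample = samples[hit], gene = g,
                                protein_change = sprintf("p.P%dL", which(hit)),
                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(recs, list(make.row.names = FALSE)))
  })

  ## clinical substream: latent-shifted categorical indexes
  eff <- params$clinical_effects
  clin <- with_seed(substream_seed(params$seed, "clinical"), {
    ordinal_draw <- function(base_probs, shift) {
      # P(category <= k) = plogis(qlogis(cum_k) + shift * z): positive shift
      # pushes high-latent (high m6A) samples toward the early categories
      cum <- stats::qlogis(cumsum(base_probs)[-length(base_probs)])
      pcum <- stats::plogis(outer(z * shift, cum, "+"))
      u <- stats::runif(n)
      k <- rowSums(u > pcum) + 1
      names(base_probs)[k]
    }
    p_diff <- stats::plogis(stats::qlogis(0.35) - eff$lauren_shift * z)
    lauren <- ifelse(stats::runif(n) < p_diff, "Diffuse",
                     ifelse(stats::runif(n) < 0.85, "Intestinal", "Others"))
    p_msih <- stats::plogis(stats::qlogis(0.18) + eff$msi_shift * z)
    msi <- ifelse(stats::runif(n) < p_msih, "MSI-H",
                  ifelse(stats::runif(n) < 0.15, "MSI-L", "MSS"))
    data.frame(
      sample = samples,
      os_months = surv$os_months,
      os_event = surv$os_event,
      gender = ifelse(stats::runif(n) < 0.55, "Male", "Female"),
      age_years = pmin(90, pmax(28, round(stats::rnorm(n, 62, 10)))),
      lauren = lauren,
      t_stage = ordinal_draw(c(t1 = 0.08, t2 = 0.22, t3 = 0.45, t4 = 0.25),
                             eff$stage_shift),
      n_stage = ordinal_draw(c(n0 = 0.30, n1 = 0.20, n2 = 0.20, n3 = 0.30),
                             eff$stage_shift),
      m_stage = ordinal_draw(c(m0 = 0.93, m1 = 0.07), eff$stage_shift),
      stage = ordinal_draw(c(I = 0.12, II = 0.30, III = 0.45, IV = 0.13),
                           eff$stage_shift),
      tmb = round(exp(stats::rnorm(n, log(8) + params$tmb_shift * z, 0.6)), 2),
      msi = msi,
      ebv = ifelse(stats::runif(n) < 0.09, "pos", "neg"),
      stringsAsFactors = FALSE)
  })

  ## gene sets: the spiked responsive set plus latent-independent decoys
  gene_sets <- with_seed(substream_seed(params$seed, "genesets"), {
    sets <- list()
    if (length(expr_parts$spiked_set))
      sets$ONCOGENIC_SPIKED <- expr_parts$spiked_set
    pool <- setdiff(rownames(expr_parts$expr), expr_parts$spiked_set)
    for (i in seq_len(min(5, floor(length(pool) / 15))))
      sets[[sprintf("RANDOM_SET_%02d", i)]] <- sample(pool, 15)
    structure(sets,
              description = stats::setNames(rep("synthetic", length(sets)),
                                            names(sets)),
              class = "gene_set_collection")
  })

  truth <- data.frame(sample = samples, latent = z,
                      tertile = as.character(tert),
                      hazard = hazard, stringsAsFactors = FALSE)
  attr(truth, "spiked_drivers") <- toupper(
    params$driver_genes$gene[params$driver_genes$odds_multiplier != 1])
  attr(truth, "spiked_set") <- expr_parts$spiked_set

  structure(list(
    expression = expression_matrix(expr_parts$expr),
    clinical = clinical_table(clin),
    mutations = mutation_table(
      if (is.null(muts)) data.frame(sample = character(), gene = character(),
                                    protein_change = character())
      else muts, samples = samples),
    gene_sets = gene_sets,
    truth = truth,
    params = params), class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the TSV / MAF-lite / GMT dialects the readers in this
#' package consume, plus the truth record as a separate TSV that no
#' pipeline stage reads.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(cohort$expression, paths["expression"])
  write_clinical(cohort$clinical, paths["clinical"])
  write_mutations(cohort$mutations, paths["mutations"])
  write_gmt(cohort$gene_sets, paths["gene_sets"])
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Parameter-recovery report for a synthetic cohort
#'
#' Runs the signature/stratification/survival/association/enrichment
#' pipeline on one (or two replicate) synthetic cohorts and checks that
#' the built-in structure is recovered:
#' \describe{
#'   \item{km_ordering}{the `WRdH_EL` (high-m6A) group outlives the
#'     `WRdL_EH` (low-m6A) group by Kaplan-Meier median;}
#'   \item{logrank_significant}{the two-group log-rank P between those
#'     corners is below `alpha`;}
#'   \item{drivers_up}{every spiked driver gene gets cross-cohort
#'     consensus call UP (requires `cohort_b`);}
#'   \item{enrichment_sign}{the spiked (anti-correlated) gene set has a
#'     negative NES in the high-m6A direction.}
#' }
#' Cohorts too small to power the checks are flagged `underpowered`
#' (checks still reported, not silently passed).
#'
#' @param cohort A [generate_cohort()] result.
#' @param cohort_b Optional second, independent replicate for the
#'   cross-cohort mutation check.
#' @param alpha Significance level for the log-rank check (default 0.05).
#' @param n_perm Permutations for the enrichment check (default 200).
#' @param run_enrichment Set `FALSE` to skip the (slowest) enrichment check.
#' @return List of class `"recovery_report"`: `checks` (named logical),
#'   `underpowered`, and the underlying `details`.
#' @export
recovery_report <- function(cohort, cohort_b = NULL, alpha = 0.05,
                            n_perm = 200, run_enrichment = TRUE) {
  pipe <- function(co) {
    sig <- compute_wre(co$expression)
    list(sig = sig, strata = stratify_all(sig))
  }
  pa <- pipe(cohort)
  wre <- pa$strata$WRE
  corner_n <- c(sum(wre$labels == "WRdL_EH"), sum(wre$labels == "WRdH_EL"))
  underpowered <- any(corner_n < 15) || cohort$params$n_samples < 100
  details <- list(corner_n = corner_n)

  cmp <- suppressWarnings(
    compare_strata_survival(cohort$clinical, wre, pair = c("WRdL_EH", "WRdH_EL")))
  med <- vapply(cmp$curves, km_median, numeric(1))
  med[is.na(med)] <- Inf  # survival never reached 0.5
  details$km_median <- med
  details$logrank_p <- cmp$logrank$p_value
  checks <- c(km_ordering = unname(med["WRdH_EL"] > med["WRdL_EH"]),
              logrank_significant = cmp$logrank$p_value < alpha)

  if (!is.null(cohort_b)) {
    pb <- pipe(cohort_b)
    spiked <- attr(cohort$truth, "spiked_drivers")
    fa <- foldchange_low_vs_high(cohort$mutations, pa$strata, genes = spiked)
    fb <- foldchange_low_vs_high(cohort_b$mutations, pb$strata, genes = spiked)
    cc <- cross_cohort_intersect(fa, fb)
    details$consensus <- cc$consensus
    checks["drivers_up"] <- all(cc$consensus[spiked] == "UP")
  }

  if (run_enrichment && length(attr(cohort$truth, "spiked_set"))) {
    labels <- stats::setNames(pa$strata$WRE$indication, names(pa$strata$WRE$labels))
    keep <- labels %in% c("low", "high")
    lab2 <- ifelse(labels[keep] == "high", "high", "low")
    names(lab2) <- names(labels)[keep]
    sub <- expression_matrix(
      unclass(cohort$expression)[, names(lab2), drop = FALSE])
    enr <- gsea(sub, lab2,
                list(ONCOGENIC_SPIKED = attr(cohort$truth, "spiked_set")),
                n_perm = max(100, n_perm), seed = cohort$params$seed)
    details$spiked_nes <- enr$nes[1]
    checks["enrichment_sign"] <- is.finite(enr$nes[1]) && enr$nes[1] < 0
  }

  structure(list(checks = checks, underpowered = underpowered,
                 details = details), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Synthetic-cohort recovery report",
      if (x$underpowered) "(UNDERPOWERED: interpret with caution)", "\n")
  for (nm in names(x$checks))
    cat(sprintf("  %-20s %s\n", nm, if (isTRUE(x$checks[[nm]])) "PASS" else "FAIL"))
  invisible(x)
}
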