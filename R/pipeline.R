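#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `inputs` (paths to on-disk cohort artifacts) or
#' `synthetic` (arguments for [simulation_params()]) must be given. The
#' seed is mandatory because the association fallback and enrichment
#' stages are stochastic.
#'
#' @param inputs Named list of paths: `expression`, `clinical`, and
#'   optionally `mutations`, `gene_sets`.
#' @param synthetic Named list of [simulation_params()] arguments (may be
#'   empty for the defaults).
#' @param schemes Stratification schemes to run (default all seven).
#' @param cutoff_mode `"median"` or `"scan"` (minimum-log-rank-P cutoff
#'   search for the single signatures).
#' @param deg_threshold DEG P threshold for the Venn stage.
#' @param n_perm GSEA permutations.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(inputs = NULL, synthetic = NULL,
                            schemes = SCHEMES,
                            cutoff_mode = c("median", "scan"),
                            deg_threshold = 0.05, n_perm = 1000,
                            seed = 1, out_dir = "m6asig_out") {
  cutoff_mode <- match.arg(cutoff_mode)
  if (is.null(inputs) == is.null(synthetic))
    stop("provide exactly one of 'inputs' or 'synthetic'")
  if (!is.null(inputs) && !all(c("expression", "clinical") %in% names(inputs)))
    stop("'inputs' requires at least 'expression' and 'clinical' paths")
  schemes <- match.arg(schemes, SCHEMES, several.ok = TRUE)
  if (is.null(seed) || !is.finite(seed)) stop("a seed is mandatory")
  structure(list(inputs = inputs, synthetic = synthetic, schemes = schemes,
                 cutoff_mode = cutoff_mode, deg_threshold = deg_threshold,
                 n_perm = n_perm, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Path to a `.yaml`/`.yml` or `.json` config file whose keys
#'   mirror the arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full m6A-signature analysis pipeline
#'
#' Executes signatures, stratification, survival, association and
#' enrichment in sequence on either an on-disk or a synthetic cohort and
#' writes every stage result as TSV under `config$out_dir`, plus a JSON
#' `manifest.json` (full config echo, seed, package version, file
#' checksums) that suffices to reproduce the run. Deterministic stages are
#' bit-identical across reruns; stochastic stages are seed-identical.
#'
#' @param config A [pipeline_config()].
#' @return Named list of stage results, invisibly (with `paths` of the
#'   written files).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must come from pipeline_config()")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## load or simulate
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    if (is.null(args$seed)) args$seed <- config$seed
    cohort <- stage("simulate", generate_cohort(do.call(simulation_params, args)))
    expr <- cohort$expression; clinical <- cohort$clinical
    mutations <- cohort$mutations; gene_sets <- cohort$gene_sets
    write_cohort(cohort, file.path(out, "cohort"))
  } else {
    expr <- stage("read_expression", read_expression(config$inputs$expression))
    clinical <- stage("read_clinical", read_clinical(config$inputs$clinical))
    mutations <- if (!is.null(config$inputs$mutations))
      stage("read_mutations",
            read_mutations(config$inputs$mutations, samples = clinical$sample,
                           allow_extra = TRUE))
    gene_sets <- if (!is.null(config$inputs$gene_sets))
      stage("read_gmt", read_gmt(config$inputs$gene_sets))
  }

  paths <- character()
  emit <- function(name, writer) {
    p <- file.path(out, name)
    writer(p)
    paths[[name]] <<- p
  }

  ## signatures
  sig <- stage("signatures", compute_wre(expr))
  emit("signatures.tsv", function(p) write_signatures(sig, p))
  corr <- stage("signatures", rbind(signature_correlations(sig, "pearson"),
                                    signature_correlations(sig, "spearman")))
  emit("signature_correlations.tsv", function(p)
    utils::write.table(corr, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## stratification
  strata <- stage("stratify", stratify_all(sig, config$schemes))
  emit("strata.tsv", function(p) write_strata(strata, p))
  if (config$cutoff_mode == "scan") {
    scans <- stage("stratify", {
      idx <- match(sig$sample, clinical$sample)
      lapply(intersect(c("W", "R", "E"), config$schemes), function(s)
        data.frame(scheme = s,
                   best_cutoff_scan(stats::setNames(sig[[s]], sig$sample),
                                    clinical$os_months[idx],
                                    clinical$os_event[idx])$scan))
    })
    emit("cutoff_scans.tsv", function(p)
      utils::write.table(do.call(rbind, scans), p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }

  ## survival
  surv_rows <- list(); km_all <- list()
  for (s in names(strata)) {
    cs <- stage("survival",
                suppressWarnings(compare_strata_survival(clinical, strata[[s]])))
    surv_rows[[s]] <- data.frame(scheme = s, comparison = "omnibus",
                                 statistic = cs$logrank$statistic,
                                 df = cs$logrank$df, p_value = cs$logrank$p_value)
    for (g in names(cs$curves)) km_all[[paste0(s, ":", g)]] <- cs$curves[[g]]
    ind <- strata[[s]]$indication
    if (all(c("low", "high") %in% ind)) {
      lab_low <- unique(strata[[s]]$labels[ind == "low"])
      lab_high <- unique(strata[[s]]$labels[ind == "high"])
      pr <- stage("survival", suppressWarnings(
        compare_strata_survival(clinical, strata[[s]],
                                pair = c(lab_low, lab_high))))
      surv_rows[[paste0(s, "_pair")]] <-
        data.frame(scheme = s, comparison = paste(lab_low, "vs", lab_high),
                   statistic = pr$logrank$statistic, df = pr$logrank$df,
                   p_value = pr$logrank$p_value)
    }
  }
  emit("survival_tests.tsv", function(p)
    utils::write.table(do.call(rbind, c(surv_rows, list(make.row.names = FALSE))),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("km_curves.tsv", function(p) write_km_curves(km_all, p))

  ## association
  if (!is.null(mutations) && ncol(mutations$matrix) > 0) {
    fc <- stage("associate", foldchange_low_vs_high(mutations, strata))
    emit("mutation_foldchange.tsv", function(p)
      utils::write.table(data.frame(gene = rownames(fc), fc, check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  } else fc <- NULL
  assoc <- stage("associate", clinical_association(clinical, strata[[length(strata)]],
                                                   seed = config$seed))
  emit("clinical_association.tsv", function(p) write_contingency(assoc, p))

  ## enrichment
  deg <- enr <- NULL
  if (all(c("W", "R", "E") %in% names(strata))) {
    deg <- stage("enrich", lapply(c(W = "W", R = "R", E = "E"), function(s)
      diff_expr(expr, strata[[s]]$labels, p_threshold = config$deg_threshold)))
    venn <- venn_counts(deg$W$gene[deg$W$deg], deg$R$gene[deg$R$deg],
                        deg$E$gene[deg$E$deg])
    emit("deg_venn.tsv", function(p)
      utils::write.table(data.frame(region = names(venn), count = venn),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  if (!is.null(gene_sets) && "WRE" %in% names(strata)) {
    ind <- strata$WRE$indication
    keep <- ind %in% c("low", "high")
    labels <- stats::setNames(ifelse(ind[keep] == "high", "high", "low"),
                              names(strata$WRE$labels)[keep])
    sub <- expression_matrix(unclass(expr)[, names(labels), drop = FALSE])
    enr <- stage("enrich", gsea(sub, labels, gene_sets,
                                n_perm = config$n_perm, seed = config$seed))
    emit("enrichment.tsv", function(p) write_enrichment(enr, p))
  }

  ## manifest: config echo + checksums; enough to reproduce the run
  manifest <- list(
    package = "m6Asig",
    version = as.character(utils::packageVersion("m6Asig")),
    seed = config$seed,
    config = unclass(config),
    checksums = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(signatures = sig, strata = strata,
                 survival = do.call(rbind, c(surv_rows, list(make.row.names = FALSE))),
                 foldchange = fc, clinical = assoc, deg = deg, enrichment = enr,
                 paths = c(paths, manifest = file.path(out, "manifest.json"))))
}
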