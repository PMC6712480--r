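#' Canonical m6A regulator genes
#'
#' The seven canonical N6-methyladenosine (m6A) regulators grouped by role:
#' writers (methyltransferases), readers (signal transducers) and erasers
#' (demethylases). All signature computations in this package are defined
#' over these gene groups.
#'
#' @return Named list with character vectors `writers`, `readers`, `erasers`.
#' @examples
#' m6a_regulators()
#' @export
m6a_regulators <- function() {
  list(
    writers = c("METTL3", "METTL14"),
    readers = c("YTHDF1", "YTHDF2", "YTHDF3"),
    erasers = c("ALKBH5", "FTO")
  )
}

# single canonical missing token used across all clinical columns
NA_TOKEN <- "n/a"

# allowed categorical levels (canonical case) per clinical variable
CLINICAL_LEVELS <- list(
  gender  = c("Male", "Female"),
  lauren  = c("Diffuse", "Intestinal", "Others"),
  t_stage = c("t1", "t2", "t3", "t4"),
  n_stage = c("n0", "n1", "n2", "n3"),
  m_stage = c("m0", "m1"),
  stage   = c("I", "II", "III", "IV"),
  msi     = c("MSI-H", "MSI-L", "MSS"),
  ebv     = c("neg", "pos")
)

#' Construct a validated expression matrix
#'
#' Wraps a numeric gene-by-sample matrix after validating the invariants the
#' downstream signature code relies on: unique gene and sample identifiers
#' and finite, nonnegative values. Gene symbols are stored uppercase so that
#' proteomics- and RNA-derived symbol case both resolve. Values are kept in
#' their input units (protein intensities or normalized RNA quantities);
#' any log transformation is an explicit downstream step.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   `rownames` (gene symbols) and `colnames` (sample IDs).
#' @return The validated matrix with class `"expression_matrix"`.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene rownames and sample colnames")
  rownames(values) <- toupper(rownames(values))
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene symbol(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite or negative expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-delimited file whose header row holds sample IDs and whose
#' first column holds gene symbols. Row and column order are preserved.
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >=1 sample column")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric expression value at row %d (gene '%s'), column '%s'",
                   bad[1, 1], genes[bad[1, 1]], colnames(m)[bad[1, 2]]))
    mode(m) <- "numeric"
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative expression value at row %d (gene '%s'), column '%s'",
                 neg[1, 1], genes[neg[1, 1]], colnames(m)[neg[1, 2]]))
  rownames(m) <- genes
  expression_matrix(m)
}

#' Write an expression matrix to TSV
#' @param expr An [expression_matrix()] (or plain named matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# normalize one categorical clinical column: case-insensitive match against
# the allowed levels, "n/a"/empty -> NA-token, anything else -> error
normalize_category <- function(x, var) {
  levels <- CLINICAL_LEVELS[[var]]
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | tolower(x) == NA_TOKEN] <- NA_TOKEN
  idx <- match(tolower(x), tolower(levels))
  bad <- x != NA_TOKEN & is.na(idx)
  if (any(bad))
    stop(sprintf("invalid value '%s' for clinical variable '%s'; allowed: %s, %s",
                 x[bad][1], var, paste(levels, collapse = ", "), NA_TOKEN))
  out <- ifelse(x == NA_TOKEN, NA_TOKEN, levels[idx])
  out
}

#' Construct a validated clinical table
#'
#' Validates per-sample overall survival and clinical-index columns.
#' Missing values are stored as the literal token `"n/a"` in categorical
#' columns and as `NA` in numeric columns. Categorical inputs are matched
#' case-insensitively and stored in canonical case.
#'
#' @param df Data frame with columns `sample`, `os_months`, `os_event` and
#'   optionally `gender`, `age_years`, `lauren`, `t_stage`, `n_stage`,
#'   `m_stage`, `stage`, `tmb`, `msi`, `ebv`.
#' @return A `data.frame` of class `"clinical_table"`.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) stop("clinical table requires a 'sample' column")
  df$sample <- as.character(df$sample)
  dup <- unique(df$sample[duplicated(df$sample)])
  if (length(dup)) stop("duplicate sample ID(s): ", paste(dup, collapse = ", "))

  num_col <- function(x) {
    x <- as.character(x)
    x[x == "" | tolower(trimws(x)) == NA_TOKEN] <- NA
    suppressWarnings(as.numeric(x))
  }
  for (v in c("os_months", "age_years", "tmb")) {
    if (v %in% names(df)) {
      df[[v]] <- num_col(df[[v]])
      if (any(df[[v]] < 0, na.rm = TRUE)) stop("negative values in '", v, "'")
    }
  }
  if ("os_event" %in% names(df)) {
    ev <- num_col(df$os_event)
    if (any(!ev %in% c(0, 1) & !is.na(ev))) stop("os_event must be 0/1")
    df$os_event <- ev
    if (!"os_months" %in% names(df))
      stop("os_event present without os_months")
    if (any(!is.na(df$os_event) & is.na(df$os_months)))
      stop("os_event present without os_months for sample(s): ",
           paste(df$sample[!is.na(df$os_event) & is.na(df$os_months)], collapse = ", "))
  }
  for (v in names(CLINICAL_LEVELS))
    if (v %in% names(df)) df[[v]] <- normalize_category(df[[v]], v)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a per-sample clinical table from TSV
#'
#' The literal string `"n/a"` (any case) and empty cells both mark missing
#' values. See [clinical_table()] for the recognized columns and levels.
#'
#' @param path Path to the TSV file.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  clinical_table(df)
}

#' Write a clinical table to TSV
#' @param clin A [clinical_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  out <- as.data.frame(clin)
  out[] <- lapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- NA_TOKEN
    x
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a mutation table from MAF-lite records
#'
#' Stores the raw (sample, gene, protein_change) records and a derived
#' binary sample-by-gene matrix in which an entry is 1 iff at least one
#' record exists for that pair (multiple variants in one gene collapse).
#'
#' @param records Data frame with columns `sample`, `gene`, `protein_change`.
#' @param samples Character vector of all cohort sample IDs (samples without
#'   mutations get all-zero rows). Defaults to the samples seen in `records`.
#' @param allow_extra If `TRUE`, records for samples outside `samples` are
#'   dropped with a warning instead of raising an error.
#' @return Object of class `"mutation_table"`: list with `records` and the
#'   binary `matrix`.
#' @export
mutation_table <- function(records, samples = NULL, allow_extra = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0)
    records <- data.frame(sample = character(), gene = character(),
                          protein_change = character(), stringsAsFactors = FALSE)
  if (!all(c("sample", "gene") %in% names(records)))
    stop("mutation records require 'sample' and 'gene' columns")
  if (is.null(records$protein_change)) records$protein_change <- ""
  records$sample <- as.character(records$sample)
  records$gene <- toupper(as.character(records$gene))
  records$protein_change <- as.character(records$protein_change)
  if (is.null(samples)) samples <- unique(records$sample)
  samples <- as.character(samples)
  extra <- setdiff(records$sample, samples)
  if (length(extra)) {
    if (!allow_extra)
      stop("mutation record(s) for unknown sample(s): ",
           paste(utils::head(extra, 5), collapse = ", "))
    warning("dropping ", sum(records$sample %in% extra),
            " record(s) for sample(s) outside the cohort")
    records <- records[!records$sample %in% extra, , drop = FALSE]
  }
  genes <- sort(unique(records$gene))
  m <- matrix(0L, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  if (nrow(records))
    m[cbind(match(records$sample, samples), match(records$gene, genes))] <- 1L
  structure(list(records = records, matrix = m), class = "mutation_table")
}

#' Read a MAF-lite mutation table from TSV
#'
#' MAF-lite is a minimal tab-delimited mutation record format with columns
#' `sample`, `gene`, `protein_change` (the last may be empty).
#'
#' @inheritParams mutation_table
#' @param path Path to the TSV file.
#' @return A [mutation_table()].
#' @export
read_mutations <- function(path, samples = NULL, allow_extra = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0)
    df <- data.frame(sample = character(), gene = character(),
                     protein_change = character(), stringsAsFactors = FALSE)
  mutation_table(df, samples = samples, allow_extra = allow_extra)
}

#' Write mutation records to MAF-lite TSV
#' @param mut A [mutation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mut, path) {
  utils::write.table(mut$records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Query mutation records for one exact variant
#'
#' @param mut A [mutation_table()].
#' @param gene Gene symbol.
#' @param protein_change Exact protein change string, e.g. `"p.D254Y"`.
#' @return Character vector of sample IDs carrying that exact variant.
#' @export
variant_carriers <- function(mut, gene, protein_change) {
  r <- mut$records
  unique(r$sample[r$gene == toupper(gene) & r$protein_change == protein_change])
}

#' Read a GMT gene set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB gene1 TAB ...`.
#' Duplicate genes within a line are deduplicated; duplicate set names or
#' lines with fewer than three fields are errors.
#'
#' @param path Path to a GMT file.
#' @return Object of class `"gene_set_collection"`: named list of character
#'   vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(f)))
    name <- f[1]
    if (name %in% names(sets)) stop("duplicate gene set name: ", name)
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("GMT line %d ('%s') has no genes", i, name))
    sets[[name]] <- genes
    desc[name] <- f[2]
  }
  structure(sets, description = desc, class = "gene_set_collection")
}

#' Write a gene set collection to GMT
#' @param sets Named list of character vectors (or a `gene_set_collection`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && !is.na(desc[nm])) desc[nm] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
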