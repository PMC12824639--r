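#' Read and write gene-by-sample matrices as TSV
#'
#' Plain tab-separated text with gene ids in the first column and sample ids
#' in the header; row and column order are preserved round-trip.
#'
#' @param path file path.
#' @param m numeric matrix with dimnames.
#' @return `read_expression_tsv` returns a numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_expr_matrix(m)
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table TSV
#'
#' One row per sample. Recognized columns: `sample_id` (required),
#' `os_months`, `os_event`, `er`, `pr`, `her2`, `subtype`, `batch`, `tmb`,
#' `response`. Categorical fields are validated on read: receptor status
#' must be pos/neg (NA allowed), response must be CR/PR/SD/PD (NA allowed),
#' survival times must be positive wherever present and events 0/1.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(df$sample_id)) stop_invalid("clinical table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop_invalid("duplicate sample ids in clinical table")
  if (!is.null(df$os_months) && any(df$os_months <= 0, na.rm = TRUE))
    stop_invalid("os_months must be > 0 where present")
  if (!is.null(df$os_event) && !all(df$os_event %in% c(0, 1, NA)))
    stop_invalid("os_event must be 0/1")
  for (col in c("er", "pr", "her2"))
    if (!is.null(df[[col]]) && !all(df[[col]] %in% c("pos", "neg", NA)))
      stop_invalid(col, " must be pos/neg or missing")
  if (!is.null(df$response) && !all(df$response %in% c("CR", "PR", "SD", "PD", NA)))
    stop_invalid("response must be CR/PR/SD/PD or missing")
  df
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Duplicate genes within a set are removed; empty sets are dropped with a
#' warning.
#'
#' @param path file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " empty gene set(s) dropped")
    sets <- sets[!empty]
  }
  sets
}

#' Write a simulated cohort to a directory of TSV files
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly. Files: `expression.tsv`, `clinical.tsv`,
#'   `true_fractions.tsv`, `true_modules.tsv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(cohort$expr, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fr <- data.frame(sample_id = rownames(cohort$truth$true_fractions),
                   cohort$truth$true_fractions, check.names = FALSE)
  utils::write.table(fr, file.path(dir, "true_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mods <- do.call(rbind, lapply(names(cohort$truth$true_module_genes), function(nm)
    data.frame(module = nm, gene_id = cohort$truth$true_module_genes[[nm]],
               beta = cohort$truth$true_betas[[nm]])))
  utils::write.table(mods, file.path(dir, "true_modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
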