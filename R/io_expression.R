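#' Read a normalized expression matrix and its 2x2 factorial sample sheet
#'
#' The matrix is a TSV with a header row of sample ids and probeset ids in the
#' first column; intensities are linear-scale (MAS 5.0 style), finite and
#' nonnegative. The sample sheet is a TSV with columns `sample_id`, `factor1`,
#' `factor2` (each `control` or `treated`) and `replicate`. Every one of the
#' four design cells must carry at least two replicates.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return An `ExpressionBundle`: list with `values` (numeric matrix,
#'   probesets x samples), `probeset_ids`, `sample_ids`, and `design`
#'   (data.frame with `sample_id`, `factor1`, `factor2`, `replicate`).
#' @export
read_expression <- function(matrix_path, sample_sheet_path) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression matrix needs a probeset column plus samples")
  probeset_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)  # covers literal NA and junk text
  if (nrow(bad) > 0L) {
    val <- vals[bad[1L, 1L], bad[1L, 2L]]
    stop(sprintf("non-numeric expression value '%s' at probeset '%s', sample '%s'",
                 if (is.na(val)) "NA" else val, probeset_ids[bad[1L, 1L]],
                 sample_ids[bad[1L, 2L]]))
  }
  dimnames(num) <- list(probeset_ids, sample_ids)

  sheet <- utils::read.delim(sample_sheet_path, header = TRUE, sep = "\t",
                             colClasses = "character")
  need <- c("sample_id", "factor1", "factor2", "replicate")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss) > 0L) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  design <- data.frame(sample_id = sheet$sample_id,
                       factor1 = sheet$factor1,
                       factor2 = sheet$factor2,
                       replicate = as.integer(sheet$replicate),
                       stringsAsFactors = FALSE)
  expression_bundle(num, design)
}

#' Construct and validate an ExpressionBundle
#'
#' @param values numeric matrix, probesets x samples, finite nonnegative
#'   linear-scale intensities with row and column names.
#' @param design data.frame with columns `sample_id`, `factor1`, `factor2`
#'   (levels `control`/`treated`) and `replicate`.
#' @return validated `ExpressionBundle` (class `"ExpressionBundle"`).
#' @export
expression_bundle <- function(values, design) {
  probeset_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(probeset_ids) || is.null(sample_ids))
    stop("expression matrix must carry probeset and sample names")
  dup_p <- unique(probeset_ids[duplicated(probeset_ids)])
  if (length(dup_p) > 0L) stop("duplicate probeset id(s): ", paste(dup_p, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0L) stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (any(values < 0)) stop("expression intensities must be nonnegative")

  missing_in_matrix <- setdiff(design$sample_id, sample_ids)
  if (length(missing_in_matrix) > 0L)
    stop("sample sheet sample(s) absent from matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  missing_in_sheet <- setdiff(sample_ids, design$sample_id)
  if (length(missing_in_sheet) > 0L)
    stop("matrix sample(s) absent from sample sheet: ",
         paste(missing_in_sheet, collapse = ", "))
  dup_sheet <- unique(design$sample_id[duplicated(design$sample_id)])
  if (length(dup_sheet) > 0L)
    stop("duplicate sample id(s) in sample sheet: ", paste(dup_sheet, collapse = ", "))

  bad_lvl <- !(design$factor1 %in% c("control", "treated")) |
    !(design$factor2 %in% c("control", "treated"))
  if (any(bad_lvl))
    stop("factor levels must be 'control' or 'treated'; offending sample(s): ",
         paste(design$sample_id[bad_lvl], collapse = ", "))
  if (anyNA(design$replicate) || any(design$replicate < 1L))
    stop("replicate indices must be integers >= 1")

  design <- design[match(sample_ids, design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  cell <- table(design$factor1, design$factor2)
  if (any(dim(cell) != c(2L, 2L)) || any(cell < 2L))
    stop("each of the 4 design cells needs >= 2 replicates; cell counts: ",
         paste(as.vector(cell), collapse = ", "))

  structure(list(values = values,
                 probeset_ids = probeset_ids,
                 sample_ids = sample_ids,
                 design = design),
            class = "ExpressionBundle")
}

#' @export
print.ExpressionBundle <- function(x, ...) {
  cat(sprintf("ExpressionBundle: %d probesets x %d samples (2x2 design, %s replicates/cell)\n",
              nrow(x$values), ncol(x$values),
              paste(sort(unique(as.vector(table(x$design$factor1, x$design$factor2)))),
                    collapse = "/")))
  invisible(x)
}

#' Read a probeset-to-gene mapping table
#'
#' Two-column TSV (`probeset_id`, `gene_id`); many probesets may map to one
#' gene, each probeset at most once.
#'
#' @param path path to the mapping TSV (with header).
#' @return named character vector: `gene_id` values named by probeset id.
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("probeset_id", "gene_id") %in% colnames(tab)))
    stop("gene map needs columns probeset_id and gene_id")
  gene_map(stats::setNames(tab$gene_id, tab$probeset_id))
}

#' Validate a probeset-to-gene map
#' @param map named character vector (names = probeset ids, values = gene ids).
#' @return the validated map.
#' @export
gene_map <- function(map) {
  if (is.null(names(map)) || any(names(map) == ""))
    stop("gene map must be named by probeset id")
  dup <- unique(names(map)[duplicated(names(map))])
  if (length(dup) > 0L) stop("probeset(s) mapped more than once: ", paste(dup, collapse = ", "))
  if (any(is.na(map) | map == "")) stop("gene ids must be non-empty strings")
  map
}

#' Read a one-gene-per-line list (e.g. ChIP-derived bound genes)
#' @param path path to the text file.
#' @return character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[x != ""])
}
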