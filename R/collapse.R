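#' Collapse probeset-level calls to gene-level calls
#'
#' Applies the conservative Unigene-style rule: a gene is retained only when
#' all of its probesets carry the same response pattern; genes whose
#' probesets disagree are dropped (reason `pattern-conflict`) so downstream
#' enrichment never counts an ambiguous gene. The retained gene inherits the
#' shared category and is represented by its probeset with the highest mean
#' intensity. Unmapped probesets pass through as singleton pseudo-genes,
#' flagged in the `pseudo` column.
#'
#' @param calls data.frame from [classify_probesets()].
#' @param map named character vector mapping probeset id to gene id (see
#'   [gene_map()]).
#' @param mean_intensity optional named numeric vector of per-probeset mean
#'   intensities used to pick the representative probeset; when absent the
#'   lexicographically first probeset is used.
#' @param by pattern granularity: `"category"` (default) compares category
#'   labels only; `"category_direction"` also requires matching directions.
#' @return list with `gene_calls` (data.frame `gene_id`, `category`,
#'   `representative_probeset`, `n_probesets`, `pseudo`) and `dropped`
#'   (data.frame `gene_id`, `reason`, `labels`).
#' @export
collapse_genes <- function(calls, map, mean_intensity = NULL,
                           by = c("category", "category_direction")) {
  by <- match.arg(by)
  if (length(map) == 0L) stop("empty gene map")
  map <- gene_map(map)

  gene <- unname(map[calls$probeset_id])
  pseudo <- is.na(gene)
  gene[pseudo] <- calls$probeset_id[pseudo]

  pattern <- calls$category
  if (by == "category_direction")
    pattern <- paste(calls$category, calls$dir_factor1, calls$dir_factor2, sep = "|")

  rank_val <- if (!is.null(mean_intensity)) {
    v <- unname(mean_intensity[calls$probeset_id])
    if (anyNA(v)) stop("mean_intensity missing for some probesets")
    v
  } else {
    -xtfrm(calls$probeset_id)  # fall back: first probeset by id order
  }

  idx <- split(seq_len(nrow(calls)), gene)
  retained <- list(); dropped <- list()
  for (g in names(idx)) {
    rows <- idx[[g]]
    pats <- unique(pattern[rows])
    if (length(pats) == 1L) {
      rep_row <- rows[[which.max(rank_val[rows])]]
      retained[[g]] <- data.frame(gene_id = g,
                                  category = calls$category[[rep_row]],
                                  representative_probeset = calls$probeset_id[[rep_row]],
                                  n_probesets = length(rows),
                                  pseudo = pseudo[[rows[[1L]]]],
                                  stringsAsFactors = FALSE)
    } else {
      dropped[[g]] <- data.frame(gene_id = g, reason = "pattern-conflict",
                                 labels = paste(sort(pats), collapse = ","),
                                 stringsAsFactors = FALSE)
    }
  }
  gene_calls <- if (length(retained)) do.call(rbind, unname(retained)) else
    data.frame(gene_id = character(0L), category = character(0L),
               representative_probeset = character(0L), n_probesets = integer(0L),
               pseudo = logical(0L), stringsAsFactors = FALSE)
  dropped_df <- if (length(dropped)) do.call(rbind, unname(dropped)) else
    data.frame(gene_id = character(0L), reason = character(0L),
               labels = character(0L), stringsAsFactors = FALSE)
  list(gene_calls = gene_calls, dropped = dropped_df)
}
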