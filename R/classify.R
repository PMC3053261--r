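#' Classification settings for the four-category response scheme
#'
#' @param alpha_fdr per-family FDR threshold (default 0.01).
#' @param fold_threshold linear fold-change filter (default 2.0).
#' @return `ClassifyConfig` list.
#' @export
classify_config <- function(alpha_fdr = 0.01, fold_threshold = 2.0) {
  stopifnot(alpha_fdr > 0, alpha_fdr < 1, fold_threshold >= 1)
  list(alpha_fdr = alpha_fdr, fold_threshold = fold_threshold)
}

#' Assign probesets to the four response categories
#'
#' Categories: `D` ("interactive") when the interaction q-value is below
#' `alpha_fdr`; otherwise `C` ("additive") when both main effects are
#' significant; `A` ("knock-down only") or `B` ("cytokine only") for a single
#' significant main effect; `none` otherwise. The interaction dominates: a
#' probeset with significant interaction is `D` regardless of its main
#' effects, since "additive" is defined by the absence of interaction.
#'
#' Directions are reported per significant main factor as the sign of that
#' factor's marginal log2 contrast. The fold change is the largest linear
#' ratio over the category-relevant contrasts: the factor-1 marginal for `A`,
#' the factor-2 marginal for `B`, both marginals for `C`, and the three
#' treated-cell-vs-control contrasts for `D`.
#'
#' @param records ANOVA table from [anova_two_way()] with q-values (see
#'   [add_fdr()]; computed here if absent).
#' @param config a [classify_config()].
#' @return data.frame with `probeset_id`, `category`, `dir_factor1`,
#'   `dir_factor2`, `fold_change`, `passes_2fold`.
#' @export
classify_probesets <- function(records, config = classify_config()) {
  if (is.null(records$q1)) records <- add_fdr(records)
  a <- config$alpha_fdr
  sig1 <- records$q1 < a
  sig2 <- records$q2 < a
  sig12 <- records$q12 < a
  category <- ifelse(sig12, "D",
              ifelse(sig1 & sig2, "C",
              ifelse(sig1, "A",
              ifelse(sig2, "B", "none"))))

  dir_of <- function(contrast, sig) ifelse(sig, ifelse(contrast >= 0, "up", "down"), "n/a")
  dir1 <- dir_of(records$contrast1, sig1)
  dir2 <- dir_of(records$contrast2, sig2)

  marg1 <- abs(records$contrast1)
  marg2 <- abs(records$contrast2)
  cell_max <- pmax(abs(records$m_cyt - records$m_ctrl),
                   abs(records$m_sh - records$m_ctrl),
                   abs(records$m_both - records$m_ctrl))
  log2fold <- ifelse(category == "A", marg1,
              ifelse(category == "B", marg2,
              ifelse(category == "D", cell_max, pmax(marg1, marg2))))
  fold <- 2^log2fold

  data.frame(probeset_id = records$probeset_id,
             category = category,
             dir_factor1 = dir1,
             dir_factor2 = dir2,
             fold_change = fold,
             passes_2fold = fold >= config$fold_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count category membership at both cut-offs, with directions
#'
#' Mirrors the study's summary tables: per category, probeset counts under
#' the FDR-only cut-off and under FDR plus the fold-change filter, split by
#' direction of each factor where defined.
#'
#' @param calls data.frame from [classify_probesets()].
#' @return data.frame with one row per category (`A`, `B`, `C`, `D`, `none`)
#'   and columns `n_fdr`, `n_2fold`, `up_factor1`, `down_factor1`,
#'   `up_factor2`, `down_factor2`.
#' @export
summarize_categories <- function(calls) {
  cats <- c("A", "B", "C", "D", "none")
  count <- function(mask) vapply(cats, function(k) sum(mask & calls$category == k), integer(1L))
  all_true <- rep(TRUE, nrow(calls))
  data.frame(category = cats,
             n_fdr = count(all_true),
             n_2fold = count(calls$passes_2fold),
             up_factor1 = count(calls$dir_factor1 == "up"),
             down_factor1 = count(calls$dir_factor1 == "down"),
             up_factor2 = count(calls$dir_factor2 == "up"),
             down_factor2 = count(calls$dir_factor2 == "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap shares between the two factors' responsive probeset sets
#'
#' From category counts, the share of factor-2 (cytokine) responsive
#' probesets that are also factor-1 responsive, `(C + D) / (B + C + D)`, and
#' the factor-1 share `(C + D) / (A + C + D)`, at both the FDR-only and the
#' FDR + fold cut-offs. A zero denominator yields `NA` (undefined), not an
#' error.
#'
#' @param summary data.frame from [summarize_categories()], or a named
#'   numeric vector / list with entries `A`, `B`, `C`, `D` (one cut-off).
#' @return data.frame with columns `cutoff`, `share_factor2_also_factor1`,
#'   `share_factor1_also_factor2` (proportions in `[0, 1]` or `NA`).
#' @export
report_overlap_shares <- function(summary) {
  one <- function(a, b, c, d, label) {
    s2 <- if ((b + c + d) > 0) (c + d) / (b + c + d) else NA_real_
    s1 <- if ((a + c + d) > 0) (c + d) / (a + c + d) else NA_real_
    data.frame(cutoff = label,
               share_factor2_also_factor1 = s2,
               share_factor1_also_factor2 = s1,
               stringsAsFactors = FALSE)
  }
  if (is.data.frame(summary)) {
    g <- function(col, k) summary[[col]][summary$category == k]
    rbind(one(g("n_fdr", "A"), g("n_fdr", "B"), g("n_fdr", "C"), g("n_fdr", "D"), "fdr"),
          one(g("n_2fold", "A"), g("n_2fold", "B"), g("n_2fold", "C"), g("n_2fold", "D"),
              "fdr+fold"))
  } else {
    s <- as.list(summary)
    one(s$A, s$B, s$C, s$D, "fdr")
  }
}
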