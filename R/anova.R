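#' Two-way fixed-effects ANOVA across probesets of a balanced 2x2 design
#'
#' Computes, for every probeset, the classical decomposition
#' `SS_total = SS_1 + SS_2 + SS_12 + SS_E` on log2-scale intensities and the
#' F statistics `MS_effect / MS_E` with (1, 4(r-1)) degrees of freedom for
#' the two main effects (factor 1 = knock-down, factor 2 = cytokines) and
#' their interaction. Only balanced designs are accepted.
#'
#' When `MS_E = 0` (all replicates identical) the result is degenerate but
#' deterministic: `F = 0, p = 1` when the effect sum of squares is also 0,
#' otherwise `F = Inf, p = 0`.
#'
#' @param x numeric matrix of log2 intensities (probesets x samples), or an
#'   `ExpressionBundle` (linear scale; transformed via `log2(value + 1)`).
#' @param design data.frame with `sample_id`, `factor1`, `factor2` matching
#'   the columns of `x`; taken from the bundle when `x` is a bundle.
#' @return data.frame (one row per probeset) with columns `probeset_id`,
#'   cell means `m_ctrl`, `m_cyt`, `m_sh`, `m_both` (log2), marginal log2
#'   contrasts `contrast1`, `contrast2`, interaction contrast `contrast12`,
#'   `F1`, `p1`, `F2`, `p2`, `F12`, `p12`, `df_resid`, `ms_resid`.
#' @export
anova_two_way <- function(x, design = NULL) {
  if (inherits(x, "ExpressionBundle")) {
    design <- x$design
    x <- log2(x$values + 1)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list("p1", names(x)))
  if (is.null(design)) stop("a design is required")
  if (!all(colnames(x) == design$sample_id))
    design <- design[match(colnames(x), design$sample_id), , drop = FALSE]
  i <- as.integer(design$factor1 == "treated")
  j <- as.integer(design$factor2 == "treated")
  cell <- i * 2L + j          # 0=ctrl, 1=cyt, 2=sh, 3=both
  counts <- tabulate(cell + 1L, nbins = 4L)
  if (length(unique(counts)) != 1L)
    stop("unbalanced design: cell replicate counts ",
         paste(counts, collapse = ", "), " (balanced layout required)")
  r <- counts[[1L]]
  if (r < 2L) stop("each design cell needs >= 2 replicates, got ", r)
  n <- 4L * r

  # cell means via group indicator
  ind <- outer(cell, 0:3, "==") / r      # samples x 4
  m <- x %*% ind                         # probesets x 4 cell means
  colnames(m) <- c("m_ctrl", "m_cyt", "m_sh", "m_both")

  c1 <- (m[, "m_sh"] + m[, "m_both"] - m[, "m_ctrl"] - m[, "m_cyt"]) / 2
  c2 <- (m[, "m_cyt"] + m[, "m_both"] - m[, "m_ctrl"] - m[, "m_sh"]) / 2
  c12 <- m[, "m_both"] - m[, "m_sh"] - m[, "m_cyt"] + m[, "m_ctrl"]
  ss1 <- n * c1^2 / 4
  ss2 <- n * c2^2 / 4
  ss12 <- n * c12^2 / 16
  fitted <- m[, cell + 1L, drop = FALSE]
  ss_e <- rowSums((x - fitted)^2)
  df_e <- n - 4L
  ms_e <- ss_e / df_e

  f_and_p <- function(ss_eff) {
    f <- ifelse(ms_e > 0, ss_eff / ms_e,
                ifelse(ss_eff > 0, Inf, 0))
    p <- ifelse(ms_e > 0, stats::pf(ss_eff / ms_e, 1, df_e, lower.tail = FALSE),
                ifelse(ss_eff > 0, 0, 1))
    list(f = f, p = p)
  }
  e1 <- f_and_p(ss1); e2 <- f_and_p(ss2); e12 <- f_and_p(ss12)

  data.frame(probeset_id = rownames(x),
             m, contrast1 = c1, contrast2 = c2, contrast12 = c12,
             F1 = e1$f, p1 = e1$p, F2 = e2$f, p2 = e2$p,
             F12 = e12$f, p12 = e12$p,
             df_resid = df_e, ms_resid = ms_e,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment within one effect family
#'
#' Step-up adjusted q-values applied separately within each effect family
#' (factor 1, factor 2, interaction) across all probesets.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Append per-family q-values to an ANOVA table
#' @param records data.frame from [anova_two_way()].
#' @return the same data.frame with columns `q1`, `q2`, `q12`.
#' @export
add_fdr <- function(records) {
  records$q1 <- fdr_adjust(records$p1)
  records$q2 <- fdr_adjust(records$p2)
  records$q12 <- fdr_adjust(records$p12)
  records
}
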