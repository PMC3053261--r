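#' One-tailed Fisher exact test (over-representation)
#'
#' Hypergeometric upper-tail probability `P(X >= a)` for the 2x2 table
#' `(a, b, c, d)` with margins fixed, where `a` counts target genes inside
#' the set, `b` target genes outside it, `c` non-target genes inside and `d`
#' the remainder. Computed in log space by summing `lchoose` terms through a
#' log-sum-exp, so p-values far below 1e-100 keep full relative precision
#' (retrieve them unexponentiated via `log.p = TRUE`).
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param log.p return the natural-log p-value instead of p.
#' @param lower.tail if `TRUE`, test depletion (`P(X <= a)`) instead of
#'   over-representation.
#' @return the one-tailed p-value (or its natural log).
#' @export
fisher_one_tailed <- function(a, b, c, d, log.p = FALSE, lower.tail = FALSE) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  n <- a + b          # target size
  K <- a + c          # set size
  N <- a + b + c + d
  ks <- if (lower.tail) 0:a else a:min(n, K)
  logs <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  m <- max(logs)
  lp <- if (is.infinite(m)) -Inf else m + log(sum(exp(logs - m)))
  lp <- min(lp, 0)    # guard rounding above 1
  if (log.p) lp else exp(lp)
}

#' Fold enrichment over the chance expectation
#'
#' `fold = (a / n_target) / (K / N)`; the expected in-set count in a target
#' of that size is `n_target * K / N`.
#'
#' @param a observed in-set count within the target.
#' @param n_target target size.
#' @param K set size in the universe.
#' @param N universe size.
#' @return list with `fold` and `expected`.
#' @export
fold_enrichment <- function(a, n_target, K, N) {
  if (n_target <= 0 || K <= 0 || N <= 0) stop("n_target, K and N must be positive")
  list(fold = (a / n_target) / (K / N), expected = n_target * K / N)
}

contingency_result <- function(set_name, a, b, c, d) {
  N <- a + b + c + d
  n_target <- a + b
  K <- a + c
  fe <- if (n_target > 0 && K > 0 && N > 0)
    fold_enrichment(a, n_target, K, N) else list(fold = NA_real_, expected = NA_real_)
  or <- if (b > 0 && c > 0) (a * d) / (b * c) else NA_real_
  data.frame(set = set_name, a = a, b = b, c = c, d = d,
             expected = fe$expected, fold_enrichment = fe$fold,
             odds_ratio = or,
             p = fisher_one_tailed(a, b, c, d),
             log_p = fisher_one_tailed(a, b, c, d, log.p = TRUE),
             stringsAsFactors = FALSE)
}

#' Gene-set over-representation across a collection
#'
#' One one-tailed Fisher test per set, target versus the remainder of the
#' universe; each set is intersected with the universe before testing (the
#' universe is the set of genes represented on the array). With
#' `correction = "bonferroni"` the significance threshold `alpha / m` over
#' the `m` sets is reported alongside the raw p-values.
#'
#' @param target character vector of target gene ids (subset of `universe`).
#' @param collection `GeneSetCollection` (or named list of gene id vectors).
#' @param universe character vector: all genes on the array.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param correction `"bonferroni"` or `"none"`.
#' @return data.frame: one row per set with cells `a,b,c,d`, `expected`,
#'   `fold_enrichment`, `odds_ratio`, `p`, `log_p`, `threshold`,
#'   `significant`.
#' @export
enrich_sets <- function(target, collection, universe, alpha = 0.05,
                        correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  target <- unique(target)
  universe <- unique(universe)
  stray <- setdiff(target, universe)
  if (length(stray) > 0L)
    stop("target gene(s) outside the universe: ",
         paste(utils::head(stray, 10L), collapse = ", "))
  m <- length(collection)
  threshold <- if (correction == "bonferroni" && m > 0L) alpha / m else alpha
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    a <- length(intersect(target, set))
    b <- length(target) - a
    c <- length(set) - a
    d <- length(universe) - a - b - c
    contingency_result(nm, a, b, c, d)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$threshold <- threshold
  out$significant <- out$p < threshold
  out[order(out$p), , drop = FALSE]
}

#' Overlap analysis between two gene sets on a common universe
#'
#' Tests whether the overlap between two gene sets (e.g. ChIP-detected bound
#' genes versus differentially expressed genes) exceeds chance, reporting
#' both conditional shares `|1 n 2| / |1|` and `|1 n 2| / |2|` and the
#' one-tailed Fisher p on the induced 2x2 table.
#'
#' Two table constructions are available. `"exclusive"` (default) keeps the
#' 2x2 cells disjoint: set-1 genes split by set-2 membership against the
#' remaining universe split the same way. `"array"` splits the set-1 genes by
#' set-2 membership but compares against the whole universe's set-2 margin
#' (the comparison column then re-counts the set-1 genes); this is the
#' construction under which the modelled study's printed overlap p-value is
#' recovered.
#'
#' @param set1,set2 character vectors of gene ids, both subsets of
#'   `universe`, both non-empty.
#' @param universe character vector of all gene ids considered.
#' @param margin `"exclusive"` or `"array"` (see above).
#' @return list with `overlap`, `share1` (= overlap/|set1|), `share2`
#'   (= overlap/|set2|) and `result` (the contingency data.frame).
#' @export
overlap_analysis <- function(set1, set2, universe,
                             margin = c("exclusive", "array")) {
  margin <- match.arg(margin)
  set1 <- unique(set1); set2 <- unique(set2); universe <- unique(universe)
  if (length(set1) == 0L || length(set2) == 0L) stop("both sets must be non-empty")
  stray <- c(setdiff(set1, universe), setdiff(set2, universe))
  if (length(stray) > 0L)
    stop("gene(s) outside the universe: ", paste(utils::head(stray, 10L), collapse = ", "))
  a <- length(intersect(set1, set2))
  b <- length(set1) - a
  if (margin == "exclusive") {
    c <- length(set2) - a
    d <- length(universe) - a - b - c
  } else {
    c <- length(set2)
    d <- length(universe) - length(set2)
  }
  list(overlap = a,
       share1 = a / length(set1),
       share2 = a / length(set2),
       result = contingency_result("overlap", a, b, c, d))
}
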