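BASES <- c("A", "C", "G", "T")

seq_to_index <- function(seq) {
  # A=1 C=2 G=3 T=4 N=5
  code <- integer(128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("N")] <- 5L
  idx <- code[utf8ToInt(seq)]
  if (any(idx == 0L)) stop("sequence contains characters outside A,C,G,T,N")
  idx
}

#' Reverse complement of a DNA string (A,C,G,T,N)
#' @param seq character string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1L]]), collapse = ""))
}

#' Extract a promoter window around a TSS
#'
#' Coordinates are 0-based half-open with the TSS at the upstream/downstream
#' boundary. On the plus strand the window is `[TSS - up, TSS + down)`; on
#' the minus strand it is the reverse complement of `[TSS - down, TSS + up)`.
#' Windows running past a contig end are clipped with a warning.
#'
#' @param genome_seq contig sequence (character string).
#' @param tss 0-based TSS position within the contig.
#' @param strand `"+"` or `"-"`.
#' @param up,down upstream/downstream window lengths in bases (defaults
#'   1000 and 500, the -1 kb / +0.5 kb window; the extended scan uses
#'   5000 / 2500).
#' @return promoter sequence (character string), 5' to 3' on the gene strand.
#' @export
extract_promoter <- function(genome_seq, tss, strand = c("+", "-"),
                             up = 1000L, down = 500L) {
  strand <- match.arg(strand)
  len <- nchar(genome_seq)
  if (tss < 0L || tss > len) stop("TSS outside the sequence [0, ", len, "]")
  if (strand == "+") { lo0 <- tss - up; hi0 <- tss + down }
  else { lo0 <- tss - down; hi0 <- tss + up }
  clip_lo <- max(lo0, 0L); clip_hi <- min(hi0, len)
  if (clip_lo > lo0 || clip_hi < hi0)
    warning(sprintf("promoter window [%d, %d) clipped to [%d, %d)",
                    lo0, hi0, clip_lo, clip_hi))
  s <- substr(genome_seq, clip_lo + 1L, clip_hi)
  if (strand == "-") s <- reverse_complement(s)
  toupper(s)
}

#' Build a log-ratio position weight matrix from a PFM
#'
#' Column probabilities are `(count + pseudocount * bg_b) / (total +
#' pseudocount)` — the total pseudocount is spread over the bases by the
#' background composition — and PWM entries are `log2(prob / bg_b)`. A
#' window's score is the sum of its per-position entries; windows containing
#' `N` score `-Inf`.
#'
#' @param pfm 4 x L count matrix, rows A,C,G,T (see [read_jaspar_pfm()]).
#' @param background base frequencies (A,C,G,T), summing to 1.
#' @param pseudocount total pseudocount per column (default 4: one per base
#'   under a uniform background).
#' @param threshold minimum per-window log2-ratio score for a site call
#'   (default 8.0).
#' @param name motif name (defaults from the PFM if unnamed).
#' @return `MotifModel` list: `name`, `pwm` (4 x L), `background`,
#'   `threshold`, `length`, `consensus` (argmax base per column), `pfm`.
#' @export
build_motif_model <- function(pfm, background = rep(0.25, 4), pseudocount = 4,
                              threshold = 8.0, name = "motif") {
  pfm <- validate_pfm(pfm, name)
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive frequencies")
  background <- background / sum(background)
  prob <- sweep(pfm, 2L, colSums(pfm) + pseudocount, "/") +
    (pseudocount * background) / rep(colSums(pfm) + pseudocount, each = 4L)
  pwm <- log2(prob / background)
  rownames(pwm) <- BASES
  structure(list(name = name, pwm = pwm, background = background,
                 threshold = threshold, length = ncol(pwm),
                 consensus = paste(BASES[apply(pwm, 2L, which.max)], collapse = ""),
                 pfm = pfm),
            class = "MotifModel")
}

# 5-row PWM with an -Inf row for N, so any window touching an N scores -Inf
pwm5 <- function(pwm) rbind(pwm, N = -Inf)

# scores of every length-L window of an index vector under a 5-row PWM
window_scores <- function(idx, pwm) {
  L <- ncol(pwm)
  nw <- length(idx) - L + 1L
  if (nw < 1L) return(numeric(0L))
  s <- numeric(nw)
  for (j in seq_len(L)) s <- s + pwm[idx[j:(j + nw - 1L)], j]
  s
}

rc_pwm <- function(pwm) {
  # scoring a window with the reverse-complement PWM equals scoring the
  # window's reverse complement with the original PWM
  out <- pwm[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- BASES
  out
}

#' Scan one sequence for motif sites on both strands
#'
#' Every length-L window on the plus and minus strand is scored as the sum
#' of PWM entries; windows with score at or above the model threshold are
#' reported. Windows containing `N` never match.
#'
#' @param model a [build_motif_model()] result.
#' @param sequence character string over A,C,G,T,N.
#' @return data.frame of hits: `motif`, `offset` (0-based window start on
#'   the given sequence), `strand`, `score`. Empty when the sequence is
#'   shorter than the motif.
#' @export
scan_motif <- function(model, sequence) {
  empty <- data.frame(motif = character(0L), offset = integer(0L),
                      strand = character(0L), score = numeric(0L),
                      stringsAsFactors = FALSE)
  if (nchar(sequence) < model$length) return(empty)
  idx <- seq_to_index(toupper(sequence))
  fwd <- window_scores(idx, pwm5(model$pwm))
  rev_ <- window_scores(idx, pwm5(rc_pwm(model$pwm)))
  hit_f <- which(fwd >= model$threshold)
  hit_r <- which(rev_ >= model$threshold)
  out <- data.frame(
    motif = rep(model$name, length(hit_f) + length(hit_r)),
    offset = c(hit_f, hit_r) - 1L,
    strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
    score = c(fwd[hit_f], rev_[hit_r]),
    stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Motif presence call per promoter
#'
#' A promoter is positive when it contains at least one window scoring at or
#' above the model threshold on either strand. Implemented on the
#' concatenated promoter set (N-spacers block cross-boundary windows) so
#' large sets scan in a single pass per strand.
#'
#' @param promoters `PromoterSet` (named character vector).
#' @param model a `MotifModel`.
#' @return named logical vector, one entry per promoter.
#' @export
motif_presence <- function(promoters, model) {
  n <- length(promoters)
  if (n == 0L) return(stats::setNames(logical(0L), character(0L)))
  lens <- nchar(promoters)
  concat <- paste(unclass(promoters), collapse = "N")
  idx <- seq_to_index(toupper(concat))
  L <- model$length
  starts <- cumsum(c(1L, utils::head(lens, -1L) + 1L))  # 1-based starts in concat
  hit_any <- rep(FALSE, n)
  for (pw in list(pwm5(model$pwm), pwm5(rc_pwm(model$pwm)))) {
    sc <- window_scores(idx, pw)
    pos <- which(sc >= model$threshold)
    if (length(pos) > 0L) {
      owner <- findInterval(pos, starts)
      hit_any[unique(owner)] <- TRUE
    }
  }
  stats::setNames(hit_any, names(promoters))
}

#' Background base composition of a promoter set (0-order)
#' @param promoters `PromoterSet`.
#' @return frequencies of A,C,G,T (N ignored), summing to 1.
#' @export
base_frequencies <- function(promoters) {
  counts <- vapply(BASES, function(b)
    sum(nchar(gsub(paste0("[^", b, "]"), "", unclass(promoters)))), numeric(1L))
  counts / sum(counts)
}

#' Presence-based motif enrichment in target versus background promoters
#'
#' For each motif, promoters are classified by whether they contain at least
#' one site (per-window log2-ratio score at or above the cut-off) and a
#' one-tailed Fisher exact test compares the target against the background
#' set. When the target is a subset of the background (the usual design:
#' background = promoters of all genes on the array) the target promoters
#' are removed from the background before testing so the 2x2 cells are
#' disjoint. The Bonferroni threshold is `alpha / m` over the `m` motifs.
#'
#' @param target `PromoterSet` of the responsive genes' promoters.
#' @param background `PromoterSet` of the array-wide promoters.
#' @param pfms named list of PFMs (count matrices) or `MotifModel`s.
#' @param alpha family-wise error rate (default 0.05).
#' @param threshold score cut-off used when building models from raw PFMs.
#' @param background_freq `"estimate"` (0-order composition of the
#'   background set) or `"uniform"`, used when building models from PFMs.
#' @return data.frame: one row per motif with the 2x2 cells, fold
#'   enrichment, raw `p`, `threshold` (Bonferroni) and `significant`.
#' @export
motif_enrich <- function(target, background, pfms, alpha = 0.05,
                         threshold = 8.0,
                         background_freq = c("estimate", "uniform")) {
  background_freq <- match.arg(background_freq)
  if (length(target) == 0L || length(background) == 0L)
    stop("target and background promoter sets must be non-empty")
  overlap_names <- intersect(names(target), names(background))
  bg <- background[!(names(background) %in% overlap_names)]
  if (length(bg) == 0L)
    stop("background is empty after removing target promoters")
  bg_comp <- if (background_freq == "estimate") base_frequencies(background)
             else rep(0.25, 4)
  models <- lapply(names(pfms), function(nm) {
    p <- pfms[[nm]]
    if (inherits(p, "MotifModel")) p
    else build_motif_model(p, background = bg_comp, threshold = threshold, name = nm)
  })
  m <- length(models)
  bonf <- alpha / m
  rows <- lapply(models, function(model) {
    t_hit <- motif_presence(promoter_set(unclass(target)[names(target)]), model)
    b_hit <- motif_presence(promoter_set(unclass(bg)[names(bg)]), model)
    a <- sum(t_hit); b_ <- sum(!t_hit)
    c_ <- sum(b_hit); d <- sum(!b_hit)
    res <- contingency_result(model$name, a, b_, c_, d)
    res
  })
  out <- do.call(rbind, rows)
  out$threshold <- bonf
  out$significant <- out$p < bonf
  out[order(out$p), , drop = FALSE]
}
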