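# small in-code fixtures shared across test files

toy_design <- function(r = 2L) {
  data.frame(
    sample_id = sprintf("s%02d", seq_len(4L * r)),
    factor1 = rep(c("control", "control", "treated", "treated"), each = r),
    factor2 = rep(c("control", "treated", "control", "treated"), each = r),
    replicate = rep(seq_len(r), times = 4L),
    stringsAsFactors = FALSE)
}

# one-probeset log2 matrix laid out as cells ctrl, cyt, sh, both (r reps each)
toy_log2_matrix <- function(cells, r = 2L, ids = "p1") {
  m <- matrix(cells, nrow = length(ids), byrow = TRUE,
              dimnames = list(ids, sprintf("s%02d", seq_len(4L * r))))
  m
}

# brute-force two-way ANOVA via a least-squares linear model fit
anova_oracle <- function(y, design) {
  f1 <- factor(design$factor1, levels = c("control", "treated"))
  f2 <- factor(design$factor2, levels = c("control", "treated"))
  fit <- stats::aov(y ~ f1 * f2)
  s <- summary(fit)[[1L]]
  rownames(s) <- trimws(rownames(s))
  list(F1 = s["f1", "F value"], p1 = s["f1", "Pr(>F)"],
       F2 = s["f2", "F value"], p2 = s["f2", "Pr(>F)"],
       F12 = s["f1:f2", "F value"], p12 = s["f1:f2", "Pr(>F)"],
       ss = s[, "Sum Sq"])
}

# exhaustive hypergeometric upper tail through the pmf
fisher_oracle <- function(a, b, c, d) {
  n <- a + b; K <- a + c; N <- a + b + c + d
  sum(stats::dhyper(a:min(n, K), K, N - K, n))
}

# naive per-window rescorer for motif scans
naive_window_scores <- function(model, sequence) {
  L <- model$length
  chars <- strsplit(toupper(sequence), "")[[1L]]
  nw <- length(chars) - L + 1L
  if (nw < 1L) return(numeric(0L))
  vapply(seq_len(nw), function(i) {
    win <- chars[i:(i + L - 1L)]
    if (any(win == "N")) return(-Inf)
    sum(vapply(seq_len(L), function(j) model$pwm[win[[j]], j], numeric(1L)))
  }, numeric(1L))
}
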