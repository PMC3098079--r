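#' Normality gate
#'
#' Shapiro-Wilk test at `alpha` (default 0.05). A degenerate
#' (zero-variance) sample fails. Shapiro-Wilk accepts at most 5000
#' observations; larger samples are gated on a deterministic evenly-spaced
#' subsample of 5000.
#'
#' @param x Numeric sample, `n >= 3`.
#' @param alpha Gate level.
#' @return List of class `normality_gate`: `pass` (logical), `p`, `n`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("normality gate needs n >= 3")
  if (stats::sd(x) == 0)
    return(structure(list(pass = FALSE, p = NA_real_, n = length(x)),
                     class = "normality_gate"))
  xs <- if (length(x) > 5000L)
    x[round(seq(1L, length(x), length.out = 5000L))] else x
  p <- stats::shapiro.test(xs)$p.value
  structure(list(pass = p >= alpha, p = p, n = length(x)),
            class = "normality_gate")
}

#' Compare two samples with a normality-gated test
#'
#' The genre-comparison testing procedure: when both samples pass the
#' normality gate, a two-sample two-tailed t-test (Welch); otherwise a
#' two-sided Mann-Whitney U test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise, as implemented by
#' [stats::wilcox.test()]). A paired Wilcoxon signed-rank variant is
#' available for per-document paired designs.
#'
#' @param a,b Numeric samples, each `n >= 3`.
#' @param feature Label carried into the result.
#' @param method `"auto"` (gate-selected, default), `"t_test"`, `"mww"`, or
#'   `"wilcoxon_signed_rank"` (paired; requires equal lengths).
#' @param normality_alpha Gate level.
#' @param m Number of comparisons for Bonferroni adjustment (default 1).
#' @return List of class `genre_comparison`: `feature`, `test`, `p`,
#'   `p_adjusted`, `m`, `normality_p` (length 2), `direction` (sign of
#'   `median(a) - median(b)`), `n` (length 2).
#' @export
compare_samples <- function(a, b, feature = "feature",
                            method = c("auto", "t_test", "mww",
                                       "wilcoxon_signed_rank"),
                            normality_alpha = 0.05, m = 1L) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L) stop("both samples need n >= 3")
  ga <- normality_gate(a, normality_alpha)
  gb <- normality_gate(b, normality_alpha)
  if (method == "auto")
    method <- if (ga$pass && gb$pass) "t_test" else "mww"
  p <- switch(method,
    t_test = stats::t.test(a, b, alternative = "two.sided")$p.value,
    mww = suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided")$p.value),
    wilcoxon_signed_rank = {
      if (length(a) != length(b))
        stop("paired signed-rank test requires equal-length samples")
      suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE,
                           alternative = "two.sided")$p.value)
    })
  structure(list(feature = feature, test = method, p = p,
                 p_adjusted = bonferroni(p, m), m = as.integer(m),
                 normality_p = c(a = ga$p, b = gb$p),
                 direction = sign(stats::median(a) - stats::median(b)),
                 n = c(a = length(a), b = length(b))),
            class = "genre_comparison")
}

#' @export
print.genre_comparison <- function(x, ...) {
  cat(sprintf("%s: %s p=%.4g (adjusted %.4g, m=%d), direction %+d\n",
              x$feature, x$test, x$p, x$p_adjusted, x$m, x$direction))
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` for `m` comparisons.
#'
#' @param p P-value(s) in \[0, 1\].
#' @param m Number of comparisons, `>= 1`.
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  if (any(m < 1)) stop("m must be >= 1")
  pmin(1, p * m)
}

#' Pairwise section comparison matrix
#'
#' Compares every pair of section samples (e.g. sentence lengths per
#' article section) with [compare_samples()], Bonferroni-adjusts over the
#' `choose(k, 2)` comparisons, and marks which pairs differ significantly
#' at `alpha`.
#'
#' @param samples Named list of `>= 2` numeric samples.
#' @param alpha Significance level applied to adjusted p-values (default
#'   0.01).
#' @param ... Passed to [compare_samples()].
#' @return List of class `section_matrix`: `significant` (logical k x k
#'   matrix, `NA` diagonal), `p_adjusted` (numeric matrix), `m`, `alpha`,
#'   `comparisons` (data frame of all pairs).
#' @export
pairwise_section_matrix <- function(samples, alpha = 0.01, ...) {
  k <- length(samples)
  stopifnot(k >= 2L, !is.null(names(samples)))
  m <- choose(k, 2L)
  nms <- names(samples)
  sig <- matrix(NA, k, k, dimnames = list(nms, nms))
  padj <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  rows <- NULL
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    cmp <- compare_samples(samples[[i]], samples[[j]],
                           feature = paste(nms[i], "vs", nms[j]),
                           m = m, ...)
    sig[i, j] <- sig[j, i] <- cmp$p_adjusted < alpha
    padj[i, j] <- padj[j, i] <- cmp$p_adjusted
    rows <- rbind(rows, data.frame(
      a = nms[i], b = nms[j], test = cmp$test, p = cmp$p,
      p_adjusted = cmp$p_adjusted, significant = cmp$p_adjusted < alpha,
      stringsAsFactors = FALSE))
  }
  structure(list(significant = sig, p_adjusted = padj, m = m,
                 alpha = alpha, comparisons = rows),
            class = "section_matrix")
}
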