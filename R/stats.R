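#' Compare three or more groups: Kruskal-Wallis plus pairwise Mann-Whitney
#'
#' Omnibus Kruskal-Wallis rank-sum test across all groups, followed by all
#' pairwise two-sided Mann-Whitney U tests with Bonferroni correction
#' (`p_adj = min(1, m * p)` with `m` the number of pairwise comparisons).
#' Each pairwise test is exact when both groups have at most 8 observations
#' and there are no ties, and otherwise uses the normal approximation with
#' tie-corrected variance.
#'
#' @param groups named or unnamed list of numeric samples (>= 2 groups,
#'   each n >= 2).
#' @param alpha significance level recorded with the result.
#' @return an object of class `"groupComparison"`: list with `omnibus` (the
#'   `htest` from [stats::kruskal.test()]), `pairwise` (data.frame with
#'   statistic, raw and adjusted p, group sizes), `m` and `alpha`.
#' @examples
#' set.seed(1)
#' groupCompare(list(a = rnorm(8), b = rnorm(8), c = rnorm(8, 2)))
#' @export
groupCompare <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 observations")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))

  omnibus <- stats::kruskal.test(groups)
  cmb <- utils::combn(length(groups), 2L)
  m <- ncol(cmb)
  pw <- lapply(seq_len(m), function(k) {
    i <- cmb[1L, k]; j <- cmb[2L, k]
    xi <- groups[[i]]; xj <- groups[[j]]
    noTies <- !anyDuplicated(c(xi, xj))
    useExact <- length(xi) <= 8L && length(xj) <= 8L && noTies
    ht <- suppressWarnings(stats::wilcox.test(
      xi, xj, alternative = "two.sided", exact = useExact, correct = FALSE))
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               U = unname(ht$statistic), p = ht$p.value,
               n1 = length(xi), n2 = length(xj), exact = useExact)
  })
  pairwise <- do.call(rbind, pw)
  pairwise$p_adj <- pmin(1, m * pairwise$p)
  structure(list(omnibus = omnibus, pairwise = pairwise, m = m,
                 alpha = alpha),
            class = "groupComparison")
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              unname(x$omnibus$statistic), unname(x$omnibus$parameter),
              x$omnibus$p.value))
  cat(sprintf("Pairwise Mann-Whitney U (Bonferroni, m = %d):\n", x$m))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Paired comparison of serial measurements
#'
#' Two-sided paired test between baseline and follow-up: the Wilcoxon
#' matched-pairs signed-rank test (zero differences are dropped and their
#' count reported) or the paired t-test.
#'
#' @param x0,x7 paired measurements (equal length, n >= 2).
#' @param method `"wilcoxon"` or `"paired_t"`.
#' @return list of class `"pairedTest"` with `method`, `statistic`, `p`,
#'   `n`, `zerosDropped`.
#' @export
pairedCompare <- function(x0, x7, method = c("wilcoxon", "paired_t")) {
  method <- match.arg(method)
  if (length(x0) != length(x7)) stop("x0 and x7 must have equal length")
  n <- length(x0)
  if (n < 2L) stop("need at least 2 pairs")
  if (method == "wilcoxon") {
    d <- x7 - x0
    nz <- sum(d != 0)
    if (nz == 0L)
      stop("degenerate input: all paired differences are zero")
    ht <- suppressWarnings(stats::wilcox.test(x7, x0, paired = TRUE,
                                              alternative = "two.sided"))
    out <- list(method = "wilcoxon signed-rank",
                statistic = unname(ht$statistic), p = ht$p.value,
                n = n, zerosDropped = n - nz)
  } else {
    d <- x7 - x0
    if (stats::sd(d) == 0 && mean(d) != 0) {
      ## exact constant shift: variance 0 makes t undefined; a negligible
      ## deterministic jitter yields the limiting (vanishing) p-value
      eps <- 1e-12 * max(abs(mean(d)), 1)
      x7 <- x7 + eps * (seq_along(x7) - (length(x7) + 1) / 2)
    }
    ht <- stats::t.test(x7, x0, paired = TRUE)
    out <- list(method = "paired t", statistic = unname(ht$statistic),
                p = ht$p.value, n = n, zerosDropped = 0L)
  }
  structure(out, class = "pairedTest")
}

#' @export
print.pairedTest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d, %d zero difference(s) dropped)\n",
              x$method, x$statistic, x$p, x$n, x$zerosDropped))
  invisible(x)
}

#' Normality-gated correlation
#'
#' Pearson correlation when both variables pass the Shapiro-Wilk normality
#' test at `alpha`, Spearman rank correlation otherwise; the choice is
#' recorded in the result.
#'
#' @param x,y numeric vectors, equal length, n >= 4, non-constant.
#' @param alpha Shapiro-Wilk significance level for the gate.
#' @return list of class `"gatedCorrelation"` with `method`, `r`, `p`, `n`
#'   and the two Shapiro-Wilk p-values.
#' @examples
#' set.seed(1); x <- rnorm(30)
#' gatedCorrelation(x, 2 * x + 1)
#' @export
gatedCorrelation <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  swx <- stats::shapiro.test(x)$p.value
  swy <- stats::shapiro.test(y)$p.value
  method <- if (swx > alpha && swy > alpha) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  structure(list(method = method, r = unname(ct$estimate), p = ct$p.value,
                 n = n, shapiroP = c(x = swx, y = swy)),
            class = "gatedCorrelation")
}

#' @export
print.gatedCorrelation <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4g, p = %.4g (n = %d)\n",
              x$method, x$r, x$p, x$n))
  invisible(x)
}
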