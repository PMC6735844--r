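# Differential expression: combined discrete + continuous likelihood-ratio
# test (two-part / hurdle model) between two groups of cells.
#
# The discrete part models whether a gene is expressed at all (Bernoulli
# on/off, binomial likelihood on the expressing-cell counts); the
# continuous part models log2 expression among expressing cells (normal
# with shared variance). The combined statistic is the sum of the two
# likelihood-ratio deviances; its null distribution is chi-square with
# 2 degrees of freedom (1 when the continuous part is untestable).

.EPS_VAR <- 1e-8   # variance floor guarding genes with zero variance

.binomLL <- function(z, n, p) {
  # 0*log(0) = 0 convention
  t1 <- if (z > 0) z * log(p) else 0
  t2 <- if (n - z > 0) (n - z) * log(1 - p) else 0
  t1 + t2
}

.normLL <- function(ss, n, v) -n / 2 * log(2 * pi * v) - ss / (2 * v)

#' Combined two-part likelihood-ratio test for one gene
#'
#' Tests whether the distribution of a gene's (normalized) counts differs
#' between two groups of cells, combining:
#' \itemize{
#'   \item a *discrete* component: binomial LRT on the fraction of cells
#'     expressing the gene (count > 0);
#'   \item a *continuous* component: normal LRT on `log2(count)` among
#'     expressing cells with a shared variance (MLE denominators), tested
#'     only when both groups have at least one expressing cell and the
#'     pooled positive-value variance is positive.
#' }
#' The statistic is the sum of the two deviances, referred to a chi-square
#' with df = 2 (or df = 1 when only the discrete part is testable).
#' Variances are floored at `1e-8` before likelihood evaluation so genes
#' with zero within-group variance (e.g. expressed at one value) remain
#' testable.
#'
#' @param countsA,countsB numeric vectors of (normalized) counts for the
#'   cells of each group; both non-empty.
#' @return list with `statistic`, `df`, `p.value`.
#' @examples
#' combinedLRT(c(0, 2, 4), c(0, 2, 4))   # statistic 0, p = 1
#' @export
combinedLRT <- function(countsA, countsB) {
  if (!length(countsA) || !length(countsB))
    stop("both groups must contain at least one cell")
  na <- length(countsA); nb <- length(countsB)
  za <- sum(countsA > 0); zb <- sum(countsB > 0)

  pp <- (za + zb) / (na + nb)
  dDisc <- 2 * (.binomLL(za, na, if (na > 0) za / na else 0.5) +
                .binomLL(zb, nb, if (nb > 0) zb / nb else 0.5) -
                .binomLL(za + zb, na + nb, pp))

  dCont <- 0; df <- 1L
  if (za >= 1 && zb >= 1) {
    ya <- log2(countsA[countsA > 0]); yb <- log2(countsB[countsB > 0])
    y <- c(ya, yb); N <- za + zb
    ssPool <- sum((y - mean(y))^2)
    vPool <- ssPool / N
    if (vPool > 0) {
      ssSep <- sum((ya - mean(ya))^2) + sum((yb - mean(yb))^2)
      vSep <- ssSep / N
      dCont <- 2 * (.normLL(ssSep, N, max(vSep, .EPS_VAR)) -
                    .normLL(ssPool, N, max(vPool, .EPS_VAR)))
      df <- 2L
    }
  }
  stat <- max(dDisc + dCont, 0)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up adjustment;
#' `NA` p-values are carried through and excluded from the test count `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjustPValues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = if (method == "bh") "BH" else "bonferroni")
  out
}

#' Adjusted log2 fold change
#'
#' `log2((meanA + delta) / (meanB + delta))`: a pseudo-mean `delta` is
#' added to both group means so the fold change stays finite and shrinks
#' toward 0 for lowly expressed genes.
#'
#' @param meanA,meanB group mean expression (non-negative).
#' @param delta pseudo-mean, > 0 (default 1).
#' @return signed log2 fold change (positive when A > B).
#' @export
foldChange <- function(meanA, meanB, delta = 1) {
  if (any(delta <= 0)) stop("delta must be positive")
  log2((meanA + delta) / (meanB + delta))
}

#' Differential expression between cell groups
#'
#' Applies [combinedLRT()] gene by gene, comparing the cells whose `group`
#' metadata label is in `conditionA` against those in `conditionB`
#' (typically one cluster against the remaining clusters). Genes expressed
#' in no cell of either group are reported with `NA` p-values and excluded
#' from the multiple-testing count.
#'
#' @param x a [CellSet-class] (normalized counts recommended).
#' @param group name of a cell metadata column (e.g. `"cluster"`).
#' @param conditionA,conditionB label(s) defining the two groups; must be
#'   non-overlapping and non-empty.
#' @param correction multiple-testing correction, `"bonferroni"` (default)
#'   or `"bh"`.
#' @param delta pseudo-mean for the adjusted fold change (default 1).
#' @return data.frame ordered by p-value then decreasing `|log2FC|`, with
#'   columns `gene_id`, `lrt_statistic`, `df`, `p_value`, `adjusted_p`,
#'   `log2_fold_change`, `mean_a`, `mean_b`, `pct_expressing_a`,
#'   `pct_expressing_b`.
#' @export
runDiffExpression <- function(x, group, conditionA, conditionB,
                              correction = c("bonferroni", "bh"), delta = 1) {
  .assertCellSet(x)
  correction <- match.arg(correction)
  cd <- colData(x)
  if (!group %in% colnames(cd))
    stop(sprintf("no cell metadata column '%s'", group))
  labels <- as.character(cd[[group]])
  conditionA <- as.character(conditionA); conditionB <- as.character(conditionB)
  if (length(intersect(conditionA, conditionB)))
    stop("conditionA and conditionB overlap")
  unknown <- setdiff(c(conditionA, conditionB), unique(labels))
  if (length(unknown))
    stop(sprintf("unknown group label(s): %s", paste(unknown, collapse = ", ")))
  selA <- labels %in% conditionA
  selB <- labels %in% conditionB
  if (!any(selA) || !any(selB)) stop("both conditions must select cells")

  mA <- as.matrix(assay(x, "counts")[, selA, drop = FALSE])
  mB <- as.matrix(assay(x, "counts")[, selB, drop = FALSE])
  nG <- nrow(x)
  stat <- df <- p <- rep(NA_real_, nG)
  for (g in seq_len(nG)) {
    a <- mA[g, ]; b <- mB[g, ]
    if (all(a == 0) && all(b == 0)) next  # untestable: never expressed here
    r <- combinedLRT(a, b)
    stat[g] <- r$statistic; df[g] <- r$df; p[g] <- r$p.value
  }
  meanA <- rowMeans(mA); meanB <- rowMeans(mB)
  res <- data.frame(
    gene_id = rownames(x),
    lrt_statistic = stat,
    df = as.integer(df),
    p_value = p,
    adjusted_p = adjustPValues(p, correction),
    log2_fold_change = foldChange(meanA, meanB, delta),
    mean_a = meanA, mean_b = meanB,
    pct_expressing_a = 100 * rowMeans(mA > 0),
    pct_expressing_b = 100 * rowMeans(mB > 0),
    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$p_value, -abs(res$log2_fold_change)), , drop = FALSE]
}
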