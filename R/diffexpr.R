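# Exact two-library differential expression after Audic & Claverie
# (1997): per-million normalized expression, log2 fold-change, the
# conditional Poisson test, Benjamini-Hochberg FDR and significance
# classes.
#
# The conditional law of the count y in library 2 given x in library 1
# (with totals N1, N2) is
#   p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)),
# which is a negative binomial with size x+1 and success probability
# N1/(N1+N2); tails are therefore computed with pnbinom, exact and
# stable at library-scale counts (no explicit factorials).

#' Normalized expression (transcripts per million)
#'
#' `NE = 1e6 * count / total`, the actual read count of a feature
#' scaled by the total clean reads of its library.
#'
#' @param count non-negative read count(s).
#' @param total positive library total (clean reads).
#' @return normalized expression, per million.
#' @export
#' @examples
#' normalize_expression(1929430, 15627457)
normalize_expression <- function(count, total) {
  check_that(all(total > 0), "`total` must be positive")
  check_that(all(count >= 0), "`count` must be non-negative")
  1e6 * count / total
}

#' Log2 fold-change of normalized expression
#'
#' `log2(ne1 / ne2)`, with a pseudocount added only to zero entries so
#' printed nonzero ratios are untouched. Features with both entries
#' zero are undefined and return `NA` (excluded from DE calling).
#'
#' @param ne1,ne2 normalized expression in library 1 (fetal) and
#'   library 2 (six-month), per million.
#' @param pseudo pseudocount in per-million units, added to zero
#'   entries only (default 0.01).
#' @return log2 fold-change; `NA` where both inputs are zero.
#' @export
log2_fold_change <- function(ne1, ne2, pseudo = 0.01) {
  check_that(all(ne1 >= 0) && all(ne2 >= 0), "NE values must be non-negative")
  check_that(pseudo > 0, "`pseudo` must be positive")
  both0 <- ne1 == 0 & ne2 == 0
  r <- log2((ne1 + pseudo * (ne1 == 0)) / (ne2 + pseudo * (ne2 == 0)))
  r[both0] <- NA_real_
  r
}

#' Exact two-library Poisson test (Audic-Claverie)
#'
#' Two-sided p-value for a count difference between two sequencing
#' libraries under Poisson sampling, conditioning on the combined
#' count: twice the smaller tail of the conditional law of `y` given
#' `x`, capped at 1. Computed via the negative-binomial identity (see
#' source), exact and numerically stable at `x + y` of order 1e7.
#'
#' A feature with zero counts in both libraries carries no evidence
#' and returns p = 1. The conditional law fixes the library-1 count,
#' so the test is exactly exchange-symmetric only for equal totals
#' (the two conditionals differ by the factor `N1/N2` on the pmf);
#' for unequal totals the swapped p agrees closely but not exactly.
#'
#' @param x,y non-negative counts in libraries 1 and 2.
#' @param n1,n2 positive library totals.
#' @return two-sided p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' audic_claverie_p(5, 1, 1000, 1000)
audic_claverie_p <- function(x, y, n1, n2) {
  check_that(all(x >= 0) && all(y >= 0), "counts must be non-negative")
  check_that(all(n1 > 0) && all(n2 > 0), "library totals must be positive")
  check_that(all(x == round(x)) && all(y == round(y)),
             "counts must be integers")
  prob <- n1 / (n1 + n2)
  lower <- pnbinom(y, size = x + 1, prob = prob)
  upper <- pnbinom(y - 1, size = x + 1, prob = prob, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[x == 0 & y == 0] <- 1
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the false discovery rate, in input
#' order. Delegates to [stats::p.adjust()] after validating the
#' domain.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  check_that(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)),
             "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

DE_CLASSES <- c("up", "down", "not_de")
SCATTER_CLASSES <- c("fold>2", "1/2<fold<=2", "fold<=1/2")

#' Call differential expression
#'
#' A feature is `up` if `fdr <= fdr_max` and `log2fc >= log2_min`,
#' `down` if `fdr <= fdr_max` and `log2fc <= -log2_min`, otherwise
#' `not_de`. Defaults are the published screen: FDR <= 0.001 and
#' |log2 ratio| >= 1.
#'
#' @param fdr adjusted p-values.
#' @param log2fc log2 fold-changes (`NA` allowed; called `not_de`).
#' @param fdr_max,log2_min thresholds.
#' @return factor with levels `up`, `down`, `not_de`.
#' @export
classify_de <- function(fdr, log2fc, fdr_max = 0.001, log2_min = 1) {
  out <- rep("not_de", length(fdr))
  sig <- !is.na(fdr) & !is.na(log2fc) & fdr <= fdr_max
  out[sig & log2fc >= log2_min] <- "up"
  out[sig & log2fc <= -log2_min] <- "down"
  factor(out, levels = DE_CLASSES)
}

#' Scatter-plot fold-change class
#'
#' The three colour classes of the expression scatter plot: ratio
#' `ne1/ne2 > 2`, `1/2 < ratio <= 2`, and `ratio <= 1/2`, with the
#' same zero-entry pseudocount rule as [log2_fold_change()].
#'
#' @inheritParams log2_fold_change
#' @return factor with levels `fold>2`, `1/2<fold<=2`, `fold<=1/2`;
#'   `NA` where both inputs are zero.
#' @export
scatter_class <- function(ne1, ne2, pseudo = 0.01) {
  r <- (ne1 + pseudo * (ne1 == 0)) / (ne2 + pseudo * (ne2 == 0))
  r[ne1 == 0 & ne2 == 0] <- NA_real_
  cls <- ifelse(is.na(r), NA_character_,
                ifelse(r > 2, "fold>2",
                       ifelse(r > 0.5, "1/2<fold<=2", "fold<=1/2")))
  factor(cls, levels = SCATTER_CLASSES)
}

#' Differential-expression table for a two-library count table
#'
#' Runs the full procedure on every feature: per-million
#' normalization, log2 fold-change, the exact conditional Poisson
#' test, BH FDR over all tested features, DE call and scatter class.
#' Features with zero counts in both libraries are excluded from DE
#' calling (`p = 1`, `log2fc = NA`, `not_de`).
#'
#' @param counts a `mir_counts` table (see [count_table()]).
#' @param fdr_max,log2_min DE thresholds (defaults 0.001 and 1).
#' @param pseudo zero-entry pseudocount in per-million units.
#' @return a `mir_de` tibble with columns `feature`, `x`, `y`, `ne1`,
#'   `ne2`, `log2fc`, `p`, `fdr`, `de_class`, `scatter_class`.
#' @export
de_table <- function(counts, fdr_max = 0.001, log2_min = 1, pseudo = 0.01) {
  check_that(inherits(counts, "mir_counts"),
             "`counts` must be a count table from count_table()/read_count_table()")
  totals <- library_totals(counts)
  x <- counts$count_lib1
  y <- counts$count_lib2
  ne1 <- normalize_expression(x, totals[1])
  ne2 <- normalize_expression(y, totals[2])
  lfc <- log2_fold_change(ne1, ne2, pseudo)
  p <- audic_claverie_p(x, y, totals[1], totals[2])
  tested <- !(x == 0 & y == 0)
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- bh_fdr(p[tested])
  out <- tibble(feature = counts$feature, x = x, y = y,
                ne1 = ne1, ne2 = ne2, log2fc = lfc, p = p, fdr = fdr,
                de_class = classify_de(fdr, lfc, fdr_max, log2_min),
                scatter_class = scatter_class(ne1, ne2, pseudo))
  structure(out, totals = totals,
            thresholds = c(fdr_max = fdr_max, log2_min = log2_min),
            class = c("mir_de", class(tibble())))
}

#' Write a differential-expression table
#' @param de a `mir_de` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
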