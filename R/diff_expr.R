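# Count-based two-group differential expression screening: CPM
# normalization, a conditional binomial exact test (the Poisson-limit of the
# negative-binomial exact test, used here as a documented stand-in),
# Benjamini-Hochberg adjustment, and the screening thresholds defining
# up/down-regulation events (CPM >= 50 in at least one sample,
# |log2FC| >= 1, FDR <= 0.05 for miRNAs).

#' Differential expression screening parameters
#'
#' @param min_cpm CPM filter: a feature is tested only if its CPM reaches
#'   this value in at least one sample of the contrast (miRNA default 50;
#'   use 0 for lncRNA abundance matrices that were filtered upstream).
#' @param min_abs_log2fc minimum |log2 fold change| (default 1).
#' @param max_fdr BH-adjusted p-value ceiling (default 0.05).
#' @param pseudocount added to group-mean CPM before the log ratio
#'   (default 0.5).
#' @param strict use strict inequalities (> , <) instead of the default
#'   inclusive (>=, <=) when assigning directions.
#' @return list of class `de_params`.
#' @export
de_params <- function(min_cpm = 50, min_abs_log2fc = 1, max_fdr = 0.05,
                      pseudocount = 0.5, strict = FALSE) {
  stopifnot(min_abs_log2fc >= 0, max_fdr > 0, max_fdr <= 1, pseudocount >= 0)
  structure(list(min_cpm = min_cpm, min_abs_log2fc = min_abs_log2fc,
                 max_fdr = max_fdr, pseudocount = pseudocount,
                 strict = isTRUE(strict)),
            class = "de_params")
}

#' Counts per million
#'
#' @param counts non-negative numeric vector (or matrix column).
#' @param library_size total retained reads for the sample (> 0).
#' @return `counts * 1e6 / library_size` (no pseudocount).
#' @export
cpm <- function(counts, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  counts * 1e6 / library_size
}

#' Log2 fold change of group-mean CPM (b over a)
#'
#' @param mean_cpm_a,mean_cpm_b non-negative group means.
#' @param pseudocount added to both means to guard zeros (default 0.5).
#' @return `log2((mean_cpm_b + pseudocount) / (mean_cpm_a + pseudocount))`.
#' @export
log2_fold_change <- function(mean_cpm_a, mean_cpm_b, pseudocount = 0.5) {
  if (any(mean_cpm_a < 0) || any(mean_cpm_b < 0)) stop("means must be >= 0")
  log2((mean_cpm_b + pseudocount) / (mean_cpm_a + pseudocount))
}

#' Conditional binomial exact test for a count contrast
#'
#' Conditions on the pooled count N = A + B of a feature across the two
#' groups: under the null, A ~ Binomial(N, pi) with
#' pi = sum(libsizes_a) / sum(all libsizes). The two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed A
#' ("minlike" convention), capped at 1. This is the dispersion-to-zero
#' (Poisson) limit of the negative-binomial exact test used by popular
#' count-DE packages, and it is anticonservative for overdispersed counts.
#'
#' @param counts_a,counts_b per-replicate counts for each group.
#' @param libsizes_a,libsizes_b per-replicate library sizes.
#' @return two-sided p-value in (0, 1]; 1.0 by convention when N = 0.
#' @export
exact_count_test <- function(counts_a, counts_b, libsizes_a, libsizes_b) {
  if (any(c(counts_a, counts_b) < 0)) stop("negative counts")
  if (any(c(libsizes_a, libsizes_b) <= 0)) stop("library sizes must be positive")
  A <- sum(counts_a)
  B <- sum(counts_b)
  N <- A + B
  if (N == 0) return(1.0)
  pi_a <- sum(libsizes_a) / (sum(libsizes_a) + sum(libsizes_b))
  # log space: at large N the extreme-tail pmf underflows a double
  lp <- dbinom(0:N, N, pi_a, log = TRUE)
  lobs <- lp[A + 1L]
  # 1e-7 tolerance absorbs floating-point ties (standard for minlike
  # two-sided exact tests); floor keeps the p-value in (0, 1] when the
  # observed pmf itself underflows
  p <- sum(exp(lp[lp <= lobs + 1e-7]))
  min(1.0, max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorts p ascending, takes `q_(i) = min_(j>=i) p_(j) * n / j`, caps at 1 and
#' maps back to input order.
#'
#' @param pvalues numeric vector with all values in (0, 1].
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  n <- length(pvalues)
  o <- order(pvalues)
  q <- pvalues[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Screen a two-group contrast for differential expression events
#'
#' Per feature: the CPM filter (max CPM over the samples of the two groups
#' must reach `min_cpm`), log2 fold change of group-mean CPM, the
#' conditional binomial exact test, and BH adjustment computed over the
#' CPM-passing features only. Directions follow [de_params()] thresholds;
#' features failing the CPM filter are reported with `NA` p-values and
#' direction `ns`.
#'
#' @param m [count_matrix()] (raw counts; for abundance matrices set
#'   `min_cpm = 0` and supply per-sample totals as library sizes).
#' @param group_a,group_b disjoint character vectors of sample ids.
#' @param params [de_params()].
#' @param group_labels optional c(label_a, label_b) for the output.
#' @return data.frame of class `contrast_result`: `feature_id`, `group_a`,
#'   `group_b`, `mean_cpm_a`, `mean_cpm_b`, `log2fc`, `pvalue`, `fdr`,
#'   `cpm_pass`, `direction` (up/down/ns; log2fc is b over a).
#' @export
screen_contrast <- function(m, group_a, group_b, params = de_params(),
                            group_labels = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  missing <- setdiff(c(group_a, group_b), colnames(m$counts))
  if (length(missing)) stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  if (is.null(group_labels))
    group_labels <- c(paste(group_a, collapse = "+"), paste(group_b, collapse = "+"))

  ca <- m$counts[, group_a, drop = FALSE]
  cb <- m$counts[, group_b, drop = FALSE]
  la <- m$library_sizes[group_a]
  lb <- m$library_sizes[group_b]
  cpm_a <- sweep(ca, 2, la, function(x, l) cpm(x, l))
  cpm_b <- sweep(cb, 2, lb, function(x, l) cpm(x, l))
  max_cpm <- pmax(apply(cpm_a, 1, max), apply(cpm_b, 1, max))
  pass <- max_cpm >= params$min_cpm

  mean_a <- rowMeans(cpm_a)
  mean_b <- rowMeans(cpm_b)
  lfc <- log2_fold_change(mean_a, mean_b, params$pseudocount)
  pval <- rep(NA_real_, nrow(m$counts))
  pval[pass] <- vapply(which(pass), function(i)
    exact_count_test(ca[i, ], cb[i, ], la, lb), numeric(1))
  fdr <- rep(NA_real_, nrow(m$counts))
  if (any(pass)) fdr[pass] <- bh_adjust(pval[pass])

  ge <- function(x, y) if (params$strict) x > y else x >= y
  le <- function(x, y) if (params$strict) x < y else x <= y
  sig <- pass & !is.na(fdr) & le(fdr, params$max_fdr) &
    ge(abs(lfc), params$min_abs_log2fc)
  direction <- rep("ns", nrow(m$counts))
  direction[sig & lfc > 0] <- "up"
  direction[sig & lfc < 0] <- "down"

  res <- data.frame(
    feature_id = rownames(m$counts),
    group_a = group_labels[1], group_b = group_labels[2],
    mean_cpm_a = mean_a, mean_cpm_b = mean_b,
    log2fc = lfc, pvalue = pval, fdr = fdr,
    cpm_pass = pass, direction = direction,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(res) <- c("contrast_result", "data.frame")
  res
}
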