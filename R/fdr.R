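#' Rank SNPs by p-value and attach the rank-based FDR estimate
#'
#' Sorts p-values ascending (ties broken by SNP id for determinism) and
#' computes, for the SNP at rank \code{i} among \code{n_tests} tests, the
#' rank-based false discovery rate estimate \code{p_i * n_tests / i}.  The
#' estimate is deliberately NOT monotonized: it is the raw expected
#' false-positive count at the observed p-value divided by the rank, so the
#' value at rank 1 can exceed the value at rank 2.  The monotonized
#' Benjamini-Hochberg step-up variant (cumulative minimum from the bottom,
#' capped at 1) is available as an extra column via \code{step_up = TRUE}.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @param n_tests total number of tests performed (defaults to
#'   \code{length(p)}; may be larger when only a top list is supplied)
#' @param snp_id optional SNP identifiers (defaults to \code{names(p)} or
#'   generated ids)
#' @param step_up also emit the Benjamini-Hochberg step-up adjusted value as
#'   column \code{fdr_step_up}
#' @return data.frame with columns \code{snp_id}, \code{p}, \code{rank},
#'   \code{fdr}, \code{n_tests} (and optionally \code{fdr_step_up}), ordered
#'   by rank
#' @examples
#' rank_and_fdr(c(a = 6.45e-9, b = 7.76e-9), n_tests = 4988)
#' @export
rank_and_fdr <- function(p, n_tests = length(p), snp_id = NULL,
                         step_up = FALSE) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] and contain no NA")
  }
  m <- length(p)
  if (n_tests < m) stop("n_tests must be at least length(p)")
  if (is.null(snp_id)) snp_id <- names(p) %||% sprintf("snp_%04d", seq_len(m))
  ord <- order(p, as.character(snp_id))
  res <- data.frame(
    snp_id = as.character(snp_id)[ord],
    p = p[ord],
    rank = seq_len(m),
    fdr = p[ord] * n_tests / seq_len(m),
    n_tests = n_tests,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (step_up) {
    res$fdr_step_up <- pmin(rev(cummin(rev(res$fdr))), 1)
  }
  res
}

#' Count p-values strictly below a threshold
#'
#' @param p numeric vector of p-values
#' @param threshold strictly positive threshold below 1
#' @return integer count of \code{p < threshold}
#' @export
count_below_threshold <- function(p, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  sum(p < threshold, na.rm = FALSE)
}

#' Published top-20 combined-test results from the WHI breast-cancer scan
#'
#' The top 20 SNPs, ranked by combined main-effect plus intervention-
#' interaction test p-value, as published for the Women's Health Initiative
#' invasive breast cancer nested case-control genotype scan of 4,988 SNPs.
#' Columns: \code{rank}, \code{snp_id}, \code{chromosome}, \code{position},
#' \code{maf}, \code{alleles} (minor/major), \code{p_combined},
#' \code{fdr_published}, \code{p_main}, \code{rank_main}, \code{gene}.
#' \code{n_tests} for FDR computations on this list is 4,988.
#'
#' @return data.frame with 20 rows
#' @export
whi_top20 <- function() {
  path <- system.file("extdata", "whi_top20_combined_test.tsv",
                      package = "gxescan", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
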