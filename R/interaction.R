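#' Genotype-stratified intervention odds ratios from case-only counts
#'
#' Case-only estimator of the intervention odds ratio at zero, one and two
#' minor alleles: with randomization fraction \code{q}, the intervention odds
#' ratio at genotype \code{g} is the case active/control odds divided by the
#' randomization odds, \code{(n_active_g / n_control_g) / (q / (1 - q))}.
#' 95 percent confidence intervals are Wald intervals on the log scale with
#' standard error \code{sqrt(1/n_active_g + 1/n_control_g)}.  A zero cell
#' triggers the Haldane-Anscombe continuity correction (+0.5 to both cells of
#' that genotype) with a flag; a genotype with both cells zero has its odds
#' ratio flagged missing.
#'
#' @param counts 2 x 3 matrix of case counts: rows \code{active},
#'   \code{control}; columns genotypes 0, 1, 2 (column names optional)
#' @param q randomization fraction assigned active
#' @param component,snp_id labels carried through to the result
#' @return object of class \code{genotype_stratified_or}: list with
#'   \code{counts}, \code{or_by_genotype}, \code{ci95_by_genotype} (3 x 2
#'   matrix), \code{continuity_corrected} (logical per genotype),
#'   \code{lrt_2df_p} (filled by \code{\link{lrt_2df_interaction}}; NA here),
#'   \code{n_cases}
#' @examples
#' genotype_stratified_or(rbind(active = c(10, 30, 12),
#'                              control = c(20, 31, 12)), q = 0.5)
#' @export
genotype_stratified_or <- function(counts, q, component = NA_character_,
                                   snp_id = NA_character_) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 3L))) stop("counts must be a 2 x 3 matrix")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  rownames(counts) <- c("active", "control")
  colnames(counts) <- colnames(counts) %||% c("0", "1", "2")
  rand_odds <- q / (1 - q)
  or <- se <- rep(NA_real_, 3)
  cc <- rep(FALSE, 3)
  for (g in 1:3) {
    na <- counts["active", g]; nc <- counts["control", g]
    if (na + nc == 0) next
    if (na == 0 || nc == 0) {
      na <- na + 0.5; nc <- nc + 0.5; cc[g] <- TRUE
    }
    or[g] <- (na / nc) / rand_odds
    se[g] <- sqrt(1 / na + 1 / nc)
  }
  ci <- cbind(lower = exp(log(or) - 1.96 * se),
              upper = exp(log(or) + 1.96 * se))
  rownames(ci) <- colnames(counts)
  structure(
    list(component = component, snp_id = snp_id, counts = counts,
         or_by_genotype = setNames(or, colnames(counts)),
         ci95_by_genotype = ci, continuity_corrected = cc,
         lrt_2df_p = NA_real_, n_cases = sum(counts)),
    class = "genotype_stratified_or"
  )
}

#' @export
print.genotype_stratified_or <- function(x, ...) {
  cat(sprintf("Intervention odds ratio by genotype%s (%d cases)\n",
              if (is.na(x$snp_id)) "" else paste0(" [", x$snp_id, "]"),
              x$n_cases))
  for (g in 1:3) {
    cat(sprintf("  %s copies: OR %.3f (%.3f, %.3f)%s\n",
                colnames(x$counts)[g], x$or_by_genotype[g],
                x$ci95_by_genotype[g, 1], x$ci95_by_genotype[g, 2],
                if (x$continuity_corrected[g]) " [continuity corrected]" else ""))
  }
  if (!is.na(x$lrt_2df_p)) cat(sprintf("  interaction LRT p = %.4g\n",
                                       x$lrt_2df_p))
  invisible(x)
}

#' Two-degree-of-freedom interaction likelihood ratio test (case-only)
#'
#' Compares the offset logistic model of assignment on genotype-level
#' indicators (reference: zero copies) against the intercept-only offset
#' model, among cases of one component: twice the log-likelihood difference
#' referred to a chi-square whose degrees of freedom equal the number of
#' genotype levels present minus one (two when all of 0, 1, 2 occur).
#'
#' @param case_genotypes minor-allele dosages of the component's cases
#' @param arm_assignments their 0/1 active assignments
#' @param q randomization fraction (enters both models as the offset
#'   \code{log(q/(1-q))}; both intercepts are free so the offset cancels in
#'   the likelihood ratio, but it is retained so fitted models report
#'   intervention odds ratios directly)
#' @return list with \code{stat}, \code{df}, \code{p}, and
#'   \code{degenerate} (TRUE with \code{p = NA} when a single genotype level
#'   is present)
#' @export
lrt_2df_interaction <- function(case_genotypes, arm_assignments, q) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  g <- as.numeric(case_genotypes)
  a <- as.numeric(arm_assignments)
  ok <- !is.na(g) & !is.na(a)
  g <- g[ok]; a <- a[ok]
  stopifnot(all(a %in% c(0, 1)), all(g %in% c(0, 1, 2)))
  levels_present <- sort(unique(g))
  if (length(levels_present) < 2L) {
    return(list(stat = NA_real_, df = 0L, p = NA_real_, degenerate = TRUE))
  }
  off <- rep(logit(q), length(a))
  full <- glm(a ~ factor(g), family = binomial(), offset = off)
  null <- glm(a ~ 1, family = binomial(), offset = off)
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(null))))
  df <- length(levels_present) - 1L
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Joint case-only interaction model for several SNPs
#'
#' One offset logistic regression of active assignment on the dosages of all
#' selected SNPs jointly, among cases of one component, giving each SNP's
#' interaction coefficient adjusted for the others; per-SNP Wald p-values.
#'
#' @param case_genotypes cases x SNPs dosage matrix (column names = SNP ids)
#' @param arm_assignments 0/1 active assignments of the same cases
#' @param q randomization fraction
#' @param component label carried on the result
#' @return list with \code{component}, \code{snp_ids}, \code{coefficients}
#'   (per-SNP interaction log odds ratios), \code{se}, \code{per_snp_p}
#' @export
multi_snp_case_only <- function(case_genotypes, arm_assignments, q,
                                component = NA_character_) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  G <- as.matrix(case_genotypes)
  a <- as.numeric(arm_assignments)
  stopifnot(nrow(G) == length(a))
  snp_ids <- colnames(G) %||% sprintf("snp_%02d", seq_len(ncol(G)))
  # fail fast on collinear SNPs, naming an offending pair
  qr_rank <- qr(cbind(1, G))$rank
  if (qr_rank < ncol(G) + 1L) {
    for (i in seq_len(ncol(G) - 1L)) {
      for (j in (i + 1L):ncol(G)) {
        r2 <- ld_r2(G[, i], G[, j])
        if (!is.na(r2) && r2 > 1 - 1e-10) {
          stop("collinear SNPs among cases: ", snp_ids[i], ", ", snp_ids[j])
        }
      }
    }
    stop("design matrix of case genotypes is rank deficient")
  }
  off <- rep(logit(q), length(a))
  df <- data.frame(a = a, G)
  names(df) <- c("a", snp_ids)
  fit <- glm(stats::reformulate(sprintf("`%s`", snp_ids), response = "a"),
             family = binomial(), offset = off, data = df)
  sm <- summary(fit)$coefficients
  rows <- match(sprintf("`%s`", snp_ids), rownames(sm))
  rows[is.na(rows)] <- match(snp_ids, rownames(sm))[is.na(rows)]
  list(component = component, snp_ids = snp_ids,
       coefficients = setNames(sm[rows, "Estimate"], snp_ids),
       se = setNames(sm[rows, "Std. Error"], snp_ids),
       per_snp_p = setNames(sm[rows, "Pr(>|z|)"], snp_ids))
}

#' Filter a case-control set by a subject-level predicate
#'
#' Applies a predicate (for example European ancestry, or estrogen-receptor
#' positive tumour) to a phenotype table while preserving matched-pair
#' integrity: by default a pair is kept only when both members pass; with
#' \code{keep_cases = TRUE} all passing cases are kept regardless of their
#' control's status, as appropriate for case-only analyses.
#'
#' @param data phenotype data.frame with columns \code{case} and, if pair
#'   integrity is to be enforced, \code{pair_id}
#' @param predicate function mapping the data.frame to a logical vector, or a
#'   logical vector itself; \code{NA} predicate values on referenced fields
#'   are an error
#' @param keep_cases keep passing cases even when their matched control fails
#' @return the filtered data.frame
#' @export
subset_filter <- function(data, predicate, keep_cases = FALSE) {
  keep <- if (is.function(predicate)) predicate(data) else predicate
  if (length(keep) != nrow(data)) stop("predicate length mismatch")
  if (any(is.na(keep))) stop("predicate evaluates to NA (missing field?)")
  if (!keep_cases && "pair_id" %in% names(data)) {
    pair_ok <- tapply(keep, data$pair_id, all)
    keep <- keep & pair_ok[as.character(data$pair_id)]
  }
  if (keep_cases) keep <- keep & (data$case == 1 | {
    if ("pair_id" %in% names(data)) {
      pair_ok <- tapply(keep, data$pair_id, all)
      pair_ok[as.character(data$pair_id)]
    } else TRUE
  })
  data[keep, , drop = FALSE]
}

#' Full interaction profile of one SNP in one component
#'
#' Convenience wrapper: tabulates the component's cases by arm and genotype,
#' computes the genotype-stratified intervention odds ratios with confidence
#' intervals, and attaches the 2-df interaction likelihood ratio p-value.
#'
#' @inheritParams lrt_2df_interaction
#' @param component,snp_id labels
#' @return \code{genotype_stratified_or} with \code{lrt_2df_p} filled
#' @export
interaction_profile <- function(case_genotypes, arm_assignments, q,
                                component = NA_character_,
                                snp_id = NA_character_) {
  g <- as.numeric(case_genotypes)
  a <- as.numeric(arm_assignments)
  ok <- !is.na(g) & !is.na(a)
  g <- g[ok]; a <- a[ok]
  counts <- rbind(
    active = vapply(0:2, function(k) sum(a == 1 & g == k), numeric(1)),
    control = vapply(0:2, function(k) sum(a == 0 & g == k), numeric(1))
  )
  out <- genotype_stratified_or(counts, q, component = component,
                                snp_id = snp_id)
  out$lrt_2df_p <- lrt_2df_interaction(g, a, q)$p
  out
}
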