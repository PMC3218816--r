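#' Minor allele frequency of a genotype column
#'
#' Computes the in-sample minor allele frequency of one SNP from minor-allele
#' dosages in \{0, 1, 2\}.  If the coded allele turns out to be the major
#' allele in-sample (coded frequency > 0.5), the coding is flipped so that the
#' returned dosages count the minor allele.  A tie at frequency 0.5 is broken
#' towards the lexicographically smaller allele label.
#'
#' @param genotype integer vector with values 0, 1, 2 or \code{NA}
#' @param coded_allele,other_allele optional allele labels for the counted and
#'   uncounted allele; used for relabelling on flips and for tie-breaking
#' @return list with elements \code{maf}, \code{minor_allele},
#'   \code{major_allele}, \code{flipped} (logical: coding was reversed),
#'   \code{monomorphic} (logical), and \code{genotype} (possibly flipped
#'   dosages)
#' @examples
#' compute_maf(c(0, 1, 2, 1))$maf            # 0.5
#' compute_maf(c(2, 2, 1, 2))$maf            # 0.125, coding flipped
#' @export
compute_maf <- function(genotype, coded_allele = "A", other_allele = "B") {
  g <- as.numeric(genotype)
  ok <- !is.na(g)
  if (!any(ok)) stop("all genotypes missing: MAF undefined")
  if (any(!(g[ok] %in% c(0, 1, 2)))) stop("genotypes must be 0, 1, 2 or NA")
  f_coded <- sum(g[ok]) / (2 * sum(ok))
  flip <- f_coded > 0.5 ||
    (f_coded == 0.5 && !is.na(other_allele) && !is.na(coded_allele) &&
       as.character(other_allele) < as.character(coded_allele))
  if (flip) {
    g <- 2 - g
    maf <- 1 - f_coded
    minor <- other_allele
    major <- coded_allele
  } else {
    maf <- f_coded
    minor <- coded_allele
    major <- other_allele
  }
  list(maf = maf, minor_allele = minor, major_allele = major,
       flipped = flip, monomorphic = maf == 0, genotype = g)
}

#' Pairwise linkage-disequilibrium r-squared from genotype dosages
#'
#' Squared Pearson correlation of unphased genotype dosages (the composite-LD
#' estimate of squared allelic correlation).  Missing values are handled
#' pairwise-complete.  Invariant to swapping the minor/major coding of either
#' SNP.
#'
#' @param geno_a,geno_b equal-length dosage vectors (0/1/2, \code{NA} allowed)
#' @return r-squared in [0, 1], or \code{NA} (flagged with attribute
#'   \code{"degenerate"}) when either vector is constant
#' @export
ld_r2 <- function(geno_a, geno_b) {
  if (length(geno_a) != length(geno_b)) {
    stop("genotype vectors must have equal length")
  }
  ok <- !is.na(geno_a) & !is.na(geno_b)
  a <- geno_a[ok]
  b <- geno_b[ok]
  if (length(a) < 2L || var(a) == 0 || var(b) == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r <- cor(a, b)
  min(r^2, 1)
}

#' Full pairwise LD matrix
#'
#' @param genotypes subjects x SNPs dosage matrix
#' @return symmetric matrix of r-squared values with unit diagonal
#' @export
ld_matrix <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  p <- ncol(genotypes)
  r2 <- matrix(NA_real_, p, p, dimnames = list(colnames(genotypes),
                                               colnames(genotypes)))
  diag(r2) <- 1
  if (p < 2L) return(r2)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      r2[i, j] <- r2[j, i] <- ld_r2(genotypes[, i], genotypes[, j])
    }
  }
  r2
}

#' Bin map-ordered SNPs into loci by LD with a locus anchor
#'
#' Greedy scan over SNPs sorted by chromosome and position: a SNP joins the
#' current locus when its dosage r-squared with the locus's first (anchor)
#' SNP is at least \code{threshold}; otherwise it opens a new locus.  A
#' chromosome change always opens a new locus.  The conventional threshold of
#' 0.2 corresponds to defining a new locus wherever adjacent regions have
#' r-squared below 0.2.
#'
#' @param snp_meta data.frame with columns \code{snp_id}, \code{chromosome},
#'   \code{position}, sorted by chromosome then position
#' @param genotypes subjects x SNPs dosage matrix, columns in the same order
#' @param threshold r-squared threshold in (0, 1]; SNPs with r-squared below
#'   this against the anchor start a new locus
#' @return integer vector of 1-based contiguous locus ids, one per SNP
#' @export
bin_adjacent_loci <- function(snp_meta, genotypes, threshold = 0.2) {
  genotypes <- as.matrix(genotypes)
  stopifnot(nrow(snp_meta) == ncol(genotypes))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ord <- order(snp_meta$chromosome, snp_meta$position)
  if (!all(ord == seq_len(nrow(snp_meta)))) {
    stop("SNPs must be sorted by chromosome and position")
  }
  p <- nrow(snp_meta)
  locus <- integer(p)
  if (p == 0L) return(locus)
  locus[1L] <- 1L
  anchor <- 1L
  for (k in seq_len(p)[-1L]) {
    new_chrom <- snp_meta$chromosome[k] != snp_meta$chromosome[anchor]
    r2 <- if (new_chrom) 0 else ld_r2(genotypes[, anchor], genotypes[, k])
    if (new_chrom || is.na(r2) || r2 < threshold) {
      locus[k] <- locus[k - 1L] + 1L
      anchor <- k
    } else {
      locus[k] <- locus[k - 1L]
    }
  }
  locus
}

#' Principal components of a genotype matrix for stratification adjustment
#'
#' Missing genotypes are mean-imputed per SNP; each SNP is centered and scaled
#' by its binomial standard deviation \code{sqrt(2 * maf * (1 - maf))}
#' (EIGENSTRAT-style standardization), and the top \code{k} components of the
#' standardized matrix are extracted by singular value decomposition.
#' Monomorphic SNPs carry no information and are dropped with a warning.
#'
#' @param genotypes subjects x SNPs dosage matrix (0/1/2, \code{NA} allowed)
#' @param k number of components, at most \code{min(n - 1, p)}
#' @return object of class \code{gxe_pca}: list with \code{eigenvectors}
#'   (subjects x k, unit-norm columns), \code{eigenvalues} (non-increasing),
#'   \code{variance_fraction} (against total standardized variance), and
#'   \code{scores} (subjects x k, eigenvector columns scaled by singular
#'   values; the per-subject covariates used for adjustment)
#' @export
pca_genotypes <- function(genotypes, k) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  if (n < 2L || p < 2L) stop("need at least 2 subjects and 2 SNPs")
  if (k < 1L || k > min(n - 1L, p)) {
    stop("k must be between 1 and min(n_subjects - 1, n_snps)")
  }
  x <- apply(genotypes, 2L, function(col) {
    m <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- m
    f <- m / 2
    s <- sqrt(2 * f * (1 - f))
    if (s == 0) rep(NA_real_, length(col)) else (col - m) / s
  })
  drop_cols <- colSums(is.na(x)) > 0L
  if (any(drop_cols)) {
    warning(sum(drop_cols), " monomorphic SNP(s) dropped from PCA")
    x <- x[, !drop_cols, drop = FALSE]
    if (ncol(x) < 2L) stop("fewer than 2 polymorphic SNPs")
  }
  sv <- svd(x, nu = k, nv = 0)
  eigenvalues <- sv$d^2 / (n - 1)
  total_var <- sum(eigenvalues)
  out <- list(
    eigenvectors = sv$u,
    eigenvalues = eigenvalues[seq_len(k)],
    variance_fraction = eigenvalues[seq_len(k)] / total_var,
    scores = sweep(sv$u, 2L, sv$d[seq_len(k)], `*`)
  )
  colnames(out$eigenvectors) <- colnames(out$scores) <-
    paste0("PC", seq_len(k))
  class(out) <- "gxe_pca"
  out
}

#' @export
print.gxe_pca <- function(x, ...) {
  cat("Genotype PCA:", nrow(x$eigenvectors), "subjects,",
      length(x$eigenvalues), "components retained\n")
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}
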