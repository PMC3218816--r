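#' Write a dosage matrix as TSV
#'
#' Tab-separated, first column \code{subject_id}, one column per SNP id,
#' values 0/1/2 or NA.
#'
#' @param genotypes subjects x SNPs matrix with rownames and colnames
#' @param path output file
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes),
                   as.data.frame(genotypes), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage TSV back into a matrix
#'
#' @param path file written by \code{\link{write_dosage_tsv}}
#' @return integer matrix with subject-id rownames
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id") stop("first column must be subject_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m[!is.na(m)] %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$subject_id
  m
}

#' Write genotypes as a VCF v4.2 text file
#'
#' One record per SNP with 1-based positions, REF = major allele,
#' ALT = minor allele, and unphased GT fields (dosage d written as the
#' genotype with d ALT alleles; missing as \code{./.}).
#'
#' @param genotypes subjects x SNPs dosage matrix (minor-allele counts)
#' @param snp_meta data.frame with \code{snp_id}, \code{chromosome},
#'   \code{position}, \code{minor_allele}, \code{major_allele}
#' @param path output file
#' @export
write_vcf <- function(genotypes, snp_meta, path) {
  stopifnot(ncol(genotypes) == nrow(snp_meta))
  samples <- rownames(genotypes) %||%
    sprintf("sample_%04d", seq_len(nrow(genotypes)))
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gxescan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  for (j in seq_len(nrow(snp_meta))) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    writeLines(paste(c(snp_meta$chromosome[j], snp_meta$position[j],
                       snp_meta$snp_id[j], snp_meta$major_allele[j],
                       snp_meta$minor_allele[j], ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF parsing is delegated to \pkg{vcfR}; GT fields are converted to ALT
#' allele counts irrespective of phasing or allele order ("0/1" and "1/0"
#' both give dosage 1).  Dosages are then re-oriented to minor-allele counts
#' in-sample: any SNP whose counted (ALT) allele has frequency above one half
#' is flipped, with the flip recorded in the returned metadata, so dosage
#' columns always agree with \code{\link{compute_maf}}.
#'
#' @param path input file
#' @param format \code{"auto"} (by extension), \code{"vcf"} or
#'   \code{"dosage"}
#' @return list with \code{genotypes} (subjects x SNPs minor-allele dosage
#'   matrix) and \code{snp_meta} (snp_id, chromosome, position,
#'   minor_allele, major_allele, maf, flipped)
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (format == "dosage") {
    m <- read_dosage_tsv(path)
    meta <- data.frame(snp_id = colnames(m), chromosome = NA_character_,
                       position = NA_integer_, minor_allele = "A",
                       major_allele = "B", stringsAsFactors = FALSE)
    alt_is_minor <- meta$minor_allele
    coded <- m
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- apply(gt, c(1, 2), function(x) {
      if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0L)
    })
    coded <- t(dose)  # subjects x SNPs
    meta <- data.frame(snp_id = unname(fix[, "ID"]),
                       chromosome = unname(fix[, "CHROM"]),
                       position = as.integer(fix[, "POS"]),
                       minor_allele = unname(fix[, "ALT"]),
                       major_allele = unname(fix[, "REF"]),
                       stringsAsFactors = FALSE)
    colnames(coded) <- meta$snp_id
  }
  meta$maf <- NA_real_
  meta$flipped <- FALSE
  for (j in seq_len(ncol(coded))) {
    mf <- compute_maf(coded[, j], coded_allele = meta$minor_allele[j],
                      other_allele = meta$major_allele[j])
    coded[, j] <- mf$genotype
    meta$maf[j] <- mf$maf
    if (mf$flipped) {
      meta$flipped[j] <- TRUE
      meta$minor_allele[j] <- mf$minor_allele
      meta$major_allele[j] <- mf$major_allele
    }
  }
  if (any(meta$flipped)) {
    message(sum(meta$flipped),
            " SNP(s) re-oriented so dosages count the minor allele")
  }
  list(genotypes = coded, snp_meta = meta)
}

#' Write / read the phenotype and assignment table
#'
#' Self-describing TSV: header row with the column dictionary of
#' \code{\link{joint_test}} (\code{subject_id}, \code{case}, covariates,
#' \code{member_*}, \code{arm_*}, \code{pair_id}).
#'
#' @param subjects phenotype data.frame
#' @param path file path
#' @export
write_phenotypes_tsv <- function(subjects, path) {
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Analysis configuration for the end-to-end pipeline
#'
#' @param genotypes_path VCF or dosage TSV (NULL to simulate instead)
#' @param phenotypes_path phenotype TSV (NULL to simulate instead)
#' @param out_dir output directory
#' @param q named randomization fractions
#' @param n_pcs principal components for stratification adjustment
#' @param covariates confounder column names for the main-effect test
#' @param fdr_step_up also emit the monotonized step-up FDR column
#' @param n_boot bootstrap replicates for the AUC comparison
#' @param n_top_snps SNPs (by combined p) profiled and carried into the
#'   discrimination models
#' @param seed master seed
#' @param sim \code{\link{sim_config}} used when no input paths are given
#' @return list of class \code{gxe_analysis_config}
#' @export
analysis_config <- function(genotypes_path = NULL, phenotypes_path = NULL,
                            out_dir = ".", q = default_q(), n_pcs = 10,
                            covariates = c("log_risk_score", "log_bmi"),
                            fdr_step_up = FALSE, n_boot = 200,
                            n_top_snps = 2, seed = 1,
                            sim = sim_config(seed = seed)) {
  if (any(q <= 0 | q >= 1)) stop("q must be in (0, 1)")
  structure(list(genotypes_path = genotypes_path,
                 phenotypes_path = phenotypes_path, out_dir = out_dir,
                 q = q, n_pcs = n_pcs, covariates = covariates,
                 fdr_step_up = fdr_step_up, n_boot = n_boot,
                 n_top_snps = n_top_snps, seed = seed, sim = sim),
            class = "gxe_analysis_config")
}

write_atomic <- function(df, path) {
  tmp <- paste0(path, ".partial")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains simulate (or load) -> genotype statistics -> per-SNP combined test
#' -> interaction profiles of the top SNPs -> FDR ranking -> nested-model AUC
#' comparison, writing one TSV per stage plus a log.  Outputs are written
#' atomically (a \code{.partial} file is renamed into place on completion);
#' a rerun with the same configuration is identical.
#'
#' @param config an \code{\link{analysis_config}}
#' @return invisible list of stage outputs (\code{persnp}, \code{ranked},
#'   \code{interaction}, \code{auc}, and the file paths)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "gxe_analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("pipeline start, seed = %d", config$seed)

  if (is.null(config$genotypes_path)) {
    logf("simulating cohort (seed %d)", config$sim$seed)
    cohort <- simulate_cohort(config$sim)
    pairs <- select_matched_case_control(cohort)
    cc <- case_control_table(cohort, pairs)
    G <- cohort$genotypes[cc$subject_id, , drop = FALSE]
    snp_meta <- cohort$snp_meta
  } else {
    gin <- read_genotypes(config$genotypes_path)
    cc <- read_phenotypes_tsv(config$phenotypes_path)
    G <- gin$genotypes
    snp_meta <- gin$snp_meta
  }
  # fail fast before any computation
  missing_cov <- setdiff(config$covariates, names(cc))
  if (length(missing_cov)) {
    stop("covariate columns missing from phenotypes: ",
         paste(missing_cov, collapse = ", "))
  }
  if (is.null(rownames(G))) rownames(G) <- as.character(cc$subject_id)

  logf("joint test on %d SNPs, %d subjects", ncol(G), nrow(cc))
  persnp <- joint_test(cc, G, covariates = config$covariates, q = config$q,
                       n_pcs = config$n_pcs)
  persnp_path <- write_atomic(persnp,
                              file.path(config$out_dir, "persnp_tests.tsv"))

  ranked <- rank_and_fdr(setNames(persnp$p_combined, persnp$snp_id),
                         step_up = config$fdr_step_up)
  ranked_path <- write_atomic(ranked,
                              file.path(config$out_dir, "ranked_fdr.tsv"))

  top <- ranked$snp_id[seq_len(min(config$n_top_snps, nrow(ranked)))]
  is_case <- cc$case == 1
  prof <- list()
  for (s in top) {
    for (comp in COMPONENTS) {
      in_comp <- is_case & cc[[paste0("member_", comp)]] %in% TRUE
      if (!any(in_comp)) next
      pr <- interaction_profile(G[in_comp, s],
                                cc[[paste0("arm_", comp)]][in_comp],
                                q = config$q[[comp]], component = comp,
                                snp_id = s)
      prof[[length(prof) + 1L]] <- data.frame(
        snp_id = s, component = comp,
        genotype = c(0, 1, 2), or = pr$or_by_genotype,
        ci_lower = pr$ci95_by_genotype[, 1],
        ci_upper = pr$ci95_by_genotype[, 2],
        lrt_2df_p = pr$lrt_2df_p, n_cases = pr$n_cases)
    }
  }
  interaction_df <- do.call(rbind, prof)
  interaction_path <- write_atomic(
    interaction_df, file.path(config$out_dir, "interaction_profiles.tsv"))

  logf("AUC bootstrap, %d replicates, SNPs: %s", config$n_boot,
       paste(top, collapse = ", "))
  disc <- bootstrap_auc_test(cc, G, snp_ids = top,
                             covariates = config$covariates,
                             model_pair = c("M0", "M2"),
                             n_boot = config$n_boot, seed = config$seed)
  fits <- fit_nested_risk_models(cc, G, top, config$covariates)
  auc_df <- data.frame(
    model_label = names(fits$auc), auc = unname(fits$auc),
    delta_auc_vs_M0 = unname(fits$auc - fits$auc["M0"]),
    bootstrap_p_M2_vs_M0 = c(NA, NA, disc$bootstrap_p),
    n_boot = config$n_boot, seed = config$seed)
  auc_path <- write_atomic(auc_df, file.path(config$out_dir, "auc.tsv"))

  logf("pipeline complete")
  invisible(list(persnp = persnp, ranked = ranked,
                 interaction = interaction_df, auc = auc_df,
                 paths = c(persnp = persnp_path, ranked = ranked_path,
                           interaction = interaction_path, auc = auc_path,
                           log = log_path)))
}
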