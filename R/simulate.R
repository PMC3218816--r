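#' Specification of one randomized trial component
#'
#' @param name one of \code{"E_ALONE"}, \code{"E_PLUS_P"}, \code{"DM"},
#'   \code{"CAD"}
#' @param q fraction of eligible participants assigned active, in (0, 1)
#' @param eligibility function of the subjects data.frame returning a logical
#'   eligibility vector (the two hormone trials must be mutually exclusive:
#'   post-hysterectomy women are eligible for estrogen alone, women with a
#'   uterus for estrogen plus progestin)
#' @param enrollment_time years from baseline at which the component
#'   randomizes (0 for the hormone and dietary components, 1 for the
#'   calcium/vitamin D component, which randomized at the one-year
#'   anniversary)
#' @return list of class \code{trial_component_spec}
#' @export
trial_component_spec <- function(name, q, eligibility, enrollment_time = 0) {
  stopifnot(name %in% c("E_ALONE", "E_PLUS_P", "DM", "CAD"),
            q > 0, q < 1, is.function(eligibility), enrollment_time >= 0)
  structure(list(name = name, q = q, eligibility = eligibility,
                 enrollment_time = enrollment_time),
            class = "trial_component_spec")
}

#' Default WHI-style component specifications
#'
#' Hormone therapy splits by hysterectomy status into two non-overlapping
#' trials (estrogen alone among post-hysterectomy women, estrogen plus
#' progestin among women with a uterus), the dietary component assigns 40
#' percent to the low-fat intervention, and the calcium/vitamin D component
#' randomizes at year one among women then event-free.
#'
#' @return named list of \code{\link{trial_component_spec}}
#' @export
default_component_specs <- function() {
  list(
    E_ALONE = trial_component_spec(
      "E_ALONE", q = 0.5,
      eligibility = function(s) s$ht_component & s$hysterectomy),
    E_PLUS_P = trial_component_spec(
      "E_PLUS_P", q = 0.5,
      eligibility = function(s) s$ht_component & !s$hysterectomy),
    DM = trial_component_spec(
      "DM", q = 0.4,
      eligibility = function(s) s$dm_component),
    CAD = trial_component_spec(
      "CAD", q = 0.5,
      eligibility = function(s) s$cad_volunteer & s$event_time > 1,
      enrollment_time = 1)
  )
}

#' Simulation configuration for the synthetic partial-factorial trial cohort
#'
#' Collects and validates every knob of the generator.  Defaults emulate the
#' WHI design at a reduced cohort size: overlapping hormone-therapy and
#' dietary components, calcium/vitamin D randomization at year one, a
#' per-year discrete-time logistic hazard around 0.4 percent, and
#' ancestry-structured genotypes in LD blocks.
#'
#' @param n_subjects cohort size
#' @param seed master seed; every stochastic stage derives from it
#' @param n_snps number of SNPs (must equal \code{sum(ld_block_sizes)})
#' @param ld_block_sizes SNP counts per LD block
#' @param within_block_adjacent_r target allelic correlation between adjacent
#'   SNPs within a block, in [0, 1)
#' @param ancestry_groups data.frame with columns \code{label},
#'   \code{proportion} (summing to 1) and \code{freq_shift} (additive
#'   allele-frequency shift per SNP for that group)
#' @param maf_range interval within (0, 0.5] from which baseline minor allele
#'   frequencies are drawn
#' @param baseline_hazard per-year event probability at covariate baseline
#' @param intervention_or named per-component intervention odds ratios
#'   (intervention main effects) over \code{E_ALONE, E_PLUS_P, DMQ, CAD}
#' @param or_per_allele named per-SNP main-effect odds ratio per minor allele
#'   (unnamed SNPs have no effect)
#' @param interaction_or_by_genotype list of entries
#'   \code{list(snp =, component =, or = c(or0, or1, or2))} giving the
#'   intervention odds ratio at 0/1/2 minor alleles of that SNP (replaces the
#'   component's main-effect odds ratio for carriers of each genotype)
#' @param covariate_effects log odds ratios for the simulated confounders
#'   (\code{log_risk_score}, \code{log_bmi}), applied to centered covariates
#' @param component_specs list of \code{\link{trial_component_spec}}
#' @param followup_years follow-up horizon in years
#' @param dmq_quartile fraction of dietary-component participants forming the
#'   high-fat subset used for interaction testing (upper quartile by default)
#' @return validated list of class \code{gxe_sim_config}
#' @export
sim_config <- function(n_subjects = 5000,
                       seed = 1,
                       n_snps = 20,
                       ld_block_sizes = c(5, 5, 5, 5),
                       within_block_adjacent_r = 0.9,
                       ancestry_groups = data.frame(
                         label = c("european", "african", "other"),
                         proportion = c(0.86, 0.09, 0.05),
                         freq_shift = c(0, 0.15, 0.05)),
                       maf_range = c(0.1, 0.5),
                       baseline_hazard = 0.004,
                       intervention_or = c(E_ALONE = 0.8, E_PLUS_P = 1.25,
                                           DMQ = 0.85, CAD = 1.0),
                       or_per_allele = NULL,
                       interaction_or_by_genotype = NULL,
                       covariate_effects = c(log_risk_score = 0.5,
                                             log_bmi = 1.0),
                       component_specs = default_component_specs(),
                       followup_years = 8,
                       dmq_quartile = 0.25) {
  if (abs(sum(ancestry_groups$proportion) - 1) > 1e-8) {
    stop("ancestry proportions must sum to 1")
  }
  if (n_snps != sum(ld_block_sizes)) {
    stop("n_snps must equal sum(ld_block_sizes)")
  }
  if (within_block_adjacent_r < 0 || within_block_adjacent_r >= 1) {
    stop("within_block_adjacent_r must be in [0, 1)")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (any(intervention_or <= 0) ||
      (!is.null(or_per_allele) && any(or_per_allele <= 0))) {
    stop("odds ratios must be positive")
  }
  for (entry in interaction_or_by_genotype %||% list()) {
    if (!all(c("snp", "component", "or") %in% names(entry)) ||
        length(entry$or) != 3L || any(entry$or <= 0)) {
      stop("interaction entries need snp, component, and a positive OR triple")
    }
  }
  if (baseline_hazard <= 0 || baseline_hazard >= 1) {
    stop("baseline_hazard must be a per-year probability in (0, 1)")
  }
  if (dmq_quartile <= 0 || dmq_quartile > 1) {
    stop("dmq_quartile must be in (0, 1]")
  }
  structure(
    list(n_subjects = n_subjects, seed = seed, n_snps = n_snps,
         ld_block_sizes = ld_block_sizes,
         within_block_adjacent_r = within_block_adjacent_r,
         ancestry_groups = ancestry_groups, maf_range = maf_range,
         baseline_hazard = baseline_hazard,
         intervention_or = intervention_or,
         or_per_allele = or_per_allele,
         interaction_or_by_genotype = interaction_or_by_genotype,
         covariate_effects = covariate_effects,
         component_specs = component_specs,
         followup_years = followup_years, dmq_quartile = dmq_quartile),
    class = "gxe_sim_config"
  )
}

# Latent Gaussian correlation giving a target allelic correlation between two
# thresholded indicators with allele frequencies f1, f2 (tetrachoric-style
# inversion; cached).
.rho_cache <- new.env(parent = emptyenv())
solve_latent_rho <- function(f1, f2, r_target) {
  if (r_target == 0) return(0)
  key <- paste(round(f1, 6), round(f2, 6), round(r_target, 6))
  hit <- .rho_cache[[key]]
  if (!is.null(hit)) return(hit)
  z1 <- qnorm(f1); z2 <- qnorm(f2)
  allelic_corr <- function(rho) {
    p11 <- integrate(function(x)
      dnorm(x) * pnorm((z2 - rho * x) / sqrt(1 - rho^2)),
      -Inf, z1, rel.tol = 1e-10)$value
    (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  }
  upper <- 0.99999
  if (allelic_corr(upper) <= r_target) {
    rho <- upper
  } else {
    rho <- uniroot(function(rho) allelic_corr(rho) - r_target,
                   c(0, upper), tol = 1e-8)$root
  }
  .rho_cache[[key]] <- rho
  rho
}

# core genotype draw (does not touch the seed; caller controls RNG state)
draw_genotypes <- function(n, block_sizes, r_target, base_maf,
                           ancestry_labels, ancestry_groups) {
  p <- sum(block_sizes)
  stopifnot(length(base_maf) == p)
  shift <- setNames(ancestry_groups$freq_shift, ancestry_groups$label)
  G <- matrix(0L, n, p)
  offset <- 0L
  for (m in block_sizes) {
    cols <- offset + seq_len(m)
    for (lab in unique(ancestry_labels)) {
      rows <- which(ancestry_labels == lab)
      f <- pmin(pmax(base_maf[cols] + shift[[lab]], 0.01), 0.99)
      nh <- 2L * length(rows)
      Z <- matrix(NA_real_, nh, m)
      Z[, 1L] <- rnorm(nh)
      if (m > 1L) {
        for (k in 2L:m) {
          rho <- solve_latent_rho(f[k - 1L], f[k], r_target)
          Z[, k] <- rho * Z[, k - 1L] + sqrt(1 - rho^2) * rnorm(nh)
        }
      }
      A <- sweep(Z, 2L, qnorm(f), `<`)
      G[rows, cols] <- A[seq_len(length(rows)), , drop = FALSE] +
        A[length(rows) + seq_len(length(rows)), , drop = FALSE]
    }
    offset <- offset + m
  }
  storage.mode(G) <- "integer"
  G
}

make_snp_meta <- function(block_sizes, maf) {
  p <- sum(block_sizes)
  chrom <- rep(paste0("chr", seq_along(block_sizes)), block_sizes)
  pos <- unlist(lapply(block_sizes, function(m) 10000L + 5000L * seq_len(m)))
  data.frame(
    snp_id = sprintf("snp_%04d", seq_len(p)),
    chromosome = chrom,
    position = pos,
    minor_allele = rep(c("A", "C", "G", "T"), length.out = p),
    major_allele = rep(c("G", "T", "A", "C"), length.out = p),
    maf = maf,
    stringsAsFactors = FALSE
  )
}

#' Simulate ancestry-structured genotypes in LD blocks
#'
#' Genotypes are built from Gaussian-copula haplotypes: within each block a
#' latent first-order autoregressive Gaussian sequence is thresholded at each
#' SNP's allele frequency, with the latent correlation solved (tetrachoric
#' inversion) so that adjacent alleles attain the target allelic correlation;
#' two independent haplotypes per subject are summed, giving Hardy-Weinberg
#' genotypes with controllable adjacent r.  Blocks are independent.  Each
#' ancestry group applies its configured additive allele-frequency shift,
#' creating the frequency structure that genotype principal components pick
#' up.
#'
#' @param config a \code{\link{sim_config}}
#' @param ancestry_labels character vector of group labels, one per subject
#'   (drawn from \code{config$ancestry_groups$label}); defaults to a draw
#'   with the configured proportions for \code{config$n_subjects} subjects
#' @param seed seed (defaults to \code{config$seed})
#' @return list with \code{genotypes} (subjects x SNPs integer matrix),
#'   \code{snp_meta} data.frame, and \code{ancestry} labels
#' @export
simulate_genotypes <- function(config, ancestry_labels = NULL,
                               seed = config$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(ancestry_labels)) {
    ancestry_labels <- sample(config$ancestry_groups$label,
                              config$n_subjects, replace = TRUE,
                              prob = config$ancestry_groups$proportion)
  }
  n <- length(ancestry_labels)
  # one base frequency per LD block: variants in strong LD carry near-equal
  # allele frequencies, and equal frequencies make any allelic correlation
  # in [0, 1) attainable by the copula
  base_maf <- rep(runif(length(config$ld_block_sizes),
                        config$maf_range[1], config$maf_range[2]),
                  config$ld_block_sizes)
  G <- draw_genotypes(n, config$ld_block_sizes,
                      config$within_block_adjacent_r, base_maf,
                      ancestry_labels, config$ancestry_groups)
  meta <- make_snp_meta(config$ld_block_sizes, base_maf)
  colnames(G) <- meta$snp_id
  list(genotypes = G, snp_meta = meta, ancestry = ancestry_labels)
}

# per-component intervention log odds for one subject-year, given genotype
intervention_logor <- function(config, comp, genotype_row) {
  for (entry in config$interaction_or_by_genotype %||% list()) {
    if (entry$component == comp) {
      g <- genotype_row[[entry$snp]]
      return(log(entry$or[g + 1L]))
    }
  }
  log(config$intervention_or[[comp]] %||% 1)
}

#' Simulate a full partial-factorial randomized trial cohort
#'
#' Generates subjects with covariates, overlapping trial memberships obeying
#' the component eligibility rules, randomized arm assignments (independent
#' of genotype by construction), ancestry-structured genotypes, and invasive
#' disease outcomes from a discrete-time per-year logistic hazard in which
#' intervention and genotype effects enter as log odds ratios and
#' genotype-by-intervention interaction enters as a genotype-specific
#' intervention log odds ratio.  The calcium/vitamin D component randomizes
#' at year one among women then event-free; the dietary high-fat subset
#' (upper baseline fat quartile among dietary participants) is flagged for
#' interaction testing.
#'
#' Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}
#' @return list of class \code{gxe_cohort} with \code{subjects} (one row per
#'   participant: covariates, \code{member_*}/\code{arm_*} columns,
#'   \code{case}, \code{event_time}, receptor status for cases),
#'   \code{genotypes}, \code{snp_meta}, \code{config}
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "gxe_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_subjects

  subjects <- data.frame(
    subject_id = sprintf("subj_%06d", seq_len(n)),
    age = sample(50:79, n, replace = TRUE,
                 prob = dnorm(50:79, mean = 63, sd = 7)),
    ethnicity = sample(config$ancestry_groups$label, n, replace = TRUE,
                       prob = config$ancestry_groups$proportion),
    hysterectomy = runif(n) < 0.40,
    bmi = rlnorm(n, log(28), 0.15),
    risk_score = rlnorm(n, log(0.012), 0.40),
    prior_e_years = sample(c("none", "<5", "5-10", ">=10"), n,
                           replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
    prior_ep_years = sample(c("none", "<5", "5-10", ">=10"), n,
                            replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05)),
    pct_energy_fat = rnorm(n, 35, 7),
    stringsAsFactors = FALSE
  )
  subjects$log_bmi <- log(subjects$bmi)
  subjects$log_risk_score <- log(subjects$risk_score)

  # membership pattern over the baseline components: every enrollee joins
  # hormone therapy, dietary modification, or both
  pattern <- sample(c("ht", "dm", "both"), n, replace = TRUE,
                    prob = c(0.283, 0.599, 0.118))
  subjects$ht_component <- pattern %in% c("ht", "both")
  subjects$dm_component <- pattern %in% c("dm", "both")
  subjects$cad_volunteer <- runif(n) < 0.62
  subjects$event_time <- Inf  # eligibility placeholder; outcomes drawn below

  specs <- config$component_specs
  for (nm in c("E_ALONE", "E_PLUS_P", "DM")) {
    memb <- specs[[nm]]$eligibility(subjects)
    subjects[[paste0("member_", nm)]] <- memb
    arm <- rep(NA_real_, n)
    arm[memb] <- as.numeric(runif(sum(memb)) < specs[[nm]]$q)
    subjects[[paste0("arm_", nm)]] <- arm
  }
  # CaD randomization happens at its year-one enrollment among volunteers;
  # assignments are drawn now and voided for women with an event before then
  cad_assign <- rep(NA_real_, n)
  cad_assign[subjects$cad_volunteer] <-
    as.numeric(runif(sum(subjects$cad_volunteer)) < specs$CAD$q)

  # high-fat subset: top dmq_quartile of dietary participants by baseline fat
  subjects$member_DMQ <- rep(FALSE, n)
  dm_idx <- which(subjects$member_DM)
  n_dmq <- round(config$dmq_quartile * length(dm_idx))
  top <- dm_idx[order(-subjects$pct_energy_fat[dm_idx])[seq_len(n_dmq)]]
  subjects$member_DMQ[top] <- TRUE
  subjects$arm_DMQ <- ifelse(subjects$member_DMQ, subjects$arm_DM, NA_real_)

  # discrete-time outcome model
  G <- simulate_genotypes(config, ancestry_labels = subjects$ethnicity,
                          seed = config$seed + 1L)
  lp_base <- qlogis(config$baseline_hazard) +
    config$covariate_effects[["log_risk_score"]] *
      (subjects$log_risk_score - mean(subjects$log_risk_score)) +
    config$covariate_effects[["log_bmi"]] *
      (subjects$log_bmi - mean(subjects$log_bmi))
  if (!is.null(config$or_per_allele)) {
    for (s in names(config$or_per_allele)) {
      lp_base <- lp_base + G$genotypes[, s] * log(config$or_per_allele[[s]])
    }
  }
  # genotype-specific (or constant) intervention log-OR per subject/component
  add_component_lp <- function(comp, active) {
    out <- rep(0, n)
    entries <- Filter(function(e) e$component == comp,
                      config$interaction_or_by_genotype %||% list())
    if (length(entries)) {
      for (e in entries) {
        out <- out + active * log(e$or[G$genotypes[, e$snp] + 1L])
      }
    } else {
      out <- active * log(config$intervention_or[[comp]] %||% 1)
    }
    out
  }
  act <- function(col) ifelse(is.na(subjects[[col]]), 0, subjects[[col]])
  lp_fixed <- lp_base +
    add_component_lp("E_ALONE", act("arm_E_ALONE")) +
    add_component_lp("E_PLUS_P", act("arm_E_PLUS_P")) +
    add_component_lp("DMQ", act("arm_DMQ"))
  cad_act <- ifelse(is.na(cad_assign), 0, cad_assign)
  lp_cad <- add_component_lp("CAD", cad_act)

  event_time <- rep(config$followup_years, n)
  case <- rep(FALSE, n)
  at_risk <- rep(TRUE, n)
  for (t in seq_len(config$followup_years)) {
    lp_t <- lp_fixed + if (t > specs$CAD$enrollment_time) lp_cad else 0
    h <- plogis(lp_t)
    ev <- at_risk & (runif(n) < h)
    event_time[ev] <- t
    case[ev] <- TRUE
    at_risk <- at_risk & !ev
  }
  subjects$case <- case
  subjects$event_time <- event_time

  # CaD membership requires being event-free at the year-one randomization
  memb_cad <- specs$CAD$eligibility(subjects)
  subjects$member_CAD <- memb_cad
  subjects$arm_CAD <- ifelse(memb_cad, cad_assign, NA_real_)

  subjects$er_status <- ifelse(case, ifelse(runif(n) < 0.75, "ER+", "ER-"),
                               NA_character_)
  subjects$pr_status <- ifelse(case, ifelse(runif(n) < 0.65, "PR+", "PR-"),
                               NA_character_)
  subjects$ht_component <- subjects$dm_component <-
    subjects$cad_volunteer <- NULL

  rownames(G$genotypes) <- subjects$subject_id
  structure(list(subjects = subjects, genotypes = G$genotypes,
                 snp_meta = G$snp_meta, config = config),
            class = "gxe_cohort")
}

#' @export
print.gxe_cohort <- function(x, ...) {
  cat(sprintf("Synthetic trial cohort: %d subjects, %d SNPs, %d cases\n",
              nrow(x$subjects), ncol(x$genotypes), sum(x$subjects$case)))
  invisible(x)
}

#' Greedy risk-set matched nested case-control selection
#'
#' Cases are processed in event-time order; each receives the eligible
#' control nearest in age, sampled without replacement.  Eligible controls
#' are event-free at the case's event time (event or censoring time at least
#' the case's event time), match exactly on the categorical factors
#' (ethnicity, hysterectomy, membership in every trial component), and lie
#' within the age caliper.  Cases with no eligible control are flagged
#' unmatched rather than failing the run.  Deterministic: ties in age
#' distance break towards the smaller subject id.
#'
#' @param cohort a \code{gxe_cohort} (or its \code{subjects} data.frame)
#' @param exact_factors column names matched exactly
#' @param age_caliper maximum age difference in years (default 2)
#' @return data.frame with one row per case: \code{case_id},
#'   \code{control_id} (NA when unmatched), \code{matched}, \code{age_case},
#'   \code{age_control}, \code{event_time}
#' @export
select_matched_case_control <- function(cohort,
                                        exact_factors = c(
                                          "ethnicity", "hysterectomy",
                                          "member_E_ALONE", "member_E_PLUS_P",
                                          "member_DM", "member_CAD"),
                                        age_caliper = 2) {
  subjects <- if (inherits(cohort, "gxe_cohort")) cohort$subjects else cohort
  cases <- subjects[subjects$case %in% TRUE, , drop = FALSE]
  pool <- subjects[!(subjects$case %in% TRUE), , drop = FALSE]
  if (nrow(cases) == 0L) stop("cohort contains no cases")
  exact_factors <- intersect(exact_factors, names(subjects))
  key <- function(df) do.call(paste, c(df[exact_factors], sep = "\r"))
  pool_key <- key(pool)
  pool_used <- rep(FALSE, nrow(pool))
  cases <- cases[order(cases$event_time, cases$subject_id), , drop = FALSE]
  case_key <- key(cases)
  out <- data.frame(case_id = cases$subject_id, control_id = NA_character_,
                    matched = FALSE, age_case = cases$age,
                    age_control = NA_real_, event_time = cases$event_time,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    elig <- which(!pool_used & pool_key == case_key[i] &
                    pool$event_time >= cases$event_time[i] &
                    abs(pool$age - cases$age[i]) <= age_caliper)
    if (!length(elig)) next
    d <- abs(pool$age[elig] - cases$age[i])
    pick <- elig[order(d, pool$subject_id[elig])[1L]]
    pool_used[pick] <- TRUE
    out$control_id[i] <- pool$subject_id[pick]
    out$age_control[i] <- pool$age[pick]
    out$matched[i] <- TRUE
  }
  out
}

#' Assemble an analysis-ready matched case-control table from a cohort
#'
#' Joins the matched pairs back to the cohort phenotypes, assigning one
#' \code{pair_id} per matched case, and returns the stacked case + control
#' phenotype rows in the column layout expected by \code{\link{joint_test}}
#' and the discrimination models.
#'
#' @param cohort a \code{gxe_cohort}
#' @param pairs result of \code{\link{select_matched_case_control}}
#' @return data.frame of phenotypes for matched cases and their controls,
#'   with columns \code{pair_id} and \code{member_E_ALONE},
#'   \code{member_E_PLUS_P}, \code{member_DMQ}, \code{member_CAD} (the DMQ
#'   and CaD analysis memberships), \code{arm_*}, \code{case}
#' @export
case_control_table <- function(cohort, pairs) {
  stopifnot(inherits(cohort, "gxe_cohort"))
  pairs <- pairs[pairs$matched, , drop = FALSE]
  subj <- cohort$subjects
  rownames(subj) <- subj$subject_id
  cc <- rbind(subj[pairs$case_id, , drop = FALSE],
              subj[pairs$control_id, , drop = FALSE])
  cc$pair_id <- rep(seq_len(nrow(pairs)), 2L)
  cc$case <- as.numeric(cc$case)
  rownames(cc) <- NULL
  cc
}

#' Directly simulate a matched nested case-control sample
#'
#' Draws the matched case-control sample from its implied marginal
#' distribution instead of simulating the full cohort: genotypes are
#' Hardy-Weinberg draws at the given frequencies (independent SNPs; use
#' \code{\link{simulate_cohort}} when LD or ancestry structure matters), the
#' genotype distribution among cases is tilted by any per-allele main-effect
#' odds ratio, controls are pair-matched on age, ethnicity, hysterectomy and
#' trial memberships, control arms follow the randomization fractions, and
#' case arms follow odds \code{q/(1-q)} times the intervention odds ratio at
#' the case's genotype (the rare-disease limit of the cohort hazard model:
#' genotype-specific odds ratios where an interaction is configured,
#' otherwise the component's main-effect odds ratio).  This is the fast path
#' for operating-characteristic studies at large case counts.
#'
#' @param n_cases number of matched pairs
#' @param seed integer seed
#' @param snp_maf named vector of minor allele frequencies (one SNP per entry)
#' @param q named randomization fractions (default \code{\link{default_q}})
#' @param membership_rates named per-component case membership probabilities
#'   (hormone components mutually exclusive; CaD additionally requires the
#'   event after its year-one randomization)
#' @param intervention_or named per-component intervention odds ratios among
#'   non-interacting SNP carriers
#' @param interaction_or_by_genotype list of
#'   \code{list(snp =, component =, or = c(or0, or1, or2))} entries
#' @param or_per_allele named per-SNP per-minor-allele case-control odds
#'   ratio (genotype main effects)
#' @param case_risk_shift,case_bmi_shift additive log-scale shifts of the
#'   case risk-score and body-mass-index distributions (confounder signal)
#' @param followup_years follow-up horizon (event times uniform over it)
#' @param dmq_quartile fraction of dietary participants in the high-fat
#'   subset
#' @return list of class \code{gxe_case_control} with \code{subjects}
#'   (phenotype rows for cases then controls, with \code{pair_id}) and
#'   \code{genotypes}
#' @export
simulate_case_control <- function(n_cases,
                                  seed = 1,
                                  snp_maf = c(snp_0001 = 0.42),
                                  q = default_q(),
                                  membership_rates = c(E_ALONE = 0.114,
                                                       E_PLUS_P = 0.217,
                                                       DM = 0.717,
                                                       CAD = 0.553),
                                  intervention_or = c(E_ALONE = 1,
                                                      E_PLUS_P = 1,
                                                      DMQ = 1, CAD = 1),
                                  interaction_or_by_genotype = NULL,
                                  or_per_allele = NULL,
                                  case_risk_shift = 0.25,
                                  case_bmi_shift = 0.05,
                                  followup_years = 8,
                                  dmq_quartile = 0.25) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_cases
  snp_ids <- names(snp_maf) %||% sprintf("snp_%04d", seq_along(snp_maf))
  names(snp_maf) <- snp_ids

  age <- sample(50:79, n, replace = TRUE, prob = dnorm(50:79, 63, 7))
  ethnicity <- sample(c("european", "african", "other"), n, replace = TRUE,
                      prob = c(0.86, 0.09, 0.05))
  p_ht <- membership_rates[["E_ALONE"]] + membership_rates[["E_PLUS_P"]]
  in_ht <- runif(n) < p_ht
  hyst <- ifelse(in_ht,
                 runif(n) < membership_rates[["E_ALONE"]] / p_ht,
                 runif(n) < 0.35)
  member_E_ALONE <- in_ht & hyst
  member_E_PLUS_P <- in_ht & !hyst
  member_DM <- runif(n) < membership_rates[["DM"]]
  member_DM[!in_ht & !member_DM] <- TRUE  # every enrollee is in >= 1 component
  event_time <- runif(n, 0, followup_years)
  member_CAD <- (runif(n) < membership_rates[["CAD"]] /
                   mean(event_time > 1)) & event_time > 1
  pct_fat <- rnorm(n, 35, 7)
  fat_cut <- qnorm(1 - dmq_quartile, 35, 7)
  member_DMQ <- member_DM & pct_fat >= fat_cut

  # case genotypes, tilted by any main-effect per-allele odds ratio
  gen_case <- sapply(snp_ids, function(s) {
    f <- snp_maf[[s]]
    pg <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    or <- if (!is.null(or_per_allele) && s %in% names(or_per_allele)) {
      or_per_allele[[s]]
    } else 1
    w <- pg * or^(0:2)
    sample(0:2, n, replace = TRUE, prob = w / sum(w))
  })
  gen_ctrl <- sapply(snp_ids, function(s) {
    rbinom(n, 2L, snp_maf[[s]])
  })
  if (length(snp_ids) == 1L) {
    gen_case <- matrix(gen_case, ncol = 1, dimnames = list(NULL, snp_ids))
    gen_ctrl <- matrix(gen_ctrl, ncol = 1, dimnames = list(NULL, snp_ids))
  }

  # case arm odds: q/(1-q) x intervention OR at the case's genotype
  case_or <- function(comp) {
    entries <- Filter(function(e) e$component == comp,
                      interaction_or_by_genotype %||% list())
    if (!length(entries)) return(rep(intervention_or[[comp]] %||% 1, n))
    or <- rep(1, n)
    for (e in entries) or <- or * e$or[gen_case[, e$snp] + 1L]
    or
  }
  draw_arm <- function(member, p_active) {
    ifelse(member, as.numeric(runif(n) < p_active), NA_real_)
  }
  arm_case <- function(comp, member) {
    odds <- q[[comp]] / (1 - q[[comp]]) * case_or(comp)
    draw_arm(member, odds / (1 + odds))
  }
  cases <- data.frame(
    subject_id = sprintf("case_%06d", seq_len(n)),
    pair_id = seq_len(n), case = 1,
    age = age, ethnicity = ethnicity, hysterectomy = hyst,
    bmi = rlnorm(n, log(28) + case_bmi_shift, 0.15),
    risk_score = rlnorm(n, log(0.012) + case_risk_shift, 0.40),
    pct_energy_fat = pct_fat, event_time = event_time,
    member_E_ALONE = member_E_ALONE, member_E_PLUS_P = member_E_PLUS_P,
    member_DM = member_DM, member_DMQ = member_DMQ, member_CAD = member_CAD,
    arm_E_ALONE = arm_case("E_ALONE", member_E_ALONE),
    arm_E_PLUS_P = arm_case("E_PLUS_P", member_E_PLUS_P),
    arm_CAD = arm_case("CAD", member_CAD),
    er_status = ifelse(runif(n) < 0.75, "ER+", "ER-"),
    pr_status = ifelse(runif(n) < 0.65, "PR+", "PR-"),
    stringsAsFactors = FALSE
  )
  # the dietary arm is shared by DM and its high-fat subset; interaction
  # odds apply inside the subset
  arm_dm_case <- {
    odds_plain <- q[["DMQ"]] / (1 - q[["DMQ"]])
    odds_dmq <- odds_plain * case_or("DMQ")
    odds <- ifelse(member_DMQ, odds_dmq, odds_plain)
    draw_arm(member_DM, odds / (1 + odds))
  }
  cases$arm_DM <- arm_dm_case
  cases$arm_DMQ <- ifelse(member_DMQ, arm_dm_case, NA_real_)

  ctrl_fat <- rnorm(n, 35, 7)
  controls <- data.frame(
    subject_id = sprintf("ctrl_%06d", seq_len(n)),
    pair_id = seq_len(n), case = 0,
    age = pmin(pmax(age + sample(-2:2, n, replace = TRUE), 50), 79),
    ethnicity = ethnicity, hysterectomy = hyst,
    bmi = rlnorm(n, log(28), 0.15),
    risk_score = rlnorm(n, log(0.012), 0.40),
    pct_energy_fat = ctrl_fat, event_time = followup_years,
    member_E_ALONE = member_E_ALONE, member_E_PLUS_P = member_E_PLUS_P,
    member_DM = member_DM,
    member_DMQ = member_DM & ctrl_fat >= fat_cut,
    member_CAD = member_CAD,
    arm_E_ALONE = draw_arm(member_E_ALONE, q[["E_ALONE"]]),
    arm_E_PLUS_P = draw_arm(member_E_PLUS_P, q[["E_PLUS_P"]]),
    arm_CAD = draw_arm(member_CAD, q[["CAD"]]),
    er_status = NA_character_, pr_status = NA_character_,
    stringsAsFactors = FALSE
  )
  controls$arm_DM <- draw_arm(member_DM, q[["DMQ"]])
  controls$arm_DMQ <- ifelse(controls$member_DMQ, controls$arm_DM, NA_real_)

  subjects <- rbind(cases, controls[, names(cases)])
  subjects$log_bmi <- log(subjects$bmi)
  subjects$log_risk_score <- log(subjects$risk_score)
  G <- rbind(gen_case, gen_ctrl)
  rownames(G) <- subjects$subject_id
  structure(list(subjects = subjects, genotypes = G,
                 snp_maf = snp_maf, seed = seed),
            class = "gxe_case_control")
}

#' @export
print.gxe_case_control <- function(x, ...) {
  cat(sprintf("Matched case-control sample: %d pairs, %d SNPs\n",
              sum(x$subjects$case == 1), ncol(x$genotypes)))
  invisible(x)
}
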