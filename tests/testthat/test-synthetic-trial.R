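test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_snps = 7, ld_block_sizes = c(5, 5)),
               "sum\\(ld_block_sizes\\)")
  expect_error(sim_config(within_block_adjacent_r = 1), "adjacent_r")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(intervention_or = c(E_ALONE = -1)), "positive")
  expect_error(sim_config(baseline_hazard = 0), "baseline_hazard")
  expect_error(sim_config(ancestry_groups = data.frame(
    label = "a", proportion = 0.9, freq_shift = 0)), "sum to 1")
  expect_error(sim_config(interaction_or_by_genotype =
                            list(list(snp = "s", component = "DMQ",
                                      or = c(1, 2)))), "OR triple")
  expect_error(trial_component_spec("E_ALONE", q = 1.5,
                                    eligibility = function(s) TRUE), "q")
})

test_that("cohort simulation is deterministic and respects the design", {
  cfg <- sim_config(n_subjects = 1200, seed = 11, baseline_hazard = 0.01)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$genotypes, c2$genotypes)

  s <- c1$subjects
  # the two hormone trials never overlap
  expect_false(any(s$member_E_ALONE & s$member_E_PLUS_P))
  # estrogen-alone is the post-hysterectomy trial
  expect_true(all(s$hysterectomy[s$member_E_ALONE]))
  expect_true(all(!s$hysterectomy[s$member_E_PLUS_P]))
  # arms only inside memberships
  for (comp in c("E_ALONE", "E_PLUS_P", "DM", "DMQ", "CAD")) {
    memb <- s[[paste0("member_", comp)]]
    arm <- s[[paste0("arm_", comp)]]
    expect_true(all(is.na(arm[!memb])))
    expect_true(all(arm[memb] %in% c(0, 1)))
  }
  # calcium/vitamin D randomizes at year one among the then event-free
  expect_true(all(s$event_time[s$member_CAD] > 1))
  # the high-fat subset is the top quartile of dietary participants (+-1)
  expect_lte(abs(sum(s$member_DMQ) - round(0.25 * sum(s$member_DM))), 1)
  expect_true(all(s$member_DM[s$member_DMQ]))
  # event times bounded by follow-up
  expect_true(all(s$event_time <= cfg$followup_years & s$event_time >= 1))
  # receptor status only for cases
  expect_true(all(is.na(s$er_status[!s$case])))
  expect_true(all(s$er_status[s$case] %in% c("ER+", "ER-")))
})

test_that("null cohort case fraction matches the discrete-hazard expectation", {
  h <- 0.01
  cfg <- sim_config(n_subjects = 4000, seed = 12, baseline_hazard = h,
                    intervention_or = c(E_ALONE = 1, E_PLUS_P = 1,
                                        DMQ = 1, CAD = 1),
                    covariate_effects = c(log_risk_score = 0,
                                          log_bmi = 0))
  coh <- simulate_cohort(cfg)
  expected <- 1 - (1 - h)^cfg$followup_years
  sd3 <- 3 * sqrt(expected * (1 - expected) / cfg$n_subjects)
  expect_lt(abs(mean(coh$subjects$case) - expected), sd3)
})

test_that("genotype generator hits its LD and ancestry targets", {
  # independence limit
  cfg0 <- sim_config(n_subjects = 4000, seed = 5, n_snps = 5,
                     ld_block_sizes = 5, within_block_adjacent_r = 0)
  g0 <- simulate_genotypes(cfg0)
  r2_0 <- sapply(1:4, function(k) ld_r2(g0$genotypes[, k],
                                        g0$genotypes[, k + 1]))
  expect_true(all(r2_0 < 0.01))
  expect_true(all(g0$genotypes %in% 0:2))

  # adjacent allelic correlation 0.9 gives adjacent r2 near 0.81
  cfg9 <- sim_config(n_subjects = 10000, seed = 4, n_snps = 5,
                     ld_block_sizes = 5, within_block_adjacent_r = 0.9,
                     ancestry_groups = data.frame(label = "a", proportion = 1,
                                                  freq_shift = 0))
  g9 <- simulate_genotypes(cfg9)
  r2_9 <- sapply(1:4, function(k) ld_r2(g9$genotypes[, k],
                                        g9$genotypes[, k + 1]))
  expect_true(all(abs(r2_9 - 0.81) < 0.05))
  # between-block correlation near zero
  cfg2b <- sim_config(n_subjects = 4000, seed = 6, n_snps = 4,
                      ld_block_sizes = c(2, 2),
                      within_block_adjacent_r = 0.9)
  g2b <- simulate_genotypes(cfg2b)
  expect_lt(ld_r2(g2b$genotypes[, 2], g2b$genotypes[, 3]), 0.01)

  # two ancestry groups with a 0.2 frequency shift separate on PC1
  cfga <- sim_config(n_subjects = 600, seed = 3, n_snps = 150,
                     ld_block_sizes = rep(5, 30),
                     within_block_adjacent_r = 0.2,
                     ancestry_groups = data.frame(
                       label = c("g1", "g2"), proportion = c(0.5, 0.5),
                       freq_shift = c(0, 0.2)))
  ga <- simulate_genotypes(cfga)
  pc <- pca_genotypes(ga$genotypes, 2)
  pb <- abs(cor(pc$scores[, 1], as.numeric(ga$ancestry == "g2")))
  expect_gt(pb, 0.9)
})

test_that("stratification adjustment removes ancestry confounding", {
  # case risk differs by ancestry while genotypes carry no causal effect:
  # unadjusted trend tests inflate, PC-adjusted ones recalibrate
  set.seed(13)
  cfg <- sim_config(n_subjects = 900, seed = 13, n_snps = 60,
                    ld_block_sizes = rep(2, 30),
                    within_block_adjacent_r = 0.3,
                    ancestry_groups = data.frame(
                      label = c("g1", "g2"), proportion = c(0.5, 0.5),
                      freq_shift = c(0, 0.25)))
  g <- simulate_genotypes(cfg)
  y <- rbinom(900, 1, ifelse(g$ancestry == "g2", 0.45, 0.15))
  pcs <- pca_genotypes(g$genotypes, 4)$scores
  chi_raw <- chi_adj <- numeric(ncol(g$genotypes))
  for (j in seq_len(ncol(g$genotypes))) {
    r <- main_effect_score_test(y, g$genotypes[, j])
    a <- main_effect_score_test(y, g$genotypes[, j], covariates = pcs)
    chi_raw[j] <- r$U^2 / r$V
    chi_adj[j] <- a$U^2 / a$V
  }
  med_null <- qchisq(0.5, 1)
  expect_gt(median(chi_raw), 2 * med_null)      # strong inflation
  expect_lt(abs(median(chi_adj) - med_null),
            abs(median(chi_raw) - med_null))    # adjustment shrinks it
  expect_lt(median(chi_adj), 1.5 * med_null)    # near-calibrated after
})

test_that("greedy risk-set matching follows the hand-computed assignment", {
  base <- data.frame(
    ethnicity = "european", hysterectomy = FALSE,
    member_E_ALONE = FALSE, member_E_PLUS_P = TRUE, member_DM = TRUE,
    member_CAD = TRUE, stringsAsFactors = FALSE)
  subjects <- cbind(
    data.frame(
      subject_id = c("caseA", "caseB", "caseC",
                     "ctrl1", "ctrl2", "ctrl3", "ctrl4", "ctrl5"),
      age = c(60, 65, 70, 61, 59, 66, 64, 71),
      case = c(TRUE, TRUE, TRUE, rep(FALSE, 5)),
      event_time = c(1, 2, 3, 8, 8, 8, 1.5, 8),
      stringsAsFactors = FALSE),
    base[rep(1, 8), ], row.names = NULL)
  m <- select_matched_case_control(subjects, age_caliper = 2)
  # caseA (t=1): ctrl1 and ctrl2 both 1 year away; id order breaks the tie
  # caseB (t=2): ctrl4 fails the risk set (event at 1.5), so ctrl3
  # caseC (t=3): ctrl5
  expect_equal(m$control_id[m$case_id == "caseA"], "ctrl1")
  expect_equal(m$control_id[m$case_id == "caseB"], "ctrl3")
  expect_equal(m$control_id[m$case_id == "caseC"], "ctrl5")
  expect_true(all(m$matched))

  # risk-set violation: the only candidate fails, case flagged unmatched
  two <- subjects[subjects$subject_id %in% c("caseB", "ctrl4"), ]
  m2 <- select_matched_case_control(two, age_caliper = 2)
  expect_false(m2$matched)
  expect_true(is.na(m2$control_id))

  expect_error(select_matched_case_control(subjects[subjects$case == FALSE, ]),
               "no cases")
})

test_that("a clone pool matches every case exactly", {
  cfg <- sim_config(n_subjects = 400, seed = 14, baseline_hazard = 0.02)
  coh <- simulate_cohort(cfg)
  cases <- coh$subjects[coh$subjects$case, , drop = FALSE]
  clones <- cases
  clones$subject_id <- paste0("clone_", cases$subject_id)
  clones$case <- FALSE
  clones$event_time <- cfg$followup_years + 1
  m <- select_matched_case_control(rbind(cases, clones))
  expect_true(all(m$matched))
  expect_equal(sort(m$control_id), sort(clones$subject_id))
  expect_true(all(m$age_case == m$age_control))
})

test_that("matched table and direct case-control generator line up", {
  cfg <- sim_config(n_subjects = 2500, seed = 15, baseline_hazard = 0.015)
  coh <- simulate_cohort(cfg)
  pairs <- select_matched_case_control(coh)
  cc <- case_control_table(coh, pairs)
  expect_equal(nrow(cc), 2 * sum(pairs$matched))
  expect_true(all(table(cc$pair_id) == 2))
  # controls outlive (or match) their case
  et <- tapply(cc$event_time, cc$pair_id, function(x) x[2] - x[1])
  expect_true(all(et >= 0))

  s <- simulate_case_control(500, seed = 16, snp_maf = c(a = 0.4, b = 0.25))
  d1 <- simulate_case_control(500, seed = 16, snp_maf = c(a = 0.4, b = 0.25))
  expect_identical(s$subjects, d1$subjects)
  expect_identical(s$genotypes, d1$genotypes)
  expect_false(any(s$subjects$member_E_ALONE & s$subjects$member_E_PLUS_P))
  expect_true(all(s$subjects$event_time[s$subjects$member_CAD] > 1))
})

test_that("randomized arms are independent of genotype across replicates", {
  set.seed(17)
  nrep <- 120
  cors <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg <- sim_config(n_subjects = 300, seed = 1000 + r, n_snps = 2,
                      ld_block_sizes = 2, baseline_hazard = 0.01)
    coh <- simulate_cohort(cfg)
    dm <- coh$subjects$member_DM
    cors[r] <- cor(coh$subjects$arm_DM[dm], coh$genotypes[dm, 1])
  }
  # mean correlation within 3 standard errors of zero
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(nrep))
})

test_that("cohort-path interaction effects reach downstream OR estimates", {
  # moderate-size full-cohort run: genotype-specific intervention ORs set in
  # the hazard model are recovered by the case-only estimator within the
  # sampling error of the component's few hundred cases
  triple <- c(0.45, 1.0, 1.8)
  cfg <- sim_config(n_subjects = 40000, seed = 18, n_snps = 4,
                    ld_block_sizes = 4, baseline_hazard = 0.004,
                    maf_range = c(0.4, 0.45),
                    intervention_or = c(E_ALONE = 1, E_PLUS_P = 1, DMQ = 1,
                                        CAD = 1),
                    interaction_or_by_genotype = list(
                      list(snp = "snp_0001", component = "E_PLUS_P",
                           or = triple)))
  coh <- simulate_cohort(cfg)
  s <- coh$subjects
  ic <- s$case & s$member_E_PLUS_P
  pr <- interaction_profile(coh$genotypes[s$subject_id[ic], "snp_0001"],
                            s$arm_E_PLUS_P[ic], q = 0.5)
  # log-scale agreement within 3 Wald standard errors per genotype
  se <- apply(pr$counts, 2, function(cc) sqrt(sum(1 / pmax(cc, 0.5))))
  expect_true(all(abs(log(pr$or_by_genotype) - log(triple)) < 3 * se))
  expect_lt(pr$lrt_2df_p, 0.05)
})
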