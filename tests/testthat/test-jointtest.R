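test_that("main-effect score test matches trend-test and full-ML oracles", {
  set.seed(101)
  n <- 200
  g <- rbinom(n, 2, 0.35)
  y <- rbinom(n, 1, plogis(-0.4 + 0.5 * g))

  # perfectly balanced construction: same genotypes among cases and controls
  gg <- rep(rbinom(50, 2, 0.4), 2)
  yy <- rep(c(1, 0), each = 50)
  bal <- main_effect_score_test(yy, gg)
  expect_equal(bal$U, 0, tolerance = 1e-12)
  expect_equal(bal$p, 1)

  # Cochran-Armitage trend oracle via prop.trend.test on the 2x3 table
  ms <- main_effect_score_test(y, g)
  tab_cases <- vapply(0:2, function(k) sum(y == 1 & g == k), numeric(1))
  tab_tot <- vapply(0:2, function(k) sum(g == k), numeric(1))
  ca <- suppressWarnings(stats::prop.trend.test(tab_cases, tab_tot,
                                                score = 0:2))
  expect_equal(ms$U^2 / ms$V, unname(ca$statistic), tolerance = 1e-8)

  # full-ML oracles, now with covariates: Rao score from iterative glm fits,
  # and the likelihood-ratio p within the usual O(n^-1/2) discrepancy
  x1 <- rnorm(n)
  f0 <- glm(y ~ x1, family = binomial())
  f1 <- glm(y ~ x1 + g, family = binomial())
  rao <- anova(f0, f1, test = "Rao")$Rao[2]
  msc <- main_effect_score_test(y, g, covariates = cbind(x1))
  expect_equal(msc$U^2 / msc$V, rao, tolerance = 1e-6)
  p_lr <- anova(f0, f1, test = "LRT")$`Pr(>Chi)`[2]
  expect_lt(abs(msc$p - p_lr), 0.02)

  # score U equals the sum of retained per-subject contributions
  expect_equal(msc$U, sum(msc$per_subject_contributions), tolerance = 1e-10)

  # monomorphic genotype flags degenerate with zero variance
  mono <- main_effect_score_test(y, rep(1, n))
  expect_true(mono$degenerate)
  expect_equal(mono$V, 0)
})

test_that("case-only interaction score test is centered and matches glm Rao", {
  # balanced construction: identical arm split at every genotype
  bal <- case_only_score_test(c(1, 0, 1, 0, 1, 0), c(0, 1, 2, 0, 1, 2),
                              q = 0.5)
  expect_equal(bal$U, 0, tolerance = 1e-12)
  expect_equal(bal$p, 1)

  # degenerate flags
  expect_true(case_only_score_test(c(1, 0, 1), rep(2, 3), 0.5)$degenerate)
  expect_true(case_only_score_test(rep(1, 4), c(0, 1, 2, 1), 0.5)$degenerate)

  # full-ML oracle: Rao score test from iterative offset logistic fits
  set.seed(102)
  n <- 300
  g <- rbinom(n, 2, 0.42)
  a <- rbinom(n, 1, plogis(0.3 + 0.25 * g))
  q <- 0.4
  off <- rep(log(q / (1 - q)), n)
  f0 <- glm(a ~ 1, family = binomial(), offset = off)
  f1 <- glm(a ~ g, family = binomial(), offset = off)
  rao <- anova(f0, f1, test = "Rao")$Rao[2]
  cs <- case_only_score_test(a, g, q = q)
  expect_equal(cs$U^2 / cs$V, rao, tolerance = 1e-6)

  # an intervention main effect alone (active fraction far from q) does not
  # generate a spurious score: the free intercept absorbs it
  a_main <- rbinom(5000, 1, 0.75)
  g_null <- rbinom(5000, 2, 0.3)
  cs_null <- case_only_score_test(a_main, g_null, q = 0.5)
  expect_equal(cs_null$U, sum((a_main - mean(a_main)) *
                                (g_null - mean(g_null))), tolerance = 1e-8)

  expect_error(case_only_score_test(c(1, 0), c(0, 1), q = 1.2), "q must")
})

test_that("covariance assembly uses structural zeros and sandwich overlaps", {
  mk <- function(comp, ids, contrib) {
    s <- list(component = comp, U = sum(contrib), V = sum(contrib^2),
              n_used = length(ids),
              per_subject_contributions = setNames(contrib, ids),
              degenerate = FALSE, failed = FALSE, p = 0.5)
    class(s) <- "component_score"
    s
  }
  set.seed(103)
  cA <- rnorm(50); cB <- rnorm(50)

  # disjoint case sets: zero covariance
  V <- assemble_covariance(list(DMQ = mk("DMQ", 1:50, cA),
                                CAD = mk("CAD", 51:100, cB)))
  expect_equal(V["DMQ", "CAD"], 0)

  # a component duplicated: correlation exactly 1
  V2 <- assemble_covariance(list(DMQ = mk("DMQ", 1:50, cA),
                                 CAD = mk("CAD", 1:50, cA)))
  expect_equal(V2["DMQ", "CAD"] / sqrt(V2["DMQ", "DMQ"] * V2["CAD", "CAD"]),
               1, tolerance = 1e-12)

  # partial overlap: cross term is the sum over shared subjects
  V3 <- assemble_covariance(list(DMQ = mk("DMQ", 1:50, cA),
                                 CAD = mk("CAD", 26:75, cB)))
  expect_equal(V3["DMQ", "CAD"], sum(cA[26:50] * cB[1:25]), tolerance = 1e-12)

  # hormone trials: structurally zero even when ids overlap artificially
  V4 <- assemble_covariance(list(E_ALONE = mk("E_ALONE", 1:50, cA),
                                 E_PLUS_P = mk("E_PLUS_P", 1:50, cB)))
  expect_identical(V4["E_ALONE", "E_PLUS_P"], 0)

  # main effect vs case-only: structural zero by default, empirical when
  # the structural zero is disabled
  V5 <- assemble_covariance(list(MAIN = mk("MAIN", 1:50, cA),
                                 CAD = mk("CAD", 1:50, cB)))
  expect_identical(V5["MAIN", "CAD"], 0)
  V6 <- assemble_covariance(list(MAIN = mk("MAIN", 1:50, cA),
                                 CAD = mk("CAD", 1:50, cB)),
                            structural_zero = FALSE)
  expect_equal(V6["MAIN", "CAD"], sum(cA * cB), tolerance = 1e-12)

  bad <- mk("DMQ", 1:5, rnorm(5))
  names(bad$per_subject_contributions) <- NULL
  expect_error(assemble_covariance(list(DMQ = bad, CAD = mk("CAD", 1:5, rnorm(5)))),
               "named by subject id")
})

test_that("sandwich cross term tracks the true score covariance", {
  # two overlapping case-only components whose arms coincide on the shared
  # subjects, so the true covariance is the shared Fisher information;
  # replicate simulation compares the empirical covariance of the scores
  # with the average sandwich estimate
  set.seed(104)
  n_shared <- 150; n_only <- 100
  nrep <- 1500
  u <- matrix(NA_real_, nrep, 2)
  sand <- numeric(nrep)
  for (r in seq_len(nrep)) {
    g <- rbinom(n_shared + 2 * n_only, 2, 0.4)
    a_shared <- rbinom(n_shared, 1, 0.55)
    aA <- c(a_shared, rbinom(n_only, 1, 0.55))
    aB <- c(a_shared, rbinom(n_only, 1, 0.55))
    idsA <- c(seq_len(n_shared), n_shared + seq_len(n_only))
    idsB <- c(seq_len(n_shared), n_shared + n_only + seq_len(n_only))
    sA <- case_only_score_test(aA, g[idsA], 0.5, "DMQ", subject_id = idsA)
    sB <- case_only_score_test(aB, g[idsB], 0.5, "CAD", subject_id = idsB)
    u[r, ] <- c(sA$U, sB$U)
    sand[r] <- assemble_covariance(list(DMQ = sA, CAD = sB))["DMQ", "CAD"]
  }
  emp <- cov(u)[1, 2]
  # Monte-Carlo error of the empirical covariance at this replicate count
  mc_se <- sd(u[, 1] * u[, 2]) / sqrt(nrep)
  expect_lt(abs(emp - mean(sand)), 3 * mc_se)
  expect_gt(mean(sand), 0)  # genuinely positive dependence detected
})

test_that("combined chi-square uses the pseudo-inverse and reduces df", {
  comps <- c("MAIN", "E_ALONE", "E_PLUS_P", "DMQ", "CAD")

  z <- combined_chi2_test(setNames(rep(0, 5), comps), diag(5))
  expect_equal(z$chi2, 0)
  expect_equal(z$p, 1)

  ct <- combined_chi2_test(setNames(rep(1, 5), comps), diag(5))
  expect_equal(ct$chi2, 5, tolerance = 1e-12)
  expect_equal(ct$df, 5L)
  expect_equal(ct$p, pchisq(5, 5, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(ct$p, 0.41588, tolerance = 1e-4)

  # one degenerate component: df 4, equal to the reduced quadratic form
  set.seed(105)
  A <- crossprod(matrix(rnorm(25), 5))
  u <- rnorm(5)
  deg <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  red <- combined_chi2_test(setNames(u, comps), A, degenerate = deg)
  expect_equal(red$df, 4L)
  direct <- drop(t(u[!deg]) %*% solve(A[!deg, !deg]) %*% u[!deg])
  expect_equal(red$chi2, direct, tolerance = 1e-8)

  # rank-deficient covariance: df follows the matrix rank
  B <- A
  B[5, ] <- B[4, ]; B[, 5] <- B[, 4]
  u2 <- u; u2[5] <- u2[4]
  rk <- combined_chi2_test(setNames(u2, comps), B)
  expect_equal(rk$df, 4L)

  expect_error(combined_chi2_test(setNames(u, comps), matrix(rnorm(25), 5)),
               "symmetric")

  # all degenerate: flagged missing
  allna <- combined_chi2_test(setNames(u, comps), A, degenerate = rep(TRUE, 5))
  expect_true(is.na(allna$p))
  expect_equal(allna$df, 0L)
})

test_that("allele-coding flips change score signs but not chi2 or p", {
  s <- simulate_case_control(400, seed = 106,
                             snp_maf = c(a = 0.3, b = 0.45))
  run <- function(G) {
    joint_test(s$subjects, G, covariates = c("log_risk_score", "log_bmi"),
               n_pcs = 0)
  }
  base <- run(s$genotypes)
  flipped <- s$genotypes
  flipped[, "a"] <- 2L - flipped[, "a"]
  fl <- run(flipped)
  expect_equal(fl$U_main[1], -base$U_main[1], tolerance = 1e-10)
  expect_equal(fl$chi2, base$chi2, tolerance = 1e-10)
  expect_equal(fl$p_combined, base$p_combined, tolerance = 1e-10)
  expect_equal(fl$p_main, base$p_main, tolerance = 1e-10)
})

test_that("joint_test validates inputs and handles degenerate SNPs", {
  s <- simulate_case_control(200, seed = 107, snp_maf = c(a = 0.3))
  expect_error(joint_test(s$subjects, s$genotypes, covariates = "nope"),
               "covariate columns")
  G2 <- cbind(s$genotypes, mono = rep(1L, nrow(s$genotypes)))
  res <- joint_test(s$subjects, G2, n_pcs = 0)
  expect_equal(res$df[res$snp_id == "mono"], 0L)
  expect_true(is.na(res$p_combined[res$snp_id == "mono"]))
  expect_equal(res$df[res$snp_id == "a"], 5L)
  expect_true(all(res$p_combined[1] >= 0 & res$p_combined[1] <= 1))
})
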