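# Independent oracles and shared fixtures for the test suite.

# all-pairs concordance count (ties one half): brute-force AUC
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (x in cases) {
    tot <- tot + sum(x > ctrls) + 0.5 * sum(x == ctrls)
  }
  tot / (length(cases) * length(ctrls))
}

# log-likelihood of an offset logistic model given a linear predictor builder
offset_loglik <- function(par, a, X, off) {
  eta <- off + drop(X %*% par)
  sum(a * eta - log1p(exp(eta)))
}

# maximize an offset logistic log-likelihood by quasi-Newton, independently
# of glm
optim_offset_logistic <- function(a, X, off) {
  fit <- optim(rep(0, ncol(X)), function(par) -offset_loglik(par, a, X, off),
               method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  list(coef = fit$par, loglik = -fit$value)
}

# five dosage columns with a known r2-to-anchor chain:
# r2(1,2) ~ .50, r2(1,3) ~ .31, r2(1,4) ~ .13, r2(4,5) ~ .92
ld_chain_fixture <- function() {
  cbind(
    s1 = c(1,2,1,1,1,0,1,1,0,2,1,0,1,1,1,2,1,1,0,0,2,1,2,0,2,1,2,1,0,1,0,2,0,0,0,1,1,0,0,1),
    s2 = c(1,1,1,1,1,0,1,1,0,2,0,0,1,1,1,2,1,1,0,2,2,1,2,1,2,1,2,0,0,1,0,2,0,0,0,1,1,2,0,1),
    s3 = c(1,1,1,1,1,1,1,1,0,2,1,0,1,1,1,2,1,1,2,0,2,2,1,0,2,2,2,0,0,2,0,2,0,0,2,2,1,0,2,0),
    s4 = c(1,0,1,2,2,0,1,1,0,2,2,1,2,2,2,2,1,1,1,1,2,1,2,2,2,1,2,1,2,2,0,0,2,1,0,1,2,0,0,0),
    s5 = c(1,1,1,2,2,0,1,1,0,2,2,1,2,2,2,2,1,1,1,1,2,1,1,2,2,1,2,1,2,2,0,0,2,1,0,1,2,0,0,0)
  )
}

# small matched case-control sample with real interaction signal, shared by
# several discrimination tests
strong_interaction_sample <- function(n_pairs = 2000, seed = 9) {
  simulate_case_control(
    n_pairs, seed = seed,
    membership_rates = c(E_ALONE = 0.5, E_PLUS_P = 0.3, DM = 0.717,
                         CAD = 0.553),
    interaction_or_by_genotype = list(
      list(snp = "snp_0001", component = "E_ALONE", or = c(0.3, 1.0, 3.0)),
      list(snp = "snp_0001", component = "CAD", or = c(0.4, 1.0, 2.5))))
}

# published top-20 combined-test list: p-values and printed FDR column
published_top20 <- function() whi_top20()
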