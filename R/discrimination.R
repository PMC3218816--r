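#' Area under the ROC curve by the Mann-Whitney statistic
#'
#' Probability that a randomly chosen case's score exceeds a randomly chosen
#' control's, with ties counting one half: computed from mid-ranks, which is
#' exactly the all-pairs concordance count.
#'
#' @param scores numeric risk scores
#' @param labels 0/1 (control/case) class labels
#' @return AUC in [0, 1]
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # mid-ranks give the tie-corrected Mann-Whitney count
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Logistic fit with a ridge-stabilized IRLS fallback for separated data.
# Returns coef, fitted, loglik, and flags (converged, ridge).
fit_logistic_stable <- function(X, y, ridge_lambda = 1e-4) {
  fit <- tryCatch(suppressWarnings(glm.fit(X, y, family = binomial())),
                  error = function(e) NULL)
  sep <- is.null(fit) || !fit$converged || any(abs(fit$coefficients) > 15,
                                               na.rm = TRUE) ||
    anyNA(fit$coefficients)
  if (!sep) {
    return(list(coef = fit$coefficients, fitted = fit$fitted.values,
                loglik = sum(y * log(fit$fitted.values) +
                               (1 - y) * log(1 - fit$fitted.values)),
                ridge = FALSE, converged = TRUE))
  }
  # ridge IRLS: small L2 penalty on non-intercept coefficients
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge_lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- tryCatch(
      solve(crossprod(X, X * w) + pen, crossprod(X, w * z)),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  mu <- plogis(drop(X %*% beta))
  list(coef = setNames(beta, colnames(X)), fitted = mu,
       loglik = sum(y * log(pmax(mu, 1e-12)) +
                      (1 - y) * log(pmax(1 - mu, 1e-12))),
       ridge = TRUE, converged = TRUE)
}

# Design matrices for the three nested risk models.
# M0: intercept + confounders + active-assignment indicators;
# M1: M0 + per-SNP indicators for one and two minor alleles;
# M2: M1 + SNP-indicator x assignment products.
build_risk_designs <- function(data, genotypes, snp_ids,
                               covariates = NULL,
                               components = COMPONENTS) {
  n <- nrow(data)
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    X0 <- cbind(X0, as.matrix(data[, covariates, drop = FALSE]))
  }
  arms <- sapply(components, function(comp) {
    a <- data[[paste0("arm_", comp)]]
    ifelse(is.na(a), 0, a)  # active-assignment indicator; non-members 0
  })
  colnames(arms) <- paste0("active_", components)
  X0 <- cbind(X0, arms)
  snp_ind <- NULL
  for (s in snp_ids) {
    g <- genotypes[, s]
    snp_ind <- cbind(snp_ind,
                     matrix(c(as.numeric(g == 1), as.numeric(g == 2)),
                            ncol = 2,
                            dimnames = list(NULL, paste0(s, c("_het", "_hom")))))
  }
  X1 <- cbind(X0, snp_ind)
  inter <- NULL
  for (j in seq_len(ncol(snp_ind))) {
    for (comp in components) {
      inter <- cbind(inter, snp_ind[, j] * arms[, paste0("active_", comp)])
      colnames(inter)[ncol(inter)] <-
        paste0(colnames(snp_ind)[j], "_x_", comp)
    }
  }
  X2 <- cbind(X1, inter)
  # drop constant interaction columns (e.g. nobody active with 2 copies)
  keep <- c(rep(TRUE, ncol(X1)),
            apply(X2[, -seq_len(ncol(X1)), drop = FALSE], 2,
                  function(x) var(x) > 0))
  X2 <- X2[, keep, drop = FALSE]
  list(M0 = X0, M1 = X1, M2 = X2)
}

#' Fit the three nested case-control risk models
#'
#' Nested logistic models of case status: M0 with confounders and the four
#' randomized assignment indicators; M1 adding, for each selected SNP,
#' indicator variables for one and for two minor alleles; M2 adding the
#' SNP-indicator by assignment interaction products.  Fitted in-sample
#' probabilities are the risk scores for the AUC analysis.  Separated fits
#' fall back to a lightly ridge-penalized refit, flagged in the result.
#'
#' @param data phenotype data.frame (needs \code{case} and \code{arm_*}
#'   columns as in \code{\link{joint_test}})
#' @param genotypes dosage matrix with columns covering \code{snp_ids}
#' @param snp_ids SNPs whose main effects and interactions enter M1/M2
#' @param covariates confounder column names in \code{data}
#' @param components trial components whose assignments enter the models
#' @return list of class \code{nested_risk_models} with per-model elements
#'   \code{coef}, \code{fitted}, \code{loglik}, \code{ridge}, plus
#'   \code{auc} per model and the design matrices
#' @export
fit_nested_risk_models <- function(data, genotypes, snp_ids,
                                   covariates = NULL,
                                   components = COMPONENTS) {
  genotypes <- as.matrix(genotypes)
  y <- as.numeric(data$case)
  designs <- build_risk_designs(data, genotypes, snp_ids, covariates,
                                components)
  fits <- lapply(designs, fit_logistic_stable, y = y)
  out <- list(models = fits,
              auc = vapply(fits, function(f) auc(f$fitted, y), numeric(1)),
              designs = designs, y = y)
  class(out) <- "nested_risk_models"
  out
}

#' @export
print.nested_risk_models <- function(x, ...) {
  for (m in names(x$models)) {
    cat(sprintf("%s: AUC = %.3f, logLik = %.2f%s\n", m, x$auc[m],
                x$models[[m]]$loglik,
                if (x$models[[m]]$ridge) " [ridge-stabilized]" else ""))
  }
  invisible(x)
}

#' Matched-pair bootstrap test of an AUC difference between nested models
#'
#' Resamples matched case-control pairs with replacement, refits both models
#' on each replicate and recomputes the AUC difference; the significance
#' level is a two-sided normal-approximation test of zero difference using
#' the bootstrap standard error of the AUC difference, and each model's
#' confidence interval comes from bootstrap percentiles.  Pair-level
#' resampling respects the dependence induced by matching.
#'
#' @param data phenotype data.frame with a \code{pair_id} column
#' @param genotypes dosage matrix aligned with \code{data}
#' @param snp_ids,covariates,components model specification as in
#'   \code{\link{fit_nested_risk_models}}
#' @param model_pair two of \code{"M0"}, \code{"M1"}, \code{"M2"}; the second
#'   is compared against the first (reference)
#' @param n_boot bootstrap replicates (default 1000; below 100 the p-value is
#'   flagged unstable)
#' @param seed integer seed for the resampling
#' @return object of class \code{discrimination_result}: list with
#'   \code{model_labels}, observed \code{auc} for both models with percentile
#'   \code{ci95}, \code{delta_auc}, \code{bootstrap_p}, \code{p_unstable}
#'   flag, \code{n_boot}, \code{seed}
#' @export
bootstrap_auc_test <- function(data, genotypes, snp_ids, covariates = NULL,
                               components = COMPONENTS,
                               model_pair = c("M1", "M2"),
                               n_boot = 1000, seed = 1) {
  stopifnot(length(model_pair) == 2L,
            all(model_pair %in% c("M0", "M1", "M2")),
            "pair_id" %in% names(data))
  genotypes <- as.matrix(genotypes)
  fit0 <- fit_nested_risk_models(data, genotypes, snp_ids, covariates,
                                 components)
  auc_obs <- fit0$auc[model_pair]
  delta_obs <- auc_obs[2L] - auc_obs[1L]

  pair_ids <- unique(data$pair_id)
  rows_of_pair <- split(seq_len(nrow(data)), data$pair_id)
  boot <- matrix(NA_real_, n_boot, 2L, dimnames = list(NULL, model_pair))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    take <- sample(length(pair_ids), replace = TRUE)
    idx <- unlist(rows_of_pair[take], use.names = FALSE)
    fb <- fit_nested_risk_models(data[idx, , drop = FALSE],
                                 genotypes[idx, , drop = FALSE],
                                 snp_ids, covariates, components)
    boot[b, ] <- fb$auc[model_pair]
  }
  delta_boot <- boot[, 2L] - boot[, 1L]
  se <- sd(delta_boot)
  p <- if (se == 0) {
    if (abs(delta_obs) < .Machine$double.eps) 1 else NA_real_
  } else {
    2 * pnorm(-abs(delta_obs) / se)
  }
  out <- list(
    model_labels = model_pair,
    auc = auc_obs,
    ci95 = apply(boot, 2L, quantile, probs = c(0.025, 0.975)),
    delta_auc = unname(delta_obs),
    bootstrap_p = p,
    p_unstable = n_boot < 100,
    n_boot = n_boot,
    seed = seed
  )
  class(out) <- "discrimination_result"
  out
}

#' @export
print.discrimination_result <- function(x, ...) {
  for (i in 1:2) {
    cat(sprintf("%s: AUC %.3f (%.3f, %.3f)\n", x$model_labels[i], x$auc[i],
                x$ci95[1, i], x$ci95[2, i]))
  }
  cat(sprintf("delta AUC = %.4f, bootstrap p = %.4g (n_boot = %d)%s\n",
              x$delta_auc, x$bootstrap_p, x$n_boot,
              if (x$p_unstable) " [unstable: n_boot < 100]" else ""))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
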