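#' @rdname main_effect_score_test
#' @param component component label carried on the result
#' @param U,V score statistic and its variance
#' @param n_used number of subjects contributing
#' @param contributions named per-subject score contributions
#' @param degenerate logical degeneracy flag
#' @param failed logical fit-failure flag
#' @keywords internal
#' @noRd
component_score <- function(component, U, V, n_used, contributions,
                            degenerate = FALSE, failed = FALSE) {
  p <- if (degenerate || failed || V <= 0) NA_real_ else
    pchisq(U^2 / V, df = 1, lower.tail = FALSE)
  structure(
    list(component = component, U = U, V = V, n_used = n_used,
         per_subject_contributions = contributions,
         degenerate = degenerate, failed = failed, p = p),
    class = "component_score"
  )
}

#' @export
print.component_score <- function(x, ...) {
  cat(sprintf("Score test [%s]: U = %.4g, V = %.4g, p = %.4g (n = %d)%s\n",
              x$component, x$U, x$V, x$p, x$n_used,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fit the covariates-only null logistic model for the main-effect score test
#'
#' The null maximum-likelihood fit of case status on confounders (without any
#' genotype term) is shared by all SNPs of a scan; computing it once and
#' passing it to \code{\link{main_effect_score_test}} avoids refitting per SNP.
#'
#' @param case_status 0/1 vector
#' @param covariates numeric matrix of confounders (no intercept column;
#'   one is added), or \code{NULL} for an intercept-only null model
#' @return list with the design matrix, fitted probabilities, IRLS weights and
#'   the inverse weighted cross-product, plus a \code{failed} flag when the
#'   fit did not converge (for example under separation)
#' @export
null_model_fit <- function(case_status, covariates = NULL) {
  y <- as.numeric(case_status)
  stopifnot(all(y %in% c(0, 1)))
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL
  )
  failed <- is.null(fit) || !fit$converged ||
    any(fit$fitted.values < 1e-12) && all(y[fit$fitted.values < 1e-12] == 1)
  if (is.null(fit)) {
    return(list(X = X, phat = rep(mean(y), n), w = NULL, XtWX_inv = NULL,
                failed = TRUE))
  }
  phat <- fit$fitted.values
  w <- phat * (1 - phat)
  XtWX <- crossprod(X, X * w)
  XtWX_inv <- tryCatch(solve(XtWX), error = function(e) NULL)
  list(X = X, phat = phat, w = w, XtWX_inv = XtWX_inv,
       failed = failed || is.null(XtWX_inv))
}

#' Main-effect logistic score test for one SNP
#'
#' Score test for the minor-allele-count coefficient in a logistic regression
#' of case (1) versus control (0) status on genotype and confounders,
#' evaluated at the covariates-only null maximum-likelihood fit with expected
#' (Fisher) information.  The score and its variance are computed from the
#' efficient-score residual (genotype weighted-least-squares-projected off the
#' covariates at the null fit), so per-subject contributions are retained in a
#' form whose cross-products estimate covariances with other components.
#'
#' In a typical scan the confounders include the log risk score, prior hormone
#' use indicators, log body-mass index, the factors used for matching, and the
#' leading genotype principal components.
#'
#' @param case_status 0/1 case-control indicator
#' @param genotype minor-allele dosages 0/1/2 (\code{NA} dropped with the
#'   corresponding subjects)
#' @param covariates numeric matrix of confounders or \code{NULL}
#' @param subject_id ids naming the per-subject contributions (defaults to
#'   positions)
#' @param null_fit optional precomputed \code{\link{null_model_fit}} on
#'   exactly these subjects
#' @return a \code{component_score} with fields \code{U}, \code{V}, \code{p},
#'   \code{n_used}, \code{per_subject_contributions}, flags
#'   \code{degenerate} (monomorphic genotype) and \code{failed}
#' @export
main_effect_score_test <- function(case_status, genotype, covariates = NULL,
                                   subject_id = NULL, null_fit = NULL) {
  y <- as.numeric(case_status)
  g <- as.numeric(genotype)
  if (is.null(subject_id)) subject_id <- as.character(seq_along(y))
  ok <- !is.na(g) & !is.na(y)
  y <- y[ok]; g <- g[ok]; ids <- as.character(subject_id)[ok]
  n <- length(y)
  if (is.null(null_fit)) {
    null_fit <- null_model_fit(y, if (!is.null(covariates))
      as.matrix(covariates)[ok, , drop = FALSE])
  }
  if (null_fit$failed) {
    return(component_score("MAIN", NA_real_, NA_real_, n,
                           setNames(rep(NA_real_, n), ids), failed = TRUE))
  }
  if (var(g) == 0) {
    return(component_score("MAIN", 0, 0, n, setNames(rep(0, n), ids),
                           degenerate = TRUE))
  }
  X <- null_fit$X
  phat <- null_fit$phat
  w <- null_fit$w
  # efficient-score residual: genotype projected off covariates in W-metric
  gstar <- g - X %*% (null_fit$XtWX_inv %*% crossprod(X, w * g))
  gstar <- drop(gstar)
  contrib <- (y - phat) * gstar
  U <- sum(contrib)
  V <- sum(w * gstar^2)
  component_score("MAIN", U, V, n, setNames(contrib, ids),
                  degenerate = V <= .Machine$double.eps)
}

#' Case-only score test for genotype-by-intervention interaction
#'
#' Among cases belonging to one randomized trial component, tests whether the
#' active-versus-control assignment odds depend on genotype.  The model is
#' \code{logit P(active) = log(q / (1 - q)) + alpha + beta * genotype} with
#' the randomization fraction \code{q} entering as a known offset and
#' \code{alpha} free, so that an intervention main effect (which shifts the
#' active fraction among cases away from \code{q}) is absorbed by
#' \code{alpha} and does not bias the interaction score.  The score statistic
#' for \code{beta = 0} is evaluated with \code{alpha} profiled at its null
#' maximum-likelihood estimate, using expected information.
#'
#' Validity rests on the genotype-assignment independence guaranteed by
#' randomization.
#'
#' @param arm_assignment 0/1 active-versus-control assignment for the cases of
#'   the component (DMQ: only cases in the upper baseline fat quartile; CaD:
#'   only cases arising after CaD randomization)
#' @param genotype minor-allele dosages for the same cases
#' @param q randomization fraction assigned active for this component
#' @param component component label for the result
#' @param subject_id ids naming per-subject contributions
#' @return a \code{component_score}; degenerate when the genotype is
#'   monomorphic among these cases or all cases fall in one arm
#' @export
case_only_score_test <- function(arm_assignment, genotype, q,
                                 component = "CASE_ONLY", subject_id = NULL) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  a <- as.numeric(arm_assignment)
  g <- as.numeric(genotype)
  if (is.null(subject_id)) subject_id <- as.character(seq_along(a))
  ok <- !is.na(a) & !is.na(g)
  a <- a[ok]; g <- g[ok]; ids <- as.character(subject_id)[ok]
  stopifnot(all(a %in% c(0, 1)))
  n <- length(a)
  if (n == 0L || var(g) == 0 || mean(a) %in% c(0, 1)) {
    return(component_score(component, 0, 0, n, setNames(rep(0, n), ids),
                           degenerate = TRUE))
  }
  # alpha profiled: fitted P(active) is the observed active fraction (the
  # offset only relocates alpha-hat, not the fitted probability)
  phat <- mean(a)
  gc <- g - mean(g)
  contrib <- (a - phat) * gc
  U <- sum(contrib)
  V <- phat * (1 - phat) * sum(gc^2)
  component_score(component, U, V, n, setNames(contrib, ids))
}

#' Assemble the covariance matrix of the five component scores
#'
#' The diagonal holds each component's score variance.  The main-effect score
#' is asymptotically independent of every case-only score, and the E-alone and
#' E+P case-only scores are independent because the two hormone trials enrol
#' non-overlapping women; those entries are structural zeros.  The remaining
#' case-only pairs (components whose case sets overlap) get an empirical
#' sandwich cross term: the sum, over subjects contributing to both
#' components, of the product of their per-subject score contributions.
#'
#' @param scores named list of \code{component_score} objects, names from
#'   \code{c("MAIN", "E_ALONE", "E_PLUS_P", "DMQ", "CAD")} (any subset)
#' @param structural_zero keep the main-effect-versus-case-only entries at
#'   their theoretical zero (default); \code{FALSE} estimates them
#'   empirically from the per-subject contribution cross-products instead
#' @return symmetric covariance matrix with one row/column per supplied
#'   component, with attribute \code{"degenerate"} marking flagged components
#' @export
assemble_covariance <- function(scores, structural_zero = TRUE) {
  comps <- names(scores)
  if (is.null(comps) || !all(comps %in% ALL_COMPONENTS)) {
    stop("scores must be a named list with names among ",
         paste(ALL_COMPONENTS, collapse = ", "))
  }
  k <- length(scores)
  V <- matrix(0, k, k, dimnames = list(comps, comps))
  degenerate <- vapply(scores, function(s) isTRUE(s$degenerate) ||
                         isTRUE(s$failed), logical(1))
  for (s in scores) {
    if (is.null(names(s$per_subject_contributions)) && s$n_used > 0L) {
      stop("per-subject contributions must be named by subject id")
    }
  }
  diag(V) <- vapply(scores, function(s) if (isTRUE(s$failed)) NA_real_ else
    s$V, numeric(1))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        ci <- comps[i]; cj <- comps[j]
        if (degenerate[i] || degenerate[j]) next
        pair <- sort(c(ci, cj))
        structural <- (("MAIN" %in% pair) && structural_zero) ||
          identical(pair, c("E_ALONE", "E_PLUS_P"))
        if (structural) next
        a <- scores[[i]]$per_subject_contributions
        b <- scores[[j]]$per_subject_contributions
        shared <- intersect(names(a), names(b))
        if (length(shared)) {
          V[i, j] <- V[j, i] <- sum(a[shared] * b[shared])
        }
      }
    }
  }
  attr(V, "degenerate") <- degenerate
  V
}

#' Combined chi-square test from component scores and their covariance
#'
#' The combined statistic is the quadratic form \code{U' V^- U} with the
#' Moore-Penrose pseudo-inverse of the covariance restricted to
#' non-degenerate components; its degrees of freedom equal the rank of that
#' restriction (five when all components are informative and the covariance
#' has full rank).  Degenerate components reduce the degrees of freedom
#' rather than invalidating the SNP.
#'
#' @param U_vec named numeric vector of component scores
#' @param V_mat their covariance from \code{\link{assemble_covariance}}
#' @param degenerate logical vector flagging components to drop (defaults to
#'   the \code{"degenerate"} attribute of \code{V_mat})
#' @param snp_id optional SNP label
#' @return object of class \code{combined_test}: list with \code{snp_id},
#'   \code{U_vec}, \code{V_mat}, \code{chi2}, \code{df}, \code{p},
#'   \code{components_used}
#' @examples
#' u <- setNames(rep(1, 5), c("MAIN", "E_ALONE", "E_PLUS_P", "DMQ", "CAD"))
#' combined_chi2_test(u, diag(5))$chi2  # 5
#' @export
combined_chi2_test <- function(U_vec, V_mat, degenerate = NULL,
                               snp_id = NA_character_) {
  V_mat <- as.matrix(V_mat)
  if (is.null(degenerate)) {
    degenerate <- attr(V_mat, "degenerate") %||%
      rep(FALSE, length(U_vec))
  }
  if (max(abs(V_mat - t(V_mat))) > 1e-8 * max(1, max(abs(V_mat)))) {
    stop("V_mat must be symmetric")
  }
  use <- !degenerate & !is.na(U_vec) & !is.na(diag(V_mat)) & diag(V_mat) > 0
  comps <- names(U_vec) %||% as.character(seq_along(U_vec))
  if (!any(use)) {
    out <- list(snp_id = snp_id, U_vec = U_vec, V_mat = V_mat,
                chi2 = NA_real_, df = 0L, p = NA_real_,
                components_used = setNames(use, comps))
    class(out) <- "combined_test"
    return(out)
  }
  u <- U_vec[use]
  v <- V_mat[use, use, drop = FALSE]
  pv <- pinv_sym(v, tol = 1e-10)
  chi2 <- max(0, drop(t(u) %*% pv$inv %*% u))
  df <- pv$rank
  out <- list(snp_id = snp_id, U_vec = U_vec, V_mat = V_mat, chi2 = chi2,
              df = df, p = pchisq(chi2, df = df, lower.tail = FALSE),
              components_used = setNames(use, comps))
  class(out) <- "combined_test"
  out
}

#' @export
print.combined_test <- function(x, ...) {
  cat(sprintf("Combined test%s: chi2 = %.4g on %d df, p = %.4g\n",
              if (is.na(x$snp_id)) "" else paste0(" [", x$snp_id, "]"),
              x$chi2, x$df, x$p))
  cat("components used:",
      paste(names(x$components_used)[x$components_used], collapse = ", "),
      "\n")
  invisible(x)
}

#' Default randomization fractions for the four trial components
#'
#' Roughly half of participants were assigned active in the hormone and
#' calcium/vitamin D components and 40 percent in the dietary modification
#' component; all values are overridable wherever a \code{q} argument exists.
#'
#' @return named numeric vector over E_ALONE, E_PLUS_P, DMQ, CAD
#' @export
default_q <- function() {
  c(E_ALONE = 0.5, E_PLUS_P = 0.5, DMQ = 0.4, CAD = 0.5)
}

#' Genome scan with the combined main-effect plus interaction test
#'
#' Runs, for every SNP of a dosage matrix, the five-component combined test on
#' a matched case-control sample: the main-effect logistic score test
#' (adjusted for confounders and, optionally, leading genotype principal
#' components) and the four case-only interaction score tests, assembled with
#' structural-zero and sandwich covariances into the combined chi-square test.
#'
#' @param data phenotype data.frame; required columns: \code{subject_id},
#'   \code{case} (0/1), and for each component \code{C} in
#'   \code{E_ALONE, E_PLUS_P, DMQ, CAD} a logical \code{member_C} and a 0/1
#'   \code{arm_C} (NA outside the component)
#' @param genotypes subjects x SNPs dosage matrix; rownames must match
#'   \code{data$subject_id}
#' @param covariates character vector of confounder column names in
#'   \code{data}
#' @param q named randomization fractions (default \code{\link{default_q}})
#' @param n_pcs number of genotype principal components appended to the
#'   main-effect confounders (default 10; 0 disables; capped at the PCA rank)
#' @param structural_zero keep main-effect-versus-case-only covariance entries
#'   at their theoretical zero
#' @return data.frame with one row per SNP: \code{snp_id}, \code{U_main},
#'   \code{p_main}, \code{p_Ealone}, \code{p_EP}, \code{p_DMQ}, \code{p_CaD},
#'   \code{chi2}, \code{df}, \code{p_combined}
#' @export
joint_test <- function(data, genotypes, covariates = NULL,
                       q = default_q(), n_pcs = 10, structural_zero = TRUE) {
  genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes))) {
    if (nrow(genotypes) != nrow(data)) {
      stop("genotypes must have rownames matching data$subject_id, or one ",
           "row per phenotype row")
    }
    rownames(genotypes) <- as.character(data$subject_id)
  }
  miss <- setdiff(as.character(data$subject_id), rownames(genotypes))
  if (length(miss)) {
    stop("subjects missing from genotype matrix: ",
         paste(head(miss, 5), collapse = ", "))
  }
  genotypes <- genotypes[as.character(data$subject_id), , drop = FALSE]
  need <- c("subject_id", "case",
            paste0("member_", COMPONENTS), paste0("arm_", COMPONENTS))
  absent <- setdiff(need, names(data))
  if (length(absent)) stop("missing phenotype columns: ",
                           paste(absent, collapse = ", "))
  if (!is.null(covariates)) {
    bad <- setdiff(covariates, names(data))
    if (length(bad)) stop("covariate columns not found: ",
                          paste(bad, collapse = ", "))
  }

  covmat <- if (!is.null(covariates))
    as.matrix(data[, covariates, drop = FALSE]) else NULL
  if (n_pcs > 0 && ncol(genotypes) >= 2L) {
    k <- min(n_pcs, nrow(genotypes) - 1L, ncol(genotypes))
    pcs <- pca_genotypes(genotypes, k)$scores
    covmat <- cbind(covmat, pcs)
  }
  nf <- null_model_fit(data$case, covmat)
  ids <- as.character(data$subject_id)
  is_case <- data$case == 1

  snp_ids <- colnames(genotypes) %||% sprintf("snp_%04d", seq_len(ncol(genotypes)))
  res <- vector("list", ncol(genotypes))
  for (s in seq_along(snp_ids)) {
    g <- genotypes[, s]
    scores <- list(MAIN = main_effect_score_test(
      data$case, g, covmat, subject_id = ids, null_fit = nf))
    for (comp in COMPONENTS) {
      in_comp <- is_case & data[[paste0("member_", comp)]] %in% TRUE
      scores[[comp]] <- case_only_score_test(
        data[[paste0("arm_", comp)]][in_comp], g[in_comp], q[[comp]],
        component = comp, subject_id = ids[in_comp])
    }
    V <- assemble_covariance(scores, structural_zero = structural_zero)
    U <- vapply(scores, `[[`, numeric(1), "U")
    ct <- combined_chi2_test(U, V, snp_id = snp_ids[s])
    res[[s]] <- data.frame(
      snp_id = snp_ids[s],
      U_main = scores$MAIN$U, p_main = scores$MAIN$p,
      p_Ealone = scores$E_ALONE$p, p_EP = scores$E_PLUS_P$p,
      p_DMQ = scores$DMQ$p, p_CaD = scores$CAD$p,
      chi2 = ct$chi2, df = ct$df, p_combined = ct$p,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}
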