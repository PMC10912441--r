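## Log-link estimating equations on pseudo-values with working independence
## and an identity working variance, solved by Fisher scoring; inference by
## the Eicker-Huber-White sandwich with clusters at the family level (the
## same child can appear as exposed and as control across sets, and siblings
## share a family, so model-based variances would be too small).

#' Fit a log-link GEE to pseudo-value rows
#'
#' Solves `sum_i x_i mu_i (y_i - mu_i) = 0` with `mu = exp(X beta)`, where
#' the design holds one intercept per evaluation time (`tau_id`), the
#' exposure indicator, and any adjustment covariates.  `exp(beta_exposed)`
#' is the relative risk of the cause-1 event.  Non-convergence is flagged,
#' not raised, mirroring how such models are reported (a dash in a results
#' table); a rank-deficient design is an error.
#'
#' @param pseudo_rows a [pseudo_values()] table.
#' @param covariates character vector of adjustment column names (factors
#'   handled via `model.matrix`).
#' @param cluster column holding the cluster id (default `"family_id"`).
#' @param exposure column holding the exposure indicator (default
#'   `"exposed"`); `NULL` fits an intercept-only model (per-time intercepts
#'   and covariates only).
#' @param tol relative score tolerance (default 1e-8).
#' @param max_iter Fisher-scoring iteration cap (default 100).
#' @return object of class `model_fit`: `beta`, `se` (sandwich), `vcov`,
#'   `converged`, `n_obs`, `n_subjects`, `n_clusters`, `tau_grid`,
#'   `exposure_term`.
#' @export
fit_gee_log <- function(pseudo_rows, covariates = character(),
                        cluster = "family_id", exposure = "exposed",
                        tol = 1e-8, max_iter = 100L) {
  x <- data.table::as.data.table(pseudo_rows)
  need <- c("pseudo", "tau_id", exposure, cluster, covariates)
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  cc <- complete.cases(x[, need, with = FALSE])
  x <- x[cc, ]
  if (!nrow(x)) stopf("no complete-case rows")

  df <- data.frame(row.names = seq_len(nrow(x)))
  if (!is.null(exposure)) df$exposed <- as.numeric(x[[exposure]])
  for (v in covariates) df[[v]] <- x[[v]]
  fml <- stats::as.formula(paste(
    c("~ 1", if (!is.null(exposure)) "exposed", covariates), collapse = " + "))
  Xc <- model.matrix(fml, df)[, -1, drop = FALSE]
  ## one intercept per evaluation time
  tau_f <- factor(x$tau_id)
  Xt <- matrix(0, nrow(x), nlevels(tau_f),
               dimnames = list(NULL, paste0(".tau", levels(tau_f))))
  Xt[cbind(seq_len(nrow(x)), as.integer(tau_f))] <- 1
  ## standardise continuous columns for a well-conditioned scoring step;
  ## coefficients and covariance are transformed back afterwards
  ctr <- rep(0, ncol(Xc)); scl <- rep(1, ncol(Xc))
  for (j in seq_len(ncol(Xc))) {
    v <- Xc[, j]
    if (length(unique(v)) > 2) {
      ctr[j] <- mean(v)
      s <- stats::sd(v)
      if (s > 0) scl[j] <- s
      Xc[, j] <- (v - ctr[j]) / scl[j]
    }
  }
  X <- cbind(Xt, Xc)
  y <- x$pseudo
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("design matrix is rank deficient (collinear covariates): rank %d < %d columns",
          qrX$rank, ncol(X))

  ## start at per-tau intercepts = log of (clipped) mean pseudo-value
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  tmeans <- tapply(y, tau_f, mean)
  beta[seq_along(tmeans)] <- log(pmax(tmeans, 1e-8))

  eta <- drop(X %*% beta)
  mu <- exp(pmin(eta, 30))
  obj <- sum((y - mu)^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu * mu
    U <- drop(crossprod(X, mu * (y - mu)))
    A <- crossprod(X * sqrt(w))
    step <- tryCatch(solve(A, U), error = function(e) NULL)
    if (is.null(step)) break
    ## step halving on the least-squares objective
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      mu_new <- exp(pmin(drop(X %*% beta_new), 30))
      obj_new <- sum((y - mu_new)^2)
      if (is.finite(obj_new) && (obj_new <= obj * (1 + 1e-12) || lam < 1e-4))
        break
      lam <- lam / 2
    }
    rel <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    beta <- beta_new; mu <- mu_new; obj <- obj_new
    if (rel < tol) { converged <- TRUE; break }
  }

  ## family-clustered sandwich covariance
  w <- mu * mu
  A <- crossprod(X * sqrt(w))
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) {
    vc <- matrix(NA_real_, ncol(X), ncol(X))
    converged <- FALSE
  } else {
    score_i <- X * (mu * (y - mu))
    S <- rowsum(score_i, group = as.character(x[[cluster]]))
    vc <- Ai %*% crossprod(S) %*% Ai
  }
  dimnames(vc) <- list(colnames(X), colnames(X))

  ## map back to the natural covariate scale: beta_nat = J beta_std
  nt <- ncol(Xt); p <- ncol(X)
  J <- diag(p)
  if (ncol(Xc)) {
    for (j in seq_len(ncol(Xc))) {
      col <- nt + j
      J[col, col] <- 1 / scl[j]
      if (ctr[j] != 0) J[seq_len(nt), col] <- -ctr[j] / scl[j]
    }
  }
  beta <- drop(J %*% beta)
  names(beta) <- colnames(X)
  if (!anyNA(vc)) vc <- J %*% vc %*% t(J)
  dimnames(vc) <- list(colnames(X), colnames(X))

  structure(list(
    beta = beta, vcov = vc, se = sqrt(pmax(diag(vc), 0)),
    converged = converged, iterations = it,
    n_obs = nrow(x), n_subjects = length(unique(x$child_id %||% seq_len(nrow(x)))),
    n_clusters = length(unique(x[[cluster]])),
    tau_grid = attr(pseudo_rows, "tau_grid"),
    exposure_term = if (is.null(exposure)) NA_character_ else "exposed"),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s, %d obs, %d clusters\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_obs, x$n_clusters))
  b <- x$beta[x$exposure_term]
  cat(sprintf("  RR(exposed) = %.4f (log %.4f, robust se %.4f)\n",
              exp(b), b, x$se[x$exposure_term]))
  invisible(x)
}

#' Plain and Bonferroni-corrected confidence intervals on the RR scale
#'
#' The corrected interval widens the normal quantile from `1 - alpha/2` to
#' `1 - alpha/(2 m)` for `m` simultaneous tests, so it always contains the
#' uncorrected one.
#'
#' @param beta_hat log-scale point estimate.
#' @param se log-scale standard error (`>= 0`).
#' @param m number of simultaneous tests (`>= 1`).
#' @param alpha nominal level (default 0.05).
#' @return list with `rr`, `ci95 = c(lo, hi)`, `ci_corrected = c(lo, hi)`,
#'   and the two quantiles `z` and `z_corrected`.
#' @export
bonferroni_ci <- function(beta_hat, se, m, alpha = 0.05) {
  if (m < 1) stopf("m must be >= 1")
  if (se < 0) stopf("se must be non-negative")
  z <- qnorm(1 - alpha / 2)
  zc <- qnorm(1 - alpha / (2 * m))
  list(rr = exp(beta_hat),
       ci95 = exp(beta_hat + c(-1, 1) * z * se),
       ci_corrected = exp(beta_hat + c(-1, 1) * zc * se),
       z = z, z_corrected = zc)
}

#' Recover the log-scale standard error from a printed 95% interval
#'
#' Assumes the interval is symmetric on the log scale (normal-theory Wald),
#' i.e. `se = (ln hi - ln lo) / (2 z_0.975)`.
#'
#' @param rr,lo95,hi95 point estimate and 95% bounds, `0 < lo95 <= rr <= hi95`.
#' @return the log-scale standard error.
#' @export
reconstruct_se_from_ci <- function(rr, lo95, hi95) {
  if (any(!(lo95 > 0 & lo95 <= rr & rr <= hi95)))
    stopf("need 0 < lo95 <= rr <= hi95")
  (log(hi95) - log(lo95)) / (2 * qnorm(0.975))
}

#' Reconstruct a Bonferroni-corrected interval from printed results
#'
#' Published tables often print the point estimate with its 95% interval and
#' a multiplicity-corrected interval; given the first two this reproduces
#' the third under the log-symmetric Wald assumption.
#'
#' @param rr,lo95,hi95 printed point estimate and 95% bounds (vectorised).
#' @param m number of simultaneous tests (default 33).
#' @return matrix with columns `lower`, `upper` of the corrected interval.
#' @export
corrected_ci_from_printed <- function(rr, lo95, hi95, m = 33) {
  se <- mapply(reconstruct_se_from_ci, rr, lo95, hi95)
  zc <- qnorm(1 - 0.05 / (2 * m))
  cbind(lower = exp(log(rr) - zc * se), upper = exp(log(rr) + zc * se))
}
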