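#' Variational Bayesian factor analysis with ARD priors ("reduced" residuals)
#'
#' Removes the contribution of known sample covariates and of up to
#' \code{n_hidden} hidden global factors from an expression matrix,
#' returning the residual profile used for association mapping.  The
#' model for sample j is y_j = W s_j + e, with the hidden part of s_j a
#' standard-normal latent vector, the known part fixed at the covariate
#' values, per-gene noise precisions, and an automatic relevance
#' determination (ARD) Gamma prior on the per-factor weight precisions
#' that switches superfluous factors off.  Inference is mean-field
#' variational Bayes (a generalization of EM); the monitored objective is
#' the expected data log-likelihood, and the fit stops when it improves
#' by less than \code{tol} relatively, or at \code{max_iter} iterations
#' (non-convergence returns the best iterate with a flag).
#'
#' The fit is intended to be run separately for each population.  When
#' the sample metadata carries a \code{gender} column it is included as a
#' known covariate by default; a pooled run across populations can pass
#' population indicator columns through \code{known_covariates}.
#'
#' @param expr \code{expression_matrix} (one column per individual).
#' @param n_hidden Number of hidden factors (default 32).
#' @param known_covariates Optional sample x covariate numeric matrix.
#' @param include_gender Add a gender indicator from the sample metadata
#'   when available (default TRUE).
#' @param ard_prior Length-2 vector (shape, rate) of the Gamma prior on
#'   weight precisions; default \code{c(21800, 0.022)}.  The shape is the
#'   value appropriate for a 21,800-probe panel.
#' @param scale_prior Scale the prior shape by (number of probes)/21800 so
#'   the regularization strength per probe is preserved at other panel
#'   sizes (default TRUE).
#' @param tol Relative objective tolerance (default 1e-6).
#' @param max_iter Maximum iterations (default 1000).
#' @return Object of class \code{factor_model}: list with
#'   \code{residuals} (an \code{expression_matrix} at stage
#'   \code{"reduced"}), \code{loadings} (probe x factor posterior means),
#'   \code{scores} (factor x sample), \code{alpha} (posterior mean weight
#'   precisions), \code{tau} (per-probe noise precisions),
#'   \code{n_effective}, \code{converged}, \code{n_iter},
#'   \code{objective}.
#' @export
fit_factor_residuals <- function(expr, n_hidden = 32,
                                 known_covariates = NULL,
                                 include_gender = TRUE,
                                 ard_prior = c(21800, 0.022),
                                 scale_prior = TRUE,
                                 tol = 1e-6, max_iter = 1000) {
  if (n_hidden < 0) stop("n_hidden must be >= 0")
  Y <- expr$values
  G <- nrow(Y); N <- ncol(Y)
  mu <- rowMeans(Y)
  Y <- Y - mu

  # known covariate scores (centred), rows = covariates
  C <- NULL
  if (include_gender && !is.null(expr$sample_meta$gender) &&
      length(unique(expr$sample_meta$gender)) > 1) {
    C <- cbind(gender = as.numeric(factor(expr$sample_meta$gender)) - 1)
  }
  if (!is.null(known_covariates)) {
    kc <- as.matrix(known_covariates)
    if (nrow(kc) != N) stop("known_covariates rows must match samples")
    C <- cbind(C, kc)
  }
  Kk <- if (is.null(C)) 0L else ncol(C)
  if (Kk > 0) {
    C <- scale(C, center = TRUE, scale = FALSE)
    Ck <- t(C)                                  # Kk x N
  } else Ck <- matrix(0, 0, N)

  Kh <- as.integer(n_hidden)
  K <- Kh + Kk
  if (K == 0) {
    res <- expression_matrix(Y, stage = expr$stage,
                             sample_meta = expr$sample_meta)
    res <- .advance_stage(res, "reduced")
    return(structure(list(residuals = res,
                          loadings = matrix(0, G, 0), scores = matrix(0, 0, N),
                          alpha = numeric(0), tau = 1 / pmax(rowMeans(Y^2), 1e-12),
                          n_effective = 0L, converged = TRUE, n_iter = 0L,
                          objective = numeric(0)),
                     class = "factor_model"))
  }

  a0 <- ard_prior[1]; b0 <- ard_prior[2]
  if (scale_prior) a0 <- a0 * G / 21800
  c0 <- 1e-3; d0 <- 1e-3                        # vague noise prior

  # initialization from a truncated SVD
  if (Kh > 0) {
    sv <- svd(Y, nu = Kh, nv = Kh)
    dh <- sv$d[seq_len(Kh)]
    Mw_h <- sv$u %*% diag(dh / sqrt(N), Kh)
    Ms_h <- sqrt(N) * t(sv$v)                    # Kh x N, unit-scale scores
    Sigma_h <- diag(1e-4, Kh)
  } else {
    Mw_h <- matrix(0, G, 0); Ms_h <- matrix(0, 0, N); Sigma_h <- matrix(0, 0, 0)
  }
  Mw <- cbind(Mw_h, matrix(0, G, Kk))
  alpha <- rep(1, K)
  tau <- 1 / pmax(rowMeans(Y^2), 1e-12)

  hid <- seq_len(Kh)
  kno <- if (Kk > 0) Kh + seq_len(Kk) else integer(0)
  Y2 <- rowSums(Y^2)
  obj_trace <- numeric(0)
  obj_old <- -Inf
  converged <- FALSE
  iter <- 0L

  ES <- rbind(Ms_h, Ck)                          # K x N
  repeat {
    iter <- iter + 1L

    # --- weight update, all genes at once ---
    # The per-gene weight posterior is N(m_g, V_g) with
    # V_g = (diag(alpha) + tau_g * ESS)^-1.  Whitening by
    # B = diag(alpha^-1/2) makes every V_g share the eigenbasis of
    # M = B ESS B = Q L Q', so V_g = P diag(1/(1+tau_g L)) P' with
    # P = B Q, and all gene-level quantities vectorize over genes.
    ESS <- tcrossprod(ES)                        # K x K
    if (Kh > 0)
      ESS[hid, hid] <- ESS[hid, hid] + N * Sigma_h
    SY <- ES %*% t(Y)                            # K x G
    B <- 1 / sqrt(alpha)
    eg <- eigen(B * t(B * ESS), symmetric = TRUE)
    L <- pmax(eg$values, 0)
    P <- B * eg$vectors                          # K x K
    U <- crossprod(P, SY)                        # K x G
    Dm <- 1 / (1 + outer(L, tau))                # K x G
    Mw <- t(P %*% (U * Dm)) * tau                # G x K
    trV <- (P * P) %*% Dm                        # K x G, diag(V_g) columns

    # --- ARD precision update ---
    w2 <- colSums(Mw^2) + rowSums(trV)
    alpha <- (a0 + G / 2) / (b0 + w2 / 2)

    # --- noise precision + expected residual sum of squares ---
    # E||y_g - S'w_g||^2 = |y|^2 - 2 m'SY + m'ESS m + tr(V ESS)
    DU <- Dm * U
    mSY <- tau * colSums(Dm * U^2)
    Z <- DU * rep(tau, each = K)                 # z_g = Q'B^-1 m_g
    mESSm <- colSums(L * Z^2)
    trVE <- colSums(L * Dm)
    Eres2 <- pmax(Y2 - 2 * mSY + mESSm + trVE, 1e-12)
    tau <- (c0 + N / 2) / (d0 + Eres2 / 2)

    # --- factor score update (hidden block) ---
    if (Kh > 0) {
      s_k <- as.vector(Dm %*% tau)               # sum_g tau_g / (1+tau_g L_k)
      A <- crossprod(Mw * sqrt(tau)) + P %*% (s_k * t(P))
      Sigma_h <- chol2inv(chol(diag(1, Kh) + A[hid, hid, drop = FALSE]))
      rhs <- crossprod(Mw[, hid, drop = FALSE] * tau, Y)   # Kh x N
      if (Kk > 0)
        rhs <- rhs - A[hid, kno, drop = FALSE] %*% Ck
      Ms_h <- Sigma_h %*% rhs
      ES <- rbind(Ms_h, Ck)
    }

    obj <- sum(N / 2 * log(tau) - tau / 2 * Eres2)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_old) &&
        abs(obj - obj_old) < tol * (abs(obj_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    obj_old <- obj
  }
  if (!converged)
    message("factor model did not converge in ", max_iter,
            " iterations; returning best iterate")

  recon <- Mw %*% ES
  res_vals <- Y - recon
  dimnames(res_vals) <- dimnames(expr$values)
  res <- expression_matrix(res_vals, stage = expr$stage,
                           sample_meta = expr$sample_meta)
  res <- .advance_stage(res, "reduced")

  comp_var <- colSums(Mw^2) / G
  n_eff <- sum(comp_var[hid] > 1e-6 * mean(Y2 / N + 1e-12))
  fac_names <- c(sprintf("factor%02d", hid),
                 if (Kk > 0) colnames(C) else NULL)
  dimnames(Mw) <- list(rownames(Y), fac_names)
  dimnames(ES) <- list(fac_names, colnames(Y))
  structure(list(residuals = res, loadings = Mw, scores = ES,
                 alpha = stats::setNames(alpha, fac_names),
                 tau = tau, n_effective = n_eff,
                 converged = converged, n_iter = iter,
                 objective = obj_trace),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("ARD factor model: ", nrow(x$loadings), " probes, ",
      ncol(x$scores), " samples, ", length(x$alpha), " factors (",
      x$n_effective, " effective)\n", sep = "")
  cat("  iterations: ", x$n_iter,
      if (x$converged) " (converged)" else " (max iterations)", "\n", sep = "")
  invisible(x)
}
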