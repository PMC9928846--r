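#' Genetic correlation from (co)variance components
#'
#' \eqn{r_G = cov_{A12} / \sqrt{\sigma_{A1}^2 \sigma_{A2}^2}}. The value is
#' not clamped; estimates outside `[-1, 1]` are returned as-is with a
#' warning.
#'
#' @param cov_g genetic covariance between the traits.
#' @param var_g1,var_g2 additive genetic variances (must be positive).
#' @return The genetic correlation.
#' @export
genetic_correlation <- function(cov_g, var_g1, var_g2) {
  if (!is.finite(var_g1) || !is.finite(var_g2) || var_g1 <= 0 ||
      var_g2 <= 0)
    stop("genetic variances must be positive")
  r <- cov_g / sqrt(var_g1 * var_g2)
  if (is.finite(r) && abs(r) > 1)
    warning("genetic correlation outside [-1, 1]: ", format(r))
  r
}

#' Phenotypic correlation from (co)variance components
#'
#' \eqn{r_P = (cov_{A12} + cov_{E12}) / \sqrt{\sigma_{P1}^2 \sigma_{P2}^2}}
#' with \eqn{\sigma_{Pt}^2 = \sigma_{At}^2 + \sigma_{Et}^2}.
#'
#' @param cov_g,cov_e genetic and residual covariances.
#' @param var_g1,var_e1,var_g2,var_e2 genetic and residual variances per
#'   trait.
#' @return The phenotypic correlation.
#' @export
phenotypic_correlation <- function(cov_g, cov_e, var_g1, var_e1, var_g2,
                                   var_e2) {
  p1 <- var_g1 + var_e1
  p2 <- var_g2 + var_e2
  if (!is.finite(p1) || !is.finite(p2) || p1 <= 0 || p2 <= 0)
    stop("phenotypic variances must be positive")
  (cov_g + cov_e) / sqrt(p1 * p2)
}

# Bend a symmetric matrix to positive definiteness by flooring eigenvalues.
bend_psd <- function(S, floor_val) {
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  if (all(eg$values >= floor_val)) return(S)
  vals <- pmax(eg$values, floor_val)
  out <- eg$vectors %*% (vals * t(eg$vectors))
  (out + t(out)) / 2
}

theta_to_mats <- function(th) {
  list(Sg = matrix(th[c(1, 2, 2, 3)], 2, 2),
       Se = matrix(th[c(4, 5, 5, 6)], 2, 2))
}
mats_to_theta <- function(Sg, Se) {
  c(Sg[1, 1], Sg[1, 2], Sg[2, 2], Se[1, 1], Se[1, 2], Se[2, 2])
}

# Per-iteration quantities for the bivariate model, eigen fast path.
# V = Sg (x) G + Se (x) I becomes 2x2 blocks d_k Sg + Se after rotating
# each trait by the eigenvectors of G.
biv_quant_eigen <- function(y1, y2, X1, X2, dvals, th) {
  p <- theta_to_mats(th); Sg <- p$Sg; Se <- p$Se
  m11 <- dvals * Sg[1, 1] + Se[1, 1]
  m12 <- dvals * Sg[1, 2] + Se[1, 2]
  m22 <- dvals * Sg[2, 2] + Se[2, 2]
  det <- m11 * m22 - m12^2
  if (any(m11 <= 0) || any(det <= 0)) return(NULL)
  i11 <- m22 / det; i12 <- -m12 / det; i22 <- m11 / det
  p1 <- ncol(X1); p2 <- ncol(X2)
  C <- rbind(cbind(crossprod(X1, X1 * i11), crossprod(X1, X2 * i12)),
             cbind(crossprod(X2, X1 * i12), crossprod(X2, X2 * i22)))
  Rc <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(Rc)) return(NULL)
  Cinv <- chol2inv(Rc)
  b <- c(crossprod(X1, i11 * y1 + i12 * y2),
         crossprod(X2, i12 * y1 + i22 * y2))
  beta <- drop(Cinv %*% b)
  r1 <- y1 - drop(X1 %*% beta[seq_len(p1)])
  r2 <- y2 - drop(X2 %*% beta[p1 + seq_len(p2)])
  Py1 <- i11 * r1 + i12 * r2
  Py2 <- i12 * r1 + i22 * r2
  yPy <- sum(r1 * Py1 + r2 * Py2)
  ll <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(Rc))) + yPy)

  applyP <- function(w1, w2) {
    bw <- drop(Cinv %*% c(crossprod(X1, i11 * w1 + i12 * w2),
                          crossprod(X2, i12 * w1 + i22 * w2)))
    rw1 <- w1 - drop(X1 %*% bw[seq_len(p1)])
    rw2 <- w2 - drop(X2 %*% bw[p1 + seq_len(p2)])
    list(i11 * rw1 + i12 * rw2, i12 * rw1 + i22 * rw2)
  }
  # w_i = V_i P y for theta order (g11, g12, g22, e11, e12, e22)
  ws <- list(list(dvals * Py1, 0 * Py2),
             list(dvals * Py2, dvals * Py1),
             list(0 * Py1, dvals * Py2),
             list(Py1, 0 * Py2),
             list(Py2, Py1),
             list(0 * Py1, Py2))
  Pws <- lapply(ws, function(w) applyP(w[[1]], w[[2]]))
  AI <- matrix(0, 6, 6)
  for (i in 1:6) for (j in i:6) {
    AI[i, j] <- 0.5 * (sum(ws[[i]][[1]] * Pws[[j]][[1]]) +
                       sum(ws[[i]][[2]] * Pws[[j]][[2]]))
    AI[j, i] <- AI[i, j]
  }
  yPVPy <- vapply(ws, function(w)
    sum(w[[1]] * Py1 + w[[2]] * Py2), numeric(1))

  # tr(P V_i) = tr(V^-1 V_i) - tr(Cinv . X'V^-1 V_i V^-1 X)
  trPV <- numeric(6)
  k <- 0
  for (comp in 1:2) {
    cc <- if (comp == 1) dvals else rep(1, length(dvals))
    tr1 <- c(sum(cc * i11), 2 * sum(cc * i12), sum(cc * i22))
    Ns <- list(c11 = cc * i11^2, c12a = cc * i11 * i12, c22a = cc * i12^2,
               d11 = 2 * cc * i11 * i12, d12 = cc * (i11 * i22 + i12^2),
               d22 = 2 * cc * i12 * i22,
               e11 = cc * i12^2, e12 = cc * i12 * i22, e22 = cc * i22^2)
    Smat <- function(n11, n12, n22) {
      rbind(cbind(crossprod(X1, X1 * n11), crossprod(X1, X2 * n12)),
            cbind(crossprod(X2, X1 * n12), crossprod(X2, X2 * n22)))
    }
    S_list <- list(Smat(Ns$c11, Ns$c12a, Ns$c22a),
                   Smat(Ns$d11, Ns$d12, Ns$d22),
                   Smat(Ns$e11, Ns$e12, Ns$e22))
    for (b_ix in 1:3) {
      k <- k + 1
      trPV[k] <- tr1[b_ix] - sum(Cinv * S_list[[b_ix]])
    }
  }
  score <- -0.5 * (trPV - yPVPy)

  # EM ingredients: quadratic-form and trace 2x2 matrices per component
  Qg <- matrix(c(sum(dvals * Py1^2), sum(dvals * Py1 * Py2),
                 sum(dvals * Py1 * Py2), sum(dvals * Py2^2)), 2, 2)
  Qe <- matrix(c(sum(Py1^2), sum(Py1 * Py2),
                 sum(Py1 * Py2), sum(Py2^2)), 2, 2)
  Tg <- matrix(c(trPV[1], trPV[2] / 2, trPV[2] / 2, trPV[3]), 2, 2)
  Te <- matrix(c(trPV[4], trPV[5] / 2, trPV[5] / 2, trPV[6]), 2, 2)
  list(ll = ll, beta = beta, score = score, AI = AI,
       Qg = Qg, Qe = Qe, Tg = Tg, Te = Te)
}

# Literal dense-algebra version of biv_quant_eigen (verification path).
biv_quant_dense <- function(y1, y2, X1, X2, G, th) {
  p <- theta_to_mats(th)
  n <- length(y1)
  In <- diag(n)
  V <- kronecker(p$Sg, G) + kronecker(p$Se, In)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Vi <- chol2inv(R)
  X <- rbind(cbind(X1, matrix(0, n, ncol(X2))),
             cbind(matrix(0, n, ncol(X1)), X2))
  y <- c(y1, y2)
  C <- crossprod(X, Vi %*% X)
  Rc <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(Rc)) return(NULL)
  Cinv <- chol2inv(Rc)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% Cinv %*% t(ViX)
  Py <- drop(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(Rc))) +
                sum(y * Py))
  E <- function(i, j) {
    B <- matrix(0, 2, 2); B[i, j] <- 1; B
  }
  Bs <- list(E(1, 1), E(1, 2) + E(2, 1), E(2, 2))
  Vd <- c(lapply(Bs, function(B) kronecker(B, G)),
          lapply(Bs, function(B) kronecker(B, In)))
  score <- numeric(6); AI <- matrix(0, 6, 6)
  ws <- lapply(Vd, function(Vi_d) drop(Vi_d %*% Py))
  for (i in 1:6) {
    score[i] <- -0.5 * (sum(P * Vd[[i]]) - sum(Py * ws[[i]]))
    for (j in i:6) {
      AI[i, j] <- 0.5 * sum(ws[[i]] * drop(P %*% ws[[j]]))
      AI[j, i] <- AI[i, j]
    }
  }
  beta <- drop(Cinv %*% crossprod(X, Vi %*% y))
  i1 <- seq_len(n); i2 <- n + i1
  Py1 <- Py[i1]; Py2 <- Py[i2]
  GPy1 <- drop(G %*% Py1); GPy2 <- drop(G %*% Py2)
  Qg <- matrix(c(sum(Py1 * GPy1), sum(Py1 * GPy2),
                 sum(Py1 * GPy2), sum(Py2 * GPy2)), 2, 2)
  Qe <- matrix(c(sum(Py1^2), sum(Py1 * Py2),
                 sum(Py1 * Py2), sum(Py2^2)), 2, 2)
  Tg <- matrix(c(sum(P[i1, i1] * G), sum(P[i1, i2] * G),
                 sum(P[i1, i2] * G), sum(P[i2, i2] * G)), 2, 2)
  Te <- matrix(c(sum(diag(P)[i1]), sum(diag(P[i1, i2])),
                 sum(diag(P[i1, i2])), sum(diag(P)[i2])), 2, 2)
  list(ll = ll, beta = beta, score = score, AI = AI,
       Qg = Qg, Qe = Qe, Tg = Tg, Te = Te)
}

#' Fit a bivariate GREML model
#'
#' Maximizes the restricted likelihood of the two-trait animal model with
#' (co)variance structure \eqn{V = \Sigma_g \otimes G + \Sigma_e \otimes I}
#' over the six parameters of the 2x2 genetic and residual (co)variance
#' matrices, by average-information REML after an EM warm-up. At every
#' iteration \eqn{\Sigma_g} and \eqn{\Sigma_e} are bent to positive
#' definiteness (eigenvalues floored), so the model stays valid while
#' \eqn{|r_G|} may approach 1. Genetic and phenotypic correlations and
#' their standard errors come from the inverse AI matrix by the delta
#' method; the sampling covariance is ordered
#' (sg1^2, sg12, sg2^2, se1^2, se12, se2^2).
#'
#' Both traits must be observed on every analyzed individual
#' (complete-case analysis); one record per animal, so the incidence
#' matrix of the general animal model is the identity here.
#'
#' @param y1,y2 numeric response vectors for the two traits.
#' @param X1,X2 fixed-effects design matrices per trait; default
#'   intercepts.
#' @param K a [grm()] object or relationship matrix aligned with the
#'   responses.
#' @param control a [greml_control()] list.
#' @param method `"eigen"` (fast path) or `"dense"` (verification).
#' @return An object of class `"greml"` with `kind = "bivariate"`; see
#'   [greml()].
#' @export
fit_greml_bivariate <- function(y1, y2, X1 = NULL, X2 = NULL, K,
                                control = greml_control(),
                                method = c("eigen", "dense")) {
  method <- match.arg(method)
  G <- as_grm_matrix(K)
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  n <- length(y1)
  if (length(y2) != n) stop("y1 and y2 lengths differ")
  if (any(is.na(y1)) || any(is.na(y2)))
    stop("bivariate fit is complete-case: subset to individuals with ",
         "both traits observed")
  if (nrow(G) != n) stop("GRM dimension does not match the responses")
  if (n < 20) stop("need at least 20 individuals")
  if (is.null(X1)) X1 <- matrix(1, n, 1)
  if (is.null(X2)) X2 <- matrix(1, n, 1)
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)

  r1 <- stats::lm.fit(X1, y1)$residuals
  r2 <- stats::lm.fit(X2, y2)$residuals
  vp1 <- stats::var(r1); vp2 <- stats::var(r2); cv <- stats::cov(r1, r2)
  floor_val <- control$variance_floor_fraction * sqrt(vp1 * vp2)
  Sg <- 0.5 * matrix(c(vp1, cv, cv, vp2), 2, 2)
  Se <- Sg

  if (method == "eigen") {
    eg <- eigen(G, symmetric = TRUE)
    y1s <- drop(crossprod(eg$vectors, y1))
    y2s <- drop(crossprod(eg$vectors, y2))
    X1s <- crossprod(eg$vectors, X1)
    X2s <- crossprod(eg$vectors, X2)
    qfun <- function(th) biv_quant_eigen(y1s, y2s, X1s, X2s, eg$values, th)
  } else {
    qfun <- function(th) biv_quant_dense(y1, y2, X1, X2, G, th)
  }

  bend_theta <- function(th) {
    p <- theta_to_mats(th)
    mats_to_theta(bend_psd(p$Sg, floor_val), bend_psd(p$Se, floor_val))
  }
  # bending also regularizes singular starts (e.g. perfectly correlated
  # traits, where the residual covariance starts rank-deficient)
  th <- bend_theta(mats_to_theta(Sg, Se))
  q <- qfun(th)
  if (is.null(q)) stop("likelihood undefined at starting values")
  em_step <- function(th, q) {
    p <- theta_to_mats(th)
    Sg_new <- p$Sg + p$Sg %*% (q$Qg - q$Tg) %*% p$Sg / n
    Se_new <- p$Se + p$Se %*% (q$Qe - q$Te) %*% p$Se / n
    bend_theta(mats_to_theta(Sg_new, Se_new))
  }
  converged <- FALSE
  it <- 0
  for (it in seq_len(control$max_iterations)) {
    ll_old <- q$ll
    if (it <= control$em_warmup_iterations) {
      th_new <- em_step(th, q)
      q_new <- qfun(th_new)
    } else {
      # a singular AI matrix (e.g. duplicated traits pinned at the
      # correlation boundary) falls back to the always-valid EM step
      delta <- tryCatch(drop(solve(q$AI, q$score)), error = function(e)
        NULL)
      if (is.null(delta)) {
        th_new <- em_step(th, q)
        q_new <- qfun(th_new)
        if (is.null(q_new))
          stop("likelihood became undefined during fitting")
        th <- th_new; q <- q_new
        if (abs(q$ll - ll_old) < control$loglik_tolerance && it > 1) {
          converged <- TRUE
          break
        }
        next
      }
      step <- 1
      repeat {
        th_new <- bend_theta(th + step * delta)
        q_new <- qfun(th_new)
        if (!is.null(q_new) && q_new$ll >= ll_old - 1e-10) break
        step <- step / 2
        if (step < 1e-8) {
          th_new <- em_step(th, q)
          q_new <- qfun(th_new)
          break
        }
      }
    }
    if (is.null(q_new)) stop("likelihood became undefined during fitting")
    th <- th_new
    q <- q_new
    if (control$verbose)
      cat(sprintf("iter %3d  logL %.6f  theta %s\n", it, q$ll,
                  paste(signif(th, 5), collapse = " ")))
    if (abs(q$ll - ll_old) < control$loglik_tolerance && it > 1) {
      converged <- TRUE
      break
    }
  }

  scov <- tryCatch(solve(q$AI), error = function(e)
    matrix(NA_real_, 6, 6))
  g11 <- th[1]; g12 <- th[2]; g22 <- th[3]
  e11 <- th[4]; e12 <- th[5]; e22 <- th[6]
  p1 <- g11 + e11; p2 <- g22 + e22
  rg <- g12 / sqrt(g11 * g22)
  rp <- phenotypic_correlation(g12, e12, g11, e11, g22, e22)
  grad_rg <- c(-rg / (2 * g11), 1 / sqrt(g11 * g22), -rg / (2 * g22),
               0, 0, 0)
  grad_rp <- c(-rp / (2 * p1), 1 / sqrt(p1 * p2), -rp / (2 * p2),
               -rp / (2 * p1), 1 / sqrt(p1 * p2), -rp / (2 * p2))
  dsub <- function(grad) sqrt(max(drop(t(grad) %*% scov %*% grad), 0))
  se_rg <- dsub(grad_rg)
  se_rp <- dsub(grad_rp)
  grad_h1 <- c(e11 / p1^2, 0, 0, -g11 / p1^2, 0, 0)
  grad_h2 <- c(0, 0, e22 / p2^2, 0, 0, -g22 / p2^2)
  components <- c("V(G)_1" = g11, "C(G)_12" = g12, "V(G)_2" = g22,
                  "V(e)_1" = e11, "C(e)_12" = e12, "V(e)_2" = e22,
                  h2_1 = g11 / p1, h2_2 = g22 / p2, rG = rg, rP = rp)
  se_all <- c("V(G)_1" = sqrt(max(scov[1, 1], 0)),
              "C(G)_12" = sqrt(max(scov[2, 2], 0)),
              "V(G)_2" = sqrt(max(scov[3, 3], 0)),
              "V(e)_1" = sqrt(max(scov[4, 4], 0)),
              "C(e)_12" = sqrt(max(scov[5, 5], 0)),
              "V(e)_2" = sqrt(max(scov[6, 6], 0)),
              h2_1 = dsub(grad_h1), h2_2 = dsub(grad_h2),
              rG = se_rg, rP = se_rp)
  fitted <- cbind(drop(X1 %*% q$beta[seq_len(ncol(X1))]),
                  drop(X2 %*% q$beta[ncol(X1) + seq_len(ncol(X2))]))
  structure(list(kind = "bivariate", components = components,
                 se = se_all, sampling_covariance = scov,
                 theta = th, beta = q$beta, fitted = fitted,
                 residuals = cbind(y1, y2) - fitted, loglik = q$ll, n = n,
                 n_iterations = it, converged = converged,
                 boundary = is.finite(rg) && abs(rg) >= 1 - 1e-3,
                 floor = floor_val, control = control, method = method),
            class = "greml")
}
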