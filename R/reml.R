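#' Control parameters for GREML fitting
#'
#' @param max_iterations maximum REML iterations (default 100).
#' @param loglik_tolerance declare convergence when the restricted
#'   log-likelihood changes by less than this between iterations (default
#'   1e-4, the convention of standard GREML software).
#' @param em_warmup_iterations number of EM iterations before switching to
#'   average-information updates (default 1).
#' @param variance_floor_fraction variance components are floored at this
#'   fraction of the phenotypic variance so they cannot go negative
#'   (default 1e-6).
#' @param verbose print one line per iteration.
#' @return A list of class `"greml_control"`.
#' @export
greml_control <- function(max_iterations = 100, loglik_tolerance = 1e-4,
                          em_warmup_iterations = 1,
                          variance_floor_fraction = 1e-6,
                          verbose = FALSE) {
  stopifnot(loglik_tolerance > 0, max_iterations >= 1,
            em_warmup_iterations >= 0,
            variance_floor_fraction > 0, variance_floor_fraction <= 0.01)
  structure(list(max_iterations = as.integer(max_iterations),
                 loglik_tolerance = loglik_tolerance,
                 em_warmup_iterations = as.integer(em_warmup_iterations),
                 variance_floor_fraction = variance_floor_fraction,
                 verbose = isTRUE(verbose)),
            class = "greml_control")
}

as_grm_matrix <- function(x) {
  if (inherits(x, "grm")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected a 'grm' object or a numeric matrix")
}

#' Restricted log-likelihood of the single-GRM animal model
#'
#' Evaluates the restricted log-likelihood of
#' \eqn{y = X b + g + e}, \eqn{g \sim N(0, G \sigma_g^2)},
#' \eqn{e \sim N(0, I \sigma_e^2)} at fixed variance components, by direct
#' dense linear algebra:
#' \deqn{\ell = -\tfrac12 [\log|V| + \log|X'V^{-1}X| + y'Py],}
#' with \eqn{V = G\sigma_g^2 + I\sigma_e^2} and
#' \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}}.
#' The additive constant \eqn{-\tfrac{n-p}{2}\log 2\pi} is dropped; values
#' are therefore comparable across calls on the same data but not across
#' sample sizes.
#'
#' @param y numeric response vector.
#' @param X fixed-effects design matrix (full column rank); defaults to an
#'   intercept.
#' @param K a [grm()] object or relationship matrix aligned with `y`.
#' @param sigma_g2,sigma_e2 variance components; `V` must be positive
#'   definite.
#' @return The restricted log-likelihood (a scalar).
#' @export
reml_loglik <- function(y, X = NULL, K, sigma_g2, sigma_e2) {
  G <- as_grm_matrix(K)
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  V <- sigma_g2 * G + diag(sigma_e2, n)
  R <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite at (sigma_g2 = ", sigma_g2,
         ", sigma_e2 = ", sigma_e2, "): ", conditionMessage(e)))
  logdetV <- 2 * sum(log(diag(R)))
  ViX <- backsolve(R, forwardsolve(t(R), X))
  Viy <- backsolve(R, forwardsolve(t(R), y))
  C <- crossprod(X, ViX)
  Rc <- tryCatch(chol(C), error = function(e)
    stop("X'V^-1 X singular: X not full column rank"))
  logdetC <- 2 * sum(log(diag(Rc)))
  beta <- backsolve(Rc, forwardsolve(t(Rc), crossprod(X, Viy)))
  r <- y - X %*% beta
  Vir <- backsolve(R, forwardsolve(t(R), r))
  yPy <- sum(r * Vir)
  -0.5 * (logdetV + logdetC + yPy)
}

# Per-iteration quantities for the univariate model, eigen fast path.
# State: rotated data (ystar, Xstar) and eigenvalues dvals of G.
uni_quant_eigen <- function(ystar, Xstar, dvals, sg, se) {
  v <- sg * dvals + se
  if (any(v <= 1e-12 * max(abs(v)))) return(NULL)
  C <- crossprod(Xstar, Xstar / v)
  Rc <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(Rc)) return(NULL)
  Cinv <- chol2inv(Rc)
  beta <- Cinv %*% crossprod(Xstar, ystar / v)
  r <- ystar - Xstar %*% beta
  Py <- r / v
  yPy <- sum(r * Py)
  ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(Rc))) + yPy)
  trPG <- sum(dvals / v) -
    sum(Cinv * crossprod(Xstar, Xstar * (dvals / v^2)))
  trPI <- sum(1 / v) - sum(Cinv * crossprod(Xstar, Xstar / v^2))
  wg <- dvals * Py
  Pw <- function(w) {
    bw <- Cinv %*% crossprod(Xstar, w / v)
    (w - Xstar %*% bw) / v
  }
  Pwg <- Pw(wg); Pwe <- Pw(Py)
  AI <- 0.5 * matrix(c(sum(wg * Pwg), sum(wg * Pwe),
                       sum(wg * Pwe), sum(Py * Pwe)), 2, 2)
  list(ll = ll, beta = drop(beta), Cinv = Cinv,
       score = -0.5 * c(trPG - sum(dvals * Py^2), trPI - sum(Py^2)),
       dLg = sum(dvals * Py^2) - trPG,       # y'P G P y - tr(PG)
       dLe = sum(Py^2) - trPI,
       AI = AI)
}

# Same quantities via literal dense algebra (verification path).
uni_quant_dense <- function(y, X, G, sg, se) {
  n <- length(y)
  V <- sg * G + diag(se, n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Vi <- chol2inv(R)
  C <- crossprod(X, Vi %*% X)
  Rc <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(Rc)) return(NULL)
  Cinv <- chol2inv(Rc)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% Cinv %*% t(ViX)
  Py <- P %*% y
  yPy <- sum(y * Py)
  ll <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(Rc))) + yPy)
  trPG <- sum(P * G)
  trPI <- sum(diag(P))
  wg <- G %*% Py
  AI <- 0.5 * matrix(c(sum(wg * (P %*% wg)), sum(wg * (P %*% Py)),
                       sum(wg * (P %*% Py)), sum(Py * (P %*% Py))), 2, 2)
  yPGPy <- sum(Py * wg); yPIPy <- sum(Py^2)
  beta <- Cinv %*% crossprod(X, Vi %*% y)
  list(ll = ll, beta = drop(beta), Cinv = Cinv,
       score = -0.5 * c(trPG - yPGPy, trPI - yPIPy),
       dLg = yPGPy - trPG, dLe = yPIPy - trPI, AI = AI)
}

#' Fit a univariate GREML model
#'
#' Maximizes the restricted likelihood of \eqn{y = Xb + g + e} with
#' \eqn{var(g) = G\sigma_g^2}, \eqn{var(e) = I\sigma_e^2} over the two
#' variance components by average-information (AI) REML after an EM
#' warm-up, with step-halving when a proposed AI update would decrease the
#' likelihood and flooring of components at
#' `variance_floor_fraction * V(p)`. Heritability and its standard error
#' come from the inverse AI matrix by the delta method.
#'
#' The default path rotates the data by the eigenvectors of `G`, making
#' every iteration O(n p); `method = "dense"` runs the identical algorithm
#' with literal dense algebra and exists for verification.
#'
#' @param y numeric response vector (complete cases only).
#' @param X fixed-effects design matrix; defaults to an intercept.
#' @param K a [grm()] object or relationship matrix aligned with `y`.
#' @param control a [greml_control()] list.
#' @param method `"eigen"` (fast path, default) or `"dense"`.
#' @return An object of class `"greml"`; see [greml()] for the fields.
#' @export
fit_greml_univariate <- function(y, X = NULL, K,
                                 control = greml_control(),
                                 method = c("eigen", "dense")) {
  method <- match.arg(method)
  G <- as_grm_matrix(K)
  y <- as.numeric(y)
  n <- length(y)
  if (any(is.na(y))) stop("y must be complete; subset to observed records")
  if (nrow(G) != n) stop("GRM dimension does not match length(y)")
  if (n < 10) stop("need at least 10 individuals")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")

  ols <- stats::lm.fit(X, y)
  vp0 <- sum(ols$residuals^2) / max(n - ncol(X), 1)
  floor_val <- control$variance_floor_fraction * vp0

  if (method == "eigen") {
    eg <- eigen(G, symmetric = TRUE)
    if (diff(range(eg$values)) < 1e-8 * (1 + max(abs(eg$values))))
      stop("singular average information: GRM is numerically proportional ",
           "to the identity, sigma_g2 and sigma_e2 are not separately ",
           "identifiable")
    ystar <- drop(crossprod(eg$vectors, y))
    Xstar <- crossprod(eg$vectors, X)
    qfun <- function(th) uni_quant_eigen(ystar, Xstar, eg$values,
                                         th[1], th[2])
  } else {
    if (sqrt(sum((G - diag(mean(diag(G)), n))^2)) <
        1e-8 * (1 + mean(diag(G))))
      stop("singular average information: GRM is numerically proportional ",
           "to the identity, sigma_g2 and sigma_e2 are not separately ",
           "identifiable")
    qfun <- function(th) uni_quant_dense(y, X, G, th[1], th[2])
  }

  th <- c(vp0 / 2, vp0 / 2)
  q <- qfun(th)
  if (is.null(q)) stop("likelihood undefined at starting values")
  converged <- FALSE
  it <- 0
  for (it in seq_len(control$max_iterations)) {
    ll_old <- q$ll
    if (it <= control$em_warmup_iterations) {
      delta <- th^2 * c(q$dLg, q$dLe) / n        # EM step
      th_new <- pmax(th + delta, floor_val)
      q_new <- qfun(th_new)
    } else {
      delta <- tryCatch(drop(solve(q$AI, q$score)), error = function(e)
        stop("singular average-information matrix"))
      step <- 1
      repeat {
        th_new <- pmax(th + step * delta, floor_val)
        q_new <- qfun(th_new)
        if (!is.null(q_new) && q_new$ll >= ll_old - 1e-10) break
        step <- step / 2
        if (step < 1e-8) {                        # AI failed; EM fallback
          th_new <- pmax(th + th^2 * c(q$dLg, q$dLe) / n, floor_val)
          q_new <- qfun(th_new)
          break
        }
      }
    }
    if (is.null(q_new)) stop("likelihood became undefined during fitting")
    th <- th_new
    q <- q_new
    if (control$verbose)
      cat(sprintf("iter %3d  logL %.6f  V(G) %.6g  V(e) %.6g\n",
                  it, q$ll, th[1], th[2]))
    if (abs(q$ll - ll_old) < control$loglik_tolerance && it > 1) {
      converged <- TRUE
      break
    }
  }

  scov <- tryCatch(solve(q$AI), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  sg <- th[1]; se <- th[2]; vp <- sg + se
  h2 <- sg / vp
  grad_h2 <- c(se, -sg) / vp^2
  se_h2 <- sqrt(max(drop(t(grad_h2) %*% scov %*% grad_h2), 0))
  se_comp <- sqrt(pmax(diag(scov), 0))
  se_vp <- sqrt(max(sum(scov), 0))
  components <- c("V(G)" = sg, "V(e)" = se, "V(p)" = vp, h2 = h2)
  se_all <- c("V(G)" = se_comp[1], "V(e)" = se_comp[2], "V(p)" = se_vp,
              h2 = se_h2)
  fitted <- drop(X %*% q$beta)
  structure(list(kind = "univariate", components = components,
                 se = se_all, sampling_covariance = scov,
                 beta = q$beta, fitted = fitted, residuals = y - fitted,
                 loglik = q$ll, n = n,
                 n_iterations = it, converged = converged,
                 at_floor = any(th <= floor_val * (1 + 1e-12)),
                 floor = floor_val, control = control, method = method),
            class = "greml")
}
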