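#' Fit a GREML animal model
#'
#' Formula front end to [fit_greml_univariate()] and
#' [fit_greml_bivariate()]. The model is the standard animal model
#' \eqn{y = Xb + g + e} with \eqn{g \sim N(0, G\sigma_g^2)} (one trait) or
#' its two-trait extension with genetic and residual (co)variance matrices
#' \eqn{\Sigma_g}, \eqn{\Sigma_e} (two traits, `cbind(t1, t2)` on the
#' left-hand side). `G` is a genomic relationship matrix; records are
#' matched to it by the `FID`/`IID` columns of `data`. Rows with a missing
#' response or covariate are dropped (complete-case), and individuals
#' absent from the GRM are dropped with a message.
#'
#' Heritability is \eqn{h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)}; for two
#' traits the genetic correlation is
#' \eqn{r_G = cov_{A12}/\sqrt{\sigma_{A1}^2\sigma_{A2}^2}} and the
#' phenotypic correlation uses the summed genetic and residual components.
#' Standard errors are delta-method transforms of the inverse
#' average-information matrix.
#'
#' @param formula model formula, e.g. `CW ~ 1` or `cbind(REA, YI) ~ 1`.
#'   Covariate terms form the fixed-effect design (an intercept is always
#'   sensible here since phenotypes are typically pre-adjusted).
#' @param data data.frame with columns `FID`, `IID` and the model
#'   variables (as returned by [read_phen()]).
#' @param K a [grm()] object (or, if `data` rows already align with it, a
#'   plain relationship matrix).
#' @param control a [greml_control()] list.
#' @param method `"eigen"` or `"dense"`; see the fitters.
#' @return An object of class `"greml"` with fields `components` (named
#'   estimates: variance components plus `h2`, and for two traits `rG`,
#'   `rP`), `se`, `sampling_covariance`, `beta`, `loglik`, `n`,
#'   `n_iterations`, `converged`, and for bivariate fits a `boundary`
#'   flag.
#' @examples
#' cfg <- sim_config(n_founders = 40, n_families = 30,
#'                   offspring_per_family = 4, n_snps = 400,
#'                   h2 = 0.5, seed = 7)
#' sim <- simulate_genotypes(cfg)
#' g <- compute_grm(sim$genotypes)
#' ph <- simulate_traits(g, cfg)$phenotypes
#' fit <- greml(trait1 ~ 1, data = ph, K = g)
#' fit
#' @export
greml <- function(formula, data, K, control = greml_control(),
                  method = c("eigen", "dense")) {
  method <- match.arg(method)
  if (!all(c("FID", "IID") %in% names(data)))
    stop("data must carry FID and IID columns for matching to the GRM")
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  Y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  Y <- as.matrix(Y)
  t_names <- if (ncol(Y) == 1) deparse(formula[[2]]) else colnames(Y)
  if (ncol(Y) > 2)
    stop("at most two traits: use cbind(t1, t2) on the left-hand side")

  ok <- stats::complete.cases(Y) & stats::complete.cases(X)
  if (inherits(K, "grm")) {
    pos <- match(id_key(data$FID, data$IID), id_key(K$fid, K$iid))
    unmatched <- sum(ok & is.na(pos))
    if (unmatched > 0)
      message(unmatched, " record(s) not present in the GRM were dropped")
    ok <- ok & !is.na(pos)
    if (!any(ok)) stop("no records match the GRM IDs")
    idx <- pos[ok]
    Gm <- K$values[idx, idx, drop = FALSE]
  } else {
    if (nrow(K) != nrow(data))
      stop("matrix K must align row-for-row with data; pass a 'grm' ",
           "object for ID matching")
    Gm <- K[ok, ok, drop = FALSE]
  }
  dropped <- sum(!(stats::complete.cases(Y) & stats::complete.cases(X)))
  if (dropped > 0)
    message(dropped, " incomplete record(s) dropped (complete-case fit)")
  Y <- Y[ok, , drop = FALSE]
  X <- X[ok, , drop = FALSE]

  fit <- if (ncol(Y) == 1) {
    fit_greml_univariate(Y[, 1], X, Gm, control = control, method = method)
  } else {
    fit_greml_bivariate(Y[, 1], Y[, 2], X, X, Gm, control = control,
                        method = method)
  }
  fit$call <- match.call()
  fit$traits <- t_names
  fit
}

#' @export
print.greml <- function(x, digits = 4, ...) {
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  kind <- if (x$kind == "univariate") "Univariate" else "Bivariate"
  cat(kind, "GREML fit:", x$n, "individuals,",
      x$n_iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  est <- formatC(x$components, digits = digits, format = "g")
  ses <- formatC(x$se, digits = digits, format = "g")
  tab <- data.frame(Estimate = est, SE = ses)
  rownames(tab) <- names(x$components)
  print(tab)
  cat("logL:", format(x$loglik, digits = 8), "\n")
  if (isTRUE(x$boundary))
    cat("note: genetic correlation at the parameter-space boundary\n")
  invisible(x)
}

#' @export
summary.greml <- function(object, ...) {
  structure(list(fit = object), class = "summary.greml")
}

#' @export
print.summary.greml <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat("\nSampling covariance of variance components:\n")
  print(signif(f$sampling_covariance, 4))
  invisible(x)
}

#' @export
coef.greml <- function(object, ...) object$beta

#' @export
residuals.greml <- function(object, ...) object$residuals

#' @export
fitted.greml <- function(object, ...) object$fitted

#' @export
logLik.greml <- function(object, ...) {
  structure(object$loglik, df = if (object$kind == "univariate") 2L else 6L,
            class = "logLik")
}

#' Sampling covariance of the variance-component estimates
#'
#' Returns the inverse average-information matrix: 2x2 for a univariate
#' fit (order V(G), V(e)), 6x6 for a bivariate fit (order sg1^2, sg12,
#' sg2^2, se1^2, se12, se2^2).
#'
#' @param object a `"greml"` fit.
#' @param ... unused.
#' @return A symmetric matrix.
#' @export
vcov.greml <- function(object, ...) object$sampling_covariance
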