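#' Re-estimate genetic parameters across a grid of relatedness ceilings
#'
#' For each ceiling: prune the GRM with [prune_by_relatedness()], intersect
#' the retained individuals with the phenotype table, fit a univariate
#' GREML per requested trait and a bivariate GREML per requested pair, and
#' record estimates, standard errors and convergence. A `NA` entry in
#' `cutoffs` (added by default) analyses the full data without pruning.
#' Failures at a single ceiling are recorded in the `status` column rather
#' than aborting the sweep; ceilings retaining fewer than `min_n`
#' individuals are flagged `"skipped"` (mirroring the practice of dropping
#' sub-populations too small to analyse).
#'
#' @param x a [grm()] object.
#' @param phenotypes data.frame with `FID`, `IID` and trait columns.
#' @param cutoffs numeric vector of ceilings (positive); `NA` = no ceiling.
#' @param traits character vector of trait columns to analyse (default all
#'   non-ID columns).
#' @param pairs list of length-2 character vectors, or `"all"` for every
#'   pair, or `NULL` for none.
#' @param control a [greml_control()] list.
#' @param min_n minimum retained sample size for fitting (default 50).
#' @param include_full prepend the no-ceiling analysis (default TRUE).
#' @param verbose print one line per ceiling.
#' @return A data.frame of class `"greml_sweep"` with one row per
#'   (ceiling, trait-or-pair): columns `cutoff`, `n_retained`, `kind`
#'   (`"h2"` or `"rG"`), `label`, `estimate`, `se`, `rP`, `se_rP`,
#'   `loglik`, `converged`, `status`. Rows are sorted by cutoff
#'   (full-data rows have `cutoff = NA` and sort last).
#' @export
run_sweep <- function(x, phenotypes, cutoffs, traits = NULL, pairs = NULL,
                      control = greml_control(), min_n = 50,
                      include_full = TRUE, verbose = FALSE) {
  validate_grm(x)
  if (!all(c("FID", "IID") %in% names(phenotypes)))
    stop("phenotypes must carry FID and IID columns")
  trait_cols <- setdiff(names(phenotypes), c("FID", "IID"))
  if (is.null(traits)) traits <- trait_cols
  if (!all(traits %in% trait_cols))
    stop("unknown trait(s): ", paste(setdiff(traits, trait_cols),
                                     collapse = ", "))
  if (identical(pairs, "all"))
    pairs <- if (length(traits) >= 2) utils::combn(traits, 2,
                                                   simplify = FALSE)
             else list()
  if (is.null(pairs)) pairs <- list()
  for (pr in pairs)
    if (length(pr) != 2 || !all(pr %in% trait_cols))
      stop("each pair must name two trait columns")
  cutoffs <- cutoffs[!is.na(cutoffs)]
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  cutoffs <- sort(unique(cutoffs))
  grid <- c(as.list(cutoffs), if (include_full) list(NA_real_))

  rows <- list()
  for (cf in grid) {
    if (is.na(cf)) {
      keep <- x
      n_ret <- length(x$fid)
    } else {
      pr_res <- prune_by_relatedness(x, cf)
      keep <- subset_grm(x, pr_res$retained_index)
      n_ret <- length(keep$fid)
    }
    if (verbose)
      cat(sprintf("ceiling %s: retained %d\n",
                  ifelse(is.na(cf), "none", format(cf)), n_ret))
    pos <- match(id_key(keep$fid, keep$iid),
                 id_key(phenotypes$FID, phenotypes$IID))
    status_base <- if (n_ret < min_n) "skipped" else "ok"
    fit_one <- function(kind, label, fitter) {
      if (status_base == "skipped")
        return(data.frame(cutoff = cf, n_retained = n_ret, kind = kind,
                          label = label, estimate = NA_real_,
                          se = NA_real_, rP = NA_real_, se_rP = NA_real_,
                          loglik = NA_real_, converged = NA,
                          status = "skipped", stringsAsFactors = FALSE))
      out <- tryCatch(fitter(), error = function(e)
        conditionMessage(e))
      if (is.character(out))
        return(data.frame(cutoff = cf, n_retained = n_ret, kind = kind,
                          label = label, estimate = NA_real_,
                          se = NA_real_, rP = NA_real_, se_rP = NA_real_,
                          loglik = NA_real_, converged = NA,
                          status = paste0("error: ", out),
                          stringsAsFactors = FALSE))
      out
    }
    for (tr in traits) {
      rows[[length(rows) + 1]] <- fit_one("h2", tr, function() {
        yv <- phenotypes[[tr]][pos]
        ok <- !is.na(pos) & !is.na(yv)
        fit <- fit_greml_univariate(yv[ok], NULL,
                                    keep$values[ok, ok, drop = FALSE],
                                    control = control)
        data.frame(cutoff = cf, n_retained = n_ret, kind = "h2",
                   label = tr, estimate = fit$components[["h2"]],
                   se = fit$se[["h2"]], rP = NA_real_, se_rP = NA_real_,
                   loglik = fit$loglik, converged = fit$converged,
                   status = "ok", stringsAsFactors = FALSE)
      })
    }
    for (pr in pairs) {
      lab <- paste(pr, collapse = ":")
      rows[[length(rows) + 1]] <- fit_one("rG", lab, function() {
        y1 <- phenotypes[[pr[1]]][pos]
        y2 <- phenotypes[[pr[2]]][pos]
        ok <- !is.na(pos) & !is.na(y1) & !is.na(y2)
        fit <- fit_greml_bivariate(y1[ok], y2[ok], NULL, NULL,
                                   keep$values[ok, ok, drop = FALSE],
                                   control = control)
        data.frame(cutoff = cf, n_retained = n_ret, kind = "rG",
                   label = lab, estimate = fit$components[["rG"]],
                   se = fit$se[["rG"]], rP = fit$components[["rP"]],
                   se_rP = fit$se[["rP"]], loglik = fit$loglik,
                   converged = fit$converged, status = "ok",
                   stringsAsFactors = FALSE)
      })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("greml_sweep", "data.frame")
  out
}

#' @export
print.greml_sweep <- function(x, ...) {
  if (!all(c("cutoff", "kind", "label") %in% names(x)))
    return(invisible(print.data.frame(x, ...)))
  cat("GREML relatedness-ceiling sweep:",
      length(unique(x$cutoff)), "ceilings,",
      length(unique(x$label[x$kind == "h2"])), "traits,",
      length(unique(x$label[x$kind == "rG"])), "pairs\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Plot a ceiling sweep
#'
#' Two base-graphics panels: estimates (h2 or rG) against the ceiling, one
#' line per trait or pair, and the retained sample size against the
#' ceiling. Full-data rows (no ceiling) are drawn as horizontal dashed
#' reference lines.
#'
#' @param x a `"greml_sweep"` object.
#' @param kind `"h2"` or `"rG"`.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.greml_sweep <- function(x, kind = c("h2", "rG"), ...) {
  kind <- match.arg(kind)
  sub <- x[x$kind == kind & !is.na(x$cutoff), ]
  if (nrow(sub) == 0) stop("no rows of kind ", kind, " with a ceiling")
  labs <- unique(sub$label)
  cuts <- sort(unique(sub$cutoff))
  est <- sapply(labs, function(l)
    sub$estimate[match(paste(cuts, l), paste(sub$cutoff, sub$label))])
  est <- matrix(est, nrow = length(cuts),
                dimnames = list(NULL, labs))
  oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  graphics::matplot(cuts, est, type = "b", pch = seq_along(labs),
                    lty = 1, xlab = "relatedness ceiling",
                    ylab = kind, ...)
  graphics::legend("bottomright", legend = labs, pch = seq_along(labs),
                   col = seq_along(labs), cex = 0.7, bty = "n")
  full <- x[x$kind == kind & is.na(x$cutoff), ]
  if (nrow(full))
    graphics::abline(h = full$estimate, lty = 2,
                     col = match(full$label, labs))
  nret <- sub$n_retained[match(cuts, sub$cutoff)]
  graphics::plot(cuts, nret, type = "b", xlab = "relatedness ceiling",
                 ylab = "retained n")
  invisible(x)
}
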