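#' Compute the genomic relationship matrix from dosages
#'
#' GCTA-style single-component GRM. With per-SNP A2 frequency `p_i`
#' estimated from the non-missing calls of the input sample, the
#' off-diagonal entry for a pair (j, k) is the mean over SNPs non-missing
#' in both individuals of
#' \deqn{(x_{ij} - 2p_i)(x_{ik} - 2p_i) / (2 p_i (1 - p_i)),}
#' and the diagonal entry for individual j is
#' \deqn{1 + \mathrm{mean}_i [x_{ij}^2 - (1 + 2p_i) x_{ij} + 2p_i^2] /
#'   (2 p_i (1 - p_i))}
#' over the SNPs non-missing in j. Monomorphic SNPs contribute to no entry.
#'
#' @param geno a [genotypes()] object with at least 2 individuals and one
#'   polymorphic SNP.
#' @return A [grm()] object whose `pair_snp_counts` records how many SNPs
#'   contributed to each entry.
#' @export
compute_grm <- function(geno) {
  validate_genotypes(geno)
  n <- length(geno$fid)
  if (n < 2) stop("GRM needs at least 2 individuals")
  d <- geno$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly))
    stop("degenerate input: no polymorphic SNPs")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  denom <- 2 * p * (1 - p)

  obs <- !is.na(d)
  W <- sweep(d, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(denom), "/")
  W[!obs] <- 0
  cnt <- tcrossprod(obs * 1)
  if (any(cnt == 0))
    stop("undefined GRM entry: a pair of individuals shares no ",
         "non-missing SNP")
  G <- tcrossprod(W) / cnt

  # Distinct diagonal estimator: 1 + mean of (x^2 - (1+2p)x + 2p^2)/denom
  Dq <- d * d - sweep(d, 2, 1 + 2 * p, "*")
  Dq <- sweep(Dq, 2, 2 * p * p, "+")
  Dq <- sweep(Dq, 2, denom, "/")
  Dq[!obs] <- 0
  diag(G) <- 1 + rowSums(Dq) / diag(cnt)

  grm(geno$fid, geno$iid, G, cnt)
}

#' Prune individuals until no pair exceeds a relatedness ceiling
#'
#' Implements the GRM-cutoff sub-population construction: individuals are
#' removed until no off-diagonal GRM value among those retained exceeds
#' `cutoff`. The base rule is greedy max-degree elimination: repeatedly
#' remove the individual participating in the largest number of
#' over-ceiling pairs, breaking ties toward the larger input index. After
#' the greedy loop a deterministic minimality pass re-adds any removed
#' individual that no longer conflicts, and a (1,2)-swap pass exchanges one
#' retained individual for two compatible removed ones when possible; both
#' refinements only enlarge the retained set and never violate the ceiling.
#'
#' @param x a [grm()] object.
#' @param cutoff positive relatedness ceiling; pairs with GRM value
#'   strictly greater than `cutoff` are disallowed.
#' @return An object of class `"prune_result"`: list with `retained`
#'   (data.frame FID, IID in input order), `removed` (data.frame FID, IID,
#'   step), `cutoff`, and `retained_index`.
#' @export
prune_by_relatedness <- function(x, cutoff) {
  validate_grm(x)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) ||
      cutoff <= 0)
    stop("cutoff must be a single positive number")
  n <- length(x$fid)
  adj0 <- x$values > cutoff
  diag(adj0) <- FALSE
  adj <- adj0
  act <- rep(TRUE, n)
  deg <- rowSums(adj)
  removed <- integer(0)
  while (any(deg[act] > 0)) {
    w <- max(deg[act])
    i <- max(which(act & deg == w))     # tie -> larger input index
    act[i] <- FALSE
    removed <- c(removed, i)
    deg <- deg - adj[, i]
    deg[i] <- 0
    adj[i, ] <- FALSE
    adj[, i] <- FALSE
  }
  # minimality + (1,2)-swap refinement; deterministic, invariant-preserving
  repeat {
    improved <- FALSE
    for (i in removed) {
      if (!act[i] && !any(adj0[i, act])) {
        act[i] <- TRUE
        improved <- TRUE
      }
    }
    out <- which(!act)
    if (length(out)) {
      # removed individuals blocked by exactly one retained individual
      blocker <- vapply(out, function(u) {
        b <- which(adj0[u, ] & act)
        if (length(b) == 1) b else NA_integer_
      }, integer(1))
      for (v in unique(blocker[!is.na(blocker)])) {
        cand <- out[!is.na(blocker) & blocker == v]
        if (length(cand) < 2) next
        done <- FALSE
        for (a in seq_along(cand)) {
          for (b in seq_len(a - 1)) {
            if (!adj0[cand[a], cand[b]]) {
              act[v] <- FALSE
              act[c(cand[b], cand[a])] <- TRUE
              done <- TRUE
              break
            }
          }
          if (done) break
        }
        if (done) {
          improved <- TRUE
          break   # recompute bookkeeping from scratch
        }
      }
    }
    if (!improved) break
  }
  removed_final <- setdiff(seq_len(n), which(act))
  step <- match(removed_final, removed)
  structure(list(
    retained = data.frame(FID = x$fid[act], IID = x$iid[act],
                          stringsAsFactors = FALSE),
    removed = data.frame(FID = x$fid[removed_final],
                         IID = x$iid[removed_final],
                         step = step, stringsAsFactors = FALSE),
    cutoff = cutoff,
    retained_index = which(act)), class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("Relatedness ceiling %.3f: retained %d, removed %d\n",
              x$cutoff, nrow(x$retained), nrow(x$removed)))
  invisible(x)
}

#' Summarize the distribution of GRM elements
#'
#' @param x a [grm()] object.
#' @param probs quantile probabilities for both element classes.
#' @return A list of class `"grm_summary"` with `n`, `diagonal` and
#'   `off_diagonal` summaries (mean, sd, min, max, quantiles) and
#'   `max_off_diagonal`.
#' @export
summarize_grm <- function(x, probs = c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95,
                                       0.99)) {
  validate_grm(x)
  dg <- diag(x$values)
  off <- x$values[upper.tri(x$values)]
  summ <- function(v) {
    if (!length(v))
      return(list(mean = NA_real_, sd = NA_real_, min = NA_real_,
                  max = NA_real_, quantiles = stats::setNames(rep(NA_real_,
                    length(probs)), paste0(100 * probs, "%"))))
    list(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
         quantiles = stats::quantile(v, probs))
  }
  structure(list(n = length(x$fid), diagonal = summ(dg),
                 off_diagonal = summ(off),
                 max_off_diagonal = if (length(off)) max(off) else NA_real_),
            class = "grm_summary")
}

#' @export
print.grm_summary <- function(x, ...) {
  cat("GRM element summary (n =", x$n, ")\n")
  cat(sprintf("  diagonal:     mean %.4f sd %.4f range [%.4f, %.4f]\n",
              x$diagonal$mean, x$diagonal$sd, x$diagonal$min,
              x$diagonal$max))
  cat(sprintf("  off-diagonal: mean %.4f sd %.4f range [%.4f, %.4f]\n",
              x$off_diagonal$mean, x$off_diagonal$sd, x$off_diagonal$min,
              x$off_diagonal$max))
  invisible(x)
}
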