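# Independent oracles used across the suite. These deliberately use naive,
# direct implementations (double loops, lgamma enumeration, literal matrix
# formulas) so they share no code path with the package internals.

# GRM by brute-force double loop over individuals and SNPs.
oracle_grm <- function(dos) {
  n <- nrow(dos); m <- ncol(dos)
  p <- numeric(m)
  for (j in seq_len(m)) p[j] <- mean(dos[, j], na.rm = TRUE) / 2
  poly <- which(!is.na(p) & p > 0 & p < 1)
  G <- matrix(NA_real_, n, n)
  cnt <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      s <- 0; k <- 0
      for (j in poly) {
        xa <- dos[a, j]; xb <- dos[b, j]
        if (is.na(xa) || is.na(xb)) next
        k <- k + 1
        if (a == b) {
          s <- s + (xa^2 - (1 + 2 * p[j]) * xa + 2 * p[j]^2) /
            (2 * p[j] * (1 - p[j]))
        } else {
          s <- s + (xa - 2 * p[j]) * (xb - 2 * p[j]) /
            (2 * p[j] * (1 - p[j]))
        }
      }
      G[a, b] <- if (a == b) 1 + s / k else s / k
      cnt[a, b] <- k
    }
  }
  list(values = G, counts = cnt)
}

# Exact HWE p-value by direct enumeration with log-factorials.
oracle_hwe <- function(counts) {
  n <- sum(counts)
  nA <- 2 * counts[1] + counts[2]
  nB <- counts[2] + 2 * counts[3]
  rare <- min(nA, nB)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
      lgamma((nB - h) / 2 + 1) + h * log(2) +
      lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(counts[2], hs)]
  min(sum(prob[prob <= obs * (1 + 1e-9)]), 1)
}

# Literal dense evaluation of the restricted log-likelihood (solve/det,
# no Cholesky), same additive-constant convention as reml_loglik.
oracle_loglik <- function(y, X, G, sg, se) {
  n <- length(y)
  V <- sg * G + se * diag(n)
  Vi <- solve(V)
  C <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(C) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus[1] + determinant(C)$modulus[1] +
          drop(t(y) %*% P %*% y))
}

# 2-D grid search plus coordinate-wise golden-section refinement of the
# restricted likelihood over (sigma_g2, sigma_e2).
oracle_grid_max <- function(y, X, K, n_grid = 200, sweeps = 3) {
  vp <- stats::var(stats::lm.fit(X, y)$residuals)
  gr <- seq(vp * 1e-3, vp * 1.5, length.out = n_grid)
  # realized GRMs can be slightly indefinite, so V may lose positive
  # definiteness at tiny residual variances; treat those points as -Inf
  f <- function(a, b) tryCatch(reml_loglik(y, X, K, a, b),
                               error = function(e) -Inf)
  best <- c(NA, NA); best_ll <- -Inf
  for (a in gr) {
    lls <- vapply(gr, function(b) f(a, b), numeric(1))
    j <- which.max(lls)
    if (lls[j] > best_ll) {
      best_ll <- lls[j]; best <- c(a, gr[j])
    }
  }
  golden <- function(fn, lo, hi, tol = 1e-7) {
    phi <- (sqrt(5) - 1) / 2
    x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
    f1 <- fn(x1); f2 <- fn(x2)
    while (hi - lo > tol * (abs(lo) + abs(hi) + 1e-12)) {
      if (f1 < f2) {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + phi * (hi - lo); f2 <- fn(x2)
      } else {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - phi * (hi - lo); f1 <- fn(x1)
      }
    }
    (lo + hi) / 2
  }
  step <- gr[2] - gr[1]
  for (s in seq_len(sweeps)) {
    best[1] <- golden(function(a) f(a, best[2]),
                      max(best[1] - step, vp * 1e-6), best[1] + step)
    best[2] <- golden(function(b) f(best[1], b),
                      max(best[2] - step, vp * 1e-6), best[2] + step)
    step <- step / 10
  }
  list(par = best, ll = f(best[1], best[2]))
}

id_key_of <- function(x) paste(x$fid, x$iid, sep = "\t")

id_key <- function(fid, iid) paste(fid, iid, sep = "\t")

# Small unrelated random genotype matrix.
rand_geno <- function(n, m, missing = 0, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  storage.mode(d) <- "double"
  if (missing > 0) d[runif(n * m) < missing] <- NA
  genotypes(rep("F", n), sprintf("I%03d", 1:n), d, NULL)
}

# Half-sib simulated dataset ready for fitting (shared by REML tests).
sim_dataset <- function(n_fam, off_per_fam, m, h2, seed,
                        rg = NULL, re = NULL, two = FALSE) {
  if (two) {
    cfg <- sim_config(n_founders = max(3 * n_fam, 60), n_families = n_fam,
                      offspring_per_family = off_per_fam,
                      mating = "half_sib", n_snps = m, h2 = h2,
                      genetic_corr = matrix(c(1, rg, rg, 1), 2),
                      residual_corr = matrix(c(1, re, re, 1), 2),
                      keep_founders = FALSE, seed = seed)
  } else {
    cfg <- sim_config(n_founders = max(3 * n_fam, 60), n_families = n_fam,
                      offspring_per_family = off_per_fam,
                      mating = "half_sib", n_snps = m, h2 = h2,
                      keep_founders = FALSE, seed = seed)
  }
  sim <- simulate_genotypes(cfg)
  g <- compute_grm(sim$genotypes)
  tr <- simulate_traits(g, cfg)
  list(grm = g, phen = tr$phenotypes, bv = tr$breeding_values, cfg = cfg)
}
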