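#' Configuration for the pedigree/trait simulator
#'
#' Describes a two-generation population: unrelated founders genotyped at
#' independent biallelic SNPs, plus families of offspring produced by
#' Mendelian gene dropping (one allele transmitted per parent per SNP, no
#' linkage). `full_sib` families share one sire and one dam (expected
#' relatedness 0.5); `half_sib` families share a sire but each offspring
#' has its own dam (expected 0.25); `mixed` alternates the two designs.
#' Traits follow the additive animal model exactly: genetic values have
#' covariance \eqn{\Sigma_g \otimes G} against the realized GRM and
#' residuals \eqn{\Sigma_e \otimes I}, with
#' \eqn{\Sigma_g = D^{1/2} R_g D^{1/2}}, \eqn{D = h^2 V_p}, and
#' \eqn{\Sigma_e} built analogously from \eqn{(1-h^2)V_p} and the residual
#' correlation matrix.
#'
#' @param n_founders number of unrelated founders (also the parent pool).
#' @param n_families number of offspring families (0 = founders only).
#' @param offspring_per_family offspring per family.
#' @param mating `"half_sib"`, `"full_sib"` or `"mixed"`.
#' @param n_snps number of simulated SNPs.
#' @param founder_maf_range range of founder allele frequencies, drawn
#'   uniformly per SNP.
#' @param h2 per-trait heritability vector, each in `[0, 1]`.
#' @param genetic_corr trait x trait genetic correlation matrix (unit
#'   diagonal, positive semidefinite).
#' @param residual_corr residual correlation matrix, same shape.
#' @param phenotypic_var per-trait phenotypic variances.
#' @param missing_rate genotype missingness rate in `[0, 1)`.
#' @param keep_founders include founders in the genotype output (default
#'   TRUE).
#' @param seed integer seed; simulation output is deterministic given the
#'   config.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 100, n_families = 0,
                       offspring_per_family = 0,
                       mating = c("half_sib", "full_sib", "mixed"),
                       n_snps = 1000, founder_maf_range = c(0.05, 0.5),
                       h2 = 0.5, genetic_corr = NULL, residual_corr = NULL,
                       phenotypic_var = NULL, missing_rate = 0,
                       keep_founders = TRUE, seed = 1L) {
  mating <- match.arg(mating)
  t <- length(h2)
  if (is.null(genetic_corr)) genetic_corr <- diag(t)
  if (is.null(residual_corr)) residual_corr <- diag(t)
  if (is.null(phenotypic_var)) phenotypic_var <- rep(1, t)
  stopifnot(n_founders >= 2, n_families >= 0, n_snps >= 1,
            length(founder_maf_range) == 2,
            founder_maf_range[1] > 0, founder_maf_range[2] <= 0.5,
            founder_maf_range[1] <= founder_maf_range[2],
            all(h2 >= 0), all(h2 <= 1),
            all(dim(genetic_corr) == c(t, t)),
            all(dim(residual_corr) == c(t, t)),
            length(phenotypic_var) == t, all(phenotypic_var > 0),
            missing_rate >= 0, missing_rate < 1)
  if (n_families > 0 && offspring_per_family < 1)
    stop("inconsistent family sizes: n_families > 0 needs ",
         "offspring_per_family >= 1")
  if (any(abs(diag(genetic_corr) - 1) > 1e-8) ||
      any(abs(diag(residual_corr) - 1) > 1e-8))
    stop("correlation matrices must have unit diagonal")
  if (min(eigen(genetic_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("genetic_corr is not positive semidefinite")
  if (min(eigen(residual_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("residual_corr is not positive semidefinite")
  structure(list(n_founders = as.integer(n_founders),
                 n_families = as.integer(n_families),
                 offspring_per_family = as.integer(offspring_per_family),
                 mating = mating, n_snps = as.integer(n_snps),
                 founder_maf_range = founder_maf_range,
                 h2 = h2, genetic_corr = genetic_corr,
                 residual_corr = residual_corr,
                 phenotypic_var = phenotypic_var,
                 missing_rate = missing_rate,
                 keep_founders = isTRUE(keep_founders),
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed",
                                envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Simulate pedigree-structured genotypes by gene dropping
#'
#' Founder dosages are Binomial(2, p) draws with per-SNP allele
#' frequencies uniform on the configured range; offspring receive one
#' allele per parent per SNP, independently across SNPs (no linkage).
#' Missing calls are masked uniformly at the configured rate.
#'
#' @param config a [sim_config()].
#' @return A list: `genotypes` (a [genotypes()] object), `pedigree`
#'   (data.frame `FID`, `IID`, `sire`, `dam`; founders have `"0"`) and
#'   `allele_freq` (the founder frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nf <- config$n_founders
    m <- config$n_snps
    p <- stats::runif(m, config$founder_maf_range[1],
                      config$founder_maf_range[2])
    founders <- matrix(stats::rbinom(nf * m, 2, rep(p, each = nf)), nf, m)
    founder_iid <- sprintf("F%04d", seq_len(nf))

    off <- NULL; off_fid <- off_iid <- off_sire <- off_dam <- character(0)
    if (config$n_families > 0) {
      k <- config$offspring_per_family
      n_off <- config$n_families * k
      sire_ix <- integer(n_off); dam_ix <- integer(n_off)
      fam_of <- rep(seq_len(config$n_families), each = k)
      for (f in seq_len(config$n_families)) {
        type <- switch(config$mating,
                       full_sib = "full_sib", half_sib = "half_sib",
                       mixed = if (f %% 2 == 1) "half_sib" else "full_sib")
        s <- sample.int(nf, 1)
        rows <- which(fam_of == f)
        sire_ix[rows] <- s
        if (type == "full_sib") {
          d <- sample.int(nf, 1)
          while (d == s) d <- sample.int(nf, 1)
          dam_ix[rows] <- d
        } else {
          for (r in rows) {
            d <- sample.int(nf, 1)
            while (d == s) d <- sample.int(nf, 1)
            dam_ix[r] <- d
          }
        }
      }
      S <- founders[sire_ix, , drop = FALSE]
      D <- founders[dam_ix, , drop = FALSE]
      off <- matrix(stats::rbinom(n_off * m, 1, S / 2), n_off, m) +
             matrix(stats::rbinom(n_off * m, 1, D / 2), n_off, m)
      off_fid <- sprintf("FAM%04d", fam_of)
      off_iid <- sprintf("O%04d_%02d", fam_of,
                         as.integer(stats::ave(fam_of, fam_of,
                                               FUN = seq_along)))
      off_sire <- founder_iid[sire_ix]
      off_dam <- founder_iid[dam_ix]
    }

    if (config$keep_founders) {
      dos <- rbind(founders, off)
      fid <- c(rep("FND", nf), off_fid)
      iid <- c(founder_iid, off_iid)
      sire <- c(rep("0", nf), off_sire)
      dam <- c(rep("0", nf), off_dam)
    } else {
      if (is.null(off))
        stop("keep_founders = FALSE with no families leaves no individuals")
      dos <- off; fid <- off_fid; iid <- off_iid
      sire <- off_sire; dam <- off_dam
    }
    storage.mode(dos) <- "double"
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(dos)) < config$missing_rate
      dos[mask] <- NA_real_
    }
    map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                      chromosome = "1", position = seq_len(m),
                      allele_a1 = "A", allele_a2 = "B",
                      stringsAsFactors = FALSE)
    list(genotypes = genotypes(fid, iid, dos, map),
         pedigree = data.frame(FID = fid, IID = iid, sire = sire,
                               dam = dam, stringsAsFactors = FALSE),
         allele_freq = p)
  })
}

#' Simulate correlated polygenic traits against a realized GRM
#'
#' Draws genetic values with covariance \eqn{\Sigma_g \otimes G} (via a
#' Cholesky factor of `G` with a 1e-8 diagonal jitter, since realized GRMs
#' of related designs are near-singular) and residuals with covariance
#' \eqn{\Sigma_e \otimes I}; phenotype = genetic + residual. The true
#' breeding values are returned so estimators can be checked against them.
#'
#' @param x a [grm()] object (the realized GRM to condition on).
#' @param config a [sim_config()]; its `h2`, correlation matrices and
#'   `phenotypic_var` define \eqn{\Sigma_g} and \eqn{\Sigma_e}.
#' @param seed seed for the trait draw; defaults to `config$seed + 1` so
#'   genotype and trait draws are decoupled but jointly reproducible.
#' @return A list: `phenotypes` (data.frame FID, IID, trait1, ...),
#'   `breeding_values` (n x t matrix), `Sigma_g`, `Sigma_e`.
#' @export
simulate_traits <- function(x, config, seed = config$seed + 1L) {
  stopifnot(inherits(x, "grm"), inherits(config, "sim_config"))
  t <- length(config$h2)
  vg <- config$h2 * config$phenotypic_var
  ve <- (1 - config$h2) * config$phenotypic_var
  Sg <- diag(sqrt(vg), t) %*% config$genetic_corr %*% diag(sqrt(vg), t)
  Se <- diag(sqrt(ve), t) %*% config$residual_corr %*% diag(sqrt(ve), t)
  if (min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("derived Sigma_g is not positive semidefinite")
  if (min(eigen(Se, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("derived Sigma_e is not positive semidefinite")
  n <- length(x$fid)
  G <- x$values
  with_seed(seed, {
    bv <- if (all(vg == 0)) {
      matrix(0, n, t)
    } else {
      off <- G; diag(off) <- 0
      Lg <- if (all(off == 0)) {
        diag(sqrt(pmax(diag(G), 0) + 1e-8), n)   # diagonal fast path
      } else {
        # realized GRMs of related designs can be slightly indefinite;
        # factor the PSD projection with a 1e-8 jitter
        eg <- eigen(G, symmetric = TRUE)
        eg$vectors %*% diag(sqrt(pmax(eg$values, 0) + 1e-8), n)
      }
      Z <- matrix(stats::rnorm(n * t), n, t)
      Lg %*% Z %*% mat_sqrt_upper(Sg)
    }
    resid <- matrix(stats::rnorm(n * t), n, t) %*% mat_sqrt_upper(Se)
    ph <- bv + resid
    phen <- data.frame(FID = x$fid, IID = x$iid, ph,
                       stringsAsFactors = FALSE)
    t_names <- attr(config, "trait_names")
    if (is.null(t_names) || length(t_names) != t)
      t_names <- paste0("trait", seq_len(t))
    colnames(phen) <- c("FID", "IID", t_names)
    list(phenotypes = phen, breeding_values = bv, Sigma_g = Sg,
         Sigma_e = Se)
  })
}

# Upper factor R with t(R) %*% R = S for a PSD matrix (eigen-based so
# singular matrices are allowed).
mat_sqrt_upper <- function(S) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  diag(sqrt(vals), length(vals)) %*% t(eg$vectors)
}

#' Synthetic preset mirroring a Japanese Black carcass-trait study design
#'
#' Six traits (CW, REA, RT, SFT, YI, BMS) with the published phenotypic
#' variances, heritabilities and genetic/phenotypic correlation structure
#' of a large Wagyu carcass dataset, on a half-sib-dominated two-generation
#' pedigree. The residual correlation matrix is derived from the reported
#' genetic and phenotypic correlations; the genetic correlation matrix is
#' bent to the nearest positive semidefinite matrix if the published table
#' is slightly indefinite. This is a synthetic stand-in for the real herd
#' (which has 65 herds and 487 sires), not a reproduction of it.
#'
#' @param n_families number of half-sib families.
#' @param offspring_per_family offspring per family.
#' @param n_snps number of SNPs.
#' @param seed integer seed.
#' @return A [sim_config()] for the six carcass traits.
#' @export
wagyu_preset <- function(n_families = 100, offspring_per_family = 10,
                         n_snps = 2000, seed = 1L) {
  traits <- c("CW", "REA", "RT", "SFT", "YI", "BMS")
  vp <- c(2195.34, 89.97, 0.624, 0.520, 2.289, 3.748)
  h2 <- c(0.51, 0.43, 0.338, 0.473, 0.446, 0.486)
  rg <- diag(6)
  rg[upper.tri(rg)] <- c(0.460,
                         0.593, 0.380,
                         0.188, -0.198, 0.131,
                         0.053, 0.811, 0.302, -0.634,
                         0.201, 0.625, 0.382, -0.096, 0.578)
  rg <- rg + t(rg) - diag(6)
  rp <- diag(6)
  rp[upper.tri(rp)] <- c(0.460,
                         0.595, 0.41,
                         0.247, -0.084, 0.141,
                         0.075, 0.812, 0.383, -0.544,
                         0.202, 0.543, 0.306, -0.067, 0.499)
  rp <- rp + t(rp) - diag(6)
  # residual covariance implied by the genetic and phenotypic tables
  sd_p <- sqrt(vp)
  cov_p <- rp * tcrossprod(sd_p)
  cov_g <- rg * tcrossprod(sqrt(h2 * vp))
  cov_e <- cov_p - cov_g
  diag(cov_e) <- (1 - h2) * vp
  re <- stats::cov2cor(cov_e)
  fix_psd <- function(R) {
    eg <- eigen(R, symmetric = TRUE)
    if (min(eg$values) >= 1e-10) return(R)
    vals <- pmax(eg$values, 1e-8)
    R2 <- eg$vectors %*% (vals * t(eg$vectors))
    stats::cov2cor((R2 + t(R2)) / 2)
  }
  cfg <- sim_config(n_founders = max(2 * n_families, 100),
                    n_families = n_families,
                    offspring_per_family = offspring_per_family,
                    mating = "half_sib", n_snps = n_snps,
                    h2 = h2, genetic_corr = fix_psd(rg),
                    residual_corr = fix_psd(re), phenotypic_var = vp,
                    keep_founders = FALSE, seed = seed)
  attr(cfg, "trait_names") <- traits
  cfg
}
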