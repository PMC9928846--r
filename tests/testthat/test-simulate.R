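test_that("the same config yields identical output; configs validate", {
  cfg <- sim_config(n_founders = 30, n_families = 10,
                    offspring_per_family = 3, n_snps = 100, seed = 9)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1, s2)
  g <- compute_grm(s1$genotypes)
  t1 <- simulate_traits(g, cfg)
  t2 <- simulate_traits(g, cfg)
  expect_identical(t1, t2)
  expect_error(sim_config(n_families = 3, offspring_per_family = 0),
               "inconsistent family sizes")
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(h2 = c(0.5, 0.5),
                          genetic_corr = matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("founders-only panels are unrelated on average", {
  cfg <- sim_config(n_founders = 80, n_families = 0, n_snps = 2000,
                    seed = 14)
  sim <- simulate_genotypes(cfg)
  expect_equal(sim$pedigree$sire, rep("0", 80))
  G <- compute_grm(sim$genotypes)
  off <- G$values[upper.tri(G$values)]
  # in-sample allele frequencies centre each SNP exactly, which shrinks the
  # mean off-diagonal to about -1/(n-1) rather than 0
  expect_lt(abs(mean(off) + 1 / (80 - 1)), 0.005)
})

test_that("full-sib pairs realize relatedness near 0.5", {
  cfg <- sim_config(n_founders = 120, n_families = 50,
                    offspring_per_family = 2, mating = "full_sib",
                    n_snps = 5000, seed = 15)
  sim <- simulate_genotypes(cfg)
  G <- compute_grm(sim$genotypes)
  key <- id_key_of(sim$genotypes)
  ped <- sim$pedigree
  sib_vals <- sapply(unique(ped$FID[ped$FID != "FND"]), function(f) {
    ix <- match(id_key_of(list(fid = ped$FID, iid = ped$IID))[ped$FID == f],
                key)
    G$values[ix[1], ix[2]]
  })
  expect_gte(mean(sib_vals), 0.45)
  expect_lte(mean(sib_vals), 0.55)
})

test_that("half-sib pairs realize relatedness near 0.25", {
  cfg <- sim_config(n_founders = 200, n_families = 40,
                    offspring_per_family = 3, mating = "half_sib",
                    n_snps = 5000, seed = 16)
  sim <- simulate_genotypes(cfg)
  G <- compute_grm(sim$genotypes)
  key <- id_key_of(sim$genotypes)
  ped <- sim$pedigree
  vals <- unlist(lapply(unique(ped$FID[ped$FID != "FND"]), function(f) {
    rows <- which(ped$FID == f)
    # pairs with the same sire but different dams
    ix <- match(paste(ped$FID[rows], ped$IID[rows], sep = "\t"), key)
    out <- c()
    for (a in seq_along(rows)) for (b in seq_len(a - 1)) {
      if (ped$dam[rows[a]] != ped$dam[rows[b]])
        out <- c(out, G$values[ix[a], ix[b]])
    }
    out
  }))
  expect_gt(length(vals), 30)
  expect_gte(mean(vals), 0.2)
  expect_lte(mean(vals), 0.3)
})

test_that("h2 = 0 produces identically zero breeding values", {
  cfg <- sim_config(n_founders = 40, n_snps = 200, h2 = 0, seed = 18)
  sim <- simulate_genotypes(cfg)
  G <- compute_grm(sim$genotypes)
  tr <- simulate_traits(G, cfg)
  expect_true(all(tr$breeding_values == 0))
  expect_equal(stats::var(tr$phenotypes$trait1), 1, tolerance = 0.3)
})

test_that("with G = I the breeding-value variance matches h2 * Vp", {
  n <- 5000
  cfg <- sim_config(n_founders = n, n_snps = 10, h2 = 0.5,
                    phenotypic_var = 1, seed = 19)
  Gi <- grm(rep("f", n), sprintf("i%05d", 1:n), diag(n))
  tr <- simulate_traits(Gi, cfg)
  v <- stats::var(drop(tr$breeding_values))
  expect_gte(v, 0.45)
  expect_lte(v, 0.55)
})

test_that("two-trait breeding values realize the requested correlation", {
  # expected-relationship sib-block design, n = 2000
  n_fam <- 500; fam_size <- 4
  n <- n_fam * fam_size
  block <- matrix(0.5, fam_size, fam_size); diag(block) <- 1
  G <- kronecker(diag(n_fam), block)
  Gobj <- grm(rep("f", n), sprintf("i%05d", 1:n), G)
  cfg <- sim_config(n_founders = 10, n_snps = 10, h2 = c(0.5, 0.5),
                    genetic_corr = matrix(c(1, 0.8, 0.8, 1), 2),
                    residual_corr = diag(2), seed = 20)
  tr <- simulate_traits(Gobj, cfg)
  r <- stats::cor(tr$breeding_values[, 1], tr$breeding_values[, 2])
  expect_gte(r, 0.75)
  expect_lte(r, 0.85)
})

test_that("simulated data written to disk and re-read fits identically", {
  d <- sim_dataset(10, 5, 300, 0.5, seed = 22)
  dir <- tempfile(); dir.create(dir)
  gpath <- file.path(dir, "sim.tsv")
  ppath <- file.path(dir, "sim.phen")
  # regenerate the genotypes behind d to write them out
  sim <- simulate_genotypes(d$cfg)
  write_genotypes(sim$genotypes, gpath, "dosage_tsv")
  write_phen(d$phen, ppath)
  g2 <- compute_grm(read_genotypes(gpath, "dosage_tsv"))
  ph2 <- read_phen(ppath)
  f1 <- greml(trait1 ~ 1, data = d$phen, K = d$grm)
  f2 <- greml(trait1 ~ 1, data = ph2, K = g2)
  expect_equal(f1$components, f2$components, tolerance = 1e-10)
})

test_that("the wagyu preset is a valid six-trait configuration", {
  cfg <- wagyu_preset(n_families = 10, offspring_per_family = 4,
                      n_snps = 200, seed = 2)
  expect_s3_class(cfg, "sim_config")
  expect_length(cfg$h2, 6)
  expect_equal(attr(cfg, "trait_names"),
               c("CW", "REA", "RT", "SFT", "YI", "BMS"))
  expect_gte(min(eigen(cfg$genetic_corr, symmetric = TRUE,
                       only.values = TRUE)$values), 0)
  sim <- simulate_genotypes(cfg)
  G <- compute_grm(sim$genotypes)
  tr <- simulate_traits(G, cfg)
  expect_equal(names(tr$phenotypes)[3:8],
               c("CW", "REA", "RT", "SFT", "YI", "BMS"))
  # phenotypic variances on the configured scale (loose Monte-Carlo check)
  expect_equal(stats::var(tr$phenotypes$CW), 2195.34, tolerance = 0.5)
})
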