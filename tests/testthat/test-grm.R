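test_that("two-individual single-SNP GRM matches the hand evaluation", {
  g <- genotypes(c("f", "f"), c("a", "b"), matrix(c(0, 2), 2, 1), NULL)
  G <- compute_grm(g)
  # p = 0.5: off-diagonal (0-1)(2-1)/0.5 = -2; diagonals 1 + 1 = 2
  expect_equal(G$values, matrix(c(2, -2, -2, 2), 2, 2))
  expect_equal(G$pair_snp_counts, matrix(1, 2, 2))
})

test_that("all-monomorphic input is a degenerate-input error", {
  g <- genotypes(c("f", "f"), c("a", "b"),
                 matrix(c(2, 2, 0, 0), 2, 2), NULL)
  expect_error(compute_grm(g), "polymorphic")
})

test_that("GRM equals the brute-force double loop with missingness", {
  g <- rand_geno(12, 40, missing = 0.07, seed = 8)
  G <- compute_grm(g)
  o <- oracle_grm(g$dosage)
  expect_equal(G$values, o$values, tolerance = 1e-12)
  expect_equal(G$pair_snp_counts, o$counts)
})

test_that("a pair sharing no genotyped SNP is an undefined-entry error", {
  d <- matrix(c(1, NA, 0, NA, 1, NA,
                NA, 1, NA, 0, NA, 1), 2, 6, byrow = TRUE)
  d <- rbind(d, c(1, 0, 1, 0, 2, 1))
  g <- genotypes(rep("f", 3), c("a", "b", "c"), d, NULL)
  expect_error(compute_grm(g), "shares no")
})

test_that("founder-only GRM has mean diagonal near 1, off-diagonal near 0", {
  cfg <- sim_config(n_founders = 150, n_snps = 3000, seed = 12)
  sim <- simulate_genotypes(cfg)
  G <- compute_grm(sim$genotypes)
  expect_equal(mean(diag(G$values)), 1, tolerance = 0.02)
  off <- G$values[upper.tri(G$values)]
  expect_lt(abs(mean(off)), 0.01)
})

test_that("pruning is a no-op when no pair exceeds the ceiling", {
  set.seed(3)
  n <- 8
  A <- matrix(rnorm(n * n, 0, 0.05), n, n); A <- (A + t(A)) / 2
  A[1, 2] <- A[2, 1] <- 0.4
  diag(A) <- 1
  g <- grm(rep("f", n), sprintf("i%d", 1:n), A)
  pr <- prune_by_relatedness(g, 0.95)
  expect_equal(nrow(pr$retained), n)
  expect_equal(nrow(pr$removed), 0)
})

test_that("tie-breaking removes the later individual of an isolated pair", {
  # A,B related 0.5; everything else ~0; cutoff 0.25 -> drop B only
  A <- diag(4) * 0 + 0.01; diag(A) <- 1
  A[1, 2] <- A[2, 1] <- 0.5
  g <- grm(rep("f", 4), c("A", "B", "C", "D"), A)
  pr <- prune_by_relatedness(g, 0.25)
  expect_equal(pr$retained$IID, c("A", "C", "D"))
  expect_equal(pr$removed$IID, "B")
  # exhaustive check: every valid removal set must drop A or B; the best
  # retains 3 individuals, which the greedy result attains
  valid_sizes <- sapply(0:15, function(s) {
    keep <- which(bitwAnd(s, 2^(0:3)) > 0)
    if (all(c(1, 2) %in% keep)) return(NA_integer_)
    length(keep)
  })
  expect_equal(nrow(pr$retained), max(valid_sizes, na.rm = TRUE))
  expect_error(prune_by_relatedness(g, 0), "positive")
})

test_that("after pruning no retained pair exceeds the cutoff", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 15
    A <- matrix(rnorm(n * n, 0.05, 0.15), n, n); A <- (A + t(A)) / 2
    diag(A) <- 1
    g <- grm(rep("f", n), sprintf("i%02d", 1:n), A)
    for (cutoff in c(0.15, 0.3, 0.5)) {
      pr <- prune_by_relatedness(g, cutoff)
      ix <- pr$retained_index
      off <- A[ix, ix, drop = FALSE]
      diag(off) <- -Inf
      expect_lte(max(off), cutoff)
    }
  }
})

test_that("retained count is non-decreasing in the cutoff", {
  set.seed(29)
  n <- 20
  A <- matrix(rnorm(n * n, 0.1, 0.2), n, n); A <- (A + t(A)) / 2
  diag(A) <- 1
  g <- grm(rep("f", n), sprintf("i%02d", 1:n), A)
  counts <- sapply(seq(0.15, 0.95, by = 0.1), function(cf)
    nrow(prune_by_relatedness(g, cf)$retained))
  expect_true(all(diff(counts) >= 0))
})

test_that("low ceilings split simulated sib pairs", {
  cfg <- sim_config(n_founders = 40, n_families = 15,
                    offspring_per_family = 2, mating = "full_sib",
                    n_snps = 3000, seed = 31)
  sim <- simulate_genotypes(cfg)
  G <- compute_grm(sim$genotypes)
  pr <- prune_by_relatedness(G, 0.2)
  kept <- id_key(pr$retained$FID, pr$retained$IID)
  ped <- sim$pedigree
  fams <- split(seq_len(nrow(ped)), ped$FID)
  for (f in names(fams)) {
    if (f == "FND") next
    members <- id_key(ped$FID[fams[[f]]], ped$IID[fams[[f]]])
    expect_lte(sum(members %in% kept), 1)
  }
})

test_that("summarize_grm reports identity and planted-pair cases", {
  g <- grm(rep("f", 4), c("a", "b", "c", "d"), diag(4))
  s <- summarize_grm(g)
  expect_equal(s$off_diagonal$mean, 0)
  expect_equal(s$max_off_diagonal, 0)
  A <- diag(4); A[1, 3] <- A[3, 1] <- 0.5
  s2 <- summarize_grm(grm(rep("f", 4), c("a", "b", "c", "d"), A))
  expect_equal(s2$max_off_diagonal, 0.5)
  expect_equal(s2$diagonal$mean, 1)
})
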