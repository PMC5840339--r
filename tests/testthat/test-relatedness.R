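test_that("genotype matrix enumerates presence/absence and drops constants", {
  csA <- setOnlyCallset("A", normal = c("k1", "k2"),
                        tumor = c("k1", "k2", "k3"),
                        culture = c("k1", "k3"))
  csB <- setOnlyCallset("B", normal = c("k1", "k4"),
                        tumor = c("k1", "k4"),
                        culture = c("k1", "k4"))
  m <- buildGenotypeMatrix(list(csA, csB), dropConstant = FALSE)
  expect_equal(nrow(m), 6L)
  expect_equal(colnames(m), sort(c("k1", "k2", "k3", "k4")))
  expect_equal(m["A:Tumor", ], c(k1 = 1, k2 = 1, k3 = 1, k4 = 0))
  expect_equal(m["B:Culture", ], c(k1 = 1, k2 = 0, k3 = 0, k4 = 1))
  # k1 is present in every sample: constant, dropped by default
  m2 <- buildGenotypeMatrix(list(csA, csB))
  expect_false("k1" %in% colnames(m2))
  expect_equal(ncol(m2), 3L)
  expect_error(buildGenotypeMatrix(list()), "at least 2")
})

test_that("PCA agrees with a covariance eigendecomposition oracle", {
  set.seed(11)
  m <- matrix(rbinom(24, 1, 0.5), nrow = 6, ncol = 4,
              dimnames = list(paste0("s", 1:6), paste0("v", 1:4)))
  k <- 3L
  res <- runPca(m, k)
  # independent oracle: eigenvectors of the covariance matrix
  cm <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(cm), symmetric = TRUE)
  oracleCoords <- cm %*% eig$vectors[, seq_len(k)]
  for (j in seq_len(k)) {
    a <- res@coordinates[, j]
    b <- oracleCoords[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  expect_equal(res@explainedVariance,
               (eig$values / sum(eig$values))[seq_len(k)],
               tolerance = 1e-8)
})

test_that("full-rank PCA reconstructs the centered matrix", {
  set.seed(12)
  m <- matrix(rbinom(40, 1, 0.4), nrow = 5, ncol = 8)
  rownames(m) <- paste0("s", 1:5)
  k <- min(nrow(m) - 1L, ncol(m))
  res <- runPca(m, k)
  centered <- scale(m, center = res@center, scale = FALSE)
  recon <- res@coordinates %*% t(res@rotation)
  expect_equal(unname(recon), unname(centered)[, ], tolerance = 1e-10)
})

test_that("identical rows collapse to the origin; k is range-checked", {
  m <- matrix(1, nrow = 4, ncol = 3,
              dimnames = list(paste0("s", 1:4), paste0("v", 1:3)))
  res <- runPca(m, 2)
  expect_true(all(abs(res@coordinates) < 1e-12))
  expect_equal(res@explainedVariance, c(0, 0))
  expect_error(runPca(m, 5), "k must lie")
})

test_that("PCA coordinates are invariant (up to sign) to row order", {
  set.seed(13)
  m <- matrix(rbinom(60, 1, 0.5), nrow = 6, ncol = 10)
  rownames(m) <- paste0("s", 1:6)
  r1 <- runPca(m, 2)
  perm <- c(4, 2, 6, 1, 3, 5)
  r2 <- runPca(m[perm, ], 2)
  expect_equal(r1@explainedVariance, r2@explainedVariance,
               tolerance = 1e-10)
  for (j in 1:2) {
    a <- r1@coordinates[rownames(m), j]
    b <- r2@coordinates[rownames(m), j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("triplet grouping score separates tight triplets from noise", {
  # two identical triplets at distinct points: within-distance 0
  coords <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  rownames(coords) <- c("A:Normal", "A:Tumor", "A:Culture",
                        "B:Normal", "B:Tumor", "B:Culture")
  res <- methods::new("PcaResult", coordinates = coords,
                      explainedVariance = c(1, 0),
                      center = c(0, 0), rotation = diag(2))
  expect_equal(tripletGroupingScore(res), 0)
  expect_error(tripletGroupingScore(res, patients = rep("A", 6)),
               "at least 2 patients")
  # random label permutations: ratio approaches 1 in expectation
  set.seed(14)
  coords2 <- matrix(rnorm(36), 18, 2)
  rownames(coords2) <- paste0("s", 1:18)
  res2 <- methods::new("PcaResult", coordinates = coords2,
                       explainedVariance = c(0.5, 0.3),
                       center = c(0, 0), rotation = diag(2))
  ratios <- replicate(300, {
    labels <- sample(rep(paste0("P", 1:6), each = 3))
    tripletGroupingScore(res2, patients = labels)
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("trio cohorts dominated by germline background group by patient", {
  cfg <- TrioSimConfig(nPatients = 3, germlineSnvCount = 300, seed = 41)
  sim <- simulateTrioCohort(cfg, tempfile())
  cohort <- readTrioCohort(sim$vcf)
  m <- buildGenotypeMatrix(cohort)
  pca <- runPca(m, 2)
  expect_lt(tripletGroupingScore(pca), 1)
})
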