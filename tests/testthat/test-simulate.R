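test_that("expectedVaf follows the purity/CCF dilution model", {
  expect_equal(expectedVaf(1, 1), 0.5)
  expect_equal(expectedVaf(1, 0.5), 0.25)
  expect_equal(expectedVaf(0.4, 0.8), 0.16)
  # closed form, cross-checked against an independent hand computation:
  # m*ccf*f / (2(1-f) + Ct*f)
  ccf <- c(0.2, 0.7, 1); f <- c(0.9, 0.4, 0.6)
  expect_equal(expectedVaf(ccf, f), 1 * ccf * f / (2 * (1 - f) + 2 * f))
  # with copy number and multiplicity
  expect_equal(expectedVaf(1, 0.5, multiplicity = 2, totalCopyNumber = 4),
               2 * 0.5 / (2 * 0.5 + 4 * 0.5))
})

test_that("expectedVaf rejects out-of-range arguments", {
  expect_error(expectedVaf(0, 1), "ccf")
  expect_error(expectedVaf(1.2, 1), "ccf")
  expect_error(expectedVaf(1, -0.1), "cancerCellFraction")
  expect_error(expectedVaf(1, 1, multiplicity = 3, totalCopyNumber = 2),
               "multiplicity")
  expect_error(expectedVaf(1, 1, totalCopyNumber = 0), "totalCopyNumber")
})

test_that("increasing culture contamination strictly decreases somatic VAF", {
  cnf <- seq(0, 0.9, by = 0.1)
  v <- expectedVaf(0.8, 1 - cnf)
  expect_true(all(diff(v) < 0))
})

test_that("degenerate simulator configs are rejected with the field named", {
  expect_error(TrioSimConfig(nPatients = 1, seed = 1, meanDepth = 0),
               "meanDepth")
  expect_error(TrioSimConfig(nPatients = 0, seed = 1), "nPatients")
  expect_error(TrioSimConfig(nPatients = 1, seed = 1, tumorPurity = 0),
               "tumorPurity")
  expect_error(TrioSimConfig(nPatients = 1, seed = 1,
                             cultureNormalFraction = 1),
               "cultureNormalFraction")
  expect_error(TrioSimConfig(nPatients = 1, seed = 1), NA)
  expect_error(TrioSimConfig(nPatients = 1), "seed")
  noTruncal <- data.frame(clone_id = "c1", ccf = 0.5,
                          n_private_mutations = 5L,
                          present_in_tumor = TRUE,
                          present_in_culture = TRUE)
  expect_error(TrioSimConfig(nPatients = 1, clones = noTruncal, seed = 1),
               "truncal")
})

test_that("the same config and seed produce byte-identical output", {
  cfg <- TrioSimConfig(nPatients = 2, germlineSnvCount = 60, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  simulateTrioCohort(cfg, d1)
  simulateTrioCohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("truth sidecar round-trips losslessly and counts mutations", {
  cfg <- TrioSimConfig(nPatients = 1, germlineSnvCount = 40,
                       clones = defaultCloneScenarios(1), seed = 5)
  sim <- simulateTrioCohort(cfg, tempfile())
  expect_equal(nrow(sim$truth), 40 + 100 + 60)
  back <- readTruth(sim$truthPath)
  expect_equal(back, sim$truth, ignore_attr = TRUE)
  # empty truth -> header-only file
  p <- tempfile()
  writeTruth(sim$truth[0, ], p)
  expect_length(readLines(p), 1L)
  expect_equal(nrow(readTruth(p)), 0L)
})

test_that("germline truth VAF is 0.5 everywhere and each site appears once", {
  cfg <- TrioSimConfig(nPatients = 3, germlineSnvCount = 50, seed = 21)
  sim <- simulateTrioCohort(cfg, tempfile())
  germ <- sim$truth[sim$truth$origin == "germline", ]
  expect_true(all(germ$vaf_normal == 0.5 & germ$vaf_tumor == 0.5 &
                    germ$vaf_culture == 0.5))
  expect_false(anyDuplicated(paste(sim$truth$patient, sim$truth$key)) > 0)
})

test_that("high-depth noiseless simulation concentrates VAFs at truth", {
  clones <- data.frame(clone_id = "truncal", ccf = 1,
                       n_private_mutations = 150L,
                       present_in_tumor = TRUE, present_in_culture = TRUE)
  cfg <- TrioSimConfig(nPatients = 1, germlineSnvCount = 150,
                       clones = clones, tumorPurity = 1,
                       cultureNormalFraction = 0,
                       meanDepth = 1000, depthModel = "fixed",
                       lowQualityReadRate = 0, seed = 31)
  sim <- simulateTrioCohort(cfg, tempfile())
  cs <- readTrioVcf(sim$vcf[[1]])
  mc <- S4Vectors::mcols(sites(cs))
  som <- siteKeys(cs) %in% sim$truth$key[sim$truth$origin != "germline"]
  for (cond in c("Tumor", "Culture")) {
    vaf <- (mc[[paste0("qAltFwd_", cond)]] + mc[[paste0("qAltRev_", cond)]]) /
      mc[[paste0("rawDepth_", cond)]]
    # somatic truncal sites: all within 0.05 of 0.5 (binomial concentration)
    expect_true(all(abs(vaf[som] - 0.5) < 0.05))
  }
  # germline empirical VAF: mean within 3 binomial standard errors of 0.5
  se <- sqrt(0.25 / 1000) / sqrt(sum(!som))
  for (cond in c("Normal", "Tumor", "Culture")) {
    vaf <- (mc[[paste0("qAltFwd_", cond)]] + mc[[paste0("qAltRev_", cond)]]) /
      mc[[paste0("rawDepth_", cond)]]
    expect_lt(abs(mean(vaf[!som]) - 0.5), 3 * se)
  }
})

test_that("clones dropped from culture have zero alt reads there", {
  clones <- data.frame(
    clone_id = c("truncal", "dropped"), ccf = c(1, 0.5),
    n_private_mutations = c(20L, 30L),
    present_in_tumor = TRUE, present_in_culture = c(TRUE, FALSE))
  cfg <- TrioSimConfig(nPatients = 1, germlineSnvCount = 10,
                       clones = clones, seed = 8)
  sim <- simulateTrioCohort(cfg, tempfile())
  cs <- readTrioVcf(sim$vcf[[1]])
  dropKeys <- sim$truth$key[sim$truth$origin == "dropped"]
  mc <- S4Vectors::mcols(sites(cs))
  idx <- match(dropKeys, siteKeys(cs))
  expect_true(all(mc$qAltFwd_Culture[idx] + mc$qAltRev_Culture[idx] == 0))
  expect_true(all(sim$truth$vaf_culture[sim$truth$origin == "dropped"] == 0))
})

test_that("strand and quality counts are conserved against raw depth", {
  cfg <- TrioSimConfig(nPatients = 1, germlineSnvCount = 80,
                       lowQualityReadRate = 0.2, strandBias = 0.3,
                       seed = 13)
  sim <- simulateTrioCohort(cfg, tempfile())
  cs <- readTrioVcf(sim$vcf[[1]])
  mc <- S4Vectors::mcols(sites(cs))
  for (cond in c("Normal", "Tumor", "Culture")) {
    qsum <- mc[[paste0("qRefFwd_", cond)]] + mc[[paste0("qRefRev_", cond)]] +
      mc[[paste0("qAltFwd_", cond)]] + mc[[paste0("qAltRev_", cond)]]
    expect_true(all(qsum <= mc[[paste0("rawDepth_", cond)]]))
    expect_true(all(qsum >= 0))
  }
  # with a zero low-quality rate, filtered depth equals raw depth exactly
  cfg0 <- TrioSimConfig(nPatients = 1, germlineSnvCount = 40,
                        lowQualityReadRate = 0, seed = 14)
  sim0 <- simulateTrioCohort(cfg0, tempfile())
  cs0 <- readTrioVcf(sim0$vcf[[1]])
  mc0 <- S4Vectors::mcols(sites(cs0))
  qsum0 <- mc0$qRefFwd_Tumor + mc0$qRefRev_Tumor +
    mc0$qAltFwd_Tumor + mc0$qAltRev_Tumor
  expect_identical(as.integer(qsum0), as.integer(mc0$rawDepth_Tumor))
})
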