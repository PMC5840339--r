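test_that("Jaccard similarity matches enumeration and flags empty input", {
  expect_equal(jaccardSimilarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccardSimilarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccardSimilarity(c("k1", "k2", "k3"),
                                 c("k2", "k3", "k4")), 0.5)
  expect_equal(jaccardSimilarity(character(), c("a")), 0)
  expect_warning(r <- jaccardSimilarity(character(), character()),
                 "undefined")
  expect_true(is.na(r))
})

test_that("shared percentage is asymmetric and rejects empty queries", {
  expect_equal(sharedPercentage(c("a", "b"), c("a", "b", "c")), 100)
  expect_equal(sharedPercentage(paste0("k", 1:4), paste0("k", 1:3)), 75)
  expect_equal(sharedPercentage(c("a"), c("b")), 0)
  expect_error(sharedPercentage(character(), c("a")), "empty query")
})

test_that("Venn counts partition the two sets", {
  expect_equal(vennCounts(c("a", "b"), c("a", "b")),
               c(only_a = 0L, both = 2L, only_b = 0L))
  expect_equal(vennCounts(c("a"), c("b", "c")),
               c(only_a = 1L, both = 0L, only_b = 2L))
  expect_equal(vennCounts(c("k1", "k2", "k3"), c("k2", "k3", "k4")),
               c(only_a = 1L, both = 2L, only_b = 1L))
})

test_that("set identities hold over random set pairs", {
  set.seed(404)
  u <- keyUniverse(30)
  for (i in 1:200) {
    a <- sample(u, sample(1:20, 1))
    b <- sample(u, sample(1:20, 1))
    j <- jaccardSimilarity(a, b)
    expect_identical(j, jaccardSimilarity(b, a))
    expect_true(j >= 0 && j <= 1)
    fa <- sharedPercentage(a, b) / 100
    fb <- sharedPercentage(b, a) / 100
    expect_lte(j, min(fa, fb) + 1e-12)
    v <- vennCounts(a, b)
    expect_equal(unname(v["only_a"] + v["both"]), length(unique(a)))
    expect_equal(unname(v["only_b"] + v["both"]), length(unique(b)))
  }
})

test_that("a BED panel restricts sets by half-open containment", {
  bed <- tempfile(fileext = ".bed")
  # interval [99, 100) in BED covers exactly 1-based position 100
  writeLines(c("1\t99\t100\tGENE1", "2\t1000\t2000\tGENE2"), bed)
  panel <- readGenePanel(bed)
  expect_equal(S4Vectors::mcols(panel)$gene, c("GENE1", "GENE2"))
  s <- c("1:100_A/G",    # on the single covered base -> kept
         "1:101_A/G",    # one past the half-open end -> dropped
         "2:1500_C/T",   # inside GENE2 -> kept
         "2:2001_C/T")   # outside -> dropped
  expect_setequal(restrictToPanel(s, panel), c("1:100_A/G", "2:1500_C/T"))
  # subset of input, idempotent, empty panel -> empty set
  r <- restrictToPanel(s, panel)
  expect_true(all(r %in% s))
  expect_identical(restrictToPanel(r, panel), r)
  expect_length(restrictToPanel(s, panel[0]), 0L)
})

test_that("panel restriction enumerates a constructed 10-site fixture", {
  bed <- tempfile(fileext = ".bed")
  writeLines("7\t100\t200\tG7", bed)
  panel <- readGenePanel(bed)
  inside <- sprintf("7:%d_A/G", c(101, 150, 177, 200))
  outside <- c(sprintf("7:%d_A/G", c(100, 201, 999)),
               sprintf("8:%d_A/G", c(101, 150, 177)))
  expect_setequal(restrictToPanel(c(inside, outside), panel), inside)
})

test_that("chr-prefix dialects are normalized, mismatches reported", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t1000\tGENE1", bed)
  expect_message(panel <- readGenePanel(bed), "chr")
  expect_equal(GenomeInfoDb::seqlevels(panel), "1")
  expect_setequal(restrictToPanel(c("1:50_A/G", "1:2000_A/G"), panel),
                  "1:50_A/G")
  # keys on chromosomes entirely absent from the panel
  expect_error(restrictToPanel("9:50_A/G", panel), "chromosome")
})

test_that("TSV panels load with 0-based half-open intervals", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tchrom\tstart\tend", "G1\t3\t99\t100"), tsv)
  panel <- readGenePanel(tsv)
  expect_equal(GenomicRanges::start(panel), 100L)
  expect_equal(GenomicRanges::end(panel), 100L)
  expect_setequal(restrictToPanel(c("3:100_A/G", "3:101_A/G"), panel),
                  "3:100_A/G")
})

test_that("cohort table reports per-patient similarity and pooled shares", {
  # two patients with unequal culture set sizes distinguish pooled
  # aggregation (sum of intersections / sum of sizes) from the mean
  csA <- setOnlyCallset("A",
                        normal = paste0("k", 1:2),
                        tumor = paste0("k", 1:8),
                        culture = paste0("k", 1:8))      # 8/8 with tumor
  csB <- setOnlyCallset("B",
                        normal = paste0("q", 1),
                        tumor = paste0("q", 1),
                        culture = paste0("q", 1:2))      # 1/2 with tumor
  tab <- cohortSimilarityTable(list(csA, csB))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$shared_pct_culture_in_tumor, c(100, 50))
  agg <- attr(tab, "aggregate")
  expect_equal(agg$pooled_shared_pct_culture_in_tumor, 100 * 9 / 10)
  expect_equal(agg$mean_shared_pct_culture_in_tumor, 75)
  expect_equal(agg$pooled_shared_pct_culture_in_normal, 100 * 3 / 10)
  # single-patient cohort -> one record
  expect_equal(nrow(cohortSimilarityTable(list(csA))), 1L)
  # empty culture set -> error naming the patient
  csBad <- setOnlyCallset("PBAD", tumor = "k1", normal = "k1")
  expect_error(cohortSimilarityTable(list(csBad)), "PBAD")
})

test_that("cohort Venn table preserves per-patient cardinalities", {
  cs <- setOnlyCallset("A", normal = character(),
                       tumor = c("k1", "k2", "k3"),
                       culture = c("k2", "k3", "k4"))
  v <- cohortVennTable(list(cs))
  expect_equal(v$only_culture, 1L)
  expect_equal(v$both, 2L)
  expect_equal(v$only_tumor, 1L)
})
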