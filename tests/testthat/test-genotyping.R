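test_that("genotype calls follow the coverage and allele-fraction thresholds", {
  # >95% P1 reads -> homozygous reference parent
  expect_equal(call_genotypes(48, 2), "HOM_P1")
  # depth 5 is not strictly greater than 5X
  expect_equal(call_genotypes(3, 2), "NO_CALL")
  # 70% P2 does not exceed the 75% cutoff; fractions sit in the het ranges
  expect_equal(call_genotypes(30, 70), "HET")
  # pure parental reads
  expect_equal(call_genotypes(100, 0), "HOM_P1")
  expect_equal(call_genotypes(0, 100), "HOM_P2")
  # boundary: exactly 95% P1 is not >95%, falls in the het range
  expect_equal(call_genotypes(95, 5), "HET")
  # non-parental reads push the marker below the 2/3 parental fraction
  expect_equal(call_genotypes(10, 10, n_other = 11), "NO_CALL")
  expect_equal(call_genotypes(10, 10, n_other = 9), "HET")
  expect_error(call_genotypes(-1, 5), "non-negative")
})

test_that("exactly one label fires over a grid of depth configurations", {
  grid <- expand.grid(n_p1 = 0:40, n_p2 = 0:40)
  calls <- call_genotypes(grid$n_p1, grid$n_p2)
  expect_true(all(calls %in% GENOTYPES))
  # deep re-check against the scalar definition
  th <- genotyping_thresholds()
  manual <- mapply(function(a, b) {
    d <- a + b
    if (d <= th$min_depth_exclusive) return("NO_CALL")
    f1 <- a / d
    if (f1 > th$p1_hom_min) return("HOM_P1")
    if (1 - f1 > th$p2_hom_min) return("HOM_P2")
    "HET"
  }, grid$n_p1, grid$n_p2)
  expect_identical(calls, unname(manual))
})

test_that("perfect reads at high depth recover simulated genotypes exactly", {
  cfg <- sim_setup(lambda_co = 1, lambda_nco = 3)
  cfg$error_rate <- 0
  cfg$depth_mean <- 100
  map <- make_marker_map(cfg, seed = 11)
  truth <- simulate_rtg_pair(map, cfg, seed = 12)$mother
  reads <- sample_reads(truth, cfg, seed = 13)
  called <- call_genotypes(reads$n_p1, reads$n_p2)
  ok <- called != "NO_CALL"
  expect_gt(mean(ok), 0.99)
  expect_identical(called[ok], truth[ok])
})

test_that("short homozygous runs in heterozygous context are reassigned", {
  expect_equal(filter_short_runs(c("HET", "HOM_P2", "HET")),
               rep("HET", 3), ignore_attr = TRUE)
  v <- c("HET", rep("HOM_P2", 3), "HET")
  expect_equal(filter_short_runs(v), v, ignore_attr = TRUE)
  # runs touching the chromosome end need the minimum length too
  expect_equal(filter_short_runs(c("HOM_P1", "HOM_P1", "HET", "HET")),
               rep("HET", 4), ignore_attr = TRUE)
  # NO_CALL markers are transparent and preserved
  v <- c("HET", "HOM_P2", "NO_CALL", "HOM_P2", "HET")
  expect_equal(filter_short_runs(v),
               c("HET", "HET", "NO_CALL", "HET", "HET"), ignore_attr = TRUE)
  v <- c("HET", "HOM_P2", "NO_CALL", "HOM_P2", "HOM_P2", "HET")
  expect_equal(filter_short_runs(v), v, ignore_attr = TRUE)
  # a short hom run bordered by the other homozygote is kept (asymmetric rule)
  v <- c(rep("HOM_P1", 4), "HOM_P2", "HOM_P2", rep("HOM_P1", 4))
  expect_equal(filter_short_runs(v), v, ignore_attr = TRUE)
  # symmetric option collapses short HET islands in homozygous context
  v <- c(rep("HOM_P1", 4), "HET", rep("HOM_P1", 4))
  expect_equal(filter_short_runs(v, symmetric = TRUE),
               rep("HOM_P1", 9), ignore_attr = TRUE)
  expect_equal(filter_short_runs(character(0)), character(0))
})

test_that("the short-run filter is idempotent and never creates hom runs", {
  set.seed(20)
  for (i in 1:50) {
    v <- sample(GENOTYPES, 60, replace = TRUE,
                prob = c(0.15, 0.15, 0.6, 0.1))
    f1 <- filter_short_runs(v)
    f2 <- filter_short_runs(f1)
    expect_equal(unclass(f2), unclass(f1), ignore_attr = TRUE)
    # no marker became homozygous
    expect_false(any(f1 %in% c("HOM_P1", "HOM_P2") &
                       !(v %in% c("HOM_P1", "HOM_P2"))))
  }
})

test_that("coverage windows flag depth ratios outside the CNV band", {
  # c1 dominates the genome so the median window depth tracks it
  pos1 <- seq(1, 1000000, by = 500)
  pos <- seq(1, 100000, by = 500)
  d <- rbind(data.frame(chrom = "c1", pos = pos1, depth = 50),
             data.frame(chrom = "c2", pos = pos, depth = 50))
  w <- coverage_windows(d)
  expect_true(all(abs(w$ratio - 1) < 1e-12))
  expect_false(any(w$flagged))
  # one chromosome at half depth: heterozygous-deletion-like, flagged at 0.5
  d2 <- d
  d2$depth[d2$chrom == "c2"] <- 25
  w2 <- coverage_windows(d2)
  expect_true(all(w2$flagged[w2$chrom == "c2"]))
  expect_equal(unique(w2$ratio[w2$chrom == "c2"]), 0.5)
  # a 1.5x segment is duplication-like
  d3 <- d
  d3$depth[d3$chrom == "c2" & d3$pos <= 20000] <- 75
  w3 <- coverage_windows(d3)
  flagged <- w3[w3$flagged, ]
  expect_true(all(flagged$chrom == "c2" & flagged$end <= 20000))
  expect_equal(unique(flagged$ratio), 1.5)
  expect_error(coverage_windows(data.frame()), "empty")
})

test_that("marker QC keeps exactly the P1/P2/HET parental triple", {
  combos <- expand.grid(p1 = GENOTYPES, p2 = GENOTYPES, hy = GENOTYPES,
                        stringsAsFactors = FALSE)
  qc <- qc_marker_set(combos$p1, combos$p2, combos$hy)
  kept <- combos[qc$keep, ]
  expect_equal(nrow(kept), 1)
  expect_equal(unlist(kept, use.names = FALSE), c("HOM_P1", "HOM_P2", "HET"))
  expect_equal(qc$reason[combos$p1 == "HOM_P1" & combos$p2 == "HOM_P1" &
                           combos$hy == "HET"], "shared_allele")
  expect_equal(qc$reason[combos$p1 == "HOM_P1" & combos$p2 == "HOM_P2" &
                           combos$hy == "HOM_P1"], "hybrid_not_heterozygous")
  expect_error(qc_marker_set("HET", c("HET", "HET"), "HET"), "equal length")
})

test_that("genotype matrices and allele depths round-trip through text files", {
  map <- tiny_map(4)
  geno <- cbind(m = c(rep("HET", 3), "HOM_P1", rep("HET", 2), "NO_CALL", "HET"),
                d = c(rep("HET", 3), "HOM_P2", rep("HET", 4)))
  f <- tempfile(fileext = ".tsv")
  write_genotype_matrix(geno, map, f)
  back <- read_genotype_matrix(f)
  expect_identical(unname(back$geno), unname(geno))
  expect_equal(back$pos, map$markers$pos)

  ad <- data.frame(chrom = map$markers$chrom, pos = map$markers$pos,
                   n_p1 = 10L, n_p2 = 12L)
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(ad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- read_allele_depths(f2)
  expect_equal(d$n_p1, rep(10L, 8))
  expect_equal(d$n_other, rep(0L, 8))
})
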