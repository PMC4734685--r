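test_that("segregation patterns cover the full 4x4 call table", {
  expect_equal(classify_segregation("HET", "HET"), "TWO_TWO_HET")
  expect_equal(classify_segregation("HOM_P1", "HOM_P2"), "TWO_TWO_HOM")
  expect_equal(classify_segregation("HOM_P2", "HOM_P1"), "TWO_TWO_HOM")
  expect_equal(classify_segregation("HET", "HOM_P1"), "THREE_ONE")
  expect_equal(classify_segregation("HOM_P2", "HET"), "THREE_ONE")
  expect_equal(classify_segregation("HOM_P2", "HOM_P2"), "FOUR_ZERO")
  expect_true(is.na(classify_segregation("NO_CALL", "HET")))
  combos <- expand.grid(m = GENOTYPES, d = GENOTYPES, stringsAsFactors = FALSE)
  pat <- classify_segregation(combos$m, combos$d)
  expect_true(all(is.na(pat) | pat %in% SEG_PATTERNS))
  expect_equal(sum(is.na(pat)), 7)  # any NO_CALL
})

test_that("mirrored homozygous runs assemble into one reciprocal tract", {
  map <- tiny_map(10)  # 20 markers, 10 per arm
  mother <- rep("HET", 20)
  daughter <- rep("HET", 20)
  mother[15:20] <- "HOM_P1"   # right arm, distal half
  daughter[15:20] <- "HOM_P2"
  pt <- classify_tract_position(assemble_pair_tracts(mother, daughter, map), map)
  tr <- pt$tracts
  expect_equal(nrow(tr), 1)
  expect_equal(tr$reciprocity, "rLOH")
  expect_equal(tr$n_markers, 6)
  expect_equal(tr$position, "terminal")
  expect_equal(tr$mother_gt, "HOM_P1")
  # complementarity at every member marker
  expect_true(all(mother[tr$start_idx:tr$end_idx] == "HOM_P1" &
                    daughter[tr$start_idx:tr$end_idx] == "HOM_P2"))
})

test_that("an isolated 3:1 run becomes a non-reciprocal tract", {
  map <- tiny_map(10)
  mother <- rep("HET", 20); daughter <- rep("HET", 20)
  mother[4:6] <- "HOM_P2"  # left arm, interior
  pt <- classify_tract_position(assemble_pair_tracts(mother, daughter, map), map)
  tr <- pt$tracts
  expect_equal(nrow(tr), 1)
  expect_equal(tr$reciprocity, "nrLOH")
  expect_equal(tr$hom_strain, "M")
  expect_equal(tr$position, "interstitial")
  expect_equal(tr$n_markers, 3)
})

test_that("an all-heterozygous pair yields no tracts", {
  map <- tiny_map(5)
  pt <- assemble_pair_tracts(rep("HET", 10), rep("HET", 10), map)
  expect_equal(nrow(pt$tracts), 0)
})

test_that("interleaved 3:1 markers do not split a reciprocal tract", {
  map <- tiny_map(10)
  mother <- rep("HET", 20); daughter <- rep("HET", 20)
  mother[13:20] <- "HOM_P1"; daughter[13:20] <- "HOM_P2"
  # one marker inside the rLOH is 3:1 (conversion inside the tract)
  daughter[16] <- "HET"
  pt <- classify_tract_position(assemble_pair_tracts(mother, daughter, map), map)
  pt <- classify_nrloh(pt, map)
  tr <- pt$tracts
  r <- tr[tr$reciprocity == "rLOH", ]
  n <- tr[tr$reciprocity == "nrLOH", ]
  expect_equal(nrow(r), 1)  # still a single tract spanning 13..20
  expect_equal(r$start_idx, 13)
  expect_equal(r$end_idx, 20)
  expect_equal(r$n_markers, 7)  # member markers exclude the 3:1 site
  expect_equal(nrow(n), 1)
  expect_equal(n$kind, "NCO")  # conversion inside an rLOH region is an NCO
})

test_that("4:0 markers are set aside, never included in tracts", {
  map <- tiny_map(10)
  mother <- rep("HET", 20); daughter <- rep("HET", 20)
  mother[4:7] <- "HOM_P1"; daughter[4:7] <- "HOM_P1"
  pt <- assemble_pair_tracts(mother, daughter, map)
  expect_equal(nrow(pt$tracts), 0)
  expect_equal(pt$four_zero, 4:7)
})

test_that("excluded (CNV) markers are transparent to tract assembly", {
  map <- tiny_map(10)
  mother <- rep("HET", 20); daughter <- rep("HET", 20)
  mother[14:20] <- "HOM_P1"; daughter[14:20] <- "HOM_P2"
  excl <- rep(FALSE, 20); excl[17] <- TRUE
  pt <- assemble_pair_tracts(mother, daughter, map, exclude = excl)
  tr <- pt$tracts
  expect_equal(nrow(tr), 1)
  expect_equal(tr$n_markers, 6)
})

test_that("every retained marker belongs to exactly one class", {
  cfg <- sim_setup(lambda_co = 2, lambda_nco = 6, gc_with_co = 0.81)
  map <- make_marker_map(cfg, seed = 31)
  for (s in 1:5) {
    pair <- simulate_rtg_pair(map, cfg, seed = 40 + s)
    pt <- assemble_pair_tracts(pair$mother, pair$daughter, map)
    tr <- pt$tracts
    membership <- integer(n_markers(map))
    for (i in seq_len(nrow(tr))) {
      idx <- tr$start_idx[i]:tr$end_idx[i]
      lab <- if (tr$reciprocity[i] == "rLOH") "TWO_TWO_HOM" else "THREE_ONE"
      idx <- idx[pt$pattern[idx] %in% lab & pt$retained[idx]]
      membership[idx] <- membership[idx] + 1L
    }
    hom_retained <- which(pt$retained & pt$pattern %in% c("TWO_TWO_HOM", "THREE_ONE"))
    expect_true(all(membership[hom_retained] == 1L))
    het_retained <- which(pt$retained & pt$pattern == "TWO_TWO_HET")
    expect_true(all(membership[het_retained] == 0L))
    # complementarity inside rLOH tracts
    for (i in which(tr$reciprocity == "rLOH")) {
      idx <- tr$start_idx[i]:tr$end_idx[i]
      idx <- idx[pt$pattern[idx] == "TWO_TWO_HOM"]
      expect_true(all(pair$mother[idx] != pair$daughter[idx]))
    }
  }
})

test_that("whole-arm homozygosity is terminal; flanked tracts interstitial", {
  map <- tiny_map(10)
  mother <- rep("HET", 20); daughter <- rep("HET", 20)
  mother[1:10] <- "HOM_P2"; daughter[1:10] <- "HOM_P1"  # entire left arm
  pt <- classify_tract_position(assemble_pair_tracts(mother, daughter, map), map)
  expect_equal(pt$tracts$position, "terminal")

  mother2 <- rep("HET", 20); daughter2 <- rep("HET", 20)
  mother2[4:7] <- "HOM_P2"; daughter2[4:7] <- "HOM_P1"
  pt2 <- classify_tract_position(assemble_pair_tracts(mother2, daughter2, map), map)
  expect_equal(pt2$tracts$position, "interstitial")
})

test_that("LOH summaries report homozygous fractions and tract stats", {
  expect_equal(summarize_loh(rep("HET", 50))$frac_hom, 0)
  # ~100 kb homozygous on a 1 Mb genome -> fraction about 0.1 in each strain
  ci <- data.frame(chrom = "c1", length = 1e6, cen_start = 499000,
                   cen_end = 501000)
  cfg <- sim_config(chromosomes = ci, marker_spacing = 1000)
  map <- make_marker_map(cfg, seed = 77)
  mother <- rep("HET", n_markers(map)); daughter <- mother
  in_tract <- map$markers$pos > 900000  # distal 100 kb
  mother[in_tract] <- "HOM_P1"; daughter[in_tract] <- "HOM_P2"
  s <- summarize_loh(cbind(m = mother, d = daughter))
  expect_equal(s$frac_hom, rep(mean(in_tract), 2))
  expect_equal(mean(in_tract), 0.1, tolerance = 0.1)
  expect_equal(s$frac_p1, c(s$frac_hom[1], 0))
  # tract count / marker totals
  tr <- data.frame(reciprocity = c("nrLOH", "nrLOH"), span_bp = c(1000, 2000),
                   n_markers = c(10, 20))
  ts <- attr(summarize_loh(mother, tr), "tract_summary")
  expect_equal(ts$n, 2)
  expect_equal(ts$total_markers, 30)
})

test_that("BED export uses 0-based half-open coordinates", {
  map <- tiny_map(10)
  mother <- rep("HET", 20); daughter <- rep("HET", 20)
  mother[15:20] <- "HOM_P1"; daughter[15:20] <- "HOM_P2"
  pt <- classify_tract_position(assemble_pair_tracts(mother, daughter, map), map)
  bed <- tracts_to_bed(pt$tracts)
  expect_equal(bed$start, pt$tracts$start_pos - 1L)
  expect_equal(bed$end, pt$tracts$end_pos)
  expect_match(bed$name, "rLOH\\|terminal\\|HOM_P1")
  f <- tempfile(fileext = ".bed")
  tracts_to_bed(pt$tracts, f)
  expect_equal(nrow(utils::read.table(f, sep = "\t")), 1)
})
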