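test_that("pseudo-tetrad construction and reconstruction are inverse", {
  mother <- c("HET", "HOM_P1", "HOM_P2", "HET", "NO_CALL")
  daughter <- c("HET", "HOM_P2", "HOM_P1", "HOM_P1", "HET")
  tet <- build_pseudotetrad(mother, daughter)
  expect_equal(tet$marker_idx, 1:4)  # NO_CALL dropped pairwise
  # all-HET marker: chromatids (P1, P2, P1, P2)
  expect_equal(unname(tet$haplotypes[, 1]), c("P1", "P2", "P1", "P2"))
  # homozygous markers: both chromatids identical
  expect_equal(unname(tet$haplotypes[, 2]), c("P1", "P1", "P2", "P2"))
  # merging chromatids 1+2 re-yields the mother's calls
  expect_equal(merge_chromatids(tet$haplotypes[1, ], tet$haplotypes[2, ]),
               mother[1:4])
  expect_equal(merge_chromatids(tet$haplotypes[3, ], tet$haplotypes[4, ]),
               daughter[1:4])
  expect_error(build_pseudotetrad("HET", c("HET", "HET")), "length")
})

test_that("crossover counting weighs terminal and interstitial tracts", {
  expect_equal(count_cos(70, 66), 202L)
  expect_equal(count_cos(0, 0), 0L)
  expect_equal(count_cos(1, 0), 1L)
  tr <- data.frame(reciprocity = c("rLOH", "rLOH", "nrLOH"),
                   position = c("terminal", "interstitial", "interstitial"))
  expect_equal(count_cos(tr), 3L)
})

test_that("conversion tracts classify by adjacency to reciprocal LOH", {
  map <- tiny_map(12)  # markers 1..12 left arm, 13..24 right arm
  mother <- rep("HET", 24); daughter <- rep("HET", 24)
  # terminal rLOH on the right arm
  mother[19:24] <- "HOM_P1"; daughter[19:24] <- "HOM_P2"
  # nrLOH immediately flanking the rLOH boundary -> conversion of that CO
  mother[16:18] <- "HOM_P1"
  # nrLOH inside het context on the left arm -> NCO
  mother[4:6] <- "HOM_P2"
  # nrLOH containing the left arm's last genotyped marker (position 1 side)
  daughter[1:2] <- "HOM_P2"
  res <- call_events(mother, daughter, map)
  tr <- res$tracts
  expect_equal(tr$kind[tr$start_idx == 16], "CO_GC")
  expect_equal(tr$kind[tr$start_idx == 4], "NCO")
  expect_equal(tr$kind[tr$start_idx == 1], "TERMINAL_NCO")
  expect_equal(res$n_co, 1L)
  ev <- res$events
  expect_equal(sort(unique(ev$kind)), c("CO", "CO_GC", "NCO", "TERMINAL_NCO"))
  # the CO breakpoint interval is the flanking gap proximal of the rLOH
  co <- ev[ev$kind == "CO", ]
  expect_equal(co$start, map$markers$pos[18])
  expect_equal(co$end, map$markers$pos[19])
})

test_that("closely spaced events merge with kind precedence", {
  ev <- data.frame(kind = c("NCO", "NCO"), chrom = "c1",
                   start = c(1000, 1700), end = c(1500, 1900),
                   stringsAsFactors = FALSE)
  m <- merge_events(ev, max_gap = 1000)
  expect_equal(nrow(m), 1)
  expect_equal(m$kind, "NCO")
  expect_equal(c(m$start, m$end), c(1000, 1900))
  expect_length(attr(m, "merge_log"), 1)
  # distant events unchanged
  ev2 <- data.frame(kind = c("CO", "NCO"), chrom = "c1",
                    start = c(1000, 60000), end = c(1500, 61000),
                    stringsAsFactors = FALSE)
  m2 <- merge_events(ev2, max_gap = 5000)
  expect_equal(nrow(m2), 2)
  # CO absorbs an adjacent conversion tract under precedence
  ev3 <- data.frame(kind = c("NCO", "CO"), chrom = "c1",
                    start = c(1000, 1800), end = c(1500, 2100),
                    stringsAsFactors = FALSE)
  expect_equal(merge_events(ev3, 1000)$kind, "CO")
  expect_equal(nrow(merge_events(ev3[0, ], 1000)), 0)
})

test_that("co-segregating recombinants are invisible in the pair but revealed by sporulation", {
  # single-arm chromosome: centromere at the far right
  ci <- data.frame(chrom = "c1", length = 400000, cen_start = 397000,
                   cen_end = 399000)
  cfg <- sim_config(chromosomes = ci, marker_spacing = 1500,
                    co_dist = list(dist = "fixed", k = 1), gc_with_co = 0,
                    nco_dist = list(dist = "fixed", k = 0),
                    cen_exclusion = 5000)
  map <- make_marker_map(cfg, seed = 50)
  cfg0 <- cfg
  cfg0$co_dist <- list(dist = "fixed", k = 0)
  for (s in 1:8) {
    pair <- simulate_rtg_pair(map, cfg, seed = 60 + s)
    ev <- pair$truth$events
    co <- ev[ev$kind == "CO", ]
    expect_equal(nrow(co), 1)
    # force both recombinant chromatids into the mother
    a <- min(co$chr_a, co$chr_b); b <- max(co$chr_a, co$chr_b)
    choice <- data.frame(chrom = "c1", m1 = a, m2 = b)
    seg <- segregate_pair(pair$truth$chromatids, map, choice)
    res <- call_events(seg$mother, seg$daughter, map)
    expect_equal(res$n_co, 0L)  # masked: both cells fully heterozygous
    haps <- pair$truth$chromatids[c(a, b), , drop = FALSE]
    tet <- sporulate(haps, map, cfg0, seed = 600 + s)
    rep <- reveal_masked_cos(seg$mother, tet$spores, map)
    expect_equal(nrow(rep$masked), 1)
    expect_equal(rep$qc$frac_hom_4_0, NA_real_)  # no homozygous markers
    expect_equal(rep$qc$frac_het_2_2_or_3_1, 1)
    # breakpoint interval brackets the true site
    expect_lte(rep$masked$start, co$site)
    expect_gte(rep$masked$end, co$site)
  }
})

test_that("a non-recombinant parent reveals no masked crossovers", {
  ci <- data.frame(chrom = "c1", length = 300000, cen_start = 149000,
                   cen_end = 151000)
  cfg <- sim_config(chromosomes = ci, marker_spacing = 1500,
                    co_dist = list(dist = "fixed", k = 0), gc_with_co = 0,
                    nco_dist = list(dist = "fixed", k = 0))
  map <- make_marker_map(cfg, seed = 51)
  parent <- rep("HET", n_markers(map))
  haps <- rbind(rep("P1", n_markers(map)), rep("P2", n_markers(map)))
  cfg_sp <- cfg
  cfg_sp$co_dist <- list(dist = "fixed", k = 1)  # sporulation recombines anew
  tet <- sporulate(haps, map, cfg_sp, seed = 52)
  rep <- reveal_masked_cos(parent, tet$spores, map)
  expect_equal(nrow(rep$masked), 0)
  expect_equal(nrow(rep$sporulation), 2)  # one CO per arm, two spores switch
  expect_error(reveal_masked_cos(parent, tet$spores[1:3, ], map), "4 spores")
})

test_that("detected plus revealed masked crossovers equal the simulated truth", {
  ci <- data.frame(chrom = "c1", length = 400000, cen_start = 199000,
                   cen_end = 201000)
  cfg <- sim_config(chromosomes = ci, marker_spacing = 1200,
                    co_dist = list(dist = "fixed", k = 1), gc_with_co = 0,
                    nco_dist = list(dist = "fixed", k = 0))
  map <- make_marker_map(cfg, seed = 53)
  cfg0 <- cfg
  cfg0$co_dist <- list(dist = "fixed", k = 0)
  for (s in 1:12) {
    pair <- simulate_rtg_pair(map, cfg, seed = 70 + s)
    res <- call_events(pair$mother, pair$daughter, map)
    rev_m <- reveal_masked_cos(
      pair$mother,
      sporulate(strain_haplotypes(pair, map, "mother"), map, cfg0,
                seed = 700 + s)$spores, map)
    rev_d <- reveal_masked_cos(
      pair$daughter,
      sporulate(strain_haplotypes(pair, map, "daughter"), map, cfg0,
                seed = 800 + s)$spores, map)
    n_true <- sum(pair$truth$events$kind == "CO")
    expect_equal(res$n_co + nrow(rev_m$masked) + nrow(rev_d$masked), n_true)
  }
})
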