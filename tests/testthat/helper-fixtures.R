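# Shared fixtures: small deterministic maps and independent oracles.

# Regular-spaced deterministic map: one chromosome, n markers per arm,
# centromere in the middle.
tiny_map <- function(n_per_arm = 10, spacing = 1000, chrom = "chrT") {
  cen_mid <- (n_per_arm + 1) * spacing
  pos <- c(seq_len(n_per_arm) * spacing,
           cen_mid + 500 + seq_len(n_per_arm) * spacing)
  len <- max(pos) + spacing
  marker_map(data.frame(chrom = chrom, pos = pos),
             data.frame(chrom = chrom, length = len,
                        cen_start = cen_mid - 200, cen_end = cen_mid + 200))
}

# Two-chromosome simulation setup used across simulator tests.
sim_setup <- function(spacing = 2000, lambda_co = 1, lambda_nco = 3,
                      gc_with_co = 0, len = c(400000, 300000)) {
  ci <- data.frame(chrom = c("chrA", "chrB"), length = len,
                   cen_start = round(len / 2) - 1000,
                   cen_end = round(len / 2) + 1000)
  sim_config(chromosomes = ci, marker_spacing = spacing,
             co_dist = list(dist = "poisson", lambda = lambda_co),
             nco_dist = list(dist = "poisson", lambda = lambda_nco),
             gc_with_co = gc_with_co)
}

# Independent brute-force oracle for the crossover detection probability:
# iterative enumeration over explicit choice sequences (no recursion, no
# shared code with the package implementation). Chromatids are segment
# content vectors; choice c_j indexes the lexicographically ordered list of
# admissible chromatid pairs at step j.
oracle_detection <- function(k, rule = c("opposite_content", "inter_homolog")) {
  rule <- match.arg(rule)
  choices <- as.matrix(expand.grid(rep(list(1:4), k)))
  total_detected <- 0
  n_outcomes <- 0
  for (row in seq_len(nrow(choices))) {
    chrom <- lapply(c(1, 1, 0, 0), function(x) rep(x, k + 1))
    for (j in seq_len(k)) {
      if (rule == "opposite_content") {
        prs <- list()
        for (a in 1:3) for (b in (a + 1):4) {
          if (chrom[[a]][j + 1] != chrom[[b]][j + 1]) {
            prs[[length(prs) + 1]] <- c(a, b)
          }
        }
      } else {
        prs <- list(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
      }
      pick <- prs[[choices[row, j]]]
      seg <- (j + 1):(k + 1)
      tmp <- chrom[[pick[1]]][seg]
      chrom[[pick[1]]][seg] <- chrom[[pick[2]]][seg]
      chrom[[pick[2]]][seg] <- tmp
    }
    for (mi in 1:2) for (mj in 3:4) {
      hom <- chrom[[mi]] == chrom[[mj]]
      detected <- 0
      in_run <- FALSE
      for (s in seq_len(k + 1)) {
        if (hom[s] && !in_run) { detected <- detected + 2; in_run <- TRUE }
        if (!hom[s]) in_run <- FALSE
      }
      if (hom[k + 1]) detected <- detected - 1  # terminal run counts once
      total_detected <- total_detected + detected
      n_outcomes <- n_outcomes + 1
    }
  }
  total_detected / (k * n_outcomes)
}

# Marker-resolution oracle for one chromosome of a simulated pair without
# conversion tracts: re-applies the recorded crossover exchanges as suffix
# swaps on marker-index content vectors and reports the mother's homozygous
# runs per arm (detected CO count and hom marker indices). Independent of
# both the simulator matrix engine and the tract caller.
oracle_chrom_detected <- function(events, seg_choice, map, chrom) {
  mk <- map$markers
  cols <- which(mk$chrom == chrom)
  cont <- list(rep(1L, length(cols)), rep(1L, length(cols)),
               rep(0L, length(cols)), rep(0L, length(cols)))
  ev <- events[events$chrom == chrom & events$kind == "CO", , drop = FALSE]
  ev <- ev[order(ev$ord), , drop = FALSE]
  for (j in seq_len(nrow(ev))) {
    pos <- mk$pos[cols]
    distal <- if (ev$arm[j] == "R") which(pos > ev$site[j]) else which(pos < ev$site[j])
    if (length(distal) == 0) next
    a <- ev$chr_a[j]; b <- ev$chr_b[j]
    tmp <- cont[[a]][distal]
    cont[[a]][distal] <- cont[[b]][distal]
    cont[[b]][distal] <- tmp
  }
  m1 <- seg_choice$m1[seg_choice$chrom == chrom]
  m2 <- seg_choice$m2[seg_choice$chrom == chrom]
  # 0 = het, 1 = hom-P1, 2 = hom-P2; two crossovers falling in one marker gap
  # can juxtapose opposite-orientation tracts, so runs split by orientation
  state <- ifelse(cont[[m1]] != cont[[m2]], 0L,
                  ifelse(cont[[m1]] == 1L, 1L, 2L))
  ci <- map$chrom_info[map$chrom_info$chrom == chrom, ]
  arm <- ifelse(mk$pos[cols] < ci$cen_start, "L", "R")
  detected <- 0
  for (a in c("L", "R")) {
    h <- state[arm == a]
    if (a == "L") h <- rev(h)  # proximal -> distal
    r <- rle(h)
    ends <- cumsum(r$lengths)
    for (q in seq_along(r$values)) {
      if (r$values[q] == 0L) next
      detected <- detected + if (ends[q] == length(h)) 1 else 2
    }
  }
  list(detected = detected, hom_local = which(state > 0L), cols = cols)
}
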