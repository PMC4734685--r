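#' Configuration for the RTG meiosis simulator
#'
#' The defaults emulate the S288c/SK1-like hybrid the analysis is designed
#' for: the sixteen yeast chromosomes, markers every 191 bp on average,
#' conversion tracts of mean 2.3 kb, 81% of crossovers carrying an adjacent
#' gene conversion, and crossover placement excluded from a 10 kb window
#' around each centromere (meiotic DSBs are depleted there, which is why
#' centromere-linked markers remain heterozygous after RTG). Per-cell event
#' numbers vary widely between RTG cells; the default draws per-arm crossover
#' counts from a Poisson with mean 0.75 (about 24 true crossovers per cell
#' over 32 arms) and per-cell non-crossover counts from a Poisson with mean
#' 42.
#'
#' @param chromosomes data.frame of chromosome metadata (`chrom`, `length`,
#'   `cen_start`, `cen_end`); default [yeast_chromosomes()].
#' @param marker_spacing mean inter-marker distance in bp (default 191).
#' @param co_dist per-arm crossover count distribution: a list with element
#'   `dist` equal to `"poisson"` (with `lambda`), `"fixed"` (with `k`) or
#'   `"table"` (with `k`, `prob`).
#' @param nco_dist per-cell non-crossover count distribution, same format.
#' @param gc_with_co probability that a crossover has an adjacent gene
#'   conversion tract (default 0.81).
#' @param gc_len_mean mean conversion tract length in bp, exponentially
#'   distributed (default 2300).
#' @param cen_exclusion crossover/NCO exclusion radius around the centromere
#'   in bp (default 10000).
#' @param pairing_rule chromatid pair choice for crossovers:
#'   `"opposite_content"` (default) or `"inter_homolog"` (see
#'   [enumerate_detection()]).
#' @param depth_mean mean sequencing depth per marker for read sampling
#'   (Poisson; default 50).
#' @param error_rate per-read probability of reporting the other parental
#'   allele (default 0.005).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chromosomes = yeast_chromosomes(),
                       marker_spacing = 191,
                       co_dist = list(dist = "poisson", lambda = 0.75),
                       nco_dist = list(dist = "poisson", lambda = 42),
                       gc_with_co = 0.81,
                       gc_len_mean = 2300,
                       cen_exclusion = 10000,
                       pairing_rule = c("opposite_content", "inter_homolog"),
                       depth_mean = 50,
                       error_rate = 0.005) {
  pairing_rule <- match.arg(pairing_rule)
  stopifnot(is.data.frame(chromosomes), all(chromosomes$length > 0),
            marker_spacing > 0, gc_with_co >= 0, gc_with_co <= 1,
            gc_len_mean > 0, cen_exclusion >= 0, depth_mean >= 0,
            error_rate >= 0, error_rate < 0.5)
  structure(list(chromosomes = chromosomes, marker_spacing = marker_spacing,
                 co_dist = co_dist, nco_dist = nco_dist,
                 gc_with_co = gc_with_co, gc_len_mean = gc_len_mean,
                 cen_exclusion = cen_exclusion, pairing_rule = pairing_rule,
                 depth_mean = depth_mean, error_rate = error_rate),
            class = "sim_config")
}

draw_count <- function(spec, n = 1) {
  switch(spec$dist,
         poisson = stats::rpois(n, spec$lambda),
         fixed = rep(as.integer(spec$k), n),
         table = sample(spec$k, n, replace = TRUE, prob = spec$prob),
         stop("unknown count distribution: ", spec$dist))
}

#' Generate a hybrid marker map
#'
#' Places markers along each chromosome at exponentially jittered spacing
#' (mean `marker_spacing`), skipping the centromere interval. Deterministic
#' for a given seed.
#'
#' @param config a [sim_config()] object.
#' @param seed RNG seed.
#' @return A [marker_map()] object.
#' @export
make_marker_map <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  ci <- config$chromosomes
  if (any(config$marker_spacing >= ci$length)) {
    stop("marker spacing must be smaller than every chromosome length")
  }
  rows <- lapply(seq_len(nrow(ci)), function(i) {
    len <- ci$length[i]
    n_exp <- ceiling(len / config$marker_spacing * 1.3)
    pos <- cumsum(1 + stats::rexp(n_exp, 1 / (config$marker_spacing - 1)))
    pos <- round(pos[pos <= len])
    pos <- unique(pos[pos >= 1])
    pos <- pos[pos < ci$cen_start[i] | pos > ci$cen_end[i]]
    alle <- sample(c("A", "C", "G", "T"), 2 * length(pos), replace = TRUE)
    data.frame(chrom = ci$chrom[i], pos = as.integer(pos),
               p1_allele = alle[seq_along(pos)],
               p2_allele = alle[length(pos) + seq_along(pos)],
               stringsAsFactors = FALSE)
  })
  marker_map(do.call(rbind, rows), ci)
}

hybrid_haplotypes <- function(map) {
  n <- n_markers(map)
  rbind(rep("P1", n), rep("P2", n))
}

# Core meiotic engine: replicate the parent's two haplotypes into four
# chromatids (rows 1,2 sisters from haplotype 1; rows 3,4 from haplotype 2),
# then apply crossovers arm by arm (proximal to distal) and non-crossover
# conversions. When `events` is NULL they are drawn from the current RNG
# state and recorded; passing a recorded event table replays deterministically.
apply_meiosis <- function(map, haplotypes, config, events = NULL) {
  mk <- map$markers
  n <- n_markers(map)
  stopifnot(ncol(haplotypes) == n, nrow(haplotypes) == 2)
  chrt <- haplotypes[c(1, 1, 2, 2), , drop = FALSE]
  rownames(chrt) <- paste0("chromatid_", 1:4)
  draw <- is.null(events)
  rec <- list()
  ord <- 0L

  do_co <- function(chrom_cols, arm, site, chr_a = NA, chr_b = NA,
                    gc = NA, gc_start = NA, gc_end = NA, donor = NA) {
    pos <- mk$pos[chrom_cols]
    distal <- if (arm == "R") chrom_cols[pos > site] else chrom_cols[pos < site]
    if (draw) {
      if (length(distal)) {
        anchor <- if (arm == "R") distal[1] else distal[length(distal)]
        cont <- chrt[, anchor] == "P1"
        prs <- if (config$pairing_rule == "opposite_content") {
          opposite_pairs(as.integer(cont))
        } else inter_homolog_pairs
        if (nrow(prs) == 0) prs <- inter_homolog_pairs
      } else prs <- inter_homolog_pairs
      pick <- prs[sample.int(nrow(prs), 1), ]
      chr_a <- pick[1]; chr_b <- pick[2]
      gc <- stats::runif(1) < config$gc_with_co
      if (gc) {
        len <- stats::rexp(1, 1 / config$gc_len_mean)
        if (arm == "R") { gc_start <- site - len; gc_end <- site }
        else { gc_start <- site; gc_end <- site + len }
        donor <- if (stats::runif(1) < 0.5) chr_a else chr_b
      }
    }
    if (length(distal)) {
      tmp <- chrt[chr_a, distal]
      chrt[chr_a, distal] <<- chrt[chr_b, distal]
      chrt[chr_b, distal] <<- tmp
    }
    if (isTRUE(gc)) {
      tract <- chrom_cols[pos >= gc_start & pos <= gc_end]
      recipient <- if (donor == chr_a) chr_b else chr_a
      if (length(tract)) chrt[recipient, tract] <<- chrt[donor, tract]
    }
    ord <<- ord + 1L
    rec[[length(rec) + 1]] <<- data.frame(
      ord = ord, kind = "CO", chrom = mk$chrom[chrom_cols[1]], arm = arm,
      site = site, chr_a = chr_a, chr_b = chr_b, gc = isTRUE(gc),
      gc_start = ifelse(isTRUE(gc), gc_start, NA_real_),
      gc_end = ifelse(isTRUE(gc), gc_end, NA_real_),
      donor = ifelse(isTRUE(gc), donor, NA_integer_),
      recipient = ifelse(isTRUE(gc), ifelse(donor == chr_a, chr_b, chr_a),
                         NA_integer_),
      n_markers_changed = NA_integer_, stringsAsFactors = FALSE)
  }

  do_nco <- function(chrom_cols, gc_start, gc_end, donor, recipient) {
    pos <- mk$pos[chrom_cols]
    tract <- chrom_cols[pos >= gc_start & pos <= gc_end]
    changed <- if (length(tract)) {
      sum(chrt[donor, tract] != chrt[recipient, tract])
    } else 0L
    if (length(tract)) chrt[recipient, tract] <<- chrt[donor, tract]
    ord <<- ord + 1L
    rec[[length(rec) + 1]] <<- data.frame(
      ord = ord, kind = "NCO", chrom = mk$chrom[chrom_cols[1]], arm = NA,
      site = gc_start, chr_a = NA_integer_, chr_b = NA_integer_, gc = TRUE,
      gc_start = gc_start, gc_end = gc_end, donor = donor,
      recipient = recipient, n_markers_changed = as.integer(changed),
      stringsAsFactors = FALSE)
  }

  ci <- map$chrom_info
  for (i in seq_len(nrow(ci))) {
    cc <- ci$chrom[i]
    chrom_cols <- which(mk$chrom == cc)
    if (length(chrom_cols) == 0) next
    if (draw) {
      for (arm in c("L", "R")) {
        rng <- if (arm == "L") {
          c(1, ci$cen_start[i] - config$cen_exclusion)
        } else {
          c(ci$cen_end[i] + config$cen_exclusion, ci$length[i])
        }
        if (rng[2] <= rng[1]) next
        k <- draw_count(config$co_dist)
        if (k == 0) next
        sites <- stats::runif(k, rng[1], rng[2])
        # proximal -> distal: away from the centromere
        sites <- if (arm == "R") sort(sites) else sort(sites, decreasing = TRUE)
        for (s in sites) do_co(chrom_cols, arm, s)
      }
    } else {
      evc <- events[events$chrom == cc & events$kind == "CO", , drop = FALSE]
      evc <- evc[order(evc$ord), , drop = FALSE]
      for (j in seq_len(nrow(evc))) {
        do_co(chrom_cols, evc$arm[j], evc$site[j], evc$chr_a[j], evc$chr_b[j],
              evc$gc[j], evc$gc_start[j], evc$gc_end[j], evc$donor[j])
      }
    }
  }
  if (draw) {
    n_nco <- draw_count(config$nco_dist)
    if (n_nco > 0) {
      w <- ci$length / sum(ci$length)
      for (q in seq_len(n_nco)) {
        i <- sample.int(nrow(ci), 1, prob = w)
        rng_ok <- FALSE
        for (try in 1:50) {
          pos0 <- stats::runif(1, 1, ci$length[i])
          if (pos0 < ci$cen_start[i] - config$cen_exclusion ||
              pos0 > ci$cen_end[i] + config$cen_exclusion) { rng_ok <- TRUE; break }
        }
        if (!rng_ok) next
        len <- stats::rexp(1, 1 / config$gc_len_mean)
        recipient <- sample.int(4, 1)
        donor <- if (recipient <= 2) sample(3:4, 1) else sample(1:2, 1)
        chrom_cols <- which(mk$chrom == ci$chrom[i])
        if (length(chrom_cols) == 0) next
        do_nco(chrom_cols, pos0, pos0 + len, donor, recipient)
      }
    }
  } else {
    evn <- events[events$kind == "NCO", , drop = FALSE]
    evn <- evn[order(evn$ord), , drop = FALSE]
    for (j in seq_len(nrow(evn))) {
      chrom_cols <- which(mk$chrom == evn$chrom[j])
      do_nco(chrom_cols, evn$gc_start[j], evn$gc_end[j], evn$donor[j],
             evn$recipient[j])
    }
  }
  events_out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(ord = integer(), kind = character(), chrom = character(),
               arm = character(), site = numeric(), chr_a = integer(),
               chr_b = integer(), gc = logical(), gc_start = numeric(),
               gc_end = numeric(), donor = integer(), recipient = integer(),
               n_markers_changed = integer(), stringsAsFactors = FALSE)
  list(chromatids = chrt, events = events_out)
}

#' Segregate four chromatids equationally into a mother-daughter pair
#'
#' One chromatid of each original sister pair goes to the mother, the other
#' two to the daughter, independently per chromosome (four equiprobable
#' choices each).
#'
#' @param chromatids 4 x n character matrix from the meiotic engine (rows
#'   1,2 and 3,4 are the original sister pairs).
#' @param map a [marker_map()] object.
#' @param choice optional data.frame with columns `chrom`, `m1` (1 or 2) and
#'   `m2` (3 or 4) forcing which chromatids the mother receives; drawn
#'   uniformly when `NULL`.
#' @return A list: `mother`, `daughter` (genotype vectors), `choice`.
#' @export
segregate_pair <- function(chromatids, map, choice = NULL) {
  mk <- map$markers
  chroms <- unique(mk$chrom)
  if (is.null(choice)) {
    choice <- data.frame(chrom = chroms,
                         m1 = sample(1:2, length(chroms), replace = TRUE),
                         m2 = sample(3:4, length(chroms), replace = TRUE),
                         stringsAsFactors = FALSE)
  }
  n <- n_markers(map)
  mother <- character(n); daughter <- character(n)
  for (i in seq_len(nrow(choice))) {
    cols <- which(mk$chrom == choice$chrom[i])
    if (length(cols) == 0) next
    m1 <- choice$m1[i]; m2 <- choice$m2[i]
    d1 <- if (m1 == 1) 2 else 1
    d2 <- if (m2 == 3) 4 else 3
    mother[cols] <- merge_chromatids(chromatids[m1, cols], chromatids[m2, cols])
    daughter[cols] <- merge_chromatids(chromatids[d1, cols], chromatids[d2, cols])
  }
  list(mother = mother, daughter = daughter, choice = choice)
}

#' Simulate one RTG mother-daughter pair with ground truth
#'
#' Runs a meiosis (crossovers, conversion tracts) on the hybrid's two
#' haplotypes and segregates the four chromatids equationally. The returned
#' truth carries the full event list, the chromatids and the segregation
#' choice, from which the genotype vectors can be reproduced exactly with
#' [replay_truth()].
#'
#' @param map a [marker_map()] object.
#' @param config a [sim_config()] object.
#' @param seed RNG seed (mandatory).
#' @param haplotypes optional 2 x n parental haplotype matrix (defaults to
#'   the fully heterozygous hybrid).
#' @param choice optional forced segregation (see [segregate_pair()]).
#' @return A list of class `rtg_pair`: `mother`, `daughter` (genotype
#'   vectors) and `truth` (list with `events`, `chromatids`, `segregation`,
#'   `haplotypes`).
#' @export
simulate_rtg_pair <- function(map, config = sim_config(), seed,
                              haplotypes = NULL, choice = NULL) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  if (is.null(haplotypes)) haplotypes <- hybrid_haplotypes(map)
  mei <- apply_meiosis(map, haplotypes, config)
  seg <- segregate_pair(mei$chromatids, map, choice)
  structure(list(mother = seg$mother, daughter = seg$daughter,
                 truth = list(events = mei$events, chromatids = mei$chromatids,
                              segregation = seg$choice,
                              haplotypes = haplotypes)),
            class = "rtg_pair")
}

#' Replay recorded simulation truth into genotype vectors
#'
#' Deterministically re-applies a recorded event list and segregation choice,
#' reproducing the simulated pair bit for bit.
#'
#' @param map a [marker_map()] object.
#' @param truth the `truth` element of an `rtg_pair`.
#' @param config a [sim_config()] (only structural fields are used).
#' @return A list with `mother`, `daughter`, `chromatids`.
#' @export
replay_truth <- function(map, truth, config = sim_config()) {
  mei <- apply_meiosis(map, truth$haplotypes, config, events = truth$events)
  seg <- segregate_pair(mei$chromatids, map, choice = truth$segregation)
  list(mother = seg$mother, daughter = seg$daughter,
       chromatids = mei$chromatids)
}

#' Haplotypes of one strain of a simulated pair
#'
#' The two chromatids a simulated RTG cell received, as a 2 x n matrix --
#' the diploid's phased haplotypes, suitable as input to [sporulate()].
#'
#' @param pair an `rtg_pair` object.
#' @param strain `"mother"` or `"daughter"`.
#' @param map the [marker_map()] used for the simulation.
#' @return 2 x n character matrix of `"P1"`/`"P2"`.
#' @export
strain_haplotypes <- function(pair, map, strain = c("mother", "daughter")) {
  strain <- match.arg(strain)
  ch <- pair$truth$segregation
  mk <- map$markers
  out <- matrix(NA_character_, 2, n_markers(map))
  for (i in seq_len(nrow(ch))) {
    cols <- which(mk$chrom == ch$chrom[i])
    rows <- if (strain == "mother") c(ch$m1[i], ch$m2[i])
            else c(if (ch$m1[i] == 1) 2 else 1, if (ch$m2[i] == 3) 4 else 3)
    out[, cols] <- pair$truth$chromatids[rows, cols]
  }
  out
}

#' Sample parental allele depths from true genotypes
#'
#' Per marker, total depth is Poisson with the configured mean; reads carry
#' the true allele(s) (an even split for heterozygous markers) and each read
#' reports the other parental allele with the configured error rate.
#'
#' @param calls character vector of true genotype labels.
#' @param config a [sim_config()] object (`depth_mean`, `error_rate`).
#' @param seed RNG seed (mandatory).
#' @return data.frame with columns `n_p1`, `n_p2`.
#' @export
sample_reads <- function(calls, config = sim_config(), seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  n <- length(calls)
  depth <- stats::rpois(n, config$depth_mean)
  t1 <- integer(n)
  t1[calls == "HOM_P1"] <- depth[calls == "HOM_P1"]
  het <- calls == "HET"
  t1[het] <- stats::rbinom(sum(het), depth[het], 0.5)
  flip_to_p2 <- stats::rbinom(n, t1, config$error_rate)
  flip_to_p1 <- stats::rbinom(n, depth - t1, config$error_rate)
  data.frame(n_p1 = t1 - flip_to_p2 + flip_to_p1,
             n_p2 = (depth - t1) - flip_to_p1 + flip_to_p2)
}

#' Sporulate a diploid into a four-spore tetrad
#'
#' Runs a fresh meiosis (new crossovers and conversions per the
#' configuration) on the diploid's two haplotypes, then completes both
#' meiotic divisions: the four resulting chromatids are the four haploid
#' spores. Markers homozygous in the parent segregate 4:0; heterozygous
#' markers segregate 2:2 except inside new conversion tracts (3:1).
#'
#' @param haplotypes 2 x n character matrix of the parent's phased haplotypes
#'   (e.g. from [strain_haplotypes()]).
#' @param map a [marker_map()] object.
#' @param config a [sim_config()] object.
#' @param seed RNG seed (mandatory).
#' @return A list of class `rtg_tetrad`: `spores` (4 x n matrix of
#'   `"P1"`/`"P2"`), `events` (the sporulation meiosis events), and
#'   `parent` (the parent's diploid genotype vector).
#' @export
sporulate <- function(haplotypes, map, config = sim_config(), seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  mei <- apply_meiosis(map, haplotypes, config)
  spores <- mei$chromatids
  rownames(spores) <- paste0("spore_", 1:4)
  structure(list(spores = spores, events = mei$events,
                 parent = merge_chromatids(haplotypes[1, ], haplotypes[2, ])),
            class = "rtg_tetrad")
}

#' Simulate an iterated-RTG pedigree
#'
#' Starting from the fully heterozygous hybrid, performs `passages` rounds of
#' RTG, each time re-inducing meiosis in the chosen descendant (the mother
#' cell by default). LOH acquired at one passage is transmitted to all
#' descendants, so homozygosity is non-decreasing along the lineage.
#'
#' @param map a [marker_map()] object.
#' @param config a [sim_config()] object.
#' @param passages number of RTG rounds (`>= 1`).
#' @param seed RNG seed (mandatory).
#' @param follow which cell to carry forward: `"mother"` or `"daughter"`.
#' @return A list of class `rtg_pedigree`: one element per passage, each an
#'   `rtg_pair` with an added `hom_frac` (mother's homozygous marker
#'   fraction).
#' @export
simulate_pedigree <- function(map, config = sim_config(), passages, seed,
                              follow = c("mother", "daughter")) {
  follow <- match.arg(follow)
  stopifnot(passages >= 1)
  if (missing(seed)) stop("a seed is required")
  haps <- hybrid_haplotypes(map)
  out <- vector("list", passages)
  for (p in seq_len(passages)) {
    pair <- simulate_rtg_pair(map, config, seed = seed + p - 1,
                              haplotypes = haps)
    pair$hom_frac <- mean(pair[[follow]] %in% c("HOM_P1", "HOM_P2"))
    out[[p]] <- pair
    haps <- strain_haplotypes(pair, map, follow)
  }
  structure(out, class = "rtg_pedigree")
}
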