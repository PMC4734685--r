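#' Classify per-marker segregation patterns in a mother-daughter pair
#'
#' The two diploids of an RTG pair jointly carry the four chromatids of one
#' meiotic cell, so each marker's parental alleles distribute 2:2, 3:1 or 4:0
#' among them. Both calls heterozygous, or opposite homozygous calls, give a
#' 2:2 pattern; one heterozygous and one homozygous call gives 3:1; the same
#' homozygous call in both gives 4:0 (a pre-meiotic event, excluded from LOH
#' analysis downstream). The pattern is `NA` when either call is `NO_CALL`.
#'
#' @param mother,daughter character vectors of genotype labels.
#' @return Character vector over [SEG_PATTERNS], `NA` where uncallable.
#' @examples
#' classify_segregation("HOM_P1", "HOM_P2")  # "TWO_TWO_HOM"
#' classify_segregation("HET", "HOM_P1")     # "THREE_ONE"
#' @export
classify_segregation <- function(mother, daughter) {
  n <- max(length(mother), length(daughter))
  mother <- rep_len(mother, n); daughter <- rep_len(daughter, n)
  out <- rep(NA_character_, n)
  ok <- mother != "NO_CALL" & daughter != "NO_CALL"
  m_het <- mother == "HET"; d_het <- daughter == "HET"
  out[ok & m_het & d_het] <- "TWO_TWO_HET"
  out[ok & (m_het != d_het)] <- "THREE_ONE"
  both_hom <- ok & !m_het & !d_het
  out[both_hom & mother != daughter] <- "TWO_TWO_HOM"
  out[both_hom & mother == daughter] <- "FOUR_ZERO"
  out
}

# per-marker tract label used for grouping:
#   "het"          2:2 heterozygous background
#   "r:P1"/"r:P2"  2:2 homozygous, mother's homozygous parent
#   "n:M:P1" etc.  3:1, which strain is homozygous and for which parent
marker_labels <- function(mother, daughter, pattern) {
  lab <- rep(NA_character_, length(pattern))
  lab[pattern == "TWO_TWO_HET"] <- "het"
  i <- which(pattern == "TWO_TWO_HOM")
  lab[i] <- paste0("r:", ifelse(mother[i] == "HOM_P1", "P1", "P2"))
  i <- which(pattern == "THREE_ONE")
  strain <- ifelse(mother[i] == "HET", "D", "M")
  hom <- ifelse(mother[i] == "HET", daughter[i], mother[i])
  lab[i] <- paste0("n:", strain, ":", ifelse(hom == "HOM_P1", "P1", "P2"))
  lab
}

#' Assemble LOH tracts from a mother-daughter genotype pair
#'
#' Two-step tract assembly. Only markers robustly genotyped in both strains
#' are used; 4:0 markers (and any markers flagged with `exclude`, e.g. for
#' copy-number variation) are set aside. In the first step the 3:1 markers
#' are ignored and contiguous 2:2 homozygous markers of the same orientation
#' are grouped into reciprocal LOH (rLOH) tracts: the mother homozygous for
#' one parent, the daughter for the other, at every member marker. In the
#' second step all retained markers are grouped by genotype/pattern and each
#' maximal run of 3:1 markers of the same orientation becomes a
#' non-reciprocal LOH (nrLOH) tract.
#'
#' Tract coordinates span the first to last member marker; the breakpoint is
#' reported as the open interval to the nearest flanking retained marker of a
#' different genotype (`NA` at arm ends).
#'
#' @param mother,daughter character genotype vectors aligned to `map`.
#' @param map a [marker_map()] object.
#' @param exclude optional logical vector over markers: `TRUE` to exclude
#'   (e.g. CNV-involved markers).
#' @return A list of class `pair_tracts`:
#'   \describe{
#'     \item{tracts}{data.frame of tracts: `chrom`, `reciprocity`
#'       (`"rLOH"`/`"nrLOH"`), `start_idx`/`end_idx` (marker row indices),
#'       `start_pos`/`end_pos`, `span_bp`, `n_markers`, `mother_gt`,
#'       `daughter_gt`, `hom_strain` (nrLOH only), `arm`, `position`
#'       (`"terminal"`/`"interstitial"`/`"spans_centromere"`),
#'       `left_flank_pos`, `right_flank_pos`.}
#'     \item{pattern}{per-marker segregation pattern (full length).}
#'     \item{retained}{logical: markers used for tract assembly.}
#'     \item{four_zero}{indices of 4:0 markers that were set aside.}
#'   }
#' @export
assemble_pair_tracts <- function(mother, daughter, map, exclude = NULL) {
  nm <- n_markers(map)
  if (length(mother) != nm || length(daughter) != nm) {
    stop("genotype vectors must match the marker map length")
  }
  if (is.null(exclude)) exclude <- rep(FALSE, nm)
  pattern <- classify_segregation(mother, daughter)
  four_zero <- which(pattern == "FOUR_ZERO" & !exclude)
  retained <- !is.na(pattern) & pattern != "FOUR_ZERO" & !exclude
  lab <- marker_labels(mother, daughter, pattern)

  all_tracts <- list()
  for (cc in unique(map$markers$chrom)) {
    sel <- which(map$markers$chrom == cc & retained)
    if (length(sel) == 0) next
    lv <- lab[sel]

    # step 1: set 3:1 aside, group 2:2 markers by genotype -> rLOH
    is22 <- !startsWith(lv, "n:")
    sub <- sel[is22]
    r_tracts <- run_tracts(sub, lab[sub], prefix = "r:")
    # step 2: all markers together, maximal 3:1 runs -> nrLOH
    n_tracts <- run_tracts(sel, lv, prefix = "n:")

    for (tr in r_tracts) {
      all_tracts[[length(all_tracts) + 1]] <-
        tract_row(tr, "rLOH", cc, map, mother, daughter, sel)
    }
    for (tr in n_tracts) {
      all_tracts[[length(all_tracts) + 1]] <-
        tract_row(tr, "nrLOH", cc, map, mother, daughter, sel)
    }
  }
  tracts <- if (length(all_tracts)) do.call(rbind, all_tracts) else empty_tracts()
  if (nrow(tracts)) {
    tracts <- tracts[order(match(tracts$chrom, unique(map$markers$chrom)),
                           tracts$start_pos), , drop = FALSE]
    rownames(tracts) <- NULL
    tracts$tract_id <- seq_len(nrow(tracts))
  }
  structure(list(tracts = tracts, pattern = pattern, retained = retained,
                 four_zero = four_zero),
            class = "pair_tracts")
}

# maximal runs of markers whose label starts with `prefix`, same label
run_tracts <- function(idx, labels, prefix) {
  if (length(idx) == 0) return(list())
  r <- rle(labels)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- startsWith(r$values, prefix)
  lapply(which(keep), function(q) idx[starts[q]:ends[q]])
}

tract_row <- function(members, reciprocity, cc, map, mother, daughter, retained_idx) {
  s <- members[1]; e <- members[length(members)]
  arm_s <- map$markers$arm[s]; arm_e <- map$markers$arm[e]
  arm <- if (!is.na(arm_s) && !is.na(arm_e) && arm_s == arm_e) arm_s else NA_character_
  hom_strain <- NA_character_
  if (reciprocity == "nrLOH") hom_strain <- if (mother[s] == "HET") "D" else "M"
  # flanking retained markers of different genotype
  before <- retained_idx[retained_idx < s]
  after <- retained_idx[retained_idx > e]
  lf <- if (length(before)) max(before) else NA_integer_
  rf <- if (length(after)) min(after) else NA_integer_
  data.frame(chrom = cc, reciprocity = reciprocity,
             start_idx = s, end_idx = e,
             start_pos = map$markers$pos[s], end_pos = map$markers$pos[e],
             span_bp = map$markers$pos[e] - map$markers$pos[s] + 1L,
             n_markers = length(members),
             mother_gt = mother[s], daughter_gt = daughter[s],
             hom_strain = hom_strain, arm = arm,
             position = NA_character_,
             left_flank_pos = if (is.na(lf)) NA_integer_ else map$markers$pos[lf],
             right_flank_pos = if (is.na(rf)) NA_integer_ else map$markers$pos[rf],
             stringsAsFactors = FALSE)
}

empty_tracts <- function() {
  data.frame(chrom = character(), reciprocity = character(),
             start_idx = integer(), end_idx = integer(),
             start_pos = integer(), end_pos = integer(), span_bp = integer(),
             n_markers = integer(), mother_gt = character(),
             daughter_gt = character(), hom_strain = character(),
             arm = character(), position = character(),
             left_flank_pos = integer(), right_flank_pos = integer(),
             tract_id = integer(), stringsAsFactors = FALSE)
}

#' Classify tracts as terminal or interstitial
#'
#' A terminal tract reaches the last genotyped marker of its chromosomal arm
#' (homozygosity extends to the telomere-proximal end of the genotyped
#' region); an interstitial tract is flanked by differently-genotyped markers
#' on both sides. For rLOH tracts the 3:1 markers are transparent, matching
#' the two-step assembly. Tracts whose members span the centromere are
#' labelled `"spans_centromere"` and flagged for review.
#'
#' @param pt a `pair_tracts` object from [assemble_pair_tracts()], or a tract
#'   data.frame plus `retained`/`pattern` vectors.
#' @param map a [marker_map()] object.
#' @return The `pair_tracts` object with the tract `position` column filled.
#' @export
classify_tract_position <- function(pt, map) {
  stopifnot(inherits(pt, "pair_tracts"))
  tr <- pt$tracts
  if (nrow(tr) == 0) return(pt)
  mk <- map$markers
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$arm[i])) {
      tr$position[i] <- "spans_centromere"
      next
    }
    on_arm <- which(mk$chrom == tr$chrom[i] & !is.na(mk$arm) &
                      mk$arm == tr$arm[i] & pt$retained)
    if (tr$reciprocity[i] == "rLOH") {
      # 3:1 markers are transparent when judging rLOH extent
      on_arm <- on_arm[pt$pattern[on_arm] != "THREE_ONE"]
    }
    distal <- if (tr$arm[i] == "L") on_arm[on_arm < tr$start_idx[i]]
              else on_arm[on_arm > tr$end_idx[i]]
    tr$position[i] <- if (length(distal) == 0) "terminal" else "interstitial"
  }
  pt$tracts <- tr
  pt
}

#' Per-strain LOH summary
#'
#' Fraction of called markers that are homozygous, split by parental origin,
#' for one or several genotype vectors.
#'
#' @param geno character vector or markers x strains matrix of genotype labels.
#' @param tracts optional tract data.frame (from [assemble_pair_tracts()]) to
#'   summarize counts and lengths.
#' @return data.frame with one row per strain: `n_called`, `frac_hom`,
#'   `frac_p1`, `frac_p2`; if `tracts` is given, the returned object also has
#'   attribute `"tract_summary"` (counts and mean spans by reciprocity).
#' @export
summarize_loh <- function(geno, tracts = NULL) {
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = 1,
                                         dimnames = list(NULL, "strain"))
  res <- do.call(rbind, lapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    called <- g != "NO_CALL"
    data.frame(strain = colnames(geno)[j], n_called = sum(called),
               frac_hom = mean(g[called] %in% c("HOM_P1", "HOM_P2")),
               frac_p1 = mean(g[called] == "HOM_P1"),
               frac_p2 = mean(g[called] == "HOM_P2"),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(tracts) && nrow(tracts)) {
    ts <- do.call(rbind, lapply(split(tracts, tracts$reciprocity), function(d) {
      data.frame(reciprocity = d$reciprocity[1], n = nrow(d),
                 mean_span_bp = mean(d$span_bp),
                 total_markers = sum(d$n_markers), stringsAsFactors = FALSE)
    }))
    rownames(ts) <- NULL
    attr(res, "tract_summary") <- ts
  }
  res
}

#' Export LOH tracts as BED
#'
#' Converts the internal 1-based inclusive tract spans to 0-based half-open
#' BED intervals. The name field encodes reciprocity, position and the
#' mother's genotype as `reciprocity|position|motherGt`.
#'
#' @param tracts tract data.frame from [assemble_pair_tracts()].
#' @param path optional output file; when given, a tab-separated BED file is
#'   written.
#' @return data.frame with BED columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
tracts_to_bed <- function(tracts, path = NULL) {
  bed <- data.frame(chrom = tracts$chrom,
                    start = tracts$start_pos - 1L,
                    end = tracts$end_pos,
                    name = paste(tracts$reciprocity,
                                 ifelse(is.na(tracts$position), "unclassified",
                                        tracts$position),
                                 tracts$mother_gt, sep = "|"),
                    score = tracts$n_markers,
                    strand = ".", stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  bed
}
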