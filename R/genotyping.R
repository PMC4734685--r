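#' Genotyping thresholds for hybrid diploid SNP calls
#'
#' Threshold set used to call a diploid genotype from parental allele read
#' counts. Defaults follow the asymmetric scheme appropriate when reads are
#' aligned to the reference-like parent (P1): the P1-homozygous cutoff is
#' stricter (>95% P1 reads) than the P2-homozygous cutoff (>75% P2 reads),
#' because alignment of the divergent parent's reads is less efficient, and a
#' call requires coverage strictly greater than `min_depth_exclusive` with at
#' least `min_parental_fraction` of all reads carrying either parental allele.
#'
#' @param min_depth_exclusive minimum coverage, exclusive: a marker is callable
#'   only when total depth is strictly greater than this (default 5, i.e.
#'   at least 6 reads).
#' @param min_parental_fraction minimum fraction of reads carrying either
#'   parental allele (default 2/3); only relevant when non-parental read
#'   counts are supplied.
#' @param p1_hom_min call `HOM_P1` when the P1 fraction of parental reads is
#'   strictly greater than this (default 0.95).
#' @param p2_hom_min call `HOM_P2` when the P2 fraction is strictly greater
#'   than this (default 0.75).
#' @param het_p1_range,het_p2_range closed intervals of the P1 and P2 read
#'   fractions compatible with a heterozygous call (defaults `[0.25, 0.95]`
#'   and `[0.05, 0.75]`, complementary to the homozygous cutoffs).
#' @param min_adjacent_switch minimum number of adjacent markers a genotype
#'   switch must span to be retained (default 3); see [filter_short_runs()].
#' @return An object of class `genotyping_thresholds`.
#' @export
genotyping_thresholds <- function(min_depth_exclusive = 5,
                                  min_parental_fraction = 2 / 3,
                                  p1_hom_min = 0.95,
                                  p2_hom_min = 0.75,
                                  het_p1_range = c(0.25, 0.95),
                                  het_p2_range = c(0.05, 0.75),
                                  min_adjacent_switch = 3) {
  stopifnot(min_depth_exclusive >= 0, min_parental_fraction > 0,
            min_parental_fraction <= 1, min_adjacent_switch >= 1)
  if (!(p2_hom_min > 0 && p2_hom_min < p1_hom_min && p1_hom_min < 1)) {
    stop("need 0 < p2_hom_min < p1_hom_min < 1")
  }
  stopifnot(length(het_p1_range) == 2, length(het_p2_range) == 2,
            het_p1_range[1] < het_p1_range[2], het_p2_range[1] < het_p2_range[2])
  structure(list(min_depth_exclusive = min_depth_exclusive,
                 min_parental_fraction = min_parental_fraction,
                 p1_hom_min = p1_hom_min, p2_hom_min = p2_hom_min,
                 het_p1_range = het_p1_range, het_p2_range = het_p2_range,
                 min_adjacent_switch = min_adjacent_switch),
            class = "genotyping_thresholds")
}

#' Call diploid genotypes from parental allele depths
#'
#' Assigns one of `HOM_P1`, `HOM_P2`, `HET` or `NO_CALL` per marker from the
#' number of reads supporting each parental allele. A marker is `NO_CALL` when
#' total depth is not strictly above the coverage cutoff or when fewer than
#' `min_parental_fraction` of its reads carry a parental allele; otherwise the
#' label is determined by the P1 read fraction among parental reads: `HOM_P1`
#' above `p1_hom_min`, `HOM_P2` when the P2 fraction exceeds `p2_hom_min`,
#' `HET` inside the heterozygous ranges. The label function is total: exactly
#' one label applies to every depth configuration.
#'
#' @param n_p1,n_p2 non-negative read counts supporting the P1 and P2 alleles
#'   (vectors are recycled to common length).
#' @param n_other reads carrying neither parental allele (default 0).
#' @param thresholds a [genotyping_thresholds()] object.
#' @return Character vector of genotype labels (see [GENOTYPES]).
#' @examples
#' call_genotypes(48, 2)        # 96% P1 reads -> "HOM_P1"
#' call_genotypes(3, 2)         # depth 5, not >5X -> "NO_CALL"
#' call_genotypes(30, 70)       # 70% P2 <= 75% cutoff -> "HET"
#' @export
call_genotypes <- function(n_p1, n_p2, n_other = 0,
                           thresholds = genotyping_thresholds()) {
  n <- max(length(n_p1), length(n_p2), length(n_other))
  n_p1 <- rep_len(n_p1, n); n_p2 <- rep_len(n_p2, n); n_other <- rep_len(n_other, n)
  if (any(n_p1 < 0 | n_p2 < 0 | n_other < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  th <- thresholds
  depth <- n_p1 + n_p2 + n_other
  parental <- n_p1 + n_p2
  out <- rep("NO_CALL", n)
  callable <- !is.na(depth) & depth > th$min_depth_exclusive &
    parental / depth >= th$min_parental_fraction
  f1 <- n_p1 / parental
  f2 <- 1 - f1
  hom1 <- callable & f1 > th$p1_hom_min
  hom2 <- callable & !hom1 & f2 > th$p2_hom_min
  het <- callable & !hom1 & !hom2 &
    f1 >= th$het_p1_range[1] & f1 <= th$het_p1_range[2] &
    f2 >= th$het_p2_range[1] & f2 <= th$het_p2_range[2]
  out[hom1] <- "HOM_P1"; out[hom2] <- "HOM_P2"; out[het] <- "HET"
  out
}

#' Remove genotype switches spanning fewer than a minimum number of markers
#'
#' A small bias in the parental read ratio can turn a single heterozygous
#' marker into a spurious homozygous call. Following the rule that a genotype
#' switch must affect at least `min_adjacent_switch` adjacent markers, any
#' maximal homozygous run shorter than the minimum that is embedded in
#' heterozygous context (or touches a chromosome end) is reassigned to `HET`.
#' `NO_CALL` markers are transparent: they neither break nor extend a run and
#' are left unchanged. The filter is idempotent and never creates a new
#' homozygous run.
#'
#' By default the rule is asymmetric (it guards only against spurious
#' homozygosity); with `symmetric = TRUE` short `HET` runs embedded in a
#' single-genotype homozygous context are likewise reassigned.
#'
#' @param calls character vector of genotype labels for one chromosome,
#'   ordered by position.
#' @param min_adjacent_switch minimum run length retained (default 3).
#' @param symmetric also collapse short HET islands inside homozygous tracts
#'   (default `FALSE`).
#' @return Character vector of filtered calls, with attribute `"n_reassigned"`
#'   giving the number of markers changed.
#' @examples
#' filter_short_runs(c("HET", "HOM_P2", "HET"))            # -> all HET
#' filter_short_runs(c("HET", rep("HOM_P2", 3), "HET"))    # unchanged
#' @export
filter_short_runs <- function(calls, min_adjacent_switch = 3, symmetric = FALSE) {
  if (length(calls) == 0) return(calls)
  out <- calls
  total_changed <- 0L
  # reassignment can expose a neighbouring short run (its context becomes
  # heterozygous), so passes repeat until a fixed point is reached
  for (pass in seq_len(length(calls) + 1L)) {
    res <- filter_short_runs_pass(out, min_adjacent_switch, symmetric)
    total_changed <- total_changed + attr(res, "n_reassigned")
    if (identical(unclass(res)[seq_along(out)], out)) break
    out <- res[seq_along(out)]
  }
  attr(out, "n_reassigned") <- total_changed
  out
}

filter_short_runs_pass <- function(calls, min_adjacent_switch, symmetric) {
  out <- calls
  idx <- which(calls != "NO_CALL")
  if (length(idx) == 0) {
    attr(out, "n_reassigned") <- 0L
    return(out)
  }
  g <- calls[idx]
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nr <- length(r$values)
  changed <- 0L
  for (q in seq_len(nr)) {
    v <- r$values[q]
    if (r$lengths[q] >= min_adjacent_switch) next
    left <- if (q > 1) r$values[q - 1] else NA_character_
    right <- if (q < nr) r$values[q + 1] else NA_character_
    at_edge <- q == 1 || q == nr
    if (v %in% c("HOM_P1", "HOM_P2")) {
      het_context <- (is.na(left) || left == "HET") && (is.na(right) || right == "HET")
      if (het_context || at_edge) {
        out[idx[starts[q]:ends[q]]] <- "HET"
        changed <- changed + r$lengths[q]
      }
    } else if (symmetric && v == "HET") {
      if (!is.na(left) && !is.na(right) && left == right &&
          left %in% c("HOM_P1", "HOM_P2")) {
        out[idx[starts[q]:ends[q]]] <- left
        changed <- changed + r$lengths[q]
      }
    }
  }
  attr(out, "n_reassigned") <- changed
  out
}

#' Apply the short-run filter chromosome by chromosome
#'
#' @param calls character vector of genotype labels aligned to `map`.
#' @param map a [marker_map()] object.
#' @param ... passed to [filter_short_runs()].
#' @return Filtered calls aligned to `map`.
#' @export
filter_genotype_vector <- function(calls, map, ...) {
  stopifnot(length(calls) == n_markers(map))
  out <- calls
  for (cc in unique(map$markers$chrom)) {
    sel <- map$markers$chrom == cc
    out[sel] <- filter_short_runs(calls[sel], ...)
  }
  out
}

#' Per-window normalized sequencing depth and candidate CNV flags
#'
#' Averages a depth track in fixed windows per chromosome, normalizes each
#' window by the genome-wide median window depth, and flags windows whose
#' ratio falls at or below `flag_low` (deletion-like; 0.5 is a heterozygous
#' deletion in a diploid) or at or above `flag_high` (duplication-like; 1.5 is
#' a single-copy gain). Markers falling in flagged windows should be excluded
#' from LOH analysis (see [cnv_excluded_markers()]).
#'
#' @param depth data.frame with columns `chrom`, `pos`, `depth` (per-base or
#'   per-interval representative depth values).
#' @param window window size in bp (default 10000).
#' @param flag_low,flag_high flagging thresholds on the normalized ratio
#'   (defaults 0.75 and 1.25).
#' @return data.frame with columns `chrom`, `start`, `end`, `mean_depth`,
#'   `ratio`, `flagged`.
#' @export
coverage_windows <- function(depth, window = 10000, flag_low = 0.75,
                             flag_high = 1.25) {
  stopifnot(window > 0)
  if (!is.data.frame(depth) || nrow(depth) == 0) stop("empty depth track")
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth)))
  res <- lapply(split(depth, depth$chrom), function(d) {
    w <- (d$pos - 1) %/% window
    mu <- tapply(d$depth, w, mean)
    wi <- as.integer(names(mu))
    data.frame(chrom = d$chrom[1], start = wi * window + 1,
               end = (wi + 1) * window, mean_depth = as.numeric(mu),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  med <- stats::median(res$mean_depth)
  if (med <= 0) stop("non-positive median window depth")
  res$ratio <- res$mean_depth / med
  res$flagged <- res$ratio <= flag_low | res$ratio >= flag_high
  res
}

#' Markers lying in CNV-flagged coverage windows
#'
#' @param map a [marker_map()] object.
#' @param windows output of [coverage_windows()].
#' @return Logical vector over the markers of `map`: `TRUE` where the marker
#'   falls inside a flagged window and should be excluded from LOH analysis.
#' @export
cnv_excluded_markers <- function(map, windows) {
  fl <- windows[windows$flagged, , drop = FALSE]
  out <- rep(FALSE, n_markers(map))
  if (nrow(fl) == 0) return(out)
  for (i in seq_len(nrow(fl))) {
    out <- out | (map$markers$chrom == fl$chrom[i] &
                    map$markers$pos >= fl$start[i] & map$markers$pos <= fl$end[i])
  }
  out
}

#' Retain markers with the expected genotype in parents and hybrid
#'
#' A marker discriminates the two parental haplotypes only if the first parent
#' is homozygous P1, the second parent homozygous P2, and the hybrid
#' heterozygous. Markers where both parents share an allele are uninformative;
#' markers where the hybrid is not heterozygous indicate mapping or calling
#' artifacts.
#'
#' @param parent1,parent2,hybrid character vectors of genotype labels over the
#'   same marker set.
#' @return data.frame with logical column `keep` and character column `reason`
#'   (`NA` for kept markers; `"shared_allele"`, `"parent_genotype_unexpected"`,
#'   `"hybrid_not_heterozygous"`, or `"no_call"` otherwise).
#' @export
qc_marker_set <- function(parent1, parent2, hybrid) {
  n <- length(parent1)
  if (length(parent2) != n || length(hybrid) != n) {
    stop("genotype vectors must have equal length")
  }
  reason <- rep(NA_character_, n)
  nc <- parent1 == "NO_CALL" | parent2 == "NO_CALL" | hybrid == "NO_CALL"
  shared <- !nc & parent1 == parent2 & parent1 %in% c("HOM_P1", "HOM_P2")
  bad_parent <- !nc & !shared & (parent1 != "HOM_P1" | parent2 != "HOM_P2")
  bad_hyb <- !nc & !shared & !bad_parent & hybrid != "HET"
  reason[nc] <- "no_call"
  reason[shared] <- "shared_allele"
  reason[bad_parent] <- "parent_genotype_unexpected"
  reason[bad_hyb] <- "hybrid_not_heterozygous"
  data.frame(keep = is.na(reason), reason = reason, stringsAsFactors = FALSE)
}

#' Read per-strain allele depths
#'
#' Reads parental allele depths either from tab-separated text with header
#' columns `chrom`, `pos`, `n_p1`, `n_p2` (optionally `strain`, `n_other`) or
#' from a VCF with a per-sample `AD` FORMAT field (first two values taken as
#' the P1 and P2 allele depths; requires the vcfR package).
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample for VCF input, the sample name (default: first sample).
#' @return data.frame with columns `chrom`, `pos`, `n_p1`, `n_p2`, `n_other`.
#' @export
read_allele_depths <- function(path, format = c("tsv", "vcf"), sample = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos", "n_p1", "n_p2") %in% names(d)))
    if (is.null(d$n_other)) d$n_other <- 0L
    return(d[, c("chrom", "pos", "n_p1", "n_p2", "n_other")])
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(sample)) sample <- colnames(ad)[1]
  x <- ad[, sample]
  parts <- strsplit(x, ",", fixed = TRUE)
  n_p1 <- vapply(parts, function(p) suppressWarnings(as.integer(p[1])), integer(1))
  n_p2 <- vapply(parts, function(p) suppressWarnings(as.integer(p[2])), integer(1))
  n_p1[is.na(n_p1)] <- 0L; n_p2[is.na(n_p2)] <- 0L
  data.frame(chrom = as.character(v@fix[, "CHROM"]),
             pos = as.integer(v@fix[, "POS"]),
             n_p1 = n_p1, n_p2 = n_p2, n_other = 0L,
             stringsAsFactors = FALSE)
}

#' Write or read a genotype matrix (markers x strains)
#'
#' Tabular text with columns `chrom`, `pos` then one column per strain holding
#' `P1`, `P2`, `HET` or `NA`.
#'
#' @param geno character matrix (markers x strains) of genotype labels.
#' @param map a [marker_map()] aligned with the rows of `geno`.
#' @param path output / input file.
#' @return `write_genotype_matrix` invisibly returns `path`;
#'   `read_genotype_matrix` returns a list with `map`-compatible columns
#'   `chrom`, `pos` and matrix `geno` of full labels.
#' @export
write_genotype_matrix <- function(geno, map, path) {
  stopifnot(nrow(geno) == n_markers(map))
  short <- c(HOM_P1 = "P1", HOM_P2 = "P2", HET = "HET", NO_CALL = NA)
  out <- data.frame(chrom = map$markers$chrom, pos = map$markers$pos,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(geno))) out[[colnames(geno)[j]]] <- short[geno[, j]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA")
  long <- c(P1 = "HOM_P1", P2 = "HOM_P2", HET = "HET")
  strains <- setdiff(names(d), c("chrom", "pos"))
  geno <- sapply(strains, function(s) {
    g <- long[as.character(d[[s]])]
    g[is.na(g)] <- "NO_CALL"
    g
  })
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = length(strains),
                                         dimnames = list(NULL, strains))
  list(chrom = d$chrom, pos = d$pos, geno = geno)
}
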