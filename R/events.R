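#' Split a mother-daughter genotype pair into a pseudo-tetrad
#'
#' Each diploid genotype is split into two haplotypes ("chromatids"): at
#' homozygous markers both chromatids carry the homozygous allele; at
#' heterozygous markers the first chromatid is systematically assigned P1 and
#' the second P2. Chromatids 1-2 derive from the mother, 3-4 from the
#' daughter, giving a tetrad-like dataset. Markers where either strain is
#' `NO_CALL` are dropped pairwise.
#'
#' @param mother,daughter character genotype vectors of equal length.
#' @return A list of class `pseudo_tetrad` with elements `haplotypes`
#'   (4 x n character matrix of `"P1"`/`"P2"`) and `marker_idx` (original
#'   indices of the retained markers).
#' @export
build_pseudotetrad <- function(mother, daughter) {
  if (length(mother) != length(daughter)) stop("genotype vectors differ in length")
  keep <- which(mother != "NO_CALL" & daughter != "NO_CALL")
  split1 <- function(g) {
    rbind(ifelse(g == "HOM_P2", "P2", "P1"),
          ifelse(g == "HOM_P1", "P1", "P2"))
  }
  h <- rbind(split1(mother[keep]), split1(daughter[keep]))
  rownames(h) <- c("mother_1", "mother_2", "daughter_1", "daughter_2")
  structure(list(haplotypes = h, marker_idx = keep), class = "pseudo_tetrad")
}

#' Merge two chromatids back into a diploid genotype vector
#'
#' Inverse of the split performed by [build_pseudotetrad()] for one strain.
#'
#' @param h1,h2 character vectors of `"P1"`/`"P2"`.
#' @return Character genotype vector.
#' @export
merge_chromatids <- function(h1, h2) {
  ifelse(h1 == h2, ifelse(h1 == "P1", "HOM_P1", "HOM_P2"), "HET")
}

#' Count crossovers from classified reciprocal LOH tracts
#'
#' Each terminal rLOH tract reflects one crossover (the proximal boundary);
#' each interstitial rLOH tract reflects two consecutive crossovers on the
#' same arm.
#'
#' @param tracts either a tract data.frame (rows with
#'   `reciprocity == "rLOH"` and a filled `position` column are counted), or
#'   the number of terminal rLOH tracts.
#' @param interstitial when `tracts` is a count, the number of interstitial
#'   rLOH tracts.
#' @return Integer crossover count.
#' @examples
#' count_cos(70, 66)  # 70 + 2*66 = 202
#' @export
count_cos <- function(tracts, interstitial = NULL) {
  if (is.numeric(tracts)) {
    stopifnot(!is.null(interstitial), tracts >= 0, interstitial >= 0)
    return(as.integer(tracts + 2 * interstitial))
  }
  r <- tracts[tracts$reciprocity == "rLOH", , drop = FALSE]
  as.integer(sum(r$position == "terminal", na.rm = TRUE) +
               2 * sum(r$position == "interstitial", na.rm = TRUE))
}

#' Classify non-reciprocal LOH tracts as CO-associated GC, NCO or terminal NCO
#'
#' A gene-conversion (3:1) tract at the border of a reciprocal LOH tract is
#' the conversion associated with that crossover (`CO_GC`); a 3:1 tract lying
#' inside heterozygous context, or fully inside an rLOH tract, is a
#' non-crossover (`NCO`); a 3:1 tract reaching the last genotyped marker of
#' its arm without touching an rLOH boundary is a `TERMINAL_NCO`
#' (break-induced-replication-like).
#'
#' @param pt a `pair_tracts` object with tract positions filled (see
#'   [classify_tract_position()]).
#' @param map a [marker_map()] object.
#' @return `pt` with a `kind` column added to the tract table: `NA` for rLOH
#'   tracts, otherwise one of `"CO_GC"`, `"NCO"`, `"TERMINAL_NCO"`.
#' @export
classify_nrloh <- function(pt, map) {
  stopifnot(inherits(pt, "pair_tracts"))
  tr <- pt$tracts
  if (nrow(tr) == 0) {
    tr$kind <- character(0)
    pt$tracts <- tr
    return(pt)
  }
  tr$kind <- NA_character_
  if (any(duplicated_span(tr))) stop("overlapping tracts of the same class")
  ret_idx <- which(pt$retained)
  # map retained marker index -> enclosing rLOH tract id (incl. interleaved 3:1)
  rl <- tr[tr$reciprocity == "rLOH", , drop = FALSE]
  encl <- function(i) {
    hit <- which(rl$chrom == mk$chrom[i] & rl$start_idx <= i & rl$end_idx >= i)
    if (length(hit)) rl$tract_id[hit[1]] else NA_integer_
  }
  mk <- map$markers
  for (j in which(tr$reciprocity == "nrLOH")) {
    s <- tr$start_idx[j]; e <- tr$end_idx[j]
    on_chr <- ret_idx[mk$chrom[ret_idx] == tr$chrom[j]]
    before <- on_chr[on_chr < s]; after <- on_chr[on_chr > e]
    nb_l <- if (length(before)) max(before) else NA_integer_
    nb_r <- if (length(after)) min(after) else NA_integer_
    t_l <- if (is.na(nb_l)) NA_integer_ else encl(nb_l)
    t_r <- if (is.na(nb_r)) NA_integer_ else encl(nb_r)
    inside_rloh <- !is.na(t_l) && !is.na(t_r) && t_l == t_r
    at_boundary <- (!is.na(t_l) || !is.na(t_r)) && !inside_rloh
    if (at_boundary) {
      tr$kind[j] <- "CO_GC"
    } else if (!inside_rloh && !is.na(tr$position[j]) &&
               tr$position[j] == "terminal") {
      tr$kind[j] <- "TERMINAL_NCO"
    } else {
      tr$kind[j] <- "NCO"
    }
  }
  pt$tracts <- tr
  pt
}

duplicated_span <- function(tr) {
  bad <- rep(FALSE, nrow(tr))
  for (rec in unique(tr$reciprocity)) {
    d <- tr[tr$reciprocity == rec, , drop = FALSE]
    for (cc in unique(d$chrom)) {
      dd <- d[d$chrom == cc, , drop = FALSE]
      dd <- dd[order(dd$start_idx), , drop = FALSE]
      if (nrow(dd) > 1 && any(dd$start_idx[-1] <= dd$end_idx[-nrow(dd)])) {
        bad[tr$reciprocity == rec & tr$chrom == cc] <- TRUE
      }
    }
  }
  bad
}

#' Call recombination events from a genotyped mother-daughter pair
#'
#' End-to-end event calling: tract assembly, positional classification,
#' crossover counting and conversion-tract classification. Crossover events
#' are emitted at rLOH boundaries (one for a terminal tract, two for an
#' interstitial tract), with the breakpoint reported as the open interval
#' between the tract's outermost member marker and the nearest flanking
#' retained marker; conversion tracts are emitted as `CO_GC`, `NCO` or
#' `TERMINAL_NCO` events spanning their markers.
#'
#' @param mother,daughter character genotype vectors aligned to `map`.
#' @param map a [marker_map()] object.
#' @param exclude optional logical exclusion mask (see
#'   [assemble_pair_tracts()]).
#' @return A list of class `pair_events`: `events` (data.frame with `kind`,
#'   `chrom`, `start`, `end`, `tract_id`, `source`), `tracts` (classified
#'   tract table), `pattern`, `retained`, and `n_co` (the crossover count).
#' @export
call_events <- function(mother, daughter, map, exclude = NULL) {
  pt <- assemble_pair_tracts(mother, daughter, map, exclude)
  pt <- classify_tract_position(pt, map)
  pt <- classify_nrloh(pt, map)
  tr <- pt$tracts
  ev <- list()
  add <- function(kind, chrom, start, end, tract_id) {
    ev[[length(ev) + 1]] <<- data.frame(kind = kind, chrom = chrom,
                                        start = start, end = end,
                                        tract_id = tract_id,
                                        source = "pair_analysis",
                                        stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tr))) {
    if (tr$reciprocity[i] == "rLOH") {
      if (is.na(tr$position[i]) || tr$position[i] == "spans_centromere") next
      # proximal boundary (toward centromere) always a CO site
      bounds <- rloh_breakpoints(tr[i, ])
      for (b in bounds) add("CO", tr$chrom[i], b[1], b[2], tr$tract_id[i])
    } else {
      add(tr$kind[i], tr$chrom[i], tr$start_pos[i], tr$end_pos[i],
          tr$tract_id[i])
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(kind = character(), chrom = character(), start = integer(),
               end = integer(), tract_id = integer(), source = character(),
               stringsAsFactors = FALSE)
  if (nrow(events)) {
    events <- events[order(events$chrom, events$start), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(events = events, tracts = tr, pattern = pt$pattern,
                 retained = pt$retained, four_zero = pt$four_zero,
                 n_co = count_cos(tr)),
            class = "pair_events")
}

# breakpoint interval(s) of an rLOH tract: open flanking intervals; a terminal
# tract has one CO (proximal side), an interstitial tract two.
rloh_breakpoints <- function(t1) {
  left <- c(if (is.na(t1$left_flank_pos)) t1$start_pos else t1$left_flank_pos,
            t1$start_pos)
  right <- c(t1$end_pos,
             if (is.na(t1$right_flank_pos)) t1$end_pos else t1$right_flank_pos)
  if (t1$position == "interstitial") return(list(left, right))
  # terminal: the proximal boundary is the CO site
  if (!is.na(t1$arm) && t1$arm == "L") list(right) else list(left)
}

#' Merge closely spaced recombination events
#'
#' Events on the same chromosome whose breakpoint intervals lie within
#' `max_gap` of each other are merged into a single event; the merged kind
#' follows the precedence `CO_GC` > `CO` > `TERMINAL_NCO` > `NCO`. Merges are
#' logged in the returned attribute `"merge_log"` for review in place of
#' manual curation.
#'
#' @param events event data.frame with columns `kind`, `chrom`, `start`,
#'   `end` sorted by position.
#' @param max_gap maximum inter-event gap in bp (default 5000).
#' @return Merged event data.frame.
#' @export
merge_events <- function(events, max_gap = 5000) {
  if (nrow(events) == 0) return(events)
  prec <- c(CO_GC = 1, CO = 2, TERMINAL_NCO = 3, NCO = 4)
  out <- list(); log <- list()
  for (cc in unique(events$chrom)) {
    d <- events[events$chrom == cc, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    cur <- d[1, , drop = FALSE]
    members <- 1L
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] - cur$end <= max_gap) {
        cur$end <- max(cur$end, d$end[i])
        cur$kind <- names(prec)[min(prec[cur$kind], prec[d$kind[i]])]
        members <- members + 1L
      } else {
        if (members > 1L) log[[length(log) + 1]] <-
            sprintf("%s:%d-%d merged %d events -> %s", cc, cur$start, cur$end,
                    members, cur$kind)
        out[[length(out) + 1]] <- cur
        cur <- d[i, , drop = FALSE]
        members <- 1L
      }
    }
    if (members > 1L) log[[length(log) + 1]] <-
        sprintf("%s:%d-%d merged %d events -> %s", cc, cur$start, cur$end,
                members, cur$kind)
    out[[length(out) + 1]] <- cur
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "merge_log") <- unlist(log)
  res
}

#' Reveal masked crossovers from a sporulated RTG tetrad
#'
#' A crossover whose two recombinant chromatids co-segregated into the same
#' RTG cell leaves both cells heterozygous and is invisible to LOH analysis.
#' Sporulating the RTG diploid reveals it: the parent's two homologs are
#' reciprocal recombinants, so after meiosis all four spores switch parental
#' content across the old breakpoint, appearing as two pairs of reciprocal
#' recombinant molecules. By contrast, an exchange that happened during the
#' sporulation itself involves only two of the four chromatids, so only two
#' spores switch. Only the four-spore reciprocal switches (restricted to the
#' regions where the parent was heterozygous) are attributed to the parent.
#'
#' The function also reports Mendelian-consistency QC: markers homozygous in
#' the parent must segregate 4:0 in the tetrad, heterozygous markers 2:2 (or
#' 3:1 inside a new conversion tract).
#'
#' @param parent character genotype vector of the sporulated RTG strain.
#' @param spores 4 x n character matrix of haploid spore genotypes
#'   (`"P1"`/`"P2"`; `HOM_P1`/`HOM_P2` also accepted), aligned to `parent`.
#' @param map a [marker_map()] object.
#' @return A list of class `masked_co_report`:
#'   \describe{
#'     \item{masked}{data.frame of masked crossovers attributed to the parent
#'       (`chrom`, `start`, `end` breakpoint interval, `source =
#'       "tetrad_reveal"`).}
#'     \item{sporulation}{data.frame of two-chromatid exchanges attributed to
#'       the sporulation meiosis.}
#'     \item{complex}{intervals with one or three switching spores (new
#'       conversion tracts or complex events).}
#'     \item{qc}{list with `frac_hom_4_0` and `frac_het_2_2_or_3_1`.}
#'   }
#' @export
reveal_masked_cos <- function(parent, spores, map) {
  if (is.data.frame(spores)) spores <- as.matrix(spores)
  if (nrow(spores) != 4) stop("a tetrad must contain exactly 4 spores")
  if (ncol(spores) != length(parent) || length(parent) != n_markers(map)) {
    stop("spore matrix must be 4 x n_markers, aligned to the parent vector")
  }
  spores[spores == "HOM_P1"] <- "P1"
  spores[spores == "HOM_P2"] <- "P2"

  called <- parent != "NO_CALL" & colSums(spores == "P1" | spores == "P2") == 4
  n_p1 <- colSums(spores == "P1")
  hom <- called & parent %in% c("HOM_P1", "HOM_P2")
  het <- called & parent == "HET"
  ok_hom <- hom & ((parent == "HOM_P1" & n_p1 == 4) |
                     (parent == "HOM_P2" & n_p1 == 0))
  ok_het <- het & n_p1 %in% 1:3
  qc <- list(frac_hom_4_0 = if (any(hom)) mean(ok_hom[hom]) else NA_real_,
             frac_het_2_2_or_3_1 = if (any(het)) mean(ok_het[het]) else NA_real_)

  masked <- list(); sporu <- list(); complexes <- list()
  mk <- map$markers
  for (cc in unique(mk$chrom)) {
    sel <- which(mk$chrom == cc & het)
    if (length(sel) < 2) next
    cont <- spores[, sel, drop = FALSE] == "P1"
    for (i in seq_len(length(sel) - 1)) {
      delta <- cont[, i + 1] - cont[, i]
      ns <- sum(delta != 0)
      if (ns == 0) next
      rec <- data.frame(chrom = cc, start = mk$pos[sel[i]],
                        end = mk$pos[sel[i + 1]], n_switch = ns,
                        stringsAsFactors = FALSE)
      if (ns == 4 && sum(delta) == 0) {
        rec$source <- "tetrad_reveal"
        masked[[length(masked) + 1]] <- rec
      } else if (ns == 2 && sum(delta) == 0) {
        rec$source <- "sporulation"
        sporu[[length(sporu) + 1]] <- rec
      } else {
        rec$source <- "complex"
        complexes[[length(complexes) + 1]] <- rec
      }
    }
  }
  bind0 <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_switch = integer(), source = character(),
               stringsAsFactors = FALSE)
  structure(list(masked = bind0(masked), sporulation = bind0(sporu),
                 complex = bind0(complexes), qc = qc),
            class = "masked_co_report")
}
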