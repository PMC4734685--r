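#' Construct a hybrid marker map
#'
#' An ordered set of SNP markers distinguishing the two parental haplotypes of
#' a hybrid diploid, together with per-chromosome metadata (length and
#' centromere interval). Marker positions are 1-based.
#'
#' @param markers data.frame with columns `chrom`, `pos`, and optionally
#'   `p1_allele`, `p2_allele` (nucleotide labels of the two parental alleles).
#' @param chrom_info data.frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end` (closed centromere interval in bp).
#' @return An object of class `marker_map`: a list with elements `markers`
#'   (with an added `arm` column, `"L"`/`"R"`, `NA` inside the centromere)
#'   and `chrom_info`.
#' @examples
#' mm <- marker_map(
#'   data.frame(chrom = "chr1", pos = c(10, 120, 500)),
#'   data.frame(chrom = "chr1", length = 1000, cen_start = 200, cen_end = 300)
#' )
#' mm$markers$arm
#' @export
marker_map <- function(markers, chrom_info) {
  stopifnot(is.data.frame(markers), is.data.frame(chrom_info))
  need <- c("chrom", "pos")
  if (!all(need %in% names(markers))) {
    stop("markers must have columns: ", paste(need, collapse = ", "))
  }
  need_ci <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(need_ci %in% names(chrom_info))) {
    stop("chrom_info must have columns: ", paste(need_ci, collapse = ", "))
  }
  markers$chrom <- as.character(markers$chrom)
  chrom_info$chrom <- as.character(chrom_info$chrom)
  if (anyDuplicated(chrom_info$chrom)) stop("duplicated chromosome in chrom_info")
  if (!all(markers$chrom %in% chrom_info$chrom)) {
    stop("markers reference chromosomes absent from chrom_info")
  }
  # keep chromosome blocks in chrom_info order, positions sorted within
  markers <- markers[order(match(markers$chrom, chrom_info$chrom), markers$pos), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  for (cc in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == cc]
    if (any(diff(p) <= 0)) stop("marker positions not strictly increasing on ", cc)
    ci <- chrom_info[chrom_info$chrom == cc, ]
    if (any(p < 1) || any(p > ci$length)) stop("marker position outside [1, length] on ", cc)
  }
  with_ci <- chrom_info
  bad <- with_ci$cen_start < 1 | with_ci$cen_end > with_ci$length |
    with_ci$cen_start > with_ci$cen_end
  if (any(bad)) stop("centromere interval outside [1, length] for: ",
                     paste(with_ci$chrom[bad], collapse = ", "))
  ci_idx <- match(markers$chrom, chrom_info$chrom)
  markers$arm <- ifelse(markers$pos < chrom_info$cen_start[ci_idx], "L",
                 ifelse(markers$pos > chrom_info$cen_end[ci_idx], "R", NA_character_))
  structure(list(markers = markers, chrom_info = chrom_info), class = "marker_map")
}

#' @export
print.marker_map <- function(x, ...) {
  cat("marker_map:", nrow(x$markers), "markers on",
      nrow(x$chrom_info), "chromosome(s)\n")
  invisible(x)
}

n_markers <- function(map) nrow(map$markers)

#' Read a marker map from tabular text
#'
#' @param markers_file path to a tab-separated file with header columns
#'   `chrom`, `pos` (and optionally `p1_allele`, `p2_allele`).
#' @param chrom_file path to a tab-separated file with header columns
#'   `chrom`, `length`, `cen_start`, `cen_end`.
#' @return A [marker_map()] object.
#' @export
read_marker_map <- function(markers_file, chrom_file) {
  mk <- utils::read.table(markers_file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ci <- utils::read.table(chrom_file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  marker_map(mk, ci)
}

#' Write a marker map to tabular text
#'
#' @param map a [marker_map()] object.
#' @param markers_file,chrom_file output paths (tab-separated, with header).
#' @return Invisibly, `map`.
#' @export
write_marker_map <- function(map, markers_file, chrom_file) {
  utils::write.table(map$markers[setdiff(names(map$markers), "arm")],
                     markers_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(map$chrom_info, chrom_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(map)
}

#' Chromosome sizes and centromere positions of S. cerevisiae
#'
#' Approximate chromosome lengths and centromere midpoints of the sixteen
#' S. cerevisiae nuclear chromosomes (reference assembly coordinates, rounded
#' to the nearest kb), used as the default genome emulated by the simulator.
#' The centromere interval is taken as the 2 kb window centred on the point
#' centromere.
#'
#' @return data.frame with columns `chrom`, `length`, `cen_start`, `cen_end`.
#' @export
yeast_chromosomes <- function() {
  len <- c(230218, 813184, 316620, 1531933, 576874, 270161, 1090940, 562643,
           439888, 745751, 666816, 1078177, 924431, 784333, 1091291, 948066)
  cen <- c(151465, 238207, 114385, 449711, 151987, 148510, 496920, 105586,
           355629, 436307, 440129, 150828, 268031, 628758, 326584, 555957)
  data.frame(chrom = paste0("chr", as.character(utils::as.roman(1:16))),
             length = len,
             cen_start = cen - 1000L, cen_end = cen + 1000L,
             stringsAsFactors = FALSE)
}
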