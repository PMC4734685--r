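#' Run configuration for the full pair-analysis pipeline
#'
#' Bundles inputs and parameters for [run_pipeline()]. Inputs may be given as
#' in-memory objects or as file paths (tab-separated dialects described in
#' [read_marker_map()] and [read_allele_depths()]).
#'
#' @param map a [marker_map()] object, or `NULL` if `marker_file` is given.
#' @param marker_file,chrom_file paths to marker map files.
#' @param mother_depths,daughter_depths allele-depth data.frames (columns
#'   `n_p1`, `n_p2`, optionally `n_other`, aligned to the map) or file paths.
#' @param depth_track optional data.frame (`chrom`, `pos`, `depth`) for CNV
#'   screening; markers in flagged windows are excluded from LOH analysis.
#' @param thresholds a [genotyping_thresholds()] object.
#' @param max_gap merge distance for closely spaced events in bp (default
#'   5000).
#' @param correction a [correction_params()] object.
#' @param out_dir output directory (created if absent); `NULL` to skip
#'   writing files.
#' @param seed integer seed recorded in the run log.
#' @return A list of class `run_config`.
#' @export
run_config <- function(map = NULL, marker_file = NULL, chrom_file = NULL,
                       mother_depths, daughter_depths = NULL,
                       depth_track = NULL,
                       thresholds = genotyping_thresholds(),
                       max_gap = 5000,
                       correction = correction_params(),
                       out_dir = NULL, seed = 1L) {
  if (is.null(map)) {
    if (is.null(marker_file) || is.null(chrom_file)) {
      stop("pipeline stage 'input': provide either map or marker_file + chrom_file")
    }
    map <- read_marker_map(marker_file, chrom_file)
  }
  structure(list(map = map, mother_depths = mother_depths,
                 daughter_depths = daughter_depths, depth_track = depth_track,
                 thresholds = thresholds, max_gap = max_gap,
                 correction = correction, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the pair-analysis pipeline end to end
#'
#' Executes genotyping (with the short-run filter), CNV screening when a
#' depth track is supplied, LOH tract assembly and classification,
#' recombination event calling and merging, and detection correction of the
#' observed counts. When `out_dir` is set, writes the genotype matrix, the
#' tract table and BED, the event table, a JSON summary and a plain-text run
#' log (package version, seed, parameter digest). A rerun with identical
#' configuration and inputs produces byte-identical outputs.
#'
#' @param config a [run_config()] object.
#' @return A list of class `pipeline_result`: `geno` (markers x 2 matrix),
#'   `windows` (coverage windows or `NULL`), `result` (a `pair_events`
#'   object), `merged_events`, `correction` (a `corrected_counts` object),
#'   `summary` (named list of headline numbers).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  map <- config$map
  get_depths <- function(x, who) {
    if (is.null(x)) stop("pipeline stage 'input': missing ", who, " depths")
    if (is.character(x)) x <- read_allele_depths(x)
    if (nrow(x) != n_markers(map)) {
      stop("pipeline stage 'input': ", who,
           " depths not aligned to marker map (", nrow(x), " vs ",
           n_markers(map), " rows)")
    }
    x
  }
  md <- get_depths(config$mother_depths, "mother")
  dd <- get_depths(config$daughter_depths, "daughter")
  th <- config$thresholds

  mother <- call_genotypes(md$n_p1, md$n_p2,
                           if (is.null(md$n_other)) 0 else md$n_other, th)
  daughter <- call_genotypes(dd$n_p1, dd$n_p2,
                             if (is.null(dd$n_other)) 0 else dd$n_other, th)
  mother <- filter_genotype_vector(mother, map, th$min_adjacent_switch)
  daughter <- filter_genotype_vector(daughter, map, th$min_adjacent_switch)
  geno <- cbind(mother = mother, daughter = daughter)

  windows <- NULL
  exclude <- NULL
  if (!is.null(config$depth_track)) {
    windows <- coverage_windows(config$depth_track)
    exclude <- cnv_excluded_markers(map, windows)
  }

  res <- call_events(mother, daughter, map, exclude)
  merged <- if (nrow(res$events)) merge_events(res$events, config$max_gap)
            else res$events
  nr <- sum(res$tracts$reciprocity == "nrLOH")
  corr <- correct_counts(res$n_co, nr, config$correction)

  summary <- list(
    n_markers = n_markers(map),
    n_called_pairwise = sum(res$retained) + length(res$four_zero),
    n_rloh = sum(res$tracts$reciprocity == "rLOH"),
    n_nrloh = nr,
    n_four_zero_markers = length(res$four_zero),
    observed_co = res$n_co,
    corrected_co = unname(corr$co),
    corrected_gc_co = unname(corr$gc_co),
    corrected_nco = unname(corr$nco),
    seed = config$seed)

  out <- structure(list(geno = geno, windows = windows, result = res,
                        merged_events = merged, correction = corr,
                        summary = summary),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, map, config)
  out
}

write_pipeline_outputs <- function(out, map, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_genotype_matrix(out$geno, map, p("genotypes.tsv"))
  utils::write.table(out$result$tracts, p("tracts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tracts_to_bed(out$result$tracts, p("tracts.bed"))
  utils::write.table(out$merged_events, p("events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("rtgrecomb %s", as.character(utils::packageVersion("rtgrecomb"))),
    sprintf("seed: %d", config$seed),
    sprintf("max_gap: %g", config$max_gap),
    sprintf("thresholds: depth>%g parental>=%.3f p1hom>%.2f p2hom>%.2f runs>=%d",
            config$thresholds$min_depth_exclusive,
            config$thresholds$min_parental_fraction,
            config$thresholds$p1_hom_min, config$thresholds$p2_hom_min,
            config$thresholds$min_adjacent_switch),
    sprintf("correction: p_low=%.4f p_high=%.4f gc_frac=%.2f",
            config$correction$p_low, config$correction$p_high,
            config$correction$gc_frac))
  writeLines(log_lines, p("run_log.txt"))
  invisible(out)
}
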