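#' Single-marker LOD scan over a cohort of genotyped diploids
#'
#' At each marker, strains are grouped by diploid genotype class (`HOM_P1`,
#' `HET`, `HOM_P2`; `NO_CALL` strains are dropped marker-wise) and the LOD
#' score is the log10 likelihood ratio of the genotype-dependent model
#' against the null of no association. With `model = "normal"` the phenotype
#' is modelled as Gaussian with class-specific means (the LOD is
#' `n/2 * log10(RSS0/RSS1)`); with `model = "binary"` the phenotype must be
#' 0/1 and class-specific Bernoulli rates are used. Markers monomorphic
#' across the cohort carry no linkage information and are absent from the
#' scan.
#'
#' Because the cohort is genotyped at dense markers, a single-marker scan is
#' used (no interval mapping or genotype imputation).
#'
#' @param geno character matrix (markers x strains) of genotype labels.
#' @param trait numeric phenotype vector, one value per strain (binary 0/1
#'   for `model = "binary"`).
#' @param map optional [marker_map()] supplying `chrom`/`pos` for the rows.
#' @param model phenotype model, `"normal"` (default) or `"binary"`.
#' @return data.frame of class `lod_scan` with columns `marker` (row index
#'   into `geno`), `chrom`, `pos` (if `map` given), `n` (strains used) and
#'   `lod`. Perfect separation yields `Inf`.
#' @export
lod_scan <- function(geno, trait, map = NULL, model = c("normal", "binary")) {
  model <- match.arg(model)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  if (ncol(geno) != length(trait)) {
    stop("trait must have one value per strain (column of geno)")
  }
  if (anyNA(trait)) stop("missing phenotype values are not supported")
  if (model == "binary" && !all(trait %in% c(0, 1))) {
    stop("binary model requires a 0/1 trait")
  }
  lods <- lod_matrix(geno, matrix(trait, ncol = 1), model)
  keep <- !is.na(lods$lod[, 1])
  if (stats::var(trait) == 0) {
    warning("phenotype constant across strains; all LOD scores are zero")
  }
  out <- data.frame(marker = which(keep),
                    n = lods$n[keep],
                    lod = lods$lod[keep, 1])
  if (!is.null(map)) {
    out$chrom <- map$markers$chrom[out$marker]
    out$pos <- map$markers$pos[out$marker]
    out <- out[, c("marker", "chrom", "pos", "n", "lod")]
  }
  class(out) <- c("lod_scan", "data.frame")
  out
}

# Vectorized LOD computation for one or many phenotype columns.
# Returns lod: markers x ncol(Y) (NA rows = monomorphic / unusable markers),
# and n: strains used per marker.
lod_matrix <- function(geno, Y, model) {
  classes <- c("HOM_P1", "HET", "HOM_P2")
  A <- lapply(classes, function(cl) (geno == cl) * 1)
  A_any <- A[[1]] + A[[2]] + A[[3]]
  n_used <- rowSums(A_any)
  present <- sapply(A, function(a) rowSums(a) > 0)
  if (is.null(dim(present))) present <- matrix(present, nrow = 1)
  usable <- rowSums(present) >= 2 & n_used >= 3
  Y2 <- Y^2
  Sy <- A_any %*% Y
  SS <- A_any %*% Y2
  if (model == "normal") {
    RSS0 <- SS - Sy^2 / n_used
    fit <- 0
    for (a in A) {
      nc <- rowSums(a)
      Sc <- a %*% Y
      term <- Sc^2 / ifelse(nc == 0, 1, nc)
      term[nc == 0, ] <- 0
      fit <- fit + term
    }
    RSS1 <- pmax(SS - fit, 0)
    RSS0 <- pmax(RSS0, 0)
    lod <- (n_used / 2) * log10(RSS0 / RSS1)  # RSS1 = 0 -> Inf (separation)
    lod[RSS0 <= 0] <- 0                       # constant phenotype at marker
  } else {
    bin_ll <- function(k, n) {
      p <- k / ifelse(n == 0, 1, n)
      l <- k * log(ifelse(p > 0, p, 1)) + (n - k) * log(ifelse(p < 1, 1 - p, 1))
      l[n == 0] <- 0
      l
    }
    ll1 <- 0
    for (a in A) {
      nc <- rowSums(a)
      k <- a %*% Y
      ll1 <- ll1 + bin_ll(k, nc)
    }
    ll0 <- bin_ll(Sy, n_used)
    lod <- (ll1 - ll0) / log(10)
  }
  lod <- pmax(lod, 0)
  lod[!usable, ] <- NA_real_
  list(lod = lod, n = n_used)
}

#' Genome-wide significance threshold by phenotype permutation
#'
#' Permutes the phenotype labels, records the maximum LOD of each permuted
#' genome-wide scan, and returns the upper `alpha` empirical quantile
#' (conservative ceiling-index order statistic). A marker exceeding this
#' threshold is genome-wide significant at level `alpha`.
#'
#' @param geno,trait,map,model as in [lod_scan()].
#' @param n_perm number of permutations (default 1000; at least 100).
#' @param alpha genome-wide type-I level (default 0.05).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return Numeric threshold, with attribute `"max_lods"` holding the
#'   permutation distribution.
#' @export
permutation_threshold <- function(geno, trait, n_perm = 1000, alpha = 0.05,
                                  seed, map = NULL,
                                  model = c("normal", "binary")) {
  model <- match.arg(model)
  if (missing(seed)) stop("a seed is required")
  if (n_perm < 100) stop("use at least 100 permutations")
  if (stats::var(trait) == 0) stop("phenotype constant across strains")
  set.seed(seed)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  Y <- replicate(n_perm, sample(trait))
  lods <- lod_matrix(geno, Y, model)$lod
  max_lods <- apply(lods, 2, max, na.rm = TRUE)
  idx <- ceiling((1 - alpha) * n_perm)
  thr <- if (idx < 1) 0 else sort(max_lods)[idx]
  attr(thr, "max_lods") <- max_lods
  thr
}

#' Contiguous marker intervals exceeding a LOD threshold
#'
#' @param scan a [lod_scan()] result carrying `chrom`/`pos` columns.
#' @param threshold LOD threshold (from [permutation_threshold()]).
#' @return data.frame with one row per significant interval: `chrom`,
#'   `start`, `end`, `peak_pos`, `peak_lod`, `n_markers`.
#' @export
significant_intervals <- function(scan, threshold) {
  stopifnot(all(c("chrom", "pos") %in% names(scan)))
  out <- list()
  for (cc in unique(scan$chrom)) {
    d <- scan[scan$chrom == cc, , drop = FALSE]
    s <- d$lod > threshold
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (q in which(r$values)) {
      seg <- d[starts[q]:ends[q], , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = cc, start = seg$pos[1], end = seg$pos[nrow(seg)],
        peak_pos = seg$pos[which.max(seg$lod)], peak_lod = max(seg$lod),
        n_markers = nrow(seg), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               peak_pos = integer(), peak_lod = numeric(),
               n_markers = integer(), stringsAsFactors = FALSE)
}
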