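#' Probability that crossovers manifest as reciprocal LOH
#'
#' Exhaustive enumeration of the generative model for `k` crossovers on one
#' chromosomal arm followed by equational segregation. Four chromatids start
#' with parental content: chromatids 1-2 are sisters carrying P1, chromatids
#' 3-4 sisters carrying P2, each sister pair joined at the original
#' centromere. Crossovers are applied proximal to distal; each uniformly
#' chooses one of the four chromatid pairs whose *current distal content* is
#' opposite (exactly four such pairs always exist, since two chromatids carry
#' each parental distal content at all times) and exchanges the content distal
#' to the site. Equational segregation then sends one chromatid of each
#' original sister pair to the mother (four equiprobable outcomes). In each
#' outcome a terminal homozygous run counts as one detected crossover and an
#' interstitial run as two; the detection probability is the expected number
#' of detected crossovers divided by `k`.
#'
#' A single crossover is detected in half of the outcomes; the probability
#' rises with `k` and tends to 2/3. The alternative `"inter_homolog"` rule
#' (uniform over the four original inter-homolog chromatid pairs, content
#' blind) is provided for model comparison only: it yields 0.375 at `k = 2`
#' and does not reproduce the observed detection behaviour of RTG pairs.
#'
#' @param k number of crossovers on the arm (`k >= 1`).
#' @param rule chromatid pair-choice rule: `"opposite_content"` (default) or
#'   `"inter_homolog"`.
#' @param method `"exhaustive"` enumerates all `4^k` pair-choice sequences
#'   times 4 segregations (exact, feasible for `k <= 10`); `"transfer"` uses
#'   an exact transfer-matrix recursion over the six distal-content
#'   assignments (equivalent, any `k`); `"auto"` picks exhaustive for
#'   `k <= 7`.
#' @return A list of class `detection_enum`: `k`, `p` (detection
#'   probability), `pct`, `expected_terminal` and `expected_interstitial`
#'   (expected number of terminal / interstitial rLOH tracts per outcome),
#'   and, for the exhaustive method, `tally` (table of detected-crossover
#'   counts over all outcomes).
#' @examples
#' enumerate_detection(1)$p    # 0.5
#' enumerate_detection(2)$pct  # 62.5
#' @export
enumerate_detection <- function(k, rule = c("opposite_content", "inter_homolog"),
                                method = c("auto", "exhaustive", "transfer")) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be a single integer >= 1")
  }
  if (method == "auto") method <- if (k <= 7) "exhaustive" else "transfer"
  if (method == "exhaustive" && k > 10) {
    stop("exhaustive enumeration is limited to k <= 10; use method = \"transfer\"")
  }
  if (method == "exhaustive") enum_exhaustive(k, rule) else enum_transfer(k, rule)
}

# pairs with opposite distal content given a 0/1 content vector
opposite_pairs <- function(distal) {
  prs <- which(outer(distal, distal, "!="), arr.ind = TRUE)
  prs[prs[, 1] < prs[, 2], , drop = FALSE]
}

inter_homolog_pairs <- cbind(a = c(1L, 1L, 2L, 2L), b = c(3L, 4L, 3L, 4L))

# detected-CO count for one chromatid pair: agreement sequence over segments
# 0..k; terminal hom run counts 1, interstitial 2
detected_for_pair <- function(agree) {
  r <- rle(agree)
  ends <- cumsum(r$lengths)
  sum(ifelse(r$values, ifelse(ends == length(agree), 1, 2), 0))
}

enum_exhaustive <- function(k, rule) {
  init <- matrix(c(1L, 1L, 0L, 0L), nrow = 4, ncol = k + 1)
  tally <- integer(2 * k + 3)  # detected counts 0 .. 2k+2 (offset by 1)
  term <- 0; inter <- 0; n_out <- 0
  recurse <- function(state, j) {
    if (j > k) {
      for (mi in 1:2) for (mj in 3:4) {
        agree <- state[mi, ] == state[mj, ]
        r <- rle(agree)
        ends <- cumsum(r$lengths)
        n_term <- sum(r$values & ends == k + 1)
        n_int <- sum(r$values) - n_term
        det <- n_term + 2 * n_int
        tally[det + 1] <<- tally[det + 1] + 1L
        term <<- term + n_term; inter <<- inter + n_int
        n_out <<- n_out + 1
      }
      return(invisible())
    }
    prs <- if (rule == "opposite_content") opposite_pairs(state[, j + 1])
           else inter_homolog_pairs
    seg <- (j + 1):(k + 1)
    for (p in seq_len(nrow(prs))) {
      st <- state
      tmp <- st[prs[p, 1], seg]
      st[prs[p, 1], seg] <- st[prs[p, 2], seg]
      st[prs[p, 2], seg] <- tmp
      recurse(st, j + 1)
    }
  }
  recurse(init, 1)
  det_total <- sum((seq_along(tally) - 1) * tally)
  structure(list(k = k, rule = rule, method = "exhaustive",
                 p = det_total / (k * n_out), pct = 100 * det_total / (k * n_out),
                 expected_terminal = term / n_out,
                 expected_interstitial = inter / n_out,
                 tally = stats::setNames(tally, seq_along(tally) - 1),
                 n_outcomes = n_out),
            class = "detection_enum")
}

# exact transfer-matrix recursion over the 6 assignments of distal content.
# The distal-content process is a Markov chain; segment s carries the chain
# state after s transitions, and for a segregation pair (i,j) the expected
# detected count is sum_s 2*P(hom starts at s) - P(hom at the last segment).
enum_transfer <- function(k, rule) {
  states <- utils::combn(4, 2, simplify = FALSE)  # chromatids carrying P1
  key <- vapply(states, paste, character(1), collapse = ",")
  idx <- function(s) match(paste(sort(s), collapse = ","), key)
  ns <- length(states)
  Tm <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    p1 <- states[[i]]; p2 <- setdiff(1:4, p1)
    prs <- if (rule == "opposite_content") {
      as.matrix(expand.grid(a = p1, b = p2))
    } else inter_homolog_pairs
    for (r in seq_len(nrow(prs))) {
      a <- prs[r, 1]; b <- prs[r, 2]
      new <- p1
      if (a %in% p1 && !(b %in% p1)) new <- c(setdiff(p1, a), b)
      if (b %in% p1 && !(a %in% p1)) new <- c(setdiff(p1, b), a)
      Tm[i, idx(new)] <- Tm[i, idx(new)] + 1 / nrow(prs)
    }
  }
  segpairs <- list(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
  hom <- vapply(seq_len(ns), function(st) vapply(segpairs, function(pr) {
    (pr[1] %in% states[[st]]) == (pr[2] %in% states[[st]])
  }, logical(1)), logical(4))  # 4 pairs x 6 states
  v <- numeric(ns); v[idx(c(1, 2))] <- 1
  e_det <- 0; e_runs <- 0
  for (s in seq_len(k)) {
    J <- v * Tm                      # joint P(d_{s-1}=i, d_s=j)
    for (pq in 1:4) {
      start_prob <- sum(J[!hom[pq, ], hom[pq, ], drop = FALSE])
      e_det <- e_det + 2 * start_prob / 4
      e_runs <- e_runs + start_prob / 4
    }
    v <- colSums(J)
  }
  e_term <- sum(vapply(1:4, function(pq) sum(v[hom[pq, ]]), numeric(1))) / 4
  e_det <- e_det - e_term
  structure(list(k = k, rule = rule, method = "transfer",
                 p = e_det / k, pct = 100 * e_det / k,
                 expected_terminal = e_term,
                 expected_interstitial = e_runs - e_term,
                 tally = NULL, n_outcomes = NA_integer_),
            class = "detection_enum")
}

#' @export
print.detection_enum <- function(x, ...) {
  cat(sprintf("CO detection for k = %d (%s rule): p = %.6f (%.1f%%)\n",
              x$k, x$rule, x$p, x$pct))
  cat(sprintf("  expected terminal rLOH %.4f, interstitial %.4f per outcome\n",
              x$expected_terminal, x$expected_interstitial))
  invisible(x)
}

#' Tabulate detection probabilities for a range of crossover counts
#'
#' @param k_max maximum crossover count per arm.
#' @param ... passed to [enumerate_detection()].
#' @return data.frame with columns `k`, `p`, `pct`, `expected_terminal`,
#'   `expected_interstitial`.
#' @export
detection_table <- function(k_max = 10, ...) {
  rows <- lapply(seq_len(k_max), function(k) {
    e <- enumerate_detection(k, ...)
    data.frame(k = k, p = e$p, pct = e$pct,
               expected_terminal = e$expected_terminal,
               expected_interstitial = e$expected_interstitial)
  })
  do.call(rbind, rows)
}

#' Monte-Carlo sampler of the crossover detection model
#'
#' Samples the same generative model as [enumerate_detection()] (random pair
#' choices and segregation instead of enumeration), as a convergence check
#' and for large `k`.
#'
#' @param k crossovers per arm.
#' @param n number of draws.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param rule pair-choice rule, as in [enumerate_detection()].
#' @return A list with `p` (mean detected fraction), `se` (standard error of
#'   the per-draw detected fraction), and `n`.
#' @export
sample_detection <- function(k, n = 1e5, seed, rule = c("opposite_content",
                                                        "inter_homolog")) {
  rule <- match.arg(rule)
  stopifnot(k >= 1, n >= 1)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  fracs <- numeric(n)
  for (d in seq_len(n)) {
    state <- matrix(c(1L, 1L, 0L, 0L), nrow = 4, ncol = k + 1)
    for (j in seq_len(k)) {
      prs <- if (rule == "opposite_content") opposite_pairs(state[, j + 1])
             else inter_homolog_pairs
      p <- prs[sample.int(nrow(prs), 1), ]
      seg <- (j + 1):(k + 1)
      tmp <- state[p[1], seg]
      state[p[1], seg] <- state[p[2], seg]
      state[p[2], seg] <- tmp
    }
    mi <- sample(1:2, 1); mj <- sample(3:4, 1)
    fracs[d] <- detected_for_pair(state[mi, ] == state[mj, ]) / k
  }
  list(p = mean(fracs), se = stats::sd(fracs) / sqrt(n), n = n)
}

#' Expected crossover detection frequency for a per-arm crossover multiset
#'
#' The expected detection frequency of a cell's crossovers is the average of
#' the per-crossover detection probabilities: arms carrying `k` crossovers
#' contribute `k` crossovers each detected with probability `p(k)`.
#'
#' @param arm_co_counts integer vector of crossover counts, one entry per arm
#'   that carries at least one crossover.
#' @param table optional precomputed [detection_table()]; computed on the fly
#'   otherwise.
#' @return Expected detection frequency in percent.
#' @examples
#' expected_detection_frequency(c(1, 1, 1, 1, 1, 1, 2, 2))  # 55
#' @export
expected_detection_frequency <- function(arm_co_counts, table = NULL) {
  if (length(arm_co_counts) == 0) stop("empty crossover multiset")
  stopifnot(all(arm_co_counts >= 1), all(arm_co_counts == round(arm_co_counts)))
  if (is.null(table)) table <- detection_table(max(arm_co_counts))
  if (!all(arm_co_counts %in% table$k)) stop("table does not cover all k present")
  p <- table$pct[match(arm_co_counts, table$k)]
  sum(arm_co_counts * p) / sum(arm_co_counts)
}

#' Detection-correction parameters
#'
#' @param p_low,p_high lower and upper bounds of the crossover detection
#'   probability under equational segregation (defaults 1/2 and 2/3, the
#'   exact limits of the enumeration).
#' @param gc_frac fraction of observed crossovers associated with an adjacent
#'   gene conversion (default 0.81).
#' @return A list of class `correction_params`.
#' @export
correction_params <- function(p_low = 1 / 2, p_high = 2 / 3, gc_frac = 0.81) {
  if (!(p_low > 0 && p_low <= p_high && p_high <= 1)) {
    stop("need 0 < p_low <= p_high <= 1")
  }
  stopifnot(gc_frac >= 0, gc_frac <= 1)
  structure(list(p_low = p_low, p_high = p_high, gc_frac = gc_frac),
            class = "correction_params")
}

#' Correct observed event counts for masked crossovers
#'
#' Because a crossover is detected with probability between `p_low` and
#' `p_high`, the real crossover count lies between `observed_co / p_high` and
#' `observed_co / p_low`. The corrected number of GC-associated crossovers is
#' `gc_frac` times the corrected crossover count, and the corrected
#' non-crossover count is the observed number of non-reciprocal LOH tracts
#' minus the corrected GC-associated crossovers (low NCO paired with high
#' GC-CO). The NCO/CO fold-excess range pairs the low NCO endpoint with the
#' high CO endpoint and vice versa. All counts are rounded to the nearest
#' integer.
#'
#' @param observed_co observed crossover count (from [count_cos()]).
#' @param observed_nrloh observed non-reciprocal LOH tract count.
#' @param params a [correction_params()] object.
#' @return A list of class `corrected_counts` with two-element ranges
#'   (`c(low, high)`): `co`, `gc_co`, `nco`, `nco_co_ratio`.
#' @examples
#' correct_counts(202, 913)
#' @export
correct_counts <- function(observed_co, observed_nrloh,
                           params = correction_params()) {
  stopifnot(observed_co >= 0, observed_nrloh >= 0)
  co <- c(low = round(observed_co / params$p_high),
          high = round(observed_co / params$p_low))
  gc_co <- round(params$gc_frac * co)
  nco <- c(low = observed_nrloh - gc_co[["high"]],
           high = observed_nrloh - gc_co[["low"]])
  ratio <- c(low = if (co[["high"]] > 0) nco[["low"]] / co[["high"]] else NA_real_,
             high = if (co[["low"]] > 0) nco[["high"]] / co[["low"]] else NA_real_)
  structure(list(observed_co = observed_co, observed_nrloh = observed_nrloh,
                 co = co, gc_co = gc_co, nco = nco, nco_co_ratio = ratio,
                 params = params),
            class = "corrected_counts")
}

#' @export
print.corrected_counts <- function(x, ...) {
  cat(sprintf("observed: %d COs, %d nrLOH tracts\n",
              x$observed_co, x$observed_nrloh))
  cat(sprintf("corrected CO:    [%d, %d]\n", x$co[1], x$co[2]))
  cat(sprintf("corrected GC-CO: [%d, %d]\n", x$gc_co[1], x$gc_co[2]))
  cat(sprintf("corrected NCO:   [%d, %d]\n", x$nco[1], x$nco[2]))
  cat(sprintf("NCO/CO excess:   %.2f- to %.2f-fold\n",
              x$nco_co_ratio[1], x$nco_co_ratio[2]))
  invisible(x)
}

#' Compare an observed crossover detection rate with its expectation
#'
#' @param detected number of crossovers detected as reciprocal LOH.
#' @param masked number of masked crossovers revealed by tetrad sequencing.
#' @param expected_pct expected detection frequency in percent (from
#'   [expected_detection_frequency()]).
#' @return A list with `observed_pct`, `expected_pct` and `p_value`
#'   (two-sided Fisher exact test of the observed detected/masked split
#'   against the expected split at the same total).
#' @examples
#' compare_detection_rates(77, 37, 60.5)$observed_pct  # 67.5
#' @export
compare_detection_rates <- function(detected, masked, expected_pct) {
  stopifnot(detected >= 0, masked >= 0)
  total <- detected + masked
  if (total == 0) stop("detected and masked cannot both be zero")
  observed_pct <- 100 * detected / total
  p_value <- NA_real_
  if (!missing(expected_pct) && !is.null(expected_pct)) {
    exp_det <- round(expected_pct / 100 * total)
    tab <- matrix(c(detected, masked, exp_det, total - exp_det), nrow = 2)
    p_value <- stats::fisher.test(tab)$p.value
  }
  list(observed_pct = observed_pct,
       expected_pct = if (missing(expected_pct)) NA_real_ else expected_pct,
       p_value = p_value)
}
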