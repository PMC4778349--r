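#' Per-motif steady-state RNA effect: log2(RNA/DNA) ratio
#'
#' Compares a cDNA (RNA) library with a genomic DNA library from the same
#' gated cells. After replicate aggregation and RPM normalization, each
#' motif's ratio `rho = log2(rna_rpm / dna_rpm)` measures its per-cell
#' steady-state transcript abundance relative to the library. Swapping the
#' two tables negates every ratio.
#'
#' @param rna_table,dna_table `count_table`s (replicates are summed if a
#'   `replicate` column is present; RPM recomputed).
#' @param motifs Optional restriction, normally the robust background set.
#' @param population Population to use when the tables contain several
#'   (default: the stringent background); ignored for single-population
#'   tables.
#' @param cutoffs Classification cutoffs on `rho`, see
#'   [classify_stability()].
#' @return A `stability_table` data frame: `motif`, `dna_rpm`, `rna_rpm`,
#'   `log2_ratio`, `class`. Motifs with zero reads in either library are
#'   dropped with a warning (ratio undefined).
#' @export
rna_dna_ratio <- function(rna_table, dna_table, motifs = NULL,
                          population = NULL, cutoffs = c(-0.5, 0.5)) {
  prep <- function(tb) {
    if (!is.null(population) && "population" %in% names(tb)) {
      tb <- tb[tb$population == population, , drop = FALSE]
    }
    if (!"population" %in% names(tb)) tb$population <- "library"
    if ("replicate" %in% names(tb)) tb <- aggregate_replicates(tb, "sum")
    else tb <- normalize_rpm(tb)
    stats::setNames(tb$rpm, tb$motif)
  }
  rna <- prep(rna_table)
  dna <- prep(dna_table)
  common <- intersect(names(rna), names(dna))
  if (!is.null(motifs)) common <- intersect(common, motifs)
  assert_that(length(common) > 0, "no shared motifs between RNA and DNA")
  rna <- rna[common]
  dna <- dna[common]
  bad <- rna <= 0 | dna <= 0
  if (any(bad)) {
    warning(sum(bad), " motif(s) dropped: zero reads in RNA or DNA library")
  }
  rho <- log2(rna[!bad] / dna[!bad])
  out <- data.frame(motif = common[!bad],
                    dna_rpm = unname(dna[!bad]),
                    rna_rpm = unname(rna[!bad]),
                    log2_ratio = unname(rho),
                    class = classify_stability(unname(rho), cutoffs),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Classify log2(RNA/DNA) ratios
#'
#' Cutoffs (default +/-0.5) bracket the ratio observed for the screen's
#' destabilizing miR-10 target-site control (-0.55). Comparisons are strict:
#' a ratio of exactly 0.5 is neutral.
#'
#' @param rho Numeric log2(RNA/DNA) ratios.
#' @param cutoffs Length-2 increasing numeric `(destabilizing, stabilizing)`.
#' @return Character vector: `"stabilizing"`, `"destabilizing"` or
#'   `"neutral"`.
#' @export
classify_stability <- function(rho, cutoffs = c(-0.5, 0.5)) {
  assert_that(length(cutoffs) == 2 && cutoffs[1] < cutoffs[2],
              "cutoffs must be increasing")
  ifelse(rho > cutoffs[2], "stabilizing",
         ifelse(rho < cutoffs[1], "destabilizing", "neutral"))
}

#' Fit a first-order decay half-life from a time course
#'
#' Transcript abundance after transcriptional shut-off (actinomycin D) is
#' modelled as first-order decay, `ln a(t) = c - k t`, fitted by ordinary
#' least squares on log abundance over all provided points (replicates are
#' pooled into one fit). The half-life is `t1/2 = ln(2) / k` with standard
#' error propagated as `se(t1/2) = ln(2) se(k) / k^2`.
#'
#' @param time Numeric times (hours); at least 3 distinct timepoints.
#' @param abundance Positive normalized abundances (reference-gene and
#'   t = 0 normalized upstream, e.g. via [ddct_abundance()]).
#' @return List with `half_life` (hours; `NA` when non-decaying), `k`,
#'   `se_k`, `se_half_life`, `decaying` flag, and the `lm` fit. A fitted
#'   `k <= 0` is flagged as non-decaying rather than an error.
#' @examples
#' fit_half_life(c(0, 1, 2), c(1, 0.5, 0.25))$half_life # exactly 1
#' @export
fit_half_life <- function(time, abundance) {
  assert_that(length(time) == length(abundance),
              "time and abundance lengths differ")
  assert_that(length(unique(time)) >= 3,
              "need at least 3 distinct timepoints")
  if (any(abundance <= 0)) abort("abundances must be strictly positive")
  fit <- stats::lm(log(abundance) ~ time)
  # noiseless series trigger the harmless "essentially perfect fit" warning
  co <- suppressWarnings(summary(fit)$coefficients)
  k <- -co["time", "Estimate"]
  se_k <- co["time", "Std. Error"]
  if (k <= 0) {
    warning("non-decaying series: fitted decay rate k = ",
            signif(k, 3), " <= 0; half-life undefined")
    return(list(half_life = NA_real_, k = k, se_k = se_k,
                se_half_life = NA_real_, decaying = FALSE, fit = fit))
  }
  list(half_life = log(2) / k, k = k, se_k = se_k,
       se_half_life = log(2) * se_k / k^2, decaying = TRUE, fit = fit)
}

#' Relative abundance from qPCR Ct values (delta-delta-Ct)
#'
#' Converts paired target/reference Ct values to abundances
#' `2^-(Ct_target - Ct_ref)`, normalized so the first element (the t = 0
#' sample) equals 1. Reference-gene normalization (e.g. GAPDH) is implicit
#' in the subtraction.
#'
#' @param ct_target,ct_ref Numeric Ct vectors of equal length, ordered with
#'   the t = 0 measurement first.
#' @return Numeric relative abundances, first element 1.
#' @export
ddct_abundance <- function(ct_target, ct_ref) {
  assert_that(length(ct_target) == length(ct_ref),
              "Ct vectors must have equal length")
  a <- 2^-(ct_target - ct_ref)
  a / a[1L]
}

#' Correlate expression scores with RNA/DNA stability ratios
#'
#' Pearson correlation (with two-sided p-value) over the motif
#' intersection, plus the discordant sets: motifs called activating by the
#' expression score but destabilizing by the RNA/DNA ratio, and vice versa.
#' Discordant motifs are candidates for regulation at the level of
#' translation rather than mRNA stability; the screen itself cannot separate
#' elements acting on stability alone from those acting on both.
#'
#' @param scores A `score_table` (needs `motif`, `score`, `class`).
#' @param stability A `stability_table` (needs `motif`, `log2_ratio`,
#'   `class`).
#' @return List with `r`, `p`, `n`, `discordant` (two character vectors:
#'   `high_score_low_ratio`, `low_score_high_ratio`).
#' @export
score_ratio_correlation <- function(scores, stability) {
  common <- intersect(scores$motif, stability$motif)
  assert_that(length(common) >= 3, "need at least 3 shared motifs")
  s <- scores$score[match(common, scores$motif)]
  r <- stability$log2_ratio[match(common, stability$motif)]
  ct <- stats::cor.test(s, r, method = "pearson", alternative = "two.sided")
  s_cls <- scores$class[match(common, scores$motif)]
  r_cls <- stability$class[match(common, stability$motif)]
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common),
       discordant = list(
         high_score_low_ratio = common[s_cls == "activating" &
                                         r_cls == "destabilizing"],
         low_score_high_ratio = common[s_cls == "repressive" &
                                         r_cls == "stabilizing"]))
}
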