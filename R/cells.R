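#' Population labels used by the sorter
#'
#' `POP_GFP_ALL` is the broad background: all GFP+ cells inside the middle-50%
#' dsRed gate, the denominator for bin enrichments. `POP_BACKGROUND` is the
#' stringent background: GFP+ cells inside the middle-25% dsRed gate, used to
#' define the robust analysis universe and for the RNA/DNA stability arm.
#'
#' @export
POP_GFP_ALL <- "GFP-ALL"

#' @rdname POP_GFP_ALL
#' @export
POP_BACKGROUND <- "BG25"

#' Describe the FACS sorting scheme
#'
#' The default mirrors the screen layout this package models: cells are first
#' gated to the middle 50% of dsRed intensity (a transcriptional-noise
#' control at the reporter locus), then five GFP-percentile bins are sorted
#' from the gated set - 0-10, 20-30, 40-60, 70-80 and 90-100% of GFP
#' intensity - carrying score weights -2, -1, 0, +1, +2. A stringent
#' middle-25% dsRed background population is sorted alongside. Each
#' population is sequenced in duplicate.
#'
#' @param dsred_window Percentile interval of dsRed intensity kept for all
#'   GFP populations (default `c(25, 75)`).
#' @param dsred_stringent_window Percentile interval for the stringent
#'   background (default `c(37.5, 62.5)`).
#' @param gfp_bins Data frame with columns `label`, `lo`, `hi` (percentiles)
#'   and `weight`; intervals must be non-overlapping, within [0, 100], and
#'   weights strictly increasing with bin position.
#' @param replicates Number of replicate libraries per population.
#' @return A `sort_scheme` list.
#' @export
sort_scheme <- function(dsred_window = c(25, 75),
                        dsred_stringent_window = c(37.5, 62.5),
                        gfp_bins = data.frame(
                          label = c("0-10", "20-30", "40-60", "70-80", "90-100"),
                          lo = c(0, 20, 40, 70, 90),
                          hi = c(10, 30, 60, 80, 100),
                          weight = c(-2, -1, 0, 1, 2)),
                        replicates = 2L) {
  check_window <- function(w, what) {
    assert_that(length(w) == 2L && all(w >= 0) && all(w <= 100) && w[1] < w[2],
                what, " must be an increasing percentile interval in [0, 100]")
  }
  check_window(dsred_window, "dsred_window")
  check_window(dsred_stringent_window, "dsred_stringent_window")
  b <- gfp_bins
  assert_that(all(c("label", "lo", "hi", "weight") %in% names(b)),
              "gfp_bins needs columns label, lo, hi, weight")
  b <- b[order(b$lo), , drop = FALSE]
  assert_that(all(b$lo < b$hi) && all(b$lo >= 0) && all(b$hi <= 100),
              "gfp bin intervals must be increasing and within [0, 100]")
  if (nrow(b) > 1L) {
    assert_that(all(b$hi[-nrow(b)] <= b$lo[-1L]),
                "gfp bin intervals must not overlap")
    assert_that(all(diff(b$weight) > 0),
                "bin weights must be strictly increasing with bin position")
  }
  assert_that(replicates >= 1, "replicates must be a positive integer")
  structure(list(dsred_window = as.numeric(dsred_window),
                 dsred_stringent_window = as.numeric(dsred_stringent_window),
                 gfp_bins = b,
                 replicates = as.integer(replicates)),
            class = "sort_scheme")
}

#' Simulate a pool of reporter-integrated cells
#'
#' Each motif receives a Poisson-distributed number of independent
#' integration events (independent rare integrations), with `mean_integrations`
#' defaulting to the ~8 events per tested element of the screen being
#' emulated. Per cell, log GFP intensity is a lognormal baseline plus the
#' motif's expression effect (scaled by the population SD `noise_sd`) plus
#' Gaussian noise; fluorescence effects act multiplicatively, hence
#' additively on the log scale. dsRed intensity is drawn independently of the
#' motif.
#'
#' @param truth A `truth_table`.
#' @param mean_integrations Positive mean number of cells per motif.
#' @param noise_sd Log-GFP population standard deviation.
#' @param baseline_log_gfp,dsred_meanlog,dsred_sdlog Baseline fluorescence
#'   parameters (arbitrary units).
#' @param seed Integer seed.
#' @return A `cell_population` data frame with columns `motif`, `gfp`,
#'   `dsred` (strictly positive intensities).
#' @export
simulate_cells <- function(truth, mean_integrations = 8, noise_sd = 1,
                           baseline_log_gfp = log(1000),
                           dsred_meanlog = log(500), dsred_sdlog = 0.4,
                           seed = NULL) {
  assert_that(is.data.frame(truth) && nrow(truth) > 0,
              "truth must be a non-empty truth_table")
  assert_that(mean_integrations > 0, "mean_integrations must be positive")
  assert_that(noise_sd > 0, "noise_sd must be positive")
  with_seed(seed, {
    k <- stats::rpois(nrow(truth), mean_integrations)
    if (sum(k) == 0L) {
      abort("empty population: no integration events were drawn")
    }
    motif <- rep(truth$motif, k)
    eff <- rep(truth$expression_effect, k)
    n <- length(motif)
    log_gfp <- baseline_log_gfp + eff * noise_sd +
      stats::rnorm(n, 0, noise_sd)
    structure(data.frame(motif = motif,
                         gfp = exp(log_gfp),
                         dsred = stats::rlnorm(n, dsred_meanlog, dsred_sdlog),
                         stringsAsFactors = FALSE),
              class = c("cell_population", "data.frame"))
  })
}

#' Gate cells on dsRed and sort GFP-percentile bins
#'
#' Applies the dsRed window first, then computes GFP percentile ranks within
#' the dsRed-gated set and assigns cells to the scheme's bins (rank-based, so
#' realized bin sizes match the requested percentile widths to within one
#' cell). Also emits the `GFP-ALL` population (every gated cell) and the
#' stringent `BG25` background (cells inside the stringent dsRed window).
#'
#' Replicate handling: with `replicate_mode = "sequencing"` (default) each
#' replicate refers to the same sorted cell subset and replicate variation
#' arises downstream from independent sequencing draws - appropriate when
#' duplicate sorts of a large pooled line differ negligibly in composition.
#' `"split"` instead partitions each population's cells at random into
#' disjoint replicate subsets, modelling physically separate sort tubes.
#'
#' @param cells A `cell_population` (at least 100 cells; percentile gates are
#'   meaningless below that).
#' @param scheme A [sort_scheme()].
#' @param replicate_mode `"sequencing"` or `"split"`.
#' @param seed Integer seed (used by `"split"` mode).
#' @return A `sorted_populations` object: named list mapping population label
#'   to a list of `scheme$replicates` cell subsets. Bins are mutually
#'   exclusive within a replicate.
#' @export
gate_and_sort <- function(cells, scheme = sort_scheme(),
                          replicate_mode = c("sequencing", "split"),
                          seed = NULL) {
  replicate_mode <- match.arg(replicate_mode)
  assert_that(is.data.frame(cells) && nrow(cells) >= 100,
              "need at least 100 cells to gate on percentiles")
  stopifnot(inherits(scheme, "sort_scheme"))

  dq <- stats::quantile(cells$dsred, scheme$dsred_window / 100, names = FALSE)
  gated <- cells[cells$dsred >= dq[1] & cells$dsred <= dq[2], , drop = FALSE]
  sq <- stats::quantile(cells$dsred, scheme$dsred_stringent_window / 100,
                        names = FALSE)
  stringent <- cells[cells$dsred >= sq[1] & cells$dsred <= sq[2], ,
                     drop = FALSE]

  pct <- 100 * rank(gated$gfp, ties.method = "first") / nrow(gated)
  pops <- list()
  for (i in seq_len(nrow(scheme$gfp_bins))) {
    b <- scheme$gfp_bins[i, ]
    sel <- pct > b$lo & pct <= b$hi
    if (!any(sel)) warning("empty gate: GFP bin ", b$label, " received no cells")
    pops[[b$label]] <- gated[sel, , drop = FALSE]
  }
  pops[[POP_GFP_ALL]] <- gated
  if (nrow(stringent) == 0L) warning("empty gate: stringent dsRed window")
  pops[[POP_BACKGROUND]] <- stringent

  R <- scheme$replicates
  reps <- if (replicate_mode == "sequencing") {
    lapply(pops, function(p) rep(list(p), R))
  } else {
    with_seed(seed, lapply(pops, function(p) {
      if (nrow(p) == 0L) return(rep(list(p), R))
      g <- sample.int(R, nrow(p), replace = TRUE)
      lapply(seq_len(R), function(r) p[g == r, , drop = FALSE])
    }))
  }
  structure(reps, class = "sorted_populations", scheme = scheme,
            replicate_mode = replicate_mode)
}
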