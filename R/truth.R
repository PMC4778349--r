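#' Generate a ground-truth motif library for a synthetic screen
#'
#' Draws `n_motifs` distinct 8mers and assigns each a latent regulatory
#' effect. Expression effects are expressed in units of the cell population's
#' log-GFP standard deviation; activating motifs get `+effect_magnitude`,
#' repressive motifs `-effect_magnitude`, neutral motifs exactly 0. A stated
#' fraction of the non-neutral motifs act through mRNA stability, receiving a
#' log2 per-cell transcript-abundance shift of `sign(effect) *
#' stability_magnitude`; the remainder model purely translational effects
#' (stability effect 0).
#'
#' Defaults emulate the composition of the focused screen this package
#' models: 3,918 tested 8mers of which roughly 461 were activating and 372
#' repressive (fractions 0.118 / 0.095), and a destabilization magnitude of
#' 0.55 matching the screen's miR-10 target-site exemplar.
#'
#' @param n_motifs Number of distinct motifs; at most `4^8 = 65536`.
#' @param class_fractions Numeric triple `(activating, repressive, neutral)`
#'   summing to 1; class counts are matched to rounding.
#' @param effect_magnitude Positive expression effect size, in population-SD
#'   units of log-GFP.
#' @param stability_fraction Fraction of non-neutral motifs whose effect is
#'   stability-mediated.
#' @param stability_magnitude Positive log2 RNA-abundance shift for
#'   stability-mediated motifs.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A `truth_table` data frame with columns `motif`,
#'   `expression_effect`, `stability_effect`, `true_class`.
#' @examples
#' tt <- generate_truth(100, c(0.2, 0.2, 0.6), seed = 1)
#' table(tt$true_class)
#' @export
generate_truth <- function(n_motifs,
                           class_fractions = c(activating = 0.118,
                                               repressive = 0.095,
                                               neutral = 0.787),
                           effect_magnitude = 1.5,
                           stability_fraction = 0.7,
                           stability_magnitude = 0.55,
                           seed = NULL) {
  assert_that(length(n_motifs) == 1L && n_motifs >= 1,
              "n_motifs must be a single positive integer")
  if (n_motifs > 4^8) {
    abort("impossible library: ", n_motifs,
          " motifs requested but only 4^8 = 65536 distinct 8mers exist")
  }
  f <- as.numeric(class_fractions)
  assert_that(length(f) == 3L && all(f >= 0) && all(f <= 1) &&
                abs(sum(f) - 1) < 1e-8,
              "class_fractions must be three values in [0, 1] summing to 1")
  assert_that(effect_magnitude > 0, "effect_magnitude must be positive")
  assert_that(stability_fraction >= 0 && stability_fraction <= 1,
              "stability_fraction must be in [0, 1]")
  n <- as.integer(n_motifs)
  n_act <- as.integer(round(f[1] * n))
  n_rep <- as.integer(round(f[2] * n))
  n_neu <- n - n_act - n_rep
  assert_that(n_neu >= 0L, "rounded class counts exceed n_motifs")

  with_seed(seed, {
    idx <- sample.int(65536L, n) - 1L
    motifs <- motif_from_index(idx)
    cls <- sample(rep(c("activating", "repressive", "neutral"),
                      c(n_act, n_rep, n_neu)))
    eff <- effect_magnitude * ((cls == "activating") - (cls == "repressive"))
    sta <- numeric(n)
    mediated <- cls != "neutral" & stats::runif(n) < stability_fraction
    sta[mediated] <- sign(eff[mediated]) * stability_magnitude
    new_truth_table(motifs, eff, sta, cls)
  })
}

new_truth_table <- function(motif, expression_effect, stability_effect,
                            true_class) {
  assert_motifs(motif)
  assert_that(!anyDuplicated(motif), "motifs must be unique")
  structure(
    data.frame(motif = motif,
               expression_effect = expression_effect,
               stability_effect = stability_effect,
               true_class = true_class,
               stringsAsFactors = FALSE),
    class = c("truth_table", "data.frame")
  )
}

#' Construct a truth table from explicit per-motif effects
#'
#' Convenience constructor for hand-built simulation scenarios. The class
#' label is derived from the sign of the expression effect under
#' `class_threshold`: effects at or above it are activating, at or below its
#' negative repressive, in between neutral.
#'
#' @param motif Character vector of unique 8mers (RNA alphabet).
#' @param expression_effect Numeric, population-SD units of log-GFP.
#' @param stability_effect Numeric, log2 per-cell RNA abundance shift.
#' @param class_threshold Positive effect size separating neutral from
#'   regulatory motifs (default `1e-9`, i.e. any nonzero effect).
#' @return A `truth_table` data frame.
#' @export
truth_table <- function(motif, expression_effect,
                        stability_effect = 0,
                        class_threshold = 1e-9) {
  expression_effect <- rep_len(expression_effect, length(motif))
  stability_effect <- rep_len(stability_effect, length(motif))
  cls <- ifelse(expression_effect >= class_threshold, "activating",
                ifelse(expression_effect <= -class_threshold,
                       "repressive", "neutral"))
  new_truth_table(motif, expression_effect, stability_effect, cls)
}

#' The ten internal-control 8mers
#'
#' Returns the screen's internal expression controls as a `truth_table`:
#' three repressive elements (including the miR-10 and let-7 target sites),
#' two no-effect controls, and five activating elements. The class labels and
#' their ordering from most repressive (AGGUAAGU) to most activating
#' (GUUGCAUU) follow the published control characterization; the numeric
#' simulation effect sizes are synthetic placeholders chosen to span that
#' order (the miR-10 site's stability effect of -0.55 log2 units is the one
#' literature-anchored magnitude).
#'
#' @return A `truth_table` with an extra `role` column.
#' @examples
#' control_truth()
#' @export
control_truth <- function() {
  path <- system.file("extdata", "control_8mers.tsv", package = "utrscreen")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tt <- new_truth_table(df$motif, df$sim_expression_effect,
                        df$sim_stability_effect,
                        c(Repressive = "repressive",
                          No_effect = "neutral",
                          Activating = "activating")[df$effect])
  tt$role <- df$role
  tt
}
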