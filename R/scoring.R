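#' Aggregate replicate libraries within each population
#'
#' Raw counts are summed (default) or averaged across replicates per
#' population before RPM normalization and scoring; summing preserves count
#' statistics at low depth. Per-replicate tables remain available for QC.
#'
#' @param table A `count_table` with a `replicate` column.
#' @param mode `"sum"` or `"mean"`.
#' @return A `count_table` without a `replicate` column, RPM-normalized.
#' @export
aggregate_replicates <- function(table, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  f <- if (mode == "sum") sum else mean
  agg <- stats::aggregate(count ~ motif + population, data = table, FUN = f)
  agg$count <- if (mode == "sum") as.integer(agg$count) else agg$count
  agg <- agg[order(agg$population, agg$motif), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("count_table", "data.frame")
  normalize_rpm(agg)
}

#' Motifs robustly present in the stringent background population
#'
#' The analysis universe: motifs whose raw count reaches `min_count` in
#' every replicate (default) of the stringent dsRed middle-25% background
#' population. Downstream enrichment, scoring and stability analyses are
#' restricted to this set.
#'
#' @param bg_counts A `count_table` containing the stringent background
#'   population.
#' @param min_count Minimum raw count per replicate (default 1, the smallest
#'   defensible "robustly included" rule; 0 admits every observed motif).
#' @param population Label of the stringent background population.
#' @param require_all_replicates If `FALSE`, one qualifying replicate
#'   suffices.
#' @return Sorted character vector of motifs.
#' @export
robust_background_set <- function(bg_counts, min_count = 1L,
                                  population = POP_BACKGROUND,
                                  require_all_replicates = TRUE) {
  sub <- bg_counts[bg_counts$population == population, , drop = FALSE]
  if (nrow(sub) == 0L) {
    abort("configuration error: stringent background population '",
          population, "' is absent from the count table")
  }
  wide <- stats::xtabs(count ~ motif + replicate, data = sub)
  ok <- if (require_all_replicates) {
    rowSums(wide >= min_count) == ncol(wide)
  } else {
    rowSums(wide >= min_count) > 0
  }
  sort(rownames(wide)[ok])
}

#' Pearson concordance of per-motif counts between replicates
#'
#' @param table A `count_table`.
#' @param population Population label to assess.
#' @return Pearson correlation of raw counts between the two replicates
#'   (minimum over pairs if more than two), with motifs absent from one
#'   replicate entered as zero.
#' @export
replicate_concordance <- function(table, population) {
  sub <- table[table$population == population, , drop = FALSE]
  assert_that(nrow(sub) > 0, "population '", population, "' not in table")
  wide <- stats::xtabs(count ~ motif + replicate, data = sub)
  assert_that(ncol(wide) >= 2, "need at least two replicates")
  pairs <- utils::combn(ncol(wide), 2L)
  min(apply(pairs, 2L, function(p) stats::cor(wide[, p[1L]], wide[, p[2L]])))
}

#' Per-motif enrichment of each GFP bin over the background population
#'
#' Enrichment is the motif's RPM in a GFP bin divided by its RPM in the
#' broad background (`GFP-ALL`: all GFP+ cells within the middle-50% dsRed
#' gate). Defined only for motifs with positive background RPM; restrict via
#' `motifs` to the robust background set in normal use.
#'
#' @param table An RPM-normalized, replicate-aggregated `count_table`.
#' @param scheme A [sort_scheme()] naming the bins.
#' @param background Background population label.
#' @param motifs Optional motif restriction (e.g. from
#'   [robust_background_set()]).
#' @param pseudocount Added to numerator and denominator RPM; default 0
#'   (only relevant if the background gate is reconfigured so zero
#'   denominators become possible).
#' @return An `enrichment_profile` data frame: `motif` plus one nonnegative
#'   column per bin label.
#' @export
bin_enrichment <- function(table, scheme = sort_scheme(),
                           background = POP_GFP_ALL, motifs = NULL,
                           pseudocount = 0) {
  assert_that("rpm" %in% names(table), "table must be RPM-normalized first")
  labels <- scheme$gfp_bins$label
  missing <- setdiff(c(labels, background), unique(table$population))
  assert_that(length(missing) == 0, "populations absent from table: ",
              paste(missing, collapse = ", "))
  wide <- stats::xtabs(rpm ~ motif + population, data = table)
  motifs <- motifs %||% rownames(wide)
  motifs <- intersect(motifs, rownames(wide))
  bg <- wide[motifs, background]
  if (pseudocount == 0 && any(bg == 0)) {
    warning(sum(bg == 0), " motif(s) dropped: zero background RPM")
    motifs <- motifs[bg > 0]
    bg <- bg[bg > 0]
  }
  enr <- (wide[motifs, labels, drop = FALSE] + pseudocount) /
    (bg + pseudocount)
  out <- data.frame(motif = motifs, as.data.frame.matrix(unclass(enr)),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Bin-weighted expression score
#'
#' The score is the RPM-weighted average of the bin weights: each bin's RPM
#' is multiplied by its weight (-2, -1, 0, +1, +2 from the lowest to the
#' highest GFP bin), summed, and divided by the total RPM over the five
#' bins. As a weighted average of the weights it is bounded by `[-2, 2]`,
#' scale-invariant, and moving read mass from a lower- to a higher-weight
#' bin never decreases it. Repressive motifs score negative, activating
#' motifs positive.
#'
#' @param rpm Nonnegative numeric vector (one motif) or matrix (motifs in
#'   rows) of per-bin RPM values, columns ordered as `weights`.
#' @param weights Bin weights, default `c(-2, -1, 0, 1, 2)`.
#' @return Numeric score(s) in `[min(weights), max(weights)]`. All-zero
#'   rows give `NA` with a warning (score undefined).
#' @examples
#' expression_score(c(100, 50, 20, 10, 5)) # -1.2432...
#' @export
expression_score <- function(rpm, weights = c(-2, -1, 0, 1, 2)) {
  if (is.null(dim(rpm))) rpm <- matrix(rpm, nrow = 1L)
  assert_that(ncol(rpm) == length(weights),
              "rpm must have one column per weight")
  assert_that(all(rpm >= 0), "RPM values must be nonnegative")
  tot <- rowSums(rpm)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " motif(s) have zero RPM in every bin; ",
            "score undefined (NA)")
  }
  s <- as.vector(rpm %*% weights) / tot
  s[tot == 0] <- NA_real_
  unname(s)
}

#' Classify expression scores into activating / repressive / neutral
#'
#' Thresholds are strict: a score must exceed `+1` to be called activating
#' and fall below `-1` to be called repressive; scores at the threshold are
#' neutral.
#'
#' @param score Numeric scores.
#' @param thresholds Length-2 numeric `(repressive, activating)` cutoffs.
#' @return Character vector of class labels.
#' @export
classify_expression <- function(score, thresholds = c(-1, 1)) {
  assert_that(length(thresholds) == 2 && thresholds[1] < thresholds[2],
              "thresholds must be increasing (repressive, activating)")
  ifelse(score > thresholds[2], "activating",
         ifelse(score < thresholds[1], "repressive", "neutral"))
}

#' Rank score records from most activating to most repressive
#'
#' Descending by score; ties broken lexicographically by motif.
#'
#' @param records Data frame with columns `motif` and `score`.
#' @return The records reordered, with a `rank` column (1 = highest score).
#' @export
rank_scores <- function(records) {
  assert_that(all(c("motif", "score") %in% names(records)),
              "records need motif and score columns")
  ord <- order(-records$score, records$motif)
  records <- records[ord, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' Score a screen count table end to end
#'
#' Pipeline: determine the robust background set from the stringent
#' background replicates, aggregate replicates (sum by default), RPM
#' normalize, compute per-bin enrichments over `GFP-ALL`, compute the
#' bin-weighted expression score from the per-bin RPM values, classify and
#' rank. Per-replicate scores are attached as attribute
#' `"replicate_scores"` for QC.
#'
#' @param table A `count_table` with replicate libraries for the five GFP
#'   bins, `GFP-ALL` and the stringent background.
#' @param scheme A [sort_scheme()].
#' @param aggregate Replicate aggregation mode, `"sum"` or `"mean"`.
#' @param thresholds Classification cutoffs, see [classify_expression()].
#' @param min_count Robust-set threshold, see [robust_background_set()].
#' @param background,stringent Population labels.
#' @param pseudocount Passed to [bin_enrichment()].
#' @return A `score_table` data frame: `motif`, one enrichment column per
#'   bin, `score`, `class`, `rank`.
#' @export
score_screen <- function(table, scheme = sort_scheme(),
                         aggregate = c("sum", "mean"),
                         thresholds = c(-1, 1), min_count = 1L,
                         background = POP_GFP_ALL,
                         stringent = POP_BACKGROUND, pseudocount = 0) {
  aggregate <- match.arg(aggregate)
  robust <- robust_background_set(table, min_count, stringent)
  agg <- aggregate_replicates(table, aggregate)
  enr <- bin_enrichment(agg, scheme, background, motifs = robust,
                        pseudocount = pseudocount)
  labels <- scheme$gfp_bins$label
  wide <- stats::xtabs(rpm ~ motif + population, data = agg)
  rpm <- unclass(wide[enr$motif, labels, drop = FALSE])
  s <- expression_score(rpm, scheme$gfp_bins$weight)
  keep <- !is.na(s)
  out <- enr[keep, , drop = FALSE]
  out$score <- s[keep]
  out$class <- classify_expression(out$score, thresholds)
  out <- rank_scores(out)
  class(out) <- c("score_table", "data.frame")

  reps <- sort(unique(table$replicate))
  rep_scores <- do.call(rbind, lapply(reps, function(r) {
    sub <- table[table$replicate == r, , drop = FALSE]
    sub <- normalize_rpm(sub)
    w <- stats::xtabs(rpm ~ motif + population, data = sub)
    m <- intersect(out$motif, rownames(w))
    have <- intersect(labels, colnames(w))
    if (length(have) < length(labels)) return(NULL)
    data.frame(motif = m, replicate = r,
               score = expression_score(unclass(w[m, labels, drop = FALSE]),
                                        scheme$gfp_bins$weight),
               stringsAsFactors = FALSE)
  }))
  attr(out, "replicate_scores") <- rep_scores
  out
}
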