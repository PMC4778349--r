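#' Build a validated pipeline run configuration
#'
#' A run is reproducible from the configuration plus its inputs alone: every
#' stochastic stage derives its seed from the single global `seed`. The
#' default configuration simulates a small screen end to end (including
#' FASTQ emission and re-counting); point `fastq`/`barcode_map` at real
#' files and set `simulate = FALSE` to analyze existing data.
#'
#' @param out_dir Output directory for all stage outputs.
#' @param seed Global integer seed.
#' @param simulate Simulate inputs (`TRUE`) or read `fastq`.
#' @param n_motifs,class_fractions,effect_magnitude,stability_fraction
#'   Truth-generator settings (see [generate_truth()]).
#' @param mean_integrations,noise_sd Cell-simulation settings.
#' @param depth Reads per library.
#' @param rna_depth Depth of the simulated cDNA library.
#' @param error_rate Read-corruption rate for emitted FASTQ.
#' @param via_fastq If `TRUE` (default) the simulation writes FASTQ and
#'   re-counts it through the read filters; `FALSE` draws count tables
#'   directly (faster, same sampling model).
#' @param fastq,barcode_map Paths used when `simulate = FALSE`.
#' @param scheme A [sort_scheme()].
#' @param layout A [read_layout()].
#' @param weights Scoring weights (default from `scheme`).
#' @param thresholds Expression-score classification cutoffs.
#' @param stability_cutoffs log2(RNA/DNA) classification cutoffs.
#' @param min_count Robust-background threshold.
#' @param categories Named list of motif vectors, or named character vector
#'   of category-file paths; defaults to the shipped validated-element
#'   categories.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("utrscreen_run_"),
                       seed = 1L,
                       simulate = TRUE,
                       n_motifs = 300L,
                       class_fractions = c(0.15, 0.15, 0.7),
                       effect_magnitude = 1.5,
                       stability_fraction = 0.7,
                       mean_integrations = 50,
                       noise_sd = 1,
                       depth = 2e4,
                       rna_depth = 2e5,
                       error_rate = 0.02,
                       via_fastq = TRUE,
                       fastq = NULL,
                       barcode_map = NULL,
                       scheme = sort_scheme(),
                       layout = read_layout(),
                       weights = NULL,
                       thresholds = c(-1, 1),
                       stability_cutoffs = c(-0.5, 0.5),
                       min_count = 1L,
                       categories = NULL) {
  if (is.null(categories)) {
    categories <- c(
      validated_activating = system.file(
        "extdata", "category_validated_activating.txt",
        package = "utrscreen"),
      validated_repressive = system.file(
        "extdata", "category_validated_repressive.txt",
        package = "utrscreen"))
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              simulate = isTRUE(simulate), n_motifs = as.integer(n_motifs),
              class_fractions = as.numeric(class_fractions),
              effect_magnitude = effect_magnitude,
              stability_fraction = stability_fraction,
              mean_integrations = mean_integrations, noise_sd = noise_sd,
              depth = depth, rna_depth = rna_depth, error_rate = error_rate,
              via_fastq = isTRUE(via_fastq), fastq = fastq,
              barcode_map = barcode_map, scheme = scheme, layout = layout,
              weights = weights %||% scheme$gfp_bins$weight,
              thresholds = as.numeric(thresholds),
              stability_cutoffs = as.numeric(stability_cutoffs),
              min_count = as.integer(min_count), categories = categories)
  if (!cfg$simulate) {
    assert_that(!is.null(cfg$fastq) && !is.null(cfg$barcode_map),
                "non-simulation mode needs fastq and barcode_map paths")
  }
  structure(cfg, class = "run_config")
}

#' Serialize / restore a run configuration (JSON)
#'
#' The configuration round-trips unchanged through serialization.
#'
#' @param config A `run_config`.
#' @param path JSON path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

config_to_list <- function(config) {
  x <- unclass(config)
  x$scheme <- unclass(x$scheme)
  x$scheme$gfp_bins <- as.list(x$scheme$gfp_bins)
  x$layout <- unclass(x$layout)
  if (is.character(x$categories)) x$categories <- as.list(x$categories)
  x
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$scheme <- sort_scheme(x$scheme$dsred_window,
                          x$scheme$dsred_stringent_window,
                          as.data.frame(x$scheme$gfp_bins),
                          x$scheme$replicates)
  x$layout <- do.call(read_layout, x$layout[c(
    "upstream_flank", "motif_length", "downstream_flank", "read_length",
    "min_phred", "barcode_length")])
  x$categories <- unlist(x$categories)  # named list -> named character
  do.call(run_config, x)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full screen pipeline
#'
#' Stages, in dependency order: truth generation (or input loading), cell
#' simulation and FACS-style sorting, sequencing (via FASTQ emission and
#' the read filters, or direct count draws), replicate-aggregated scoring,
#' RNA/DNA stability, and category enrichment. All stage outputs are written
#' as TSV under `config$out_dir` together with a JSON run report; reruns
#' with the same configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @return A `run_report` list (invisibly): per-stage record counts, filter
#'   statistics, call counts, concordance metrics, configuration echo and
#'   package version.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(version = as.character(utils::packageVersion("utrscreen")),
                 config = config_to_list(config), stages = list())

  truth <- NULL
  pops <- NULL
  if (config$simulate) {
    truth <- run_stage("truth", {
      tt <- generate_truth(config$n_motifs, config$class_fractions,
                           config$effect_magnitude,
                           config$stability_fraction,
                           seed = derive_seed(config$seed, "truth"))
      utils::write.table(tt, out("truth.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      tt
    })
    pops <- run_stage("sort", {
      cells <- simulate_cells(truth, config$mean_integrations,
                              config$noise_sd,
                              seed = derive_seed(config$seed, "cells"))
      gate_and_sort(cells, config$scheme,
                    seed = derive_seed(config$seed, "sort"))
    })
  }

  counts <- run_stage("count", {
    if (config$simulate && config$via_fastq) {
      fq <- emit_fastq(pops, config$layout, config$depth, config$error_rate,
                       path = out("reads.fastq"),
                       seed = derive_seed(config$seed, "fastq"))
      parsed <- parse_and_filter(fq$path, config$layout, fq$barcode_map)
      utils::write.table(as.data.frame(parsed$stats),
                         out("filter_stats.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      report$stages$filter <- unclass(parsed$stats)
      count_motifs(parsed$reads)
    } else if (config$simulate) {
      sequence_counts(pops, config$depth,
                      seed = derive_seed(config$seed, "seq"))
    } else {
      if (!file.exists(config$fastq)) {
        abort("input FASTQ not found: ", config$fastq)
      }
      bm <- utils::read.delim(config$barcode_map, stringsAsFactors = FALSE)
      parsed <- parse_and_filter(config$fastq, config$layout, bm)
      utils::write.table(as.data.frame(parsed$stats),
                         out("filter_stats.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      report$stages$filter <- unclass(parsed$stats)
      count_motifs(parsed$reads)
    }
  })
  counts <- normalize_rpm(counts)
  write_count_table(counts, out("counts.tsv"))
  report$stages$count <- list(rows = nrow(counts),
                              libraries = nrow(unique(
                                counts[, c("population", "replicate")])))

  scores <- run_stage("score", {
    sc <- score_screen(counts, config$scheme,
                       thresholds = config$thresholds,
                       min_count = config$min_count)
    utils::write.table(sc, out("scores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sc
  })
  report$stages$score <- list(
    rows = nrow(scores),
    activating = sum(scores$class == "activating"),
    repressive = sum(scores$class == "repressive"),
    neutral = sum(scores$class == "neutral"))
  report$concordance <- list()
  for (pop in c(config$scheme$gfp_bins$label, POP_GFP_ALL, POP_BACKGROUND)) {
    if (pop %in% counts$population &&
        length(unique(counts$replicate[counts$population == pop])) >= 2) {
      report$concordance[[pop]] <- replicate_concordance(counts, pop)
    }
  }

  stability <- NULL
  if (config$simulate) {
    stability <- run_stage("stability", {
      robust <- robust_background_set(counts, config$min_count)
      dna <- counts[counts$population == POP_BACKGROUND, , drop = FALSE]
      dna_sum <- stats::aggregate(count ~ motif, data = dna, FUN = sum)
      rna <- simulate_rna(truth, dna_sum, depth = config$rna_depth,
                          seed = derive_seed(config$seed, "rna"))
      rna$population <- POP_BACKGROUND
      class(rna) <- c("count_table", "data.frame")
      dna_sum$population <- POP_BACKGROUND
      class(dna_sum) <- c("count_table", "data.frame")
      st <- rna_dna_ratio(rna, dna_sum, motifs = robust,
                          cutoffs = config$stability_cutoffs)
      utils::write.table(st, out("stability.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      st
    })
    report$stages$stability <- list(
      rows = nrow(stability),
      stabilizing = sum(stability$class == "stabilizing"),
      destabilizing = sum(stability$class == "destabilizing"))
    sr <- score_ratio_correlation(scores, stability)
    report$score_ratio_pearson <- sr$r
  }

  enrich <- run_stage("enrich", {
    cats <- config$categories
    if (is.character(cats)) {
      cats <- stats::setNames(lapply(cats, read_category), names(cats))
    }
    suppressWarnings(
      e <- enrich_categories(cats, scores, universe = scores$motif))
    utils::write.table(e, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    e
  })
  report$stages$enrich <- list(rows = nrow(enrich))

  write_run_config(config, out("config.json"))
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  class(report) <- "run_report"
  invisible(report)
}

#' Geometric mean of strictly positive values
#'
#' @param x Positive numeric vector.
#' @return `exp(mean(log(x)))`. Zeros or negatives are an error (log
#'   undefined).
#' @examples
#' geometric_mean(c(4, 9)) # 6
#' @export
geometric_mean <- function(x) {
  if (any(x <= 0)) abort("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Reporter measurements normalized to no-effect controls
#'
#' Generic summary for reporter-assay tables (e.g. luciferase): each motif's
#' geometric mean is divided by the geometric mean of the pooled
#' measurements of two no-effect reference motifs. The spread of each
#' motif's normalized values is reported two ways - the central 68%
#' interval, and a literal band of +/- 33% of the value range - because the
#' two readings of "a third of the spread" differ. Significance versus the
#' pooled reference values is a two-sided Wilcoxon rank-sum test, starred at
#' p < 0.05 / 0.005 / 0.0005.
#'
#' @param measurements Data frame with columns `motif` and `value`
#'   (replicated positive measurements per motif).
#' @param reference_motifs Two no-effect reference motifs; both must be
#'   present.
#' @return Data frame: `motif`, `relative` (normalized geometric mean),
#'   `lo68`, `hi68`, `band33_lo`, `band33_hi`, `p`, `stars`.
#' @export
relative_expression_report <- function(measurements,
                                       reference_motifs = c("UUCCGUUA",
                                                            "UAAUGCCC")) {
  assert_that(all(c("motif", "value") %in% names(measurements)),
              "measurements needs motif and value columns")
  assert_that(all(measurements$value > 0),
              "measurements must be strictly positive")
  ref <- measurements$value[measurements$motif %in% reference_motifs]
  assert_that(all(reference_motifs %in% measurements$motif),
              "reference motifs missing from measurements")
  g_ref <- geometric_mean(ref)
  motifs <- unique(measurements$motif)
  rows <- lapply(motifs, function(m) {
    v <- measurements$value[measurements$motif == m] / g_ref
    q <- stats::quantile(v, c(0.16, 0.84), names = FALSE)
    spread <- diff(range(v))
    rel <- geometric_mean(v)
    p <- if (length(v) > 1 && length(ref) > 1) {
      suppressWarnings(stats::wilcox.test(v * g_ref, ref)$p.value)
    } else {
      NA_real_
    }
    data.frame(motif = m, relative = rel, lo68 = q[1], hi68 = q[2],
               band33_lo = rel - 0.33 * spread, band33_hi = rel +
                 0.33 * spread, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- as.character(cut(out$p, c(0, 5e-4, 5e-3, 5e-2, 1),
                                labels = c("***", "**", "*", ""),
                                include.lowest = TRUE))
  out$stars[is.na(out$p)] <- ""
  rownames(out) <- NULL
  out
}
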