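#' Describe the amplicon read layout
#'
#' Reads are fixed-layout 50 nt amplicons: a sample barcode, the constant
#' upstream flank `CATAC`, the variable 8mer (DNA alphabet), the constant
#' downstream flank `ATA`, then filler up to the read length. Bases in the
#' barcode and 8mer must exceed the Phred threshold (strictly greater than
#' `min_phred`) for a read to pass filtering.
#'
#' @param upstream_flank,downstream_flank Constant sequences flanking the
#'   variable 8mer.
#' @param motif_length Length of the variable insert.
#' @param read_length Total read length in nucleotides.
#' @param min_phred Exclusive Phred bound; a base at exactly `min_phred`
#'   fails.
#' @param barcode_length Length of the sample barcode; fixed-length barcodes
#'   are automatically prefix-free.
#' @return A `read_layout` list.
#' @export
read_layout <- function(upstream_flank = "CATAC", motif_length = 8L,
                        downstream_flank = "ATA", read_length = 50L,
                        min_phred = 20L, barcode_length = 6L) {
  assert_that(grepl("^[ACGT]+$", upstream_flank) &&
                grepl("^[ACGT]+$", downstream_flank),
              "flanks must be DNA sequences")
  used <- barcode_length + nchar(upstream_flank) + motif_length +
    nchar(downstream_flank)
  assert_that(used <= read_length,
              "barcode + flanks + motif (", used,
              " nt) do not fit in a ", read_length, " nt read")
  assert_that(min_phred >= 0 && min_phred <= 41, "min_phred out of range")
  structure(list(upstream_flank = upstream_flank,
                 motif_length = as.integer(motif_length),
                 downstream_flank = downstream_flank,
                 read_length = as.integer(read_length),
                 min_phred = as.integer(min_phred),
                 barcode_length = as.integer(barcode_length)),
            class = "read_layout")
}

#' Generate a prefix-free set of sample barcodes
#'
#' Fixed-length DNA barcodes; indices are spread over the code space with an
#' odd multiplier so consecutive barcodes are not single-base neighbours.
#' Deterministic (no RNG).
#'
#' @param n Number of barcodes.
#' @param width Barcode length in nucleotides.
#' @return Character vector of `n` distinct DNA barcodes.
#' @export
make_barcodes <- function(n, width = 6L) {
  assert_that(n >= 1 && n <= 4^width, "cannot make ", n, " barcodes of width ",
              width)
  idx <- ((seq_len(n) - 1) * 89) %% 4^width  # 89 is odd: bijective mod 4^width
  x <- as.integer(idx)
  cols <- vector("list", width)
  for (p in width:1) {
    cols[[p]] <- DNA_BASES[x %% 4L + 1L]
    x <- x %/% 4L
  }
  do.call(paste0, cols)
}

#' Build a barcode map for a set of sorted populations
#'
#' @param populations Character vector of population labels.
#' @param replicates Number of replicates per population.
#' @param width Barcode length.
#' @return Data frame with columns `barcode`, `population`, `replicate`.
#' @export
barcode_map <- function(populations, replicates = 2L, width = 6L) {
  grid <- expand.grid(replicate = seq_len(replicates),
                      population = populations,
                      stringsAsFactors = FALSE)[, 2:1]
  grid$barcode <- make_barcodes(nrow(grid), width)
  grid[, c("barcode", "population", "replicate")]
}

new_count_table <- function(motif, population, replicate, count) {
  structure(data.frame(motif = motif, population = population,
                       replicate = as.integer(replicate),
                       count = as.integer(count), stringsAsFactors = FALSE),
            class = c("count_table", "data.frame"))
}

# Draw one sequencing library from per-motif cell frequencies.
# dispersion = Inf gives plain multinomial sampling; a finite Dirichlet
# concentration adds PCR-jackpotting-style overdispersion.
draw_library <- function(freq, depth, dispersion) {
  p <- freq / sum(freq)
  if (is.finite(dispersion)) {
    g <- stats::rgamma(length(p), shape = dispersion * p)
    if (sum(g) == 0) g <- p
    p <- g / sum(g)
  }
  stats::rmultinom(1L, size = depth, prob = p)[, 1L]
}

#' Draw sequencing count libraries from sorted populations
#'
#' For every population and replicate, reads are sampled (near-)multinomially
#' from the replicate subset's motif frequencies. This is the counts-only
#' equivalent of [emit_fastq()]: identical sampling model, no read strings.
#'
#' @param pops A `sorted_populations` object from [gate_and_sort()].
#' @param depth Reads per library; a single number or a named vector by
#'   population label.
#' @param dispersion Dirichlet concentration; `Inf` (default) means plain
#'   multinomial.
#' @param seed Integer seed.
#' @return A `count_table` data frame: `motif`, `population`, `replicate`,
#'   `count`.
#' @export
sequence_counts <- function(pops, depth, dispersion = Inf, seed = NULL) {
  stopifnot(inherits(pops, "sorted_populations"))
  assert_that(all(depth >= 1), "depth must be a positive read count")
  with_seed(seed, {
    out <- list()
    for (label in names(pops)) {
      d <- if (length(depth) > 1L) depth[[label]] else depth
      for (r in seq_along(pops[[label]])) {
        cells <- pops[[label]][[r]]
        if (nrow(cells) == 0L) next
        tb <- table(cells$motif)
        cnt <- draw_library(as.numeric(tb), d, dispersion)
        out[[length(out) + 1L]] <-
          new_count_table(names(tb), label, r, cnt)
      }
    }
    do.call(rbind, out)
  })
}

#' Emit multiplexed amplicon FASTQ reads from sorted populations
#'
#' Writes one Phred+33 FASTQ file containing every population x replicate
#' library. Each read is `barcode + upstream flank + motif (DNA alphabet) +
#' downstream flank + filler`; intact reads carry uniform Q40 qualities. A
#' fraction `error_rate` of reads is corrupted to exercise the downstream
#' filters, split evenly between (i) one barcode/motif base dropped to
#' exactly the Phred bound (which the strict filter must reject), (ii) a
#' substitution in the upstream flank, (iii) a substitution in the
#' downstream flank.
#'
#' @param pops A `sorted_populations` object.
#' @param layout A [read_layout()].
#' @param depth Reads per library (scalar or named by population).
#' @param error_rate Fraction of reads corrupted, in `[0, 1)`.
#' @param path Output FASTQ path; a `.gz` suffix gzip-compresses.
#' @param dispersion Passed to [sequence_counts()].
#' @param seed Integer seed.
#' @return Invisibly, a list with `path`, `truth` (the exact intended
#'   per-motif `count_table`, before corruption), `barcode_map`, `layout`.
#' @export
emit_fastq <- function(pops, layout = read_layout(), depth, error_rate = 0,
                       path = tempfile(fileext = ".fastq"),
                       dispersion = Inf, seed = NULL) {
  stopifnot(inherits(layout, "read_layout"))
  assert_that(all(depth >= 1), "depth must be a positive read count")
  assert_that(error_rate >= 0 && error_rate < 1,
              "error_rate must be in [0, 1)")
  truth <- sequence_counts(pops, depth, dispersion,
                           seed = derive_seed(seed, "counts"))
  libs <- unique(truth[, c("population", "replicate")])
  bm <- barcode_map(unique(libs$population),
                    max(libs$replicate), layout$barcode_length)
  bm <- merge(libs, bm, by = c("population", "replicate"), sort = FALSE)

  L <- layout$barcode_length
  nup <- nchar(layout$upstream_flank)
  filler_len <- layout$read_length - L - nup - layout$motif_length -
    nchar(layout$downstream_flank)
  filler <- strrep("A", filler_len)
  q_ok <- strrep("I", layout$read_length)            # Q40 everywhere
  q_bound <- rawToChar(as.raw(33L + layout$min_phred))
  qc_region <- c(seq_len(L), L + nup + seq_len(layout$motif_length))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  with_seed(derive_seed(seed, "reads"), {
    for (i in seq_len(nrow(bm))) {
      sub <- truth[truth$population == bm$population[i] &
                     truth$replicate == bm$replicate[i] & truth$count > 0, ]
      motifs <- rna_to_dna(rep(sub$motif, sub$count))
      n <- length(motifs)
      motifs <- motifs[sample.int(n)]                 # shuffle read order
      seqs <- paste0(bm$barcode[i], layout$upstream_flank, motifs,
                     layout$downstream_flank, filler)
      quals <- rep.int(q_ok, n)
      if (error_rate > 0) {
        bad <- which(stats::runif(n) < error_rate)
        mode <- sample.int(3L, length(bad), replace = TRUE)
        lowq <- bad[mode == 1L]
        pos <- sample(qc_region, length(lowq), replace = TRUE)
        substr(quals[lowq], pos, pos) <- q_bound
        for (m in 2:3) {
          hit <- bad[mode == m]
          if (!length(hit)) next
          off <- if (m == 2L) L else L + nup + layout$motif_length
          flank_len <- if (m == 2L) nup else nchar(layout$downstream_flank)
          p <- off + sample.int(flank_len, length(hit), replace = TRUE)
          old <- substr(seqs[hit], p, p)
          new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L),
                        character(1L), USE.NAMES = FALSE)
          substr(seqs[hit], p, p) <- new
        }
      }
      hdr <- paste0("@", bm$population[i], ":", bm$replicate[i], ":",
                    seq_len(n))
      writeLines(as.vector(rbind(hdr, seqs, "+", quals)), con)
    }
  })
  invisible(list(path = path, truth = truth, barcode_map = bm,
                 layout = layout))
}

#' Simulate a cDNA (RNA) library from DNA counts and stability effects
#'
#' Models steady-state RNA abundance per cell as proportional to the DNA
#' (cell) count times `2^stability_effect`, then draws a multinomial
#' sequencing library. Motifs with stability effect 0 therefore have an
#' expected log2(RNA/DNA) ratio of 0.
#'
#' @param truth A `truth_table` supplying `stability_effect` per motif.
#' @param dna_counts Named integer vector or data frame with columns
#'   `motif`, `count`.
#' @param depth Library depth; defaults to the DNA total.
#' @param seed Integer seed.
#' @return Data frame `motif`, `count` of RNA reads.
#' @export
simulate_rna <- function(truth, dna_counts, depth = NULL, seed = NULL) {
  if (is.data.frame(dna_counts)) {
    cnt <- stats::setNames(dna_counts$count, dna_counts$motif)
  } else {
    cnt <- dna_counts
  }
  cnt <- cnt[cnt > 0]
  assert_that(length(cnt) > 0, "dna_counts has no positive entries")
  miss <- setdiff(names(cnt), truth$motif)
  assert_that(length(miss) == 0, "motifs absent from truth table: ",
              paste(utils::head(miss, 3L), collapse = ", "))
  sta <- truth$stability_effect[match(names(cnt), truth$motif)]
  depth <- depth %||% sum(cnt)
  assert_that(depth >= 1, "depth must be positive")
  w <- as.numeric(cnt) * 2^sta
  with_seed(seed, {
    rna <- stats::rmultinom(1L, size = depth, prob = w / sum(w))[, 1L]
    data.frame(motif = names(cnt), count = as.integer(rna),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate a complete screen to a replicate count table
#'
#' Convenience wrapper: [simulate_cells()] then [gate_and_sort()] then
#' [sequence_counts()], with sub-seeds derived from one master seed.
#'
#' @inheritParams simulate_cells
#' @inheritParams sequence_counts
#' @param scheme A [sort_scheme()].
#' @return A `count_table` covering all bins, `GFP-ALL` and `BG25`.
#' @export
simulate_screen <- function(truth, mean_integrations = 8, noise_sd = 1,
                            depth = 1e5, scheme = sort_scheme(),
                            dispersion = Inf, seed = NULL) {
  cells <- simulate_cells(truth, mean_integrations, noise_sd,
                          seed = derive_seed(seed, "cells"))
  pops <- gate_and_sort(cells, scheme, seed = derive_seed(seed, "sort"))
  sequence_counts(pops, depth, dispersion, seed = derive_seed(seed, "seq"))
}
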