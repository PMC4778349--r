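#' Two-sided Fisher exact test for a 2x2 membership table
#'
#' Exact hypergeometric test that `b` of the `n` category members fall in a
#' call set of size `B` drawn from a screened universe of size `N`. The
#' two-sided p-value follows the minimum-likelihood convention: the sum of
#' the probabilities of all outcomes no more likely than the observed one
#' (with the customary 1e-7 relative tolerance for ties); the doubling
#' convention (twice the smaller tail, capped at 1) is available via
#' `convention = "doubling"`.
#'
#' @param b Category members inside the call set.
#' @param n Category size within the universe.
#' @param B Call-set size.
#' @param N Universe size.
#' @param convention `"minlike"` (default) or `"doubling"`.
#' @return p-value in (0, 1].
#' @examples
#' fisher_two_sided(2, 2, 2, 4) # 1/6
#' @export
fisher_two_sided <- function(b, n, B, N, convention = c("minlike", "doubling")) {
  convention <- match.arg(convention)
  assert_that(n <= N && B <= N && b <= min(n, B) && b >= max(0, n + B - N),
              "inconsistent 2x2 table: b=", b, " n=", n, " B=", B, " N=", N)
  k <- max(0L, n + B - N):min(n, B)
  pr <- stats::dhyper(k, B, N - B, n)
  p_obs <- pr[match(b, k)]
  p <- if (convention == "minlike") {
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(pr[k <= b])
    upper <- sum(pr[k >= b])
    min(1, 2 * min(lower, upper))
  }
  min(p, 1)
}

#' Enrichment of a motif category among activating or repressive calls
#'
#' Fold enrichment is `(b/n) / (B/N)`: the category's rate inside the call
#' set relative to the background rate, with `b` the category motifs among
#' the calls, `n` the category size within the screened universe, `B` the
#' call-set size and `N` the universe size. Significance is a two-sided
#' Fisher exact test. The universe should be the robust background set -
#' motifs that could have been called at all.
#'
#' @param category Character vector of category motifs.
#' @param calls Character vector of called motifs (e.g. all activating).
#' @param universe Character vector: the screened universe. Category or call
#'   motifs outside it are dropped with a warning.
#' @param name Category label for the result row.
#' @param direction Call-set label (e.g. `"activating"`).
#' @return A one-row `data.frame`: `category`, `direction`, `b`, `n`, `B`,
#'   `N`, `fold`, `p`.
#' @export
category_enrichment <- function(category, calls, universe,
                                name = "category", direction = "calls") {
  drop_cat <- setdiff(category, universe)
  drop_call <- setdiff(calls, universe)
  if (length(drop_cat) || length(drop_call)) {
    warning(length(drop_cat), " category and ", length(drop_call),
            " call motif(s) outside the universe were dropped")
  }
  category <- unique(intersect(category, universe))
  calls <- unique(intersect(calls, universe))
  universe <- unique(universe)
  b <- length(intersect(category, calls))
  n <- length(category)
  B <- length(calls)
  N <- length(universe)
  fold <- if (n == 0 || B == 0) NA_real_ else (b / n) / (B / N)
  data.frame(category = name, direction = direction,
             b = b, n = n, B = B, N = N, fold = fold,
             p = fisher_two_sided(b, n, B, N),
             stringsAsFactors = FALSE)
}

#' Run category enrichment for both call directions
#'
#' @param categories Named list of motif character vectors.
#' @param scores A `score_table` (columns `motif`, `class`).
#' @param universe Universe motifs; defaults to every scored motif.
#' @return Data frame with one row per category x direction.
#' @export
enrich_categories <- function(categories, scores, universe = NULL) {
  universe <- universe %||% scores$motif
  do.call(rbind, lapply(names(categories), function(nm) {
    do.call(rbind, lapply(c("activating", "repressive"), function(dir) {
      category_enrichment(categories[[nm]],
                          scores$motif[scores$class == dir],
                          universe, name = nm, direction = dir)
    }))
  }))
}

#' Read a motif category list (one 8mer per line)
#'
#' Lines are upper-cased and converted to the RNA alphabet; blank lines and
#' `#` comments are ignored.
#'
#' @param path Text file path.
#' @return Character vector of motifs.
#' @export
read_category <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x <- dna_to_rna(toupper(x))
  assert_motifs(x, what = "category motif")
  x
}

#' Score correlation across reverse-complement motif pairs
#'
#' If elements acted on the DNA, an 8mer and its reverse complement would
#' mark the same double-stranded site and their scores should correlate;
#' for RNA-level regulation they are unrelated words. Each unordered pair is
#' used once; self-reverse-complementary motifs (possible for even-length
#' words, e.g. AAAAUUUU) cannot form a pair and are excluded.
#'
#' @param scores A data frame with `motif` and `score`.
#' @return List with `r` (Pearson correlation, `NA` if no complete pairs,
#'   with a warning), `n_pairs`, and the pair data frame.
#' @export
revcomp_score_correlation <- function(scores) {
  m <- scores$motif
  rc <- reverse_complement(m)
  have <- rc %in% m & m < rc          # dedupe unordered pairs
  if (!any(have)) {
    warning("no complete reverse-complement pairs among scored motifs")
    return(list(r = NA_real_, n_pairs = 0L,
                pairs = data.frame(motif = character(),
                                   revcomp = character())))
  }
  a <- m[have]
  b <- rc[have]
  sa <- scores$score[match(a, m)]
  sb <- scores$score[match(b, m)]
  list(r = stats::cor(sa, sb), n_pairs = length(a),
       pairs = data.frame(motif = a, revcomp = b, score = sa,
                          score_revcomp = sb, stringsAsFactors = FALSE))
}

#' Read aligned orthologous 3'UTR blocks from multi-FASTA files
#'
#' Each file holds one gene's alignment: equal-length gapped rows for the
#' four species (human, mouse, rat, dog), reference species first.
#' Sequences are upper-cased and converted to the RNA alphabet; gaps (`-`)
#' are preserved.
#'
#' @param paths Character vector of aligned multi-FASTA files.
#' @param n_species Required number of rows per block.
#' @return Named list of character vectors (one per block).
#' @export
read_alignment_blocks <- function(paths, n_species = 4L) {
  blocks <- lapply(paths, function(p) {
    x <- Biostrings::readBStringSet(p)
    rows <- dna_to_rna(toupper(as.character(x)))
    assert_that(length(rows) == n_species,
                p, ": expected ", n_species, " aligned rows, found ",
                length(rows))
    assert_that(length(unique(nchar(rows))) == 1L,
                p, ": aligned rows differ in length")
    rows
  })
  names(blocks) <- basename(paths)
  blocks
}

#' Count conserved instances of a motif across aligned species
#'
#' A conserved instance is a gap-free window of alignment columns where the
#' reference row spells the motif and every other species' row is identical
#' to it over those columns. Overlapping occurrences are all counted.
#'
#' @param alignments List of alignment blocks (character vectors of
#'   equal-length aligned rows, reference first), e.g. from
#'   [read_alignment_blocks()].
#' @param motif One RNA-alphabet motif.
#' @return Integer count over all blocks.
#' @export
conserved_instance_count <- function(alignments, motif) {
  assert_motifs(motif, len = nchar(motif), what = "motif")
  mlen <- nchar(motif)
  total <- 0L
  for (block in alignments) {
    width <- unique(nchar(block))
    assert_that(length(width) == 1L, "aligned rows differ in length")
    if (width < mlen) next
    starts <- seq_len(width - mlen + 1L)
    ref_hits <- starts[substring(block[1L], starts, starts + mlen - 1L) ==
                         motif]
    if (!length(ref_hits)) next
    ok <- rep(TRUE, length(ref_hits))
    for (row in block[-1L]) {
      ok <- ok & substring(row, ref_hits, ref_hits + mlen - 1L) == motif
    }
    total <- total + sum(ok)
  }
  total
}

#' Conservation signal of a motif against shuffled controls
#'
#' The motif's conserved-instance count is judged against the mean count of
#' composition-preserving shuffles of the motif (same nucleotide multiset).
#' Shuffles equal to the original motif are excluded; a degenerate motif
#' whose only permutation is itself (a homopolymer) has signal 1 by
#' definition.
#'
#' @param motif One RNA-alphabet motif.
#' @param alignments As in [conserved_instance_count()].
#' @param n_shuffles Number of shuffled controls (default 50).
#' @param seed Integer seed; results are deterministic given it.
#' @return A one-row data frame: `motif`, `conserved_count`,
#'   `shuffled_mean`, `signal`, `n_shuffles_used`. If the shuffled mean is 0
#'   while the motif was observed, `signal` is `NA` with a warning.
#' @export
conservation_signal <- function(motif, alignments, n_shuffles = 50L,
                                seed = NULL) {
  obs <- conserved_instance_count(alignments, motif)
  letters <- strsplit(motif, "", fixed = TRUE)[[1L]]
  shuffles <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    paste(sample(letters), collapse = "")
  }, character(1L)))
  shuffles <- shuffles[shuffles != motif]
  if (!length(shuffles)) {
    # homopolymer-like motif: every permutation is the motif itself
    return(data.frame(motif = motif, conserved_count = obs,
                      shuffled_mean = obs, signal = 1,
                      n_shuffles_used = 0L, stringsAsFactors = FALSE))
  }
  cnt <- vapply(shuffles, conserved_instance_count, numeric(1L),
                alignments = alignments, USE.NAMES = FALSE)
  mu <- mean(cnt)
  signal <- if (mu > 0) obs / mu else if (obs == 0) 0 else NA_real_
  if (is.na(signal)) {
    warning("shuffled controls never conserved but motif was; ",
            "signal undefined")
  }
  data.frame(motif = motif, conserved_count = obs, shuffled_mean = mu,
             signal = signal, n_shuffles_used = length(shuffles),
             stringsAsFactors = FALSE)
}
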