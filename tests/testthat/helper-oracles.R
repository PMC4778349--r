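# Independent brute-force oracles. These deliberately re-derive results with
# naive per-element loops so the vectorized implementations are checked
# against a second, structurally different route.

# per-read loop re-implementation of the read filters
oracle_filter <- function(seqs, quals, layout, barcodes) {
  L <- layout$barcode_length
  up <- layout$upstream_flank
  nup <- nchar(up)
  ml <- layout$motif_length
  dn <- layout$downstream_flank
  status <- character(length(seqs))
  motif <- rep(NA_character_, length(seqs))
  reg <- c(seq_len(L), (L + nup + 1):(L + nup + ml))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    q <- quals[i]
    if (nchar(s) < layout$read_length) {
      status[i] <- "quality"
      next
    }
    qs <- utf8ToInt(q) - 33L
    bases <- strsplit(s, "")[[1]]
    if (any(qs[reg] <= layout$min_phred) || any(bases[reg] == "N")) {
      status[i] <- "quality"
    } else if (substr(s, L + 1, L + nup) != up) {
      status[i] <- "upstream"
    } else if (substr(s, L + nup + ml + 1, L + nup + ml + nchar(dn)) != dn) {
      status[i] <- "downstream"
    } else if (!substr(s, 1, L) %in% barcodes) {
      status[i] <- "barcode"
    } else {
      status[i] <- "pass"
      motif[i] <- chartr("T", "U", substr(s, L + nup + 1, L + nup + ml))
    }
  }
  list(status = status, motif = motif)
}

# exact hypergeometric pmf from binomial coefficients (exact doubles for
# N <= 30), minimum-likelihood two-sided sum
oracle_fisher_p <- function(b, n, B, N) {
  k <- max(0, n + B - N):min(n, B)
  pmf <- choose(B, k) * choose(N - B, n - k) / choose(N, n)
  sum(pmf[pmf <= pmf[k == b] * (1 + 1e-7)])
}

# character-by-character scan for conserved motif windows
oracle_conserved <- function(blocks, motif) {
  m <- strsplit(motif, "")[[1]]
  ml <- length(m)
  total <- 0L
  for (b in blocks) {
    rows <- lapply(b, function(r) strsplit(r, "")[[1]])
    W <- length(rows[[1]])
    if (W < ml) next
    for (s in seq_len(W - ml + 1L)) {
      win <- s:(s + ml - 1L)
      hit <- all(rows[[1]][win] == m) &&
        all(vapply(rows[-1], function(r) all(r[win] == m), logical(1)))
      if (hit) total <- total + 1L
    }
  }
  total
}

# scalar-arithmetic expression score
oracle_score <- function(x, w = c(-2, -1, 0, 1, 2)) sum(w * x) / sum(x)

# n distinct random motifs (indices sampled without replacement)
random_motifs <- function(n, len = 8L, exclude = character()) {
  idx <- sample.int(4L^len, n + length(exclude)) - 1L
  out <- vapply(idx, function(x) {
    chars <- character(len)
    for (p in len:1) {
      chars[p] <- c("A", "C", "G", "U")[x %% 4L + 1L]
      x <- x %/% 4L
    }
    paste(chars, collapse = "")
  }, character(1))
  setdiff(out, exclude)[seq_len(n)]
}

# random 4-row alignment blocks: a reference row plus 3 species rows that
# mostly copy it but carry substitutions and occasional gaps
random_alignment_blocks <- function(n_blocks, width = 60, diverge = 0.1) {
  lapply(seq_len(n_blocks), function(i) {
    ref <- sample(c("A", "C", "G", "U"), width, replace = TRUE)
    rows <- c(list(ref), lapply(1:3, function(s) {
      r <- ref
      mut <- runif(width) < diverge
      r[mut] <- sample(c("A", "C", "G", "U", "-"), sum(mut), replace = TRUE)
      r
    }))
    vapply(rows, paste, character(1), collapse = "")
  })
}

# keep only some populations of a sorted_populations object
subset_pops <- function(pops, labels) {
  structure(pops[labels], class = "sorted_populations",
            scheme = attr(pops, "scheme"),
            replicate_mode = attr(pops, "replicate_mode"))
}

# one small shared screen simulation, built once per test run
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- generate_truth(150, c(0.15, 0.15, 0.7),
                              effect_magnitude = 1.5, seed = 101)
      counts <- normalize_rpm(simulate_screen(
        truth, mean_integrations = 80, depth = 5e4, seed = 202))
      cache <<- list(truth = truth, counts = counts)
    }
    cache
  }
})
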