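#' RNA alphabet used for motifs
#'
#' Candidate regulatory elements are stored throughout the package in the RNA
#' alphabet (A, C, G, U); sequencing reads use the DNA alphabet, and
#' conversion happens only at the read boundary.
#'
#' @format Character vector of the four RNA bases.
#' @export
RNA_BASES <- c("A", "C", "G", "U")

DNA_BASES <- c("A", "C", "G", "T")

#' Convert between DNA and RNA alphabets
#'
#' @param x Character vector of sequences.
#' @return `x` with T substituted for U (or vice versa), case preserved.
#' @examples
#' dna_to_rna("ACAGGGTA") # "ACAGGGUA"
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Check that motifs are valid fixed-length RNA words
#' @param x Character vector.
#' @param len Required motif length (default 8).
#' @return Logical vector.
#' @export
is_valid_motif <- function(x, len = 8L) {
  nchar(x) == len & grepl("^[ACGU]+$", x)
}

assert_motifs <- function(x, len = 8L, what = "motif") {
  bad <- !is_valid_motif(x, len)
  if (any(bad)) {
    abort(sprintf("invalid %s(s): %s (must be %d-letter words over A/C/G/U)",
                  what, paste(utils::head(x[bad], 3L), collapse = ", "), len))
  }
  invisible(x)
}

# Map 0-based indices in [0, 4^len) to RNA words; used by the truth generator
# to sample motifs without enumerating the full 4^8 library.
motif_from_index <- function(i, len = 8L) {
  x <- as.integer(i)
  stopifnot(all(x >= 0L), all(x < 4L^len))
  cols <- vector("list", len)
  for (p in len:1) {
    cols[[p]] <- RNA_BASES[x %% 4L + 1L]
    x <- x %/% 4L
  }
  do.call(paste0, cols)
}

#' Reverse complement of an RNA motif
#'
#' Used to test whether candidate elements act on the RNA (where an element
#' and its reverse complement are unrelated words) or on the DNA (where they
#' would mark the same double-stranded site). The operation is an involution.
#'
#' @param motif Character vector of RNA-alphabet motifs.
#' @return Character vector of reverse complements, RNA alphabet.
#' @examples
#' reverse_complement("ACAGGGUA") # "UACCCUGU"
#' @export
reverse_complement <- function(motif) {
  assert_motifs(motif, len = nchar(motif), what = "sequence")
  comp <- chartr("ACGU", "UGCA", motif)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L),
         USE.NAMES = FALSE)
}
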