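#' Parse amplicon FASTQ reads and apply the screen's quality filters
#'
#' A read passes if and only if (i) every base of the sample barcode and the
#' variable 8mer has Phred quality strictly greater than `layout$min_phred`
#' (a base at exactly the bound fails), with reads shorter than the layout
#' read length or containing N in barcode/8mer also failing quality; (ii) the
#' constant flanks match exactly at their expected positions (`CATAC`
#' upstream, `ATA` downstream by default); (iii) the barcode matches a map
#' entry exactly (0 mismatches). The 8mer is extracted between the flanks and
#' returned in the RNA alphabet.
#'
#' Failure attribution is first-failure and order-stable: quality is checked
#' before the upstream flank, then the downstream flank, then the barcode.
#' An unknown barcode is counted (`fail_barcode`), not fatal; a structurally
#' malformed FASTQ record raises a parse error naming the offending line.
#'
#' @param fastq Path to a FASTQ file (Phred+33), optionally gzipped.
#' @param layout A [read_layout()].
#' @param barcode_map Data frame with columns `barcode`, `population`,
#'   `replicate`; all barcodes must share the layout's barcode length
#'   (fixed-length codes are prefix-free).
#' @param scan If `TRUE`, locate the upstream flank by scanning the read
#'   after the barcode instead of assuming the fixed offset; a robustness
#'   switch for indel-containing amplicons.
#' @return List with `reads` (data frame `population`, `replicate`, `motif`)
#'   and `stats` (a `read_filter_stats` object).
#' @export
parse_and_filter <- function(fastq, layout = read_layout(), barcode_map,
                             scan = FALSE) {
  stopifnot(inherits(layout, "read_layout"))
  assert_that(all(c("barcode", "population", "replicate") %in%
                    names(barcode_map)),
              "barcode_map needs columns barcode, population, replicate")
  assert_that(!anyDuplicated(barcode_map$barcode),
              "barcode_map barcodes must be unique")
  assert_that(all(nchar(barcode_map$barcode) == layout$barcode_length),
              "all barcodes must have the layout's barcode length")

  rec <- read_fastq_records(fastq)
  seqs <- rec$seq
  quals <- rec$qual

  L <- layout$barcode_length
  nup <- nchar(layout$upstream_flank)
  ndn <- nchar(layout$downstream_flank)
  mlen <- layout$motif_length

  if (scan) {
    up_pos <- as.integer(regexpr(layout$upstream_flank, seqs, fixed = TRUE))
    found <- up_pos > L
    motif_start <- ifelse(found, up_pos + nup, L + nup + 1L)
    up_ok <- found
  } else {
    motif_start <- rep.int(L + nup + 1L, length(seqs))
    up_ok <- substr(seqs, L + 1L, L + nup) == layout$upstream_flank
  }
  bc <- substr(seqs, 1L, L)
  mot <- substr(seqs, motif_start, motif_start + mlen - 1L)
  dwn <- substr(seqs, motif_start + mlen, motif_start + mlen + ndn - 1L)

  # any base at or below the bound fails; Phred+33 chars '!' .. bound
  lowq_class <- paste0("[!-", rawToChar(as.raw(33L + layout$min_phred)), "]")
  q_check <- paste0(substr(quals, 1L, L),
                    substr(quals, motif_start, motif_start + mlen - 1L))
  s_check <- paste0(bc, mot)
  fail_q <- nchar(seqs) < layout$read_length |
    grepl(lowq_class, q_check) | grepl("N", s_check, fixed = TRUE)
  fail_up <- !fail_q & !up_ok
  fail_dn <- !fail_q & !fail_up & dwn != layout$downstream_flank
  known <- bc %in% barcode_map$barcode
  fail_bc <- !fail_q & !fail_up & !fail_dn & !known
  pass <- !(fail_q | fail_up | fail_dn | fail_bc)

  stats <- new_read_filter_stats(
    total_reads = length(seqs),
    fail_quality = sum(fail_q),
    fail_upstream_flank = sum(fail_up),
    fail_downstream_flank = sum(fail_dn),
    fail_barcode = sum(fail_bc),
    passed = sum(pass))

  idx <- match(bc[pass], barcode_map$barcode)
  reads <- data.frame(population = barcode_map$population[idx],
                      replicate = as.integer(barcode_map$replicate[idx]),
                      motif = dna_to_rna(mot[pass]),
                      stringsAsFactors = FALSE)
  list(reads = reads, stats = stats)
}

# Read 4-line FASTQ records with structural validation. Implemented on
# readLines rather than a library parser because the error contract requires
# line-numbered diagnostics for malformed records (and the amplicon layout
# needs the raw quality string anyway). Gzip handled transparently.
read_fastq_records <- function(fastq) {
  con <- if (grepl("\\.gz$", fastq)) gzfile(fastq) else file(fastq)
  lines <- tryCatch(readLines(con, warn = FALSE), finally = close(con))
  n <- length(lines)
  if (n == 0L) return(list(seq = character(), qual = character()))
  if (n %% 4L != 0L) {
    abort("malformed FASTQ record at line ", 4L * (n %/% 4L) + 1L,
          ": truncated record (file has ", n, " lines)")
  }
  hdr <- seq(1L, n, by = 4L)
  bad <- hdr[!startsWith(lines[hdr], "@")]
  if (length(bad)) {
    abort("malformed FASTQ record at line ", bad[1L],
          ": header does not start with '@'")
  }
  bad <- hdr[!startsWith(lines[hdr + 2L], "+")]
  if (length(bad)) {
    abort("malformed FASTQ record at line ", bad[1L] + 2L,
          ": separator does not start with '+'")
  }
  seqs <- lines[hdr + 1L]
  quals <- lines[hdr + 3L]
  bad <- hdr[nchar(seqs) != nchar(quals)]
  if (length(bad)) {
    abort("malformed FASTQ record at line ", bad[1L] + 3L,
          ": quality length differs from sequence length")
  }
  list(seq = seqs, qual = quals)
}

new_read_filter_stats <- function(total_reads, fail_quality,
                                  fail_upstream_flank, fail_downstream_flank,
                                  fail_barcode, passed) {
  s <- list(total_reads = total_reads, fail_quality = fail_quality,
            fail_upstream_flank = fail_upstream_flank,
            fail_downstream_flank = fail_downstream_flank,
            fail_barcode = fail_barcode, passed = passed)
  stopifnot(total_reads == passed + fail_quality + fail_upstream_flank +
              fail_downstream_flank + fail_barcode)
  structure(s, class = "read_filter_stats")
}

#' @export
print.read_filter_stats <- function(x, ...) {
  cat("read filter statistics (first-failure attribution:",
      "quality > upstream flank > downstream flank > barcode)\n")
  for (f in names(x)) cat(sprintf("  %-22s %d\n", f, x[[f]]))
  invisible(x)
}

#' @export
as.data.frame.read_filter_stats <- function(x, ...) {
  data.frame(metric = names(x), reads = unlist(x, use.names = FALSE))
}

#' Count parsed 8mers per population and replicate
#'
#' @param reads Data frame of parsed reads (`population`, `replicate`,
#'   `motif`), e.g. from [parse_and_filter()].
#' @param whitelist Optional motif set; reads whose motif is not listed are
#'   collapsed into a single `"other"` tally (kept in the table so RPM
#'   denominators can include them, the default convention).
#' @return A `count_table` data frame; zero-count rows are retained for every
#'   motif observed anywhere in a library's population set, so replicate
#'   comparisons see explicit zeros. An empty input yields an empty table.
#' @export
count_motifs <- function(reads, whitelist = NULL) {
  if (NROW(reads) == 0L) {
    return(new_count_table(character(), character(), integer(), integer()))
  }
  m <- reads$motif
  if (!is.null(whitelist)) m[!(m %in% whitelist)] <- "other"
  tb <- as.data.frame(table(motif = m, population = reads$population,
                            replicate = reads$replicate),
                      responseName = "count", stringsAsFactors = FALSE)
  # the full cross product can invent libraries that never occurred; drop them
  lib <- paste(tb$population, tb$replicate)
  seen <- unique(paste(reads$population, reads$replicate))
  tb <- tb[lib %in% seen, , drop = FALSE]
  new_count_table(tb$motif, tb$population, as.integer(tb$replicate), tb$count)
}

#' Normalize a count table to reads per million (RPM)
#'
#' `rpm = count * 1e6 / library total`, where a library is one
#' population-replicate combination (or one population after replicate
#' aggregation). Per library the RPM values sum to 1e6 by construction.
#'
#' @param table A `count_table`.
#' @return The table with an `rpm` column added/overwritten.
#' @export
normalize_rpm <- function(table) {
  assert_that(is.data.frame(table) &&
                all(c("motif", "population", "count") %in% names(table)),
              "not a count table")
  key <- if ("replicate" %in% names(table)) {
    paste(table$population, table$replicate)
  } else {
    table$population
  }
  tot <- stats::ave(table$count, key, FUN = sum)
  if (any(tot == 0)) {
    abort("empty library: zero total reads in ",
          paste(unique(key[tot == 0]), collapse = ", "),
          "; RPM is undefined")
  }
  table$rpm <- table$count * 1e6 / tot
  table
}

#' Read or write a count table as tidy TSV
#'
#' @param table A `count_table`.
#' @param path TSV path.
#' @return `read_count_table()` returns a `count_table`;
#'   `write_count_table()` returns `path` invisibly.
#' @export
write_count_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("motif", "population", "replicate", "count") %in%
                    names(df)), "file is not a count table TSV")
  out <- new_count_table(df$motif, df$population, df$replicate, df$count)
  if ("rpm" %in% names(df)) out$rpm <- df$rpm
  out
}
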