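# assemble a FASTQ on disk from (sequence, quality) pairs
write_fastq <- function(seqs, quals, path = tempfile(fileext = ".fastq")) {
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs,
                             "+", quals)), path)
  path
}

test_layout <- read_layout()          # CATAC / 8mer / ATA, 50 nt, Q>20, bc 6
test_map <- data.frame(barcode = "AAAAAA", population = "GFP-ALL",
                       replicate = 1L, stringsAsFactors = FALSE)

mk_read <- function(barcode = "AAAAAA", up = "CATAC", motif = "ACAGGGTA",
                    down = "ATA", len = 50) {
  body <- paste0(barcode, up, motif, down)
  paste0(body, strrep("G", len - nchar(body)))
}

test_that("an intact read passes and yields the RNA-alphabet motif", {
  q40 <- strrep("I", 50)
  out <- parse_and_filter(write_fastq(mk_read(), q40), test_layout, test_map)
  expect_equal(out$stats$passed, 1L)
  expect_equal(out$reads$motif, "ACAGGGUA")
  expect_equal(out$reads$population, "GFP-ALL")
})

test_that("the Phred bound is strict and applies to barcode and 8mer", {
  # motif base at exactly Q20 fails; Q21 passes
  q_at <- function(pos, ch) {
    q <- strrep("I", 50)
    substr(q, pos, pos) <- ch
    q
  }
  motif_pos <- 6 + 5 + 1          # first motif base
  for (case in list(list(q_at(motif_pos, "5"), 0L),   # Q20: fail
                    list(q_at(motif_pos, "6"), 1L),   # Q21: pass
                    list(q_at(3, "5"), 0L),           # barcode base Q20
                    list(q_at(20, "!"), 1L))) {       # low qual outside region
    out <- parse_and_filter(write_fastq(mk_read(), case[[1]]),
                            test_layout, test_map)
    expect_equal(out$stats$passed, case[[2]])
    if (case[[2]] == 0L) expect_equal(out$stats$fail_quality, 1L)
  }
  # N in the motif fails quality even at high Q
  out <- parse_and_filter(write_fastq(mk_read(motif = "ACAGNGTA"),
                                      strrep("I", 50)),
                          test_layout, test_map)
  expect_equal(out$stats$fail_quality, 1L)
  # short read fails quality
  out <- parse_and_filter(write_fastq(substr(mk_read(), 1, 30),
                                      strrep("I", 30)),
                          test_layout, test_map)
  expect_equal(out$stats$fail_quality, 1L)
})

test_that("every single-edit flank variant fails with correct attribution", {
  q40 <- strrep("I", 50)
  for (pos in 1:5) {
    for (b in setdiff(c("A", "C", "G", "T"), substr("CATAC", pos, pos))) {
      up <- "CATAC"
      substr(up, pos, pos) <- b
      out <- parse_and_filter(write_fastq(mk_read(up = up), q40),
                              test_layout, test_map)
      expect_equal(out$stats$fail_upstream_flank, 1L)
    }
  }
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr("ATA", pos, pos))) {
      dn <- "ATA"
      substr(dn, pos, pos) <- b
      out <- parse_and_filter(write_fastq(mk_read(down = dn), q40),
                              test_layout, test_map)
      expect_equal(out$stats$fail_downstream_flank, 1L)
    }
  }
})

test_that("failure attribution is first-failure and order-stable", {
  q_low <- paste0(strrep("I", 11), "5", strrep("I", 38))  # motif base low
  # read fails quality AND both flanks; attributed to quality only
  out <- parse_and_filter(
    write_fastq(mk_read(up = "GGGGG", down = "GGG"), q_low),
    test_layout, test_map)
  expect_equal(out$stats$fail_quality, 1L)
  expect_equal(out$stats$fail_upstream_flank, 0L)
  # flank beats barcode: unknown barcode with broken flank -> upstream
  out <- parse_and_filter(
    write_fastq(mk_read(barcode = "CCCCCC", up = "GGGGG"), strrep("I", 50)),
    test_layout, test_map)
  expect_equal(out$stats$fail_upstream_flank, 1L)
  expect_equal(out$stats$fail_barcode, 0L)
  # unknown barcode alone is counted, not fatal
  out <- parse_and_filter(
    write_fastq(c(mk_read(barcode = "CCCCCC"), mk_read()),
                rep(strrep("I", 50), 2)),
    test_layout, test_map)
  expect_equal(out$stats$fail_barcode, 1L)
  expect_equal(out$stats$passed, 1L)
  # stats always reconcile
  expect_equal(out$stats$total_reads,
               out$stats$passed + out$stats$fail_quality +
                 out$stats$fail_upstream_flank +
                 out$stats$fail_downstream_flank + out$stats$fail_barcode)
})

test_that("malformed FASTQ records raise line-numbered parse errors", {
  p <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", mk_read(), "+", strrep("I", 50), "@r2", mk_read()), p)
  expect_error(parse_and_filter(p, test_layout, test_map),
               "line 5.*truncated")
  writeLines(c("@r1", mk_read(), "noplus", strrep("I", 50)), p)
  expect_error(parse_and_filter(p, test_layout, test_map), "line 3")
})

test_that("filter matches a naive per-read oracle on random reads", {
  withr::with_seed(404, {
    n <- 1e4
    bcs <- make_barcodes(4)
    map <- data.frame(barcode = bcs,
                      population = c("0-10", "90-100", "GFP-ALL", "BG25"),
                      replicate = 1L)
    barcode <- sample(c(bcs, "TTTTTT"), n, replace = TRUE)
    up <- sample(c("CATAC", "CATAG", "AATAC"), n, TRUE, c(0.8, 0.1, 0.1))
    down <- sample(c("ATA", "AAA"), n, TRUE, c(0.9, 0.1))
    motif <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), 8, TRUE,
                   c(rep(0.245, 4), 0.02)), collapse = "")
    }, character(1))
    seqs <- paste0(barcode, up, motif, down,
                   strrep("A", 50 - 6 - 5 - 8 - 3))
    quals <- vapply(seq_len(n), function(i) {
      paste(sample(c("I", "J", "6", "5", "!"), 50, TRUE,
                   c(0.85, 0.1, 0.02, 0.02, 0.01)), collapse = "")
    }, character(1))
    out <- parse_and_filter(write_fastq(seqs, quals), test_layout, map)
    orc <- oracle_filter(seqs, quals, test_layout, bcs)
    expect_equal(out$stats$passed, sum(orc$status == "pass"))
    expect_equal(out$stats$fail_quality, sum(orc$status == "quality"))
    expect_equal(out$stats$fail_upstream_flank,
                 sum(orc$status == "upstream"))
    expect_equal(out$stats$fail_downstream_flank,
                 sum(orc$status == "downstream"))
    expect_equal(out$stats$fail_barcode, sum(orc$status == "barcode"))
    expect_equal(sort(out$reads$motif),
                 sort(orc$motif[orc$status == "pass"]))
  })
})

test_that("count_motifs tallies reads and honours the whitelist", {
  reads <- data.frame(population = "GFP-ALL", replicate = 1L,
                      motif = rep("ACAGGGUA", 3))
  tb <- count_motifs(reads)
  expect_equal(tb$count[tb$motif == "ACAGGGUA"], 3L)

  # empty stream: empty table, no error
  empty <- count_motifs(reads[0, ])
  expect_s3_class(empty, "count_table")
  expect_equal(nrow(empty), 0L)

  # whitelist collapses unlisted motifs into "other"
  reads2 <- data.frame(population = "GFP-ALL", replicate = 1L,
                       motif = c("ACAGGGUA", "ACAGGGUA", "UUUUUUUU"))
  tb2 <- count_motifs(reads2, whitelist = "ACAGGGUA")
  expect_setequal(tb2$motif, c("ACAGGGUA", "other"))
  expect_equal(tb2$count[tb2$motif == "other"], 1L)
})

test_that("RPM normalization is exact and conserves 1e6 per library", {
  tb <- data.frame(motif = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"),
                             population = "GFP-ALL", replicate = 1L,
                             count = c(1L, 1L, 2L))
  out <- normalize_rpm(tb)
  expect_equal(out$rpm, c(250000, 250000, 500000))

  one <- normalize_rpm(data.frame(motif = "AAAAAAAA",
                                  population = "0-10", replicate = 1L,
                                  count = 100L))
  expect_equal(one$rpm, 1e6)

  # summation oracle on a random table
  sim <- shared_sim()
  sums <- tapply(sim$counts$rpm,
                 paste(sim$counts$population, sim$counts$replicate), sum)
  expect_true(all(abs(sums - 1e6) < 1e-6 * 1e6))

  expect_error(normalize_rpm(data.frame(motif = "AAAAAAAA",
                                        population = "0-10",
                                        replicate = 1L, count = 0L)),
               "empty library")
})

test_that("emit -> parse -> count round-trips exactly at error rate 0", {
  sim <- shared_sim()
  cells <- simulate_cells(sim$truth, 80, seed = 91)
  pops <- subset_pops(gate_and_sort(cells), c("0-10", "90-100", "BG25"))
  fq <- emit_fastq(pops, depth = 3000, error_rate = 0, seed = 92)
  parsed <- parse_and_filter(fq$path, fq$layout, fq$barcode_map)
  got <- count_motifs(parsed$reads)
  got <- got[got$count > 0, c("motif", "population", "replicate", "count")]
  want <- fq$truth[fq$truth$count > 0,
                   c("motif", "population", "replicate", "count")]
  key <- function(d) d[order(d$motif, d$population, d$replicate), ]
  expect_equal(unname(as.list(key(got))), unname(as.list(key(want))))
})

test_that("count tables survive a TSV round trip", {
  sim <- shared_sim()
  p <- tempfile(fileext = ".tsv")
  write_count_table(sim$counts, p)
  back <- read_count_table(p)
  expect_equal(back$count, sim$counts$count)
  expect_equal(back$rpm, sim$counts$rpm, tolerance = 1e-12)
})
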