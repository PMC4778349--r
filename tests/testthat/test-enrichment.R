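test_that("fisher_two_sided matches the enumeration oracle", {
  # frozen from the exact pmf (1/6, 4/6, 1/6): outcomes k=0 and k=2 qualify
  expect_equal(fisher_two_sided(2, 2, 2, 4), 1 / 3, tolerance = 1e-12)
  expect_equal(oracle_fisher_p(2, 2, 2, 4), 1 / 3, tolerance = 1e-12)

  # no-association table attains p = 1
  expect_equal(fisher_two_sided(1, 2, 2, 4), 1)

  # random sample of valid tables with N <= 30 (full sweep in acceptance)
  withr::with_seed(67, {
    for (i in 1:300) {
      N <- sample(2:30, 1)
      B <- sample(0:N, 1)
      n <- sample(0:N, 1)
      rng <- max(0, n + B - N):min(n, B)
      b <- if (length(rng) == 1L) rng else sample(rng, 1)
      expect_equal(fisher_two_sided(b, n, B, N),
                   oracle_fisher_p(b, n, B, N), tolerance = 1e-12)
    }
  })

  expect_error(fisher_two_sided(3, 2, 2, 4), "inconsistent")

  # doubling convention stays a valid p-value and differs where expected
  expect_lte(fisher_two_sided(5, 5, 5, 20, convention = "doubling"), 1)
})

test_that("category_enrichment computes fold = (b/n)/(B/N) with Fisher p", {
  u <- paste0("m", 1:1000)
  calls <- u[1:100]
  category <- c(u[1:5], u[101:105])          # b = 5, n = 10
  res <- category_enrichment(category, calls, u)
  expect_equal(res$b, 5)
  expect_equal(res$n, 10)
  expect_equal(res$B, 100)
  expect_equal(res$N, 1000)
  expect_equal(res$fold, 5)
  # algebraic identity: fold * (B/N) * n = b
  expect_equal(res$fold * (res$B / res$N) * res$n, res$b)

  # degenerate: category = calls = universe
  res2 <- category_enrichment(u, u, u)
  expect_equal(res2$fold, 1)
  expect_equal(res2$p, 1)

  # motifs outside the universe are dropped with a warning
  expect_warning(res3 <- category_enrichment(c(u[1:5], "zzz"), calls, u),
                 "outside the universe")
  expect_equal(res3$n, 5)
})

test_that("an activating-biased category enriches with small p", {
  withr::with_seed(71, {
    u <- random_motifs(1000)
    act <- sample(u, 150)
    category <- c(sample(act, 30), sample(setdiff(u, act), 20))
    res <- category_enrichment(category, act, u,
                               name = "conserved", direction = "activating")
    expect_gt(res$fold, 1)
    expect_lt(res$p, 0.05)
  })
  # fold direction is stable under uniform universe subsampling
  withr::with_seed(72, {
    u <- paste0("m", 1:2000)
    calls <- u[1:200]
    category <- c(u[1:40], u[201:260])        # enriched 2x
    full <- category_enrichment(category, calls, u)
    sub <- u[sample(2000, 1000)]
    res <- category_enrichment(intersect(category, sub),
                               intersect(calls, sub), sub)
    expect_gt(res$fold, 1)
    expect_lt(abs(res$fold - full$fold) / full$fold, 0.5)
  })
})

test_that("enrich_categories covers both directions", {
  sim <- shared_sim()
  sc <- score_screen(sim$counts)
  cats <- list(up = sim$truth$motif[sim$truth$true_class == "activating"],
               down = sim$truth$motif[sim$truth$true_class == "repressive"])
  suppressWarnings(res <- enrich_categories(cats, sc))
  expect_equal(nrow(res), 4)
  expect_setequal(res$direction, c("activating", "repressive"))
  # the truly activating category is most enriched among activating calls
  fold_aa <- res$fold[res$category == "up" & res$direction == "activating"]
  fold_ar <- res$fold[res$category == "up" & res$direction == "repressive"]
  expect_gt(fold_aa, fold_ar)
})

test_that("reverse_complement is correct and involutive", {
  expect_equal(reverse_complement("ACAGGGUA"), "UACCCUGU")
  withr::with_seed(73, {
    m <- random_motifs(200)
    expect_equal(reverse_complement(reverse_complement(m)), m)
  })
  # even-length RNA words can be self-reverse-complementary
  expect_equal(reverse_complement("AAAAUUUU"), "AAAAUUUU")
  expect_error(reverse_complement("ACGTACGT"), "invalid")
})

test_that("revcomp_score_correlation pairs, dedupes and warns", {
  # scores symmetric under reverse complement: r = 1
  withr::with_seed(79, {
    base <- unique(random_motifs(150))
    rc <- reverse_complement(base)
    keep <- !(rc %in% base)          # drops self-RC and double-listed pairs
    base <- base[keep]
    rc <- rc[keep]
    s <- rnorm(length(base))
    sc <- data.frame(motif = c(base, rc), score = c(s, s))
    out <- revcomp_score_correlation(sc)
    expect_equal(out$r, 1)
    expect_equal(out$n_pairs, length(base))

    # independent scores: near-zero correlation
    sc2 <- data.frame(motif = c(base, rc),
                      score = rnorm(2 * length(base)))
    expect_lt(abs(revcomp_score_correlation(sc2)$r), 0.35)
  })
  # no complete pairs: NA with a warning
  expect_warning(out3 <- revcomp_score_correlation(
    data.frame(motif = c("AAAAAAAC", "AAAAAAAG"), score = c(1, 2))),
    "no complete")
  expect_true(is.na(out3$r))
})

test_that("conserved_instance_count matches the naive scan oracle", {
  # all four rows identical, motif present once
  block1 <- rep(paste0("GG", "ACAGGGUA", "CCUUA"), 4)
  expect_equal(conserved_instance_count(list(block1), "ACAGGGUA"), 1)

  # one substitution inside the motif in the fourth species: not conserved
  block2 <- block1
  block2[4] <- paste0("GG", "ACAGGGCA", "CCUUA")
  expect_equal(conserved_instance_count(list(block2), "ACAGGGUA"), 0)

  # a gap inside the motif window breaks conservation
  block3 <- block1
  block3[2] <- paste0("GG", "ACAG-GUA", "CCUUA")
  expect_equal(conserved_instance_count(list(block3), "ACAGGGUA"), 0)

  # overlapping occurrences all counted
  block4 <- rep(strrep("A", 9), 4)
  expect_equal(conserved_instance_count(list(block4), "AAAAAAAA"), 2)

  # 100 random blocks against the independent scan
  withr::with_seed(83, {
    blocks <- random_alignment_blocks(100, width = 40, diverge = 0.15)
    for (motif in c("ACAGGGUA", random_motifs(3), "AAAAAAAA")) {
      expect_equal(conserved_instance_count(blocks, motif),
                   oracle_conserved(blocks, motif))
    }
  })

  expect_error(conserved_instance_count(list(c("ACGU", "ACG", "ACGU",
                                               "ACGU")), "ACAGGGUA"),
               "differ in length")
})

test_that("conservation_signal detects planted conservation", {
  planted <- "ACAGGGUA"
  withr::with_seed(89, {
    # fully conserved background whose letter frequencies match the motif's
    # composition, so shuffled controls occur at a measurable baseline rate
    bg <- lapply(1:3, function(i) {
      row <- paste(sample(c("A", "C", "G", "U"), 5000, replace = TRUE,
                          prob = c(3, 1, 3, 1) / 8), collapse = "")
      rep(row, 4)
    })
    # plant 40 conserved instances of the motif in dedicated blocks
    planted_blocks <- lapply(1:40, function(i) {
      rep(paste0(paste(sample(c("A", "C", "G", "U"), 10, TRUE), collapse = ""),
                 planted,
                 paste(sample(c("A", "C", "G", "U"), 10, TRUE), collapse = "")),
          4)
    })
    blocks <- c(bg, planted_blocks)
    res <- conservation_signal(planted, blocks, n_shuffles = 50, seed = 90)
    expect_gt(res$shuffled_mean, 0)
    expect_gt(res$signal, 1)
    expect_gte(res$conserved_count, 40)
  })

  # homopolymer: every shuffle is the motif itself, signal 1 by definition
  blocks0 <- list(rep(strrep("A", 20), 4))
  res0 <- conservation_signal("AAAAAAAA", blocks0, seed = 1)
  expect_equal(res0$signal, 1)

  # motif absent everywhere: signal 0 (or flagged NA if shuffles also absent)
  res1 <- conservation_signal("ACAGGGUA", list(rep(strrep("C", 30), 4)),
                              n_shuffles = 20, seed = 2)
  expect_equal(res1$signal, 0)

  # deterministic given seed
  expect_identical(conservation_signal(planted, blocks0, seed = 5),
                   conservation_signal(planted, blocks0, seed = 5))
})

test_that("read_category parses plain text motif lists", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "ACAGGGUA", "", "acaggGta"), p)
  expect_equal(read_category(p), c("ACAGGGUA", "ACAGGGUA"))
  writeLines("TOOSHORT", p)
  expect_error(read_category(p), "invalid")
})

test_that("shipped category fixtures load as valid motif sets", {
  act <- read_category(system.file("extdata",
                                   "category_validated_activating.txt",
                                   package = "utrscreen"))
  rep_ <- read_category(system.file("extdata",
                                    "category_validated_repressive.txt",
                                    package = "utrscreen"))
  expect_length(act, 5)
  expect_length(rep_, 3)
  expect_true(all(is_valid_motif(c(act, rep_))))
  controls <- control_truth()
  expect_equal(nrow(controls), 10)
  expect_equal(sum(controls$true_class == "repressive"), 3)
  expect_equal(sum(controls$true_class == "neutral"), 2)
  expect_equal(sum(controls$true_class == "activating"), 5)
  # the miR-10 site carries the destabilizing exemplar effect
  expect_equal(controls$stability_effect[controls$motif == "ACAGGGUA"],
               -0.55)
})
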