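test_that("identical positive and negative sets yield no motifs", {
  withr::with_seed(2, {
    probes <- vapply(1:100, function(i) random_rna_string(20), character(1))
  })
  expect_identical(nrow(discover_motifs(probes, probes, "sequence")), 0L)
})

test_that("a planted hexamer is recovered with its consensus", {
  cfg <- generator_config(n_probes = 5000, probe_length = 20, seed = 12)
  bg <- generate_background(cfg)
  pos <- plant_motif(bg, "AUGCAU", rate = 0.5, seed = 12)$sequence
  neg <- generate_background(generator_config(n_probes = 5000,
                                              probe_length = 20,
                                              seed = 13))$sequence
  motifs <- discover_motifs(pos, neg, "sequence")
  expect_gt(nrow(motifs), 0)
  expect_true(any(grepl("AUGCAU", motifs$consensus, fixed = TRUE) |
                    vapply(motifs$consensus, function(k) {
                      grepl(k, "AUGCAU", fixed = TRUE)
                    }, logical(1))))
  # direct count oracle: the top motif is genuinely enriched
  top <- motifs[1, ]
  n_in <- function(strings, k) sum(grepl(k, strings, fixed = TRUE))
  expect_gt(n_in(pos, top$consensus), n_in(neg, top$consensus))
})

test_that("at most 40 PFMs are returned even when many seeds pass", {
  # positives over {A,C,G}, negatives all-U: every positive k-mer is
  # massively enriched and far more than 40 non-redundant seeds pass
  withr::with_seed(6, {
    pos <- vapply(1:200, function(i) {
      paste(sample(c("A", "C", "G"), 30, replace = TRUE), collapse = "")
    }, character(1))
    neg <- rep(strrep("U", 30), 200)
  })
  motifs <- discover_motifs(pos, neg, "sequence")
  expect_identical(nrow(motifs), 40L)
  expect_true(all(motifs$width >= 4 & motifs$width <= 6))
  expect_true(all(diff(motifs$p_adjusted) >= 0))
  # no two selected seeds of one width are within Hamming distance 1
  for (w in unique(motifs$width)) {
    seeds <- motifs$consensus[motifs$width == w]
    if (length(seeds) > 1) {
      for (i in seq_along(seeds)[-1]) {
        for (j in seq_len(i - 1)) {
          expect_gt(sum(strsplit(seeds[i], "")[[1]] !=
                          strsplit(seeds[j], "")[[1]]), 1)
        }
      }
    }
  }
})

test_that("bonferroni_cap applies the correction, threshold, sort and cap", {
  row <- function(id, p) {
    m <- tiny_motif_tbl("ACGU")
    m$motif <- id
    m$p_value <- p
    m
  }
  motifs <- dplyr::bind_rows(row("a", 0.001), row("b", 0.005))
  # p = 0.001 with 5 tests -> 0.005, retained; p = 0.005 -> 0.025, dropped
  out <- bonferroni_cap(motifs, n_tests = 5)
  expect_identical(out$motif, "a")
  expect_equal(out$p_adjusted, 0.005)
  # p = 0.005 with 10 tests -> 0.05, dropped at the 0.01 threshold (and
  # 0.001 x 10 = 0.01 sits exactly on the strict boundary, also dropped)
  expect_identical(nrow(bonferroni_cap(motifs, n_tests = 10)), 0L)
  # cap: 60 passing motifs truncate to the 40 smallest corrected p
  many <- dplyr::bind_rows(lapply(1:60, function(i) {
    row(sprintf("m%02d", i), i * 1e-6)
  }))
  capped <- bonferroni_cap(many, n_tests = 2)
  expect_identical(nrow(capped), 40L)
  expect_identical(capped$motif, sprintf("m%02d", 1:40))
  expect_error(bonferroni_cap(motifs, n_tests = 0),
               class = "ssmotif_config_error")
})

test_that("presence-test p-values match Fisher's exact test", {
  withr::with_seed(14, {
    pos <- plant_motif(
      generate_background(generator_config(n_probes = 150, probe_length = 15,
                                           seed = 41)),
      "ACGU", rate = 0.4, seed = 41)$sequence
    neg <- generate_background(generator_config(n_probes = 180,
                                                probe_length = 15,
                                                seed = 42))$sequence
  })
  for (k in c("ACGU", "UUUU", "GCGC")) {
    a <- sum(grepl(k, pos, fixed = TRUE))
    b <- sum(grepl(k, neg, fixed = TRUE))
    oracle <- stats::fisher.test(
      matrix(c(a, length(pos) - a, b, length(neg) - b), nrow = 2),
      alternative = "greater")$p.value
    mine <- stats::phyper(a - 1, a + b, length(pos) + length(neg) - a - b,
                          length(pos), lower.tail = FALSE)
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
  # and the discovery output reports exactly those p-values
  motifs <- discover_motifs(pos, neg, "sequence", p_threshold = 1)
  for (i in seq_len(min(3, nrow(motifs)))) {
    k <- motifs$consensus[i]
    a <- sum(grepl(k, pos, fixed = TRUE))
    b <- sum(grepl(k, neg, fixed = TRUE))
    oracle <- stats::fisher.test(
      matrix(c(a, length(pos) - a, b, length(neg) - b), nrow = 2),
      alternative = "greater")$p.value
    expect_equal(motifs$p_value[i], oracle, tolerance = 1e-12)
    expect_gt(a / length(pos), b / length(neg))
  }
})

test_that("label-shuffled data rarely yields any motif", {
  hits <- vapply(1:20, function(rep) {
    withr::with_seed(1000 + rep, {
      pool <- vapply(1:200, function(i) random_rna_string(25), character(1))
      idx <- sample(200, 100)
    })
    nrow(discover_motifs(pool[idx], pool[-idx], "sequence"))
  }, numeric(1))
  expect_gte(sum(hits == 0), 19)
})

test_that("PFM construction concentrates on the seed with pseudocounts", {
  motifs <- tiny_motif_tbl("ACGU")
  pfm <- motifs$pfm[[1]]
  expect_identical(pfm$consensus, "ACGU")
  expect_equal(colSums(pfm$matrix), rep(1, 4), tolerance = 1e-12)
  # 5 sites, pseudocount 0.1: consensus cell (5 + 0.1) / (5 + 0.4)
  expect_equal(unname(pfm$matrix["A", 1]), 5.1 / 5.4, tolerance = 1e-12)
  expect_equal(unname(pfm$matrix["C", 1]), 0.1 / 5.4, tolerance = 1e-12)
})

test_that("the STREME backend demands the external binary", {
  withr::local_envvar(PATH = tempdir())
  expect_error(discover_motifs("ACGU", "UUUU", "sequence",
                               backend = "streme"),
               class = "ssmotif_config_error")
})
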