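hmm_motifs <- function(widths, kind = "sequence") {
  alph <- ss_alphabet(kind)
  rows <- purrr::imap(widths, function(w, i) {
    withr::with_seed(100 + i, {
      m <- matrix(stats::rgamma(alph$size * w, 1), alph$size, w,
                  dimnames = list(alph$symbols, NULL))
      m <- sweep(m, 2, colSums(m), "/")
    })
    pfm <- ssmotif:::new_ss_pfm(sprintf("m%d", i), kind, m)
    tibble::tibble(motif = pfm$id, alphabet = kind, width = w,
                   consensus = pfm$consensus, p_value = 1e-4,
                   p_adjusted = 1e-3, n_pos = 5L, n_neg = 0L,
                   pfm = list(pfm))
  })
  dplyr::bind_rows(rows)
}

test_that("gap-HMM state counts follow the ordered-pair topology", {
  # 1 PFM of width 4: 4 PFM states + begin/end + 1 self-gap = 7
  h1 <- build_gap_hmm(hmm_motifs(4))
  expect_identical(nrow(h1$states), 7L)
  # 2 PFMs of widths 4 and 5: 9 + 4 gaps + begin + end = 15
  h2 <- build_gap_hmm(hmm_motifs(c(4, 5)))
  expect_identical(nrow(h2$states), 15L)
  expect_true(all(abs(rowSums(h2$transition) - 1) < 1e-9))
  expect_error(build_gap_hmm(hmm_motifs(rep(4, 11))),
               class = "ssmotif_config_error")
  mixed <- dplyr::bind_rows(hmm_motifs(4), hmm_motifs(4, "structure2"))
  expect_error(build_gap_hmm(mixed), class = "ssmotif_config_error")
})

test_that("PFM states emit exactly the PFM columns; others are uniform", {
  motifs <- hmm_motifs(c(4, 5))
  hmm <- build_gap_hmm(motifs)
  st <- hmm$states
  for (i in 1:2) {
    rows <- st$state[st$type == "pfm" & st$motif == motifs$motif[i]]
    expect_equal(unname(t(hmm$emission[rows, ])),
                 unname(motifs$pfm[[i]]$matrix), tolerance = 1e-12)
  }
  other <- st$state[st$type != "pfm"]
  expect_true(all(hmm$emission[other, ] == 0.25))
  expect_identical(hmm$start, c(1, rep(0, nrow(st) - 1)))
})

test_that("forward log-probabilities match exhaustive path enumeration", {
  # 1-PFM model over structure2: 5 states, strings up to length 4
  small <- build_gap_hmm(hmm_motifs(2, kind = "structure2"))
  expect_identical(nrow(small$states), 5L)
  withr::with_seed(71, {
    for (L in 1:4) {
      for (rep in 1:5) {
        s <- paste(sample(c("U", "P"), L, replace = TRUE), collapse = "")
        expect_equal(log_probability(small, s),
                     log(oracle_hmm_prob(small, s)), tolerance = 1e-10)
      }
    }
  })
  # 7-state model over sequence, length 3
  bigger <- build_gap_hmm(hmm_motifs(4))
  expect_identical(nrow(bigger$states), 7L)
  withr::with_seed(72, {
    for (rep in 1:5) {
      s <- random_rna_string(3)
      expect_equal(log_probability(bigger, s),
                   log(oracle_hmm_prob(bigger, s)), tolerance = 1e-10)
    }
  })
})

test_that("total probability mass over fixed-length strings is bounded by one", {
  small <- build_gap_hmm(hmm_motifs(2, kind = "structure2"))
  strings <- do.call(paste0, expand.grid(rep(list(c("U", "P")), 3)))
  total <- sum(exp(vapply(strings, function(s) log_probability(small, s),
                          numeric(1))))
  expect_lte(total, 1 + 1e-12)
  expect_error(log_probability(small, ""), class = "ssmotif_format_error")
  expect_error(log_probability(small, "UPX"), class = "ssmotif_format_error")
})

test_that("Baum-Welch training freezes emissions and keeps structural zeros", {
  motifs <- hmm_motifs(c(4, 4))
  hmm <- build_gap_hmm(motifs)
  withr::with_seed(73, {
    train <- vapply(1:30, function(i) random_rna_string(15), character(1))
  })
  trained <- train_transitions(hmm, train, max_iter = 25)
  # log-likelihood is non-decreasing across EM iterations
  expect_true(all(diff(trained$log_likelihood) >= -1e-8))
  # emissions untouched
  expect_identical(trained$emission, hmm$emission)
  # forbidden transitions stay exactly zero
  expect_true(all(trained$transition[hmm$transition == 0] == 0))
  expect_true(all(abs(rowSums(trained$transition) - 1) < 1e-9))
  expect_error(train_transitions(hmm, character(0)),
               class = "ssmotif_config_error")
})

test_that("training on model-generated data does not hurt held-out likelihood", {
  motifs <- hmm_motifs(3, kind = "structure2")
  deltas <- vapply(1:10, function(rep) {
    # generating model: random (seeded) transition probabilities on the
    # allowed topology, away from the uniform initialization
    generator <- build_gap_hmm(motifs)
    withr::with_seed(300 + rep, {
      mask <- generator$transition > 0
      rnd <- matrix(stats::rgamma(length(mask), 1), nrow(mask)) * mask
      generator$transition <- rnd / rowSums(rnd)
      train <- vapply(1:60, function(i) sample_hmm(generator, 12), character(1))
      heldout <- vapply(1:60, function(i) sample_hmm(generator, 12),
                        character(1))
    })
    fresh <- build_gap_hmm(motifs)
    trained <- train_transitions(fresh, train, max_iter = 15)
    before <- sum(vapply(heldout, function(s) log_probability(fresh, s),
                         numeric(1)))
    after <- sum(vapply(heldout, function(s) log_probability(trained, s),
                        numeric(1)))
    after - before
  }, numeric(1))
  expect_gte(stats::median(deltas), 0)
})

test_that("the random-forest combiner behaves at the contract level", {
  withr::with_seed(81, {
    # identically distributed features for both classes: no signal
    same <- tibble::tibble(
      label = rep(c("positive", "negative"), each = 60),
      f1 = stats::rnorm(120), f2 = stats::rnorm(120)
    )
  })
  res <- combine_hmm_scores(same, nfolds = 2, ntree_grid = 100L, seed = 4)
  expect_gt(res$auroc, 0.35)
  expect_lt(res$auroc, 0.65)

  withr::with_seed(82, {
    sep <- tibble::tibble(
      label = rep(c("positive", "negative"), each = 60),
      f1 = c(stats::rnorm(60, 5), stats::rnorm(60, -5)),
      f2 = stats::rnorm(120)
    )
  })
  res2 <- combine_hmm_scores(sep, nfolds = 2, ntree_grid = 100L, seed = 4)
  # training-resubstitution on a perfectly separating feature
  p <- predict(res2$forest, as.matrix(sep[, c("f1", "f2")]),
               type = "prob")[, "1"]
  y <- sep$label == "positive"
  expect_equal(compute_auroc(p[y], p[!y]), 1.0)
  one_class <- same
  one_class$label <- "positive"
  expect_error(combine_hmm_scores(one_class), class = "ssmotif_config_error")
})

test_that("the HMM training-size rule follows the stated subsampling", {
  expect_identical(hmm_training_size(30000), 10000L)
  expect_identical(hmm_training_size(20000), 10000L)
  expect_identical(hmm_training_size(19999), 9999)
  expect_identical(hmm_training_size(5000), 2500)
})

test_that("gap-HMM features separate bipartite planted data", {
  cfg <- generator_config(n_probes = 500, probe_length = 40,
                          structure_mode = "bipartite", motif = "UACUAAC",
                          motif2 = "UAAC", gap_range = c(1, 20),
                          plant_rate = 0.8, seed = 91)
  ds <- generate_dataset(cfg)
  probes <- preprocess_probes(ds$positive, ds$negative, seed = 91)
  probes <- split_probes(probes, seed = 91)
  probes <- annotate_probes(probes)
  disc <- probes[probes$split == "discovery", ]
  motifs <- discover_motifs(disc$ann_sequence[disc$label == "positive"],
                            disc$ann_sequence[disc$label == "negative"],
                            "sequence")
  expect_gt(nrow(motifs), 0)
  hf <- hmm_features(probes, head(motifs, 4), seed = 91, max_iter = 10)
  feats <- hf$features
  lp <- feats$lp_sequence
  expect_true(all(is.finite(lp)))
  tr <- feats[probes$split %in% c("train", "validation"), ]
  te <- feats[probes$split == "test", ]
  res <- combine_hmm_scores(tr, te, nfolds = 2, ntree_grid = 200L, seed = 91)
  expect_gt(res$auroc, 0.7)
})
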