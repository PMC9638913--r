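test_that("AUROC handles separation, ties and partial concordance", {
  expect_equal(compute_auroc(c(3, 4), c(1, 2)), 1.0)
  expect_equal(compute_auroc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(compute_auroc(c(3, 1), c(2, 0)), 0.75)
  expect_error(compute_auroc(numeric(0), 1), class = "ssmotif_config_error")
})

test_that("AUROC equals exhaustive pairwise concordance counting", {
  withr::with_seed(3, {
    for (rep in 1:25) {
      np <- sample(1:50, 1)
      nn <- sample(1:50, 1)
      # discrete scores force plenty of ties
      pos <- sample(0:5, np, replace = TRUE) + stats::rnorm(np, sd = 0.01) *
        rbinom(np, 1, 0.5)
      neg <- sample(0:5, nn, replace = TRUE)
      expect_equal(compute_auroc(pos, neg), oracle_auroc(pos, neg),
                   tolerance = 1e-12)
    }
  })
})

test_that("L1 fits select the separating feature and shrink fully at high strength", {
  feats <- simulated_features(n = 100, seed = 5, strength = 4)
  fit <- fit_l1_logreg(feats, l1_strength = 0.01)
  expect_gt(fit$coefficients["signal"], 0)
  expect_true(all(abs(fit$coefficients[paste0("noise", 1:4)]) <=
                    abs(fit$coefficients["signal"])))

  full <- fit_l1_logreg(feats, l1_strength = 1e6)
  expect_true(all(full$coefficients == 0))
  expect_equal(full$intercept, stats::qlogis(mean(feats$label == "positive")),
               tolerance = 1e-6)

  one_class <- feats
  one_class$label <- "positive"
  expect_error(fit_l1_logreg(one_class, 0.1), class = "ssmotif_config_error")
})

test_that("fits match an independent proximal-gradient optimizer", {
  withr::with_seed(7, {
    X <- matrix(stats::rnorm(6 * 2), nrow = 6)
    y <- c(1, 0, 1, 1, 0, 0)
  })
  Xs <- scale(X)
  feats <- tibble::tibble(label = ifelse(y == 1, "positive", "negative"),
                          f1 = Xs[, 1], f2 = Xs[, 2])
  for (lambda in c(0.01, 0.05, 0.2)) {
    # glmnet warns about the deliberately tiny class sizes
    fit <- suppressWarnings(fit_l1_logreg(feats, lambda))
    # oracle works on the already-standardized design the fit sees
    Zs <- scale(as.matrix(feats[, c("f1", "f2")]))
    oracle <- oracle_l1_logreg(Zs, y, lambda)
    expect_equal(unname(fit$coefficients), oracle$beta, tolerance = 1e-4)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-4)
  }
})

test_that("duplicate feature columns collapse onto the first occurrence", {
  feats <- simulated_features(n = 80, seed = 9, strength = 3)
  feats$copy_of_signal <- feats$signal * 2 + 5  # identical after z-scoring
  fit <- fit_l1_logreg(feats, 0.02)
  expect_gt(abs(fit$coefficients["signal"]), 0)
  expect_identical(unname(fit$coefficients["copy_of_signal"]), 0)
  expect_identical(unname(fit$dup_of["copy_of_signal"]), "signal")
})

test_that("the strength search maximizes cross-validated AUROC", {
  train <- simulated_features(n = 200, seed = 11, strength = 3)
  val <- simulated_features(n = 100, seed = 12, strength = 3)
  # singleton grid: returns that value
  single <- optimize_l1(train, val, grid = 0.05, nfolds = 3)
  expect_identical(single$l1_strength, 0.05)
  opt <- optimize_l1(train, val, nfolds = 3, seed = 2)
  expect_gt(opt$initial_auroc, 0.9)
  expect_gt(abs(opt$fit$coefficients["signal"]), 0)

  # pure noise: validation AUROC near chance
  noise_tr <- simulated_features(n = 200, seed = 13, strength = 0)
  noise_val <- simulated_features(n = 100, seed = 14, strength = 0)
  noise <- optimize_l1(noise_tr, noise_val, nfolds = 3, seed = 2)
  expect_gt(noise$initial_auroc, 0.4)
  expect_lt(noise$initial_auroc, 0.6)
})

test_that("simplification scales the penalty by 1.25 and keeps 90% of power", {
  train <- simulated_features(n = 300, seed = 15, strength = 2)
  val <- simulated_features(n = 200, seed = 16, strength = 2)
  opt <- optimize_l1(train, val, nfolds = 3, seed = 3)
  model <- simplify_model(train, val, opt$l1_strength)
  # consecutive strengths in the trace have ratio exactly 1.25
  ratios <- model$trace$l1_strength[-1] / head(model$trace$l1_strength, -1)
  expect_equal(ratios, rep(1.25, length(ratios)), tolerance = 1e-12)
  # the returned model satisfies the retention bound on the validation set
  bound <- 0.5 + 0.9 * (model$initial_auroc - 0.5)
  expect_gte(model$final_auroc, bound)
  # retained motifs are exactly the nonzero coefficients
  expect_true(all(model$coefficients != 0))
  # simplification never keeps more features than the initial fit
  expect_lte(length(model$coefficients), model$trace$n_nonzero[1])
})

test_that("a first failing refit returns the initial optimized model", {
  train <- simulated_features(n = 100, seed = 17, strength = 2)
  val <- simulated_features(n = 80, seed = 18, strength = 2)
  # enormous scale factor: the very first scaled refit empties the model
  model <- simplify_model(train, val, 0.01, scale_factor = 1e6)
  expect_identical(model$l1_strength, 0.01)
  expect_identical(model$final_auroc, model$initial_auroc)
  expect_identical(nrow(model$trace), 2L)
  expect_false(model$trace$accepted[2])
})

test_that("chance-level initial models are returned unchanged with a warning", {
  train <- simulated_features(n = 100, seed = 19, strength = 0)
  val <- simulated_features(n = 500, seed = 20, strength = 0)
  expect_warning(
    model <- simplify_model(train, val, 1e5),
    "AUROC"
  )
  expect_identical(model$l1_strength, 1e5)
  expect_identical(model$final_auroc, model$initial_auroc)
})

test_that("apply_model runs the full pipeline and tolerates bad probes", {
  cfg <- generator_config(n_probes = 500, probe_length = 30, plant_rate = 0.6,
                          motif = "UGCAUG", seed = 27)
  ds <- generate_dataset(cfg)
  model <- ss_train(ds$positive, ds$negative,
                    ss_config(seed = 27, nfolds = 3), quiet = TRUE)
  probes <- dplyr::bind_rows(ds$positive[1:40, ], ds$negative[1:40, ])
  scored <- apply_model(model, probes)
  expect_identical(nrow(scored), 80L)
  expect_true(all(is.na(scored$error)))
  expect_true(all(scored$score >= 0 & scored$score <= 1))
  # order invariance
  perm <- sample(nrow(probes))
  scored2 <- apply_model(model, probes[perm, ])
  expect_equal(scored2$score[order(perm)], scored$score)
  # planted probes score above background (generator truth as oracle)
  planted_ids <- ds$truth$probe_id[ds$truth$planted]
  all_scores <- apply_model(model, dplyr::bind_rows(ds$positive, ds$negative))
  sp <- all_scores$score[all_scores$probe_id %in% planted_ids]
  sn <- all_scores$score[grepl("^neg", all_scores$probe_id)]
  expect_gt(compute_auroc(sp, sn), 0.9)
  # a malformed probe yields an error record, not an abort
  bad <- tibble::tibble(probe_id = "bad", sequence = "ACGUACGU",
                        dotbracket = "((((((((")
  mixed <- apply_model(model, dplyr::bind_rows(probes[1:3, ], bad))
  expect_identical(sum(!is.na(mixed$error)), 1L)
  expect_identical(sum(is.na(mixed$score)), 1L)
})

test_that("an empty model scores every probe at the intercept", {
  train <- simulated_features(n = 100, seed = 21, strength = 0)
  val <- simulated_features(n = 80, seed = 22, strength = 0)
  suppressWarnings(model <- simplify_model(train, val, 1e6))
  probes <- generate_dataset(generator_config(n_probes = 5, seed = 1))$positive
  scored <- apply_model(model, probes)
  expect_equal(scored$score, rep(plogis(model$intercept), 5))
})
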