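# L1-regularized logistic regression on motif features: strength search,
# iterative model simplification, and the fitted-model class.

#' Rank-based AUROC
#'
#' Area under the receiver operating characteristic computed from the
#' Mann-Whitney statistic; tied scores count one half.
#'
#' @param scores_pos,scores_neg Numeric score vectors for the positive and
#'   negative class (both non-empty).
#' @return AUROC in `[0, 1]`.
#' @examples
#' compute_auroc(c(3, 1), c(2, 0))
#' @export
compute_auroc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    abort("both score sets must be non-empty", class = "ssmotif_config_error")
  }
  r <- rank(c(scores_pos, scores_neg))
  np <- length(scores_pos)
  nn <- length(scores_neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

label_to_binary <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.numeric(label)) return(as.integer(label != 0))
  as.integer(label == "positive")
}

# standardization + exact-duplicate collapse shared by all fits
prepare_design <- function(features) {
  cols <- feature_columns(features)
  X <- as.matrix(features[, cols, drop = FALSE])
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  # columns identical after z-scoring carry the same information (the same
  # motif rediscovered in an isomorphic alphabet); the L1 solution is not
  # unique under exact duplication, so duplicates collapse onto their first
  # occurrence in canonical column order
  keys <- apply(signif(Xs, 10), 2, paste, collapse = ",")
  first <- match(keys, keys)
  dup_of <- setNames(cols[first], cols)
  keep <- which(first == seq_along(cols))
  list(X = Xs[, keep, drop = FALSE], cols = cols, keep = cols[keep],
       dup_of = dup_of, center = center, scale = scale)
}

glmnet_at <- function(X, y, lambda, thresh = 1e-12) {
  # glmnet needs >= 2 columns; pad with an inert zero column when necessary
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, `.pad` = 0)
  path <- sort(unique(lambda * c(16, 8, 4, 2, 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1, lambda = path,
                        standardize = FALSE, thresh = thresh, maxit = 1e6)
  beta <- as.numeric(coef(fit, s = lambda))
  names(beta) <- c("(Intercept)", colnames(X))
  if (padded) beta <- beta[names(beta) != ".pad"]
  beta
}

#' Fit an L1-penalized logistic regression at a fixed strength
#'
#' Features are z-scored from the supplied data before fitting and
#' coefficients are reported on the standardized scale. The penalty
#' `l1_strength` multiplies the L1 norm of the coefficients in the
#' per-observation-scaled binomial deviance objective.
#'
#' @param features Tibble with a `label` column (`"positive"`/`"negative"`,
#'   logical, or 0/1) and numeric feature columns; `probe_id`/`split`
#'   columns are ignored.
#' @param l1_strength Positive penalty multiplier.
#' @return An `ss_fit` list: standardized-scale `coefficients` (named, one
#'   per feature column), `intercept`, `l1_strength`, standardization
#'   `center`/`scale`, and the duplicate-column map `dup_of`.
#' @export
fit_l1_logreg <- function(features, l1_strength) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  y <- label_to_binary(features$label)
  if (length(unique(y)) < 2) {
    abort("labels contain a single class", class = "ssmotif_config_error")
  }
  design <- prepare_design(features)
  if (ncol(design$X) == 0) {
    beta <- setNames(numeric(0), character(0))
    intercept <- stats::qlogis(mean(y))
  } else {
    b <- glmnet_at(design$X, y, l1_strength)
    intercept <- b[["(Intercept)"]]
    beta <- setNames(rep(0, length(design$cols)), design$cols)
    beta[design$keep] <- b[design$keep]
  }
  structure(
    list(coefficients = beta, intercept = intercept, l1_strength = l1_strength,
         center = design$center, scale = design$scale, dup_of = design$dup_of),
    class = "ss_fit"
  )
}

fit_linear_predictor <- function(fit, features) {
  cols <- names(fit$coefficients)
  if (length(cols) == 0) {
    return(rep(fit$intercept, nrow(features)))
  }
  X <- as.matrix(features[, cols, drop = FALSE])
  Xs <- sweep(sweep(X, 2, fit$center[cols], "-"), 2, fit$scale[cols], "/")
  drop(fit$intercept + Xs %*% fit$coefficients)
}

fit_auroc <- function(fit, features) {
  eta <- fit_linear_predictor(fit, features)
  y <- label_to_binary(features$label)
  compute_auroc(eta[y == 1], eta[y == 0])
}

#' Select the L1 strength by cross-validated AUROC
#'
#' Evaluates a log-spaced grid of penalty strengths by stratified k-fold
#' cross-validation on the training features, picks the strength maximizing
#' mean AUROC (ties break toward the stronger penalty, i.e. the sparser
#' model), refits on the full training set, and reports the initial AUROC on
#' the validation set.
#'
#' @param train,validation Feature tibbles (disjoint probes) with `label`
#'   columns.
#' @param grid Penalty grid; default 33 log-spaced points on `[1e-4, 1e4]`.
#' @param nfolds Cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @return List with `l1_strength`, the refitted `fit` (`ss_fit`),
#'   `initial_auroc` on the validation set, and the `cv` tibble of mean AUROC
#'   per grid point.
#' @export
optimize_l1 <- function(train, validation,
                        grid = 10^seq(-4, 4, length.out = 33),
                        nfolds = 5L, seed = 1L) {
  stopifnot(is.data.frame(train), is.data.frame(validation))
  y <- label_to_binary(train$label)
  design <- prepare_design(train)
  grid <- sort(grid, decreasing = TRUE)
  if (ncol(design$X) == 0) {
    best <- grid[1]
    fit <- fit_l1_logreg(train, best)
    return(list(l1_strength = best, fit = fit,
                initial_auroc = fit_auroc(fit, validation),
                cv = tibble(l1_strength = grid, mean_auroc = 0.5)))
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      rows <- which(y == cls)
      folds[rows] <- sample(rep_len(seq_len(nfolds), length(rows)))
    }
  })
  padded <- ncol(design$X) == 1
  Xcv <- if (padded) cbind(design$X, `.pad` = 0) else design$X
  auc <- matrix(NA_real_, nrow = nfolds, ncol = length(grid))
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    fit <- glmnet::glmnet(Xcv[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 1, lambda = grid, standardize = FALSE,
                          maxit = 1e6)
    eta <- predict(fit, Xcv[!tr, , drop = FALSE], s = grid)
    yf <- y[!tr]
    auc[f, ] <- apply(eta, 2, function(e) {
      compute_auroc(e[yf == 1], e[yf == 0])
    })
  }
  mean_auc <- colMeans(auc)
  best <- grid[which.max(mean_auc)]  # grid descends: first max is sparsest
  fit <- fit_l1_logreg(train, best)
  list(l1_strength = best, fit = fit,
       initial_auroc = fit_auroc(fit, validation),
       cv = tibble(l1_strength = grid, mean_auroc = mean_auc))
}

#' Iteratively simplify a fitted model by scaling up the L1 penalty
#'
#' Starting from the optimized strength, the penalty is multiplied by
#' `scale_factor` (default 1.25) at each iteration, the model refitted on the
#' training features and re-evaluated on the validation set, until the
#' validation AUROC drops below `0.5 + retention * (initial_auroc - 0.5)`,
#' i.e. until less than `retention` (default 90%) of the initial predictive
#' power (AUROC minus 0.5) remains. The last model still satisfying the
#' retention bound is returned.
#'
#' @param train,validation Feature tibbles with `label` columns.
#' @param l1_strength Optimized starting strength (from [optimize_l1()]).
#' @param motifs Optional motif tibble ([discover_motifs()] rows for all
#'   feature columns); retained PFMs are attached to the returned model.
#' @param scale_factor Per-iteration multiplier on the penalty.
#' @param retention Fraction of initial predictive power that must be kept.
#' @param max_iter Iteration safety cap.
#' @param config,seed Run metadata stored on the model.
#' @return An `ss_model`: retained PFMs (nonzero coefficients only),
#'   coefficients and intercept, initial/final L1 strengths and validation
#'   AUROCs, and the full iteration `trace` (`iteration`, `l1_strength`,
#'   `auroc`, `n_nonzero`, `accepted`).
#' @export
simplify_model <- function(train, validation, l1_strength, motifs = NULL,
                           scale_factor = 1.25, retention = 0.9,
                           max_iter = 200L, config = list(), seed = NA_integer_) {
  fit <- fit_l1_logreg(train, l1_strength)
  initial_auroc <- fit_auroc(fit, validation)
  trace <- tibble(iteration = 0L, l1_strength = l1_strength,
                  auroc = initial_auroc,
                  n_nonzero = sum(fit$coefficients != 0), accepted = TRUE)
  if (initial_auroc <= 0.5) {
    warn("initial validation AUROC <= 0.5; returning the initial model unchanged")
    return(new_ss_model_from_fit(fit, motifs, l1_strength, initial_auroc,
                                 initial_auroc, trace, config, seed))
  }
  threshold <- 0.5 + retention * (initial_auroc - 0.5)
  best_fit <- fit
  best_auroc <- initial_auroc
  s <- l1_strength
  for (it in seq_len(max_iter)) {
    s <- s * scale_factor
    cand <- fit_l1_logreg(train, s)
    auroc <- fit_auroc(cand, validation)
    ok <- auroc >= threshold
    trace <- dplyr::bind_rows(trace, tibble(
      iteration = it, l1_strength = s, auroc = auroc,
      n_nonzero = sum(cand$coefficients != 0), accepted = ok))
    if (!ok) break
    best_fit <- cand
    best_auroc <- auroc
    if (all(cand$coefficients == 0)) break  # cannot simplify further
  }
  new_ss_model_from_fit(best_fit, motifs, l1_strength, initial_auroc,
                        best_auroc, trace, config, seed)
}

new_ss_model_from_fit <- function(fit, motifs, initial_l1, initial_auroc,
                                  final_auroc, trace, config, seed) {
  nz <- names(fit$coefficients)[fit$coefficients != 0]
  pfms <- if (is.null(motifs)) {
    empty_motif_tibble()[, c("motif", "alphabet", "width", "consensus",
                             "p_value", "p_adjusted", "pfm")]
  } else {
    motifs[match(nz, motifs$motif), , drop = FALSE]
  }
  new_ss_model(
    pfms = pfms,
    coefficients = fit$coefficients[nz],
    intercept = fit$intercept,
    l1_strength = fit$l1_strength,
    initial_l1_strength = initial_l1,
    initial_auroc = initial_auroc,
    final_auroc = final_auroc,
    center = fit$center[nz],
    scale = fit$scale[nz],
    trace = trace,
    config = config,
    seed = seed
  )
}

new_ss_model <- function(pfms, coefficients, intercept, l1_strength,
                         initial_l1_strength, initial_auroc, final_auroc,
                         center, scale, trace, config, seed) {
  structure(
    list(pfms = pfms, coefficients = coefficients, intercept = intercept,
         l1_strength = l1_strength, initial_l1_strength = initial_l1_strength,
         initial_auroc = initial_auroc, final_auroc = final_auroc,
         center = center, scale = scale, trace = trace, config = config,
         seed = seed),
    class = "ss_model"
  )
}

#' @export
print.ss_model <- function(x, ...) {
  cat(sprintf(
    "<ss_model> %d retained motif(s); validation AUROC %.3f -> %.3f; L1 %.4g -> %.4g\n",
    length(x$coefficients), x$initial_auroc, x$final_auroc,
    x$initial_l1_strength, x$l1_strength))
  if (length(x$coefficients) > 0) {
    print(tidy(x), n = 10)
  }
  invisible(x)
}

#' Score probes with a fitted model
#'
#' Runs the full application pipeline: annotate each probe under the seven
#' alphabets, scan the retained PFMs, standardize features with the stored
#' training statistics, and map the linear predictor through the logistic
#' function. Probes that fail annotation are recorded and skipped rather than
#' aborting the run.
#'
#' @param model An `ss_model`.
#' @param probes Tibble with `sequence` and `dotbracket` columns (flanks per
#'   the model's config).
#' @return Tibble with `probe_id`, `score` (binding probability; `NA` on
#'   failure) and `error` (message or `NA`).
#' @export
apply_model <- function(model, probes) {
  stopifnot(inherits(model, "ss_model"), is.data.frame(probes))
  probes <- as_tibble(probes)
  if (is.null(probes$probe_id)) {
    probes$probe_id <- sprintf("probe_%05d", seq_len(nrow(probes)))
  }
  cfg <- model$config
  errors <- rep(NA_character_, nrow(probes))
  anns <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    anns[[i]] <- tryCatch(
      annotate_probe(probes$sequence[i], probes$dotbracket[i],
                     variable_region_of(probes$sequence[i], cfg)),
      error = function(e) {
        errors[i] <<- conditionMessage(e)
        NULL
      }
    )
  }
  ok <- is.na(errors)
  scores <- rep(NA_real_, nrow(probes))
  if (any(ok)) {
    ann_tbl <- tibble(probe_id = probes$probe_id[ok])
    for (kind in alphabet_kinds()) {
      ann_tbl[[ANNOTATION_COLS[[kind]]]] <-
        vapply(anns[ok], function(a) a[[kind]], character(1))
    }
    feats <- build_feature_matrix(model$pfms, ann_tbl)
    eta <- rep(model$intercept, sum(ok))
    if (length(model$coefficients) > 0) {
      X <- as.matrix(feats[, names(model$coefficients), drop = FALSE])
      Xs <- sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
      eta <- drop(model$intercept + Xs %*% model$coefficients)
    }
    scores[ok] <- plogis(eta)
  }
  tibble(probe_id = probes$probe_id, score = scores, error = errors)
}

variable_region_of <- function(sequence, config) {
  n5 <- nchar(config$flank5 %||% "")
  n3 <- nchar(config$flank3 %||% "")
  c(n5 + 1L, nchar(sequence) - n3)
}

#' @export
predict.ss_model <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  scores <- apply_model(object, newdata)$score
  if (type == "link") stats::qlogis(scores) else scores
}

#' Tidy a fitted sequence-structure motif model
#'
#' @param x An `ss_model`.
#' @param ... Unused.
#' @return Tibble with one row per retained motif: `motif`, `alphabet`,
#'   `consensus`, `width`, `coefficient` (standardized scale) and
#'   `weight_proportion` (share of the total absolute coefficient mass),
#'   sorted by descending weight proportion.
#' @export
tidy.ss_model <- function(x, ...) {
  if (length(x$coefficients) == 0) {
    return(tibble(motif = character(0), alphabet = character(0),
                  consensus = character(0), width = integer(0),
                  coefficient = numeric(0), weight_proportion = numeric(0)))
  }
  total <- sum(abs(x$coefficients))
  has_pfms <- nrow(x$pfms) == length(x$coefficients)
  tibble(
    motif = names(x$coefficients),
    alphabet = if (has_pfms) x$pfms$alphabet else NA_character_,
    consensus = if (has_pfms) x$pfms$consensus else NA_character_,
    width = if (has_pfms) x$pfms$width else NA_integer_,
    coefficient = unname(x$coefficients),
    weight_proportion = abs(unname(x$coefficients)) / total
  ) |>
    dplyr::arrange(dplyr::desc(.data$weight_proportion))
}

#' One-row summary of a fitted model
#'
#' @param x An `ss_model`.
#' @param ... Unused.
#' @return Tibble with motif count, initial/final L1 strength, initial/final
#'   validation AUROC and the retained fraction of predictive power.
#' @export
glance.ss_model <- function(x, ...) {
  power0 <- x$initial_auroc - 0.5
  tibble(
    n_motifs = length(x$coefficients),
    initial_l1_strength = x$initial_l1_strength,
    final_l1_strength = x$l1_strength,
    initial_auroc = x$initial_auroc,
    final_auroc = x$final_auroc,
    power_retained = ifelse(power0 > 0, (x$final_auroc - 0.5) / power0, NA_real_)
  )
}

#' Plot retained motif weights
#'
#' Bar chart of each retained motif's share of the total model weight,
#' coloured by source alphabet.
#'
#' @param object An `ss_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ss_model <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(
    x = stats::reorder(.data$motif, .data$weight_proportion),
    y = .data$weight_proportion, fill = .data$alphabet)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion of model weight",
                  fill = "alphabet") +
    ggplot2::theme_minimal()
}

#' Plot the simplification trace
#'
#' Validation AUROC and retained-motif count against the L1 strength over the
#' simplification iterations, with the retention bound marked.
#'
#' @param model An `ss_model`.
#' @param retention Retention fraction used during fitting (for the bound).
#' @return A ggplot object.
#' @export
plot_simplification_trace <- function(model, retention = 0.9) {
  stopifnot(inherits(model, "ss_model"))
  bound <- 0.5 + retention * (model$initial_auroc - 0.5)
  ggplot2::ggplot(model$trace,
                  ggplot2::aes(x = .data$l1_strength, y = .data$auroc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accepted)) +
    ggplot2::geom_hline(yintercept = bound, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "L1 strength", y = "validation AUROC") +
    ggplot2::theme_minimal()
}
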