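# Gap-aware hidden Markov model over discovered PFMs: recursive begin/end
# states, one state per PFM position with frozen PFM emissions, and one
# recursive gap state per ordered PFM pair (self-pairs included) so repeated
# and bidirectional spacings are representable.

#' Build a gap-HMM from a set of PFMs over one alphabet
#'
#' State topology: the recursive `begin` state may self-loop or enter the
#' first position of any PFM; PFM-internal states chain to the next position
#' only (a PFM always occurs in its entirety); each PFM-final state may enter
#' any PFM's first position (back-to-back motifs), any gap state whose source
#' is that PFM, or `end`; gap state `(i -> j)` self-loops or enters PFM `j`'s
#' first position; `end` is recursive/absorbing. All mass starts in `begin`.
#' Transition probabilities are initialized uniformly over each state's
#' allowed moves. Emissions are the PFM columns for PFM-position states and
#' uniform `1/|alphabet|` elsewhere, and are never updated.
#'
#' @param motifs Motif tibble ([discover_motifs()] rows), 1 to 10 PFMs, all
#'   over the same alphabet.
#' @return A `gap_hmm`: `states` tibble (`state`, `type`, `motif`,
#'   `position`, `gap_from`, `gap_to`), `transition` and `emission` matrices,
#'   `start` vector and the `alphabet` kind.
#' @export
build_gap_hmm <- function(motifs) {
  stopifnot(is.data.frame(motifs), nrow(motifs) >= 1)
  if (nrow(motifs) > 10) {
    abort("at most 10 PFMs per gap-HMM", class = "ssmotif_config_error")
  }
  kind <- unique(motifs$alphabet)
  if (length(kind) != 1) {
    abort("all PFMs in a gap-HMM must share one alphabet",
          class = "ssmotif_config_error")
  }
  alph <- ss_alphabet(kind)
  P <- nrow(motifs)
  widths <- motifs$width

  states <- tibble(type = "begin", motif = NA_character_,
                   position = NA_integer_, gap_from = NA_integer_,
                   gap_to = NA_integer_)
  for (i in seq_len(P)) {
    states <- dplyr::bind_rows(states, tibble(
      type = "pfm", motif = motifs$motif[i], position = seq_len(widths[i]),
      gap_from = NA_integer_, gap_to = NA_integer_))
  }
  pairs <- expand.grid(gap_to = seq_len(P), gap_from = seq_len(P))[, 2:1]
  states <- dplyr::bind_rows(states, tibble(
    type = "gap", motif = NA_character_, position = NA_integer_,
    gap_from = pairs$gap_from, gap_to = pairs$gap_to))
  states <- dplyr::bind_rows(states, tibble(
    type = "end", motif = NA_character_, position = NA_integer_,
    gap_from = NA_integer_, gap_to = NA_integer_))
  states <- dplyr::mutate(states, state = dplyr::row_number(),
                          .before = 1)
  S <- nrow(states)

  first_of <- vapply(seq_len(P), function(i) {
    min(states$state[states$type == "pfm" & states$motif == motifs$motif[i]])
  }, integer(1))
  last_of <- first_of + widths - 1L
  begin <- 1L
  end <- S
  gap_state <- function(i, j) {
    states$state[states$type == "gap" & states$gap_from == i &
                   states$gap_to == j]
  }

  mask <- matrix(FALSE, S, S)
  mask[begin, c(begin, first_of)] <- TRUE
  for (i in seq_len(P)) {
    if (widths[i] > 1) {
      for (p in seq_len(widths[i] - 1L)) {
        mask[first_of[i] + p - 1L, first_of[i] + p] <- TRUE
      }
    }
    gaps_i <- vapply(seq_len(P), function(j) gap_state(i, j), integer(1))
    mask[last_of[i], c(first_of, gaps_i, end)] <- TRUE
    for (j in seq_len(P)) {
      g <- gap_state(i, j)
      mask[g, c(g, first_of[j])] <- TRUE
    }
  }
  mask[end, end] <- TRUE

  transition <- mask / rowSums(mask)
  emission <- matrix(1 / alph$size, S, alph$size,
                     dimnames = list(NULL, alph$symbols))
  for (i in seq_len(P)) {
    pfm <- motifs$pfm[[i]]
    emission[first_of[i]:last_of[i], ] <- t(pfm$matrix)
  }
  start <- c(1, rep(0, S - 1L))

  structure(
    list(alphabet = kind, states = states, transition = transition,
         emission = emission, start = start, motifs = motifs$motif,
         widths = widths),
    class = "gap_hmm"
  )
}

#' @export
print.gap_hmm <- function(x, ...) {
  cat(sprintf("<gap_hmm> %d PFM(s) over %s; %d states\n",
              length(x$motifs), x$alphabet, nrow(x$states)))
  invisible(x)
}

encode_symbols <- function(annotation, alphabet) {
  if (!nzchar(annotation)) {
    abort("empty annotation string", class = "ssmotif_format_error")
  }
  idx <- match(strsplit(annotation, "", fixed = TRUE)[[1]],
               ss_alphabet(alphabet)$symbols)
  if (anyNA(idx)) {
    abort("annotation symbol outside the HMM's alphabet",
          class = "ssmotif_format_error")
  }
  idx
}

# scaled forward pass; returns list(alpha = S x L scaled matrix, logc)
forward_pass <- function(hmm, idx) {
  S <- nrow(hmm$transition)
  L <- length(idx)
  alpha <- matrix(0, S, L)
  logc <- numeric(L)
  f <- hmm$start * hmm$emission[, idx[1]]
  c1 <- sum(f)
  alpha[, 1] <- f / c1
  logc[1] <- log(c1)
  if (L > 1) {
    tT <- t(hmm$transition)
    for (t in 2:L) {
      f <- (tT %*% alpha[, t - 1L]) * hmm$emission[, idx[t]]
      ct <- sum(f)
      alpha[, t] <- f / ct
      logc[t] <- log(ct)
    }
  }
  list(alpha = alpha, logc = logc)
}

#' Log-probability of an annotation under a gap-HMM
#'
#' Forward-algorithm `log P(annotation | model)`, computed with per-step
#' scaling so long probes stay numerically stable.
#'
#' @param hmm A `gap_hmm`.
#' @param annotation Non-empty annotation string over the HMM's alphabet.
#' @return Log probability (natural log).
#' @export
log_probability <- function(hmm, annotation) {
  stopifnot(inherits(hmm, "gap_hmm"))
  idx <- encode_symbols(annotation, hmm$alphabet)
  sum(forward_pass(hmm, idx)$logc)
}

# batched forward over many equal-length annotations: probes x states matrix
log_probability_batch <- function(hmm, annotations) {
  vapply(annotations, function(a) log_probability(hmm, a), numeric(1),
         USE.NAMES = FALSE)
}

#' Train gap-HMM transitions by Baum-Welch with frozen emissions
#'
#' Expectation-maximization updates of the start and transition probabilities
#' only; emission rows are never touched, leaving the information in the PFMs
#' intact. Structural zeros in the transition matrix remain exactly zero.
#' Iteration stops when the relative improvement in total log-likelihood
#' falls below `tol` or after `max_iter` iterations.
#'
#' @param hmm A `gap_hmm`.
#' @param annotations Non-empty character vector of training annotations over
#'   the HMM's alphabet.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood improvement threshold.
#' @return The trained `gap_hmm`, with a `log_likelihood` vector (one value
#'   per iteration) attached.
#' @export
train_transitions <- function(hmm, annotations, max_iter = 100L, tol = 1e-4) {
  stopifnot(inherits(hmm, "gap_hmm"))
  if (length(annotations) == 0) {
    abort("empty training set", class = "ssmotif_config_error")
  }
  idx_list <- lapply(annotations, encode_symbols, alphabet = hmm$alphabet)
  S <- nrow(hmm$transition)
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    A_num <- matrix(0, S, S)
    pi_num <- numeric(S)
    ll <- 0
    for (idx in idx_list) {
      L <- length(idx)
      fw <- forward_pass(hmm, idx)
      ll <- ll + sum(fw$logc)
      beta <- matrix(0, S, L)
      beta[, L] <- 1
      if (L > 1) {
        for (t in (L - 1L):1L) {
          b <- hmm$transition %*% (hmm$emission[, idx[t + 1L]] * beta[, t + 1L])
          beta[, t] <- b / exp(fw$logc[t + 1L])
        }
        for (t in seq_len(L - 1L)) {
          xi <- hmm$transition *
            (fw$alpha[, t] %o% (hmm$emission[, idx[t + 1L]] * beta[, t + 1L]))
          A_num <- A_num + xi / sum(xi)
        }
      }
      gamma1 <- fw$alpha[, 1] * beta[, 1]
      pi_num <- pi_num + gamma1 / sum(gamma1)
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1) {
      rel <- (ll - ll_trace[iter - 1L]) / abs(ll_trace[iter - 1L])
      if (rel < tol) break
    }
    rs <- rowSums(A_num)
    newT <- hmm$transition
    upd <- rs > 0
    newT[upd, ] <- A_num[upd, , drop = FALSE] / rs[upd]
    hmm$transition <- newT
    hmm$start <- pi_num / sum(pi_num)
  }
  hmm$log_likelihood <- ll_trace
  hmm
}

#' Training-set size rule for the gap-HMM
#'
#' At most 10 000 probes are used; when fewer than 20 000 are available, half
#' of them are used.
#'
#' @param n_available Number of candidate training probes.
#' @return Number of probes to train on.
#' @export
hmm_training_size <- function(n_available) {
  if (n_available < 20000L) floor(n_available / 2) else 10000L
}

#' Per-alphabet gap-HMM log-probability features
#'
#' For each alphabet with discovered motifs, builds a gap-HMM from the top
#' `max_pfms` motifs, trains its transitions on positive-set annotations from
#' the training split (subsampled by [hmm_training_size()]), and computes the
#' log-probability of every probe under the trained model.
#'
#' @param probes Annotated probe tibble with `label` and `split` columns.
#' @param motifs Motif tibble spanning one or more alphabets.
#' @param max_pfms PFMs per HMM (<= 10).
#' @param seed Integer seed for the training subsample.
#' @param max_iter,tol Passed to [train_transitions()].
#' @return List with `features` (tibble: `probe_id`, `label`, one `lp_<kind>`
#'   column per alphabet) and `hmms` (named list of trained models).
#' @export
hmm_features <- function(probes, motifs, max_pfms = 10L, seed = 1L,
                         max_iter = 20L, tol = 1e-4) {
  stopifnot(is.data.frame(probes), all(c("label", "split") %in% names(probes)))
  kinds <- intersect(alphabet_kinds(), unique(motifs$alphabet))
  out <- tibble(probe_id = probes$probe_id, label = probes$label)
  hmms <- list()
  train_pool <- which(probes$label == "positive" & probes$split == "train")
  n_train <- hmm_training_size(length(train_pool))
  withr::with_seed(seed, {
    train_rows <- sample(train_pool, min(n_train, length(train_pool)))
  })
  for (kind in kinds) {
    sub <- head(motifs[motifs$alphabet == kind, ], max_pfms)
    hmm <- build_gap_hmm(sub)
    col <- ANNOTATION_COLS[[kind]]
    hmm <- train_transitions(hmm, probes[[col]][train_rows],
                             max_iter = max_iter, tol = tol)
    out[[paste0("lp_", kind)]] <- log_probability_batch(hmm, probes[[col]])
    hmms[[kind]] <- hmm
  }
  list(features = out, hmms = hmms)
}

#' Combine gap-HMM log-probability features with a random forest
#'
#' Tunes tree count and depth by stratified cross-validated AUROC on the
#' training features, refits the best configuration, and reports held-out
#' AUROC.
#'
#' @param train Feature tibble with `label` and numeric feature columns.
#' @param test Held-out feature tibble in the same layout; when `NULL`, a
#'   seeded 75/25 split of `train` is used.
#' @param ntree_grid,nodesize_grid Tuning grids.
#' @param nfolds Cross-validation folds.
#' @param seed Integer seed.
#' @return List with the fitted `forest`, chosen `params`, `cv` table and
#'   held-out `auroc`.
#' @export
combine_hmm_scores <- function(train, test = NULL,
                               ntree_grid = c(100L, 300L),
                               nodesize_grid = c(1L, 8L),
                               nfolds = 3L, seed = 1L) {
  stopifnot(is.data.frame(train), "label" %in% names(train))
  if (length(unique(train$label)) < 2) {
    abort("labels contain a single class", class = "ssmotif_config_error")
  }
  if (is.null(test)) {
    split <- split_probes(train, c(train = 0.75, test = 0.25), seed = seed)
    test <- split[split$split == "test", , drop = FALSE]
    train <- split[split$split == "train", , drop = FALSE]
  }
  cols <- setdiff(feature_columns(train), "label")
  Xtr <- as.matrix(train[, cols, drop = FALSE])
  ytr <- factor(label_to_binary(train$label), levels = c(0, 1))
  folds <- integer(nrow(train))
  withr::with_seed(seed, {
    for (cls in levels(ytr)) {
      rows <- which(ytr == cls)
      folds[rows] <- sample(rep_len(seq_len(nfolds), length(rows)))
    }
  })
  grid <- expand.grid(ntree = ntree_grid, nodesize = nodesize_grid)
  grid$auroc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(nfolds)
    for (f in seq_len(nfolds)) {
      tr <- folds != f
      withr::with_seed(seed + g * 100L + f, {
        rf <- randomForest::randomForest(
          Xtr[tr, , drop = FALSE], ytr[tr],
          ntree = grid$ntree[g], nodesize = grid$nodesize[g])
      })
      p <- predict(rf, Xtr[!tr, , drop = FALSE], type = "prob")[, "1"]
      aucs[f] <- compute_auroc(p[ytr[!tr] == "1"], p[ytr[!tr] == "0"])
    }
    grid$auroc[g] <- mean(aucs)
  }
  best <- grid[which.max(grid$auroc), ]
  withr::with_seed(seed, {
    forest <- randomForest::randomForest(Xtr, ytr, ntree = best$ntree,
                                         nodesize = best$nodesize)
  })
  Xte <- as.matrix(test[, cols, drop = FALSE])
  yte <- label_to_binary(test$label)
  p <- predict(forest, Xte, type = "prob")[, "1"]
  auroc <- compute_auroc(p[yte == 1], p[yte == 0])
  list(forest = forest, params = best[, c("ntree", "nodesize")],
       cv = as_tibble(grid), auroc = auroc)
}
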