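# Independent oracle implementations used to cross-check the package. Each
# deliberately uses a different algorithm from the code under test.

# -- dot-bracket ----------------------------------------------------------

# stack parser written independently of the package's
oracle_pairs <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") open <- c(open, i)
    if (chars[i] == ")") {
      pairs <- rbind(pairs, c(open[length(open)], i))
      open <- open[-length(open)]
    }
  }
  pairs
}

# brute-force context classifier: loops derived directly from the pair list
oracle_classify <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pairs <- oracle_pairs(db)
  out <- character(n)
  out[chars == "("] <- "L"
  out[chars == ")"] <- "R"
  unpaired <- which(chars == ".")
  enclosing_of <- function(k) {
    enc <- which(pairs[, 1] < k & pairs[, 2] > k)
    if (length(enc) == 0) return(NULL)
    enc[which.min(pairs[enc, 2] - pairs[enc, 1])]
  }
  for (k in unpaired) {
    e <- enclosing_of(k)
    if (is.null(e)) {
      out[k] <- "E"
      next
    }
    i <- pairs[e, 1]; j <- pairs[e, 2]
    inside <- which(pairs[, 1] > i & pairs[, 2] < j)
    # children: pairs inside (i,j) not nested within another inside pair
    child <- inside[vapply(inside, function(p) {
      !any(pairs[inside, 1] < pairs[p, 1] & pairs[inside, 2] > pairs[p, 2])
    }, logical(1))]
    if (length(child) == 0) {
      out[k] <- "H"
    } else if (length(child) >= 2) {
      out[k] <- "M"
    } else {
      a <- pairs[child, 1]; b <- pairs[child, 2]
      loop_unpaired <- unpaired[unpaired > i & unpaired < j &
                                  !(unpaired > a & unpaired < b)]
      left <- any(loop_unpaired < a)
      right <- any(loop_unpaired > b)
      out[k] <- if (left && right) "T" else "B"
    }
  }
  paste(out, collapse = "")
}

# all balanced dot-bracket strings of exactly length n
enumerate_balanced <- function(n) {
  grow <- function(prefix, depth, remaining) {
    if (remaining == 0) {
      return(if (depth == 0) prefix else character(0))
    }
    out <- character(0)
    if (depth + 1 <= remaining - 1) {  # room left to close all opens
      out <- c(out, grow(paste0(prefix, "("), depth + 1, remaining - 1))
    }
    if (depth > 0) {
      out <- c(out, grow(paste0(prefix, ")"), depth - 1, remaining - 1))
    }
    c(out, grow(paste0(prefix, "."), depth, remaining - 1))
  }
  grow("", 0, n)
}

# uniform-ish random balanced dot-bracket for property tests
random_dotbracket <- function(n) {
  repeat {
    chars <- sample(c("(", ")", "."), n, replace = TRUE, prob = c(.3, .3, .4))
    depth <- cumsum((chars == "(") - (chars == ")"))
    if (all(depth >= 0) && depth[n] == 0) {
      return(paste(chars, collapse = ""))
    }
  }
}

random_rna_string <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# -- scanning -------------------------------------------------------------

# direct enumeration of all windows using raw matrix arithmetic
oracle_top4 <- function(mat, annotation) {
  w <- ncol(mat)
  letters <- strsplit(annotation, "", fixed = TRUE)[[1]]
  n_win <- length(letters) - w + 1
  scores <- vapply(seq_len(n_win), function(p) {
    s <- 0
    for (j in seq_len(w)) {
      pr <- max(mat[letters[p + j - 1], j], 1e-3)
      s <- s + log2(pr * nrow(mat))
    }
    s
  }, numeric(1))
  sum(rev(sort(scores))[seq_len(min(4, n_win))])
}

random_pfm <- function(alphabet_kind, width, seed = NULL) {
  alph <- ss_alphabet(alphabet_kind)
  m <- matrix(stats::rgamma(alph$size * width, shape = 0.5),
              nrow = alph$size)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- alph$symbols
  ssmotif:::new_ss_pfm("test", alphabet_kind, m)
}

# -- AUROC ----------------------------------------------------------------

oracle_auroc <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# -- L1 logistic regression ----------------------------------------------

# proximal gradient descent on the glmnet-style objective
# (1/N) * sum(log(1 + exp(-y*eta))) + lambda * ||beta||_1, intercept free
oracle_l1_logreg <- function(X, y, lambda, iters = 200000, step = 0.1) {
  n <- nrow(X); p <- ncol(X)
  beta <- rep(0, p); b0 <- 0
  for (it in seq_len(iters)) {
    eta <- b0 + X %*% beta
    mu <- 1 / (1 + exp(-eta))
    g <- crossprod(X, mu - y) / n
    g0 <- mean(mu - y)
    beta_new <- beta - step * g
    beta_new <- sign(beta_new) * pmax(abs(beta_new) - step * lambda, 0)
    b0_new <- b0 - step * g0
    if (max(abs(c(beta_new - beta, b0_new - b0))) < 1e-10) {
      beta <- beta_new; b0 <- b0_new
      break
    }
    beta <- beta_new; b0 <- b0_new
  }
  list(beta = as.numeric(beta), intercept = b0)
}

# -- HMM ------------------------------------------------------------------

# exhaustive path enumeration of P(x | hmm)
oracle_hmm_prob <- function(hmm, annotation) {
  idx <- match(strsplit(annotation, "", fixed = TRUE)[[1]],
               ss_alphabet(hmm$alphabet)$symbols)
  S <- nrow(hmm$transition)
  L <- length(idx)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), L)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    p <- hmm$start[st[1]] * hmm$emission[st[1], idx[1]]
    if (L > 1) {
      for (t in 2:L) {
        p <- p * hmm$transition[st[t - 1], st[t]] * hmm$emission[st[t], idx[t]]
      }
    }
    total <- total + p
  }
  unname(total)
}

# sample an annotation string from a gap-HMM
sample_hmm <- function(hmm, length) {
  symbols <- ss_alphabet(hmm$alphabet)$symbols
  S <- nrow(hmm$transition)
  s <- sample.int(S, 1, prob = hmm$start)
  out <- character(length)
  for (t in seq_len(length)) {
    out[t] <- sample(symbols, 1, prob = hmm$emission[s, ])
    if (t < length) s <- sample.int(S, 1, prob = hmm$transition[s, ])
  }
  paste(out, collapse = "")
}

# -- fixtures -------------------------------------------------------------

tiny_motif_tbl <- function(consensus = "ACGU", kind = "sequence") {
  discover_motifs(rep(consensus, 5), c("GGGG", "UUUU", "GGUU", "UUGG", "GUGU"),
                  kind, min_width = nchar(consensus),
                  max_width = nchar(consensus), p_threshold = 1)
}

# small feature set with one informative and several noise features
simulated_features <- function(n = 120, p_noise = 4, seed = 1,
                               strength = 2) {
  withr::with_seed(seed, {
    label <- rep(c("positive", "negative"), each = n / 2)
    signal <- stats::rnorm(n) + strength * (label == "positive")
    noise <- matrix(stats::rnorm(n * p_noise), nrow = n)
    out <- tibble::tibble(probe_id = sprintf("p%03d", seq_len(n)),
                          label = label, signal = signal)
    for (j in seq_len(p_noise)) out[[paste0("noise", j)]] <- noise[, j]
    out
  })
}
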