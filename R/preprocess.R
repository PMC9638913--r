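# Dataset preprocessing and seeded stratified splitting.

#' Clean and subsample positive/negative probe sets
#'
#' Removes probes containing ambiguous (non-`ACGUT`) letters, normalizes `T`
#' to `U`, and subsamples both sets (seeded, without replacement) to
#' `min(cap, n_pos, n_neg)` so the two classes are balanced and bounded by
#' the cap.
#'
#' @param positive,negative Tibbles with `probe_id` and `sequence` columns
#'   (a `dotbracket` column, if present, is carried through).
#' @param cap Per-set subsample cap (default one million probes).
#' @param seed Integer seed for the subsampling.
#' @return One tibble holding both sets with a `label` column
#'   (`"positive"`/`"negative"`).
#' @export
preprocess_probes <- function(positive, negative, cap = 1e6, seed = 1L) {
  clean <- function(df, lab) {
    df <- as_tibble(df)
    df$sequence <- toupper(df$sequence)
    keep <- grepl("^[ACGUT]+$", df$sequence)
    df <- df[keep, , drop = FALSE]
    df$sequence <- normalize_rna(df$sequence)
    df$label <- lab
    df
  }
  pos <- clean(positive, "positive")
  neg <- clean(negative, "negative")
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    abort("a probe set is empty after removing ambiguous-base probes",
          class = "ssmotif_config_error")
  }
  target <- min(cap, nrow(pos), nrow(neg))
  withr::with_seed(seed, {
    pos <- pos[sort(sample.int(nrow(pos), target)), , drop = FALSE]
    neg <- neg[sort(sample.int(nrow(neg), target)), , drop = FALSE]
  })
  dplyr::bind_rows(pos, neg)
}

#' Split probes into discovery / training / validation / held-out subsets
#'
#' Seeded random partition, stratified by label, with largest-remainder
#' rounding so per-class subset sizes are exact for the stated fractions.
#' The default fractions are 50% motif discovery, 20% regression training,
#' 5% regression validation and 25% held-out testing.
#'
#' @param probes Tibble with a `label` column.
#' @param fractions Named fractions summing to 1; names become split labels.
#' @param seed Integer seed.
#' @return The input tibble with a `split` factor column appended.
#' @export
split_probes <- function(probes,
                         fractions = c(discovery = 0.50, train = 0.20,
                                       validation = 0.05, test = 0.25),
                         seed = 1L) {
  stopifnot(is.data.frame(probes), "label" %in% names(probes))
  if (abs(sum(fractions) - 1) > 1e-8) {
    abort("split fractions must sum to 1", class = "ssmotif_config_error")
  }
  if (nrow(probes) < 20) {
    abort("fewer than 20 probes; too few to split",
          class = "ssmotif_config_error")
  }
  probes <- as_tibble(probes)
  probes$split <- NA_character_
  withr::with_seed(seed, {
    for (lab in unique(probes$label)) {
      rows <- which(probes$label == lab)
      n <- length(rows)
      exact <- fractions * n
      sizes <- floor(exact)
      rem <- n - sum(sizes)
      if (rem > 0) {
        extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1L
      }
      shuffled <- sample(rows)
      probes$split[shuffled] <- rep(names(fractions), times = sizes)
    }
  })
  probes$split <- factor(probes$split, levels = names(fractions))
  probes
}
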