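# End-to-end training pipeline: preprocess -> split -> annotate -> per-alphabet
# motif discovery -> scan -> L1 strength search -> iterative simplification.

#' Pipeline configuration
#'
#' @param flank5,flank3 Constant flank sequences present on every probe (the
#'   full probe is folded; only the variable region between the flanks is
#'   annotated and scanned).
#' @param temperature Folding temperature in degrees Celsius; recorded for
#'   provenance and passed to the external folding hook when used.
#' @param subsample_cap Per-set probe cap before splitting.
#' @param fractions Named split fractions (discovery / train / validation /
#'   test), summing to 1.
#' @param min_width,max_width Motif width bounds.
#' @param p_threshold Corrected discovery p-value threshold.
#' @param max_motifs Per-alphabet PFM cap.
#' @param grid L1 strength search grid.
#' @param nfolds Cross-validation folds for the strength search.
#' @param scale_factor,retention Simplification loop parameters.
#' @param backend Motif discovery backend.
#' @param seed Integer master seed; per-stage seeds derive from it.
#' @return An `ss_config` list.
#' @export
ss_config <- function(flank5 = "", flank3 = "", temperature = 37,
                      subsample_cap = 1e6,
                      fractions = c(discovery = 0.50, train = 0.20,
                                    validation = 0.05, test = 0.25),
                      min_width = 4L, max_width = 6L, p_threshold = 0.01,
                      max_motifs = 40L, grid = 10^seq(-4, 4, length.out = 33),
                      nfolds = 5L, scale_factor = 1.25, retention = 0.9,
                      backend = c("builtin", "streme"), seed = 1L) {
  backend <- match.arg(backend)
  structure(
    list(flank5 = flank5, flank3 = flank3, temperature = temperature,
         subsample_cap = subsample_cap, fractions = fractions,
         min_width = as.integer(min_width), max_width = as.integer(max_width),
         p_threshold = p_threshold, max_motifs = as.integer(max_motifs),
         grid = grid, nfolds = as.integer(nfolds),
         scale_factor = scale_factor, retention = retention,
         backend = backend, seed = as.integer(seed)),
    class = "ss_config"
  )
}

#' Train a sequence-structure motif model end to end
#'
#' Cleans and subsamples the two probe sets, splits them (stratified) into
#' discovery / training / validation / held-out subsets, annotates every
#' probe under the seven alphabets, discovers enriched PFMs per alphabet on
#' the discovery subset, scans all PFMs on the remaining subsets
#' (top-four-window-sum features), selects the L1 strength by cross-validated
#' AUROC, and iteratively simplifies the regression until just over 90% of
#' the initial predictive power remains.
#'
#' @param positive,negative Tibbles with `probe_id`, `sequence` and
#'   `dotbracket` columns (structures for the full, flanked probes).
#' @param config An [ss_config()].
#' @param quiet Suppress progress messages.
#' @return An `ss_model`. Extra fields: `motifs` (all discovered PFMs),
#'   `test_auroc` (held-out), and `counts` (per-stage probe counts).
#' @export
ss_train <- function(positive, negative, config = ss_config(), quiet = FALSE) {
  stopifnot(inherits(config, "ss_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- Sys.time()

  probes <- preprocess_probes(positive, negative, cap = config$subsample_cap,
                              seed = config$seed)
  probes <- split_probes(probes, config$fractions, seed = config$seed + 1L)
  say("preprocessed: %d probes per class",
      sum(probes$label == "positive"))

  probes <- annotate_probes(probes, flank5 = config$flank5,
                            flank3 = config$flank3)
  disc <- probes[probes$split == "discovery", ]
  motifs <- purrr::map(alphabet_kinds(), function(kind) {
    col <- ANNOTATION_COLS[[kind]]
    discover_motifs(disc[[col]][disc$label == "positive"],
                    disc[[col]][disc$label == "negative"],
                    kind, min_width = config$min_width,
                    max_width = config$max_width,
                    p_threshold = config$p_threshold,
                    max_motifs = config$max_motifs,
                    backend = config$backend)
  }) |>
    dplyr::bind_rows()
  say("discovered %d PFMs across %d alphabets", nrow(motifs),
      dplyr::n_distinct(motifs$alphabet))

  scan_split <- function(s) {
    build_feature_matrix(motifs, probes[probes$split == s, ], label = "label")
  }
  train <- scan_split("train")
  validation <- scan_split("validation")

  if (nrow(motifs) == 0) {
    warn("no motifs discovered; returning an intercept-only model")
  }
  opt <- optimize_l1(train, validation, grid = config$grid,
                     nfolds = config$nfolds, seed = config$seed + 2L)
  say("optimized L1 strength: %.4g (validation AUROC %.3f)",
      opt$l1_strength, opt$initial_auroc)

  model <- simplify_model(train, validation, opt$l1_strength, motifs = motifs,
                          scale_factor = config$scale_factor,
                          retention = config$retention,
                          config = config[c("flank5", "flank3", "temperature",
                                            "min_width", "max_width",
                                            "p_threshold", "max_motifs",
                                            "scale_factor", "retention")],
                          seed = config$seed)
  say("simplified to %d motif(s); validation AUROC %.3f -> %.3f",
      length(model$coefficients), model$initial_auroc, model$final_auroc)

  test <- scan_split("test")
  eta <- if (length(model$coefficients) > 0) {
    X <- as.matrix(test[, names(model$coefficients), drop = FALSE])
    drop(sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/") %*%
           model$coefficients)
  } else {
    rep(model$intercept, nrow(test))
  }
  y <- label_to_binary(test$label)
  model$test_auroc <- compute_auroc(eta[y == 1], eta[y == 0])
  model$motifs <- motifs
  model$counts <- table(probes$split, probes$label)
  say("held-out AUROC %.3f; elapsed %.1fs", model$test_auroc,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  model
}

#' Optional external folding hook
#'
#' Folds probe sequences with an external `RNAfold` binary in
#' partition-function mode and extracts the centroid structure line. This is
#' never required by the rest of the package (annotation takes dot-brackets
#' as input); it exists for users working from raw FASTA.
#'
#' @param probes Tibble with `sequence` column.
#' @param temperature Folding temperature in degrees Celsius.
#' @param rnafold Path to the `RNAfold` binary.
#' @return The input tibble with a `dotbracket` column added.
#' @export
fold_probes <- function(probes, temperature = 37,
                        rnafold = Sys.which("RNAfold")) {
  if (!nzchar(rnafold)) {
    abort("no RNAfold binary found; supply dot-brackets directly",
          class = "ssmotif_config_error")
  }
  probes <- as_tibble(probes)
  input <- paste0(">", probes$probe_id %||% seq_len(nrow(probes)), "\n",
                  probes$sequence, collapse = "\n")
  out <- system2(rnafold, c("-p", "--noPS", "--noDP", "-T", temperature),
                 input = input, stdout = TRUE)
  # RNAfold -p record: >id / sequence / MFE line / pairing-propensity line /
  # centroid line "....{} ( -1.20 d=2.1)" / frequency line
  headers <- grep("^>", out)
  centroid <- out[headers + 4L]
  probes$dotbracket <- sub("\\s.*$", "", centroid)
  probes
}
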