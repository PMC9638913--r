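# SELEX-like synthetic probe-pool generator with planted sequence,
# hairpin-embedded and bipartite motifs, emitting self-consistent
# dot-bracket structures so the whole pipeline runs folder-free.

IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

sample_iupac <- function(consensus) {
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  sets <- IUPAC[letters]
  if (any(vapply(sets, is.null, logical(1)))) {
    abort("motif consensus contains non-IUPAC letters",
          class = "ssmotif_format_error")
  }
  paste(vapply(sets, function(s) s[sample.int(length(s), 1)], character(1)),
        collapse = "")
}

RC_MAP <- c(A = "U", U = "A", G = "C", C = "G")

reverse_complement <- function(seq) {
  paste(rev(RC_MAP[strsplit(seq, "", fixed = TRUE)[[1]]]), collapse = "")
}

#' Configuration for the SELEX-like probe simulator
#'
#' Describes one simulated selection experiment: fixed-length randomized
#' probes (N`probe_length`) with optional constant flanks, a consensus motif
#' planted in a fraction `plant_rate` of positive probes, and one of three
#' planting modes: `"none"` (motif dropped into unstructured background),
#' `"hairpin_loop"` (motif embedded in the loop of a hairpin with a
#' Watson-Crick complementary stem), or `"bipartite"` (two sub-motifs
#' separated by a uniform random gap).
#'
#' @param n_probes Probes per set (positive and negative each).
#' @param probe_length Variable-region length in bases.
#' @param flank5,flank3 Constant flank sequences (may be empty).
#' @param plant_rate Fraction of positive probes receiving a planted motif.
#' @param motif Consensus to plant (IUPAC codes allowed).
#' @param motif2 Second sub-consensus, bipartite mode only.
#' @param structure_mode One of `"none"`, `"hairpin_loop"`, `"bipartite"`.
#' @param gap_range Integer `c(min, max)` gap between sub-motifs (bipartite).
#' @param stem_length Hairpin stem length in base pairs (>= 3).
#' @param loop_length Hairpin loop length; must be >= `nchar(motif)`.
#' @param base_composition Probabilities for A, C, G, U; must sum to 1.
#' @param seed Integer seed; every sampling step derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_probes = 2000, probe_length = 40,
                             flank5 = "", flank3 = "",
                             plant_rate = 0.5, motif = "UGCAUG",
                             motif2 = NULL,
                             structure_mode = c("none", "hairpin_loop", "bipartite"),
                             gap_range = c(1L, 20L),
                             stem_length = 4L,
                             loop_length = NULL,
                             base_composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                             seed = 1L) {
  structure_mode <- match.arg(structure_mode)
  if (abs(sum(base_composition) - 1) > 1e-8 || any(base_composition < 0)) {
    abort("base_composition must be non-negative and sum to 1",
          class = "ssmotif_config_error")
  }
  if (plant_rate < 0 || plant_rate > 1) {
    abort("plant_rate must be in [0, 1]", class = "ssmotif_config_error")
  }
  loop_length <- loop_length %||% nchar(motif)
  if (structure_mode == "hairpin_loop") {
    if (stem_length < 3) abort("stem_length must be >= 3",
                               class = "ssmotif_config_error")
    if (loop_length < nchar(motif)) {
      abort("loop_length must be >= motif length", class = "ssmotif_config_error")
    }
  }
  if (structure_mode == "bipartite" && is.null(motif2)) {
    abort("bipartite mode requires motif2", class = "ssmotif_config_error")
  }
  structure(
    list(n_probes = as.integer(n_probes), probe_length = as.integer(probe_length),
         flank5 = flank5, flank3 = flank3, plant_rate = plant_rate,
         motif = toupper(motif), motif2 = if (is.null(motif2)) NULL else toupper(motif2),
         structure_mode = structure_mode, gap_range = as.integer(gap_range),
         stem_length = as.integer(stem_length), loop_length = as.integer(loop_length),
         base_composition = base_composition, seed = as.integer(seed)),
    class = "generator_config"
  )
}

random_rna <- function(n, length, composition) {
  chars <- sample(SEQ_SYMBOLS, n * length, replace = TRUE, prob = composition)
  apply(matrix(chars, nrow = n), 1, paste, collapse = "")
}

#' Generate unstructured background probes
#'
#' Draws i.i.d. sequences from the configured base composition; dot-brackets
#' are all-dots (background probes are emitted unfolded).
#'
#' @param config A [generator_config()].
#' @param n Number of probes; defaults to `config$n_probes`.
#' @param prefix Probe-identifier prefix.
#' @return Tibble with `probe_id`, `sequence` (variable region only) and
#'   `dotbracket` columns.
#' @export
generate_background <- function(config, n = config$n_probes, prefix = "bg") {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    seqs <- random_rna(n, config$probe_length, config$base_composition)
  })
  tibble(
    probe_id = sprintf("%s_%05d", prefix, seq_len(n)),
    sequence = seqs,
    dotbracket = strrep(".", config$probe_length)
  )
}

#' Plant a consensus motif into a fraction of probes
#'
#' Each probe independently receives the motif with probability `rate`; the
#' instance (IUPAC codes sampled uniformly over their nucleotide sets) is
#' written at a uniform random valid offset, overwriting background letters.
#'
#' @param probes Tibble with a `sequence` column.
#' @param consensus Motif consensus (IUPAC allowed).
#' @param rate Per-probe planting probability.
#' @param seed Integer seed.
#' @return The input tibble with `planted` (logical) and `plant_start`
#'   (1-based offset or `NA`) columns added and sequences modified in place.
#' @export
plant_motif <- function(probes, consensus, rate, seed = 1L) {
  stopifnot(is.data.frame(probes), "sequence" %in% names(probes))
  probes <- as_tibble(probes)
  w <- nchar(consensus)
  if (any(nchar(probes$sequence) < w)) {
    abort("consensus longer than probe", class = "ssmotif_bounds_error")
  }
  n <- nrow(probes)
  withr::with_seed(seed, {
    planted <- runif(n) < rate
    starts <- rep(NA_integer_, n)
    seqs <- probes$sequence
    for (i in which(planted)) {
      inst <- sample_iupac(consensus)
      s <- sample.int(nchar(seqs[i]) - w + 1L, 1)
      substr(seqs[i], s, s + w - 1L) <- inst
      starts[i] <- s
    }
  })
  probes$sequence <- seqs
  probes$planted <- planted
  probes$plant_start <- starts
  probes
}

#' Build one probe with a motif embedded in a hairpin loop
#'
#' Constructs a stem-loop within a random background probe: a random stem of
#' `stem_length` Watson-Crick pairs, a loop containing `loop_motif` at a
#' random position within the loop, and the closing strand equal to the
#' reverse complement of the stem. The emitted dot-bracket pairs exactly the
#' stem strands, so [classify_contexts()] labels every loop base `H`.
#'
#' @param loop_motif Consensus placed inside the loop (IUPAC allowed).
#' @param stem_length Stem length in base pairs (>= 3).
#' @param config A [generator_config()] (supplies probe length, composition,
#'   loop length).
#' @return List with `sequence`, `dotbracket`, `motif_start` (1-based position
#'   of the motif in the probe) and `hairpin_start`.
#' @export
generate_hairpin_probe <- function(loop_motif, stem_length, config) {
  stopifnot(inherits(config, "generator_config"))
  if (stem_length < 3) abort("stem_length must be >= 3",
                             class = "ssmotif_config_error")
  L <- config$probe_length
  loop_len <- max(config$loop_length, nchar(loop_motif))
  hp_len <- 2L * stem_length + loop_len
  if (hp_len > L) {
    abort("hairpin longer than probe", class = "ssmotif_bounds_error")
  }
  bg <- random_rna(1, L, config$base_composition)
  stem <- random_rna(1, stem_length, config$base_composition)
  inst <- sample_iupac(loop_motif)
  pad <- loop_len - nchar(inst)
  pad_before <- if (pad > 0) sample.int(pad + 1L, 1) - 1L else 0L
  loop <- paste0(
    if (pad_before > 0) random_rna(1, pad_before, config$base_composition) else "",
    inst,
    if (pad - pad_before > 0) random_rna(1, pad - pad_before, config$base_composition) else ""
  )
  hairpin <- paste0(stem, loop, reverse_complement(stem))
  offset <- sample.int(L - hp_len + 1L, 1)
  seq <- bg
  substr(seq, offset, offset + hp_len - 1L) <- hairpin
  db <- strrep(".", L)
  substr(db, offset, offset + stem_length - 1L) <- strrep("(", stem_length)
  substr(db, offset + stem_length + loop_len, offset + hp_len - 1L) <-
    strrep(")", stem_length)
  list(sequence = seq, dotbracket = db,
       motif_start = offset + stem_length + pad_before,
       hairpin_start = offset)
}

plant_bipartite <- function(seq, motif1, motif2, gap_range) {
  w1 <- nchar(motif1); w2 <- nchar(motif2)
  gap <- sample(seq.int(gap_range[1], gap_range[2]), 1)
  total <- w1 + gap + w2
  if (total > nchar(seq)) {
    abort("bipartite plant longer than probe", class = "ssmotif_bounds_error")
  }
  s <- sample.int(nchar(seq) - total + 1L, 1)
  i1 <- sample_iupac(motif1); i2 <- sample_iupac(motif2)
  substr(seq, s, s + w1 - 1L) <- i1
  substr(seq, s + w1 + gap, s + total - 1L) <- i2
  list(sequence = seq, start1 = s, start2 = s + w1 + gap, gap = gap)
}

#' Generate a full positive/negative simulated dataset
#'
#' Positives receive plants according to `config$structure_mode`; negatives
#' are pure background. A truth table records every plant for oracle-based
#' evaluation.
#'
#' @param config A [generator_config()].
#' @return List with tibbles `positive`, `negative` (columns `probe_id`,
#'   `sequence`, `dotbracket`; sequences include configured flanks) and
#'   `truth` (`probe_id`, `planted`, `start1`, `start2`, `gap`). Positions in
#'   `truth` are 1-based within the variable region.
#' @examples
#' ds <- generate_dataset(generator_config(n_probes = 10, seed = 42))
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_probes
  L <- config$probe_length
  withr::with_seed(config$seed, {
    neg <- random_rna(n, L, config$base_composition)
    pos <- random_rna(n, L, config$base_composition)
    pos_db <- rep(strrep(".", L), n)
    planted <- runif(n) < config$plant_rate
    start1 <- rep(NA_integer_, n)
    start2 <- rep(NA_integer_, n)
    gap <- rep(NA_integer_, n)
    for (i in which(planted)) {
      if (config$structure_mode == "none") {
        inst <- sample_iupac(config$motif)
        s <- sample.int(L - nchar(inst) + 1L, 1)
        substr(pos[i], s, s + nchar(inst) - 1L) <- inst
        start1[i] <- s
      } else if (config$structure_mode == "hairpin_loop") {
        hp <- generate_hairpin_probe(config$motif, config$stem_length, config)
        pos[i] <- hp$sequence
        pos_db[i] <- hp$dotbracket
        start1[i] <- hp$motif_start
      } else {
        bp <- plant_bipartite(pos[i], config$motif, config$motif2,
                              config$gap_range)
        pos[i] <- bp$sequence
        start1[i] <- bp$start1
        start2[i] <- bp$start2
        gap[i] <- bp$gap
      }
    }
  })
  flank_db <- function(db) {
    paste0(strrep(".", nchar(config$flank5)), db, strrep(".", nchar(config$flank3)))
  }
  add_flanks <- function(s) paste0(config$flank5, s, config$flank3)
  list(
    positive = tibble(probe_id = sprintf("pos_%05d", seq_len(n)),
                      sequence = add_flanks(pos),
                      dotbracket = flank_db(pos_db)),
    negative = tibble(probe_id = sprintf("neg_%05d", seq_len(n)),
                      sequence = add_flanks(neg),
                      dotbracket = flank_db(strrep(".", L))),
    truth = tibble(probe_id = sprintf("pos_%05d", seq_len(n)),
                   planted = planted, start1 = start1, start2 = start2,
                   gap = gap)
  )
}
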