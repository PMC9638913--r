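# Enriched-motif discovery: per-alphabet k-mer enrichment testing with
# Bonferroni correction, greedy non-redundant seed selection, and PFM
# construction from matching sites.

new_ss_pfm <- function(id, alphabet_kind, matrix, p_value = NA_real_,
                       p_adjusted = NA_real_, n_sites = NA_integer_) {
  stopifnot(is.matrix(matrix))
  csums <- colSums(matrix)
  if (any(abs(csums - 1) > 1e-9) || any(matrix < 0)) {
    abort("PFM columns must be non-negative and sum to 1",
          class = "ssmotif_format_error")
  }
  alph <- ss_alphabet(alphabet_kind)
  if (nrow(matrix) != alph$size) {
    abort("PFM row count does not match alphabet size",
          class = "ssmotif_format_error")
  }
  rownames(matrix) <- alph$symbols
  consensus <- paste(alph$symbols[apply(matrix, 2, which.max)], collapse = "")
  structure(
    list(id = id, alphabet = alphabet_kind, width = ncol(matrix),
         matrix = matrix, consensus = consensus, p_value = p_value,
         p_adjusted = p_adjusted, n_sites = n_sites),
    class = "ss_pfm"
  )
}

#' @export
print.ss_pfm <- function(x, ...) {
  cat(sprintf("<ss_pfm> %s [%s] w=%d consensus=%s p.adj=%.3g\n",
              x$id, x$alphabet, x$width, x$consensus, x$p_adjusted))
  invisible(x)
}

# distinct k-mers per probe -> per-set presence counts
kmer_presence <- function(strings, k) {
  keep <- nchar(strings) >= k
  lst <- lapply(strings[keep], function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  tab <- table(unlist(lst, use.names = FALSE))
  tibble(kmer = names(tab), count = as.integer(tab))
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# positional letter counts over all exact occurrences of `seed` in `strings`
pfm_from_seed <- function(seed, strings, alphabet, pseudocount = 0.1) {
  w <- nchar(seed)
  counts <- matrix(0, nrow = alphabet$size, ncol = w,
                   dimnames = list(alphabet$symbols, NULL))
  n_sites <- 0L
  for (s in strings) {
    hits <- gregexpr(seed, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    n_sites <- n_sites + length(hits)
  }
  # exact matches: every site spells the seed, so counts are concentrated on
  # the seed letters; pseudocounts spread the remaining mass
  letters <- strsplit(seed, "", fixed = TRUE)[[1]]
  for (j in seq_len(w)) counts[letters[j], j] <- n_sites
  counts <- counts + pseudocount
  mat <- sweep(counts, 2, colSums(counts), "/")
  list(matrix = mat, n_sites = n_sites)
}

#' Apply Bonferroni correction, threshold, sort and cap a motif list
#'
#' Corrects discovery p-values for the number of hypotheses tested
#' (`corrected = min(1, p * n_tests)`), retains motifs with corrected
#' p < `threshold`, sorts ascending by corrected p, and truncates to
#' `max_motifs`.
#'
#' @param motifs Motif tibble with a `p_value` column.
#' @param n_tests Bonferroni family size (>= 1).
#' @param threshold Corrected-p retention threshold.
#' @param max_motifs Cap on the number of motifs returned.
#' @return Filtered motif tibble with `p_adjusted` recomputed.
#' @export
bonferroni_cap <- function(motifs, n_tests, threshold = 0.01, max_motifs = 40L) {
  if (n_tests < 1) abort("n_tests must be >= 1", class = "ssmotif_config_error")
  motifs |>
    dplyr::mutate(p_adjusted = pmin(1, .data$p_value * n_tests)) |>
    dplyr::filter(.data$p_adjusted < threshold) |>
    dplyr::arrange(.data$p_adjusted, .data$p_value, .data$motif) |>
    head(max_motifs)
}

#' Discover motifs enriched in the positive annotation set
#'
#' The built-in backend enumerates all k-mers (`min_width`..`max_width`)
#' observed in either set, tests per-probe occurrence enrichment in the
#' positive set by a one-sided Fisher's exact test, Bonferroni-corrects over
#' the number of k-mers tested, greedily selects significant non-redundant
#' seeds (a seed within Hamming distance 1 of an already-selected seed of the
#' same width is skipped), and builds each PFM from the positional letter
#' frequencies of the seed's matching sites in the positive set with
#' pseudocounts. At most `max_motifs` PFMs with corrected p < `p_threshold`
#' are returned, sorted by ascending corrected p.
#'
#' An external STREME backend with the same output contract can be selected
#' with `backend = "streme"`; it requires the MEME suite on the PATH.
#'
#' @param positive,negative Character vectors of annotation strings over
#'   `alphabet`.
#' @param alphabet An [ss_alphabet()] or a kind name.
#' @param min_width,max_width Motif width bounds in bases.
#' @param p_threshold Corrected discovery p-value threshold.
#' @param max_motifs Cap on returned PFMs.
#' @param pseudocount Per-cell pseudocount used in PFM construction.
#' @param backend `"builtin"` or `"streme"`.
#' @return Tibble with one row per PFM: `motif`, `alphabet`, `width`,
#'   `consensus`, `p_value`, `p_adjusted`, `n_pos`, `n_neg` (per-probe
#'   occurrence counts) and a `pfm` list-column of `ss_pfm` objects.
#' @examples
#' pos <- c("ACGUACGUAC", "UUACGUACUU", "GGGACGUCCC")
#' neg <- c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG")
#' discover_motifs(pos, neg, "sequence", p_threshold = 1)
#' @export
discover_motifs <- function(positive, negative, alphabet,
                            min_width = 4L, max_width = 6L,
                            p_threshold = 0.01, max_motifs = 40L,
                            pseudocount = 0.1,
                            backend = c("builtin", "streme")) {
  backend <- match.arg(backend)
  if (is.character(alphabet)) alphabet <- ss_alphabet(alphabet)
  if (length(positive) == 0 || length(negative) == 0) {
    abort("positive and negative sets must be non-empty",
          class = "ssmotif_config_error")
  }
  if (backend == "streme") {
    streme <- Sys.which("streme")
    if (!nzchar(streme)) {
      abort("STREME backend selected but no 'streme' binary is on the PATH",
            class = "ssmotif_config_error")
    }
    return(discover_motifs_streme(positive, negative, alphabet, min_width,
                                  max_width, p_threshold, max_motifs, streme))
  }

  n_pos_total <- length(positive)
  n_neg_total <- length(negative)
  cand <- purrr::map(seq.int(min_width, max_width), function(k) {
    pos_counts <- kmer_presence(positive, k)
    neg_counts <- kmer_presence(negative, k)
    dplyr::full_join(pos_counts, neg_counts, by = "kmer",
                     suffix = c("_pos", "_neg")) |>
      tidyr::replace_na(list(count_pos = 0L, count_neg = 0L)) |>
      dplyr::mutate(width = k)
  }) |>
    dplyr::bind_rows()
  if (nrow(cand) == 0) return(empty_motif_tibble())
  # one-sided Fisher's exact test on probe-level presence/absence, vectorized
  # through the hypergeometric tail
  m <- cand$count_pos + cand$count_neg
  cand$p_value <- stats::phyper(cand$count_pos - 1L, m,
                                n_pos_total + n_neg_total - m,
                                n_pos_total, lower.tail = FALSE)
  n_tests <- nrow(cand)
  cand <- cand |>
    dplyr::mutate(p_adjusted = pmin(1, .data$p_value * n_tests)) |>
    dplyr::filter(.data$p_adjusted < p_threshold) |>
    dplyr::arrange(.data$p_adjusted, .data$p_value, .data$kmer)
  selected <- list()
  for (i in seq_len(nrow(cand))) {
    seed <- cand$kmer[i]
    redundant <- any(vapply(selected, function(s) {
      nchar(s$kmer) == nchar(seed) && hamming(s$kmer, seed) <= 1
    }, logical(1)))
    if (redundant) next
    selected[[length(selected) + 1L]] <- cand[i, ]
    if (length(selected) >= max_motifs) break
  }
  if (length(selected) == 0) return(empty_motif_tibble())
  rows <- purrr::imap(selected, function(row, i) {
    built <- pfm_from_seed(row$kmer, positive, alphabet, pseudocount)
    id <- sprintf("%s_%02d", alphabet$kind, i)
    pfm <- new_ss_pfm(id, alphabet$kind, built$matrix,
                      p_value = row$p_value, p_adjusted = row$p_adjusted,
                      n_sites = built$n_sites)
    tibble(motif = id, alphabet = alphabet$kind, width = row$width,
           consensus = pfm$consensus, p_value = row$p_value,
           p_adjusted = row$p_adjusted, n_pos = row$count_pos,
           n_neg = row$count_neg, pfm = list(pfm))
  })
  dplyr::bind_rows(rows)
}

empty_motif_tibble <- function() {
  tibble(motif = character(0), alphabet = character(0), width = integer(0),
         consensus = character(0), p_value = numeric(0),
         p_adjusted = numeric(0), n_pos = integer(0), n_neg = integer(0),
         pfm = list())
}

# external STREME backend: writes FASTA-like annotation files plus a custom
# alphabet definition, runs STREME with the discovery flags, and maps its
# motifs into the built-in output contract.
discover_motifs_streme <- function(positive, negative, alphabet, min_width,
                                   max_width, p_threshold, max_motifs,
                                   streme) {
  dir <- tempfile("streme")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  alph_file <- file.path(dir, "alphabet.txt")
  write_meme_alphabet(alphabet, alph_file)
  write_ann <- function(strings, path) {
    writeLines(as.vector(rbind(paste0(">s", seq_along(strings)), strings)),
               path)
  }
  posf <- file.path(dir, "pos.fa"); negf <- file.path(dir, "neg.fa")
  write_ann(positive, posf)
  write_ann(negative, negf)
  out <- file.path(dir, "out")
  status <- system2(streme, c("-p", posf, "-n", negf, "-alph", alph_file,
                              "-pvt", format(p_threshold), "-minw", min_width,
                              "-maxw", max_width, "-oc", out, "-text"),
                    stdout = file.path(dir, "streme.txt"), stderr = FALSE)
  if (status != 0) {
    abort("STREME run failed", class = "ssmotif_external_error")
  }
  motifs <- read_meme_motifs(file.path(dir, "streme.txt"),
                             alphabet_kind = alphabet$kind)
  bonferroni_cap(motifs, n_tests = max(1L, nrow(motifs)),
                 threshold = p_threshold, max_motifs = max_motifs)
}
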