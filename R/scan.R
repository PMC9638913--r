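# PFM scanning: log-odds window scores against a uniform background and the
# top-four-window-sum probe feature.

PFM_PROB_FLOOR <- 1e-3

pfm_log_odds <- function(pfm) {
  alph_size <- nrow(pfm$matrix)
  log2(pmax(pfm$matrix, PFM_PROB_FLOOR) * alph_size)
}

floor_feature <- function(width, alph_size) {
  4 * width * log2(PFM_PROB_FLOOR * alph_size)
}

#' Score one PFM window on an annotation
#'
#' Log-odds score in bits against a uniform background: the sum over window
#' positions of `log2(p(letter) / (1/|alphabet|))`, with matrix entries
#' floored at probability `1e-3` before the log so mismatches stay finite.
#'
#' @param pfm An `ss_pfm`.
#' @param annotation Annotation string over the PFM's alphabet.
#' @param pos 1-based window start; `pos + width - 1` must not exceed the
#'   annotation length.
#' @return Window score in bits.
#' @export
score_window <- function(pfm, annotation, pos) {
  stopifnot(inherits(pfm, "ss_pfm"))
  if (pos < 1 || pos + pfm$width - 1L > nchar(annotation)) {
    abort("window position out of range", class = "ssmotif_bounds_error")
  }
  logm <- pfm_log_odds(pfm)
  letters <- strsplit(substr(annotation, pos, pos + pfm$width - 1L),
                      "", fixed = TRUE)[[1]]
  idx <- match(letters, rownames(logm))
  if (anyNA(idx)) {
    abort("annotation letter outside the PFM's alphabet",
          class = "ssmotif_format_error")
  }
  sum(logm[cbind(idx, seq_len(pfm$width))])
}

#' Top-four-window-sum feature of a PFM on one probe
#'
#' Scores the PFM at every window of the annotation and returns the sum of
#' the `min(4, n_windows)` largest window scores. Annotations shorter than
#' the PFM width yield the hard floor value `4 * width * log2(1e-3 *
#' |alphabet|)` so mixed-length inputs survive scanning.
#'
#' @param pfm An `ss_pfm`.
#' @param annotation Annotation string over the PFM's alphabet.
#' @return Feature value in bits.
#' @export
probe_feature <- function(pfm, annotation) {
  stopifnot(inherits(pfm, "ss_pfm"))
  n <- nchar(annotation)
  if (n < pfm$width) {
    return(floor_feature(pfm$width, nrow(pfm$matrix)))
  }
  scores <- vapply(seq_len(n - pfm$width + 1L),
                   function(p) score_window(pfm, annotation, p), numeric(1))
  sum(sort(scores, decreasing = TRUE)[seq_len(min(4L, length(scores)))])
}

# vectorized scanner: annotations encoded once per alphabet as integer
# matrices (probes x positions), grouped by length
encode_annotations <- function(strings, alphabet) {
  idx_map <- alphabet_index(alphabet)
  lens <- nchar(strings)
  groups <- split(seq_along(strings), lens)
  purrr::map(groups, function(rows) {
    L <- nchar(strings[rows[1]])
    if (L == 0) return(list(rows = rows, mat = NULL, length = 0L))
    chars <- matrix(unlist(strsplit(strings[rows], "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = length(rows), byrow = TRUE)
    mat <- matrix(idx_map[chars], nrow = length(rows))
    if (anyNA(mat)) {
      abort("annotation letter outside the alphabet",
            class = "ssmotif_format_error")
    }
    list(rows = rows, mat = mat, length = L)
  })
}

scan_pfm_encoded <- function(pfm, encoded) {
  logm <- pfm_log_odds(pfm)
  w <- pfm$width
  out <- numeric(sum(vapply(encoded, function(g) length(g$rows), integer(1))))
  for (g in encoded) {
    if (g$length < w) {
      out[g$rows] <- floor_feature(w, nrow(pfm$matrix))
      next
    }
    n_win <- g$length - w + 1L
    W <- matrix(0, nrow = nrow(g$mat), ncol = n_win)
    for (p in seq_len(n_win)) {
      acc <- logm[g$mat[, p], 1L]
      for (j in seq_len(w - 1L)) {
        acc <- acc + logm[g$mat[, p + j], j + 1L]
      }
      W[, p] <- acc
    }
    if (n_win <= 4L) {
      out[g$rows] <- rowSums(W)
    } else {
      # top-4 row sum without per-row sorting: peel off the row maximum
      # four times
      acc <- numeric(nrow(W))
      ridx <- seq_len(nrow(W))
      for (r in 1:4) {
        j <- max.col(W, ties.method = "first")
        hit <- cbind(ridx, j)
        acc <- acc + W[hit]
        W[hit] <- -Inf
      }
      out[g$rows] <- acc
    }
  }
  out
}

#' Build the probe-by-motif feature matrix
#'
#' Computes the top-four-window-sum feature of every PFM on every probe, each
#' PFM scored on the probe annotation matching its alphabet. Columns follow a
#' deterministic order: alphabet kinds in canonical order, then discovery
#' rank within each alphabet.
#'
#' @param motifs Motif tibble from [discover_motifs()] (rows may span several
#'   alphabets).
#' @param probes Annotated probe tibble from [annotate_probes()].
#' @param label Optional label column name carried through (e.g. `"label"`).
#' @return Tibble with `probe_id` (generated if absent), the optional label
#'   column, and one numeric feature column per PFM named by its motif id.
#' @export
build_feature_matrix <- function(motifs, probes, label = NULL) {
  stopifnot(is.data.frame(motifs), is.data.frame(probes))
  out <- tibble(probe_id = probes$probe_id %||%
                  sprintf("probe_%05d", seq_len(nrow(probes))))
  if (!is.null(label)) out[[label]] <- probes[[label]]
  if (nrow(motifs) == 0) return(out)
  kinds <- intersect(alphabet_kinds(), unique(motifs$alphabet))
  for (kind in kinds) {
    col <- ANNOTATION_COLS[[kind]]
    if (!col %in% names(probes)) {
      abort(sprintf("probes lack the %s annotation column '%s'", kind, col),
            class = "ssmotif_format_error")
    }
    alph <- ss_alphabet(kind)
    encoded <- encode_annotations(probes[[col]], alph)
    sub <- motifs[motifs$alphabet == kind, ]
    for (i in seq_len(nrow(sub))) {
      out[[sub$motif[i]]] <- scan_pfm_encoded(sub$pfm[[i]], encoded)
    }
  }
  out
}

feature_columns <- function(features) {
  setdiff(names(features), c("probe_id", "label", "split"))
}
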