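# Per-probe annotation under all seven alphabets.

ANNOTATION_COLS <- c(
  sequence = "ann_sequence", structure2 = "ann_structure2",
  structure4 = "ann_structure4", structure7 = "ann_structure7",
  seqstruct8 = "ann_seqstruct8", seqstruct16 = "ann_seqstruct16",
  seqstruct28 = "ann_seqstruct28"
)

normalize_rna <- function(seq) {
  chartr("Tt", "Uu", toupper(seq))
}

#' Annotate one probe under all seven alphabets
#'
#' Classifies the structural context of every base from the dot-bracket of
#' the full (flanked) probe and emits the seven annotation strings: sequence;
#' structure at two-, four- and seven-letter granularity; and the three
#' sequence-structure products. Probes are folded in full but only the
#' variable region is annotated: each returned string is trimmed to
#' `variable_region`.
#'
#' @param seq Full probe RNA sequence (flanks included); `T` is normalized to
#'   `U` on read.
#' @param db Dot-bracket string for the full probe.
#' @param variable_region Integer `c(start, end)`, 1-based inclusive, within
#'   the probe. Defaults to the whole probe.
#' @return Named list of seven annotation strings, names as in
#'   [alphabet_kinds()].
#' @examples
#' annotate_probe("GGACGUCC", "((....))", variable_region = c(3, 6))
#' @export
annotate_probe <- function(seq, db, variable_region = NULL) {
  seq <- normalize_rna(seq)
  if (nchar(seq) != nchar(db)) {
    abort("sequence and dot-bracket differ in length",
          class = "ssmotif_format_error")
  }
  if (is.null(variable_region)) variable_region <- c(1L, nchar(seq))
  vr <- as.integer(variable_region)
  if (length(vr) != 2 || anyNA(vr) || vr[1] < 1 || vr[2] > nchar(seq) || vr[1] > vr[2]) {
    abort("variable_region out of bounds", class = "ssmotif_bounds_error")
  }
  s7 <- classify_contexts(db)
  s4 <- project_structure(s7, "structure4")
  s2 <- project_structure(s7, "structure2")
  trim <- function(x) substr(x, vr[1], vr[2])
  vseq <- trim(seq)
  if (!grepl("^[ACGU]*$", vseq)) {
    abort("sequence contains non-ACGU letters in the variable region",
          class = "ssmotif_format_error")
  }
  list(
    sequence = vseq,
    structure2 = trim(s2),
    structure4 = trim(s4),
    structure7 = trim(s7),
    seqstruct8 = combine_annotation(vseq, trim(s2), "structure2"),
    seqstruct16 = combine_annotation(vseq, trim(s4), "structure4"),
    seqstruct28 = combine_annotation(vseq, trim(s7), "structure7")
  )
}

#' Annotate a probe table under all seven alphabets
#'
#' Data-frame interface over [annotate_probe()]. The input must carry
#' `sequence` and `dotbracket` columns holding the full (flanked) probe and
#' its structure; seven `ann_*` columns are appended, each trimmed to the
#' variable region.
#'
#' @param probes A data frame with `sequence` and `dotbracket` columns.
#' @param flank5,flank3 Constant flank sequences present at the ends of
#'   `sequence`. When given, the variable region defaults to the interval
#'   between them.
#' @param variable_region Optional explicit `c(start, end)` (1-based,
#'   inclusive) overriding the flank-derived interval; applied to every probe.
#' @return The input as a tibble with columns `ann_sequence`,
#'   `ann_structure2`, `ann_structure4`, `ann_structure7`, `ann_seqstruct8`,
#'   `ann_seqstruct16`, `ann_seqstruct28` appended.
#' @examples
#' probes <- tibble::tibble(sequence = "GGACGUCC", dotbracket = "((....))")
#' annotate_probes(probes, flank5 = "GG", flank3 = "CC")
#' @export
annotate_probes <- function(probes, flank5 = "", flank3 = "",
                            variable_region = NULL) {
  stopifnot(is.data.frame(probes),
            all(c("sequence", "dotbracket") %in% names(probes)))
  probes <- as_tibble(probes)
  n5 <- nchar(flank5)
  n3 <- nchar(flank3)
  anns <- purrr::map2(probes$sequence, probes$dotbracket, function(s, d) {
    vr <- variable_region %||% c(n5 + 1L, nchar(s) - n3)
    annotate_probe(s, d, vr)
  })
  for (kind in alphabet_kinds()) {
    probes[[ANNOTATION_COLS[[kind]]]] <-
      vapply(anns, function(a) a[[kind]], character(1))
  }
  probes
}
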