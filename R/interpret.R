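# Structure-specificity metrics derived from the retained motif weights, and
# the ranked motif report.

#' Per-alphabet share of the total model weight
#'
#' For each of the seven annotation alphabets, the sum of absolute
#' coefficients over its retained PFMs divided by the sum over all retained
#' PFMs. A model whose retained motifs are all primary-sequence PFMs has a
#' sequence share of 1.
#'
#' @param model An `ss_model` with at least one nonzero coefficient.
#' @return Tibble with `alphabet` (all seven kinds, canonical order) and
#'   `weight_proportion` columns; proportions sum to 1.
#' @export
alphabet_weight_proportions <- function(model) {
  stopifnot(inherits(model, "ss_model"))
  if (length(model$coefficients) == 0) {
    abort("model has no nonzero coefficients; weight proportions are undefined",
          class = "ssmotif_undefined_report")
  }
  w <- abs(model$coefficients)
  by_alph <- tapply(w, factor(model$pfms$alphabet, levels = alphabet_kinds()),
                    sum, default = 0)
  tibble(alphabet = alphabet_kinds(),
         weight_proportion = as.numeric(by_alph) / sum(w))
}

# column information content (bits) of a PFM: log2|A| - H(column)
pfm_information_content <- function(pfm) {
  p <- pfm$matrix
  h <- apply(p, 2, function(col) {
    nz <- col[col > 0]
    -sum(nz * log2(nz))
  })
  log2(nrow(p)) - h
}

# share of a PFM's information content attributed to paired-context symbols:
# each column's IC weighted by its probability mass on paired symbols
pfm_paired_share <- function(pfm) {
  alph <- ss_alphabet(pfm$alphabet)
  paired <- alph$decomposition$paired
  if (!any(paired)) return(0)
  ic <- pfm_information_content(pfm)
  if (sum(ic) == 0) return(0)
  paired_mass <- colSums(pfm$matrix[paired, , drop = FALSE])
  sum(ic * paired_mass) / sum(ic)
}

#' Fraction of model weight attributed to paired bases
#'
#' For every structure-inclusive retained PFM, the information content of
#' each column is split between paired- and unpaired-context symbols in
#' proportion to their probability mass (paired contexts: `P` in the two- and
#' four-letter structure alphabets, `L`/`R` in the seven-letter alphabet);
#' the PFM's paired share of information content is then multiplied by the
#' weight placed on the PFM. Sequence-only PFMs contribute a paired share of
#' zero.
#'
#' @param model An `ss_model` with at least one nonzero coefficient.
#' @return Fraction in `[0, 1]`.
#' @export
paired_weight_fraction <- function(model) {
  stopifnot(inherits(model, "ss_model"))
  if (length(model$coefficients) == 0) {
    abort("model has no nonzero coefficients; paired fraction is undefined",
          class = "ssmotif_undefined_report")
  }
  w <- abs(model$coefficients)
  shares <- vapply(model$pfms$pfm, pfm_paired_share, numeric(1))
  sum(w * shares) / sum(w)
}

#' Structure-specificity report
#'
#' Combines the per-alphabet weight proportions with the paired/unpaired
#' decomposition of structure-inclusive motif weight: `sequence` (weight on
#' sequence-only PFMs), `paired` and `unpaired` (structure-inclusive weight
#' split by each PFM's paired information-content share). The three fractions
#' sum to 1.
#'
#' @param model An `ss_model` with at least one nonzero coefficient.
#' @return List with `per_alphabet` (tibble), `sequence_weight_fraction`,
#'   `paired_weight_fraction`, `unpaired_weight_fraction`, and
#'   `per_pfm` (tibble: motif, alphabet, weight share, paired IC share).
#' @export
structure_specificity <- function(model) {
  per_alphabet <- alphabet_weight_proportions(model)
  w <- abs(model$coefficients)
  shares <- vapply(model$pfms$pfm, pfm_paired_share, numeric(1))
  is_seq <- model$pfms$alphabet == "sequence"
  seq_frac <- sum(w[is_seq]) / sum(w)
  paired_frac <- sum(w * shares) / sum(w)
  unpaired_frac <- sum(w[!is_seq] * (1 - shares[!is_seq])) / sum(w)
  list(
    per_alphabet = per_alphabet,
    sequence_weight_fraction = seq_frac,
    paired_weight_fraction = paired_frac,
    unpaired_weight_fraction = unpaired_frac,
    per_pfm = tibble(motif = model$pfms$motif, alphabet = model$pfms$alphabet,
                     weight_share = as.numeric(w / sum(w)),
                     paired_ic_share = shares)
  )
}

#' Ranked motif report
#'
#' Retained PFMs sorted by descending weight proportion, with alphabet tags,
#' consensus strings, coefficient signs and logo-ready matrices. Weight
#' proportions are rounded to three decimals in the printed column; the exact
#' values are kept alongside.
#'
#' @param model An `ss_model`.
#' @return Tibble with `rank`, `motif`, `alphabet`, `consensus`, `width`,
#'   `weight` (printed, 3 decimals), `weight_proportion`, `coefficient` and a
#'   `matrix` list-column. Empty models yield an empty report with a warning.
#' @export
motif_report <- function(model) {
  stopifnot(inherits(model, "ss_model"))
  if (length(model$coefficients) == 0) {
    warn("model retains no motifs; report is empty")
    return(tibble(rank = integer(0), motif = character(0),
                  alphabet = character(0), consensus = character(0),
                  width = integer(0), weight = numeric(0),
                  weight_proportion = numeric(0), coefficient = numeric(0),
                  matrix = list()))
  }
  td <- tidy(model)
  mats <- purrr::map(model$pfms$pfm, "matrix")
  td |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      weight = round(.data$weight_proportion, 3),
      matrix = mats[match(.data$motif, model$pfms$motif)]
    ) |>
    dplyr::select("rank", "motif", "alphabet", "consensus", "width",
                  "weight", "weight_proportion", "coefficient", "matrix")
}

#' Plot per-alphabet weight proportions
#'
#' @param model An `ss_model`.
#' @return A ggplot bar chart of the seven alphabet weight shares.
#' @export
plot_alphabet_weights <- function(model) {
  pw <- alphabet_weight_proportions(model)
  pw$alphabet <- factor(pw$alphabet, levels = alphabet_kinds())
  ggplot2::ggplot(pw, ggplot2::aes(x = .data$alphabet,
                                   y = .data$weight_proportion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of model weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Information-content logo data for one motif
#'
#' Per-position, per-symbol letter heights (probability times column
#' information content), ready for a stacked-bar logo.
#'
#' @param pfm An `ss_pfm`.
#' @return Tibble with `position`, `symbol`, `probability`, `ic_height`.
#' @export
logo_data <- function(pfm) {
  stopifnot(inherits(pfm, "ss_pfm"))
  ic <- pfm_information_content(pfm)
  tidyr::expand_grid(position = seq_len(pfm$width),
                     symbol = rownames(pfm$matrix)) |>
    dplyr::mutate(
      probability = pfm$matrix[cbind(.data$symbol, .data$position)],
      ic_height = .data$probability * ic[.data$position]
    )
}
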