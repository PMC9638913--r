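# File formats: FASTA probes, Vienna-style structure files, MEME minimal
# motif files, JSON model documents.

#' Read probe sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Tibble with `probe_id` and `sequence` columns; `T` is normalized
#'   to `U`.
#' @export
read_fasta_probes <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "ssmotif_io_error")
  }
  x <- Biostrings::readBStringSet(path)
  tibble(
    probe_id = sub("\\s.*$", "", names(x)),
    sequence = unname(normalize_rna(as.character(x)))
  )
}

#' Write probe sequences to a FASTA file
#'
#' @param probes Tibble with `probe_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_probes <- function(probes, path) {
  x <- Biostrings::BStringSet(setNames(probes$sequence, probes$probe_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a Vienna-style structure file
#'
#' Parses the alternating sequence / dot-bracket record layout emitted by
#' standard RNA folding tools: an optional `>identifier` line, the sequence
#' line, then the structure line (a trailing free-energy suffix such as
#' `( -3.20)` is tolerated and stripped).
#'
#' @param path Structure file path.
#' @return Tibble with `probe_id`, `sequence` and `dotbracket` columns.
#' @export
read_vienna <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "ssmotif_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(0); seqs <- character(0); dbs <- character(0)
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    rec <- rec + 1L
    if (startsWith(lines[i], ">")) {
      ids <- c(ids, trimws(sub("^>", "", lines[i])))
      i <- i + 1L
    } else {
      ids <- c(ids, sprintf("probe_%05d", rec))
    }
    if (i + 1L > length(lines)) {
      abort("truncated structure record", class = "ssmotif_format_error")
    }
    seqs <- c(seqs, normalize_rna(trimws(lines[i])))
    db <- trimws(lines[i + 1L])
    db <- sub("\\s+\\(.*$", "", db)  # strip free-energy suffix "( -1.20 ...)"
    dbs <- c(dbs, db)
    i <- i + 2L
  }
  out <- tibble(probe_id = ids, sequence = seqs, dotbracket = dbs)
  bad <- nchar(out$sequence) != nchar(out$dotbracket)
  if (any(bad)) {
    abort("sequence/structure length mismatch in structure file",
          class = "ssmotif_format_error")
  }
  out
}

#' Write a Vienna-style structure file
#'
#' @param probes Tibble with `probe_id`, `sequence`, `dotbracket` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(probes, path) {
  lines <- as.vector(rbind(paste0(">", probes$probe_id),
                           probes$sequence, probes$dotbracket))
  writeLines(lines, path)
  invisible(path)
}

#' Write motifs in MEME minimal format
#'
#' Emits a MEME minimal motif file with a custom alphabet header so motifs
#' over structure or sequence-structure alphabets remain self-describing.
#'
#' @param motifs Motif tibble as returned by [discover_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path) {
  stopifnot(is.data.frame(motifs))
  kinds <- unique(motifs$alphabet)
  if (length(kinds) > 1) {
    abort("one MEME file holds motifs over a single alphabet",
          class = "ssmotif_format_error")
  }
  alph <- ss_alphabet(kinds)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               sprintf("ALPHABET \"%s\"", alph$kind),
               paste0(alph$symbols, " \"", alphabet_symbol_names(alph), "\""),
               "END ALPHABET", ""), con)
  for (i in seq_len(nrow(motifs))) {
    pfm <- motifs$pfm[[i]]
    writeLines(sprintf("MOTIF %s", motifs$motif[i]), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= %d w= %d nsites= %d E= %g",
      alph$size, pfm$width, pfm$n_sites, motifs$p_adjusted[i]), con)
    writeLines(apply(pfm$matrix, 2, function(col) {
      paste(sprintf("%.6f", col), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal file written by [write_meme_motifs()]
#'
#' @param path MEME minimal motif file path.
#' @param alphabet_kind Alphabet the motifs are defined over (the custom
#'   alphabet header records the kind; this argument overrides it).
#' @return Motif tibble in the [discover_motifs()] layout (discovery
#'   p-values carry the stored E-values; `n_pos`/`n_neg` are not preserved
#'   by the format and are `NA`).
#' @export
read_meme_motifs <- function(path, alphabet_kind = NULL) {
  lines <- readLines(path)
  if (is.null(alphabet_kind)) {
    al <- grep("^ALPHABET ", lines, value = TRUE)[1]
    alphabet_kind <- gsub("^ALPHABET \"|\"$", "", al)
  }
  alph <- ss_alphabet(alphabet_kind)
  starts <- grep("^MOTIF ", lines)
  rows <- purrr::map(starts, function(s) {
    id <- sub("^MOTIF ", "", lines[s])
    hdr <- lines[s + 1L]
    w <- as.integer(sub(".* w= *(\\d+).*", "\\1", hdr))
    nsites <- as.integer(sub(".* nsites= *(\\d+).*", "\\1", hdr))
    ev <- as.numeric(sub(".* E= *([-+eE0-9.]+).*", "\\1", hdr))
    mat <- vapply(lines[(s + 2L):(s + 1L + w)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }, numeric(alph$size))
    mat <- sweep(mat, 2, colSums(mat), "/")  # undo fixed-precision rounding
    dimnames(mat) <- list(alph$symbols, NULL)
    pfm <- new_ss_pfm(id, alphabet_kind, mat, p_value = ev, p_adjusted = ev,
                      n_sites = nsites)
    tibble(motif = id, alphabet = alphabet_kind, width = w,
           consensus = pfm$consensus, p_value = ev, p_adjusted = ev,
           n_pos = NA_integer_, n_neg = NA_integer_, pfm = list(pfm))
  })
  dplyr::bind_rows(rows)
}

#' Serialize a fitted model to a JSON document
#'
#' Stores retained PFMs (matrices and alphabets), regression coefficients,
#' standardization statistics, AUROCs, the simplification trace and the run
#' configuration in one machine-readable file, from which the model can be
#' reconstructed exactly.
#'
#' @param model An `ss_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "ss_model"))
  pfms <- purrr::map(seq_len(nrow(model$pfms)), function(i) {
    p <- model$pfms$pfm[[i]]
    list(motif = p$id, alphabet = p$alphabet, width = p$width,
         consensus = p$consensus, p_value = p$p_value,
         p_adjusted = p$p_adjusted, n_sites = p$n_sites,
         matrix = unname(t(p$matrix)))
  })
  doc <- list(
    format = "ssmotif-model",
    version = 1L,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    l1_strength = model$l1_strength,
    initial_l1_strength = model$initial_l1_strength,
    initial_auroc = model$initial_auroc,
    final_auroc = model$final_auroc,
    center = as.list(model$center),
    scale = as.list(model$scale),
    trace = model$trace,
    config = model$config,
    seed = model$seed,
    pfms = pfms
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model serialized by [write_model_json()]
#'
#' @param path JSON model path.
#' @return An `ss_model`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "ssmotif-model")) {
    abort("not an ssmotif model document", class = "ssmotif_format_error")
  }
  pf <- doc$pfms
  rows <- purrr::map(seq_len(length(pf$motif)), function(i) {
    mat <- t(pf$matrix[[i]])
    alph <- ss_alphabet(pf$alphabet[i])
    rownames(mat) <- alph$symbols
    pfm <- new_ss_pfm(pf$motif[i], pf$alphabet[i], mat,
                      p_value = pf$p_value[i], p_adjusted = pf$p_adjusted[i],
                      n_sites = pf$n_sites[i])
    tibble(motif = pf$motif[i], alphabet = pf$alphabet[i],
           width = pfm$width, consensus = pfm$consensus,
           p_value = pf$p_value[i], p_adjusted = pf$p_adjusted[i],
           n_pos = NA_integer_, n_neg = NA_integer_, pfm = list(pfm))
  })
  new_ss_model(
    pfms = dplyr::bind_rows(rows),
    coefficients = unlist(doc$coefficients),
    intercept = doc$intercept,
    l1_strength = doc$l1_strength,
    initial_l1_strength = doc$initial_l1_strength,
    initial_auroc = doc$initial_auroc,
    final_auroc = doc$final_auroc,
    center = unlist(doc$center),
    scale = unlist(doc$scale),
    trace = as_tibble(doc$trace),
    config = doc$config,
    seed = doc$seed
  )
}
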