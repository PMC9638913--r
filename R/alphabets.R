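# Seven probe-annotation alphabets: primary sequence, secondary-structure
# context at three granularities, and the nucleotide x context products.

SEQ_SYMBOLS <- c("A", "C", "G", "U")
S7_SYMBOLS <- c("E", "B", "L", "R", "T", "M", "H")
S4_SYMBOLS <- c("P", "L", "U", "M")
S2_SYMBOLS <- c("U", "P")

# structure7 -> structure4 / structure2 letterwise projections
PROJ_7_TO_4 <- c(L = "P", R = "P", H = "L", E = "U", B = "M", T = "M", M = "M")
PROJ_7_TO_2 <- c(L = "P", R = "P", H = "U", E = "U", B = "U", T = "U", M = "U")

# paired-context letters per structure alphabet
PAIRED_LETTERS <- list(structure2 = "P", structure4 = "P", structure7 = c("L", "R"))

# symbol pool for product alphabets; single printable characters, assigned in
# a fixed (context-major, nucleotide-minor) order so annotations stay strings
PRODUCT_POOL <- c(LETTERS, letters, as.character(0:9))

#' Alphabet kinds in canonical order
#'
#' The seven annotation alphabets, in the fixed order used for feature-matrix
#' columns and reports: primary sequence, the three structure-only alphabets
#' from coarse to fine, then the three sequence-structure product alphabets.
#'
#' @return Character vector of the seven kind names.
#' @export
alphabet_kinds <- function() {
  c("sequence", "structure2", "structure4", "structure7",
    "seqstruct8", "seqstruct16", "seqstruct28")
}

struct_kind_of_product <- function(kind) {
  switch(kind,
    seqstruct8 = "structure2",
    seqstruct16 = "structure4",
    seqstruct28 = "structure7",
    abort(sprintf("'%s' is not a product alphabet kind", kind))
  )
}

struct_symbols_of <- function(kind) {
  switch(kind,
    structure2 = S2_SYMBOLS,
    structure4 = S4_SYMBOLS,
    structure7 = S7_SYMBOLS,
    abort(sprintf("'%s' is not a structure alphabet kind", kind))
  )
}

#' Construct an annotation alphabet
#'
#' Builds one of the seven probe-annotation alphabets. Product alphabets
#' (`seqstruct8`, `seqstruct16`, `seqstruct28`) assign one printable symbol to
#' each (nucleotide, structure context) combination; the decomposition is kept
#' on the object so combined annotations can be traced back to their sequence
#' and structure parts.
#'
#' @param kind One of [alphabet_kinds()].
#' @return An object of class `ss_alphabet` with fields `kind`, `symbols`,
#'   `size`, a `decomposition` tibble (`symbol`, `nt`, `struct`, `paired`),
#'   and for product alphabets a named lookup `combine` from "nt|struct" keys
#'   to product symbols.
#' @examples
#' ss_alphabet("seqstruct8")
#' @export
ss_alphabet <- function(kind = alphabet_kinds()) {
  kind <- match.arg(kind)
  cached <- .alphabet_cache[[kind]]
  if (!is.null(cached)) return(cached)
  built <- build_alphabet(kind)
  assign(kind, built, envir = .alphabet_cache)
  built
}

.alphabet_cache <- new.env(parent = emptyenv())

build_alphabet <- function(kind) {
  if (kind == "sequence") {
    symbols <- SEQ_SYMBOLS
    decomp <- tibble(symbol = symbols, nt = symbols,
                     struct = NA_character_, paired = FALSE)
    combine <- NULL
  } else if (kind %in% c("structure2", "structure4", "structure7")) {
    symbols <- struct_symbols_of(kind)
    decomp <- tibble(symbol = symbols, nt = NA_character_, struct = symbols,
                     paired = symbols %in% PAIRED_LETTERS[[kind]])
    combine <- NULL
  } else {
    skind <- struct_kind_of_product(kind)
    ssym <- struct_symbols_of(skind)
    grid <- expand.grid(nt = SEQ_SYMBOLS, struct = ssym,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    symbols <- PRODUCT_POOL[seq_len(nrow(grid))]
    decomp <- tibble(symbol = symbols, nt = grid$nt, struct = grid$struct,
                     paired = grid$struct %in% PAIRED_LETTERS[[skind]])
    combine <- setNames(symbols, paste(grid$nt, grid$struct, sep = "|"))
  }
  structure(
    list(kind = kind, symbols = symbols, size = length(symbols),
         decomposition = decomp, combine = combine),
    class = "ss_alphabet"
  )
}

#' @export
print.ss_alphabet <- function(x, ...) {
  cat(sprintf("<ss_alphabet> %s (%d symbols): %s\n",
              x$kind, x$size, paste(x$symbols, collapse = "")))
  invisible(x)
}

#' Write a MEME-suite custom alphabet definition
#'
#' Emits an alphabet definition file in the MEME custom-alphabet format, as
#' required to run external motif discovery tools on structure or
#' sequence-structure annotations.
#'
#' @param alphabet An [ss_alphabet()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meme_alphabet <- function(alphabet, path) {
  stopifnot(inherits(alphabet, "ss_alphabet"))
  lines <- c("ALPHABET \"%s\"" |> sprintf(alphabet$kind),
             paste0(alphabet$symbols, " \"",
                    alphabet_symbol_names(alphabet), "\""))
  writeLines(lines, path)
  invisible(path)
}

alphabet_symbol_names <- function(alphabet) {
  d <- alphabet$decomposition
  dplyr::case_when(
    is.na(d$struct) ~ d$nt,
    is.na(d$nt) ~ paste0("context_", d$struct),
    TRUE ~ paste0(d$nt, "_in_", d$struct)
  )
}

# fast symbol -> index map for encoding annotation strings
alphabet_index <- function(alphabet) {
  setNames(seq_len(alphabet$size), alphabet$symbols)
}
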