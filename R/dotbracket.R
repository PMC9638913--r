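# Dot-bracket parsing and per-base structural-context classification.

#' Parse a dot-bracket string into a base-pair table
#'
#' Matches parentheses under stack discipline. Only the plain `(`, `)` and `.`
#' characters are accepted: centroid structures from standard RNA folding
#' carry no pseudoknot bracket layers, and inputs containing them are rejected
#' rather than silently misread.
#'
#' @param db Dot-bracket string.
#' @return Integer vector, one element per base: the 1-based index of the
#'   pairing partner, or `NA` for unpaired bases. The matching is symmetric.
#' @examples
#' parse_dotbracket("((..))")
#' @export
parse_dotbracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1, !is.na(db))
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad) > 0) {
    abort(sprintf("illegal character(s) in dot-bracket string: %s",
                  paste(dQuote(bad, FALSE), collapse = ", ")),
          class = "ssmotif_format_error")
  }
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) {
        abort("unbalanced dot-bracket string: unmatched ')'",
              class = "ssmotif_malformed_structure")
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0) {
    abort("unbalanced dot-bracket string: unmatched '('",
          class = "ssmotif_malformed_structure")
  }
  partner
}

#' Classify every base into one of seven structural contexts
#'
#' Decomposes the structure into loops and labels each base: `L`/`R` for the
#' left/right strands of a helix, `E` for unpaired external bases, `H` for
#' hairpin loops (no enclosed helix), `M` for multiloops (two or more enclosed
#' helices), and for loops enclosing exactly one helix `B` (bulge: unpaired
#' bases on one side of the stem only) or `T` (internal loop: unpaired bases
#' on both sides).
#'
#' @param db Dot-bracket string.
#' @return A string over `{E,B,L,R,T,M,H}` of the same length as `db`.
#' @examples
#' classify_contexts("((((....))))")
#' classify_contexts("((.((....))))")
#' @export
classify_contexts <- function(db) {
  partner <- parse_dotbracket(db)
  n <- length(partner)
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  out <- character(n)
  out[chars == "("] <- "L"
  out[chars == ")"] <- "R"

  # walk the loop delimited by closing pair (i, j); i = 0/j = n + 1 walks the
  # exterior. Members: unpaired positions directly inside, skipping children.
  label_loop <- function(i, j, exterior = FALSE) {
    unpaired <- integer(0)
    children <- integer(0)   # child helix start positions
    gaps <- integer(0)       # unpaired run length before each child / close
    run <- 0L
    k <- i + 1L
    while (k <= j - 1L) {
      if (is.na(partner[k])) {
        unpaired <- c(unpaired, k)
        run <- run + 1L
        k <- k + 1L
      } else {
        children <- c(children, k)
        gaps <- c(gaps, run)
        run <- 0L
        k <- partner[k] + 1L
      }
    }
    gaps <- c(gaps, run)  # trailing unpaired run
    label <-
      if (exterior) "E"
      else if (length(children) == 0) "H"
      else if (length(children) >= 2) "M"
      else if (gaps[1] > 0 && gaps[2] > 0) "T"
      else "B"
    out[unpaired] <<- label
    children
  }

  # breadth-first over loops starting from the exterior
  queue <- label_loop(0L, n + 1L, exterior = TRUE)
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    queue <- c(queue, label_loop(i, partner[i]))
  }
  paste(out, collapse = "")
}

#' Project a seven-letter structure annotation to a coarser alphabet
#'
#' Letterwise projection: to the four-letter alphabet `L,R -> P` (paired),
#' `H -> L` (hairpin loop), `E -> U` (unpaired/external) and `B,T,M -> M`
#' (bulge/internal/multi loop); to the two-letter alphabet `L,R -> P` and all
#' other letters to `U`.
#'
#' @param s7 String over `{E,B,L,R,T,M,H}`.
#' @param granularity `"structure4"` or `"structure2"`.
#' @return Projected structure string.
#' @examples
#' project_structure("LLLLHHHHRRRR", "structure4")
#' @export
project_structure <- function(s7, granularity = c("structure4", "structure2")) {
  granularity <- match.arg(granularity)
  chars <- strsplit(s7, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), S7_SYMBOLS)
  if (length(bad) > 0) {
    abort(sprintf("unknown structure7 letter(s): %s", paste(bad, collapse = ", ")),
          class = "ssmotif_format_error")
  }
  map <- if (granularity == "structure4") PROJ_7_TO_4 else PROJ_7_TO_2
  paste(map[chars], collapse = "")
}

#' Combine sequence and structure annotations into a product annotation
#'
#' Maps position `i` to the product symbol for `(seq[i], struct[i])` under the
#' corresponding 8-, 16- or 28-letter sequence-structure alphabet.
#'
#' @param seq RNA string over `A,C,G,U`.
#' @param struct Structure annotation of equal length, over the two-, four- or
#'   seven-letter structure alphabet.
#' @param struct_kind Which structure alphabet `struct` uses; one of
#'   `"structure2"`, `"structure4"`, `"structure7"`.
#' @return Product-alphabet annotation string.
#' @examples
#' combine_annotation("ACGU", "EHLR", "structure7")
#' @export
combine_annotation <- function(seq, struct,
                               struct_kind = c("structure2", "structure4", "structure7")) {
  struct_kind <- match.arg(struct_kind)
  if (nchar(seq) != nchar(struct)) {
    abort("sequence and structure annotations differ in length",
          class = "ssmotif_format_error")
  }
  if (nchar(seq) == 0) return("")
  kind <- switch(struct_kind, structure2 = "seqstruct8",
                 structure4 = "seqstruct16", structure7 = "seqstruct28")
  alph <- ss_alphabet(kind)
  keys <- paste(strsplit(seq, "", fixed = TRUE)[[1]],
                strsplit(struct, "", fixed = TRUE)[[1]], sep = "|")
  sym <- alph$combine[keys]
  if (anyNA(sym)) {
    abort("sequence/structure letters outside their alphabets",
          class = "ssmotif_format_error")
  }
  paste(sym, collapse = "")
}
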