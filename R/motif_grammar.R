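# Motif pattern grammar: dash-separated positional tokens, "/" for residue
# alternatives, "X"/"x" for a wildcard position. One position is the
# phospho-acceptor (S, T or Y).

#' @keywords internal
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
.ACCEPTOR_RESIDUES <- c("S", "T", "Y")

#' @keywords internal
.GAP <- "-"

.is_wildcard <- function(set) identical(set, "X")

#' Parse a phosphomotif pattern string
#'
#' Parses a PROSITE-like positional pattern such as `"S/T-P"` or
#' `"R-X-X-S/T"` into a `motif_pattern` object. Tokens are separated by
#' `-`; a token is either the wildcard `X` (any residue, but never a gap)
#' or one-letter amino-acid codes joined by `/`. Parsing is
#' case-insensitive.
#'
#' The phospho-acceptor position is, by default, the first position whose
#' residue set is a non-empty subset of \{S, T, Y\}; it can be overridden
#' with `acceptor_index` for motifs that contain several such positions.
#'
#' @param text Pattern string, e.g. `"R-X-X-S/T"`.
#' @param motif_id Label for the motif; defaults to the pattern text.
#' @param acceptor_index Optional 0-based index of the acceptor position.
#' @return An object of class `motif_pattern` with elements `motif_id`,
#'   `raw`, `positions` (list of residue sets; a wildcard is stored as
#'   `"X"`) and `acceptor_offset` (0-based).
#' @examples
#' p <- parse_motif_pattern("R-X-X-S/T")
#' p$acceptor_offset  # 3
#' @export
parse_motif_pattern <- function(text, motif_id = text, acceptor_index = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("motif '", motif_id, "': pattern must be a non-empty string")
  tokens <- strsplit(text, "-", fixed = TRUE)[[1L]]
  if (length(tokens) == 0L || any(!nzchar(tokens)))
    stop("motif '", motif_id, "': empty token in pattern '", text, "'")
  positions <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- toupper(tokens[[i]])
    if (tok == "X") {
      positions[[i]] <- "X"
      next
    }
    set <- strsplit(tok, "/", fixed = TRUE)[[1L]]
    if (length(set) == 0L || any(!nzchar(set)))
      stop("motif '", motif_id, "': empty alternative in token '",
           tokens[[i]], "'")
    bad <- setdiff(set, .AA20)
    if (length(bad))
      stop("motif '", motif_id, "': unknown residue code '", bad[[1L]],
           "' in token '", tokens[[i]], "'")
    positions[[i]] <- unique(set)
  }
  is_acceptor_set <- vapply(positions, function(s) {
    !.is_wildcard(s) && all(s %in% .ACCEPTOR_RESIDUES)
  }, logical(1L))
  if (is.null(acceptor_index)) {
    if (!any(is_acceptor_set))
      stop("motif '", motif_id, "': no acceptor (S/T/Y) position in '",
           text, "'")
    acceptor_offset <- which(is_acceptor_set)[[1L]] - 1L
  } else {
    acceptor_offset <- as.integer(acceptor_index)
    if (is.na(acceptor_offset) || acceptor_offset < 0L ||
        acceptor_offset >= length(positions))
      stop("motif '", motif_id, "': acceptor_index ", acceptor_index,
           " out of range for pattern '", text, "'")
    if (!is_acceptor_set[[acceptor_offset + 1L]])
      stop("motif '", motif_id, "': position ", acceptor_index,
           " is not an S/T/Y residue set")
  }
  structure(
    list(motif_id = motif_id, raw = text, positions = positions,
         acceptor_offset = acceptor_offset),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$motif_id, ": ", x$raw,
      " (acceptor offset ", x$acceptor_offset, ", length ",
      length(x$positions), ")\n", sep = "")
  invisible(x)
}

# Core matcher over a pre-split character vector. `pos` indexes `chars`
# directly, so it works both on ungapped sequences (residue coordinates)
# and on aligned rows (column coordinates).
.match_at_chars <- function(positions, acceptor_offset, chars, pos) {
  idx <- pos + seq_along(positions) - 1L - acceptor_offset
  if (idx[[1L]] < 1L || idx[[length(idx)]] > length(chars))
    return(FALSE)
  res <- chars[idx]
  .window_satisfies(res, positions)
}

# A residue window satisfies a pattern iff every position is non-gap and
# each non-wildcard position's residue lies in that position's residue set.
.window_satisfies <- function(res, positions) {
  if (anyNA(res) || any(res == .GAP))
    return(FALSE)
  for (i in seq_along(positions)) {
    set <- positions[[i]]
    if (.is_wildcard(set)) next
    if (!(res[[i]] %in% set)) return(FALSE)
  }
  TRUE
}

#' Test a motif match at a given acceptor position
#'
#' Returns `TRUE` iff placing the pattern's acceptor on `acceptor_pos`
#' puts every pattern position on an existing, non-gap residue that lies
#' in that position's residue set (wildcards accept any non-gap residue).
#' Windows running off either end of the sequence return `FALSE`.
#'
#' @param pattern A `motif_pattern`.
#' @param sequence Residue string (upper-cased internally).
#' @param acceptor_pos 1-based position of the putative acceptor.
#' @return Logical scalar.
#' @examples
#' match_at(parse_motif_pattern("R-X-X-S/T"), "MRPGSAP", 5)  # TRUE
#' @export
match_at <- function(pattern, sequence, acceptor_pos) {
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  .match_at_chars(pattern$positions, pattern$acceptor_offset, chars,
                  as.integer(acceptor_pos))
}

#' Enumerate all motif matches along a sequence
#'
#' @param pattern A `motif_pattern`.
#' @param sequence Non-empty residue string.
#' @return Sorted integer vector of 1-based acceptor positions at which
#'   [match_at()] is `TRUE`.
#' @examples
#' scan_sequence(parse_motif_pattern("S/T-P"), "SPSPA")  # c(1, 3)
#' @export
scan_sequence <- function(pattern, sequence) {
  stopifnot(inherits(pattern, "motif_pattern"), nzchar(sequence))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  hits <- vapply(seq_along(chars), function(p) {
    .match_at_chars(pattern$positions, pattern$acceptor_offset, chars, p)
  }, logical(1L))
  which(hits)
}

#' Classify a motif pattern by its structural context
#'
#' Flags the two structural classes whose conservation behaviour differs
#' most in phosphoproteomes: proline-directed motifs (proline immediately
#' C-terminal of the acceptor, the CMGC-kinase signature) and basophilic
#' motifs (arginine/lysine 2, 3 or 4 positions N-terminal of the acceptor,
#' the AGC/CAMK signature). The flags are independent and may all be
#' `FALSE`.
#'
#' @param pattern A `motif_pattern`.
#' @return Named logical vector with elements `proline_directed`,
#'   `basic_minus2`, `basic_minus3`, `basic_minus4`.
#' @examples
#' classify_pattern(parse_motif_pattern("S/T-P"))["proline_directed"]
#' @export
classify_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  pos <- pattern$positions
  aoff <- pattern$acceptor_offset  # 0-based
  set_at <- function(offset) {     # offset relative to acceptor
    i <- aoff + offset + 1L
    if (i < 1L || i > length(pos)) NULL else pos[[i]]
  }
  subset_of <- function(set, allowed) {
    !is.null(set) && !.is_wildcard(set) && all(set %in% allowed)
  }
  c(proline_directed = subset_of(set_at(1L), "P"),
    basic_minus2 = subset_of(set_at(-2L), c("R", "K")),
    basic_minus3 = subset_of(set_at(-3L), c("R", "K")),
    basic_minus4 = subset_of(set_at(-4L), c("R", "K")))
}

#' Is any basophilic flag set?
#'
#' Convenience predicate: `TRUE` when [classify_pattern()] reports a basic
#' residue at -2, -3 or -4.
#'
#' @param pattern A `motif_pattern`.
#' @return Logical scalar.
#' @export
is_basophilic <- function(pattern) {
  fl <- classify_pattern(pattern)
  any(fl[c("basic_minus2", "basic_minus3", "basic_minus4")])
}
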