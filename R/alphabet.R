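#' Construct an alphabet with a designated gap symbol
#'
#' An alphabet is an ordered set of distinct single-character symbols, one of
#' which is the gap. The declared order is total and fixed: it defines the
#' bit position of every symbol (symbol i maps to bit `2^(i-1)`), and thereby
#' all lexical comparisons of symbol sets and contexts. At least three
#' symbols (counting the gap) are required.
#'
#' @param symbols character vector of distinct single-character symbols,
#'   including the gap character.
#' @param gap the gap character; must occur exactly once in `symbols`.
#'   Defaults to the last symbol.
#' @return an object of class `ia_alphabet` with fields `symbols`, `gap`,
#'   `gap_bit` and `size`.
#' @examples
#' ia_alphabet(c("A", "C", "G", "T", "-"))
#' @export
ia_alphabet <- function(symbols, gap = symbols[length(symbols)]) {
  symbols <- as.character(symbols)
  if (any(nchar(symbols) != 1L))
    stop("alphabet symbols must be single characters")
  if (anyDuplicated(symbols))
    stop("duplicate symbols in alphabet: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  if (length(symbols) < 3L)
    stop("alphabet must contain at least 3 symbols (including the gap), got ",
         length(symbols))
  if (length(symbols) > 30L)
    stop("alphabets larger than 30 symbols are not supported")
  gi <- match(gap, symbols)
  if (is.na(gi))
    stop("gap symbol '", gap, "' is not a member of the alphabet")
  structure(list(symbols = symbols, gap = gap,
                 gap_bit = bitwShiftL(1L, gi - 1L),
                 size = length(symbols)),
            class = "ia_alphabet")
}

#' @export
print.ia_alphabet <- function(x, ...) {
  cat("Alphabet of", x$size, "symbols:",
      paste(x$symbols, collapse = " "),
      sprintf("(gap = '%s')\n", x$gap))
  invisible(x)
}

#' The nucleotide alphabet A, C, G, T with '-' as gap
#' @return an [ia_alphabet()].
#' @export
dna_alphabet <- function() ia_alphabet(c("A", "C", "G", "T", "-"))

#' Encode characters as a symbol-set bitset
#'
#' Symbol sets (nonempty subsets of the alphabet) are represented as integer
#' bitsets under the alphabet's symbol order.
#'
#' @param chars character vector of symbols (or a single string of them).
#' @param alphabet an [ia_alphabet()].
#' @return a single integer bitset.
#' @export
set_encode <- function(chars, alphabet) {
  if (length(chars) == 1L && nchar(chars) > 1L)
    chars <- strsplit(chars, "")[[1]]
  idx <- match(chars, alphabet$symbols)
  if (anyNA(idx))
    stop("symbol(s) not in alphabet: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  if (length(idx) == 0L) stop("symbol sets must be nonempty")
  as.integer(sum(bitwShiftL(1L, unique(idx) - 1L)))
}

#' Decode a symbol-set bitset to its member characters
#' @param bits integer bitset.
#' @param alphabet an [ia_alphabet()].
#' @return character vector of member symbols in alphabet order.
#' @export
set_decode <- function(bits, alphabet) {
  if (bits <= 0L) stop("symbol sets must be nonempty")
  alphabet$symbols[bitwAnd(bitwShiftR(bits, seq_len(alphabet$size) - 1L), 1L) == 1L]
}

#' Load a transition cost matrix (TCM)
#'
#' The TCM format: the first line lists the whitespace-separated symbols,
#' ending with the gap character (e.g. `A C G T -`); the following lines give
#' a square matrix of nonnegative costs, row-major, in the same symbol order.
#' The matrix must be symmetric with a zero diagonal. Triangle-inequality
#' violations are reported as a warning, not an error: the alignment
#' machinery requires only symmetry and nonnegativity.
#'
#' @param x path to a TCM file, the file content as a single string, or a
#'   character vector of lines. The bundled fixtures can be named directly:
#'   `"sigma0"` (substitution-preferring), `"sigma1"`
#'   (indel-preferring) and `"sigma3"` (discrete).
#' @param gap_in_indel logical; if `TRUE` (default) the effective set of an
#'   indel-derived (LEFT/RIGHT-tagged) element includes the gap symbol, the
#'   direct-optimization median convention. If `FALSE` the gap is excluded
#'   (unless that would empty the set). See [effective_set()].
#' @return an object of class `ia_tcm` with fields `alphabet`, `costs`,
#'   `integral` and `gap_in_indel`.
#' @examples
#' s0 <- load_tcm("sigma0")
#' s0$costs["A", "-"]
#' @export
load_tcm <- function(x, gap_in_indel = TRUE) {
  if (length(x) == 1L && x %in% c("sigma0", "sigma1", "sigma3"))
    x <- system.file("extdata", paste0(x, ".tcm"), package = "impliedalign",
                     mustWork = TRUE)
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    x <- readLines(x)
  if (length(x) == 1L) x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) < 2L) stop("TCM input must contain a symbol line and a matrix")
  syms <- strsplit(x[1], "\\s+")[[1]]
  alphabet <- ia_alphabet(syms)  # validates duplicates, size, single chars
  rows <- lapply(x[-1], function(ln) as.numeric(strsplit(ln, "\\s+")[[1]]))
  ns <- length(syms)
  if (length(rows) != ns || any(vapply(rows, length, 1L) != ns))
    stop("TCM matrix is not square: expected ", ns, " x ", ns)
  costs <- do.call(rbind, rows)
  dimnames(costs) <- list(syms, syms)
  make_tcm(alphabet, costs, gap_in_indel = gap_in_indel)
}

#' Construct a transition metric from an alphabet and a cost matrix
#'
#' @param alphabet an [ia_alphabet()].
#' @param costs square numeric matrix of nonnegative costs in alphabet order.
#' @inheritParams load_tcm
#' @return an `ia_tcm` object.
#' @export
make_tcm <- function(alphabet, costs, gap_in_indel = TRUE) {
  ns <- alphabet$size
  costs <- as.matrix(costs)
  if (nrow(costs) != ns || ncol(costs) != ns)
    stop("cost matrix is not square over the alphabet: expected ",
         ns, " x ", ns, ", got ", nrow(costs), " x ", ncol(costs))
  if (anyNA(costs)) stop("cost matrix contains missing values")
  if (any(costs < 0)) stop("cost matrix contains negative entries")
  if (any(abs(diag(costs)) > .IA_TOL))
    stop("cost matrix diagonal must be zero")
  if (any(abs(costs - t(costs)) > .IA_TOL)) {
    bad <- which(abs(costs - t(costs)) > .IA_TOL, arr.ind = TRUE)[1, ]
    stop(sprintf("cost matrix is asymmetric: cost(%s,%s) != cost(%s,%s)",
                 alphabet$symbols[bad[1]], alphabet$symbols[bad[2]],
                 alphabet$symbols[bad[2]], alphabet$symbols[bad[1]]))
  }
  dimnames(costs) <- list(alphabet$symbols, alphabet$symbols)
  # Triangle inequality is advisory only.
  viol <- FALSE
  for (z in seq_len(ns)) {
    if (any(outer(costs[, z], costs[z, ], `+`) < costs - .IA_TOL)) {
      viol <- TRUE
      break
    }
  }
  if (viol)
    warning("cost matrix violates the triangle inequality; ",
            "alignment costs remain valid but the matrix is not a metric")
  structure(list(alphabet = alphabet, costs = costs,
                 integral = all(abs(costs - round(costs)) < .IA_TOL),
                 gap_in_indel = isTRUE(gap_in_indel),
                 cache = new.env(parent = emptyenv())),
            class = "ia_tcm")
}

#' @export
print.ia_tcm <- function(x, ...) {
  cat("Transition cost matrix over {",
      paste(x$alphabet$symbols, collapse = ", "), "}\n")
  print(x$costs)
  invisible(x)
}

#' Minimal transition cost and median between two symbol sets
#'
#' Expands the symbol-level metric to nonempty symbol subsets: the cost is
#' the minimum of `sigma(a, b)` over all `a` in `x`, `b` in `y`; the median
#' is the set of all symbols `z` minimising
#' `min_a sigma(a, z) + min_b sigma(z, b)` (Sankoff-style minimised summed
#' distance through an intermediate symbol). The operation is commutative and
#' the median is never empty.
#'
#' @param x,y symbol sets: integer bitsets or character vectors of symbols.
#' @param metric an `ia_tcm`.
#' @return a list with components `cost` (nonnegative number) and `median`
#'   (integer bitset; use [set_decode()] for the member symbols).
#' @examples
#' s0 <- load_tcm("sigma0")
#' subset_cost_median("A", "C", s0)
#' @export
subset_cost_median <- function(x, y, metric) {
  x <- as_bits(x, metric$alphabet)
  y <- as_bits(y, metric$alphabet)
  list(cost = cpp_subset_cost(x, y, metric$costs),
       median = cpp_subset_median(x, y, metric$costs, .IA_TOL))
}

as_bits <- function(x, alphabet) {
  if (is.character(x)) x <- set_encode(x, alphabet)
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x <= 0L)
    stop("symbol sets must be single nonempty bitsets")
  if (bitwAnd(x, bitwNot(bitwShiftL(1L, alphabet$size) - 1L)) != 0L)
    stop("bitset has bits outside the alphabet")
  x
}

#' Construct a single tagged element
#'
#' Elements of the extended alphabet carry one of four tags. `BOTH` elements
#' pair the first-argument-side and second-argument-side symbol sets of an
#' aligned position; `LEFT`/`RIGHT` elements carry the set of the side that
#' supplied the residue of an indel position; `GAPPED` elements carry no
#' payload and arise only during the pre-order pass.
#'
#' @param tag one of `"BOTH"`, `"LEFT"`, `"RIGHT"`, `"GAPPED"`.
#' @param x first payload set (bitset or characters) for `BOTH`/`LEFT`.
#' @param y second payload set for `BOTH`/`RIGHT`.
#' @param alphabet an [ia_alphabet()]; required when payloads are characters.
#' @return an object of class `ia_element`: a list with `tag`, `a`, `b`.
#' @export
ia_element <- function(tag, x = NULL, y = NULL, alphabet = NULL) {
  tag <- match.arg(tag, .TAG_NAMES)
  enc <- function(v) {
    if (is.null(v)) return(0L)
    if (is.character(v)) {
      if (is.null(alphabet)) stop("alphabet required for character payloads")
      return(set_encode(v, alphabet))
    }
    as.integer(v)
  }
  a <- enc(x); b <- enc(y)
  ok <- switch(tag,
    BOTH   = a > 0L && b > 0L,
    LEFT   = a > 0L && b == 0L,
    RIGHT  = a == 0L && b > 0L,
    GAPPED = a == 0L && b == 0L)
  if (!ok) stop("payload shape does not match tag ", tag)
  structure(list(tag = tag, a = a, b = b), class = "ia_element")
}

#' Succinct two-bit tag codec
#'
#' The four element tags map to the four distinct codes 0..3, so one tag fits
#' in two bits alongside its payload.
#'
#' @param tag tag name(s) (`"BOTH"`, `"LEFT"`, `"RIGHT"`, `"GAPPED"`) or an
#'   `ia_element`.
#' @return integer code(s) in 0..3.
#' @export
tag_encode <- function(tag) {
  if (inherits(tag, "ia_element")) tag <- tag$tag
  code <- .TAGS[match(tag, .TAG_NAMES)]
  if (anyNA(code)) stop("unknown tag: ", paste(tag[is.na(code)], collapse = ", "))
  unname(code)
}

#' @rdname tag_encode
#' @param code integer code(s) in 0..3.
#' @export
tag_decode <- function(code) {
  code <- as.integer(code)
  if (anyNA(code) || any(code < 0L | code > 3L))
    stop("tag codes must lie in 0..3")
  .TAG_NAMES[code + 1L]
}

#' Effective symbol set of a tagged element
#'
#' Projects an element of the extended alphabet back to a plain symbol set so
#' that the symbol-level metric can score it at higher tree levels:
#' `BOTH(x, y)` projects to the [subset_cost_median()] median of `x` and `y`;
#' `LEFT(x)`/`RIGHT(y)` project to the payload, with the gap symbol included
#' when the metric uses the direct-optimization indel-median convention
#' (`gap_in_indel = TRUE`, the default) and excluded otherwise; `GAPPED`
#' projects to the gap singleton.
#'
#' @param e an [ia_element()].
#' @param metric an `ia_tcm`.
#' @return integer bitset of the effective set.
#' @examples
#' s0 <- load_tcm("sigma0")
#' set_decode(effective_set(ia_element("BOTH", "A", "C", s0$alphabet), s0),
#'            s0$alphabet)
#' @export
effective_set <- function(e, metric) {
  stopifnot(inherits(e, "ia_element"))
  gb <- metric$alphabet$gap_bit
  switch(e$tag,
    BOTH   = subset_cost_median(e$a, e$b, metric)$median,
    LEFT   = indel_effective(e$a, gb, metric$gap_in_indel),
    RIGHT  = indel_effective(e$b, gb, metric$gap_in_indel),
    GAPPED = gb)
}

indel_effective <- function(payload, gap_bit, gap_in_indel) {
  if (gap_in_indel) return(bitwOr(payload, gap_bit))
  excl <- bitwAnd(payload, bitwNot(gap_bit))
  if (excl > 0L) excl else payload
}
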