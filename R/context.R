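# Contexts: finite sequences of tagged elements, stored as integer matrices
# with columns (tag, a, b, eff). `a` holds the first-argument-side payload,
# `b` the second-argument-side payload (0 when absent), `eff` the cached
# effective symbol set of the element under the metric the context was built
# with. Serves both as "preliminary context" and "final alignment".

new_context <- function(tag = integer(), a = integer(), b = integer(),
                        eff = integer()) {
  m <- cbind(tag = as.integer(tag), a = as.integer(a),
             b = as.integer(b), eff = as.integer(eff))
  class(m) <- c("ia_context", class(m))
  m
}

#' @export
print.ia_context <- function(x, ...) {
  cat("Context of", nrow(x), "tagged element(s)\n")
  if (nrow(x)) {
    df <- data.frame(tag = tag_decode(x[, "tag"]), a = x[, "a"],
                     b = x[, "b"], eff = x[, "eff"])
    print(utils::head(df, 20L), row.names = FALSE)
    if (nrow(x) > 20L) cat("...", nrow(x) - 20L, "more\n")
  }
  invisible(x)
}

#' Lift a raw symbol-set sequence into an initial context
#'
#' Each residue set `X` of a leaf sequence lifts to a `BOTH(X, X)` element
#' whose effective set is `X` itself: leaves have no subtree asymmetry, and
#' the lift must carry the residue set through [effective_set()] unchanged
#' (the median of identical sets is that set).
#'
#' @param bits integer vector of symbol-set bitsets (see [parse_fasta()]).
#' @return an `ia_context`.
#' @export
lift_sequence <- function(bits) {
  bits <- as.integer(bits)
  if (any(is.na(bits) | bits <= 0L))
    stop("raw sequences must consist of nonempty symbol sets")
  new_context(tag = rep(.TAGS[["BOTH"]], length(bits)),
              a = bits, b = bits, eff = bits)
}

# Extract element i of a context as an ia_element.
context_element <- function(ctx, i) {
  structure(list(tag = tag_decode(ctx[i, "tag"]),
                 a = ctx[i, "a"], b = ctx[i, "b"]),
            class = "ia_element")
}

# Build a context from a list of ia_element plus a metric (eff recomputed).
context_from_elements <- function(elements, metric) {
  if (length(elements) == 0L) return(new_context())
  tag <- vapply(elements, function(e) .TAGS[[e$tag]], 0L)
  a <- vapply(elements, function(e) as.integer(e$a), 0L)
  b <- vapply(elements, function(e) as.integer(e$b), 0L)
  eff <- vapply(elements, effective_set, 0L, metric = metric)
  new_context(tag, a, b, eff)
}

# Drop GAPPED elements and return the per-element residue sets of what
# remains (for leaf rows these are the original residue sets).
context_residues <- function(ctx) {
  keep <- ctx[, "tag"] != .TAGS[["GAPPED"]]
  ctx[keep, , drop = FALSE]
}

# Lexical order on contexts: elementwise comparison of effective-set bitsets
# under the declared symbol order, ties broken by length (shorter first).
# Returns -1, 0, 1.
context_compare <- function(c1, c2) {
  e1 <- c1[, "eff"]; e2 <- c2[, "eff"]
  l <- min(length(e1), length(e2))
  if (l > 0L) {
    d <- which(e1[seq_len(l)] != e2[seq_len(l)])
    if (length(d)) return(if (e1[d[1]] < e2[d[1]]) -1L else 1L)
  }
  sign(length(e1) - length(e2))
}
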