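#' Canonical operand assignment for the tagged alignment
#'
#' The commutativity of the tagged alignment operator rests on a
#' deterministic choice of which operand fills the columns of the dynamic
#' programming matrix and which the rows: the longer string goes to the
#' columns; on equal length, the first string under the lexical ordering of
#' effective sets goes to the columns. Identical inputs are flagged. If the
#' first argument was not assigned to the rows, the LEFT/RIGHT tags of the
#' resulting alignment are exchanged downstream.
#'
#' @param s1,s2 contexts (see [lift_sequence()]).
#' @return list with `row`, `col` (the reordered contexts), `swapped`
#'   (`TRUE` iff `s1` was not assigned to the rows) and `identical`.
#' @export
canonicalize_pair <- function(s1, s2) {
  n1 <- nrow(s1); n2 <- nrow(s2)
  if (n1 > n2) return(list(row = s2, col = s1, swapped = TRUE, identical = FALSE))
  if (n1 < n2) return(list(row = s1, col = s2, swapped = FALSE, identical = FALSE))
  cmp <- context_compare(s1, s2)
  if (cmp == 0L && identical(s1[, 1:3], s2[, 1:3]))
    return(list(row = s1, col = s2, swapped = FALSE, identical = TRUE))
  if (cmp < 0L)  # s1 lexically first -> columns
    list(row = s2, col = s1, swapped = TRUE, identical = FALSE)
  else
    list(row = s1, col = s2, swapped = FALSE, identical = FALSE)
}

#' Commutative tagged pairwise alignment
#'
#' Aligns two contexts by dynamic programming over their effective symbol
#' sets and tags every output element with its origin: `BOTH(leftSet,
#' rightSet)` for an aligned (diagonal) position, `LEFT(leftSet)` for a
#' position consuming only the first argument, `RIGHT(rightSet)` for a
#' position consuming only the second. The cost is the minimum over all
#' pairwise alignments of the sum of subset costs (substitution: metric cost
#' of the two effective sets; indel: metric cost of an effective set against
#' the gap singleton). The operator is commutative — swapping the arguments
#' yields the same cost and the tag-swapped alignment — and deterministic:
#' co-optimal traceback steps resolve by the fixed preference
#' leftward > upward > diagonal.
#'
#' @param left,right contexts containing no GAPPED elements.
#' @param metric an `ia_tcm`.
#' @return list with `cost` (nonnegative number) and `alignment` (an
#'   `ia_context`; `LEFT` always means "originated from the first argument").
#' @examples
#' s0 <- load_tcm("sigma0")
#' a <- dna_alphabet()
#' x <- lift_sequence(vapply(c("A", "C"), set_encode, 0L, alphabet = a))
#' y <- lift_sequence(set_encode("A", a))
#' align_tagged(x, y, s0)
#' @export
align_tagged <- function(left, right, metric) {
  check_no_gapped(left); check_no_gapped(right)
  check_alphabet(left, metric); check_alphabet(right, metric)
  cp <- canonicalize_pair(left, right)
  res <- cpp_align_tagged(cp$row[, "eff"], cp$col[, "eff"], metric$costs,
                          metric$alphabet$gap_bit, metric$gap_in_indel,
                          .IA_TOL)
  tag <- res$tag
  # Canonical frame: row side = LEFT. Payloads are the effective sets of the
  # consumed input elements.
  a <- ifelse(res$ia > 0L, cp$row[, "eff"][pmax(res$ia, 1L)], 0L)
  b <- ifelse(res$ib > 0L, cp$col[, "eff"][pmax(res$ib, 1L)], 0L)
  if (cp$swapped) {
    tag <- ifelse(tag == .TAGS[["LEFT"]], .TAGS[["RIGHT"]],
                  ifelse(tag == .TAGS[["RIGHT"]], .TAGS[["LEFT"]], tag))
    tmp <- a; a <- b; b <- tmp
  }
  list(cost = res$cost,
       alignment = new_context(tag, a, b, res$eff))
}

check_no_gapped <- function(ctx) {
  if (nrow(ctx) && any(ctx[, "tag"] == .TAGS[["GAPPED"]]))
    stop("GAPPED elements cannot occur in alignment inputs ",
         "(they are only derived during the pre-order pass)")
  invisible(ctx)
}

check_alphabet <- function(ctx, metric) {
  mask <- bitwNot(bitwShiftL(1L, metric$alphabet$size) - 1L)
  if (nrow(ctx) && any(bitwAnd(ctx[, "eff"], mask) != 0L))
    stop("context symbols fall outside the metric's alphabet")
  invisible(ctx)
}

#' Reference minimum alignment cost by direct dynamic programming
#'
#' An independent, plain-R computation of the minimum pairwise alignment cost
#' over effective sets, used as a testing oracle for [align_tagged()]. No
#' canonicalization, tagging or traceback is involved.
#'
#' @param left,right contexts.
#' @param metric an `ia_tcm`.
#' @param max_len maximum allowed length of either input (guards against
#'   accidentally large instances).
#' @return the minimum alignment cost (nonnegative number).
#' @export
alignment_oracle <- function(left, right, metric, max_len = 200L) {
  e1 <- left[, "eff"]; e2 <- right[, "eff"]
  if (length(e1) > max_len || length(e2) > max_len)
    stop("inputs too long for the reference oracle")
  gb <- metric$alphabet$gap_bit
  tab <- subset_table(metric)
  if (is.null(tab)) {
    sc <- function(x, y) cpp_subset_cost(x, y, metric$costs)
    S <- outer(e1, e2, Vectorize(sc))
    g1 <- vapply(e1, sc, 0.0, y = gb)
    g2 <- vapply(e2, sc, 0.0, y = gb)
  } else {
    S <- matrix(tab[cbind(rep(e1, times = length(e2)),
                          rep(e2, each = length(e1)))],
                length(e1), length(e2))
    g1 <- tab[cbind(e1, rep(gb, length(e1)))]
    g2 <- tab[cbind(e2, rep(gb, length(e2)))]
  }
  n1 <- length(e1); n2 <- length(e2)
  D <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in seq_len(n1)) D[i + 1L, 1L] <- D[i, 1L] + g1[i]
  for (j in seq_len(n2)) D[1L, j + 1L] <- D[1L, j] + g2[j]
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + S[i, j],
                               D[i, j + 1L] + g1[i],
                               D[i + 1L, j] + g2[j])
    }
  }
  D[n1 + 1L, n2 + 1L]
}

# Lazily built full subset-cost table (small alphabets), cached per metric.
subset_table <- function(metric) {
  if (is.null(metric$cache)) return(NULL)
  if (is.null(metric$cache$tab)) {
    if (metric$alphabet$size > 8L) return(NULL)
    metric$cache$tab <- cpp_subset_table(metric$costs)
  }
  metric$cache$tab
}

# Exhaustive enumeration of all monotone alignments (exponential; tiny inputs
# only). Used to validate the oracle itself.
enumerate_min_cost <- function(left, right, metric) {
  e1 <- left[, "eff"]; e2 <- right[, "eff"]
  if (length(e1) + length(e2) > 14L)
    stop("inputs too long for exhaustive enumeration")
  sig <- metric$costs
  gb <- metric$alphabet$gap_bit
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- Inf
    if (i > 0L && j > 0L)
      best <- min(best, rec(i - 1L, j - 1L) + cpp_subset_cost(e1[i], e2[j], sig))
    if (i > 0L)
      best <- min(best, rec(i - 1L, j) + cpp_subset_cost(e1[i], gb, sig))
    if (j > 0L)
      best <- min(best, rec(i, j - 1L) + cpp_subset_cost(e2[j], gb, sig))
    best
  }
  rec(length(e1), length(e2))
}
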