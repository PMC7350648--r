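#' Post-order decoration of a tree with preliminary contexts
#'
#' Visits the tree leaves-to-root (iteratively, so deep trees cannot overflow
#' the call stack) and assigns to every internal node the tagged alignment
#' of its children's preliminary contexts, accumulating costs: an internal
#' node's cost is the sum of both child costs plus the local alignment cost.
#' After the pass the root's context covers the full leaf set and the root
#' cost is the tree cost. No GAPPED element can arise during this pass.
#'
#' @param tree an `ia_tree` with leaves decorated by [decorate_leaves()].
#' @param metric an `ia_tcm`.
#' @return the tree with all `$prelim` contexts and `$cost` values filled.
#' @export
postorder_decorate <- function(tree, metric) {
  if (is.null(tree$prelim))
    stop("leaves are not decorated; call decorate_leaves() first")
  for (v in tree$postorder) {
    if (is.na(tree$children[v, 1])) {
      if (is.null(tree$prelim[[v]]))
        stop("undecorated leaf: ", tree$label[v])
      next
    }
    l <- tree$children[v, 1]; r <- tree$children[v, 2]
    res <- align_tagged(tree$prelim[[l]], tree$prelim[[r]], metric)
    tree$prelim[[v]] <- res$alignment
    tree$cost[v] <- tree$cost[l] + tree$cost[r] + res$cost
  }
  tree$metric <- metric
  tree
}

#' Derive one child's final alignment by the sliding zip
#'
#' Merges the parent's final alignment (the basis of the zip), the parent's
#' preliminary context and the child's preliminary context into the child's
#' final alignment. At every step exactly one parent-final element is
#' consumed and one output element emitted; the cases are evaluated strictly
#' in order, first match wins:
#'
#' * Case 0 — parent-final element is GAPPED: emit GAPPED.
#' * Case 1 — child's preliminary context exhausted: emit GAPPED (consuming
#'   one parent-preliminary element, since the parent-final element here is
#'   never GAPPED, mirroring Case 5, so the parent context is exactly
#'   exhausted on return).
#' * Case 2 — parent-final element is BOTH: the child was aligned with its
#'   sister subtree here; consume one element of each preliminary context
#'   and emit the child's element.
#' * Case 3 — parent-final and parent-preliminary elements are the same LEFT
#'   element and the child is the left child: consume both preliminary
#'   elements, emit the child's element.
#' * Case 4 — symmetric for RIGHT elements and the right child.
#' * Case 5 — otherwise: consume one parent-preliminary element, emit GAPPED
#'   (the subtrees were not aligned here, or an indel from the sister
#'   subtree introduces a new gap).
#'
#' @param parent_final,parent_prelim,child_prelim contexts with
#'   `|parent_final| >= |parent_prelim| >= |child_prelim|`.
#' @param child_side `"left"` or `"right"` (or 1/2).
#' @param gap_bit the alphabet's gap bit (defaults taken from context eff
#'   values is not possible, so pass the metric's `alphabet$gap_bit`).
#' @return the child's final alignment, an `ia_context` of length
#'   `|parent_final|`; its non-GAPPED elements are exactly the child's
#'   preliminary elements in order.
#' @export
sliding_zip <- function(parent_final, parent_prelim, child_prelim,
                        child_side, gap_bit) {
  side <- if (is.character(child_side))
    match(match.arg(child_side, c("left", "right")), c("left", "right"))
  else as.integer(child_side)
  out <- cpp_sliding_zip(unclass_ctx(parent_final), unclass_ctx(parent_prelim),
                         unclass_ctx(child_prelim), side, as.integer(gap_bit))
  colnames(out) <- c("tag", "a", "b", "eff")
  class(out) <- c("ia_context", class(out))
  out
}

unclass_ctx <- function(x) {
  attr(x, "class") <- NULL
  x
}

#' Pre-order finalization: equal-length final alignments for every node
#'
#' Initializes the root's final alignment to its preliminary context, then
#' visits the remaining nodes root-to-leaves (parents before children,
#' siblings left-then-right), deriving each node's final alignment with
#' [sliding_zip()]. All final alignments share the length of the root's
#' preliminary context.
#'
#' @param tree an `ia_tree` after [postorder_decorate()].
#' @return the tree with `$final` (per-node contexts) added.
#' @export
preorder_finalize <- function(tree) {
  if (is.null(tree$metric))
    stop("post-order decorations missing; call postorder_decorate() first")
  res <- cpp_preorder_all(tree$preorder, tree$parent, tree$side,
                          lapply(tree$prelim, unclass_ctx),
                          tree$metric$alphabet$gap_bit, 1L)
  tree$final <- lapply(res$final, function(m) {
    colnames(m) <- c("tag", "a", "b", "eff")
    class(m) <- c("ia_context", class(m))
    m
  })
  tree
}

# Time the pre-order phase alone: runs the full traversal `inner` times
# inside the compiled kernel and returns the elapsed seconds.
time_preorder <- function(tree, inner = 1L) {
  res <- cpp_preorder_all(tree$preorder, tree$parent, tree$side,
                          lapply(tree$prelim, unclass_ctx),
                          tree$metric$alphabet$gap_bit, as.integer(inner))
  res$seconds
}
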