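#' Render the leaf rows of the implied alignment
#'
#' One equal-length row per leaf, in a chosen order. GAPPED elements render
#' as the gap character; a residue set renders as its symbol when singleton
#' and otherwise per policy: the IUPAC ambiguity code when the alphabet and
#' set admit one (the default for nucleotide alphabets), else set notation
#' like `[AG]` (which widens the column — set notation is for inspection,
#' not for strict FASTA alignment output).
#'
#' @param tree an `ia_tree` after [preorder_finalize()].
#' @param ambiguity `"iupac"` or `"set"`.
#' @param internal_nodes also emit rows for internal nodes (named
#'   `node<i>`), rendered via their effective sets.
#' @param order leaf-name order for the output rows; defaults to the tree's
#'   leaf order.
#' @return named character vector of aligned rows.
#' @export
render_leaf_msa <- function(tree, ambiguity = c("iupac", "set"),
                            internal_nodes = FALSE, order = NULL) {
  ambiguity <- match.arg(ambiguity)
  if (is.null(tree$final))
    stop("final alignments missing; call preorder_finalize() first")
  alph <- tree$alphabet
  rev_iupac <- reverse_iupac(alph)
  render_set <- function(bits) {
    ch <- set_decode(bits, alph)
    if (length(ch) == 1L) return(ch)
    key <- paste(sort(ch), collapse = "")
    if (ambiguity == "iupac" && !is.null(rev_iupac[[key]])) rev_iupac[[key]]
    else paste0("[", paste(ch, collapse = ""), "]")
  }
  render_ctx <- function(ctx, payload_col) {
    if (nrow(ctx) == 0L) return("")
    paste(vapply(seq_len(nrow(ctx)), function(i) {
      if (ctx[i, "tag"] == .TAGS[["GAPPED"]]) alph$gap
      else render_set(ctx[i, payload_col])
    }, ""), collapse = "")
  }
  leaves <- seq_len(tree$n_leaves)
  rows <- vapply(leaves, function(v) render_ctx(tree$final[[v]], "a"), "")
  names(rows) <- tree$label
  if (!is.null(order)) {
    if (!setequal(order, tree$label))
      stop("row order must be a permutation of the leaf names")
    rows <- rows[order]
  }
  if (internal_nodes) {
    internals <- setdiff(seq_len(tree$N), leaves)
    irows <- vapply(internals, function(v) render_ctx(tree$final[[v]], "eff"), "")
    names(irows) <- paste0("node", internals)
    rows <- c(rows, irows)
  }
  rows
}

reverse_iupac <- function(alphabet) {
  out <- list()
  iupac <- Biostrings::IUPAC_CODE_MAP
  for (code in names(iupac)) {
    members <- sort(strsplit(iupac[[code]], "")[[1]])
    if (all(members %in% alphabet$symbols))
      out[[paste(members, collapse = "")]] <- code
  }
  out
}

#' Write named sequences as FASTA text
#' @param seqs named character vector.
#' @param path optional output file; when `NULL` the text is returned.
#' @param width line-wrap width.
#' @return FASTA text, invisibly when written to a file.
#' @export
write_fasta <- function(seqs, path = NULL, width = 80L) {
  chunks <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    body <- if (nchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
            collapse = "\n")
    } else ""
    paste0(">", names(seqs)[i], "\n", body)
  }, "")
  txt <- paste0(paste(chunks, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' End-to-end implied alignment pipeline
#'
#' Parses the inputs, decorates the leaves, runs the post-order and
#' pre-order passes and renders the leaf alignment. Deterministic for fixed
#' inputs; the output row order follows the input FASTA order.
#'
#' @param fasta FASTA text or path (unaligned sequences).
#' @param newick Newick text or path (rooted strictly binary tree whose leaf
#'   names match the FASTA headers).
#' @param tcm an `ia_tcm`, a TCM path/text, or a bundled fixture name
#'   (`"sigma0"`, `"sigma1"`, `"sigma3"`).
#' @param degap,keep_gap_symbol passed to [parse_fasta()].
#' @param ambiguity,internal_nodes passed to [render_leaf_msa()].
#' @param verify run the structural invariant checks (equal row lengths,
#'   degap recovery, no all-gap column, cost conservation) on the result and
#'   fail if any is violated.
#' @return an object of class `ia_result`: list with `msa` (named rows in
#'   input FASTA order), `cost` (tree cost; integer-valued when the TCM is
#'   integral), `a` (alignment length), `k` (longest input length), `m`
#'   (`a / k`), and the decorated `tree`.
#' @examples
#' fa <- ">t1\nACGT\n>t2\nACGT\n>t3\nACGA\n>t4\nACGA"
#' run_pipeline(fa, "((t1,t2),(t3,t4));", "sigma0")
#' @export
run_pipeline <- function(fasta, newick, tcm, degap = FALSE,
                         keep_gap_symbol = FALSE,
                         ambiguity = c("iupac", "set"),
                         internal_nodes = FALSE, verify = FALSE) {
  metric <- if (inherits(tcm, "ia_tcm")) tcm else load_tcm(tcm)
  tree <- parse_newick(newick)
  seqs <- parse_fasta(fasta, metric$alphabet, degap = degap,
                      keep_gap_symbol = keep_gap_symbol)
  tree <- decorate_leaves(tree, seqs, metric$alphabet)
  tree <- postorder_decorate(tree, metric)
  tree <- preorder_finalize(tree)
  msa <- render_leaf_msa(tree, ambiguity = ambiguity,
                         internal_nodes = internal_nodes)
  msa <- c(msa[names(seqs)], msa[setdiff(names(msa), tree$label)])
  k <- max(vapply(seqs, length, 0L))
  a <- nrow(tree$prelim[[tree$root]])
  cost <- tree$cost[tree$root]
  if (metric$integral) cost <- round(cost)
  res <- structure(list(msa = msa, cost = cost, a = a, k = k,
                        m = a / k, tree = tree),
                   class = "ia_result")
  if (verify) verify_result(res, seqs)
  res
}

#' @export
print.ia_result <- function(x, ...) {
  cat("Implied alignment of", x$tree$n_leaves, "sequences\n")
  cat("  alignment length a =", x$a, " longest input k =", x$k,
      " m = a/k =", sprintf("%.4f", x$m), "\n")
  cat("  tree cost =", x$cost, "\n")
  show <- utils::head(x$msa, 8L)
  for (nm in names(show))
    cat(sprintf("  %-12s %s\n", nm,
                if (nchar(show[[nm]]) > 60)
                  paste0(substr(show[[nm]], 1, 57), "...")
                else show[[nm]]))
  if (length(x$msa) > 8L) cat("  ...", length(x$msa) - 8L, "more rows\n")
  invisible(x)
}

# Structural invariant checks used by --verify and by the test-suite.
verify_result <- function(res, seqs) {
  tree <- res$tree
  lens <- vapply(tree$final, nrow, 0L)
  if (length(unique(lens)) != 1L)
    stop("invariant violated: final alignments differ in length")
  if (lens[1] != res$a)
    stop("invariant violated: alignment length != root context length")
  for (i in seq_len(tree$n_leaves)) {
    rec <- context_residues(tree$final[[i]])[, "a"]
    if (!identical(as.integer(rec), as.integer(seqs[[tree$label[i]]])))
      stop("invariant violated: degapping leaf '", tree$label[i],
           "' does not recover its input sequence")
  }
  gap_mat <- vapply(seq_len(tree$n_leaves),
                    function(i) tree$final[[i]][, "tag"] == .TAGS[["GAPPED"]],
                    logical(res$a))
  if (res$a > 0L && any(apply(as.matrix(gap_mat), 1, all)))
    stop("invariant violated: all-gap column across leaf rows")
  local_costs <- 0
  for (v in tree$postorder) {
    if (is.na(tree$children[v, 1])) next
    l <- tree$children[v, 1]; r <- tree$children[v, 2]
    local_costs <- local_costs +
      (tree$cost[v] - tree$cost[l] - tree$cost[r])
  }
  if (abs(local_costs - tree$cost[tree$root]) > 1e-6)
    stop("invariant violated: root cost != sum of local alignment costs")
  invisible(TRUE)
}
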