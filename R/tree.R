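#' Parse a rooted strictly binary Newick tree
#'
#' Branch lengths and internal-node labels are parsed and ignored. Child
#' order is preserved as written: the first child of each node is its left
#' child. Non-binary nodes (including a trifurcating, i.e. unrooted-style,
#' root) are rejected rather than auto-rooted, because rooting changes the
#' implied alignment — the alignment operator is commutative but not
#' associative.
#'
#' @param text Newick text, or a path to a Newick file.
#' @return an object of class `ia_tree`: a list with the node count `N`,
#'   leaf count `n_leaves`, per-node `parent`, `children` (N x 2, NA for
#'   leaves), `side` (1 = left child, 2 = right child), `label` (leaf names),
#'   `root`, and `preorder`/`postorder` node orderings. The underlying
#'   `ape::phylo` object is kept in `$phylo`.
#' @examples
#' parse_newick("((a,b),(c,d));")
#' @export
parse_newick <- function(text) {
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "\n")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick syntax error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick syntax error: could not parse tree text")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  tip <- phy$tip.label
  if (any(is.na(tip) | !nzchar(tip)))
    stop("every leaf must be named")
  if (anyDuplicated(tip))
    stop("duplicate leaf names: ",
         paste(unique(tip[duplicated(tip)]), collapse = ", "))
  ia_tree_from_phylo(phy)
}

ia_tree_from_phylo <- function(phy) {
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  kids <- tabulate(phy$edge[, 1], nbins = N)
  internal <- setdiff(seq_len(N), seq_len(n))
  if (any(kids[internal] != 2L)) {
    bad <- internal[kids[internal] != 2L][1]
    stop("tree is not strictly binary: node has ", kids[bad],
         " children (polytomy or unrooted tree); root the tree explicitly")
  }
  parent <- integer(N)
  children <- matrix(NA_integer_, N, 2)
  side <- integer(N)
  filled <- integer(N)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; c <- phy$edge[e, 2]
    filled[p] <- filled[p] + 1L
    children[p, filled[p]] <- c
    parent[c] <- p
    side[c] <- filled[p]
  }
  root <- which(parent == 0L & (seq_len(N) > n | N == 1L))
  if (length(root) != 1L) stop("tree must have exactly one root")
  # Iterative orderings (explicit stack) so deep trees cannot overflow.
  pre <- integer(N); stack <- root; top <- 1L; np <- 0L
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    np <- np + 1L; pre[np] <- v
    if (!is.na(children[v, 1])) {
      # push right first so the left child is visited first
      top <- top + 1L; stack[top] <- children[v, 2]
      top <- top + 1L; stack[top] <- children[v, 1]
      length(stack) <- max(length(stack), top)
    }
  }
  structure(list(phylo = phy, N = N, n_leaves = n, parent = parent,
                 children = children, side = side,
                 label = phy$tip.label, root = root,
                 preorder = pre, postorder = rev(pre)),
            class = "ia_tree")
}

#' @export
print.ia_tree <- function(x, ...) {
  cat("Strictly binary rooted tree:", x$n_leaves, "leaves,",
      x$N - x$n_leaves, "internal nodes\n")
  if (!is.null(x$cost)) cat("tree cost:", x$cost[x$root], "\n")
  invisible(x)
}

#' Serialize an `ia_tree` back to Newick
#' @param tree an `ia_tree`.
#' @return single Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree$phylo)
}

#' Parse FASTA sequences into symbol-set sequences
#'
#' Each residue becomes a nonempty symbol set over the alphabet; IUPAC
#' ambiguity codes are expanded (e.g. `R` to `{A, G}`) when the alphabet
#' contains the corresponding nucleotides. Gap characters in the input are
#' rejected by default: implied alignment consumes unaligned sequences. Use
#' `degap = TRUE` to strip them (e.g. when feeding alignment slices back in),
#' or `keep_gap_symbol = TRUE` to admit the gap character as a literal
#' residue when the alphabet treats it as an ordinary symbol.
#'
#' @param text FASTA text or a path to a FASTA file.
#' @param alphabet an [ia_alphabet()].
#' @param degap strip gap characters from the sequences.
#' @param keep_gap_symbol treat the gap character as a literal residue.
#' @return named list of integer bitset vectors, in input order.
#' @examples
#' parse_fasta(">x\nAC\n>y\nGT", dna_alphabet())
#' @export
parse_fasta <- function(text, alphabet, degap = FALSE, keep_gap_symbol = FALSE) {
  path <- text
  if (length(text) > 1L || grepl("^\\s*>", text[1]) || grepl("\n", text[1])) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(paste(text, collapse = "\n"), path)
  } else if (!file.exists(text)) {
    stop("FASTA input is neither FASTA text nor an existing file: ", text)
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("FASTA input contains no records")
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA headers: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  lut <- residue_lut(alphabet, degap, keep_gap_symbol)
  out <- lapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (degap) ch <- ch[ch != alphabet$gap]
    bits <- lut[ch]
    if (anyNA(bits))
      stop("unknown residue(s) for this alphabet: ",
           paste(unique(ch[is.na(bits)]), collapse = ", "))
    as.integer(unname(bits))
  })
  names(out) <- nm
  out
}

# Residue -> bitset lookup, with IUPAC ambiguity expansion where the
# alphabet supports the expansion.
residue_lut <- function(alphabet, degap, keep_gap_symbol) {
  lut <- integer(0)
  for (i in seq_along(alphabet$symbols)) {
    s <- alphabet$symbols[i]
    if (s == alphabet$gap && !keep_gap_symbol && !degap) next
    lut[s] <- bitwShiftL(1L, i - 1L)
  }
  if (!keep_gap_symbol && !degap) lut[alphabet$gap] <- NA_integer_
  iupac <- Biostrings::IUPAC_CODE_MAP
  for (code in names(iupac)) {
    if (code %in% names(lut)) next
    members <- strsplit(iupac[[code]], "")[[1]]
    if (all(members %in% alphabet$symbols))
      lut[code] <- as.integer(sum(bitwShiftL(1L, match(members, alphabet$symbols) - 1L)))
  }
  lut
}

#' Attach leaf sequences to a tree
#'
#' Every leaf receives cost 0 and a preliminary context equal to the lift of
#' its raw sequence (each residue set `X` becomes `BOTH(X, X)`); internal
#' nodes stay undecorated until [postorder_decorate()].
#'
#' @param tree an `ia_tree`.
#' @param seqs named list of bitset vectors from [parse_fasta()].
#' @param alphabet an [ia_alphabet()] (retained on the tree for rendering).
#' @return the tree with `$prelim` (per-node contexts) and `$cost` added.
#' @export
decorate_leaves <- function(tree, seqs, alphabet) {
  leaves <- tree$label
  missing_seq <- setdiff(leaves, names(seqs))
  if (length(missing_seq))
    stop("leaf (leaves) without sequence: ", paste(missing_seq, collapse = ", "))
  extra <- setdiff(names(seqs), leaves)
  if (length(extra))
    stop("sequence(s) without a matching leaf: ", paste(extra, collapse = ", "))
  prelim <- vector("list", tree$N)
  cost <- rep(NA_real_, tree$N)
  for (i in seq_len(tree$n_leaves)) {
    s <- seqs[[leaves[i]]]
    if (length(s) == 0L) {
      warning("leaf '", leaves[i], "' has an empty sequence")
      prelim[[i]] <- new_context()
    } else {
      prelim[[i]] <- lift_sequence(s)
    }
    cost[i] <- 0
  }
  tree$prelim <- prelim
  tree$cost <- cost
  tree$alphabet <- alphabet
  tree
}
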