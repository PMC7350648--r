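# Shared fixture builders. All data is generated in code.

DNA <- dna_alphabet()
SIG0 <- load_tcm("sigma0")
SIG1 <- suppressWarnings(load_tcm("sigma1"))
SIG3 <- load_tcm("sigma3")
SIG1X <- suppressWarnings(load_tcm("sigma1", gap_in_indel = FALSE))

# Lift a plain string (e.g. "ACGT") into an initial context.
ctx <- function(s, alphabet = DNA) {
  chars <- strsplit(s, "")[[1]]
  lift_sequence(vapply(chars, set_encode, 0L, alphabet = alphabet,
                       USE.NAMES = FALSE))
}

# Build a context from tagged elements, eff filled from the metric.
el <- function(tag, x = NULL, y = NULL, alphabet = DNA)
  ia_element(tag, x, y, alphabet = alphabet)
elt_ctx <- function(elements, metric)
  impliedalign:::context_from_elements(elements, metric)

bits <- function(s, alphabet = DNA) set_encode(s, alphabet)

# Independent brute-force subset cost and median straight from the
# definition, by exhaustive search over symbols.
bf_subset <- function(xch, ych, metric) {
  sig <- metric$costs
  syms <- metric$alphabet$symbols
  tot <- vapply(syms, function(z) min(sig[xch, z]) + min(sig[z, ych]), 0.0)
  list(cost = min(sig[xch, ych, drop = FALSE]),
       median = syms[tot <= min(tot) + 1e-9])
}

# Random unaligned instance: a random rooted binary tree plus random
# nucleotide sequences of varying length.
random_instance <- function(n, kmax, kmin = 1L) {
  phy <- ape::rtree(n)
  phy$tip.label <- paste0("s", seq_len(n))
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(kmin:kmax, 1), replace = TRUE),
          collapse = "")
  }, "")
  names(seqs) <- phy$tip.label
  list(newick = ape::write.tree(phy),
       fasta = paste0(">", names(seqs), "\n", seqs, collapse = "\n"),
       seqs = seqs)
}

# Split single-line-per-record FASTA text into a named character vector.
strsplit_fasta <- function(fa) {
  lines <- strsplit(fa, "\n")[[1]]
  h <- grepl("^>", lines)
  stats::setNames(lines[!h], sub("^>", "", lines[h]))
}

# Full decoration run returning the tree.
run_tree <- function(newick, seqs_named, metric) {
  tree <- parse_newick(newick)
  raw <- lapply(seqs_named, function(s)
    vapply(strsplit(s, "")[[1]], set_encode, 0L, alphabet = metric$alphabet,
           USE.NAMES = FALSE))
  tree <- decorate_leaves(tree, raw, metric$alphabet)
  tree <- postorder_decorate(tree, metric)
  preorder_finalize(tree)
}

# Flip the children of randomly chosen internal nodes in a Newick string by
# rewriting the underlying phylo edges.
flip_children <- function(newick, prob = 0.5) {
  tree <- parse_newick(newick)
  phy <- tree$phylo
  for (v in seq_len(tree$N)) {
    kids <- tree$children[v, ]
    if (!is.na(kids[1]) && stats::runif(1) < prob) {
      e1 <- which(phy$edge[, 1] == v & phy$edge[, 2] == kids[1])
      e2 <- which(phy$edge[, 1] == v & phy$edge[, 2] == kids[2])
      phy$edge[c(e1, e2), ] <- phy$edge[c(e2, e1), ]
    }
  }
  ape::write.tree(phy)
}
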