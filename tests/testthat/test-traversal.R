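test_that("post-order pass accumulates contexts and costs", {
  # identical leaves: zero cost everywhere, all-BOTH root context
  tr <- run_tree("((a,b),(c,d));",
                 c(a = "AA", b = "AA", c = "AA", d = "AA"), SIG0)
  expect_true(all(tr$cost == 0))
  root_ctx <- tr$prelim[[tr$root]]
  expect_equal(nrow(root_ctx), 2L)
  expect_true(all(root_ctx[, "tag"] == tag_encode("BOTH")))

  # cherry: root cost is the single substitution cost
  tr <- run_tree("(a,b);", c(a = "A", b = "C"), SIG0)
  expect_equal(tr$cost[tr$root], 1)
  expect_false(any(vapply(tr$prelim, function(p)
    any(p[, "tag"] == tag_encode("GAPPED")), TRUE)))
})

test_that("quartet homopolymer costs match the oracle applied per node", {
  for (metric in list(SIG1, SIG1X)) {
    ch1 <- align_tagged(ctx("A"), ctx("C"), metric)
    ch2 <- align_tagged(ctx("G"), ctx("T"), metric)
    expected_root <- ch1$cost + ch2$cost +
      alignment_oracle(ch1$alignment, ch2$alignment, metric)
    tr <- run_tree("((a,b),(c,d));",
                   c(a = "A", b = "C", c = "G", d = "T"), metric)
    expect_equal(tr$cost[tr$root], expected_root)
    expect_equal(nrow(tr$prelim[[tr$root]]), 4L)
  }
  # frozen: DO indel medians make the quartet-root join free (cost 4 total);
  # the gap-exclusive variant pays 1 per indel there (cost 8 total)
  t_do <- run_tree("((a,b),(c,d));", c(a = "A", b = "C", c = "G", d = "T"),
                   SIG1)
  expect_equal(t_do$cost[t_do$root], 4)
  t_ex <- run_tree("((a,b),(c,d));", c(a = "A", b = "C", c = "G", d = "T"),
                   SIG1X)
  expect_equal(t_ex$cost[t_ex$root], 8)
})

test_that("sliding zip implements the six cases", {
  gb <- DNA$gap_bit
  gapped <- elt_ctx(list(el("GAPPED")), SIG0)
  empty <- elt_ctx(list(), SIG0)
  e <- elt_ctx(list(el("BOTH", "G", "G")), SIG0)

  # Case 0: gap in the parent's final propagates
  out <- sliding_zip(gapped, empty, empty, "left", gb)
  expect_identical(tag_decode(out[, "tag"]), "GAPPED")

  # Case 2: aligned with the sister subtree -> child's element survives
  pb <- elt_ctx(list(el("BOTH", "A", "C")), SIG0)
  out <- sliding_zip(pb, pb, e, "left", gb)
  expect_equal(unclass(out), unclass(e))
  out <- sliding_zip(pb, pb, e, "right", gb)
  expect_equal(unclass(out), unclass(e))

  # Cases 3 and 5: LEFT element is the child's own only on the left side
  pl <- elt_ctx(list(el("LEFT", "A")), SIG0)
  out <- sliding_zip(pl, pl, e, "left", gb)
  expect_equal(unclass(out), unclass(e))
  out <- sliding_zip(pl, pl, empty, "right", gb)
  expect_identical(tag_decode(out[, "tag"]), "GAPPED")

  # Case 4 symmetric
  pr <- elt_ctx(list(el("RIGHT", y = "A")), SIG0)
  out <- sliding_zip(pr, pr, e, "right", gb)
  expect_equal(unclass(out), unclass(e))

  # Case 1: child context exhausted -> gap, parent context still consumed
  two <- elt_ctx(list(el("BOTH", "A", "C"), el("RIGHT", y = "G")), SIG0)
  out <- sliding_zip(two, two, e, "left", gb)
  expect_identical(tag_decode(out[, "tag"]), c("BOTH", "GAPPED"))

  # precondition violations surface as errors
  expect_error(sliding_zip(empty, pl, empty, "left", gb), "precondition")
})

test_that("pre-order finalization yields equal-length alignments and known rows", {
  tr <- run_tree("(a,b);", c(a = "AC", b = "A"), SIG0)
  msa <- render_leaf_msa(tr)
  expect_equal(unname(msa[c("a", "b")]), c("AC", "A-"))

  tr <- run_tree("((a,b),(c,d));", c(a = "A", b = "A", c = "A", d = "A"), SIG0)
  expect_equal(unname(render_leaf_msa(tr)), rep("A", 4))

  tr <- run_tree("((a,b),(c,d));", c(a = "A", b = "C", c = "G", d = "T"), SIG1)
  msa <- render_leaf_msa(tr)
  expect_true(all(nchar(msa) == 4L))
  expect_true(all(vapply(msa, function(r)
    sum(strsplit(r, "")[[1]] != "-") == 1L, TRUE)))
})

test_that("a two-leaf tree reproduces the pairwise alignment", {
  set.seed(5)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1), replace = TRUE),
               collapse = "")
    metric <- list(SIG0, SIG1)[[1 + i %% 2]]
    tr <- run_tree("(x,y);", c(x = a, y = b), metric)
    msa <- render_leaf_msa(tr)
    pair <- align_tagged(ctx(a), ctx(b), metric)$alignment
    render_side <- function(col) paste(vapply(seq_len(nrow(pair)), function(j) {
      if (pair[j, col] == 0L) "-" else set_decode(pair[j, col], DNA)
    }, ""), collapse = "")
    expect_equal(unname(msa["x"]), render_side("a"))
    expect_equal(unname(msa["y"]), render_side("b"))
    expect_equal(tr$cost[tr$root], align_tagged(ctx(a), ctx(b), metric)$cost)
  }
})

test_that("structural invariants hold on random trees with label invariance", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(4:16, 1)
    inst <- random_instance(n, kmax = 20)
    metric <- list(SIG0, SIG1, SIG3)[[1 + i %% 3]]
    tr <- run_tree(inst$newick, inst$seqs, metric)
    a <- nrow(tr$prelim[[tr$root]])
    lens <- vapply(tr$final, nrow, 0L)
    expect_true(all(lens == a))
    k <- max(nchar(inst$seqs))
    expect_gte(a, k)
    expect_lte(a, sum(nchar(inst$seqs)))
    msa <- render_leaf_msa(tr)
    expect_identical(gsub("-", "", msa[names(inst$seqs)], fixed = TRUE),
                     inst$seqs)
    cols <- do.call(rbind, strsplit(unname(msa), ""))
    expect_false(any(apply(cols == "-", 2, all)))
    local_sum <- sum(vapply(seq_len(tr$N), function(v) {
      if (is.na(tr$children[v, 1])) return(0)
      tr$cost[v] - sum(tr$cost[tr$children[v, ]])
    }, 0.0))
    expect_equal(local_sum, tr$cost[tr$root])
    # transposing children anywhere leaves the leaf alignments unchanged
    flipped <- flip_children(inst$newick)
    tr2 <- run_tree(flipped, inst$seqs, metric)
    msa2 <- render_leaf_msa(tr2)
    expect_identical(msa2[names(msa)], msa)
    expect_equal(tr2$cost[tr2$root], tr$cost[tr$root])
  }
})

test_that("re-bracketing a tree may change the alignment but stays valid", {
  seqs <- c(A = "ACGTT", B = "AGTT", C = "CCGT", D = "TTGA")
  t1 <- run_tree("((A,(B,C)),D);", seqs, SIG0)
  t2 <- run_tree("((A,B),(C,D));", seqs, SIG0)
  for (tr in list(t1, t2)) {
    msa <- render_leaf_msa(tr)
    expect_length(unique(nchar(msa)), 1L)
    expect_identical(gsub("-", "", msa[names(seqs)], fixed = TRUE), seqs)
  }
})
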