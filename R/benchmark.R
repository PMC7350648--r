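#' Generate the pathological best/worst-case dataset
#'
#' Balanced binary tree of `n` leaves assembled from `n/4` quartet subtrees;
#' each quartet's four leaves carry the homopolymers `A^k`, `C^k`, `G^k`,
#' `T^k`. Under the substitution-preferring metric (`"perfect"` mode,
#' `sigma0`) the implied alignment collapses to the longest input length
#' (`m = 1`); under the indel-preferring metric (`"degenerate"` mode,
#' `sigma1`) no two subtree contexts align and the alignment length is the
#' sum of all input lengths (`m = n`).
#'
#' @param k homopolymer length (>= 1).
#' @param n leaf count: a power of two, >= 4.
#' @param mode `"perfect"` or `"degenerate"`.
#' @param seed optional seed for leaf-name shuffling; the generator itself
#'   is fully deterministic and by default no shuffling is applied.
#' @return list with `newick`, `fasta`, `tcm` (fixture name), `k`, `n`,
#'   `mode`.
#' @examples
#' generate_pathological(2, 4, "perfect")
#' @export
generate_pathological <- function(k, n, mode = c("perfect", "degenerate"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  k <- as.integer(k); n <- as.integer(n)
  if (k < 1L) stop("k must be >= 1")
  if (n < 4L || bitwAnd(n, n - 1L) != 0L)
    stop("n must be a power of two and >= 4, got ", n)
  names_ <- paste0("t", seq_len(n))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    names_ <- sample(names_)
  }
  quartet <- function(i) {
    nm <- names_[(4L * i - 3L):(4L * i)]
    sprintf("((%s,%s),(%s,%s))", nm[1], nm[2], nm[3], nm[4])
  }
  sub <- vapply(seq_len(n %/% 4L), quartet, "")
  while (length(sub) > 1L)
    sub <- vapply(seq_len(length(sub) %/% 2L), function(i)
      sprintf("(%s,%s)", sub[2L * i - 1L], sub[2L * i]), "")
  newick <- paste0(sub, ";")
  base <- c("A", "C", "G", "T")
  seqs <- strrep(base[((seq_len(n) - 1L) %% 4L) + 1L], k)
  fasta <- paste0(">", names_, "\n", seqs, collapse = "\n")
  list(newick = newick, fasta = fasta,
       tcm = if (mode == "perfect") "sigma0" else "sigma1",
       k = k, n = n, mode = mode)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Halve an aligned dataset into nested scaling instances
#'
#' Emulates the construction of doubling-size inputs from one large aligned
#' dataset: at each level the leaf set is halved (the tree pruned with
#' degree-2 nodes suppressed, so it stays strictly binary) and the alignment
#' is truncated to the central slice of half the current width, after which
#' all gap characters are removed from each slice.
#'
#' @param aligned named character vector of equal-length aligned rows
#'   (gap character `-`).
#' @param newick Newick text for a strictly binary tree over the row names.
#' @param halvings number of halving levels to produce.
#' @return list of instances, largest first (level 0 = degapped full data);
#'   each a list with `newick`, `seqs` (named, degapped), `width` (slice
#'   width) and `leaves`. Rows that become all-gap in a slice yield empty
#'   strings and are flagged with a warning.
#' @export
degrade_dataset <- function(aligned, newick, halvings) {
  widths <- unique(nchar(aligned))
  if (length(widths) != 1L)
    stop("aligned input rows must have equal length")
  tree <- parse_newick(newick)
  if (!setequal(names(aligned), tree$label))
    stop("tree leaves do not match the aligned row names")
  out <- vector("list", halvings + 1L)
  cur_rows <- aligned[tree$label]
  cur_phy <- tree$phylo
  width <- widths
  offset <- 0L
  for (lev in 0:halvings) {
    slice <- substr(cur_rows, offset + 1L, offset + width)
    seqs <- gsub("-", "", slice, fixed = TRUE)
    if (any(!nzchar(seqs)))
      warning("level ", lev, ": row(s) became all-gap in the central slice: ",
              paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
    out[[lev + 1L]] <- list(newick = ape::write.tree(cur_phy),
                            seqs = seqs, width = width,
                            leaves = length(seqs))
    if (lev == halvings) break
    keep <- head(names(cur_rows), ceiling(length(cur_rows) / 2))
    if (length(keep) < 2L)
      stop("halving level ", lev + 1L, " would leave fewer than 2 leaves")
    cur_phy <- ape::keep.tip(cur_phy, keep)
    cur_rows <- cur_rows[cur_phy$tip.label]
    new_width <- max(1L, width %/% 2L)
    offset <- offset + (width - new_width) %/% 2L
    width <- new_width
  }
  out
}

#' Time the pre-order phase over a grid of problem sizes
#'
#' For each `(k, n)` pair the pathological dataset is generated and the
#' post-order pass run once (untimed); the pre-order pass is then timed on a
#' monotonic clock as the median of `repeats` measurements, each averaging
#' enough whole-traversal repetitions to fill a minimum timing window (one
#' calibration run is discarded as warm-up).
#'
#' @param k_grid,n_grid integer vectors of string lengths and leaf counts.
#' @param mode `"perfect"` or `"degenerate"`.
#' @param repeats timed measurements per grid point.
#' @param seed passed to the generator (leaf-name shuffling only).
#' @param min_time minimum seconds per measurement window.
#' @return data frame with columns `n`, `k`, `runtime_ms` (per pre-order
#'   traversal), plus `a` and `inner` (repetitions used).
#' @export
run_scaling_study <- function(k_grid, n_grid, mode = c("perfect", "degenerate"),
                              repeats = 3L, seed = NULL, min_time = 0.01) {
  mode <- match.arg(mode)
  grid <- expand.grid(n = as.integer(n_grid), k = as.integer(k_grid))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    inst <- generate_pathological(grid$k[g], grid$n[g], mode, seed = seed)
    metric <- load_tcm(inst$tcm)
    tree <- parse_newick(inst$newick)
    seqs <- parse_fasta(inst$fasta, metric$alphabet)
    tree <- decorate_leaves(tree, seqs, metric$alphabet)
    tree <- postorder_decorate(tree, metric)
    # calibrate the inner repetition count (doubles as warm-up)
    inner <- 1L
    repeat {
      el <- time_preorder(tree, inner)
      if (el >= min_time || inner >= 2^24) break
      inner <- as.integer(min(2^24, max(inner * 2L,
                                        ceiling(inner * min_time / max(el, 1e-9)))))
    }
    meas <- vapply(seq_len(repeats), function(i) time_preorder(tree, inner),
                   0.0)
    rows[[g]] <- data.frame(n = grid$n[g], k = grid$k[g],
                            runtime_ms = stats::median(meas) / inner * 1000,
                            a = nrow(tree$prelim[[tree$root]]),
                            inner = inner)
  }
  do.call(rbind, rows)
}

#' Ordinary least squares fit of runtime scaling on the log2 scale
#'
#' Fits `log2(runtime) = beta0 + beta1 * log2(n) + beta2 * log2(k) + eps` by
#' OLS. On noiseless power-law data the coefficients are recovered exactly;
#' on measured data `beta1` near 1 indicates linear and near 2 quadratic
#' scaling in the leaf count.
#'
#' @param records data frame with columns `n`, `k` and a runtime column
#'   (`runtime_ms` by default).
#' @param runtime_col name of the runtime column.
#' @return object of class `ia_loglog_fit`: list with `beta0`, `beta1`
#'   (coefficient of `log2(n)`), `beta2` (coefficient of `log2(k)`),
#'   `adj_r2` and the underlying `lm` fit.
#' @examples
#' rec <- expand.grid(n = c(4, 8, 16), k = c(16, 32))
#' rec$runtime_ms <- rec$n^2 * rec$k
#' fit_loglog(rec)
#' @export
fit_loglog <- function(records, runtime_col = "runtime_ms") {
  need <- c("n", "k", runtime_col)
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  if (nrow(records) < 4L)
    stop("at least 4 records are required")
  if (length(unique(records$n)) < 2L || length(unique(records$k)) < 2L)
    stop("rank-deficient design: need at least 2 distinct n and 2 distinct k")
  if (any(records[[runtime_col]] <= 0))
    stop("runtimes must be positive")
  df <- data.frame(y = log2(records[[runtime_col]]),
                   ln = log2(records$n), lk = log2(records$k))
  fit <- stats::lm(y ~ ln + lk, data = df)
  co <- stats::coef(fit)
  structure(list(beta0 = unname(co[["(Intercept)"]]),
                 beta1 = unname(co[["ln"]]),
                 beta2 = unname(co[["lk"]]),
                 adj_r2 = summary(fit)$adj.r.squared,
                 model = fit),
            class = "ia_loglog_fit")
}

#' @export
print.ia_loglog_fit <- function(x, ...) {
  cat(sprintf("log2(runtime) = %.3f + %.3f*log2(n) + %.3f*log2(k)   adj R^2 = %.4f\n",
              x$beta0, x$beta1, x$beta2, x$adj_r2))
  invisible(x)
}

#' Alignment-length ratio m = a / k
#'
#' `a` is the length of the root node's preliminary context and `k` the
#' longest leaf input length; `m` ranges from 1 (perfect alignment) to the
#' leaf count `n` (fully degenerate alignment).
#'
#' @param tree an `ia_tree` after [postorder_decorate()].
#' @return the ratio `a / k`.
#' @export
compute_m <- function(tree) {
  if (is.null(tree$prelim) || is.null(tree$prelim[[tree$root]]))
    stop("post-order decorations missing")
  if (tree$n_leaves < 1L) stop("tree has no leaves")
  k <- max(vapply(seq_len(tree$n_leaves),
                  function(i) nrow(tree$prelim[[i]]), 0L))
  if (k == 0L) stop("all leaf sequences are empty")
  nrow(tree$prelim[[tree$root]]) / k
}
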