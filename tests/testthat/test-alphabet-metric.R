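test_that("bundled cost matrices reproduce their defining values", {
  expect_equal(SIG0$costs["A", "-"], 2)
  expect_equal(SIG0$costs["A", "C"], 1)
  expect_equal(unname(diag(SIG0$costs)), rep(0, 5))
  expect_equal(SIG1$costs["A", "C"], 3)
  expect_equal(SIG1$costs["A", "-"], 1)
  # sigma3 is the discrete metric: 0 on the diagonal, 1 elsewhere
  off <- SIG3$costs[upper.tri(SIG3$costs)]
  expect_true(all(off == 1))
  expect_true(all(diag(SIG3$costs) == 0))
  expect_true(SIG0$integral && SIG1$integral && SIG3$integral)
})

test_that("malformed cost matrices raise distinct diagnostics", {
  expect_error(load_tcm("A C G T -\n0 1\n1 0"), "not square")
  expect_error(load_tcm("A C G T -\n0 1 1 1 2\n2 0 1 1 2\n1 1 0 1 2\n1 1 1 0 2\n2 2 2 2 0"),
               "asymmetric")
  expect_error(make_tcm(DNA, matrix(-1, 5, 5)), "negative")
  expect_error(load_tcm("A C G T -\n1 1 1 1 2\n1 1 1 1 2\n1 1 1 1 2\n1 1 1 1 2\n2 2 2 2 1"),
               "diagonal")
  expect_error(load_tcm("A C A T -\n0 1 1 1 2\n1 0 1 1 2\n1 1 0 1 2\n1 1 1 0 2\n2 2 2 2 0"),
               "duplicate")
  expect_error(load_tcm("A -\n0 1\n1 0"), "at least 3 symbols")
  expect_warning(load_tcm(system.file("extdata", "sigma1.tcm",
                                      package = "impliedalign")),
                 "triangle")
})

test_that("subset cost and median match the exhaustive definition", {
  cases <- list(list("A", "A", SIG0), list("A", "C", SIG0),
                list("AC", "CG", SIG0), list("A", "C", SIG1),
                list("AG", "T", SIG1), list("ACGT", "-", SIG3))
  for (cs in cases) {
    got <- subset_cost_median(cs[[1]], cs[[2]], cs[[3]])
    want <- bf_subset(strsplit(cs[[1]], "")[[1]], strsplit(cs[[2]], "")[[1]],
                      cs[[3]])
    expect_equal(got$cost, want$cost)
    expect_setequal(set_decode(got$median, cs[[3]]$alphabet), want$median)
  }
  # frozen values, derived from the exhaustive definition above
  expect_equal(subset_cost_median("A", "A", SIG0),
               list(cost = 0, median = bits("A")))
  expect_equal(subset_cost_median("A", "C", SIG0),
               list(cost = 1, median = bits("AC")))
  expect_equal(subset_cost_median("AC", "CG", SIG0),
               list(cost = 0, median = bits("C")))
})

test_that("subset cost/median is commutative and consistent on singletons", {
  ns <- 5L
  M <- bitwShiftL(1L, ns) - 1L
  for (metric in list(SIG0, SIG1)) {
    for (x in 1:M) for (y in x:M) {
      a <- subset_cost_median(x, y, metric)
      b <- subset_cost_median(y, x, metric)
      expect_identical(a, b)
    }
  }
  syms <- DNA$symbols
  for (i in seq_along(syms)) for (j in seq_along(syms)) {
    r <- subset_cost_median(syms[i], syms[j], SIG0)
    expect_equal(r$cost, SIG0$costs[i, j])
    if (i == j) {
      expect_equal(r$cost, 0)
      expect_equal(r$median, bits(syms[i]))
    }
  }
})

test_that("the tagged alphabet over x symbols has 2^(2x) representable values", {
  a3 <- ia_alphabet(c("A", "B", "-"))
  sets <- 1:(2^3 - 1)
  count <- 0L
  for (x in sets) for (y in sets)
    count <- count + inherits(try(ia_element("BOTH", x, y), silent = TRUE),
                              "ia_element")
  for (x in sets) {
    count <- count + inherits(try(ia_element("LEFT", x), silent = TRUE),
                              "ia_element")
    count <- count + inherits(try(ia_element("RIGHT", y = x), silent = TRUE),
                              "ia_element")
  }
  count <- count + inherits(ia_element("GAPPED"), "ia_element")
  expect_equal(count, 2^(2 * 3))
  # malformed payload shapes are rejected
  expect_error(ia_element("LEFT", 1L, 2L), "payload shape")
  expect_error(ia_element("GAPPED", 1L), "payload shape")
})

test_that("tag codec is a two-bit bijection", {
  tags <- c("BOTH", "LEFT", "RIGHT", "GAPPED")
  codes <- tag_encode(tags)
  expect_length(unique(codes), 4L)
  expect_true(all(codes >= 0L & codes < 4L))
  expect_identical(tag_decode(codes), tags)
  expect_identical(tag_encode(tag_decode(0:3)), 0:3)
  expect_error(tag_decode(4L), "0..3")
  expect_error(tag_encode("MIDDLE"), "unknown tag")
})

test_that("effective sets follow the projection rules", {
  expect_equal(effective_set(el("BOTH", "A", "C"), SIG0), bits("AC"))
  expect_equal(effective_set(el("BOTH", "A", "A"), SIG1), bits("A"))
  expect_equal(effective_set(el("GAPPED"), SIG0), bits("-"))
  # DO convention: indel-derived elements include the gap
  expect_equal(effective_set(el("LEFT", "G"), SIG1), bits("G-"))
  expect_equal(effective_set(el("RIGHT", y = "G"), SIG1), bits("G-"))
  # gap-exclusive variant
  expect_equal(effective_set(el("LEFT", "G"), SIG1X), bits("G"))
  expect_equal(effective_set(el("LEFT", "G-"), SIG1X), bits("G"))
  expect_equal(effective_set(el("LEFT", "-"), SIG1X), bits("-"))
})

test_that("symbol-set codecs validate and round-trip", {
  expect_equal(set_decode(bits("AG"), DNA), c("A", "G"))
  expect_equal(bits("GA"), bits("AG"))
  expect_error(set_encode("Z", DNA), "not in alphabet")
  expect_error(set_decode(0L, DNA), "nonempty")
  expect_error(ia_alphabet(c("A", "A", "-")), "duplicate")
  expect_error(ia_alphabet(c("AB", "C", "-")), "single characters")
  expect_error(ia_alphabet(c("A", "C", "G"), gap = "-"), "not a member")
})
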