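fl <- fixture_landscape()

test_that("path enumeration yields exactly k! paths for k = 0..4", {
  expect_equal(nrow(enumerate_paths(fl, "1000", "1000")), 1) # trivial path
  expect_equal(nrow(enumerate_paths(fl, "1000", "1010")), 1)
  expect_equal(nrow(enumerate_paths(fl, "1000", "1011")), 2)
  expect_equal(nrow(enumerate_paths(fl, "1000", "1111")), 6)
  expect_equal(nrow(enumerate_paths(fl, "0000", "1111")), 24)
  # every path steps by exactly one added deletion
  p <- enumerate_paths(fl, "1000", "1111")
  for (gts in p$genotypes) {
    bits <- vapply(gts, function(g) sum(utf8ToInt(g) == utf8ToInt("1")),
                   numeric(1))
    expect_equal(unname(diff(bits)), rep(1, length(gts) - 1))
  }
  expect_error(enumerate_paths(fl, "1010", "1100"), "reverted")
})

test_that("accessible paths match a brute-force monotonicity filter", {
  brute_accessible <- function(lsc, start, end, delta = 0) {
    p <- enumerate_paths(lsc, start, end)
    keep <- vapply(p$genotypes, function(gts) {
      w <- landscape_rate(lsc, gts)
      all(diff(w) > delta)
    }, logical(1))
    sort(p$order[keep])
  }
  got <- accessible_paths(fl, "1000", "1111", criterion = "epsilon")
  expect_equal(sort(got$order), brute_accessible(fl, "1000", "1111"))
  # only orderings with BEM2 last survive on the fixture
  expect_setequal(got$order, c("BEM3>NRP1>BEM2", "NRP1>BEM3>BEM2"))
  # z criterion agrees on this landscape (all true gains are many SE wide)
  got_z <- accessible_paths(fl, "1000", "1111", criterion = "z")
  expect_setequal(got_z$order, got$order)
})

test_that("accessibility is monotone in the epsilon margin", {
  deltas <- c(0, 0.01, 0.05, 0.1, 0.5)
  n_acc <- vapply(deltas, function(d) {
    nrow(accessible_paths(fl, "1000", "1111", criterion = "epsilon",
                          delta = d))
  }, numeric(1))
  expect_true(all(diff(n_acc) <= 0))
  # a flat landscape with positive margin admits no paths
  flat <- neutral_landscape()
  expect_equal(nrow(accessible_paths(flat, "1000", "1111",
                                     criterion = "epsilon", delta = 0.01)), 0)
  # strictly increasing toy landscape: all 6 paths accessible
  inc <- fitness_landscape(tibble::tibble(
    genotype = all_genotypes(4),
    rate = 0.1 + 0.1 * vapply(all_genotypes(4), function(g) {
      sum(as.integer(strsplit(g, "")[[1]]))
    }, numeric(1))
  ))
  expect_equal(nrow(accessible_paths(inc, "1000", "1111",
                                     criterion = "epsilon")), 6)
})

test_that("unevaluable paths are flagged rather than dropped", {
  part <- fitness_landscape(
    dplyr::filter(tibble::as_tibble(fl), genotype != "1010")
  )
  p <- accessible_paths(part, "1000", "1111", criterion = "epsilon")
  expect_true(any(p$unevaluable))
  expect_true(all(is.na(p$min_step_gain[p$unevaluable])))
})

test_that("epistasis classification covers the sign-pattern enumeration", {
  gts <- all_genotypes(4)
  nbit <- function(g) sum(as.integer(strsplit(g, "")[[1]]))
  bit <- function(g, i) as.integer(substr(g, i, i))
  # additive landscape -> none (for any pair, any background)
  add <- fitness_landscape(tibble::tibble(
    genotype = gts,
    rate = vapply(gts, function(g) {
      0.5 - 0.05 * bit(g, 1) - 0.02 * bit(g, 2) + 0.03 * bit(g, 3)
    }, numeric(1))
  ))
  expect_equal(epistasis_class(add, "BEM1", "BEM2", "0000")$class, "none")
  expect_equal(epistasis_class(add, "BEM2", "BEM3", "1001")$class, "none")
  # magnitude: same signs, non-additive
  mag <- fitness_landscape(tibble::tibble(
    genotype = gts,
    rate = vapply(gts, function(g) {
      0.2 + 0.1 * bit(g, 3) + 0.1 * bit(g, 4) + 0.15 * bit(g, 3) * bit(g, 4)
    }, numeric(1))
  ))
  expect_equal(epistasis_class(mag, "BEM3", "NRP1", "0000")$class, "magnitude")
  # sign: w(ab) > w(a) > w(0) > w(b)
  sgn <- fitness_landscape(tibble::tibble(
    genotype = c("0000", "0100", "0010", "0110"),
    rate = c(0.3, 0.2, 0.4, 0.5)
  ), loci = c("BEM1", "BEM2", "BEM3", "NRP1"))
  cl <- epistasis_class(sgn, "BEM2", "BEM3", "0000")
  expect_equal(cl$class, "sign")
  expect_lt(cl$effect_a_given_b_intact, 0)
  expect_gt(cl$effect_a_given_b_deleted, 0)
  # XOR-like: only single mutants fit -> reciprocal sign
  xor <- fitness_landscape(tibble::tibble(
    genotype = c("0000", "0100", "0010", "0110"),
    rate = c(0.1, 0.4, 0.4, 0.1)
  ))
  expect_equal(epistasis_class(xor, "BEM2", "BEM3", "0000")$class,
               "reciprocal_sign")
  expect_error(epistasis_class(sgn, "BEM2", "NRP1", "0000"), "missing genotype")
})

test_that("epistasis class is symmetric under locus relabeling", {
  for (bg in c("0000", "1000")) {
    a <- epistasis_class(fl, "BEM2", "NRP1", bg)
    b <- epistasis_class(fl, "NRP1", "BEM2", bg)
    expect_equal(a$class, b$class)
    expect_equal(a$epsilon, b$epsilon)
    expect_equal(a$effect_a_given_b_intact, b$effect_b_given_a_intact)
  }
})

test_that("fixture landscape encodes the observed qualitative structure", {
  w <- function(g) landscape_rate(fl, g)
  # the observed trajectory is monotonically beneficial
  expect_true(w("1010") > w("1000") && w("1011") > w("1010") &&
                w("1111") > w("1011"))
  # deleting BEM2 helps only after both BEM3 and NRP1 are gone
  for (g in setdiff(fl$genotype, c("1011", "0100", "0101", "0110", "0111",
                                   "1100", "1101", "1110", "1111"))) {
    bits <- as.integer(strsplit(g, "")[[1]])
    if (bits[2] == 1) next
    with_bem2 <- paste0(substr(g, 1, 1), "1", substr(g, 3, 4))
    expect_lte(w(with_bem2), w(g))
  }
  expect_gt(w("1111"), w("1011"))
  # ~12-fold wild-type to bem1-deleted ratio
  expect_equal(w("0000") / w("1000"), 12, tolerance = 0.05)
})

test_that("bem1_dependence reports the sign flip across backgrounds", {
  dep <- bem1_dependence(fl)
  expect_equal(nrow(dep), 8)
  # restoring BEM1 in the wild-type background is strongly beneficial
  expect_gt(dep$effect[dep$background == "000"], 0.4)
  # ... and slightly deleterious in the triple-deletion background
  expect_lt(dep$effect[dep$background == "111"], 0)
  expect_equal(dep$se, rep(sqrt(2 * 0.008^2), 8))
  # equal states give zero effect
  eq <- fitness_landscape(tibble::tibble(
    genotype = c("0000", "1000"), rate = 0.3, se = c(0.01, 0.02)
  ))
  dep_eq <- suppressWarnings(bem1_dependence(eq))
  expect_equal(dep_eq$effect, 0)
  expect_equal(dep_eq$se, sqrt(0.01^2 + 0.02^2))
  # missing backgrounds warn (once each) instead of failing
  msgs <- capture_warnings(bem1_dependence(eq))
  expect_true(all(grepl("skipping", msgs)))
  expect_length(msgs, 7)
})

test_that("landscape round-trips through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape_csv(fl, path)
  back <- read_landscape_csv(path)
  expect_equal(landscape_loci(back), landscape_loci(fl))
  expect_equal(back$genotype, fl$genotype)
  expect_equal(back$rate, fl$rate)
})
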