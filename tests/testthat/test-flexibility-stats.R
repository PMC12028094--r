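test_that("frequency_map normalizes over non-Z frames and flags empty positions", {
  labels <- rbind(
    c("Z", "m", "Z"),
    c("Z", "m", "Z"),
    c("Z", "m", "Z"),
    c("Z", "d", "Z")
  )
  fm <- frequency_map(pb_trajectory(labels, 4:6))
  expect_equal(fm$m[fm$position == 5], 0.75)
  expect_equal(fm$d[fm$position == 5], 0.25)
  expect_identical(fm$n_frames, c(0L, 4L, 0L))
  # empty positions are flagged (n_frames 0, NA frequencies), not NaN rows
  expect_true(all(is.na(fm$a[fm$n_frames == 0])))
  # non-empty rows sum to 1
  expect_equal(sum(fm[fm$position == 5, letters[1:16]]), 1, tolerance = 1e-12)
})

test_that("neq hits its analytic boundary and midpoint values", {
  expect_identical(neq(c(1, rep(0, 15))), 1)
  expect_equal(neq(rep(1 / 16, 16)), 16, tolerance = 1e-12)
  expect_equal(neq(c(0.5, 0.5, rep(0, 14))), 2, tolerance = 1e-12)
  expect_true(is.na(neq(rep(NA_real_, 16))))
  expect_error(neq(c(0.7, 0.7, rep(0, 14))), "sum to 1")
})

test_that("neq stays in [1,16], is 1 iff one PB dominates, and is label-invariant", {
  set.seed(5)
  for (i in 1:200) {
    f <- random_profile()
    v <- neq(f)
    expect_gte(v, 1)
    expect_lte(v, 16)
    expect_gt(v, 1) # all components positive here, so never exactly 1
    expect_equal(neq(sample(f)), v, tolerance = 1e-12)
  }
})

test_that("delta_neq is the symmetric absolute difference (8.7 vs 5.7 gives 3.0)", {
  a <- tibble::tibble(position = c(949, 950), neq = c(2.0, 8.7))
  b <- tibble::tibble(position = c(949, 950), neq = c(2.0, 5.7))
  d_ab <- delta_neq(a, b)
  expect_equal(d_ab$delta_neq, c(0, 3.0))
  expect_equal(delta_neq(b, a)$delta_neq, d_ab$delta_neq)
  expect_equal(delta_neq(a, a)$delta_neq, c(0, 0))
  b_bad <- tibble::tibble(position = c(949, 951), neq = c(2.0, 5.7))
  expect_error(delta_neq(a, b_bad), "951")
})

test_that("delta_pb spans [0,2] with the documented boundary cases", {
  self <- make_freq(list(`1` = c(m = 1)))
  expect_equal(delta_pb(self, self)$delta_pb, 0)
  other <- make_freq(list(`1` = c(d = 1)))
  expect_equal(delta_pb(self, other)$delta_pb, 2)
  half <- make_freq(list(`1` = c(m = 0.5, d = 0.5)))
  expect_equal(delta_pb(self, half)$delta_pb, 1.0)
})

test_that("delta_pb is a metric on normalized profiles", {
  set.seed(17)
  l1 <- function(a, b) sum(abs(a - b))
  for (i in 1:300) {
    a <- random_profile()
    b <- random_profile()
    cc <- random_profile()
    fa <- make_freq(list(`1` = a))
    fb <- make_freq(list(`1` = b))
    fc <- make_freq(list(`1` = cc))
    expect_equal(delta_pb(fa, fb)$delta_pb, delta_pb(fb, fa)$delta_pb)
    expect_equal(delta_pb(fa, fa)$delta_pb, 0)
    expect_lte(
      delta_pb(fa, fc)$delta_pb,
      delta_pb(fa, fb)$delta_pb + delta_pb(fb, fc)$delta_pb + 1e-12
    )
    expect_equal(delta_pb(fa, fb)$delta_pb, l1(a, b), tolerance = 1e-12)
  }
})

test_that("equal N_eq does not imply equal PB profiles", {
  # same frequencies on distinct labels: identical entropy, maximal delta_pb
  a <- make_freq(list(`1` = c(m = 0.5, n = 0.5)))
  b <- make_freq(list(`1` = c(d = 0.5, e = 0.5)))
  na <- neq_profile(a)$neq
  nb <- neq_profile(b)$neq
  expect_equal(na, nb)
  expect_equal(delta_neq(neq_profile(a), neq_profile(b))$delta_neq, 0)
  expect_gt(delta_pb(a, b)$delta_pb, 0)
})

test_that("delta_pb zero forces delta_neq zero", {
  set.seed(29)
  for (i in 1:20) {
    f <- random_profile()
    fa <- make_freq(list(`1` = f))
    expect_equal(delta_pb(fa, fa)$delta_pb, 0)
    expect_equal(
      delta_neq(neq_profile(fa), neq_profile(fa))$delta_neq, 0
    )
  }
})

test_that("categorization follows the six-bin table with rigid pinned at 1", {
  expect_identical(as.character(categorize(1.0)), "rigid")
  expect_identical(as.character(categorize(1 + 1e-9)), "rigid")
  expect_identical(as.character(categorize(1.5)), "quite_rigid")
  expect_identical(as.character(categorize(2.0)), "quite_rigid")
  expect_identical(as.character(categorize(3.0)), "moderate")
  expect_identical(as.character(categorize(4.5)), "flexible")
  expect_identical(as.character(categorize(7.0)), "extremely_flexible")
  expect_identical(as.character(categorize(8.09)), "disordered")
  expect_identical(as.character(categorize(16)), "disordered")
  expect_true(is.na(categorize(NA_real_)))
  expect_error(categorize(0.5), "out of")
  expect_error(categorize(17), "out of")
})

test_that("category percentages are over categorized positions and sum to 100", {
  flex <- tibble::tibble(
    position = 1:4,
    neq = c(1.0, 8.5, NA, 1.0),
    category = categorize(c(1.0, 8.5, NA, 1.0))
  )
  cs <- category_summary(flex)
  expect_equal(sum(cs$percent), 100, tolerance = 1e-9)
  expect_equal(cs$percent[cs$category == "rigid"], 200 / 3, tolerance = 1e-9)
  expect_equal(cs$percent[cs$category == "disordered"], 100 / 3, tolerance = 1e-9)
  all_rigid <- tibble::tibble(category = categorize(rep(1, 5)))
  cs2 <- category_summary(all_rigid)
  expect_equal(cs2$percent[cs2$category == "rigid"], 100)
  expect_equal(sum(cs2$percent), 100) # zero-count categories kept at 0

})

test_that("pearson handles exact linearity, pairwise deletion and zero variance", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_true(is.na(pearson(x, rep(2, 5))))
  # pairwise deletion: NAs dropped in either series
  expect_equal(pearson(c(x, NA), c(2 * x + 1, 3)), 1)
  expect_error(pearson(c(1, NA, NA, NA), c(1, 2, 3, 4)), "fewer than 3")
})

test_that("logo_matrix extracts labelled frequency rows over a range", {
  fm <- make_freq(list(`10` = c(f = 1), `11` = c(m = 0.5, d = 0.5)))
  m <- logo_matrix(fm)
  expect_identical(dim(m), c(2L, 16L))
  expect_identical(colnames(m), letters[1:16])
  expect_equal(unname(m["10", "f"]), 1)
  expect_equal(unname(rowSums(m)), c(1, 1))
  expect_warning(out <- logo_matrix(fm, c(900, 950)), "outside")
  expect_identical(nrow(out), 0L)
})

test_that("pooled replicates give the frame-count-weighted mean of per-replicate maps", {
  set.seed(61)
  tmpls <- list(helix_template(9), strand_template(9))
  s1 <- sample_dihedral_frames(tmpls, c(0.5, 0.5), n_frames = 30, seed = 1)
  s2 <- sample_dihedral_frames(tmpls, c(0.2, 0.8), n_frames = 70, seed = 2)
  t1 <- assign_ensemble(s1)
  t2 <- assign_ensemble(s2)
  pooled <- pb_trajectory(rbind(t1$labels, t2$labels), t1$positions)
  fm_pooled <- frequency_map(pooled)
  f1 <- frequency_map(t1)
  f2 <- frequency_map(t2)
  lab <- letters[1:16]
  ok <- fm_pooled$n_frames > 0
  weighted <- (as.matrix(f1[ok, lab]) * f1$n_frames[ok] +
    as.matrix(f2[ok, lab]) * f2$n_frames[ok]) /
    (f1$n_frames[ok] + f2$n_frames[ok])
  expect_equal(as.matrix(fm_pooled[ok, lab]), weighted, tolerance = 1e-12)
})
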