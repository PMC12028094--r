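test_that("torsion follows the IUPAC convention on planar and orthogonal cases", {
  expect_equal(torsion(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(torsion(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  # sign frozen from an independent atan2 formulation (and bio3d::torsion.xyz)
  expect_equal(torsion(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
})

test_that("torsion agrees with bio3d's implementation on random quadruples", {
  set.seed(11)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(
      torsion(p[1, ], p[2, ], p[3, ], p[4, ]),
      as.numeric(bio3d::torsion.xyz(as.vector(t(p)))),
      tolerance = 1e-8
    )
  }
})

test_that("torsion errors on degenerate geometry instead of returning NaN", {
  expect_error(torsion(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0), c(0, 1, 0)), "degenerate")
  # three collinear consecutive points
  expect_error(torsion(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)), "degenerate")
})

test_that("torsion is invariant under rigid motion and antisymmetric under reversal", {
  set.seed(7)
  for (i in 1:10) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    a <- torsion(p[1, ], p[2, ], p[3, ], p[4, ])
    # random proper rotation via QR
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    t0 <- rnorm(3, sd = 10)
    pr <- sweep(p %*% t(q), 2, t0, "+")
    expect_equal(torsion(pr[1, ], pr[2, ], pr[3, ], pr[4, ]), a, tolerance = 1e-8)
    b <- torsion(p[4, ], p[3, ], p[2, ], p[1, ])
    expect_equal(wrap180(a - b), 0, tolerance = 1e-8) # reversal preserves value
  }
})

test_that("backbone dihedrals recover the angles an ideal chain was built with", {
  ch <- build_chain(rep(-57, 12), rep(-47, 12))
  dh <- backbone_dihedrals(ch)
  expect_equal(unname(dh$phi[1, -1]), rep(-57, 11), tolerance = 1e-9)
  expect_equal(unname(dh$psi[1, -12]), rep(-47, 11), tolerance = 1e-9)
  expect_true(is.na(dh$phi[1, 1]) && is.na(dh$psi[1, 12]))
})

test_that("dihedral termini rule and frame count are preserved", {
  tmpl <- helix_template(2)
  ch <- build_chain(tmpl$phi, tmpl$psi)
  two <- conf_ensemble(
    array(rep(ch$coords, 2), c(dim(ch$coords)[1:2], 2)), ch$atoms
  )
  dh <- backbone_dihedrals(two)
  expect_equal(nrow(dh$phi), 2) # frames in = frames out
  expect_true(is.na(dh$phi[1, 1]) && !is.na(dh$phi[1, 2]))
  expect_true(!is.na(dh$psi[1, 1]) && is.na(dh$psi[1, 2]))
})

test_that("superpose removes rigid motion exactly and is a proper rotation", {
  set.seed(3)
  x <- matrix(rnorm(30), 10, 3)
  self <- superpose(x, x)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  y <- sweep(x %*% t(q), 2, c(3, -2, 7), "+")
  fit <- superpose(y, x)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(x[1:2, ], x[1:2, ]), "3 points")
})

test_that("superpose residual for a uniformly scaled copy matches a brute-force minimum", {
  # unit square vs the same square scaled by 2, both planar
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  fit <- superpose(sq * 2, sq)
  # independent oracle: numerically minimise RMSD over rotation angle +
  # translation in the plane
  obj <- function(par) {
    th <- par[1]
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    moved <- sweep((sq[, 1:2] * 2) %*% t(R), 2, par[2:3], "+")
    sqrt(mean(rowSums((moved - sq[, 1:2])^2)))
  }
  best <- stats::optim(c(0, 0, 0), obj, method = "BFGS")$value
  expect_equal(fit$rmsd, best, tolerance = 1e-6)
  # and the Kabsch fit can never beat the unfitted distance
  expect_lte(fit$rmsd, sqrt(mean(rowSums((sq * 2 - sq)^2))))
})

test_that("rmsd_series is zero at the reference and for identical frames", {
  tmpl <- helix_template(8)
  base <- build_chain(tmpl$phi, tmpl$psi)
  ens <- conf_ensemble(
    array(rep(base$coords, 3), c(dim(base$coords)[1:2], 3)), base$atoms
  )
  # translate frame 3 rigidly
  ens$coords[, 1, 3] <- ens$coords[, 1, 3] + 3
  ens$coords[, 2, 3] <- ens$coords[, 2, 3] + 4
  rs <- rmsd_series(ens, reference_frame = 1)
  expect_equal(rs$rmsd, rep(0, 3), tolerance = 1e-9)
  expect_error(rmsd_series(ens, 9), "1..3")
})

test_that("rmsf is zero for a single frame and exact for an alternating atom", {
  tmpl <- helix_template(5)
  base <- build_chain(tmpl$phi, tmpl$psi)
  expect_equal(rmsf(base)$rmsf, rep(0, 5))
  # CA of residue 3 alternates between x and x+2 over many frames: RMSF 1.0
  nf <- 40
  ens <- conf_ensemble(
    array(rep(base$coords, nf), c(dim(base$coords)[1:2], nf)), base$atoms
  )
  ca3 <- which(base$atoms$elety == "CA" & base$atoms$resid == 3)
  ens$coords[ca3, 1, seq(2, nf, by = 2)] <- ens$coords[ca3, 1, 1] + 2
  prof <- rmsf(ens, fit = FALSE)
  expect_equal(prof$rmsf[3], 1.0, tolerance = 1e-12)
  expect_equal(prof$rmsf[-3], rep(0, 4), tolerance = 1e-12)
  expect_identical(attr(prof, "fit_mode"), "unfitted")
})

test_that("unfitted rmsf on isotropic Gaussian noise recovers sd*sqrt(3)", {
  tmpl <- helix_template(6)
  base <- build_chain(tmpl$phi, tmpl$psi)
  sigma <- 0.5
  nf <- 2000
  ens <- gaussian_ensemble(base, sd = sigma, n_frames = nf, seed = 104)
  prof <- rmsf(ens, fit = FALSE)
  # E|r - rbar|^2 = 3 sigma^2; MC standard error of the mean of chi2_3 terms
  expected <- sigma * sqrt(3)
  se <- sigma * sqrt(3) * sqrt(2 / (3 * nf)) / 2 # delta method on sqrt
  expect_true(all(abs(prof$rmsf - expected) < 3 * se + 1e-3 * expected))
})

test_that("fitted rmsf never exceeds unfitted rmsd-style fluctuation", {
  tmpl <- strand_template(6)
  base <- build_chain(tmpl$phi, tmpl$psi)
  ens <- gaussian_ensemble(base, sd = 0.3, n_frames = 50, seed = 9)
  # superposed frame pair RMSD <= unfitted RMSD, on every frame pair sampled
  ca <- ca_coords(ens)
  for (f in c(2, 17, 41)) {
    unfit <- sqrt(mean(rowSums((ca[, , f] - ca[, , 1])^2)))
    expect_lte(superpose(ca[, , f], ca[, , 1])$rmsd, unfit + 1e-12)
  }
})
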