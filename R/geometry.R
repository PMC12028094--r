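#' Torsion (dihedral) angle between four points
#'
#' Computes the torsion angle p1-p2-p3-p4 under the IUPAC sign convention
#' (cis = 0 degrees, trans = 180 degrees), returned in degrees in
#' `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 numeric length-3 vectors, Cartesian coordinates in
#'   Angstrom.
#' @return The torsion angle in degrees.
#' @details Degenerate geometry (coincident consecutive points, or three
#'   consecutive collinear points) is an error, never a silent `NaN`.
#' @examples
#' torsion(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)) # cis, 0
#' torsion(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)) # trans, 180
#' @export
torsion <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == 3, length(p2) == 3, length(p3) == 3, length(p4) == 3)
  out <- unname(torsion_many(
    matrix(p1, 1), matrix(p2, 1), matrix(p3, 1), matrix(p4, 1)
  ))
  if (is.na(out)) abort("degenerate geometry: coincident or collinear points")
  out
}

# vectorised torsion: each argument an m x 3 matrix; returns m angles (deg).
# Degenerate rows and rows with NA coordinates yield NA.
torsion_many <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(
      a[, 2] * b[, 3] - a[, 3] * b[, 2],
      a[, 3] * b[, 1] - a[, 1] * b[, 3],
      a[, 1] * b[, 2] - a[, 2] * b[, 1]
    )
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * (b2 / b2n))
  bad <- !is.finite(b2n) | b2n < 1e-10 |
    rowSums(n1^2) < 1e-20 | rowSums(n2^2) < 1e-20
  ang <- wrap_angle(atan2(y, x) * 180 / pi)
  ang[bad] <- NA_real_
  ang
}

#' Backbone phi/psi dihedral series of an ensemble
#'
#' Extracts, for every frame and residue, the backbone dihedrals
#' `phi_i = torsion(C_{i-1}, N_i, CA_i, C_i)` and
#' `psi_i = torsion(N_i, CA_i, C_i, N_{i+1})`.
#' Phi is undefined at the first residue and psi at the last; both are
#' undefined around incomplete residues (with a warning).
#'
#' @param ensemble a [conf_ensemble()].
#' @return A `dihedral_series`: a list with matrices `phi` and `psi`
#'   (`n_frames x n_residues`, degrees in `(-180, 180]`, `NA` where
#'   undefined) and the author-numbered `positions`. Convert with
#'   [as_tibble()] to a long `frame, position, phi, psi` tibble.
#' @export
backbone_dihedrals <- function(ensemble) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  pos <- positions(ensemble)
  nres <- length(pos)
  nf <- n_frames(ensemble)
  N <- atom_coords(ensemble, "N")
  CA <- atom_coords(ensemble, "CA")
  C <- atom_coords(ensemble, "C")

  flat <- function(a, res_idx) {
    # rows = frame-major pairs (residue res_idx, every frame) -> (nf*len) x 3
    m <- a[res_idx, , , drop = FALSE]
    matrix(aperm(m, c(3, 1, 2)), ncol = 3)
  }
  phi <- matrix(NA_real_, nf, nres)
  psi <- matrix(NA_real_, nf, nres)
  if (nres >= 2) {
    i <- 2:nres
    phi[, i] <- matrix(
      torsion_many(flat(C, i - 1L), flat(N, i), flat(CA, i), flat(C, i)),
      nrow = nf
    )
    j <- 1:(nres - 1)
    psi[, j] <- matrix(
      torsion_many(flat(N, j), flat(CA, j), flat(C, j), flat(N, j + 1L)),
      nrow = nf
    )
  }
  if (any(!ensemble$residues$complete)) {
    warn("incomplete residues: adjacent phi/psi set to undefined")
  }
  dihedral_series(phi, psi, pos)
}

#' @rdname backbone_dihedrals
#' @param phi,psi `n_frames x n_residues` matrices of angles in degrees.
#' @param positions integer vector of author residue numbers.
#' @export
dihedral_series <- function(phi, psi, positions) {
  stopifnot(
    is.matrix(phi), is.matrix(psi), all(dim(phi) == dim(psi)),
    ncol(phi) == length(positions)
  )
  vals <- c(phi, psi)
  vals <- vals[is.finite(vals)]
  if (length(vals) && (min(vals) <= -180 || max(vals) > 180)) {
    abort("angles must lie in (-180, 180]")
  }
  structure(
    list(phi = phi, psi = psi, positions = as.integer(positions)),
    class = "dihedral_series"
  )
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(
    "<dihedral_series> ", nrow(x$phi), " frame(s) x ", ncol(x$phi),
    " residue(s), positions ", min(x$positions), "-", max(x$positions), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @rdname backbone_dihedrals
#' @param x a `dihedral_series`.
#' @param ... ignored.
as_tibble.dihedral_series <- function(x, ...) {
  nf <- nrow(x$phi)
  tibble(
    frame = rep(seq_len(nf), times = ncol(x$phi)),
    position = rep(x$positions, each = nf),
    phi = as.vector(x$phi),
    psi = as.vector(x$psi)
  )
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired point sets, in closed form via singular value decomposition.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @return A list with `rotation` (3x3, determinant +1), `translation`
#'   (length 3), `rmsd` (Angstrom), and `transform(coords)`, a function
#'   applying the fit to any `m x 3` matrix.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3)
  if (nrow(mobile) != nrow(reference)) abort("point counts differ")
  if (nrow(mobile) < 3) abort("at least 3 points are required")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transform <- function(coords) {
    sweep(sweep(as.matrix(coords), 2, cm) %*% t(R), 2, cr, "+")
  }
  fitted <- transform(mobile)
  list(
    rotation = R,
    translation = cr - as.vector(R %*% cm),
    rmsd = sqrt(mean(rowSums((fitted - reference)^2))),
    transform = transform
  )
}

#' Per-frame Calpha RMSD against a reference frame
#'
#' Each frame is optimally superposed onto the reference frame (by default the
#' starting frame) on Calpha atoms, and the root mean square deviation of the
#' Calpha coordinates is reported.
#'
#' @param ensemble a [conf_ensemble()].
#' @param reference_frame index of the reference frame (default 1).
#' @return A tibble `frame, rmsd` (Angstrom); `rmsd` is 0 at the reference.
#' @export
rmsd_series <- function(ensemble, reference_frame = 1L) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  nf <- n_frames(ensemble)
  if (reference_frame < 1L || reference_frame > nf) {
    abort(paste0("reference_frame must be in 1..", nf))
  }
  ca <- ca_coords(ensemble)
  ok <- stats::complete.cases(ca[, , reference_frame])
  ref <- ca[ok, , reference_frame]
  vals <- vapply(seq_len(nf), function(f) superpose(ca[ok, , f], ref)$rmsd, 1.0)
  tibble(frame = seq_len(nf), rmsd = vals)
}

#' Per-residue Calpha RMSF
#'
#' Root mean square fluctuation of each residue's Calpha about its mean
#' position over the frames. With `fit = TRUE` all frames are first superposed
#' onto the starting frame on Calpha atoms (one pass, no iterative mean
#' refitting); with `fit = FALSE` coordinates are used as given, which is the
#' mode whose expectation is analytically known for isotropic noise
#' (RMSF -> sd * sqrt(3)).
#'
#' @param ensemble a [conf_ensemble()].
#' @param fit superpose frames onto frame 1 before measuring? Default `TRUE`.
#' @return A tibble `position, rmsf` (Angstrom) with attribute `fit_mode`
#'   (`"fitted"` or `"unfitted"`); all zeros for a single-frame ensemble.
#' @export
rmsf <- function(ensemble, fit = TRUE) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  ca <- ca_coords(ensemble)
  nf <- dim(ca)[3]
  if (fit && nf > 1) {
    ok <- stats::complete.cases(ca[, , 1])
    ref <- ca[ok, , 1]
    for (f in seq_len(nf)) {
      ca[, , f] <- superpose(ca[ok, , f], ref)$transform(ca[, , f])
    }
  }
  mean_str <- apply(ca, c(1, 2), mean)
  dev2 <- sweep(ca, c(1, 2), mean_str)^2
  vals <- unname(sqrt(apply(dev2, 1, function(m) mean(colSums(m)))))
  out <- tibble(position = positions(ensemble), rmsf = vals)
  attr(out, "fit_mode") <- if (fit) "fitted" else "unfitted"
  out
}
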