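# Fixed internal-coordinate constants for synthetic backbone construction
# (standard peptide geometry; synthetic-data use only, not a modelling claim).
BOND_N_CA <- 1.458 # Angstrom
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
ANGLE_N_CA_C <- 111.2 # degrees
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
OMEGA <- 180 # trans peptide bond

# place atom D given A, B, C with |CD| = d, angle(B,C,D) = theta and
# torsion(A,B,C,D) = chi (degrees), matching torsion()'s sign convention
nerf_place <- function(A, B, C, d, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  local <- d * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  C + local[1] * bc + local[2] * m + local[3] * n
}

#' Build backbone coordinates from phi/psi dihedrals
#'
#' Sequential internal-coordinate (NeRF-style) chain extension: N, CA and C
#' atoms are placed residue by residue from fixed bond lengths (N-CA 1.458,
#' CA-C 1.525, C-N 1.329 Angstrom), fixed bond angles and a trans peptide
#' bond (omega = 180 degrees), with the supplied phi/psi torsions.
#' Recomputing torsions from the built chain reproduces the inputs, which
#' makes the builder an exact oracle for the dihedral-extraction and PB
#' assignment stages.
#'
#' @param phi,psi numeric vectors of torsions in degrees, one per residue;
#'   `phi[1]` and `psi[n]` are unused (undefined at chain termini) but any
#'   other `NA` is an error.
#' @param start_position author number of the first residue (default 1).
#' @param origin coordinates of the first N atom.
#' @return A single-frame [conf_ensemble()] with N, CA, C atoms per residue.
#' @examples
#' helix <- build_chain(rep(-57, 10), rep(-47, 10))
#' @export
build_chain <- function(phi, psi, start_position = 1L, origin = c(0, 0, 0)) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1L)
  if (n > 1 && (anyNA(phi[-1]) || anyNA(psi[-n]))) {
    abort("undefined interior phi/psi angle; only phi[1] and psi[n] may be NA")
  }
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- origin
  CA[1, ] <- origin + c(BOND_N_CA, 0, 0)
  th <- (180 - ANGLE_N_CA_C) * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(cos(th), sin(th), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], BOND_C_N, ANGLE_CA_C_N, psi[i])
    CA[i + 1L, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1L, ], BOND_N_CA, ANGLE_C_N_CA, OMEGA)
    C[i + 1L, ] <- nerf_place(C[i, ], N[i + 1L, ], CA[i + 1L, ], BOND_CA_C, ANGLE_N_CA_C, phi[i + 1L])
  }
  coords <- array(NA_real_, c(3L * n, 3L, 1L))
  ord <- rep(seq_len(n), each = 3L)
  # atoms interleaved N, CA, C per residue
  coords[, , 1] <- do.call(rbind, lapply(seq_len(n), function(i) rbind(N[i, ], CA[i, ], C[i, ])))
  atoms <- tibble(
    elety = rep(c("N", "CA", "C"), n),
    resid = as.integer(start_position) + ord - 1L,
    resname = "ALA",
    chain = "A"
  )
  conf_ensemble(coords, atoms)
}

#' Repetitive dihedral templates
#'
#' Whole-chain phi/psi templates with ideal repetitive backbone dihedrals:
#' `helix_template()` uses the canonical alpha-helix (phi = -57, psi = -47)
#' and `strand_template()` the extended beta-strand (phi = -120, psi = 135).
#' Termini (phi of the first residue, psi of the last) are `NA`.
#'
#' @param n_residues chain length.
#' @param start_position author number of the first residue.
#' @return A tibble `position, phi, psi` usable as a template for
#'   [sample_dihedral_frames()] or, columnwise, for [build_chain()].
#' @export
helix_template <- function(n_residues, start_position = 1L) {
  dihedral_template(n_residues, start_position, phi = -57, psi = -47)
}

#' @rdname helix_template
#' @export
strand_template <- function(n_residues, start_position = 1L) {
  dihedral_template(n_residues, start_position, phi = -120, psi = 135)
}

dihedral_template <- function(n_residues, start_position, phi, psi) {
  stopifnot(n_residues >= 1)
  tibble(
    position = as.integer(start_position) + seq_len(n_residues) - 1L,
    phi = c(NA_real_, rep(phi, n_residues - 1L)),
    psi = c(rep(psi, n_residues - 1L), NA_real_)
  )
}

#' Sample dihedral frames from a template mixture
#'
#' Each frame picks one of `K` whole-chain phi/psi templates with the given
#' mixture weights and adds wrapped Gaussian noise in angle space. Because
#' weights are known, the expected per-position N_eq of the resulting PB
#' trajectory is known in closed form at positions where the templates map to
#' distinct PBs — an exact ground truth for the whole pipeline. The sampled
#' frame-to-template assignment is recorded as an attribute.
#'
#' @param templates list of template tibbles (`position, phi, psi`), all on
#'   the same position axis, e.g. from [helix_template()].
#' @param weights mixture weights, non-negative, summing to 1.
#' @param n_frames number of frames to draw.
#' @param noise_sd standard deviation (degrees) of the Gaussian angular noise,
#'   re-wrapped to `(-180, 180]`. Default 0.
#' @param seed integer seed; every draw is reproducible from it.
#' @return A [dihedral_series()] with attributes `ground_truth` (tibble
#'   `frame, template`), `weights` and `seed`.
#' @export
sample_dihedral_frames <- function(templates, weights, n_frames,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(is.list(templates), length(templates) >= 1L)
  K <- length(templates)
  if (length(weights) != K || any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("weights must be non-negative, one per template, and sum to 1")
  }
  pos <- templates[[1]]$position
  for (tmpl in templates) {
    if (!identical(tmpl$position, pos)) abort("templates must share one position axis")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- sample.int(K, n_frames, replace = TRUE, prob = weights)
  phi_t <- vapply(templates, function(t) t$phi, numeric(length(pos)))
  psi_t <- vapply(templates, function(t) t$psi, numeric(length(pos)))
  phi <- t(phi_t[, k, drop = FALSE])
  psi <- t(psi_t[, k, drop = FALSE])
  if (noise_sd > 0) {
    add_noise <- function(m) {
      def <- !is.na(m)
      m[def] <- wrap_angle(m[def] + rnorm(sum(def), sd = noise_sd))
      m
    }
    phi <- add_noise(phi)
    psi <- add_noise(psi)
  }
  out <- dihedral_series(phi, psi, pos)
  attr(out, "ground_truth") <- tibble(frame = seq_len(n_frames), template = k)
  attr(out, "weights") <- weights
  attr(out, "seed") <- seed
  out
}

#' Materialise a dihedral series as a 3D ensemble
#'
#' Runs [build_chain()] on every frame, producing a backbone-only
#' [conf_ensemble()] whose recomputed dihedrals reproduce the input series.
#'
#' @param dihedrals a [dihedral_series()].
#' @return A [conf_ensemble()] with `n_frames` frames.
#' @export
ensemble_from_dihedrals <- function(dihedrals) {
  stopifnot(inherits(dihedrals, "dihedral_series"))
  nf <- nrow(dihedrals$phi)
  frames <- lapply(seq_len(nf), function(f) {
    build_chain(dihedrals$phi[f, ], dihedrals$psi[f, ],
      start_position = dihedrals$positions[1]
    )
  })
  coords <- array(
    unlist(lapply(frames, function(e) e$coords)),
    dim = c(dim(frames[[1]]$coords)[1:2], nf)
  )
  out <- conf_ensemble(coords, frames[[1]]$atoms)
  attr(out, "seed") <- attr(dihedrals, "seed")
  out
}

#' Gaussian positional-noise ensemble
#'
#' Frames are independent copies of a base structure with isotropic Gaussian
#' offsets added to every atom. The unfitted RMSF of such an ensemble
#' converges to `sd * sqrt(3)`, giving an exact recovery target for the
#' fluctuation stage.
#'
#' @param base a [conf_ensemble()]; its first frame is the base structure.
#' @param sd isotropic per-axis standard deviation (Angstrom); a scalar or
#'   one value per residue (applied to all atoms of the residue).
#' @param n_frames number of frames to draw.
#' @param seed integer seed.
#' @return A [conf_ensemble()] with attribute `seed`.
#' @export
gaussian_ensemble <- function(base, sd, n_frames, seed = NULL) {
  stopifnot(inherits(base, "conf_ensemble"), all(sd >= 0))
  base_xyz <- base$coords[, , 1]
  na <- nrow(base_xyz)
  if (length(sd) == 1L) {
    sd_atom <- rep(sd, na)
  } else {
    if (length(sd) != n_residues(base)) {
      abort("`sd` must be a scalar or one value per residue")
    }
    sd_atom <- sd[match(base$atoms$resid, positions(base))]
  }
  if (!is.null(seed)) set.seed(seed)
  noise <- array(rnorm(na * 3 * n_frames, sd = sd_atom), c(na, 3L, n_frames))
  coords <- array(base_xyz, c(na, 3L, n_frames)) + noise
  out <- conf_ensemble(coords, base$atoms)
  attr(out, "seed") <- seed
  out
}
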