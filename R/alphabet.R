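PB_LABELS <- letters[1:16]
PB_UNDEF <- "Z"
PB_ALPHABET_MD5 <- "df1e0de5c8b000d354f1b4d70b5556e3"

# the 8 dihedrals of the 5-residue window centred on residue i, in order
PB_WINDOW_LAYOUT <- c(
  "psi_m2", "phi_m1", "psi_m1", "phi_0", "psi_0", "phi_p1", "psi_p1", "phi_p2"
)

#' The Protein Block structural alphabet
#'
#' Loads the 16 Protein Block (PB) prototypes, labelled `a` to `p`. Each
#' prototype is defined by 8 reference dihedral angles (degrees) spanning the
#' phi/psi angles of five consecutive residues, in the order
#' psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1), phi(i+2);
#' the assignment is focused on the central residue i. PB `m` is the
#' alpha-helix core prototype and `d` the central beta-strand; `a`-`c` are
#' strand N-caps, `e`-`f` strand C-caps, `a`-`j` coils, `k`-`l` helix N-caps
#' and `n`-`p` helix C-caps.
#'
#' The reference table ships with the package as a versioned data file whose
#' md5 checksum is validated on load, along with its shape (16 rows x 8
#' angles) and angle range.
#'
#' @return A `pb_alphabet`: a 16 x 8 numeric matrix of reference angles with
#'   row names `a`-`p`, column names giving the window layout, and attribute
#'   `checksum`.
#' @examples
#' alpha <- pb_alphabet()
#' nrow(alpha) # 16 prototypes
#' @export
pb_alphabet <- function() {
  path <- system.file("extdata", "pb_reference_angles.csv",
    package = "pbflex", mustWork = TRUE
  )
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, PB_ALPHABET_MD5)) {
    abort("PB reference-angle file checksum mismatch; installation is corrupt")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(tab$pb, PB_LABELS) || ncol(tab) != 9L) {
    abort("PB reference-angle table must have 16 rows (a-p) and 8 angle columns")
  }
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$pb
  colnames(m) <- PB_WINDOW_LAYOUT
  if (any(m <= -180 | m > 180)) {
    abort("PB reference angles must lie in (-180, 180]")
  }
  structure(m, class = c("pb_alphabet", "matrix", "array"), checksum = sum)
}

#' @export
print.pb_alphabet <- function(x, ...) {
  cat("<pb_alphabet> 16 Protein Block prototypes (a-p), 8 reference dihedrals each\n")
  print(unclass(x))
  invisible(x)
}

#' Angular root mean square deviation (RMSDA) between two dihedral windows
#'
#' The distance used to match an observed 8-dihedral window to its nearest PB
#' prototype: the root mean square of the wrapped angular differences, where
#' each difference is reduced to `[-180, 180]` degrees.
#'
#' @param v,w numeric 8-vectors of angles in degrees.
#' @return Non-negative degrees, or `NA` if either input has an undefined
#'   component.
#' @export
rmsda <- function(v, w) {
  stopifnot(length(v) == length(w))
  if (anyNA(v) || anyNA(w)) return(NA_real_)
  sqrt(mean(angle_diff(v, w)^2))
}

#' Dihedral window vector for PB assignment
#'
#' The 8 dihedrals of the 5-residue window centred on `position`:
#' psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1), phi(i+2).
#' Undefined (`NA` throughout) when the position is within two residues of a
#' chain end, outside the chain, or any component angle is undefined.
#'
#' @param dihedrals a [dihedral_series()].
#' @param frame frame index.
#' @param position author residue number of the central residue.
#' @return Named numeric 8-vector (degrees), or all-`NA` if undefined.
#' @export
window_vector <- function(dihedrals, frame, position) {
  stopifnot(inherits(dihedrals, "dihedral_series"))
  und <- setNames(rep(NA_real_, 8), PB_WINDOW_LAYOUT)
  i <- match(position, dihedrals$positions)
  n <- length(dihedrals$positions)
  if (is.na(i) || i < 3L || i > n - 2L) return(und)
  phi <- dihedrals$phi[frame, ]
  psi <- dihedrals$psi[frame, ]
  v <- setNames(
    c(
      psi[i - 2L], phi[i - 1L], psi[i - 1L], phi[i], psi[i],
      phi[i + 1L], psi[i + 1L], phi[i + 2L]
    ),
    PB_WINDOW_LAYOUT
  )
  if (anyNA(v)) und else v
}

#' Assign Protein Blocks to every residue of every frame
#'
#' Each assignable position receives the label of the prototype with minimal
#' RMSDA to its dihedral window; exact ties go to the first label in `a`-`p`
#' order. The two N-terminal and two C-terminal positions, and positions with
#' any undefined window angle, receive the unassignable label `Z`.
#'
#' @param dihedrals a [dihedral_series()].
#' @param alphabet a [pb_alphabet()].
#' @return `assign_ensemble()`: a `pb_trajectory` — a
#'   `n_frames x n_positions` character matrix of labels from `{a..p, Z}`
#'   plus author-numbered `positions`; use [as_tibble()] for a long
#'   `frame, position, pb` tibble. `assign_frame()`: a single PB string.
#' @export
assign_ensemble <- function(dihedrals, alphabet = pb_alphabet()) {
  stopifnot(inherits(dihedrals, "dihedral_series"))
  nf <- nrow(dihedrals$phi)
  n <- ncol(dihedrals$phi)
  labels <- matrix(PB_UNDEF, nf, n)
  if (n >= 5L) {
    centre <- 3:(n - 2L)
    phi <- dihedrals$phi
    psi <- dihedrals$psi
    # nf x n_centre x 8 window array, layout psi_m2 .. phi_p2
    win <- array(NA_real_, c(nf, length(centre), 8L))
    win[, , 1] <- psi[, centre - 2L]
    win[, , 2] <- phi[, centre - 1L]
    win[, , 3] <- psi[, centre - 1L]
    win[, , 4] <- phi[, centre]
    win[, , 5] <- psi[, centre]
    win[, , 6] <- phi[, centre + 1L]
    win[, , 7] <- psi[, centre + 1L]
    win[, , 8] <- phi[, centre + 2L]
    best <- matrix(Inf, nf, length(centre))
    lab <- matrix(NA_character_, nf, length(centre))
    for (r in seq_len(16L)) {
      d2 <- matrix(0, nf, length(centre))
      for (k in 1:8) d2 <- d2 + angle_diff(win[, , k], alphabet[r, k])^2
      better <- !is.na(d2) & d2 < best # strict: ties keep earlier label
      lab[better] <- PB_LABELS[r]
      best[better] <- d2[better]
    }
    lab[is.na(lab)] <- PB_UNDEF
    labels[, centre] <- lab
  }
  pb_trajectory(labels, dihedrals$positions)
}

#' @rdname assign_ensemble
#' @param frame frame index.
#' @export
assign_frame <- function(dihedrals, frame, alphabet = pb_alphabet()) {
  stopifnot(inherits(dihedrals, "dihedral_series"))
  sub <- dihedral_series(
    dihedrals$phi[frame, , drop = FALSE],
    dihedrals$psi[frame, , drop = FALSE],
    dihedrals$positions
  )
  paste(assign_ensemble(sub, alphabet)$labels[1, ], collapse = "")
}

#' @rdname assign_ensemble
#' @param labels `n_frames x n_positions` character matrix over `{a..p, Z}`.
#' @param positions integer author residue numbers.
#' @export
pb_trajectory <- function(labels, positions) {
  stopifnot(is.matrix(labels), ncol(labels) == length(positions))
  bad <- !(labels %in% c(PB_LABELS, PB_UNDEF))
  if (any(bad)) {
    abort(paste0("invalid PB label(s): ", paste(unique(labels[bad]), collapse = ", ")))
  }
  structure(
    list(labels = labels, positions = as.integer(positions)),
    class = "pb_trajectory"
  )
}

#' @export
print.pb_trajectory <- function(x, ...) {
  cat(
    "<pb_trajectory> ", nrow(x$labels), " frame(s) x ", ncol(x$labels),
    " position(s)\n  frame 1: ", paste(x$labels[1, ], collapse = ""), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @rdname assign_ensemble
#' @param x a `pb_trajectory`.
#' @param ... ignored.
as_tibble.pb_trajectory <- function(x, ...) {
  nf <- nrow(x$labels)
  tibble(
    frame = rep(seq_len(nf), times = ncol(x$labels)),
    position = rep(x$positions, each = nf),
    pb = as.vector(x$labels)
  )
}
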