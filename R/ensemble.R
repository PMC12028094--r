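#' Conformational ensembles
#'
#' A `conf_ensemble` holds the Cartesian coordinates (in Angstrom) of one
#' protein chain over a series of frames, together with a per-atom table.
#' Every frame shares the identical atom table; positions are always reported
#' in author (PDB) residue numbering.
#'
#' @param coords numeric array of dimension `n_atoms x 3 x n_frames` (Angstrom).
#' @param atoms data frame with one row per atom and columns `elety` (atom
#'   name, e.g. `"CA"`), `resid` (author residue number, integer), `resname`
#'   (3-letter residue code) and `chain` (chain identifier).
#' @param replicate_id optional vector of length `n_frames` tagging the
#'   replicate each frame came from; kept for per-replicate statistics.
#'
#' @return An object of class `conf_ensemble`: a list with elements `coords`,
#'   `atoms` (tibble), `residues` (tibble with `position`, `resname`,
#'   `complete`), and `replicate_id`.
#'
#' @details A residue is flagged incomplete (with a warning) when any of its
#'   backbone atoms N, CA, C is absent; dihedrals touching such a residue are
#'   undefined downstream. Author residue numbers must be strictly increasing
#'   within the chain.
#'
#' @seealso [read_ensemble()], [gaussian_ensemble()], [build_chain()]
#' @export
conf_ensemble <- function(coords, atoms, replicate_id = NULL) {
  atoms <- as_tibble(atoms)
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(atoms)) {
    abort("number of atoms in `coords` and `atoms` differ")
  }
  needed <- c("elety", "resid", "resname", "chain")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("`atoms` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  atoms$resid <- as.integer(atoms$resid)
  if (length(unique(atoms$chain)) > 1L) {
    abort("multiple chains in one ensemble; select a single chain on input")
  }
  res_first <- atoms$resid[!duplicated(atoms$resid)]
  if (any(diff(res_first) <= 0L)) {
    abort("author residue numbers are not strictly increasing within the chain")
  }
  n_frames <- dim(coords)[3]
  if (!is.null(replicate_id) && length(replicate_id) != n_frames) {
    abort("`replicate_id` must have one entry per frame")
  }

  residues <- atoms |>
    dplyr::group_by(position = .data$resid) |>
    dplyr::summarise(
      resname = dplyr::first(.data$resname),
      complete = all(c("N", "CA", "C") %in% .data$elety),
      .groups = "drop"
    )
  if (any(!residues$complete)) {
    warn(paste0(
      "residue(s) ", paste(residues$position[!residues$complete], collapse = ", "),
      " lack backbone atoms (N, CA, C); flagged incomplete"
    ))
  }

  structure(
    list(
      coords = coords, atoms = atoms, residues = residues,
      replicate_id = replicate_id
    ),
    class = "conf_ensemble"
  )
}

#' @rdname conf_ensemble
#' @param x,ensemble a `conf_ensemble`.
#' @export
n_frames <- function(ensemble) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  dim(ensemble$coords)[3]
}

#' @rdname conf_ensemble
#' @export
n_residues <- function(ensemble) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  nrow(ensemble$residues)
}

#' @rdname conf_ensemble
#' @export
positions <- function(x) UseMethod("positions")

#' @export
positions.conf_ensemble <- function(x) x$residues$position

# coordinates of one named backbone atom per residue: n_res x 3 x n_frames,
# NA rows where the atom is absent
atom_coords <- function(ensemble, elety) {
  pos <- positions(ensemble)
  idx <- match(
    pos,
    ifelse(ensemble$atoms$elety == elety, ensemble$atoms$resid, NA_integer_)
  )
  out <- ensemble$coords[ifelse(is.na(idx), 1L, idx), , , drop = FALSE]
  out[is.na(idx), , ] <- NA_real_
  dimnames(out) <- list(pos, c("x", "y", "z"), NULL)
  out
}

#' @rdname conf_ensemble
#' @export
ca_coords <- function(ensemble) atom_coords(ensemble, "CA")

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(
    "<conf_ensemble> ", n_frames(x), " frame(s), ", n_residues(x),
    " residue(s), positions ", min(positions(x)), "-", max(positions(x)),
    ", chain ", unique(x$atoms$chain), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @rdname conf_ensemble
#' @param ... ignored.
as_tibble.conf_ensemble <- function(x, ...) {
  nf <- n_frames(x)
  na <- nrow(x$atoms)
  tibble(
    frame = rep(seq_len(nf), each = na),
    elety = rep(x$atoms$elety, nf),
    position = rep(x$atoms$resid, nf),
    resname = rep(x$atoms$resname, nf),
    chain = rep(x$atoms$chain, nf),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]),
    z = as.vector(x$coords[, 3, ])
  )
}

#' Pool frames of several ensembles into one
#'
#' Frames are concatenated in argument order (e.g. independent replicates
#' pooled into a single series for statistics); the atom tables must match
#' exactly. Each input's frames are tagged with a replicate identifier.
#'
#' @param ... `conf_ensemble` objects sharing an identical atom table.
#' @param replicate_ids optional character vector naming each input; defaults
#'   to `"rep1"`, `"rep2"`, ...
#' @return A pooled `conf_ensemble` whose `replicate_id` records provenance.
#' @export
pool_ensembles <- function(..., replicate_ids = NULL) {
  ens <- list(...)
  stopifnot(length(ens) >= 1L, all(vapply(ens, inherits, TRUE, "conf_ensemble")))
  ref <- ens[[1]]$atoms
  for (i in seq_along(ens)[-1]) {
    if (!identical(ref[c("elety", "resid", "resname", "chain")],
                   ens[[i]]$atoms[c("elety", "resid", "resname", "chain")])) {
      abort(paste0("atom table of input ", i, " differs from input 1; cannot pool"))
    }
  }
  replicate_ids <- replicate_ids %||% paste0("rep", seq_along(ens))
  coords <- array(
    unlist(lapply(ens, function(e) e$coords)),
    dim = c(nrow(ref), 3L, sum(vapply(ens, n_frames, 1L)))
  )
  rep_id <- rep(replicate_ids, vapply(ens, n_frames, 1L))
  conf_ensemble(coords, ref, replicate_id = rep_id)
}
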