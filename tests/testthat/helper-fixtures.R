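# Shared in-code fixtures: tiny ensembles and dihedral series built on the fly.

# dihedral_series holding a single frame taken from a template tibble
series_from_template <- function(template) {
  dihedral_series(
    matrix(template$phi, nrow = 1),
    matrix(template$psi, nrow = 1),
    template$position
  )
}

# n_frames identical copies of one template, as a dihedral series
constant_series <- function(template, n_frames) {
  dihedral_series(
    matrix(rep(template$phi, each = n_frames), nrow = n_frames),
    matrix(rep(template$psi, each = n_frames), nrow = n_frames),
    template$position
  )
}

# wrap helper mirrored from the package internals for independent checks
wrap180 <- function(x) {
  out <- x - 360 * round(x / 360)
  ifelse(out == -180, 180, out)
}

# frequency tibble from a named list of per-position PB weights, e.g.
# make_freq(list(`5` = c(m = 0.75, d = 0.25)))
make_freq <- function(rows) {
  pbs <- letters[1:16]
  out <- lapply(names(rows), function(pos) {
    f <- setNames(rep(0, 16), pbs)
    f[names(rows[[pos]])] <- rows[[pos]]
    c(position = as.integer(pos), n_frames = 100L, f)
  })
  out <- tibble::as_tibble(do.call(rbind, out))
  class(out) <- c("pb_freq", class(out))
  out
}

# random normalized 16-vector (Dirichlet-ish via normalized uniforms)
random_profile <- function() {
  f <- stats::runif(16)
  setNames(f / sum(f), letters[1:16])
}

# a tiny multi-model PDB text fixture written to a temp file
write_tiny_pdb <- function(path, models, resnos = NULL, with_water = FALSE,
                           drop_atom_in_model = NULL) {
  # models: list of coordinate matrices (n_atoms x 3); atoms are N, CA, C
  # of consecutive ALA residues
  lines <- character(0)
  n_at <- nrow(models[[1]])
  n_res <- n_at %/% 3
  resnos <- resnos %||% seq_len(n_res)
  elety <- rep(c("N", "CA", "C"), n_res)
  fmt <- "ATOM  %5d %-4s%-4sA%4d    %8.3f%8.3f%8.3f%6.2f%6.2f"
  for (m in seq_along(models)) {
    lines <- c(lines, sprintf("MODEL %8d", m))
    xyz <- models[[m]]
    for (a in seq_len(n_at)) {
      if (!is.null(drop_atom_in_model) && m == drop_atom_in_model && a == n_at) next
      nm <- elety[a]
      lines <- c(lines, sprintf(
        fmt, a, paste0(" ", nm), "ALA", resnos[(a - 1) %/% 3 + 1],
        xyz[a, 1], xyz[a, 2], xyz[a, 3], 1.0, 10.0
      ))
    }
    if (with_water) {
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s%-4sA%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        n_at + 1L, " O", "HOH", max(resnos) + 10L, 99.0, 99.0, 99.0, 1.0, 0.0
      ))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
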