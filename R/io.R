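WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP4", "SOL", "H2O", "DOD")

# atom counts per MODEL block; single implicit model when no MODEL records
scan_model_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(rec == "MODEL ")
  if (!length(model_starts)) return(sum(is_atom))
  model_of <- findInterval(which(is_atom), model_starts)
  tabulate(model_of, nbins = length(model_starts))
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' Each `MODEL` record becomes one frame, in file order. Heteroatoms and
#' waters are excluded; for alternate locations only the highest-occupancy
#' conformer is kept. Multi-chain files require an explicit `chain`.
#'
#' @param path path to a (multi-model) PDB file.
#' @param chain chain identifier to analyse; may be omitted for single-chain
#'   files.
#' @return A [conf_ensemble()].
#' @details Models with diverging atom tables are a hard error naming the
#'   first divergent model; a residue missing a backbone atom only triggers a
#'   warning and an incomplete flag.
#' @export
read_ensemble <- function(path, chain = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  counts <- scan_model_counts(path)
  if (length(counts) > 1L && length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    abort(paste0(
      "inconsistent atom tables across models: model ", bad, " has ",
      counts[bad], " atoms, model 1 has ", counts[1]
    ))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & !(at$resid %in% WATER_RESNAMES)
  chains <- unique(at$chain[keep])
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      abort(paste0(
        "file has chains ", paste(chains, collapse = ", "),
        "; pass `chain` to select one"
      ))
    }
  } else {
    keep <- keep & at$chain == chain
    if (!any(keep)) abort(paste0("no atoms for chain ", chain))
  }
  # altloc: keep the highest-occupancy conformer per (residue, atom name)
  idx <- which(keep)
  alt_tbl <- tibble(
    i = idx,
    resno = at$resno[idx], elety = at$elety[idx],
    o = ifelse(is.na(at$o[idx]), 1, at$o[idx])
  ) |>
    dplyr::group_by(.data$resno, .data$elety) |>
    dplyr::slice_max(.data$o, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  idx <- sort(alt_tbl$i)

  xyz <- pdb$xyz[, bio3d::atom2xyz(idx), drop = FALSE] # frames x 3n
  nf <- nrow(xyz)
  coords <- aperm(array(t(xyz), c(3L, length(idx), nf)), c(2L, 1L, 3L))
  atoms <- tibble(
    elety = at$elety[idx],
    resid = as.integer(at$resno[idx]),
    resname = at$resid[idx],
    chain = ifelse(is.na(at$chain[idx]), "A", at$chain[idx])
  )
  conf_ensemble(coords, atoms)
}

#' Write a conformational ensemble as a multi-model PDB file
#'
#' One `MODEL` block per frame, in frame order. Coordinates round-trip through
#' [read_ensemble()] at the PDB format's printed precision (0.001 Angstrom).
#'
#' @param ensemble a [conf_ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  nf <- n_frames(ensemble)
  na <- nrow(ensemble$atoms)
  # frames x (3*atoms), columns interleaved x1,y1,z1,x2,...
  xyz <- t(matrix(aperm(ensemble$coords, c(2L, 1L, 3L)), nrow = 3L * na, ncol = nf))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = ensemble$atoms$resid,
    resid = ensemble$atoms$resname,
    eleno = seq_len(na),
    elety = ensemble$atoms$elety,
    chain = ensemble$atoms$chain
  )
  invisible(path)
}

#' Read per-residue B-factors from a single-model PDB file
#'
#' Takes the B-factor of each residue's Calpha atom (the per-residue
#' convention used when comparing with RMSF and N_eq profiles). Residues
#' without a Calpha get `NA`, never 0.
#'
#' @param path path to a single-model PDB file.
#' @param chain optional chain selection.
#' @return A tibble `position, bfactor` (Angstrom squared).
#' @export
read_bfactors <- function(path, chain = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & !(at$resid %in% WATER_RESNAMES)
  if (!is.null(chain)) keep <- keep & at$chain == chain
  at <- at[keep, ]
  res <- unique(at$resno)
  ca <- at[at$elety == "CA", ]
  b <- ca$b[match(res, ca$resno)]
  if (any(!is.na(b) & b < 0)) abort("negative B-factor encountered")
  tibble(position = as.integer(res), bfactor = b)
}

#' Read region annotations from a TSV file
#'
#' Expects a header line and three columns `name`, `start`, `end`
#' (tab-separated, author numbering, both ends inclusive). Regions may
#' overlap; names must be unique.
#'
#' @param path path to the TSV file. Lines starting with `#` are comments.
#' @return A tibble `name, start, end`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      name = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer()
    )
  )
  if (!all(c("name", "start", "end") %in% names(tab))) {
    abort("region TSV must have columns name, start, end")
  }
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$start > tab$end)
  if (length(bad)) {
    abort(paste0("malformed region at data line ", bad[1],
                 " (", tab$name[bad[1]], "): start > end or not an integer"))
  }
  if (anyDuplicated(tab$name)) abort("region names must be unique")
  tab
}

#' Default JH1 kinase-domain region annotation
#'
#' The functional regions of the JAK2 JH1 kinase domain used for region-level
#' flexibility comparison (author numbering). Bounds whose limits are not
#' fully established are marked approximate in the shipped file's comments;
#' override with your own TSV via [read_regions()].
#'
#' @return A tibble `name, start, end`.
#' @export
jh1_regions <- function() {
  read_regions(system.file("extdata", "jh1_regions.tsv",
    package = "pbflex", mustWork = TRUE
  ))
}

#' Write / read per-position profiles as CSV
#'
#' Plain CSV with a header and one row per position (`position,<metric...>`);
#' `read_profile(write_profile(x)) == x`.
#'
#' @param profile a tibble with a `position` column.
#' @param path file path.
#' @return `write_profile()`: `path`, invisibly. `read_profile()`: a tibble.
#' @export
write_profile <- function(profile, path) {
  stopifnot("position" %in% names(profile))
  readr::write_csv(full_precision(profile), path)
  invisible(path)
}

# render doubles at 17 significant digits so values round-trip bit-identically
full_precision <- function(tab) {
  dplyr::mutate(tab, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  ))
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  # base parser: correctly-rounded doubles, so 17-digit values round-trip
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a PB frequency map as CSV
#'
#' One row per position with the 16 labelled frequency columns `a`-`p` and
#' the contributing frame count; round-trips exactly.
#'
#' @param freqs a `pb_freq` tibble from [frequency_map()].
#' @param path file path.
#' @return `write_frequency_map()`: `path`, invisibly;
#'   `read_frequency_map()`: a `pb_freq` tibble.
#' @export
write_frequency_map <- function(freqs, path) {
  stopifnot(all(c("position", "n_frames", PB_LABELS) %in% names(freqs)))
  readr::write_csv(full_precision(freqs), path)
  invisible(path)
}

#' @rdname write_frequency_map
#' @export
read_frequency_map <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("position", "n_frames", PB_LABELS) %in% names(out))) {
    abort("not a PB frequency map: missing position/n_frames/a..p columns")
  }
  out$position <- as.integer(out$position)
  out$n_frames <- as.integer(out$n_frames)
  class(out) <- c("pb_freq", class(out))
  out
}

#' Write / read a PB trajectory in PB-fasta dialect
#'
#' One fasta record per frame; the sequence is one PB letter per residue,
#' with `Z` marking unassignable positions (chain termini, incomplete
#' windows). The first-position author number is recorded in the header so
#' the position axis survives the round trip.
#'
#' @param pbtraj a `pb_trajectory` from [assign_ensemble()].
#' @param path file path.
#' @return `write_pb_fasta()`: `path`, invisibly; `read_pb_fasta()`: a
#'   `pb_trajectory`.
#' @export
write_pb_fasta <- function(pbtraj, path) {
  stopifnot(inherits(pbtraj, "pb_trajectory"))
  seqs <- apply(pbtraj$labels, 1, paste, collapse = "")
  lines <- as.vector(rbind(
    paste0(">frame_", seq_along(seqs), " | first_position=", pbtraj$positions[1]),
    seqs
  ))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pb_fasta
#' @export
read_pb_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr) || any(diff(which(hdr)) != 2L)) {
    abort("malformed PB-fasta: expected alternating header/sequence lines")
  }
  seqs <- lines[!hdr]
  first_pos <- suppressWarnings(
    as.integer(sub(".*first_position=([0-9-]+).*", "\\1", lines[hdr][1]))
  )
  if (is.na(first_pos)) first_pos <- 1L
  labels <- do.call(rbind, strsplit(seqs, ""))
  pb_trajectory(labels, first_pos + seq_len(ncol(labels)) - 1L)
}
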