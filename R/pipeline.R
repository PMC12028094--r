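#' Full single-system flexibility analysis
#'
#' Runs the whole pipeline on one conformational ensemble: backbone dihedrals
#' -> PB assignment -> per-position PB frequencies -> N_eq and flexibility
#' categories, alongside Calpha RMSF and the per-frame RMSD series computed on
#' the same frames. Deterministic given its inputs and options.
#'
#' @param ensemble a [conf_ensemble()].
#' @param name system name used in reports (e.g. `"apo"`).
#' @param alphabet a [pb_alphabet()].
#' @param fit superpose frames before RMSF? See [rmsf()].
#' @param reference_frame reference for the RMSD series (default: starting
#'   frame).
#' @param bfactors optional tibble `position, bfactor` from [read_bfactors()]
#'   to carry along for metric correlation.
#' @return A `pb_system` object: list with `name`, `frequencies` (`pb_freq`),
#'   `flexibility` (`flex_profile`), `rmsd` (tibble `frame, rmsd`), `pb`
#'   (the `pb_trajectory`) and `metadata` (frame counts, fit mode, alphabet
#'   checksum, seed when the ensemble is synthetic). Errors from any stage are
#'   tagged with the stage name.
#' @seealso [compare_systems()], [tidy()], [glance()], [autoplot()]
#' @export
analyze_system <- function(ensemble, name = "system", alphabet = pb_alphabet(),
                           fit = TRUE, reference_frame = 1L, bfactors = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  dihedrals <- with_stage("backbone_dihedrals", backbone_dihedrals(ensemble))
  pb <- with_stage("pb_assignment", assign_ensemble(dihedrals, alphabet))
  freq <- with_stage("frequency_map", frequency_map(pb))
  fluct <- with_stage("rmsf", rmsf(ensemble, fit = fit))
  flex <- with_stage(
    "flexibility_profile",
    flexibility_profile(freq, rmsf = fluct, bfactors = bfactors)
  )
  rmsd <- with_stage("rmsd_series", rmsd_series(ensemble, reference_frame))
  structure(
    list(
      name = name,
      frequencies = freq,
      flexibility = flex,
      rmsd = rmsd,
      pb = pb,
      metadata = list(
        n_frames = n_frames(ensemble),
        n_residues = n_residues(ensemble),
        fit_mode = attr(fluct, "fit_mode"),
        reference_frame = as.integer(reference_frame),
        alphabet_checksum = attr(alphabet, "checksum"),
        seed = attr(ensemble, "seed")
      )
    ),
    class = "pb_system"
  )
}

#' @export
print.pb_system <- function(x, ...) {
  md <- x$metadata
  cat(
    "<pb_system> '", x$name, "': ", md$n_frames, " frame(s), ",
    md$n_residues, " residue(s), RMSF ", md$fit_mode, "\n",
    sep = ""
  )
  defined <- !is.na(x$flexibility$neq)
  if (any(defined)) {
    cat(
      "  N_eq range ",
      paste(format(range(x$flexibility$neq[defined]), digits = 3), collapse = " - "),
      " over ", sum(defined), " assignable position(s)\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
tidy.pb_system <- function(x, ...) {
  out <- x$flexibility
  class(out) <- class(tibble())
  out
}

#' @export
glance.pb_system <- function(x, ...) {
  flex <- x$flexibility
  def <- !is.na(flex$neq)
  tibble(
    name = x$name,
    n_frames = x$metadata$n_frames,
    n_positions = nrow(flex),
    n_assignable = sum(def),
    mean_neq = mean(flex$neq[def]),
    max_neq = if (any(def)) max(flex$neq[def]) else NA_real_,
    pct_rigid = 100 * mean(flex$category[def] == "rigid"),
    max_rmsf = if ("rmsf" %in% names(flex)) max(flex$rmsf, na.rm = TRUE) else NA_real_
  )
}

#' Region-by-region comparison of two analysed systems
#'
#' Computes per-position delta-N_eq, delta-PB and delta-RMSF between two
#' [analyze_system()] results on a matched position axis, aggregates them over
#' annotated regions (mean and max over defined positions), and flags
#' positions whose delta-PB exceeds a threshold (default 0.4, the level at
#' which a PB-profile change is treated as notable), listed in descending
#' order.
#'
#' @param result_a,result_b `pb_system` objects on the same position axis
#'   (error naming the first unmatched position otherwise).
#' @param regions optional region annotation tibble `name, start, end`
#'   (e.g. [jh1_regions()] or [read_regions()]).
#' @param delta_pb_threshold flagging threshold on delta-PB.
#' @return A `pb_comparison` object: list with `systems` (the two names),
#'   `profile` (tibble `position, delta_neq, delta_pb[, delta_rmsf]`),
#'   `regions` (per-region mean/max aggregates, `NULL` if no annotation) and
#'   `flagged` (positions above threshold, descending delta-PB).
#' @export
compare_systems <- function(result_a, result_b, regions = NULL,
                            delta_pb_threshold = 0.4) {
  stopifnot(inherits(result_a, "pb_system"), inherits(result_b, "pb_system"))
  check_positions(result_a$frequencies$position, result_b$frequencies$position)
  profile <- dplyr::inner_join(
    delta_neq(result_a$flexibility, result_b$flexibility),
    delta_pb(result_a$frequencies, result_b$frequencies),
    by = "position"
  )
  both_rmsf <- all(c("rmsf") %in% names(result_a$flexibility)) &&
    "rmsf" %in% names(result_b$flexibility)
  if (both_rmsf) {
    profile$delta_rmsf <- abs(result_a$flexibility$rmsf - result_b$flexibility$rmsf)
  }
  region_agg <- NULL
  if (!is.null(regions)) {
    agg <- function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) c(NA_real_, NA_real_) else c(mean(v), max(v))
    }
    region_agg <- purrr::pmap_dfr(
      regions[c("name", "start", "end")],
      function(name, start, end) {
        inside <- profile[profile$position >= start & profile$position <= end, ]
        dpb <- agg(inside$delta_pb)
        dnq <- agg(inside$delta_neq)
        drm <- if (both_rmsf) agg(inside$delta_rmsf) else c(NA_real_, NA_real_)
        tibble(
          name = name, start = start, end = end,
          n_positions = nrow(inside),
          mean_delta_pb = dpb[1], max_delta_pb = dpb[2],
          mean_delta_neq = dnq[1], max_delta_neq = dnq[2],
          mean_delta_rmsf = drm[1], max_delta_rmsf = drm[2]
        )
      }
    )
  }
  flagged <- profile |>
    dplyr::filter(!is.na(.data$delta_pb), .data$delta_pb > delta_pb_threshold) |>
    dplyr::arrange(dplyr::desc(.data$delta_pb)) |>
    dplyr::mutate(fraction_differing = interpret_delta_pb(.data$delta_pb))
  structure(
    list(
      systems = c(result_a$name, result_b$name),
      profile = profile,
      regions = region_agg,
      flagged = flagged,
      delta_pb_threshold = delta_pb_threshold
    ),
    class = "pb_comparison"
  )
}

#' @export
print.pb_comparison <- function(x, ...) {
  cat(
    "<pb_comparison> ", x$systems[1], " vs ", x$systems[2], ": ",
    nrow(x$flagged), " position(s) with delta-PB > ", x$delta_pb_threshold, "\n",
    sep = ""
  )
  if (nrow(x$flagged)) print(head(x$flagged, 5))
  invisible(x)
}

#' @export
tidy.pb_comparison <- function(x, ...) x$profile

#' @export
glance.pb_comparison <- function(x, ...) {
  p <- x$profile
  tibble(
    system_a = x$systems[1],
    system_b = x$systems[2],
    n_positions = nrow(p),
    max_delta_pb = if (any(!is.na(p$delta_pb))) max(p$delta_pb, na.rm = TRUE) else NA_real_,
    max_delta_neq = if (any(!is.na(p$delta_neq))) max(p$delta_neq, na.rm = TRUE) else NA_real_,
    n_flagged = nrow(x$flagged)
  )
}

#' Read a delta-PB value as a fraction of differing PB assignments
#'
#' Since delta-PB is an L1 distance between probability vectors, half its
#' value is the fraction of PB assignments that differ between the two
#' systems: delta-PB 2 means 100% different, 0.7 means 35%.
#'
#' @param value numeric delta-PB value(s) in `[0, 2]`.
#' @return `value / 2`.
#' @export
interpret_delta_pb <- function(value) {
  if (any(is.na(value)) || any(value < 0 | value > 2)) {
    abort("delta-PB values must lie in [0, 2]")
  }
  value / 2
}
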