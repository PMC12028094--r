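#' Per-position PB frequency map
#'
#' For every position, the frequency `f_x` of each Protein Block `x` over the
#' frames, with unassignable (`Z`) frames excluded from the denominator. A
#' position where no frame is assignable is flagged empty (`n_frames = 0`,
#' frequencies `NA`) rather than producing `NaN`.
#'
#' @param pbtraj a `pb_trajectory` from [assign_ensemble()].
#' @return A `pb_freq` tibble with columns `position`, `n_frames` (count of
#'   contributing non-`Z` frames) and `a` ... `p` (frequencies summing to 1
#'   per non-empty row).
#' @export
frequency_map <- function(pbtraj) {
  stopifnot(inherits(pbtraj, "pb_trajectory"))
  if (nrow(pbtraj$labels) < 1L) abort("at least one frame is required")
  counts <- vapply(
    seq_along(pbtraj$positions),
    function(j) tabulate(factor(pbtraj$labels[, j], levels = PB_LABELS), 16L),
    integer(16)
  ) # 16 x n_positions
  n <- colSums(counts)
  freq <- t(counts) / ifelse(n == 0L, NA_real_, n)
  colnames(freq) <- PB_LABELS
  out <- dplyr::bind_cols(
    tibble(position = pbtraj$positions, n_frames = as.integer(n)),
    as_tibble(freq)
  )
  class(out) <- c("pb_freq", class(out))
  out
}

# 16-column frequency matrix of a pb_freq tibble (rows = positions)
freq_matrix <- function(freq) {
  stopifnot(all(PB_LABELS %in% names(freq)))
  m <- as.matrix(freq[, PB_LABELS])
  rownames(m) <- freq$position
  m
}

#' Equivalent number of Protein Blocks (N_eq)
#'
#' The exponential of the Shannon entropy (natural log) of a position's PB
#' frequency vector:
#' `N_eq = exp(-sum_x f_x ln f_x)`, with `0 * ln 0 := 0`.
#' `N_eq = 1` means a single PB is ever observed (a rigid position); 16 means
#' all PBs occur uniformly, as in a random distribution.
#'
#' @param f a normalized numeric frequency vector (any length up to 16;
#'   must sum to 1).
#' @return A value in `[1, 16]`, or `NA` for an empty (all-`NA`) row.
#' @examples
#' neq(c(1, rep(0, 15))) # 1
#' neq(rep(1 / 16, 16)) # 16
#' @export
neq <- function(f) {
  if (all(is.na(f))) return(NA_real_)
  if (anyNA(f) || any(f < 0)) abort("frequencies must be non-negative and defined")
  if (abs(sum(f) - 1) > 1e-6) abort("frequency vector must sum to 1")
  p <- f[f > 0]
  exp(-sum(p * log(p)))
}

#' Per-position N_eq profile of a frequency map
#'
#' @param freq a `pb_freq` tibble from [frequency_map()].
#' @return A tibble `position, neq` (`NA` at empty positions).
#' @export
neq_profile <- function(freq) {
  m <- freq_matrix(freq)
  tibble(
    position = freq$position,
    neq = unname(apply(m, 1, neq))
  )
}

#' Flexibility categories from N_eq
#'
#' Categorizes positions by their N_eq: `rigid` at exactly 1 (within
#' `eps = 1e-6`, a single PB observed throughout), then half-open bins
#' `(1, 2]` `quite_rigid`, `(2, 4]` `moderate`, `(4, 6]` `flexible`,
#' `(6, 8]` `extremely_flexible`, `(8, 16]` `disordered`.
#'
#' @param x numeric N_eq values in `[1, 16]` (`NA` allowed).
#' @return A factor with the six category levels.
#' @examples
#' categorize(c(1, 4.5, 8.09)) # rigid, flexible, disordered
#' @export
categorize <- function(x) {
  eps <- 1e-6
  ok <- is.na(x) | (x >= 1 - eps & x <= 16 + eps)
  if (!all(ok)) {
    abort(paste0(
      "N_eq value out of [1, 16]: ", paste(format(x[!ok]), collapse = ", "),
      " (upstream frequency error?)"
    ))
  }
  lev <- c(
    "rigid", "quite_rigid", "moderate", "flexible",
    "extremely_flexible", "disordered"
  )
  out <- cut(pmin(pmax(x, 1), 16),
    breaks = c(1 + eps, 2, 4, 6, 8, 16 + eps),
    labels = lev[-1], right = TRUE
  )
  out <- as.character(out)
  out[!is.na(x) & x <= 1 + eps] <- "rigid"
  factor(out, levels = lev)
}

#' Per-position flexibility profile
#'
#' Combines N_eq (and its category) with optional RMSF and B-factor columns on
#' a common author-numbered position axis.
#'
#' @param freq a `pb_freq` tibble from [frequency_map()].
#' @param rmsf optional tibble `position, rmsf` from [rmsf()].
#' @param bfactors optional tibble `position, bfactor` from [read_bfactors()].
#' @return A `flex_profile` tibble `position, neq, category[, rmsf][, bfactor]`.
#' @export
flexibility_profile <- function(freq, rmsf = NULL, bfactors = NULL) {
  out <- neq_profile(freq)
  out$category <- categorize(out$neq)
  if (!is.null(rmsf)) {
    out <- dplyr::left_join(out, rmsf[c("position", "rmsf")], by = "position")
  }
  if (!is.null(bfactors)) {
    out <- dplyr::left_join(out, bfactors[c("position", "bfactor")], by = "position")
  }
  class(out) <- c("flex_profile", class(out))
  out
}

#' Absolute N_eq difference between two systems
#'
#' `|N_eq^1 - N_eq^2|` per matched position; symmetric in its arguments.
#'
#' @param profile1,profile2 tibbles with `position` and `neq` columns on the
#'   same position axis (error on mismatch).
#' @return A tibble `position, delta_neq` (`NA` where either side undefined).
#' @export
delta_neq <- function(profile1, profile2) {
  check_positions(profile1$position, profile2$position)
  tibble(
    position = profile1$position,
    delta_neq = abs(profile1$neq - profile2$neq)
  )
}

#' PB-profile distance between two systems (delta-PB)
#'
#' The L1 distance between matched per-position PB frequency vectors:
#' `sum_x |f_x^1 - f_x^2|`. 0 means identical PB profiles; 2 is the maximum
#' total difference (disjoint PB usage). Half this value reads as the fraction
#' of PB assignments that differ (see [interpret_delta_pb()]).
#'
#' @param freqs1,freqs2 `pb_freq` tibbles on the same position axis.
#' @return A tibble `position, delta_pb` with values in `[0, 2]` (`NA` where
#'   either row is empty).
#' @export
delta_pb <- function(freqs1, freqs2) {
  check_positions(freqs1$position, freqs2$position)
  d <- rowSums(abs(freq_matrix(freqs1) - freq_matrix(freqs2)))
  tibble(position = freqs1$position, delta_pb = unname(d))
}

check_positions <- function(p1, p2) {
  if (length(p1) != length(p2) || any(p1 != p2)) {
    first <- if (length(p1) != length(p2)) {
      "position axes differ in length"
    } else {
      paste0("first unmatched position: ", p1[which(p1 != p2)[1]],
             " vs ", p2[which(p1 != p2)[1]])
    }
    abort(paste0("position axes do not match; ", first))
  }
  invisible(TRUE)
}

#' Category percentages over a flexibility profile
#'
#' @param flex_profile a [flexibility_profile()] (or any tibble with a
#'   `category` column).
#' @return A tibble `category, n, percent`; percentages are over categorized
#'   positions and sum to 100.
#' @export
category_summary <- function(flex_profile) {
  cats <- flex_profile$category[!is.na(flex_profile$category)]
  if (!length(cats)) abort("no categorized positions")
  tab <- table(cats)
  tibble(
    category = factor(names(tab), levels = levels(flex_profile$category)),
    n = as.integer(tab),
    percent = 100 * as.integer(tab) / length(cats)
  )
}

#' Pearson correlation between two per-position metrics
#'
#' Standard product-moment correlation with pairwise deletion of positions
#' undefined in either series (e.g. `Z`-labelled termini). Returns `NA`
#' (undefined), not an error, when either series has zero variance.
#'
#' @param series_a,series_b numeric vectors on the same position axis.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) abort("series lengths differ")
  ok <- !is.na(series_a) & !is.na(series_b)
  if (sum(ok) < 3L) abort("fewer than 3 paired defined values")
  if (sd(series_a[ok]) == 0 || sd(series_b[ok]) == 0) return(NA_real_)
  cor(series_a[ok], series_b[ok])
}

#' Frequency matrix for PB sequence-logo rendering
#'
#' Extracts the per-position PB frequency vectors over a position range as a
#' plain matrix (rows = positions, 16 columns `a`-`p`), the input consumed by
#' sequence-logo tools.
#'
#' @param freqs a `pb_freq` tibble from [frequency_map()].
#' @param position_range length-2 integer vector `c(first, last)` (inclusive);
#'   default spans the whole profile.
#' @return A numeric matrix; empty (0-row, with a warning) if the range lies
#'   outside the profile.
#' @export
logo_matrix <- function(freqs, position_range = range(freqs$position)) {
  stopifnot(length(position_range) == 2L)
  keep <- freqs$position >= position_range[1] & freqs$position <= position_range[2]
  if (!any(keep)) {
    warn("position range outside profile; empty logo matrix")
  }
  freq_matrix(freqs[keep, ])
}
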