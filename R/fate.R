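# Cell fate decision: two-threshold mechanism (p21-based cell-cycle arrest;
# combined active p53 + Bax apoptosis) and clonogenic viability rules.

#' Fate thresholds
#'
#' The lower threshold (p21 level) marks cell-cycle arrest; the higher
#' threshold requires active nuclear p53 and Bax to be elevated
#' simultaneously and marks apoptosis.  A cell is not viable (cannot found a
#' colony of at least 30 cells within 10 days) when it becomes apoptotic
#' before its first division or when its total arrested time exceeds
#' `max_arrest` hours.
#'
#' @param p21_arrest arrest threshold on p21 (molecules).
#' @param p53_apoptosis apoptosis threshold on active nuclear p53.
#' @param bax_apoptosis apoptosis threshold on Bax.
#' @param max_arrest longest arrest compatible with colony formation (h).
#' @param division_window time of the first division after treatment (h).
#' @return list of class `fate_thresholds`.
#' @export
fate_thresholds <- function(p21_arrest = 500, p53_apoptosis = 350,
                            bax_apoptosis = 495, max_arrest = 63.9,
                            division_window = 24) {
  stopifnot(p21_arrest > 0, p53_apoptosis > 0, bax_apoptosis > 0,
            max_arrest > 0, division_window > 0)
  structure(list(p21_arrest = p21_arrest, p53_apoptosis = p53_apoptosis,
                 bax_apoptosis = bax_apoptosis, max_arrest = max_arrest,
                 division_window = division_window),
            class = "fate_thresholds")
}

#' Calibrate thresholds from a resting state
#'
#' Helper setting the thresholds at stated multiples of the resting levels
#' (the apoptosis thresholds must sit strictly above rest).
#'
#' @param rest resting levels as returned by [find_rest()]`$y` (named, with
#'   `P21`, `P53a_nuc`, `BAX`).
#' @param p21_mult,p53_mult,bax_mult multiples of the resting level.
#' @param ... passed to [fate_thresholds()].
#' @return a `fate_thresholds`.
#' @export
thresholds_from_rest <- function(rest, p21_mult = 4, p53_mult = 8,
                                 bax_mult = 8, ...) {
  fate_thresholds(p21_arrest = p21_mult * rest[["P21"]],
                  p53_apoptosis = p53_mult * rest[["P53a_nuc"]],
                  bax_apoptosis = bax_mult * rest[["BAX"]], ...)
}

#' Classify one cell trajectory
#'
#' Scans the post-treatment part (t >= 0) of a trajectory.  The cell is
#' apoptotic at the first sample where active nuclear p53 and Bax are both
#' at or above their thresholds simultaneously; it is arrested during every
#' interval with p21 at or above the arrest threshold (intervals are summed,
#' contiguity is not required); it is not viable when apoptotic before the
#' first division (whose clock pauses during arrest) or when total arrest
#' exceeds `max_arrest` hours.
#'
#' @param traj a `cell_trajectory` (must carry `P53a_nuc`, `BAX`, `P21`).
#' @param th a [fate_thresholds()].
#' @param t0 anchor (s) for the division clock, typically the IR start.
#' @return list of class `fate_record`: `apoptosis_time` (s, or `NA`),
#'   `arrest_intervals` (matrix start/end in s), `arrest_hours`,
#'   `divided_before_death`, `viable`.
#' @export
classify_cell <- function(traj, th, t0 = 0) {
  need <- c("P53a_nuc", "BAX", "P21")
  if (!all(need %in% colnames(traj$Y)))
    stop("trajectory missing ", paste(setdiff(need, colnames(traj$Y)),
                                      collapse = ", "), call. = FALSE)
  sel <- traj$times >= 0
  t <- traj$times[sel]
  p53a <- traj$Y[sel, "P53a_nuc"]
  bax <- traj$Y[sel, "BAX"]
  p21 <- traj$Y[sel, "P21"]

  apo <- which(p53a >= th$p53_apoptosis & bax >= th$bax_apoptosis)
  apoptosis_time <- if (length(apo)) t[apo[1]] else NA_real_

  arr <- p21 >= th$p21_arrest
  runs <- rle(arr)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  keep <- runs$values
  intervals <- cbind(start = t[starts[keep]], end = t[ends[keep]])
  dt_sample <- if (length(t) > 1) t[2] - t[1] else 0
  arrest_hours <- sum(arr) * dt_sample / 3600

  # the division clock runs only while the cell is not arrested: the first
  # division happens once division_window hours of unarrested time have
  # accumulated after t0
  cum_unarrested <- cumsum((t >= t0) & !arr) * dt_sample
  idiv <- which(cum_unarrested >= th$division_window * 3600)
  division_time <- if (length(idiv)) t[idiv[1]] else Inf
  died_before_division <- !is.na(apoptosis_time) &&
    apoptosis_time <= division_time
  viable <- !died_before_division && arrest_hours <= th$max_arrest
  structure(list(apoptosis_time = apoptosis_time,
                 arrest_intervals = intervals,
                 arrest_hours = arrest_hours,
                 divided_before_death = !died_before_division &&
                   !is.na(apoptosis_time),
                 viable = viable),
            class = "fate_record")
}

#' Apoptotic fraction per time window
#'
#' Windows are half-open `(lo, hi]` hours after the anchor; a cell counts in
#' exactly one window (the one containing its apoptosis time), so summing
#' windows gives the cumulative death without double counting — cells
#' already apoptotic in an earlier window are excluded from later ones.
#'
#' @param fates list of `fate_record`s.
#' @param windows matrix or list of `(t_lo, t_hi)` pairs in hours, ordered
#'   and non-overlapping.
#' @param t0 anchor in seconds (IR time).
#' @return numeric vector of fractions, one per window.
#' @export
apoptotic_fraction <- function(fates, windows = list(c(0, 24), c(24, 48)),
                               t0 = 0) {
  if (is.matrix(windows))
    windows <- lapply(seq_len(nrow(windows)), function(i) windows[i, ])
  lo <- vapply(windows, `[`, numeric(1), 1)
  hi <- vapply(windows, `[`, numeric(1), 2)
  if (any(diff(as.vector(rbind(lo, hi))) < 0))
    stop("windows must be ordered and non-overlapping", call. = FALSE)
  at <- vapply(fates, function(f)
    if (is.na(f$apoptosis_time)) NA_real_ else
      (f$apoptosis_time - t0) / 3600, numeric(1))
  vapply(seq_along(windows), function(w)
    sum(!is.na(at) & at > lo[w] & at <= hi[w]) / length(fates), numeric(1))
}

#' Clonogenic surviving fraction
#'
#' @param fates list of `fate_record`s.
#' @return fraction of viable cells.
#' @export
clonogenic_survival <- function(fates) {
  mean(vapply(fates, function(f) isTRUE(f$viable), logical(1)))
}

#' @export
print.fate_record <- function(x, ...) {
  cat("<fate_record> ",
      if (is.na(x$apoptosis_time)) "no apoptosis" else
        sprintf("apoptosis at %.1f h", x$apoptosis_time / 3600),
      sprintf(", arrest %.1f h, %s", x$arrest_hours,
              if (x$viable) "viable" else "not viable"), "\n", sep = "")
  invisible(x)
}
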