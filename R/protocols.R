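# Virtual experiment protocols: burn-in, ionizing radiation, TNF-alpha
# pulses and shRNA knockdown.

#' Construct a treatment protocol
#'
#' Time 0 is the treatment-reference instant; burn-in (pre-treatment
#' equilibration with all stochastic channels on) runs at negative times.
#' Radiation is delivered as a window of elevated DSB-induction propensity of
#' length `ir_dose / ir_dose_rate`, so the integrated dose is exact.  TNF is
#' a square pulse: the extracellular level returns to exactly 0 at washout
#' (the medium is physically replaced).
#'
#' @param burn_in equilibration time before 0 (s).
#' @param ir_dose total dose (Gy); 0 = unirradiated.
#' @param ir_start start of delivery (s).
#' @param ir_dose_rate delivery rate (Gy/min).
#' @param tnf_dose TNF-alpha level during the pulse (ng/ml); 0 = none.
#' @param tnf_start pulse start (s).
#' @param tnf_duration pulse length (s).
#' @param horizon end of simulation (s after time 0).
#' @param name label.
#' @return list of class `ddr_protocol`.
#' @export
ddr_protocol <- function(burn_in = 24 * 3600, ir_dose = 0, ir_start = 0,
                         ir_dose_rate = 1, tnf_dose = 0, tnf_start = 0,
                         tnf_duration = 3600, horizon = 48 * 3600,
                         name = "custom") {
  stopifnot(ir_dose >= 0, ir_dose_rate > 0, tnf_dose >= 0, burn_in >= 0,
            horizon > 0)
  structure(list(burn_in = burn_in, ir_dose = ir_dose, ir_start = ir_start,
                 ir_dose_rate = ir_dose_rate,
                 ir_window = ir_dose / ir_dose_rate * 60,
                 tnf_dose = tnf_dose, tnf_start = tnf_start,
                 tnf_duration = tnf_duration, horizon = horizon,
                 name = name),
            class = "ddr_protocol")
}

#' Preset protocols
#'
#' Presets mirror the standard treatment schedules:
#' \describe{
#'   \item{`untreated`}{burn-in only.}
#'   \item{`tnf_only`}{10 ng/ml TNF-alpha for 1 h starting at time 0.}
#'   \item{`ir_only`}{dose `dose` Gy at 1 Gy/min starting at time 0.}
#'   \item{`tnf_then_ir`}{TNF pulse at time 0 for 1 h, medium replaced, then
#'     IR starting 2 h after washout (i.e. at +3 h).}
#'   \item{`ir_then_tnf`}{IR at time 0, then TNF added `lag` seconds later
#'     (default 6 h).}
#' }
#'
#' @param preset one of the names above.
#' @param dose IR dose (Gy).
#' @param tnf_dose TNF-alpha dose (ng/ml).
#' @param lag IR-to-TNF delay for `ir_then_tnf` (s).
#' @param burn_in,horizon see [ddr_protocol()].  The default horizon covers
#'   48 h after the irradiation start.
#' @return a `ddr_protocol`.
#' @export
make_protocol <- function(preset = c("untreated", "tnf_only", "ir_only",
                                     "tnf_then_ir", "ir_then_tnf"),
                          dose = 4, tnf_dose = 10, lag = 6 * 3600,
                          burn_in = 24 * 3600, horizon = NULL) {
  preset <- match.arg(preset)
  if (lag < 0) stop("negative lag", call. = FALSE)
  h <- function(default) if (is.null(horizon)) default else horizon
  switch(preset,
    untreated = ddr_protocol(burn_in = burn_in, horizon = h(48 * 3600),
                             name = "untreated"),
    tnf_only = ddr_protocol(burn_in = burn_in, tnf_dose = tnf_dose,
                            tnf_start = 0, tnf_duration = 3600,
                            horizon = h(48 * 3600), name = "tnf_only"),
    ir_only = ddr_protocol(burn_in = burn_in, ir_dose = dose, ir_start = 0,
                           horizon = h(48 * 3600),
                           name = sprintf("ir_only_%ggy", dose)),
    tnf_then_ir = ddr_protocol(burn_in = burn_in, tnf_dose = tnf_dose,
                               tnf_start = 0, tnf_duration = 3600,
                               ir_dose = dose, ir_start = 3 * 3600,
                               horizon = h(3 * 3600 + 48 * 3600),
                               name = sprintf("tnf_then_ir_%ggy", dose)),
    ir_then_tnf = ddr_protocol(burn_in = burn_in, ir_dose = dose,
                               ir_start = 0, tnf_dose = tnf_dose,
                               tnf_start = lag, tnf_duration = 3600,
                               horizon = h(48 * 3600),
                               name = sprintf("ir_then_tnf_%ggy", dose)))
}

#' Apply an shRNA knockdown to a model
#'
#' Knockdown is modelled by scaling the target's translation efficiency so
#' that the steady-state protein level is `factor` times wild type
#' (knockdown efficiency is quantified on protein immunoblots, and protein
#' output is proportional to the translation rate at every transcript
#' level).  `factor = 0` silences the target entirely.  The input model is
#' not modified.
#'
#' @param spec a `ddr_model`.
#' @param target knocked-down gene; currently `"wip1"`.
#' @param factor remaining expression fraction in `[0, 1]`.
#' @return a new `ddr_model`.
#' @export
apply_knockdown <- function(spec, target = "wip1", factor = 0.25) {
  stopifnot(factor >= 0, factor <= 1)
  tgt <- list(wip1 = "k_wtr")
  if (!target %in% names(tgt)) stop("unknown target '", target, "'",
                                    call. = FALSE)
  if (factor == 1) return(spec)
  pn <- tgt[[target]]
  do.call(set_params,
          stats::setNames(list(spec, param_value(spec, pn) * factor),
                          c("spec", pn)))
}
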