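# Population orchestration: n-cell runs, quantile trajectories, fate
# summaries, experiment grids.

within_genes <- function(state, val) {
  state$genes[] <- val
  state
}

derive_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) %% 65011 * 31627 + i * 7919) %%
               2147483562 + 1)
}

#' Simulate a population of cells
#'
#' Runs `n` independent cells under one protocol, each with a seed derived
#' deterministically from `(master_seed, cell index)`, and aggregates
#' per-time-point nearest-rank quartiles for the tracked species plus a fate
#' record per cell.  The result is a pure function of
#' (model, protocol, cfg, master_seed); cell order never matters.
#'
#' @param spec a `ddr_model`.
#' @param protocol a `ddr_protocol`.
#' @param n number of cells (>= 1).
#' @param master_seed integer.
#' @param cfg an [engine_config()]; population runs typically use a coarser
#'   `save_every` than single-cell runs.
#' @param thresholds a [fate_thresholds()] (or `NULL` to skip fates).
#' @param track species (and `"dsb"`) to keep quantile trajectories for.
#' @param fate_t0 anchor (s) for the division/apoptosis clock; defaults to
#'   the protocol's IR start.
#' @param init named initial levels; defaults to the model's mean-field
#'   resting point (computed once per population).
#' @return object of class `population_result`: `times` (s), `quantiles`
#'   (list per tracked series of a 3 x T matrix q1/median/q3), `fates`,
#'   `fate_table` (data frame), `n`, `seeds`, `failures`.
#' @export
run_population <- function(spec, protocol, n, master_seed = 1,
                           cfg = engine_config(dt = 2, save_every = 600,
                                               t_end = protocol$horizon),
                           thresholds = NULL,
                           track = c("WIP1", "WIP1_mRNA", "P53a_nuc", "P21",
                                     "BAX", "dsb"),
                           fate_t0 = protocol$ir_start, init = NULL) {
  stopifnot(n >= 1)
  cm <- compile_model(spec)
  rest <- find_rest(spec, background = TRUE)
  # per-cell initial allele states drawn from each gene's stationary law at
  # the resting point, so slow gene switching needs no extra burn-in
  rest_state <- cell_state(spec, y = rest$y)
  pi_on <- vapply(spec$genes$name, function(g) {
    a2 <- gene_activation_propensity(g, within_genes(rest_state, 0L), spec) / 2
    d <- gene_deactivation_propensity(g, within_genes(rest_state, 1L), spec)
    if (a2 + d <= 0) 1 else a2 / (a2 + d)
  }, numeric(1))
  track_sp <- intersect(track, cm$species_names)
  track_dsb <- "dsb" %in% track
  store <- NULL
  fates <- vector("list", n)
  failures <- list()
  times <- NULL
  # conditional resting levels per allele configuration: genes slower than
  # the burn-in would otherwise leave cells at the population-average state
  rest_cache <- new.env(parent = emptyenv())
  cond_init <- function(genes0) {
    key <- paste(genes0, collapse = "")
    if (is.null(rest_cache[[key]]))
      rest_cache[[key]] <- find_rest(spec, t_relax = 3e5, dt = 10,
                                     background = TRUE, genes = genes0)$y
    rest_cache[[key]]
  }
  for (i in seq_len(n)) {
    cfg$seed <- derive_seed(master_seed, i)
    set.seed(derive_seed(master_seed + 7, i))
    genes0 <- rbinom(length(pi_on), 2, pi_on)
    tr <- tryCatch(simulate_cell(cm, protocol, cfg,
                                 init = if (is.null(init)) cond_init(genes0)
                                        else init,
                                 genes0 = genes0),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      failures[[length(failures) + 1]] <- list(cell = i,
                                               message = conditionMessage(tr))
      next
    }
    if (is.null(store)) {
      times <- tr$times
      store <- lapply(c(track_sp, if (track_dsb) "dsb"),
                      function(s) matrix(NA_real_, n, length(times)))
      names(store) <- c(track_sp, if (track_dsb) "dsb")
    }
    for (s in track_sp) store[[s]][i, ] <- tr$Y[, s]
    if (track_dsb) store[["dsb"]][i, ] <- tr$dsb
    if (!is.null(thresholds))
      fates[[i]] <- classify_cell(tr, thresholds, t0 = fate_t0)
  }
  if (length(failures) > n / 100)
    stop(length(failures), " of ", n, " cells aborted", call. = FALSE)
  ok <- !vapply(fates, is.null, logical(1))
  fates <- fates[ok]
  quant <- lapply(store, function(M) {
    M <- M[stats::complete.cases(M), , drop = FALSE]
    apply(M, 2, quantile_nearest_rank, probs = c(0.25, 0.5, 0.75))
  })
  for (s in names(quant)) rownames(quant[[s]]) <- c("q1", "median", "q3")
  fate_table <- if (length(fates))
    data.frame(cell = which(ok),
               apoptosis_time = vapply(fates, function(f)
                 f$apoptosis_time, numeric(1)),
               arrest_hours = vapply(fates, function(f)
                 f$arrest_hours, numeric(1)),
               viable = vapply(fates, function(f) f$viable, logical(1)))
    else NULL
  structure(list(times = times, quantiles = quant, fates = fates,
                 fate_table = fate_table, n = n,
                 seeds = vapply(seq_len(n), function(i)
                   derive_seed(master_seed, i), integer(1)),
                 failures = failures, protocol = protocol),
            class = "population_result")
}

#' Nearest-rank quantiles
#'
#' Deterministic, platform-independent quantile: the `ceiling(p * n)`-th
#' order statistic.
#'
#' @param x numeric vector.
#' @param probs probabilities in (0, 1].
#' @return numeric vector.
#' @export
quantile_nearest_rank <- function(x, probs) {
  xs <- sort(x)
  xs[pmax(1L, ceiling(probs * length(xs)))]
}

#' @export
print.population_result <- function(x, ...) {
  cat("<population_result> n = ", x$n, ", protocol ", x$protocol$name,
      "\n", sep = "")
  if (!is.null(x$fate_table))
    cat("  viable: ", sum(x$fate_table$viable), "/",
        nrow(x$fate_table), "\n", sep = "")
  invisible(x)
}

#' Time and level of a median-trajectory peak
#'
#' @param pop a `population_result`.
#' @param series tracked series name.
#' @param from,to restrict the search window (s).
#' @return list with `time_h` (hours after 0) and `level`.
#' @export
peak_time <- function(pop, series, from = 0, to = Inf) {
  med <- pop$quantiles[[series]]["median", ]
  sel <- pop$times >= from & pop$times <= to
  i <- which.max(med[sel])
  list(time_h = pop$times[sel][i] / 3600, level = med[sel][i])
}

#' Run an experiment grid
#'
#' Crosses model variants (e.g. genotypes) with protocols and summarises
#' fates per grid cell.
#'
#' @param spec_variants named list of `ddr_model`s.
#' @param protocols named list of `ddr_protocol`s.
#' @param n cells per grid cell.
#' @param master_seed integer; each grid cell uses an offset stream.
#' @param thresholds a [fate_thresholds()].
#' @param windows apoptosis-count windows (hours after IR).
#' @param ... passed to [run_population()].
#' @return data frame with one row per (variant, protocol): apoptotic
#'   percentages per window and clonogenic survival percentage, plus the
#'   list of `population_result`s in attribute `"populations"`.
#' @export
run_grid <- function(spec_variants, protocols, n, master_seed = 1,
                     thresholds, windows = list(c(0, 24), c(24, 48)), ...) {
  stopifnot(length(spec_variants) >= 1, length(protocols) >= 1)
  rows <- list(); pops <- list()
  k <- 0
  for (v in names(spec_variants)) for (pn in names(protocols)) {
    k <- k + 1
    pop <- run_population(spec_variants[[v]], protocols[[pn]], n,
                          master_seed = master_seed + 1000 * k,
                          thresholds = thresholds, ...)
    fr <- apoptotic_fraction(pop$fates, windows,
                             t0 = protocols[[pn]]$ir_start)
    rows[[k]] <- data.frame(variant = v, protocol = pn,
                            dose = protocols[[pn]]$ir_dose,
                            t(setNames(100 * fr, paste0("apo_pct_",
                              vapply(windows, `[`, numeric(1), 2), "h"))),
                            survival_pct = 100 *
                              clonogenic_survival(pop$fates))
    pops[[paste(v, pn, sep = ".")]] <- pop
  }
  out <- do.call(rbind, rows)
  attr(out, "populations") <- pops
  out
}
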