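hours <- function(h) h * 3600
tgrid <- seq(0, hours(96), by = 600)

test_that("apoptosis requires both thresholds simultaneously", {
  th <- fate_thresholds(p21_arrest = 100, p53_apoptosis = 500,
                        bax_apoptosis = 300)
  # p53 high while Bax low, then Bax high while p53 low: never simultaneous
  p53 <- ifelse(tgrid < hours(10), 600, 100)
  bax <- ifelse(tgrid < hours(10), 100, 600)
  f <- classify_cell(synth_traj(tgrid, p53, bax, 0 * tgrid), th)
  expect_true(is.na(f$apoptosis_time))
  # simultaneous crossing is apoptosis at the first such instant
  p53b <- ifelse(tgrid >= hours(5), 600, 0)
  baxb <- ifelse(tgrid >= hours(8), 350, 0)
  f2 <- classify_cell(synth_traj(tgrid, p53b, baxb, 0 * tgrid), th)
  expect_equal(f2$apoptosis_time, hours(8))
  expect_false(f2$viable)
})

test_that("arrest beyond the colony-forming limit is not viable", {
  th <- fate_thresholds(p21_arrest = 400, p53_apoptosis = 1e5,
                        bax_apoptosis = 1e5, max_arrest = 63.9)
  p21_64 <- ifelse(tgrid <= hours(64.2), 500, 0)
  f <- classify_cell(synth_traj(tgrid, 0 * tgrid, 0 * tgrid, p21_64), th)
  expect_gt(f$arrest_hours, 63.9)
  expect_false(f$viable)
  p21_40 <- ifelse(tgrid <= hours(40), 500, 0)
  f2 <- classify_cell(synth_traj(tgrid, 0 * tgrid, 0 * tgrid, p21_40), th)
  expect_true(f2$viable)
})

test_that("non-contiguous arrest intervals are summed", {
  th <- fate_thresholds(p21_arrest = 400, p53_apoptosis = 1e5,
                        bax_apoptosis = 1e5, max_arrest = 63.9)
  on <- (tgrid < hours(40)) | (tgrid > hours(50) & tgrid < hours(80))
  f <- classify_cell(synth_traj(tgrid, 0 * tgrid, 0 * tgrid,
                                ifelse(on, 500, 0)), th)
  expect_equal(nrow(f$arrest_intervals), 2)
  expect_gt(f$arrest_hours, 63.9)
  expect_false(f$viable)
})

test_that("a resting trajectory is viable with no arrest", {
  th <- fate_thresholds()
  f <- classify_cell(synth_traj(tgrid, rep(5, length(tgrid)),
                                rep(150, length(tgrid)),
                                rep(260, length(tgrid))), th)
  expect_true(f$viable)
  expect_equal(f$arrest_hours, 0)
  expect_true(is.na(f$apoptosis_time))
})

test_that("missing fate species is an error", {
  th <- fate_thresholds()
  tr <- synth_traj(tgrid, 0 * tgrid, 0 * tgrid, 0 * tgrid)
  colnames(tr$Y)[2] <- "NOT_BAX"
  expect_error(classify_cell(tr, th), "BAX")
})

test_that("window fractions follow the closed-right convention", {
  mk_fate <- function(at) {
    structure(list(apoptosis_time = at, arrest_intervals = NULL,
                   arrest_hours = 0, divided_before_death = FALSE,
                   viable = is.na(at)), class = "fate_record")
  }
  fates <- c(lapply(rep(hours(10), 13), mk_fate),
             lapply(rep(hours(30), 45), mk_fate),
             lapply(rep(NA_real_, 942), mk_fate))
  fr <- apoptotic_fraction(fates, list(c(0, 24), c(24, 48)))
  expect_equal(fr, c(0.013, 0.045))
  # boundary cell counts in the earlier window only
  fb <- apoptotic_fraction(list(mk_fate(hours(24))),
                           list(c(0, 24), c(24, 48)))
  expect_equal(fb, c(1, 0))
  # no apoptosis -> zero in every window
  expect_equal(apoptotic_fraction(lapply(rep(NA_real_, 5), mk_fate),
                                  list(c(0, 24), c(24, 48))), c(0, 0))
  expect_error(apoptotic_fraction(fates, list(c(0, 30), c(24, 48))),
               "overlap")
})

test_that("per-window counts sum to the total without double counting", {
  set.seed(1)
  at <- ifelse(runif(500) < 0.3, runif(500, 0, hours(48)), NA)
  fates <- lapply(at, function(a)
    structure(list(apoptosis_time = a, arrest_intervals = NULL,
                   arrest_hours = 0, divided_before_death = FALSE,
                   viable = is.na(a)), class = "fate_record"))
  fr <- apoptotic_fraction(fates, list(c(0, 12), c(12, 24), c(24, 36),
                                       c(36, 48)))
  expect_equal(sum(fr) * 500, sum(!is.na(at)))
})

test_that("raising apoptosis thresholds never increases the fraction", {
  set.seed(2)
  n <- 60
  trajs <- lapply(1:n, function(i) {
    p53 <- pmax(0, cumsum(rnorm(length(tgrid), 0, 20)) + 300)
    bax <- pmax(0, cumsum(rnorm(length(tgrid), 0, 10)) + 200)
    synth_traj(tgrid, p53, bax, 0 * tgrid)
  })
  frac <- function(p53_th, bax_th) {
    th <- fate_thresholds(p21_arrest = 1e5, p53_apoptosis = p53_th,
                          bax_apoptosis = bax_th)
    mean(vapply(trajs, function(tr)
      !is.na(classify_cell(tr, th)$apoptosis_time), logical(1)))
  }
  prev <- 1
  for (s in c(200, 300, 400, 600, 900)) {
    cur <- frac(s, s * 0.7)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("every cell falls in exactly one fate class", {
  set.seed(3)
  th <- fate_thresholds(p21_arrest = 400, p53_apoptosis = 500,
                        bax_apoptosis = 350, max_arrest = 63.9)
  for (i in 1:50) {
    p53 <- pmax(0, 700 * exp(-tgrid / hours(runif(1, 5, 40))) *
                  (0.5 + runif(1)))
    bax <- pmax(0, runif(1, 100, 500) * tgrid / max(tgrid) + 100)
    p21 <- runif(1, 200, 900) * exp(-tgrid / hours(runif(1, 10, 90)))
    f <- classify_cell(synth_traj(tgrid, p53, bax, p21), th)
    apoptotic_death <- !is.na(f$apoptosis_time) && !f$divided_before_death
    arrested_death <- f$arrest_hours > th$max_arrest
    classes <- c(apoptotic_not_viable = !f$viable && apoptotic_death,
                 arrested_not_viable = !f$viable && !apoptotic_death &&
                   arrested_death,
                 viable = f$viable)
    expect_equal(sum(classes), 1)
  }
})

test_that("clonogenic survival counts viable cells", {
  mk <- function(v) structure(list(apoptosis_time = NA_real_,
                                   arrest_intervals = NULL,
                                   arrest_hours = if (v) 0 else 70,
                                   divided_before_death = FALSE,
                                   viable = v), class = "fate_record")
  expect_equal(clonogenic_survival(lapply(rep(TRUE, 10), mk)), 1)
  expect_equal(clonogenic_survival(lapply(rep(FALSE, 10), mk)), 0)
  expect_equal(clonogenic_survival(lapply(c(TRUE, FALSE), mk)), 0.5)
})
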