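test_that("lag-matrix entries follow event-relative calendar arithmetic", {
  g <- mk_grid(1, 1)
  nm <- 216
  vals <- array(seq_len(nm), c(1, 1, nm))   # value == month index
  f <- monthly_field(vals, g, c(2001, 1))
  # single event at July 2010: lag -5 is February 2010, lag 0 the event month
  t_jul2010 <- ym_to_index(2010, 7, c(2001, 1))
  ev <- mk_events(1, 1, t_jul2010, n_times = nm)
  lm <- event_lag_matrix(f, ev, c(-5, 0))
  expect_equal(lm[1, "lag-5"], ym_to_index(2010, 2, c(2001, 1)),
               ignore_attr = TRUE)
  expect_equal(lm[1, "lag0"], t_jul2010, ignore_attr = TRUE)
  # lags outside the record are masked, not dropped
  ev2 <- mk_events(1, 1, 3L, n_times = nm)
  lm2 <- event_lag_matrix(f, ev2, c(-5, 0))
  expect_true(is.na(lm2[1, "lag-5"]))
  expect_false(is.na(lm2[1, "lag0"]))
  expect_error(event_lag_matrix(f, ev[0, ], -1:0), "empty")
})

test_that("full lag matrices equal a per-event loop", {
  sc <- null_scene_small()
  sm <- daily_to_monthly(sc$sm_daily)
  anom <- normalize_anomaly(sm, monthly_climatology(sm))
  tr <- sc$truth$events
  ev <- mk_events(tr$lat_idx, tr$lon_idx, tr$event_index,
                  n_times = dim(anom$values)[3])
  lags <- -12:6
  lm <- event_lag_matrix(anom, ev, lags)
  nt <- dim(anom$values)[3]
  for (e in seq_len(nrow(ev))) for (l in seq_along(lags)) {
    t_idx <- ev$event_index[e] + lags[l]
    want <- if (t_idx < 1 || t_idx > nt) NA_real_
            else anom$values[ev$lat_idx[e], ev$lon_idx[e], t_idx]
    expect_identical(unname(lm[e, l]), want)
  }
})

test_that("composite medians follow the documented quantile definition", {
  g <- mk_grid(3, 1)
  vals <- array(NA_real_, c(3, 1, 10))
  vals[1, 1, 5] <- -0.2; vals[2, 1, 5] <- -0.5; vals[3, 1, 5] <- -0.9
  f <- monthly_field(vals, g, c(2001, 1))
  ev <- mk_events(1:3, c(1, 1, 1), c(6, 6, 6), n_times = 10L)
  cs <- composite_median(event_lag_matrix(f, ev, -1L))
  expect_equal(cs$median, -0.5)
  expect_equal(cs$n, 3L)
  # (1, 2, 3, 4): median 2.5, linear-interpolation quartiles 1.75 / 3.25
  g4 <- mk_grid(4, 1)
  vals4 <- array(NA_real_, c(4, 1, 3))
  vals4[, 1, 2] <- 1:4
  f4 <- monthly_field(vals4, g4, c(2001, 1))
  ev4 <- mk_events(1:4, rep(1, 4), rep(2L, 4), n_times = 3L)
  cs4 <- composite_median(event_lag_matrix(f4, ev4, 0L))
  expect_equal(cs4$median, 2.5)
  expect_equal(cs4$q25, 1.75)
  expect_equal(cs4$q75, 3.25)
  expect_true(all(cs4$q25 <= cs4$median & cs4$median <= cs4$q75))
  # an all-masked lag yields masked statistics and n = 0
  cs_na <- composite_median(event_lag_matrix(f4, ev4, 1L))
  expect_true(is.na(cs_na$median))
  expect_equal(cs_na$n, 0L)
})

test_that("per-box composites equal composite_median restricted to the box", {
  sc <- null_scene_small()
  sm <- daily_to_monthly(sc$sm_daily)
  anom <- normalize_anomaly(sm, monthly_climatology(sm))
  tmean <- longterm_mean(sc$temperature)
  aridity <- compute_aridity(sc$net_radiation, sc$precipitation)
  cand <- select_largest_events(sc$burned_area, sc$observed_fraction,
                                sc$land_area)
  ev <- filter_events(cand, anom, tmean, sc$population, pop_percentile = 100)
  boxes <- assign_boxes(ev, tmean, aridity, temp_edges = c(0, 15, 30),
                        aridity_edges = c(0.5, 2, 8), min_box_size = 5)
  lm <- event_lag_matrix(anom, ev, c(-5L, -1L))
  tab <- box_composites_at_lag(lm, boxes, -5L)
  m <- attr(boxes, "membership")
  for (r in seq_len(nrow(tab))) {
    sub <- which(m == tab$box[r])
    cs <- composite_median(lm, sub)
    expect_equal(tab$median[r], cs$median[cs$lag == -5])
    expect_equal(tab$n[r], cs$n[cs$lag == -5])
  }
})

test_that("compositing commutes with restricting the event set", {
  sc <- null_scene_small()
  sm <- daily_to_monthly(sc$sm_daily)
  anom <- normalize_anomaly(sm, monthly_climatology(sm))
  tr <- sc$truth$events
  ev <- mk_events(tr$lat_idx, tr$lon_idx, tr$event_index,
                  n_times = dim(anom$values)[3])
  sub <- seq(1, nrow(ev), by = 3)
  lm_all <- event_lag_matrix(anom, ev, -6:2)
  ev_sub <- ev[sub, ]; class(ev_sub) <- class(ev)
  attr(ev_sub, "start") <- attr(ev, "start")
  attr(ev_sub, "n_times") <- attr(ev, "n_times")
  lm_sub <- event_lag_matrix(anom, ev_sub, -6:2)
  expect_equal(composite_median(lm_all, sub), composite_median(lm_sub))
})

test_that("stratification yields disjoint exhaustive groups", {
  set.seed(9)
  ev <- mk_events(rep(1, 8), rep(1, 8), rep(10L, 8), n_times = 24L,
                  ba_fraction = c(0.31, 0.05, 0.62, 0.11, 0.99, 0.44, 0.21, 0.76))
  # equal-count quartiles over 8 distinct values: 2 events per group
  grp <- stratify(ev, ev$ba_fraction)
  expect_equal(as.integer(sort(table(grp))), c(2L, 2L, 2L, 2L))
  expect_equal(length(grp), 8L)
  # half-open explicit edges
  grp2 <- stratify(ev, ev$ba_fraction, scheme = c(0, 0.01, 0.1, 1))
  expect_equal(grp2, c(3L, 2L, 3L, 3L, 3L, 3L, 3L, 3L), ignore_attr = TRUE)
  # degenerate key collapses to one group with a warning
  expect_warning(g1 <- stratify(ev, rep(0.5, 8)), "degenerate")
  expect_equal(unique(g1), 1L)
  # strata partition events: each used exactly once, n conserved
  sc <- null_scene_small()
  sm <- daily_to_monthly(sc$sm_daily)
  anom <- normalize_anomaly(sm, monthly_climatology(sm))
  tr <- sc$truth$events
  evs <- mk_events(tr$lat_idx, tr$lon_idx, tr$event_index,
                   n_times = dim(anom$values)[3],
                   ba_fraction = tr$ba_fraction)
  q <- stratify(evs, evs$ba_fraction)
  expect_equal(sum(table(q)), nrow(evs))
  lm <- event_lag_matrix(anom, evs, -1L)
  n_total <- composite_median(lm)$n
  n_strata <- vapply(sort(unique(q)), function(k)
    composite_median(lm, which(q == k))$n, integer(1))
  expect_equal(sum(n_strata), n_total)
})

test_that("stratified composites recover an injected size ordering", {
  # larger burned-area fraction paired with stronger lag -5 anomaly
  sc <- signal_scene()
  sm <- daily_to_monthly(sc$sm_daily)
  anom <- normalize_anomaly(sm, monthly_climatology(sm))
  tr <- sc$truth$events
  ev <- mk_events(tr$lat_idx, tr$lon_idx, tr$event_index,
                  n_times = dim(anom$values)[3], ba_fraction = tr$ba_fraction)
  lm <- event_lag_matrix(anom, ev, -5L)
  q <- stratify(ev, ev$ba_fraction)
  meds <- vapply(1:4, function(k)
    composite_median(lm, which(q == k))$median, numeric(1))
  # the injected profile is identical across sizes: all quartiles recover it
  expect_true(all(abs(meds - 0.5) < 0.25))
})

test_that("population strata order composites as the injected signal orders", {
  # hand-crafted population-dependent signal: sparsely populated cells get a
  # strong wet anomaly at lag -5, dense cells none
  g <- mk_grid(8, 1)
  pop <- c(0.5, 1, 2, 3, 10, 20, 50, 100)
  vals <- array(0, c(8, 1, 12))
  vals[1:4, 1, 5] <- 1.0        # lag -5 of an event at month 10
  vals[5:8, 1, 5] <- 0.0
  f <- monthly_field(vals, g, c(2001, 1))
  ev <- mk_events(1:8, rep(1, 8), rep(10L, 8), n_times = 12L)
  lm <- event_lag_matrix(f, ev, -5L)
  grp <- stratify(ev, pop)
  meds <- vapply(1:4, function(k)
    composite_median(lm, which(grp == k))$median, numeric(1))
  expect_equal(meds, c(1, 1, 0, 0))
})
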