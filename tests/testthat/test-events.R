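mk_ba_cell <- function(burns, obs = rep(1, length(burns))) {
  g <- mk_grid(1, 1)
  list(ba = mk_monthly(array(burns, c(1, 1, length(burns))), grid = g),
       obs = mk_monthly(array(obs, c(1, 1, length(obs))), grid = g),
       land = mk_static(matrix(100), grid = g))
}

test_that("the largest admissible burn month is selected", {
  x <- mk_ba_cell(c(0, 5, 3, 9, 2))
  ev <- select_largest_events(x$ba, x$obs, x$land)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_index, 4L)
  expect_equal(ev$ba_fraction, 9 / 100)
  # the 9 km^2 month drops below the observed-fraction rule -> 5 km^2 month
  x2 <- mk_ba_cell(c(0, 5, 3, 9, 2), obs = c(1, 1, 1, 0.7, 1))
  expect_equal(select_largest_events(x2$ba, x2$obs, x2$land)$event_index, 2L)
  # a tie on the maximum resolves to the earliest month
  x3 <- mk_ba_cell(c(0, 9, 3, 9, 2))
  expect_equal(select_largest_events(x3$ba, x3$obs, x3$land)$event_index, 2L)
  # all-zero cells yield no event; non-positive land area masks the cell
  x4 <- mk_ba_cell(c(0, 0, 0))
  expect_equal(nrow(select_largest_events(x4$ba, x4$obs, x4$land)), 0L)
  x5 <- mk_ba_cell(c(0, 5, 3))
  x5$land$values[1, 1] <- 0
  expect_equal(nrow(select_largest_events(x5$ba, x5$obs, x5$land)), 0L)
})

test_that("population threshold uses linear-interpolation percentiles", {
  g <- mk_grid(2, 2)
  pop <- static_field(matrix(c(1, 2, 3, 4), 2, 2), g)
  avail <- matrix(TRUE, 2, 2)
  expect_equal(population_threshold(pop, avail, 25), 1.75)
  expect_equal(population_threshold(pop, avail, 0), 1)
  pop2 <- static_field(matrix(7, 2, 2), g)
  expect_equal(population_threshold(pop2, avail, 25), 7)
  # only soil-moisture-available cells enter the percentile
  avail2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(population_threshold(pop, avail2, 100), 2)
  expect_error(population_threshold(pop, matrix(FALSE, 2, 2)), "no cells")
})

test_that("the filter cascade window, temperature and population rules hold", {
  nm <- 24L
  g <- mk_grid(2, 2)
  z <- monthly_field(array(0.1, c(2, 2, nm)), g, c(2001, 1))
  tmean <- static_field(matrix(c(10, -2, 10, 10), 2, 2), g)
  pop <- static_field(matrix(c(1, 1, 1, 50), 2, 2), g)
  # events: cell (1,1) in March 2001 (lag -5 precedes the record start),
  # cell (2,1) cold, cell (1,2) fine, cell (2,2) too populated
  ev <- mk_events(c(1, 2, 1, 2), c(1, 1, 2, 2), c(3, 12, 12, 12),
                  n_times = nm)
  out <- filter_events(ev, z, tmean, pop, pop_percentile = 80)
  expect_equal(nrow(out), 1L)
  expect_equal(out$lat_idx, 1L)
  expect_equal(out$lon_idx, 2L)
  rep_ <- attr(out, "report")
  expect_equal(rep_$count[rep_$stage == "candidates"], 4)
  expect_equal(rep_$count[rep_$stage == "removed_window"], 1)
  expect_equal(rep_$count[rep_$stage == "removed_temperature"], 1)
  expect_equal(rep_$count[rep_$stage == "removed_population"], 1)
  # masked anomaly inside the window removes the event
  z2 <- z
  z2$values[1, 2, 11] <- NA
  expect_equal(nrow(filter_events(ev, z2, tmean, pop, pop_percentile = 80)), 0L)
})

test_that("filtering matches a brute-force loop on a synthetic scene", {
  sc <- null_scene_small()
  sm <- daily_to_monthly(sc$sm_daily)
  anom <- normalize_anomaly(sm, monthly_climatology(sm))
  tmean <- longterm_mean(sc$temperature)
  cand <- select_largest_events(sc$burned_area, sc$observed_fraction,
                                sc$land_area)
  got <- filter_events(cand, anom, tmean, sc$population)
  # direct application of (a) window completeness, (b) temperature,
  # (c) strict population cut over soil-moisture-available cells
  sm_avail <- apply(!is.na(anom$values), 1:2, any)
  thr <- stats::quantile(sc$population$values[sm_avail], 0.25, type = 7)
  keep <- logical(nrow(cand))
  nt <- dim(anom$values)[3]
  for (e in seq_len(nrow(cand))) {
    i <- cand$lat_idx[e]; j <- cand$lon_idx[e]; t0 <- cand$event_index[e]
    win <- (t0 - 5):(t0 + 1)
    ok_a <- all(win >= 1 & win <= nt) && !anyNA(anom$values[i, j, pmax(pmin(win, nt), 1)])
    ok_b <- tmean$values[i, j] >= 0
    ok_c <- sc$population$values[i, j] < thr
    keep[e] <- ok_a && ok_b && ok_c
  }
  expect_equal(got$event_index, cand$event_index[keep])
  expect_equal(got$lat_idx, cand$lat_idx[keep])
  rep_ <- attr(got, "report")
  expect_equal(sum(rep_$count[rep_$stage != "candidates" &
                                rep_$stage != "retained"]) +
                 rep_$count[rep_$stage == "retained"],
               rep_$count[rep_$stage == "candidates"])
})

test_that("tightening any filter threshold never adds events", {
  sc <- null_scene_small()
  sm <- daily_to_monthly(sc$sm_daily)
  anom <- normalize_anomaly(sm, monthly_climatology(sm))
  tmean <- longterm_mean(sc$temperature)
  base_cand <- select_largest_events(sc$burned_area, sc$observed_fraction,
                                     sc$land_area, min_obs_fraction = 0.8)
  base <- filter_events(base_cand, anom, tmean, sc$population,
                        temp_min = 0, pop_percentile = 25)
  key <- function(ev) paste(ev$lat_idx, ev$lon_idx, ev$event_index)
  for (obs in c(0.85, 0.95)) {
    cand <- select_largest_events(sc$burned_area, sc$observed_fraction,
                                  sc$land_area, min_obs_fraction = obs)
    expect_lte(nrow(cand), nrow(base_cand))
  }
  for (tmin in c(2, 5)) {
    ev <- filter_events(base_cand, anom, tmean, sc$population,
                        temp_min = tmin, pop_percentile = 25)
    expect_true(all(key(ev) %in% key(base)))
  }
  for (pp in c(15, 5)) {
    ev <- filter_events(base_cand, anom, tmean, sc$population,
                        temp_min = 0, pop_percentile = pp)
    expect_true(all(key(ev) %in% key(base)))
  }
})
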