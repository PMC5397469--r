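# brute-force oracle: transitive closure of the |onset_i - onset_j| <= w
# graph, then the same per-electrode dedup rule (earliest wins)
oracle_groups <- function(events, w, min_electrodes) {
  n <- nrow(events)
  if (n == 0) return(list())
  adj <- abs(outer(events$onset_s, events$onset_s, "-")) <= w
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { k <- k + 1; comp[which(reach[i, ])] <- k }
  }
  out <- list()
  for (g in unique(comp)) {
    m <- events[comp == g, , drop = FALSE]
    m <- m[order(m$onset_s, m$electrode_id), , drop = FALSE]
    m <- m[!duplicated(m$electrode_id), , drop = FALSE]
    if (length(unique(m$electrode_id)) >= min_electrodes)
      out[[length(out) + 1]] <- sort(paste(m$electrode_id, m$onset_s))
  }
  out[order(vapply(out, `[`, "", 1))]
}

test_that("grouping matches the brute-force transitive-closure oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:25, 1)
    ev <- make_events(
      electrode_id = sample(sprintf("e%d", 1:8), n, replace = TRUE),
      onset_s = round(sort(runif(n, 0, 6)), 3))
    w <- sample(c(0.1, 0.3, 0.5), 1)
    me <- sample(1:3, 1)
    # stray-leader detachment off: the oracle defines pure chaining semantics
    ds <- group_events(ev, propagation_params(group_window_s = w,
                                              min_electrodes = me,
                                              stray_lead_s = 0))
    got <- lapply(split(ds$members, ds$members$discharge_id), function(m)
      sort(paste(m$electrode_id, m$onset_s)))
    got <- unname(got[order(vapply(got, `[`, "", 1))])
    expect_equal(got, oracle_groups(ev, w, me))
  }
})

test_that("grouping examples behave as specified", {
  ev <- make_events(c("a", "b", "c"), c(0.00, 0.02, 0.05))
  ds <- group_events(ev, propagation_params())
  expect_equal(nrow(ds$discharges), 1)
  expect_equal(ds$discharges$n_electrodes, 3)

  ev2 <- make_events(c("a", "a"), c(1, 1.5))
  ds2 <- group_events(ev2, propagation_params(min_electrodes = 1))
  expect_equal(nrow(ds2$discharges), 2)

  expect_equal(nrow(group_events(make_events(character(0), numeric(0)),
                                 propagation_params())$discharges), 0)
})

test_that("an isolated leading noise trigger is detached from the front", {
  # one electrode fires 0.25 s before a 5-electrode front: it must not
  # become the initiation site of that discharge
  ev <- rbind(make_events("12", 9.80),
              make_events(c("27", "17", "26", "41", "82"),
                          c(10.000, 10.004, 10.004, 10.015, 10.030)))
  ds <- group_events(ev, propagation_params())
  expect_equal(nrow(ds$discharges), 1)
  expect_false("12" %in% ds$members$electrode_id)
  expect_equal(ds$discharges$network_onset_s, 10)
  # a genuine front lead of a few ms is untouched
  ev2 <- make_events(c("27", "17", "26"), c(10.000, 10.004, 10.008))
  ds2 <- group_events(ev2, propagation_params())
  expect_equal(ds2$discharges$n_electrodes, 3)
})

test_that("each event joins at most one discharge (partition invariant)", {
  set.seed(32)
  ev <- make_events(sample(sprintf("e%d", 1:10), 60, replace = TRUE),
                    sort(runif(60, 0, 30)))
  ds <- group_events(ev, propagation_params(min_electrodes = 1))
  key <- paste(ds$members$electrode_id, ds$members$onset_s)
  expect_equal(anyDuplicated(key), 0L)
  expect_lte(nrow(ds$members), nrow(ev))
  # every member is one of the input events
  expect_true(all(key %in% paste(ev$electrode_id, ev$onset_s)))
})

test_that("delay map is zero at the reference and errors on non-members", {
  ev <- make_events(c("27", "41", "82"), c(1.000, 1.015, 1.030))
  ds <- group_events(ev, propagation_params())
  id <- ds$discharges$discharge_id[1]
  dm <- delay_map(ds, id, "27")
  expect_equal(dm$delay_ms[dm$electrode_id == "27"], 0)
  expect_true(all(dm$delay_ms >= 0))
  expect_equal(dm$delay_ms[dm$electrode_id == "82"], 30)
  dm2 <- delay_map(ds, id, "41")
  expect_equal(dm2$delay_ms[dm2$electrode_id == "27"], -15)
  expect_error(delay_map(ds, id, "99"), "not a member")
})

test_that("average delay map is the element-wise mean", {
  ev <- rbind(make_events(c("27", "41"), c(1.000, 1.010)),
              make_events(c("27", "41", "82"), c(5.000, 5.020, 5.040)))
  ds <- group_events(ev, propagation_params(min_electrodes = 2))
  ids <- ds$discharges$discharge_id
  avg <- average_delay_map(ds, ids, "27")
  expect_equal(avg$delay_ms[avg$electrode_id == "41"], mean(c(10, 20)))
  # electrode present in one discharge only: its own delay
  expect_equal(avg$delay_ms[avg$electrode_id == "82"], 40)
  one <- average_delay_map(ds, ids[1], "27")
  expect_equal(one$delay_ms, delay_map(ds, ids[1], "27")$delay_ms)
  expect_error(average_delay_map(ds, character(0), "27"), "no discharges")
})

test_that("delay grid places values at the layout positions", {
  ev <- make_events(c("27", "41"), c(1.000, 1.010))
  ds <- group_events(ev, propagation_params(min_electrodes = 2))
  g <- delay_grid(delay_map(ds, ds$discharges$discharge_id[1], "27"))
  expect_equal(dim(g), c(8, 8))
  expect_equal(g[7, 2], 0)    # electrode "27": column 2, row 7
  expect_equal(g[1, 4], 10)   # electrode "41"
  expect_true(is.na(g[1, 1]))
})

test_that("IID/ID classification switches exactly at the 5 s cutoff", {
  expect_equal(classify_type(0.4), "IID")
  expect_equal(classify_type(30), "ID")
  expect_equal(classify_type(5), "IID")        # "more than 5 s" is strict
  expect_equal(classify_type(5 + 1e-9), "ID")
  lo <- 0.1; hi <- 60
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (classify_type(mid) == "ID") hi <- mid else lo <- mid
  }
  expect_equal(hi, 5, tolerance = 1e-6)
})

test_that("origin classification follows the initiation region", {
  regions <- default_region_map()
  m <- make_events(c("27", "41", "82", "28", "54"),
                   c(1.000, 1.015, 1.030, 1.010, 1.020))
  cl <- classify_origin(m, regions)
  expect_equal(cl$initiation_electrode, "27")
  expect_equal(cl$origin, "CA3")
  expect_match(cl$pattern, "CA3b")
  expect_false(cl$conflict)

  m2 <- make_events(c("82", "83", "74"), c(2.000, 2.004, 2.008))
  cl2 <- classify_origin(m2, regions)
  expect_equal(cl2$origin, "Sub")
  expect_false(cl2$conflict)

  # Sub initiation with a CA1 onset inside the backward limit is flagged
  m3 <- make_events(c("82", "83", "41"), c(2.000, 2.004, 2.100))
  cl3 <- classify_origin(m3, regions)
  expect_equal(cl3$origin, "Sub")
  expect_true(cl3$conflict)

  m4 <- make_events(c("54", "44", "45"), c(3.000, 3.002, 3.004))
  expect_equal(classify_origin(m4, regions)$origin, "other")
})

test_that("Sub and CA1 events split exactly beyond a 300 ms delay", {
  n_groups <- function(d) {
    ev <- rbind(make_events(c("82", "83", "84"), rep(10, 3)),
                make_events(c("41", "42", "31"), rep(10 + d, 3)))
    nrow(group_events(ev, propagation_params())$discharges)
  }
  delays <- c(0.05, 0.1, 0.2, 0.29, 0.31, 0.4, 0.6, 1)
  expect_equal(vapply(delays, n_groups, 0L) > 1, delays > 0.3)
  # bisection over the split point
  lo <- 0.01; hi <- 1
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (n_groups(mid) > 1) hi <- mid else lo <- mid
  }
  expect_equal(hi, 0.3, tolerance = 1e-4)
})

test_that("annotation assigns duration at the initiation electrode", {
  regions <- default_region_map()
  ev <- rbind(make_events("27", 1.000, duration_s = 6.2),
              make_events("41", 1.015, duration_s = 3.0),
              make_events("82", 1.030, duration_s = 2.0))
  ds <- annotate_discharges(group_events(ev, propagation_params()), regions)
  d <- ds$discharges
  expect_equal(d$initiation_electrode, "27")
  expect_equal(d$duration_s, 6.2)
  expect_equal(d$discharge_class, "ID")
  expect_equal(d$origin, "CA3")
})
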