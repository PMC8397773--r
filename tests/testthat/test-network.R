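events_of <- function(ev, a, b) {
  ev[ev$id_a == a & ev$id_b == b, ]
}

test_that("association detection follows the instance definition", {
  ind <- make_individuals(c("A", "B"))
  # same logger, 2 minutes apart
  rec <- make_records(list(c("A", "L1", "23:10"), c("B", "L1", "23:12")))
  ev10 <- detect_associations(rec, ind, 10)
  expect_equal(events_of(ev10, "A", "B")$x, 1)
  # boundary inclusive: difference exactly 2 min <= window of 2
  ev2 <- detect_associations(rec, ind, 2)
  expect_equal(events_of(ev2, "A", "B")$x, 1)

  # different loggers: no association, co-observation bookkeeping instead
  rec2 <- make_records(list(c("A", "L1", "23:10"), c("B", "L2", "23:12")))
  ev <- detect_associations(rec2, ind, 720)
  ab <- events_of(ev, "A", "B")
  expect_equal(ab$x, 0)
  expect_equal(ab$y_ab, 2)  # per-logger: one instance each at L1 and L2
  expect_equal(ab$y_a + ab$y_b, 0)

  # per-night convention collapses those to a single co-observed instance
  evn <- detect_associations(rec2, ind, 720, yab_convention = "per_night")
  expect_equal(events_of(evn, "A", "B")$y_ab, 1)

  # same logger but outside the window goes to y_ab
  rec3 <- make_records(list(c("A", "L1", "23:10"), c("B", "L1", "23:40")))
  ev3 <- detect_associations(rec3, ind, 10)
  ab3 <- events_of(ev3, "A", "B")
  expect_equal(ab3$x, 0)
  expect_equal(ab3$y_ab, 1)

  # multiple qualifying detection pairs in one instance still count X once
  rec4 <- make_records(list(c("A", "L1", "23:10"), c("B", "L1", "23:11"),
                            c("A", "L1", "23:13"), c("B", "L1", "23:14")))
  expect_equal(events_of(detect_associations(rec4, ind, 10), "A", "B")$x, 1)
})

test_that("y counts respect lifespans: unobserved-but-alive versus dead partners", {
  ind <- make_individuals(c("A", "B", "C"))
  ind$last_obs[3] <- base_night - 5  # C's lifespan ended before the night
  rec <- make_records(list(c("A", "L1", "23:00"), c("A", "L3", "23:10"),
                           c("B", "L1", "23:05")))
  ev <- detect_associations(rec, ind, 2)
  ab <- events_of(ev, "A", "B")
  # L1: both present, 5 min apart > 2 -> y_ab; L3: A alone, B observed
  # elsewhere that night -> y_ab
  expect_equal(ab$x, 0)
  expect_equal(ab$y_ab, 2)
  # C was not alive: the night contributes nothing to dyads with C
  ac <- events_of(ev, "A", "C")
  expect_equal(ac$x + ac$y_ab + ac$y_a + ac$y_b, 0)

  # with C alive, A's two instances count towards y_a of dyad (A, C)
  ind2 <- make_individuals(c("A", "B", "C"))
  ev2 <- detect_associations(rec, ind2, 2)
  expect_equal(events_of(ev2, "A", "C")$y_a, 2)
  expect_equal(events_of(ev2, "B", "C")$y_a, 1)
})

test_that("adjusted SRI evaluates the printed formula and handles degeneracies", {
  ev <- structure(
    tibble::tibble(id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
                   x = c(2, 0, 3), y_ab = c(1, 2, 0), y_a = c(3, 1, 0),
                   y_b = c(2, 0, 0)),
    window_minutes = 720, ids = c("A", "B", "C"),
    class = c("assoc_events", class(tibble::tibble())))
  sri <- adjusted_sri(ev)
  expect_equal(sri["A", "B"], 2 / 8)   # 2/(2+1+3+2)
  expect_equal(sri["A", "C"], 0)       # X = 0
  expect_equal(sri["B", "C"], 1)       # perfect association
  expect_true(isSymmetric(unclass(sri)))
  expect_true(all(sri >= 0 & sri <= 1))

  # zero denominator -> 0 with the no-overlap flag
  ev$x[1] <- 0; ev$y_ab[1] <- 0; ev$y_a[1] <- 0; ev$y_b[1] <- 0
  sri2 <- adjusted_sri(ev)
  expect_equal(sri2["A", "B"], 0)
  expect_true(attr(sri2, "no_overlap")["A", "B"])

  bi <- binary_index(ev)
  expect_equal(unname(bi[cbind(c("A", "B"), c("C", "C"))]), c(0, 1))
  expect_true(all(bi %in% c(0, 1)))
})

test_that("adjusted SRI reduces to the classical SRI under full lifespans", {
  # 5-individual toy stream over three nights with mixed co-detections
  rows <- list(
    c("A", "L1", "23:00"), c("B", "L1", "23:04"), c("C", "L2", "22:30"),
    c("D", "L2", "01:00"), c("A", "L2", "01:10"), c("E", "L3", "21:00"),
    c("A", "L1", "22:00", 1), c("C", "L1", "22:03", 1),
    c("B", "L3", "23:30", 1), c("E", "L3", "23:31", 1),
    c("D", "L1", "02:00", 1),
    c("C", "L2", "20:15", 2), c("D", "L2", "20:16", 2),
    c("E", "L2", "20:30", 2), c("A", "L3", "03:00", 2))
  rec <- make_records(rows)
  ids <- c("A", "B", "C", "D", "E")
  ind <- make_individuals(ids, first = base_night - 10, last = base_night + 10)
  for (w in c(2, 10, 720)) {
    sri <- adjusted_sri(detect_associations(rec, ind, w))
    expect_equal(unclass(sri)[ids, ids], oracle_classical_sri(rec, ids, w),
                 info = paste("window", w))
  }
})

test_that("windows are nested: X and BI monotone in the window", {
  st <- small_sim(seed = 11, n_nights = 25)
  evs <- detect_associations(st$records, st$individuals,
                             c(2, 10, 30, 60, 240, 720))
  ws <- c("2", "10", "30", "60", "240", "720")
  for (k in seq_len(length(ws) - 1)) {
    expect_true(all(evs[[ws[k]]]$x <= evs[[ws[k + 1]]]$x),
                info = paste(ws[k], "vs", ws[k + 1]))
    bi1 <- binary_index(evs[[ws[k]]])
    bi2 <- binary_index(evs[[ws[k + 1]]])
    expect_true(all(bi1 <= bi2))
  }
  # SRI monotonicity in the y counts, holding X fixed
  ev <- evs[["720"]]
  base <- adjusted_sri(ev)
  ev$y_a <- ev$y_a + 5
  more <- adjusted_sri(ev)
  active <- ev$x > 0
  expect_true(all(more[cbind(ev$id_a, ev$id_b)][active] <=
                    base[cbind(ev$id_a, ev$id_b)][active]))
})

test_that("spatial summaries match hand geometry", {
  loggers <- tibble::tibble(logger_id = c("L1", "L2", "L3"),
                            x = c(0, 30, 60), y = c(0, 0, 0))
  rec <- make_records(list(
    c("A", "L1", "23:00"), c("A", "L1", "23:30"),
    c("B", "L2", "23:10"),
    c("C", "L1", "22:00"), c("C", "L3", "22:30")), loggers = loggers)
  sp <- spatial_summary(rec)
  co <- sp$coords
  expect_equal(co$x[co$individual_id == "A"], 0)   # all records at one logger
  expect_equal(co$x[co$individual_id == "C"], 30)  # mean of 0 and 60
  expect_equal(sp$distance["A", "B"], 30)
  # brute-force nearest neighbour over all pairs
  for (id in co$individual_id) {
    expect_equal(co$nearest_neighbour_m[co$individual_id == id],
                 min(sp$distance[id, setdiff(co$individual_id, id)]))
  }
  # closest social partner needs SRI > 0
  sri <- assoc_matrix <- structure(
    matrix(c(0, 0, 1, 0, 0, 0, 1, 0, 0), 3, 3,
           dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
    class = c("assoc_matrix", "matrix"))
  sp2 <- spatial_summary(rec, sri = sri)
  expect_equal(sp2$coords$closest_partner_m[sp2$coords$individual_id == "A"],
               30)  # partner C at 30 m, B excluded (SRI 0)
  expect_true(is.na(sp2$coords$closest_partner_m[
    sp2$coords$individual_id == "B"]))

  expect_message(spatial_summary(rec, min_records = 2), "Excluded")
})

test_that("network comparison and summaries behave", {
  set.seed(4)
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[upper.tri(m)] <- runif(6)
  m <- m + t(m)
  cmp <- compare_networks(m, m, n_perm = 99, seed = 1)
  expect_equal(cmp$r, 1)

  m2 <- matrix(0, 4, 4, dimnames = dimnames(m))
  m2[upper.tri(m2)] <- runif(6)
  m2 <- m2 + t(m2)
  cmp2 <- compare_networks(m, m2, n_perm = 99, seed = 1)
  expect_equal(cmp2$r, oracle_mantel_r(m, m2))

  m3 <- m; rownames(m3) <- colnames(m3) <- LETTERS[1:4]
  expect_error(compare_networks(m, m3), "same individuals")

  full <- matrix(1, 4, 4); diag(full) <- 0
  dimnames(full) <- dimnames(m)
  expect_equal(network_summary(full)$density, 1)
  expect_equal(network_summary(matrix(0, 3, 3))$density, 0)
  five <- matrix(0, 5, 5)
  five[cbind(1:4, 2:5)] <- 1; five <- five + t(five)
  expect_equal(network_summary(five)$density, 0.4)  # 4 of C(5,2)
})

test_that("chained grouping links detections the pairwise rule separates", {
  ind <- make_individuals(c("A", "B", "C"))
  rec <- make_records(list(c("A", "L1", "23:00"), c("C", "L1", "23:09"),
                           c("B", "L1", "23:18")))
  pairwise <- detect_associations(rec, ind, 10)
  expect_equal(events_of(pairwise, "A", "B")$x, 0)  # 18 min apart
  chained <- detect_associations(rec, ind, 10, chain = TRUE)
  expect_equal(events_of(chained, "A", "B")$x, 1)   # linked through C
})
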