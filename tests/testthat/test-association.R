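test_that("cosine distance over a gallery equals the exhaustive scan", {
  q <- flat_feature()
  expect_equal(cosine_distance(q, q), 0)
  u <- c(1, rep(0, 99)); v <- c(0, 1, rep(0, 98))
  expect_equal(cosine_distance(u, v), 1)
  expect_equal(cosine_distance(rep(0, 100), u), 1)  # zero vector -> 1
  set.seed(21)
  for (k in 1:20) {
    g <- matrix(rnorm(5 * 100), 5, 100)
    g <- g / sqrt(rowSums(g^2))
    q <- rnorm(100); q <- q / sqrt(sum(q^2))
    expect_equal(cosine_distance(g, q),
                 min(vapply(1:5, function(i) 1 - sum(g[i, ] * q), 0)))
  }
})

test_that("iou cost gates weak overlaps", {
  b <- matrix(c(0, 0, 10, 10), 1, 4)
  expect_equal(iou_cost(b, b)[1, 1], 0)
  far <- matrix(c(100, 100, 10, 10), 1, 4)
  expect_equal(iou_cost(b, far)[1, 1], infeasible_cost())
  third <- matrix(c(5, 0, 10, 10), 1, 4)   # IOU 1/3 -> cost 2/3, feasible
  expect_equal(iou_cost(b, third)[1, 1], 2 / 3)
  expect_lt(iou_cost(b, third)[1, 1], 0.7)
})

test_that("assignment solves trivial and degenerate cases", {
  r <- solve_assignment(matrix(0.2, 1, 1), max_cost = 0.9)
  expect_equal(unname(r$matches), matrix(c(1L, 1L), 1, 2))
  allbad <- matrix(infeasible_cost(), 3, 3)
  r <- solve_assignment(allbad, max_cost = 0.9)
  expect_equal(nrow(r$matches), 0)
  expect_equal(r$unmatched_rows, 1:3)
  expect_equal(r$unmatched_cols, 1:3)
  r <- solve_assignment(matrix(numeric(0), 0, 3))
  expect_equal(r$unmatched_cols, 1:3)
})

test_that("assignment equals the brute-force permutation minimum", {
  set.seed(22)
  for (k in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    cost <- matrix(runif(n * m), n, m)
    if (runif(1) < 0.3)  # sprinkle infeasible entries
      cost[sample(n * m, ceiling(n * m / 4))] <- infeasible_cost()
    r <- solve_assignment(cost)
    expect_equal(attr(r, "total_cost"), brute_force_assignment_cost(cost),
                 tolerance = 1e-6)
  }
})

test_that("assignment result is a valid partition", {
  set.seed(23)
  for (k in 1:20) {
    n <- sample(1:8, 1); m <- sample(1:8, 1)
    r <- solve_assignment(matrix(runif(n * m), n, m), max_cost = 0.8)
    rows <- c(r$matches[, 1], r$unmatched_rows)
    cols <- c(r$matches[, 2], r$unmatched_cols)
    expect_setequal(rows, seq_len(n)); expect_false(anyDuplicated(rows) > 0)
    expect_setequal(cols, seq_len(m)); expect_false(anyDuplicated(cols) > 0)
  }
})

# build a confirmed track by stepping a tracker over consecutive detections
make_confirmed_track <- function(b, feature, n_steps = 4, line) {
  tk <- tracker_create(tracker_params(), line)
  det <- data.frame(left = b[1], top = b[2], width = b[3], height = b[4],
                    conf = 1, class = "pig")
  for (f in seq_len(n_steps))
    tk <- tracker_step(tk, det, f, matrix(feature, 1))
  tk$tracks[[1]]
}

test_that("cascade matches a detection to its track in the appearance stage", {
  line <- counting_line(160)
  u <- flat_feature()
  tr <- make_confirmed_track(c(100, 50, 30, 24), u, line = line)
  tr$kf <- kf_predict(tr$kf); tr$time_since_update <- 1L
  m <- pigcount:::matching_cascade(list(tr), matrix(c(100, 50, 30, 24), 1, 4),
                                   matrix(u, 1), tracker_params())
  expect_equal(nrow(m$matches), 1)
  expect_equal(m$matches[1, ], c(1L, 1L))
})

test_that("the cascade prefers recently updated tracks over older ones", {
  line <- counting_line(160)
  u <- flat_feature()
  fresh <- make_confirmed_track(c(100, 50, 30, 24), u, line = line)
  stale <- make_confirmed_track(c(100, 50, 30, 24), u, line = line)
  stale$id <- 99L
  # age them: fresh missed 1 frame, stale missed 5
  for (k in 1:1) fresh$kf <- kf_predict(fresh$kf)
  for (k in 1:5) stale$kf <- kf_predict(stale$kf)
  fresh$time_since_update <- 1L
  stale$time_since_update <- 5L
  # the stale track's gallery matches the query slightly better
  q <- unit_at_cosine(u, 0.95)
  stale$features <- matrix(q, 1)
  det <- matrix(c(100, 50, 30, 24), 1, 4)
  m <- pigcount:::matching_cascade(list(fresh, stale), det, matrix(q, 1),
                                   tracker_params())
  expect_equal(m$matches[1, 1], 1L)   # age-1 track wins despite higher cost
})

test_that("a detection failing the appearance gate is recovered by the IOU stage", {
  line <- counting_line(160)
  u <- flat_feature()
  tr <- make_confirmed_track(c(100, 50, 30, 24), u, line = line)
  tr$kf <- kf_predict(tr$kf); tr$time_since_update <- 1L
  q <- unit_at_cosine(u, 0.05)        # cosine distance 0.95 > max_distance
  det <- matrix(c(101, 50, 30, 24), 1, 4)
  m <- pigcount:::matching_cascade(list(tr), det, matrix(q, 1),
                                   tracker_params())
  expect_equal(nrow(m$matches), 1)    # matched, but only via IOU
  # and with an impossible IOU it stays unmatched
  far <- matrix(c(300, 50, 30, 24), 1, 4)
  m2 <- pigcount:::matching_cascade(list(tr), far, matrix(q, 1),
                                    tracker_params())
  expect_equal(nrow(m2$matches), 0)
})

test_that("cascade output partitions tracks and detections on random scenes", {
  set.seed(25)
  line <- counting_line(160)
  for (k in 1:10) {
    n_tr <- sample(1:12, 1); n_det <- sample(0:12, 1)
    tracks <- lapply(seq_len(n_tr), function(i) {
      tr <- make_confirmed_track(c(runif(1, 0, 280), runif(1, 0, 200), 30, 24),
                                 flat_feature(), n_steps = sample(1:4, 1),
                                 line = line)
      tr$id <- i
      tr$kf <- kf_predict(tr$kf)
      tr$time_since_update <- sample(1:6, 1)
      tr
    })
    dets <- matrix(c(runif(n_det, 0, 280), runif(n_det, 0, 200),
                     rep(30, n_det), rep(24, n_det)), n_det, 4)
    feats <- matrix(rep(flat_feature(), n_det), n_det, 100, byrow = TRUE)
    m <- pigcount:::matching_cascade(tracks, dets, feats, tracker_params())
    tr_idx <- c(m$matches[, 1], m$unmatched_tracks)
    dt_idx <- c(m$matches[, 2], m$unmatched_detections)
    expect_setequal(tr_idx, seq_len(n_tr))
    expect_false(anyDuplicated(tr_idx) > 0)
    expect_setequal(dt_idx, seq_len(n_det))
    expect_false(anyDuplicated(dt_idx) > 0)
  }
})
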