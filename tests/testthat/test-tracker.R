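pig_det <- function(left, top = 50, w = 30, h = 24, class = "pig") {
  data.frame(left = left, top = top, width = w, height = h, conf = 1,
              class = class)
}

test_that("detections spawn tentative tracks with fresh ids", {
  tk <- tracker_create(tracker_params(), counting_line(160))
  tk <- tracker_step(tk, rbind(pig_det(10), pig_det(100, 100),
                               pig_det(250, 150)), 1)
  expect_length(tk$tracks, 3)
  expect_setequal(vapply(tk$tracks, `[[`, integer(1), "id"), 1:3)
  expect_true(all(vapply(tk$tracks, `[[`, character(1), "lifecycle") ==
                    "tentative"))
})

test_that("a track becomes confirmed after init consecutive updates", {
  tk <- tracker_create(tracker_params(init_hits = 3), counting_line(160))
  for (f in 1:2) {
    tk <- tracker_step(tk, pig_det(100 + 2 * f), f)
    expect_equal(tk$tracks[[1]]$lifecycle, "tentative")
  }
  tk <- tracker_step(tk, pig_det(106), 3)
  expect_equal(tk$tracks[[1]]$lifecycle, "confirmed")
})

test_that("confirmed tracks die once unseen longer than max_age", {
  tk <- tracker_create(tracker_params(max_age = 20), counting_line(160))
  for (f in 1:4) tk <- tracker_step(tk, pig_det(100 + 2 * f), f)
  for (f in 5:24) {          # 20 missed frames: still alive
    tk <- tracker_step(tk, pig_det(100)[0, ], f)
  }
  expect_length(tk$tracks, 1)
  tk <- tracker_step(tk, pig_det(100)[0, ], 25)   # 21st miss: deleted
  expect_length(tk$tracks, 0)
  expect_length(tk$finished, 1)
})

test_that("tentative tracks die on their first missed frame", {
  tk <- tracker_create(tracker_params(), counting_line(160))
  tk <- tracker_step(tk, pig_det(100), 1)
  tk <- tracker_step(tk, pig_det(100)[0, ], 2)
  expect_length(tk$tracks, 0)
})

test_that("person detections are ignored unless track_persons is set", {
  tk <- tracker_create(tracker_params(), counting_line(160))
  tk <- tracker_step(tk, rbind(pig_det(100), pig_det(200, class = "person")), 1)
  expect_length(tk$tracks, 1)
  expect_equal(tk$tracks[[1]]$object_class, "pig")
  tk2 <- tracker_create(tracker_params(track_persons = TRUE),
                        counting_line(160))
  tk2 <- tracker_step(tk2, pig_det(200, class = "person"), 1)
  expect_length(tk2$tracks, 1)
})

test_that("out-of-order frames are rejected", {
  tk <- tracker_create(tracker_params(), counting_line(160))
  tk <- tracker_step(tk, pig_det(100), 5)
  expect_error(tracker_step(tk, pig_det(100), 5), "increasing")
  expect_error(tracker_step(tk, pig_det(100), 3), "increasing")
})

test_that("a clean single crossing produces one finished pig track", {
  sc <- generate_scene(preset_scenarios()$forward_cross)
  run <- tracker_run(sc$detections, tracker_params(), sc$line)
  ended <- run$track_log[run$track_log$ended, ]
  expect_equal(nrow(run$track_log), 1)
  expect_equal(run$track_log$class, "pig")
})

test_that("the tracker is deterministic", {
  sc <- generate_scene(preset_scenarios()$four_pigs)
  r1 <- tracker_run(sc$detections, tracker_params(), sc$line)
  r2 <- tracker_run(sc$detections, tracker_params(), sc$line)
  expect_identical(r1$tracks, r2$tracks)
  expect_identical(r1$track_log, r2$track_log)
  expect_identical(r1$per_frame_cr, r2$per_frame_cr)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_detections(r1$tracks, f1); write_detections(r2$tracks, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("k separated constant-velocity objects yield k confirmed tracks and no switches", {
  actors <- rbind(scene_actor(entry = 1, side = "right", speed = 5),
                  scene_actor(entry = 1, side = "left", speed = 6),
                  scene_actor(entry = 1, side = "right", speed = 4))
  sc <- generate_scene(scenario_spec(actors, n_frames = 40, seed = 17))
  run <- tracker_run(sc$detections, tracker_params(), sc$line)
  # after init_hits frames all three are confirmed
  tk <- tracker_create(tracker_params(), sc$line)
  for (f in 1:3)
    tk <- tracker_step(tk, sc$detections[sc$detections$frame == f, ], f)
  expect_equal(sum(vapply(tk$tracks, `[[`, character(1), "lifecycle") ==
                     "confirmed"), 3)
  expect_equal(nrow(run$track_log), 3)
  s <- score_tracking(sc$gt, run$tracks)
  expect_equal(s$id_switches, 0)
})

test_that("live tracks never exceed cumulative distinct detections", {
  sc <- generate_scene(preset_scenarios()$dense)
  tk <- tracker_create(tracker_params(), sc$line)
  seen <- 0
  for (f in sort(unique(sc$detections$frame))) {
    det <- sc$detections[sc$detections$frame == f, ]
    seen <- seen + nrow(det)
    tk <- tracker_step(tk, det, f)
    expect_lte(length(tk$tracks), seen)
  }
})

test_that("appearance features do not change results when objects never overlap", {
  sc <- generate_scene(preset_scenarios()$four_pigs, render = TRUE)
  r_flat <- tracker_run(sc$detections, tracker_params(), sc$line)
  r_real <- tracker_run(sc$detections, tracker_params(), sc$line,
                        frames = sc$frames)
  expect_identical(r_flat$tracks[, c("frame", "id")],
                   r_real$tracks[, c("frame", "id")])
  expect_identical(r_flat$final_cr, r_real$final_cr)
})
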