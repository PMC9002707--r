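# The lightweight hallway tracker: tracking-by-detection with a
# constant-velocity Kalman filter, an age-cascaded matching scheme combining
# Mahalanobis-gated cosine-appearance costs with a final IOU stage, and the
# flattened 10x10 grayscale crop as appearance descriptor. Track start/end
# zone statuses feed the hallway counting tally.

#' Tracker parameters
#'
#' @param init_hits Consecutive matched frames before a tentative track is
#'   confirmed (default 3).
#' @param max_age Maximum number of consecutive missed frames before a
#'   confirmed track is deleted (default 20); tentative tracks die on their
#'   first missed frame.
#' @param max_distance Cosine-distance threshold for appearance matches in
#'   the cascade (default 0.9).
#' @param gallery_size Number of most recent appearance features kept per
#'   track (default 100), bounding memory on embedded targets.
#' @param track_persons Track person detections too (default `FALSE`). Person
#'   tracks are useful for visualization and evaluation but never touch the
#'   counting tally.
#' @return A list of class `tracker_params`.
#' @export
tracker_params <- function(init_hits = 3L, max_age = 20L, max_distance = 0.9,
                           gallery_size = 100L, track_persons = FALSE) {
  stopifnot(init_hits >= 1, max_age >= 1,
            max_distance > 0, max_distance <= 2)
  structure(list(init_hits = as.integer(init_hits),
                 max_age = as.integer(max_age),
                 max_distance = max_distance,
                 gallery_size = as.integer(gallery_size),
                 track_persons = isTRUE(track_persons)),
            class = "tracker_params")
}

#' Create an empty tracker
#'
#' @param params A [tracker_params()].
#' @param line A [counting_line()] used to derive zone statuses for the
#'   counting tally.
#' @return Tracker state: a list carrying live tracks, the id counter, the
#'   counting tally and a log of finished tracks.
#' @export
tracker_create <- function(params = tracker_params(), line) {
  stopifnot(inherits(line, "counting_line"))
  structure(list(tracks = list(), next_id = 1L, last_frame = -Inf,
                 params = params, line = line, tally = counting_tally(),
                 finished = list()),
            class = "pig_tracker")
}

# internal: spawn a new track from a detection row (+ feature)
new_track <- function(id, det, feature, frame, line) {
  b <- c(det$left, det$top, det$width, det$height)
  status <- zone_of(b[1] + b[3] / 2, line)
  if (is.na(status)) status <- 0L      # born on the line: entrance status
  list(id = id,
       kf = kf_initiate(b),
       lifecycle = "tentative",
       hits = 1L,
       time_since_update = 0L,
       features = matrix(feature, nrow = 1),
       object_class = det$class,
       start_status = status,
       end_status = status,
       start_frame = frame,
       last_frame = frame,
       last_box = b)
}

# internal: predicted box of a track
track_box <- function(tr) {
  z <- tr$kf$mean[1:4]
  w <- max(z[3] * z[4], 1e-6)
  c(left = z[1] - w / 2, top = z[2] - z[4] / 2,
    width = w, height = max(z[4], 1e-6))
}

# internal: age-cascaded matching.
# tracks: list; det_boxes: n x 4 matrix; features: n x 100 matrix.
# Returns list(matches = 2-col matrix (track index, det index),
#              unmatched_tracks, unmatched_detections).
matching_cascade <- function(tracks, det_boxes, features, params) {
  n_tr <- length(tracks); n_det <- nrow(det_boxes)
  if (n_tr == 0 || n_det == 0)
    return(list(matches = matrix(integer(0), 0, 2),
                unmatched_tracks = seq_len(n_tr),
                unmatched_detections = seq_len(n_det)))
  confirmed <- which(vapply(tracks, function(t) t$lifecycle == "confirmed",
                            logical(1)))
  unconfirmed <- setdiff(seq_len(n_tr), confirmed)
  gate <- chi2_gate()
  matches <- matrix(integer(0), 0, 2)
  unmatched_det <- seq_len(n_det)
  unmatched_conf <- confirmed

  # stage 1: appearance matching, most recently updated tracks first
  for (age in seq_len(params$max_age)) {
    if (length(unmatched_det) == 0) break
    tier <- unmatched_conf[vapply(tracks[unmatched_conf],
                                  function(t) t$time_since_update == age,
                                  logical(1))]
    if (length(tier) == 0) next
    cost <- cosine_cost_matrix(lapply(tracks[tier], `[[`, "features"),
                               features[unmatched_det, , drop = FALSE])
    for (k in seq_along(tier)) {       # Mahalanobis gating
      gd <- kf_gating_distance(tracks[[tier[k]]]$kf,
                               det_boxes[unmatched_det, , drop = FALSE])
      cost[k, gd > gate] <- infeasible_cost()
    }
    res <- solve_assignment(cost, max_cost = params$max_distance)
    if (nrow(res$matches) > 0) {
      matches <- rbind(matches,
                       cbind(tier[res$matches[, 1]],
                             unmatched_det[res$matches[, 2]]))
      unmatched_det <- unmatched_det[-res$matches[, 2]]
      unmatched_conf <- setdiff(unmatched_conf, tier[res$matches[, 1]])
    }
  }

  # stage 2: IOU matching for unconfirmed tracks and just-missed confirmed ones
  recent_conf <- unmatched_conf[vapply(tracks[unmatched_conf],
                                       function(t) t$time_since_update == 1L,
                                       logical(1))]
  iou_cand <- c(unconfirmed, recent_conf)
  if (length(iou_cand) > 0 && length(unmatched_det) > 0) {
    tb <- t(vapply(tracks[iou_cand], track_box, numeric(4)))
    cost <- iou_cost(tb, det_boxes[unmatched_det, , drop = FALSE])
    res <- solve_assignment(cost, max_cost = 0.7)
    if (nrow(res$matches) > 0) {
      matches <- rbind(matches,
                       cbind(iou_cand[res$matches[, 1]],
                             unmatched_det[res$matches[, 2]]))
      unmatched_det <- unmatched_det[-res$matches[, 2]]
    }
  }
  matched_tracks <- if (nrow(matches) > 0) matches[, 1] else integer(0)
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(n_tr), matched_tracks),
       unmatched_detections = unmatched_det)
}

#' Advance the tracker by one frame
#'
#' Predicts all tracks, associates them with this frame's detections through
#' the matching cascade, Kalman-updates matched tracks (incrementing hits,
#' appending the appearance feature and refreshing the end status from the
#' new box center), ages unmatched tracks, deletes tentative tracks on their
#' first miss and confirmed tracks older than `max_age`, freezes deleted
#' tracks into the counting tally, and spawns tentative tracks from unmatched
#' pig detections.
#'
#' @param tracker Tracker state from [tracker_create()] or a previous step.
#' @param detections Data frame with one row per detection in this frame:
#'   columns `left`, `top`, `width`, `height`, `conf`, `class` (`"pig"` or
#'   `"person"`). May have zero rows.
#' @param frame Integer frame index; must exceed the previous frame.
#' @param features Optional n x 100 matrix of appearance features aligned
#'   with `detections`; defaults to the flat appearance-free descriptor.
#' @return The updated tracker state; element `cr` holds the counting result
#'   after this frame.
#' @export
tracker_step <- function(tracker, detections, frame, features = NULL) {
  stopifnot(inherits(tracker, "pig_tracker"))
  if (frame <= tracker$last_frame)
    stop("frames must be presented in increasing order (got ", frame,
         " after ", tracker$last_frame, ")")
  tracker$last_frame <- frame
  n_det <- if (is.null(detections)) 0L else nrow(detections)
  if (n_det > 0) {
    if (any(detections$width <= 0 | detections$height <= 0))
      stop("detections must have positive width and height")
    if (is.null(features))
      features <- matrix(flat_feature(), n_det, 100, byrow = TRUE)
  } else {
    features <- matrix(numeric(0), 0, 100)
  }

  # predict every track and age it
  tracker$tracks <- lapply(tracker$tracks, function(tr) {
    tr$kf <- kf_predict(tr$kf)
    tr$time_since_update <- tr$time_since_update + 1L
    tr
  })

  det_boxes <- if (n_det > 0)
    as_box_matrix(detections[, c("left", "top", "width", "height")])
  else matrix(numeric(0), 0, 4)
  m <- matching_cascade(tracker$tracks, det_boxes, features, tracker$params)

  p <- tracker$params
  if (nrow(m$matches) > 0) {
    for (r in seq_len(nrow(m$matches))) {
      ti <- m$matches[r, 1]; di <- m$matches[r, 2]
      tr <- tracker$tracks[[ti]]
      b <- det_boxes[di, ]
      tr$kf <- kf_update(tr$kf, b)
      tr$hits <- tr$hits + 1L
      tr$time_since_update <- 0L
      tr$features <- rbind(tr$features, features[di, ])
      if (nrow(tr$features) > p$gallery_size)
        tr$features <- tr$features[nrow(tr$features) -
                                     (p$gallery_size - 1L):0, , drop = FALSE]
      z <- zone_of(b[1] + b[3] / 2, tracker$line)
      if (!is.na(z)) tr$end_status <- z
      if (tr$lifecycle == "tentative" && tr$hits >= p$init_hits)
        tr$lifecycle <- "confirmed"
      tr$last_frame <- frame
      tr$last_box <- unname(b)
      tracker$tracks[[ti]] <- tr
    }
  }

  # deletion: tentative tracks die on a miss; confirmed beyond max_age
  dead <- vapply(tracker$tracks, function(tr) {
    (tr$lifecycle == "tentative" && tr$time_since_update > 0L) ||
      tr$time_since_update > p$max_age
  }, logical(1))
  for (tr in tracker$tracks[dead]) {
    tracker$tally <- tally_freeze(tracker$tally, tr)
    tracker$finished[[length(tracker$finished) + 1L]] <- tr
  }
  tracker$tracks <- tracker$tracks[!dead]

  # spawn tracks from unmatched detections
  for (di in m$unmatched_detections) {
    cls <- detections$class[di]
    if (cls == "person" && !p$track_persons) next
    det <- list(left = det_boxes[di, 1], top = det_boxes[di, 2],
                width = det_boxes[di, 3], height = det_boxes[di, 4],
                class = cls)
    tracker$tracks[[length(tracker$tracks) + 1L]] <-
      new_track(tracker$next_id, det, features[di, ], frame, tracker$line)
    tracker$next_id <- tracker$next_id + 1L
  }

  tracker$cr <- counting_result(tracker$tracks, tracker$tally)
  tracker
}

#' Run the tracker over a full detection stream
#'
#' Steps through every frame from the first to the last frame index present
#' (frames with no detections still age the tracks), producing the
#' MOTChallenge-style track output, the per-frame counting result and the
#' finished-track log. Deterministic given the stream.
#'
#' @param detections Data frame with columns `frame`, `left`, `top`,
#'   `width`, `height`, `conf`, `class`, sorted or sortable by frame.
#' @param params A [tracker_params()].
#' @param line A [counting_line()].
#' @param features Optional matrix of appearance features, one row per
#'   detection row.
#' @param frames Optional list of grayscale frame matrices (indexed by frame
#'   number) from which appearance features are extracted when `features` is
#'   not given.
#' @param output Which tracks to emit per frame: `"all"` live tracks updated
#'   this frame (the default — counting considers all existing tracks), or
#'   `"confirmed"` only.
#' @return A list of class `tracking_run`: `tracks` (data frame
#'   frame/id/left/top/width/height/conf/class), `per_frame_cr` (data frame
#'   frame/cr), `final_cr`, `track_log` (one row per track ever created, with
#'   start/end statuses, contribution and first/last frames) and the final
#'   tracker state.
#' @export
tracker_run <- function(detections, params = tracker_params(), line,
                        features = NULL, frames = NULL,
                        output = c("all", "confirmed")) {
  output <- match.arg(output)
  stopifnot(is.data.frame(detections))
  if (nrow(detections) > 0 && is.unsorted(detections$frame))
    detections <- detections[order(detections$frame), , drop = FALSE]
  tracker <- tracker_create(params, line)
  out_rows <- list(); cr_rows <- list()
  if (nrow(detections) == 0) {
    return(finish_run(tracker, out_rows, cr_rows))
  }
  f_range <- seq(min(detections$frame), max(detections$frame))
  for (f in f_range) {
    idx <- which(detections$frame == f)
    det <- detections[idx, , drop = FALSE]
    feat <- NULL
    if (!is.null(features)) {
      feat <- features[idx, , drop = FALSE]
    } else if (!is.null(frames) && length(idx) > 0) {
      feat <- t(vapply(seq_len(nrow(det)), function(i)
        extract_feature(frames[[f]], c(det$left[i], det$top[i],
                                       det$width[i], det$height[i])),
        numeric(100)))
    }
    tracker <- tracker_step(tracker, det, f, feat)
    emit <- Filter(function(tr) {
      tr$time_since_update == 0L &&
        (output == "all" || tr$lifecycle == "confirmed")
    }, tracker$tracks)
    for (tr in emit) {
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        frame = f, id = tr$id, left = tr$last_box[1], top = tr$last_box[2],
        width = tr$last_box[3], height = tr$last_box[4], conf = 1,
        class = tr$object_class)
    }
    cr_rows[[length(cr_rows) + 1L]] <- data.frame(frame = f, cr = tracker$cr)
  }
  finish_run(tracker, out_rows, cr_rows)
}

# assemble the tracking_run result object
finish_run <- function(tracker, out_rows, cr_rows) {
  tracks <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(frame = integer(0), id = integer(0), left = numeric(0),
               top = numeric(0), width = numeric(0), height = numeric(0),
               conf = numeric(0), class = character(0))
  tracks <- tracks[order(tracks$frame, tracks$id), , drop = FALSE]
  rownames(tracks) <- NULL
  per_frame <- if (length(cr_rows)) do.call(rbind, cr_rows) else
    data.frame(frame = integer(0), cr = integer(0))
  all_tracks <- c(tracker$finished, tracker$tracks)
  log <- if (length(all_tracks)) do.call(rbind, lapply(all_tracks, function(tr)
    data.frame(id = tr$id, class = tr$object_class,
               start_status = tr$start_status, end_status = tr$end_status,
               contribution = if (tr$object_class == "pig")
                 crossing_contribution(tr$start_status, tr$end_status) else 0L,
               first_frame = tr$start_frame, last_frame = tr$last_frame,
               ended = !tr$id %in% vapply(tracker$tracks, `[[`,
                                          integer(1), "id"))))
  else data.frame(id = integer(0), class = character(0),
                  start_status = integer(0), end_status = integer(0),
                  contribution = integer(0), first_frame = integer(0),
                  last_frame = integer(0), ended = logical(0))
  log <- log[order(log$id), , drop = FALSE]
  rownames(log) <- NULL
  final_cr <- counting_result(tracker$tracks, tracker$tally)
  structure(list(tracks = tracks, per_frame_cr = per_frame,
                 final_cr = final_cr, track_log = log, state = tracker),
            class = "tracking_run")
}

#' @export
print.tracking_run <- function(x, ...) {
  cat("tracking run:", length(unique(x$tracks$id)), "emitted tracks over",
      nrow(x$per_frame_cr), "frames; final counting result CR =",
      x$final_cr, "\n")
  invisible(x)
}
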