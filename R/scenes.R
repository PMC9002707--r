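# Synthetic hallway scenes: scripted rectangular animals moving horizontally
# across a vertical counting line in a top-view grayscale image, with
# optional back-and-forth reversals, detection dropout, bounding-box jitter
# and occasional person-class objects. Everything is deterministic under the
# scenario seed, so the full pipeline is testable without any video data.

#' Script one actor of a hallway scenario
#'
#' @param class `"pig"` or `"person"`.
#' @param entry First frame in which the actor is present.
#' @param side Side of the image the actor enters from (`"right"` or
#'   `"left"`); it starts flush with that edge and walks toward the other.
#' @param speed Walking speed in pixels per frame (must be nonzero).
#' @param w,h Box size in pixels.
#' @param y Top coordinate of the box (its "lane"); chosen automatically by
#'   [generate_scene()] when `NA`.
#' @param reversals Integer vector of frames at which the horizontal velocity
#'   flips sign (each listed frame toggles the direction from then on).
#' @return A one-row data frame describing the actor.
#' @export
scene_actor <- function(class = "pig", entry = 1L, side = "right", speed = 6,
                        w = 36, h = 24, y = NA, reversals = integer(0)) {
  stopifnot(class %in% c("pig", "person"), side %in% c("right", "left"),
            speed > 0, w > 0, h > 0, entry >= 1)
  data.frame(class = class, entry = as.integer(entry), side = side,
             speed = speed, w = w, h = h, y = y,
             reversals = I(list(as.integer(reversals))))
}

#' Define a synthetic hallway scenario
#'
#' @param actors Data frame of actors, built by rbinding [scene_actor()]
#'   rows.
#' @param width,height Image size in pixels (defaults 320 x 240, the
#'   detector's working resolution and a hallway-like aspect).
#' @param n_frames Number of frames.
#' @param dropout_prob Probability that a true box is dropped from the
#'   detection stream (independent per box).
#' @param jitter_sd Standard deviation, in pixels, of Gaussian jitter added
#'   to box corners and sizes (truncated so boxes stay valid and inside the
#'   frame).
#' @param line_x Counting-line coordinate (default `width / 2`).
#' @param entrance_side Side of the line that is the entrance area
#'   (default `"right"`).
#' @param seed Integer seed fixing all randomness of the scenario.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(actors, width = 320, height = 240, n_frames = 80,
                          dropout_prob = 0, jitter_sd = 0,
                          line_x = width / 2, entrance_side = "right",
                          seed = 1L) {
  stopifnot(is.data.frame(actors), nrow(actors) >= 1,
            dropout_prob >= 0, dropout_prob < 1, jitter_sd >= 0,
            line_x > 0, line_x < width)
  if (any(actors$w >= width))
    stop("impossible scenario: actor wider than the image")
  structure(list(actors = actors, width = width, height = height,
                 n_frames = as.integer(n_frames),
                 dropout_prob = dropout_prob, jitter_sd = jitter_sd,
                 line_x = line_x, entrance_side = entrance_side,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# center-x trajectory of one actor over frames 1..n_frames; NA when absent.
# The actor starts flush inside its entry edge and is removed for good once
# its box has fully left the image.
actor_trajectory <- function(actor, spec) {
  n <- spec$n_frames
  x <- rep(NA_real_, n)
  half <- actor$w / 2
  dir <- if (actor$side == "right") -1 else 1
  pos <- if (actor$side == "right") spec$width - half else half
  revs <- actor$reversals[[1]]
  for (f in seq(actor$entry, n)) {
    if (f > actor$entry) {
      if (f %in% revs) dir <- -dir
      pos <- pos + dir * actor$speed
    }
    if (pos <= -half || pos >= spec$width + half) break  # fully out: gone
    x[f] <- pos
  }
  x
}

# signed line-crossing count of a center trajectory: +1 per entrance->exit
# transition, -1 per exit->entrance; on-line samples keep the prior status
signed_crossings <- function(x, line) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(0L)
  z <- zone_of(x, line)
  status <- if (is.na(z[1])) 0L else z[1]
  total <- 0L
  for (k in seq_along(z)[-1]) {
    if (is.na(z[k]) || z[k] == status) next
    total <- total + (z[k] - status)
    status <- z[k]
  }
  as.integer(total)
}

#' Generate a synthetic hallway scene
#'
#' Produces ground-truth trajectories, a noisy detection stream and
#' (optionally) rendered grayscale frames for a scenario. Actors are drawn
#' as filled rectangles with distinct seeded intensities on a textured
#' background; detections are the true boxes with truncated Gaussian jitter,
#' dropped independently with the scenario's dropout probability. Fully
#' deterministic under the scenario seed.
#'
#' @param spec A [scenario_spec()].
#' @param render Render frames as grayscale matrices (default `FALSE`; the
#'   tracker and counter only need boxes, and features fall back to the flat
#'   descriptor when frames are absent).
#' @return A list of class `hallway_scene`: `spec`, `line`
#'   (the [counting_line()]), `gt` (data frame frame/id/left/top/width/
#'   height/class of true boxes), `gt_crossings` (per-actor signed crossing
#'   counts and their total), `detections` (noisy stream, same columns plus
#'   `conf`), and `frames` (list of matrices, or `NULL`).
#' @export
generate_scene <- function(spec, render = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  line <- counting_line(spec$line_x, spec$entrance_side)
  na <- nrow(spec$actors)
  actors <- spec$actors
  # automatic non-overlapping lanes for actors without a y
  lane_pitch <- spec$height / na
  for (i in seq_len(na)) {
    if (is.na(actors$y[i]))
      actors$y[i] <- round((i - 0.5) * lane_pitch - actors$h[i] / 2)
    actors$y[i] <- min(max(actors$y[i], 0), spec$height - actors$h[i])
  }
  intensities <- 0.55 + 0.4 * (sample(na) - 1) / max(na - 1, 1)

  traj <- lapply(seq_len(na), function(i)
    actor_trajectory(actors[i, , drop = FALSE], spec))
  gt_rows <- list()
  for (i in seq_len(na)) {
    f <- which(!is.na(traj[[i]]))
    if (length(f) == 0) next
    gt_rows[[i]] <- data.frame(
      frame = f, id = i,
      left = traj[[i]][f] - actors$w[i] / 2, top = actors$y[i],
      width = actors$w[i], height = actors$h[i], class = actors$class[i])
  }
  gt <- do.call(rbind, gt_rows)
  gt <- gt[order(gt$frame, gt$id), , drop = FALSE]
  rownames(gt) <- NULL
  crossings <- data.frame(
    id = seq_len(na), class = actors$class,
    signed = vapply(traj, signed_crossings, integer(1), line = line))
  gt_total <- sum(crossings$signed[crossings$class == "pig"])

  # noisy detections
  keep <- stats::runif(nrow(gt)) >= spec$dropout_prob
  det <- gt[keep, , drop = FALSE]
  if (spec$jitter_sd > 0 && nrow(det) > 0) {
    n <- nrow(det)
    det$left <- det$left + stats::rnorm(n, 0, spec$jitter_sd)
    det$top <- det$top + stats::rnorm(n, 0, spec$jitter_sd)
    det$width <- pmax(det$width + stats::rnorm(n, 0, spec$jitter_sd), 4)
    det$height <- pmax(det$height + stats::rnorm(n, 0, spec$jitter_sd), 4)
    det$left <- pmin(pmax(det$left, -det$width / 2),
                     spec$width - det$width / 2)
    det$top <- pmin(pmax(det$top, -det$height / 2),
                    spec$height - det$height / 2)
  }
  det$conf <- if (nrow(det)) round(stats::runif(nrow(det), 0.8, 1), 3)
  else numeric(0)
  det$id <- NULL
  det <- det[, c("frame", "left", "top", "width", "height", "conf", "class")]
  rownames(det) <- NULL

  frames <- NULL
  if (render) {
    background <- matrix(stats::runif(spec$height * spec$width, 0.2, 0.4),
                         spec$height, spec$width)
    frames <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      img <- background
      rows <- which(gt$frame == f)
      for (r in rows) {
        i <- gt$id[r]
        x0 <- max(0, floor(gt$left[r])); x1 <- min(spec$width,
                                                   ceiling(gt$left[r] + gt$width[r]))
        y0 <- max(0, floor(gt$top[r])); y1 <- min(spec$height,
                                                  ceiling(gt$top[r] + gt$height[r]))
        if (x1 > x0 && y1 > y0)
          img[(y0 + 1):y1, (x0 + 1):x1] <- intensities[i]
      }
      frames[[f]] <- img
    }
  }
  structure(list(spec = spec, line = line, gt = gt,
                 gt_crossings = crossings, gt_total = gt_total,
                 detections = det, frames = frames),
            class = "hallway_scene")
}

#' Named preset scenarios
#'
#' Small scripted scenes exercising the canonical counting situations:
#' \describe{
#'   \item{forward_cross}{one pig entering from the entrance side and
#'     leaving through the exit side (expected CR +1).}
#'   \item{backward_cross}{one pig walking the opposite way (expected CR -1).}
#'   \item{back_and_forth}{one pig crossing forward, returning over the line,
#'     then crossing forward again (net CR +1).}
#'   \item{four_pigs}{four concurrent tracks with statuses 0-to-1, 0-to-1,
#'     1-to-0 and 0-to-0 (expected CR +1).}
#'   \item{net_count}{ten pigs crossing entrance-to-exit of which two turn
#'     around mid-hallway and go back, for a net count of eight.}
#'   \item{dense}{thirty pigs with overlapping traffic and 10% detection
#'     dropout — the stress case.}
#' }
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
preset_scenarios <- function() {
  one <- function(side, reversals = integer(0), n_frames = 70)
    scenario_spec(scene_actor(side = side, reversals = reversals),
                  n_frames = n_frames, seed = 11L)
  four <- rbind(
    scene_actor(entry = 1, side = "right", speed = 6),           # 0 -> 1
    scene_actor(entry = 5, side = "right", speed = 6),           # 0 -> 1
    scene_actor(entry = 3, side = "left", speed = 6),            # 1 -> 0
    scene_actor(entry = 20, side = "right", speed = 2))          # 0 -> 0
  ten <- do.call(rbind, lapply(1:10, function(i)
    scene_actor(entry = 1L + 6L * (i - 1L), side = "right", speed = 6,
                reversals = if (i > 8) 40L + 6L * (i - 1L) else integer(0))))
  dense <- do.call(rbind, lapply(1:30, function(i)
    scene_actor(entry = 1L + ((i * 7L) %% 40L),
                side = if (i %% 4 == 0) "left" else "right",
                speed = 4 + (i %% 5), w = 30, h = 18)))
  list(
    forward_cross = one("right"),
    backward_cross = one("left"),
    back_and_forth = one("right", reversals = c(29L, 35L), n_frames = 110),
    four_pigs = scenario_spec(four, n_frames = 60, seed = 21L),
    net_count = scenario_spec(ten, n_frames = 160, seed = 31L),
    dense = scenario_spec(dense, height = 480, n_frames = 140,
                          dropout_prob = 0.1, jitter_sd = 1, seed = 41L)
  )
}
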