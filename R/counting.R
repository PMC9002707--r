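# Hallway line-crossing counting: a vertical counting line splits the camera
# view into an entrance zone (status 0) and an exit zone (status 1). Each
# track records the zone where it was born (start status) and the zone of its
# latest detection (end status). The signed counting result CR is recomputed
# every frame as the sum of per-track contributions: +1 for entrance-to-exit,
# -1 for exit-to-entrance, 0 otherwise, over ended (frozen) plus live tracks.

#' Define the hallway counting line
#'
#' @param line_x Horizontal pixel coordinate of the vertical counting line,
#'   typically the hallway center (image width / 2).
#' @param entrance_side Which side of the line is the entrance area:
#'   `"right"` (the default, so right-to-left crossings count +1) or
#'   `"left"` for the mirrored configuration.
#' @return A list of class `counting_line`.
#' @export
counting_line <- function(line_x, entrance_side = c("right", "left")) {
  entrance_side <- match.arg(entrance_side)
  stopifnot(is.finite(line_x), line_x > 0)
  structure(list(line_x = line_x, entrance_side = entrance_side),
            class = "counting_line")
}

#' Zone status of an x coordinate
#'
#' Returns the zone bit for a box-center x coordinate: 0 in the entrance
#' area, 1 in the exit area. A center lying exactly on the line returns
#' `NA`, meaning "keep the previous status" — this avoids count chattering
#' from sub-pixel jitter around the line.
#'
#' @param center_x Numeric vector of x coordinates (pixels).
#' @param line A [counting_line()].
#' @return Integer vector of 0 (entrance), 1 (exit) or `NA` (on the line).
#' @export
zone_of <- function(center_x, line) {
  stopifnot(inherits(line, "counting_line"), all(is.finite(center_x)))
  right <- ifelse(center_x > line$line_x, TRUE,
                  ifelse(center_x < line$line_x, FALSE, NA))
  if (line$entrance_side == "right") as.integer(!right) else as.integer(right)
}

#' Counting contribution of one track
#'
#' @param start_status,end_status Zone bits (0 entrance, 1 exit).
#' @return `+1` for a track that started in the entrance area and currently
#'   sits in the exit area, `-1` for the reverse, `0` when both statuses are
#'   equal.
#' @examples
#' crossing_contribution(0, 1) # +1
#' crossing_contribution(1, 0) # -1
#' @export
crossing_contribution <- function(start_status, end_status) {
  stopifnot(all(start_status %in% c(0, 1)), all(end_status %in% c(0, 1)))
  as.integer(end_status) - as.integer(start_status)
}

#' Create an empty counting tally
#'
#' The tally holds the frozen contributions of ended tracks; live tracks
#' contribute on the fly via [counting_result()].
#'
#' @return A list of class `counting_tally` with `frozen_sum` and the ids
#'   already frozen.
#' @export
counting_tally <- function() {
  structure(list(frozen_sum = 0L, frozen_ids = integer(0)),
            class = "counting_tally")
}

#' Freeze an ended track into the tally
#'
#' Called when a track is deleted: its contribution becomes permanent. Each
#' track id may be frozen exactly once; person tracks never contribute.
#'
#' @param tally A [counting_tally()].
#' @param track A track (list with `id`, `object_class`, `start_status`,
#'   `end_status`).
#' @return The updated tally.
#' @export
tally_freeze <- function(tally, track) {
  stopifnot(inherits(tally, "counting_tally"))
  if (track$id %in% tally$frozen_ids)
    stop("track ", track$id, " already frozen")
  tally$frozen_ids <- c(tally$frozen_ids, track$id)
  if (identical(track$object_class, "pig"))
    tally$frozen_sum <- tally$frozen_sum +
      crossing_contribution(track$start_status, track$end_status)
  tally
}

#' Signed counting result CR
#'
#' The frozen sum of ended tracks plus the live contributions of all
#' currently existing pig tracks (tentative tracks included: a short-lived
#' spurious track necessarily has equal start and end status and contributes
#' 0). Person tracks never contribute.
#'
#' @param tracks List of live tracks.
#' @param tally A [counting_tally()].
#' @return Integer CR: net entrance-to-exit crossings.
#' @export
counting_result <- function(tracks, tally = counting_tally()) {
  live <- 0L
  for (tr in tracks) {
    if (!identical(tr$object_class, "pig")) next
    live <- live + crossing_contribution(tr$start_status, tr$end_status)
  }
  as.integer(tally$frozen_sum + live)
}
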