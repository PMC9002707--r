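# MOTChallenge-dialect CSV readers/writers and the flat key:value pipeline
# configuration. One detection per row:
# frame,id,bb_left,bb_top,bb_width,bb_height,conf,class,visibility
# frame indices are 1-based, id is -1 for raw detections, class 1 = pig,
# 2 = person.

.class_codes <- c(pig = 1L, person = 2L)

#' Read a MOTChallenge-style detection or track file
#'
#' @param path CSV file path. Lines starting with `#` are comments.
#' @return Data frame with columns `frame`, `id`, `left`, `top`, `width`,
#'   `height`, `conf`, `class` (`"pig"`/`"person"`). Malformed rows abort
#'   with their line number.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0)
    return(data.frame(frame = integer(0), id = integer(0), left = numeric(0),
                      top = numeric(0), width = numeric(0),
                      height = numeric(0), conf = numeric(0),
                      class = character(0)))
  parts <- strsplit(lines[rows], ",")
  out <- matrix(NA_real_, length(rows), 9)
  for (k in seq_along(rows)) {
    p <- suppressWarnings(as.numeric(parts[[k]]))
    if (length(p) < 8 || anyNA(p[1:8]))
      stop("malformed detection row at line ", rows[k], " of ", path)
    if (p[5] <= 0 || p[6] <= 0)
      stop("non-positive box size at line ", rows[k], " of ", path)
    if (p[1] < 1)
      stop("frame index must be >= 1 at line ", rows[k], " of ", path)
    out[k, seq_along(p)] <- p[1:min(9, length(p))]
  }
  cls <- names(.class_codes)[match(out[, 8], .class_codes)]
  if (anyNA(cls))
    stop("unknown class code in ", path,
         " (expected 1 = pig or 2 = person)")
  data.frame(frame = as.integer(out[, 1]), id = as.integer(out[, 2]),
             left = out[, 3], top = out[, 4], width = out[, 5],
             height = out[, 6], conf = out[, 7], class = cls)
}

#' Write detections or tracks in the MOTChallenge dialect
#'
#' Rows are sorted by `(frame, id)`; the round trip through
#' [read_detections()] is lossless for all fields.
#'
#' @param x Data frame with columns `frame`, `left`, `top`, `width`,
#'   `height`, `conf`, `class`, and optionally `id` (defaults to -1, the
#'   raw-detection marker).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(x, path) {
  if (is.null(x$id)) x$id <- -1L
  x <- x[order(x$frame, x$id), , drop = FALSE]
  lines <- c(
    "# frame,id,bb_left,bb_top,bb_width,bb_height,conf,class,visibility (class: 1=pig, 2=person)",
    sprintf("%d,%d,%g,%g,%g,%g,%g,%d,1",
            x$frame, x$id, x$left, x$top, x$width, x$height, x$conf,
            .class_codes[x$class]))
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunables of the counting pipeline with their defaults: tracker
#' parameters (`init_hits` 3, `max_age` 20, `max_distance` 0.9), counting
#' line (`line_x`, `entrance_side` "right"), `seed`, and flags
#' (`track_persons`). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(init_hits = 3L, max_age = 20L, max_distance = 0.9,
                   line_x = 160, entrance_side = "right", seed = 1L,
                   track_persons = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Read / write a pipeline config file
#'
#' Flat `key: value` text; `#` lines are comments.
#'
#' @param path File path.
#' @return For `read_config`, a [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":")
  args <- list()
  for (p in kv) {
    key <- trimws(p[1]); val <- trimws(paste(p[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (!is.na(num)) num
      else if (val %in% c("true", "false")) val == "true"
      else val
  }
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v)
    if (is.logical(v)) tolower(as.character(v)) else as.character(v),
    character(1))
  writeLines(paste0(names(config), ": ", vals), path)
  invisible(path)
}
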