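# Minimum-cost linear assignment (Hungarian / shortest augmenting path).
# Written here because no installed package exposes a linear-assignment
# solver; validated in the test suite against exhaustive permutation search.

#' Sentinel cost marking an infeasible assignment entry
#'
#' Cost-matrix entries at or above this value are never turned into matches.
#' @return A large positive constant.
#' @export
infeasible_cost <- function() 1e5

# Jonker-Volgenant style shortest augmenting path solver.
# cost: n x m matrix with n <= m, finite entries. Returns integer vector
# row_of_col of length m (0 = unassigned). O(n^2 m).
lapjv <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n); v <- numeric(m)
  p <- integer(m)        # p[j]: row assigned to column j (0 = none)
  way <- integer(m)
  for (i in seq_len(n)) {
    p0 <- i; j0 <- 0L    # p0: row on the virtual column 0
    minv <- rep(Inf, m)
    used <- rep(FALSE, m); used0 <- FALSE
    repeat {
      if (j0 == 0L) used0 <- TRUE else used[j0] <- TRUE
      i0 <- if (j0 == 0L) p0 else p[j0]
      free <- which(!used)
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      k <- free[which.min(minv[free])]
      delta <- minv[k]
      usedcols <- which(used)
      rows <- c(p0, p[usedcols])
      rows <- rows[rows > 0L]
      u[rows] <- u[rows] + delta
      v[usedcols] <- v[usedcols] - delta
      minv[free] <- minv[free] - delta
      j0 <- k
      if (p[j0] == 0L) break
    }
    repeat {                            # augment along the alternating path
      j1 <- way[j0]
      p[j0] <- if (j1 == 0L) p0 else p[j1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p
}

#' Solve a minimum-cost assignment problem
#'
#' Finds the one-to-one assignment of rows (tracks) to columns (detections)
#' with minimum total cost. Matched pairs whose cost exceeds `max_cost`, or
#' whose entry carries the infeasible sentinel, are demoted to unmatched.
#' Among equal-cost optima the lexicographically smallest assignment by
#' (row, column) is returned, which keeps runs byte-reproducible.
#'
#' @param cost Numeric cost matrix (rows x columns), non-negative entries;
#'   use [infeasible_cost()] for forbidden pairs.
#' @param max_cost Matches with cost strictly greater than this are demoted
#'   to unmatched (default `Inf`).
#' @return A list of class `assignment_result`: `matches` (2-column integer
#'   matrix of row/column pairs), `unmatched_rows`, `unmatched_cols`. The
#'   attribute `total_cost` holds the optimal total over the full assignment
#'   (before demotion).
#' @export
solve_assignment <- function(cost, max_cost = Inf) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  empty <- function() structure(
    list(matches = matrix(integer(0), 0, 2,
                          dimnames = list(NULL, c("row", "col"))),
         unmatched_rows = seq_len(n), unmatched_cols = seq_len(m)),
    total_cost = 0, class = "assignment_result")
  if (n == 0 || m == 0) return(empty())
  # deterministic lexicographic tie-break: bias each entry by a tiny amount
  # increasing in (row, col); far below any meaningful cost difference
  eps <- 1e-9
  bias <- outer(seq_len(n) - 1L, seq_len(m) - 1L,
                function(i, j) (i * m + j) * eps / (n * m))
  transposed <- n > m
  cb <- cost + bias
  if (transposed) cb <- t(cb)
  p <- lapjv(cb)                        # row assigned to each column
  pairs <- cbind(row = p[p > 0L], col = which(p > 0L))
  if (transposed) pairs <- pairs[, c(2, 1), drop = FALSE]
  colnames(pairs) <- c("row", "col")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  total <- sum(cost[pairs])
  ok <- cost[pairs] <= max_cost & cost[pairs] < infeasible_cost()
  matches <- pairs[ok, , drop = FALSE]
  structure(list(matches = matches,
                 unmatched_rows = setdiff(seq_len(n), matches[, 1]),
                 unmatched_cols = setdiff(seq_len(m), matches[, 2])),
            total_cost = total, class = "assignment_result")
}

#' Minimum cosine distance between a feature gallery and a query feature
#'
#' For unit-norm features the cosine distance is `1 - <g, q>`; the gallery
#' distance is the minimum over all stored features. An all-zero feature has
#' dot product 0 with everything and therefore contributes distance 1.
#'
#' @param gallery Matrix with one feature per row (length-100 rows), or a
#'   single feature vector.
#' @param query Feature vector of length 100.
#' @return A single distance in `[0, 2]`.
#' @export
cosine_distance <- function(gallery, query) {
  if (is.null(dim(gallery))) gallery <- matrix(gallery, nrow = 1)
  stopifnot(nrow(gallery) >= 1, ncol(gallery) == length(query))
  1 - max(gallery %*% query)
}

# cosine cost matrix: one row per track gallery, one column per detection
cosine_cost_matrix <- function(galleries, features) {
  out <- matrix(0, length(galleries), nrow(features))
  for (i in seq_along(galleries)) {
    g <- galleries[[i]]
    if (is.null(dim(g))) g <- matrix(g, nrow = 1)
    sims <- g %*% t(features)           # gallery x detections
    out[i, ] <- 1 - apply(sims, 2, max)
  }
  out
}

#' IOU-distance cost matrix with gating
#'
#' Entry `(i, j)` is `1 - iou(track i, detection j)`; entries above the gate
#' (default 0.7, i.e. IOU below 0.3) are replaced by the infeasible sentinel.
#'
#' @param track_boxes,det_boxes n x 4 box matrices (or data frames) with
#'   columns `left`, `top`, `width`, `height`.
#' @param gate Maximum feasible IOU distance (default 0.7).
#' @return A cost matrix suitable for [solve_assignment()].
#' @export
iou_cost <- function(track_boxes, det_boxes, gate = 0.7) {
  cost <- 1 - iou_matrix(track_boxes, det_boxes)
  cost[cost > gate] <- infeasible_cost()
  cost
}
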