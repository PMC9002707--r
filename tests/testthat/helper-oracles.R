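# Independent oracles used across the suite. These deliberately do not call
# the package code paths they are checking.

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# exhaustive minimum-total-cost assignment over all row-to-column injections
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  transposed <- n > m
  if (transposed) { cost <- t(cost); tmp <- n; n <- m; m <- tmp }
  cols <- utils::combn(m, n, simplify = FALSE)
  p <- perms(n)
  best <- Inf
  for (cc in cols) {
    for (r in seq_len(nrow(p))) {
      tot <- sum(cost[cbind(seq_len(n), cc[p[r, ]])])
      if (tot < best) best <- tot
    }
  }
  best
}

# independent signed-crossing sweep over a center-x trajectory (NA = absent)
oracle_signed_crossings <- function(x, line_x, entrance_side = "right") {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(0L)
  zone <- function(v) {
    if (v == line_x) return(NA_integer_)
    right <- v > line_x
    if (entrance_side == "right") as.integer(!right) else as.integer(right)
  }
  z <- vapply(x, zone, integer(1))
  status <- if (is.na(z[1])) 0L else z[1]
  total <- 0L
  for (k in seq_along(z)[-1]) {
    if (is.na(z[k]) || z[k] == status) next
    total <- total + (z[k] - status)
    status <- z[k]
  }
  as.integer(total)
}

# signed ground-truth count of a whole scene, by sweeping every pig actor's
# true center trajectory (recomputed from gt boxes, not from the generator's
# own crossing table)
oracle_scene_count <- function(scene) {
  total <- 0L
  for (i in unique(scene$gt$id)) {
    rows <- scene$gt[scene$gt$id == i, ]
    if (rows$class[1] != "pig") next
    x <- rep(NA_real_, max(scene$gt$frame))
    x[rows$frame] <- rows$left + rows$width / 2
    total <- total + oracle_signed_crossings(x, scene$line$line_x,
                                             scene$line$entrance_side)
  }
  total
}

# random noise-free hallway scenario with reversals and occasional persons
random_scenario <- function(seed, n_frames = 70) {
  set.seed(seed)
  n <- sample(1:4, 1)
  actors <- do.call(rbind, lapply(seq_len(n), function(i) {
    revs <- if (stats::runif(1) < 0.3)
      sort(sample(10:60, sample(1:2, 1))) else integer(0)
    scene_actor(class = if (stats::runif(1) < 0.15) "person" else "pig",
                entry = sample(1:15, 1),
                side = sample(c("right", "left"), 1),
                speed = sample(4:9, 1), reversals = revs)
  }))
  scenario_spec(actors, n_frames = n_frames, seed = seed)
}

# direct 3x3 convolution with pad 1, stride 1 (reference forward pass):
# input list of H x W channel matrices, weights filters x channels x 3 x 3
oracle_conv_forward <- function(channels, w, b = NULL) {
  nf <- dim(w)[1]; nc <- dim(w)[2]
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  pad <- function(m) {
    p <- matrix(0, H + 2, W + 2); p[2:(H + 1), 2:(W + 1)] <- m; p
  }
  padded <- lapply(channels, pad)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    acc <- matrix(if (is.null(b)) 0 else b[f], H, W)
    for (c in seq_len(nc)) {
      for (dy in 0:2) for (dx in 0:2) {
        acc <- acc + w[f, c, dy + 1, dx + 1] *
          padded[[c]][(1 + dy):(H + dy), (1 + dx):(W + dx)]
      }
    }
    out[[f]] <- acc
  }
  out
}

# unit vector at a prescribed cosine similarity to u
unit_at_cosine <- function(u, sim) {
  w <- rep(0, length(u)); w[which.min(abs(u))] <- 1
  w <- w - sum(w * u) * u
  w <- w / sqrt(sum(w^2))
  v <- sim * u + sqrt(1 - sim^2) * w
  v / sqrt(sum(v^2))
}
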