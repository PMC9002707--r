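# Filter-clustering (FC) pruning for 3x3 convolution layers: every filter is
# scored against the bank of all 511 nonzero binary 3x3 patterns, assigned to
# the pattern with the maximum response, and each non-empty cluster keeps
# only its best-scoring filter. Consumers of a pruned layer drop the
# corresponding input channels.

#' The bank of 511 nonzero binary 3x3 patterns
#'
#' Patterns are enumerated in ascending 9-bit integer order: pattern `k`
#' (1..511) is the binary expansion of `k`, bit `j` (least significant
#' first) giving cell `j` of the 3x3 grid in row-major order. The all-zero
#' pattern (integer 0) is excluded, leaving 2^9 - 1 = 511 patterns.
#'
#' @return A 3 x 3 x 511 binary array.
#' @export
build_pattern_bank <- function() {
  bank <- array(0, dim = c(3, 3, 511))
  for (k in 1:511) {
    bits <- as.integer(bitwAnd(bitwShiftR(k, 0:8), 1L))
    bank[, , k] <- matrix(bits, 3, 3, byrow = TRUE)  # bit j -> row-major cell j
  }
  bank
}

# 511 x 9 pattern matrix (row-major flattened patterns) for fast scoring
bank_matrix <- function(bank) {
  t(apply(bank, 3, function(p) as.vector(t(p))))
}

# channel-summed 3x3 signature of one filter (matrix, or in_channels x 3 x 3)
filter_signature <- function(f) {
  if (is.matrix(f)) {
    sig <- f
  } else {
    stopifnot(length(dim(f)) == 3)
    sig <- apply(f, c(2, 3), sum)
  }
  if (!all(dim(sig) == c(3, 3))) stop("filter kernel must be 3x3")
  sig
}

#' Response of a filter to a binary pattern
#'
#' The inner product at zero offset between the channel-summed 3x3 kernel
#' and the pattern, i.e. the sum of the summed kernel over the pattern's
#' active cells. Linear in the filter weights.
#'
#' @param f A single filter: a 3x3 matrix or an `in_channels x 3 x 3` array
#'   (multi-channel filters are summed across input channels first).
#' @param pattern A 3x3 binary matrix.
#' @return A single number.
#' @export
score_filter <- function(f, pattern) {
  sum(filter_signature(f) * pattern)
}

#' Cluster the filters of one convolution layer by pattern response
#'
#' Each filter joins the cluster of its maximum-response pattern (ties go to
#' the lowest pattern index); each non-empty cluster keeps the filter with
#' the maximum response (ties to the lowest filter index). The kept filters,
#' in their original order, are the layer's surviving channels.
#'
#' @param w Layer weights: a 4-D array `filters x in_channels x 3 x 3`.
#' @param bank Pattern bank from [build_pattern_bank()].
#' @return A list of class `filter_cluster_report`: `assignment` (pattern
#'   index per filter), `score` (response at the assigned pattern),
#'   `representatives` (named integer vector pattern -> filter index) and
#'   `kept_filters` (ordered indices of surviving filters).
#' @export
cluster_layer <- function(w, bank = build_pattern_bank()) {
  stopifnot(length(dim(w)) == 4, dim(w)[3] == 3, dim(w)[4] == 3,
            dim(w)[1] >= 1)
  n <- dim(w)[1]
  sig <- t(vapply(seq_len(n),
                  function(i) as.vector(t(filter_signature(w[i, , , ]))),
                  numeric(9)))
  scores <- sig %*% t(bank_matrix(bank))          # n x 511
  assignment <- apply(scores, 1, which.max)       # first max: lowest pattern
  score <- scores[cbind(seq_len(n), assignment)]
  reps <- integer(0)
  for (p in sort(unique(assignment))) {
    members <- which(assignment == p)
    reps[as.character(p)] <- members[which.max(score[members])]
  }
  structure(list(assignment = assignment, score = score,
                 representatives = reps,
                 kept_filters = sort(unname(reps))),
            class = "filter_cluster_report")
}

#' Prune a network's 3x3 convolution layers by filter clustering
#'
#' Applies [cluster_layer()] to every 3x3 convolution layer of the graph
#' (1x1 layers pass through untouched), keeps each layer's surviving filters
#' and bias entries, and drops the corresponding input channels from every
#' consumer, resolving concatenating and channel-splitting routes so the
#' surviving channels flow to the right places.
#'
#' @param graph A [layer_graph()].
#' @param weights Named list of conv-layer weights, names = layer ids (as
#'   printed in the architecture table, 0-based); each element a list with
#'   `w` (4-D array `filters x in_channels x kh x kw`) and optional `b`
#'   (bias vector).
#' @return A list: `graph` (with updated filter counts), `weights` (pruned),
#'   `reports` (per pruned layer), `channel_maps` (per layer, indices of its
#'   surviving output channels relative to the unpruned network).
#' @export
prune_network <- function(graph, weights) {
  stopifnot(inherits(graph, "layer_graph"))
  bank <- build_pattern_bank()
  layers <- graph$layers
  kept <- vector("list", length(layers))   # surviving channels per layer,
  reports <- list()                        # relative to the current graph
  out_w <- weights
  src_of <- function(j) {  # kept channels + current size of layer j's output
    if (j == 0L) {
      nc <- graph$input_shape[3]
      list(kept = seq_len(nc), n = nc)
    } else {
      list(kept = kept[[j]], n = layer_out_channels(graph, j))
    }
  }
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    id <- as.character(ly$id)
    if (ly$type == "conv") {
      in_kept <- src_of(i - 1L)$kept
      wl <- weights[[id]]
      if (is.null(wl)) {   # no weights supplied: structural pass-through
        kept[[i]] <- seq_len(ly$filters)
        next
      }
      w <- wl$w[, in_kept, , , drop = FALSE]   # drop pruned input channels
      if (dim(w)[3] == 3 && dim(w)[4] == 3) {
        rep_ <- cluster_layer(w, bank)
        kf <- rep_$kept_filters
        if (length(kf) == 0) stop("pruning left layer ", id, " with 0 filters")
        reports[[id]] <- rep_
      } else {
        kf <- seq_len(dim(w)[1])               # 1x1 layers are not clustered
      }
      out_w[[id]] <- list(w = w[kf, , , , drop = FALSE],
                          b = if (!is.null(wl$b)) wl$b[kf])
      kept[[i]] <- kf
      layers[[i]]$filters <- length(kf)
    } else if (ly$type == "route") {
      srcs <- ly$sources + 1L                  # 0-based ids -> list positions
      if (isTRUE(ly$split)) {
        s <- src_of(srcs[1])
        if (is.null(ly$select)) {
          # darknet group routing: the last floor(C/2) source channels
          half <- floor(s$n / 2); lo <- s$n - half
          sel <- (lo + 1L):s$n
        } else {
          sel <- ly$select                     # recorded by an earlier pass
        }
        surv <- which(sel %in% s$kept)         # relative to this route's output
        kept[[i]] <- surv
        # re-express the selection against the source's pruned channel order
        layers[[i]]$select <- match(sel[surv], s$kept)
      } else {
        offs <- 0L; outk <- integer(0)
        for (j in srcs) {
          s <- src_of(j)
          outk <- c(outk, s$kept + offs)
          offs <- offs + s$n
        }
        kept[[i]] <- outk
      }
    } else {
      kept[[i]] <- src_of(i - 1L)$kept         # maxpool/upsample/yolo
    }
  }
  pruned_graph <- graph
  pruned_graph$layers <- layers
  list(graph = pruned_graph, weights = out_w, reports = reports,
       channel_maps = kept)
}
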