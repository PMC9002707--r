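# Darknet-style layer graph for the lightweight hallway detector: an ordered
# list of conv / maxpool / route (concat or channel-split) / upsample / yolo
# layers, with optional declared input/output shapes so computed shapes can
# be cross-checked against a printed architecture table.

#' Build a layer graph
#'
#' @param layers List of layer descriptions built with [conv_layer()],
#'   [maxpool_layer()], [route_layer()], [upsample_layer()], [yolo_layer()].
#'   Layer ids are 0-based (the convention of printed darknet tables); route
#'   sources must precede the route.
#' @param input_shape Integer vector `c(H, W, C)` of the network input.
#' @return A list of class `layer_graph`.
#' @export
layer_graph <- function(layers, input_shape = c(320L, 320L, 1L)) {
  ids <- vapply(layers, `[[`, numeric(1), "id")
  stopifnot(identical(as.integer(ids), seq_along(layers) - 1L))
  for (ly in layers) {
    if (ly$type == "route" && any(ly$sources >= ly$id))
      stop("route layer ", ly$id, " references a non-preceding layer")
  }
  structure(list(layers = layers, input_shape = as.integer(input_shape)),
            class = "layer_graph")
}

#' @rdname layer_graph
#' @param id 0-based layer index.
#' @param filters Number of output filters (conv).
#' @param size Kernel or pool size.
#' @param stride Stride.
#' @param declared_in,declared_out Optional `c(H, W, C)` shapes as printed in
#'   an architecture table, used by [propagate_shapes()] to flag mismatches.
#' @export
conv_layer <- function(id, filters, size = 3L, stride = 1L,
                       declared_in = NULL, declared_out = NULL) {
  list(id = as.integer(id), type = "conv", filters = as.integer(filters),
       size = as.integer(size), stride = as.integer(stride),
       declared_in = declared_in, declared_out = declared_out)
}

#' @rdname layer_graph
#' @export
maxpool_layer <- function(id, size = 2L, stride = 2L,
                          declared_in = NULL, declared_out = NULL) {
  list(id = as.integer(id), type = "maxpool", size = as.integer(size),
       stride = as.integer(stride),
       declared_in = declared_in, declared_out = declared_out)
}

#' @rdname layer_graph
#' @param sources 0-based ids of the routed layers.
#' @param split If `TRUE`, the route forwards only the last `floor(C/2)`
#'   channels of its single source (darknet group routing, the halved
#'   channel counts of the tiny backbone).
#' @export
route_layer <- function(id, sources, split = FALSE) {
  list(id = as.integer(id), type = "route", sources = as.integer(sources),
       split = isTRUE(split), select = NULL,
       declared_in = NULL, declared_out = NULL)
}

#' @rdname layer_graph
#' @param factor Upsampling factor.
#' @export
upsample_layer <- function(id, factor = 2L,
                           declared_in = NULL, declared_out = NULL) {
  list(id = as.integer(id), type = "upsample", factor = as.integer(factor),
       declared_in = declared_in, declared_out = declared_out)
}

#' @rdname layer_graph
#' @export
yolo_layer <- function(id) {
  list(id = as.integer(id), type = "yolo",
       declared_in = NULL, declared_out = NULL)
}

# output channel count of layer at list position j (1-based), for the graph
# as currently declared
layer_out_channels <- function(graph, j) {
  if (j == 0L) return(graph$input_shape[3])
  ly <- graph$layers[[j]]
  switch(ly$type,
    conv = ly$filters,
    route = {
      if (isTRUE(ly$split)) {
        if (!is.null(ly$select)) length(ly$select)
        else floor(layer_out_channels(graph, ly$sources[1] + 1L) / 2)
      } else {
        sum(vapply(ly$sources + 1L,
                   function(s) layer_out_channels(graph, s), numeric(1)))
      }
    },
    layer_out_channels(graph, j - 1L)  # maxpool / upsample / yolo
  )
}

#' Propagate feature-map shapes through a layer graph
#'
#' Computes each layer's output shape from the input shape: a 3x3 conv with
#' pad 1 maps `H` to `floor((H + 2 - 3) / stride) + 1` (a 1x1 conv keeps
#' `H / stride` likewise with pad 0), a 2x2/2 maxpool halves the spatial
#' size, upsample multiplies it, a concatenating route sums channels and a
#' split route keeps the last `floor(C/2)` channels of its source. Computed
#' shapes are compared against any declared shapes; disagreements are listed
#' as mismatches, not errors.
#'
#' @param graph A [layer_graph()].
#' @param input_shape `c(H, W, C)`; defaults to the graph's own.
#' @return A data frame with one row per layer: `id`, `type`, computed
#'   output `h`/`w`/`c`, and logical `mismatch` (TRUE where a declared
#'   shape disagrees with the computed one).
#' @export
propagate_shapes <- function(graph, input_shape = graph$input_shape) {
  stopifnot(inherits(graph, "layer_graph"))
  n <- length(graph$layers)
  H <- integer(n); W <- integer(n); C <- integer(n)
  mism <- logical(n)
  shape_of <- function(j) {   # output shape of list position j (0 = input)
    if (j == 0L) input_shape else c(H[j], W[j], C[j])
  }
  conv_dim <- function(x, size, stride) {
    pad <- if (size == 3L) 1L else 0L
    (x + 2L * pad - size) %/% stride + 1L
  }
  for (i in seq_len(n)) {
    ly <- graph$layers[[i]]
    s <- switch(ly$type,
      conv = {
        p <- shape_of(i - 1L)
        c(conv_dim(p[1], ly$size, ly$stride),
          conv_dim(p[2], ly$size, ly$stride), ly$filters)
      },
      maxpool = {
        p <- shape_of(i - 1L)
        c(p[1] %/% ly$stride, p[2] %/% ly$stride, p[3])
      },
      upsample = {
        p <- shape_of(i - 1L)
        c(p[1] * ly$factor, p[2] * ly$factor, p[3])
      },
      route = {
        ps <- lapply(ly$sources + 1L, shape_of)
        if (isTRUE(ly$split))
          c(ps[[1]][1], ps[[1]][2], floor(ps[[1]][3] / 2))
        else
          c(ps[[1]][1], ps[[1]][2], sum(vapply(ps, `[[`, numeric(1), 3)))
      },
      yolo = shape_of(i - 1L)
    )
    H[i] <- s[1]; W[i] <- s[2]; C[i] <- s[3]
    declared_ok <- TRUE
    if (!is.null(ly$declared_in))
      declared_ok <- declared_ok &&
        all(ly$declared_in == shape_of(i - 1L))
    if (!is.null(ly$declared_out))
      declared_ok <- declared_ok && all(ly$declared_out == s)
    mism[i] <- !declared_ok
  }
  data.frame(id = vapply(graph$layers, `[[`, numeric(1), "id"),
             type = vapply(graph$layers, `[[`, character(1), "type"),
             h = H, w = W, c = C, mismatch = mism)
}

#' The lightweight hallway detector architecture
#'
#' The 38-layer tiny-YOLO-style backbone and two detection heads used by the
#' hallway pig detector after filter-clustering pruning, encoded with the
#' printed per-layer shapes so [propagate_shapes()] can flag the rows whose
#' declared channel counts disagree with the computed concatenations.
#'
#' @return A [layer_graph()] with input 320 x 320 x 1.
#' @export
hallway_net_graph <- function() {
  d <- function(h, w, c) c(h, w, c)
  layers <- list(
    conv_layer(0, 27, 3, 2, d(320, 320, 1), d(160, 160, 27)),
    conv_layer(1, 49, 3, 2, d(160, 160, 27), d(80, 80, 49)),
    conv_layer(2, 45, 3, 1, d(80, 80, 49), d(80, 80, 45)),
    route_layer(3, 2, split = TRUE),
    conv_layer(4, 31, 3, 1, d(80, 80, 22), d(80, 80, 31)),
    conv_layer(5, 28, 3, 1, d(80, 80, 31), d(80, 80, 28)),
    route_layer(6, c(4, 5)),
    conv_layer(7, 64, 1, 1, d(80, 80, 59), d(80, 80, 64)),
    route_layer(8, c(2, 7)),
    maxpool_layer(9, 2, 2, d(80, 80, 109), d(40, 40, 109)),
    conv_layer(10, 86, 3, 1, d(40, 40, 109), d(40, 40, 86)),
    route_layer(11, 10, split = TRUE),
    conv_layer(12, 56, 3, 1, d(40, 40, 43), d(40, 40, 56)),
    conv_layer(13, 47, 3, 1, d(40, 40, 56), d(40, 40, 47)),
    route_layer(14, c(12, 13)),
    conv_layer(15, 128, 1, 1, d(40, 40, 128), d(40, 40, 128)),
    route_layer(16, c(10, 15)),
    maxpool_layer(17, 2, 2, d(40, 40, 214), d(20, 20, 214)),
    conv_layer(18, 164, 3, 1, d(20, 20, 214), d(20, 20, 164)),
    route_layer(19, 18, split = TRUE),
    conv_layer(20, 83, 3, 1, d(20, 20, 82), d(20, 20, 83)),
    conv_layer(21, 83, 3, 1, d(20, 20, 83), d(20, 20, 83)),
    route_layer(22, c(20, 21)),
    conv_layer(23, 256, 1, 1, d(20, 20, 166), d(20, 20, 256)),
    route_layer(24, c(18, 23)),
    maxpool_layer(25, 2, 2, d(20, 20, 420), d(10, 10, 420)),
    conv_layer(26, 189, 3, 1, d(10, 10, 420), d(10, 10, 189)),
    conv_layer(27, 256, 1, 1, d(10, 10, 189), d(10, 10, 256)),
    conv_layer(28, 174, 3, 1, d(10, 10, 256), d(10, 10, 174)),
    conv_layer(29, 18, 1, 1, d(10, 10, 174), d(10, 10, 18)),
    yolo_layer(30),
    route_layer(31, 27),
    conv_layer(32, 128, 1, 1, d(10, 10, 256), d(10, 10, 128)),
    upsample_layer(33, 2, d(10, 10, 128), d(20, 20, 128)),
    route_layer(34, c(23, 33)),
    conv_layer(35, 120, 3, 1, d(20, 20, 384), d(20, 20, 120)),
    conv_layer(36, 18, 1, 1, d(20, 20, 256), d(20, 20, 18)),
    yolo_layer(37)
  )
  layer_graph(layers, input_shape = c(320L, 320L, 1L))
}

#' Read / write a layer-graph config file
#'
#' Plain-text format mirroring the printed architecture table: one line per
#' layer, whitespace-separated columns
#' `id type filters size stride sources split declared_in declared_out`,
#' with `-` for empty fields, shapes as `HxWxC` and sources as
#' comma-separated 0-based ids. Lines starting with `#` are comments; a
#' `input H W C` header line sets the network input shape.
#'
#' @param path File path.
#' @return For `read_layer_graph`, a [layer_graph()].
#' @export
read_layer_graph <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  input_shape <- c(320L, 320L, 1L)
  layers <- list()
  parse_shape <- function(tok) {
    if (tok == "-") NULL else as.integer(strsplit(tok, "x")[[1]])
  }
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "input") {
      input_shape <- as.integer(tok[2:4]); next
    }
    id <- as.integer(tok[1]); type <- tok[2]
    di <- parse_shape(tok[8]); do_ <- parse_shape(tok[9])
    layers[[length(layers) + 1L]] <- switch(type,
      conv = conv_layer(id, as.integer(tok[3]), as.integer(tok[4]),
                        as.integer(tok[5]), di, do_),
      maxpool = maxpool_layer(id, as.integer(tok[4]), as.integer(tok[5]),
                              di, do_),
      route = route_layer(id, as.integer(strsplit(tok[6], ",")[[1]]),
                          split = tok[7] == "yes"),
      upsample = upsample_layer(id, as.integer(tok[5]), di, do_),
      yolo = yolo_layer(id),
      stop("unknown layer type '", type, "' at layer ", id))
  }
  layer_graph(layers, input_shape)
}

#' @rdname read_layer_graph
#' @param graph A [layer_graph()].
#' @export
write_layer_graph <- function(graph, path) {
  fmt_shape <- function(s) if (is.null(s)) "-" else paste(s, collapse = "x")
  lines <- c("# id type filters size stride sources split declared_in declared_out",
             paste("input", paste(graph$input_shape, collapse = " ")))
  for (ly in graph$layers) {
    lines <- c(lines, paste(
      ly$id, ly$type,
      if (ly$type == "conv") ly$filters else "-",
      if (!is.null(ly$size)) ly$size else "-",
      if (!is.null(ly$stride)) ly$stride
      else if (ly$type == "upsample") ly$factor else "-",
      if (ly$type == "route") paste(ly$sources, collapse = ",") else "-",
      if (ly$type == "route" && isTRUE(ly$split)) "yes" else "-",
      fmt_shape(ly$declared_in), fmt_shape(ly$declared_out)))
  }
  writeLines(lines, path)
  invisible(path)
}
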