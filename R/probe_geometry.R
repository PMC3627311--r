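#' Build an optode probe layout and derive measurement channels
#'
#' Models the rectangular optode lattice used in infant auditory fNIRS
#' montages: one pad per temporal area, sources and detectors assigned in a
#' checkerboard (top-left node is a source), with measurement channels
#' derived from source-detector adjacency.  For the standard 2 x 4 pad this
#' yields 10 "short-distance" channels (separation = `spacing_mm`) per
#' hemisphere and, when `include_long = TRUE`, 4 additional "long-distance"
#' channels between nodes offset by one row and two columns (separation =
#' `spacing_mm * sqrt(5)`, about 56 mm for a 25 mm lattice).
#'
#' Channels are enumerated deterministically: nodes are scanned in row-major
#' order and each node contributes its rightward then downward lattice edge,
#' so two builds with identical inputs always produce identical channel ids.
#' Long channels are appended after all short channels, scanning partners at
#' (+1 row, +2 cols) then (+1 row, -2 cols).
#'
#' @param rows,cols Lattice dimensions (the standard pad is 2 x 4).
#' @param spacing_mm Nearest-neighbour source-detector separation in mm
#'   (25 for infants, 30 for adults).
#' @param include_long If `TRUE`, also derive the long-distance channels
#'   (only available on some instruments).
#' @param hemispheres Pads to instantiate; mirrored pads share channel ids.
#' @param roi_channels Integer ids of channels treated as the auditory
#'   region of interest.  The conventional montage tags channels 4, 6 and 7;
#'   remap here if your cap labelling differs, since laterality results
#'   depend only on which channels carry the ROI flag.
#'
#' @return An object of class `nirs_layout`: a list with `rows`, `cols`,
#'   `spacing_mm`, `nodes` (data frame: `row`, `col`, `role`) and `channels`
#'   (data frame: `id`, `hemisphere`, `kind`, `distance_mm`, source/detector
#'   lattice coordinates, `roi`).
#' @examples
#' lay <- build_layout()
#' table(lay$channels$kind, lay$channels$hemisphere)
#' @export
build_layout <- function(rows = 2, cols = 4, spacing_mm = 25,
                         include_long = FALSE,
                         hemispheres = c("left", "right"),
                         roi_channels = c(4, 6, 7)) {
  stopifnot(rows >= 1, cols >= 1, spacing_mm > 0, length(hemispheres) >= 1)
  hemispheres <- match.arg(hemispheres, c("left", "right"), several.ok = TRUE)

  nodes <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  # checkerboard: top-left (1,1) is a source
  nodes$role <- ifelse((nodes$row + nodes$col) %% 2 == 0, "source", "detector")

  edges <- .enumerate_channels(rows, cols, include_long)
  if (nrow(edges) == 0L) {
    stop("no channels derivable: lattice of ", rows, " x ", cols,
         " nodes has no source-detector pairs")
  }
  edges$distance_mm <- spacing_mm *
    sqrt((edges$a_row - edges$b_row)^2 + (edges$a_col - edges$b_col)^2)

  # orient each edge as (source, detector) using the checkerboard parity
  a_is_source <- (edges$a_row + edges$a_col) %% 2 == 0
  ch <- data.frame(
    id = edges$id,
    kind = edges$kind,
    distance_mm = edges$distance_mm,
    src_row = ifelse(a_is_source, edges$a_row, edges$b_row),
    src_col = ifelse(a_is_source, edges$a_col, edges$b_col),
    det_row = ifelse(a_is_source, edges$b_row, edges$a_row),
    det_col = ifelse(a_is_source, edges$b_col, edges$a_col)
  )
  ch$roi <- ch$id %in% roi_channels & ch$kind == "short"

  channels <- do.call(rbind, lapply(hemispheres, function(h) {
    out <- ch
    out$hemisphere <- h
    out
  }))
  channels <- channels[, c("id", "hemisphere", "kind", "distance_mm",
                           "src_row", "src_col", "det_row", "det_col", "roi")]
  rownames(channels) <- NULL

  structure(
    list(rows = rows, cols = cols, spacing_mm = spacing_mm,
         include_long = include_long, hemispheres = hemispheres,
         roi_channels = roi_channels, nodes = nodes, channels = channels),
    class = "nirs_layout"
  )
}

# Deterministic edge enumeration over the lattice.  Every lattice edge joins
# nodes of opposite checkerboard parity, so every adjacent pair (and every
# (1,2)-offset pair) is automatically a source-detector pair.
.enumerate_channels <- function(rows, cols, include_long) {
  short <- list()
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c + 1 <= cols) short[[length(short) + 1L]] <- c(r, c, r, c + 1)
      if (r + 1 <= rows) short[[length(short) + 1L]] <- c(r, c, r + 1, c)
    }
  }
  long <- list()
  if (include_long) {
    for (r in seq_len(rows)) {
      for (c in seq_len(cols)) {
        if (r + 1 <= rows && c + 2 <= cols)
          long[[length(long) + 1L]] <- c(r, c, r + 1, c + 2)
        if (r + 1 <= rows && c - 2 >= 1)
          long[[length(long) + 1L]] <- c(r, c, r + 1, c - 2)
      }
    }
  }
  as_df <- function(lst, kind, offset) {
    if (length(lst) == 0L) {
      return(data.frame(id = integer(), a_row = integer(), a_col = integer(),
                        b_row = integer(), b_col = integer(),
                        kind = character()))
    }
    m <- do.call(rbind, lst)
    data.frame(id = offset + seq_len(nrow(m)),
               a_row = m[, 1], a_col = m[, 2],
               b_row = m[, 3], b_col = m[, 4],
               kind = kind)
  }
  s <- as_df(short, "short", 0L)
  l <- as_df(long, "long", nrow(s))
  rbind(s, l)
}

#' Mirror a channel onto the opposite hemisphere
#'
#' The two pads are mirror images placed over the left and right temporal
#' areas, so the homologous ("hemispheric counterpart") channel carries the
#' same id on the other pad.  The map is an involution:
#' `counterpart(counterpart(k)) == k`.
#'
#' @param layout A [build_layout()] result covering both hemispheres.
#' @param channel_id Channel id to mirror.
#' @param hemisphere Hemisphere the id refers to (`"left"` or `"right"`).
#' @return A list with `id` and `hemisphere` of the counterpart channel.
#' @export
hemispheric_counterpart <- function(layout, channel_id, hemisphere = "left") {
  stopifnot(inherits(layout, "nirs_layout"))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  other <- if (hemisphere == "left") "right" else "left"
  ch <- layout$channels
  if (!any(ch$id == channel_id & ch$hemisphere == hemisphere) ||
      !any(ch$id == channel_id & ch$hemisphere == other)) {
    stop("channel id ", channel_id, " does not exist in both hemispheres")
  }
  list(id = channel_id, hemisphere = other)
}

#' Serialize a probe layout to JSON
#'
#' Writes nodes (row, col, role) and channels (id, source, detector,
#' distance_mm, kind, hemisphere, roi) as a JSON document.
#'
#' @param layout A `nirs_layout`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
layout_to_json <- function(layout, path = NULL) {
  stopifnot(inherits(layout, "nirs_layout"))
  obj <- list(
    rows = layout$rows, cols = layout$cols, spacing_mm = layout$spacing_mm,
    nodes = layout$nodes,
    channels = layout$channels
  )
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.nirs_layout <- function(x, ...) {
  cat(sprintf("<nirs_layout> %d x %d lattice, %g mm spacing\n",
              x$rows, x$cols, x$spacing_mm))
  tab <- table(x$channels$hemisphere, x$channels$kind)
  print(tab)
  invisible(x)
}
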