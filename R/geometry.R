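#' Electrode montage geometry
#'
#' The montage consists of four 8 x 8 electrode arrays (256 channels in
#' total) with 10 mm pitch: two adjacent arrays on the flexor side and two on
#' the extensor side of the forearm, each pair forming a 16 x 8 grid along
#' the proximal-distal long axis. Row 1 is the most distal row (nearest the
#' wrist); rows increase towards the elbow. Columns 1..8 run around the arm
#' circumference within each side.
#'
#' Channel numbering is fixed: channels 1-128 are the flexor side, 129-256
#' the extensor side; within a side, `channel = offset + (row - 1) * 8 + col`.
#'
#' @return An `electrode_layout`: a data frame with one row per channel and
#'   columns `channel`, `side` (`"flexor"`/`"extensor"`), `row` (1..16, distal
#'   to proximal) and `col` (1..8), with the 10 mm pitch stored in
#'   `attr(, "pitch_mm")`.
#' @examples
#' layout <- build_layout()
#' nrow(layout) # 256
#' @export
build_layout <- function() {
  grid <- expand.grid(col = 1:8, row = 1:16, side = c("flexor", "extensor"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  side_offset <- ifelse(grid$side == "flexor", 0L, 128L)
  channel <- side_offset + (grid$row - 1L) * 8L + grid$col
  layout <- data.frame(channel = channel, side = grid$side,
                       row = grid$row, col = grid$col,
                       stringsAsFactors = FALSE)
  layout <- layout[order(layout$channel), ]
  rownames(layout) <- NULL
  attr(layout, "pitch_mm") <- 10
  class(layout) <- c("electrode_layout", class(layout))
  layout
}

#' Default axial row ranges of the three forearm regions
#'
#' Each region is a 4 x 16 sub-array (4 axial rows on both sides, 16
#' circumferential positions). The three defaults are maximally separated
#' along the forearm: distal wrist rows 1-4, mid-forearm rows 7-10,
#' proximal elbow rows 13-16.
#'
#' @return Named list of integer row ranges (`c(first, last)`).
#' @export
default_region_rows <- function() {
  list(distal_wrist = c(1L, 4L),
       mid_forearm = c(7L, 10L),
       proximal_elbow = c(13L, 16L))
}

#' Select a 64-channel forearm region
#'
#' Extracts the 64 channels of one of the three named regions (or a custom
#' 4-row band) in a fixed raster order: for each of the region's 4 axial rows
#' (distal to proximal), the 16 circumferential positions are listed flexor
#' columns 1-8 then extensor columns 1-8. Reshaping the ordered values with
#' `matrix(v, 16, 4)` therefore reproduces the 16 x 4 spatial feature map
#' (circumference x axial row) used by the outlier-repair stage.
#'
#' @param layout An [build_layout()] electrode layout.
#' @param region_id One of `"distal_wrist"`, `"mid_forearm"`,
#'   `"proximal_elbow"`.
#' @param row_ranges Named list of row ranges, as [default_region_rows()].
#' @return A `region_selection` list with `region_id`, `rows`, `channels`
#'   (64 channel ids in raster order) and `map_shape = c(16, 4)`.
#' @export
select_region <- function(layout, region_id,
                          row_ranges = default_region_rows()) {
  if (!region_id %in% names(row_ranges)) {
    stop("unknown region_id '", region_id, "'; expected one of: ",
         paste(names(row_ranges), collapse = ", "))
  }
  rng <- row_ranges[[region_id]]
  if (length(rng) != 2L || rng[2] - rng[1] != 3L || rng[1] < 1L || rng[2] > 16L) {
    stop("region row range must span exactly 4 rows within 1..16")
  }
  rows <- seq.int(rng[1], rng[2])
  # raster order: axial row (outer), then flexor cols 1-8, extensor cols 1-8
  channels <- integer(0)
  for (r in rows) {
    fl <- layout$channel[layout$side == "flexor" & layout$row == r]
    ex <- layout$channel[layout$side == "extensor" & layout$row == r]
    channels <- c(channels, fl[order(layout$col[match(fl, layout$channel)])],
                  ex[order(layout$col[match(ex, layout$channel)])])
  }
  stopifnot(length(channels) == 64L, !anyDuplicated(channels))
  structure(list(region_id = region_id, rows = rows, channels = channels,
                 map_shape = c(16L, 4L)),
            class = "region_selection")
}

#' Grid coordinates of a region's channels in raster order
#'
#' Returns, for each of the 64 region channels (raster order), its
#' circumferential position (1..16: flexor cols 1-8 then extensor cols 1-8)
#' and axial row (1..16 montage row).
#'
#' @param layout An electrode layout.
#' @param region A `region_selection`.
#' @return Data frame with columns `channel`, `circ`, `row`.
#' @keywords internal
#' @export
region_grid_coords <- function(layout, region) {
  idx <- match(region$channels, layout$channel)
  circ <- ifelse(layout$side[idx] == "flexor", layout$col[idx],
                 8L + layout$col[idx])
  data.frame(channel = region$channels, circ = circ, row = layout$row[idx])
}

#' Map a region's 64 raster-ordered values to the 16 x 4 spatial map
#'
#' @param values Numeric vector of length 64 in region raster order.
#' @return 16 x 4 matrix (circumferential position x axial row).
#' @export
region_map <- function(values) {
  stopifnot(length(values) == 64L)
  matrix(values, nrow = 16L, ncol = 4L)
}
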