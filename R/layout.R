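#' Screen layout of the mouse-tracking Stroop display
#'
#' Describes the start box and the four response boxes in screen pixels
#' (origin top-left, y increasing downward, as delivered by experiment
#' software). The red-green and blue-yellow response boxes sit at mirrored
#' positions about the vertical midline in the upper part of the screen; the
#' start box sits below them on the midline. Clicking the start box centres
#' the cursor, so every trajectory starts at `start_center`.
#'
#' @param screen_size Numeric length-2, screen width and height in px.
#' @param start_center Numeric length-2, start-box centre (px).
#' @param response_centers Named list of four numeric length-2 centres, names
#'   `red`, `green`, `blue`, `yellow`.
#' @param box_half_size Numeric length-2, half-width and half-height of the
#'   response boxes (px).
#' @return A `screen_layout` object (list).
#' @export
#' @examples
#' layout <- screen_layout()
#' layout$response_centers$red
screen_layout <- function(screen_size = c(1920, 1080),
                          start_center = c(960, 940),
                          response_centers = list(
                            red = c(260, 180),
                            green = c(1660, 180),
                            blue = c(660, 180),
                            yellow = c(1260, 180)
                          ),
                          box_half_size = c(120, 60)) {
  layout <- structure(
    list(
      screen_size = as.numeric(screen_size),
      start_center = as.numeric(start_center),
      response_centers = lapply(response_centers, as.numeric),
      box_half_size = as.numeric(box_half_size)
    ),
    class = "screen_layout"
  )
  validate_screen_layout(layout)
  layout
}

validate_screen_layout <- function(layout) {
  rc <- layout$response_centers
  needed <- c("red", "green", "blue", "yellow")
  if (!all(needed %in% names(rc))) {
    abort("`response_centers` must name boxes red, green, blue and yellow")
  }
  mid_x <- layout$screen_size[1] / 2
  for (pair in colour_pairs()) {
    a <- rc[[pair[1]]]; b <- rc[[pair[2]]]
    if (abs((a[1] - mid_x) + (b[1] - mid_x)) > 1e-6 || abs(a[2] - b[2]) > 1e-6) {
      abort(paste0("Boxes ", pair[1], " and ", pair[2],
                   " must mirror each other about the vertical midline"))
    }
  }
  # screen y grows downward: the start box is *below* the response boxes
  if (any(vapply(rc, function(p) p[2] >= layout$start_center[2], logical(1)))) {
    abort("Start box must lie below all response boxes")
  }
  all_pts <- c(rc, list(layout$start_center))
  inb <- vapply(all_pts, function(p) {
    all(p >= 0) && p[1] <= layout$screen_size[1] && p[2] <= layout$screen_size[2]
  }, logical(1))
  if (!all(inb)) abort("All box centres must lie within the screen bounds")
  invisible(layout)
}

#' @export
print.screen_layout <- function(x, ...) {
  cat("<screen_layout> ", x$screen_size[1], "x", x$screen_size[2], " px\n", sep = "")
  cat("  start: (", paste(x$start_center, collapse = ", "), ")\n", sep = "")
  for (nm in names(x$response_centers)) {
    cat("  ", format(nm, width = 7), "(",
        paste(x$response_centers[[nm]], collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

# box centre lookup as a 2-row matrix keyed by colour
box_center <- function(layout, colour) {
  vapply(layout$response_centers[colour], identity, numeric(2))
}
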