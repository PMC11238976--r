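#' Overlay rendering options
#'
#' @param keypoint_color color of the keypoint dots (default red).
#' @param line_color color of the match lines (default green).
#' @param point_radius dot radius in pixels, `>= 1`.
#' @param line_width line width in pixels, `>= 1`.
#' @param gap horizontal gap between the two panels in pixels.
#' @export
overlay_spec <- function(keypoint_color = "red", line_color = "green",
                         point_radius = 2, line_width = 1, gap = 16) {
  if (point_radius < 1 || line_width < 1) {
    stop("`point_radius` and `line_width` must be >= 1")
  }
  structure(list(keypoint_color = keypoint_color, line_color = line_color,
                 point_radius = point_radius, line_width = line_width,
                 gap = as.integer(gap)),
            class = "overlay_spec")
}

#' Render keypoints and matches side by side
#'
#' Builds the qualitative output of the framework: reference (left) and
#' target (right) panels with every keypoint drawn as a dot and one line per
#' matched pair connecting the corresponding points (target x-coordinates
#' offset by the reference width plus the gap). The return value carries a
#' structured list of drawing primitives, so tests and downstream code can
#' count dots and lines without pixel forensics; [rasterize_overlay()] turns
#' it into an RGB raster and [write_overlay()] writes a PNG.
#'
#' @param ref,tgt 8-bit [gray_image()]s.
#' @param kp_ref,kp_tgt keypoint data frames from [detect_and_describe()].
#' @param matches a `match_set` between the two keypoint sets.
#' @param spec an [overlay_spec()].
#' @return an object of class `match_overlay` with `primitives` (`points`
#'   and `lines` data frames in canvas coordinates), `width`, `height`.
#' @export
render_matches <- function(ref, tgt, kp_ref, kp_tgt, matches,
                           spec = overlay_spec()) {
  assert_gray_image(ref, 8L)
  assert_gray_image(tgt, 8L)
  stopifnot(inherits(matches, "match_set"))
  if (matches$N > 0) {
    if (max(matches$pairs$ref_index) > nrow(kp_ref) ||
        max(matches$pairs$tgt_index) > nrow(kp_tgt)) {
      stop("match indices exceed the keypoint tables")
    }
  }
  wr <- ncol(ref$pixels); wt <- ncol(tgt$pixels)
  hr <- nrow(ref$pixels); ht <- nrow(tgt$pixels)
  off <- wr + spec$gap
  points <- rbind(
    if (nrow(kp_ref)) data.frame(x = kp_ref$x, y = kp_ref$y, panel = "ref"),
    if (nrow(kp_tgt)) data.frame(x = kp_tgt$x + off, y = kp_tgt$y, panel = "tgt")
  )
  if (is.null(points)) points <- data.frame(x = numeric(0), y = numeric(0),
                                            panel = character(0))
  lines <- if (matches$N > 0) {
    data.frame(
      x0 = kp_ref$x[matches$pairs$ref_index],
      y0 = kp_ref$y[matches$pairs$ref_index],
      x1 = kp_tgt$x[matches$pairs$tgt_index] + off,
      y1 = kp_tgt$y[matches$pairs$tgt_index]
    )
  } else {
    data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
               y1 = numeric(0))
  }
  structure(list(primitives = list(points = points, lines = lines),
                 width = off + wt, height = max(hr, ht),
                 spec = spec, ref = ref, tgt = tgt),
            class = "match_overlay")
}

#' Rasterize a match overlay to an RGB array
#'
#' @param overlay a `match_overlay` from [render_matches()].
#' @return a `height x width x 3` numeric array in `[0, 1]`.
#' @export
rasterize_overlay <- function(overlay) {
  stopifnot(inherits(overlay, "match_overlay"))
  h <- overlay$height; w <- overlay$width
  canvas <- array(0, dim = c(h, w, 3))
  put_panel <- function(canvas, img, x_off) {
    g <- img$pixels / 255
    for (ch in 1:3) {
      canvas[seq_len(nrow(g)), x_off + seq_len(ncol(g)), ch] <- g
    }
    canvas
  }
  canvas <- put_panel(canvas, overlay$ref, 0L)
  canvas <- put_panel(canvas, overlay$tgt,
                      ncol(overlay$ref$pixels) + overlay$spec$gap)
  lcol <- grDevices::col2rgb(overlay$spec$line_color)[, 1] / 255
  pcol <- grDevices::col2rgb(overlay$spec$keypoint_color)[, 1] / 255
  set_px <- function(canvas, x, y, col) {
    ok <- x >= 0 & x < w & y >= 0 & y < h
    x <- x[ok]; y <- y[ok]
    for (ch in 1:3) canvas[cbind(y + 1L, x + 1L, ch)] <- col[ch]
    canvas
  }
  ln <- overlay$primitives$lines
  for (i in seq_len(nrow(ln))) {
    len <- max(abs(ln$x1[i] - ln$x0[i]), abs(ln$y1[i] - ln$y0[i]), 1)
    t <- seq(0, 1, length.out = 2L * ceiling(len) + 1L)
    canvas <- set_px(canvas,
                     round(ln$x0[i] + t * (ln$x1[i] - ln$x0[i])),
                     round(ln$y0[i] + t * (ln$y1[i] - ln$y0[i])), lcol)
  }
  pts <- overlay$primitives$points
  r <- overlay$spec$point_radius
  disc <- expand.grid(dx = -r:r, dy = -r:r)
  disc <- disc[disc$dx^2 + disc$dy^2 <= r^2, ]
  for (i in seq_len(nrow(pts))) {
    canvas <- set_px(canvas, round(pts$x[i]) + disc$dx,
                     round(pts$y[i]) + disc$dy, pcol)
  }
  canvas
}

#' Write a match overlay as a PNG file
#'
#' @param overlay a `match_overlay`.
#' @param path output PNG path.
#' @export
write_overlay <- function(overlay, path) {
  png::writePNG(rasterize_overlay(overlay), path)
  invisible(path)
}
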