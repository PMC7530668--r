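# ECG-paper rendering. All geometry derives from one constants block:
# standard paper (25 mm/s, 10 mm/mV, 1-mm small boxes = 0.04 s) at
# 5 px/mm on a fixed 675 x 1450 canvas. The 0.2-s calibration pulse plus
# the 10-s trace span 10.2 s = 255 mm = 1275 px; the remaining 175 px
# are margins. Traces are crisp 2-px polylines so that a pixel
# measurement oracle recovers amplitude and duration exactly.

#' ECG paper template constants
#'
#' @param px_per_mm Pixels per millimetre (>= 3, default 5).
#' @param paper_speed Paper feed, mm/s (default 25; one 1-mm small box
#'   is then 0.04 s).
#' @param mm_per_mV Amplitude gain, mm per mV (default 10).
#' @param trace_px Trace thickness in pixels.
#' @return List of template constants (colors are RGB 0-255 triples).
#' @export
paper_template <- function(px_per_mm = 5L, paper_speed = 25, mm_per_mV = 10,
                           trace_px = 2L) {
  if (px_per_mm < 3) stopf("px_per_mm must be >= 3")
  list(px_per_mm = as.integer(px_per_mm), paper_speed = paper_speed,
       mm_per_mV = mm_per_mV, small_box_s = 1 / paper_speed,
       bg = c(255, 255, 255), minor = c(255, 205, 205),
       major = c(242, 135, 135), trace = c(0, 0, 0),
       label = c(40, 40, 40), trace_px = as.integer(trace_px))
}

#' Standard plot layout: 3 x 4 short panels plus a lead II rhythm row
#'
#' Rows 1-3 hold four 2.5-s panels each in the conventional clinical
#' order (I, aVR, V1, V4 / II, aVL, V2, V5 / III, aVF, V3, V6); row 4 is
#' the 10-s lead II rhythm strip. Every row starts with a 1-mV, 0.2-s
#' calibration pulse.
#'
#' @param canvas Height, width in pixels (default c(675, 1450)).
#' @return List of layout constants.
#' @export
plot_layout <- function(canvas = c(675L, 1450L)) {
  list(canvas = as.integer(canvas),
       grid_x0 = 88L, grid_w = 1275L, grid_y0 = 15L, grid_y1 = 660L,
       baselines = c(105L, 265L, 425L, 585L),
       cal_w_s = 0.2,
       lead_rows = list(c("I", "aVR", "V1", "V4"),
                        c("II", "aVL", "V2", "V5"),
                        c("III", "aVF", "V3", "V6")),
       rhythm_lead = "II",
       label_dx = 10L, label_dy = 62L, label_scale = 2L)
}

# ---- low-level raster helpers ------------------------------------------

blank_canvas <- function(template, canvas) {
  img <- array(0, c(canvas[1], canvas[2], 3L))
  for (ch in 1:3) img[, , ch] <- template$bg[ch]
  img
}

set_px <- function(img, rows, cols, color) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ok <- rows >= 1L & rows <= H & cols >= 1L & cols <= W
  if (!any(ok)) return(img)
  idx <- rows[ok] + (cols[ok] - 1L) * H
  HW <- H * W
  img[idx] <- color[1]; img[idx + HW] <- color[2]; img[idx + 2L * HW] <- color[3]
  img
}

# Draw a polyline sampled at (xs, ys) in pixel coordinates. Column-run
# rasterization: every pixel column covered by the trace gets a vertical
# run joining it to its neighbours, then runs are thickened to trace_px.
draw_trace <- function(img, xs, ys, color, thickness = 2L) {
  cols <- as.integer(round(xs)); yr <- as.integer(round(ys))
  n <- length(cols)
  if (n == 0L) return(img)
  brk <- c(TRUE, cols[-1] != cols[-n])
  starts <- which(brk); ends <- c(starts[-1] - 1L, n)
  g <- length(starts)
  cmin <- cmax <- clast <- integer(g)
  for (k in seq_len(g)) {
    seg <- yr[starts[k]:ends[k]]
    cmin[k] <- min(seg); cmax[k] <- max(seg); clast[k] <- seg[length(seg)]
  }
  prev_last <- c(clast[1], clast[-g])
  lo <- pmin(cmin, prev_last); hi <- pmax(cmax, prev_last)
  hi <- hi + (thickness - 1L)
  lens <- hi - lo + 1L
  rows_idx <- sequence(lens, from = lo)
  cols_idx <- rep(cols[starts], lens)
  set_px(img, rows_idx, cols_idx, color)
}

# ---- 5x7 bitmap font for lead labels -----------------------------------

.font <- list(
  "I" = c("XXXXX", "..X..", "..X..", "..X..", "..X..", "..X..", "XXXXX"),
  "V" = c("X...X", "X...X", "X...X", "X...X", "X...X", ".X.X.", "..X.."),
  "a" = c(".....", ".....", ".XXX.", "....X", ".XXXX", "X...X", ".XXXX"),
  "R" = c("XXXX.", "X...X", "X...X", "XXXX.", "X.X..", "X..X.", "X...X"),
  "L" = c("X....", "X....", "X....", "X....", "X....", "X....", "XXXXX"),
  "F" = c("XXXXX", "X....", "X....", "XXXX.", "X....", "X....", "X...."),
  "1" = c("..X..", ".XX..", "..X..", "..X..", "..X..", "..X..", ".XXX."),
  "2" = c(".XXX.", "X...X", "....X", "...X.", "..X..", ".X...", "XXXXX"),
  "3" = c(".XXX.", "X...X", "....X", "..XX.", "....X", "X...X", ".XXX."),
  "4" = c("...X.", "..XX.", ".X.X.", "X..X.", "XXXXX", "...X.", "...X."),
  "5" = c("XXXXX", "X....", "XXXX.", "....X", "....X", "X...X", ".XXX."),
  "6" = c(".XXX.", "X....", "XXXX.", "X...X", "X...X", "X...X", ".XXX."))

draw_text <- function(img, text, x, y, color, scale = 2L) {
  rows_all <- cols_all <- integer(0)
  cx <- x
  for (ch in strsplit(text, "")[[1]]) {
    pat <- .font[[ch]]
    if (!is.null(pat)) {
      for (r in 1:7) {
        on <- which(strsplit(pat[r], "")[[1]] == "X")
        for (c in on) {
          rows <- y + (r - 1L) * scale + seq_len(scale) - 1L
          cols <- cx + (c - 1L) * scale + seq_len(scale) - 1L
          rows_all <- c(rows_all, rep(rows, each = length(cols)))
          cols_all <- c(cols_all, rep(cols, length(rows)))
        }
      }
    }
    cx <- cx + 6L * scale
  }
  set_px(img, rows_all, cols_all, color)
}

# ---- grid and record rendering -----------------------------------------

#' Render the blank ECG-paper grid
#'
#' Minor grid lines every 1 mm and major lines every 5 mm (5 small boxes
#' per large box) within the plotting area. Deterministic.
#'
#' @param template From [paper_template()].
#' @param canvas Height, width in pixels.
#' @param layout From [plot_layout()].
#' @return `rendered_image`: integer array \[H, W, 3\] with values 0-255.
#' @export
render_grid <- function(template = paper_template(), canvas = c(675L, 1450L),
                        layout = plot_layout(canvas)) {
  ppm <- template$px_per_mm
  if (layout$grid_x0 + layout$grid_w > canvas[2] || layout$grid_y1 > canvas[1])
    stopf("canvas too small for layout at %d px/mm", ppm)
  img <- blank_canvas(template, canvas)
  yy <- layout$grid_y0:layout$grid_y1
  xx <- layout$grid_x0:(layout$grid_x0 + layout$grid_w)
  lines_px <- function(xs, ys) {
    # all pixels of the vertical lines at xs plus horizontal lines at ys
    list(rows = c(rep(yy, length(xs)), rep(ys, each = length(xx))),
         cols = c(rep(xs, each = length(yy)), rep(xx, length(ys))))
  }
  mn <- lines_px(seq(layout$grid_x0, layout$grid_x0 + layout$grid_w, by = ppm),
                 seq(layout$grid_y0, layout$grid_y1, by = ppm))
  img <- set_px(img, mn$rows, mn$cols, template$minor)
  mj <- lines_px(seq(layout$grid_x0, layout$grid_x0 + layout$grid_w,
                     by = 5L * ppm),
                 seq(layout$grid_y0, layout$grid_y1, by = 5L * ppm))
  img <- set_px(img, mj$rows, mj$cols, template$major)
  structure(img, class = "rendered_image")
}

#' Render a standard record as an ECG-paper image
#'
#' Plots the four 2.5-s short-lead panels per row (3 x 4 clinical
#' layout) and the 10-s lead II rhythm strip at 25 mm/s and 10 mm/mV,
#' with a 1-mV (10 mm) x 0.2-s calibration pulse at the start of every
#' row and a label next to each lead plot. Output is always
#' \[675, 1450, 3\].
#'
#' @param record A `standard_record`.
#' @param template From [paper_template()].
#' @param layout From [plot_layout()].
#' @return `rendered_image`: integer array \[675, 1450, 3\], 0-255.
#' @export
render_record <- function(record, template = paper_template(),
                          layout = plot_layout()) {
  if (!inherits(record, "standard_record"))
    stopf("record must be a standard_record")
  if (!is.matrix(record$short) || nrow(record$short) != 12L ||
      ncol(record$short) != WIN_SAMPLES || length(record$long) != SEG_SAMPLES)
    stopf("record has malformed signal blocks")
  ppm <- template$px_per_mm
  img <- render_grid(template, layout$canvas, layout)
  px_per_mV <- template$mm_per_mV * ppm                 # 50
  px_per_s <- template$paper_speed * ppm                # 125
  px_per_sample <- px_per_s / 500                       # 0.25
  cal_w <- layout$cal_w_s * px_per_s                    # 25
  x_trace0 <- layout$grid_x0 + cal_w
  cal_pulse <- function(img, b) {
    xs <- layout$grid_x0 + c(0, 0, cal_w, cal_w)
    ys <- b - px_per_mV * c(0, 1, 1, 0)
    draw_trace(img, xs, ys, template$trace, template$trace_px)
  }
  for (r in 1:3) {
    b <- layout$baselines[r]
    img <- cal_pulse(img, b)
    leads <- layout$lead_rows[[r]]
    for (w in 0:3) {
      li <- match(leads[w + 1L], ECG_LEADS)
      s <- record$short[li, ]
      xs <- x_trace0 + (w * WIN_SAMPLES + seq_along(s) - 1) * px_per_sample
      ys <- b - s * px_per_mV
      img <- draw_trace(img, xs, ys, template$trace, template$trace_px)
      img <- draw_text(img, leads[w + 1L],
                       as.integer(round(x_trace0 + w * WIN_SAMPLES *
                                          px_per_sample)) + layout$label_dx,
                       b - layout$label_dy, template$label, layout$label_scale)
    }
  }
  b <- layout$baselines[4]
  img <- cal_pulse(img, b)
  xs <- x_trace0 + (seq_len(SEG_SAMPLES) - 1) * px_per_sample
  ys <- b - record$long * px_per_mV
  img <- draw_trace(img, xs, ys, template$trace, template$trace_px)
  img <- draw_text(img, layout$rhythm_lead,
                   layout$grid_x0 + cal_w + layout$label_dx,
                   b - layout$label_dy, template$label, layout$label_scale)
  structure(img, class = "rendered_image")
}

# ---- geometry measurement oracle ---------------------------------------

#' Measure trace geometry from a rendered image
#'
#' Pixel-measurement oracle: inspects exact trace-colored pixels inside
#' one panel (or a full rhythm row) and recovers the peak amplitude in
#' mV (signed, largest deviation from the baseline) and the duration in
#' seconds over which the trace deviates from the baseline by more than
#' `min_dev_mV`.
#'
#' @param img A `rendered_image` from [render_record()].
#' @param row Row number 1-4 (4 = rhythm strip).
#' @param panel Panel 1-4 within rows 1-3; ignored for row 4.
#' @param template,layout Constants used to render `img`.
#' @param min_dev_mV Deviation threshold defining "on baseline".
#' @return List with `amp_mV` and `dur_s`.
#' @export
measure_trace <- function(img, row, panel = 1L, template = paper_template(),
                          layout = plot_layout(), min_dev_mV = 0.1) {
  ppm <- template$px_per_mm
  px_per_mV <- template$mm_per_mV * ppm
  px_per_s <- template$paper_speed * ppm
  b <- layout$baselines[row]
  x0 <- layout$grid_x0 + layout$cal_w_s * px_per_s
  if (row <= 3) {
    panel_w <- WIN_SAMPLES * px_per_s / 500
    xr <- round(c(x0 + (panel - 1L) * panel_w, x0 + panel * panel_w - 1))
  } else xr <- round(c(x0, x0 + SEG_SAMPLES * px_per_s / 500 - 1))
  # skip the calibration pulse's falling edge at the very first columns
  if (panel == 1L || row == 4L) xr[1] <- xr[1] + template$trace_px
  # restrict to this row's vertical band so neighbouring rows' traces
  # cannot contaminate the measurement
  band <- max(1L, b - 80L):min(dim(img)[1], b + 80L)
  img <- img[band, , , drop = FALSE]
  b <- b - (min(band) - 1L)
  sub <- img[, xr[1]:xr[2], , drop = FALSE]
  mask <- sub[, , 1] == template$trace[1] & sub[, , 2] == template$trace[2] &
    sub[, , 3] == template$trace[3]
  if (!any(mask)) return(list(amp_mV = NA_real_, dur_s = NA_real_))
  # per-column extreme deviation from baseline (trace thickness extends
  # downward, so an upward peak is exact and a downward one is off by
  # thickness-1 pixels, corrected here)
  dev_px <- apply(mask, 2, function(col) {
    rows <- which(col)
    if (!length(rows)) return(0)
    up <- b - min(rows); dn <- max(rows) - (template$trace_px - 1L) - b
    if (up >= dn) up else -dn
  })
  peak <- dev_px[which.max(abs(dev_px))]
  on <- abs(dev_px) > min_dev_mV * px_per_mV
  list(amp_mV = peak / px_per_mV, dur_s = sum(on) / px_per_s)
}

# ---- image I/O and resizing --------------------------------------------

#' Write a rendered image to PNG
#' @param img Integer array \[H, W, 3\], values 0-255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Read a PNG back as an integer intensity array
#' @param path PNG file path.
#' @return `rendered_image`: integer array \[H, W, 3\], 0-255.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3]
  structure(round(x * 255), class = "rendered_image")
}

#' Downsample an image by integer box averaging
#'
#' Crops to a multiple of `factor` in each dimension, then averages each
#' factor x factor block. Used to build reduced-resolution image inputs.
#'
#' @param img Array \[H, W, 3\].
#' @param factor Integer downsampling factor.
#' @return Array \[H/factor, W/factor, 3\] (doubles, same 0-255 scale).
#' @export
downsample_image <- function(img, factor = 4L) {
  f <- as.integer(factor)
  H <- dim(img)[1] %/% f * f; W <- dim(img)[2] %/% f * f
  x <- unclass(img)[seq_len(H), seq_len(W), , drop = FALSE]
  # average rows
  dim(x) <- c(f, H %/% f, W, 3L)
  x <- colMeans(x)                       # (H/f, W, 3)
  # average cols
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- c(f, W %/% f, H %/% f, 3L)
  x <- colMeans(x)                       # (W/f, H/f, 3)
  aperm(x, c(2, 1, 3))
}
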