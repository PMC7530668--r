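# Smartphone-acquisition simulation: a random projective (perspective)
# warp of the rendered plot composited over a procedural table-texture
# background. Fully deterministic from its seeds; bilinear interpolation.

#' Perspective jitter specification
#'
#' @param max_disp Maximum corner displacement as a fraction of each
#'   image dimension, in \[0, 0.25\] (default 0.08).
#' @param canvas Output height, width (default c(675, 1450)).
#' @return List spec.
#' @export
perspective_spec <- function(max_disp = 0.08, canvas = c(675L, 1450L)) {
  if (max_disp < 0 || max_disp > 0.25) stopf("max_disp must lie in [0, 0.25]")
  list(max_disp = max_disp, canvas = as.integer(canvas))
}

# Solve the 3x3 projective map sending (x_i, y_i) -> (u_i, v_i) for 4
# point pairs (exact direct linear transform, h33 fixed to 1).
solve_homography <- function(src, dst) {
  A <- matrix(0, 8, 8); bvec <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    bvec[2 * i - 1] <- u; bvec[2 * i] <- v
  }
  h <- solve(A, bvec)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Draw a random perspective homography
#'
#' Each corner of the canvas is displaced by an independent uniform
#' jitter within +/- `max_disp` of the corresponding dimension; the
#' returned 3x3 matrix maps the 4 source corners to the jittered corners
#' exactly. Degenerate (near-collinear) draws are resampled internally.
#'
#' @param spec From [perspective_spec()].
#' @param seed Integer seed.
#' @return A `homography`: 3x3 matrix with attributes `src` and `dst`
#'   (4 x 2 corner coordinates, columns x then y).
#' @export
random_homography <- function(spec = perspective_spec(), seed = 1L) {
  H <- spec$canvas[1]; W <- spec$canvas[2]
  src <- cbind(x = c(1, W, W, 1), y = c(1, 1, H, H))
  with_seed(seed, {
    for (try in 1:100) {
      dx <- runif(4, -spec$max_disp, spec$max_disp) * W
      dy <- runif(4, -spec$max_disp, spec$max_disp) * H
      dst <- src + cbind(dx, dy)
      M <- tryCatch(solve_homography(src, dst), error = function(e) NULL)
      if (!is.null(M) && abs(det(M)) > 1e-8)
        return(structure(M, src = src, dst = dst, class = "homography"))
    }
    stopf("failed to draw a non-degenerate homography")
  })
}

#' Apply a homography to points
#' @param h A `homography` (3x3 matrix).
#' @param pts n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
apply_homography <- function(h, pts) {
  p <- cbind(pts[, 1], pts[, 2], 1) %*% t(unclass(h))
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

#' Procedural table-texture background
#'
#' Seeded procedural textures standing in for photographs of table
#' surfaces: `flat` (constant color), `speckle` (per-pixel noise),
#' `cloth` (smoothed noise with a weave modulation), `wood-grain`
#' (noise smoothed strongly along one axis into elongated grain).
#'
#' @param family One of "wood-grain", "cloth", "speckle", "flat".
#' @param canvas Height, width.
#' @param base_color RGB triple 0-255; default picked per family.
#' @param seed Integer seed.
#' @return Integer array \[H, W, 3\], 0-255.
#' @export
generate_background <- function(family = c("wood-grain", "cloth", "speckle",
                                           "flat"),
                                canvas = c(675L, 1450L), base_color = NULL,
                                seed = 1L) {
  family <- match.arg(family)
  H <- canvas[1]; W <- canvas[2]
  base <- base_color %||% switch(family,
    "wood-grain" = c(150, 108, 66), "cloth" = c(96, 112, 140),
    "speckle" = c(120, 120, 120), "flat" = c(135, 135, 135))
  img <- array(0, c(H, W, 3L))
  smooth_rows <- function(m, k) {
    if (k <= 1) return(m)
    kern <- rep(1 / k, k)
    t(apply(m, 1, function(r) {
      n <- length(r)
      as.numeric(stats::filter(c(rev(r[1:k]), r, rev(r[(n - k + 1):n])),
                               kern, sides = 2))[(k + 1):(k + n)]
    }))
  }
  with_seed(seed, {
    tex <- switch(family,
      "flat" = matrix(0, H, W),
      "speckle" = matrix(rnorm(H * W, 0, 1), H, W),
      "cloth" = {
        m <- smooth_rows(matrix(rnorm(H * W), H, W), 9)
        m <- t(smooth_rows(t(m), 9))
        weave <- outer(sin(seq_len(H) / 2.1), sin(seq_len(W) / 2.1))
        3.5 * m + 0.35 * weave
      },
      "wood-grain" = {
        m <- smooth_rows(matrix(rnorm(H * W), H, W), 61)
        m <- t(smooth_rows(t(m), 3))
        rings <- sin(outer(seq_len(H) / 17, rep(1, W)) + 9 * m)
        6 * m + 0.6 * rings
      })
    for (ch in 1:3) {
      jit <- if (family == "flat") 0 else rnorm(1, 0, 2)
      img[, , ch] <- pmin(255, pmax(0, base[ch] + jit + tex * 28))
    }
  })
  round(img)
}

#' Warp a plot image and composite it over a background
#'
#' Inverse-maps every output pixel through `h`; pixels whose preimage
#' falls inside the source image take the bilinearly interpolated plot
#' intensity, all others take the background.
#'
#' @param image Plot image, array \[H, W, 3\] (0-255).
#' @param h A `homography` mapping source to output coordinates.
#' @param bg Background image of identical shape.
#' @return Array \[H, W, 3\] (0-255), same shape as the inputs.
#' @export
distort <- function(image, h, bg) {
  di <- dim(image); db <- dim(bg)
  if (!all(di == db)) stopf("image and background sizes differ")
  H <- di[1]; W <- di[2]
  Minv <- solve(unclass(h))
  xs <- rep(seq_len(W), each = H); ys <- rep(seq_len(H), W)
  p <- cbind(xs, ys, 1) %*% t(Minv)
  sx <- p[, 1] / p[, 3]; sy <- p[, 2] / p[, 3]
  eps <- 1e-6
  inside <- sx >= 1 - eps & sx <= W + eps & sy >= 1 - eps & sy <= H + eps
  out <- array(0, di)
  sxc <- pmin(pmax(sx[inside], 1), W); syc <- pmin(pmax(sy[inside], 1), H)
  x0 <- pmin(pmax(floor(sxc), 1), W - 1); fx <- sxc - x0
  y0 <- pmin(pmax(floor(syc), 1), H - 1); fy <- syc - y0
  i00 <- y0 + (x0 - 1) * H
  lin_in <- which(inside)
  for (ch in 1:3) {
    plane <- unclass(image)[, , ch]
    v <- (1 - fx) * (1 - fy) * plane[i00] + fx * (1 - fy) * plane[i00 + H] +
      (1 - fx) * fy * plane[i00 + 1] + fx * fy * plane[i00 + H + 1]
    o <- unclass(bg)[, , ch]
    o[lin_in] <- v
    out[, , ch] <- o
  }
  structure(out, class = "rendered_image")
}

#' One-call smartphone-acquisition simulation
#'
#' Draws a random homography and background from `seed` substreams and
#' applies [distort()]. Identical inputs give byte-identical output.
#'
#' @param image Plot image \[675, 1450, 3\].
#' @param seed Integer seed.
#' @param max_disp Corner jitter fraction (default 0.08).
#' @param bg_family Background texture family.
#' @return Distorted image, same shape.
#' @export
simulate_camera <- function(image, seed = 1L, max_disp = 0.08,
                            bg_family = "wood-grain") {
  spec <- perspective_spec(max_disp, dim(image)[1:2])
  h <- random_homography(spec, child_seed(seed, 1L))
  bg <- generate_background(bg_family, dim(image)[1:2],
                            seed = child_seed(seed, 2L))
  distort(image, h, bg)
}
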