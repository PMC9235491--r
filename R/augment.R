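# Stochastic augmentation for contrastive views.
#
# Each member of a positive pair is independently passed through a fixed
# pipeline: random crop -> HSV color jitter -> scale -> rotation. The output
# is always crop_size x crop_size x 3 in [0,1]. Randomness is drawn from R's
# global RNG in a fixed order, so seeding the RNG makes the result a pure
# function of (image, config, RNG state).

#' Augmentation configuration
#'
#' @param crop_size side of the square crop in pixels.
#' @param hue_jitter maximum absolute hue shift, on the [0,1) hue circle
#'   (0.5 = opposite hue).
#' @param sat_jitter,val_jitter maximum relative shift of saturation / value.
#' @param scale_range length-2 numeric, relative scale factor range
#'   (min <= max). `c(1, 1)` disables scaling.
#' @param rotation_range maximum absolute rotation in degrees; rotation fills
#'   out-of-frame pixels by reflection.
#' @return an `augment_config` list.
#' @export
augment_config <- function(crop_size = 256L, hue_jitter = 0.05,
                           sat_jitter = 0.2, val_jitter = 0.2,
                           scale_range = c(0.8, 1.2), rotation_range = 90) {
  stopifnot(crop_size >= 1, hue_jitter >= 0, hue_jitter <= 0.5,
            sat_jitter >= 0, val_jitter >= 0,
            length(scale_range) == 2L, scale_range[1] <= scale_range[2],
            all(scale_range > 0), rotation_range >= 0)
  structure(
    list(crop_size = as.integer(crop_size), hue_jitter = hue_jitter,
         sat_jitter = sat_jitter, val_jitter = val_jitter,
         scale_range = as.numeric(scale_range),
         rotation_range = rotation_range),
    class = "augment_config"
  )
}

#' Augment one image
#'
#' Applies, in fixed order: uniform random crop to `crop_size`, HSV color
#' jitter, then a combined scale-and-rotate resampling (bilinear, reflection
#' fill). When a step's sampled parameters are the identity the pixel data
#' pass through bit-exactly.
#'
#' @param image numeric array `H x W x 3` with values in `[0,1]`; both sides
#'   must be at least `crop_size`.
#' @param config an [augment_config()].
#' @return numeric array `crop_size x crop_size x 3`, values clipped to
#'   `[0,1]`.
#' @export
augment_image <- function(image, config = augment_config()) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stopf("image must be H x W x 3")
  cs <- config$crop_size
  if (d[1] < cs || d[2] < cs) {
    stopf("image (%dx%d) smaller than crop_size %d", d[1], d[2], cs)
  }
  # 1. random crop (uniform over valid offsets)
  oy <- if (d[1] > cs) sample.int(d[1] - cs + 1L, 1L) - 1L else 0L
  ox <- if (d[2] > cs) sample.int(d[2] - cs + 1L, 1L) - 1L else 0L
  img <- image[(oy + 1L):(oy + cs), (ox + 1L):(ox + cs), , drop = FALSE]
  # 2. HSV jitter
  dh <- runif(1L, -config$hue_jitter, config$hue_jitter)
  ds <- runif(1L, -config$sat_jitter, config$sat_jitter)
  dv <- runif(1L, -config$val_jitter, config$val_jitter)
  if (dh != 0 || ds != 0 || dv != 0) {
    hsv <- rgb_to_hsv_array(img)
    hsv[, , 1] <- (hsv[, , 1] + dh) %% 1
    hsv[, , 2] <- pmin(pmax(hsv[, , 2] * (1 + ds), 0), 1)
    hsv[, , 3] <- pmin(pmax(hsv[, , 3] * (1 + dv), 0), 1)
    img <- hsv_to_rgb_array(hsv)
  }
  # 3-4. scale then rotate, as one bilinear resampling about the center
  sc <- runif(1L, config$scale_range[1], config$scale_range[2])
  th <- runif(1L, -config$rotation_range, config$rotation_range) * pi / 180
  if (sc != 1 || th != 0) img <- affine_resample(img, scale = sc, theta = th)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# Bilinear resampling of a square image under scale-then-rotate about the
# center. Out-of-frame source coordinates are reflected back into the frame
# (avoids black-corner shortcuts a contrastive model could latch onto).
affine_resample <- function(img, scale, theta) {
  s <- dim(img)[1]
  ctr <- (s + 1) / 2
  gx <- rep(seq_len(s), each = s)   # column index of output pixel
  gy <- rep(seq_len(s), times = s)  # row index
  dx <- gx - ctr
  dy <- gy - ctr
  # inverse map: un-rotate then un-scale
  ct <- cos(-theta); st <- sin(-theta)
  sx <- (ct * dx - st * dy) / scale + ctr
  sy <- (st * dx + ct * dy) / scale + ctr
  sx <- reflect_coord(sx, s)
  sy <- reflect_coord(sy, s)
  x0 <- pmin(floor(sx), s - 1); fx <- sx - x0
  y0 <- pmin(floor(sy), s - 1); fy <- sy - y0
  out <- array(0, dim(img))
  n <- s * s
  i00 <- y0 + (x0 - 1) * s
  i10 <- i00 + 1
  i01 <- i00 + s
  i11 <- i01 + 1
  w00 <- (1 - fx) * (1 - fy); w10 <- (1 - fx) * fy
  w01 <- fx * (1 - fy);       w11 <- fx * fy
  for (ch in 1:3) {
    v <- img[, , ch]
    out[, , ch] <- matrix(
      v[i00] * w00 + v[i10] * w10 + v[i01] * w01 + v[i11] * w11,
      nrow = s
    )
  }
  out
}

# Reflect continuous coordinates into [1, s] with period 2(s-1).
reflect_coord <- function(t, s) {
  if (s == 1L) return(rep(1, length(t)))
  m <- (t - 1) %% (2 * (s - 1))
  m <- ifelse(m > (s - 1), 2 * (s - 1) - m, m)
  1 + m
}

# Vectorized RGB <-> HSV on H x W x 3 arrays, hue in [0,1).
rgb_to_hsv_array <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  rm <- nz & (mx == r)
  gm <- nz & !rm & (mx == g)
  bm <- nz & !rm & !gm
  h[rm] <- (((g - b)[rm] / d[rm]) %% 6) / 6
  h[gm] <- (((b - r)[gm] / d[gm]) + 2) / 6
  h[bm] <- (((r - g)[bm] / d[bm]) + 4) / 6
  s <- ifelse(mx > 0, d / mx, 0)
  array(c(h, s, mx), dim(img))
}

hsv_to_rgb_array <- function(hsv) {
  h <- hsv[, , 1] * 6; s <- hsv[, , 2]; v <- hsv[, , 3]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), dim(hsv))
}
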