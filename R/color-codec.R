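# Seven-color lesion codec.
#
# Ground-truth masks paint each lesion/structure polygon in one fully
# saturated, fully bright color identified by its hue. Decoding a predicted
# segmentation back to classes is done per pixel in HSV space: a pixel is
# assigned to the nearest class hue within a band of +/- `half_width_units`
# on OpenCV's 0-179 hue scale (1 unit = 2 degrees), provided its saturation
# and value clear configurable floors; everything else is background.

#' Canonical lesion color table
#'
#' The seven lesion/structure classes with their canonical hue (degrees),
#' full saturation/value, 8-bit RGB triple and hex code. Class ids are
#' `0:6` in the order Benign Tumor, Subglottis, R-TVC, L-TVC, R-FVC, L-FVC,
#' Cancer (TVC/FVC: true/false vocal cord, right/left).
#'
#' @return A data frame with columns `name`, `class_id`, `hue_deg`,
#'   `saturation`, `value`, `r`, `g`, `b`, `hex`.
#' @export
#' @examples
#' lesion_color_table()
lesion_color_table <- function() {
  tab <- data.frame(
    name = c("Benign Tumor", "Subglottis", "R-TVC", "L-TVC",
             "R-FVC", "L-FVC", "Cancer"),
    class_id = 0:6,
    hue_deg = c(0, 60, 105, 180, 210, 255, 300),
    saturation = 1,
    value = 1,
    stringsAsFactors = FALSE
  )
  rgb <- t(vapply(tab$hue_deg, function(h) hsv_to_rgb(h, 1, 1), integer(3)))
  tab$r <- rgb[, 1]; tab$g <- rgb[, 2]; tab$b <- rgb[, 3]
  tab$hex <- apply(rgb, 1, rgb_to_hex)
  tab
}

#' Convert an HSV color to an 8-bit RGB triple
#'
#' Standard hexcone conversion with channels rounded to integers in 0-255.
#'
#' @param h Hue in degrees, `0 <= h < 360`.
#' @param s,v Saturation and value as fractions in `[0, 1]`.
#' @return Integer vector `c(r, g, b)`.
#' @export
#' @examples
#' hsv_to_rgb(105, 1, 1) # c(64, 255, 0)
hsv_to_rgb <- function(h, s, v) {
  if (!is.numeric(h) || length(h) != 1 || h < 0 || h >= 360)
    stop("`h` must be a single hue in degrees with 0 <= h < 360")
  if (!is.numeric(s) || s < 0 || s > 1) stop("`s` must be a fraction in [0, 1]")
  if (!is.numeric(v) || v < 0 || v > 1) stop("`v` must be a fraction in [0, 1]")
  hp <- h / 60
  c_ <- v * s
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- v - c_
  sector <- floor(hp) %% 6
  rgb1 <- switch(as.character(sector),
    "0" = c(c_, x, 0), "1" = c(x, c_, 0), "2" = c(0, c_, x),
    "3" = c(0, x, c_), "4" = c(x, 0, c_), "5" = c(c_, 0, x))
  as.integer(round((rgb1 + m) * 255))
}

#' Format an RGB triple as an uppercase hex code
#'
#' @param rgb Integer vector of length 3, each channel in 0-255.
#' @return String `"#RRGGBB"`.
#' @export
#' @examples
#' rgb_to_hex(c(64, 255, 0)) # "#40FF00"
rgb_to_hex <- function(rgb) {
  if (length(rgb) != 3 || any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255))
    stop("`rgb` must be three channel values in 0-255")
  toupper(sprintf("#%02X%02X%02X", as.integer(rgb[1]), as.integer(rgb[2]),
                  as.integer(rgb[3])))
}

#' Hue-band classification rule
#'
#' Controls how pixels are decoded back to classes: a pixel is assigned to
#' the class with the nearest canonical hue (circular distance on the 0-179
#' unit scale) if that distance is at most `half_width_units` (default 10
#' units, i.e. a 20-unit / 40-degree total band) and its saturation and value
#' clear the floors; otherwise it is background. Ties break toward the lower
#' class id.
#'
#' @param half_width_units Band half-width on the 0-179 hue scale.
#' @param min_saturation,min_value 8-bit floors (0-255) below which a pixel is
#'   treated as background regardless of hue.
#' @return An object of class `hue_band_rule`.
#' @export
hue_band_rule <- function(half_width_units = 10, min_saturation = 64,
                          min_value = 64) {
  stopifnot(half_width_units > 0, min_saturation >= 0, min_value >= 0)
  structure(list(half_width_units = half_width_units,
                 min_saturation = min_saturation,
                 min_value = min_value),
            class = "hue_band_rule")
}

#' Background sentinel used by the pixel classifier
#' @export
BACKGROUND <- -1L

# Circular hue distance on the 0-180 wrap (OpenCV scale). Vectorised over h.
hue_distance <- function(h, center) {
  d <- abs(h - center) %% 180
  pmin(d, 180 - d)
}

#' Classify one HSV pixel into a lesion class or background
#'
#' @param hsv Numeric triple on the OpenCV integer scales: hue 0-179,
#'   saturation 0-255, value 0-255.
#' @param table Color table as returned by [lesion_color_table()].
#' @param rule A [hue_band_rule()].
#' @return Integer class id in `0:6`, or [BACKGROUND].
#' @export
#' @examples
#' classify_pixel(c(150, 255, 255)) # 6 (Cancer, 300 degrees)
classify_pixel <- function(hsv, table = lesion_color_table(),
                           rule = hue_band_rule()) {
  stopifnot(nrow(table) == 7L)
  if (hsv[2] < rule$min_saturation || hsv[3] < rule$min_value) return(BACKGROUND)
  centers <- table$hue_deg / 2  # degrees -> 0-179 units (may be half-units)
  d <- hue_distance(hsv[1], centers)
  best <- which.min(d)  # which.min takes the first (lowest class id) on ties
  if (d[best] > rule$half_width_units) return(BACKGROUND)
  as.integer(table$class_id[best])
}

# Vectorised decoder for a whole image. `image` is an (H, W, 3) array either
# in [0, 1] doubles or 0-255; returns an (H, W) integer matrix of class ids
# with BACKGROUND elsewhere.
classify_image <- function(image, table = lesion_color_table(),
                           rule = hue_band_rule()) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  d <- dim(image)
  px <- matrix(image, ncol = 3L)
  if (max(px) <= 1) px <- px * 255
  hsv01 <- grDevices::rgb2hsv(t(px), maxColorValue = 255)
  h <- (hsv01[1, ] * 180) %% 180  # fraction of the circle -> 0-179 units
  s <- hsv01[2, ] * 255
  v <- hsv01[3, ] * 255
  centers <- table$hue_deg / 2
  dist <- matrix(vapply(centers, function(ctr) hue_distance(h, ctr),
                        numeric(length(h))),
                 nrow = length(h), ncol = length(centers))
  best <- max.col(-dist, ties.method = "first")
  ok <- dist[cbind(seq_along(h), best)] <= rule$half_width_units &
    s >= rule$min_saturation & v >= rule$min_value
  out <- ifelse(ok, table$class_id[best], BACKGROUND)
  matrix(as.integer(out), nrow = d[1], ncol = d[2])
}

#' Binary mask of one class in an RGB image
#'
#' @param image RGB array `H x W x 3` (values in `[0, 1]` or 0-255).
#' @param class_id Integer class id in `0:6`.
#' @param rule A [hue_band_rule()].
#' @param table Color table.
#' @return Logical `H x W` matrix, `TRUE` where the pixel decodes to
#'   `class_id`.
#' @export
class_mask <- function(image, class_id, rule = hue_band_rule(),
                       table = lesion_color_table()) {
  if (!class_id %in% table$class_id) stop("unknown class_id: ", class_id)
  classify_image(image, table, rule) == class_id
}

#' Export the color table as CSV
#'
#' Writes columns `name, class_id, hue_deg, r, g, b, hex`.
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_color_table <- function(path) {
  tab <- lesion_color_table()
  utils::write.csv(tab[, c("name", "class_id", "hue_deg", "r", "g", "b", "hex")],
                   path, row.names = FALSE)
  invisible(path)
}
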