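#' The heat color scale used for masked expression images
#'
#' Masked ISH expression images encode scalar expression intensity with a
#' "heat" colormap running black -> red -> yellow -> white; pure black means
#' no detected expression. The table is the piecewise-linear path through
#' those anchor colors, sampled at 256 equally spaced positions, so that the
#' entry at position `t = (i - 1)/255` is the color of intensity `t`.
#'
#' @return A 256 x 3 numeric matrix of RGB values in `[0, 1]`, one row per
#'   intensity level; row 1 is black, row 256 white.
#' @seealso [heat_to_intensity()], [intensity_to_heat()]
#' @export
#' @examples
#' tab <- heat_colormap()
#' tab[1, ]    # black
#' tab[256, ]  # white
heat_colormap <- function() {
  t <- (0:255) / 255
  cbind(
    r = pmin(1, 3 * t),
    g = pmin(1, pmax(0, 3 * t - 1)),
    b = pmax(0, 3 * t - 2)
  )
}

#' Render an intensity grid with the heat colormap
#'
#' Maps each intensity to the nearest of the 256 colormap entries, so a
#' round trip through [heat_to_intensity()] recovers intensities to within
#' 1/255.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @return An `H x W x 3` array of RGB values in `[0, 1]`.
#' @export
intensity_to_heat <- function(pixels) {
  check_intensity_matrix(pixels)
  tab <- heat_colormap()
  idx <- round(pixels * 255) + 1L
  out <- array(0, dim = c(nrow(pixels), ncol(pixels), 3L))
  for (ch in 1:3) {
    out[, , ch] <- matrix(tab[idx, ch], nrow(pixels), ncol(pixels))
  }
  out
}

#' Invert the heat colormap to recover scalar intensity
#'
#' Every RGB triplet is mapped to the position of its nearest color (squared
#' Euclidean distance) along the 256-entry heat table, normalized to
#' `[0, 1]`. Nearest-neighbor lookup is robust to small color perturbations
#' from lossy compression. Pure black maps to exactly 0.
#'
#' @param rgb An `H x W x 3` numeric array with values in `[0, 1]`.
#' @return A numeric matrix of intensities in `[0, 1]`.
#' @export
#' @examples
#' img <- intensity_to_heat(matrix(c(0, 1/3, 2/3, 1), 2))
#' heat_to_intensity(img)
heat_to_intensity <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] < 3L) {
    stop("expected an RGB raster (H x W x 3 array)", call. = FALSE)
  }
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  px <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
              as.vector(rgb[, , 3]))
  tab <- heat_colormap()
  # argmin_k |px - tab_k|^2 = argmin_k (|tab_k|^2 - 2 px . tab_k)
  d <- matrix(rowSums(tab^2), nrow(px), 256, byrow = TRUE) -
    2 * (px %*% t(tab))
  idx <- max.col(-d, ties.method = "first")
  matrix((idx - 1) / 255, h, w)
}
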