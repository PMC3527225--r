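#' The five layer classes
#'
#' The four cerebellar layer classes plus the negative (non-localized)
#' class. The molecular class contains genes expressed in the molecular
#' layer and also in the Purkinje layer, because molecular-layer expression
#' almost always includes the Purkinje dendritic arbors' cell bodies.
#'
#' @param include_negative Include the `"negative"` class?
#' @return Character vector of class names.
#' @export
layer_classes <- function(include_negative = TRUE) {
  c("purkinje", "granular", "molecular", "white_matter",
    if (include_negative) "negative")
}

#' Specification of one synthetic gene
#'
#' Draws the per-gene parameters (folded-band geometry, texture, expression
#' level, number of images) that all images of the gene share, from a gene
#' RNG seed. Images of a gene then differ only by per-image jitter
#' (simulating different slices/brains), applied in
#' [generate_gene_images()].
#'
#' The coarse geometry is a sinusoidally folded band skeleton with 2-4
#' "fingers", mimicking the folded cortical sheet of the cerebellum. Each
#' class renders a distinct signature relative to the skeleton:
#' * `purkinje`: a thin bright stripe tracing the band contour
#' * `granular`: a wide band below the stripe filled with dense speckle
#' * `molecular`: the outer band above the stripe plus the stripe itself
#' * `white_matter`: a patchy interior core, deeper than the granular band
#' * `negative`: one of three non-localized sub-patterns
#'   (uniform diffuse field, random blobs, near-blank)
#'
#' @param gene_id Gene identifier string.
#' @param layer One of [layer_classes()].
#' @param n_images Number of images for this gene, in `[2, 8]`. `NULL`
#'   draws uniformly from 2:8.
#' @param intensity_level Peak expression intensity in `[0, 1]`. 0 is the
#'   degenerate blank limit (all images completely black, i.e. excluded by
#'   the blank filter downstream). `NULL` draws from U(0.35, 0.9).
#' @param seed Integer RNG seed; identical spec + seed reproduce identical
#'   images byte-for-byte.
#' @param size Image side length in pixels (square images).
#' @param jitter Named list of per-image jitter amplitudes, see
#'   [jitter_defaults()].
#' @return An object of class `synth_gene_spec`.
#' @export
#' @examples
#' spec <- synth_gene_spec("g1", "purkinje", seed = 1)
#' imgs <- generate_gene_images(spec)
#' length(imgs)
synth_gene_spec <- function(gene_id, layer, n_images = NULL,
                            intensity_level = NULL, seed = 1L,
                            size = 256L, jitter = jitter_defaults()) {
  layer <- match.arg(layer, layer_classes())
  if (!is.null(n_images) &&
      (length(n_images) != 1 || n_images < 2 || n_images > 8)) {
    stop("n_images must be a single integer in [2, 8]", call. = FALSE)
  }
  if (!is.null(intensity_level) &&
      (length(intensity_level) != 1 || intensity_level < 0 ||
       intensity_level > 1)) {
    stop("intensity_level must lie in [0, 1]", call. = FALSE)
  }
  if (size < 32) stop("size must be at least 32 pixels", call. = FALSE)
  with_seed(seed, {
    spec <- list(
      gene_id = as.character(gene_id),
      layer = layer,
      n_images = as.integer(n_images %||% sample(2:8, 1)),
      intensity_level = intensity_level %||% runif(1, 0.35, 0.9),
      shape_params = list(
        fingers = sample(2:4, 1),          # folds of the band skeleton
        amplitude = runif(1, 0.12, 0.20),  # fold depth, image fractions
        phase = runif(1, 0, 2 * pi),
        stripe_hw = runif(1, 0.006, 0.010),   # Purkinje stripe half-width
        gran_width = runif(1, 0.10, 0.15),    # granular band width
        mol_width = runif(1, 0.10, 0.14),     # molecular band width
        wm_depth = runif(1, 0.14, 0.18),      # white-matter core onset
        wm_width = runif(1, 0.10, 0.14)
      ),
      texture_params = list(
        speckle_density = runif(1, 0.45, 0.65),
        grain = sample(1:2, 1),
        neg_pattern = sample(c("diffuse", "blobs", "near_blank"), 1)
      ),
      size = as.integer(size),
      jitter = jitter,
      rng_seed = as.integer(seed)
    )
    structure(spec, class = "synth_gene_spec")
  })
}

#' Default per-image jitter amplitudes
#'
#' Images of one gene come from different slices and brains, so the band
#' shape, size, position and staining intensity vary between them. Each
#' image perturbs the gene's geometry by these amounts (uniform draws in
#' +/- the stated value, multiplicative factors in 1 +/- value) and
#' resamples its texture independently. The magnitudes are free parameters;
#' the defaults produce clearly related but visibly different images.
#'
#' @return Named list of jitter amplitudes.
#' @export
jitter_defaults <- function() {
  list(
    shift_v = 0.03,      # vertical translation, image fractions
    shift_u = 0.04,      # horizontal translation
    phase = 0.25,        # radians added to the fold phase
    amplitude = 0.15,    # multiplicative, fold amplitude
    width = 0.10,        # multiplicative, band widths
    scale_u = 0.10,      # multiplicative, horizontal stretch
    intensity = 0.15     # multiplicative, expression level
  )
}

#' Generate all images of one synthetic gene
#'
#' Renders `spec$n_images` images of the gene's layer pattern, each with
#' independent jitter and texture (see [synth_gene_spec()]). Background
#' pixels outside the expression mask are exactly 0.
#'
#' @param spec A [synth_gene_spec()] object.
#' @return A list of `size x size` numeric matrices with values in
#'   `[0, 1]`.
#' @export
generate_gene_images <- function(spec) {
  if (!inherits(spec, "synth_gene_spec")) {
    stop("spec must be a synth_gene_spec", call. = FALSE)
  }
  with_seed(spec$rng_seed, {
    lapply(seq_len(spec$n_images), function(i) render_synth_image(spec))
  })
}

# One image: draw jitter, then render the layer pattern. Consumes RNG.
render_synth_image <- function(spec) {
  H <- spec$size; W <- spec$size
  sp <- spec$shape_params
  jt <- spec$jitter
  u <- matrix((seq_len(W) - 0.5) / W, H, W, byrow = TRUE)
  v <- matrix((seq_len(H) - 0.5) / H, H, W)

  phase <- sp$phase + runif(1, -jt$phase, jt$phase)
  amp <- sp$amplitude * runif(1, 1 - jt$amplitude, 1 + jt$amplitude)
  dv <- runif(1, -jt$shift_v, jt$shift_v)
  du <- runif(1, -jt$shift_u, jt$shift_u)
  su <- runif(1, 1 - jt$scale_u, 1 + jt$scale_u)
  wmul <- runif(1, 1 - jt$width, 1 + jt$width)
  intens <- spec$intensity_level * runif(1, 1 - jt$intensity, 1 + jt$intensity)
  intens <- min(1, max(0, intens))

  # signed distance to the folded band skeleton; s > 0 is the interior side
  v0 <- 0.5 + dv + amp * sin(2 * pi * sp$fingers * (su * u + du) + phase)
  s <- v - v0

  stripe_hw <- sp$stripe_hw * wmul
  img <- matrix(0, H, W)
  tp <- spec$texture_params

  stripe_vals <- function(mask) {
    # mildly modulated bright stripe
    field <- 0.85 + 0.15 * smooth_noise(H, W, 4)
    ifelse(mask, pmin(1, intens * field), 0)
  }

  if (spec$layer == "purkinje") {
    img <- stripe_vals(abs(s) <= stripe_hw)
  } else if (spec$layer == "granular") {
    gw <- sp$gran_width * wmul
    band <- s > stripe_hw & s <= stripe_hw + gw
    img <- speckle_fill(band, intens, tp$speckle_density, tp$grain, H, W)
  } else if (spec$layer == "molecular") {
    mw <- sp$mol_width * wmul
    outer_band <- s < -stripe_hw & s >= -stripe_hw - mw
    field <- 0.55 + 0.45 * smooth_noise(H, W, 8)
    img <- ifelse(outer_band, pmin(1, intens * 0.8 * field), 0)
    st <- stripe_vals(abs(s) <= stripe_hw)
    img <- pmax(img, st)
  } else if (spec$layer == "white_matter") {
    d0 <- sp$wm_depth * wmul
    core <- s > d0 & s <= d0 + sp$wm_width * wmul
    field <- smooth_noise(H, W, 16)
    img <- ifelse(core & field > 0.25, pmin(1, intens * (0.5 + 0.5 * field)), 0)
  } else { # negative: non-localized patterns
    img <- render_negative(spec, intens, H, W)
  }
  img
}

render_negative <- function(spec, intens, H, W) {
  pat <- spec$texture_params$neg_pattern
  if (pat == "diffuse") {
    field <- smooth_noise(H, W, 8)
    pmin(intens * 0.5 * (0.35 + 0.65 * field), 1)
  } else if (pat == "blobs") {
    blob_field(H, W, n_blobs = sample(4:10, 1),
               r_range = c(0.03, 0.09), intens = intens)
  } else { # near_blank: a couple of faint specks
    blob_field(H, W, n_blobs = sample(2:4, 1),
               r_range = c(0.010, 0.022), intens = intens * 0.6)
  }
}

blob_field <- function(H, W, n_blobs, r_range, intens) {
  u <- matrix((seq_len(W) - 0.5) / W, H, W, byrow = TRUE)
  v <- matrix((seq_len(H) - 0.5) / H, H, W)
  img <- matrix(0, H, W)
  for (b in seq_len(n_blobs)) {
    cu <- runif(1, 0.1, 0.9); cv <- runif(1, 0.1, 0.9)
    r <- runif(1, r_range[1], r_range[2])
    lev <- intens * runif(1, 0.5, 1)
    inside <- (u - cu)^2 + (v - cv)^2 <= r^2
    img[inside] <- pmin(1, pmax(img[inside], lev))
  }
  img
}

# Dense speckle texture inside a mask: Bernoulli grains of `grain` pixels.
speckle_fill <- function(mask, intens, density, grain, H, W) {
  hc <- ceiling(H / grain); wc <- ceiling(W / grain)
  on <- matrix(runif(hc * wc) < density, hc, wc)
  lev <- matrix(runif(hc * wc, 0.5, 1), hc, wc)
  up <- function(m) {
    m2 <- m[rep(seq_len(hc), each = grain), rep(seq_len(wc), each = grain)]
    m2[seq_len(H), seq_len(W), drop = FALSE]
  }
  ifelse(mask & up(on), pmin(1, intens * up(lev)), 0)
}

# Smooth random field in [0,1]: coarse uniform grid upsampled bilinearly.
smooth_noise <- function(H, W, scale) {
  hc <- max(2L, ceiling(H / scale) + 1L)
  wc <- max(2L, ceiling(W / scale) + 1L)
  resize_bilinear(matrix(runif(hc * wc), hc, wc), H, W)
}

resize_bilinear <- function(m, H, W) {
  ry <- seq(1, nrow(m), length.out = H)
  rx <- seq(1, ncol(m), length.out = W)
  y0 <- pmin(floor(ry), nrow(m) - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), ncol(m) - 1L); fx <- rx - x0
  a <- m[y0, x0]; b <- m[y0, x0 + 1L]
  c_ <- m[y0 + 1L, x0]; d <- m[y0 + 1L, x0 + 1L]
  fxm <- matrix(fx, H, W, byrow = TRUE)
  top <- a + fxm * (b - a)
  bot <- c_ + fxm * (d - c_)
  top + fy * (bot - top)
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_per_class` genes for each of the four layer classes plus
#' `n_negative` negative genes, each with 2-8 images, as PNG files plus a
#' `manifest.csv` (columns `gene_id,label,image_path`) and a `params.json`
#' recording the generation parameters. Fully reproducible under `seed`.
#'
#' @param n_per_class Genes per layer class (at least 5).
#' @param n_negative Number of negative (non-localized) genes.
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if missing).
#' @param colormap `"gray"` writes 8-bit grayscale PNGs; `"heat"` writes
#'   RGB PNGs through the heat colormap (exercising the colormap inverse
#'   on the way back in).
#' @param size Image side length in pixels.
#' @return The manifest as a data frame (invisibly carries the dataset
#'   directory in `attr(, "dir")`).
#' @export
#' @examples
#' \donttest{
#' man <- generate_dataset(5, 10, seed = 7, out_dir = tempfile(), size = 64)
#' nrow(unique(man["gene_id"]))  # 30 genes
#' }
generate_dataset <- function(n_per_class, n_negative, seed,
                             out_dir, colormap = c("gray", "heat"),
                             size = 256L) {
  colormap <- match.arg(colormap)
  if (n_per_class < 5) stop("n_per_class must be at least 5", call. = FALSE)
  if (n_negative < 0) stop("n_negative must be non-negative", call. = FALSE)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }

  layers <- rep(layer_classes(include_negative = FALSE), each = n_per_class)
  layers <- c(layers, rep("negative", n_negative))
  gene_ids <- unlist(lapply(layer_classes(), function(l) {
    n <- if (l == "negative") n_negative else n_per_class
    sprintf("%s_%03d", l, seq_len(n))
  }))

  rows <- with_seed(seed, {
    gene_seeds <- sample.int(.Machine$integer.max - 1L, length(gene_ids))
    out <- vector("list", length(gene_ids))
    for (g in seq_along(gene_ids)) {
      spec <- synth_gene_spec(gene_ids[g], layers[g], seed = gene_seeds[g],
                              size = size)
      imgs <- generate_gene_images(spec)
      paths <- character(length(imgs))
      for (i in seq_along(imgs)) {
        fn <- sprintf("%s_%02d.png", gene_ids[g], i)
        paths[i] <- file.path("images", fn)
        write_expression_image(imgs[[i]], file.path(img_dir, fn), colormap)
      }
      out[[g]] <- data.frame(gene_id = gene_ids[g], label = layers[g],
                             image_path = paths)
    }
    out
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_per_class = n_per_class, n_negative = n_negative, seed = seed,
         colormap = colormap, size = size),
    file.path(out_dir, "params.json"), auto_unbox = TRUE)
  attr(manifest, "dir") <- out_dir
  manifest
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.csv` with columns
#'   `gene_id,label,image_path`; image paths are resolved relative to the
#'   manifest's directory.
#' @return Manifest data frame with the dataset directory in
#'   `attr(, "dir")`.
#' @export
read_manifest <- function(path) {
  manifest <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "label", "image_path")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  attr(manifest, "dir") <- dirname(normalizePath(path))
  manifest
}
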