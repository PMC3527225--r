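test_that("lbp_code follows the tie and orientation conventions", {
  expect_equal(lbp_code(matrix(0.5, 7, 7), c(4, 4)), 255)
  m <- matrix(0.2, 7, 7); m[4, 4] <- 0.9
  expect_equal(lbp_code(m, c(4, 4)), 0)
  # east neighbor (bit 0) brighter only
  m2 <- matrix(0.5, 7, 7); m2[4, 4] <- 0.6; m2[4, 6] <- 0.9
  expect_equal(lbp_code(m2, c(4, 4)), 1)
  expect_error(lbp_code(matrix(0.5, 7, 7), c(2, 4)), "border")
})

test_that("lbp_code matches a brute-force bilinear oracle on a ramp", {
  ramp <- matrix(rep(seq(0, 1, length.out = 7), each = 7), 7, 7,
                 byrow = TRUE)
  expect_equal(lbp_code(ramp, c(4, 4)), oracle_lbp_code(ramp, 4, 4))
  set.seed(9)
  img <- matrix(runif(49), 7, 7)
  for (rc in list(c(3, 3), c(4, 4), c(5, 3), c(3, 5))) {
    expect_equal(lbp_code(img, rc), oracle_lbp_code(img, rc[1], rc[2]))
  }
})

test_that("histogram of a constant image puts all mass in bin 255", {
  h <- lbp_histogram(matrix(0.5, 64, 64))
  expect_equal(unname(h["255"]), 60 * 60)  # 2-pixel border excluded
  expect_equal(sum(h), 60 * 60)
})

test_that("histogram bins always sum to the interior pixel count", {
  set.seed(4)
  for (dims in list(c(16, 16), c(7, 20), c(31, 9))) {
    img <- matrix(runif(prod(dims)), dims[1], dims[2])
    h <- lbp_histogram(img)
    expect_equal(sum(h), (dims[1] - 4) * (dims[2] - 4))
  }
  expect_error(lbp_histogram(matrix(0.5, 5, 10)), "larger than")
})

test_that("vectorized histogram equals the exhaustive per-pixel oracle", {
  set.seed(7)
  img <- matrix(runif(16 * 16), 16, 16)
  expect_equal(lbp_histogram(img), oracle_lbp_histogram(img))
})

test_that("LBP histograms are invariant to increasing gain/offset maps", {
  # codes compare interpolated neighbor intensities to the center, so any
  # strictly increasing affine rescaling (staining gain and offset, the
  # variation seen across brains) leaves every code unchanged exactly
  set.seed(12)
  for (i in 1:5) {
    img <- matrix(runif(20 * 20), 20, 20)
    h0 <- lbp_histogram(img)
    expect_equal(lbp_histogram(0.2 + 0.5 * img), h0)
    expect_equal(lbp_histogram(0.9 * img), h0)
    expect_equal(lbp_histogram(0.05 + 0.25 * img), h0)
  }
})

test_that("codes at integer-offset neighbors survive any monotone map", {
  # bits 0,2,4,6 sample exact grid pixels; a nonlinear strictly
  # increasing transform cannot flip those comparisons
  set.seed(13)
  img <- matrix(runif(15 * 15), 15, 15)
  axial_bits <- function(m) {
    codes <- cereblayers:::lbp_code_matrix(m)
    bitwAnd(as.integer(codes), as.integer(1 + 4 + 16 + 64))
  }
  expect_equal(axial_bits(img^3), axial_bits(img))
  expect_equal(axial_bits(sqrt(img)), axial_bits(img))
})

test_that("uniform LBP and non-8 neighborhoods are rejected", {
  expect_error(lbp_config(uniform = TRUE), "not supported")
  expect_error(lbp_config(n_neighbors = 16), "must be 8")
})

test_that("feature vectors have the 257-per-level block layout", {
  img <- generate_gene_images(synth_gene_spec("g", "granular", seed = 3,
                                              size = 128))[[1]]
  f1 <- image_features(build_pyramid(img, 1))
  expect_length(f1, 257)
  f3 <- image_features(build_pyramid(img, c(1, 2, 4)))
  expect_length(f3, 3 * 257)
  # first block equals the single-level result on the factor-1 image
  expect_equal(f3[1:257], f1, ignore_attr = TRUE)
  # scaled histogram maximum is exactly 1 in every block
  for (b in 0:2) {
    block <- f3[b * 257 + 1:256]
    expect_equal(max(block), 1)
    expect_true(all(block >= 0 & block <= 1))
  }
  # mean-intensity entries are the raw level means
  expect_equal(f3[257], mean(img))
  expect_equal(f3[2 * 257], mean(downsample(img, 2)))
})

test_that("a constant image yields the degenerate feature block", {
  f <- image_features(build_pyramid(matrix(0.3, 32, 32), 1))
  expect_equal(unname(f[256]), 1)        # bin 255 scaled to 1
  expect_equal(unname(f[1:255]), rep(0, 255))
  expect_equal(unname(f[257]), 0.3)      # raw mean intensity
})

test_that("too-small pyramid levels are reported with their factor", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_error(image_features(build_pyramid(img, c(1, 16))), "16")
})

test_that("featurization is deterministic", {
  img <- generate_gene_images(synth_gene_spec("g", "molecular", seed = 8,
                                              size = 64))[[1]]
  p <- build_pyramid(img, c(1, 2))
  expect_identical(image_features(p), image_features(p))
})
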