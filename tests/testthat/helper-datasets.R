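# Shared fixtures built in code. Expensive objects are memoised in this
# environment so several test files can reuse one computation.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Small on-disk dataset for pipeline tests (64 px, factors up to 4).
small_dataset <- function() {
  memo("small_dataset", {
    man <- generate_dataset(5, 10, seed = 11,
                            out_dir = file.path(tempdir(), "cb_small"),
                            size = 64)
    featurize_manifest(man, factors = c(1, 2, 4))
  })
}

# A tiny featurized "dataset" with hand-made 2-D features: positives and
# negatives drawn from well-separated clusters, several images per gene.
# Fast to evaluate and fully controlled.
toy_dataset <- function(n_pos = 10, n_neg = 15, sep = 3, seed = 5) {
  set.seed(seed)
  rows <- list(); meta <- list()
  gene_ids <- c(sprintf("pos_%02d", seq_len(n_pos)),
                sprintf("neg_%02d", seq_len(n_neg)))
  labs <- rep(c("target", "negative"), c(n_pos, n_neg))
  for (i in seq_along(gene_ids)) {
    n_img <- sample(2:4, 1)
    mu <- if (labs[i] == "target") c(sep, sep) else c(0, 0)
    rows[[i]] <- cbind(rnorm(n_img, mu[1], 0.5), rnorm(n_img, mu[2], 0.5))
    meta[[i]] <- data.frame(gene_id = gene_ids[i],
                            image_id = paste0(gene_ids[i], "_", seq_len(n_img)),
                            label = labs[i])
  }
  structure(list(features = do.call(rbind, rows),
                 meta = do.call(rbind, meta),
                 factors = 1L, config = lbp_config()),
            class = "ish_features")
}

digest_file <- function(path) unname(tools::md5sum(path))

# Config with a single grid point: makes evaluation runs fast and
# deterministic where hyper-parameter search is not under test.
fast_config <- function(seed = 1) {
  image_model_config(grid_C = 1, grid_gamma = 0.5,
                     gene_grid_C = c(0.1, 1), seed = seed)
}
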