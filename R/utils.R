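# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Coerce labels (logical, 0/1, factor or character) to logical "is positive".
# For two-valued factors/characters the positive level must be given.
as_binary <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1", call. = FALSE)
    }
    return(labels == 1)
  }
  labels <- as.character(labels)
  if (is.null(positive)) {
    stop("character/factor labels need an explicit `positive` class",
         call. = FALSE)
  }
  labels == positive
}

check_intensity_matrix <- function(pixels, what = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > 1)) {
    stop(what, " intensities must lie in [0, 1]", call. = FALSE)
  }
  invisible(pixels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
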