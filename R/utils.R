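# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Resize a grayscale matrix m[row, col] to nr x nc. EBImage::resize treats the
# first matrix dimension as its "width", so w/h map to rows/cols here.
resize_gray <- function(m, nr, nc) {
  nr <- max(1L, as.integer(round(nr)))
  nc <- max(1L, as.integer(round(nc)))
  if (nr == nrow(m) && nc == ncol(m)) return(m)
  out <- EBImage::resize(m, w = nr, h = nc)
  clamp(matrix(as.numeric(out), nr, nc), min(m), max(m))
}

flip_lr <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_ud <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

# Run expr with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# (x, y) coordinates (0-based) of foreground pixels of a binary matrix.
mask_xy <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  data.frame(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

as_binary <- function(m) {
  storage.mode(m) <- "integer"
  m[m != 0L] <- 1L
  m
}

new_box <- function(x0, y0, x1, y1, ...) {
  data.frame(x0 = as.integer(x0), y0 = as.integer(y0),
             x1 = as.integer(x1), y1 = as.integer(y1), ...)
}

empty_boxes <- function() new_box(integer(0), integer(0), integer(0), integer(0))

check_box <- function(b, dim = NULL) {
  stopifnot(all(b$x0 < b$x1), all(b$y0 < b$y1))
  if (!is.null(dim))
    stopifnot(all(b$x0 >= 0), all(b$y0 >= 0),
              all(b$x1 <= dim[2]), all(b$y1 <= dim[1]))
  invisible(b)
}
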