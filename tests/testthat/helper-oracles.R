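# Independent oracles implemented in plain R, kept deliberately naive so they
# never share code with the implementation they check.

# 8-connected component labeling by flood fill.
label8_r <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (m[r0, c0] != 0 && lab[r0, c0] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(r0, c0)); lab[r0, c0] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              m[rr, cc] != 0 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive-shift zero-normalized cross-correlation (template fully inside).
zncc_brute <- function(tmpl, img) {
  th <- nrow(tmpl); tw <- ncol(tmpl)
  tz <- tmpl - mean(tmpl); tss <- sum(tz^2)
  best <- -Inf
  for (r in 0:(nrow(img) - th)) for (c in 0:(ncol(img) - tw)) {
    w <- img[(r + 1):(r + th), (c + 1):(c + tw)]
    wz <- w - mean(w); wss <- sum(wz^2)
    if (wss <= 1e-12) next
    best <- max(best, sum(tz * wz) / sqrt(tss * wss))
  }
  best
}

# Rasterize a half-open box onto a grid of given dimensions.
rasterize_box <- function(b, nr, nc) {
  m <- matrix(0L, nr, nc)
  if (b$y1 > b$y0 && b$x1 > b$x0)
    m[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1] <- 1L
  m
}

random_box <- function(nr, nc) {
  x <- sort(sample(0:nc, 2)); y <- sort(sample(0:nr, 2))
  if (x[1] == x[2]) x[2] <- x[2] + 1L
  if (y[1] == y[2]) y[2] <- y[2] + 1L
  data.frame(x0 = x[1], y0 = y[1], x1 = min(x[2], nc), y1 = min(y[2], nr))
}

clamp_test <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

with_fixed_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
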