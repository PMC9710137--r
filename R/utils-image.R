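# Shared low-level raster helpers (translation warp, column-major index math).

# Translate an H x W matrix by (dy, dx) pixels (content moves down/right for
# positive shifts) with bilinear interpolation; pixels sampled from outside
# the source are set to `fill`.
bilinear_translate <- function(m, dy, dx, fill = stats::median(m)) {
  h <- nrow(m); w <- ncol(m)
  if (dy == 0 && dx == 0) return(m)
  r <- matrix(seq_len(h), h, w) - dy
  c <- matrix(rep(seq_len(w), each = h), h, w) - dx
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- matrix(fill, h, w)
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * at(r0, c0) +
    (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) +
    fr * fc * at(r0 + 1, c0 + 1)
}

# linear index (column-major) -> (row, col)
idx_to_rc <- function(idx, h) cbind(((idx - 1L) %% h) + 1L, ((idx - 1L) %/% h) + 1L)
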