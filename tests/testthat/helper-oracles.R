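# Independent brute-force oracles for the morphological primitives. These
# deliberately use the naive fixed-point / frontier-scan formulations so
# they share no code with the implementations they check.

# grayscale reconstruction-by-erosion of (img + h) under img, 8-connectivity,
# by iterating J <- pmax(img, erode8(J)) to a fixed point
oracle_suppress_minima <- function(img, h) {
  J <- img + h
  nr <- nrow(J); nc <- ncol(J)
  repeat {
    Jp <- J
    er <- matrix(Inf, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      sh <- matrix(Inf, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      sh[rs - dr, cs - dc] <- J[rs, cs]
      er <- pmin(er, sh)
    }
    J <- pmax(img, er)
    if (identical(J, Jp)) return(J)
  }
}

# greedy background growth: global-minimum seed (ties -> smallest row-major
# index), admit the 4-neighbour frontier pixel closest to the running mean,
# update the mean, stop when the smallest difference exceeds tol; returns
# the logical foreground mask (complement of the grown region)
oracle_region_grow <- function(img, tol) {
  nr <- nrow(img); nc <- ncol(img)
  rowmajor <- function(idx) ((idx - 1) %% nr) * nc + ((idx - 1) %/% nr) # 0-based
  state <- integer(nr * nc) # 0 free, 1 frontier, 2 region
  ord <- order(as.vector(img), rowmajor(seq_len(nr * nc)))
  cur <- ord[1]
  s <- 0; n <- 0
  frontier <- integer(0)
  neighbours <- function(idx) {
    r <- ((idx - 1) %% nr) + 1; c <- ((idx - 1) %/% nr) + 1
    out <- integer(0)
    if (r > 1) out <- c(out, idx - 1)
    if (r < nr) out <- c(out, idx + 1)
    if (c > 1) out <- c(out, idx - nr)
    if (c < nc) out <- c(out, idx + nr)
    out
  }
  repeat {
    state[cur] <- 2
    s <- s + img[cur]; n <- n + 1
    for (nb in neighbours(cur))
      if (state[nb] == 0) { state[nb] <- 1; frontier <- c(frontier, nb) }
    if (!length(frontier)) break
    d <- abs(img[frontier] - s / n)
    best <- frontier[order(d, rowmajor(frontier))][1]
    if (abs(img[best] - s / n) > tol) break
    frontier <- setdiff(frontier, best)
    cur <- best
  }
  matrix(state != 2, nr, nc)
}

# greedy one-to-one matching of detected to true event onsets within tol_s;
# returns c(tp, n_true, n_detected)
match_events <- function(truth, detected, tol_s = 1) {
  tp <- 0L
  for (r in unique(truth$roi_id)) {
    to <- truth$onset_time_s[truth$roi_id == r]
    dd <- detected$onset_time_s[detected$roi_id == r]
    used <- rep(FALSE, length(dd))
    for (t1 in to) {
      j <- which(!used & abs(dd - t1) <= tol_s)
      if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
    }
  }
  c(tp = tp, n_true = nrow(truth), n_detected = nrow(detected))
}

# schema-complete empty event table for tests that need one
empty_event_table_for_test <- function() {
  tibble::tibble(roi_id = integer(), onset_frame = integer(),
                 duration_frames = integer(), onset_time_s = double(),
                 duration_s = double(), motif_id = integer(),
                 peak_correlation = double())
}
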