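# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force or closed form, never by calling the package
# code they are checking.

# closed-form generative EPSC waveform (rise filter x biexponential decay)
oracle_epsc <- function(t, stim_onset, amp_fast, amp_slow, tau_fast,
                        tau_slow, rise_tau) {
  tt <- t - stim_onset
  ifelse(tt < 0, 0,
         (1 - exp(-tt / rise_tau)) *
           (amp_fast * exp(-tt / tau_fast) + amp_slow * exp(-tt / tau_slow)))
}

# printed weighted-tau formula, written out directly
oracle_tau_w <- function(af, as_, tf, ts) {
  tf * (af / (af + as_)) + ts * (as_ / (af + as_))
}

# stack-based flood fill (8-connected), structurally different from the
# package's label-propagation implementation
oracle_flood_fill <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  k <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    stack <- start
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[j] != 0L) next
      lab[j] <- k
      y <- (j - 1L) %% H + 1L
      x <- (j - 1L) %/% H + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W &&
            mask[yy, xx] && lab[yy, xx] == 0L) {
          stack <- c(stack, (xx - 1L) * H + yy)
        }
      }
    }
  }
  lab
}

# component pixel sets in canonical order, for exact set comparison
component_sets <- function(lab) {
  sets <- split(which(lab != 0), lab[lab != 0])
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, min, numeric(1)))])
}

# brute-force pixel count of a rasterized disc
oracle_disc_area <- function(r, cy, cx, size) {
  y <- matrix(seq_len(size), size, size)
  x <- t(y)
  sum((y - cy)^2 + (x - cx)^2 <= r^2)
}

# map detected site centres to generator site ids by nearest position
site_map_by_position <- function(centers, truth_positions, max_dist = 3) {
  vapply(centers, function(ctr) {
    d <- abs(truth_positions - ctr)
    if (min(d) > max_dist) NA_integer_ else which.min(d)
  }, integer(1))
}

# dff_kymograph built directly from a frames x positions ΔF/F0 matrix,
# bypassing the extraction path, for synchrony-only tests
dff_from_matrix <- function(dff, fps = 7, px_size = 10 / 65) {
  structure(list(dff = dff, f0 = rep(1, ncol(dff)),
                 baseline_frames = "constructed", fps = fps,
                 px_size = px_size),
            class = "dff_kymograph")
}
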