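# shared fixtures and independent oracles

tiny_phantom <- function(n = 6)
  make_embryo_phantom(n, image_shape = c(64L, 64L), pixel_scale = 25.6)

one_event_schedule <- function(onset = 5, amplitude = 0.6, duration = 20)
  structure(list(onsets = onset, amplitudes = amplitude, duration = duration,
                 refractory = 0, rate = NA, scenario = "fixture"),
            class = "spike_schedule")

# brute-force flood fill: independent oracle for connected-component
# labeling on small frames
flood_fill_label <- function(bin, connectivity = 8L) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!bin[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
            bin[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nxt
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# canonical noiseless single-event readout at a given rate
canonical_rate_trace <- function(hz, waveform = transient_waveform("cytosol"),
                                 model = aequorin_model(), duration = 20) {
  tc <- ca_timecourse(one_event_schedule(duration = duration), waveform, hz,
                      duration)
  aequorin_emission(tc$ca, 1 / hz, model)$rate
}

# glue two half-field stacks back into one split-field stack
abind_frames <- function(left, right) {
  d <- dim(left)
  out <- array(0, c(d[1], 2 * d[2], d[3]))
  for (f in seq_len(d[3])) out[, , f] <- cbind(left[, , f], right[, , f])
  out
}

# partition two labelings up to label renumbering
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  pos <- a > 0
  pairs <- unique(cbind(a[pos], b[pos]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}
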