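#' Transient detection parameters
#'
#' A suprathreshold region counts as a calcium transient only if it lies
#' over the embryo trunk and is larger than 9 adjacent pixels, i.e. at
#' least `min_component_size = 10` connected pixels. Adjacency defaults to
#' 8-connectivity (diagonals count), the FIJI convention.
#'
#' @param min_component_size smallest accepted component, pixels.
#' @param connectivity 4 or 8.
#' @export
detection_params <- function(min_component_size = 10L, connectivity = 8L) {
  stopifnot(min_component_size >= 1)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(min_component_size = as.integer(min_component_size),
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}

# sparse union-find labeling of TRUE pixels of a logical matrix
label_components <- function(bin, connectivity = 8L) {
  idx <- which(bin)
  lab <- matrix(0L, nrow(bin), ncol(bin))
  if (length(idx) == 0) return(lab)
  h <- nrow(bin)
  pos <- match(seq_len(h * ncol(bin)), idx)  # pixel -> rank among TRUE
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  offs <- list(c(-1L, 0L), c(0L, -1L))
  if (connectivity == 8L) offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L)))
  for (o in offs) {
    nr <- rows + o[1]; nc <- cols + o[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= ncol(bin)
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    nbr <- pos[nidx]
    cur <- which(ok)[!is.na(nbr)]
    nbr <- nbr[!is.na(nbr)]
    for (k in seq_along(cur)) union_(cur[k], nbr[k])
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Detect suprathreshold components in one frame
#'
#' Connected components of pixels strictly above the frame threshold,
#' intersected with the trunk mask; components at or below the minimum
#' size are rejected.
#'
#' @param frame numeric matrix.
#' @param threshold scalar detection threshold for this frame.
#' @param mask logical trunk mask (same shape as `frame`).
#' @param params a [detection_params()].
#' @return list: `labels` (integer matrix, 0 = background, accepted
#'   components renumbered 1..k) and `sizes` (pixels per component).
#' @export
detect_components <- function(frame, threshold, mask,
                              params = detection_params()) {
  if (!all(dim(frame) == dim(mask)))
    stop("frame and mask shapes differ")
  if (sum(mask) == 0) stop("mask is empty")
  lab <- label_components(frame > threshold & mask, params$connectivity)
  if (max(lab) == 0)
    return(list(labels = lab, sizes = integer(0)))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_component_size)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(keep)) out[lab == keep[k]] <- k
  list(labels = out, sizes = sizes[keep])
}

#' Integrated density of detected transients, per frame
#'
#' For each frame, the sum of raw pixel values (no background subtraction)
#' over all accepted components. Frames with no accepted component score
#' zero.
#'
#' @param mov a [movie()].
#' @param bg a `background_estimate` from [frame_thresholds()] (or a
#'   numeric vector of per-frame thresholds).
#' @param mask logical trunk mask.
#' @param params a [detection_params()].
#' @return An `id_trace`: `values` (RLU x pixels per frame) and
#'   `frame_interval`.
#' @export
integrated_density <- function(mov, bg, mask, params = detection_params()) {
  thr <- if (inherits(bg, "background_estimate")) bg$threshold_per_frame else bg
  stopifnot(length(thr) == n_frames(mov))
  vals <- vapply(seq_len(n_frames(mov)), function(f) {
    fr <- mov$frames[, , f]
    det <- detect_components(fr, thr[f], mask, params)
    if (length(det$sizes) == 0) 0 else sum(fr[det$labels > 0L])
  }, numeric(1))
  structure(list(values = vals, frame_interval = mov$frame_interval),
            class = "id_trace")
}

#' Segment an integrated-density trace into events
#'
#' Events are maximal runs of strictly positive trace values; runs
#' separated by at most `merge_gap` zero frames are merged. The peak frame
#' is the earliest maximum within the run.
#'
#' @param values numeric trace (or an `id_trace`).
#' @param merge_gap maximum number of zero frames bridged, >= 0.
#' @return data.frame with `start`, `end`, `peak` (1-based frame indices).
#' @export
segment_events <- function(values, merge_gap = 0L) {
  if (inherits(values, "id_trace")) values <- values$values
  stopifnot(merge_gap >= 0)
  pos <- values > 0
  if (!any(pos)) return(data.frame(start = integer(0), end = integer(0),
                                   peak = integer(0)))
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L <= merge_gap)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
  }
  merged$peak <- vapply(seq_len(nrow(merged)), function(i) {
    seg <- values[merged$start[i]:merged$end[i]]
    merged$start[i] + which.max(seg) - 1L
  }, numeric(1))
  rownames(merged) <- NULL
  merged
}
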