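# Face-region detection, track stabilization and cropping.
#
# The ROI source is pluggable: `auto` runs the built-in skin-chromaticity
# detector frame by frame, `fixed` uses one caller-supplied box for the whole
# clip (the usual choice for synthetic skin-patch clips, whose flat texture a
# feature-based face detector would not fire on). Either way the downstream
# contract is the same: one box per frame, constant size after stabilization.

#' Construct an ROI track
#'
#' @param boxes Integer matrix `T x 4` with columns `x, y, w, h` (0-based
#'   half-open boxes, one row per frame).
#' @param source `"auto"` or `"fixed"`.
#' @param detector_hits Logical vector: did the detector fire on this frame
#'   (before any carry-forward)?
#' @return An object of class `roi_track`.
#' @export
roi_track <- function(boxes, source = c("auto", "fixed"),
                      detector_hits = rep(TRUE, nrow(boxes))) {
  source <- match.arg(source)
  boxes <- as.matrix(boxes)
  if (ncol(boxes) != 4L) stop("boxes must have columns x, y, w, h", call. = FALSE)
  colnames(boxes) <- c("x", "y", "w", "h")
  if (any(boxes[, "w"] <= 0) || any(boxes[, "h"] <= 0))
    stop("all boxes must have positive size", call. = FALSE)
  structure(list(boxes = boxes, source = source,
                 detector_hits = as.logical(detector_hits)),
            class = "roi_track")
}

#' @export
print.roi_track <- function(x, ...) {
  cat(sprintf("<roi_track> %d frames, source=%s, %d distinct boxes, %d detector hits\n",
              nrow(x$boxes), x$source,
              nrow(unique(x$boxes)), sum(x$detector_hits)))
  invisible(x)
}

#' Constant ROI track for a frame stack
#'
#' @param frames A [frame_stack()].
#' @param box A [roi_box()] used for every frame.
#' @return A `fixed`-source [roi_track()].
#' @export
fixed_track <- function(frames, box) {
  stopifnot(inherits(frames, "frame_stack"), inherits(box, "roi_box"))
  nt <- n_frames(frames)
  roi_track(matrix(rep(c(box$x, box$y, box$w, box$h), each = nt), nrow = nt),
            source = "fixed")
}

# --- skin detector -----------------------------------------------------------

# Pixel-level skin classifier: skin reflectance is red-dominant
# (R > G > B with a margin), which separates a skin patch from gray or
# achromatic backgrounds.
skin_mask <- function(r, g, b, r_margin = 0.04, r_min = 0.25) {
  (r > g + r_margin) & (g >= b) & (r > r_min)
}

# Largest 4-connected TRUE component of a logical matrix, via row-run
# union-find. Returns list(x, y, w, h, area) in 0-based half-open
# coordinates, or NULL when the mask is empty.
largest_component_box <- function(mask) {
  H <- nrow(mask)
  run_row <- integer(0); run_c0 <- integer(0); run_c1 <- integer(0)
  for (i in seq_len(H)) {
    row <- mask[i, ]
    if (!any(row)) next
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    run_row <- c(run_row, rep(i, sum(keep)))
    run_c0 <- c(run_c0, starts[keep])
    run_c1 <- c(run_c1, ends[keep])
  }
  nr <- length(run_row)
  if (nr == 0L) return(NULL)
  parent <- seq_len(nr)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  prev <- integer(0)
  for (i in sort(unique(run_row))) {
    cur <- which(run_row == i)
    if (length(prev) && any(run_row[prev] == i - 1L)) {
      for (a in cur) for (b in prev[run_row[prev] == i - 1L]) {
        if (run_c0[a] <= run_c1[b] && run_c1[a] >= run_c0[b]) union2(a, b)
      }
    }
    prev <- cur
  }
  roots <- vapply(seq_len(nr), find, integer(1L))
  areas <- tapply(run_c1 - run_c0 + 1L, roots, sum)
  best <- as.integer(names(areas)[which.max(areas)])
  sel <- roots == best
  x0 <- min(run_c0[sel]); x1 <- max(run_c1[sel])
  y0 <- min(run_row[sel]); y1 <- max(run_row[sel])
  list(x = x0 - 1L, y = y0 - 1L, w = x1 - x0 + 1L, h = y1 - y0 + 1L,
       area = as.integer(areas[as.character(best)]))
}

#' Detect the face region in every frame
#'
#' Runs a skin-chromaticity detector per frame: pixels are classified as skin
#' when red-dominant (`R > G + margin`, `G >= B`, `R` above a floor), and the
#' largest 4-connected skin component's bounding box is kept (when several
#' components compete, the largest-area one wins). Frames where the largest
#' component is smaller than `min_pixels` count as misses; misses carry the
#' last successful box forward, and frames before the first hit use the first
#' successful box. Detection fails with an error when no frame yields a hit.
#'
#' @param frames A [frame_stack()] (RGB).
#' @param detector_cfg Optional list with `r_margin`, `r_min`, `min_pixels`.
#' @return An `auto`-source [roi_track()]; `detector_hits` records the raw
#'   per-frame detection success.
#' @export
detect_face_track <- function(frames, detector_cfg = list()) {
  stopifnot(inherits(frames, "frame_stack"))
  cfg <- utils::modifyList(list(r_margin = 0.04, r_min = 0.25, min_pixels = 16L),
                           detector_cfg)
  nt <- n_frames(frames)
  boxes <- matrix(NA_integer_, nrow = nt, ncol = 4L)
  hits <- logical(nt)
  for (t in seq_len(nt)) {
    fr <- frames$frames[, , , t]
    m <- skin_mask(fr[, , 1L], fr[, , 2L], fr[, , 3L], cfg$r_margin, cfg$r_min)
    comp <- largest_component_box(m)
    if (!is.null(comp) && comp$area >= cfg$min_pixels) {
      boxes[t, ] <- c(comp$x, comp$y, comp$w, comp$h)
      hits[t] <- TRUE
    }
  }
  if (!any(hits)) stop("no face region detected in any frame", call. = FALSE)
  first_hit <- which(hits)[1L]
  for (t in seq_len(nt)) {
    if (!hits[t]) boxes[t, ] <- boxes[if (t < first_hit) first_hit else
      max(which(hits[seq_len(t)])), ]
  }
  roi_track(boxes, source = "auto", detector_hits = hits)
}

#' Stabilize an ROI track with a translation threshold
#'
#' Suppresses detector jitter: the output box stays at the previously
#' committed position until the raw box centre has moved at least
#' `translation_threshold_px` (Euclidean distance) away from it, at which
#' point the raw position is committed. The box size is frozen to the first
#' box's size throughout, so all output boxes share one shape. A threshold of
#' 0 commits every frame (output centres equal raw centres, size still
#' frozen).
#'
#' The threshold trades real-motion tracking against jitter suppression; 10
#' px is a sensible default at 720p and should be scaled with frame height
#' for other resolutions.
#'
#' @param track A raw [roi_track()].
#' @param translation_threshold_px Commit threshold in pixels (>= 0).
#' @return A stabilized [roi_track()] of the same length.
#' @export
stabilize_track <- function(track, translation_threshold_px = 10) {
  stopifnot(inherits(track, "roi_track"))
  if (translation_threshold_px < 0) stop("threshold must be >= 0", call. = FALSE)
  b <- track$boxes
  nt <- nrow(b)
  w0 <- unname(b[1L, "w"]); h0 <- unname(b[1L, "h"])
  cx <- b[, "x"] + b[, "w"] / 2
  cy <- b[, "y"] + b[, "h"] / 2
  out_cx <- numeric(nt); out_cy <- numeric(nt)
  cur_x <- cx[1L]; cur_y <- cy[1L]
  for (t in seq_len(nt)) {
    if (sqrt((cx[t] - cur_x)^2 + (cy[t] - cur_y)^2) >= translation_threshold_px) {
      cur_x <- cx[t]; cur_y <- cy[t]
    }
    out_cx[t] <- cur_x; out_cy[t] <- cur_y
  }
  boxes <- cbind(x = round(out_cx - w0 / 2), y = round(out_cy - h0 / 2),
                 w = rep(w0, nt), h = rep(h0, nt))
  roi_track(boxes, source = track$source, detector_hits = track$detector_hits)
}

#' Crop a frame stack to an ROI track
#'
#' All boxes must share one size (run [stabilize_track()] first for raw auto
#' tracks). Boxes extending past the frame edge are clamped and the crop is
#' padded back to the frozen size by edge replication; a box lying fully
#' outside the frame is an error.
#'
#' @param frames A [frame_stack()].
#' @param track An [roi_track()] with `nrow(boxes) == n` frames.
#' @return A [frame_stack()] of size `h x w x 3 x T` with the same fps.
#' @export
crop_to_roi <- function(frames, track) {
  stopifnot(inherits(frames, "frame_stack"), inherits(track, "roi_track"))
  b <- track$boxes
  nt <- n_frames(frames)
  if (nrow(b) != nt) stop("track length does not match frame count", call. = FALSE)
  if (length(unique(b[, "w"])) != 1L || length(unique(b[, "h"])) != 1L)
    stop("boxes must share one size; stabilize the track first", call. = FALSE)
  d <- dim(frames$frames); H <- d[1L]; W <- d[2L]
  w0 <- unname(b[1L, "w"]); h0 <- unname(b[1L, "h"])
  out <- array(0, dim = c(h0, w0, 3L, nt))
  for (t in seq_len(nt)) {
    x <- unname(b[t, "x"]); y <- unname(b[t, "y"])
    if (x + w0 <= 0 || x >= W || y + h0 <= 0 || y >= H)
      stop(sprintf("box at frame %d lies fully outside the frame", t), call. = FALSE)
    cols <- pmin(pmax((x + 1L):(x + w0), 1L), W)  # clamp = edge replication
    rows <- pmin(pmax((y + 1L):(y + h0), 1L), H)
    out[, , , t] <- frames$frames[rows, cols, , t]
  }
  frame_stack(out, fps = frames$fps, t0 = frames$t0, channels = frames$channels)
}
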