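# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately naive (double loops, direct definitions) so
# they share no code path with the implementation they check.

# All strict local maxima of a vector, by direct scan.
naive_local_maxima <- function(v) {
  which(vapply(seq_along(v), function(i) {
    left <- if (i == 1L) -Inf else v[i - 1L]
    right <- if (i == length(v)) -Inf else v[i + 1L]
    v[i] > left && v[i] >= right
  }, logical(1L)))
}

# Sample entropy by the textbook O(N^2) double loop.
naive_sampen <- function(x, m = 2L, r = 0.2) {
  n <- length(x)
  tol <- r * sd(x)
  count <- function(len) {
    nt <- n - len + 1L
    cnt <- 0L
    for (i in 1:(nt - 1L)) for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + len - 1L)] - x[j:(j + len - 1L)])) < tol) cnt <- cnt + 1L
    }
    cnt
  }
  -log(count(m + 1L) / count(m))
}

# Benjamini-Hochberg by explicit sort / step-up / map back.
brute_bh <- function(p, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  k <- length(p)
  q <- ps * m / seq_len(k)
  if (k > 1L) for (i in (k - 1L):1L) q[i] <- min(q[i], q[i + 1L])
  q <- pmin(q, 1)
  out <- numeric(k)
  out[ord] <- q
  out
}

# A small synthetic video with a known skin patch, short enough for unit
# tests.
tiny_study <- function(duration_s = 30, hr = 72, w = 24, h = 24, seed = 1,
                       depth = 0.05, noise = 0) {
  truth <- generate_rr_series(duration_s, hr, seed = seed)
  synthesize_face_video(truth, fps = 30, width = w, height = h,
                        roi = roi_box(w %/% 4, h %/% 4, w %/% 2, h %/% 2),
                        modulation_depth = depth, noise_sd = noise,
                        seed = seed)
}

# Frame stack filled with a constant colour.
solid_stack <- function(rgb = c(0.5, 0.5, 0.5), h = 16, w = 16, nt = 8, fps = 30) {
  arr <- array(rep(rgb, each = h * w), dim = c(h, w, 3, 1))[, , , rep(1, nt), drop = FALSE]
  frame_stack(array(arr, dim = c(h, w, 3, nt)), fps = fps)
}

# Paint a rectangular patch of a colour onto every frame of a stack.
paint_patch <- function(stack, box, rgb) {
  for (ch in 1:3)
    stack$frames[(box$y + 1):(box$y + box$h), (box$x + 1):(box$x + box$w), ch, ] <- rgb[ch]
  stack
}
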