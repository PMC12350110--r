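# Shared fixtures: all synthetic, built in code at test time.

# Flat-intensity disk image (no additive overlap between disks).
draw_disks <- function(h, w, cx, cy, r, val = 100) {
  img <- matrix(0, h, w)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  n <- max(length(cx), length(cy))
  cx <- rep_len(cx, n); cy <- rep_len(cy, n); r <- rep_len(r, n)
  for (k in seq_len(n)) {
    img[(xs - cx[k])^2 + (ys - cy[k])^2 <= r[k]^2] <- val
  }
  img
}

# A small noiseless field configuration for fast unit tests.
small_field_config <- function(n_cells = 12, field_size_px = c(256L, 256L),
                               ...) {
  sim_config(field_size_px = field_size_px, n_cells = n_cells,
             frac_pyroptotic = 0, frac_apoptotic = 0,
             noise_poisson = FALSE, noise_gaussian_sd = 0, ...)
}
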