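# Shared fixture builders; everything is generated in code at test time.

random_mask <- function(h, w, p = 0.4) {
  matrix(runif(h * w) < p, h, w)
}

disc_mask <- function(r, size = 2 * r + 5) {
  cx <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), size), size, size)
  (xs - cx)^2 + (ys - cx)^2 <= r^2
}

# Brute-force per-pixel confusion oracle (independent loop, no vectorizing).
loop_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] && truth[i, j]) tp <- tp + 1L
      else if (pred[i, j] && !truth[i, j]) fp <- fp + 1L
      else if (!pred[i, j] && truth[i, j]) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

make_pairs <- function(n, img_size = 64, seed_off = 0) {
  lapply(seq_len(n), function(i)
    render_rosette(rosette_spec(
      target_pa = (0.04 + 0.03 * (i %% 10)) * img_size^2,
      n_leaves = 4 + i %% 6,
      img_size = img_size, seed = i + seed_off)))
}

tray_fixture <- function(n_cells = 8, cell = 96L, margin = 32L,
                         target_pa = 3500, seed_off = 0) {
  lapply(seq_len(n_cells), function(i)
    render_rosette(rosette_spec(target_pa, n_leaves = 10, aspect = 0.8,
                                img_size = cell, seed = i + seed_off)))
}
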