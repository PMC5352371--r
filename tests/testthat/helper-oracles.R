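# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: the contraction oracle rebuilds the
# smoothed-interface definition with plain R loops and exhaustive distance
# search, the AUC oracle counts positive-negative pairs directly, and the
# DeLong variance oracle bootstraps.

# brute-force contraction: anti-alias the mask with a half-voxel Gaussian on
# a 2x refined lattice (direct triple-loop convolution), threshold at 0.5,
# then exhaustively compute each coarse voxel's representative-fine-sample
# distance to every fine background sample (plus the virtual outside layer)
brute_force_contract <- function(mask, depth_mm) {
  d <- dim(mask)
  sp <- mask_spacing(mask)
  m <- 2L * d
  R <- 4L # kernel radius = 4 sigma, sigma = 1 fine sample (= spacing/2 mm)
  w1 <- exp(-((-R:R))^2 / 2)
  w1 <- w1 / sum(w1)

  fine <- array(0, m)
  for (x in seq_len(m[1])) {
    for (y in seq_len(m[2])) {
      for (z in seq_len(m[3])) {
        fine[x, y, z] <- as.numeric(mask[(x + 1) %/% 2, (y + 1) %/% 2, (z + 1) %/% 2])
      }
    }
  }
  conv_axis <- function(arr, axis) {
    out <- array(0, dim(arr))
    n <- dim(arr)[axis]
    for (k in seq_len(n)) {
      js <- (k - R):(k + R)
      ok <- js >= 1 & js <= n
      sl <- 0
      for (ji in seq_along(js)) {
        if (!ok[ji]) next
        idx <- switch(axis,
          `1` = arr[js[ji], , , drop = FALSE],
          `2` = arr[, js[ji], , drop = FALSE],
          `3` = arr[, , js[ji], drop = FALSE]
        )
        sl <- sl + w1[ji] * idx
      }
      switch(axis,
        `1` = out[k, , ] <- sl,
        `2` = out[, k, ] <- sl,
        `3` = out[, , k] <- sl
      )
    }
    out
  }
  field <- conv_axis(conv_axis(conv_axis(fine, 1L), 2L), 3L)
  fg_fine <- field >= 0.5

  fsp <- sp / 2
  # fine background coordinates, including a one-sample virtual outside ring
  bg_idx <- which(!fg_fine)
  bg_co <- (arrayInd(bg_idx, m) - 1) %*% diag(fsp)
  pad <- expand.grid(x = 0:(m[1] + 1), y = 0:(m[2] + 1), z = 0:(m[3] + 1))
  on_ring <- pad$x %in% c(0, m[1] + 1) | pad$y %in% c(0, m[2] + 1) |
    pad$z %in% c(0, m[3] + 1)
  ring_co <- as.matrix(pad[on_ring, ] - 1) %*% diag(fsp)
  bg_all <- rbind(bg_co, ring_co)

  keep <- array(FALSE, d)
  for (i in which(mask)) {
    ci <- arrayInd(i, d)
    fine_rep <- (2 * (ci - 1)) * fsp # representative fine sample
    d2 <- (bg_all[, 1] - fine_rep[1])^2 + (bg_all[, 2] - fine_rep[2])^2 +
      (bg_all[, 3] - fine_rep[3])^2
    keep[i] <- min(d2) > depth_mm^2
  }
  seg_mask(keep, spacing = sp)
}

# pairwise-counting AUC: mean over positive-negative pairs of
# 1[pos > neg] + 0.5 * 1[pos == neg]
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# bootstrap variance of the AUC difference between two paired scores
bootstrap_var_auc_diff <- function(a, b, labels, n_boot = 10000, seed = 1) {
  withr::with_seed(seed, {
    n <- length(labels)
    diffs <- replicate(n_boot, {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(labels[idx])) < 2) {
        return(NA_real_)
      }
      roc(a[idx], labels[idx], "as_is")$auc - roc(b[idx], labels[idx], "as_is")$auc
    })
    stats::var(diffs, na.rm = TRUE)
  })
}

# small deterministic masks used in several files
tiny_box_mask <- function(n = 5, spacing = c(1, 1, 1)) {
  seg_mask(array(1L, c(n, n, n)), spacing = spacing)
}

single_voxel_mask <- function(spacing = c(1, 1, 1)) {
  a <- array(0L, c(3, 3, 3))
  a[2, 2, 2] <- 1L
  seg_mask(a, spacing = spacing)
}
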