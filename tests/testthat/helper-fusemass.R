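# shared fixtures and independent oracles, built in code

# brute-force bounding box: scan every voxel, track per-axis min/max (0-based)
oracle_bounding_box <- function(mask_arr) {
  d <- dim(mask_arr)
  mins <- d; maxs <- c(-1L, -1L, -1L)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask_arr[i, j, k] != 0) {
      mins <- pmin(mins, c(i, j, k)); maxs <- pmax(maxs, c(i, j, k))
    }
  }
  list(min_index = mins - 1L, max_index = maxs - 1L)
}

# O(n^2) concordant-pair AUC, ties count one half
oracle_auc_pairs <- function(score, truth) {
  pos <- score[truth]; neg <- score[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# direct double-loop 3x3 correlation with edge-replicating padding
oracle_conv3x3 <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (u in -1:1) for (v in -1:1) {
      ii <- min(max(i + u, 1L), nr); jj <- min(max(j + v, 1L), nc)
      acc <- acc + kern[u + 2, v + 2] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# voxel-face surface area and volume of a binary mask (unit voxels)
mask_surface_volume <- function(m) {
  d <- dim(m)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  faces <- 0
  for (axis in 1:3) {
    dif <- switch(axis,
                  pad[-1, , ] - pad[-(d[1] + 2), , ],
                  pad[, -1, ] - pad[, -(d[2] + 2), ],
                  pad[, , -1] - pad[, , -(d[3] + 2)])
    faces <- faces + sum(abs(dif))
  }
  list(area = faces, volume = sum(m))
}

random_mask <- function(dim3 = c(12L, 14L, 10L), n_pts = 5L) {
  m <- array(0, dim3)
  idx <- cbind(sample(dim3[1], n_pts, TRUE), sample(dim3[2], n_pts, TRUE),
               sample(dim3[3], n_pts, TRUE))
  m[idx] <- 1
  m
}

# small reduced network config for fast training-path tests
tiny_net_config <- function(in_channels = 8L) {
  fusemass:::.scaled_config(run_config(target_side = 16L), in_channels)
}

# a small phantom tensor cohort shared by training tests; cached so test
# blocks reusing the same configuration do not re-render
.phantom_cache <- new.env(parent = emptyenv())
make_phantom_tensors <- function(n, difficulty = 5, seed = 101,
                                 scenario = "standard",
                                 modalities = c("T2WI", "nonfs_T1WI",
                                                "d1", "d2"),
                                 fuse_modalities = NULL,
                                 include_sobel = TRUE) {
  key <- paste(n, difficulty, seed, scenario,
               paste(modalities, collapse = "+"),
               paste(fuse_modalities %||% "all", collapse = "+"),
               include_sobel, sep = "|")
  if (!is.null(.phantom_cache[[key]])) return(.phantom_cache[[key]])
  coh <- generate_cohort(n, 0.5, difficulty = difficulty, seed = seed,
                         modalities = modalities, scenario = scenario)
  tens <- cohort_tensors(coh, target_side = 16L,
                         include_sobel = include_sobel,
                         modalities = fuse_modalities)
  out <- list(tensors = tens,
              labels = vapply(tens, function(t) t$label, ""),
              ids = vapply(tens, function(t) t$case_id, ""))
  .phantom_cache[[key]] <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pooled_oof_auc <- function(cv) {
  roc_auc(scored_cohort(cv$oof_scores$case_id, cv$oof_scores$label,
                        cv$oof_scores$P2))$auc
}
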