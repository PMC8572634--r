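# Shared fixtures: everything is generated in code at test time.

# quiet, noise-free small phantom for geometry checks
quiet_phantom <- function(shape = 64L, spacing = 1.0, seed = 11L, ...) {
  generate_phantom(phantom_spec(volume_shape = rep(shape, 3L),
                                spacing_mm = spacing, noise_sd = 0,
                                bias_field_amplitude = 0, seed = seed, ...))
}

# statuses with every segment absent except `keep`
only_segments <- function(keep) {
  st <- setNames(rep("absent", length(cow_segment_names())),
                 cow_segment_names())
  st[keep] <- "normal"
  as.list(st)
}

# independent brute-force rasterisation oracle: a voxel is foreground iff its
# centre lies within radius_profile[t] of some centreline sample t of a
# non-absent segment (pure R, per-sample bounding boxes, no shared code with
# the C++ rasteriser)
brute_force_mask <- function(phantom) {
  d <- dim(phantom$mask$data)
  sp <- phantom$mask$spacing_mm
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  inside <- array(FALSE, d)
  for (seg in phantom$tree) {
    if (seg$status == "absent") next
    pts <- seg$centerline
    r <- seg$radius_profile
    for (t in seq_len(nrow(pts))) {
      if (r[t] <= 0) next
      idx <- lapply(1:3, function(a) which(abs(ax[[a]] - pts[t, a]) <= r[t]))
      if (any(lengths(idx) == 0)) next
      d2 <- outer(outer((ax[[1]][idx[[1]]] - pts[t, 1])^2,
                        (ax[[2]][idx[[2]]] - pts[t, 2])^2, "+"),
                  (ax[[3]][idx[[3]]] - pts[t, 3])^2, "+")
      cur <- array(inside[idx[[1]], idx[[2]], idx[[3]]], dim = dim(d2))
      inside[idx[[1]], idx[[2]], idx[[3]]] <- cur | (d2 <= r[t]^2)
    }
  }
  inside
}

# memoised scaled training experiment shared by the acceptance checks
.experiment_cache <- new.env(parent = emptyenv())
acceptance_experiment <- function() {
  if (is.null(.experiment_cache$res))
    .experiment_cache$res <- compare_baselines(seed = 42L)
  .experiment_cache$res
}
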