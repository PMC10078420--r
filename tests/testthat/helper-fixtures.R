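# Shared small fixtures: a compact grid and phantom keep the simulator and
# pixel-wise fits fast while exercising every pipeline stage.

tiny_grid <- c(32, 21)

tiny_seq <- function(...) sequence_params(...)

tiny_phantom <- function(t1s = c(51, 120, 235), grid = tiny_grid,
                         bath_t1 = NULL) {
  geom <- vial_geometry(n_vials = length(t1s), grid = grid, bath_radius = 9,
                        ring_radius = 5.5, vial_radius = 2)
  make_vial_phantom(vial_t1s = t1s, geometry = geom, grid = grid,
                    bath_t1 = bath_t1)
}

# per-vial mean of a map over interior (ground-truth label) pixels
vial_means <- function(map_values, phantom) {
  labs <- phantom$params$label[phantom$params$label > 1]
  vapply(labs, function(l) mean(map_values[phantom$labels == l], na.rm = TRUE),
         0)
}

# 1-pixel band around a logical region's boundary (4-neighbour dilation of
# the edge), used to compare segmentations up to boundary effects
boundary_band <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  shift <- function(m, dx, dy) {
    out <- matrix(FALSE, nx, ny)
    xs <- seq_len(nx) - dx; ys <- seq_len(ny) - dy
    ok_x <- xs >= 1 & xs <= nx; ok_y <- ys >= 1 & ys <= ny
    out[ok_x, ok_y] <- m[xs[ok_x], ys[ok_y]]
    out
  }
  dil <- mask | shift(mask, 1, 0) | shift(mask, -1, 0) |
    shift(mask, 0, 1) | shift(mask, 0, -1)
  ero <- mask & shift(mask, 1, 0) & shift(mask, -1, 0) &
    shift(mask, 0, 1) & shift(mask, 0, -1)
  dil & !ero
}

# direct image_series construction from a pixel-level signal function,
# bypassing k-space (for fit-level tests)
series_from_signal <- function(times, signal_matrix_list, na = NULL) {
  np <- length(times)
  d <- dim(signal_matrix_list[[1]])
  img <- array(0, c(d[1], d[2], np))
  for (k in seq_len(np)) img[, , k] <- signal_matrix_list[[k]]
  structure(list(images = img, times = times,
                 na = if (is.null(na)) rep(1L, np) else na, grid = d),
            class = "image_series")
}
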