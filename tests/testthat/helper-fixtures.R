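# Shared fixtures: small phantoms and deterministic images.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 24), brain_axes = c(2.8, 3.3, 4.5),
               ...)
}

# uniform-scaling displacement field u(x) = (s-1) x on an isotropic grid
scaling_field <- function(s, n = 32, spacing = 1) {
  g <- volume(array(0, c(n, n, n)), spacing = rep(spacing, 3))
  xyz <- voxel_world_coords(g)
  displacement_field(array((s - 1) * xyz, c(n, n, n, 3)),
                     spacing = rep(spacing, 3))
}

rotation_field <- function(theta, n = 32, spacing = 1) {
  g <- volume(array(0, c(n, n, n)), spacing = rep(spacing, 3))
  xyz <- voxel_world_coords(g)
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  u <- t((R - diag(3)) %*% t(xyz))
  displacement_field(array(u, c(n, n, n, 3)), spacing = rep(spacing, 3))
}

interior <- function(d, margin = 1) {
  arr <- array(FALSE, d)
  arr[(1 + margin):(d[1] - margin), (1 + margin):(d[2] - margin),
      (1 + margin):(d[3] - margin)] <- TRUE
  arr
}
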