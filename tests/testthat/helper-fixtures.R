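# shared fixture builders (everything is generated in code; no stored data)

# scattered samples of an arbitrary analytic function over a square box
sample_fn_cloud <- function(f, n = 2000, half = 50, noise_sd = 0, seed = 1) {
  set.seed(seed)
  x <- runif(n, -half, half)
  y <- runif(n, -half, half)
  z <- f(x, y) + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
  leaflet_cloud(cbind(x, y, z))
}

# analytic height field on a grid (bypasses interpolation)
analytic_field <- function(f, half = 50, spacing = 2) {
  g <- grid_spec(c(-half, half), c(-half, half), spacing)
  xy <- expand.grid(x = g$x, y = g$y)
  z <- matrix(f(xy$x, xy$y), length(g$x), length(g$y))
  height_field(g, z)
}

# a generic quadratic for exactness tests
quad_fn <- function(a = 0.01, b = -0.004, cc = 0.006, d = 0.3, e = -0.2,
                    f0 = 5) {
  function(x, y) a * x^2 + b * x * y + cc * y^2 + d * x + e * y + f0
}

# minimal trajectory with scripted head z positions:
# z_heads is n_lipids x n_frames
scripted_head_traj <- function(z_heads, x = NULL, y = NULL) {
  nl <- nrow(z_heads); nf <- ncol(z_heads)
  if (is.null(x)) x <- seq_len(nl) * 10
  if (is.null(y)) y <- rep(0, nl)
  co <- array(0, c(nl, 3, nf))
  for (f in seq_len(nf)) co[, , f] <- cbind(x, y, z_heads[, f])
  lipid_trajectory(co, data.frame(lipid = seq_len(nl), role = "head",
                                  carbon = NA_integer_, name = "PO4"),
                   time = seq_len(nf))
}
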