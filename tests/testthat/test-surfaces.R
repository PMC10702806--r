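test_that("Delaunay interpolation is exact on planes inside the hull", {
  cl <- sample_fn_cloud(function(x, y) 2 * x - y + 3, n = 500, half = 50,
                        seed = 1)
  g <- grid_spec(c(-40, 40), c(-40, 40), spacing = 4)
  f <- interpolate_scattered(cl, g)
  xy <- field_xy(f)
  truth <- 2 * xy$x - xy$y + 3
  expect_true(all(f$valid))
  expect_lt(max(abs(f$z - truth)), 1e-9)
})

test_that("grid cells outside the convex hull are invalid", {
  set.seed(2)
  ang <- runif(200, 0, 2 * pi); rad <- sqrt(runif(200)) * 10
  cl <- leaflet_cloud(cbind(rad * cos(ang), rad * sin(ang), 1))
  g <- grid_spec(c(-30, 30), c(-30, 30), spacing = 5)
  f <- interpolate_scattered(cl, g)
  xy <- field_xy(f)
  expect_true(all(!f$valid[sqrt(xy$x^2 + xy$y^2) > 11]))
  expect_true(any(f$valid))
})

test_that("collinear lateral positions raise a triangulation error", {
  cl <- leaflet_cloud(cbind(1:10, 2 * (1:10), rnorm(10)))
  g <- grid_spec(c(0, 10), c(0, 20), spacing = 2)
  expect_error(interpolate_scattered(cl, g), "triangulation error")
})

test_that("interpolation error on a sphere cap respects the per-triangle bound", {
  sp <- surface_spec("sphere_cap", extent = 150, density = 0.05, R = 320,
                     seed = 3)
  cl <- gen_surface_cloud(sp)
  g <- grid_spec(c(-70, 70), c(-70, 70), spacing = 2)
  f <- interpolate_scattered(cl, g)
  xy <- field_xy(f)
  err <- abs(f$z - surface_height(sp, xy$x, xy$y))
  # brute-force oracle: linear interpolation error on a triangle of diameter h
  # is at most h^2 / 8 * max ||Hessian||; bound the Hessian norm on the cap
  tm <- interp::tri.mesh(cl$x, cl$y)
  tri <- interp::triangles(tm)
  hmax <- 0
  for (t in seq_len(nrow(tri))) {
    p <- cbind(cl$x[tri[t, 1:3]], cl$y[tri[t, 1:3]])
    hmax <- max(hmax, dist(p))
  }
  s_min <- sqrt(320^2 - 2 * 75^2)          # min sqrt(R^2 - r^2) over the box
  hess_bound <- 2 * (1 / s_min + 150^2 / s_min^3)
  expect_lt(max(err[f$valid], na.rm = TRUE), hmax^2 / 8 * hess_bound)
})

test_that("degree-2 LOESS reproduces global quadratics to < 1e-6 A", {
  f <- quad_fn()
  cl <- sample_fn_cloud(f, n = 1000, half = 50, seed = 4)
  g <- grid_spec(c(-40, 40), c(-40, 40), spacing = 5)
  for (span in c(0.2, 0.5, 1)) {
    sm <- loess_smooth(cl, loess_config(span_fraction = span), grid = g)
    xy <- field_xy(sm)
    expect_lt(max(abs(sm$z - f(xy$x, xy$y))), 1e-6)
  }
  # the composed pipeline is exact on planes (linear interpolation step)
  plane <- sample_fn_cloud(function(x, y) 0.5 * x - 2 * y + 1, n = 800,
                           half = 50, seed = 40)
  fl <- fit_leaflet(plane, g)
  xy <- field_xy(fl)
  truth <- 0.5 * xy$x - 2 * xy$y + 1
  expect_lt(max(abs(fl$z[fl$valid] - truth[fl$valid])), 1e-8)
})

test_that("span 1 matches a global quadratic least-squares fit", {
  f <- quad_fn(0.02, 0.01, -0.015, 1, -2, 10)
  cl <- sample_fn_cloud(f, n = 400, half = 30, seed = 5)
  g <- grid_spec(c(-20, 20), c(-20, 20), spacing = 10)
  sm <- loess_smooth(cl, loess_config(span_fraction = 1), grid = g)
  glob <- lm(z ~ poly(x, y, degree = 2, raw = TRUE), data = cl)
  xy <- field_xy(sm)
  pred <- predict(glob, newdata = data.frame(x = as.numeric(xy$x),
                                             y = as.numeric(xy$y)))
  expect_equal(as.numeric(sm$z), as.numeric(pred), tolerance = 1e-6)
})

test_that("local fits agree with an independent weighted lm oracle", {
  set.seed(6)
  cl <- sample_fn_cloud(function(x, y) sin(x / 10) + 0.02 * y^2, n = 600,
                        half = 40, noise_sd = 0.5, seed = 6)
  g <- grid_spec(c(-10, 10), c(-10, 10), spacing = 10)   # 9 nodes
  cfg <- loess_config(span_fraction = 0.3, degree = 2)
  sm <- loess_smooth(cl, cfg, grid = g)
  nodes <- expand.grid(x = g$x, y = g$y)
  k <- ceiling(0.3 * nrow(cl))
  for (i in seq_len(nrow(nodes))) {
    d <- sqrt((cl$x - nodes$x[i])^2 + (cl$y - nodes$y[i])^2)
    idx <- order(d)[1:k]
    w <- (1 - (d[idx] / max(d[idx]))^3)^3
    df <- data.frame(dx = cl$x[idx] - nodes$x[i], dy = cl$y[idx] - nodes$y[i],
                     z = cl$z[idx], w = w)
    fit <- lm(z ~ dx + dy + I(dx^2) + I(dx * dy) + I(dy^2), data = df,
              weights = w)
    expect_equal(as.numeric(sm$z)[i], unname(coef(fit)[1]), tolerance = 1e-8)
  }
})

test_that("LOESS denoises a bump below the noise level", {
  sp <- surface_spec("gaussian_bump", extent = 224, density = 0.1,
                     noise_sd = 1, A = 10, sigma = 40, seed = 7)
  cl <- gen_surface_cloud(sp)    # ~5,000 points
  g <- grid_spec(c(-90, 90), c(-90, 90), spacing = 4)
  sm <- loess_smooth(cl, loess_config(span_fraction = 0.2), grid = g)
  xy <- field_xy(sm)
  rms <- sqrt(mean((sm$z - surface_height(sp, xy$x, xy$y))^2))
  expect_lt(rms, 1)
})

test_that("LOESS is invariant under joint in-plane translation", {
  cl <- sample_fn_cloud(function(x, y) 0.01 * x^2 - 0.3 * y, n = 500,
                        half = 40, noise_sd = 0.3, seed = 8)
  g <- grid_spec(c(-30, 30), c(-30, 30), spacing = 6)
  sm1 <- loess_smooth(cl, grid = g)
  shift <- c(123.4, -56.7)
  cl2 <- leaflet_cloud(cbind(cl$x + shift[1], cl$y + shift[2], cl$z))
  g2 <- grid_spec(c(-30, 30) + shift[1], c(-30, 30) + shift[2], spacing = 6)
  sm2 <- loess_smooth(cl2, grid = g2)
  expect_equal(sm1$z, sm2$z, tolerance = 1e-8)
})

test_that("larger spans reduce the variance of fits to white noise", {
  vars <- sapply(1:8, function(s) {
    cl <- sample_fn_cloud(function(x, y) 0 * x, n = 400, half = 40,
                          noise_sd = 1, seed = 100 + s)
    g <- grid_spec(c(-25, 25), c(-25, 25), spacing = 10)
    small <- loess_smooth(cl, loess_config(span_fraction = 0.1), grid = g)
    large <- loess_smooth(cl, loess_config(span_fraction = 0.6), grid = g)
    c(var(as.numeric(small$z)), var(as.numeric(large$z)))
  })
  expect_lt(mean(vars[2, ]), mean(vars[1, ]))
})

test_that("phosphate height fields average head positions per cell", {
  # constant heads at z = 17 give a constant field
  z <- matrix(17, 25, 4)
  tr <- scripted_head_traj(z, x = runif(25, 0, 100), y = runif(25, 0, 100))
  g <- grid_spec(c(0, 100), c(0, 100), spacing = 20)
  f <- phosphate_height_field(tr, "upper", g)
  expect_true(all(abs(f$z[f$valid] - 17) < 1e-12))
  # single lipid, single frame: exactly one valid cell
  tr1 <- scripted_head_traj(matrix(17, 1, 1), x = 50, y = 50)
  f1 <- phosphate_height_field(tr1, "upper", g)
  expect_equal(sum(f1$valid), 1)
  expect_error(phosphate_height_field(tr1, "lower", g), "selection error")
})

test_that("trajectory head fields recover the generator's bump within noise", {
  # lower leaflet bumped upward at the center; field mean tracks analytic z
  nl <- 400; nf <- 50
  set.seed(9)
  x <- runif(nl, -100, 100); y <- runif(nl, -100, 100)
  mu <- -17 + 5 * exp(-(x^2 + y^2) / (2 * 40^2))
  z <- matrix(rnorm(nl * nf, mean = mu, sd = 1), nl, nf)
  tr <- scripted_head_traj(z, x = x, y = y)
  g <- grid_spec(c(-100, 100), c(-100, 100), spacing = 25)
  f <- phosphate_height_field(tr, "lower", g)
  # per-cell SEM is 1/sqrt(n_cell); compare cell means to analytic surface
  xy <- field_xy(f)
  truth <- -17 + 5 * exp(-(xy$x^2 + xy$y^2) / (2 * 40^2))
  # cell-center vs within-cell positions differ; allow bump gradient slack
  expect_lt(max(abs(f$z[f$valid] - truth[f$valid])), 1.5)
})
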