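# Edge indicator, regional fits, data terms, regularizer flow, and the
# combined evolution step.

test_that("evolution_params validates its invariants", {
  p <- evolution_params()
  expect_s3_class(p, "evolution_params")
  expect_equal(p$alpha, 2); expect_equal(p$lam, 1)
  expect_equal(p$eps, 2); expect_equal(p$dt, 1.5)
  expect_lt(p$dt * p$mu, 0.25)
  expect_error(evolution_params(ksize = 14), "odd")
  expect_error(evolution_params(dt = 2, mu = 0.2), "stability")
  expect_error(evolution_params(lam = -1), "positive")
})

test_that("edge indicator is 1 on flat images and drops with step height", {
  const <- matrix(42, 16, 16)
  expect_equal(edge_indicator(const), matrix(1, 16, 16))

  step_img <- function(h) {
    I <- matrix(100, 32, 32)
    I[, 17:32] <- 100 + h
    I
  }
  g1 <- edge_indicator(step_img(20), 2.5, 15)
  g2 <- edge_indicator(step_img(80), 2.5, 15)
  expect_lt(min(g2), min(g1))
  expect_true(all(g1 > 0 & g1 <= 1))
})

test_that("edge indicator matches the brute-force convolution oracle", {
  I <- random_field(c(16, 16), 21, 0, 255)
  got <- edge_indicator(I, 1.7, 7)
  want <- oracle_edge_indicator(I, 1.7, 7)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("average and median edge kernels are accepted", {
  I <- random_field(c(16, 16), 5, 0, 255)
  for (k in c("average", "median")) {
    g <- edge_indicator(I, 2.5, 5, kernel = k)
    expect_true(all(g > 0 & g <= 1))
  }
})

test_that("regional fits reproduce constants, oracles and global means", {
  const <- matrix(7, 20, 20)
  phi <- sdf_circle(c(20, 20), 6)
  fits <- regional_fits(const, phi)
  expect_equal(fits$f1, const, tolerance = 1e-12)
  expect_equal(fits$f2, const, tolerance = 1e-12)

  # two-region image: fits near the true values away from the boundary
  shape <- c(64, 64)
  phi <- sdf_circle(shape, 20)
  I <- ifelse(phi < 0, 40, 120)
  fits <- regional_fits(I, phi, eps = 8, sigma = 2.5, ksize = 15)
  ctr <- 32
  expect_lt(abs(fits$f1[ctr, ctr] - 40), 1.0)       # deep inside
  expect_lt(abs(fits$f2[3, 3] - 120), 1.0)          # far outside

  # brute-force double-loop oracle on small random instances
  for (seed in c(2, 9)) {
    I <- random_field(c(24, 24), seed, 0, 255)
    phi <- sdf_circle(c(24, 24), 7) + (seed - 5.5) / 10
    got <- regional_fits(I, phi)
    want <- oracle_regional_fits(I, phi, 2, 2.5, 15)
    expect_lt(max(abs(got$f1 - want$f1)), 1e-9)
    expect_lt(max(abs(got$f2 - want$f2)), 1e-9)
  }

  # edge-weighted global fits equal g-weighted means of each region
  I <- random_field(c(16, 16), 3, 0, 255)
  phi <- sdf_circle(c(16, 16), 5)
  g <- edge_indicator(I, 2.5, 9)
  fits <- regional_fits(I, phi, fits_kernel = "edge_weighted_global", g = g)
  m1 <- smoothed_heaviside(-phi, 2, "sine")
  expect_equal(fits$f1[1, 1], sum(g * m1 * I) / sum(g * m1))
  expect_equal(fits$f2[1, 1], sum(g * (1 - m1) * I) / sum(g * (1 - m1)))
  expect_true(all(fits$f1 == fits$f1[1, 1]))

  # degenerate phi with a single saturated membership is rejected
  expect_error(regional_fits(I, matrix(10, 16, 16)), "degenerate")
})

test_that("data terms are the pointwise squared residuals", {
  I <- matrix(100, 5, 5)
  fits <- list(f1 = matrix(40, 5, 5), f2 = matrix(120, 5, 5))
  e <- data_terms(I, fits)
  expect_equal(e$e1, matrix(3600, 5, 5))
  expect_equal(e$e2, matrix(400, 5, 5))
  expect_equal(data_terms(fits$f1, fits)$e1, matrix(0, 5, 5))
  I <- random_field(c(8, 8), 1)
  e <- data_terms(I, list(f1 = random_field(c(8, 8), 2),
                          f2 = random_field(c(8, 8), 3)))
  expect_true(all(e$e1 >= 0) && all(e$e2 >= 0))
})

test_that("distance regularizer vanishes on signed distances", {
  phi <- sdf_line(c(20, 20), 10.5)
  expect_lt(max(abs(distance_regularizer_flow(phi))), 1e-8)

  # constant phi sits in the s = 0 well: flow equals the Laplacian there,
  # which is zero for a constant
  expect_lt(max(abs(distance_regularizer_flow(matrix(5, 10, 10)))), 1e-12)

  # doubling the slope creates |grad| = 2 > 1; the flow must push the
  # regularizer energy down over one explicit step
  phi2 <- 2 * sdf_line(c(20, 20), 10.5)
  flow <- distance_regularizer_flow(phi2)
  reg_energy <- function(p) {
    g <- field_gradient(neumann_extend(p))
    s <- sqrt(g$x^2 + g$y^2)
    sum(ifelse(s <= 1, (1 - cos(2 * pi * s)) / (2 * pi)^2, (s - 1)^2 / 2))
  }
  expect_lt(reg_energy(phi2 + 0.2 * flow), reg_energy(phi2))
})

test_that("evolution step has the ideal fixed point and correct signs", {
  p <- evolution_params(curvature_weight = 0)

  # constant image: both fits equal the image, data flow is exactly zero;
  # a straight-line signed distance annihilates the regularizer.  The
  # step re-imposes the mirrored border, so feed it a field that already
  # satisfies the boundary condition: then phi is unchanged
  shape <- c(32, 32)
  phi <- neumann_extend(sdf_line(shape, 16.5))
  I <- matrix(80, 32, 32)
  g <- edge_indicator(I)
  expect_lt(max(abs(evolution_step(phi, I, g, p) - phi)), 1e-6)

  # contour displaced outward from a dark disk: at pixels matching the
  # outside fit the data force (lam e1 - alpha e2) is positive, pushing
  # phi up (towards outside)
  truth_phi <- sdf_circle(c(64, 64), 15)
  I <- ifelse(truth_phi < 0, 40, 120)
  phi <- sdf_circle(c(64, 64), 20)   # 5 px too wide
  g <- edge_indicator(I)
  fits <- regional_fits(I, phi)
  e <- data_terms(I, fits)
  ring <- truth_phi > 2 & phi < -1   # background wrongly inside
  expect_true(all((p$lam * e$e1 - p$alpha * e$e2)[ring] > 0))
  phi_new <- evolution_step(phi, I, g, p)
  expect_gt(mean(phi_new[ring] - phi[ring]), 0)
})

test_that("data flow cancels when lam = alpha and f1 = f2", {
  p <- evolution_params(alpha = 1, lam = 1, curvature_weight = 0,
                        pre_sigma = 0)
  I <- matrix(55, 24, 24)   # constant: f1 = f2 everywhere
  g <- edge_indicator(I)
  phi <- sdf_circle(c(24, 24), 8)
  fits <- regional_fits(I, phi)
  expect_equal(fits$f1, fits$f2, tolerance = 1e-12)
  e <- data_terms(I, fits)
  expect_equal(p$lam * e$e1 - p$alpha * e$e2, matrix(0, 24, 24))
})

test_that("combined energy is non-increasing along the evolution", {
  ph <- make_disk_phantom()
  p <- evolution_params()
  I <- ph$image
  g <- edge_indicator(I, p$sigma, p$ksize)
  kw <- 2L * ceiling(3 * p$pre_sigma) + 1L
  Id <- ventseg:::conv2(I, gaussian_kernel(p$pre_sigma, kw))
  phi <- initialize_lsf(ph$box, dim(I), p$c0)
  en_first <- level_set_energy(phi, Id, g, p)
  for (i in 1:60) phi <- evolution_step(phi, Id, g, p)
  en <- numeric(11)
  for (i in 1:11) {
    en[i] <- level_set_energy(phi, Id, g, p)
    phi <- evolution_step(phi, Id, g, p)
  }
  expect_true(all(diff(en) <= 1e-6))
  expect_lt(en[1], en_first)
  expect_true(all(is.finite(phi)))
})

test_that("evolution with only the regularizer relaxes a box plateau", {
  # alpha and lam cannot be zero by contract; emulate the pure-regularizer
  # flow by running on a constant image (data terms vanish identically)
  p <- evolution_params(curvature_weight = 0)
  I <- matrix(100, 32, 32)
  g <- edge_indicator(I)
  phi <- initialize_lsf(bounding_box(10, 22, 10, 22), c(32, 32))
  reg_energy <- function(q) {
    gr <- field_gradient(neumann_extend(q))
    s <- sqrt(gr$x^2 + gr$y^2)
    sum(ifelse(s <= 1, (1 - cos(2 * pi * s)) / (2 * pi)^2, (s - 1)^2 / 2))
  }
  e0 <- reg_energy(phi)
  phi <- evolution_step(phi, I, g, p)
  expect_lt(reg_energy(phi), e0)
})
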