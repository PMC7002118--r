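test_that("adjacency weights are the Euclidean edge lengths of the 4-cycle", {
  es <- extreme_set(top = c(0, -5), left = c(-5, 0), bottom = c(0, 5), right = c(5, 0))
  A <- build_adjacency(es)
  expect_true(isSymmetric(A))
  expect_equal(unname(diag(A)), rep(0, 4))
  expect_equal(unname(A[cbind(1:4, c(2, 3, 4, 1))]), rep(sqrt(50), 4))
  expect_equal(A[1, 3], 0)  # non-adjacent pairs carry no edge
  expect_equal(A[2, 4], 0)

  es2 <- extreme_set(top = c(0, -3), left = c(-4, 0), bottom = c(0, 3), right = c(4, 0))
  expect_equal(unname(build_adjacency(es2)[cbind(1:4, c(2, 3, 4, 1))]), rep(5, 4))
})

test_that("coincident extremes warn but keep the matrix symmetric", {
  es <- extreme_set(top = c(2, 3), left = c(0, 3), bottom = c(2, 3), right = c(4, 3))
  expect_warning(A <- build_adjacency(es), "coincident")
  expect_true(isSymmetric(A))
})

test_that("non-finite coordinates are rejected", {
  expect_error(
    build_adjacency(list(top = c(NA, 0), right = c(1, 0), bottom = c(0, 1),
                         left = c(-1, 0))),
    class = "invalid_input")
  expect_error(spectrum_of(matrix(runif(16), 4)), class = "invalid_input")
})

test_that("closed-form spectra: equal and alternating edge weights", {
  # equal-weight cycle w: (2w, 0, 0, -2w)
  es <- extreme_set(top = c(0, -5), left = c(-5, 0), bottom = c(0, 5), right = c(5, 0))
  expect_equal(spectrum_of(build_adjacency(es)), c(sqrt(200), 0, 0, -sqrt(200)),
               tolerance = 1e-9)
  # alternating weights a, b: (a+b, |a-b|, -|a-b|, -(a+b))
  set.seed(1)
  for (k in 1:100) {
    a <- runif(1, 0.5, 20); b <- runif(1, 0.5, 20)
    A <- matrix(0, 4, 4)
    A[1, 2] <- A[2, 1] <- a
    A[2, 3] <- A[3, 2] <- b
    A[3, 4] <- A[4, 3] <- a
    A[4, 1] <- A[1, 4] <- b
    expect_equal(spectrum_of(A), c(a + b, abs(a - b), -abs(a - b), -(a + b)),
                 tolerance = 1e-8)
  }
  # degenerate all-zero matrix
  expect_equal(spectrum_of(matrix(0, 4, 4)), rep(0, 4))
})

test_that("spectrum matches the characteristic-polynomial root oracle", {
  set.seed(2)
  for (k in 1:1000) {
    es <- random_extreme_set()
    A <- build_adjacency(es)
    sp <- spectrum_of(A)
    expect_equal(sp, oracle_spectrum(A), tolerance = 1e-8)
    expect_lt(abs(sum(sp)), 1e-9)               # zero trace
    expect_equal(sp[1], -sp[4], tolerance = 1e-8)  # bipartite symmetry
    expect_equal(sp[2], -sp[3], tolerance = 1e-8)
  }
})

test_that("spectrum is invariant to rigid motions and scales linearly", {
  set.seed(3)
  for (k in 1:1000) {
    es <- random_extreme_set()
    sp <- extreme_spectrum(es)
    th <- runif(1, 0, 2 * pi); tr <- runif(2, -100, 100)
    refl <- sample(c(1, -1), 1)
    R <- matrix(c(cos(th), sin(th), -refl * sin(th), refl * cos(th)), 2)
    moved <- lapply(es[c("top", "left", "bottom", "right")],
                    function(p) as.numeric(R %*% p + tr))
    sp2 <- spectrum_of(build_adjacency(moved))
    expect_equal(sp, sp2, tolerance = 1e-8)
    k_ <- runif(1, 0.1, 10)
    scaled <- lapply(es[c("top", "left", "bottom", "right")], function(p) k_ * p)
    sp3 <- spectrum_of(build_adjacency(scaled))
    expect_equal(sp3, k_ * sp, tolerance = 1e-8 * max(1, abs(k_ * sp[1])))
  }
})

test_that("spectrum distance is a metric on sorted spectra", {
  expect_identical(spectrum_distance(c(3, 1, -1, -3), c(3, 1, -1, -3)), 0)
  expect_equal(spectrum_distance(c(10, 0, 0, -10), c(7, 1, -1, -7)), sqrt(20))
  set.seed(4)
  for (k in 1:100) {
    s1 <- sort(rnorm(4), decreasing = TRUE)
    s2 <- sort(rnorm(4), decreasing = TRUE)
    s3 <- sort(rnorm(4), decreasing = TRUE)
    expect_equal(spectrum_distance(s1, s2), spectrum_distance(s2, s1))
    expect_lte(spectrum_distance(s1, s3),
               spectrum_distance(s1, s2) + spectrum_distance(s2, s3) + 1e-12)
  }
})

test_that("single-instance reference has zero radius at its own spectrum", {
  es <- random_extreme_set()
  ref <- build_reference(list(es), class = "x", radius_rule = "max")
  expect_equal(ref$centroid, extreme_spectrum(es))
  expect_equal(ref$radius, 0)
  v <- verify_spectrum(extreme_spectrum(es), ref)
  expect_true(v$accepted)
  expect_equal(v$distance, 0)
})

test_that("congruent instances give identical spectra and zero radius", {
  set.seed(5)
  base <- random_extreme_set()
  sets <- lapply(1:20, function(k) {
    th <- runif(1, 0, 2 * pi); tr <- runif(2, -50, 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    lapply(base[c("top", "left", "bottom", "right")],
           function(p) as.numeric(R %*% p + tr))
  })
  ref <- build_reference(sets, radius_rule = "max")
  expect_lt(ref$radius, 1e-8)
})

test_that("max-rule reference covers all its training spectra", {
  set.seed(6)
  sets <- lapply(1:200, function(k) {
    r <- 10 * runif(1, 0.9, 1.1)  # 10% size jitter
    extreme_points(make_shape(shape_spec("ellipse", center = runif(2, 20, 40),
                                         size = c(a = r, b = r * 0.8),
                                         orientation = runif(1, 0, 2 * pi)), 64L))
  })
  ref <- build_reference(sets, radius_rule = "max")
  for (es in sets) {
    expect_true(verify_spectrum(extreme_spectrum(es), ref)$accepted)
  }
  # quantile rule leaves at most 5% (x multiplier slack) outside
  refq <- build_reference(sets, radius_rule = "quantile", q = 0.95)
  inside <- vapply(sets, function(es)
    verify_spectrum(extreme_spectrum(es), refq)$accepted, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("a doubled-scale candidate is rejected, infinite radius accepts all", {
  set.seed(7)
  sets <- lapply(1:50, function(k) random_extreme_set())
  # congruent training shapes: tight reference
  base <- sets[[1]]
  congruent <- lapply(1:20, function(k) {
    tr <- runif(2, -50, 50)
    lapply(base[c("top", "left", "bottom", "right")], function(p) p + tr)
  })
  ref <- build_reference(congruent, radius_rule = "max")
  big <- lapply(base[c("top", "left", "bottom", "right")], function(p) 2 * p)
  v <- verify_spectrum(spectrum_of(build_adjacency(big)), ref)
  expect_false(v$accepted)
  # eigenvalues scale linearly, so the distance is the centroid norm itself
  expect_equal(v$distance, sqrt(sum(ref$centroid^2)), tolerance = 1e-6)
  ref_inf <- ref; ref_inf$radius <- Inf
  for (es in sets) {
    expect_true(verify_spectrum(extreme_spectrum(es), ref_inf)$accepted)
  }
})

test_that("empty annotation sets are rejected", {
  expect_error(build_reference(list()), class = "invalid_input")
})

test_that("perimeter-normalized spectra are magnification invariant", {
  es <- random_extreme_set()
  sp1 <- extreme_spectrum(es, normalize = TRUE)
  big <- es
  for (nm in c("top", "left", "bottom", "right")) big[[nm]] <- 3 * es[[nm]]
  sp2 <- extreme_spectrum(big, normalize = TRUE)
  expect_equal(sp1, sp2, tolerance = 1e-10)
})
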