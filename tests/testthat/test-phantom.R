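test_that("noise-free phantom takes exactly the three base levels", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0))
  lv <- sort(unique(as.vector(ph$image$pixels)))
  expect_identical(lv, c(25L, 100L, 180L))
  expect_identical(ph$image$pixels[ph$pectoral_mask],
                   rep(180L, sum(ph$pectoral_mask)))
  expect_true(ph$pectoral_mask[1, 1]) # wedge reaches the top corner
  expect_false(ph$pectoral_mask[nrow(ph$image$pixels), 1])
})

test_that("mass mask is the analytic half-maximum disc", {
  m <- c(64, 64, 6, 80)
  ph <- generate_phantom(phantom_spec(masses = list(m), noise_sigma = 0))
  rows <- matrix(seq_len(128), 128, 128)
  cols <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  disc <- (rows - m[1])^2 + (cols - m[2])^2 <= 2 * log(2) * m[3]^2
  expect_identical(ph$mass_mask, disc)
  # radius matches sigma * sqrt(2 log 2)
  expect_equal(max(abs(which(ph$mass_mask, arr.ind = TRUE)[, 1] - 64)),
               floor(m[3] * sqrt(2 * log(2))))
})

test_that("phantoms are seed-reproducible and leave the RNG untouched", {
  spec <- phantom_spec(masses = list(c(60, 60, 5, 90)), noise_sigma = 5,
                       seed = 99L)
  a <- generate_phantom(spec)
  set.seed(123)
  expected_draw <- runif(1)
  set.seed(123)
  b <- generate_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_equal(runif(1), expected_draw) # caller's stream unaffected
  c2 <- generate_phantom(phantom_spec(masses = list(c(60, 60, 5, 90)),
                                      noise_sigma = 5, seed = 100L))
  expect_false(identical(a$image$pixels, c2$image$pixels))
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(background_level = 120, breast_level = 100),
               "levels")
  expect_error(phantom_spec(masses = list(c(2, 125, 5, 50))), "silhouette")
  expect_error(phantom_spec(masses = list(c(10, 6, 6, 80))), "pectoral")
  expect_error(phantom_spec(masses = list(c(64, 64, -1, 50))), "sigma")
  expect_error(phantom_spec(noise_sigma = -2), "noise_sigma")
})

test_that("phantom suites are varied, reproducible and masked consistently", {
  s1 <- phantom_suite(8, master_seed = 5)
  s2 <- phantom_suite(8, master_seed = 5)
  s3 <- phantom_suite(8, master_seed = 6)
  expect_length(s1, 8)
  expect_identical(s1[[3]]$image$pixels, s2[[3]]$image$pixels)
  expect_false(all(mapply(function(a, b) identical(a$image$pixels,
                                                   b$image$pixels), s1, s3)))
  expect_length(s1[[1]]$spec$masses, 0) # negative case always present
  for (ph in s1) {
    expect_true(all(ph$mass_mask[ph$mass_mask] &
                      ph$breast_mask[ph$mass_mask]))
    expect_false(any(ph$mass_mask & ph$pectoral_mask))
    expect_true(all(ph$image$pixels >= 0 &
                      ph$image$pixels <= ph$spec$max_level))
  }
})

test_that("recovery suite delivers single conspicuous masses", {
  rs <- phantom_recovery_suite(6, master_seed = 3, noise_sigma = 0)
  expect_length(rs, 6)
  for (ph in rs) {
    expect_length(ph$spec$masses, 1)
    m <- ph$spec$masses[[1]]
    expect_true(m[3] >= 4 && m[3] <= 7)
    expect_true(m[4] >= 100 && m[4] <= 160)
  }
  rs2 <- phantom_recovery_suite(6, master_seed = 3, noise_sigma = 0)
  expect_identical(rs[[5]]$image$pixels, rs2[[5]]$image$pixels)
})
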