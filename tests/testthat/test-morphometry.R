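test_that("classify_spine matches the worked examples", {
  expect_identical(classify_spine(2.5, 0.4, 1), "filopodia")
  expect_identical(classify_spine(1.5, 0.7, 1), "mushroom")
  expect_identical(classify_spine(1.5, 0.7, 2), "branched")  # heads dominate
  expect_identical(classify_spine(0.4, 0.5, 1), "stubby")    # ratio 0.8 < 1
  expect_identical(classify_spine(0.8, 0.5, 1), "thin")
  expect_identical(classify_spine(1.5, 0.5, 1), "long_thin")
  expect_error(classify_spine(-1, 0.5), "positive")
  expect_error(classify_spine(1, 1, 0), ">= 1")
})

test_that("classifier totality: the decision regions partition the grid", {
  lens <- seq(0.05, 4, length.out = 200)
  wids <- seq(0.05, 2, length.out = 200)
  grid <- expand.grid(length_um = lens, width_um = wids,
                      heads = 1:3)
  cls <- classify_spine(grid$length_um, grid$width_um, grid$heads)
  expect_false(anyNA(cls))
  expect_true(all(cls %in% c("filopodia", "long_thin", "thin", "stubby",
                             "mushroom", "branched")))
  # precedence pinned: each predicate holds on its assigned region
  expect_true(all(grid$heads[cls == "branched"] >= 2))
  one <- grid$heads == 1
  expect_true(all(grid$length_um[one & cls == "filopodia"] > 2))
  expect_true(all(grid$width_um[one & cls == "mushroom"] > 0.6))
  st <- one & cls == "stubby"
  expect_true(all(grid$length_um[st] / grid$width_um[st] < 1))
  th <- one & cls == "thin"
  expect_true(all(grid$length_um[th] < 1 & grid$width_um[th] <= 0.6 &
                    grid$length_um[th] / grid$width_um[th] >= 1))
  lt <- one & cls == "long_thin"
  expect_true(all(grid$length_um[lt] >= 1 & grid$length_um[lt] <= 2 &
                    grid$width_um[lt] <= 0.6))
})

test_that("spine_density normalizes to 50 um and splits consistently", {
  tab <- simulate_spines(c(mushroom = 10, thin = 15), seed = 3)
  d <- spine_density(tab, segment_length_um = 50)
  expect_equal(d$density_per_norm, 25)
  expect_equal(sum(d$composition), 1)
  expect_equal(unname(d$composition["mushroom"]), 10 / 25)

  # splitting a segment and recombining leaves density invariant
  half1 <- tab[1:12, ]
  half2 <- tab[13:25, ]
  d1 <- spine_density(half1, 24)
  d2 <- spine_density(half2, 26)
  combined <- (d1$density_per_norm * 24 + d2$density_per_norm * 26) / 50
  expect_equal(combined, d$density_per_norm)

  # empty segment: zero density, flagged composition
  d0 <- spine_density(tab[0, ], 50)
  expect_equal(d0$density_per_norm, 0)
  expect_true(d0$empty)
})

test_that("aggregate_hierarchy averages unweighted at both levels", {
  # identity: one segment per neuron, one neuron per animal
  df <- data.frame(animal = c("m1", "m2"), neuron = "n1", value = c(3, 5))
  out <- aggregate_hierarchy(df)
  expect_equal(out$mean_value, c(3, 5))

  # unbalanced design: neuron means unweighted by segment count
  df <- data.frame(animal = "m1",
                   neuron = c("n1", "n1", "n1", "n2", "n2"),
                   value = c(1, 2, 3, 10, 20))
  out <- aggregate_hierarchy(df)
  # oracle: mean(mean(1,2,3), mean(10,20)) = mean(2, 15) = 8.5
  expect_equal(out$mean_value, 8.5)
  expect_equal(out$n_neurons, 2)

  # direct two-level arithmetic oracle on a random layout
  set.seed(4)
  df <- data.frame(animal = sample(c("a", "b"), 40, TRUE),
                   neuron = sample(c("n1", "n2", "n3"), 40, TRUE),
                   value = rnorm(40))
  out <- aggregate_hierarchy(df)
  for (an in c("a", "b")) {
    sub <- df[df$animal == an, ]
    oracle <- mean(tapply(sub$value, sub$neuron, mean))
    expect_equal(out$mean_value[out$animal == an], unname(oracle))
  }
})

test_that("roi_mean_intensity matches unit arithmetic and the mask oracle", {
  img <- matrix(5, 40, 40)
  square <- list(x = c(5, 25, 25, 5), y = c(5, 5, 25, 25))
  # uniform image, pixel size 1 um -> v per um^2
  expect_equal(roi_mean_intensity(img, square, 1), 5)
  # pixel size 0.5 um -> area shrinks by 4 -> 4v per um^2
  expect_equal(roi_mean_intensity(img, square, 0.5), 20)

  # random image against a brute-force double-loop mask oracle (exact)
  set.seed(8)
  img <- matrix(runif(1600), 40, 40)
  tri <- list(x = c(3.2, 34.7, 10.1), y = c(4.5, 18.3, 36.2))
  got <- roi_mean_intensity(img, tri, 0.25)
  acc <- 0; cnt <- 0
  for (r in 1:40) for (cc in 1:40) {
    # point-in-polygon by winding of angles (independent method)
    px <- cc - 0.5; py <- r - 0.5
    ang <- atan2(tri$y - py, tri$x - px)
    ang <- c(ang, ang[1])
    w <- sum(((diff(ang) + pi) %% (2 * pi)) - pi)
    if (abs(w) > pi) { acc <- acc + img[r, cc]; cnt <- cnt + 1 }
  }
  expect_identical(got, acc / (cnt * 0.25^2))

  expect_error(roi_mean_intensity(img, list(x = c(-5, 10, 10),
                                            y = c(1, 1, 10)), 1), "bounds")
  expect_error(roi_mean_intensity(img, list(x = c(5, 5.4, 5.2),
                                            y = c(5, 5, 5.4)), 1), "empty ROI")
})

test_that("detect_puncta finds well-separated spots at their centroids", {
  # blank image -> empty set
  expect_equal(nrow(detect_puncta(matrix(0, 50, 50), 0.5)), 0)

  sim <- simulate_puncta_image(field_um = 20, px_size_um = 0.1,
                               n_puncta_a = 12, n_puncta_b = 12,
                               coloc_fraction = 0.5, seed = 10)
  ps <- detect_puncta(sim$channel_a, 0.3, min_area_um2 = 0.02,
                      px_size_um = 0.1)
  expect_equal(nrow(ps), 12)
  # centroids within one pixel of ground truth
  tr <- sim$truth$a_centroids_um
  for (i in seq_len(nrow(ps))) {
    d <- sqrt((tr$x_um - ps$x_um[i])^2 + (tr$y_um - ps$y_um[i])^2)
    expect_lt(min(d), 0.1)
  }

  # a spot below min_area is excluded
  img <- matrix(0, 50, 50)
  img[25, 25] <- 1                       # single-pixel spot: 0.01 um^2
  img[10:13, 10:13] <- 1                 # 16 px: 0.16 um^2
  ps <- detect_puncta(img, 0.5, min_area_um2 = 0.05, px_size_um = 0.1)
  expect_equal(nrow(ps), 1)
  # and max_area excludes the large one
  ps <- detect_puncta(img, 0.5, min_area_um2 = 0, max_area_um2 = 0.05,
                      px_size_um = 0.1)
  expect_equal(nrow(ps), 1)
})

test_that("colocalize matches greedily, symmetrically, within the radius", {
  a <- data.frame(x_um = c(1, 5, 9), y_um = c(1, 1, 1))
  # identical sets: all matched
  m <- colocalize(a, a, max_dist_um = 0.5)
  expect_equal(m$n_matched, 3)
  expect_equal(m$double_positive_per_norm, 3)

  # all farther than the radius: zero
  b <- data.frame(x_um = a$x_um + 2, y_um = a$y_um)
  expect_equal(colocalize(a, b, 0.5)$n_matched, 0)

  # symmetry of the matched count
  set.seed(5)
  a <- data.frame(x_um = runif(30, 0, 20), y_um = runif(30, 0, 20))
  b <- data.frame(x_um = runif(25, 0, 20), y_um = runif(25, 0, 20))
  expect_equal(colocalize(a, b, 1)$n_matched, colocalize(b, a, 1)$n_matched)

  # each punctum used once: pairs are unique
  p <- colocalize(a, b, 2)$pairs
  expect_false(any(duplicated(p$i_a)))
  expect_false(any(duplicated(p$i_b)))

  # generator truth: fraction 0.6 of n = 100 recovered within +/- 2
  sim <- simulate_puncta_image(field_um = 60, px_size_um = 0.2,
                               n_puncta_a = 100, n_puncta_b = 100,
                               coloc_fraction = 0.6, seed = 9)
  pa <- detect_puncta(sim$channel_a, 0.3, min_area_um2 = 0.05,
                      px_size_um = 0.2)
  pb <- detect_puncta(sim$channel_b, 0.3, min_area_um2 = 0.05,
                      px_size_um = 0.2)
  m <- colocalize(pa, pb, max_dist_um = 0.5, segment_length_um = 50)
  expect_lte(abs(m$n_matched - 60), 2)
})
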