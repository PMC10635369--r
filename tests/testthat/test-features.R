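test_that("helix_axis recovers the generator's axis and is equivariant", {
  h <- ideal_helix(12)
  ax <- helix_axis(h, c(0, 11))
  expect_lt(vector_angle(ax$direction, attr(h, "true_axis")), 5)
  # secondary oracle: principal direction of a least-squares line through CAs
  cas <- t(vapply(0:11, function(i) get_residue(h, i)$coords["CA", ], numeric(3)))
  pc <- prcomp(cas)$rotation[, 1]
  expect_lt(min(vector_angle(ax$direction, pc), vector_angle(ax$direction, -pc)), 5)

  R <- seeded_rotation(12)
  ax2 <- helix_axis(transform_chain(h, R, c(4, 4, 4)), c(0, 11))
  expect_equal(ax2$direction, drop(R %*% ax$direction), tolerance = 1e-6)

  expect_error(helix_axis(h, c(0, 3)), "helix too short")
  broken <- h
  broken$coords[[3]] <- broken$coords[[3]][rownames(broken$coords[[3]]) != "O", ]
  expect_error(helix_axis(broken, c(0, 11)), "missing backbone atom O in residue 2")
})

test_that("interhelical_tilt hits 0/90/180 on constructed cases", {
  h <- ideal_helix(10)
  ax <- helix_axis(h, c(0, 9))
  moved <- transform_chain(h, diag(3), c(10, 0, 0))
  expect_equal(interhelical_tilt(ax, helix_axis(moved, c(0, 9))), 0)
  # rotate the axis itself by 90 degrees about a perpendicular direction
  perp_dir <- c(ax$direction[3], 0, -ax$direction[1])  # perpendicular to axis
  b90 <- drop(rotation_matrix(perp_dir, 90) %*% ax$direction)
  expect_equal(interhelical_tilt(ax$direction, b90), 90, tolerance = 1e-9)
  expect_equal(interhelical_tilt(ax$direction, -ax$direction), 180)
  expect_equal(interhelical_tilt(b90, ax$direction),
               interhelical_tilt(ax$direction, b90))
  expect_error(interhelical_tilt(c(0, 0, 0), c(0, 0, 1)), "zero")
})

test_that("pair distance features match brute force and their identity", {
  a <- res_fix(CA = c(0, 0, 0)); b <- res_fix(CA = c(0, 0, 7))
  expect_equal(unname(pair_distance_features(a, b)), c(7, 0, 7))
  expect_error(pair_distance_features(a, res_fix(N = c(1, 1, 1))),
               "missing alpha carbon")

  with_seed(77, {
    for (rep in 1:20) {
      A <- matrix(rnorm(12, sd = 4), 4, 3); rownames(A) <- c("N", "CA", "C", "O")
      B <- matrix(rnorm(12, sd = 4), 4, 3); rownames(B) <- c("N", "CA", "C", "O")
      ra <- residue(A); rb <- residue(B)
      d <- numeric(0)
      for (i in 1:4) for (j in 1:4) d <- c(d, sqrt(sum((A[i, ] - B[j, ])^2)))
      f <- pair_distance_features(ra, rb)
      expect_equal(unname(f["d1_mean"]), mean(d), tolerance = 1e-10)
      expect_equal(unname(f["d1_sd"]), sqrt(sum((d - mean(d))^2) / 16),
                   tolerance = 1e-10)
      expect_equal(unname(f["d_alpha"]), sqrt(sum((A["CA", ] - B["CA", ])^2)))
      # population-SD identity: sd^2 + mean^2 = mean of squared distances
      expect_equal(f[["d1_sd"]]^2 + f[["d1_mean"]]^2, mean(d^2), tolerance = 1e-8)
      # rigid invariance
      R <- rotation_matrix(rnorm(3), runif(1, 0, 360)); t <- rnorm(3, sd = 10)
      tr <- function(M) sweep(M %*% t(R), 2, t, "+")
      f2 <- pair_distance_features(residue(tr(A)), residue(tr(B)))
      expect_equal(f, f2, tolerance = 1e-9)
    }
  })
})

test_that("residue plane normal and relative residue angle behave", {
  r <- res_fix(N = c(1, 0, 0), CA = c(0, 0, 0), C = c(0, 1, 0))
  expect_equal(residue_plane_normal(r), c(0, 0, 1))
  R <- seeded_rotation(9)
  r2 <- residue(r$coords %*% t(R))
  expect_equal(residue_plane_normal(r2), drop(R %*% c(0, 0, 1)),
               tolerance = 1e-9)
  expect_error(residue_plane_normal(
    res_fix(N = c(1, 0, 0), CA = c(0, 0, 0), C = c(2, 0, 0))), "degenerate plane")

  a <- full_res(c(0, 0, 0))
  expect_equal(relative_residue_angle(a, a), 0)
  moved <- residue(sweep(a$coords, 2, c(5, 5, 5), "+"))
  expect_equal(relative_residue_angle(a, moved), 0, tolerance = 1e-9)
  # independent-implementation oracle on a rotated copy
  rot <- residue(a$coords %*% t(rotation_matrix(c(0, 1, 0), 64)))
  n1 <- residue_plane_normal(a); n2 <- residue_plane_normal(rot)
  oracle <- acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
  expect_equal(relative_residue_angle(a, rot), oracle)
  expect_equal(relative_residue_angle(rot, a), oracle)
})

test_that("sdf_vector is length 40, constant in theta slots, rigid-invariant", {
  b <- two_helix_chain()
  cp <- candidate_pairs(b$chain, b$annotation)
  pair <- cp[cp$i >= 2 & cp$j <= max(cp$j) - 2, ][5, ]
  v <- sdf_vector(b$chain, b$annotation, pair)
  expect_length(v, 40)
  theta_slots <- v[seq(1, 40, by = 5)]
  expect_true(all(theta_slots == theta_slots[1]))  # exact equality by design

  R <- seeded_rotation(21)
  ch2 <- transform_chain(b$chain, R, c(7, -2, 13))
  expect_equal(unname(sdf_vector(ch2, b$annotation, pair)), unname(v),
               tolerance = 1e-6)

  # a window touching the chain terminus is an incomplete neighborhood
  first <- cp[cp$i == 0, ][1, ]
  expect_error(sdf_vector(b$chain, b$annotation, first), class = "incomplete_neighborhood")
})

test_that("cf_vector is length 192, translation-equivariant, glycine falls back", {
  b <- two_helix_chain()
  cp <- candidate_pairs(b$chain, b$annotation)
  pair <- cp[cp$i >= 2 & cp$j <= max(cp$j) - 2, ][6, ]
  v <- cf_vector(b$chain, pair)
  expect_length(v, 192)
  shifted <- transform_chain(b$chain, diag(3), c(10, 0, 0))
  v2 <- cf_vector(shifted, pair)
  xs <- seq(1, 192, by = 3)
  expect_equal(v2[xs], v[xs] + 10, tolerance = 1e-9)
  expect_equal(v2[-xs], v[-xs], tolerance = 1e-9)

  gly <- b$chain
  k <- pair$i + 1L  # 0-based -> list slot of residue i
  gly$coords[[k]] <- gly$coords[[k]][rownames(gly$coords[[k]]) != "CB", ]
  gly$residues$aa[k] <- "G"
  vg <- cf_vector(gly, pair)
  # the CB slot of residue i (window position where di = 0 occurs at w4: (0,-1))
  # equals its CA coordinates
  blocks <- matrix(vg, nrow = 24)  # one column per window position
  ca <- gly$coords[[k]]["CA", ]
  expect_equal(unname(blocks[10:12, 4]), unname(ca), tolerance = 1e-12)  # CB slot, residue i
  expect_equal(unname(blocks[4:6, 4]), unname(ca), tolerance = 1e-12)    # CA slot agrees
})

test_that("feature matrix assembly skips incomplete windows consistently", {
  b <- two_helix_chain()
  cp <- candidate_pairs(b$chain, b$annotation)
  fm <- build_feature_matrix(b$chain, b$annotation, cp, "SDF", "seq1")
  expect_equal(ncol(fm$x), 40)
  expect_equal(nrow(fm$x) + fm$n_skipped, nrow(cp))
  # the cached batch path agrees with the one-shot sdf_vector
  k <- 10
  v <- sdf_vector(b$chain, b$annotation, fm$pairs[k, ])
  expect_equal(unname(fm$x[k, ]), unname(v), tolerance = 1e-12)
  fmc <- build_feature_matrix(b$chain, b$annotation, cp, "CF", "seq1")
  expect_equal(ncol(fmc$x), 192)
  expect_identical(fm$kept, fmc$kept)
})

test_that("scaler follows the [-1,1] formula without clipping", {
  m <- cbind(c(2, 4, 6), c(5, 5, 5))
  sc <- fit_scaler(m)
  scaled <- apply_scaler(sc, m)
  expect_equal(scaled[, 1], c(-1, 0, 1))
  expect_equal(scaled[, 2], c(0, 0, 0))  # constant column -> midpoint
  # test values outside the training range are not clipped
  expect_equal(apply_scaler(sc, cbind(0, 5))[1, 1], -2)
  # fit+apply is idempotent on the training matrix
  sc2 <- fit_scaler(scaled)
  expect_equal(apply_scaler(sc2, scaled)[, 1], scaled[, 1])
  # training matrix attains exactly -1 and 1 per non-constant feature
  expect_equal(range(scaled[, 1]), c(-1, 1))
})

test_that("feature matrix and scaler TSV round-trips preserve values", {
  b <- two_helix_chain()
  cp <- candidate_pairs(b$chain, b$annotation)
  fm <- build_feature_matrix(b$chain, b$annotation, cp, "SDF", "seqX")
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, p1)
  back <- read_feature_matrix(p1)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_equal(back$kind, "SDF")
  expect_equal(back$pairs$i, fm$pairs$i)
  sc <- fit_scaler(fm)
  write_scaling_params(sc, p2)
  sc2 <- read_scaling_params(p2)
  expect_equal(sc2$min, sc$min, tolerance = 1e-12)
  expect_equal(sc2$max, sc$max, tolerance = 1e-12)
})
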