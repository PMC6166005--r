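test_that("hydrogen-bond occupancy is the qualifying-frame percentage", {
  always <- hbond_occupancy(onoff_trajectory(1:10, 10), threshold = 0)
  expect_equal(nrow(always), 1)
  expect_equal(always$occupancy, 100)
  some <- hbond_occupancy(onoff_trajectory(c(2, 5, 9), 10), threshold = 0)
  expect_equal(some$occupancy, 30)
  expect_equal(some$donor, "SER1:OG")
  expect_equal(some$acceptor, "FRU1:N")
})

test_that("the reporting threshold excludes marginal pairs", {
  # 29 of 600 frames -> 4.83%, below the 5% floor
  rare <- hbond_occupancy(onoff_trajectory(1:29, 600), threshold = 5)
  expect_equal(nrow(rare), 0)
  kept <- hbond_occupancy(onoff_trajectory(1:30, 600), threshold = 5)
  expect_equal(kept$occupancy, 5)
})

test_that("occupancies are invariant to frame order and rows sort by occupancy", {
  tr <- onoff_trajectory(c(1, 2, 3), 8)
  trp <- new_trajectory(tr$topology, tr$frames[c(5, 3, 8, 1, 7, 2, 4, 6)])
  expect_equal(hbond_occupancy(trp, threshold = 0),
               hbond_occupancy(tr, threshold = 0))
  s <- make_toy_protein(20, 4, seed = 1)
  occ <- hbond_occupancy(perturb_trajectory(s, 30, 0.25, seed = 3),
                         threshold = 5)
  expect_true(all(diff(occ$occupancy) <= 0))
  expect_true(all(occ$occupancy >= 5 & occ$occupancy <= 100))
})

test_that("hydrogen-bond counts along the reaction coordinate bin correctly", {
  # bond intact while rc < 15, broken beyond: step from 1 to 0 at 15
  n <- 20
  tr <- onoff_trajectory(1:10, n)
  tr$rc <- seq(5.5, 24.5, by = 1)  # frames 1:10 have rc < 15
  curve <- hbond_count_vs_rc(tr, bin_width = 1)
  expect_equal(curve$mean_count[curve$rc_lo < 15], rep(1, 10))
  expect_equal(curve$mean_count[curve$rc_lo >= 15], rep(0, 10))
  # no geometry anywhere -> all-zero curve
  none <- onoff_trajectory(integer(0), 5)
  none$rc <- 1:5
  expect_true(all(hbond_count_vs_rc(none)$mean_count == 0))
  # persistent bond -> constant 1
  all_on <- onoff_trajectory(1:5, 5)
  all_on$rc <- 1:5
  expect_true(all(hbond_count_vs_rc(all_on)$mean_count == 1))
  expect_error(hbond_count_vs_rc(onoff_trajectory(1, 2)), "reaction coordinate")
})

quad_trajectory <- function(p4_list) {
  top <- tibble::tibble(
    chain = "A", resid = 1L, resname = "GLY", is_ligand = FALSE,
    atom = paste0("A", 1:4), element = "C",
    x = 0, y = 0, z = 0)
  frames <- lapply(p4_list, function(p4) {
    rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), p4)
  })
  new_trajectory(as_structure(top), frames)
}

test_that("dihedrals follow the IUPAC sign convention", {
  tr <- quad_trajectory(list(c(1, 0, 1),    # cis
                             c(-1, 0, 1),   # trans
                             c(0, 1, 1)))   # +90 rotation about the bond
  d <- dihedral_series(tr, 1:4)
  expect_equal(d$dihedral[1], 0)
  expect_equal(d$dihedral[2], 180)  # trans maps to +180, not -180
  expect_equal(d$dihedral[3], 90, tolerance = 1e-6)
  # the torsion is invariant when read from the opposite end of the bond
  drev <- dihedral_series(tr, 4:1)
  expect_equal(drev$dihedral[3], 90, tolerance = 1e-6)
  # a mirror reflection negates the angle
  mir <- quad_trajectory(list(c(0, -1, 1)))
  expect_equal(dihedral_series(mir, 1:4)$dihedral, -90, tolerance = 1e-6)
  # independent implementation agrees on value and reversal behaviour
  ref <- bio3d::torsion.xyz(c(1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 1, 1))
  expect_equal(d$dihedral[3], as.numeric(ref), tolerance = 1e-6)
  ref_rev <- bio3d::torsion.xyz(c(0, 1, 1, 0, 0, 1, 0, 0, 0, 1, 0, 0))
  expect_equal(drev$dihedral[3], as.numeric(ref_rev), tolerance = 1e-6)
})

test_that("colinear atom triples raise an error naming the frame", {
  tr <- quad_trajectory(list(c(0, 1, 1), c(0, 0, 2)))  # frame 2: p4 on bond axis
  expect_error(dihedral_series(tr, 1:4), "frame 2")
  expect_error(dihedral_series(tr, c(1, 2, 3)), "four distinct")
  expect_error(dihedral_series(tr, c(1, 2, 3, 3)), "four distinct")
})

test_that("centroid distances are exact for constructed geometries", {
  top <- tibble::tibble(
    chain = "A", resid = 1L, resname = "GLY", is_ligand = FALSE,
    atom = paste0("A", 1:6), element = "C", x = 0, y = 0, z = 0)
  # triangle A at centroid (0,0,0); triangle B at centroid (7.25,0,0)
  tri_a <- rbind(c(1, 0, 0), c(-0.5, 0.5, 0), c(-0.5, -0.5, 0))
  tri_b <- sweep(tri_a, 2, c(7.25, 0, 0), "+")
  tr <- new_trajectory(as_structure(top), list(rbind(tri_a, tri_b)))
  expect_equal(centroid_distance(tr, 1:3, 4:6)$distance, 7.25)
  expect_equal(centroid_distance(tr, 1:3, 1:3)$distance, 0)
  # two single atoms 5 apart
  tr2 <- new_trajectory(as_structure(top),
                        list(rbind(c(0, 0, 0), c(0, 5, 0), tri_a, c(0, 0, 0))))
  expect_equal(centroid_distance(tr2, 1, 2)$distance, 5)
  expect_error(centroid_distance(tr, integer(0), 1:3), "non-empty")
})

test_that("Kabsch superposition removes rigid-body motion", {
  s <- make_toy_protein(15, 3, seed = 7)
  ref <- as.matrix(s[, c("x", "y", "z")])
  expect_equal(superpose(ref, ref)$rmsd, 0)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(ref %*% rot, 2, c(5, -3, 2), "+")
  fit <- superpose(moved, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(unname(fit$coords), unname(ref), tolerance = 1e-9)
  # pure noise: post-fit RMSD ~ sd * sqrt(3)
  big <- withr::with_seed(31, matrix(rnorm(300, sd = 5), 100, 3))
  noisy <- big + withr::with_seed(3, matrix(rnorm(300, sd = 0.1), 100, 3))
  expect_equal(superpose(noisy, big)$rmsd, 0.1 * sqrt(3), tolerance = 0.2)
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "colinear")
})

test_that("PCA landscapes anchor the minimum at zero and flag empty bins", {
  s <- make_toy_protein(12, 3, seed = 2)
  tr <- perturb_trajectory(s, n_frames = 200, noise_sd = 0.3, seed = 4)
  fel <- pca_fel(tr, temperature = 333, bins = 12)
  occupied <- fel$grid$free_energy[is.finite(fel$grid$free_energy)]
  expect_equal(min(occupied), 0)
  expect_true(all(occupied >= 0))
  expect_true(all(is.infinite(
    fel$grid$free_energy[fel$grid$probability == 0])))
  expect_equal(sum(fel$grid$probability), 1)
  expect_error(pca_fel(new_trajectory(s, list(as.matrix(s[, c("x", "y", "z")])))),
               "at least 2")
})

test_that("variance along one coordinate loads entirely on PC1", {
  top <- make_toy_protein(8, 3, seed = 1)
  ref <- as.matrix(top[, c("x", "y", "z")])
  frames <- lapply(seq(-1, 1, length.out = 40), function(a) {
    f <- ref
    f[1, 1] <- f[1, 1] + a
    f
  })
  fel <- pca_fel(new_trajectory(top, frames), bins = 8, superpose = FALSE)
  expect_equal(fel$variance_explained[1], 1, tolerance = 1e-9)
})

test_that("a two-cluster trajectory shows two landscape minima with a barrier", {
  top <- make_toy_protein(8, 3, seed = 1)
  ref <- as.matrix(top[, c("x", "y", "z")])
  frames <- withr::with_seed(9, lapply(1:300, function(i) {
    shift <- if (i %% 2 == 0) 3 else -3
    f <- ref + matrix(rnorm(length(ref), 0, 0.15), nrow(ref), 3)
    f[1:4, 1] <- f[1:4, 1] + shift
    f
  }))
  fel <- pca_fel(new_trajectory(top, frames), bins = 14, superpose = FALSE)
  # project the landscape onto PC1: two low-energy regions separated by a
  # high/empty band
  prof <- fel$grid |>
    dplyr::group_by(pc1) |>
    dplyr::summarise(g = min(free_energy))
  low <- which(is.finite(prof$g) & prof$g < 1)
  expect_gte(max(diff(sort(low))), 3)  # gap between the two basins
})
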