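# Structure metrics: CSP, PDB reading, angles, Kabsch, local RMSD.

test_that("combined CSP follows the scaled quadrature formula", {
  expect_equal(csp(0, 4), 1)
  expect_equal(csp(0.1, 0), 0.1)
  expect_equal(csp(0.5, 2), sqrt(0.25 + 0.25))
  expect_equal(csp(0.5, 2), csp(-0.5, -2)) # sign-flip invariance
  expect_equal(csp(0, 2, scale = 2), 1)
  expect_error(csp(0.1, 0.4, scale = 0), "positive")
})

test_that("PDB reading returns coordinates and resolves altlocs by
           occupancy", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 1.111, 2.222, 3.333),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 4.5, 5.5, 6.5),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 0, 0, 9.999)
  ))
  co <- read_structure(p)
  expect_equal(nrow(co), 3)
  expect_equal(co$x[co$atom == "N"], 1.111)
  expect_equal(co$z[co$atom == "CB"], 9.999)

  # altloc A at 0.6 beats B at 0.4; tie goes to A
  p2 <- write_pdb_fixture(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 2, 0, 0, occ = 0.4, alt = "B"),
    pdb_atom_line(3, "CA", "ALA", "A", 2, 3, 0, 0, occ = 0.5, alt = "B"),
    pdb_atom_line(4, "CA", "ALA", "A", 2, 4, 0, 0, occ = 0.5, alt = "A")
  ))
  co2 <- read_structure(p2)
  expect_equal(nrow(co2), 2)
  expect_equal(co2$x[co2$resno == 1], 1)
  expect_equal(co2$x[co2$resno == 2], 4)

  expect_error(read_structure(p, chains = "Z"), "not in file")
})

test_that("write-read round-trip preserves coordinates to PDB precision", {
  withr::with_seed(5, {
    xyz <- matrix(runif(30, -50, 50), ncol = 3)
  })
  lines <- vapply(seq_len(nrow(xyz)), function(i) {
    pdb_atom_line(i, "CA", "GLY", "A", i, xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
  co <- read_structure(write_pdb_fixture(lines))
  expect_equal(co[order(co$resno), ]$x, round(xyz[, 1], 3))
  expect_equal(co[order(co$resno), ]$y, round(xyz[, 2], 3))
  expect_equal(co[order(co$resno), ]$z, round(xyz[, 3], 3))
})

test_that("three-point angle uses the middle atom as vertex", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 1, 0, 0),
    pdb_atom_line(3, "CA", "ALA", "A", 3, 1, 1, 0),
    pdb_atom_line(4, "CA", "ALA", "A", 4, 2, 0, 0)
  ))
  co <- read_structure(p)
  expect_equal(three_point_angle(co, list("A", 1, "CA"), list("A", 2, "CA"),
                                 list("A", 3, "CA")), 90)
  # collinear, vertex between the endpoints
  expect_equal(three_point_angle(co, list("A", 1, "CA"), list("A", 2, "CA"),
                                 list("A", 4, "CA")), 180)
  expect_error(three_point_angle(co, list("A", 1, "CA"),
                                 list("A", 1, "CA"), list("A", 3, "CA")),
               "Coincident")
})

test_that("three-point angle is invariant under rigid motion of all
           coordinates", {
  p <- synthetic_two_conformer_pdb()
  co <- read_structure(p)
  a_open <- three_point_angle(co, list("C", 120, "CA"),
                              list("D", 123, "CA"), list("D", 52, "CA"))
  withr::with_seed(11, R <- random_rotation())
  co_rot <- dplyr::mutate(co, dplyr::across(c(x, y, z), as.numeric))
  xyz <- as.matrix(co_rot[, c("x", "y", "z")]) %*% R
  co_rot$x <- xyz[, 1] + 12.3
  co_rot$y <- xyz[, 2] - 4.56
  co_rot$z <- xyz[, 3] + 7.89
  a_rot <- three_point_angle(co_rot, list("C", 120, "CA"),
                             list("D", 123, "CA"), list("D", 52, "CA"))
  expect_equal(a_open, a_rot, tolerance = 1e-10)
})

test_that("the synthetic two-conformer fixture shows the open and closed
           inter-subunit angles", {
  co <- read_structure(synthetic_two_conformer_pdb())
  open <- three_point_angle(co, list("C", 120, "CA"), list("D", 123, "CA"),
                            list("D", 52, "CA"))
  closed <- three_point_angle(co, list("E", 120, "CA"), list("F", 123, "CA"),
                              list("F", 52, "CA"))
  expect_equal(round(open), 25)
  expect_equal(round(closed), 10)
})

test_that("Kabsch superposition is exact on rigid copies and proper", {
  withr::with_seed(21, {
    X <- matrix(rnorm(60), ncol = 3)
    R <- random_rotation()
  })
  Y <- X %*% R + matrix(rep(c(3, -2, 7), each = nrow(X)), ncol = 3)
  fit <- kabsch_superpose(X, Y)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # identity case
  expect_lt(kabsch_superpose(X, X)$rmsd, 1e-12)
  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "n >= 3")
  collinear <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(collinear, collinear + 1), "Degenerate")
})

test_that("Kabsch rmsd is optimal: no random rigid transform and no
           general-purpose optimiser beats it", {
  # 4-point toy set with one displaced atom
  X <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  Y <- X
  Y[4, ] <- Y[4, ] + c(0, 0, 2) # displaced by 2 A
  fit <- kabsch_superpose(X, Y)
  # random-transform probe
  withr::with_seed(31, {
    worst <- min(vapply(1:2000, function(i) {
      R <- random_rotation()
      Xr <- sweep(X, 2, colMeans(X)) %*% R
      sqrt(mean(rowSums((sweep(Xr, 2, colMeans(Y), `+`) - Y)^2)))
    }, numeric(1)))
  })
  expect_lte(fit$rmsd, worst + 1e-12)
  # oracle: multi-start quasi-Newton over Euler angles
  obj <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    X0 <- sweep(X, 2, colMeans(X)); Y0 <- sweep(Y, 2, colMeans(Y))
    sqrt(mean(rowSums((X0 %*% R - Y0)^2)))
  }
  withr::with_seed(32, {
    best_oracle <- min(vapply(1:40, function(i) {
      stats::optim(runif(3, -pi, pi), obj, method = "BFGS")$value
    }, numeric(1)))
  })
  expect_equal(fit$rmsd, best_oracle, tolerance = 1e-6)
})

test_that("local backbone RMSD is zero for identical chains and
           localizes a constructed loop displacement", {
  coords <- backbone_chain_coords(40)
  pa <- write_pdb_fixture(backbone_chain_pdb_lines(coords, "A"))
  pb_same <- write_pdb_fixture(backbone_chain_pdb_lines(coords, "B"))
  A <- read_structure(pa); B <- read_structure(pb_same)
  r0 <- local_backbone_rmsd(A, "A", B, "B")
  expect_equal(nrow(r0), 40)
  expect_true(all(r0$rmsd_A < 1e-6))

  # displace residues 18-22 by 3 A in an otherwise rigid chain
  pb_disp <- write_pdb_fixture(backbone_chain_pdb_lines(
    coords, "B", displace = 18:22, shift = c(0, 0, 3)))
  Bd <- read_structure(pb_disp)
  r <- local_backbone_rmsd(A, "A", Bd, "B")
  in_loop <- r$resno %in% 18:22
  expect_gt(min(r$rmsd_A[in_loop]), 2.5)
  expect_lt(max(r$rmsd_A[!in_loop]), 0.5)
  expect_equal(which.max(r$rmsd_A) %in% 18:22, TRUE)
})

test_that("chains without shared numbering are rejected", {
  coords <- backbone_chain_coords(10)
  pa <- write_pdb_fixture(backbone_chain_pdb_lines(coords, "A"))
  shifted <- backbone_chain_pdb_lines(coords, "B")
  # renumber far away so residue numbers do not overlap
  shifted <- gsub("B   ([1-9]) ", "B  5\\1 ", shifted)
  pb <- write_pdb_fixture(shifted)
  A <- read_structure(pa); B <- read_structure(pb)
  expect_error(local_backbone_rmsd(A, "A", B, "B"))
})
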