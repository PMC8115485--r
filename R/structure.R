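# Structural comparison metrics: chemical shift perturbations, three-atom
# inter-subunit angles, Kabsch superposition and per-residue local
# backbone RMSD between two conformations.

#' Combined chemical shift perturbation
#'
#' `CSP = sqrt((delta_X / scale)^2 + delta_H^2)`, the conventional
#' combined proton/heteronucleus shift change between two spectra. The
#' default divisor of 4 is the usual carbon scaling.
#'
#' @param delta_H Proton shift difference (ppm).
#' @param delta_X Heteronucleus (carbon or nitrogen) shift difference (ppm).
#' @param scale Heteronucleus scaling divisor (> 0), default 4.
#' @return CSP in ppm.
#' @examples
#' csp(0.1, 0.8)
#' @export
csp <- function(delta_H, delta_X, scale = 4) {
  if (scale <= 0) abort("`scale` must be positive.")
  sqrt((delta_X / scale)^2 + delta_H^2)
}

#' Read atomic coordinates from a PDB file
#'
#' Parses ATOM/HETATM records into a flat atom table. Alternate locations
#' are resolved to the highest-occupancy altloc per atom (ties go to
#' altloc "A").
#'
#' @param path Path to a PDB-format file.
#' @param chains Optional character vector restricting to these chain ids;
#'   an error is raised if a requested chain is absent.
#' @return A tibble with columns `chain`, `resno`, `resid`, `atom`,
#'   `x`, `y`, `z`, `occupancy`, `altloc`.
#' @export
read_structure <- function(path, chains = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    abort(sprintf("Failed to parse PDB file '%s': %s",
                                  path, conditionMessage(e)))
                  })
  a <- pdb$atom
  out <- tibble(
    chain = a$chain,
    resno = a$resno,
    resid = a$resid,
    atom = a$elety,
    x = a$x, y = a$y, z = a$z,
    occupancy = a$o %||% 1,
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt)
  )
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    abort("Malformed ATOM records: non-finite coordinates.")
  }
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(out$chain))
    if (length(missing) > 0) {
      abort(sprintf("Requested chain(s) not in file: %s",
                    paste(missing, collapse = ", ")))
    }
    out <- filter(out, .data$chain %in% chains)
  }
  # resolve altlocs: keep highest occupancy, ties -> altloc "A" (then first)
  out <- out |>
    group_by(.data$chain, .data$resno, .data$atom) |>
    arrange(dplyr::desc(.data$occupancy), .data$altloc,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$chain, .data$resno, .data$atom)
  out
}

# fetch one atom's coordinates from the atom table
atom_xyz <- function(coords, chain, resno, atom) {
  hit <- coords[coords$chain == chain & coords$resno == resno &
                  coords$atom == atom, ]
  if (nrow(hit) != 1) {
    abort(sprintf("Atom %s/%s/%s matched %d records.",
                  chain, resno, atom, nrow(hit)))
  }
  c(hit$x, hit$y, hit$z)
}

#' Angle defined by three atoms
#'
#' The angle at the second (vertex) atom between the vectors to the first
#' and third atoms, in degrees.
#'
#' @param coords An atom table from [read_structure()].
#' @param a1,a2,a3 Atom selectors, each a list/vector
#'   `(chain, resno, atom)`; `a2` is the vertex.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
three_point_angle <- function(coords, a1, a2, a3) {
  p1 <- atom_xyz(coords, a1[[1]], as.integer(a1[[2]]), a1[[3]])
  p2 <- atom_xyz(coords, a2[[1]], as.integer(a2[[2]]), a2[[3]])
  p3 <- atom_xyz(coords, a3[[1]], as.integer(a3[[2]]), a3[[3]])
  v1 <- p1 - p2
  v2 <- p3 - p2
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) abort("Coincident atoms: angle undefined.")
  ct <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of matched coordinate sets by singular
#' value decomposition of the covariance matrix, with the reflection
#' branch corrected so the returned rotation is proper (determinant +1).
#'
#' @param X,Y Numeric matrices (n x 3) of matched atoms; `X` is rotated
#'   onto `Y`.
#' @return A list with `rotation` (3x3), `translation` (length 3; the
#'   transform is `X %*% rotation + translation`), `rmsd` (Angstrom) and
#'   `transformed` (the superposed X).
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3 || nrow(X) < 3) {
    abort("X and Y must be matched n x 3 matrices with n >= 3.")
  }
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  if (qr(X0)$rank < 2) abort("Degenerate (collinear) geometry.")
  s <- svd(crossprod(X0, Y0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Xr <- X0 %*% R
  rmsd <- sqrt(mean(rowSums((Xr - Y0)^2)))
  translation <- cy - as.vector(cx %*% R)
  list(rotation = R, translation = translation, rmsd = rmsd,
       transformed = sweep(Xr, 2, cy, `+`))
}

backbone_atoms <- c("N", "CA", "C", "O")

#' Per-residue local backbone RMSD between two conformations of a chain
#'
#' Superposes the backbone (N, CA, C, O) of one chain onto the matching
#' chain of a second coordinate set by a single global Kabsch fit over all
#' shared residues, then reports the RMSD over the backbone atoms of each
#' residue individually. Because each protein is aligned on itself as a
#' whole, large per-residue values flag local conformational changes
#' (loop rearrangements) rather than overall domain motion.
#'
#' @param coords_a,coords_b Atom tables from [read_structure()].
#' @param chain_a,chain_b Chain ids to compare (must share residue
#'   numbering for at least 80 percent of residues).
#' @return A tibble with `resno`, `resid`, `n_atoms`, `rmsd_A`.
#' @export
local_backbone_rmsd <- function(coords_a, chain_a, coords_b, chain_b) {
  A <- filter(coords_a, .data$chain == chain_a,
              .data$atom %in% backbone_atoms)
  B <- filter(coords_b, .data$chain == chain_b,
              .data$atom %in% backbone_atoms)
  m <- dplyr::inner_join(A, B, by = c("resno", "atom"),
                         suffix = c("_a", "_b"))
  if (nrow(m) == 0) abort("No shared residues between the two chains.")
  shared_res <- length(unique(m$resno))
  total_res <- max(length(unique(A$resno)), length(unique(B$resno)))
  if (shared_res < 0.8 * total_res) {
    abort(sprintf(
      "Chains share only %d of %d residues (< 80%%); check numbering.",
      shared_res, total_res
    ))
  }
  fit <- kabsch_superpose(as.matrix(m[, c("x_a", "y_a", "z_a")]),
                          as.matrix(m[, c("x_b", "y_b", "z_b")]))
  m$d2 <- rowSums((fit$transformed -
                     as.matrix(m[, c("x_b", "y_b", "z_b")]))^2)
  m |>
    group_by(.data$resno) |>
    summarise(resid = .data$resid_a[1], n_atoms = n(),
              rmsd_A = sqrt(mean(.data$d2)), .groups = "drop") |>
    arrange(.data$resno)
}
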