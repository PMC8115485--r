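# Shared fixture builders and independent numerical oracles.

# --- PDB fixture writing --------------------------------------------------

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = "") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# A synthetic two-conformer heterodimer: chains C/D carry a three-atom
# inter-subunit geometry with a 25 degree angle, chains E/F the same
# geometry closed to 10 degrees. Purely constructed coordinates; no
# deposited structure is reproduced.
synthetic_two_conformer_pdb <- function() {
  ang <- function(deg, chF, chH, base) {
    th <- deg * pi / 180
    c(
      pdb_atom_line(base + 1, "CA", "PHE", chF, 120,
                    10 * cos(th), 10 * sin(th), 0),
      pdb_atom_line(base + 2, "CA", "TRP", chH, 123, 0, 0, 0),
      pdb_atom_line(base + 3, "CA", "GLY", chH, 52, 10, 0, 0)
    )
  }
  write_pdb_fixture(c(ang(25, "C", "D", 0), ang(10, "E", "F", 10)))
}

# A rigid pseudo-helical backbone chain of n residues (N, CA, C, O), with
# a deterministic but irregular shape so superpositions are well posed.
backbone_chain_coords <- function(n = 40) {
  res <- list()
  for (i in seq_len(n)) {
    t0 <- i * 100 * pi / 180
    base <- c(2.3 * cos(t0), 2.3 * sin(t0), 1.5 * i)
    res[[i]] <- rbind(
      N = base + c(0.4, 0.2, -0.5),
      CA = base,
      C = base + c(-0.5, 0.6, 0.4),
      O = base + c(-0.9, 1.2, 0.3)
    )
  }
  res
}

backbone_chain_pdb_lines <- function(coords, chain, serial0 = 0,
                                     displace = NULL, shift = c(0, 0, 0)) {
  lines <- character(0)
  serial <- serial0
  for (i in seq_along(coords)) {
    xyz <- coords[[i]]
    if (!is.null(displace) && i %in% displace) {
      xyz <- sweep(xyz, 2, shift, `+`)
    }
    for (a in rownames(xyz)) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, a, "ALA", chain, i,
                                      xyz[a, 1], xyz[a, 2], xyz[a, 3]))
    }
  }
  lines
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# --- independent oracles --------------------------------------------------

# ZZ-exchange via numerical matrix exponential (Matrix::expm)
zz_expm_oracle <- function(k_IA, k_AI, R1_I, R1_A, t, amp_I, amp_A) {
  K <- matrix(c(-R1_I - k_IA, k_AI, k_IA, -R1_A - k_AI), 2, 2,
              byrow = TRUE)
  E <- as.matrix(Matrix::expm(K * t))
  mi <- E %*% c(amp_I, 0)
  ma <- E %*% c(0, amp_A)
  c(I_II = mi[1], I_AA = ma[2], I_IA = mi[2], I_AI = ma[1])
}

# Two-site lineshape via time-domain propagation of the complex McConnell
# evolution matrix followed by explicit Fourier integration (Simpson).
lineshape_time_domain_oracle <- function(freq_hz, delta_free_hz,
                                         delta_bound_hz, r2_free, r2_bound,
                                         p_bound, kex, t_max = 1,
                                         dt = 1e-5) {
  wf <- 2i * pi * delta_free_hz
  wb <- 2i * pi * delta_bound_hz
  k_fb <- p_bound * kex
  k_bf <- (1 - p_bound) * kex
  L <- matrix(c(wf - r2_free - k_fb, k_bf,
                k_fb, wb - r2_bound - k_bf), 2, 2, byrow = TRUE)
  eg <- eigen(L)
  Vinv <- solve(eg$vectors)
  c0 <- Vinv %*% c(1 - p_bound, p_bound)
  t <- seq(0, t_max, by = dt)
  # s(t) = rowSums over states of V diag(e^{lambda t}) c0
  modes <- eg$vectors %*% diag(as.vector(c0), 2)
  s <- modes[1, 1] * exp(eg$values[1] * t) +
    modes[1, 2] * exp(eg$values[2] * t) +
    modes[2, 1] * exp(eg$values[1] * t) +
    modes[2, 2] * exp(eg$values[2] * t)
  simpson <- function(y) {
    n <- length(y)
    if (n %% 2 == 0) { y <- y[-n]; n <- n - 1 }
    h <- dt
    h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, by = 2)]) +
               2 * sum(y[seq(3, n - 2, by = 2)]))
  }
  vapply(freq_hz, function(f) {
    Re(simpson(s * exp(-2i * pi * f * t)))
  }, numeric(1))
}

# trapezoid integral over an irregular grid
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# numeric brute-force equilibrium for the three-state model: solve for all
# species concentrations directly, independent of the package's closed
# forms (used as a root-finder oracle)
three_state_brute_oracle <- function(L_tot, P_tot, kd_i, kd_a) {
  f <- function(lf) {
    p1 <- P_tot / (1 + lf / kd_i + lf / kd_a)
    p2 <- p1 * lf / kd_i
    p3 <- p1 * lf / kd_a
    lf + p2 + p3 - L_tot
  }
  lf <- stats::uniroot(f, c(0, L_tot), tol = 1e-14)$root
  p1 <- P_tot / (1 + lf / kd_i + lf / kd_a)
  c(p1 = p1 / P_tot, p2 = p1 * (lf / kd_i) / P_tot,
    p3 = p1 * (lf / kd_a) / P_tot)
}
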