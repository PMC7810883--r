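# Internal-coordinate backbone construction (NeRF) used by the synthetic
# generator and by the ideal-geometry secondary-structure constructs.
# Bond lengths/angles are standard peptide values (nm, degrees):
#   N-CA 0.1458, CA-C 0.1525, C-N 0.1329, C=O 0.1231
#   N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.5, omega 180

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame: returns the position `d` with bond
#' length `|d - c| = bond`, angle b-c-d = `angle`, and dihedral
#' a-b-c-d = `dihedral`.
#'
#' @param a,b,c positions (length-3 numeric), nm.
#' @param bond bond length, nm.
#' @param angle bond angle, degrees.
#' @param dihedral torsion, degrees.
#' @return position of the new atom (length-3 numeric).
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build a peptide backbone from phi/psi dihedrals
#'
#' Ideal-geometry N/CA/C/O (+ optional CB) coordinates for one chain.
#' `phi[1]` is unused (no preceding carbonyl); the chain starts at the
#' origin running roughly along +x.
#'
#' @param phi,psi numeric vectors of dihedrals, degrees, one per residue.
#' @param cb also place a CB-like pseudo side-chain atom per residue.
#' @param omega peptide-bond torsion, default 180 (trans).
#' @return list of `n_res x 3` matrices `N`, `CA`, `C`, `O` (and `CB`).
#' @keywords internal
build_backbone <- function(phi, psi, cb = FALSE, omega = 180) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(0.1458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 0.1525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 0.1329, 116.2, psi[i])
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], 0.1458, 121.7, omega)
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ], 0.1525, 111.2,
                              phi[i + 1L])
    O[i, ] <- place_atom(N[i + 1L, ], CA[i, ], C[i, ], 0.1231, 120.5, 180)
  }
  O[n, ] <- place_atom(N[n, ], CA[n, ], C[n, ], 0.1231, 120.5, psi[n] - 180)
  out <- list(N = N, CA = CA, C = C, O = O)
  if (cb) {
    CB <- matrix(NA_real_, n, 3L)
    for (i in seq_len(n)) {
      CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], 0.1530, 110.5, 122.6)
    }
    out$CB <- CB
  }
  out
}

backbone_to_topology <- function(bb, residue_numbers, chain_id = "A",
                                 resname = "ALA", sc_atoms = NULL) {
  # sc_atoms: optional data.frame(residue_number, atom_name, residue_name)
  # for pseudo side-chain atoms placed along the CA->CB direction
  n <- nrow(bb$N)
  stopifnot(length(residue_numbers) == n)
  resname <- rep_len(resname, n)
  rows <- list(); coords <- list()
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    rn <- resname[i]
    if (!is.null(sc_atoms)) {
      hit <- which(sc_atoms$residue_number == residue_numbers[i])
      if (length(hit)) {
        stopifnot(!is.null(bb$CB))
        for (h in hit) {
          nm <- c(nm, sc_atoms$atom_name[h])
          # pseudo side chain: 0.25 nm out from CA along the CB direction
          dir <- unit3(bb$CB[i, ] - bb$CA[i, ])
          xyz <- rbind(xyz, bb$CA[i, ] + 0.25 * dir)
          if (!is.null(sc_atoms$residue_name)) rn <- sc_atoms$residue_name[h]
        }
      }
    }
    rows[[i]] <- data.frame(atom_name = nm,
                            residue_number = residue_numbers[i],
                            residue_name = rn,
                            chain_id = chain_id,
                            element = substr(nm, 1, 1),
                            stringsAsFactors = FALSE)
    coords[[i]] <- xyz
  }
  list(atoms = do.call(rbind, rows), coords = do.call(rbind, coords))
}

#' Ideal poly-alanine alpha helix
#'
#' Built at phi = -57, psi = -47 degrees; interior residues of a
#' sufficiently long helix satisfy the i -> i+4 hydrogen-bond pattern.
#'
#' @param n_res number of residues (>= 6).
#' @param residue_start first residue number.
#' @return list with `topology` and `coords_nm` (n_atoms x 3).
#' @export
ideal_helix <- function(n_res = 15L, residue_start = 1L) {
  bb <- build_backbone(rep(-57, n_res), rep(-47, n_res))
  parts <- backbone_to_topology(bb, seq(residue_start, length.out = n_res))
  list(topology = topology(parts$atoms), coords_nm = parts$coords)
}

#' Fully extended isolated chain
#'
#' phi = psi = 180 degrees; with no partner strand every residue is coil.
#'
#' @inheritParams ideal_helix
#' @export
ideal_extended <- function(n_res = 10L, residue_start = 1L) {
  bb <- build_backbone(rep(180, n_res), rep(180, n_res))
  parts <- backbone_to_topology(bb, seq(residue_start, length.out = n_res))
  list(topology = topology(parts$atoms), coords_nm = parts$coords)
}

rot_about <- function(u, theta) {
  u <- unit3(u); ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
         3L, 3L, byrow = TRUE)
}

#' Ideal antiparallel two-stranded beta sheet
#'
#' Two strands at ideal antiparallel-beta dihedrals (phi = -139.9,
#' psi = 135.2). The second strand is the first rotated 180 degrees about
#' the sheet normal (which reverses the chain direction) and docked by a
#' deterministic rigid-body refinement that minimizes the Kabsch-Sander
#' hydrogen-bond energy of the narrow-pair register (residue i of strand A
#' with residue n+1-i of strand B at alternating positions), with a
#' steric penalty keeping non-bonded atoms apart.
#'
#' @param n_res residues per strand.
#' @return list with `topology` (chains A and B) and `coords_nm`.
#' @export
ideal_sheet <- function(n_res = 8L) {
  stopifnot(n_res >= 4L)
  phi <- rep(-139.9, n_res); psi <- rep(135.2, n_res)
  bb <- build_backbone(phi, psi)
  partsA <- backbone_to_topology(bb, seq_len(n_res), chain_id = "A")
  A <- partsA$coords
  ca <- bb$CA
  axis1 <- unit3(ca[n_res, ] - ca[1, ])
  perp <- unit3(cross3(axis1, c(0, 0, 1)))
  sheet_normal <- unit3(cross3(axis1, perp))
  base_R <- rot_about(sheet_normal, pi)
  centerA <- colMeans(A)
  atomsB <- partsA$atoms
  atomsB$chain_id <- "B"
  top <- topology(rbind(partsA$atoms, atomsB))
  res <- ss_residue_table(top)
  nA <- nrow(A)
  pair_i <- seq(2L, n_res - 1L, by = 2L)  # narrow-pair register
  objective <- function(par) {
    Rp <- rot_about(c(1, 0, 0), par[4]) %*% rot_about(c(0, 1, 0), par[5]) %*%
      rot_about(c(0, 0, 1), par[6]) %*% base_R
    B <- sweep(sweep(A, 2, centerA) %*% t(Rp), 2, centerA + par[1:3], "+")
    co <- rbind(A, B)
    dAB <- as.matrix(stats::dist(co))[seq_len(nA), nA + seq_len(nA)]
    E <- 5000 * sum(pmax(0.26 - dAB, 0)^2)
    for (i in pair_i) {
      j <- n_res + 1L - i
      E <- E + ks_pair_energy(co, res, i, n_res + j) +
        ks_pair_energy(co, res, n_res + j, i)
    }
    E
  }
  fit <- stats::optim(c(-0.48 * sheet_normal, 0, 0, 0), objective,
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-10))
  par <- fit$par
  Rp <- rot_about(c(1, 0, 0), par[4]) %*% rot_about(c(0, 1, 0), par[5]) %*%
    rot_about(c(0, 0, 1), par[6]) %*% base_R
  B <- sweep(sweep(A, 2, centerA) %*% t(Rp), 2, centerA + par[1:3], "+")
  list(topology = top, coords_nm = rbind(A, B))
}
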