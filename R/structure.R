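#' Extract per-residue structure features from a PDB file
#'
#' Reads a single-chain structure (e.g. an AlphaFold model) and returns, per
#' residue: pLDDT taken from the B-factor column (CA atom), solvent
#' accessible surface area by the rolling-probe (Shrake-Rupley) algorithm
#' with a 1.4 A probe summed over the residue's atoms, and a 3-state
#' secondary structure (H/E/C) from a backbone hydrogen-bond-pattern
#' heuristic (Kabsch-Sander electrostatic energy with an i,i+4 rule for
#' helix and bridge rules for strand). Residues lacking backbone atoms are
#' reported with missing features and a warning.
#'
#' @param structure_file Path to a PDB file.
#' @param probe_radius Probe radius in Angstrom (default 1.4).
#' @return data.frame: residue, aa, asa, ss, plddt.
#' @export
extract_structure_features <- function(structure_file, probe_radius = 1.4) {
  pdb <- bio3d::read.pdb(structure_file)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  resno <- sort(unique(at$resno))
  n <- length(resno)
  aa3to1 <- vapply(resno, function(r) {
    code <- at$resid[at$resno == r][1]
    a <- bio3d::aa321(code)
    if (is.na(a)) "X" else a
  }, character(1))
  plddt <- vapply(resno, function(r) {
    ca <- at[at$resno == r & at$elety == "CA", , drop = FALSE]
    if (nrow(ca)) ca$b[1] else mean(at$b[at$resno == r])
  }, numeric(1))
  asa_atom <- shrake_rupley(as.matrix(at[, c("x", "y", "z")]),
                            at$elesy %||% substr(trimws(at$elety), 1, 1),
                            probe_radius = probe_radius)
  asa <- vapply(resno, function(r) sum(asa_atom[at$resno == r]), numeric(1))
  ss <- assign_ss_hbond(at, resno)
  missing_bb <- vapply(resno, function(r) {
    !all(c("N", "CA", "C", "O") %in% at$elety[at$resno == r])
  }, logical(1))
  if (any(missing_bb)) {
    warning(sprintf("residues with missing backbone atoms: %s",
                    paste(resno[missing_bb], collapse = ",")))
    ss[missing_bb] <- NA_character_
    asa[missing_bb] <- NA_real_
  }
  data.frame(residue = seq_len(n), aa = aa3to1, asa = asa, ss = ss,
             plddt = plddt, stringsAsFactors = FALSE)
}

# Shrake-Rupley SASA per atom: fraction of probe-sphere points not occluded
# by any neighbour, times the sphere area.
shrake_rupley <- function(xyz, elements, probe_radius = 1.4,
                          n_points = 96) {
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  r <- vdw[toupper(substr(trimws(elements), 1, 1))]
  r[is.na(r)] <- 1.70
  r <- r + probe_radius
  n <- nrow(xyz)
  # Fibonacci sphere point set
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  sphere <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  out <- numeric(n)
  maxr <- max(r)
  for (a in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[a, ])^2)
    nb <- which(d2 < (r[a] + maxr)^2 & d2 > 1e-9)
    nb <- nb[sqrt(d2[nb]) < r[a] + r[nb]]
    pts <- sweep(sphere * r[a], 2, xyz[a, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (b in nb) {
        dd <- rowSums(sweep(pts, 2, xyz[b, ])^2)
        free <- free & dd > r[b]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    out[a] <- frac * 4 * pi * r[a]^2
  }
  out
}

# Kabsch-Sander style backbone H-bond energy and 3-state assignment
assign_ss_hbond <- function(at, resno) {
  n <- length(resno)
  get_atom <- function(r, name) {
    row <- at[at$resno == r & at$elety == name, , drop = FALSE]
    if (nrow(row)) as.numeric(row[1, c("x", "y", "z")]) else NULL
  }
  N <- lapply(resno, get_atom, "N")
  CA <- lapply(resno, get_atom, "CA")
  C <- lapply(resno, get_atom, "C")
  O <- lapply(resno, get_atom, "O")
  # amide H inferred from the previous residue's C=O geometry
  H <- vector("list", n)
  for (i in 2:n) {
    if (!is.null(N[[i]]) && !is.null(C[[i - 1]]) && !is.null(O[[i - 1]])) {
      co <- C[[i - 1]] - O[[i - 1]]
      H[[i]] <- N[[i]] + co / sqrt(sum(co^2))
    }
  }
  hbond <- matrix(FALSE, n, n)  # hbond[i, j]: N-H of i donates to C=O of j
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || is.null(H[[i]]) || is.null(N[[i]]) ||
          is.null(C[[j]]) || is.null(O[[j]])) next
      rON <- sqrt(sum((O[[j]] - N[[i]])^2))
      if (rON > 5.5) next
      rCH <- sqrt(sum((C[[j]] - H[[i]])^2))
      rOH <- sqrt(sum((O[[j]] - H[[i]])^2))
      rCN <- sqrt(sum((C[[j]] - N[[i]])^2))
      e <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hbond[i, j] <- e < -0.5
    }
  }
  ss <- rep("C", n)
  # helix: consecutive i+4 -> i hydrogen bonds
  turn4 <- vapply(seq_len(n), function(i)
    i + 4 <= n && hbond[i + 4, i], logical(1))
  for (i in seq_len(max(n - 1L, 1L))) {
    if (turn4[i] && ((i > 1 && turn4[i - 1]) ||
                     (i + 1 <= n && turn4[i + 1]))) {
      ss[i:min(i + 4L, n)] <- "H"
    }
  }
  # strand bridges (antiparallel or parallel), assigned on coil only
  for (i in seq_len(n)) {
    if (ss[i] != "C") next
    for (j in seq_len(n)) {
      if (abs(i - j) <= 2) next
      anti <- hbond[i, j] && hbond[j, i]
      para <- i > 1 && i < n &&
        ((hbond[i + 1, j] && hbond[j, i - 1]) ||
         (j > 1 && j < n && hbond[i, j - 1] && hbond[j + 1, i]))
      if (anti || para) { ss[i] <- "E"; break }
    }
  }
  ss
}

#' Build an ideal polypeptide backbone
#'
#' Constructs backbone coordinates (N, CA, C, O per residue) for a chain
#' with constant phi/psi dihedrals using standard bond lengths and angles
#' (NeRF internal-to-Cartesian construction). Defaults give an ideal
#' alpha-helix; `phi = -139, psi = 135` gives an extended beta strand.
#'
#' @param n_residues Number of residues.
#' @param phi,psi Backbone dihedrals in degrees.
#' @return data.frame: residue, elety (N/CA/C/O), x, y, z.
#' @export
build_ideal_backbone <- function(n_residues, phi = -57, psi = -47) {
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7; a_CaCO <- 120.8
  omega <- 180
  place <- function(a, b, c, bond, angle, torsion) {
    # NeRF: position a fourth atom from bond length, bond angle and torsion
    ang <- angle * pi / 180; tor <- torsion * pi / 180
    bc <- c - b; bc <- bc / sqrt(sum(bc^2))
    nv <- pracma_cross(b - a, bc); nv <- nv / sqrt(sum(nv^2))
    mv <- pracma_cross(nv, bc)
    c + bond * (-cos(ang) * bc + sin(ang) * (cos(tor) * mv + sin(tor) * nv))
  }
  N <- CA <- C <- O <- vector("list", n_residues)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(b_NCa, 0, 0)
  a1 <- (180 - a_NCaC) * pi / 180
  C[[1]] <- CA[[1]] + b_CaC * c(cos(a1), sin(a1), 0)
  for (i in seq_len(n_residues - 1L) + 1L) {
    N[[i]] <- place(N[[i - 1]], CA[[i - 1]], C[[i - 1]], b_CN, a_CaCN, psi)
    CA[[i]] <- place(CA[[i - 1]], C[[i - 1]], N[[i]], b_NCa, a_CNCa, omega)
    C[[i]] <- place(C[[i - 1]], N[[i]], CA[[i]], b_CaC, a_NCaC, phi)
  }
  for (i in seq_len(n_residues)) {
    O[[i]] <- place(N[[i]], CA[[i]], C[[i]], b_CO, a_CaCO, psi + 180)
  }
  rows <- lapply(seq_len(n_residues), function(i)
    data.frame(residue = i, elety = c("N", "CA", "C", "O"),
               rbind(N[[i]], CA[[i]], C[[i]], O[[i]])))
  out <- do.call(rbind, rows)
  names(out)[3:5] <- c("x", "y", "z")
  rownames(out) <- NULL
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Write backbone coordinates to a minimal PDB file
#'
#' @param backbone data.frame from [build_ideal_backbone()].
#' @param path Output path.
#' @param aa One-letter residue code used for every residue (default A).
#' @param bfactor B-factor written for every atom (default 90).
#' @export
write_backbone_pdb <- function(backbone, path, aa = "A", bfactor = 90) {
  res3 <- bio3d::aa123(aa)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(backbone[, c("x", "y", "z")]))),
                   resno = backbone$residue,
                   resid = rep(res3, nrow(backbone)),
                   elety = backbone$elety,
                   chain = rep("A", nrow(backbone)),
                   b = rep(bfactor, nrow(backbone)))
  invisible(path)
}
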