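# Run expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  force(expr)
}

.mk_atoms <- function(name, xyz, resname, chain, resseq, element = NULL) {
  if (is.null(element)) {
    element <- substr(name, 1, 1)
    element[name == "CO"] <- "Co"
  }
  data.frame(name = name, resname = resname, chain = chain, resseq = resseq,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = element,
             stringsAsFactors = FALSE)
}

.rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
         byrow = TRUE)
}

# Idealized planar corrin template: polar layout (angle deg, radius A).
# The hinge axis is x (through Co and C10); the northern butterfly half
# occupies y > 0, the southern y < 0.
.corrin_template <- function() {
  t <- rbind(
    c("C10",    0, 2.45), c("C9",    30, 2.45), c("N22",  52, 1.90),
    c("C6",    75, 2.45), c("C5",   105, 2.45), c("N21", 128, 1.90),
    c("C4",   140, 2.45), c("C11",  -30, 2.45), c("N23", -52, 1.90),
    c("C14",  -75, 2.45), c("C15", -105, 2.45), c("N24",-128, 1.90),
    c("C16", -140, 2.45), c("C1",   162, 2.60), c("C2",  176, 3.00),
    c("C3",   150, 3.00), c("C7",    88, 3.00), c("C8",   40, 3.00),
    c("C12",  -40, 3.00), c("C13",  -88, 3.00), c("C17",-150, 3.00),
    c("C18", -176, 3.00), c("C19", -162, 2.60),
    # peripheral pseudo side-chain carbons widening the disc
    c("C30",   15, 4.30), c("C31",   60, 4.30), c("C32", 115, 4.30),
    c("C33",  165, 4.30), c("C34",  -60, 4.30), c("C35",-115, 4.30),
    c("C36", -165, 4.30), c("C40",   38, 5.30), c("C41",  90, 5.30),
    c("C42",  142, 5.30), c("C43",  -38, 5.30), c("C44", -90, 5.30),
    c("C45", -142, 5.30))
  ang <- as.numeric(t[, 2]) * pi / 180
  r <- as.numeric(t[, 3])
  data.frame(name = t[, 1], x = r * cos(ang), y = r * sin(ang), z = 0,
             stringsAsFactors = FALSE)
}

#' Generate an idealized corrin with a controlled butterfly fold
#'
#' Emits a planar corrin template (cobalt at the origin, equatorial
#' nitrogens N21-N24 at 1.9 angstrom, ring carbons at canonical in-plane
#' positions, the dimethylbenzimidazole nitrogen N3B 2.2 angstrom below
#' cobalt) and folds the southern butterfly half (C11, N23, C14, C15,
#' C16, N24) by \code{fold_angle} about the Co-C10 hinge axis, towards
#' the beta face.  Because the rotation axis lies in the ring plane, the
#' plane-plane angle recovered from the construction equals
#' \code{fold_angle} exactly (up to coordinate noise).
#'
#' @param fold_angle butterfly fold angle in degrees, within [0, 45].
#' @param seed RNG seed (only consumed when \code{noise > 0}).
#' @param noise isotropic Gaussian coordinate noise, sd in angstrom.
#' @return A [b12_structure()] (chain L, residue B12 1).
#' @export
make_corrin <- function(fold_angle, seed = 1, noise = 0) {
  if (fold_angle < 0 || fold_angle > 45)
    stop("fold_angle must lie in [0, 45] degrees")
  tpl <- .corrin_template()
  south <- c("C11", "N23", "C14", "C15", "C16", "N24")
  R <- .rot_x(-fold_angle)  # fold the y<0 half up towards +z
  idx <- tpl$name %in% south
  xyz <- as.matrix(tpl[, c("x", "y", "z")])
  xyz[idx, ] <- xyz[idx, , drop = FALSE] %*% t(R)
  # alpha-face bulk: dimethylbenzimidazole ring carbons around N3B and a
  # nucleotide-tail-like arm below the ring plane
  lower <- rbind(
    C2B = c(1.20, 0.45, -2.95),  C8B = c(-1.15, -0.40, -3.05),
    C9B = c(0.10, 0.95, -4.05),  C4B = c(2.30, -1.60, -1.60),
    C5B = c(3.20, -2.70, -2.60), C6B = c(2.60, -2.40, -4.05),
    C1R = c(1.30, -1.55, -4.60), O4R = c(-2.45, 1.30, -4.55),
    C2R = c(-1.45, 0.60, -5.15), C3R = c(-3.60, -1.35, -2.05),
    O2P = c(-3.00, -2.60, -3.60), C60 = c(3.55, 1.45, -1.45),
    C61 = c(-3.40, 1.75, -1.50), C62 = c(0.55, 3.75, -1.45),
    C63 = c(-0.85, -3.70, -1.45), C64 = c(4.60, -0.85, -1.40),
    C65 = c(-4.55, -0.30, -1.40), C66 = c(2.35, 4.35, -1.35),
    C67 = c(-2.15, 4.45, -1.35), C68 = c(2.05, -4.50, -1.35),
    C69 = c(-4.20, -2.85, -1.35))
  xyz <- rbind(xyz, c(0, 0, 0), c(0, 0, -2.2), lower)
  names <- c(tpl$name, "CO", "N3B", rownames(lower))
  if (noise > 0)
    xyz <- xyz + .with_seed(seed, matrix(rnorm(length(xyz), 0, noise),
                                         nrow(xyz), 3))
  b12_structure(.mk_atoms(names, xyz, "B12", "L", 1L),
                id = sprintf("corrin_fold%.1f", fold_angle))
}

# Sparse glutathione-like pseudo-chain anchored at the beta face; atoms
# spaced ~2.6-2.8 A so single-clash constructions are unambiguous.
.gsh_sparse <- function() {
  p <- rbind(SG2 = c(0, 0, 2.4),    CB2 = c(2.0, 0.8, 4.2),
             CA2 = c(3.4, 1.8, 6.3), N2 = c(2.6, 3.9, 7.9),
             C2 = c(0.6, 5.1, 9.0),  O2 = c(-1.6, 5.9, 10.0),
             N3 = c(-3.5, 5.2, 8.6), CA3 = c(-5.2, 4.3, 7.1),
             C3 = c(-6.0, 2.3, 5.9), O11 = c(-5.6, 0.2, 5.3))
  .mk_atoms(rownames(p), p, "GSH", "L", 2L)
}

# Full glutathione with the chemical-component atom naming, anchored at
# the beta face (SG2 bonded to Co at 2.4 A).
.gsh_full <- function() {
  p <- rbind(
    SG2 = c(0.00, 0.00, 2.40), CB2 = c(1.25, 0.55, 3.25),
    CA2 = c(1.40, 0.50, 4.75), N2  = c(0.55, 1.50, 5.30),
    C2  = c(2.80, 0.75, 5.30), O2  = c(3.80, 0.10, 5.00),
    N3  = c(3.00, 1.80, 6.05), CA3 = c(4.30, 2.10, 6.55),
    C3  = c(4.35, 3.45, 7.25), O31 = c(3.30, 4.10, 7.35),
    O32 = c(5.45, 3.85, 7.60), CD1 = c(-0.70, 1.80, 5.75),
    OE1 = c(-1.85, 1.55, 5.45), CG1 = c(-0.45, 2.85, 6.75),
    CB1 = c(-1.55, 3.75, 7.05), CA1 = c(-1.25, 4.70, 8.15),
    N1  = c(-0.05, 5.40, 7.90), C1  = c(-2.40, 5.65, 8.45),
    O11 = c(-3.50, 5.30, 8.85), O12 = c(-2.25, 6.85, 8.30))
  .mk_atoms(rownames(p), p, "GSH", "L", 2L)
}

# Quasi-uniform shell atoms between polar angles [th1, th2] (degrees,
# from +z) at the given radius, thinned against a set of keep-out
# coordinates.
.shell_cap <- function(radius, th_deg, n_sphere, avoid_xyz, clearance = 3.6) {
  pts <- .sphere_points(n_sphere) * radius
  th <- acos(pmin(1, pmax(-1, pts[, 3] / radius))) * 180 / pi
  pts <- pts[th >= th_deg[1] & th <= th_deg[2], , drop = FALSE]
  if (!is.null(avoid_xyz) && nrow(avoid_xyz) > 0 && nrow(pts) > 0) {
    d <- .cross_dist(pts, avoid_xyz)
    pts <- pts[apply(d, 1, min) > clearance, , drop = FALSE]
  }
  pts
}

#' Generate a minimal synthetic binding pocket
#'
#' A folded corrin plus a sparse glutathione-like chain on the beta face,
#' enclosed in a shell of apolar pseudo-protein atoms kept clear of the
#' ligand.  With \code{block_offset} set, one carbon atom is placed on
#' the beta-axial axis at \code{block_offset} angstrom from the
#' glutathione sulfur site, forcing a single steric clash of
#' hand-computable overlap when the glutathione is transplanted back:
#' overlap = r_C + r_S - soft_tol - block_offset.
#'
#' @param block_offset \code{NULL} (open pocket) or distance in angstrom
#'   (sensible range 0.5-2) of the blocking carbon from the sulfur site.
#' @param shell_radius radius of the pseudo-protein shell (angstrom).
#' @param fold_angle corrin fold angle (degrees).
#' @param seed RNG seed (determinism only; the construction is
#'   deterministic).
#' @return A [b12_structure()] labelled synthetic.
#' @export
make_pocket <- function(block_offset = NULL, shell_radius = 12,
                        fold_angle = 5, seed = 1) {
  corrin <- as.data.frame(make_corrin(fold_angle, seed = seed))
  gsh <- .gsh_sparse()
  lig_xyz <- rbind(as.matrix(corrin[, c("x", "y", "z")]),
                   as.matrix(gsh[, c("x", "y", "z")]))
  shell <- .shell_cap(shell_radius, c(0, 180), 400, lig_xyz)
  prot <- .mk_atoms(rep("CB", nrow(shell)), shell, "ALA", "A",
                    seq_len(nrow(shell)) + 10L, element = "C")
  atoms <- rbind(corrin[, names(prot)], gsh[, names(prot)], prot)
  if (!is.null(block_offset)) {
    if (block_offset <= 0 || block_offset > 2.3)
      stop("block_offset must lie in (0, 2.3] angstrom")
    blk <- .mk_atoms("CB", matrix(c(0, 0, 2.4 - block_offset), 1, 3),
                     "ALA", "A", 5L, element = "C")
    atoms <- rbind(atoms, blk)
  }
  b12_structure(atoms, id = if (is.null(block_offset)) "synthetic_pocket_open"
                else sprintf("synthetic_pocket_block%.1f", block_offset))
}

# Choose, among quasi-uniform candidate directions, a placement at
# `dist` from `anchor`, staying > polar_floor from every polar atom that
# must not gain a contact and > steric_floor from everything else; the
# anchor itself is excluded from both sets.  Deterministic.
.place_near <- function(anchor, dist, polar_xyz, steric_xyz,
                        polar_floor = 3.55, steric_floor = 2.55) {
  drop_anchor <- function(m) {
    if (is.null(m) || nrow(m) == 0) return(m)
    keep <- sqrt(colSums((t(m) - anchor)^2)) > 1e-6
    m[keep, , drop = FALSE]
  }
  polar_xyz <- drop_anchor(polar_xyz)
  steric_xyz <- drop_anchor(steric_xyz)
  nc <- 960
  cand <- .sphere_points(nc) * dist +
    matrix(anchor, nc, 3, byrow = TRUE)
  margin <- function(m, floor) {
    if (is.null(m) || nrow(m) == 0) rep(Inf, nrow(cand))
    else apply(.cross_dist(cand, m), 1, min) - floor
  }
  score <- pmin(margin(polar_xyz, polar_floor),
                margin(steric_xyz, steric_floor))
  best <- which.max(score)
  if (score[best] <= 0)
    stop("designed-contact placement failed: pocket too crowded")
  cand[best, ]
}

#' Generate a synthetic transcobalamin-like cobalamin complex
#'
#' Builds, entirely in code, a stand-in for a cobalamin-transporter
#' complex with known ground truth in every analysis dimension: a corrin
#' with a prescribed fold angle and axial geometry (glutathionyl sulfur
#' at 2.40 angstrom or histidine NE2 at 2.10 angstrom on the beta face,
#' dimethylbenzimidazole nitrogen at 2.20 angstrom on the alpha face);
#' four disulfide-bonded cysteine pairs at the canonical transcobalamin
#' positions (21-268, 83-96, 116-310, 165-208); for the glutathionyl
#' form, a designed polar-contact network of 4 direct contacts (Ser195,
#' Thr198 side chains and the Tyr154/Tyr155 helix N-terminal amides
#' against the gamma-glutamate carboxylate) plus 10 water-mediated
#' bridges; and a two-domain pseudo-protein envelope (alpha: residues
#' below 315, beta: 320 and up) whose buried-interface areas rank
#' ligand/beta > ligand/alpha > alpha/beta.  The \code{"blocked"} pocket
#' variant inserts loop atoms over the beta face where the glutathione
#' would sit, emulating the occluded haptocorrin/intrinsic-factor
#' pockets.
#'
#' This is a synthetic object: geometry is idealized, not
#' crystallographic, and it stands in for deposited coordinates wherever
#' those are analysed.
#'
#' @param ligand \code{"GSCbl"} (glutathionylcobalamin, default fold
#'   angle 6.6 degrees) or \code{"HOCbl"} (histidine-ligated, default
#'   fold 5.3 degrees).
#' @param pocket \code{"open"} (transcobalamin-like) or \code{"blocked"}
#'   (haptocorrin/intrinsic-factor-like).
#' @param fold_angle override of the default fold angle (degrees).
#' @param seed RNG seed (the construction itself is deterministic).
#' @return A [b12_structure()] labelled synthetic.  Chains: L ligand,
#'   A protein, W waters.
#' @export
make_tc_complex <- function(ligand = c("GSCbl", "HOCbl"),
                            pocket = c("open", "blocked"),
                            fold_angle = NULL, seed = 1) {
  ligand <- match.arg(ligand)
  pocket <- match.arg(pocket)
  if (is.null(fold_angle)) fold_angle <- if (ligand == "GSCbl") 6.6 else 5.3
  corrin <- as.data.frame(make_corrin(fold_angle, seed = seed))
  cols <- c("name", "resname", "chain", "resseq", "x", "y", "z", "element")
  parts <- list(corrin[, cols])
  avoid <- as.matrix(corrin[, c("x", "y", "z")])

  add <- function(df) {
    parts[[length(parts) + 1]] <<- df[, cols]
    avoid <<- rbind(avoid, as.matrix(df[, c("x", "y", "z")]))
  }

  his <- rbind(NE2 = c(0.00, 0.00, 2.10), CE1 = c(1.25, 0.10, 2.70),
               ND1 = c(1.75, 0.30, 3.95), CD2 = c(-0.45, 0.60, 3.25),
               CG = c(0.65, 0.75, 4.30),  CB = c(0.85, 1.45, 5.60),
               CA = c(-0.25, 2.45, 5.95), N = c(-1.50, 1.85, 6.25),
               C = c(0.10, 3.30, 7.10),   O = c(-0.60, 4.25, 7.35))
  if (ligand == "GSCbl") {
    gsh <- .gsh_full()
    add(gsh)
    # outward-facing His193 loop, swung away from the occupied beta site
    his_out <- sweep(his, 2, c(6.5, -4.0, 2.2), "+")
    add(.mk_atoms(rownames(his_out), his_out, "HIS", "A", 193L))
  } else {
    add(.mk_atoms(rownames(his), his, "HIS", "A", 193L))
  }

  # four disulfide-bonded cysteine pairs (SG-SG 2.05 A)
  ss_pairs <- list(c(21L, 268L), c(83L, 96L), c(116L, 310L), c(165L, 208L))
  ss_ctr <- rbind(c(8.5, -3.0, 7.0), c(-8.5, -3.5, 6.0),
                  c(1.5, -9.0, 7.5), c(-2.5, -8.0, 8.8))
  ss_tan <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0), c(1, 1, 0) / sqrt(2))
  for (k in seq_along(ss_pairs)) {
    for (m in 1:2) {
      sg <- ss_ctr[k, ] + (if (m == 1) -1 else 1) * 1.025 * ss_tan[k, ]
      add(.mk_atoms("SG", matrix(sg, 1, 3), "CYS", "A", ss_pairs[[k]][m],
                    element = "S"))
    }
  }

  waters <- NULL
  if (ligand == "GSCbl") {
    gsh_xyz <- as.matrix(gsh[, c("x", "y", "z")])
    rownames(gsh_xyz) <- gsh$name
    lig_polar <- gsh_xyz[gsh$element %in% c("N", "O"), , drop = FALSE]
    at <- function(nm) gsh_xyz[nm, ]
    # polar atoms that must not gain an undesigned contact: ligand polar
    # atoms, the outward His193 nitrogens/oxygen, and every designed
    # polar atom placed so far
    polar_avoid <- rbind(lig_polar,
                         his_out[c("NE2", "ND1", "N", "O"), , drop = FALSE])
    # 4 direct polar contacts
    direct <- list(list("N2", "SER", 195L, "OG", 2.70),
                   list("O2", "THR", 198L, "OG1", 2.80),
                   list("O11", "TYR", 154L, "N", 2.90),
                   list("O12", "TYR", 155L, "N", 2.90))
    for (d in direct) {
      p <- .place_near(at(d[[1]]), d[[5]], polar_avoid, avoid)
      add(.mk_atoms(d[[4]], matrix(p, 1, 3), d[[2]], "A", d[[3]]))
      polar_avoid <- rbind(polar_avoid, matrix(p, 1, 3))
    }
    # 10 water-mediated bridges (ligand atom - water - serine OG),
    # distributed over the glutathione polar atoms; anchors that run out
    # of uncrowded directions are skipped deterministically
    anchor_cycle <- rep(c("N1", "OE1", "N3", "O31", "O32", "N2", "O2",
                          "O11", "O12"), 3)
    wrows <- list()
    k <- 0
    for (nm in anchor_cycle) {
      if (k >= 10) break
      placed <- tryCatch({
        w <- .place_near(at(nm), 2.80, polar_avoid, avoid)
        # the bridge partner must stay clear of every ligand polar atom
        # (no accidental direct contact) and of every other water
        p <- .place_near(w, 2.80, rbind(polar_avoid, at(nm)), avoid)
        list(w = w, p = p)
      }, error = function(e) NULL)
      if (is.null(placed)) next
      k <- k + 1
      add(.mk_atoms("OG", matrix(placed$p, 1, 3), "SER", "A", 39L + k))
      polar_avoid <- rbind(polar_avoid, placed$w, placed$p)
      wrows[[k]] <- .mk_atoms("O", matrix(placed$w, 1, 3), "HOH", "W",
                              400L + k)
      avoid <- rbind(avoid, matrix(placed$w, 1, 3))
    }
    if (k < 10)
      stop("could not place 10 water bridges; pocket too crowded")
    waters <- do.call(rbind, wrows)
  }

  if (pocket == "blocked") {
    loop <- rbind(c(0.30, 0.60, 3.40), c(1.60, 1.10, 4.90),
                  c(2.70, 2.00, 6.30), c(0.10, 2.60, 5.90))
    add(.mk_atoms(rep("CB", 4), loop, "ALA", "A", 185L:188L, element = "C"))
  }

  # two-domain pseudo-protein envelope: the beta domain cups the lower
  # face and the equatorial rim of the cobalamin, the alpha domain
  # encloses the upper (beta-face) hemisphere at larger radius, with the
  # two domains adjoining only along a narrow seam.  In the
  # glutathionyl form the upper space is occupied by the glutathione
  # (which contacts the outer alpha envelope); in the histidine-ligated
  # form the alpha domain instead closes down onto the unoccupied face,
  # mirroring the inward alpha7/alpha8-loop conformation.
  if (ligand == "GSCbl") {
    beta_shell <- rbind(.shell_cap(6.8, c(95, 180), 700, avoid, 2.9),
                        .shell_cap(8.3, c(80, 102), 350, avoid, 3.1))
    alpha_shell <- .shell_cap(14.0, c(12, 70), 350, avoid, 3.6)
  } else {
    beta_shell <- rbind(.shell_cap(6.8, c(95, 180), 700, avoid, 2.9),
                        .shell_cap(8.3, c(86, 102), 350, avoid, 3.1))
    alpha_shell <- rbind(.shell_cap(14.0, c(12, 66), 350, avoid, 3.6),
                         .shell_cap(5.8, c(0, 52), 300, avoid, 2.9))
  }
  used <- unique(unlist(lapply(parts, function(p)
    p$resseq[p$chain == "A"])))
  alpha_free <- setdiff(2:314, used)
  if (nrow(alpha_shell) > length(alpha_free))
    alpha_shell <- alpha_shell[seq_along(alpha_free), , drop = FALSE]
  add(.mk_atoms(rep("CB", nrow(alpha_shell)), alpha_shell, "ALA", "A",
                alpha_free[seq_len(nrow(alpha_shell))], element = "C"))
  add(.mk_atoms(rep("CB", nrow(beta_shell)), beta_shell, "ALA", "A",
                319L + seq_len(nrow(beta_shell)), element = "C"))
  if (!is.null(waters)) parts[[length(parts) + 1]] <- waters[, cols]

  b12_structure(do.call(rbind, parts),
                id = sprintf("synthetic_rTC_%s_%s", ligand, pocket))
}

#' Generate a synthetic absorbance spectrum
#'
#' Gaussian-sum spectrum on a 300-700 nm, 1 nm grid.
#'
#' @param peaks list of length-3 numeric vectors (center nm, height AU,
#'   sd nm).
#' @param seed RNG seed (consumed when \code{noise > 0}).
#' @param noise additive Gaussian noise sd (AU).
#' @param grid wavelength grid (nm).
#' @param label spectrum label.
#' @return A [spectrum()].
#' @export
make_spectrum <- function(peaks, seed = 1, noise = 0,
                          grid = seq(300, 700, by = 1), label = "synthetic") {
  a <- rep(0, length(grid))
  for (p in peaks) a <- a + p[2] * exp(-(grid - p[1])^2 / (2 * p[3]^2))
  if (noise > 0) a <- a + .with_seed(seed, rnorm(length(grid), 0, noise))
  spectrum(grid, a, label = label)
}

#' Canonical cobalamin band presets for synthetic spectra
#'
#' Two-band descriptions emulating the diagnostic difference between a
#' histidine/hydroxo-ligated cobalamin and the glutathionyl form: the
#' gamma band collapses to roughly half height and shifts red, and the
#' alpha/beta band shifts red by roughly 12 nm.
#'
#' @param form \code{"HOCbl"} or \code{"GSCbl"}.
#' @return A peak list for [make_spectrum()].
#' @export
cobalamin_peaks <- function(form = c("HOCbl", "GSCbl")) {
  switch(match.arg(form),
         HOCbl = list(c(356, 1.00, 12), c(527, 0.45, 20)),
         GSCbl = list(c(368, 0.50, 14), c(539, 0.45, 20)))
}

#' Generate a synthetic thermophoresis dilution series
#'
#' A 16-point two-fold dilution from a stated top concentration with
#' responses from the 1:1 probe-depletion isotherm; noise is i.i.d.
#' Gaussian on the per-mil response, with sd expressed as a fraction of
#' the response amplitude.  Raw capillary traces consistent with the
#' responses are emitted alongside (cold plateau before laser-on at
#' t = 0, exponential approach to the hot plateau).
#'
#' @param kd dissociation constant (molar).
#' @param probe labelled-probe concentration (molar).
#' @param amplitude response amplitude in per-mil (sign = direction of
#'   the thermophoresis change on binding).
#' @param noise noise sd as a fraction of \code{abs(amplitude)}.
#' @param seed RNG seed.
#' @param n number of dilution points.
#' @param top top ligand concentration (molar).
#' @param f0 unbound-state Fnorm (per-mil).
#' @param f_cold cold-state fluorescence (counts).
#' @return List with \code{concentrations} (ascending),
#'   \code{delta_fnorm} (per-mil responses), \code{traces} (list of
#'   [mst_trace()]) and \code{truth}.
#' @export
make_mst <- function(kd, probe, amplitude = -20, noise = 0, seed = 1,
                     n = 16, top = 800e-9, f0 = 940, f_cold = 900) {
  conc <- top / 2^((n - 1):0)
  fb <- .bound_fraction(conc, probe, kd)
  fn <- f0 + amplitude * fb
  if (noise > 0)
    fn <- fn + .with_seed(seed, rnorm(n, 0, noise * abs(amplitude)))
  tm <- seq(-2, 21, by = 0.05)
  traces <- lapply(seq_len(n), function(i) {
    plateau <- fn[i] / 1000
    f <- ifelse(tm < 0, 1, plateau + (1 - plateau) * exp(-tm / 1.5))
    mst_trace(tm, f_cold * f, conc[i])
  })
  list(concentrations = conc, delta_fnorm = fn, traces = traces,
       truth = list(kd = kd, probe = probe, amplitude = amplitude,
                    f0 = f0, noise = noise))
}

#' Generate a random protein sequence
#'
#' @param n sequence length.
#' @param seed RNG seed.
#' @return A character string over the 20 standard residues.
#' @export
make_sequence <- function(n, seed = 1) {
  aa <- setdiff(.aa_alphabet, "X")
  .with_seed(seed, paste(sample(aa, n, replace = TRUE), collapse = ""))
}

#' Generate a homolog by point substitution
#'
#' @param reference reference sequence (character string).
#' @param mutations either an integer count of substitutions (positions
#'   drawn under the seed) or an integer vector of positions.
#' @param seed RNG seed.
#' @return List with \code{sequence}, \code{positions}, \code{from},
#'   \code{to}.
#' @export
make_homolog <- function(reference, mutations, seed = 1) {
  chars <- strsplit(reference, "")[[1]]
  aa <- setdiff(.aa_alphabet, "X")
  .with_seed(seed, {
    # a single number is a count; a vector is explicit positions
    pos <- if (length(mutations) == 1)
      sort(sample(length(chars), mutations)) else sort(unique(mutations))
    if (any(pos < 1 | pos > length(chars)))
      stop("mutation positions outside the sequence")
    from <- chars[pos]
    to <- vapply(from, function(ch) sample(setdiff(aa, ch), 1), character(1))
    chars[pos] <- to
    list(sequence = paste(chars, collapse = ""), positions = pos,
         from = from, to = to)
  })
}

#' Generate a smooth random C-alpha trace
#'
#' A self-avoiding-ish random walk with directional momentum and 3.8
#' angstrom steps, returned as a C-alpha-only structure; useful for
#' superposition and domain-deviation tests.
#'
#' @param n_res number of residues.
#' @param seed RNG seed.
#' @param chain chain identifier.
#' @return A [b12_structure()] with one CA atom per residue.
#' @export
make_ca_trace <- function(n_res, seed = 1, chain = "A") {
  xyz <- .with_seed(seed, {
    d <- c(1, 0, 0)
    out <- matrix(0, n_res, 3)
    for (i in 2:n_res) {
      d <- 0.75 * d + 0.25 * rnorm(3)
      d <- d / sqrt(sum(d^2))
      out[i, ] <- out[i - 1, ] + 3.8 * d
    }
    out
  })
  b12_structure(.mk_atoms(rep("CA", n_res), xyz, "ALA", chain,
                          seq_len(n_res), element = "C"),
                id = sprintf("synthetic_ca_trace_%d", n_res))
}
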