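# Squared-distance matrix between two coordinate matrices.
.cross_dist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.atom_desc <- function(s, i) {
  sprintf("%s/%s%d/%s", s$chain[i], s$resname[i], s$resseq[i], s$name[i])
}

#' Polar contacts between a ligand and a protein
#'
#' Enumerates hydrogen-bond-like polar contacts by donor-acceptor
#' distance: a direct contact is a polar (N or O) ligand atom within
#' \code{cutoff} of a polar protein atom; a water bridge is a ligand polar
#' atom and a protein polar atom each within \code{cutoff} of the same
#' water oxygen.  No angle term is applied by default.  Each
#' (ligand atom, protein atom) pair, or (ligand atom, water, protein atom)
#' triple, is reported once.
#'
#' @param structure a [b12_structure()] containing ligand, protein and
#'   (for bridges) waters.
#' @param ligand selection expression for the ligand atoms.
#' @param protein selection expression for the protein atoms (default:
#'   all standard amino-acid residues).
#' @param waters selection expression for waters, or \code{"auto"} (all
#'   HOH/WAT/DOD oxygens), or \code{NULL} to skip bridge detection.
#' @param cutoff donor-acceptor distance cutoff in angstrom.
#' @param include_sulfur treat sulfur as hydrogen-bond capable in the
#'   ligand and protein (thiol/thioether donors); default \code{FALSE}.
#' @return An object of class \code{contact_report}: data frame with
#'   columns \code{kind} (\code{direct}/\code{water_bridge}),
#'   \code{ligand_atom}, \code{protein_atom}, \code{water},
#'   \code{distance} (for bridges, the longer of the two legs), plus
#'   attributes \code{n_direct} and \code{n_water}.
#' @export
polar_contacts <- function(structure, ligand, protein = "protein",
                           waters = "auto", cutoff = 3.5,
                           include_sulfur = FALSE) {
  s <- reduce_altlocs(structure)
  lig <- select_atoms(s, ligand)
  pro <- select_atoms(s, protein)
  pol <- function(x) {
    el <- c("N", "O", if (include_sulfur) "S")
    x[x$element %in% el, , drop = FALSE]
  }
  ligp <- pol(lig); prop <- pol(pro)
  rows <- list()
  if (nrow(ligp) > 0 && nrow(prop) > 0) {
    d <- .cross_dist(coords(ligp), coords(prop))
    hit <- which(d <= cutoff, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      i <- hit[k, 1]; j <- hit[k, 2]
      rows[[length(rows) + 1]] <- data.frame(
        kind = "direct", ligand_atom = .atom_desc(ligp, i),
        protein_atom = .atom_desc(prop, j), water = NA_character_,
        distance = d[i, j], stringsAsFactors = FALSE)
    }
  }
  if (!is.null(waters)) {
    wsel <- if (identical(waters, "auto")) "water and elem O" else waters
    wat <- select_atoms(s, wsel)
    if (nrow(wat) > 0 && nrow(ligp) > 0 && nrow(prop) > 0) {
      dlw <- .cross_dist(coords(ligp), coords(wat))
      dwp <- .cross_dist(coords(wat), coords(prop))
      for (w in seq_len(nrow(wat))) {
        li <- which(dlw[, w] <= cutoff)
        pj <- which(dwp[w, ] <= cutoff)
        for (i in li) for (j in pj) {
          rows[[length(rows) + 1]] <- data.frame(
            kind = "water_bridge", ligand_atom = .atom_desc(ligp, i),
            protein_atom = .atom_desc(prop, j),
            water = .atom_desc(wat, w),
            distance = max(dlw[i, w], dwp[w, j]), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(kind = character(0), ligand_atom = character(0),
               protein_atom = character(0), water = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  out <- unique(out)
  rownames(out) <- NULL
  attr(out, "n_direct") <- sum(out$kind == "direct")
  attr(out, "n_water") <- sum(out$kind == "water_bridge")
  class(out) <- c("contact_report", "data.frame")
  out
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("Polar contacts: %d total (%d direct, %d water-mediated)\n",
              nrow(x), attr(x, "n_direct"), attr(x, "n_water")))
  if (nrow(x) > 0) print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Detect disulfide bonds
#'
#' Pairs cysteine SG atoms within \code{max_ss} of each other, greedily by
#' ascending distance so that no cysteine appears in more than one pair.
#'
#' @param structure a [b12_structure()].
#' @param max_ss maximum S-S bond length (angstrom).
#' @return Data frame with one row per bond: chains, residue numbers and
#'   the S-S distance, ordered by residue number of the first partner.
#' @export
find_disulfides <- function(structure, max_ss = 2.5) {
  s <- reduce_altlocs(structure)
  sg <- s[s$resname == "CYS" & s$name == "SG", , drop = FALSE]
  empty <- data.frame(chain1 = character(0), resno1 = integer(0),
                      chain2 = character(0), resno2 = integer(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sg) < 2) return(empty)
  d <- .cross_dist(coords(sg), coords(sg))
  cand <- which(upper.tri(d) & d <= max_ss, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used <- rep(FALSE, nrow(sg))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    lo <- if (sg$resseq[i] <= sg$resseq[j]) i else j
    hi <- if (lo == i) j else i
    rows[[length(rows) + 1]] <- data.frame(
      chain1 = sg$chain[lo], resno1 = sg$resseq[lo],
      chain2 = sg$chain[hi], resno2 = sg$resseq[hi],
      distance = d[i, j], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$resno1), , drop = FALSE]
}

#' Helix-dipole contact of a carboxylate
#'
#' Tests whether a carboxylate interacts with the positive pole of an
#' alpha-helix: true when any carboxylate oxygen lies within \code{cutoff}
#' of a backbone amide nitrogen of the helix's first two residues.
#'
#' @param structure a [b12_structure()].
#' @param carboxylate selection expression for the carboxylate oxygens.
#' @param helix_residues integer vector of residue numbers; the first two
#'   are taken as the helix N-terminal residues.
#' @param chain chain of the helix residues.
#' @param cutoff distance cutoff (angstrom).
#' @return List with \code{contact} (logical) and \code{min_dist}.
#' @export
helix_dipole_contact <- function(structure, carboxylate, helix_residues,
                                 chain = "A", cutoff = 3.5) {
  s <- reduce_altlocs(structure)
  ox <- select_atoms(s, carboxylate)
  ox <- ox[ox$element == "O", , drop = FALSE]
  if (nrow(ox) == 0) stop("carboxylate selection contains no oxygens")
  nt <- head(sort(unique(helix_residues)), 2)
  am <- s[s$chain == chain & s$resseq %in% nt & s$name == "N", , drop = FALSE]
  if (nrow(am) == 0) return(list(contact = FALSE, min_dist = Inf))
  dmin <- min(.cross_dist(coords(ox), coords(am)))
  list(contact = dmin <= cutoff, min_dist = dmin)
}
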