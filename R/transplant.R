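#' Transplant a glutathionyl adduct into another cobalamin pocket
#'
#' Reproduces the ligand-transplant construction used to ask whether a
#' transporter pocket could accommodate glutathionylcobalamin: the corrin
#' of the source complex is superimposed (Kabsch, matched by atom name on
#' the 13 butterfly atoms plus cobalt) onto the corrin bound in the target
#' structure, the transform is applied to the glutathione atoms only, and
#' steric overlap of the transplanted atoms with the target protein is
#' scored.  The target keeps its own cobalamin, which is excluded from the
#' clash check along with all waters: a clash is counted between
#' transplanted atom i and target protein atom j when
#' d(i, j) < r_i + r_j - soft_tol.
#'
#' @param source [b12_structure()] containing a corrin plus a glutathione
#'   component bonded at the beta face.
#' @param target [b12_structure()] containing any bound cobalamin.
#' @param soft_tol soft van der Waals overlap tolerance in angstrom; a
#'   "severe" tier is always reported at 0.6.
#' @param gsh selection expression identifying the transplanted atoms in
#'   \code{source}.
#' @param radii radius set from [default_radii()].
#' @param max_fit_rmsd corrin-fit RMSD above which the superposition is
#'   rejected as unreliable.
#' @return An object of class \code{clash_report}: list with
#'   \code{n_clashes}, \code{n_severe}, \code{worst_overlap},
#'   \code{clashes} (data frame of target atoms and overlaps),
#'   \code{corrin_fit_rmsd}, \code{n_fit_atoms}, \code{transform} and
#'   \code{transplanted} (the moved atoms, as a structure).
#' @export
transplant <- function(source, target, soft_tol = 0.4, gsh = "resn GSH",
                       radii = default_radii(), max_fit_rmsd = 1.5) {
  cs <- extract_corrin(source)
  ct <- extract_corrin(target)
  ring <- function(cr) {
    at <- rbind(cr$equatorial_n, cr$ring_carbons, cr$co)
    at$label <- ifelse(at$element == "Co", "CO", at$name)
    at
  }
  rs <- ring(cs); rt <- ring(ct)
  fit_names <- intersect(intersect(c(union(.butterfly_a, .butterfly_b), "CO"),
                                   rs$label), rt$label)
  if (length(fit_names) < 8)
    stop("only ", length(fit_names),
         " matched corrin atoms; at least 8 are required")
  sup <- kabsch(coords(rs[match(fit_names, rs$label), ]),
                coords(rt[match(fit_names, rt$label), ]))
  if (sup$rmsd > max_fit_rmsd)
    stop(sprintf("corrin superposition unreliable (rmsd %.2f A > %.2f A)",
                 sup$rmsd, max_fit_rmsd))
  payload <- select_atoms(reduce_altlocs(source), gsh)
  if (nrow(payload) == 0) stop("source has no atoms matching '", gsh, "'")
  moved <- apply_transform(payload, sup)

  tgt <- reduce_altlocs(target)
  prot <- select_atoms(tgt, "protein and not water")
  prot <- prot[prot$element != "H", , drop = FALSE]
  mv <- moved[moved$element != "H", , drop = FALSE]
  r_i <- .atom_radii(mv$element, radii)
  r_j <- .atom_radii(prot$element, radii)
  d <- .cross_dist(coords(mv), coords(prot))
  lim <- outer(r_i, r_j, "+")
  ov <- lim - soft_tol - d
  hit <- which(ov > 0, arr.ind = TRUE)
  clashes <- if (nrow(hit) == 0) {
    data.frame(ligand_atom = character(0), chain = character(0),
               resname = character(0), resno = integer(0),
               atom = character(0), overlap = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(ligand_atom = mv$name[hit[, 1]],
               chain = prot$chain[hit[, 2]],
               resname = prot$resname[hit[, 2]],
               resno = prot$resseq[hit[, 2]],
               atom = prot$name[hit[, 2]],
               overlap = ov[hit], stringsAsFactors = FALSE)
  }
  clashes <- clashes[order(-clashes$overlap), , drop = FALSE]
  rownames(clashes) <- NULL
  out <- list(n_clashes = nrow(clashes),
              n_severe = sum(lim - d > 0.6),
              worst_overlap = if (nrow(clashes) > 0) max(clashes$overlap) else 0,
              clashes = clashes,
              corrin_fit_rmsd = sup$rmsd,
              n_fit_atoms = length(fit_names),
              transform = sup,
              transplanted = moved,
              soft_tol = soft_tol)
  class(out) <- "clash_report"
  out
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf(paste0("Ligand-transplant clash report (soft tol %.2f A, ",
                     "corrin fit rmsd %.3f A on %d atoms)\n"),
              x$soft_tol, x$corrin_fit_rmsd, x$n_fit_atoms))
  cat(sprintf("  clashes: %d (%d severe), worst overlap %.2f A\n",
              x$n_clashes, x$n_severe, x$worst_overlap))
  if (x$n_clashes > 0)
    print.data.frame(head(x$clashes, 10), row.names = FALSE, digits = 3)
  invisible(x)
}
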