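# Atom names of the two corrin "butterfly" half-planes; C10 is shared.
.butterfly_a <- c("N21", "C4", "C5", "C6", "N22", "C9", "C10")
.butterfly_b <- c("C10", "C11", "N23", "C14", "C15", "C16", "N24")

#' Locate the corrin ring of a cobalamin
#'
#' Identification is chemistry-based, not component-code-based: the corrin
#' is the unique residue containing a cobalt atom equatorially coordinated
#' by at least four nitrogens within 2.5 angstrom (hydroxo-, glutathionyl-
#' and cyanocobalamin carry different three-letter codes across entries).
#' The alpha-axial (lower, dimethylbenzimidazole-side) nitrogen is the
#' non-equatorial nitrogen coordinating cobalt; the beta-axial atom is the
#' nearest non-corrin heavy atom within 3.0 angstrom on the opposite face.
#'
#' Alternate locations are reduced to the highest-occupancy conformer
#' before any geometry is measured.
#'
#' @param structure a [b12_structure()].
#' @param coord_cutoff cobalt coordination cutoff for the equatorial and
#'   alpha-axial nitrogens (angstrom).
#' @param beta_cutoff search cutoff for the beta-axial atom (angstrom).
#' @return An object of class \code{corrin_atoms}: list with elements
#'   \code{co}, \code{equatorial_n}, \code{ring_carbons}, \code{dmb_n},
#'   \code{beta_atom} (single-row atom tables or \code{NULL}) and
#'   \code{residue}.
#' @export
extract_corrin <- function(structure, coord_cutoff = 2.5, beta_cutoff = 3.0) {
  s <- reduce_altlocs(structure)
  s <- s[s$element != "H", , drop = FALSE]
  xyz <- coords(s)
  co_idx <- which(s$element == "Co")
  candidates <- integer(0)
  for (i in co_idx) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    n_near <- sum(s$element == "N" & d <= coord_cutoff)
    if (n_near >= 4) candidates <- c(candidates, i)
  }
  if (length(candidates) != 1) {
    desc <- if (length(candidates) == 0) "none" else
      paste(sprintf("%s %s %d", s$chain[candidates], s$resname[candidates],
                    s$resseq[candidates]), collapse = "; ")
    stop("expected exactly one corrin candidate (Co coordinated by >= 4 N), ",
         "found: ", desc)
  }
  i <- candidates
  co <- s[i, , drop = FALSE]
  same_res <- s$chain == co$chain & s$resseq == co$resseq & s$icode == co$icode
  res <- s[same_res, , drop = FALSE]
  eq <- res[res$name %in% c("N21", "N22", "N23", "N24"), , drop = FALSE]
  if (nrow(eq) != 4)
    stop("corrin residue lacks the four equatorial nitrogens N21-N24 (found ",
         nrow(eq), ")")
  ring <- res[grepl("^C([1-9]|1[0-9])$", res$name), , drop = FALSE]
  ring_names <- c(eq$name, ring$name, co$name)

  d_all <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
  pl <- fit_plane(coords(eq))
  side <- drop((xyz - matrix(xyz[i, ], nrow(xyz), 3, byrow = TRUE)) %*% pl$normal)

  ax_cand <- which(d_all > 0 & d_all <= beta_cutoff &
                     !(same_res & s$name %in% ring_names))
  # alpha axial: coordinating non-equatorial nitrogen, same component first
  n_cand <- ax_cand[s$element[ax_cand] == "N" & d_all[ax_cand] <= coord_cutoff]
  dmb_i <- if (length(n_cand) == 0) NA_integer_ else {
    own <- n_cand[same_res[n_cand]]
    pool <- if (length(own) > 0) own else n_cand
    pool[which.min(d_all[pool])]
  }
  dmb <- if (is.na(dmb_i)) NULL else s[dmb_i, , drop = FALSE]
  beta <- NULL
  if (!is.na(dmb_i)) {
    opp <- ax_cand[sign(side[ax_cand]) != sign(side[dmb_i]) & ax_cand != dmb_i]
    if (length(opp) > 0) beta <- s[opp[which.min(d_all[opp])], , drop = FALSE]
  } else {
    # base-off: take the two nearest axial candidates on opposite faces
    up <- ax_cand[side[ax_cand] > 0]
    if (length(up) > 0) beta <- s[up[which.min(d_all[up])], , drop = FALSE]
  }
  out <- list(co = co, equatorial_n = eq, ring_carbons = ring, dmb_n = dmb,
              beta_atom = beta,
              residue = list(chain = co$chain, resseq = co$resseq,
                             resname = co$resname))
  class(out) <- "corrin_atoms"
  out
}

#' @export
print.corrin_atoms <- function(x, ...) {
  cat(sprintf("<corrin_atoms> %s %s %d: Co + %d equatorial N + %d ring C\n",
              x$residue$chain, x$residue$resname, x$residue$resseq,
              nrow(x$equatorial_n), nrow(x$ring_carbons)))
  if (!is.null(x$dmb_n))
    cat(sprintf("  alpha-axial N: %s (%s %d)\n", x$dmb_n$name,
                x$dmb_n$resname, x$dmb_n$resseq))
  if (!is.null(x$beta_atom))
    cat(sprintf("  beta-axial atom: %s (%s %d)\n", x$beta_atom$name,
                x$beta_atom$resname, x$beta_atom$resseq))
  invisible(x)
}

#' Total least-squares plane fit
#'
#' Fits a plane through points by the eigenvector of the coordinate
#' covariance with the smallest eigenvalue (orthogonal regression).
#'
#' @param points m x 3 coordinate matrix, m >= 3, not collinear.
#' @return List with unit \code{normal}, \code{centroid} and \code{rmsd} of
#'   the orthogonal residuals.
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("plane fit needs at least 3 points")
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  ev <- eigen(crossprod(cen) / nrow(points), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1))
    stop("points are collinear; plane is undefined")
  normal <- ev$vectors[, 3]
  normal <- normal / sqrt(sum(normal^2))
  resd <- drop(cen %*% normal)
  list(normal = normal, centroid = ctr, rmsd = sqrt(mean(resd^2)))
}

#' Corrin butterfly fold angle
#'
#' The fold angle is the angle between the total least-squares planes of
#' the two corrin halves, northern (N21, C4, C5, C6, N22, C9, C10) and
#' southern (C10, C11, N23, C14, C15, C16, N24); C10 belongs to both.  The
#' result is folded into [0, 90] degrees.
#'
#' @param corrin a \code{corrin_atoms} object from [extract_corrin()], or a
#'   [b12_structure()] (extracted on the fly).
#' @return Fold angle in degrees.
#' @export
corrin_fold_angle <- function(corrin) {
  if (inherits(corrin, "b12_structure")) corrin <- extract_corrin(corrin)
  atoms <- rbind(corrin$equatorial_n, corrin$ring_carbons)
  need <- union(.butterfly_a, .butterfly_b)
  missing <- setdiff(need, atoms$name)
  if (length(missing) > 0)
    stop("fold angle needs atoms missing from the corrin: ",
         paste(missing, collapse = ", "))
  pa <- fit_plane(coords(atoms[match(.butterfly_a, atoms$name), ]))
  pb <- fit_plane(coords(atoms[match(.butterfly_b, atoms$name), ]))
  cosang <- abs(sum(pa$normal * pb$normal))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Axial coordination geometry of a cobalamin
#'
#' Measures the Co to dimethylbenzimidazole-nitrogen (alpha-axial) and Co
#' to beta-axial bond lengths and classifies the base-on/base-off state
#' (base-on when the alpha-axial nitrogen lies within \code{base_on_cutoff}
#' of cobalt).
#'
#' @param corrin a \code{corrin_atoms} object or a [b12_structure()].
#' @param base_on_cutoff base-on classification distance (angstrom).
#' @return An object of class \code{corrin_report}: list with
#'   \code{fold_angle} (degrees), \code{co_alpha_dist}, \code{co_beta_dist}
#'   (angstrom or \code{NA}), \code{beta_ligand_identity} and
#'   \code{base_on}.
#' @export
axial_geometry <- function(corrin, base_on_cutoff = 2.5) {
  if (inherits(corrin, "b12_structure")) corrin <- extract_corrin(corrin)
  co <- as.numeric(coords(corrin$co))
  dist_to <- function(a) sqrt(sum((as.numeric(coords(a)) - co)^2))
  d_alpha <- if (is.null(corrin$dmb_n)) NA_real_ else dist_to(corrin$dmb_n)
  d_beta <- if (is.null(corrin$beta_atom)) NA_real_ else dist_to(corrin$beta_atom)
  beta_id <- if (is.null(corrin$beta_atom)) "none" else
    sprintf("%s %d %s", corrin$beta_atom$resname, corrin$beta_atom$resseq,
            corrin$beta_atom$name)
  out <- list(fold_angle = corrin_fold_angle(corrin),
              co_alpha_dist = d_alpha,
              co_beta_dist = d_beta,
              beta_ligand_identity = beta_id,
              base_on = !is.na(d_alpha) && d_alpha <= base_on_cutoff)
  class(out) <- "corrin_report"
  out
}

#' @export
print.corrin_report <- function(x, ...) {
  cat("Corrin geometry report\n")
  cat(sprintf("  fold angle        : %.2f deg\n", x$fold_angle))
  cat(sprintf("  Co-alpha (DMB N)  : %s\n",
              if (is.na(x$co_alpha_dist)) "absent" else
                sprintf("%.2f A", x$co_alpha_dist)))
  cat(sprintf("  Co-beta           : %s (%s)\n",
              if (is.na(x$co_beta_dist)) "absent" else
                sprintf("%.2f A", x$co_beta_dist), x$beta_ligand_identity))
  cat(sprintf("  base-on           : %s\n", x$base_on))
  invisible(x)
}
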