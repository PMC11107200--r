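# Deterministic quasi-uniform sphere points (golden-angle spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each atom is given a quasi-uniform point shell at
#' radius (vdW radius + probe); a point is accessible if it lies outside
#' the expanded sphere of every other atom.  Hydrogens are ignored
#' (united-atom radii).  Waters are not removed here; exclude them in the
#' selection if a solvent-free surface is wanted.
#'
#' @param structure a [b12_structure()] (or atom table with coordinates
#'   and elements).
#' @param probe probe radius in angstrom (water: 1.4).
#' @param n_points number of test points per atom (>= 100).
#' @param radii radius set from [default_radii()].
#' @return Numeric vector of per-atom areas (angstrom squared) for the
#'   non-hydrogen atoms, with attribute \code{"total"}; the sum equals the
#'   total SASA.  An empty selection returns an empty vector with total 0.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960,
                 radii = default_radii()) {
  if (probe <= 0) stop("probe radius must be positive")
  if (n_points < 100) stop("use at least 100 quadrature points per atom")
  s <- structure[structure$element != "H", , drop = FALSE]
  n <- nrow(s)
  if (n == 0) {
    out <- numeric(0); attr(out, "total") <- 0; return(out)
  }
  xyz <- coords(s)
  r_exp <- .atom_radii(s$element, radii) + probe
  pts <- .sphere_points(n_points)
  # neighbour lists from the full pairwise distance matrix
  d2 <- as.matrix(stats::dist(xyz))^2
  areas <- numeric(n)
  for (i in seq_len(n)) {
    shell <- pts * r_exp[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    nb <- which(d2[i, ] < (r_exp[i] + r_exp)^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- shell[, 1] - xyz[j, 1]
      dy <- shell[, 2] - xyz[j, 2]
      dz <- shell[, 3] - xyz[j, 3]
      acc <- acc & (dx * dx + dy * dy + dz * dz > r_exp[j]^2)
    }
    areas[i] <- 4 * pi * r_exp[i]^2 * mean(acc)
  }
  attr(areas, "total") <- sum(areas)
  areas
}

#' Buried interface area between two components
#'
#' Half the solvent-accessible surface area lost on association:
#' (SASA(a) + SASA(b) - SASA(a+b)) / 2.  The components must be disjoint
#' atom sets; waters should normally be excluded from both.
#'
#' @param a,b disjoint [b12_structure()] atom subsets, in their complex
#'   coordinates.
#' @param probe,n_points,radii passed to [sasa()].
#' @return Buried area in angstrom squared (non-negative up to quadrature
#'   error).
#' @export
buried_area <- function(a, b, probe = 1.4, n_points = 960,
                        radii = default_radii()) {
  key <- function(s) paste(s$chain, s$resseq, s$icode, s$name, s$altloc,
                           round(s$x, 3), round(s$y, 3), round(s$z, 3))
  if (length(intersect(key(a), key(b))) > 0)
    stop("components overlap; buried area needs disjoint atom sets")
  sa <- attr(sasa(a, probe, n_points, radii), "total")
  sb <- attr(sasa(b, probe, n_points, radii), "total")
  ab <- rbind(as.data.frame(a), as.data.frame(b))
  sab <- attr(sasa(ab, probe, n_points, radii), "total")
  (sa + sb - sab) / 2
}

#' Pairwise buried areas and favorability ranking of a complex
#'
#' Computes the buried interface area for every pair of named components
#' and ranks the pairs from largest to smallest buried area.  In the
#' cobalamin-transporter context the canonical components are the ligand
#' (cobalamin + its beta-axial adduct), the alpha-domain and the
#' beta-domain; the ranking mirrors the interface-favorability ordering
#' used to interpret how the sandwich complex assembles.
#'
#' @param structure a [b12_structure()] of the full complex.
#' @param components named character vector or list of selection
#'   expressions (see [select_atoms()]), e.g. \code{c(ligand = "chain L",
#'   alpha = "chain A and resi 1-314", beta = "chain A and resi 315-999")}.
#'   Waters are always excluded from the components.
#' @param probe,n_points,radii passed to [sasa()].
#' @return An object of class \code{interface_report}: list with
#'   \code{pairs} (data frame: pair label, buried area, component SASAs)
#'   and \code{ranking} (pair labels, decreasing buried area).
#' @export
interface_report <- function(structure,
                             components = c(ligand = "chain L",
                                            alpha = "chain A and resi 1-314",
                                            beta = "chain A and resi 315-9999"),
                             probe = 1.4, n_points = 960,
                             radii = default_radii()) {
  labs <- names(components)
  if (is.null(labs) || any(!nzchar(labs)))
    stop("components must be a named vector of selection expressions")
  sel <- lapply(components, function(e)
    select_atoms(structure, paste(e, "and not water")))
  tot <- vapply(sel, function(s)
    attr(sasa(s, probe, n_points, radii), "total"), numeric(1))
  combos <- utils::combn(length(sel), 2)
  pair_lab <- character(ncol(combos)); buried <- numeric(ncol(combos))
  for (k in seq_len(ncol(combos))) {
    i <- combos[1, k]; j <- combos[2, k]
    pair_lab[k] <- paste0(labs[i], "/", labs[j])
    ab <- rbind(as.data.frame(sel[[i]]), as.data.frame(sel[[j]]))
    sab <- attr(sasa(ab, probe, n_points, radii), "total")
    buried[k] <- (tot[i] + tot[j] - sab) / 2
  }
  pairs <- data.frame(pair = pair_lab, buried_area = buried,
                      sasa_a = tot[combos[1, ]], sasa_b = tot[combos[2, ]],
                      stringsAsFactors = FALSE)
  out <- list(pairs = pairs,
              ranking = pair_lab[order(buried, decreasing = TRUE)],
              component_sasa = tot)
  class(out) <- "interface_report"
  out
}

#' @export
print.interface_report <- function(x, ...) {
  cat("Buried interface areas (A^2):\n")
  for (k in order(x$pairs$buried_area, decreasing = TRUE))
    cat(sprintf("  %-16s %8.1f\n", x$pairs$pair[k], x$pairs$buried_area[k]))
  cat("ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}
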