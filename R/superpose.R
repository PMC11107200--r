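#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired point sets, by singular value decomposition of the covariance
#' matrix; a reflection in the optimum is corrected by flipping the sign of
#' the smallest singular vector, since mirror superpositions are
#' chemically meaningless.
#'
#' @param mobile n x 3 coordinates to move.
#' @param reference n x 3 coordinates to match (same n, n >= 3, not
#'   collinear).
#' @return An object of class \code{superposition}: list with
#'   \code{rotation} (3 x 3, det +1), \code{translation} (length-3),
#'   \code{rmsd}, \code{n_pairs} and \code{per_pair_deviation}.  The
#'   transform maps a row vector p to \code{p \%*\% t(rotation) +
#'   translation}.
#' @export
kabsch <- function(mobile, reference) {
  m <- as.matrix(mobile); r <- as.matrix(reference)
  if (nrow(m) != nrow(r)) stop("point sets differ in length")
  if (nrow(m) < 3) stop("superposition needs at least 3 point pairs")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  if (max(svd(mc)$d) < 1e-12 || svd(mc)$d[2] < 1e-9 * max(svd(mc)$d, 1))
    stop("degenerate (collinear or coincident) mobile geometry")
  H <- crossprod(mc, rc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - drop(R %*% cm)
  moved <- m %*% t(R) + matrix(t_vec, nrow(m), 3, byrow = TRUE)
  dev <- sqrt(rowSums((moved - r)^2))
  out <- list(rotation = R, translation = t_vec,
              rmsd = sqrt(mean(dev^2)), n_pairs = nrow(m),
              per_pair_deviation = dev)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, rmsd %.4f A (max dev %.4f A)\n",
              x$n_pairs, x$rmsd, max(x$per_pair_deviation)))
  invisible(x)
}

#' Apply a rigid transform
#'
#' @param x an n x 3 coordinate matrix or a [b12_structure()].
#' @param transform a \code{superposition} (or any list with
#'   \code{rotation} and \code{translation}).
#' @return Object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  R <- transform$rotation; tv <- transform$translation
  if (inherits(x, "b12_structure") ||
      (is.data.frame(x) && all(c("x", "y", "z") %in% names(x)))) {
    xyz <- coords(x) %*% t(R) + matrix(tv, nrow(x), 3, byrow = TRUE)
    x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
    x
  } else {
    as.matrix(x) %*% t(R) + matrix(tv, nrow(as.matrix(x)), 3, byrow = TRUE)
  }
}

#' Pair C-alpha coordinates through a sequence alignment
#'
#' Walks the columns of a pairwise alignment and emits the C-alpha
#' coordinate pair for every column where both sequences have a residue
#' and both residues have a C-alpha atom; gap columns are skipped.
#' Residues are taken in chain order, so the k-th sequence position maps
#' to the k-th C-alpha of the chain.
#'
#' @param a,b [b12_structure()] objects (or chain subsets thereof).
#' @param alignment an \code{aligned_pair} from [global_align()], with
#'   \code{a} as the first sequence.
#' @param chain_a,chain_b optional chain identifiers to restrict each
#'   structure.
#' @return List with \code{xyz_a}, \code{xyz_b} (m x 3 matrices) and
#'   \code{resno_a}, \code{resno_b}.
#' @export
pair_by_alignment <- function(a, b, alignment, chain_a = NULL, chain_b = NULL) {
  ca_of <- function(s, ch) {
    if (!is.null(ch)) s <- s[s$chain == ch, , drop = FALSE]
    s <- reduce_altlocs(s)
    s[s$name == "CA" & s$resname %in% .aa3, , drop = FALSE]
  }
  ca_a <- ca_of(a, chain_a); ca_b <- ca_of(b, chain_b)
  cols_a <- strsplit(alignment$a_aln, "")[[1]]
  cols_b <- strsplit(alignment$b_aln, "")[[1]]
  ia <- cumsum(cols_a != "-"); ib <- cumsum(cols_b != "-")
  both <- which(cols_a != "-" & cols_b != "-")
  pa <- ia[both]; pb <- ib[both]
  ok <- pa <= nrow(ca_a) & pb <= nrow(ca_b)
  pa <- pa[ok]; pb <- pb[ok]
  if (length(pa) == 0) stop("alignment yields no C-alpha pairs")
  list(xyz_a = coords(ca_a[pa, ]), xyz_b = coords(ca_b[pb, ]),
       resno_a = ca_a$resseq[pa], resno_b = ca_b$resseq[pb])
}

#' Superpose on one domain, report deviations over another
#'
#' Superposes structure \code{b} onto \code{a} using the C-alpha atoms of
#' \code{fit_range} (residues matched by number) and reports per-residue
#' C-alpha deviations over \code{report_range}.  This is the standard way
#' to expose inter-domain reorientation: a good fit on one domain with
#' large deviations over the other indicates the second domain has moved.
#'
#' @param a,b [b12_structure()] objects.
#' @param fit_range length-2 integer vector, inclusive residue interval
#'   used for the superposition.
#' @param report_range length-2 integer vector, interval over which
#'   deviations are reported.
#' @param chain optional chain restriction applied to both structures.
#' @return List with \code{deviations} (data frame resno/deviation),
#'   \code{max_deviation} and the \code{superposition} used.
#' @export
domain_superpose <- function(a, b, fit_range, report_range, chain = NULL) {
  ca_of <- function(s) {
    if (!is.null(chain)) s <- s[s$chain == chain, , drop = FALSE]
    s <- reduce_altlocs(s)
    s[s$name == "CA", , drop = FALSE]
  }
  ca_a <- ca_of(a); ca_b <- ca_of(b)
  in_rng <- function(r, rng) r >= rng[1] & r <= rng[2]
  common_fit <- intersect(ca_a$resseq[in_rng(ca_a$resseq, fit_range)],
                          ca_b$resseq[in_rng(ca_b$resseq, fit_range)])
  if (length(common_fit) == 0) stop("empty fit-range overlap")
  sup <- kabsch(coords(ca_b[match(common_fit, ca_b$resseq), ]),
                coords(ca_a[match(common_fit, ca_a$resseq), ]))
  common_rep <- intersect(ca_a$resseq[in_rng(ca_a$resseq, report_range)],
                          ca_b$resseq[in_rng(ca_b$resseq, report_range)])
  if (length(common_rep) == 0) stop("empty report-range overlap")
  moved <- apply_transform(coords(ca_b[match(common_rep, ca_b$resseq), ]), sup)
  dev <- sqrt(rowSums((moved - coords(ca_a[match(common_rep, ca_a$resseq), ]))^2))
  list(deviations = data.frame(resno = common_rep, deviation = dev),
       max_deviation = max(dev), superposition = sup)
}
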