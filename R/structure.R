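#' @importFrom stats coef cor median optim predict resid rnorm runif sd setNames approx
#' @importFrom utils head tail
NULL

# Three-letter codes treated as protein when partitioning structures.
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

.water_res <- c("HOH", "WAT", "DOD")

#' Construct an atom-table structure
#'
#' A structure is a data frame with one row per atom and the columns
#' \code{serial}, \code{name}, \code{altloc}, \code{resname}, \code{chain},
#' \code{resseq}, \code{icode}, \code{x}, \code{y}, \code{z}, \code{occ},
#' \code{b} and \code{element}.  Coordinates are in angstrom throughout; no
#' internal unit conversion is ever applied.
#'
#' @param atoms data frame carrying at least \code{name}, \code{resname},
#'   \code{chain}, \code{resseq}, \code{x}, \code{y}, \code{z} and
#'   \code{element}; missing bookkeeping columns are filled with defaults.
#' @param id identifier string stored as the structure id.
#' @param dialect source dialect label (\code{"pdb"}, \code{"mmcif"} or
#'   \code{"generated"}).
#' @return An object of class \code{b12_structure} (a data frame).
#' @export
b12_structure <- function(atoms, id = "unnamed", dialect = "generated") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(max(n, 0L))
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  req <- c("serial", "name", "altloc", "resname", "chain", "resseq",
           "icode", "x", "y", "z", "occ", "b", "element")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("missing atom columns: ", paste(miss, collapse = ", "))
  atoms <- atoms[, req]
  atoms$resseq <- as.integer(atoms$resseq)
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) stop("non-finite coordinates for ", sum(bad), " atom(s)")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancies must lie in [0, 1]")
  if (any(!nzchar(atoms$element)))
    stop("every atom needs a chemical element")
  attr(atoms, "id") <- id
  attr(atoms, "dialect") <- dialect
  class(atoms) <- c("b12_structure", "data.frame")
  atoms
}

#' @export
print.b12_structure <- function(x, ...) {
  cat(sprintf("<b12_structure '%s'> %d atoms, %d chain(s), %d residue(s)\n",
              attr(x, "id"), nrow(x), length(unique(x$chain)),
              nrow(unique(x[, c("chain", "resseq", "icode")]))))
  het <- setdiff(unique(x$resname), c(.aa3, .water_res))
  if (length(het) > 0)
    cat("  hetero components:", paste(het, collapse = " "), "\n")
  invisible(x)
}

# Normalise an element symbol ("CO", "co" -> "Co").
.norm_element <- function(e) {
  e <- trimws(e)
  out <- paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
  out[!nzchar(e)] <- ""
  out
}

# Guess element from a PDB atom name when the element column is absent.
.element_from_name <- function(name) {
  stripped <- gsub("[0-9']", "", toupper(trimws(name)))
  two <- substr(stripped, 1, 2)
  known2 <- c("CO", "FE", "ZN", "MG", "MN", "NI", "CU", "NA", "CL", "BR", "SE")
  ifelse(nchar(stripped) >= 2 & two %in% known2 & nchar(trimws(name)) == 4,
         two, substr(stripped, 1, 1))
}

#' Read a macromolecular structure
#'
#' Parses PDB or mmCIF coordinates (via \pkg{bio3d}) into the flat atom
#' table used throughout the package.  All ATOM and HETATM records are
#' retained, including waters; alternate-location identifiers and insertion
#' codes are preserved.
#'
#' @param path path to a coordinate file.
#' @param dialect \code{"pdb"}, \code{"mmcif"} or \code{"auto"} (by file
#'   extension; \code{.cif} selects mmCIF).
#' @return A [b12_structure()].
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (dialect == "auto")
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  pdb <- if (dialect == "mmcif")
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE)) else
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE))
  a <- pdb$atom
  element <- a$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(a))
  element <- ifelse(is.na(element) | !nzchar(trimws(element)),
                    .element_from_name(a$elety), element)
  atoms <- data.frame(
    serial  = a$eleno,
    name    = trimws(a$elety),
    altloc  = ifelse(is.na(a$alt), "", a$alt),
    resname = trimws(a$resid),
    chain   = ifelse(is.na(a$chain), "", a$chain),
    resseq  = a$resno,
    icode   = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, pmin(1, pmax(0, a$o))),
    b   = ifelse(is.na(a$b), 0, a$b),
    element = .norm_element(element),
    stringsAsFactors = FALSE)
  b12_structure(atoms, id = sub("\\.[^.]+$", "", basename(path)),
                dialect = dialect)
}

#' Write a structure in PDB format
#'
#' @param structure a [b12_structure()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(structure, path) {
  s <- structure
  het <- !(s$resname %in% .aa3)
  bio3d::write.pdb(
    file = path,
    type = ifelse(het, "HETATM", "ATOM"),
    xyz = as.vector(t(as.matrix(s[, c("x", "y", "z")]))),
    resno = s$resseq, resid = s$resname, eleno = s$serial,
    elety = s$name, chain = ifelse(nzchar(s$chain), s$chain, " "),
    insert = ifelse(nzchar(s$icode), s$icode, ""),
    alt = ifelse(nzchar(s$altloc), s$altloc, ""),
    o = s$occ, b = s$b, elesy = toupper(s$element))
  invisible(path)
}

#' Coordinate matrix of a structure
#'
#' @param structure a [b12_structure()] or atom-table data frame.
#' @return An n x 3 numeric matrix of coordinates (angstrom).
#' @export
coords <- function(structure) {
  m <- as.matrix(structure[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Reduce alternate locations to a single conformer
#'
#' Keeps, per (chain, residue, insertion code, atom name), the conformer
#' with the highest occupancy; ties are broken by altloc identifier order.
#' Downstream geometry therefore always sees one conformer.
#'
#' @param structure a [b12_structure()].
#' @return The reduced structure.
#' @export
reduce_altlocs <- function(structure) {
  key <- paste(structure$chain, structure$resseq, structure$icode,
               structure$name, sep = "\r")
  ord <- order(key, -structure$occ, structure$altloc)
  s <- structure[ord, ]
  s <- s[!duplicated(paste(s$chain, s$resseq, s$icode, s$name, sep = "\r")), ]
  s <- s[order(s$serial), ]
  attributes(s)[c("id", "dialect")] <- attributes(structure)[c("id", "dialect")]
  class(s) <- class(structure)
  s
}

# Parse one clause of a selection expression.
.match_clause <- function(structure, clause) {
  clause <- trimws(clause)
  neg <- grepl("^not\\s+", clause)
  if (neg) clause <- sub("^not\\s+", "", clause)
  hit <- if (clause == "water") {
    structure$resname %in% .water_res
  } else if (clause == "protein") {
    structure$resname %in% .aa3
  } else if (clause == "all") {
    rep(TRUE, nrow(structure))
  } else if (clause == "none") {
    rep(FALSE, nrow(structure))
  } else {
    parts <- strsplit(clause, "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed selection clause: '", clause, "'")
    field <- parts[1]
    vals <- strsplit(parts[2], ",")[[1]]
    if (field == "resi") {
      idx <- rep(FALSE, nrow(structure))
      for (v in vals) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
          ab <- as.integer(strsplit(v, "(?<=[0-9])-", perl = TRUE)[[1]])
          idx <- idx | (structure$resseq >= ab[1] & structure$resseq <= ab[2])
        } else if (grepl("^-?[0-9]+$", v)) {
          idx <- idx | structure$resseq == as.integer(v)
        } else stop("malformed residue range: '", v, "'")
      }
      idx
    } else if (field == "chain") {
      structure$chain %in% vals
    } else if (field == "resn") {
      structure$resname %in% toupper(vals)
    } else if (field == "name") {
      structure$name %in% toupper(vals)
    } else if (field == "elem") {
      structure$element %in% .norm_element(vals)
    } else stop("unknown selection field: '", field, "'")
  }
  if (neg) !hit else hit
}

#' Select atoms by expression
#'
#' Selection expressions are conjunctions of clauses joined by
#' \code{" and "}: \code{chain}, \code{resi} (single numbers or ranges,
#' comma-separated), \code{resn}, \code{name}, \code{elem}, plus the
#' keywords \code{water}, \code{protein}, \code{all}, \code{none}; any
#' clause may be prefixed \code{not}.  The returned subset preserves input
#' order; an empty selection is allowed.
#'
#' @param structure a [b12_structure()].
#' @param expr selection expression string, e.g.
#'   \code{"chain A and resi 1-314 and not water"}.
#' @return The selected atoms, as a [b12_structure()].
#' @export
select_atoms <- function(structure, expr = "all") {
  clauses <- strsplit(expr, "\\s+and\\s+")[[1]]
  if (length(clauses) == 0) stop("empty selection expression")
  keep <- rep(TRUE, nrow(structure))
  for (cl in clauses) keep <- keep & .match_clause(structure, cl)
  s <- structure[keep, , drop = FALSE]
  attributes(s)[c("id", "dialect")] <- attributes(structure)[c("id", "dialect")]
  class(s) <- class(structure)
  s
}

#' Van der Waals radii
#'
#' Default united-atom radius set used for surface areas and steric
#' clashes: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, Co 1.26; any other
#' element falls back to 1.70.  Hydrogens are ignored by the consumers of
#' this table.
#'
#' @param overrides optional named numeric vector of per-element overrides,
#'   e.g. \code{c(Co = 1.40)}.
#' @return Named numeric vector with a \code{"fallback"} attribute.
#' @export
default_radii <- function(overrides = NULL) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, Co = 1.26)
  if (!is.null(overrides)) {
    if (any(overrides <= 0)) stop("radii must be strictly positive")
    r[names(overrides)] <- overrides
  }
  attr(r, "fallback") <- 1.70
  r
}

# Per-atom radii for an element vector.
.atom_radii <- function(elements, radii = default_radii()) {
  out <- unname(radii[elements])
  out[is.na(out)] <- attr(radii, "fallback")
  out
}

# Polar atoms (hydrogen-bond capable) are nitrogens and oxygens.
.is_polar <- function(structure) structure$element %in% c("N", "O")
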