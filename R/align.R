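.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment (end gaps penalised) with an affine
#' gap model, computed via \pkg{Biostrings}.  Defaults are BLOSUM62, gap
#' open 10, gap extend 0.5.
#'
#' @param a,b protein sequences (character strings, standard amino-acid
#'   alphabet; X tolerated).
#' @param ids length-2 character vector of sequence identifiers.
#' @param substitution substitution matrix name (\code{"BLOSUM62"},
#'   \code{"BLOSUM45"}, \code{"PAM250"}, ...), or a numeric matrix.
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return An object of class \code{aligned_pair}: list with \code{ids},
#'   \code{a_aln}, \code{b_aln} (equal-length gapped strings),
#'   \code{score} and \code{identity} (percent, see
#'   [percent_identity()]).
#' @export
global_align <- function(a, b, ids = c("a", "b"), substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  a <- toupper(gsub("\\s", "", a)); b <- toupper(gsub("\\s", "", b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  for (s in c(a, b)) {
    bad <- setdiff(strsplit(s, "")[[1]], .aa_alphabet)
    if (length(bad) > 0)
      stop("illegal residue character(s): ", paste(unique(bad), collapse = ""))
  }
  submat <- if (is.matrix(substitution)) substitution else {
    e <- new.env()
    utils::data(list = substitution, package = "Biostrings", envir = e)
    get(substitution, envir = e)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  out <- list(ids = ids,
              a_aln = as.character(Biostrings::pattern(aln)),
              b_aln = as.character(Biostrings::subject(aln)),
              score = Biostrings::score(aln))
  class(out) <- "aligned_pair"
  out$identity <- percent_identity(out)
  out
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %s vs %s: score %.1f, identity %.1f%%\n",
              x$ids[1], x$ids[2], x$score, x$identity))
  w <- 60
  n <- nchar(x$a_aln)
  for (i in seq(1, n, by = w)) {
    cat(substr(x$a_aln, i, min(i + w - 1, n)), "\n")
    cat(substr(x$b_aln, i, min(i + w - 1, n)), "\n\n")
  }
  invisible(x)
}

#' Percent identity of an aligned pair
#'
#' Identical columns divided by mutually aligned columns (positions where
#' both sequences carry a residue; all gap columns, terminal or internal,
#' are excluded from the denominator), times 100.
#'
#' @param pair an \code{aligned_pair} from [global_align()].
#' @return Percent identity in [0, 100].
#' @export
percent_identity <- function(pair) {
  ca <- strsplit(pair$a_aln, "")[[1]]
  cb <- strsplit(pair$b_aln, "")[[1]]
  if (length(ca) != length(cb)) stop("aligned strings differ in length")
  both <- ca != "-" & cb != "-"
  if (!any(both)) stop("no mutually aligned columns; identity undefined")
  100 * sum(ca[both] == cb[both]) / sum(both)
}

#' Conservation of chosen residues across homologs
#'
#' For each listed residue of the reference sequence (numbered 1..L in
#' full-length reference numbering) reports the aligned residue in each
#' homolog and whether it is conserved (identical).  Used to ask, e.g.,
#' whether the glutathione-contacting residues of rat transcobalamin are
#' retained in other transporters.
#'
#' @param pairs named list of \code{aligned_pair} objects, each aligning
#'   the same reference (as first sequence) to one homolog; names label
#'   the homologs.
#' @param residues integer vector of reference residue numbers.
#' @return Data frame with one row per (residue, homolog): \code{resno},
#'   \code{ref_aa}, \code{homolog}, \code{aligned_aa} (\code{"-"} if the
#'   position is deleted) and \code{conserved}.
#' @export
map_conservation <- function(pairs, residues) {
  if (is.null(names(pairs)) || any(!nzchar(names(pairs))))
    stop("pairs must be a named list")
  rows <- list()
  for (h in names(pairs)) {
    p <- pairs[[h]]
    ca <- strsplit(p$a_aln, "")[[1]]
    cb <- strsplit(p$b_aln, "")[[1]]
    ref_pos <- cumsum(ca != "-")
    ref_len <- max(ref_pos)
    for (r in residues) {
      if (r < 1 || r > ref_len)
        stop("residue ", r, " outside the reference length ", ref_len)
      col <- which(ref_pos == r & ca != "-")[1]
      rows[[length(rows) + 1]] <- data.frame(
        resno = r, ref_aa = ca[col], homolog = h, aligned_aa = cb[col],
        conserved = ca[col] == cb[col], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
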