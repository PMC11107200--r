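#' Run the full binding-pocket analysis pipeline
#'
#' Orchestrates the structural, spectroscopic and binding analyses from a
#' single configuration: corrin geometry, polar contacts and disulfides,
#' buried-interface ranking, ligand-transplant clash screening, spectrum
#' comparison and thermophoresis fitting.  Modules run in dependency
#' order; a failure in one block is recorded in that block and does not
#' abort independent blocks.
#'
#' The configuration is a named list (or a YAML file with the same
#' shape):
#' \describe{
#'   \item{structures}{named list of coordinate file paths; each is read
#'     with [read_structure()].}
#'   \item{corrin}{character vector of structure names to analyse with
#'     [axial_geometry()].}
#'   \item{contacts}{list with \code{structure}, \code{ligand} (selection),
#'     optional \code{cutoff}.}
#'   \item{disulfides}{character vector of structure names.}
#'   \item{interfaces}{list with \code{structure} and \code{components}
#'     (named selections).}
#'   \item{transplant}{list with \code{source}, \code{targets} (structure
#'     names), optional \code{soft_tol}.}
#'   \item{spectra}{list with \code{reference} and \code{comparison} CSV
#'     paths.}
#'   \item{mst}{list with \code{concentrations} and \code{delta_fnorm}
#'     numeric vectors (or a \code{csv} path with those two columns) and
#'     \code{probe_conc}.}
#'   \item{seed}{integer seed applied before any stochastic step.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return An object of class \code{analysis_report}: named list with one
#'   element per executed block, each either the block result or an
#'   element \code{error} describing the failure; attribute \code{"ok"}
#'   is \code{TRUE} when every requested block succeeded.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (!is.null(config$seed)) set.seed(config$seed)
  structures <- list()
  for (nm in names(config$structures))
    structures[[nm]] <- read_structure(config$structures[[nm]])
  get_struct <- function(nm) {
    if (is.null(structures[[nm]])) stop("unknown structure '", nm, "'")
    structures[[nm]]
  }
  report <- list()
  block <- function(name, expr) {
    report[[name]] <<- tryCatch(expr, error = function(e)
      list(error = conditionMessage(e)))
  }

  for (nm in config$corrin)
    block(paste0("corrin.", nm), unclass(axial_geometry(get_struct(nm))))
  if (!is.null(config$contacts)) {
    cc <- config$contacts
    block("contacts", {
      ct <- polar_contacts(get_struct(cc$structure), ligand = cc$ligand,
                           cutoff = if (is.null(cc$cutoff)) 3.5 else cc$cutoff)
      list(n_total = nrow(ct), n_direct = attr(ct, "n_direct"),
           n_water_mediated = attr(ct, "n_water"),
           contacts = as.data.frame(ct))
    })
  }
  for (nm in config$disulfides)
    block(paste0("disulfides.", nm), find_disulfides(get_struct(nm)))
  if (!is.null(config$interfaces)) {
    ic <- config$interfaces
    block("interfaces", {
      ir <- interface_report(get_struct(ic$structure),
                             components = unlist(ic$components))
      list(pairs = ir$pairs, ranking = ir$ranking)
    })
  }
  if (!is.null(config$transplant)) {
    tc <- config$transplant
    for (tgt in tc$targets)
      block(paste0("transplant.", tgt), {
        cr <- transplant(get_struct(tc$source), get_struct(tgt),
                         soft_tol = if (is.null(tc$soft_tol)) 0.4
                         else tc$soft_tol)
        list(n_clashes = cr$n_clashes, n_severe = cr$n_severe,
             worst_overlap = cr$worst_overlap,
             corrin_fit_rmsd = cr$corrin_fit_rmsd)
      })
  }
  if (!is.null(config$spectra)) {
    sc <- config$spectra
    block("spectra", {
      a <- read_spectrum(sc$reference)
      b <- read_spectrum(sc$comparison)
      compare_spectra(a, b)
    })
  }
  if (!is.null(config$mst)) {
    mc <- config$mst
    block("mst", {
      if (!is.null(mc$csv)) {
        d <- utils::read.csv(mc$csv)
        mc$concentrations <- d[[1]]; mc$delta_fnorm <- d[[2]]
      }
      fit <- fit_kd(mc$concentrations, mc$delta_fnorm, mc$probe_conc)
      list(kd = fit$kd, kd_is_lower_limit = fit$kd_is_lower_limit,
           amplitude = fit$amplitude, baseline = fit$baseline)
    })
  }
  attr(report, "ok") <- !any(vapply(report, function(b)
    is.list(b) && !is.null(b$error), logical(1)))
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d block(s), %s\n", length(x),
              if (isTRUE(attr(x, "ok"))) "all succeeded" else "with failures"))
  for (nm in names(x)) {
    err <- if (is.list(x[[nm]]) && !is.null(x[[nm]]$error))
      paste(" ERROR:", x[[nm]]$error) else ""
    cat("  -", nm, err, "\n")
  }
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report an \code{analysis_report} from [run_pipeline()].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
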