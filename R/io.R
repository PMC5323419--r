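#' Read a long-format panel from CSV
#'
#' Expects comma-separated UTF-8 with a header and columns \code{subject},
#' \code{occasion}, \code{y}, \code{z}, \code{c}. The panel is validated on
#' read (integer occasions, no missing cells, no duplicated
#' (subject, occasion) pairs, equal spacing within subject); schema errors
#' name the offending rows. Balance across subjects is not required.
#'
#' @param path Path to a CSV file.
#' @return A validated panel data frame with subjects in file order.
#' @export
read_long_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
}

#' Write a panel (raw or transformed) to CSV
#'
#' @param panel Panel data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_long_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Write a bias report as per-parameter TSV tables plus a long CSV
#'
#' Each parameter block becomes one TSV with one row per (N, L) pair and
#' nine value columns (\eqn{\bar\rho} 0 / 0.3 / 0.6 by method ID / AR1 /
#' CT, restricted to the methods and \eqn{\bar\rho} values present in the
#' report). Missing cells are written as the literal string \code{NA}; a
#' partial report triggers a warning. A machine-readable long-format CSV of
#' the full report is written alongside. Output bytes are a deterministic
#' function of the report.
#'
#' @param report A \code{"bias_report"} from [run_grid()].
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_bias_report <- function(report, dir) {
  stopifnot(inherits(report, "bias_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)

  long_path <- file.path(dir, "bias_report_long.csv")
  utils::write.csv(as.data.frame(report)[, c("N", "L", "rho_bar", "method",
                                             "parameter", "rel_bias",
                                             "n_converged", "conv_rate")],
                   long_path, row.names = FALSE)
  files <- c(files, long_path)

  methods <- intersect(c("ID", "AR1", "CT"), unique(report$method))
  rhos <- sort(unique(report$rho_bar))
  cells <- unique(as.data.frame(report)[, c("N", "L")])
  cells <- cells[order(cells$N, cells$L), , drop = FALSE]

  for (par in unique(report$parameter)) {
    tab <- cells
    for (rho in rhos) {
      for (m in methods) {
        col <- paste0("rho", rho, "_", m)
        tab[[col]] <- vapply(seq_len(nrow(cells)), function(i) {
          hit <- report$parameter == par & report$method == m &
            report$rho_bar == rho & report$N == cells$N[i] &
            report$L == cells$L[i]
          if (any(hit)) report$rel_bias[hit][1] else NA_real_
        }, numeric(1))
      }
    }
    if (anyNA(tab))
      warning(sprintf("partial report: NA cells in block '%s'", par))
    path <- file.path(dir, paste0("bias_", par, ".tsv"))
    utils::write.table(format(tab, digits = 4, trim = TRUE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    files <- c(files, path)
  }
  invisible(files)
}

#' Read and validate a run configuration file
#'
#' JSON configuration for the command-line interface. Recognized keys:
#' \code{mode} (\code{simulate}, \code{fit}, \code{transform},
#' \code{bias-report}), \code{N}, \code{L}, \code{rho_bar}, \code{reps},
#' \code{seed}, \code{methods}, \code{p}, \code{order_select},
#' \code{rescale}, \code{data}, \code{out}, \code{truth} (list of
#' [true_parameters()] overrides). Unknown keys are rejected before any
#' computation; defaults are the simulation-study settings.
#'
#' @param path Path to a JSON file.
#' @return Validated configuration list of class \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("mode", "N", "L", "rho_bar", "reps", "seed", "methods", "p",
             "order_select", "rescale", "data", "out", "truth")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$mode) ||
      !cfg$mode %in% c("simulate", "fit", "transform", "bias-report"))
    stop("config 'mode' must be one of simulate, fit, transform, bias-report")
  if (!is.null(cfg$truth)) {
    bad <- setdiff(names(cfg$truth),
                   names(formals(true_parameters)))
    if (length(bad))
      stop("unknown truth override(s): ", paste(bad, collapse = ", "))
  }
  defaults <- list(N = 20L, L = 20L, rho_bar = 0.6, reps = 500L, seed = 1L,
                   methods = c("ID", "AR1", "CT"), p = 1L,
                   order_select = "fixed", rescale = FALSE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}
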