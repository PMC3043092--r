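#' Read and write denaturation-curve CSV files
#'
#' Curves are stored as CSV with columns `axis_kind`, `x`, `y`,
#' `probe`; metadata (including any generator ground truth) travels in
#' `#key=value` header comment lines, with the ground truth serialized
#' as full-precision JSON so it round-trips bit-exactly.
#'
#' @param curve a [denaturation_curve()].
#' @param path file path.
#' @return `read_curve_csv` returns a [denaturation_curve()];
#'   `write_curve_csv` returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "denaturation_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  gt <- attr(curve, "ground_truth")
  if (!is.null(gt)) {
    writeLines(paste0("#ground_truth=",
                      jsonlite::toJSON(gt, auto_unbox = TRUE,
                                       digits = NA)), con)
  }
  df <- data.frame(axis_kind = attr(curve, "axis_kind"),
                   x = curve$x, y = curve$y,
                   probe = attr(curve, "probe"))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  gt <- NULL
  gt_line <- grep("^#ground_truth=", hdr, value = TRUE)
  if (length(gt_line)) {
    gt <- jsonlite::fromJSON(sub("^#ground_truth=", "", gt_line[1]),
                             simplifyVector = TRUE)
  }
  df <- read.csv(text = lines[!grepl("^#", lines)],
                 stringsAsFactors = FALSE)
  denaturation_curve(as.numeric(df$x), as.numeric(df$y),
                     axis_kind = df$axis_kind[1], probe = df$probe[1],
                     ground_truth = gt)
}

#' Read and write emission-spectrum CSV files
#'
#' Two-column CSV (`wavelength_nm`, `intensity`) with `#key=value`
#' header lines for the condition metadata.
#'
#' @param spectrum an [emission_spectrum()].
#' @param path file path.
#' @return `read_spectrum_csv` returns an [emission_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#condition=",
                    jsonlite::toJSON(spectrum$condition,
                                     auto_unbox = TRUE, digits = NA)),
             con)
  df <- data.frame(wavelength_nm = spectrum$wavelengths,
                   intensity = spectrum$intensities)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  cond_line <- grep("^#condition=", lines, value = TRUE)
  cond <- if (length(cond_line)) {
    jsonlite::fromJSON(sub("^#condition=", "", cond_line[1]))
  } else {
    list(axis_kind = "denaturant", value = 0)
  }
  df <- read.csv(text = lines[!grepl("^#", lines)],
                 stringsAsFactors = FALSE)
  emission_spectrum(as.numeric(df$wavelength_nm),
                    as.numeric(df$intensity), condition = cond)
}

#' Read an ASA CSV into a list of ASA tables
#'
#' Expects columns `protein`, `folded_nonpolar`, `folded_polar`,
#' `extended_nonpolar`, `extended_polar` and optionally `hbond_count`.
#'
#' @param path file path.
#' @return list of [asa_table()] objects, one per row.
#' @export
read_asa_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  lapply(seq_len(nrow(df)), function(i) {
    asa_table(df$protein[i], df$folded_nonpolar[i], df$folded_polar[i],
              df$extended_nonpolar[i], df$extended_polar[i],
              if ("hbond_count" %in% names(df)) df$hbond_count[i]
              else NA_integer_)
  })
}

#' Write a fit report as JSON
#'
#' Serializes a [fit_result()] (model, estimates, standard errors,
#' fixed pins, convergence diagnostics, flags and metadata) to a JSON
#' file.
#'
#' @param fit a [fit_result()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(model = fit$model,
              estimates = as.list(fit$estimates),
              stderr = as.list(fit$stderr),
              ssr = fit$ssr,
              n = length(fit$residuals),
              converged = fit$converged,
              niter = fit$niter,
              fixed = as.list(fit$fixed),
              flags = fit$flags,
              meta = fit$meta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' One-row flat summary of a fit
#'
#' @param fit a [fit_result()].
#' @param label optional row label.
#' @return a one-row data frame with the model, label, estimates and
#'   convergence status, suitable for `rbind`-ing into a summary CSV.
#' @export
fit_summary_row <- function(fit, label = "") {
  stopifnot(inherits(fit, "fit_result"))
  est <- as.list(fit$estimates)
  names(est) <- names(fit$estimates)
  cbind(data.frame(label = label, model = fit$model,
                   converged = fit$converged, ssr = fit$ssr),
        as.data.frame(est))
}
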