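#' Write tidy trajectory or ensemble CSV files
#'
#' Writes the long-format data frame of a mean-field trajectory, SSA run or
#' SSA ensemble to CSV, together with a JSON metadata sidecar describing
#' the model (variant, qualities, rates), the seeds used, and the file's
#' MD5 checksum.
#'
#' @param x An `mf_trajectory`, `ssa_trajectory` or `ssa_ensemble`.
#' @param path Output CSV path; the sidecar is written to
#'   `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(x, path) {
  df <- as.data.frame(x)
  write.csv(df, path, row.names = FALSE)
  sys <- x$system
  meta <- list(
    class = class(x)[1],
    variant = sys$variant,
    qualities = sys$environment$qualities,
    a = sys$rates$a, r = sys$rates$r, rho = sys$rates$rho, z = sys$rates$z,
    seeds = if (!is.null(x$seeds)) x$seeds else x$seed,
    master_seed = x$master_seed,
    S = x$S,
    rows = nrow(df),
    md5 = unname(tools::md5sum(path))
  )
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write an experiment manifest
#'
#' Records, for a directory of experiment outputs, the configuration used,
#' per-file MD5 checksums, and the package version, as a JSON manifest.
#' A configuration plus the package version determines every output byte,
#' so the manifest makes re-runs auditable.
#'
#' @param dir Output directory containing the files.
#' @param config Named list: the experiment configuration (including the
#'   master seed).
#' @param files Character vector of file names inside `dir`.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, files) {
  paths <- file.path(dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) {
    stop("missing output files: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("stopsignal")),
    config = config,
    files = lapply(seq_along(files), function(i) {
      list(name = files[i], md5 = unname(tools::md5sum(paths[i])))
    })
  )
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
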