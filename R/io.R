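#' Read voxel time courses
#'
#' Reads a delimited-text time-course matrix (time x voxel, tab separated,
#' percent signal change at 1 s sampling) with `#`-prefixed metadata lines
#' (`n_runs`, `tr_s`), or a 4D NIfTI file with a JSON sidecar carrying the
#' same fields (voxels are unpacked in array order).
#'
#' @param path File path (`.tsv`/`.txt`, or `.nii`/`.nii.gz` with a `.json`
#'   sidecar next to it).
#' @return Matrix (time x voxel) of class `voxel_timecourses` with attributes
#'   `n_runs` and `tr_s`.
#' @export
read_timeseries <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) return(read_timeseries_nifti(path))
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- parse_meta(lines[meta_idx])
  body_lines <- setdiff(seq_along(lines), meta_idx)
  body <- lines[body_lines]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad)) {
    stop("parse error at line ", body_lines[bad[1] + 1], ": expected ",
         length(header), " fields, got ", length(rows[[bad[1]]]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  if (anyNA(m)) {
    bad_vox <- header[unique(which(is.na(m), arr.ind = TRUE)[, 2])]
    stop("NaN/non-numeric cells in voxels: ", paste(bad_vox, collapse = ", "))
  }
  tr <- as.numeric(meta[["tr_s"]] %||% 1)
  if (tr != 1) stop("sampling interval is ", tr, " s; expected 1 s")
  n_runs <- as.integer(meta[["n_runs"]] %||% 1)
  if (nrow(m) %% n_runs != 0) {
    stop("row count ", nrow(m), " not divisible by n_runs ", n_runs)
  }
  structure(m, n_runs = n_runs, tr_s = tr,
            class = c("voxel_timecourses", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_meta <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- strsplit(lines[grepl(":", lines)], ":\\s*")
  setNames(lapply(kv, function(p) paste(p[-1], collapse = ":")),
           vapply(kv, `[`, "", 1))
}

read_timeseries_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI support requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  m <- t(matrix(img, prod(d[1:3]), d[4]))  # time x voxel
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  n_runs <- as.integer(meta[["n_runs"]] %||% 1)
  tr <- as.numeric(meta[["tr_s"]] %||% 1)
  if (tr != 1) stop("sampling interval is ", tr, " s; expected 1 s")
  if (anyNA(m)) stop("NaN cells in NIfTI volume")
  structure(m, n_runs = n_runs, tr_s = tr,
            class = c("voxel_timecourses", "matrix", "array"))
}

#' Write voxel time courses
#'
#' @param bold Matrix (time x voxel), e.g. from [synthesize_bold()].
#' @param path Output path (tab-separated text).
#' @param n_runs Runs spanned by the rows (default from the attribute).
#' @return The path, invisibly.
#' @export
write_timeseries <- function(bold, path, n_runs = attr(bold, "n_runs")) {
  m <- as.matrix(bold)
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# prfst timeseries", paste0("# n_runs: ", n_runs %||% 1),
               "# tr_s: 1"), con)
  writeLines(paste(colnames(m), collapse = "\t"), con)
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a solved-parameter table
#'
#' One row per voxel with all model parameters, gains, R-squared and
#' exclusion flags; units are documented in `#` header comments (degrees for
#' x/y/sigma; CST tau in 10 ms samples with a derived `tau_ms` column;
#' DN-ST tau1/tau2 in seconds).
#'
#' @param results Data frame from [solve_prf()].
#' @param path Output path (tab-separated text).
#' @param model_kind Model the results belong to.
#' @param seed Seed used by the solve (recorded in the header).
#' @return The path, invisibly.
#' @export
write_results <- function(results, path, model_kind = NULL, seed = NULL) {
  res <- as.data.frame(results)
  if (!is.null(res$tau) && is.null(res$tau_ms)) res$tau_ms <- cst_tau_ms(res$tau)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# prfst results",
               paste0("# model: ", model_kind %||% "unspecified"),
               paste0("# seed: ", seed %||% "unspecified"),
               "# units: x,y,sigma deg; tau 10ms-samples; tau_ms ms; tau1,tau2 s; beta,r2 dimensionless"),
             con)
  utils::write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a run configuration
#'
#' A fully serializable description of a pipeline run: design, model kind,
#' HRF mode, solver and noise settings, seeds and output directory. A config
#' plus its seeds reproduces every deterministic output.
#'
#' @param path JSON file path.
#' @param config Named list to write.
#' @return The configuration list (classed `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("design", "model")
  miss <- setdiff(needed, names(cfg))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  defaults <- list(hrf = "default", n_voxels = 300L, seed = 1L,
                   snr_db = snr_db_for_r2(0.3), out_dir = ".")
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  structure(cfg, class = c("run_config", class(cfg)))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
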