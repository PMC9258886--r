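# File-format round-trips: the calibration CSV schema (profiles + lengths
# sidecar), run manifests, and frame dumps.

#' Write / read a profile dataset in the calibration CSV schema
#'
#' \code{<stem>_profiles.csv}: columns \code{cohort}, \code{timepoint},
#' \code{normalized_position}, \code{density_um3}.
#' \code{<stem>_lengths.csv}: columns \code{timepoint}, \code{length_um}.
#'
#' @param dataset A \code{cortexfold_dataset}.
#' @param stem Path stem for the two CSV files.
#' @return \code{write_dataset_csv} returns the two paths invisibly;
#'   \code{read_dataset_csv} returns a \code{cortexfold_dataset}.
#' @export
write_dataset_csv <- function(dataset, stem) {
  stopifnot(inherits(dataset, "cortexfold_dataset"))
  pp <- paste0(stem, "_profiles.csv")
  lp <- paste0(stem, "_lengths.csv")
  prof <- dataset$profiles
  names(prof)[names(prof) == "density"] <- "density_um3"
  utils::write.csv(prof, pp, row.names = FALSE)
  utils::write.csv(dataset$lengths, lp, row.names = FALSE)
  invisible(c(pp, lp))
}

#' @rdname write_dataset_csv
#' @param mode Dataset layout (see \code{\link{experimental_dataset}}).
#' @export
read_dataset_csv <- function(stem, mode = "three_cohort") {
  prof <- utils::read.csv(paste0(stem, "_profiles.csv"))
  names(prof)[names(prof) == "density_um3"] <- "density"
  lens <- utils::read.csv(paste0(stem, "_lengths.csv"))
  # files may hold model-generated data, whose lengths need not increase
  experimental_dataset(prof, lens, mode, strict = FALSE)
}

#' Write a run manifest
#'
#' JSON snapshot of the configuration, seeds, package version, wall times
#' and an inventory (with MD5 checksums) of the files in the output
#' directory.
#'
#' @param out_dir Output directory.
#' @param config Configuration object (any list).
#' @param seed The run seed.
#' @param started POSIXct start time.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, config, seed = NA, started = Sys.time()) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  inv <- data.frame(file = files,
                    md5 = vapply(file.path(out_dir, files),
                                 function(f) unname(tools::md5sum(f)), ""),
                    row.names = NULL)
  man <- list(package = "cortexfold",
              version = as.character(utils::packageVersion("cortexfold")),
              seed = seed,
              started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
              finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = config,
              files = inv)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write simulation frames as CSV (and VTK for 2-D runs)
#'
#' Bar frames become \code{frame_<t>.csv} with position and per-cohort
#' spatial densities; half-circle frames additionally get a VTK file with
#' densities, volume ratio and true strain.
#'
#' @param sim A \code{cortexfold_sim}.
#' @param out_dir Output directory (created if missing).
#' @param vtk Also write VTK files for 2-D frames.
#' @return The directory, invisibly.
#' @export
write_frames <- function(sim, out_dir, vtk = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- sim$mesh
  for (fr in sim$frames) {
    tag <- formatC(fr$t, format = "f", digits = 2)
    if (fr$geometry == "bar") {
      df <- data.frame(x_um = mesh$x + fr$u)
      for (i in seq_len(ncol(fr$c_spatial)))
        df[[paste0("c", i, "_um3")]] <- fr$c_spatial[, i]
      utils::write.csv(df, file.path(out_dir, paste0("frame_", tag, ".csv")),
                       row.names = FALSE)
    } else {
      df <- data.frame(x_um = mesh$nodes[, 1] + fr$u[, 1],
                       y_um = mesh$nodes[, 2] + fr$u[, 2])
      for (i in seq_len(ncol(fr$c_spatial)))
        df[[paste0("c", i, "_um3")]] <- fr$c_spatial[, i]
      utils::write.csv(df, file.path(out_dir, paste0("frame_", tag, ".csv")),
                       row.names = FALSE)
      if (vtk) {
        pd <- lapply(seq_len(ncol(fr$c_spatial)), function(i) fr$c_spatial[, i])
        names(pd) <- paste0("c", seq_along(pd))
        write_vtk(mesh, file.path(out_dir, paste0("frame_", tag, ".vtk")),
                  point_data = pd,
                  cell_data = list(J = fr$J, ln_lambda = fr$ln_lambda),
                  displacements = fr$u)
      }
    }
  }
  invisible(out_dir)
}
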