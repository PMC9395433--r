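## Plain-text interchange: OBJ surfaces, CSV per-vertex maps, BIDS-style
## events tables, design matrices, warp fields and JSON manifests.

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a `sphere_mesh` or `folded_mesh`.
#' @param path output path (.obj).
#' @return the path, invisibly.
#' @export
write_surface_obj <- function(mesh, path) {
  V <- if (inherits(mesh, "folded_mesh")) mesh$vertices else mesh$vertices
  Fc <- if (inherits(mesh, "folded_mesh")) mesh$mesh$faces else mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("f %d %d %d", Fc[, 1], Fc[, 2], Fc[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ surface
#'
#' @param path an .obj file with `v` and triangular `f` records.
#' @return list with `vertices` (n x 3) and `faces` (m x 3).
#' @export
read_surface_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  vertices <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(sub("/.*", "", x[2:4]))
  }))
  list(vertices = vertices, faces = faces)
}

#' Write a per-vertex map as single-column CSV (header = label)
#'
#' @param values numeric per-vertex values (or `scalar_map`).
#' @param path output path (.csv).
#' @param label column header (defaults to the scalar map's label).
#' @return the path, invisibly.
#' @export
write_map_csv <- function(values, path, label = NULL) {
  if (is.null(label)) {
    label <- attr(values, "label")
    if (is.null(label) || !nzchar(label)) label <- "value"
  }
  df <- stats::setNames(data.frame(as.numeric(values)), label)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-vertex map written by [write_map_csv()]
#'
#' @param path the .csv file.
#' @return numeric vector with attribute `"label"`.
#' @export
read_map_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(as.numeric(df[[1]]), label = names(df)[1])
}

#' Write a paradigm as a BIDS-style events table (TSV)
#'
#' Columns: onset, duration, trial_type, is_target.
#'
#' @param paradigm a [generate_paradigm()] object.
#' @param path output path (.tsv).
#' @return the path, invisibly.
#' @export
write_events_tsv <- function(paradigm, path) {
  df <- data.frame(
    onset = paradigm$trials$onset,
    duration = paradigm$trials$duration,
    trial_type = as.character(paradigm$trials$condition),
    is_target = paradigm$trials$is_target
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table back into a paradigm
#'
#' Metadata not stored in the table (lead-in/out, prolonged-ITI schedule) is
#' reconstructed from the onsets.
#'
#' @param path a .tsv written by [write_events_tsv()].
#' @param lead_in,lead_out fixation periods in seconds.
#' @return a `paradigm` object.
#' @export
read_events_tsv <- function(path, lead_in = 10, lead_out = 20) {
  df <- utils::read.delim(path)
  n <- nrow(df)
  gaps <- diff(df$onset) - df$duration[-n]
  prolonged_after <- which(gaps > 0)
  structure(
    list(
      trials = tibble::tibble(
        trial = seq_len(n),
        condition = factor(df$trial_type, levels = QUADRANTS),
        onset = df$onset, duration = df$duration,
        is_target = as.logical(df$is_target)
      ),
      prolonged_iti_after = prolonged_after,
      lead_in = lead_in, lead_out = lead_out,
      total_duration = lead_in + sum(df$duration) + sum(gaps) + lead_out
    ),
    class = "paradigm"
  )
}

#' Write a design matrix as CSV with named columns
#' @param design a [build_design()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design$matrix), path, row.names = FALSE)
  invisible(path)
}

#' Write a warp field (unit target positions) as CSV
#' @param warp n x 3 matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_warp_csv <- function(warp, path) {
  df <- stats::setNames(as.data.frame(warp), c("x", "y", "z"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a warp field written by [write_warp_csv()]
#' @param path the .csv file.
#' @return n x 3 matrix of unit positions.
#' @export
read_warp_csv <- function(path) {
  as.matrix(utils::read.csv(path))
}
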