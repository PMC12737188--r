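# Volume and table I/O. All downstream modules consume only the containers
# defined in volumes.R; nothing else in the package touches files.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Write voxel spacing sidecar
#'
#' Writes a YAML sidecar (`spacing_um: [dz, dy, dx]`) next to a volume file.
#' Spacing travels in a sidecar rather than TIFF tags because holotomography
#' vendors disagree on tag dialects.
#'
#' @param spacing A [voxel_spacing()].
#' @param path Path of the volume file the sidecar belongs to.
#' @return The sidecar path, invisibly.
#' @export
write_spacing_sidecar <- function(spacing, path) {
  stopifnot(inherits(spacing, "voxel_spacing"))
  sp <- sidecar_path(path)
  yaml::write_yaml(list(spacing_um = c(spacing$dz, spacing$dy, spacing$dx)), sp)
  invisible(sp)
}

#' Read voxel spacing sidecar
#' @param path Path of the volume file (not the sidecar itself).
#' @return A [voxel_spacing()], or `NULL` when no sidecar exists.
#' @export
read_spacing_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  y <- yaml::read_yaml(sp)
  if (is.null(y$spacing_um) || length(y$spacing_um) != 3L)
    stop("sidecar ", sp, " lacks a 3-element spacing_um key", call. = FALSE)
  voxel_spacing(y$spacing_um[1], y$spacing_um[2], y$spacing_um[3])
}

#' Read a 3D volume from a multi-page TIFF
#'
#' One TIFF page per z slice, z ascending; float pages are preserved
#' bit-exactly (at 32-bit precision). Spacing is taken from the `spacing`
#' argument or, failing that, from the YAML sidecar written by
#' [write_volume()].
#'
#' @param path Path to a multi-page TIFF.
#' @param spacing Optional [voxel_spacing()]; overrides any sidecar.
#' @param type `"ri"`, `"fluorescence"` or `"labels"` — which container to
#'   return.
#' @return An [ri_tomogram()], [fluorescence_volume()] or [label_volume()].
#' @export
read_volume <- function(path, spacing = NULL,
                        type = c("ri", "fluorescence", "labels")) {
  type <- match.arg(type)
  if (is.null(spacing)) spacing <- read_spacing_sidecar(path)
  if (is.null(spacing))
    stop("no spacing given and no sidecar found for ", path, call. = FALSE)
  arr <- read_tiff_stack(path)
  switch(type,
         ri = ri_tomogram(arr, spacing),
         fluorescence = fluorescence_volume(arr, spacing),
         labels = label_volume(array(as.integer(arr), dim(arr)), spacing))
}

#' Write a 3D volume to a multi-page TIFF
#'
#' RI and fluorescence volumes are written as float32 pages, label volumes as
#' uint16. A YAML spacing sidecar is written alongside unless `sidecar =
#' FALSE`.
#'
#' @param volume An [ri_tomogram()], [fluorescence_volume()] or
#'   [label_volume()].
#' @param path Output path.
#' @param sidecar Write the spacing sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, sidecar = TRUE) {
  if (inherits(volume, "label_volume")) {
    write_tiff_stack(volume$labels, path, "uint16")
  } else if (inherits(volume, "hq_volume")) {
    write_tiff_stack(volume$values, path, "float32")
  } else stop("not a holoquant volume object", call. = FALSE)
  if (sidecar) write_spacing_sidecar(volume$spacing, path)
  invisible(path)
}

#' Write a results table to CSV
#'
#' Comma-separated, header row, UTF-8, `.` decimal separator. Doubles survive
#' a round trip through [read_table()] to at least 12 significant digits.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) {
    s <- sprintf("%.15g", x)
    s[is.na(x)] <- NA_character_
    s
  })
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
            na = "")
  invisible(path)
}

#' Read a results table from CSV
#' @param path Path written by [write_table()] (or any well-formed CSV with a
#'   header row).
#' @return A data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("malformed table ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  df
}
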