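#' Read and write pipeline artifacts
#'
#' Volumetric data travels as NIfTI-1 (uncompressed `.nii`, 64-bit float;
#' spectral stacks as one 4-D volume with the 4th axis indexing saturation
#' offsets), offsets and tidy tables as UTF-8 CSV with a header row, and
#' reports/manifests as JSON. All writers are lossless for numeric payloads
#' and deterministic (no timestamps embedded), so reruns of an identical
#' pipeline produce byte-identical files.
#'
#' @param stack 3-D array (row, col, offset).
#' @param file Path to write/read.
#' @return Readers return the parsed object; writers return `file`
#'   invisibly.
#' @name cest_io
NULL

#' @rdname cest_io
#' @export
write_zstack <- function(stack, file) {
  stopifnot(length(dim(stack)) == 3L)
  arr <- array(as.numeric(stack), dim = c(dim(stack)[1], dim(stack)[2], 1L,
                                          dim(stack)[3]))
  RNifti::writeNifti(arr, file, datatype = "double")
  invisible(file)
}

#' @rdname cest_io
#' @export
read_zstack <- function(file) {
  arr <- as.array(RNifti::readNifti(file))
  if (length(dim(arr)) == 4L) {
    if (dim(arr)[3] != 1L)
      stop(sprintf("%s: expected a single slice, found %d", file,
                   dim(arr)[3]), call. = FALSE)
    arr <- array(arr, dim = dim(arr)[c(1, 2, 4)])
  }
  if (length(dim(arr)) != 3L)
    stop(sprintf("%s: expected a 3-D or 4-D spectral stack", file),
         call. = FALSE)
  arr
}

#' @rdname cest_io
#' @param image 2-D matrix (e.g. a B0 map or contrast map).
#' @export
write_map <- function(image, file) {
  RNifti::writeNifti(array(as.numeric(image), dim = c(dim(image), 1L)),
                     file, datatype = "double")
  invisible(file)
}

#' @rdname cest_io
#' @export
read_map <- function(file) {
  arr <- as.array(RNifti::readNifti(file))
  matrix(arr, dim(arr)[1], dim(arr)[2])
}

#' @rdname cest_io
#' @param axis Numeric offsets in ppm.
#' @export
write_offsets_csv <- function(axis, file) {
  utils::write.csv(data.frame(offset_ppm = as.numeric(axis)), file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname cest_io
#' @export
read_offsets_csv <- function(file) {
  d <- utils::read.csv(file)
  if (!"offset_ppm" %in% names(d))
    stop(sprintf("%s: missing column 'offset_ppm'", file), call. = FALSE)
  axis <- as.numeric(d$offset_ppm)
  if (any(!is.finite(axis)))
    stop(sprintf("%s: non-finite offsets", file), call. = FALSE)
  if (is.unsorted(axis, strictly = TRUE)) {
    warning(sprintf("%s: offsets not sorted; sorting on load", file),
            call. = FALSE)
    axis <- sort(unique(axis))
  }
  axis
}

#' @rdname cest_io
#' @param labels Integer matrix with region names in attribute `regions`.
#' @export
write_labels <- function(labels, file) {
  RNifti::writeNifti(array(as.integer(labels), dim = c(dim(labels), 1L)),
                     file, datatype = "int16")
  jsonlite::write_json(list(regions = attr(labels, "regions")),
                       paste0(file, ".json"), auto_unbox = FALSE)
  invisible(file)
}

#' @rdname cest_io
#' @export
read_labels <- function(file) {
  arr <- as.array(RNifti::readNifti(file))
  lab <- matrix(as.integer(arr), dim(arr)[1], dim(arr)[2])
  sidecar <- paste0(file, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("%s: missing region registry sidecar %s", file, sidecar),
         call. = FALSE)
  regions <- unlist(jsonlite::read_json(sidecar)$regions)
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) && max(ids) > length(regions))
    stop(sprintf("%s: label %d has no entry in the region registry",
                 file, max(ids)), call. = FALSE)
  attr(lab, "regions") <- regions
  lab
}

#' @rdname cest_io
#' @param table data frame.
#' @export
write_table_csv <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname cest_io
#' @export
read_table_csv <- function(file) utils::read.csv(file)

#' Write a simulated phantom to a directory
#'
#' Lays out the on-disk form the pipeline consumes: `offsets.csv`,
#' `wassr_offsets.csv`, `labels.nii` (+ region-registry sidecar),
#' `subjects.csv`, per-subject `z_<id>.nii` and `wassr_<id>.nii` 4-D
#' stacks, plus ground truth (`truth.csv`, `b0_true.nii`) for validation.
#'
#' @param phantom A `cest_phantom` from [simulate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "cest_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_offsets_csv(phantom$axis, p("offsets.csv"))
  write_offsets_csv(phantom$wassr_axis, p("wassr_offsets.csv"))
  write_labels(phantom$labels, p("labels.nii"))
  write_table_csv(phantom$subject_table, p("subjects.csv"))
  write_table_csv(phantom$truth, p("truth.csv"))
  write_map(phantom$b0_true, p("b0_true.nii"))
  for (s in phantom$subjects) {
    write_zstack(s$z, p(sprintf("z_%s.nii", s$id)))
    write_zstack(s$wassr, p(sprintf("wassr_%s.nii", s$id)))
  }
  invisible(dir)
}

#' Read a phantom directory back
#'
#' @param dir Directory written by [write_phantom()] (ground-truth files
#'   optional).
#' @return List with `axis`, `wassr_axis`, `labels`, `subject_table` and
#'   `subjects` (per subject: `id`, `arm`, `z`, `wassr`).
#' @export
read_phantom_dir <- function(dir) {
  p <- function(...) file.path(dir, ...)
  for (f in c("offsets.csv", "wassr_offsets.csv", "labels.nii",
              "subjects.csv"))
    if (!file.exists(p(f)))
      stop(sprintf("input directory %s is missing %s", dir, f),
           call. = FALSE)
  axis <- read_offsets_csv(p("offsets.csv"))
  waxis <- read_offsets_csv(p("wassr_offsets.csv"))
  labels <- read_labels(p("labels.nii"))
  tab <- read_table_csv(p("subjects.csv"))
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$subject[i]
    z <- read_zstack(p(sprintf("z_%s.nii", id)))
    w <- read_zstack(p(sprintf("wassr_%s.nii", id)))
    if (dim(z)[3] != length(axis))
      stop(sprintf("z_%s.nii has %d offset volumes but offsets.csv has %d rows",
                   id, dim(z)[3], length(axis)), call. = FALSE)
    if (dim(w)[3] != length(waxis))
      stop(sprintf("wassr_%s.nii has %d offset volumes but wassr_offsets.csv has %d rows",
                   id, dim(w)[3], length(waxis)), call. = FALSE)
    list(id = id, arm = tab$arm[i], z = z, wassr = w)
  })
  names(subjects) <- tab$subject
  list(axis = axis, wassr_axis = waxis, labels = labels,
       subject_table = tab, subjects = subjects)
}
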