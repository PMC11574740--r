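# NIfTI and table I/O. Volumes are written with an identity affine in the
# synthetic grid; real-data users are expected to supply atlas-registered
# inputs on a common grid.

#' Write a volume or 4-D series as NIfTI
#' @param vol numeric/integer array (3-D or 4-D).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param tr repetition interval in seconds, stored in the header for 4-D data.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, tr = NULL) {
  img <- RNifti::asNifti(vol)
  if (!is.null(tr) && length(dim(vol)) == 4)
    RNifti::pixdim(img) <- c(1, 1, 1, tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path NIfTI file path.
#' @return numeric array; the repetition interval (if 4-D) is attached as
#'   attribute `"tr"`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 4)
    attr(arr, "tr") <- RNifti::pixdim(img)[4]
  arr
}

#' Round-trip an object through a supported on-disk format
#'
#' Volumes (3-D/4-D arrays) go through NIfTI, data frames through CSV/TSV,
#' and lists through JSON, chosen by the path's extension. Tables reproduce
#' bitwise including column order; volumes to float precision.
#'
#' @param x array, data.frame, or list.
#' @param path destination; extension selects the format
#'   (`.nii`/`.nii.gz`, `.csv`, `.tsv`, `.json`).
#' @return the object as read back from `path`.
#' @export
io_roundtrip <- function(x, path) {
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", basename(path)))
  if (ext %in% c(".nii", ".nii.gz")) {
    stopifnot(is.array(x))
    write_volume(x, path)
    out <- read_volume(path)
    attr(out, "tr") <- NULL
    out
  } else if (ext %in% c(".csv", ".tsv")) {
    stopifnot(is.data.frame(x))
    sep <- if (ext == ".csv") "," else "\t"
    utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
    utils::read.table(path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else if (ext == ".json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported extension: ", ext)
  }
}
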