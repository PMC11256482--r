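#' Read a NIfTI-1 volume
#'
#' Loads a `.nii`/`.nii.gz` file into a [volume()], canonicalising the array
#' to RAS+ orientation so downstream world-coordinate computation is
#' consistent across inputs. Non-finite voxels do not abort the read; their
#' count is attached as a validation report.
#'
#' @param path path to a NIfTI-1 file.
#' @param units unit tag to attach (the format does not carry one).
#' @return a `morpho_volume`; `attr(, "validation")` holds
#'   `list(n_nonfinite = ...)`.
#' @export
read_volume <- function(path, units = "arbitrary") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI-1 file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (length(dim(img)) == 3L) RNifti::orientation(img) <- "RAS"
  aff <- unclass(RNifti::xform(img))
  sp <- abs(RNifti::pixdim(img))[1:3]
  dat <- array(as.double(img), dim = dim(img))
  vol <- volume(dat, spacing = sp, affine = aff, units = units)
  attr(vol, "validation") <- list(n_nonfinite = sum(!is.finite(dat)))
  vol
}

#' Write a volume to NIfTI-1
#'
#' @param vol a `morpho_volume` (3D, or 4D with the vector/channel dimension
#'   last, as used for displacement fields and diffusion series).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param allow_nonfinite set `TRUE` to permit NaN/Inf voxels (off by
#'   default: silent NaNs in maps are almost always a bug upstream).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, allow_nonfinite = FALSE) {
  stopifnot(is_volume(vol))
  if (!allow_nonfinite && any(!is.finite(vol$data)))
    stop("refusing to write non-finite voxel data (set allow_nonfinite = TRUE to override)")
  img <- RNifti::asNifti(vol$data)
  # pixdim assignment must cover every data dimension (silently ignored
  # otherwise for 4D images)
  RNifti::pixdim(img) <- c(vol$spacing, rep(1, length(dim(vol$data)) - 3L))
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a dense displacement field
#'
#' Fields are stored as 4D NIfTI with the 3-vector dimension last, values in
#' world millimetres, direction template -> subject.
#'
#' @param path NIfTI file path.
#' @return a `morpho_field` (see [displacement_field()]).
#' @export
read_field <- function(path) {
  vol <- read_volume(path)
  d <- dim(vol$data)
  if (length(d) != 4L || d[4] != 3L)
    stop("a displacement field must be 4D with 3 components in the last dimension")
  displacement_field(vol$data, spacing = vol$spacing, affine = vol$affine)
}

#' @rdname read_field
#' @param field a `morpho_field`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "morpho_field"))
  vol <- volume(field$data, spacing = field$spacing, affine = field$affine,
                units = "mm")
  write_volume(vol, path)
}

#' Dense displacement field container
#'
#' `u(x)` in mm on the reference grid; the spatial map is
#' `Phi(x) = x + u(x)`, world coordinates, direction template -> subject.
#'
#' @param data 4D array `(nx, ny, nz, 3)` of mm displacements.
#' @param spacing,affine geometry of the reference grid (see [volume()]).
#' @return an object of class `morpho_field`.
#' @export
displacement_field <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 4L || dim(data)[4] != 3L)
    stop("field data must be (nx, ny, nz, 3)")
  if (any(!is.finite(data))) stop("field contains non-finite values")
  v <- volume(data, spacing = spacing, affine = affine, units = "mm")
  structure(list(data = v$data, spacing = v$spacing, affine = v$affine),
            class = "morpho_field")
}

#' @export
print.morpho_field <- function(x, ...) {
  d <- dim(x$data)
  mag <- sqrt(x$data[, , , 1]^2 + x$data[, , , 2]^2 + x$data[, , , 3]^2)
  cat(sprintf("<morpho_field> %s grid, |u| mean %.3g mm, max %.3g mm\n",
              paste(d[1:3], collapse = "x"), mean(mag), max(mag)))
  invisible(x)
}

field_as_volume <- function(field, component) {
  volume(field$data[, , , component], spacing = field$spacing,
         affine = field$affine, units = "mm")
}

#' Read/write FSL-style b-value and b-vector tables
#'
#' `bval` is one row of b-values (s/mm^2); `bvec` is three rows of gradient
#' components, one column per measurement.
#'
#' @param bval_path,bvec_path file paths.
#' @return `read_btable`: list with `bvals` (numeric) and `bvecs`
#'   (n x 3 matrix).
#' @export
read_btable <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3L) stop("bvec file must have 3 rows")
  if (ncol(bv) != length(bvals))
    stop("bval/bvec measurement counts differ")
  list(bvals = bvals, bvecs = t(unname(bv)))
}

#' @rdname read_btable
#' @param bvals numeric vector of b-values.
#' @param bvecs n x 3 matrix of gradient directions.
#' @export
write_btable <- function(bvals, bvecs, bval_path, bvec_path) {
  writeLines(paste(format(bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  write.table(t(bvecs), bvec_path, row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a YAML run/phantom configuration
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Run manifest: structured provenance log
#'
#' Every pipeline stage appends an entry (stage name, parameters, seed,
#' output file checksums); [write_manifest()] serialises to JSON.
#'
#' @param study_name free-text study label.
#' @return an environment-backed manifest object.
#' @export
new_manifest <- function(study_name = "dbm-study") {
  env <- new.env(parent = emptyenv())
  env$study <- study_name
  env$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  env$entries <- list()
  structure(env, class = "morpho_manifest")
}

#' @rdname new_manifest
#' @param manifest a manifest object.
#' @param stage stage name.
#' @param params named list of parameters (include seeds here).
#' @param files character vector of output paths to checksum (md5).
#' @export
manifest_add <- function(manifest, stage, params = list(), files = character()) {
  files <- files[file.exists(files)]
  sums <- if (length(files)) as.list(tools::md5sum(files)) else list()
  manifest$entries[[length(manifest$entries) + 1L]] <-
    list(stage = stage, params = params, checksums = sums)
  invisible(manifest)
}

#' @rdname new_manifest
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(
    list(study = manifest$study, created = manifest$created,
         entries = manifest$entries),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
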