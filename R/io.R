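# NIfTI I/O. Grid metadata (spacing, origin) and semantic tags (field
# direction convention, mask label maps) travel in a sidecar JSON next to
# each image so that round trips are exact and the DVF convention is always
# explicit. Spacing is additionally written to the NIfTI pixdim.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".json")
}

is_metaimage <- function(path) grepl("\\.mh[da]$", path, ignore.case = TRUE)

# MetaImage (MHA/MHD) writer: text header plus raw little-endian doubles,
# either appended to the header (.mha, ElementDataFile = LOCAL) or in a
# sibling .raw file (.mhd). Vector fields are stored channel-interleaved
# with ElementNumberOfChannels = 3 and the package's direction convention
# recorded as an explicit DirectionConvention header tag.
write_metaimage <- function(arr, grid, path, convention = NULL) {
  nchan <- if (length(dim(arr)) == 4L) dim(arr)[4] else 1L
  local_data <- grepl("\\.mha$", path, ignore.case = TRUE)
  raw_name <- paste0(sub("\\.mh[da]$", "", basename(path), ignore.case = TRUE),
                     ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(grid$origin, trim = TRUE), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =",
          paste(format(grid$spacing, trim = TRUE), collapse = " ")),
    paste("DimSize =", paste(grid$shape, collapse = " ")),
    if (nchan > 1) paste("ElementNumberOfChannels =", nchan),
    if (!is.null(convention)) paste("DirectionConvention =", convention),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", if (local_data) "LOCAL" else raw_name))
  data <- if (nchan > 1) as.vector(aperm(arr, c(4, 1, 2, 3))) else as.vector(arr)
  if (local_data) {
    con <- file(path, "wb")
    writeLines(header, con)
    writeBin(as.numeric(data), con, size = 8, endian = "little")
    close(con)
  } else {
    writeLines(header, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    writeBin(as.numeric(data), con, size = 8, endian = "little")
    close(con)
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  header <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "\\s*=\\s*")[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: ", line)
    header[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(header$ElementType, "MET_DOUBLE"))
    stop("only MET_DOUBLE MetaImage data is supported")
  msb <- identical(tolower(header$BinaryDataByteOrderMSB %||% "false"), "true")
  shape <- as.integer(strsplit(header$DimSize, "\\s+")[[1]])
  nchan <- as.integer(header$ElementNumberOfChannels %||% "1")
  n <- prod(shape) * nchan
  if (identical(header$ElementDataFile, "LOCAL")) {
    data <- readBin(con, "numeric", n = n, size = 8,
                    endian = if (msb) "big" else "little")
  } else {
    raw_path <- file.path(dirname(path), header$ElementDataFile)
    data <- readBin(raw_path, "numeric", n = n, size = 8,
                    endian = if (msb) "big" else "little")
  }
  grid <- image_grid(shape,
                     as.numeric(strsplit(header$ElementSpacing, "\\s+")[[1]]),
                     as.numeric(strsplit(header$Offset %||% "0 0 0",
                                         "\\s+")[[1]]))
  arr <- if (nchan > 1) {
    aperm(array(data, c(nchan, shape)), c(2, 3, 4, 1))
  } else {
    array(data, shape)
  }
  list(grid = grid, values = arr,
       convention = header$DirectionConvention)
}


write_nifti_array <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(grid$spacing, rep(1, length(dim(arr)) - 3))
  RNifti::writeNifti(img, path)
}

read_grid_sidecar <- function(path, dims) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    grid <- image_grid(meta$grid$shape, meta$grid$spacing, meta$grid$origin)
    list(grid = grid, meta = meta)
  } else {
    img <- RNifti::readNifti(path)
    list(grid = image_grid(dims, RNifti::pixdim(img)[1:3], c(0, 0, 0)),
         meta = NULL)
  }
}

grid_meta <- function(grid) {
  list(shape = grid$shape, spacing = grid$spacing, origin = grid$origin)
}

#' Write / read a scalar volume
#'
#' NIfTI (`.nii` / `.nii.gz`) stores spacing in `pixdim` and the full grid
#' (including origin) in a sidecar JSON of the same basename; MetaImage
#' (`.mha` single file, `.mhd` + `.raw`) carries the complete geometry in
#' its own header.
#'
#' @param volume A [scalar_volume()].
#' @param path Output file: `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [scalar_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  if (is_metaimage(path)) return(write_metaimage(volume$values, volume$grid, path))
  write_nifti_array(volume$values, volume$grid, path)
  jsonlite::write_json(list(kind = "scalar_volume",
                            grid = grid_meta(volume$grid)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (is_metaimage(path)) {
    mi <- read_metaimage(path)
    if (length(dim(mi$values)) != 3L)
      stop("expected a scalar MetaImage volume: ", path)
    return(scalar_volume(mi$grid, mi$values))
  }
  img <- RNifti::readNifti(path)
  info <- read_grid_sidecar(path, dim(img)[1:3])
  scalar_volume(info$grid, as.array(img))
}

#' Write / read a displacement field
#'
#' The field is stored as 3-component voxel data in mm: a 4D NIfTI
#' (x, y, z, component) with the direction convention in the sidecar JSON,
#' or a 3-channel MetaImage whose header carries an explicit
#' `DirectionConvention` tag. dirqa fields are `target_to_source`: defined
#' on the target (SOT) grid, mapping target world points into source (EOT)
#' space. A file declaring `source_to_target` is inverted at load time so
#' every in-memory field obeys the package convention.
#'
#' @param field A [vector_field()].
#' @param path Output file: `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return `write_field` returns `path` invisibly; `read_field` returns a
#'   [vector_field()] in the `target_to_source` convention.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "vector_field"))
  if (is_metaimage(path)) {
    return(write_metaimage(field$displacements, field$grid, path,
                           convention = "target_to_source"))
  }
  write_nifti_array(field$displacements, field$grid, path)
  jsonlite::write_json(list(kind = "vector_field",
                            convention = "target_to_source",
                            units = "mm",
                            grid = grid_meta(field$grid)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (is_metaimage(path)) {
    mi <- read_metaimage(path)
    arr <- mi$values
    info <- list(grid = mi$grid,
                 meta = list(convention = mi$convention %||% "target_to_source"))
  } else {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 5L) arr <- arr[, , , 1, ]  # NIfTI vector-intent layout
    info <- read_grid_sidecar(path, dim(arr)[1:3])
  }
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("field file must hold a 3-component displacement volume")
  field <- vector_field(info$grid, arr)
  conv <- if (!is.null(info$meta)) info$meta$convention else "target_to_source"
  if (identical(conv, "source_to_target")) {
    field <- invert_field(field)
  } else if (!identical(conv, "target_to_source")) {
    stop("unknown field convention in header: ", conv)
  }
  field
}

#' Write / read a set of ROI masks as a label volume
#'
#' Masks are packed into one integer label volume (0 = background, one label
#' per organ, later masks overwrite earlier ones where they overlap — phantom
#' organ masks are disjoint so only `external` is overwritten) plus a JSON
#' name-to-label map. The external mask, which contains all organs, is
#' written first so organ labels survive the packing.
#'
#' @param masks Named list of [roi_mask()]s on a common grid.
#' @param path Output file, `.nii` or `.nii.gz`.
#' @return `write_masks` returns `path` invisibly; `read_masks` returns a
#'   named list of [roi_mask()]s.
#' @export
write_masks <- function(masks, path) {
  stopifnot(length(masks) >= 1)
  grid <- masks[[1]]$grid
  nm <- vapply(masks, function(m) m$name, "")
  ord <- order(nm != "external")  # external first, then organs
  lab <- array(0L, dim = grid$shape)
  labels <- list()
  l <- 0L
  for (i in ord) {
    l <- l + 1L
    lab[masks[[i]]$membership] <- l
    labels[[masks[[i]]$name]] <- l
  }
  write_nifti_array(lab, grid, path)
  jsonlite::write_json(list(kind = "roi_masks", labels = labels,
                            grid = grid_meta(grid)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  img <- RNifti::readNifti(path)
  info <- read_grid_sidecar(path, dim(img)[1:3])
  if (is.null(info$meta) || is.null(info$meta$labels))
    stop("mask label file requires a sidecar JSON with a name-to-label map")
  lab <- as.array(img)
  labels <- info$meta$labels
  masks <- list()
  for (nm in names(labels)) {
    member <- lab == labels[[nm]]
    if (nm == "external") member <- lab > 0  # organs sit inside external
    masks[[nm]] <- roi_mask(info$grid, nm, member)
  }
  masks
}

#' Write / read a phantom directory
#'
#' Serializes a phantom to `sot.nii.gz`, `eot.nii.gz`, `gt_field.nii.gz`,
#' `masks.nii.gz`, `eot_dose.nii.gz` and a `manifest.json` holding the
#' deformation model, seed and configuration.
#'
#' @param phantom A `dir_phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `write_phantom` returns `dir` invisibly; `read_phantom` returns a
#'   `dir_phantom`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "dir_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$sot, file.path(dir, "sot.nii.gz"))
  write_volume(phantom$eot, file.path(dir, "eot.nii.gz"))
  write_field(phantom$gt_field, file.path(dir, "gt_field.nii.gz"))
  write_masks(phantom$masks, file.path(dir, "masks.nii.gz"))
  write_volume(phantom$eot_dose, file.path(dir, "eot_dose.nii.gz"))
  jsonlite::write_json(list(kind = "dir_phantom", seed = phantom$seed,
                            model = phantom$model, config = phantom$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(
    sot = read_volume(file.path(dir, "sot.nii.gz")),
    eot = read_volume(file.path(dir, "eot.nii.gz")),
    gt_field = read_field(file.path(dir, "gt_field.nii.gz")),
    masks = read_masks(file.path(dir, "masks.nii.gz")),
    eot_dose = read_volume(file.path(dir, "eot_dose.nii.gz")),
    model = manifest$model, config = manifest$config,
    seed = manifest$seed), class = "dir_phantom")
}
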