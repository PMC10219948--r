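#' Write a per-vertex scalar to two-column TSV
#'
#' Columns `vertex_index` (1-based) and `value`; missing vertices written
#' as empty fields.
#'
#' @param values numeric vector (or a `scalar_map`, whose values are taken).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scalar_tsv <- function(values, path) {
  if (inherits(values, "scalar_map")) values <- values$values
  data.table::fwrite(
    data.table::data.table(vertex_index = seq_along(values), value = values),
    path, sep = "\t", na = ""
  )
  invisible(path)
}

#' Read a per-vertex scalar from two-column TSV
#' @param path file written by [write_scalar_tsv()].
#' @return Numeric vector ordered by vertex index.
#' @export
read_scalar_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", na.strings = "")
  out <- rep(NA_real_, max(df$vertex_index))
  out[df$vertex_index] <- df$value
  out
}

#' Write a per-vertex scalar as ASCII-encoded GIFTI
#'
#' Minimal GIFTI-1.0 writer (single float32 data array, ASCII encoding) for
#' interchange of vertex scalar maps; values round-trip at full printed
#' precision.
#'
#' @param values numeric vector (or `scalar_map`).
#' @param path output `.gii` file.
#' @return `path`, invisibly.
#' @export
write_gifti_scalar <- function(values, path) {
  if (inherits(values, "scalar_map")) values <- values$values
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  da <- xml2::xml_add_child(doc, "DataArray",
                            Intent = "NIFTI_INTENT_NONE",
                            DataType = "NIFTI_TYPE_FLOAT32",
                            ArrayIndexingOrder = "RowMajorOrder",
                            Dimensionality = "1",
                            Dim0 = as.character(length(values)),
                            Encoding = "ASCII",
                            Endian = "LittleEndian")
  dat <- xml2::xml_add_child(da, "Data")
  xml2::xml_text(dat) <- paste(
    ifelse(is.na(values), "NaN", sprintf("%.9g", values)),
    collapse = " "
  )
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a scalar GIFTI data array
#' @param path a `.gii` file with one ASCII-encoded data array.
#' @return Numeric vector (`NaN` read back as `NA`).
#' @export
read_gifti_scalar <- function(path) {
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  if (is.na(xml2::xml_attr(da, "Encoding")) ||
      xml2::xml_attr(da, "Encoding") != "ASCII") {
    stop("only ASCII-encoded GIFTI data arrays are supported")
  }
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  v <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  v[is.nan(v)] <- NA_real_
  v
}

#' Write a volume grid as NIfTI-1
#'
#' The value array goes to `path`; the mask, if not all-true, goes to a
#' sibling `*_mask.nii` file. The affine is stored as both sform and qform.
#'
#' @param vol a `volume_grid`.
#' @param path output `.nii` file.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$array)
  vs <- voxel_size(vol)
  RNifti::pixdim(img) <- vs
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  if (!all(vol$mask)) {
    mimg <- RNifti::asNifti(array(as.numeric(vol$mask), dim(vol$mask)))
    RNifti::pixdim(mimg) <- vs
    mimg <- RNifti::`sform<-`(mimg, structure(vol$affine, code = 2L))
    RNifti::writeNifti(mimg, sub("\\.nii(\\.gz)?$", "_mask.nii", path))
  }
  invisible(path)
}

#' Read a NIfTI-1 volume into a volume grid
#' @param path a `.nii` file; a sibling `*_mask.nii` is picked up if present.
#' @return A `volume_grid`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  arr <- array(as.numeric(img), dim = dim(img))
  mask_path <- sub("\\.nii(\\.gz)?$", "_mask.nii", path)
  mask <- NULL
  if (file.exists(mask_path) && mask_path != path) {
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(m) > 0.5, dim = dim(m))
  }
  volume_grid(arr, affine, mask)
}

#' Write a pipeline bundle to a directory
#'
#' One directory per bundle: TSV components plus a `manifest.json` listing
#' every file with its md5 checksum, the subject/pipeline identity, and the
#' timeseries metadata.
#'
#' @param bundle a `pipeline_bundle`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  data.table::fwrite(
    data.table::data.table(
      x = bundle$surface$vertex_coords[, 1],
      y = bundle$surface$vertex_coords[, 2],
      z = bundle$surface$vertex_coords[, 3],
      hemi = bundle$surface$vertex_hemi
    ), fp("surface_vertices.tsv"), sep = "\t"
  )
  data.table::fwrite(
    data.table::as.data.table(bundle$surface$faces),
    fp("surface_faces.tsv"), sep = "\t", col.names = FALSE
  )
  data.table::fwrite(
    data.table::data.table(vertex_index = seq_along(bundle$scheme$labels),
                           label = bundle$scheme$labels),
    fp("labels.tsv"), sep = "\t"
  )
  data.table::fwrite(
    data.table::data.table(id = seq_len(bundle$scheme$n_parcels),
                           name = bundle$scheme$parcel_names),
    fp("parcel_names.tsv"), sep = "\t"
  )
  write_scalar_tsv(bundle$thickness, fp("thickness.tsv"))
  write_scalar_tsv(bundle$gyrification, fp("gyrification.tsv"))
  data.table::fwrite(bundle$parcel_volumes, fp("parcel_volumes.tsv"),
                     sep = "\t")
  data.table::fwrite(data.table::as.data.table(bundle$timeseries$data),
                     fp("timeseries.tsv"), sep = "\t", col.names = FALSE)
  files <- c("surface_vertices.tsv", "surface_faces.tsv", "labels.tsv",
             "parcel_names.tsv", "thickness.tsv", "gyrification.tsv",
             "parcel_volumes.tsv", "timeseries.tsv")
  if (!is.null(bundle$seed_volumes)) {
    for (roi in names(bundle$seed_volumes)) {
      f <- paste0("seed_", roi, ".nii")
      write_volume_nifti(bundle$seed_volumes[[roi]], fp(f))
      files <- c(files, f)
    }
  }
  manifest <- list(
    subject_id = bundle$subject_id,
    pipeline_id = bundle$pipeline_id,
    hemisphere = bundle$surface$hemisphere,
    tr_seconds = bundle$timeseries$tr_seconds,
    run_boundaries = as.integer(bundle$timeseries$run_boundaries),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, files))), files
    ))
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pipeline bundle from a directory
#'
#' Verifies the manifest's file list and checksums, then reconstructs and
#' re-validates the bundle (all type invariants are checked on load).
#'
#' @param dir directory written by [write_bundle()].
#' @return A `pipeline_bundle`.
#' @export
read_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf)
  required <- c("surface_vertices.tsv", "surface_faces.tsv", "labels.tsv",
                "parcel_names.tsv", "thickness.tsv", "gyrification.tsv",
                "parcel_volumes.tsv", "timeseries.tsv")
  missing <- setdiff(required, names(manifest$files))
  if (length(missing)) {
    stop("manifest is missing component(s): ", paste(missing, collapse = ", "))
  }
  for (f in names(manifest$files)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing file: ", f)
    actual <- unname(tools::md5sum(p))
    if (!identical(actual, manifest$files[[f]])) {
      stop("checksum mismatch for ", f)
    }
  }
  verts <- data.table::fread(file.path(dir, "surface_vertices.tsv"))
  faces <- as.matrix(data.table::fread(file.path(dir, "surface_faces.tsv"),
                                       header = FALSE))
  hemi <- manifest$hemisphere
  surface <- surface_model(
    as.matrix(verts[, c("x", "y", "z")]), faces, hemisphere = hemi,
    vertex_hemi = if (hemi == "both") verts$hemi else NULL
  )
  lab <- data.table::fread(file.path(dir, "labels.tsv"))
  labels <- integer(n_vertices(surface))
  labels[lab$vertex_index] <- lab$label
  pn <- data.table::fread(file.path(dir, "parcel_names.tsv"))
  scheme <- parcel_scheme(labels, pn$name[order(pn$id)])
  ts <- as.matrix(data.table::fread(file.path(dir, "timeseries.tsv"),
                                    header = FALSE))
  dimnames(ts) <- NULL
  seed_volumes <- NULL
  seed_files <- grep("^seed_.*\\.nii$", names(manifest$files), value = TRUE)
  seed_files <- seed_files[!grepl("_mask\\.nii$", seed_files)]
  if (length(seed_files)) {
    seed_volumes <- stats::setNames(
      lapply(seed_files, function(f) read_volume_nifti(file.path(dir, f))),
      sub("^seed_(.*)\\.nii$", "\\1", seed_files)
    )
  }
  pipeline_bundle(
    subject_id = manifest$subject_id,
    pipeline_id = manifest$pipeline_id,
    surface = surface,
    scheme = scheme,
    thickness = scalar_map(read_scalar_tsv(file.path(dir, "thickness.tsv")),
                           "thickness_mm", surface),
    gyrification = scalar_map(
      read_scalar_tsv(file.path(dir, "gyrification.tsv")),
      "gyrification", surface
    ),
    parcel_volumes = as.data.frame(
      data.table::fread(file.path(dir, "parcel_volumes.tsv"))
    ),
    timeseries = timeseries_bundle(
      ts, manifest$tr_seconds,
      as.integer(unlist(manifest$run_boundaries))
    ),
    seed_volumes = seed_volumes
  )
}
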