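# Readers and writers for pipeline artifacts.  All I/O is in millimetres;
# no operation rescales silently.  Volumes use zero-based voxel indexing
# with the voxel-centre convention internally mapped to R's 1-based arrays:
# world = origin + (index - 1) * spacing.

.canonical_landmarks <- c("apex", "oval_window", "canal_bifurcation")

#' Write / read a volume (NIfTI or MetaImage)
#'
#' Format is chosen by extension: `.nii` / `.nii.gz` (NIfTI, via RNifti) or
#' `.mha` (MetaImage, uncompressed local data).  Round trips preserve voxel
#' values and geometry exactly.  Anisotropic input volumes are rejected with
#' a request to resample first.
#'
#' @param vol a `ct_volume`.
#' @param path output file path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- rep(vol$spacing, 3)
    m <- rbind(cbind(diag(vol$spacing, 3), vol$origin), c(0, 0, 0, 1))
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", path)) {
    d <- dim(vol$data)
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False", "CompressedData = False",
             "TransformMatrix = 1 0 0 0 1 0 0 0 1",
             paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
             paste("ElementSpacing =", paste(rep(format(vol$spacing, digits = 17), 3), collapse = " ")),
             paste("DimSize =", paste(d, collapse = " ")),
             "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' @rdname write_volume
#' @param path file to read.
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3) stop("format error: ", path, ": missing pixdim")
    if (diff(range(pd[1:3])) > 1e-6 * max(pd[1:3]))
      stop("anisotropic voxel spacing in ", path,
           "; resample to isotropic spacing before use")
    x <- RNifti::xform(img)
    ct_volume(array(as.numeric(img), dim(img)), pd[1], x[1:3, 4])
  } else if (grepl("\\.mha$", path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- list()
    repeat {
      line <- readLines(con, n = 1)
      if (!length(line)) stop("format error: ", path, ": truncated header")
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
      if (key == "ElementDataFile") break
    }
    need <- c("DimSize", "ElementSpacing", "ElementType")
    for (k in need)
      if (is.null(hdr[[k]])) stop("format error: ", path, ": missing ", k)
    d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
    sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
    if (diff(range(sp)) > 1e-6 * max(sp))
      stop("anisotropic voxel spacing in ", path,
           "; resample to isotropic spacing before use")
    org <- if (is.null(hdr$Offset)) c(0, 0, 0)
           else as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
    if (hdr$ElementType != "MET_DOUBLE")
      stop("format error: ", path, ": unsupported ElementType ", hdr$ElementType)
    vals <- readBin(con, "numeric", n = prod(d), size = 8, endian = "little")
    ct_volume(array(vals, d), sp[1], org)
  } else stop("unsupported volume format: ", path)
}

#' Write / read a triangle mesh (PLY, STL or OBJ)
#'
#' ASCII formats; coordinates round trip at double precision.
#'
#' @param mesh a `trimesh`.
#' @param path file path; extension selects the format.
#' @export
write_mesh <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  if (grepl("\\.ply$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(V)),
                 "property double x", "property double y", "property double z",
                 paste("element face", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(format(V, digits = 17, trim = TRUE, scientific = FALSE), 1,
                     paste, collapse = " "), con)
    writeLines(paste(3, F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
  } else if (grepl("\\.obj$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("v", V[, 1], V[, 2], V[, 3]), con)
    writeLines(paste("f", F[, 1], F[, 2], F[, 3]), con)
  } else if (grepl("\\.stl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(F))) {
      tri <- V[F[i, ], , drop = FALSE]
      n <- c(0, 0, 0)
      writeLines(c(paste("facet normal", n[1], n[2], n[3]), "  outer loop",
                   paste("    vertex", tri[, 1], tri[, 2], tri[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else stop("unsupported mesh format: ", path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (grepl("\\.ply$", path)) {
    lines <- readLines(path)
    if (lines[1] != "ply" || !grepl("ascii", lines[2]))
      stop("format error: ", path, ": only ASCII PLY is supported")
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    start <- which(lines == "end_header") + 1
    vl <- lines[start:(start + nv - 1)]
    V <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(x) as.numeric(x[1:3])))
    fl <- lines[(start + nv):(start + nv + nf - 1)]
    F <- do.call(rbind, lapply(strsplit(fl, "\\s+"),
                               function(x) as.integer(x[2:4]) + 1L))
    trimesh(V, F)
  } else if (grepl("\\.obj$", path)) {
    lines <- readLines(path)
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(x) as.numeric(x[2:4])))
    F <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
    trimesh(V, F)
  } else if (grepl("\\.stl$", path)) {
    lines <- readLines(path)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[2:4])))
    F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
    trimesh(V, F)
  } else stop("unsupported mesh format: ", path)
}

#' Write / read landmarks as JSON
#'
#' Landmarks use the canonical names `apex`, `oval_window`,
#' `canal_bifurcation`, each a 3-vector in mm.
#'
#' @param landmarks named list of 3-vectors.
#' @param path JSON file path.
#' @export
write_landmarks <- function(landmarks, path) {
  missing <- setdiff(.canonical_landmarks, names(landmarks))
  if (length(missing))
    stop("schema error: missing landmark ", paste(missing, collapse = ", "))
  jsonlite::write_json(landmarks[.canonical_landmarks], path,
                       digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(.canonical_landmarks, names(lm))
  if (length(missing))
    stop("schema error: missing landmark ", paste(missing, collapse = ", "))
  lapply(lm[.canonical_landmarks], as.numeric)
}

#' Write / read a statistical shape model
#'
#' Stores the model as a single JSON container of named numeric arrays
#' (mean shape, modes, eigenvalues, face topology, reference vertices,
#' training count) at full double precision.
#'
#' @param model a `shape_model`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  obj <- list(mean_shape = model$mean_shape,
              modes = model$modes, eigenvalues = model$eigenvalues,
              faces = model$faces, reference = model$reference,
              n_training = model$n_training)
  jsonlite::write_json(obj, path, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean_shape = as.numeric(obj$mean_shape),
                 modes = as.matrix(obj$modes),
                 eigenvalues = as.numeric(obj$eigenvalues),
                 faces = if (!is.null(obj$faces)) as.matrix(obj$faces),
                 reference = as.matrix(obj$reference),
                 n_training = as.integer(obj$n_training)),
            class = "shape_model")
}

#' Write / read a point cloud (XYZ text or PLY points)
#'
#' @param cloud a `point_cloud`.
#' @param path `.xyz` (whitespace-separated text) or `.ply`.
#' @export
write_cloud <- function(cloud, path) {
  p <- cloud$points
  if (grepl("\\.xyz$", path)) {
    utils::write.table(p, path, row.names = FALSE, col.names = FALSE)
  } else if (grepl("\\.ply$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(p)),
                 "property double x", "property double y", "property double z",
                 "end_header"), con)
    writeLines(apply(format(p, digits = 17, trim = TRUE, scientific = FALSE), 1,
                     paste, collapse = " "), con)
  } else stop("unsupported cloud format: ", path)
  invisible(path)
}

#' @rdname write_cloud
#' @export
read_cloud <- function(path) {
  if (grepl("\\.xyz$", path)) {
    point_cloud(as.matrix(utils::read.table(path)))
  } else if (grepl("\\.ply$", path)) {
    lines <- readLines(path)
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    start <- which(lines == "end_header") + 1
    vl <- lines[start:(start + nv - 1)]
    point_cloud(do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                      function(x) as.numeric(x[1:3]))))
  } else stop("unsupported cloud format: ", path)
}

#' Serialize / read a similarity transform as JSON
#'
#' @param tf a `similarity_transform`.
#' @param path JSON file path.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(list(rotation = as.numeric(t(tf$rotation)),
                            scale = tf$scale, translation = tf$translation,
                            reflect = tf$reflect),
                       path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(matrix(obj$rotation, 3, 3, byrow = TRUE),
                       obj$scale, obj$translation, obj$reflect)
}
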