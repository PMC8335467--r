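#' Write a 3D array as NRRD
#'
#' Minimal NRRD0004 writer for the two payloads this package emits: float32
#' dose grids (Gy) and uint8 binary masks. `raw` encoding is little-endian;
#' `ascii` produces a plain-text file.
#'
#' @param x 3D numeric or logical array.
#' @param path output file.
#' @param grid the array's [grid_spec()].
#' @param type `"float"` or `"uint8"`.
#' @param encoding `"raw"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, grid, type = c("float", "uint8"),
                       encoding = c("raw", "ascii")) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  stopifnot(inherits(grid, "grid_spec"), all(dim(x) == grid$dim))
  sp <- grid$spacing
  hdr <- c(
    "NRRD0004",
    "# adaptrt minimal NRRD writer",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", grid$dim[1], grid$dim[2], grid$dim[3]),
    "space dimension: 3",
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            sp[1], sp[2], sp[3]),
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    "endian: little",
    sprintf("encoding: %s", encoding),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  vals <- as.vector(x)
  if (encoding == "ascii") {
    if (type == "uint8") writeLines(paste(as.integer(vals), collapse = " "), con)
    else writeLines(paste(format(vals, digits = 9), collapse = " "), con)
  } else {
    if (type == "uint8") writeBin(as.integer(vals), con, size = 1)
    else writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NRRD file written by [write_nrrd()]
#'
#' Supports 3D raw/ascii files of type float/double/uint8 with axis-aligned
#' space directions.
#'
#' @param path NRRD file.
#' @return list with `values` (numeric or logical array) and `grid`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("not a NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    if (startsWith(ln, "#")) next
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2) fields[[kv[1]]] <- kv[2]
  }
  sizes <- as.integer(strsplit(fields$sizes, " ")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD supported")
  type <- fields$type
  encoding <- fields$encoding
  nums <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  dirs <- strsplit(fields[["space directions"]], " ")[[1]]
  spacing <- vapply(seq_len(3), function(i) nums(dirs[i])[i], numeric(1))
  origin <- nums(fields[["space origin"]])
  n <- prod(sizes)
  if (encoding == "ascii") {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else if (encoding == "raw") {
    if (type == "uint8") {
      vals <- as.integer(readBin(con, "integer", n = n, size = 1,
                                 signed = FALSE))
    } else if (type == "float") {
      vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
    } else if (type == "double") {
      vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
    } else stop("unsupported NRRD type: ", type)
  } else stop("unsupported NRRD encoding: ", encoding)
  if (length(vals) != n) stop("truncated NRRD payload in ", path)
  values <- array(vals, dim = sizes)
  if (type == "uint8") values <- array(values > 0, dim = sizes)
  list(values = values, grid = grid_spec(spacing, origin, sizes))
}

#' Write a structure set as NRRD masks plus a JSON manifest
#'
#' One uint8 NRRD per mask plus `<stem>_manifest.json` recording the lattice,
#' provenance and mask file names; [read_structure_set()] restores the set.
#'
#' @param ss a [structure_set()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem, e.g. `"P01_fx2"`.
#' @param encoding NRRD encoding.
#' @param extra named list merged into the manifest (seeds, registration, ...).
#' @return the manifest path, invisibly.
#' @export
write_structure_set <- function(ss, dir, stem, encoding = "raw",
                                extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(ss$masks)) {
    f <- file.path(dir, sprintf("%s_%s.nrrd", stem, nm))
    write_nrrd(ss$masks[[nm]], f, ss$grid, type = "uint8",
               encoding = encoding)
    files[nm] <- basename(f)
  }
  manifest <- c(list(stem = stem, provenance = ss$provenance,
                     spacing = ss$grid$spacing, origin = ss$grid$origin,
                     dim = ss$grid$dim, masks = as.list(files)), extra)
  mf <- file.path(dir, sprintf("%s_manifest.json", stem))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Read a structure set written by [write_structure_set()]
#' @param manifest path to the `_manifest.json` file.
#' @return a [structure_set()].
#' @export
read_structure_set <- function(manifest) {
  mf <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  masks <- lapply(mf$masks, function(f) read_nrrd(file.path(dir, f))$values)
  grid <- grid_spec(mf$spacing, mf$origin, mf$dim)
  structure_set(masks, grid, mf$provenance)
}
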