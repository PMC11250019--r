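# Interchange formats: grids as NRRD (detached-header-free NRRD0004 with
# raw little-endian or ascii encoding), plans as JSON. Coordinates are DCS
# millimetres, LPS axes, voxel-centre origin, half-open voxel extents.

#' Write a grid as NRRD
#'
#' Minimal NRRD0004 writer for 3D scalar grids: `double` (dose/density) or
#' `uint8` (masks), raw little-endian or ascii encoding, `space origin` /
#' `space directions` carrying the lattice geometry.
#'
#' @param grid A [dose_grid()], [density_grid()] or [structure_mask()].
#' @param path Output file path.
#' @param encoding `"raw"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(grid, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(grid, "volume_grid"))
  v <- grid$values
  is_mask <- is.logical(v)
  d <- dim(v)
  hdr <- c("NRRD0004",
           sprintf("type: %s", if (is_mask) "uint8" else "double"),
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           "space: left-posterior-superior",
           sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
                   grid$spacing, grid$spacing, grid$spacing),
           sprintf("space origin: (%.9g,%.9g,%.9g)",
                   grid$origin[1], grid$origin[2], grid$origin[3]),
           "endian: little",
           sprintf("encoding: %s", encoding),
           sprintf("fifwbi-class: %s", class(grid)[1]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  if (encoding == "raw") {
    if (is_mask) writeBin(as.integer(v), con, size = 1)
    else writeBin(as.vector(v), con, size = 8, endian = "little")
  } else {
    writeLines(paste(if (is_mask) as.integer(v) else
                     format(as.vector(v), digits = 17), collapse = " "), con)
  }
  invisible(path)
}

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(x) as.numeric(strsplit(gsub("[()]", "", x), ",")[[1]]))
}

#' Read a grid from NRRD
#'
#' Supports the subset written by [write_nrrd()] plus common variants:
#' types double/float/uint8/uchar/int, raw or ascii/text encoding.
#'
#' @param path NRRD file path.
#' @return A [dose_grid()], [density_grid()] or [structure_mask()] depending
#'   on the `fifwbi-class` hint (defaults to `dose_grid` for numeric data).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    if (startsWith(ln, "#")) next
    kv <- regmatches(ln, regexpr(":=?", ln), invert = TRUE)[[1]]
    fields[[trimws(tolower(kv[1]))]] <- trimws(kv[2])
  }
  dimension <- as.integer(fields[["dimension"]])
  if (is.na(dimension) || dimension != 3L)
    stop("only 3D NRRD grids are supported (dimension: ",
         fields[["dimension"]], ")")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (is.null(fields[["space origin"]]) || is.null(fields[["space directions"]]))
    stop("NRRD header lacks space origin / space directions")
  origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  dirs <- parse_nrrd_vectors(fields[["space directions"]])
  spacing <- dirs[[1]][1]
  if (!all(abs(c(dirs[[2]][2], dirs[[3]][3]) - spacing) < 1e-9))
    stop("only isotropic axis-aligned NRRD grids are supported")
  type <- fields[["type"]]
  enc <- fields[["encoding"]]
  n <- prod(sizes)
  if (enc == "raw") {
    endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
    v <- switch(type,
      "double" = readBin(con, "double", n, size = 8, endian = endian),
      "float" = readBin(con, "double", n, size = 4, endian = endian),
      "uint8" = , "uchar" = , "unsigned char" =
        as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
      "int" = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
      stop("unsupported NRRD type: ", type))
  } else if (enc %in% c("ascii", "text", "txt")) {
    v <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(v) != n) stop("NRRD data truncated")
  a <- array(v, sizes)
  cls <- fields[["fifwbi-class"]]
  if (identical(cls, "structure_mask") || type %in% c("uint8", "uchar", "unsigned char"))
    structure_mask(array(a > 0, sizes), origin, spacing)
  else if (identical(cls, "density_grid")) density_grid(a, origin, spacing)
  else dose_grid(a, origin, spacing)
}

beam_to_doc <- function(b) {
  list(id = b$id, role = b$role, gantry = b$gantry, collimator = b$collimator,
       isocenter = b$isocenter, sad = b$sad, energy_mv = b$energy_mv,
       weight = b$weight, jaw = b$aperture$jaw,
       mlc_boundaries = b$aperture$bank$boundaries,
       mlc_x1 = b$aperture$x1, mlc_x2 = b$aperture$x2,
       extra = b$extra)
}

doc_to_beam <- function(d) {
  req <- c("id", "role", "gantry", "collimator", "isocenter", "sad", "weight",
           "jaw", "mlc_boundaries", "mlc_x1", "mlc_x2")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop(sprintf("beam '%s': missing field(s) %s",
                 if (is.null(d$id)) "<no id>" else d$id,
                 paste(miss, collapse = ", ")))
  ap <- mlc_aperture(mlc_bank(unlist(d$mlc_boundaries)),
                     unlist(d$mlc_x1), unlist(d$mlc_x2), unlist(d$jaw))
  b <- fif_beam(d$id, d$gantry, d$collimator, unlist(d$isocenter), ap,
                d$weight, d$role, d$sad,
                if (is.null(d$energy_mv)) 10 else d$energy_mv)
  known <- c(req, "energy_mv", "extra")
  b$extra <- c(d$extra, d[setdiff(names(d), known)])
  if (length(b$extra) == 0) b$extra <- NULL
  b
}

#' Write a plan as JSON
#'
#' Lossless schema: prescription, normalization statement, and per-beam
#' geometry, jaw rectangle, MLC bank boundaries and leaf tip arrays, and
#' weight. Unknown fields read by [read_plan()] are preserved.
#'
#' @param plan An [fif_plan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  doc <- list(format = "fifwbi-plan-1",
              prescription_gy = plan$prescription_gy,
              fractions = plan$fractions,
              normalization = plan$normalization,
              beams = lapply(plan$beams, beam_to_doc))
  doc <- c(doc, plan$extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a plan from JSON
#'
#' @param path Plan JSON path (schema of [write_plan()]).
#' @return An [fif_plan()].
#' @export
read_plan <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("prescription_gy", "fractions", "beams"))
    if (is.null(d[[f]])) stop("plan document: missing field '", f, "'")
  plan <- fif_plan(lapply(d$beams, doc_to_beam), d$prescription_gy, d$fractions)
  known <- c("format", "prescription_gy", "fractions", "normalization", "beams")
  plan$extra <- d[setdiff(names(d), known)]
  if (length(plan$extra) == 0) plan$extra <- NULL
  plan
}

#' Write a run manifest
#'
#' Records the configuration, seed, thresholds and package version next to
#' a run's outputs so every artifact is reproducible.
#'
#' @param path Output file path.
#' @param cfg A [fif_config()].
#' @param seed Integer seed used for the run.
#' @param extra Named list of additional entries (e.g. phantom parameters).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, cfg, seed, extra = list()) {
  doc <- c(list(package = "fifwbi",
                version = as.character(utils::packageVersion("fifwbi")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed,
                d_th = cfg$d_th, criterion = cfg$criterion,
                mu_eff = cfg$engine$mu_eff, t_mlc = cfg$engine$t_mlc,
                inv_square = cfg$engine$inv_square,
                bev_pixel = cfg$bev_pixel, bev_pad = cfg$bev_pad),
           extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
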