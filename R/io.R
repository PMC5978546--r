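#' Read and write voxel volumes (NRRD / MetaImage)
#'
#' NRRD (`.nrrd`, detached-header-free, `raw` little-endian or `text`
#' encoding) is the canonical format; MetaImage (`.mha`, local binary data)
#' is also supported. The value unit, frame label and provenance metadata are
#' carried as NRRD key-value pairs (or packed into the MetaImage `Comment`
#' field) and survive a round trip; geometry round-trips exactly and values
#' bitwise (raw encoding).
#'
#' @param volume a [voxel_volume()].
#' @param path file path ending in `.nrrd` or `.mha`.
#' @param encoding NRRD payload encoding.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` the
#'   [voxel_volume()].
#' @export
write_volume <- function(volume, path, encoding = c("raw", "text")) {
  encoding <- match.arg(encoding)
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") write_nrrd(volume, path, encoding)
  else if (ext == "mha") write_mha(volume, path)
  else stop(sprintf("unknown volume extension '.%s' (use .nrrd or .mha): %s", ext, path))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("volume file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") read_nrrd(path)
  else if (ext == "mha") read_mha(path)
  else stop(sprintf("unknown volume extension '.%s' (use .nrrd or .mha): %s", ext, path))
}

meta_to_kv <- function(meta) {
  if (!length(meta)) return(character())
  keep <- vapply(meta, function(v) is.atomic(v) && length(v) >= 1, TRUE)
  vapply(names(meta)[keep], function(nm)
    sprintf("meta.%s:=%s", nm, paste(format(meta[[nm]], digits = 17), collapse = ",")),
    "")
}

kv_to_meta <- function(kv) {
  out <- list()
  for (nm in names(kv)) {
    if (!startsWith(nm, "meta.")) next
    v <- strsplit(kv[[nm]], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    out[[substring(nm, 6)]] <- if (!any(is.na(num))) num else v
  }
  out
}

write_nrrd <- function(volume, path, encoding = "raw") {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by xpanderdose",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", volume$dims[1], volume$dims[2], volume$dims[3]),
           "space: left-posterior-superior",
           sprintf("space origin: (%.17g,%.17g,%.17g)", volume$origin[1],
                   volume$origin[2], volume$origin[3]),
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   volume$spacing[1], volume$spacing[2], volume$spacing[3]),
           sprintf("encoding: %s", encoding),
           if (encoding == "raw") "endian: little",
           sprintf("unit:=%s", volume$unit),
           sprintf("frame:=%s", volume$frame),
           meta_to_kv(volume$meta),
           "")
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(volume$values), con, size = 8, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(volume$values), digits = 17, trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop(sprintf("corrupt NRRD header (bad magic): %s", path))
  fields <- list(); kv <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop(sprintf("corrupt NRRD header (no blank line): %s", path))
    if (ln == "") break
    if (startsWith(ln, "#")) next
    if (grepl(":=", ln, fixed = TRUE)) {
      p <- regmatches(ln, regexpr(":=", ln), invert = TRUE)[[1]]
      kv[[p[1]]] <- p[2]
    } else {
      p <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1]]
      if (length(p) != 2) stop(sprintf("corrupt NRRD header line '%s': %s", ln, path))
      fields[[p[1]]] <- p[2]
    }
  }
  dims <- as.integer(strsplit(fields$sizes, " ")[[1]])
  nums <- function(s) as.numeric(regmatches(s, gregexpr("[-0-9.eE+]+", s))[[1]])
  origin <- nums(fields[["space origin"]])
  spacing <- nums(fields[["space directions"]])
  spacing <- spacing[spacing != 0]
  n <- prod(dims)
  vals <- if (identical(fields$encoding, "raw")) {
    readBin(con, "double", n = n, size = 8, endian = "little")
  } else if (identical(fields$encoding, "text")) {
    txt <- readLines(con)
    as.numeric(strsplit(paste(txt, collapse = " "), "\\s+")[[1]])
  } else stop(sprintf("unsupported NRRD encoding '%s': %s", fields$encoding, path))
  vals <- vals[!is.na(vals)][seq_len(n)]
  unit <- if (!is.null(kv$unit)) kv$unit else "density"
  voxel_volume(array(vals, dims), origin, spacing, unit = unit,
               frame = if (!is.null(kv$frame)) kv$frame else "world",
               meta = kv_to_meta(kv))
}

write_mha <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  comment <- sprintf("unit=%s;frame=%s", volume$unit, volume$frame)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           sprintf("DimSize = %d %d %d", volume$dims[1], volume$dims[2], volume$dims[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g", volume$spacing[1],
                   volume$spacing[2], volume$spacing[3]),
           sprintf("Offset = %.17g %.17g %.17g", volume$origin[1],
                   volume$origin[2], volume$origin[3]),
           sprintf("Comment = %s", comment),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(volume$values), con, size = 8, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop(sprintf("corrupt MetaImage header: %s", path))
    p <- sub(" = .*$", "", ln)
    v <- sub("^[^=]+ = ", "", ln)
    fields[[p]] <- v
    if (identical(p, "ElementDataFile")) break
  }
  if (!identical(fields$ElementDataFile, "LOCAL"))
    stop(sprintf("only LOCAL MetaImage payloads are supported: %s", path))
  dims <- as.integer(strsplit(fields$DimSize, " ")[[1]])
  spacing <- as.numeric(strsplit(fields$ElementSpacing, " ")[[1]])
  origin <- as.numeric(strsplit(fields$Offset, " ")[[1]])
  vals <- readBin(con, "double", n = prod(dims), size = 8, endian = "little")
  unit <- "density"; frame <- "world"
  if (!is.null(fields$Comment)) {
    for (part in strsplit(fields$Comment, ";", fixed = TRUE)[[1]]) {
      kvp <- strsplit(part, "=", fixed = TRUE)[[1]]
      if (kvp[1] == "unit") unit <- kvp[2]
      if (kvp[1] == "frame") frame <- kvp[2]
    }
  }
  voxel_volume(array(vals, dims), origin, spacing, unit = unit, frame = frame)
}

#' Read and write structure sets (JSON)
#'
#' JSON layout: a list of ROIs, each with `name`, `override_density`,
#' `priority` and `slices` (each with `z` in mm and an N x 2 vertex array in
#' mm, closed on write by repeating the first vertex). Round-trips are
#' vertex-identical.
#'
#' @param structures a [structure_set()].
#' @param path output/input path (`.json`).
#' @param format only `"json"` is supported.
#' @export
write_structures <- function(structures, path, format = "json") {
  if (!identical(format, "json")) stop(sprintf("unsupported format '%s'", format))
  rois <- lapply(structures$rois, function(r) {
    list(name = r$name, override_density = r$override_density,
         priority = r$priority,
         slices = lapply(r$contours, function(ct) {
           v <- ct$vertices
           list(z = ct$z, vertices = rbind(v, v[1, , drop = FALSE]))
         }))
  })
  jsonlite::write_json(list(rois = rois), path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_structures
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop(sprintf("structure file not found: %s", path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  rois <- lapply(js$rois, function(r) {
    contours <- lapply(r$slices, function(s) {
      v <- s$vertices
      if (is.list(v)) v <- do.call(rbind, v)
      v <- matrix(as.numeric(v), ncol = 2)
      if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
      list(z = s$z, vertices = v)
    })
    roi(r$name, contours, r$override_density, r$priority)
  })
  structure_set(rois)
}

#' Read and write measurement sets (CSV)
#'
#' Point sets use columns `label, x_mm, y_mm, z_mm, dose, sd`; depth-dose sets
#' use `setup, energy_mv, depth_mm, dose`.
#'
#' @param measurements a `measurement_set`.
#' @param path CSV path.
#' @export
write_measurements <- function(measurements, path) {
  if (measurements$type == "points") {
    df <- measurements$points
    write.csv(data.frame(label = df$label, x_mm = df$x, y_mm = df$y, z_mm = df$z,
                         dose = df$dose, sd = df$sd), path, row.names = FALSE)
  } else {
    rows <- do.call(rbind, lapply(measurements$records, function(r)
      data.frame(setup = r$setup, energy_mv = r$energy_mv,
                 depth_mm = r$data$depth_mm, dose = r$data$dose)))
    write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop(sprintf("measurement file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("label" %in% names(df)) {
    measurement_points(data.frame(label = df$label, x = df$x_mm, y = df$y_mm,
                                  z = df$z_mm, dose = df$dose,
                                  sd = if ("sd" %in% names(df)) df$sd else NA_real_))
  } else if (all(c("setup", "energy_mv", "depth_mm", "dose") %in% names(df))) {
    recs <- list()
    for (key in unique(paste(df$setup, df$energy_mv))) {
      sub <- df[paste(df$setup, df$energy_mv) == key, ]
      sub <- sub[order(sub$depth_mm), ]
      recs[[length(recs) + 1L]] <- depth_dose_record(sub$setup[1], sub$energy_mv[1],
                                                     sub$depth_mm, sub$dose)
    }
    measurement_depth_doses(recs)
  } else stop(sprintf("unrecognized measurement CSV columns in %s", path))
}

#' Read a plan description (YAML)
#'
#' Plan files carry `prescription_gy`, `fractions`, optional
#' `isocenter_mm`/`normalization_point`, and a `beams` list; each beam has
#' `energy`, `gantry`, `field` (mm), optional `ssd_mm`/`sad_mm`, `wedge`
#' (`angle`, `orientation`), `weight`, or an `arc` (`start`, `stop`, `step`)
#' expanded into discrete beams.
#'
#' @param path YAML file.
#' @return a [plan_spec()].
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop(sprintf("plan file not found: %s", path))
  y <- yaml::read_yaml(path)
  beams <- list()
  for (b in y$beams) {
    template <- beam_spec(energy = b$energy %||% 6,
                          gantry_angle = b$gantry %||% 0,
                          field_size = unlist(b$field %||% c(100, 100)),
                          ssd_mm = b$ssd_mm, sad_mm = b$sad_mm %||% 1000,
                          isocenter_mm = unlist(b$isocenter_mm) %||% unlist(y$isocenter_mm),
                          wedge = b$wedge, weight = b$weight %||% 1)
    if (!is.null(b$arc)) {
      beams <- c(beams, arc_to_beams(b$arc$start, b$arc$stop,
                                     b$arc$step %||% 10, template))
    } else beams <- c(beams, list(template))
  }
  plan_spec(beams, prescription_gy = y$prescription_gy %||% 1,
            fractions = y$fractions %||% 1L,
            normalization_point = unlist(y$normalization_point))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
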