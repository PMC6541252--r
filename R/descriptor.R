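#' Section series descriptors
#'
#' A series descriptor is the interchange object tying a folder of section
#' images to their anchorings: a named, ordered collection of slices, each
#' with a filename, a serial number `nr`, the pixel dimensions of the
#' original full-resolution image, and (optionally) anchoring vectors plus a
#' status — `"verified"` for anchorings approved by a user, `"estimated"`
#' for algorithmically propagated ones.
#'
#' In this package a series is a tibble of class `section_series` with one
#' row per slice and columns `filename`, `nr`, `width`, `height`, the nine
#' anchoring components `ox, oy, oz, ux, uy, uz, vx, vy, vz` (all `NA` when
#' a slice is unanchored) and `status`. The series name is carried as the
#' `series_name` attribute. Rows are kept sorted by `nr`, which must be
#' unique.
#'
#' @param slices A data frame with at least `filename`, `nr`, `width`,
#'   `height`; anchoring columns and `status` are filled in if missing.
#' @param name Series name.
#' @return A `section_series` tibble.
#' @export
section_series <- function(slices, name = "series") {
  stopifnot(is.data.frame(slices))
  req <- c("filename", "nr", "width", "height")
  missing_cols <- setdiff(req, names(slices))
  if (length(missing_cols) > 0) {
    stop("slices is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  s <- tibble::as_tibble(slices)
  for (col in anchoring_cols()) {
    if (is.null(s[[col]])) s[[col]] <- NA_real_
  }
  if (is.null(s[["status"]])) s$status <- NA_character_
  s$status <- ifelse(is.na(s$status),
                     ifelse(is.na(s$ox), "estimated", "verified"),
                     s$status)
  if (!all(s$status %in% c("estimated", "verified"))) {
    stop("status must be 'estimated' or 'verified'", call. = FALSE)
  }
  s$nr <- as.integer(s$nr)
  if (anyNA(s$nr) || any(s$nr < 0)) {
    stop("slice serial numbers must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(s$nr)) {
    dups <- unique(s$nr[duplicated(s$nr)])
    stop("duplicate slice serial number(s): ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  if (any(s$width < 1) || any(s$height < 1)) {
    stop("slice pixel dimensions must be >= 1", call. = FALSE)
  }
  s <- s[order(s$nr), c(req, anchoring_cols(), "status")]
  structure(s, series_name = name,
            class = c("section_series", class(tibble::tibble())))
}

anchoring_cols <- function() c("ox", "oy", "oz", "ux", "uy", "uz",
                               "vx", "vy", "vz")

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf("# Section series '%s': %d slice(s), %d anchored (%d verified)\n",
              series_name(x), nrow(x), sum(!is.na(x$ox)),
              sum(x$status == "verified" & !is.na(x$ox))))
  NextMethod()
}

#' @rdname section_series
#' @param s A `section_series`.
#' @export
series_name <- function(s) attr(s, "series_name") %||% "series"

#' Extract or set one slice's anchoring
#'
#' @param s A [section_series()].
#' @param nr Slice serial number.
#' @param a An [anchoring()].
#' @param status `"verified"` or `"estimated"`.
#' @return `slice_anchoring()`: the slice's [anchoring()], or `NULL` if the
#'   slice is unanchored. `set_slice_anchoring()`: the updated series.
#' @export
slice_anchoring <- function(s, nr) {
  i <- match(as.integer(nr), s$nr)
  if (is.na(i)) stop("no slice with nr = ", nr, call. = FALSE)
  comp <- as.numeric(s[i, anchoring_cols()])
  if (anyNA(comp)) return(NULL)
  anchoring(comp[1:3], comp[4:6], comp[7:9])
}

#' @rdname slice_anchoring
#' @export
set_slice_anchoring <- function(s, nr, a, status = "verified") {
  stopifnot(inherits(a, "anchoring"))
  i <- match(as.integer(nr), s$nr)
  if (is.na(i)) stop("no slice with nr = ", nr, call. = FALSE)
  s[i, anchoring_cols()] <- as.list(c(a$o, a$u, a$v))
  s$status[i] <- match.arg(status, c("verified", "estimated"))
  s
}

# ---- XML dialect ------------------------------------------------------------

parse_anchoring_string <- function(str, slice_id) {
  str <- utils::URLdecode(str)
  parts <- strsplit(str, "&", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexec("^\\s*([a-z]{2})\\s*=\\s*(.*?)\\s*$", parts))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop("slice ", slice_id, ": malformed anchoring component '",
         parts[bad][1], "'", call. = FALSE)
  }
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 3)))
  if (!setequal(keys, anchoring_cols()) || length(keys) != 9L) {
    stop("slice ", slice_id, ": anchoring must contain the 9 keys ",
         paste(anchoring_cols(), collapse = ","), " (got ",
         paste(keys, collapse = ","), ")", call. = FALSE)
  }
  if (anyNA(vals)) {
    stop("slice ", slice_id, ": non-numeric anchoring component '",
         keys[is.na(vals)][1], "'", call. = FALSE)
  }
  vals[match(anchoring_cols(), keys)]
}

format_anchoring_string <- function(comp) {
  paste(paste0(anchoring_cols(), "=", fmt_double(comp)), collapse = "&")
}

#' Read and write series descriptors (XML dialect)
#'
#' The XML dialect stores one `<slice>` element per section under a
#' `<series>` root; anchoring vectors travel as a single URL-encoded
#' attribute string `"ox=...&oy=...&...&vz=..."`. Optional whitespace
#' around `=` is tolerated on input (published examples contain it); none
#' is emitted. On read, slices carrying an anchoring are `"verified"`
#' (stored descriptors contain only user-approved anchorings) unless a
#' `status` attribute says otherwise; slices without one are
#' `"estimated"`/unanchored.
#'
#' @param x Path to an XML file, or a literal XML string.
#' @return A [section_series()].
#' @export
read_series_xml <- function(x) {
  doc <- xml2::read_xml(x)
  if (xml2::xml_name(doc) != "series") {
    stop("descriptor root element must be <series>", call. = FALSE)
  }
  name <- xml2::xml_attr(doc, "name")
  if (is.na(name)) name <- "series"
  nodes <- xml2::xml_find_all(doc, "slice")
  rows <- lapply(nodes, parse_slice_node)
  build_series_from_rows(rows, name)
}

parse_slice_node <- function(node) {
  att <- function(k) xml2::xml_attr(node, k)
  filename <- att("filename")
  slice_id <- if (is.na(filename)) "<unnamed>" else filename
  for (k in c("filename", "nr", "width", "height")) {
    if (is.na(att(k))) {
      stop("slice ", slice_id, ": missing required attribute '", k, "'",
           call. = FALSE)
    }
  }
  num_att <- function(k) {
    v <- suppressWarnings(as.numeric(att(k)))
    if (is.na(v)) stop("slice ", slice_id, ": attribute '", k,
                       "' is not numeric", call. = FALSE)
    v
  }
  anch_str <- att("anchoring")
  status <- att("status")
  if (is.na(anch_str)) {
    comp <- rep(NA_real_, 9)
    status <- "estimated"
  } else {
    comp <- parse_anchoring_string(anch_str, slice_id)
    if (is.na(status)) status <- "verified"
  }
  c(list(filename = filename, nr = num_att("nr"),
         width = num_att("width"), height = num_att("height")),
    stats::setNames(as.list(comp), anchoring_cols()),
    list(status = status))
}

build_series_from_rows <- function(rows, name) {
  if (length(rows) == 0) {
    empty <- tibble::tibble(filename = character(), nr = integer(),
                            width = numeric(), height = numeric())
    return(section_series(empty, name = name))
  }
  section_series(dplyr::bind_rows(lapply(rows, tibble::as_tibble)),
                 name = name)
}

#' @rdname read_series_xml
#' @param s A [section_series()].
#' @param path Optional output file; when `NULL` the XML text is returned.
#' @param include_estimates Write anchorings for `"estimated"` slices too
#'   (flagged with a `status="estimated"` attribute, an extension of the
#'   interchange format). By default only verified anchorings are stored,
#'   matching the convention that descriptors hold user-approved anchorings
#'   only.
#' @export
write_series_xml <- function(s, path = NULL, include_estimates = FALSE) {
  stopifnot(inherits(s, "section_series"))
  doc <- xml2::xml_new_root("series", name = series_name(s))
  for (i in seq_len(nrow(s))) {
    attrs <- list(filename = s$filename[i],
                  nr = as.character(s$nr[i]),
                  width = fmt_double(s$width[i]),
                  height = fmt_double(s$height[i]))
    comp <- as.numeric(s[i, anchoring_cols()])
    anchored <- !anyNA(comp)
    if (anchored && (s$status[i] == "verified" || include_estimates)) {
      attrs$anchoring <- format_anchoring_string(comp)
      if (s$status[i] == "estimated") attrs$status <- "estimated"
    }
    node <- xml2::xml_add_child(doc, "slice")
    do.call(xml2::xml_set_attrs, list(node, unlist(attrs)))
  }
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(path))
  }
  txt
}

# ---- JSON dialect -----------------------------------------------------------

#' Read and write series descriptors (JSON dialect)
#'
#' The JSON dialect is an object with `"name"` and `"slices"`; each slice
#' carries `"anchoring"` as a flat array of exactly nine numbers in
#' `ox, oy, oz, ux, uy, uz, vx, vy, vz` order (absent when unanchored).
#' An optional `"status"` field is honoured as an extension; slices with an
#' anchoring but no status read as `"verified"`. Anchoring numbers are
#' written with shortest round-trip precision, so cross-format conversion
#' is lossless digit-for-digit.
#'
#' @param x Path to a JSON file, or a literal JSON string.
#' @return A [section_series()].
#' @export
read_series_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (!is.list(obj) || is.null(obj$name) || is.null(obj$slices)) {
    stop("JSON descriptor must be an object with 'name' and 'slices'",
         call. = FALSE)
  }
  rows <- lapply(obj$slices, function(sl) {
    slice_id <- sl$filename %||% "<unnamed>"
    for (k in c("filename", "nr", "width", "height")) {
      if (is.null(sl[[k]])) stop("slice ", slice_id,
                                 ": missing field '", k, "'", call. = FALSE)
    }
    if (is.null(sl$anchoring)) {
      comp <- rep(NA_real_, 9)
      status <- sl$status %||% "estimated"
    } else {
      comp <- as.numeric(unlist(sl$anchoring))
      if (length(comp) != 9L || anyNA(comp)) {
        stop("slice ", slice_id, ": 'anchoring' must be an array of ",
             "exactly 9 numbers (got ", length(comp), ")", call. = FALSE)
      }
      status <- sl$status %||% "verified"
    }
    c(list(filename = sl$filename, nr = as.numeric(sl$nr),
           width = as.numeric(sl$width), height = as.numeric(sl$height)),
      stats::setNames(as.list(comp), anchoring_cols()),
      list(status = status))
  })
  build_series_from_rows(rows, obj$name)
}

json_str <- function(x) as.character(jsonlite::toJSON(x, auto_unbox = TRUE))

#' @rdname read_series_json
#' @inheritParams write_series_xml
#' @export
write_series_json <- function(s, path = NULL, include_estimates = FALSE) {
  stopifnot(inherits(s, "section_series"))
  slices <- vapply(seq_len(nrow(s)), function(i) {
    fields <- c(
      paste0("\"filename\":", json_str(s$filename[i])),
      paste0("\"nr\":", s$nr[i]),
      paste0("\"width\":", fmt_double(s$width[i])),
      paste0("\"height\":", fmt_double(s$height[i])))
    comp <- as.numeric(s[i, anchoring_cols()])
    anchored <- !anyNA(comp)
    if (anchored && (s$status[i] == "verified" || include_estimates)) {
      fields <- c(fields, paste0("\"anchoring\":[",
                                 paste(fmt_double(comp), collapse = ","), "]"))
      if (s$status[i] == "estimated") {
        fields <- c(fields, "\"status\":\"estimated\"")
      }
    }
    paste0("{", paste(fields, collapse = ","), "}")
  }, character(1))
  txt <- paste0("{\"name\":", json_str(series_name(s)),
                ",\"slices\":[", paste(slices, collapse = ","), "]}")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(path))
  }
  txt
}

#' Read or write a descriptor, dispatching on file extension
#'
#' @param path File path ending in `.xml` or `.json`.
#' @inheritParams write_series_xml
#' @return [read_series()]: a [section_series()].
#' @export
read_series <- function(path) {
  switch(tolower(tools::file_ext(path)),
         xml = read_series_xml(path),
         json = read_series_json(path),
         stop("cannot infer descriptor format from extension of '", path,
              "' (expected .xml or .json)", call. = FALSE))
}

#' @rdname read_series
#' @export
write_series <- function(s, path, include_estimates = FALSE) {
  switch(tolower(tools::file_ext(path)),
         xml = write_series_xml(s, path, include_estimates),
         json = write_series_json(s, path, include_estimates),
         stop("cannot infer descriptor format from extension of '", path,
              "' (expected .xml or .json)", call. = FALSE))
}

# ---- FileBuilder equivalent -------------------------------------------------

#' Extract a serial number from a section image filename
#'
#' Serial ordering of a section series is conventionally encoded in the
#' filename, e.g. `Sample_ID_s001.tif`. The rule: the last run of decimal
#' digits in the basename (extension excluded) is the serial number.
#'
#' @param filename Character vector of filenames (paths allowed).
#' @return Integer vector; `NA` where no digits occur.
#' @examples
#' parse_serial_number(c("Sample_ID_s001.tif", "case12_s034.png", "image.png"))
#' @export
parse_serial_number <- function(filename) {
  base <- sub("\\.[^.]*$", "", basename(filename))
  m <- regmatches(base, gregexpr("[0-9]+", base))
  vapply(m, function(runs) {
    if (length(runs) == 0) NA_integer_ else as.integer(runs[length(runs)])
  }, integer(1))
}

#' Build a series descriptor from an image listing
#'
#' The headless equivalent of the FileBuilder helper: given the images of a
#' section series with their pixel dimensions, infers serial numbers from
#' the filenames and assembles an (unanchored) descriptor. Store the
#' dimensions the anchorings will refer to — typically the original
#' full-resolution dimensions, even when downscaled copies are what gets
#' viewed.
#'
#' @param listing A data frame with columns `filename`, `width`, `height`,
#'   or a character vector of PNG file paths (dimensions are then read from
#'   the files).
#' @param name Series name.
#' @param strict If `TRUE`, filenames without a parsable serial number are
#'   an error; otherwise they are numbered sequentially after the largest
#'   parsed number, in listing order, with a warning.
#' @return A [section_series()] with all slices unanchored.
#' @export
build_descriptor <- function(listing, name = "series", strict = FALSE) {
  if (is.character(listing)) {
    listing <- scan_image_listing(listing)
  }
  stopifnot(is.data.frame(listing),
            all(c("filename", "width", "height") %in% names(listing)))
  if (nrow(listing) == 0) stop("no images in listing", call. = FALSE)
  nr <- parse_serial_number(listing$filename)
  if (anyNA(nr)) {
    missing <- listing$filename[is.na(nr)]
    if (strict) {
      stop("no serial number in filename(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    warning("no serial number in filename(s): ",
            paste(missing, collapse = ", "),
            "; assigning sequential numbers", call. = FALSE)
    start <- if (all(is.na(nr))) 0L else max(nr, na.rm = TRUE)
    nr[is.na(nr)] <- start + seq_len(sum(is.na(nr)))
  }
  if (anyDuplicated(nr)) {
    dups <- unique(nr[duplicated(nr)])
    offenders <- listing$filename[nr %in% dups]
    stop("duplicate serial number(s) ", paste(dups, collapse = ", "),
         " from: ", paste(offenders, collapse = ", "), call. = FALSE)
  }
  section_series(tibble::tibble(filename = basename(listing$filename),
                                nr = nr,
                                width = listing$width,
                                height = listing$height),
                 name = name)
}

# PNG-only folder scan; dimensions come from the decoded image
scan_image_listing <- function(paths) {
  dims <- lapply(paths, function(p) {
    if (tolower(tools::file_ext(p)) != "png") {
      stop("can only read dimensions from PNG files, got '", p,
           "'; pass an explicit (filename, width, height) listing instead",
           call. = FALSE)
    }
    d <- dim(png::readPNG(p))
    c(width = d[2], height = d[1])
  })
  tibble::tibble(filename = paths,
                 width = vapply(dims, `[[`, numeric(1), "width"),
                 height = vapply(dims, `[[`, numeric(1), "height"))
}
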