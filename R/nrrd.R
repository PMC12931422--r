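# Minimal NRRD (ascii-encoded) raster I/O for the phantom container.
# Only the subset needed here is supported: 3-D integer/float arrays,
# encoding "ascii", "space directions" diagonal (axis-aligned spacing),
# first axis fastest (x) as in the NRRD spec.

write_nrrd <- function(array3d, path, spacing, origin,
                       type = "int") {
  stopifnot(length(dim(array3d)) == 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# marrowdose phantom raster",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(array3d)[1], dim(array3d)[2], dim(array3d)[3]),
    "encoding: ascii",
    "space: left-posterior-superior",
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            spacing[1], spacing[2], spacing[3]),
    sprintf("space origin: (%.9g,%.9g,%.9g)", origin[1], origin[2], origin[3]),
    ""
  )
  writeLines(hdr, con)
  # x fastest: R arrays are already first-index-fastest
  vals <- as.vector(array3d)
  txt <- if (type %in% c("int", "short", "uchar")) {
    format(as.integer(vals), scientific = FALSE, trim = TRUE)
  } else {
    format(vals, digits = 12, trim = TRUE)
  }
  # wrap lines to keep files diffable
  writeLines(vapply(split(txt, ceiling(seq_along(txt) / 16)),
                    paste, "", collapse = " "), con)
  invisible(path)
}

read_nrrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD: no blank line after header", call. = FALSE)
  hdr <- lines[seq_len(blank - 1)]
  body <- lines[seq(blank + 1, length(lines))]
  get_field <- function(key) {
    m <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^", key, ": "), "", m[1])
  }
  enc <- get_field("encoding")
  if (!identical(enc, "ascii")) {
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  }
  sizes <- as.integer(strsplit(get_field("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-D NRRD supported", call. = FALSE)
  parse_vecs <- function(s) {
    m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    lapply(m, function(v) as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
  }
  dirs <- parse_vecs(get_field("space directions"))
  spacing <- vapply(seq_len(3), function(a) dirs[[a]][a], 0)
  if (any(spacing <= 0)) stop("NRRD spacing must be positive", call. = FALSE)
  off_diag <- vapply(seq_len(3), function(a) sum(abs(dirs[[a]][-a])), 0)
  if (any(off_diag > 0)) stop("only axis-aligned NRRD supported", call. = FALSE)
  org <- get_field("space origin")
  origin <- if (is.null(org)) c(0, 0, 0) else {
    as.numeric(strsplit(gsub("[()]", "", org), ",")[[1]])
  }
  vals <- as.numeric(scan(text = paste(body, collapse = " "),
                          what = double(), quiet = TRUE))
  if (length(vals) != prod(sizes)) {
    stop("NRRD data length ", length(vals), " does not match sizes ",
         prod(sizes), call. = FALSE)
  }
  list(
    data = array(vals, dim = sizes),
    spacing = spacing,
    origin = origin,
    type = get_field("type")
  )
}
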