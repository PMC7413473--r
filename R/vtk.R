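# VTK legacy ASCII I/O for structured fields. The on-disk interface is a
# DATASET RECTILINEAR_GRID with POINT_DATA arrays: VECTORS "velocity",
# SCALARS "viscosity" (optional) and SCALARS "mask". 2D fields are written
# with a singleton z dimension.

#' Write a structured field as VTK legacy ASCII
#'
#' @param field A [structured_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_field()]
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "structured_field"))
  nx <- length(field$x); ny <- length(field$y)
  num <- function(v) format(v, digits = 15, scientific = TRUE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     "cathflow structured field",
     "ASCII",
     "DATASET RECTILINEAR_GRID",
     sprintf("DIMENSIONS %d %d 1", nx, ny),
     sprintf("X_COORDINATES %d double", nx),
     paste(num(field$x), collapse = " "),
     sprintf("Y_COORDINATES %d double", ny),
     paste(num(field$y), collapse = " "),
     "Z_COORDINATES 1 double",
     "0")
  # point data in VTK order: x fastest, then y
  wl(sprintf("POINT_DATA %d", nx * ny),
     "VECTORS velocity double")
  u <- as.vector(field$u); v <- as.vector(field$v)
  wl(paste(num(u), num(v), "0"))
  if (!is.null(field$viscosity)) {
    wl("SCALARS viscosity double 1", "LOOKUP_TABLE default")
    wl(num(as.vector(field$viscosity)))
  }
  if (!is.null(attr(field, "shear_rate"))) {
    wl("SCALARS shear_rate double 1", "LOOKUP_TABLE default")
    wl(num(as.vector(attr(field, "shear_rate"))))
  }
  wl("SCALARS mask int 1", "LOOKUP_TABLE default")
  wl(as.character(as.integer(as.vector(field$mask))))
  invisible(path)
}

#' Read a structured field from VTK legacy ASCII
#'
#' Parses a `DATASET RECTILINEAR_GRID` legacy file with a point-data
#' vector array named `velocity` and optional scalars `viscosity` and
#' `mask`. Malformed input raises an error naming the offending line.
#' `read_field(write_field(f))` reproduces `f` to text-formatting
#' precision (15 significant digits).
#'
#' @param path Path to a VTK legacy ASCII file.
#' @return A [structured_field()].
#' @export
read_field <- function(path) {
  stop_unless(file.exists(path), "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  bad <- function(i, why) {
    stop(sprintf("VTK parse error at line %d ('%s'): %s",
                 i, if (i <= length(lines)) lines[i] else "<eof>", why),
         call. = FALSE)
  }
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    bad(1L, "missing '# vtk DataFile' header")
  if (toupper(trimws(lines[3])) != "ASCII") bad(3L, "expected ASCII format")
  dsl <- grep("^DATASET", lines)[1]
  if (is.na(dsl)) bad(4L, "missing DATASET line")
  if (!grepl("RECTILINEAR_GRID", lines[dsl]))
    bad(dsl, "only DATASET RECTILINEAR_GRID is supported")

  # token stream after splitting lines; keep a map back to line numbers
  toks <- list(); tokline <- integer(0)
  for (i in seq_along(lines)) {
    tt <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    tt <- tt[nzchar(tt)]
    if (length(tt)) {
      toks[[length(toks) + 1]] <- tt
      tokline <- c(tokline, rep(i, length(tt)))
    }
  }
  toks <- unlist(toks)
  pos <- 1L
  need <- function(n, what) {
    if (pos + n - 1L > length(toks))
      bad(length(lines), sprintf("unexpected end of file reading %s", what))
    out <- toks[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  need_num <- function(n, what) {
    out <- suppressWarnings(as.numeric(need(n, what)))
    if (anyNA(out)) bad(tokline[pos - 1L], sprintf("non-numeric %s", what))
    out
  }
  seek_tok <- function(key) {
    while (pos <= length(toks) && toupper(toks[pos]) != key) pos <<- pos + 1L
    if (pos > length(toks)) bad(length(lines), sprintf("missing %s", key))
    pos <<- pos + 1L
  }

  seek_tok("DIMENSIONS")
  dims <- need_num(3, "DIMENSIONS")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  if (nz != 1) bad(tokline[pos - 1L], "only singleton z dimension supported")
  seek_tok("X_COORDINATES")
  nxc <- need_num(1, "X_COORDINATES count"); need(1, "type")
  if (nxc != nx) bad(tokline[pos - 1L], "X_COORDINATES count != DIMENSIONS")
  xs <- need_num(nx, "x coordinates")
  seek_tok("Y_COORDINATES")
  nyc <- need_num(1, "Y_COORDINATES count"); need(1, "type")
  if (nyc != ny) bad(tokline[pos - 1L], "Y_COORDINATES count != DIMENSIONS")
  ys <- need_num(ny, "y coordinates")
  seek_tok("Z_COORDINATES")
  need_num(1, "count"); need(1, "type"); need_num(1, "z coordinate")

  seek_tok("POINT_DATA")
  npts <- need_num(1, "POINT_DATA count")
  if (npts != nx * ny)
    bad(tokline[pos - 1L], "POINT_DATA count != nx*ny")

  u <- v <- visc <- msk <- shr <- NULL
  while (pos <= length(toks)) {
    kw <- toupper(toks[pos]); pos <- pos + 1L
    if (kw == "VECTORS") {
      nm <- need(1, "vector name"); need(1, "vector type")
      dat <- need_num(3 * npts, sprintf("vector '%s' data", nm))
      if (nm == "velocity") {
        u <- matrix(dat[seq(1, by = 3, length.out = npts)], nx, ny)
        v <- matrix(dat[seq(2, by = 3, length.out = npts)], nx, ny)
      }
    } else if (kw == "SCALARS") {
      nm <- need(1, "scalar name"); need(1, "scalar type")
      # optional numComp token then LOOKUP_TABLE <name>
      if (pos <= length(toks) &&
          !toupper(toks[pos]) %in% "LOOKUP_TABLE") pos <- pos + 1L
      seek_tok("LOOKUP_TABLE")  # consumes the keyword
      pos <- pos + 0L
      need(1, "lookup table name")
      dat <- need_num(npts, sprintf("scalar '%s' data", nm))
      if (nm == "viscosity") visc <- matrix(dat, nx, ny)
      if (nm == "shear_rate") shr <- matrix(dat, nx, ny)
      if (nm == "mask") msk <- matrix(dat != 0, nx, ny)
    } else if (kw %in% c("CELL_DATA", "FIELD")) {
      break
    }
  }
  if (is.null(u))
    stop("VTK file has no POINT_DATA vector array named 'velocity': ", path,
         call. = FALSE)
  out <- structured_field(xs, ys, u, v, viscosity = visc, mask = msk)
  if (!is.null(shr)) attr(out, "shear_rate") <- shr
  out
}
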