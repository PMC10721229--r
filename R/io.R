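# Readers and writers for the plain-text formats the pipeline touches.
# All coordinates surface in nm: GRO is native nm, PDB and XYZ are Angstrom
# on disk and divided by 10 on read. Atom order is preserved; raw reads never
# wrap coordinates into the box (profile code applies minimum image itself).

#' Read a coordinate file into a trajectory
#'
#' Dispatches on file extension (`.gro`, `.pdb`, `.xyz`) unless `format` is
#' forced. Multi-frame files (concatenated GRO blocks, PDB MODELs, stacked
#' XYZ blocks) yield multi-frame trajectories.
#'
#' @param path file path.
#' @param format `"gro"`, `"pdb"` or `"xyz"`; default auto-detects from the
#'   extension.
#' @param topology optional [topology()] to attach. When missing, a minimal
#'   one (unit masses, species `"protein"`) is built from the file's atom
#'   records.
#' @return A [trajectory()].
#' @export
read_coordinates <- function(path, format = c("auto", "gro", "pdb", "xyz"),
                             topology = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("gro", "pdb", "xyz")) {
      stop("cannot auto-detect format from extension '", ext,
           "'; pass format= explicitly")
    }
    format <- ext
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         gro = read_gro(path, topology = topology),
         pdb = read_pdb(path, topology = topology),
         xyz = read_xyz(path, topology = topology))
}

default_topology <- function(n, name = "X", resid = 1L, resname = "RES") {
  topology(mass = rep(1, n), species = "protein", name = name,
           resid = resid, resname = resname)
}

check_topology_count <- function(top, n, path) {
  if (!is.null(top) && nrow(top) != n) {
    stop("topology has ", nrow(top), " atoms but ", path, " has ", n)
  }
}

#' Read a GROMACS GRO file (single or concatenated multi-frame)
#'
#' @inheritParams read_coordinates
#' @return A [trajectory()]; coordinates in nm as stored.
#' @export
read_gro <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  names_first <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || n < 1L) {
      stop("malformed GRO atom count at line ", i + 1L, " of ", path)
    }
    if (i + 1L + n + 1L > length(lines)) {
      stop("truncated GRO frame starting at line ", i, " of ", path)
    }
    rec <- lines[(i + 2L):(i + 1L + n)]
    xs <- suppressWarnings(as.numeric(substr(rec, 21, 28)))
    ys <- suppressWarnings(as.numeric(substr(rec, 29, 36)))
    zs <- suppressWarnings(as.numeric(substr(rec, 37, 44)))
    bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
    if (length(bad)) {
      stop("malformed GRO atom record at line ", i + 1L + bad[1], " of ", path)
    }
    box <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 1L + n + 1L]),
                                                "\\s+")[[1]]))
    if (length(box) < 3L || any(is.na(box[1:3]))) {
      stop("malformed GRO box line at line ", i + 1L + n + 1L, " of ", path)
    }
    tm <- length(frames)
    mt <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(mt)) tm <- as.numeric(sub("t=\\s*", "", mt))
    if (is.null(names_first)) {
      names_first <- list(resid = as.integer(substr(rec, 1, 5)),
                          resname = trimws(substr(rec, 6, 10)),
                          name = trimws(substr(rec, 11, 15)))
    }
    frames[[length(frames) + 1L]] <-
      list(coords = cbind(xs, ys, zs), box = box[1:3], time = tm)
    i <- i + n + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("no frames found in ", path)
  n <- nrow(frames[[1]]$coords)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$coords) != n) {
      stop("mismatched atom counts across frames in ", path,
           " (frame ", k, ")")
    }
  }
  if (is.null(topology)) {
    topology <- default_topology(n, name = names_first$name,
                                 resid = names_first$resid,
                                 resname = names_first$resname)
  }
  check_topology_count(topology, n, path)
  trajectory(topology, frames)
}

#' Write a trajectory as (multi-frame) GRO
#'
#' Coordinates are written in nm at the format's native 3-decimal precision,
#' 1-based atom numbering.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @export
write_gro <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    writeLines(sprintf("mabsolkit frame t= %.4f", fr$time), con)
    writeLines(sprintf("%5d", nrow(top)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       top$resid %% 100000L, substr(top$resname, 1, 5),
                       substr(top$name, 1, 5), top$id %% 100000L,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]),
               con)
  }
  invisible(path)
}

#' Read a PDB file (coordinate subset of the standard)
#'
#' Parses ATOM/HETATM records and MODEL blocks; coordinates are converted
#' from Angstrom to nm. CRYST1, when present, provides the box; otherwise a
#' generous bounding box is used.
#'
#' @inheritParams read_coordinates
#' @return A [trajectory()].
#' @export
read_pdb <- function(path, topology = NULL) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_starts <- grep("^MODEL", lines)
  box <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33))) / 10
  }
  parse_block <- function(idx) {
    rec <- lines[idx]
    xs <- suppressWarnings(as.numeric(substr(rec, 31, 38)))
    ys <- suppressWarnings(as.numeric(substr(rec, 39, 46)))
    zs <- suppressWarnings(as.numeric(substr(rec, 47, 54)))
    bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
    if (length(bad)) {
      stop("malformed PDB coordinate record at line ", idx[bad[1]],
           " of ", path)
    }
    cbind(xs, ys, zs) / 10   # Angstrom -> nm
  }
  if (length(model_starts) > 1L) {
    ends <- c(model_starts[-1] - 1L, length(lines))
    blocks <- lapply(seq_along(model_starts), function(k) {
      idx <- which(is_atom & seq_along(lines) >= model_starts[k] &
                     seq_along(lines) <= ends[k])
      parse_block(idx)
    })
  } else {
    blocks <- list(parse_block(which(is_atom)))
  }
  n <- nrow(blocks[[1]])
  for (k in seq_along(blocks)) {
    if (nrow(blocks[[k]]) != n) {
      stop("mismatched atom counts across MODELs in ", path)
    }
  }
  first <- lines[which(is_atom)][1:n]
  if (is.null(topology)) {
    el <- trimws(substr(first, 77, 78))
    el[!nzchar(el)] <- NA_character_
    topology <- topology(mass = rep(1, n), species = "protein",
                         name = trimws(substr(first, 13, 16)),
                         element = el,
                         resid = suppressWarnings(as.integer(substr(first, 23, 26))),
                         resname = trimws(substr(first, 18, 20)))
  }
  check_topology_count(topology, n, path)
  if (is.null(box)) {
    span <- apply(blocks[[1]], 2, function(v) diff(range(v)))
    box <- pmax(span * 2, 1)
  }
  frames <- lapply(seq_along(blocks), function(k) {
    list(coords = blocks[[k]], box = box, time = k - 1)
  })
  trajectory(topology, frames)
}

#' Read an XYZ file (single or stacked multi-frame)
#'
#' XYZ stores Angstrom by convention; coordinates are converted to nm. The
#' comment line may carry `box= lx ly lz` (nm); otherwise a bounding box is
#' used.
#'
#' @inheritParams read_coordinates
#' @return A [trajectory()].
#' @export
read_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  el_first <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ count at line ", i, " of ", path)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    comment <- lines[i + 1L]
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    bad <- which(vapply(rec, length, 1L) < 4L)
    if (length(bad)) stop("malformed XYZ record at line ", i + 1L + bad[1])
    co <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3))) / 10
    if (any(!is.finite(co))) stop("non-numeric XYZ coordinates near line ", i + 2L)
    if (is.null(el_first)) el_first <- vapply(rec, `[[`, "", 1L)
    box <- NULL
    mb <- regmatches(comment,
                     regexpr("box=\\s*[-0-9.eE+]+\\s+[-0-9.eE+]+\\s+[-0-9.eE+]+",
                             comment))
    if (length(mb)) box <- as.numeric(strsplit(sub("box=\\s*", "", mb),
                                               "\\s+")[[1]])
    tm <- length(frames)
    frames[[length(frames) + 1L]] <- list(coords = co, box = box, time = tm)
    i <- i + n + 2L
  }
  if (!length(frames)) stop("no frames found in ", path)
  n <- nrow(frames[[1]]$coords)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$coords) != n) {
      stop("mismatched atom counts across frames in ", path)
    }
    if (is.null(frames[[k]]$box)) {
      span <- apply(frames[[k]]$coords, 2, function(v) diff(range(v)))
      frames[[k]]$box <- pmax(span * 2, 1)
    }
  }
  if (is.null(topology)) {
    topology <- topology(mass = rep(1, n), species = "protein",
                         name = el_first, element = el_first)
  }
  check_topology_count(topology, n, path)
  trajectory(topology, frames)
}

#' Write a trajectory as stacked XYZ (Angstrom on disk)
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  el <- traj$topology$element
  el[is.na(el)] <- "X"
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf("t= %.4f box= %.6f %.6f %.6f",
                       fr$time, fr$box[1], fr$box[2], fr$box[3]), con)
    writeLines(sprintf("%-4s %14.8f %14.8f %14.8f", el,
                       fr$coords[, 1] * 10, fr$coords[, 2] * 10,
                       fr$coords[, 3] * 10), con)
  }
  invisible(path)
}

#' Read an XVG table (GROMACS dialect)
#'
#' Lines beginning with `#` or `@` are retained as metadata; the rest must
#' form a rectangular numeric table.
#'
#' @param path file path.
#' @return A `data.frame` with attributes `metadata` (character vector of
#'   header lines) and `source` (the path).
#' @export
read_xvg <- function(path) {
  lines <- readLines(path)
  meta <- grepl("^\\s*[#@]", lines)
  blank <- !nzchar(trimws(lines))
  data_lines <- lines[!meta & !blank]
  if (!length(data_lines)) stop("no data rows in ", path)
  toks <- strsplit(trimws(data_lines), "\\s+")
  nc <- vapply(toks, length, 1L)
  if (length(unique(nc)) != 1L) {
    bad <- which(!meta & !blank)[which(nc != nc[1])[1]]
    stop("ragged XVG row at line ", bad, " of ", path)
  }
  vals <- suppressWarnings(vapply(toks, function(r) as.numeric(r),
                                  numeric(nc[1])))
  vals <- if (nc[1] == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (any(!is.finite(vals))) stop("non-numeric value in XVG table ", path)
  df <- as.data.frame(vals)
  names(df) <- paste0("V", seq_len(ncol(df)))
  attr(df, "metadata") <- lines[meta]
  attr(df, "source") <- path
  df
}

#' Write a two-or-more-column table as XVG
#'
#' @param x data.frame or matrix of numeric columns.
#' @param path output path.
#' @param title,xlabel,ylabel header strings written as `@`-metadata.
#' @param comments extra `#` comment lines (e.g. provenance).
#' @export
write_xvg <- function(x, path, title = "", xlabel = "", ylabel = "",
                      comments = character()) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  writeLines(sprintf('@    title "%s"', title), con)
  writeLines(sprintf('@    xaxis  label "%s"', xlabel), con)
  writeLines(sprintf('@    yaxis  label "%s"', ylabel), con)
  apply(x, 1, function(r) writeLines(paste(sprintf("%.8g", r), collapse = "  "),
                                     con))
  invisible(path)
}

#' Write a topology as CSV
#' @param top a [topology()].
#' @param path output path.
#' @export
write_topology_csv <- function(top, path) {
  utils::write.csv(as.data.frame(top), path, row.names = FALSE)
  invisible(path)
}

#' Read a topology from CSV written by [write_topology_csv()]
#' @param path file path.
#' @return A [topology()].
#' @export
read_topology_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  topology(mass = df$mass, species = df$species, charge = df$charge,
           resid = df$resid, resname = df$resname, name = df$name,
           element = df$element, hydrophobic = df$hydrophobic,
           marker = df$marker)
}
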