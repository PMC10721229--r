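# Shared coordinate data model: Topology + Trajectory.
#
# Unit convention (global, enforced at the I/O boundary): distances nm,
# energies kJ/mol, charges in units of e, times ps, masses g/mol.

#' Construct an atom topology table
#'
#' The topology carries the static per-atom attributes every analysis needs:
#' masses for mass-weighted metrics, species tags and flags for selections,
#' charges for double-layer profiles, and optional axis-marker labels used by
#' [axis_dimensions()].
#'
#' @param mass numeric vector of atomic masses (g/mol), all > 0.
#' @param species character vector: one of `"protein"`, `"cation"`,
#'   `"anion"`, `"water"`.
#' @param charge numeric vector of partial/formal charges (e). Default 0.
#' @param resid integer residue ids. Default 1.
#' @param resname character residue names. Default `"RES"`.
#' @param name per-atom names. Default `"X"`.
#' @param element optional element symbols (used by [sasa()] radius lookup).
#' @param hydrophobic logical flag per atom. Default `FALSE`.
#' @param marker optional axis-marker label per atom: `NA`, `"LA"`, `"W"` or
#'   `"H"`. If any marker is set, each used label must occur exactly twice.
#' @return A `data.frame` of class `"topology"` with one row per atom and an
#'   `id` column (1-based, unique).
#' @export
topology <- function(mass, species = "protein", charge = 0, resid = 1L,
                     resname = "RES", name = "X", element = NA_character_,
                     hydrophobic = FALSE, marker = NA_character_) {
  n <- length(mass)
  if (n < 1L) stop("topology needs at least one atom")
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("all atomic masses must be finite and > 0")
  }
  species <- rep_len(as.character(species), n)
  bad <- setdiff(unique(species), c("protein", "cation", "anion", "water"))
  if (length(bad)) {
    stop("unknown species tag(s): ", paste(bad, collapse = ", "))
  }
  marker <- rep_len(as.character(marker), n)
  used <- marker[!is.na(marker)]
  if (length(used)) {
    if (!all(used %in% c("LA", "W", "H"))) {
      stop("marker labels must be 'LA', 'W' or 'H'")
    }
    cnt <- table(used)
    if (any(cnt != 2L)) {
      stop("each axis marker label must occur exactly twice, got: ",
           paste(names(cnt), cnt, sep = "=", collapse = ", "))
    }
  }
  top <- data.frame(
    id = seq_len(n),
    name = rep_len(as.character(name), n),
    element = rep_len(as.character(element), n),
    mass = as.numeric(mass),
    charge = rep_len(as.numeric(charge), n),
    species = species,
    resid = rep_len(as.integer(resid), n),
    resname = rep_len(as.character(resname), n),
    hydrophobic = rep_len(as.logical(hydrophobic), n),
    marker = marker,
    stringsAsFactors = FALSE
  )
  class(top) <- c("topology", "data.frame")
  top
}

#' Construct a trajectory
#'
#' @param topology a [topology()] table.
#' @param frames list of frames; each frame is a list with `coords`
#'   (n_atoms x 3 numeric matrix, nm), `box` (3 orthorhombic edge lengths,
#'   nm) and `time` (ps).
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(topology, frames) {
  if (!inherits(topology, "topology")) stop("'topology' must be a topology object")
  if (!length(frames)) stop("trajectory needs at least one frame")
  n <- nrow(topology)
  frames <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    co <- as.matrix(fr$coords)
    if (!is.numeric(co) || ncol(co) != 3L) {
      stop("frame ", i, ": coords must be an n x 3 numeric matrix")
    }
    if (nrow(co) != n) {
      stop("frame ", i, ": has ", nrow(co), " atoms, topology has ", n)
    }
    box <- as.numeric(fr$box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      stop("frame ", i, ": box must be 3 positive edge lengths (nm)")
    }
    tm <- if (is.null(fr$time)) (i - 1) * 1.0 else as.numeric(fr$time)
    dimnames(co) <- list(NULL, c("x", "y", "z"))
    list(coords = co, box = box, time = tm)
  })
  structure(list(topology = topology, frames = frames), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$topology)
  nf <- length(x$frames)
  sp <- table(x$topology$species)
  cat("Trajectory: ", nf, " frame(s), ", n, " atoms (",
      paste(names(sp), sp, sep = ": ", collapse = ", "), ")\n", sep = "")
  b <- x$frames[[1]]$box
  cat(sprintf("  box (frame 1): %.3f x %.3f x %.3f nm\n", b[1], b[2], b[3]))
  tms <- vapply(x$frames, `[[`, numeric(1), "time")
  cat(sprintf("  time: %.1f .. %.1f ps\n", min(tms), max(tms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x a trajectory
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "trajectory"))
  length(x$frames)
}

#' @export
`[.trajectory` <- function(x, i) {
  trajectory(x$topology, x$frames[i])
}

#' Select atom ids from a topology by predicate
#'
#' The predicate is an unquoted expression over topology columns only
#' (e.g. `species == "protein" & hydrophobic`). Evaluation is restricted to
#' the topology's fields; referencing anything else is an error, so typos in
#' field names fail loudly instead of capturing variables from the caller.
#'
#' @param topology a [topology()] table (or the `topology` element of a
#'   trajectory).
#' @param expr predicate expression.
#' @return Sorted integer vector of matching atom ids (possibly empty, with
#'   a warning).
#' @export
#' @examples
#' top <- topology(mass = c(12, 23, 35.5), species = c("protein", "cation", "anion"))
#' select_atoms(top, species == "protein")
select_atoms <- function(topology, expr) {
  if (inherits(topology, "trajectory")) topology <- topology$topology
  stopifnot(inherits(topology, "topology"))
  e <- substitute(expr)
  env <- as.environment(as.list(topology))
  parent.env(env) <- baseenv()
  keep <- tryCatch(eval(e, env), error = function(err) {
    stop("selection predicate failed (unknown field?): ",
         conditionMessage(err), call. = FALSE)
  })
  if (!is.logical(keep)) stop("selection predicate must evaluate to logical")
  keep[is.na(keep)] <- FALSE
  ids <- sort(topology$id[keep])
  if (!length(ids)) warning("selection matched no atoms")
  ids
}

# mass-weighted centre of mass of rows `ids` of a coordinate matrix
com <- function(coords, mass, ids = seq_len(nrow(coords))) {
  m <- mass[ids]
  colSums(coords[ids, , drop = FALSE] * m) / sum(m)
}

# minimum-image displacement for an orthorhombic box
min_image <- function(d, box) {
  d - round(sweep(d, 2, box, "/")) %*% diag(box)
}

assert_orthorhombic <- function(box) {
  if (length(box) != 3L) {
    stop("only orthorhombic boxes (3 edge lengths) are supported; ",
         "triclinic boxes are rejected")
  }
  invisible(box)
}
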