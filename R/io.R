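## Trajectory file I/O.  Multi-model PDB goes through bio3d; XYZ is a
## trivial line format handled directly.  Coordinates are nm in memory and
## Angstrom on disk for both formats, as the formats require.

NM_PER_ANGSTROM <- 0.1

## stable subunit -> chain letter mapping (and back)
subunit_chain_map <- function(subunits) {
  u <- unique(subunits)
  if (length(u) > 26L) stop("more than 26 subunits cannot map to PDB chains")
  stats::setNames(LETTERS[seq_along(u)], u)
}

#' Write a trajectory ensemble to disk
#'
#' Writes each trajectory as one multi-model PDB (\code{MODEL}/\code{ENDMDL}
#' records, via bio3d) or one multi-frame XYZ file.  Subunit labels are
#' encoded as PDB chain identifiers; the mapping used is returned so readers
#' can restore the labels.  XYZ files carry only site names, so reading them
#' back requires an explicit topology.
#'
#' @param ensemble a \code{\link{traj_ensemble}}.
#' @param paths character vector of output paths, one per trajectory;
#'   extension selects the format (\code{.pdb} or \code{.xyz}).
#' @return invisibly, a list with the \code{paths} written and the
#'   \code{chain_map} (named chain letters by subunit).
#' @export
write_ensemble <- function(ensemble, paths) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  if (length(paths) != length(ensemble$trajectories))
    stop("need one output path per trajectory")
  topo <- ensemble$topology
  cmap <- subunit_chain_map(topo$subunit)
  for (k in seq_along(paths)) {
    tr <- ensemble$trajectories[[k]]
    ext <- tolower(tools::file_ext(paths[k]))
    nf <- dim(tr$coords)[1L]
    ns <- dim(tr$coords)[2L]
    ## frames x 3N matrix in Angstrom, xyz interleaved per site
    xyz <- matrix(aperm(tr$coords, c(3L, 2L, 1L)), nrow = nf,
                  byrow = TRUE) / NM_PER_ANGSTROM
    if (ext == "pdb") {
      bio3d::write.pdb(file = paths[k], xyz = xyz,
                       resno = topo$resno, resid = topo$resname,
                       eleno = seq_len(ns), elety = topo$elety,
                       chain = unname(cmap[topo$subunit]))
    } else if (ext == "xyz") {
      con <- file(paths[k], "w")
      on.exit(close(con), add = TRUE)
      for (f in seq_len(nf)) {
        writeLines(c(as.character(ns),
                     sprintf("frame %d t= %.6f ns", f, traj_times(tr)[f])),
                   con)
        writeLines(sprintf("%-4s %12.5f %12.5f %12.5f", topo$elety,
                           tr$coords[f, , 1L] / NM_PER_ANGSTROM,
                           tr$coords[f, , 2L] / NM_PER_ANGSTROM,
                           tr$coords[f, , 3L] / NM_PER_ANGSTROM), con)
      }
    } else {
      stop("format error: unknown trajectory format '.", ext, "'")
    }
  }
  invisible(list(paths = paths, chain_map = cmap))
}

read_xyz_file <- function(path) {
  lines <- readLines(path)
  frames <- list()
  names_first <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("structure error: bad atom count line in ", path)
    if (i + 1L + nat > length(lines))
      stop("structure error: truncated frame in ", path)
    rec <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(rec), "[[:space:]]+")
    nm <- vapply(toks, `[[`, "", 1L)
    co <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (is.null(names_first)) {
      names_first <- nm
    } else if (length(nm) != length(names_first) || any(nm != names_first)) {
      stop("structure error: inconsistent sites across frames in ", path)
    }
    frames[[length(frames) + 1L]] <- co
    i <- i + 2L + nat
  }
  if (length(frames) == 0L) stop("structure error: no frames in ", path)
  coords <- array(0, dim = c(length(frames), length(names_first), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  list(coords = coords * NM_PER_ANGSTROM, names = names_first)
}

#' Read a trajectory ensemble from disk
#'
#' Reads one trajectory per file.  Multi-model PDB is parsed with bio3d and
#' coordinates are converted from Angstrom to nm; chain identifiers become
#' subunit labels (optionally renamed through \code{chain_map}).  XYZ files
#' carry no residue information, so a full \code{topology} data.frame must be
#' supplied for them.
#'
#' @param paths character vector of trajectory files (all the same format).
#' @param frame_interval frame spacing in ns; the formats do not carry it.
#' @param t0 start time in ns of each trajectory (recycled).
#' @param model_tag model label attached to each trajectory (recycled).
#' @param chain_map optional named character vector mapping subunit labels to
#'   chain letters (as returned by \code{\link{write_ensemble}}); inverted on
#'   read so subunit labels are restored.
#' @param topology optional topology data.frame; required for XYZ.
#' @return a \code{\link{traj_ensemble}}.
#' @export
read_ensemble <- function(paths, frame_interval = 1, t0 = 0,
                          model_tag = "2xPscC", chain_map = NULL,
                          topology = NULL) {
  if (length(paths) == 0L) stop("no input files")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  t0 <- rep_len(t0, length(paths))
  model_tag <- rep_len(model_tag, length(paths))
  trajectories <- vector("list", length(paths))
  topo <- topology
  for (k in seq_along(paths)) {
    ext <- tolower(tools::file_ext(paths[k]))
    if (ext == "pdb") {
      pdb <- bio3d::read.pdb(paths[k], multi = TRUE, verbose = FALSE)
      xyz <- pdb$xyz
      if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
      nf <- nrow(xyz)
      ns <- ncol(xyz) / 3L
      coords <- aperm(array(t(xyz), dim = c(3L, ns, nf)),
                      c(3L, 2L, 1L)) * NM_PER_ANGSTROM
      sub <- pdb$atom$chain
      sub[is.na(sub)] <- "A"
      if (!is.null(chain_map)) {
        inv <- stats::setNames(names(chain_map), chain_map)
        hit <- sub %in% names(inv)
        sub[hit] <- inv[sub[hit]]
      }
      this_topo <- data.frame(elety = pdb$atom$elety, resno = pdb$atom$resno,
                              resname = pdb$atom$resid, subunit = sub,
                              stringsAsFactors = FALSE)
    } else if (ext == "xyz") {
      dat <- read_xyz_file(paths[k])
      coords <- dat$coords
      ns <- length(dat$names)
      this_topo <- if (!is.null(topology)) topology else
        data.frame(elety = dat$names, resno = seq_len(ns),
                   resname = rep("UNK", ns), subunit = rep("A", ns),
                   stringsAsFactors = FALSE)
    } else {
      stop("format error: unknown trajectory format '.", ext,
           if (ext == "dcd") "' (DCD reading is not supported; convert to multi-model PDB)"
           else "'")
    }
    if (is.null(topo)) topo <- this_topo
    else if (nrow(this_topo) != nrow(topo))
      stop("structure error: inconsistent site count across files")
    trajectories[[k]] <- make_trajectory(
      coords, frame_interval = frame_interval, t0 = t0[k],
      trajectory_id = tools::file_path_sans_ext(basename(paths[k])),
      model_tag = model_tag[k])
  }
  traj_ensemble(trajectories, topo)
}
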