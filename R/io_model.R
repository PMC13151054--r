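#' @useDynLib gasport, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

# ---- frame container ---------------------------------------------------------

#' Construct a raw frame set
#'
#' A `gas_frames` object holds, per saved frame, the absolute positions of all
#' tracked gas molecules, the position of the catalytic anchor (the metal
#' center), and optionally the coordinates of reference atoms used for
#' rigid-body superposition.
#'
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param ids character vector of molecule identifiers (constant across frames).
#' @param pos numeric array `c(n_frames, n_molecules, 3)` of absolute positions
#'   in Angstrom.
#' @param anchor numeric matrix `n_frames x 3`: anchor (metal) position per
#'   frame, Angstrom.
#' @param ref optional numeric array `c(n_frames, n_ref_atoms, 3)` of
#'   superposition reference atoms.
#' @return an object of class `gas_frames`.
#' @export
gas_frames <- function(times, ids, pos, anchor, ref = NULL) {
  times <- as.numeric(times)
  ids <- as.character(ids)
  if (length(times) < 2L) {
    stop("a trajectory needs at least 2 frames, got ", length(times))
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop("frame times must be strictly increasing (violated at frame ", bad, ")")
  }
  pos <- as_coord_array(pos, length(times), length(ids), "pos")
  anchor <- matrix(as.numeric(anchor), nrow = length(times), ncol = 3L)
  if (!all(is.finite(pos)) || !all(is.finite(anchor))) {
    stop("non-finite coordinates in trajectory")
  }
  if (!is.null(ref)) {
    ref <- as_coord_array(ref, length(times), dim(ref)[2L], "ref")
    if (!all(is.finite(ref))) stop("non-finite reference-atom coordinates")
  }
  structure(list(times = times, ids = ids, pos = pos, anchor = anchor,
                 ref = ref),
            class = "gas_frames")
}

as_coord_array <- function(x, nf, nm, what) {
  x <- array(as.numeric(x), dim = c(nf, nm, 3L))
  if (any(dim(x) != c(nf, nm, 3L))) stop("bad dimensions for ", what)
  x
}

#' @export
print.gas_frames <- function(x, ...) {
  cat(sprintf("gas_frames: %d frames, %d molecules, t = %g..%g ps%s\n",
              length(x$times), length(x$ids), x$times[1L],
              x$times[length(x$times)],
              if (is.null(x$ref)) "" else sprintf(", %d ref atoms",
                                                  dim(x$ref)[2L])))
  invisible(x)
}

# ---- relative trajectory -----------------------------------------------------

#' Construct a relative (anchor-centered) trajectory
#'
#' Positions are stored as gas minus anchor (so clouds exported from the model
#' overlay the protein frame naturally); the per-frame distance matrix is the
#' Euclidean norm of those vectors and is recomputed here to enforce the
#' consistency invariant.
#'
#' @param times frame times (ps).
#' @param ids molecule identifiers.
#' @param rel array `c(n_frames, n_molecules, 3)` of anchor-relative positions
#'   (Angstrom).
#' @param stride frame spacing in ps; if `NULL`, inferred from `times`.
#' @param provenance list of free-form metadata (source file, whether
#'   superposition was applied, ...).
#' @return an object of class `gas_traj` with elements `times`, `ids`, `rel`,
#'   `dist` (`n_frames x n_molecules`), `stride`, `provenance`.
#' @export
gas_traj <- function(times, ids, rel, stride = NULL, provenance = list()) {
  times <- as.numeric(times)
  ids <- as.character(ids)
  rel <- as_coord_array(rel, length(times), length(ids), "rel")
  if (is.null(stride)) {
    stride <- if (length(times) > 1L) times[2L] - times[1L] else NA_real_
  }
  if (length(times) > 2L) {
    dts <- diff(times)
    if (max(abs(dts - stride)) > 1e-6 * max(stride, 1)) {
      stop("frame times are not uniformly strided")
    }
  }
  d <- sqrt(rel[, , 1L, drop = FALSE]^2 + rel[, , 2L, drop = FALSE]^2 +
              rel[, , 3L, drop = FALSE]^2)
  dim(d) <- dim(rel)[1:2]
  structure(list(times = times, ids = ids, rel = rel, dist = d,
                 stride = stride, provenance = provenance),
            class = "gas_traj")
}

#' @export
print.gas_traj <- function(x, ...) {
  cat(sprintf(
    "gas_traj: %d frames x %d molecules, stride %g ps, superposed: %s\n",
    length(x$times), length(x$ids), x$stride,
    isTRUE(x$provenance$superposed)))
  invisible(x)
}

n_frames <- function(traj) length(traj$times)

# ---- native columnar format --------------------------------------------------

# Grammar: comment lines start with '#'; '# stride_ps: <x>' is honoured.
# Then a header row 'time id x y z' and one row per (frame, atom). Reserved
# ids: 'anchor' for the metal center, ids starting with 'ref:' for
# superposition reference atoms; everything else is a gas molecule.

#' Write a frame set to the native columnar text format
#'
#' @param frames a `gas_frames` object.
#' @param path output file path.
#' @param digits significant digits for coordinates (default preserves
#'   round-tripping well below 1e-4 Angstrom).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path, digits = 10L) {
  stopifnot(inherits(frames, "gas_frames"))
  nf <- length(frames$times)
  nm <- length(frames$ids)
  nr <- if (is.null(frames$ref)) 0L else dim(frames$ref)[2L]
  ids_all <- c("anchor", if (nr) paste0("ref:", seq_len(nr)), frames$ids)
  per_frame <- 1L + nr + nm
  tab <- data.table::data.table(
    time = rep(frames$times, each = per_frame),
    id = rep(ids_all, times = nf),
    x = 0, y = 0, z = 0)
  for (k in 1:3) {
    cols <- matrix(NA_real_, nrow = per_frame, ncol = nf)
    cols[1L, ] <- frames$anchor[, k]
    if (nr) cols[1L + seq_len(nr), ] <- t(frames$ref[, , k])
    cols[1L + nr + seq_len(nm), ] <- t(matrix(frames$pos[, , k], nrow = nf))
    data.table::set(tab, j = c("x", "y", "z")[k], value = as.vector(cols))
  }
  hdr <- c("# gasport-traj 1",
           sprintf("# stride_ps: %.10g",
                   if (nf > 1L) frames$times[2L] - frames$times[1L] else NA))
  writeLines(c(hdr, "time id x y z"), path)
  data.table::fwrite(tab, path, sep = " ", append = TRUE, col.names = FALSE,
                     scipen = 0)
  invisible(path)
}

#' Load a trajectory from disk
#'
#' Reads the native columnar format or multi-frame XYZ (atom labels are used
#' as molecule ids; labels `anchor` and `ref:*` are reserved as in the
#' columnar grammar). Frames must be time-ordered with a constant molecule
#' set.
#'
#' @param path input file.
#' @param format `"columnar"` or `"xyz"`.
#' @return a `gas_frames` object.
#' @export
load_trajectory <- function(path, format = c("columnar", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "columnar") load_columnar(path) else load_xyz(path)
}

load_columnar <- function(path) {
  head_lines <- readLines(path, n = 50L)
  n_comment <- sum(cumprod(startsWith(head_lines, "#")))
  tab <- withCallingHandlers(
    tryCatch(
      data.table::fread(path, skip = n_comment, header = TRUE,
                        colClasses = list(character = "id")),
      error = function(e) report_bad_line(path, n_comment,
                                          conditionMessage(e))),
    warning = function(w) {
      if (grepl("cleaned up", conditionMessage(w), ignore.case = TRUE)) {
        invokeRestart("muffleWarning")
      } else {
        report_bad_line(path, n_comment, conditionMessage(w))
      }
    })
  need <- c("time", "id", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("columnar trajectory must have columns: ", paste(need, collapse = " "))
  }
  if (anyNA(tab$x) || anyNA(tab$y) || anyNA(tab$z) || anyNA(tab$time)) {
    bad <- which(!stats::complete.cases(tab[, c("time", "x", "y", "z")]))[1L]
    stop("parse error at data line ", bad, " of ", path,
         " (line ", bad + n_comment + 1L, " of file): non-numeric field")
  }
  frames_from_long(tab, path)
}

report_bad_line <- function(path, n_comment, msg) {
  nfld <- utils::count.fields(path, comment.char = "#")
  exp_n <- nfld[1L]
  bad <- which(nfld != exp_n)[1L]
  if (!is.na(bad)) {
    stop("malformed line ", bad + n_comment, " of ", path, ": expected ",
         exp_n, " fields, found ", nfld[bad])
  }
  stop("failed to parse ", path, ": ", msg)
}

frames_from_long <- function(tab, path) {
  times <- unique(tab$time)
  if (any(diff(times) <= 0)) {
    stop("frame times not strictly increasing in ", path)
  }
  ids0 <- tab$id[tab$time == times[1L]]
  nf <- length(times)
  per_frame <- length(ids0)
  if (nrow(tab) != nf * per_frame ||
      !identical(tab$id, rep(ids0, times = nf))) {
    stop("molecule set is not constant across frames in ", path)
  }
  is_anchor <- ids0 == "anchor"
  is_ref <- startsWith(ids0, "ref:")
  is_gas <- !is_anchor & !is_ref
  shape <- function(sel) {
    n <- sum(sel)
    a <- array(NA_real_, dim = c(nf, n, 3L))
    m <- matrix(sel, nrow = per_frame, ncol = nf)
    for (k in 1:3) {
      v <- matrix(tab[[c("x", "y", "z")[k]]], nrow = per_frame)
      a[, , k] <- t(v[sel, , drop = FALSE])
    }
    a
  }
  anchor <- if (any(is_anchor)) shape(is_anchor)[, 1L, ] else
    matrix(0, nf, 3L)
  gas_frames(times = times, ids = ids0[is_gas], pos = shape(is_gas),
             anchor = anchor,
             ref = if (any(is_ref)) shape(is_ref) else NULL)
}

load_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  natoms <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(natoms) || natoms < 1L) {
    stop("malformed line 1 of ", path, ": expected atom count")
  }
  blk <- natoms + 2L
  if (length(lines) %% blk != 0L) {
    stop("XYZ file ", path, " is not a whole number of ", blk, "-line frames")
  }
  nf <- length(lines) %/% blk
  comment_idx <- (seq_len(nf) - 1L) * blk + 2L
  tm <- regmatches(lines[comment_idx],
                   regexpr("t=\\s*([-0-9.eE+]+)", lines[comment_idx]))
  times <- if (length(tm) == nf) {
    as.numeric(sub("t=\\s*", "", tm))
  } else {
    as.numeric(seq_len(nf) - 1L)
  }
  atom_idx <- as.vector(outer(2L + seq_len(natoms), (seq_len(nf) - 1L) * blk,
                              "+"))
  tab <- data.table::fread(text = lines[atom_idx], header = FALSE,
                           col.names = c("id", "x", "y", "z"),
                           colClasses = list(character = 1L))
  tab$time <- rep(times, each = natoms)
  frames_from_long(tab[, c("time", "id", "x", "y", "z")], path)
}

#' Write a frame set as multi-frame XYZ
#'
#' @inheritParams write_trajectory
#' @export
write_xyz <- function(frames, path, digits = 6L) {
  stopifnot(inherits(frames, "gas_frames"))
  nf <- length(frames$times)
  nr <- if (is.null(frames$ref)) 0L else dim(frames$ref)[2L]
  ids_all <- c("anchor", if (nr) paste0("ref:", seq_len(nr)), frames$ids)
  natoms <- length(ids_all)
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  out <- character(nf * (natoms + 2L))
  pos <- 1L
  for (f in seq_len(nf)) {
    xyz <- rbind(frames$anchor[f, ],
                 if (nr) matrix(frames$ref[f, , ], ncol = 3L),
                 matrix(frames$pos[f, , ], ncol = 3L))
    out[pos] <- as.character(natoms)
    out[pos + 1L] <- sprintf("t=%.6f", frames$times[f])
    out[pos + 1L + seq_len(natoms)] <-
      sprintf(fmt, ids_all, xyz[, 1L], xyz[, 2L], xyz[, 3L])
    pos <- pos + natoms + 2L
  }
  writeLines(out, path)
  invisible(path)
}

# ---- superposition -----------------------------------------------------------

#' Least-squares rigid-body fit (Kabsch)
#'
#' Returns the rotation `R` and translation such that `x %*% R + t` maps the
#' mobile coordinates onto the target with minimum RMSD. All atoms are
#' weighted equally.
#'
#' @param mobile,target `n x 3` coordinate matrices, row-matched.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`.
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3L, all(dim(mobile) == dim(target)))
  if (nrow(mobile) < 3L) {
    stop("superposition needs at least 3 reference atoms, got ", nrow(mobile))
  }
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2L, cm); Q <- sweep(target, 2L, ct)
  sv_p <- svd(P)$d
  if (sv_p[2L] < 1e-8 * max(sv_p[1L], 1)) {
    stop("reference atoms are collinear; superposition is underdetermined")
  }
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P %*% R
  list(rotation = R, translation = ct - cm %*% R,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

#' Superpose frames and express gas positions relative to the anchor
#'
#' Each frame is rigid-body fitted onto the reference frame using the
#' reference atoms (equal weights), then every gas position is re-expressed as
#' gas minus anchor. Without reference atoms the fit is skipped and only the
#' anchor subtraction (centering) is applied.
#'
#' @param frames a `gas_frames` object.
#' @param reference frame index used as the fit target (default 1), or a
#'   `n_ref x 3` coordinate matrix.
#' @return a `gas_traj` with `provenance$superposed` recording whether a fit
#'   was applied.
#' @export
superpose_and_center <- function(frames, reference = 1L) {
  stopifnot(inherits(frames, "gas_frames"))
  nf <- length(frames$times)
  nm <- length(frames$ids)
  rel <- array(NA_real_, dim = c(nf, nm, 3L))
  superposed <- !is.null(frames$ref)
  target <- NULL
  if (superposed) {
    target <- if (is.matrix(reference)) reference else
      matrix(frames$ref[reference, , ], ncol = 3L)
  }
  for (f in seq_len(nf)) {
    gas <- matrix(frames$pos[f, , ], ncol = 3L)
    anc <- frames$anchor[f, ]
    if (superposed) {
      fit <- kabsch_fit(matrix(frames$ref[f, , ], ncol = 3L), target)
      gas <- gas %*% fit$rotation +
        matrix(fit$translation, nm, 3L, byrow = TRUE)
      anc <- as.vector(anc %*% fit$rotation + fit$translation)
    }
    rel[f, , ] <- sweep(gas, 2L, anc)
  }
  gas_traj(frames$times, frames$ids, rel,
           provenance = list(superposed = superposed))
}

# ---- state cloud export ------------------------------------------------------

cloud_class <- function(p) {
  cut(p, breaks = c(-Inf, 0.01, 0.10, 0.40, Inf),
      labels = c("none", "orange", "blue", "red"), right = TRUE)
}

#' Export the stationary distribution as a pseudo-atom state cloud
#'
#' One pseudo-atom per MSM state within `radius_max` of the anchor; the
#' stationary probability is written to the PDB B-factor column scaled by 100
#' (preserving four significant digits at the field's two-decimal precision)
#' and clamped to `[0, 999.99]`. States are classed by probability:
#' `pi > 0.40` red, `> 0.10` blue, `> 0.01` orange, else `"none"` (excluded
#' from the file when `exclude_low` is `TRUE`).
#'
#' @param model a `gas_msm` with a stationary distribution.
#' @param grid the `grid_spec` used to build the model.
#' @param radius_max radial display cutoff from the anchor (Angstrom).
#' @param file optional path; when given, a PDB file of HETATM pseudo-atoms is
#'   written.
#' @param exclude_low drop states with `pi <= 0.01` from the file (default
#'   `TRUE`, matching the display convention).
#' @return data.frame (`state`, `x`, `y`, `z`, `pi`, `class`), invisibly when
#'   `file` is given.
#' @export
export_state_cloud <- function(model, grid, radius_max = 20, file = NULL,
                               exclude_low = TRUE) {
  stopifnot(inherits(model, "gas_msm"), radius_max > 0)
  xyz <- state_to_grid(model$active, grid)
  r <- sqrt(rowSums(xyz^2))
  keep <- r <= radius_max
  cloud <- data.frame(state = model$active[keep],
                      x = xyz[keep, 1L], y = xyz[keep, 2L], z = xyz[keep, 3L],
                      pi = model$pi[keep])
  cloud$class <- cloud_class(cloud$pi)
  cloud <- cloud[order(-cloud$pi), , drop = FALSE]
  rownames(cloud) <- NULL
  if (!is.null(file)) {
    sub <- if (exclude_low) cloud[cloud$class != "none", , drop = FALSE] else
      cloud
    if (nrow(sub) == 0L) {
      warning("no states to export after filtering; writing header-only file")
    }
    write_cloud_pdb(sub, file)
    return(invisible(cloud))
  }
  cloud
}

write_cloud_pdb <- function(cloud, file) {
  b <- pmin(pmax(cloud$pi * 100, 0), 999.99)
  lines <- sprintf(
    "HETATM%5d  X   STA X%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           X",
    seq_len(nrow(cloud)) %% 100000L, seq_len(nrow(cloud)) %% 10000L,
    cloud$x, cloud$y, cloud$z, rep(1, nrow(cloud)), b)
  writeLines(c("REMARK   state cloud: B-factor = 100 * stationary probability",
               lines, "END"), file)
  invisible(file)
}

# ---- environment model -------------------------------------------------------

#' Build an environment model from residue atoms
#'
#' The environment model holds labeled residues (real residues from a PDB, or
#' the synthetic generator's cavity-lining pseudo-residues) and named regions
#' — sets of residue ids used as pathway signatures.
#'
#' @param atoms data.frame with columns `residue_id`, `label`, `x`, `y`, `z`
#'   (anchor-relative Angstrom).
#' @param regions named list of residue-id vectors.
#' @return an object of class `gas_env`.
#' @export
environment_model <- function(atoms, regions = list()) {
  need <- c("residue_id", "label", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  atoms$residue_id <- as.character(atoms$residue_id)
  lab <- unique(atoms[, c("residue_id", "label")])
  if (anyDuplicated(lab$residue_id)) {
    stop("residue_id maps to more than one label")
  }
  known <- unique(atoms$residue_id)
  for (nm in names(regions)) {
    miss <- setdiff(as.character(regions[[nm]]), known)
    if (length(miss)) {
      stop("region '", nm, "' references unknown residues: ",
           paste(miss, collapse = ", "))
    }
  }
  structure(list(atoms = atoms, regions = regions), class = "gas_env")
}

#' Read an environment model from a PDB file
#'
#' Residue ids are `<chain>:<resno>` and labels `<resid><resno>`; coordinates
#' are shifted so that `anchor` (an atom selection or explicit coordinate)
#' sits at the origin.
#'
#' @param path PDB file.
#' @param anchor either a length-3 coordinate or a `bio3d` selection string
#'   such as `"FE"` (element/atom name of the catalytic metal).
#' @param regions named list of residue-id vectors (optional).
#' @return a `gas_env`.
#' @export
read_environment_pdb <- function(path, anchor = c(0, 0, 0), regions = list()) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (is.character(anchor)) {
    hit <- at[at$elety == anchor | at$resid == anchor, , drop = FALSE]
    if (nrow(hit) == 0L) stop("anchor atom '", anchor, "' not found in ", path)
    anchor <- as.numeric(hit[1L, c("x", "y", "z")])
  }
  atoms <- data.frame(
    residue_id = paste0(at$chain, ":", at$resno),
    label = paste0(at$resid, at$resno),
    x = at$x - anchor[1L], y = at$y - anchor[2L], z = at$z - anchor[3L],
    stringsAsFactors = FALSE)
  environment_model(atoms, regions)
}
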