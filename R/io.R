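#' Read a LAMMPS text dump
#'
#' Parses an orthogonal-box LAMMPS dump (\code{ITEM: TIMESTEP} /
#' \code{BOX BOUNDS} / \code{ATOMS} sections) into a
#' \code{\link{trajectory}}.  Scaled coordinates (\code{xs ys zs}) are
#' converted to Cartesian \enc{Å}{A} via the box lengths; atoms are
#' normalised to ascending id order regardless of file order.
#'
#' @param path path to the dump file.
#' @param time_per_step fs per timestep used to convert the integer
#'   \code{TIMESTEP} to a frame time. Default 1.
#' @return A \code{\link{trajectory}} (wrapped coordinates, no topology).
#' @export
read_lammps_dump <- function(path, time_per_step = 1) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty dump file: ", path)
  item_idx <- grep("^ITEM:", lines)
  ts_idx <- grep("^ITEM: TIMESTEP", lines)
  if (length(ts_idx) == 0) stop("no 'ITEM: TIMESTEP' section found in ", path)

  frames <- vector("list", length(ts_idx))
  for (fi in seq_along(ts_idx)) {
    i0 <- ts_idx[fi]
    i1 <- if (fi < length(ts_idx)) ts_idx[fi + 1] - 1L else length(lines)
    block <- lines[i0:i1]
    bitems <- grep("^ITEM:", block)

    get_section <- function(pattern) {
      j <- grep(pattern, block)
      if (length(j) != 1)
        stop(sprintf("malformed dump: expected one '%s' header near line %d",
                     pattern, i0))
      jn <- bitems[bitems > j]
      end <- if (length(jn)) min(jn) - 1L else length(block)
      list(header = block[j], body = block[(j + 1L):end])
    }

    step <- as.numeric(get_section("^ITEM: TIMESTEP")$body[1])
    natoms <- as.integer(get_section("^ITEM: NUMBER OF ATOMS")$body[1])
    bb <- get_section("^ITEM: BOX BOUNDS")
    if (grepl("xy|xz|yz", bb$header))
      stop("triclinic boxes are not supported (line ", i0, ")")
    bounds <- do.call(rbind, lapply(bb$body[1:3], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])[1:2]))
    L <- bounds[, 2] - bounds[, 1]
    if (any(!is.finite(L)) || any(L <= 0))
      stop("malformed BOX BOUNDS near line ", i0)

    at <- get_section("^ITEM: ATOMS")
    colnames_at <- strsplit(sub("^ITEM: ATOMS\\s*", "", at$header), "\\s+")[[1]]
    body <- at$body[nzchar(trimws(at$body))]
    if (length(body) != natoms)
      stop(sprintf("frame at line %d declares %d atoms but has %d rows",
                   i0, natoms, length(body)))
    vals <- utils::read.table(text = body, col.names = colnames_at)
    scaled <- all(c("xs", "ys", "zs") %in% colnames_at)
    if (!scaled && !all(c("x", "y", "z") %in% colnames_at))
      stop("dump ATOMS section must contain x y z or xs ys zs columns")
    if (!"id" %in% colnames_at) stop("dump ATOMS section must contain an id column")
    vals <- vals[order(vals$id), , drop = FALSE]
    xyz <- if (scaled) {
      cbind(bounds[1, 1] + vals$xs * L[1],
            bounds[2, 1] + vals$ys * L[2],
            bounds[3, 1] + vals$zs * L[3])
    } else {
      cbind(vals$x, vals$y, vals$z)
    }
    # shift to [0, L) origin convention
    xyz <- sweep(xyz, 2, bounds[, 1])
    frames[[fi]] <- list(step = step, box = L, xyz = xyz, n = natoms)
  }

  ns <- vapply(frames, `[[`, integer(1), "n")
  if (length(unique(ns)) != 1)
    stop("atom count varies across frames: ", paste(unique(ns), collapse = ", "))
  nf <- length(frames)
  na <- ns[1]
  coords <- array(NA_real_, c(nf, na, 3))
  box <- matrix(NA_real_, nf, 3)
  for (fi in seq_len(nf)) {
    coords[fi, , ] <- frames[[fi]]$xyz
    box[fi, ] <- frames[[fi]]$box
  }
  steps <- vapply(frames, `[[`, numeric(1), "step")
  o <- order(steps)
  trajectory(coords[o, , , drop = FALSE], box[o, , drop = FALSE],
             steps[o] * time_per_step, wrapped = TRUE)
}

#' Write a LAMMPS text dump
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path output path.
#' @param time_per_step fs per timestep (inverse of the reader's conversion).
#' @return \code{path}, invisibly.
#' @export
write_lammps_dump <- function(traj, path, time_per_step = 1) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  na <- n_atoms(traj)
  types <- if (!is.null(traj$topology)) traj$topology$atom_type else rep("1", na)
  for (fi in seq_len(n_frames(traj))) {
    L <- traj$box[fi, ]
    writeLines(c("ITEM: TIMESTEP",
                 format(traj$times[fi] / time_per_step, scientific = FALSE),
                 "ITEM: NUMBER OF ATOMS",
                 as.character(na),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("%.10g %.10g", 0, L[1]),
                 sprintf("%.10g %.10g", 0, L[2]),
                 sprintf("%.10g %.10g", 0, L[3]),
                 "ITEM: ATOMS id type x y z"), con)
    writeLines(sprintf("%d %s %.10g %.10g %.10g", seq_len(na), types,
                       traj$coords[fi, , 1], traj$coords[fi, , 2],
                       traj$coords[fi, , 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Supports the common extended-XYZ convention: per-frame comment line with
#' \code{Lattice="ax 0 0 0 by 0 0 0 cz"} and a \code{Properties} field.
#' Only orthogonal lattices are accepted.
#'
#' @param path path to the file.
#' @param dt time between frames, fs (extended-XYZ rarely stores times).
#' @return A \code{\link{trajectory}}.
#' @export
read_extxyz <- function(path, dt = 1) {
  lines <- readLines(path)
  lines <- lines[seq_len(length(lines))]
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty extended-XYZ file: ", path)
  i <- 1L
  frames <- list()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na)) stop("expected atom count at line ", i)
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    if (length(m) == 0) stop("missing Lattice field in frame header at line ", i + 1L)
    lat <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", m), "\\s+")[[1]])
    if (length(lat) != 9) stop("Lattice must contain 9 numbers (line ", i + 1L, ")")
    off_diag <- lat[c(2, 3, 4, 6, 7, 8)]
    if (any(abs(off_diag) > 1e-12))
      stop("non-orthogonal lattice is not supported (line ", i + 1L, ")")
    L <- lat[c(1, 5, 9)]
    body <- lines[(i + 2L):(i + 1L + na)]
    vals <- utils::read.table(text = body, stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <- list(
      species = as.character(vals[[1]]),
      xyz = as.matrix(vals[, 2:4]),
      box = L, n = na)
    i <- i + 2L + na
  }
  ns <- vapply(frames, `[[`, integer(1), "n")
  if (length(unique(ns)) != 1) stop("atom count varies across frames")
  nf <- length(frames)
  coords <- array(NA_real_, c(nf, ns[1], 3))
  box <- matrix(NA_real_, nf, 3)
  for (fi in seq_len(nf)) {
    coords[fi, , ] <- frames[[fi]]$xyz
    box[fi, ] <- frames[[fi]]$box
  }
  attr_species <- frames[[1]]$species
  tr <- trajectory(coords, box, times = (seq_len(nf) - 1) * dt, wrapped = TRUE)
  tr$species <- attr_species
  tr
}

#' Write an extended-XYZ trajectory
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path output path.
#' @param species per-atom species labels; defaults to the trajectory's own
#'   \code{species}, then to topology atom types, then to \code{"X"}.
#' @return \code{path}, invisibly.
#' @export
write_extxyz <- function(traj, path, species = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  na <- n_atoms(traj)
  if (is.null(species)) {
    species <- if (!is.null(traj$species)) traj$species
    else if (!is.null(traj$topology)) traj$topology$atom_type
    else rep("X", na)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_len(n_frames(traj))) {
    L <- traj$box[fi, ]
    writeLines(c(as.character(na),
                 sprintf('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3',
                         L[1], L[2], L[3])), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", species,
                       traj$coords[fi, , 1], traj$coords[fi, , 2],
                       traj$coords[fi, , 3]), con)
  }
  invisible(path)
}

#' Read a topology table
#'
#' Reads the tab- or comma-separated topology schema: one row per atom
#' with columns \code{atom_id}, \code{atom_type}, \code{mass},
#' \code{molecule_id}, \code{molecule_name} (required) and
#' \code{charge}, \code{donor}, \code{acceptor} (optional; default 0 /
#' FALSE).  Lines starting with \code{#} are comments.
#'
#' @param path path to the file.
#' @return A \code{\link{topology}}.
#' @export
read_topology <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("atom_id", "atom_type", "mass", "molecule_id", "molecule_name")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("topology file lacks required columns: ",
         paste(missing, collapse = ", "))
  topology(raw$atom_id, raw$atom_type, raw$mass, raw$molecule_id,
           raw$molecule_name,
           charge = if (!is.null(raw$charge)) raw$charge else 0,
           donor = if (!is.null(raw$donor)) as.logical(raw$donor) else FALSE,
           acceptor = if (!is.null(raw$acceptor)) as.logical(raw$acceptor) else FALSE)
}

#' Read a delimited thermodynamic table
#'
#' Reads a CSV/TSV of per-record thermodynamic properties into a
#' \code{\link{thermo_series}}.  Column aliases are resolved through
#' \code{aliases}; missing optional columns stay absent (never silent
#' zeros).
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator; inferred from the extension when \code{NULL}
#'   (\code{.csv} comma, otherwise whitespace/tab).
#' @param aliases named list mapping canonical names (\code{time}, \code{T},
#'   \code{P}, \code{V}, \code{U}, \code{H}) to accepted column names.
#' @return A \code{\link{thermo_series}}.
#' @export
read_thermo_table <- function(path, sep = NULL,
                              aliases = list(
                                time = c("time", "t", "Time", "Step"),
                                T = c("T", "Temp", "temp", "temperature", "Temperature"),
                                P = c("P", "Press", "press", "pressure", "Pressure"),
                                V = c("V", "Vol", "vol", "volume", "Volume"),
                                U = c("U", "PotEng", "poteng", "potential", "E_pot"),
                                H = c("H", "Enthalpy", "enthalpy", "TotEng"))) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA)
  pick <- function(canon) {
    hit <- intersect(aliases[[canon]], names(raw))
    if (length(hit) == 0) return(NULL)
    col <- raw[[hit[1]]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num) && !anyNA(col)) {
      bad <- which(is.na(num))[1]
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                   col[bad], hit[1], bad))
    }
    num
  }
  Tcol <- pick("T")
  if (is.null(Tcol)) stop("no recognizable temperature column in ", path,
                          " (accepted: ", paste(aliases$T, collapse = ", "), ")")
  tcol <- pick("time")
  if (is.null(tcol)) tcol <- seq_along(Tcol)
  thermo_series(time = tcol, T = Tcol, P = pick("P"), V = pick("V"),
                U = pick("U"), H = pick("H"))
}

#' Read and write thermal-scan tables
#'
#' Thermal scans are stored as tab-separated tables with \code{#}-prefixed
#' metadata header lines (ground truth from generators, composition labels).
#'
#' @param scan a \code{\link{thermal_scan}}.
#' @param path file path.
#' @return \code{read_thermal_scan}: a \code{\link{thermal_scan}};
#'   \code{write_thermal_scan}: \code{path}, invisibly.
#' @export
write_thermal_scan <- function(scan, path) {
  stopifnot(inherits(scan, "thermal_scan"))
  con <- file(path, "w")
  on.exit(close(con))
  tr <- attr(scan, "truth")
  if (!is.null(tr))
    writeLines(sprintf("# truth %s", paste(names(tr),
                                           vapply(tr, function(v) paste(format(v, digits = 15), collapse = ","), ""),
                                           sep = "=", collapse = " ")), con)
  utils::write.table(as.data.frame(scan), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_thermal_scan
#' @export
read_thermal_scan <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  truth <- NULL
  tm <- grep("^# truth ", meta, value = TRUE)
  if (length(tm)) {
    kv <- strsplit(strsplit(sub("^# truth ", "", tm[1]), " ")[[1]], "=")
    truth <- lapply(kv, function(p) {
      vals <- suppressWarnings(as.numeric(strsplit(p[2], ",")[[1]]))
      if (anyNA(vals)) p[2] else vals
    })
    names(truth) <- vapply(kv, `[[`, "", 1)
  }
  thermal_scan(df$T, rho = df$rho, rho_sd = df$rho_sd, D = df$D,
               D_sd = df$D_sd, truth = truth)
}
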