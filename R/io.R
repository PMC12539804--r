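# Structure, trajectory, parameter and table I/O.
#
# Internal units: nm for all coordinates. PDB files (Angstrom) are converted
# at the boundary. The plain trajectory format is per frame a header line
# "natoms time_ps" followed by natoms lines "x y z" in nm.

#' Read a molecular structure
#'
#' Parses a PDB file (via bio3d, ATOM/HETATM records, coordinates converted
#' from Angstrom to nm) or the package's plain whitespace structure format
#' (columns: atom_id atom_name element chain resid resname x y z [vdw],
#' already in nm). Chain and author residue numbering are preserved verbatim.
#'
#' @param path file path.
#' @param format "pdb" or "plain".
#' @return a \linkS4class{MolecularStructure}.
#' @export
readStructure <- function(path, format = c("pdb", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) stop("PDB parse error in ", path,
                                             ": ", conditionMessage(e)))
    a <- pdb$atom
    atoms <- data.frame(
      atom_id = as.integer(a$eleno),
      atom_name = trimws(a$elety),
      element = trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                              substr(trimws(a$elety), 1, 1), a$elesy)),
      resid = as.integer(a$resno),
      resname = trimws(a$resid),
      chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
      x = a$x / 10, y = a$y / 10, z = a$z / 10,
      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    rows <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(rows)
    if (length(nf) && any(nf < 9))
      stop("plain structure parse error at line ", which(nf < 9)[1],
           ": expected >= 9 fields")
    atoms <- do.call(rbind, lapply(seq_along(rows), function(i) {
      r <- rows[[i]]
      num <- suppressWarnings(as.numeric(r[c(1, 5, 7, 8, 9)]))
      if (any(is.na(num)))
        stop("plain structure parse error at line ", i,
             ": non-numeric field")
      data.frame(atom_id = as.integer(num[1]), atom_name = r[2],
                 element = r[3], resid = as.integer(num[2]), resname = r[6],
                 chain = r[4], x = num[3], y = num[4], z = num[5],
                 vdw = if (length(r) >= 10 && r[10] != "NA")
                   as.numeric(r[10]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  if (anyDuplicated(atoms$atom_id))
    stop("parse error: duplicated atom_id ",
         atoms$atom_id[duplicated(atoms$atom_id)][1])
  new("MolecularStructure", atoms = atoms)
}

#' Write a molecular structure
#'
#' @param x a \linkS4class{MolecularStructure}.
#' @param path output path.
#' @param format "pdb" (coordinates written in Angstrom) or "plain" (nm).
#' @return invisibly, the path.
#' @export
writeStructure <- function(x, path, format = c("pdb", "plain")) {
  format <- match.arg(format)
  a <- atoms(x)
  if (format == "pdb") {
    bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(
      a[c("x", "y", "z")]) * 10)), resno = a$resid, resid = a$resname,
      eleno = a$atom_id, elety = a$atom_name, chain = a$chain,
      elesy = a$element)
  } else {
    vdw <- if ("vdw" %in% names(a)) a$vdw else rep(NA_real_, nrow(a))
    writeLines(sprintf("%d %s %s %s %d %s %.9f %.9f %.9f %s",
                       a$atom_id, a$atom_name, a$element, a$chain, a$resid,
                       a$resname, a$x, a$y, a$z,
                       ifelse(is.na(vdw), "NA", sprintf("%.6f", vdw))),
               path)
  }
  invisible(path)
}

#' Read a plain-text trajectory
#'
#' Each frame is a header line "natoms time_ps" followed by natoms lines
#' "x y z" in nm. The atom count must match the structure and frame times
#' must be strictly increasing.
#'
#' @param path file path.
#' @param structure the matching \linkS4class{MolecularStructure}.
#' @return a \linkS4class{FrameSequence}.
#' @export
readTrajectory <- function(path, structure) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  nref <- nAtoms(structure)
  times <- numeric(0)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(hdr) < 2 || any(is.na(hdr)))
      stop("trajectory parse error: bad frame header at line ", i)
    nat <- as.integer(hdr[1])
    if (nat != nref)
      stop("shape error: frame has ", nat, " atoms but structure has ", nref)
    if (i + nat > length(lines))
      stop("trajectory parse error: truncated frame at line ", i)
    block <- lines[(i + 1L):(i + nat)]
    m <- matrix(suppressWarnings(
      as.numeric(unlist(strsplit(trimws(block), "\\s+")))), ncol = 3,
      byrow = TRUE)
    if (any(is.na(m)))
      stop("trajectory parse error: non-numeric coordinate near line ", i + 1L)
    frames[[length(frames) + 1L]] <- m
    times <- c(times, hdr[2])
    i <- i + nat + 1L
  }
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("ordering error: frame times must be strictly increasing")
  coords <- array(unlist(frames), dim = c(nref, 3, length(frames)))
  new("FrameSequence", coords = coords, times = times,
      box = matrix(NA_real_, length(frames), 3))
}

#' Write a plain-text trajectory
#'
#' @param x a \linkS4class{FrameSequence}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTrajectory <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nat <- dim(x@coords)[1]
  for (i in seq_len(nFrames(x))) {
    writeLines(sprintf("%d %.6f", nat, x@times[i]), con)
    m <- x@coords[, , i, drop = TRUE]
    writeLines(sprintf("%.9f %.9f %.9f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read an xvg-style whitespace/comma series table
#'
#' Numeric table, comment lines starting with '#' or '@' ignored. All rows
#' must have the same number of columns.
#'
#' @param path file path.
#' @param colnames optional column names.
#' @return data.frame of numeric columns (zero rows for an empty file).
#' @export
readSeriesTable <- function(path, colnames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*([#@]|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(data.frame())
  rows <- strsplit(trimws(gsub(",", " ", lines)), "\\s+")
  nf <- lengths(rows)
  if (length(unique(nf)) != 1L)
    stop("parse error: ragged row at line ", lineno[which(nf != nf[1])[1]])
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- vapply(vals, anyNA, logical(1))
  if (any(bad))
    stop("parse error: non-numeric token at line ", lineno[which(bad)[1]])
  out <- as.data.frame(do.call(rbind, vals))
  names(out) <- if (!is.null(colnames)) colnames else paste0("V", seq_len(nf[1]))
  out
}

#' Read a residue-to-domain mapping file
#'
#' Lines "label chain first_resid last_resid"; '#' comments allowed. Used to
#' supply domain and ankyrin-repeat unit boundaries, which are author input
#' rather than derivable from structure files.
#'
#' @param path file path.
#' @return data.frame(label, chain, first, last).
#' @export
readDomainMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(rows) != 4))
    stop("domain map parse error: expected 'label chain first last'")
  data.frame(label = vapply(rows, `[`, "", 1),
             chain = vapply(rows, `[`, "", 2),
             first = as.integer(vapply(rows, `[`, "", 3)),
             last = as.integer(vapply(rows, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Select atoms by a simple expression
#'
#' Clauses separated by "and": \code{chain <id>}, \code{resid <n>} or
#' \code{resid <a>-<b>} (comma-separated lists allowed), \code{name <atom
#' name>} (comma-separated). Clause order is irrelevant; the result is the
#' sorted, de-duplicated set of matching atom ids. An empty selection is an
#' error, never silently empty.
#'
#' @param structure a \linkS4class{MolecularStructure}.
#' @param selector e.g. "chain A and resid 1571-1581", "name CA".
#' @return sorted integer vector of atom ids.
#' @export
selectGroup <- function(structure, selector) {
  a <- atoms(structure)
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(selector, "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) < 2) stop("bad selector clause: '", cl, "'")
    key <- tok[1]
    vals <- strsplit(paste(tok[-1], collapse = ""), ",")[[1]]
    if (key == "chain") {
      keep <- keep & a$chain %in% vals
    } else if (key == "resid") {
      ids <- unlist(lapply(vals, function(v) {
        if (grepl("-", v)) {
          rng <- as.integer(strsplit(v, "-")[[1]])
          seq(rng[1], rng[2])
        } else as.integer(v)
      }))
      keep <- keep & a$resid %in% ids
    } else if (key == "name") {
      keep <- keep & a$atom_name %in% vals
    } else stop("unknown selector key: '", key, "'")
  }
  ids <- sort(unique(a$atom_id[keep]))
  if (!length(ids)) stop("empty selection for '", selector, "'")
  ids
}

#' Read an interaction-parameter file
#'
#' Sectioned columnar text: \code{[atoms]} lines "atom_id charge sigma
#' epsilon"; \code{[bonds]} "ai aj k r0"; \code{[angles]} "ai aj ak k
#' theta0_deg"; \code{[dihedrals]} "ai aj ak al k mult phase_deg";
#' \code{[options]} "switch_on x", "cutoff x", "exclusions 1-2,1-3",
#' "scale14 x". Angles are converted to radians internally.
#'
#' @param path file path.
#' @param natoms expected atom count (checked against the [atoms] section).
#' @return an \linkS4class{InteractionParameters}.
#' @export
readParameters <- function(path, natoms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  section <- NA_character_
  store <- list(atoms = list(), bonds = list(), angles = list(),
                dihedrals = list(), options = list())
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("[][]", "", ln)
      if (!section %in% names(store)) stop("unknown section [", section, "]")
      next
    }
    if (is.na(section)) stop("parameter file: data before first section")
    store[[section]][[length(store[[section]]) + 1L]] <-
      strsplit(ln, "\\s+")[[1]]
  }
  numRows <- function(rows, n, what) {
    if (!length(rows)) return(matrix(numeric(0), 0, n))
    if (any(lengths(rows) != n))
      stop("parameter parse error in [", what, "]: expected ", n, " fields")
    m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = n,
                byrow = TRUE)
    if (anyNA(m)) stop("parameter parse error in [", what, "]")
    m
  }
  am <- numRows(store$atoms, 4, "atoms")
  am <- am[order(am[, 1]), , drop = FALSE]
  if (!is.null(natoms) && nrow(am) != natoms)
    stop("parameter error: [atoms] has ", nrow(am), " rows, expected ", natoms)
  bm <- numRows(store$bonds, 4, "bonds")
  gm <- numRows(store$angles, 5, "angles")
  dm <- numRows(store$dihedrals, 7, "dihedrals")
  opts <- list(switch_on = 1.0, cutoff = 1.2, exclusions = "1-2,1-3",
               scale14 = 1.0)
  for (row in store$options) {
    if (length(row) != 2) stop("parameter parse error in [options]")
    opts[[row[1]]] <- row[2]
  }
  new("InteractionParameters",
      charge = am[, 2], sigma = am[, 3], epsilon = am[, 4],
      bonds = data.frame(ai = as.integer(bm[, 1]), aj = as.integer(bm[, 2]),
                         k = bm[, 3], r0 = bm[, 4]),
      angles = data.frame(ai = as.integer(gm[, 1]), aj = as.integer(gm[, 2]),
                          ak = as.integer(gm[, 3]), k = gm[, 4],
                          theta0 = gm[, 5] * pi / 180),
      dihedrals = data.frame(ai = as.integer(dm[, 1]), aj = as.integer(dm[, 2]),
                             ak = as.integer(dm[, 3]), al = as.integer(dm[, 4]),
                             k = dm[, 5], mult = as.integer(dm[, 6]),
                             phase = dm[, 7] * pi / 180),
      exclusions = strsplit(as.character(opts$exclusions), ",")[[1]],
      scale14 = as.numeric(opts$scale14),
      switchOn = as.numeric(opts$switch_on),
      cutoff = as.numeric(opts$cutoff))
}

#' Write an interaction-parameter file
#'
#' @param params an \linkS4class{InteractionParameters}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeParameters <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[atoms]", con)
  writeLines(sprintf("%d %.9f %.9f %.9f", seq_along(params@charge),
                     params@charge, params@sigma, params@epsilon), con)
  if (nrow(params@bonds)) {
    writeLines("[bonds]", con)
    b <- params@bonds
    writeLines(sprintf("%d %d %.9f %.9f", b$ai, b$aj, b$k, b$r0), con)
  }
  if (nrow(params@angles)) {
    writeLines("[angles]", con)
    g <- params@angles
    writeLines(sprintf("%d %d %d %.9f %.9f", g$ai, g$aj, g$ak, g$k,
                       g$theta0 * 180 / pi), con)
  }
  if (nrow(params@dihedrals)) {
    writeLines("[dihedrals]", con)
    d <- params@dihedrals
    writeLines(sprintf("%d %d %d %d %.9f %d %.9f", d$ai, d$aj, d$ak, d$al,
                       d$k, d$mult, d$phase * 180 / pi), con)
  }
  writeLines("[options]", con)
  writeLines(sprintf("switch_on %.9f", params@switchOn), con)
  writeLines(sprintf("cutoff %.9f", params@cutoff), con)
  writeLines(paste("exclusions", paste(params@exclusions, collapse = ",")), con)
  writeLines(sprintf("scale14 %.9f", params@scale14), con)
  invisible(path)
}

#' Write / read force tables as CSV
#'
#' Tabular exchange format for \linkS4class{PairForceTable} and
#' \linkS4class{NetForceTable}; metadata (frame counts) are carried on
#' '#'-prefixed header lines.
#'
#' @param x a PairForceTable or NetForceTable.
#' @param path file path.
#' @return \code{writeForceTable}: invisibly the path; \code{readForceTable}:
#'   the reconstructed object.
#' @export
writeForceTable <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is(x, "PairForceTable")) {
    writeLines(sprintf("# ChannelMech PairForceTable nframes=%d", x@nframes),
               con)
  } else if (is(x, "NetForceTable")) {
    writeLines(sprintf("# ChannelMech NetForceTable nForced=%d nFree=%d",
                       x@nForced, x@nFree), con)
  } else stop("unsupported object")
  utils::write.csv(x@entries, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeForceTable
#' @export
readForceTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1)
  e <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (grepl("PairForceTable", hdr)) {
    nf <- as.integer(sub(".*nframes=(\\d+).*", "\\1", hdr))
    new("PairForceTable", entries = e, nframes = nf)
  } else if (grepl("NetForceTable", hdr)) {
    new("NetForceTable", entries = e,
        nForced = as.integer(sub(".*nForced=(\\d+).*", "\\1", hdr)),
        nFree = as.integer(sub(".*nFree=(\\d+).*", "\\1", hdr)))
  } else stop("not a ChannelMech force table: ", path)
}
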