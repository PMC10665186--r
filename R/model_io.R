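## Atomic model and particle-table I/O.
##
## Internal units are Angstrom for coordinates and degrees for angles,
## everywhere. An `atom_model` is a data.frame with columns
## chain / resno / atom / x / y / z (class c("atom_model", "data.frame")),
## optionally carrying a named character attribute `chain_labels` used to tag
## chains with roles such as "myosin-tail-crown2" or "titin-alpha".

#' Construct an atom model
#'
#' @param chain character vector of chain identifiers.
#' @param resno integer residue numbers (strictly increasing within a chain).
#' @param atom character atom names (e.g. "CA").
#' @param x,y,z coordinates in Angstrom.
#' @param chain_labels optional named character vector mapping chain ids to
#'   annotation labels.
#' @return an `atom_model` data.frame.
#' @export
atom_model <- function(chain, resno, atom, x, y, z, chain_labels = NULL) {
  m <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                  atom = as.character(atom),
                  x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                  stringsAsFactors = FALSE)
  class(m) <- c("atom_model", "data.frame")
  attr(m, "chain_labels") <- chain_labels
  validate_atom_model(m)
  m
}

validate_atom_model <- function(m) {
  if (nrow(m) == 0) stop("empty atom model")
  if (!all(is.finite(m$x) & is.finite(m$y) & is.finite(m$z)))
    stop("non-finite atom coordinates")
  key <- paste(m$chain, m$resno, m$atom, sep = "|")
  if (anyDuplicated(key))
    stop("duplicated (chain, residue, atom) triple: ",
         key[duplicated(key)][1])
  for (ch in unique(m$chain)) {
    r <- m$resno[m$chain == ch]
    if (is.unsorted(r, strictly = FALSE))
      stop("residue numbering not increasing in chain ", ch)
  }
  invisible(m)
}

#' Read an atomic model from mmCIF or PDB
#'
#' Thin wrapper over `bio3d::read.pdb()` / `bio3d::read.cif()` returning the
#' coordinate records as an [atom_model()]. Format `"auto"` dispatches on the
#' file extension (`.cif`/`.mmcif` vs anything else).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"mmcif"`, `"pdb"`.
#' @return an `atom_model`.
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    ## suppressWarnings: read.cif announces its beta status on every call
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path,
                                                            verbose = FALSE))
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("no ATOM/HETATM records in ", path)
  atom_model(chain = a$chain, resno = a$resno, atom = a$elety,
             x = a$x, y = a$y, z = a$z)
}

#' Write an atomic model to PDB or mmCIF
#'
#' PDB output uses `bio3d::write.pdb()`; mmCIF output writes a minimal
#' `atom_site` loop (coordinates to three decimals, the format's precision).
#'
#' @param model an `atom_model`.
#' @param path output path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  validate_atom_model(model)
  if (format == "pdb") {
    xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz, resno = model$resno,
                     chain = model$chain, elety = model$atom,
                     resid = "ALA")
  } else {
    ## canonical PDBx atom_site column order
    hdr <- c("data_model", "#",
             "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
    elem <- substr(gsub("[0-9]", "", model$atom), 1, 1)
    rows <- sprintf(
      "ATOM %d %s %s . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA %s %s 1",
      seq_len(nrow(model)), elem, model$atom, model$chain, model$resno,
      model$x, model$y, model$z, model$resno, model$chain, model$atom)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Select atoms as an ordered point set
#'
#' Returns the atoms matching the selection, sequence-ordered within each
#' chain, as a `point_set` data.frame with columns `id, x, y, z`. An empty
#' selection is returned as an empty set, but naming a chain absent from the
#' model is an error (listing the available chains).
#'
#' @param model an `atom_model`.
#' @param chain chain id(s) to keep, or `NULL` for all chains.
#' @param resno residue numbers to keep (vector or range), or `NULL` for all.
#' @param atom atom name(s) to keep (e.g. `"CA"`), or `NULL` for all.
#' @return a `point_set` data.frame.
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, atom = NULL) {
  validate_atom_model(model)
  if (!is.null(chain)) {
    missing <- setdiff(chain, unique(model$chain))
    if (length(missing))
      stop("unknown chain(s) ", paste(missing, collapse = ", "),
           "; available: ", paste(unique(model$chain), collapse = ", "))
  }
  keep <- rep(TRUE, nrow(model))
  if (!is.null(chain)) keep <- keep & model$chain %in% chain
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  if (!is.null(atom)) keep <- keep & model$atom %in% atom
  s <- model[keep, , drop = FALSE]
  s <- s[order(match(s$chain, unique(model$chain)), s$resno), , drop = FALSE]
  out <- data.frame(id = paste(s$chain, s$resno, s$atom, sep = "."),
                    x = s$x, y = s$y, z = s$z, stringsAsFactors = FALSE)
  class(out) <- c("point_set", "data.frame")
  out
}

point_matrix <- function(ps) {
  as.matrix(ps[, c("x", "y", "z"), drop = FALSE])
}

## ---- particle tables --------------------------------------------------

particle_columns <- c("filament_id", "segment_index", "x_A", "y_A", "z_A",
                      "rot_deg", "tilt_deg", "psi_deg")

empty_particle_table <- function() {
  data.frame(filament_id = character(), segment_index = integer(),
             x_A = numeric(), y_A = numeric(), z_A = numeric(),
             rot_deg = numeric(), tilt_deg = numeric(), psi_deg = numeric(),
             class = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

validate_particles <- function(p) {
  need <- setdiff(c("filament_id", "segment_index", "x_A", "y_A", "z_A"),
                  names(p))
  if (length(need)) stop("particle table missing column(s): ",
                         paste(need, collapse = ", "))
  pos <- as.matrix(p[, c("x_A", "y_A", "z_A")])
  if (nrow(p) && !all(is.finite(pos))) stop("non-finite particle position")
  for (col in c("rot_deg", "tilt_deg", "psi_deg"))
    if (!is.null(p[[col]])) p[[col]] <- normalize_angle(p[[col]])
  p
}

#' Read a particle table (native TSV or STAR)
#'
#' The native dialect is UTF-8 TSV with header columns
#' `filament_id segment_index x_A y_A z_A rot_deg tilt_deg psi_deg`
#' (plus optional `class`, `score`); positions are Angstrom, angles degrees
#' in the Z-Y-Z particle convention, segment indices 1-based. STAR import
#' reads `rlnCoordinateX/Y/Z` (pixels; a `pixel_size` in Angstrom per pixel is
#' then mandatory) and `rlnAngleRot/Tilt/Psi` (degrees, carried over
#' unchanged). Orientation columns may be absent; they are then `NA` and
#' operations that need orientations reject such records.
#'
#' @param path file path.
#' @param dialect `"native-tsv"` or `"star"`.
#' @param pixel_size Angstrom per pixel; required for the STAR dialect.
#' @return a particle data.frame (one row per record).
#' @export
read_particle_table <- function(path, dialect = c("native-tsv", "star"),
                                pixel_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "native-tsv") {
    p <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
    for (col in c("x_A", "y_A", "z_A", "rot_deg", "tilt_deg", "psi_deg")) {
      if (!is.null(p[[col]]) && !is.numeric(p[[col]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(p[[col]]))))[1]
        stop("non-numeric value in column ", col, " at row ", bad)
      }
    }
    p <- validate_particles(p)
    p$segment_index <- as.integer(p$segment_index)
    return(p)
  }
  ## minimal STAR reader: first loop_ block containing rlnCoordinate columns
  if (is.null(pixel_size) || pixel_size <= 0)
    stop("STAR import requires a positive pixel_size (Angstrom per pixel)")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lab_idx <- grep("^_rln", lines)
  if (!length(lab_idx)) stop("no _rln column labels found in STAR file")
  labels <- sub("\\s+#?\\d*$", "", lines[lab_idx])
  first <- max(lab_idx) + 1
  body <- lines[first:length(lines)]
  body <- body[!grepl("^(#|data_|loop_)", body) & nzchar(body)]
  if (!length(body)) stop("no data rows in STAR file")
  fields <- strsplit(body, "\\s+")
  ncol_star <- length(labels)
  ok <- vapply(fields, length, 1L) == ncol_star
  fields <- fields[ok]
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- sub("^_", "", labels)
  getnum <- function(nm) {
    if (!nm %in% names(tab)) return(NULL)
    v <- suppressWarnings(as.numeric(tab[[nm]]))
    if (anyNA(v)) stop("non-numeric value in STAR column ", nm,
                       " at row ", which(is.na(v))[1])
    v
  }
  cx <- getnum("rlnCoordinateX"); cy <- getnum("rlnCoordinateY")
  cz <- getnum("rlnCoordinateZ")
  if (is.null(cx) || is.null(cy) || is.null(cz))
    stop("STAR file lacks rlnCoordinateX/Y/Z")
  n <- length(cx)
  fil <- if ("rlnHelicalTubeID" %in% names(tab)) tab$rlnHelicalTubeID
         else rep("star", n)
  p <- data.frame(filament_id = as.character(fil),
                  segment_index = seq_len(n),
                  x_A = cx * pixel_size, y_A = cy * pixel_size,
                  z_A = cz * pixel_size, stringsAsFactors = FALSE)
  rot <- getnum("rlnAngleRot"); tilt <- getnum("rlnAngleTilt")
  psi <- getnum("rlnAnglePsi")
  p$rot_deg <- if (is.null(rot)) NA_real_ else rot
  p$tilt_deg <- if (is.null(tilt)) NA_real_ else tilt
  p$psi_deg <- if (is.null(psi)) NA_real_ else psi
  validate_particles(p)
}

#' Write a particle table in the native TSV dialect
#'
#' Round-trips bit-identically with [read_particle_table()] for the native
#' dialect (coordinates and angles printed with full precision).
#'
#' @param particles a particle data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(particles, path) {
  particles <- validate_particles(particles)
  utils::write.table(particles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- filament traces --------------------------------------------------

#' Construct a filament trace
#'
#' An ordered 3D polyline describing one traced filament. The point order is
#' the trace's own direction; `polarity = +1` declares that direction Z-ward
#' (away from the M band, increasing z), `-1` the reverse.
#'
#' @param filament_id token identifying the filament.
#' @param points n x 3 numeric matrix of Angstrom coordinates (n >= 2,
#'   consecutive points distinct).
#' @param polarity `+1` or `-1`.
#' @return a `filament_trace` object.
#' @export
filament_trace <- function(filament_id, points, polarity = 1L) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a trace needs at least 2 points")
  if (!all(is.finite(points))) stop("non-finite trace coordinates")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("consecutive trace points must be distinct")
  if (!polarity %in% c(1L, -1L)) stop("polarity must be +1 or -1")
  structure(list(filament_id = as.character(filament_id), points = points,
                 arc = c(0, cumsum(seg)), polarity = as.integer(polarity)),
            class = "filament_trace")
}

#' Total arc length of a trace
#' @param trace a `filament_trace`.
#' @return length in Angstrom.
#' @export
trace_length <- function(trace) {
  stopifnot(inherits(trace, "filament_trace"))
  trace$arc[length(trace$arc)]
}

## point and unit tangent at arc position s (clamped to [0, L])
trace_at <- function(trace, s) {
  arc <- trace$arc; pts <- trace$points
  L <- arc[length(arc)]
  s <- max(0, min(L, s))
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  i <- max(1, min(i, nrow(pts) - 1))
  t_ <- (s - arc[i]) / (arc[i + 1] - arc[i])
  p <- pts[i, ] + t_ * (pts[i + 1, ] - pts[i, ])
  tan <- unit_vec(pts[i + 1, ] - pts[i, ], "trace tangent")
  list(point = p, tangent = tan)
}

## arc position of the closest polyline point to x (projection)
trace_project <- function(trace, x) {
  pts <- trace$points; arc <- trace$arc
  n <- nrow(pts)
  best_d2 <- Inf; best_s <- 0
  for (i in seq_len(n - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    ab <- b - a
    t_ <- sum((x - a) * ab) / sum(ab * ab)
    t_ <- max(0, min(1, t_))
    p <- a + t_ * ab
    d2 <- sum((x - p)^2)
    if (d2 < best_d2) {
      best_d2 <- d2
      best_s <- arc[i] + t_ * (arc[i + 1] - arc[i])
    }
  }
  best_s
}
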