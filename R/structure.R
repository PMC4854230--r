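# core model types: atomic structures, residue segments, SSE annotations and
# rigid-body schemes, plus their file formats.

ATOM_COLS <- c("serial", "name", "element", "alt_loc", "res_name", "chain_id",
               "res_seq", "insertion_code", "x", "y", "z", "occupancy", "b_iso")

#' Construct a model structure
#'
#' A `model_structure` is an ordered table of atom records with a
#' chain/residue index.  Coordinates are in Angstrom in the map frame;
#' residue numbering follows the input file and insertion codes are
#' preserved.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `alt_loc`, `res_name`, `chain_id`, `res_seq`, `insertion_code`,
#'   `x`, `y`, `z`, `occupancy`, `b_iso`.
#' @param title optional title string.
#' @return an object of class `model_structure`.
#' @export
model_structure <- function(atoms, title = "") {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, ATOM_COLS]
  if (nrow(atoms) == 0L) stop("empty structure: no atom records")
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$name <- as.character(atoms$name)
  atoms$element <- as.character(atoms$element)
  atoms$alt_loc <- as.character(atoms$alt_loc)
  atoms$insertion_code <- as.character(atoms$insertion_code)
  atoms$res_seq <- as.integer(atoms$res_seq)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(is.na(atoms$occupancy))) atoms$occupancy[is.na(atoms$occupancy)] <- 1
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancy outside [0, 1]")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbol in atom record(s) ",
         paste(utils::head(which(!nzchar(atoms$element)), 5L), collapse = ", "))
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$insertion_code,
               atoms$name, atoms$alt_loc)
  if (anyDuplicated(key))
    stop("duplicate atom identity: ", key[duplicated(key)][1L])
  rownames(atoms) <- NULL
  x <- list(atoms = atoms, title = title)
  class(x) <- "model_structure"
  x$residue_index <- build_residue_index(x)
  x
}

## residue table in atom order: one row per (chain, res_seq, icode) span
build_residue_index <- function(structure) {
  a <- structure$atoms
  uid <- residue_uid(a$chain_id, a$res_seq, a$insertion_code)
  first <- !duplicated(uid)
  spans <- data.frame(chain_id = a$chain_id[first],
                      res_seq = a$res_seq[first],
                      insertion_code = a$insertion_code[first],
                      res_name = a$res_name[first],
                      uid = uid[first],
                      stringsAsFactors = FALSE)
  spans$first <- match(spans$uid, uid)
  spans$last <- nrow(a) - match(spans$uid, rev(uid)) + 1L
  ## the span must be contiguous, otherwise a residue's atoms are interleaved
  run <- rle(uid)
  if (length(run$values) != nrow(spans))
    stop("atoms of one residue are not contiguous in the file")
  rownames(spans) <- NULL
  spans
}

residue_uid <- function(chain_id, res_seq, insertion_code = "") {
  paste(chain_id, res_seq, insertion_code, sep = "|")
}

#' @export
print.model_structure <- function(x, ...) {
  cat(sprintf("model_structure: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms), nrow(x$residue_index),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' Atom coordinates as an n x 3 matrix
#' @param structure a `model_structure`.
#' @return numeric matrix with one row per atom.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param structure a `model_structure`.
#' @param value n x 3 numeric matrix.
#' @export
`coords<-` <- function(structure, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(structure$atoms),
            ncol(value) == 3L, all(is.finite(value)))
  structure$atoms$x <- value[, 1L]
  structure$atoms$y <- value[, 2L]
  structure$atoms$z <- value[, 3L]
  structure
}

#' Residue table of a structure
#' @param structure a `model_structure`.
#' @return data.frame with one row per residue, in file order.
#' @export
residues <- function(structure) structure$residue_index

## atom row indices of the listed residues (uids), in atom order
atom_rows_of_uids <- function(structure, uids) {
  ri <- structure$residue_index
  hit <- ri[ri$uid %in% uids, , drop = FALSE]
  if (nrow(hit) != length(unique(uids)))
    stop("residues not in structure: ",
         paste(setdiff(uids, ri$uid), collapse = ", "))
  sort(unlist(mapply(seq, hit$first, hit$last, SIMPLIFY = FALSE)))
}

## atom rows for a chain/res-range selection
atom_rows_of_range <- function(structure, chain_id, start, end) {
  ri <- structure$residue_index
  hit <- ri$chain_id == chain_id & ri$res_seq >= start & ri$res_seq <= end
  if (!any(hit)) return(integer())
  atom_rows_of_uids(structure, ri$uid[hit])
}

# ---------------------------------------------------------------------------
# residue segments

#' Define a residue segment
#'
#' A contiguous run of residues in one chain, the unit the local fit score
#' is computed over.
#'
#' @param chain_id chain identifier.
#' @param res_seq integer vector of residue numbers (ordered).
#' @param label free-text label, e.g. `"H2"` or `"loop 185-193"`.
#' @param allow_gaps permit non-contiguous numbering (off by default).
#' @export
residue_segment <- function(chain_id, res_seq, label = NULL,
                            allow_gaps = FALSE) {
  res_seq <- as.integer(res_seq)
  if (!length(res_seq)) stop("empty residue segment")
  if (is.unsorted(res_seq)) stop("segment residues must be ordered")
  if (!allow_gaps && length(res_seq) > 1L &&
      any(diff(res_seq) != 1L))
    stop("segment residues are not contiguous; pass allow_gaps = TRUE to permit")
  if (is.null(label))
    label <- sprintf("%s:%d-%d", chain_id, min(res_seq), max(res_seq))
  x <- list(chain_id = as.character(chain_id), res_seq = res_seq, label = label)
  class(x) <- "residue_segment"
  x
}

segment_uids <- function(segment, structure) {
  ri <- structure$residue_index
  hit <- ri$chain_id == segment$chain_id & ri$res_seq %in% segment$res_seq
  if (sum(hit) < length(unique(segment$res_seq)))
    stop("segment ", segment$label, " references residues absent from the structure")
  ri$uid[hit]
}

# ---------------------------------------------------------------------------
# SSE annotation

#' Construct a secondary-structure annotation
#'
#' @param segments data.frame with columns `kind` ("helix" or "strand"),
#'   `chain_id`, `start`, `end` (residue numbers, inclusive).
#' @param structure optional `model_structure` to validate against.
#' @export
sse_annotation <- function(segments, structure = NULL) {
  need <- c("kind", "chain_id", "start", "end")
  stopifnot(is.data.frame(segments), all(need %in% names(segments)))
  segments <- segments[, need]
  segments$kind <- as.character(segments$kind)
  segments$chain_id <- as.character(segments$chain_id)
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  if (nrow(segments)) {
    if (!all(segments$kind %in% c("helix", "strand")))
      stop("SSE kind must be 'helix' or 'strand'")
    if (any(segments$start > segments$end))
      stop("SSE with start > end")
    ## non-overlap within chains
    for (ch in unique(segments$chain_id)) {
      s <- segments[segments$chain_id == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
        stop("overlapping SSE segments in chain ", ch)
    }
    if (!is.null(structure)) {
      ri <- structure$residue_index
      for (i in seq_len(nrow(segments))) {
        want <- segments$start[i]:segments$end[i]
        have <- ri$res_seq[ri$chain_id == segments$chain_id[i]]
        if (!all(want %in% have))
          stop("SSE ", segments$chain_id[i], ":", segments$start[i], "-",
               segments$end[i], " references residues absent from the structure")
      }
    }
  }
  rownames(segments) <- NULL
  x <- list(segments = segments)
  class(x) <- "sse_annotation"
  x
}

#' Read an SSE annotation from a TSV file
#'
#' Columns: kind, chain, start, end (header optional).
#' @param path file path.
#' @param structure optional structure to validate against.
#' @export
read_sse_tsv <- function(path, structure = NULL) {
  raw <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (identical(tolower(as.character(raw[1L, 1L])), "kind"))
    raw <- raw[-1L, , drop = FALSE]
  if (ncol(raw) < 4L) stop("SSE TSV needs 4 columns: kind chain start end")
  sse_annotation(data.frame(kind = tolower(raw[[1L]]), chain_id = raw[[2L]],
                            start = as.integer(raw[[3L]]),
                            end = as.integer(raw[[4L]])), structure)
}

#' Extract SSE annotation from HELIX/SHEET records of a PDB file
#' @param path PDB file path.
#' @param structure optional structure to validate against.
#' @export
sse_from_pdb <- function(path, structure = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  seg <- list()
  if (length(pdb$helix$start))
    seg[[1L]] <- data.frame(kind = "helix", chain_id = pdb$helix$chain,
                            start = as.integer(pdb$helix$start),
                            end = as.integer(pdb$helix$end))
  if (length(pdb$sheet$start))
    seg[[2L]] <- data.frame(kind = "strand", chain_id = pdb$sheet$chain,
                            start = as.integer(pdb$sheet$start),
                            end = as.integer(pdb$sheet$end))
  segments <- if (length(seg)) do.call(rbind, seg) else
    data.frame(kind = character(), chain_id = character(),
               start = integer(), end = integer())
  sse_annotation(segments, structure)
}

## uids of residues covered by any SSE segment
sse_uids <- function(sses, structure) {
  ri <- structure$residue_index
  covered <- rep(FALSE, nrow(ri))
  seg <- sses$segments
  for (i in seq_len(nrow(seg)))
    covered <- covered | (ri$chain_id == seg$chain_id[i] &
                          ri$res_seq >= seg$start[i] & ri$res_seq <= seg$end[i])
  ri$uid[covered]
}

# ---------------------------------------------------------------------------
# rigid-body schemes

#' Construct a rigid-body scheme
#'
#' @param bodies list of rigid bodies; each body is a data.frame with columns
#'   `chain_id`, `start`, `end` (one row per residue range).
#' @param level one of `"ribfind_clusters"`, `"sse"`, `"all_atom"`.
#' @param structure optional structure to validate residue existence and
#'   body disjointness against.
#' @export
rigid_body_scheme <- function(bodies = list(),
                              level = c("ribfind_clusters", "sse", "all_atom"),
                              structure = NULL) {
  level <- match.arg(level)
  bodies <- lapply(bodies, function(b) {
    stopifnot(is.data.frame(b), all(c("chain_id", "start", "end") %in% names(b)))
    b$chain_id <- as.character(b$chain_id)
    b$start <- as.integer(b$start)
    b$end <- as.integer(b$end)
    if (any(b$start > b$end)) stop("rigid-body range with start > end")
    b[, c("chain_id", "start", "end")]
  })
  x <- list(bodies = bodies, level = level)
  class(x) <- "rigid_body_scheme"
  if (!is.null(structure)) validate_scheme(x, structure)
  x
}

## residue uids of one body
body_uids <- function(body, structure) {
  ri <- structure$residue_index
  uids <- character()
  for (i in seq_len(nrow(body))) {
    hit <- ri$chain_id == body$chain_id[i] &
      ri$res_seq >= body$start[i] & ri$res_seq <= body$end[i]
    want <- body$start[i]:body$end[i]
    have <- ri$res_seq[ri$chain_id == body$chain_id[i]]
    miss <- setdiff(want, have)
    if (length(miss))
      stop("rigid body references missing residues ", body$chain_id[i], ":",
           paste(utils::head(miss, 10L), collapse = ","))
    uids <- c(uids, ri$uid[hit])
  }
  unique(uids)
}

#' Validate a rigid-body scheme against a structure
#'
#' Checks that every referenced residue exists and that no residue belongs
#' to more than one body.
#' @param scheme a `rigid_body_scheme`.
#' @param structure a `model_structure`.
#' @return invisibly, the list of per-body residue uid vectors.
#' @export
validate_scheme <- function(scheme, structure) {
  uids <- lapply(scheme$bodies, body_uids, structure = structure)
  if (length(uids) > 1L) {
    all_u <- unlist(uids)
    dup <- unique(all_u[duplicated(all_u)])
    if (length(dup))
      stop("rigid bodies overlap on residues: ",
           paste(utils::head(sub("\\|$", "", gsub("\\|", ":", dup)), 12L),
                 collapse = ", "))
  }
  invisible(uids)
}

#' Read a rigid-body definition file
#'
#' Plain-text dialect: one rigid body per line, each line whitespace-separated
#' triples `start end chain` (several triples on one line form one body of
#' several ranges); blank lines and `#` comments ignored.  A `.json` file is
#' read as a list of bodies, each a list of `{"chain": , "start": , "end": }`
#' ranges.
#'
#' @param path file path.
#' @param structure `model_structure` the definitions must be valid for.
#' @param level level tag for the returned scheme.
#' @return a validated `rigid_body_scheme`.
#' @export
read_rigid_body_file <- function(path, structure,
                                 level = "ribfind_clusters") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    bodies <- lapply(raw, function(b)
      do.call(rbind, lapply(b, function(r)
        data.frame(chain_id = as.character(r$chain), start = as.integer(r$start),
                   end = as.integer(r$end)))))
  } else {
    lines <- readLines(path)
    lines <- trimws(sub("#.*", "", lines))
    lines <- lines[nzchar(lines)]
    bodies <- lapply(seq_along(lines), function(i) {
      tok <- strsplit(lines[i], "\\s+")[[1L]]
      if (length(tok) %% 3L != 0L)
        stop("rigid-body file line ", i, " is not a sequence of 'start end chain' triples: ",
             lines[i])
      k <- length(tok) / 3L
      data.frame(chain_id = tok[seq(3L, by = 3L, length.out = k)],
                 start = as.integer(tok[seq(1L, by = 3L, length.out = k)]),
                 end = as.integer(tok[seq(2L, by = 3L, length.out = k)]))
    })
  }
  rigid_body_scheme(bodies, level = level, structure = structure)
}

#' Write a rigid-body scheme in the plain-text dialect
#' @param scheme a `rigid_body_scheme`.
#' @param path output path.
#' @export
write_rigid_body_file <- function(scheme, path) {
  lines <- vapply(scheme$bodies, function(b)
    paste(sprintf("%d %d %s", b$start, b$end, b$chain_id), collapse = "  "),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# structure file I/O

#' Read an atomic structure from PDB or mmCIF
#'
#' All ATOM/HETATM records are kept.  Alternate locations are resolved by
#' keeping the highest-occupancy conformer (ties: first encountered).
#' Hydrogens are retained if present, never added.
#'
#' @param path file path.
#' @param dialect `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @return a `model_structure`.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  ## rm.alt = FALSE: alternate locations are resolved below by occupancy,
  ## not by bio3d's first-letter rule
  pdb <- tryCatch(
    suppressWarnings(
      if (dialect == "mmcif") bio3d::read.cif(path, verbose = FALSE,
                                              rm.alt = FALSE)
      else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", dialect, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty structure: ", path)
  blank <- function(v) { v <- as.character(v); v[is.na(v)] <- ""; v }
  atoms <- data.frame(serial = as.integer(a$eleno),
                      name = as.character(a$elety),
                      element = blank(a$elesy),
                      alt_loc = blank(a$alt),
                      res_name = as.character(a$resid),
                      chain_id = blank(a$chain),
                      res_seq = as.integer(a$resno),
                      insertion_code = blank(a$insert),
                      x = a$x, y = a$y, z = a$z,
                      occupancy = ifelse(is.na(a$o), 1, a$o),
                      b_iso = ifelse(is.na(a$b), 0, a$b),
                      stringsAsFactors = FALSE)
  ## infer missing element symbols from the atom name
  noel <- !nzchar(atoms$element)
  if (any(noel))
    atoms$element[noel] <- gsub("[^A-Za-z].*$|[a-z0-9'].*$", "",
                                sub("^[0-9]", "", atoms$name[noel]))
  atoms$element[!nzchar(atoms$element)] <-
    substr(gsub("[^A-Z]", "", toupper(atoms$name[!nzchar(atoms$element)])), 1L, 1L)
  ## alternate locations: keep the highest-occupancy conformer per atom identity
  ident <- paste(atoms$chain_id, atoms$res_seq, atoms$insertion_code, atoms$name)
  if (anyDuplicated(ident)) {
    keep <- rep(TRUE, nrow(atoms))
    for (g in unique(ident[duplicated(ident)])) {
      idx <- which(ident == g)
      best <- idx[which.max(atoms$occupancy[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  atoms$alt_loc <- ""
  model_structure(atoms, title = basename(path))
}

#' Write an atomic structure to PDB or mmCIF
#' @param structure a `model_structure`.
#' @param path output path.
#' @param dialect `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @export
write_structure <- function(structure, path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  a <- structure$atoms
  if (dialect == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$res_seq, resid = a$res_name, eleno = a$serial,
                     elety = a$name, chain = a$chain_id,
                     insert = ifelse(nzchar(a$insertion_code), a$insertion_code, NA),
                     alt = ifelse(nzchar(a$alt_loc), a$alt_loc, NA),
                     o = a$occupancy, b = a$b_iso, elesy = a$element)
  } else {
    ## canonical wwPDB atom_site column order
    hdr <- c("data_model", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
    dot <- function(v) ifelse(nzchar(v), v, ".")
    rows <- sprintf(
      "ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      a$serial, a$element, a$name, dot(a$alt_loc), a$res_name,
      dot(a$chain_id), a$res_seq, dot(a$insertion_code),
      a$x, a$y, a$z, a$occupancy, a$b_iso, a$res_seq, a$res_name,
      dot(a$chain_id), a$name)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}
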