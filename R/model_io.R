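# Standard three-letter codes of the 20 proteinogenic amino acids.
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Parse PDB-format coordinates into a structure object
#'
#' Reads fixed-column ATOM/HETATM records (PDB v3.3 layout) into a
#' `cdl_structure`: an atom table plus residue bookkeeping. The
#' crystallographic resolution is taken from the `REMARK   2 RESOLUTION.`
#' card when present. Atoms are grouped into residues in file order;
#' non-protein residues (waters, ligands, HETATM amino acids such as MSE)
#' are retained but flagged as non-standard.
#'
#' Multi-model files are refused unless `model` selects one explicitly:
#' silently picking a model hides errors upstream.
#'
#' @param text Character scalar (whole file) or character vector of lines.
#' @param model Integer model number to select from a multi-MODEL file, or
#'   `NULL` (the default) to require a single-model file.
#' @param id Structure identifier stored on the object.
#' @return An object of class `cdl_structure`: a list with elements
#'   `atoms` (data.frame: one row per atom with residue ordinal `resno`,
#'   `chain`, `seqnum`, `icode`, `resname`, `record`, `name`, `altloc`,
#'   `element`, `x`, `y`, `z`, `occ`, `b`), `residues` (data.frame: one
#'   row per residue with `resno`, `chain`, `seqnum`, `icode`, `resname`,
#'   `standard`, `het`), `resolution` (angstroms, `NA` if absent) and `id`.
#' @export
#' @examples
#' txt <- c(
#'   "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N",
#'   "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 10.00           C")
#' s <- parse_pdb(txt)
#' nrow(s$atoms)
parse_pdb <- function(text, model = NULL, id = "structure") {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }

  rec <- substr(lines, 1, 6)
  is_atom <- trimws(rec) %in% c("ATOM", "HETATM")
  model_lines <- which(trimws(rec) == "MODEL")

  keep <- is_atom
  if (length(model_lines) > 1L && is.null(model)) {
    stop("multi-model file (", length(model_lines),
         " MODEL records); select one explicitly with `model = <n>`",
         call. = FALSE)
  }
  if (length(model_lines) >= 1L && !is.null(model)) {
    model_nums <- suppressWarnings(as.integer(substr(lines[model_lines], 7, 14)))
    sel <- which(model_nums == model)
    if (length(sel) != 1L) {
      stop("model ", model, " not found in file", call. = FALSE)
    }
    endmdl <- which(trimws(rec) == "ENDMDL")
    lo <- model_lines[sel]
    hi <- endmdl[endmdl > lo]
    hi <- if (length(hi)) min(hi) else length(lines)
    keep <- is_atom & seq_along(lines) > lo & seq_along(lines) < hi
  }

  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    m <- regmatches(rem2[1],
                    regexpr("[0-9]+\\.?[0-9]*(?=[[:space:]]*ANGSTROM)",
                            rem2[1], perl = TRUE))
    if (length(m)) resolution <- as.numeric(m)
  }

  idx <- which(keep)
  if (!length(idx)) {
    return(new_structure(empty_atom_frame(), resolution, id))
  }
  al <- lines[idx]
  short <- which(nchar(al) < 54)
  if (length(short)) {
    stop("malformed ATOM/HETATM record at line ", idx[short[1]],
         ": fewer than 54 columns", call. = FALSE)
  }
  num <- function(from, to) suppressWarnings(as.numeric(substr(al, from, to)))
  x <- num(31, 38); y <- num(39, 46); z <- num(47, 54)
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad)) {
    stop("malformed coordinate field at line ", idx[bad[1]], call. = FALSE)
  }
  occ <- num(55, 60); b <- num(61, 66)
  occ[!is.finite(occ)] <- 1
  b[!is.finite(b)] <- 0

  atoms <- data.frame(
    record  = trimws(substr(al, 1, 6)),
    name    = trimws(substr(al, 13, 16)),
    altloc  = trimws(substr(al, 17, 17)),
    resname = trimws(substr(al, 18, 20)),
    chain   = trimws(substr(al, 22, 22)),
    seqnum  = suppressWarnings(as.integer(substr(al, 23, 26))),
    icode   = trimws(substr(al, 27, 27)),
    x = x, y = y, z = z, occ = occ, b = b,
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE
  )
  bad_seq <- which(is.na(atoms$seqnum))
  if (length(bad_seq)) {
    stop("malformed residue sequence number at line ", idx[bad_seq[1]],
         call. = FALSE)
  }
  # infer element from the atom name when the element column is absent
  noel <- !nzchar(atoms$element)
  atoms$element[noel] <- substr(gsub("[0-9']", "", atoms$name[noel]), 1, 1)

  new_structure(atoms, resolution, id)
}

empty_atom_frame <- function() {
  data.frame(record = character(), name = character(), altloc = character(),
             resname = character(), chain = character(), seqnum = integer(),
             icode = character(), x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), b = numeric(), element = character(),
             stringsAsFactors = FALSE)
}

new_structure <- function(atoms, resolution = NA_real_, id = "structure") {
  if (nrow(atoms)) {
    key <- paste(atoms$chain, atoms$seqnum, atoms$icode, atoms$resname,
                 sep = "\r")
    # residue ordinal increments whenever the residue key changes in file
    # order (the same key re-appearing later starts a new residue)
    changed <- c(TRUE, key[-1] != key[-length(key)])
    atoms$resno <- cumsum(changed)
  } else {
    atoms$resno <- integer()
  }
  first <- !duplicated(atoms$resno)
  residues <- data.frame(
    resno   = atoms$resno[first],
    chain   = atoms$chain[first],
    seqnum  = atoms$seqnum[first],
    icode   = atoms$icode[first],
    resname = atoms$resname[first],
    record  = atoms$record[first],
    stringsAsFactors = FALSE
  )
  residues$standard <- residues$resname %in% STANDARD_AA &
    residues$record == "ATOM"
  residues$het <- residues$record == "HETATM"
  structure(
    list(atoms = atoms, residues = residues,
         resolution = resolution, id = id),
    class = "cdl_structure"
  )
}

#' @export
print.cdl_structure <- function(x, ...) {
  cat("<cdl_structure> ", x$id, ": ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " atoms",
      if (is.finite(x$resolution)) paste0(", ", x$resolution, " A"), "\n",
      sep = "")
  invisible(x)
}

#' Read a PDB file from disk
#'
#' @param path Path to a PDB-format file.
#' @inheritParams parse_pdb
#' @return A `cdl_structure`; see [parse_pdb()].
#' @export
read_pdb <- function(path, model = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  parse_pdb(readLines(path, warn = FALSE), model = model, id = id)
}

#' Serialize a structure to PDB format
#'
#' Fixed-column output: coordinates to three decimals, occupancy and
#' B factor to two. `parse_pdb(write_pdb(s))` reproduces `s` up to that
#' serialization precision.
#'
#' @param s A `cdl_structure`.
#' @return Character vector of PDB lines.
#' @export
write_pdb <- function(s) {
  stopifnot(inherits(s, "cdl_structure"))
  a <- s$atoms
  long <- which(nchar(a$name) > 4)
  if (length(long)) {
    stop("atom name longer than 4 characters: '", a$name[long[1]], "'",
         call. = FALSE)
  }
  out <- character(0)
  if (is.finite(s$resolution)) {
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                          s$resolution))
  }
  if (nrow(a)) {
    # names of <4 chars start in column 14 unless they begin with a digit
    nm <- ifelse(nchar(a$name) >= 4 | grepl("^[0-9]", a$name),
                 formatC(a$name, width = -4),
                 paste0(" ", formatC(a$name, width = -3)))
    out <- c(out, sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$record, seq_len(nrow(a)) %% 100000L, nm, a$altloc, a$resname,
      a$chain, a$seqnum, a$icode, a$x, a$y, a$z, a$occ, a$b, a$element))
  }
  c(out, "END")
}

#' Segment a structure into peptide-bonded runs
#'
#' Consecutive residues i and i+1 belong to the same segment iff both have
#' the backbone atoms C(i) and N(i+1) and their distance is below the link
#' cutoff. The default 2.0 angstrom cutoff sits comfortably above the
#' ~1.33 angstrom peptide bond and below any non-bonded approach. A change
#' of chain identifier always breaks a segment, and non-protein residues
#' never join one.
#'
#' @param s A `cdl_structure`.
#' @param cutoff Maximum C--N distance (angstroms) treated as a bond.
#' @return List of integer vectors of residue ordinals (`resno`), each a
#'   contiguous peptide-bonded run.
#' @export
link_residues <- function(s, cutoff = 2.0) {
  stopifnot(inherits(s, "cdl_structure"))
  res <- s$residues
  # peptide-like residues: standard amino acids, plus anything carrying a
  # full N/CA/C backbone (covers HETATM amino acids such as MSE, which
  # join segments but later receive single-value targets only)
  has_bb <- vapply(res$resno, function(r) {
    nm <- s$atoms$name[s$atoms$resno == r]
    all(c("N", "CA", "C") %in% nm)
  }, logical(1))
  aa <- res[res$standard | res$resname %in% STANDARD_AA | has_bb,
            , drop = FALSE]
  aa <- aa[!aa$resname %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (!nrow(aa)) return(list())
  segs <- list()
  cur <- aa$resno[1]
  n <- nrow(aa)
  if (n > 1) {
    for (k in 2:n) {
      i <- aa$resno[k - 1]; j <- aa$resno[k]
      linked <- FALSE
      if (aa$chain[k] == aa$chain[k - 1]) {
        ci <- atom_xyz(s, i, "C")
        nj <- atom_xyz(s, j, "N")
        if (!is.null(ci) && !is.null(nj)) {
          linked <- distance(ci, nj) < cutoff
        }
      }
      if (linked) {
        cur <- c(cur, j)
      } else {
        segs[[length(segs) + 1L]] <- cur
        cur <- j
      }
    }
  }
  segs[[length(segs) + 1L]] <- cur
  segs
}

# Coordinates of one named atom of a residue, or NULL when absent.
# With a non-blank `altloc`, an atom carrying that altloc id is preferred
# and a blank-altloc atom is shared across conformers.
atom_xyz <- function(s, resno, name, altloc = "") {
  a <- s$atoms
  hit <- which(a$resno == resno & a$name == name &
                 (a$altloc == altloc | a$altloc == ""))
  if (!length(hit)) return(NULL)
  if (length(hit) > 1L) {
    exact <- hit[a$altloc[hit] == altloc]
    hit <- if (length(exact)) exact[1] else hit[1]
  }
  c(a$x[hit], a$y[hit], a$z[hit])
}

# Row index into s$atoms of one named atom, or NA (same altloc rule).
atom_row <- function(s, resno, name, altloc = "") {
  a <- s$atoms
  hit <- which(a$resno == resno & a$name == name &
                 (a$altloc == altloc | a$altloc == ""))
  if (!length(hit)) return(NA_integer_)
  if (length(hit) > 1L) {
    exact <- hit[a$altloc[hit] == altloc]
    hit <- if (length(exact)) exact[1] else hit[1]
  }
  hit[1]
}
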