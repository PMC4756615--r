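# Backbone internal-coordinate measurement: distances, bond angles,
# torsions (phi, psi, omega), trans/cis classification, and the
# restrained-parameter observation stream.

#' The restrained backbone parameter vocabulary
#'
#' Twelve parameters per residue: five bond lengths and seven bond angles.
#' Parameters written with `(-1)` or `(+1)` span a peptide bond; spanning
#' parameters are owned by the earlier residue of the pair.
#'
#' @return Data frame with columns `param`, `kind` (`"length"` or
#'   `"angle"`) and `needs_cb` (omitted for glycine).
#' @export
param_vocabulary <- function() {
  data.frame(
    param = c("N-CA", "CA-C", "C-O", "CA-CB", "C-N(+1)",
              "C(-1)-N-CA", "N-CA-C", "N-CA-CB", "CB-CA-C",
              "CA-C-O", "CA-C-N(+1)", "O-C-N(+1)"),
    kind = c(rep("length", 5), rep("angle", 7)),
    needs_cb = c(FALSE, FALSE, FALSE, TRUE, FALSE,
                 FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# atom composition of each parameter: "p"/"c"/"n" prefix = previous /
# central / next residue. Spanning parameters are expressed from the
# owning (earlier) residue: "C(-1)-N-CA" is C(i)-N(i+1)-CA(i+1) owned by i.
PARAM_ATOMS <- list(
  "N-CA"       = list(res = c("c", "c"),      atm = c("N", "CA")),
  "CA-C"       = list(res = c("c", "c"),      atm = c("CA", "C")),
  "C-O"        = list(res = c("c", "c"),      atm = c("C", "O")),
  "CA-CB"      = list(res = c("c", "c"),      atm = c("CA", "CB")),
  "C-N(+1)"    = list(res = c("c", "n"),      atm = c("C", "N")),
  "C(-1)-N-CA" = list(res = c("c", "n", "n"), atm = c("C", "N", "CA")),
  "N-CA-C"     = list(res = c("c", "c", "c"), atm = c("N", "CA", "C")),
  "N-CA-CB"    = list(res = c("c", "c", "c"), atm = c("N", "CA", "CB")),
  "CB-CA-C"    = list(res = c("c", "c", "c"), atm = c("CB", "CA", "C")),
  "CA-C-O"     = list(res = c("c", "c", "c"), atm = c("CA", "C", "O")),
  "CA-C-N(+1)" = list(res = c("c", "c", "n"), atm = c("CA", "C", "N")),
  "O-C-N(+1)"  = list(res = c("c", "c", "n"), atm = c("O", "C", "N"))
)

#' Euclidean distance between two points
#'
#' @param p,q Numeric 3-vectors (angstroms).
#' @return Distance in angstroms.
#' @export
distance <- function(p, q) {
  d <- p - q
  sqrt(sum(d * d))
}

#' Bond angle at a vertex
#'
#' Angle at `q` between the rays `q -> p` and `q -> r`.
#'
#' @param p,q,r Numeric 3-vectors (angstroms).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
bond_angle <- function(p, q, r) {
  u <- p - q
  v <- r - q
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("zero-length ray in bond_angle", call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Signed torsion angle of four points
#'
#' IUPAC convention: looking from `q` towards `r`, a clockwise rotation of
#' the far bond relative to the near bond is positive. The result lies in
#' the half-open range `[-180, 180)`; an exact trans arrangement is
#' reported as -180.
#'
#' @param p,q,r,s Numeric 3-vectors (angstroms).
#' @return Torsion in degrees in `[-180, 180)`.
#' @export
dihedral <- function(p, q, r, s) {
  b1 <- q - p
  b2 <- r - q
  b3 <- s - r
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1 * n1) == 0 || sum(n2 * n2) == 0) {
    stop("undefined torsion: collinear points", call. = FALSE)
  }
  m1 <- cross3(n1, b2 / sqrt(sum(b2 * b2)))
  xang <- sum(n1 * n2)
  yang <- sum(m1 * n2)
  ang <- -atan2(yang, xang) * 180 / pi
  wrap_180(ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# map any angle (degrees) into [-180, 180)
wrap_180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y >= 180] <- -180
  y
}

#' Classify a peptide-bond omega torsion
#'
#' `|omega| >= 150` is trans, `|omega| <= 30` is cis, anything between is
#' twisted. Conformation-dependent targets apply only across trans bonds;
#' cis and twisted linkages fall back to single-value targets.
#'
#' @param omega Torsion in degrees, or `NA`.
#' @param trans_min,cis_max Classification cutoffs in degrees.
#' @return `"trans"`, `"cis"`, `"twisted"`, or `NA` for undefined omega.
#' @export
classify_omega <- function(omega, trans_min = 150, cis_max = 30) {
  ifelse(is.na(omega), NA_character_,
         ifelse(abs(omega) >= trans_min, "trans",
                ifelse(abs(omega) <= cis_max, "cis", "twisted")))
}

#' Backbone torsions of a peptide segment
#'
#' For each residue i in the segment: phi(i) = C(i-1)-N(i)-CA(i)-C(i),
#' psi(i) = N(i)-CA(i)-C(i)-N(i+1), and omega of the bond i -> i+1 =
#' CA(i)-C(i)-N(i+1)-CA(i+1). The first residue has no phi; the last has
#' no psi and no omega. A missing backbone atom leaves the affected
#' torsions `NA` rather than raising an error.
#'
#' @param s A `cdl_structure`.
#' @param seg Integer vector of residue ordinals from [link_residues()].
#' @param altloc Conformer id; blank-altloc atoms are shared.
#' @return Data frame with one row per residue: `resno`, `phi`, `psi`,
#'   `omega` (torsion of the bond to the next residue), `omega_class`.
#' @export
backbone_torsions <- function(s, seg, altloc = "") {
  n <- length(seg)
  out <- data.frame(resno = seg, phi = NA_real_, psi = NA_real_,
                    omega = NA_real_, omega_class = NA_character_,
                    stringsAsFactors = FALSE)
  xyz <- lapply(seg, function(r) {
    list(N = atom_xyz(s, r, "N", altloc),
         CA = atom_xyz(s, r, "CA", altloc),
         C = atom_xyz(s, r, "C", altloc))
  })
  safe_dihedral <- function(a, b, c, d) {
    if (is.null(a) || is.null(b) || is.null(c) || is.null(d)) return(NA_real_)
    tryCatch(dihedral(a, b, c, d), error = function(e) NA_real_)
  }
  for (i in seq_len(n)) {
    if (i > 1) {
      out$phi[i] <- safe_dihedral(xyz[[i - 1]]$C, xyz[[i]]$N,
                                  xyz[[i]]$CA, xyz[[i]]$C)
    }
    if (i < n) {
      out$psi[i] <- safe_dihedral(xyz[[i]]$N, xyz[[i]]$CA,
                                  xyz[[i]]$C, xyz[[i + 1]]$N)
      out$omega[i] <- safe_dihedral(xyz[[i]]$CA, xyz[[i]]$C,
                                    xyz[[i + 1]]$N, xyz[[i + 1]]$CA)
    }
  }
  out$omega_class <- classify_omega(out$omega)
  out
}

# Conformer ids present among the backbone atoms of a segment ("" when
# the segment has no alternative locations).
segment_altlocs <- function(s, seg) {
  a <- s$atoms
  sel <- a$resno %in% seg & a$name %in% c("N", "CA", "C", "O", "CB")
  alts <- setdiff(unique(a$altloc[sel]), "")
  if (length(alts)) sort(alts) else ""
}

#' Enumerate backbone parameter instances with their atoms
#'
#' Internal workhorse shared by measurement, restraint generation and
#' validation: one row per measurable parameter instance, with the atom
#' row indices that define it and its current value. Inter-residue
#' parameters are owned by the earlier residue; CB parameters are omitted
#' for glycine. Instances are emitted per altloc conformer.
#'
#' @param s A `cdl_structure`.
#' @param seg Integer vector of residue ordinals.
#' @return Data frame: `resno` (owning residue), `altloc`, `param`,
#'   `kind`, `i1`..`i3` (rows of `s$atoms`; `i3` is `NA` for lengths),
#'   `value` (angstroms or degrees).
#' @keywords internal
backbone_param_atoms <- function(s, seg) {
  vocab <- param_vocabulary()
  rows <- list()
  alts <- segment_altlocs(s, seg)
  n <- length(seg)
  for (alt in alts) {
    for (i in seq_len(n)) {
      resno <- seg[i]
      resname <- s$residues$resname[s$residues$resno == resno]
      has_next <- i < n
      for (k in seq_len(nrow(vocab))) {
        pname <- vocab$param[k]
        spec <- PARAM_ATOMS[[pname]]
        if (vocab$needs_cb[k] && identical(resname, "GLY")) next
        if (any(spec$res == "n") && !has_next) next
        res_of <- ifelse(spec$res == "c", resno, seg[i + 1])
        ai <- mapply(function(rr, nm) atom_row(s, rr, nm, alt),
                     res_of, spec$atm)
        if (anyNA(ai)) next
        coords <- lapply(ai, function(j) {
          c(s$atoms$x[j], s$atoms$y[j], s$atoms$z[j])
        })
        val <- if (vocab$kind[k] == "length") {
          distance(coords[[1]], coords[[2]])
        } else {
          bond_angle(coords[[1]], coords[[2]], coords[[3]])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          resno = resno, altloc = alt, param = pname, kind = vocab$kind[k],
          i1 = ai[1], i2 = ai[2], i3 = if (length(ai) == 3) ai[3] else NA_integer_,
          value = val, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(resno = integer(), altloc = character(),
                      param = character(), kind = character(),
                      i1 = integer(), i2 = integer(), i3 = integer(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Measure the restrained backbone parameters of a segment
#'
#' Emits one observation per measurable parameter instance of the
#' vocabulary in [param_vocabulary()]: bond lengths N-CA, CA-C, C-O,
#' CA-CB and C-N(+1), and bond angles C(-1)-N-CA, N-CA-C, N-CA-CB,
#' CB-CA-C, CA-C-O, CA-C-N(+1) and O-C-N(+1). Missing atoms silently
#' skip the affected observation; glycine omits CB parameters.
#'
#' @inheritParams backbone_param_atoms
#' @return Data frame: `resno` (owning residue), `altloc`, `param`,
#'   `kind`, `value`.
#' @export
measure_backbone <- function(s, seg) {
  obs <- backbone_param_atoms(s, seg)
  obs[, c("resno", "altloc", "param", "kind", "value")]
}
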