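# Shared fixtures: small peptides, hand-written tables, and independent
# geometric oracles used across the module tests.

# independent torsion oracle: project the outer atoms onto the plane
# perpendicular to the q->r axis and take the signed (right-handed about
# the axis) angle between the projections
oracle_dihedral <- function(p, q, r, s) {
  e <- r - q
  e <- e / sqrt(sum(e * e))
  u <- (p - q) - sum((p - q) * e) * e
  v <- (s - r) - sum((s - r) * e) * e
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  a <- atan2(sum(e * cr), sum(u * v)) * 180 / pi
  if (a >= 180) a - 360 else a
}

# independent bond-angle oracle via atan2(|u x v|, u.v)
oracle_angle <- function(p, q, r) {
  u <- p - q
  v <- r - q
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr * cr)), sum(u * v)) * 180 / pi
}

# random proper rotation matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigid_transform <- function(pts, R, t) lapply(pts, function(p) R %*% p + t)

# a tiny two-bin table with hand-chosen values, used to exercise lookup
# fallback and target switching: General bin (-70,-50) and (-60,-50)
# differ in the N-CA-C mean; one Gly entry sits below min_count
toy_table <- function(min_count = 20) {
  entries <- data.frame(
    group = c("General", "General", "Gly", "General"),
    next_is_pro = c(FALSE, FALSE, FALSE, TRUE),
    phi_lo = c(-70, -60, -70, -70),
    psi_lo = c(-50, -50, -50, -50),
    param = "N-CA-C",
    mean = c(109.5, 112.5, 113.9, 110.7),
    sigma = c(1.1, 1.3, 1.5, 1.2),
    count = c(50, 40, 5, 30),
    stringsAsFactors = FALSE)
  cdl_table(entries = entries, min_count = min_count)
}

# peptide built exactly at the built-in single-value means
ideal_peptide <- function(n = 5, seq = rep("ALA", n), phi = -60, psi = -45,
                          omega = 180, resolution = NA_real_) {
  build_peptide(seq, phi = phi, psi = psi, omega = omega,
                resolution = resolution)
}

# a single-value slice tuned so that a uniform +0.5 degree shift of every
# constructible angle also shifts the implied O-C-N(+1) by exactly +0.5
# (the carbonyl O sits in the peptide plane, so the three angles at C sum
# to 360 when coplanar)
shift_svl_table <- function() {
  svl <- svl_defaults()
  i <- svl$group == "General" & svl$param == "O-C-N(+1)"
  meanO <- svl$mean[svl$group == "General" & svl$param == "CA-C-O"]
  meanN <- svl$mean[svl$group == "General" & svl$param == "CA-C-N(+1)"]
  svl$mean[i] <- 360 - meanO - meanN - 1.5
  cdl_table(svl = svl)
}

# internals of an all-ALA peptide with every constructible angle shifted
angles_plus <- function(n, delta, params = c("C(-1)-N-CA", "N-CA-C",
                                             "N-CA-CB", "CB-CA-C",
                                             "CA-C-O", "CA-C-N(+1)")) {
  base <- default_internals(rep("ALA", n))
  sel <- base$param %in% params
  base$value[sel] <- base$value[sel] + delta
  base[, c("resno", "param", "value")]
}

# random internal-coordinate spec for round-trip properties: torsions
# uniform, internal values jittered around their defaults
random_spec <- function(n = 3) {
  seqs <- sample(c("ALA", "GLY", "VAL", "LEU", "PRO", "SER"), n,
                 replace = TRUE)
  base <- default_internals(seqs)
  jitter_sd <- ifelse(base$param %in% c("N-CA", "CA-C", "C-O", "CA-CB",
                                        "C-N(+1)"), 0.015, 1.5)
  base$value <- base$value + rnorm(nrow(base), 0, jitter_sd)
  list(sequence = seqs,
       phi = runif(n, -180, 180),
       psi = runif(n, -180, 180),
       omega = runif(max(n - 1, 1), -180, 180),
       internals = base)
}
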