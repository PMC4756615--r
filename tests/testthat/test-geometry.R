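test_that("distance matches hand values and a sum-of-squares oracle", {
  expect_equal(distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(11)
  for (i in 1:200) {
    p <- rnorm(3, sd = 10); q <- rnorm(3, sd = 10)
    oracle <- sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2 + (p[3] - q[3])^2)
    expect_lt(abs(distance(p, q) - oracle), 1e-12)
  }
})

test_that("bond_angle matches hand values and the atan2 oracle", {
  expect_equal(bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(bond_angle(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)), 180)
  expect_error(bond_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")
  set.seed(12)
  for (i in 1:200) {
    p <- rnorm(3); q <- rnorm(3); r <- rnorm(3)
    expect_lt(abs(bond_angle(p, q, r) - oracle_angle(p, q, r)), 1e-9)
  }
})

test_that("dihedral reproduces planar trans/cis and the projection oracle", {
  p <- c(0, 0, 0); q <- c(1, 0, 0); r <- c(1.5, 1, 0)
  expect_equal(dihedral(p, q, r, c(2.5, 1, 0)), -180)  # trans, half-open wrap
  expect_equal(dihedral(p, q, r, c(1, 2, 0)), 0)       # cis
  set.seed(13)
  for (i in 1:200) {
    pts <- lapply(1:4, function(k) rnorm(3))
    d <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    o <- oracle_dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    dd <- abs(d - o)
    expect_lt(min(dd, 360 - dd), 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral recovers a constructively rotated torsion", {
  set.seed(14)
  for (i in 1:100) {
    p <- rnorm(3); q <- rnorm(3); r <- q + rnorm(3)
    e <- (r - q) / sqrt(sum((r - q)^2))
    u <- (p - q) - sum((p - q) * e) * e
    theta <- runif(1, -179, 179)
    th <- theta * pi / 180
    exu <- c(e[2] * u[3] - e[3] * u[2],
             e[3] * u[1] - e[1] * u[3],
             e[1] * u[2] - e[2] * u[1])
    s <- r + u * cos(th) + exu * sin(th) + runif(1, 0.2, 1) * e
    expect_lt(abs(dihedral(p, q, r, s) - theta), 1e-9)
  }
})

test_that("dihedral is symmetric under atom-order reversal and flips under mirror", {
  # the IUPAC torsion is unchanged by reading the four atoms backwards;
  # its sign flips only under an improper (mirror) transformation
  set.seed(15)
  for (i in 1:100) {
    pts <- lapply(1:4, function(k) rnorm(3))
    d1 <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    d2 <- dihedral(pts[[4]], pts[[3]], pts[[2]], pts[[1]])
    dd <- abs(d1 - d2) %% 360
    expect_lt(min(dd, 360 - dd), 1e-9)
    mir <- lapply(pts, function(p) c(-p[1], p[2], p[3]))
    d3 <- dihedral(mir[[1]], mir[[2]], mir[[3]], mir[[4]])
    dd <- abs(d1 + d3) %% 360
    expect_lt(min(dd, 360 - dd), 1e-9)
  }
})

test_that("measures are invariant under rigid-body transforms", {
  set.seed(16)
  for (i in 1:50) {
    pts <- lapply(1:4, function(k) rnorm(3, sd = 3))
    R <- random_rotation()
    t <- rnorm(3, sd = 20)
    tp <- rigid_transform(pts, R, t)
    expect_lt(abs(distance(pts[[1]], pts[[2]]) -
                    distance(tp[[1]], tp[[2]])), 1e-9)
    expect_lt(abs(bond_angle(pts[[1]], pts[[2]], pts[[3]]) -
                    bond_angle(tp[[1]], tp[[2]], tp[[3]])), 1e-9)
    d1 <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    d2 <- dihedral(tp[[1]], tp[[2]], tp[[3]], tp[[4]])
    dd <- abs(d1 - d2)
    expect_lt(min(dd, 360 - dd), 1e-9)
  }
})

test_that("omega classification follows the 150/30 degree cutoffs", {
  expect_equal(classify_omega(179.5), "trans")
  expect_equal(classify_omega(-165), "trans")
  expect_equal(classify_omega(-3), "cis")
  expect_equal(classify_omega(90), "twisted")
  expect_equal(classify_omega(c(150, 30, 149.9)),
               c("trans", "cis", "twisted"))
  expect_true(is.na(classify_omega(NA)))
})

test_that("backbone torsions round-trip the builder's inputs", {
  phi <- c(0, -60, -120, 70)
  psi <- c(-45, -40, 130, 40)
  omega <- c(180, 175, -170)
  s <- build_peptide(rep("ALA", 4), phi, psi, omega)
  tor <- backbone_torsions(s, link_residues(s)[[1]])
  expect_true(is.na(tor$phi[1]))
  expect_true(is.na(tor$psi[4]))
  expect_true(is.na(tor$omega[4]))
  expect_lt(max(abs(tor$phi[2:4] - phi[2:4])), 1e-4)
  expect_lt(max(abs(tor$psi[1:3] - psi[1:3])), 1e-4)
  expect_lt(max(abs(abs(tor$omega[1:3]) - abs(omega))), 1e-4)
  expect_equal(tor$omega_class[1:3], rep("trans", 3))
})

test_that("terminal residues carry only the defined torsions", {
  s <- build_peptide(rep("ALA", 2), psi = -45)
  tor <- backbone_torsions(s, link_residues(s)[[1]])
  expect_true(is.na(tor$phi[1]))
  expect_false(is.na(tor$psi[1]))
  expect_false(is.na(tor$phi[2]))
  expect_true(is.na(tor$psi[2]))
})

test_that("a missing CA only undefines the torsions that use it", {
  s <- build_peptide(rep("ALA", 4), phi = -60, psi = -45)
  s$atoms <- s$atoms[!(s$atoms$resno == 3 & s$atoms$name == "CA"), ]
  tor <- backbone_torsions(s, link_residues(s)[[1]])
  expect_true(is.na(tor$phi[3]))
  expect_true(is.na(tor$omega[2]))
  expect_false(is.na(tor$psi[2]))  # psi(2) needs N(3), which is present
  expect_false(is.na(tor$phi[2]))
  expect_false(is.na(tor$omega[1]))
})

test_that("measure_backbone emits the full vocabulary with glycine gaps", {
  s <- build_peptide(c("ALA", "GLY", "ALA"), phi = -60, psi = -45)
  obs <- measure_backbone(s, link_residues(s)[[1]])
  # intra parameters: 8 per non-Gly residue, 5 for Gly; spanning
  # parameters: 4 per linked pair, owned by the earlier residue
  expect_equal(nrow(obs), 8 + 5 + 8 + 2 * 4)
  expect_false(any(obs$param %in% c("CA-CB", "N-CA-CB", "CB-CA-C") &
                     obs$resno == 2))
  expect_equal(sum(obs$resno == 3 & obs$param == "C-N(+1)"), 0)
})

test_that("prescribed internal values are measured back exactly", {
  internals <- data.frame(resno = 2, param = "N-CA-C", value = 111.0)
  s <- build_peptide(rep("ALA", 3), phi = -60, psi = -45,
                     internals = internals)
  obs <- measure_backbone(s, link_residues(s)[[1]])
  v <- obs$value[obs$resno == 2 & obs$param == "N-CA-C"]
  expect_lt(abs(v - 111.0), 1e-4)
})

test_that("an isolated residue yields no spanning observations", {
  s <- build_peptide("ALA", psi = -45)
  obs <- measure_backbone(s, link_residues(s)[[1]])
  expect_false(any(grepl("\\(\\+1\\)|\\(-1\\)", obs$param)))
  expect_equal(nrow(obs), 8)
})

test_that("alternative locations give one observation stream per conformer", {
  s <- build_peptide(rep("ALA", 3), phi = -60, psi = -45)
  ca2 <- which(s$atoms$resno == 2 & s$atoms$name == "CA")
  dup <- s$atoms[ca2, ]
  s$atoms$altloc[ca2] <- "A"
  dup$altloc <- "B"
  dup$x <- dup$x + 0.05
  s$atoms <- rbind(s$atoms, dup)  # retains resno 2 on the copy
  obs <- measure_backbone(s, link_residues(s)[[1]])
  expect_setequal(unique(obs$altloc), c("A", "B"))
  a <- obs[obs$altloc == "A", ]
  b <- obs[obs$altloc == "B", ]
  expect_equal(nrow(a), nrow(b))
  # conformers differ exactly where CA(2) is involved
  ncac2 <- function(d) d$value[d$resno == 2 & d$param == "N-CA-C"]
  expect_gt(abs(ncac2(a) - ncac2(b)), 1e-3)
  co1 <- function(d) d$value[d$resno == 1 & d$param == "C-O"]
  expect_equal(co1(a), co1(b))
})
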