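# a table whose CDL entries in the helical bins differ visibly from the
# single-value slice, for gating and idealization tests
shifted_table <- function() {
  bins <- expand.grid(phi_lo = c(-80, -70, -60), psi_lo = c(-60, -50, -40))
  entries <- do.call(rbind, lapply(seq_len(nrow(bins)), function(i) {
    data.frame(group = "General", next_is_pro = FALSE,
               phi_lo = bins$phi_lo[i], psi_lo = bins$psi_lo[i],
               param = c("N-CA-C", "CA-C-O", "C(-1)-N-CA", "N-CA"),
               mean = c(109.0, 119.0, 122.8, 1.470),
               sigma = c(1.0, 1.2, 1.4, 0.012),
               count = 100, stringsAsFactors = FALSE)
  }))
  cdl_table(entries = entries)
}

test_that("restraint weights are exactly 1/sigma^2 and arity matches", {
  s <- build_peptide(rep("ALA", 4), phi = -63, psi = -45)
  rs <- generate_restraints(s, shifted_table(), mode = "cdl")
  r <- rs$restraints
  expect_equal(r$weight, 1 / r$sigma^2)
  expect_true(all(is.na(r$i3[r$kind == "length"])))
  expect_false(any(is.na(r$i3[r$kind == "angle"])))
})

test_that("trans gating selects CDL for interior residues only", {
  s <- build_peptide(rep("ALA", 4), phi = -63, psi = -45)
  rs <- generate_restraints(s, shifted_table(), mode = "cdl")
  r <- rs$restraints
  # interior residues with both flanks trans get the binned targets
  ncac <- r[r$param == "N-CA-C", ]
  expect_equal(ncac$source[ncac$resno %in% 2:3], rep("CDL", 2))
  expect_equal(ncac$mean[ncac$resno == 2], 109.0)
  # terminal residues have undefined phi or psi: single-value targets
  expect_equal(ncac$source[ncac$resno %in% c(1, 4)], rep("SVL", 2))
  # mode = svl forces single-value targets everywhere
  rs_svl <- generate_restraints(s, shifted_table(), mode = "svl")
  expect_true(all(rs_svl$restraints$source == "SVL"))
  expect_equal(rs_svl$restraints$mean[rs_svl$restraints$param == "N-CA-C"],
               rep(111.0, 4))
})

test_that("a cis peptide bond forces single-value targets locally only", {
  s <- build_peptide(rep("ALA", 6), phi = -63, psi = -45,
                     omega = c(180, 0, 180, 180, 180))
  rs <- generate_restraints(s, shifted_table(), mode = "cdl")
  r <- rs$restraints
  ncac <- r[r$param == "N-CA-C", ]
  # residues 2 and 3 flank the cis bond 2->3: forced SVL
  expect_equal(ncac$source[ncac$resno %in% 2:3], rep("SVL", 2))
  # spanning parameters across the cis bond (owned by residue 2) are SVL
  span <- r[r$resno == 2 & grepl("\\(\\+1\\)", r$param), ]
  expect_true(all(span$source == "SVL"))
  # distant interior residues are unaffected
  expect_equal(ncac$source[ncac$resno %in% 4:5], rep("CDL", 2))
})

test_that("the objective has closed-form values at and near the targets", {
  s <- build_peptide(rep("ALA", 4), phi = -63, psi = -45)
  tab <- cdl_table()
  rs <- generate_restraints(s, tab, mode = "svl")
  ev <- evaluate_restraints(s, rs)
  expect_lt(ev$E, 1e-18)  # built exactly at the single-value means

  # shifting one target mean by 2 sigma adds exactly overall_weight * 4
  rs2 <- rs
  rs2$overall_weight <- 2.5
  i <- which(rs2$restraints$param == "N-CA-C")[2]
  rs2$restraints$mean[i] <- rs2$restraints$mean[i] +
    2 * rs2$restraints$sigma[i]
  ev2 <- evaluate_restraints(s, rs2)
  expect_equal(ev2$E, 2.5 * 4, tolerance = 1e-9)
})

test_that("the objective matches a term-by-term brute-force sum", {
  set.seed(41)
  s <- perturb(build_peptide(rep("ALA", 5), phi = -63, psi = -45),
               0.05, seed = 8)
  rs <- generate_restraints(s, shifted_table(), mode = "cdl",
                            overall_weight = 1.7)
  ev <- evaluate_restraints(s, rs)
  r <- rs$restraints
  X <- cbind(s$atoms$x, s$atoms$y, s$atoms$z)
  E <- 0
  for (k in seq_len(nrow(r))) {
    v <- if (r$kind[k] == "length") {
      distance(X[r$i1[k], ], X[r$i2[k], ])
    } else {
      bond_angle(X[r$i1[k], ], X[r$i2[k], ], X[r$i3[k], ])
    }
    E <- E + 1.7 * ((v - r$mean[k]) / r$sigma[k])^2
  }
  expect_lt(abs(ev$E - E), 1e-9 * max(1, E))
})

test_that("the objective is invariant under rigid-body motion", {
  set.seed(42)
  s <- perturb(build_peptide(rep("ALA", 5), phi = -63, psi = -45),
               0.03, seed = 9)
  rs <- generate_restraints(s, shifted_table(), mode = "cdl")
  E0 <- evaluate_restraints(s, rs)$E
  R <- random_rotation()
  t <- rnorm(3, sd = 30)
  X <- cbind(s$atoms$x, s$atoms$y, s$atoms$z) %*% t(R)
  s$atoms$x <- X[, 1] + t[1]
  s$atoms$y <- X[, 2] + t[2]
  s$atoms$z <- X[, 3] + t[3]
  expect_lt(abs(evaluate_restraints(s, rs)$E - E0), 1e-9 * max(1, E0))
})

test_that("target updates are idempotent and track bin crossings", {
  tab <- toy_table()
  s <- build_peptide(rep("ALA", 3), phi = -63, psi = -45)
  rs <- generate_restraints(s, tab, mode = "cdl")
  rs2 <- update_targets(s, rs, tab)
  expect_equal(rs2$restraints, rs$restraints)

  # same topology rebuilt with phi across the bin boundary: the central
  # N-CA-C target moves to the neighbouring bin's value
  m <- function(st) {
    r <- generate_restraints(st, tab, mode = "cdl")$restraints
    r$mean[r$param == "N-CA-C" & r$resno == 2]
  }
  expect_equal(m(build_peptide(rep("ALA", 3), phi = -63, psi = -45)), 109.5)
  expect_equal(m(build_peptide(rep("ALA", 3), phi = -55, psi = -45)), 112.5)

  # omega driven from trans to cis switches the central residue to SVL
  s_cis <- build_peptide(rep("ALA", 3), phi = -63, psi = -45,
                         omega = c(180, 20))
  rs3 <- update_targets(s_cis, rs, tab)
  r3 <- rs3$restraints
  expect_equal(r3$source[r3$param == "N-CA-C" & r3$resno == 2], "SVL")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(43)
  s <- perturb(build_peptide(rep("ALA", 4), phi = -63, psi = -45),
               0.05, seed = 10)
  rs <- generate_restraints(s, shifted_table(), mode = "cdl")
  r <- rs$restraints
  atom_rows <- sort(unique(c(r$i1, r$i2, r$i3[!is.na(r$i3)])))
  terms <- cdlkit:::restraint_terms(rs, atom_rows)
  X <- cbind(s$atoms$x[atom_rows], s$atoms$y[atom_rows],
             s$atoms$z[atom_rows])
  res <- cdlkit:::restraint_objective(X, terms)
  h <- 1e-6
  num <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) {
    for (d in 1:3) {
      Xp <- X; Xp[i, d] <- Xp[i, d] + h
      Xm <- X; Xm[i, d] <- Xm[i, d] - h
      num[i, d] <- (cdlkit:::restraint_objective(Xp, terms, FALSE)$E -
                      cdlkit:::restraint_objective(Xm, terms, FALSE)$E) / (2 * h)
    }
  }
  scale <- max(abs(num), 1)
  expect_lt(max(abs(res$grad - num)) / scale, 1e-5)
})

test_that("a structure at its targets is a fixed point of idealization", {
  s <- build_peptide(rep("ALA", 4), phi = -63, psi = -45)
  res <- idealize(s, cdl_table(), mode = "svl", macrocycles = 2)
  expect_lt(max(res$trace$E), 1e-12)
  expect_lt(max(abs(res$structure$atoms$x - s$atoms$x)), 1e-8)
  expect_lt(max(abs(res$structure$atoms$y - s$atoms$y)), 1e-8)
})

test_that("idealization converges with a monotone within-macrocycle trace", {
  s0 <- build_peptide(rep("ALA", 10), phi = -63, psi = -45)
  s <- perturb(s0, 0.02, seed = 77)
  tab <- cdl_table()
  res <- idealize(s, tab, mode = "svl", macrocycles = 5)
  tr <- res$trace
  for (mc in unique(tr$macrocycle)) {
    E <- tr$E[tr$macrocycle == mc]
    expect_true(all(diff(E) <= 1e-10))
  }
  rs <- generate_restraints(res$structure, tab, mode = "svl")
  ev <- evaluate_restraints(res$structure, rs)
  ang <- ev$restraints$kind == "angle"
  expect_lt(sqrt(mean(ev$restraints$dev[ang]^2)), 0.1)
})

test_that("idealization under each library converges to its own targets", {
  tab <- shifted_table()
  s <- perturb(build_peptide(rep("ALA", 8), phi = -63, psi = -45),
               0.02, seed = 5)
  res_cdl <- idealize(s, tab, mode = "cdl", macrocycles = 4)
  res_svl <- idealize(s, tab, mode = "svl", macrocycles = 4)
  dev_vs <- function(st, mode) {
    rs <- generate_restraints(st, tab, mode = mode)
    ev <- evaluate_restraints(st, rs)
    sqrt(mean(ev$restraints$dev[ev$restraints$kind == "angle"]^2))
  }
  # each run sits at its own targets...
  expect_lt(dev_vs(res_cdl$structure, "cdl"), 0.05)
  expect_lt(dev_vs(res_svl$structure, "svl"), 0.05)
  # ...and the CDL-refined structure is measurably closer to the CDL
  # targets than to the single-value ones
  expect_gt(dev_vs(res_cdl$structure, "svl"),
            dev_vs(res_cdl$structure, "cdl") + 0.1)
})
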