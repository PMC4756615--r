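# Weighted harmonic geometry restraints: generation with trans-peptide
# gating, residual evaluation, per-macrocycle target refresh, and
# Cartesian idealization against the geometric objective
#   E = overall_weight * sum(((value - mean) / sigma)^2).

#' Generate weighted restraints for a structure
#'
#' One harmonic restraint per measurable backbone parameter instance.
#' Under `mode = "cdl"` a conformation-dependent target is looked up for
#' a parameter only when the owning residue has defined phi and psi and
#' every peptide bond involved -- the bonds defining those torsions,
#' which include any bond the parameter spans -- is trans; cis or twisted
#' linkages, terminal residues and non-standard residues fall back to the
#' single-value slice. `mode = "svl"` (the conformation-dependence
#' off-switch) forces single-value targets everywhere. Each restraint is
#' weighted `1 / sigma^2` from its own target.
#'
#' @param s A `cdl_structure`.
#' @param table A `cdl_table`.
#' @param mode `"cdl"` or `"svl"`.
#' @param overall_weight Scalar multiplier on the whole objective; the
#'   user-facing knob scaling all restraints at once.
#' @return Object of class `restraint_set`: a list with `restraints`
#'   (data.frame: `resno`, `altloc`, `param`, `kind`, atom rows
#'   `i1`..`i3`, `mean`, `sigma`, `source`, `weight`), `mode`,
#'   `overall_weight`. Atom rows index `s$atoms` of the generating
#'   structure.
#' @export
generate_restraints <- function(s, table, mode = c("cdl", "svl"),
                                overall_weight = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "cdl_structure"), inherits(table, "cdl_table"))
  segs <- link_residues(s)
  rows <- list()
  for (seg in segs) {
    obs <- backbone_param_atoms(s, seg)
    if (!nrow(obs)) next
    resnames <- s$residues$resname[match(seg, s$residues$resno)]
    standard <- s$residues$standard[match(seg, s$residues$resno)]
    for (alt in unique(obs$altloc)) {
      tor <- backbone_torsions(s, seg, altloc = alt)
      oa <- obs[obs$altloc == alt, , drop = FALSE]
      pos <- match(oa$resno, seg)
      tgt <- vector("list", nrow(oa))
      for (r in seq_len(nrow(oa))) {
        i <- pos[r]
        grp <- residue_group(resnames[i])
        if (is.na(grp)) grp <- "General"
        eligible <- mode == "cdl" && standard[i] &&
          !is.na(tor$phi[i]) && !is.na(tor$psi[i]) &&
          identical(tor$omega_class[i - 1], "trans") &&
          identical(tor$omega_class[i], "trans")
        if (eligible) {
          key <- assign_key(if (i > 1) resnames[i - 1] else NA,
                            resnames[i],
                            if (i < length(seg)) resnames[i + 1] else NA)
          tgt[[r]] <- cdl_lookup(table, key, tor$phi[i], tor$psi[i],
                                 oa$param[r], group = grp)
        } else {
          tgt[[r]] <- cdl_lookup(table, NULL, NA, NA, oa$param[r],
                                 group = grp)
        }
      }
      oa$mean <- vapply(tgt, `[[`, numeric(1), "mean")
      oa$sigma <- vapply(tgt, `[[`, numeric(1), "sigma")
      oa$source <- vapply(tgt, `[[`, character(1), "source")
      rows[[length(rows) + 1L]] <- oa
    }
  }
  restraints <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resno = integer(), altloc = character(), param = character(),
               kind = character(), i1 = integer(), i2 = integer(),
               i3 = integer(), value = numeric(), mean = numeric(),
               sigma = numeric(), source = character(),
               stringsAsFactors = FALSE)
  restraints$weight <- 1 / restraints$sigma^2
  restraints$value <- NULL
  rownames(restraints) <- NULL
  structure(list(restraints = restraints, mode = mode,
                 overall_weight = overall_weight),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  src <- table(x$restraints$source)
  cat("<restraint_set> ", nrow(x$restraints), " restraints (mode ",
      x$mode, "): ", paste(names(src), src, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate restraint residuals on current coordinates
#'
#' @param s The `cdl_structure` the restraints were generated from (atom
#'   rows must still be valid; coordinates may have moved).
#' @param rs A `restraint_set`.
#' @return List of class `residual_report`: `restraints` with added
#'   `value`, `dev` (value - mean, natural units) and `dev_sigma`
#'   (sigma units), and the total objective `E`.
#' @export
evaluate_restraints <- function(s, rs) {
  stopifnot(inherits(rs, "restraint_set"))
  r <- rs$restraints
  X <- cbind(s$atoms$x, s$atoms$y, s$atoms$z)
  val <- numeric(nrow(r))
  for (k in seq_len(nrow(r))) {
    if (r$kind[k] == "length") {
      val[k] <- distance(X[r$i1[k], ], X[r$i2[k], ])
    } else {
      val[k] <- bond_angle(X[r$i1[k], ], X[r$i2[k], ], X[r$i3[k], ])
    }
  }
  r$value <- val
  r$dev <- r$value - r$mean
  r$dev_sigma <- r$dev / r$sigma
  structure(list(restraints = r,
                 E = rs$overall_weight * sum(r$dev_sigma^2)),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat("<residual_report> ", nrow(x$restraints), " terms, E = ",
      format(x$E), "\n", sep = "")
  invisible(x)
}

#' Refresh restraint targets from current coordinates
#'
#' Recomputes phi/psi/omega from the current coordinates and re-runs the
#' lookup for every restraint: targets move to the new bin, weights track
#' the new sigmas, and parameters whose trans gating changed switch
#' between conformation-dependent and single-value sources. Idempotent
#' at fixed coordinates.
#'
#' @inheritParams evaluate_restraints
#' @param table A `cdl_table`.
#' @return A new `restraint_set` with the same mode and overall weight.
#' @export
update_targets <- function(s, rs, table) {
  generate_restraints(s, table, mode = rs$mode,
                      overall_weight = rs$overall_weight)
}

# --- vectorized objective and analytic gradient over a coordinate block ---

# terms: list(len = df(j1, j2, w, mu), ang = df(j1, j2, j3, w, mu)) with
# j* indexing rows of the movable-coordinate matrix; w includes the
# overall weight
restraint_terms <- function(rs, atom_rows) {
  r <- rs$restraints
  map <- match(c(r$i1, r$i2, r$i3), atom_rows)
  n <- nrow(r)
  j1 <- map[seq_len(n)]
  j2 <- map[n + seq_len(n)]
  j3 <- map[2 * n + seq_len(n)]
  islen <- r$kind == "length"
  list(
    len = data.frame(j1 = j1[islen], j2 = j2[islen],
                     w = rs$overall_weight * r$weight[islen],
                     mu = r$mean[islen]),
    ang = data.frame(j1 = j1[!islen], j2 = j2[!islen], j3 = j3[!islen],
                     w = rs$overall_weight * r$weight[!islen],
                     mu = r$mean[!islen])
  )
}

# scatter-add rows of C into G at (possibly duplicated) indices idx
scatter_add <- function(G, idx, C) {
  acc <- rowsum(C, idx)
  rows <- as.integer(rownames(acc))
  G[rows, ] <- G[rows, ] + acc
  G
}

restraint_objective <- function(X, terms, gradient = TRUE) {
  E <- 0
  G <- if (gradient) matrix(0, nrow(X), 3) else NULL
  L <- terms$len
  if (nrow(L)) {
    D <- X[L$j1, , drop = FALSE] - X[L$j2, , drop = FALSE]
    d <- sqrt(rowSums(D * D))
    dev <- d - L$mu
    E <- E + sum(L$w * dev^2)
    if (gradient) {
      coef <- 2 * L$w * dev / d
      G <- scatter_add(G, L$j1, coef * D)
      G <- scatter_add(G, L$j2, -coef * D)
    }
  }
  A <- terms$ang
  if (nrow(A)) {
    U <- X[A$j1, , drop = FALSE] - X[A$j2, , drop = FALSE]
    V <- X[A$j3, , drop = FALSE] - X[A$j2, , drop = FALSE]
    nu <- sqrt(rowSums(U * U))
    nv <- sqrt(rowSums(V * V))
    Uh <- U / nu
    Vh <- V / nv
    cosang <- pmin(1, pmax(-1, rowSums(Uh * Vh)))
    theta <- acos(cosang)
    dev <- theta * 180 / pi - A$mu
    E <- E + sum(A$w * dev^2)
    if (gradient) {
      sinang <- pmax(sqrt(1 - cosang^2), 1e-10)
      # d(theta)/dp1 and /dp3 in radians per angstrom
      G1 <- (cosang * Uh - Vh) / (nu * sinang)
      G3 <- (cosang * Vh - Uh) / (nv * sinang)
      coef <- 2 * A$w * dev * 180 / pi
      G <- scatter_add(G, A$j1, coef * G1)
      G <- scatter_add(G, A$j3, coef * G3)
      G <- scatter_add(G, A$j2, -coef * (G1 + G3))
    }
  }
  list(E = E, grad = G)
}

#' Idealize geometry against a restraint table
#'
#' Runs `macrocycles` outer iterations. At the start of each macrocycle
#' the restraint targets are regenerated from the current coordinates
#' (phi/psi re-binned, trans gating re-applied); within the macrocycle
#' the targets are frozen and the objective is minimized over the
#' Cartesian coordinates of the restrained atoms with analytic gradients
#' (L-BFGS, run in bounded chunks whose endpoints form the accepted
#' iterates of the trace).
#'
#' @param s A `cdl_structure`.
#' @param table A `cdl_table`.
#' @param mode `"cdl"` or `"svl"`.
#' @param macrocycles Number of target-refresh cycles (>= 1).
#' @param overall_weight Scalar multiplier on the objective.
#' @param max_chunks,chunk_iters Inner minimizer budget per macrocycle:
#'   up to `max_chunks` L-BFGS runs of `chunk_iters` iterations each.
#' @param etol Relative objective decrease below which the inner loop
#'   stops early.
#' @return List with `structure` (idealized), `trace` (data.frame
#'   `macrocycle`, `iter`, `E`: accepted objective values, `iter = 0`
#'   at the macrocycle start), and `E_final`.
#' @export
idealize <- function(s, table, mode = c("cdl", "svl"), macrocycles = 5,
                     overall_weight = 1, max_chunks = 40,
                     chunk_iters = 50, etol = 1e-12) {
  mode <- match.arg(mode)
  stopifnot(macrocycles >= 1)
  trace <- list()
  for (mc in seq_len(macrocycles)) {
    rs <- generate_restraints(s, table, mode = mode,
                              overall_weight = overall_weight)
    r <- rs$restraints
    if (!nrow(r)) stop("no restraints could be generated", call. = FALSE)
    atom_rows <- sort(unique(c(r$i1, r$i2, r$i3[!is.na(r$i3)])))
    terms <- restraint_terms(rs, atom_rows)
    X0 <- cbind(s$atoms$x[atom_rows], s$atoms$y[atom_rows],
                s$atoms$z[atom_rows])
    nmov <- nrow(X0)
    fn <- function(p) {
      res <- restraint_objective(matrix(p, nmov, 3), terms,
                                 gradient = FALSE)
      if (!is.finite(res$E)) stop("non-finite objective", call. = FALSE)
      res$E
    }
    gr <- function(p) {
      res <- restraint_objective(matrix(p, nmov, 3), terms)
      g <- as.vector(res$grad)
      if (any(!is.finite(g))) stop("non-finite gradient", call. = FALSE)
      g
    }
    par <- as.vector(X0)
    E <- fn(par)
    trace[[length(trace) + 1L]] <- data.frame(macrocycle = mc, iter = 0L,
                                              E = E)
    for (ch in seq_len(max_chunks)) {
      fit <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = chunk_iters,
                                         factr = 10))
      par <- fit$par
      Enew <- fit$value
      trace[[length(trace) + 1L]] <- data.frame(macrocycle = mc,
                                                iter = ch, E = Enew)
      converged <- fit$convergence == 0 ||
        (E - Enew) <= etol * max(E, 1e-300)
      E <- Enew
      if (converged) break
    }
    Xf <- matrix(par, nmov, 3)
    s$atoms$x[atom_rows] <- Xf[, 1]
    s$atoms$y[atom_rows] <- Xf[, 2]
    s$atoms$z[atom_rows] <- Xf[, 3]
  }
  list(structure = s, trace = do.call(rbind, trace), E_final = E)
}
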