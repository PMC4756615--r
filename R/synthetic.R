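# Synthetic backbones and corpora: build peptides at prescribed internal
# coordinates (natural-extension placement), simulate corpora whose bond
# geometry varies smoothly with conformation, and add coordinate noise.

# evaluate expr under a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Place atom D bonded to C: |C-D| = len, angle B-C-D = ang (deg), torsion
# A-B-C-D = tau (deg). Natural-extension reference frame construction.
place_atom <- function(a, b, c, len, ang, tau) {
  if (!is.finite(ang) || ang <= 0 || ang >= 180) {
    stop("impossible geometry: bond angle must lie strictly in (0, 180)",
         call. = FALSE)
  }
  ang <- ang * pi / 180
  tau <- tau * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n * n))
  if (nn < 1e-12) {
    stop("impossible geometry: collinear reference atoms", call. = FALSE)
  }
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- c(-len * cos(ang), len * sin(ang) * cos(tau),
          len * sin(ang) * sin(tau))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# construction parameters: everything except O-C-N(+1), which is implied
# by the placement of O in the peptide plane
BUILD_PARAMS <- c("N-CA", "CA-C", "C-O", "CA-CB", "C-N(+1)",
                  "C(-1)-N-CA", "N-CA-C", "N-CA-CB", "CB-CA-C",
                  "CA-C-O", "CA-C-N(+1)")

#' Default internal-coordinate values for a sequence
#'
#' One row per (residue, construction parameter), taken from the built-in
#' single-value means for the residue's group. The O-C-N(+1) angle is not
#' a construction parameter: the carbonyl O is placed in the peptide
#' plane, which implies it.
#'
#' @param sequence Character vector of three-letter residue codes.
#' @return Data frame with columns `resno`, `param`, `value`.
#' @export
default_internals <- function(sequence) {
  svl <- svl_defaults()
  grp <- residue_group(sequence)
  grp[is.na(grp)] <- "General"
  out <- do.call(rbind, lapply(seq_along(sequence), function(i) {
    pars <- BUILD_PARAMS
    if (sequence[i] == "GLY") {
      pars <- setdiff(pars, c("CA-CB", "N-CA-CB", "CB-CA-C"))
    }
    sel <- svl[svl$group == grp[i] & svl$param %in% pars, c("param", "mean")]
    data.frame(resno = i, param = sel$param, value = sel$mean,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Build a peptide from internal coordinates
#'
#' Places backbone atoms sequentially: each new atom is positioned from
#' three previously placed atoms at a prescribed bond length, bond angle
#' and torsion. The carbonyl O of residue i is placed at the CA-C-O angle
#' with torsion psi(i) + 180 (anti to the next amide N); CB is placed to
#' satisfy both the N-CA-CB and CB-CA-C angles exactly, on a fixed side
#' of the N-CA-C plane. With `noise_sigma = 0`, [measure_backbone()] on
#' the result reproduces every prescribed value and torsion exactly (to
#' numerical precision).
#'
#' @param sequence Character vector of three-letter residue codes.
#' @param phi,psi Per-residue torsions in degrees. `phi[1]` is unused;
#'   `psi` of the last residue orients its carbonyl O and must be given.
#' @param omega Torsions of the peptide bonds i -> i+1 (length
#'   `length(sequence) - 1`, or a scalar recycled).
#' @param internals Optional data frame `resno`, `param`, `value`
#'   overriding [default_internals()] entries.
#' @param noise_sigma Gaussian noise added to internal values: a single
#'   number applied to every parameter, or a named vector per parameter
#'   (units of the parameter). Torsions are not perturbed.
#' @param seed Integer seed controlling the noise draws; the caller's RNG
#'   state is preserved.
#' @param chain,id,resolution Metadata stored on the structure.
#' @return A `cdl_structure`.
#' @export
build_peptide <- function(sequence, phi = -60, psi = -45, omega = 180,
                          internals = NULL, noise_sigma = 0, seed = NULL,
                          chain = "A", id = "peptide",
                          resolution = NA_real_) {
  n <- length(sequence)
  stopifnot(n >= 1)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- if (n > 1) rep_len(omega, n - 1) else numeric(0)

  vals <- default_internals(sequence)
  if (!is.null(internals)) {
    key <- paste(vals$resno, vals$param)
    okey <- paste(internals$resno, internals$param)
    hit <- match(okey, key)
    if (anyNA(hit)) {
      stop("internals override names an unknown (resno, param): ",
           okey[which(is.na(hit))[1]], call. = FALSE)
    }
    vals$value[hit] <- internals$value
  }
  if (any(noise_sigma > 0)) {
    vals <- with_seed(seed, {
      ns <- if (is.null(names(noise_sigma))) {
        stats::setNames(rep_len(noise_sigma, length(BUILD_PARAMS)),
                        BUILD_PARAMS)
      } else noise_sigma
      sd <- ns[vals$param]
      sd[is.na(sd)] <- 0
      vals$value <- vals$value + stats::rnorm(nrow(vals), 0, sd)
      vals
    })
  }
  v <- function(i, param) {
    x <- vals$value[vals$resno == i & vals$param == param]
    if (!length(x)) stop("missing internal value: residue ", i, " ", param,
                         call. = FALSE)
    x[1]
  }

  N <- CA <- C <- O <- CB <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(v(1, "N-CA"), 0, 0)
  angNCAC <- v(1, "N-CA-C") * pi / 180
  C[[1]] <- CA[[1]] + v(1, "CA-C") * c(-cos(angNCAC), sin(angNCAC), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                               v(i, "C-N(+1)"), v(i, "CA-C-N(+1)"), psi[i])
      CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]],
                                v(i + 1, "N-CA"), v(i, "C(-1)-N-CA"),
                                omega[i])
      C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]],
                               v(i + 1, "CA-C"), v(i + 1, "N-CA-C"),
                               phi[i + 1])
    }
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         v(i, "C-O"), v(i, "CA-C-O"), psi[i] + 180)
    if (sequence[i] != "GLY") {
      CB[[i]] <- place_cb(N[[i]], CA[[i]], C[[i]],
                          v(i, "CA-CB"), v(i, "N-CA-CB"), v(i, "CB-CA-C"))
    }
  }

  rows <- list()
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O", if (sequence[i] != "GLY") "CB")
    xyz <- list(N[[i]], CA[[i]], C[[i]], O[[i]],
                if (sequence[i] != "GLY") CB[[i]])
    xyz <- xyz[!vapply(xyz, is.null, logical(1))]
    for (k in seq_along(nm)) {
      rows[[length(rows) + 1L]] <- data.frame(
        record = "ATOM", name = nm[k], altloc = "", resname = sequence[i],
        chain = chain, seqnum = i, icode = "",
        x = xyz[[k]][1], y = xyz[[k]][2], z = xyz[[k]][3],
        occ = 1, b = 10, element = substr(nm[k], 1, 1),
        stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows), resolution = resolution, id = id)
}

# CB satisfying both angles N-CA-CB (alpha) and CB-CA-C (beta) exactly;
# the out-of-plane component takes a fixed sign so construction is
# deterministic
place_cb <- function(N, CA, C, len, alpha, beta) {
  u <- N - CA; u <- u / sqrt(sum(u * u))
  v <- C - CA; v <- v / sqrt(sum(v * v))
  G <- sum(u * v)
  ca <- cos(alpha * pi / 180)
  cb <- cos(beta * pi / 180)
  den <- 1 - G^2
  if (den < 1e-12) {
    stop("impossible geometry: N, CA, C collinear", call. = FALSE)
  }
  a <- (ca - G * cb) / den
  b <- (cb - G * ca) / den
  c2 <- 1 - a^2 - b^2 - 2 * a * b * G
  w <- a * u + b * v
  if (c2 > 0) {
    nrm <- cross3(u, v)
    nrm <- nrm / sqrt(sum(nrm * nrm))
    w <- w + sqrt(c2) * nrm
  }
  CA + len * w / sqrt(sum(w * w))
}

#' Specification of a simulated structure corpus
#'
#' Describes a corpus whose backbone bond geometry varies with
#' conformation in a known way, so the table builder's parameter recovery
#' can be tested against ground truth.
#'
#' @param n_structures Number of peptides.
#' @param length_range Inclusive range of chain lengths to sample.
#' @param sequence_pool Residue codes sampled uniformly per position.
#' @param phi_psi Sampling scheme: `list(type = "uniform", phi_range=,
#'   psi_range=)` or `list(type = "clusters", centers = 2-column matrix,
#'   sd =, weights =)` (Ramachandran-like mixture, wrapped into
#'   `[-180, 180)`).
#' @param mu Named list of `function(phi, psi)` giving the true
#'   conformation-dependent mean of a parameter; parameters not listed
#'   use their single-value default mean.
#' @param noise_sigma Named numeric vector of per-parameter Gaussian
#'   noise (or scalar for all construction parameters).
#' @param omega Peptide-bond torsion used throughout (degrees).
#' @param resolution Resolution assigned to each structure: scalar,
#'   vector recycled over structures, or `function(n)` returning one
#'   value per structure.
#' @param seed Integer seed; all corpus randomness flows from it.
#' @return List of class `corpus_spec`.
#' @export
corpus_spec <- function(n_structures = 50,
                        length_range = c(6, 10),
                        sequence_pool = c("ALA", "LEU", "SER"),
                        phi_psi = list(type = "clusters",
                                       centers = rbind(c(-63, -43),
                                                       c(-120, 130)),
                                       sd = 12, weights = c(0.5, 0.5)),
                        mu = list(),
                        noise_sigma = 0,
                        omega = 180,
                        resolution = 0.9,
                        seed = 1) {
  spec <- list(n_structures = n_structures, length_range = length_range,
               sequence_pool = sequence_pool, phi_psi = phi_psi, mu = mu,
               noise_sigma = noise_sigma, omega = omega,
               resolution = resolution, seed = seed)
  class(spec) <- "corpus_spec"
  spec
}

sample_phi_psi <- function(scheme, n) {
  if (identical(scheme$type, "uniform")) {
    phi <- stats::runif(n, scheme$phi_range[1], scheme$phi_range[2])
    psi <- stats::runif(n, scheme$psi_range[1], scheme$psi_range[2])
  } else if (identical(scheme$type, "clusters")) {
    k <- sample.int(nrow(scheme$centers), n, replace = TRUE,
                    prob = scheme$weights)
    sd <- rep_len(scheme$sd, nrow(scheme$centers))
    phi <- stats::rnorm(n, scheme$centers[k, 1], sd[k])
    psi <- stats::rnorm(n, scheme$centers[k, 2], sd[k])
  } else {
    stop("unknown phi/psi sampling scheme: ", scheme$type, call. = FALSE)
  }
  data.frame(phi = wrap_180(phi), psi = wrap_180(psi))
}

#' Simulate a corpus of peptides with known geometry
#'
#' Each structure is built with [build_peptide()]; per-residue internal
#' values are drawn as `mu_param(phi, psi) + Normal(0, noise_sigma)`.
#' The manifest records every torsion draw and every internal value
#' actually built, so any downstream observation can be traced to its
#' ground truth.
#'
#' @param spec A [corpus_spec()].
#' @return List with `structures` (list of `cdl_structure`) and
#'   `manifest`: a list of `torsions` (`id`, `resno`, `phi`, `psi`,
#'   `omega`) and `values` (`id`, `resno`, `param`, `mu`, `value`).
#' @export
simulate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    nres_all <- sample(seq(spec$length_range[1], spec$length_range[2]),
                       spec$n_structures, replace = TRUE)
    res_fun <- spec$resolution
    resolutions <- if (is.function(res_fun)) {
      res_fun(spec$n_structures)
    } else {
      rep_len(res_fun, spec$n_structures)
    }
    structures <- vector("list", spec$n_structures)
    tors <- vector("list", spec$n_structures)
    valrec <- vector("list", spec$n_structures)
    ns <- spec$noise_sigma
    if (is.null(names(ns))) {
      ns <- stats::setNames(rep_len(ns, length(BUILD_PARAMS)), BUILD_PARAMS)
    }
    for (j in seq_len(spec$n_structures)) {
      nres <- nres_all[j]
      sid <- sprintf("synth%04d", j)
      seq_j <- sample(spec$sequence_pool, nres, replace = TRUE)
      pp <- sample_phi_psi(spec$phi_psi, nres)
      omega_j <- rep_len(spec$omega, max(nres - 1, 1))
      base <- default_internals(seq_j)
      base$mu <- base$value
      for (pn in names(spec$mu)) {
        sel <- base$param == pn
        base$mu[sel] <- spec$mu[[pn]](pp$phi[base$resno[sel]],
                                      pp$psi[base$resno[sel]])
      }
      sd <- ns[base$param]
      sd[is.na(sd)] <- 0
      base$value <- base$mu + stats::rnorm(nrow(base), 0, sd)
      # O sits in the peptide plane, so O-C-N(+1) is implied by the two
      # flanking angles; record the derived truth so every measured
      # observation has a manifest entry
      if (nres > 1) {
        orow <- base[base$param == "CA-C-O" & base$resno < nres, ]
        nrow_ <- base[base$param == "CA-C-N(+1)" & base$resno < nres, ]
        stopifnot(identical(orow$resno, nrow_$resno))
        base <- rbind(base, data.frame(
          resno = orow$resno, param = "O-C-N(+1)",
          value = 360 - orow$value - nrow_$value,
          mu = 360 - orow$mu - nrow_$mu,
          stringsAsFactors = FALSE))
      }
      built <- base[base$param %in% BUILD_PARAMS, ]
      structures[[j]] <- build_peptide(
        seq_j, phi = pp$phi, psi = pp$psi, omega = omega_j,
        internals = built[, c("resno", "param", "value")],
        id = sid, resolution = resolutions[j])
      tors[[j]] <- data.frame(id = sid, resno = seq_len(nres),
                              phi = pp$phi, psi = pp$psi,
                              omega = c(omega_j[seq_len(max(nres - 1, 0))],
                                        NA_real_)[seq_len(nres)],
                              stringsAsFactors = FALSE)
      valrec[[j]] <- cbind(id = sid,
                           base[, c("resno", "param", "mu", "value")])
    }
    list(structures = structures,
         manifest = list(torsions = do.call(rbind, tors),
                         values = do.call(rbind, valrec)))
  })
}

#' Add isotropic Gaussian coordinate noise to a structure
#'
#' @param s A `cdl_structure`.
#' @param noise Standard deviation of the per-axis displacement
#'   (angstroms); 0 returns the structure unchanged.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return The perturbed `cdl_structure`.
#' @export
perturb <- function(s, noise, seed = NULL) {
  stopifnot(inherits(s, "cdl_structure"), noise >= 0)
  if (noise == 0) return(s)
  with_seed(seed, {
    n <- nrow(s$atoms)
    s$atoms$x <- s$atoms$x + stats::rnorm(n, 0, noise)
    s$atoms$y <- s$atoms$y + stats::rnorm(n, 0, noise)
    s$atoms$z <- s$atoms$z + stats::rnorm(n, 0, noise)
    s
  })
}
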