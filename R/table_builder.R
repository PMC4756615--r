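# Empirical derivation of a conformation-dependent table from a corpus of
# structures: corpus filtering, per-cell accumulation, outlier trimming,
# and finalization into a cdl_table.

#' Configuration for the empirical table builder
#'
#' @param resolution_cutoff Keep structures solved at this resolution
#'   (angstroms) or better; structures without resolution metadata are
#'   excluded rather than assumed high-resolution.
#' @param max_b Maximum backbone B factor (angstrom^2) for a residue to
#'   contribute.
#' @param min_occ Minimum backbone occupancy.
#' @param width Phi/psi bin width in degrees.
#' @param min_count Minimum final per-cell observation count for a binned
#'   entry to be emitted.
#' @param sigma_floor_angle,sigma_floor_length Lower clamps on emitted
#'   sigmas (degrees / angstroms).
#' @param trim_k Sigma multiple beyond which values are trimmed as
#'   outliers.
#' @param trim_rounds Number of trimming passes (0 disables trimming).
#' @return List of class `builder_config`.
#' @export
builder_config <- function(resolution_cutoff = 1.0, max_b = 30,
                           min_occ = 1.0, width = 10, min_count = 20,
                           sigma_floor_angle = 0.5,
                           sigma_floor_length = 0.005,
                           trim_k = 4, trim_rounds = 2) {
  cfg <- list(resolution_cutoff = resolution_cutoff, max_b = max_b,
              min_occ = min_occ, width = width, min_count = min_count,
              sigma_floor_angle = sigma_floor_angle,
              sigma_floor_length = sigma_floor_length,
              trim_k = trim_k, trim_rounds = trim_rounds)
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x >= 0,
                       logical(1))))
  class(cfg) <- "builder_config"
  cfg
}

#' Filter a corpus for table building
#'
#' Keeps structures solved at the resolution cutoff or better, and within
#' them the residues whose backbone atoms (N, CA, C, O, and CB where
#' present) all have occupancy at or above `min_occ`, B factor at or
#' below `max_b` and a single (blank) alternative location, and whose
#' existing flanking peptide bonds are trans.
#'
#' @param structures List of `cdl_structure`.
#' @param cfg A [builder_config()].
#' @return List with one element per accepted structure:
#'   `list(structure =, segments =, accepted = <residue ordinals>)`, plus
#'   an attribute `rejected_structures` counting resolution rejections.
#' @export
filter_corpus <- function(structures, cfg = builder_config()) {
  out <- list()
  rejected <- 0L
  for (s in structures) {
    if (!is.finite(s$resolution) || s$resolution > cfg$resolution_cutoff) {
      rejected <- rejected + 1L
      next
    }
    segs <- link_residues(s)
    accepted <- integer(0)
    for (seg in segs) {
      # judge trans gating on an existing conformer so that a residue
      # with alternative locations does not spuriously reject its
      # neighbours (it is itself excluded by the altloc rule below)
      tor <- backbone_torsions(s, seg, altloc = segment_altlocs(s, seg)[1])
      for (i in seq_along(seg)) {
        r <- seg[i]
        sel <- s$atoms$resno == r &
          s$atoms$name %in% c("N", "CA", "C", "O", "CB")
        if (!any(sel)) next
        if (any(s$atoms$occ[sel] < cfg$min_occ)) next
        if (any(s$atoms$b[sel] > cfg$max_b)) next
        if (any(nzchar(s$atoms$altloc[sel]))) next
        prev_ok <- i == 1 || identical(tor$omega_class[i - 1], "trans")
        next_ok <- i == length(seg) || identical(tor$omega_class[i], "trans")
        if (is.na(prev_ok) || is.na(next_ok) || !prev_ok || !next_ok) next
        accepted <- c(accepted, r)
      }
    }
    out[[length(out) + 1L]] <- list(structure = s, segments = segs,
                                    accepted = accepted)
  }
  attr(out, "rejected_structures") <- rejected
  out
}

# Observation frame for one filtered structure: measured parameters of
# accepted residues joined with the owning residue's key and phi/psi bin.
corpus_observations <- function(filtered, cfg) {
  rows <- list()
  for (f in filtered) {
    s <- f$structure
    for (seg in f$segments) {
      tor <- backbone_torsions(s, seg)
      obs <- measure_backbone(s, seg)
      obs <- obs[obs$resno %in% f$accepted & obs$altloc == "", , drop = FALSE]
      if (!nrow(obs)) next
      pos <- match(obs$resno, seg)
      resnames <- s$residues$resname[match(seg, s$residues$resno)]
      prev <- ifelse(pos > 1, resnames[pos - 1], NA)
      nxt <- ifelse(pos < length(seg), resnames[pos + 1], NA)
      grp <- residue_group(resnames[pos])
      ti <- match(obs$resno, tor$resno)
      keep <- !is.na(grp) & !is.na(tor$phi[ti]) & !is.na(tor$psi[ti])
      if (!any(keep)) next
      obs <- obs[keep, , drop = FALSE]
      ti <- ti[keep]; pos <- pos[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        id = s$id,
        group = grp[keep],
        next_is_pro = !is.na(nxt[keep]) & nxt[keep] == "PRO",
        phi_lo = cfg$width * floor(tor$phi[ti] / cfg$width),
        psi_lo = cfg$width * floor(tor$psi[ti] / cfg$width),
        param = obs$param, kind = obs$kind, value = obs$value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(), group = character(),
                      next_is_pro = logical(), phi_lo = numeric(),
                      psi_lo = numeric(), param = character(),
                      kind = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Streaming per-cell accumulation of observations
#'
#' One-pass numerically stable (Welford) mean/variance update per
#' (key, bin, parameter) cell. Results are independent of observation
#' order to well below 1e-9.
#'
#' @param obs Data frame with columns `group`, `next_is_pro`, `phi_lo`,
#'   `psi_lo`, `param`, `value` (as produced internally from
#'   [measure_backbone()] plus key/bin assignment).
#' @return Data frame of cell statistics: the cell columns plus `count`,
#'   `mean`, `M2` (sum of squared deviations from the running mean).
#' @export
accumulate_observations <- function(obs) {
  cell <- paste(obs$group, obs$next_is_pro, obs$phi_lo, obs$psi_lo,
                obs$param, sep = "|")
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(cell)) {
    st <- get0(cell[i], envir = env)
    if (is.null(st)) st <- c(n = 0, mean = 0, M2 = 0)
    st["n"] <- st["n"] + 1
    delta <- obs$value[i] - st["mean"]
    st["mean"] <- st["mean"] + delta / st["n"]
    st["M2"] <- st["M2"] + delta * (obs$value[i] - st["mean"])
    assign(cell[i], st, envir = env)
  }
  keys <- ls(env)
  if (!length(keys)) {
    return(data.frame(group = character(), next_is_pro = logical(),
                      phi_lo = numeric(), psi_lo = numeric(),
                      param = character(), count = integer(),
                      mean = numeric(), M2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  stats <- do.call(rbind, lapply(keys, function(k) get(k, envir = env)))
  data.frame(group = parts[, 1], next_is_pro = as.logical(parts[, 2]),
             phi_lo = as.numeric(parts[, 3]),
             psi_lo = as.numeric(parts[, 4]), param = parts[, 5],
             count = as.integer(stats[, "n"]), mean = stats[, "mean"],
             M2 = stats[, "M2"], stringsAsFactors = FALSE)
}

# k-sigma trimming of a value vector: `rounds` passes of removing values
# beyond k sample standard deviations from the sample mean
trim_values <- function(v, k, rounds) {
  for (r in seq_len(rounds)) {
    if (length(v) < 3) break
    m <- mean(v)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) break
    keep <- abs(v - m) <= k * s
    if (all(keep)) break
    v <- v[keep]
  }
  v
}

#' Finalize accumulated observations into a restraint table
#'
#' Per cell: apply `trim_rounds` passes of `trim_k`-sigma outlier
#' trimming (on the retained per-cell value lists), then emit cells whose
#' final count reaches `min_count`, with sigma clamped up to the floor
#' for its unit. The single-value slice is the conformation-pooled
#' per-group mean/sigma over all accepted observations (same trimming),
#' backfilled from the built-in defaults for (group, parameter) pairs the
#' corpus never observed.
#'
#' @param obs Observation frame (see [accumulate_observations()]).
#' @param cfg A [builder_config()].
#' @param provenance Free-text note stored in the table metadata.
#' @return A `cdl_table`.
#' @export
finalize_table <- function(obs, cfg = builder_config(),
                           provenance = "empirical") {
  if (!nrow(obs)) stop("empty corpus: no accepted observations",
                       call. = FALSE)
  vocab <- param_vocabulary()
  floor_of <- function(param) {
    ifelse(vocab$kind[match(param, vocab$param)] == "angle",
           cfg$sigma_floor_angle, cfg$sigma_floor_length)
  }
  cell <- paste(obs$group, obs$next_is_pro, obs$phi_lo, obs$psi_lo,
                obs$param, sep = "|")
  groups <- split(obs$value, cell)
  rows <- lapply(sort(names(groups)), function(k) {
    v <- trim_values(groups[[k]], cfg$trim_k, cfg$trim_rounds)
    if (length(v) < cfg$min_count) return(NULL)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(group = parts[1], next_is_pro = as.logical(parts[2]),
               phi_lo = as.numeric(parts[3]), psi_lo = as.numeric(parts[4]),
               param = parts[5], mean = mean(v),
               sigma = max(stats::sd(v), floor_of(parts[5])),
               count = length(v), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  entries <- if (length(rows)) do.call(rbind, rows) else NULL

  # pooled single-value slice per (group, param)
  pool_key <- paste(obs$group, obs$param, sep = "|")
  pools <- split(obs$value, pool_key)
  svl_rows <- lapply(sort(names(pools)), function(k) {
    v <- trim_values(pools[[k]], cfg$trim_k, cfg$trim_rounds)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    sdv <- if (length(v) > 1) stats::sd(v) else 0
    data.frame(group = parts[1], param = parts[2], mean = mean(v),
               sigma = max(sdv, floor_of(parts[2])),
               stringsAsFactors = FALSE)
  })
  svl <- do.call(rbind, svl_rows)
  defaults <- svl_defaults()
  miss <- !paste(defaults$group, defaults$param) %in%
    paste(svl$group, svl$param)
  svl <- rbind(svl, defaults[miss, , drop = FALSE])

  cdl_table(entries = entries, svl = svl, width = cfg$width,
            min_count = cfg$min_count,
            sigma_floor_angle = cfg$sigma_floor_angle,
            sigma_floor_length = cfg$sigma_floor_length,
            provenance = provenance)
}

#' Build an empirical restraint table from a corpus
#'
#' The full codification pipeline: filter structures and residues
#' ([filter_corpus()]), measure backbone parameters of accepted residues
#' with their keys and phi/psi bins, and finalize per-cell statistics
#' into a `cdl_table` ([finalize_table()]).
#'
#' @param structures List of `cdl_structure` with resolution metadata.
#' @param cfg A [builder_config()].
#' @param provenance Free-text note stored in the table metadata.
#' @return A `cdl_table`.
#' @export
build_cdl_table <- function(structures, cfg = builder_config(),
                            provenance = "empirical") {
  filtered <- filter_corpus(structures, cfg)
  obs <- corpus_observations(filtered, cfg)
  finalize_table(obs, cfg, provenance = provenance)
}
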