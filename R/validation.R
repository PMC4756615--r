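# Validation of structures against conformation-dependent and
# single-value targets: per-category RMSDs, sigma-outlier counts, and
# resolution-binned cohort summaries.

#' Validation configuration
#'
#' @param outlier_k Sigma multiple beyond which a deviation is counted as
#'   an outlier (default 6).
#' @param resolution_bin_width Width of resolution bins (angstroms).
#' @param min_bin_n Minimum number of structures for a resolution bin to
#'   be reported with confidence; smaller bins are flagged.
#' @return List of class `validation_config`.
#' @export
validation_config <- function(outlier_k = 6, resolution_bin_width = 0.1,
                              min_bin_n = 50) {
  stopifnot(outlier_k > 0, resolution_bin_width > 0, min_bin_n > 0)
  structure(list(outlier_k = outlier_k,
                 resolution_bin_width = resolution_bin_width,
                 min_bin_n = min_bin_n),
            class = "validation_config")
}

BACKBONE_BONDS <- c("N-CA", "CA-C", "C-O", "C-N(+1)")

rmsd_of <- function(x) if (length(x)) sqrt(mean(x^2)) else NA_real_

#' Validate a structure against both target libraries
#'
#' Every backbone observation is scored twice: against its
#' conformation-dependent target (the gated lookup, falling back to
#' single values where conformation dependence does not apply) and
#' against its single-value target. Reported per library: bond-angle and
#' bond-length RMSDs, the same restricted to the observations whose
#' targets actually differ between the two libraries ("CDL-unique"), and
#' counts of observations deviating by more than `outlier_k` target
#' sigmas of the library being validated against.
#'
#' @param s A `cdl_structure`.
#' @param table A `cdl_table`.
#' @param cfg A [validation_config()].
#' @return List of class `validation_report`: `obs` (per-observation
#'   frame with both targets and deviations), `stats` (data.frame, one
#'   row per library: `library`, `rmsd_angles_all`,
#'   `rmsd_angles_cdl_unique`, `rmsd_bonds_all`, `rmsd_bonds_backbone`,
#'   `n_angle_outliers`, `n_bond_outliers`, `n_angles`, `n_bonds`,
#'   `n_angles_cdl_unique`), and `resolution`.
#' @export
validate_structure <- function(s, table, cfg = validation_config()) {
  cdl_rs <- generate_restraints(s, table, mode = "cdl")
  svl_rs <- generate_restraints(s, table, mode = "svl")
  cdl <- evaluate_restraints(s, cdl_rs)$restraints
  svl <- evaluate_restraints(s, svl_rs)$restraints
  stopifnot(nrow(cdl) == nrow(svl))
  obs <- data.frame(
    resno = cdl$resno, altloc = cdl$altloc, param = cdl$param,
    kind = cdl$kind, value = cdl$value,
    cdl_mean = cdl$mean, cdl_sigma = cdl$sigma, cdl_source = cdl$source,
    svl_mean = svl$mean, svl_sigma = svl$sigma,
    stringsAsFactors = FALSE)
  obs$cdl_dev <- obs$value - obs$cdl_mean
  obs$svl_dev <- obs$value - obs$svl_mean
  obs$cdl_unique <- obs$cdl_mean != obs$svl_mean |
    obs$cdl_sigma != obs$svl_sigma

  stat_row <- function(libname, dev, sigma) {
    ang <- obs$kind == "angle"
    bnd <- obs$kind == "length"
    bb <- bnd & obs$param %in% BACKBONE_BONDS
    data.frame(
      library = libname,
      rmsd_angles_all = rmsd_of(dev[ang]),
      rmsd_angles_cdl_unique = rmsd_of(dev[ang & obs$cdl_unique]),
      rmsd_bonds_all = rmsd_of(dev[bnd]),
      rmsd_bonds_backbone = rmsd_of(dev[bb]),
      n_angle_outliers = sum(abs(dev[ang]) > cfg$outlier_k * sigma[ang]),
      n_bond_outliers = sum(abs(dev[bnd]) > cfg$outlier_k * sigma[bnd]),
      n_angles = sum(ang),
      n_bonds = sum(bnd),
      n_angles_cdl_unique = sum(ang & obs$cdl_unique),
      stringsAsFactors = FALSE)
  }
  stats <- rbind(stat_row("CDL", obs$cdl_dev, obs$cdl_sigma),
                 stat_row("SVL", obs$svl_dev, obs$svl_sigma))
  structure(list(obs = obs, stats = stats, resolution = s$resolution,
                 id = s$id),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$id, "\n", sep = "")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Library-to-library validation deltas
#'
#' Differences `SVL - CDL` of each RMSD statistic and outlier count of a
#' [validate_structure()] report: positive values mean the structure sits
#' closer to its conformation-dependent targets than to the single-value
#' ones.
#'
#' @param report A `validation_report`.
#' @return Named numeric vector of deltas.
#' @export
compare_libraries <- function(report) {
  st <- report$stats
  svl <- st[st$library == "SVL", ]
  cdl <- st[st$library == "CDL", ]
  cols <- c("rmsd_angles_all", "rmsd_angles_cdl_unique", "rmsd_bonds_all",
            "rmsd_bonds_backbone", "n_angle_outliers", "n_bond_outliers")
  a <- unlist(svl[cols])
  b <- unlist(cdl[cols])
  out <- ifelse(is.na(a) & is.na(b), 0, a - b)  # both undefined: no change
  names(out) <- cols
  out
}

#' Summarize validation reports by resolution bin
#'
#' Half-open resolution bins of `resolution_bin_width`; per bin, the
#' arithmetic mean over structures of each per-structure statistic. Bins
#' holding fewer than `min_bin_n` structures are flagged low-confidence;
#' reports without resolution metadata are excluded and counted.
#'
#' @param reports List of `validation_report`.
#' @param cfg A [validation_config()].
#' @return List with `summary` (data.frame: `res_lo`, `library`,
#'   per-statistic means, `n_structures`, `flagged`) and
#'   `n_no_resolution`.
#' @export
summarize_by_resolution <- function(reports, cfg = validation_config()) {
  res <- vapply(reports, function(r) as.numeric(r$resolution), numeric(1))
  no_res <- !is.finite(res)
  reports <- reports[!no_res]
  res <- res[!no_res]
  if (!length(reports)) {
    return(list(summary = NULL, n_no_resolution = sum(no_res)))
  }
  w <- cfg$resolution_bin_width
  lo <- w * floor(res / w)
  stats <- do.call(rbind, lapply(seq_along(reports), function(i) {
    cbind(res_lo = lo[i], reports[[i]]$stats)
  }))
  cols <- c("rmsd_angles_all", "rmsd_angles_cdl_unique", "rmsd_bonds_all",
            "rmsd_bonds_backbone", "n_angle_outliers", "n_bond_outliers")
  key <- interaction(stats$res_lo, stats$library, drop = TRUE)
  parts <- split(stats, key)
  summary <- do.call(rbind, lapply(parts, function(p) {
    out <- data.frame(res_lo = p$res_lo[1], library = p$library[1],
                      stringsAsFactors = FALSE)
    for (cl in cols) out[[cl]] <- mean(p[[cl]], na.rm = TRUE)
    out$n_structures <- nrow(p)
    out$flagged <- nrow(p) < cfg$min_bin_n
    out
  }))
  summary <- summary[order(summary$res_lo, summary$library), ]
  rownames(summary) <- NULL
  list(summary = summary, n_no_resolution = sum(no_res))
}
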