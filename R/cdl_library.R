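# The lookup core: residue-class keys from amino-acid triplets, phi/psi
# binning, target retrieval with fallback to single-value (SVL) defaults,
# and the on-disk table format.

RESIDUE_GROUPS <- c("Gly", "Pro", "IleVal", "General")

#' Residue class of an amino acid
#'
#' Four classes drive the conformation-dependent tables: `Gly` (glycine,
#' no CB), `Pro` (proline, ring-constrained N), `IleVal` (beta-branched
#' isoleucine/valine) and `General` (all other standard residues).
#'
#' @param resname Three-letter residue code.
#' @return One of `"Gly"`, `"Pro"`, `"IleVal"`, `"General"`, or `NA` for a
#'   non-standard residue.
#' @export
residue_group <- function(resname) {
  ifelse(!resname %in% STANDARD_AA, NA_character_,
         ifelse(resname == "GLY", "Gly",
                ifelse(resname == "PRO", "Pro",
                       ifelse(resname %in% c("ILE", "VAL"), "IleVal",
                              "General"))))
}

#' Conformation-dependent lookup key for a residue triplet
#'
#' The key carries the residue class of the central residue and whether
#' the following residue is proline (which perturbs the C-N(+1) region).
#' The preceding residue enters only through the spanning parameters it
#' owns, so it does not appear in the key.
#'
#' @param prev Residue name of position i-1, or `NA`/`NULL` when absent.
#' @param cur Residue name of the central position i (must be standard).
#' @param nxt Residue name of position i+1, or `NA`/`NULL` when absent.
#' @return List with `group` and `next_is_pro`, or `NULL` when `cur` is
#'   non-standard (signalling SVL-only treatment).
#' @export
assign_key <- function(prev, cur, nxt) {
  g <- residue_group(cur)
  if (is.na(g)) return(NULL)
  nip <- !is.null(nxt) && !is.na(nxt) && identical(unname(nxt), "PRO")
  list(group = g, next_is_pro = nip)
}

#' Phi/psi bin of a backbone conformation
#'
#' Half-open square bins tiling `[-180, 180)^2`: the bin of an angle x is
#' `width * floor(x / width)`.
#'
#' @param phi,psi Backbone torsions in degrees; `NA` for undefined.
#' @param width Bin width in degrees (default 10).
#' @return List with `phi_lo`, `psi_lo`, `width`, or `NULL` when either
#'   angle is undefined.
#' @export
bin_of <- function(phi, psi, width = 10) {
  if (is.na(phi) || is.na(psi)) return(NULL)
  list(phi_lo = width * floor(phi / width),
       psi_lo = width * floor(psi / width),
       width = width)
}

#' Construct a conformation-dependent restraint table
#'
#' @param entries Data frame with columns `group`, `next_is_pro`
#'   (logical), `phi_lo`, `psi_lo`, `param`, `mean`, `sigma`, `count`.
#' @param svl Data frame with columns `group`, `param`, `mean`, `sigma`:
#'   the conformation-independent fallback, which must cover every
#'   (group, param) pair so lookup is total (glycine CB parameters are
#'   exempt: they are never measured).
#' @param width Bin width in degrees.
#' @param min_count Minimum observation count for a binned entry to be
#'   served.
#' @param sigma_floor_angle,sigma_floor_length Lower clamps on served
#'   sigmas (degrees / angstroms).
#' @param provenance Free-text origin note stored in the metadata.
#' @return Object of class `cdl_table`.
#' @export
cdl_table <- function(entries = NULL, svl = svl_defaults(), width = 10,
                      min_count = 20, sigma_floor_angle = 0.5,
                      sigma_floor_length = 0.005, provenance = "") {
  if (is.null(entries)) {
    entries <- data.frame(group = character(), next_is_pro = logical(),
                          phi_lo = numeric(), psi_lo = numeric(),
                          param = character(), mean = numeric(),
                          sigma = numeric(), count = integer(),
                          stringsAsFactors = FALSE)
  }
  tab <- structure(
    list(entries = entries, svl = svl,
         meta = list(width = width, min_count = min_count,
                     sigma_floor_angle = sigma_floor_angle,
                     sigma_floor_length = sigma_floor_length,
                     provenance = provenance)),
    class = "cdl_table"
  )
  check_table(tab)
  tab
}

check_table <- function(tab) {
  e <- tab$entries
  vocab <- param_vocabulary()
  if (nrow(e)) {
    bad <- which(!e$param %in% vocab$param)
    if (length(bad)) stop("unknown parameter in table: ", e$param[bad[1]],
                          call. = FALSE)
    if (any(e$sigma <= 0)) {
      stop("table entry with sigma <= 0 (row ",
           which(e$sigma <= 0)[1], ")", call. = FALSE)
    }
    w <- tab$meta$width
    off <- which(e$phi_lo %% w != 0 | e$psi_lo %% w != 0 |
                   e$phi_lo < -180 | e$phi_lo >= 180 |
                   e$psi_lo < -180 | e$psi_lo >= 180)
    if (length(off)) {
      stop("table entry bin not aligned to the ", w,
           " degree tiling (row ", off[1], ")", call. = FALSE)
    }
  }
  svl <- tab$svl
  if (any(svl$sigma <= 0)) {
    stop("SVL entry with sigma <= 0", call. = FALSE)
  }
  need <- expand.grid(group = RESIDUE_GROUPS, param = vocab$param,
                      stringsAsFactors = FALSE)
  need <- need[!(need$group == "Gly" &
                   need$param %in% vocab$param[vocab$needs_cb]), ]
  have <- paste(svl$group, svl$param)
  miss <- need[!paste(need$group, need$param) %in% have, , drop = FALSE]
  if (nrow(miss)) {
    stop("incomplete SVL slice; missing (group, param): ",
         paste(paste(miss$group, miss$param, sep = "/"), collapse = ", "),
         call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.cdl_table <- function(x, ...) {
  cat("<cdl_table> ", nrow(x$entries), " binned entries, bin width ",
      x$meta$width, " deg, min_count ", x$meta$min_count, "\n", sep = "")
  invisible(x)
}

#' Built-in single-value restraint defaults
#'
#' Conventional conformation-independent target values and sigmas for the
#' backbone parameter vocabulary, one row per (residue group, parameter).
#' These are generic textbook-style values for protein backbones; they do
#' not reproduce any published library's exact numbers.
#'
#' @return Data frame with columns `group`, `param`, `mean`, `sigma`.
#' @export
svl_defaults <- function() {
  path <- system.file("extdata", "svl_default.tsv", package = "cdlkit")
  if (!nzchar(path)) stop("built-in SVL table not found", call. = FALSE)
  read_svl_tsv(path)
}

read_svl_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# hashed lookup environment for a table's binned entries, built once and
# cached on the object's attributes
entry_index <- function(tab) {
  idx <- attr(tab, "entry_index")
  if (!is.null(idx) && identical(attr(tab, "entry_index_n"), nrow(tab$entries))) {
    return(idx)
  }
  e <- tab$entries
  key <- paste(e$group, e$next_is_pro, e$phi_lo, e$psi_lo, e$param,
               sep = "|")
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(e))) assign(key[i], i, envir = idx)
  idx
}

svl_index <- function(tab) {
  sv <- tab$svl
  key <- paste(sv$group, sv$param, sep = "|")
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(sv))) assign(key[i], i, envir = idx)
  idx
}

#' Look up the restraint target for one parameter
#'
#' The fallback chain, most to least specific: (1) the exact
#' (key, bin, param) entry when its observation count reaches the table's
#' `min_count`; (2) the same bin under the (General, next_is_pro) key;
#' (3) the same bin under (General, FALSE); (4) the single-value slice
#' for the residue's own group. Undefined phi or psi (terminal residues)
#' and non-standard residues (`key = NULL`) go directly to (4).
#'
#' @param tab A `cdl_table`.
#' @param key Result of [assign_key()] (may be `NULL`).
#' @param phi,psi Backbone torsions in degrees (may be `NA`).
#' @param param Parameter name from [param_vocabulary()].
#' @param group SVL group used when `key` is `NULL` (default `"General"`).
#' @return List with `mean`, `sigma`, `source` (`"CDL"` or `"SVL"`) and
#'   `count` (0 for SVL).
#' @export
cdl_lookup <- function(tab, key, phi, psi, param, group = "General") {
  stopifnot(inherits(tab, "cdl_table"))
  if (!param %in% param_vocabulary()$param) {
    stop("unknown parameter: ", param, call. = FALSE)
  }
  svl_i <- svl_index(tab)
  svl_get <- function(g) {
    i <- get0(paste(g, param, sep = "|"), envir = svl_i)
    if (is.null(i)) i <- get0(paste("General", param, sep = "|"),
                              envir = svl_i)
    list(mean = tab$svl$mean[i], sigma = tab$svl$sigma[i],
         source = "SVL", count = 0L)
  }
  if (is.null(key)) return(svl_get(group))
  b <- bin_of(phi, psi, tab$meta$width)
  if (is.null(b)) return(svl_get(key$group))
  idx <- entry_index(tab)
  tries <- list(
    c(key$group, key$next_is_pro),
    c("General", key$next_is_pro),
    c("General", FALSE)
  )
  for (tr in tries) {
    k <- paste(tr[1], as.logical(tr[2]), b$phi_lo, b$psi_lo, param,
               sep = "|")
    i <- get0(k, envir = idx)
    if (!is.null(i) && tab$entries$count[i] >= tab$meta$min_count) {
      return(list(mean = tab$entries$mean[i], sigma = tab$entries$sigma[i],
                  source = "CDL", count = tab$entries$count[i]))
    }
  }
  svl_get(key$group)
}

#' Write a restraint table to the TSV schema
#'
#' Tab-separated with `#meta key=value` header lines; binned rows carry
#' numeric `phi_lo`/`psi_lo`, single-value rows use `*` in both. Numeric
#' fields are serialized at fixed precision so identical tables produce
#' byte-identical files.
#'
#' @param tab A `cdl_table`.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
save_table <- function(tab, path = NULL) {
  stopifnot(inherits(tab, "cdl_table"))
  m <- tab$meta
  lines <- c(
    sprintf("#meta width=%s", format(m$width)),
    sprintf("#meta min_count=%s", format(m$min_count)),
    sprintf("#meta sigma_floor_angle=%s", format(m$sigma_floor_angle)),
    sprintf("#meta sigma_floor_length=%s", format(m$sigma_floor_length)),
    sprintf("#meta provenance=%s", m$provenance),
    paste("key_group", "next_is_pro", "phi_lo", "psi_lo", "param",
          "mean", "sigma", "count", sep = "\t")
  )
  e <- tab$entries
  if (nrow(e)) {
    ord <- order(e$group, e$next_is_pro, e$phi_lo, e$psi_lo, e$param)
    e <- e[ord, , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%d\t%g\t%g\t%s\t%.6f\t%.6f\t%d",
                              e$group, as.integer(e$next_is_pro),
                              e$phi_lo, e$psi_lo, e$param,
                              e$mean, e$sigma, as.integer(e$count)))
  }
  sv <- tab$svl
  ord <- order(sv$group, sv$param)
  sv <- sv[ord, , drop = FALSE]
  lines <- c(lines, sprintf("%s\t0\t*\t*\t%s\t%.6f\t%.6f\t0",
                            sv$group, sv$param, sv$mean, sv$sigma))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a restraint table from the TSV or JSON schema
#'
#' Integrity checks (sigma positivity, bin tiling, SVL completeness) run
#' at load time so lookup can assume a sound table.
#'
#' @param path Path to a table written by [save_table()] (or its JSON
#'   mirror, recognized by a `.json` extension).
#' @return A `cdl_table`.
#' @export
load_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(table_from_json(path))
  }
  lines <- readLines(path, warn = FALSE)
  meta <- list(width = 10, min_count = 20, sigma_floor_angle = 0.5,
               sigma_floor_length = 0.005, provenance = "")
  mlines <- grep("^#meta ", lines, value = TRUE)
  for (ml in mlines) {
    kv <- sub("^#meta ", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    k <- substr(kv, 1, eq - 1)
    v <- substr(kv, eq + 1, nchar(kv))
    if (k %in% c("width", "min_count", "sigma_floor_angle",
                 "sigma_floor_length")) {
      meta[[k]] <- as.numeric(v)
    } else if (k == "provenance") {
      meta[[k]] <- v
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("empty table file: ", path, call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != 8)) {
    stop("malformed table row ", which(widths != 8)[1] , " in ", path,
         ": expected 8 tab-separated fields", call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  header <- mat[1, ]
  expect <- c("key_group", "next_is_pro", "phi_lo", "psi_lo", "param",
              "mean", "sigma", "count")
  if (!identical(unname(header), expect)) {
    stop("unexpected table header in ", path, call. = FALSE)
  }
  mat <- mat[-1, , drop = FALSE]
  is_svl <- mat[, 3] == "*" | mat[, 4] == "*"
  num <- function(v, row_off) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) {
      stop("non-numeric field in table row ", which(is.na(out))[1] + 1,
           " of ", path, call. = FALSE)
    }
    out
  }
  svl <- data.frame(group = mat[is_svl, 1], param = mat[is_svl, 5],
                    mean = num(mat[is_svl, 6]), sigma = num(mat[is_svl, 7]),
                    stringsAsFactors = FALSE)
  eb <- mat[!is_svl, , drop = FALSE]
  entries <- data.frame(
    group = eb[, 1],
    next_is_pro = as.integer(num(eb[, 2])) != 0L,
    phi_lo = num(eb[, 3]), psi_lo = num(eb[, 4]), param = eb[, 5],
    mean = num(eb[, 6]), sigma = num(eb[, 7]),
    count = as.integer(num(eb[, 8])),
    stringsAsFactors = FALSE)
  cdl_table(entries = entries, svl = svl, width = meta$width,
            min_count = meta$min_count,
            sigma_floor_angle = meta$sigma_floor_angle,
            sigma_floor_length = meta$sigma_floor_length,
            provenance = meta$provenance)
}

table_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cdl_table(entries = as.data.frame(x$entries, stringsAsFactors = FALSE),
            svl = as.data.frame(x$svl, stringsAsFactors = FALSE),
            width = x$meta$width, min_count = x$meta$min_count,
            sigma_floor_angle = x$meta$sigma_floor_angle,
            sigma_floor_length = x$meta$sigma_floor_length,
            provenance = x$meta$provenance)
}

#' Write the JSON mirror of a restraint table
#'
#' @param tab A `cdl_table`.
#' @param path Output path (`.json`).
#' @export
save_table_json <- function(tab, path) {
  jsonlite::write_json(
    list(meta = tab$meta, entries = tab$entries, svl = tab$svl),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
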