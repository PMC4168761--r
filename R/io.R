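#' Read a labelled distance matrix file
#'
#' Accepts the layouts used for deposited distance matrices: tab- or
#' comma-delimited (detected from the header line), a leading label row
#' and label column, and either a full square matrix or a triangle-only
#' file (lower or upper), which is mirrored to the full square. Symmetry
#' is validated to `tol`, with the worst cell reported on failure; a
#' nonzero diagonal or a non-square layout is an error.
#'
#' @param path Path to the matrix file.
#' @param tol Symmetry tolerance passed to [as_distmat()].
#' @return A [as_distmat()] matrix, labels in file order.
#' @export
read_distance_matrix <- function(path, tol = 1e-6) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) abort("distance matrix file has no data rows")
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  split1 <- function(s) {
    out <- strsplit(s, sep, fixed = TRUE)[[1]]
    trimws(out)
  }
  header <- split1(lines[[1]])
  if (header[1] == "") header <- header[-1]
  n <- length(header)
  if (length(lines) - 1L != n) {
    abort(sprintf("non-square matrix file: %d labels in header, %d data rows",
                  n, length(lines) - 1L))
  }
  m <- matrix(NA_real_, n, n, dimnames = list(header, header))
  row_labels <- character(n)
  for (i in seq_len(n)) {
    f <- split1(lines[[i + 1L]])
    row_labels[i] <- f[1]
    vals <- f[-1]
    if (length(vals) > n) {
      abort(sprintf("non-square matrix file: row '%s' has %d values for %d columns",
                    f[1], length(vals), n))
    }
    num <- suppressWarnings(as.numeric(vals))
    num[vals == ""] <- NA_real_
    m[i, seq_along(num)] <- num
  }
  if (!setequal(row_labels, header)) {
    abort("row labels do not match header labels")
  }
  m <- m[, , drop = FALSE]
  rownames(m) <- row_labels
  m <- m[, row_labels, drop = FALSE][row_labels, , drop = FALSE]
  rownames(m) <- colnames(m) <- row_labels
  # mirror triangle-only entries
  filled <- !is.na(m)
  mt <- t(m)
  m[!filled & !is.na(mt)] <- mt[!filled & !is.na(mt)]
  diag(m)[is.na(diag(m))] <- 0
  if (anyNA(m)) {
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    if (nrow(bad)) {
      abort(sprintf("missing distance for pair (%s, %s)",
                    row_labels[bad[1, 1]], row_labels[bad[1, 2]]))
    }
  }
  as_distmat(m, tol = tol)
}

#' Write a labelled distance matrix
#'
#' Full-precision output (`%.17g`) so that write/read round-trips are
#' exact; labels keep their current order.
#'
#' @param D A [as_distmat()] matrix.
#' @param path Output path.
#' @param sep Field delimiter, tab by default.
#' @param comment Optional character vector of comment lines (each is
#'   prefixed with `#`), used to record configuration and seed.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, sep = "\t", comment = NULL) {
  D <- as_distmat(D)
  ids <- rownames(D)
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  }
  lines <- c(
    if (length(comment)) paste0("# ", comment),
    paste(c("", ids), collapse = sep),
    vapply(seq_along(ids), function(i) {
      paste(c(ids[i], fmt(D[i, ])), collapse = sep)
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read specimen coordinates
#'
#' CSV with a header containing `specimen_id`, `lon`, `lat` columns
#' (decimal degrees). Ids must be unique; latitudes outside [-90, 90] or
#' longitudes outside [-180, 180] are errors.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `specimen_id`, `lon`, `lat`.
#' @export
read_coordinates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("specimen_id", "lon", "lat")
  if (!all(need %in% names(df))) {
    abort(sprintf("coordinate file must have columns %s",
                  paste(need, collapse = ", ")))
  }
  df <- tibble::as_tibble(df[need])
  df$specimen_id <- as.character(df$specimen_id)
  validate_coordinates(df)
}

validate_coordinates <- function(df) {
  if (anyDuplicated(df$specimen_id)) {
    abort(sprintf("duplicated specimen id in coordinates: %s",
                  df$specimen_id[duplicated(df$specimen_id)][1]))
  }
  if (anyNA(df$lon) || anyNA(df$lat)) abort("missing coordinate values")
  if (any(df$lat < -90 | df$lat > 90)) {
    abort(sprintf("latitude out of range [-90, 90] for specimen '%s'",
                  df$specimen_id[which(df$lat < -90 | df$lat > 90)[1]]))
  }
  if (any(df$lon < -180 | df$lon > 180)) {
    abort(sprintf("longitude out of range [-180, 180] for specimen '%s'",
                  df$specimen_id[which(df$lon < -180 | df$lon > 180)[1]]))
  }
  df
}

#' Write specimen coordinates
#'
#' @param coords Tibble with `specimen_id`, `lon`, `lat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(coords, path) {
  validate_coordinates(coords)
  df <- data.frame(specimen_id = coords$specimen_id,
                   lon = sprintf("%.17g", coords$lon),
                   lat = sprintf("%.17g", coords$lat))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis run configuration
#'
#' Bundles every tunable of the congruence pipeline with validated
#' defaults: both dependent-matrix directions, uncorrected p-distances,
#' automatic truncation of the spatial eigenfunction basis (largest
#' minimum-spanning-tree edge), forward-selection entry threshold
#' `alpha = 0.05` with 999 permutations per candidate, 10000 association
#' randomisations for the Procrustes test, and positive-eigenvalue axis
#' retention for explanatory matrices. Per-stage seeds are derived from
#' `seed` by fixed offsets so stages are independently reproducible.
#'
#' @param dependent Which direction(s) to analyse: `"both"`, `"algae"`
#'   or `"fungi"`.
#' @param distance_model `"p"` (uncorrected) or `"tn93"` for genetic
#'   distances computed from alignments.
#' @param mem_truncation Positive truncation distance in meters, or
#'   `NULL` for the automatic minimum-spanning-tree rule.
#' @param forward_alpha Entry threshold for forward selection, in (0, 1].
#' @param n_perm_select Permutations per forward-selection candidate.
#' @param n_perm_paco Association randomisations for the Procrustes test.
#' @param seed Master integer seed.
#' @param axis_rule Explanatory-axis retention rule: `"positive"`,
#'   `"first_k"` or `"cum95"` (see [explanatory_axes()]).
#' @param axis_k Number of axes when `axis_rule = "first_k"`.
#' @param pcoa_correction Negative-eigenvalue handling for PCoA:
#'   `"none"`, `"lingoes"` or `"cailliez"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dependent = c("both", "algae", "fungi"),
                       distance_model = c("p", "tn93"),
                       mem_truncation = NULL,
                       forward_alpha = 0.05,
                       n_perm_select = 999,
                       n_perm_paco = 10000,
                       seed = 1L,
                       axis_rule = c("positive", "first_k", "cum95"),
                       axis_k = NULL,
                       pcoa_correction = c("none", "lingoes", "cailliez")) {
  dependent <- match.arg(dependent)
  distance_model <- match.arg(distance_model)
  axis_rule <- match.arg(axis_rule)
  pcoa_correction <- match.arg(pcoa_correction)
  if (!is.null(mem_truncation) && (!is.numeric(mem_truncation) || mem_truncation <= 0)) {
    abort("mem_truncation must be a positive number or NULL (auto)")
  }
  if (!is.numeric(forward_alpha) || forward_alpha <= 0 || forward_alpha > 1) {
    abort("forward_alpha must lie in (0, 1]")
  }
  if (n_perm_select < 1 || n_perm_paco < 1) abort("permutation counts must be >= 1")
  structure(list(
    dependent = dependent, distance_model = distance_model,
    mem_truncation = mem_truncation, forward_alpha = forward_alpha,
    n_perm_select = as.integer(n_perm_select),
    n_perm_paco = as.integer(n_perm_paco),
    seed = as.integer(seed), axis_rule = axis_rule, axis_k = axis_k,
    pcoa_correction = pcoa_correction), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s %s\n", nm,
                if (is.null(x[[nm]])) "auto" else paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

# internal: per-stage seed derivation (fixed offsets, kept under 2^31)
stage_seed <- function(config_seed, offset) {
  (as.integer(config_seed) %% 2000000000L) + as.integer(offset)
}
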