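#' Labelled distance matrices
#'
#' A `distmat` is the package's universal currency: a square, symmetric,
#' zero-diagonal, non-negative matrix whose row and column names are the
#' specimen identifiers. Genetic and geographic distances use the same
#' representation. `as_distmat()` validates and classes a plain matrix
#' (or a [stats::dist] object); validation is repeated at every module
#' boundary rather than assumed.
#'
#' Entries may be `NA` only where a distance is flagged inestimable
#' (see [tn93_distance()]); the `NA` pattern must itself be symmetric.
#'
#' @param x A square numeric matrix with identical, unique row and column
#'   names, or a [stats::dist] object (labels taken from its `Labels`).
#' @param tol Symmetry/diagonal tolerance (absolute).
#' @return A matrix of class `distmat`.
#' @examples
#' m <- matrix(c(0, 0.08, 0.08, 0), 2, 2, dimnames = list(c("s1", "s2"), c("s1", "s2")))
#' as_distmat(m)
#' @export
as_distmat <- function(x, tol = 1e-9) {
  if (inherits(x, "dist")) {
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("a distance matrix must be a numeric matrix")
  }
  if (nrow(x) != ncol(x)) {
    abort(sprintf("distance matrix must be square, got %d x %d", nrow(x), ncol(x)))
  }
  ids <- rownames(x)
  if (is.null(ids) && nrow(x) > 0) {
    ids <- paste0("S", seq_len(nrow(x)))
    dimnames(x) <- list(ids, ids)
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated specimen ids: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (!identical(rownames(x), colnames(x))) {
    abort("row and column labels of a distance matrix must be identical")
  }
  na <- is.na(x)
  if (!identical(na, t(na))) {
    abort("pattern of missing (inestimable) entries must be symmetric")
  }
  gap <- abs(x - t(x))
  if (any(gap > tol, na.rm = TRUE)) {
    worst <- which(gap == max(gap, na.rm = TRUE), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "matrix asymmetric beyond tolerance %g: worst cell (%s, %s), |d_ij - d_ji| = %g",
      tol, ids[worst[1]], ids[worst[2]], max(gap, na.rm = TRUE)))
  }
  if (any(abs(diag(x)) > tol)) {
    bad <- ids[which.max(abs(diag(x)))]
    abort(sprintf("nonzero diagonal entry for specimen '%s'", bad))
  }
  if (any(x < -tol, na.rm = TRUE)) {
    abort("negative distance entries are not allowed")
  }
  x[x < 0] <- 0
  x <- (x + t(x)) / 2
  diag(x) <- 0
  structure(x, class = c("distmat", "matrix", "array"))
}

#' @export
print.distmat <- function(x, ...) {
  cat(sprintf("<distmat: %d specimens>\n", nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 6) cat(sprintf("... %d more specimens\n", nrow(x) - 6))
  invisible(x)
}

#' @rdname as_distmat
#' @export
is_distmat <- function(x) inherits(x, "distmat")

#' Specimen identifiers of a package object
#'
#' @param x A `distmat`, alignment, or result object carrying labels.
#' @return Character vector of specimen ids.
#' @export
specimen_ids <- function(x) {
  if (is.matrix(x)) return(rownames(x))
  if (inherits(x, "dna_alignment")) return(names(x))
  attr(x, "labels") %||% x$labels
}

#' Align several labelled objects to a common specimen order
#'
#' Joins are always by label, never by position: the first object's label
#' order is the reference, and any discrepancy in label *sets* is an
#' error naming the offending specimens. Pairing integrity (which alga
#' goes with which fungus) is the core assumption of the congruence
#' analyses, so silent positional matching is never allowed.
#'
#' @param ... Named `distmat` objects and/or matrices with row names
#'   (predictor matrices, coordinates with `specimen_id`).
#' @return A list of the inputs, reordered to the first object's labels.
#' @export
align_specimens <- function(...) {
  objs <- list(...)
  nm <- names(objs) %||% paste0("input", seq_along(objs))
  nm[nm == ""] <- paste0("input", which(nm == ""))
  get_ids <- function(o) {
    if (is.data.frame(o)) as.character(o$specimen_id) else rownames(o)
  }
  ref <- get_ids(objs[[1]])
  if (is.null(ref)) abort("first input carries no specimen labels")
  for (i in seq_along(objs)) {
    ids <- get_ids(objs[[i]])
    if (is.null(ids)) abort(sprintf("input '%s' carries no specimen labels", nm[i]))
    miss <- setdiff(ref, ids)
    extra <- setdiff(ids, ref)
    if (length(miss) || length(extra)) {
      abort(sprintf(
        "specimen labels of '%s' do not match '%s'%s%s",
        nm[i], nm[1],
        if (length(miss)) paste0("; missing: ", paste(head(miss, 5), collapse = ", ")) else "",
        if (length(extra)) paste0("; unexpected: ", paste(head(extra, 5), collapse = ", ")) else ""))
    }
  }
  lapply(objs, function(o) {
    if (is.data.frame(o)) {
      o[match(ref, as.character(o$specimen_id)), , drop = FALSE]
    } else if (identical(nrow(o), ncol(o)) && identical(rownames(o), colnames(o))) {
      out <- o[ref, ref, drop = FALSE]
      if (is_distmat(o)) out <- as_distmat(out) else out
    } else {
      o[ref, , drop = FALSE]
    }
  })
}

# internal: upper-triangle values (off-diagonal) of a square matrix
upper_vals <- function(m) m[upper.tri(m)]
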