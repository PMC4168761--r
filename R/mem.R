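#' Moran's eigenvector maps from geographic distances
#'
#' Builds the classic distance-based spatial eigenfunction basis (PCNM):
#' geographic distances above the truncation threshold `t` are replaced
#' by `4 t`, the modified matrix is passed through principal coordinates
#' analysis, and the positive-eigenvalue axes are retained. Eigenvector
#' 1 describes the broadest spatial scale and the index increases toward
#' finer scales; there can be at most `n - 1` eigenvectors for `n`
#' locations. When `truncation` is omitted, `t` is the largest edge of a
#' minimum spanning tree over the locations, the smallest threshold that
#' keeps all points connected.
#'
#' @param geoD A geographic [as_distmat()] (meters).
#' @param truncation Positive truncation distance, or `NULL` for the
#'   minimum-spanning-tree rule.
#' @param eps Relative eigenvalue tolerance (fraction of the leading
#'   eigenvalue) for retaining an axis.
#' @return An object of class `mem_basis`: `vectors` (n x m matrix,
#'   columns `MEM1`..., scaled by the square root of their eigenvalue),
#'   `values`, `truncation`, `labels`.
#' @export
mem_basis <- function(geoD, truncation = NULL, eps = 1e-10) {
  geoD <- as_distmat(geoD, tol = 1e-6)
  n <- nrow(geoD)
  if (n < 3) abort("need at least 3 locations for a spatial basis")
  off <- upper_vals(geoD)
  if (all(off <= .Machine$double.eps * 100)) {
    abort("all locations coincide: no spatial structure representable")
  }
  t <- truncation %||% mst_max_edge(geoD)
  if (t <= 0) abort("truncation distance must be positive")
  Dstar <- unclass(geoD)
  Dstar[Dstar > t] <- 4 * t
  diag(Dstar) <- 0
  ord <- pcoa(as_distmat(Dstar), eps = eps)
  m <- ncol(ord$coordinates)
  if (m > n - 1) {
    ord$coordinates <- ord$coordinates[, seq_len(n - 1), drop = FALSE]
    m <- n - 1
  }
  vectors <- ord$coordinates
  colnames(vectors) <- paste0("MEM", seq_len(m))
  structure(list(
    vectors = vectors,
    values = ord$values[seq_len(m)],
    truncation = t,
    labels = rownames(geoD)), class = "mem_basis")
}

# internal: largest edge of the minimum spanning tree (Prim's algorithm,
# deterministic: equal candidate edges resolved by lexicographic node order)
mst_max_edge <- function(D) {
  n <- nrow(D)
  in_tree <- rep(FALSE, n)
  in_tree[1] <- TRUE
  best <- D[1, ]
  max_edge <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    max_edge <- max(max_edge, best[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & D[j, ] < best
    best[upd] <- D[j, upd]
  }
  max_edge
}

#' @export
print.mem_basis <- function(x, ...) {
  cat(sprintf("<mem_basis: %d eigenvectors over %d locations, truncation %.6g m>\n",
              ncol(x$vectors), length(x$labels), x$truncation))
  invisible(x)
}

#' @method tidy mem_basis
#' @export
tidy.mem_basis <- function(x, ...) {
  tibble::as_tibble(x$vectors, rownames = "specimen_id") %>%
    tidyr::pivot_longer(-"specimen_id", names_to = "mem", values_to = "score") %>%
    dplyr::mutate(mem = as.integer(sub("^MEM", "", .data$mem))) %>%
    dplyr::arrange(.data$mem, .data$specimen_id)
}

#' @method glance mem_basis
#' @export
glance.mem_basis <- function(x, ...) {
  tibble::tibble(
    n = length(x$labels),
    n_vectors = ncol(x$vectors),
    truncation = x$truncation)
}
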