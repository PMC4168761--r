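#' Principal coordinates analysis
#'
#' Gower double-centering of \eqn{-\tfrac12 D \circ D} followed by a
#' symmetric eigendecomposition. Axes are ordered by decreasing
#' eigenvalue and scaled by \eqn{\sqrt{\lambda}}, so squared Euclidean
#' distances between coordinate rows reproduce the input distances
#' exactly when the matrix is Euclidean-embeddable. Negative eigenvalues
#' are counted and, with `correction = "none"` (default), their axes are
#' excluded from the coordinates; the Lingoes and Cailliez additive
#' corrections are available to make all eigenvalues non-negative.
#'
#' @param D A [as_distmat()] matrix (n >= 2).
#' @param correction `"none"`, `"lingoes"` or `"cailliez"`.
#' @param eps Relative tolerance for treating an eigenvalue as positive,
#'   as a fraction of the leading eigenvalue.
#' @return An object of class `pcoa_ord`: eigenvalues (all, descending),
#'   `coordinates` (n x k, positive axes), `n_negative`, `correction`,
#'   `trace` (sum of positive eigenvalues).
#' @examples
#' pts <- cbind(x = c(0, 3, 0), y = c(0, 0, 4))
#' rownames(pts) <- c("a", "b", "c")
#' ord <- pcoa(as_distmat(as.matrix(dist(pts))))
#' ord$values
#' @export
pcoa <- function(D, correction = c("none", "lingoes", "cailliez"),
                 eps = 1e-10) {
  correction <- match.arg(correction)
  D <- as_distmat(D)
  if (anyNA(D)) abort("PCoA requires a complete distance matrix (no inestimable entries)")
  n <- nrow(D)
  if (n < 2) abort("PCoA needs at least 2 specimens")
  Dw <- unclass(D)
  applied <- "none"
  if (correction != "none") {
    e0 <- eigen(gower_center(Dw), symmetric = TRUE, only.values = TRUE)$values
    tol0 <- eps * max(abs(e0))
    if (min(e0) < -tol0) {
      if (correction == "lingoes") {
        c1 <- -min(e0)
        D2 <- Dw^2 + 2 * c1
        diag(D2) <- 0
        Dw <- sqrt(D2)
      } else {
        c2 <- cailliez_constant(Dw)
        Dw <- Dw + c2
        diag(Dw) <- 0
      }
      applied <- correction
    }
  }
  G <- gower_center(Dw)
  e <- eigen(G, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  tol <- eps * max(abs(values), 1e-300)
  pos <- which(values > tol)
  coords <- vectors[, pos, drop = FALSE] %*% diag(sqrt(values[pos]), length(pos))
  rownames(coords) <- rownames(D)
  if (length(pos)) colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(
    values = values,
    coordinates = coords,
    n_negative = sum(values < -tol),
    correction = applied,
    trace = sum(values[pos]),
    labels = rownames(D)), class = "pcoa_ord")
}

# internal: Gower-centered -0.5 * D^2
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rs <- rowMeans(A)
  A - outer(rs, rep(1, n)) - outer(rep(1, n), rs) + mean(A)
}

# internal: Cailliez additive constant (largest real eigenvalue of the
# 2n x 2n companion block matrix of Legendre & Legendre)
cailliez_constant <- function(D) {
  n <- nrow(D)
  G1 <- gower_center(D)
  G2 <- {
    A <- -0.5 * D
    rs <- rowMeans(A)
    A - outer(rs, rep(1, n)) - outer(rep(1, n), rs) + mean(A)
  }
  B <- rbind(cbind(matrix(0, n, n), 2 * G1),
             cbind(-diag(n), -4 * G2))
  ev <- eigen(B, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("<pcoa_ord: %d specimens, %d positive axes, %d negative eigenvalues, correction: %s>\n",
              length(x$labels), ncol(x$coordinates), x$n_negative, x$correction))
  cat("eigenvalues:", paste(signif(head(x$values, 5), 4), collapse = ", "),
      if (length(x$values) > 5) "..." else "", "\n")
  invisible(x)
}

#' @method tidy pcoa_ord
#' @export
tidy.pcoa_ord <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "specimen_id")
}

#' @method glance pcoa_ord
#' @export
glance.pcoa_ord <- function(x, ...) {
  tibble::tibble(
    n = length(x$labels),
    n_axes = ncol(x$coordinates),
    n_negative = x$n_negative,
    trace = x$trace,
    correction = x$correction)
}

#' Predictor axes from an explanatory distance matrix
#'
#' Converts a distance matrix into a predictor matrix for constrained
#' ordination by retaining principal-coordinate axes. The default rule
#' keeps all positive-eigenvalue axes; `"first_k"` keeps the first `k`;
#' `"cum95"` keeps the smallest leading set explaining at least 95% of
#' the positive inertia.
#'
#' @param D A [as_distmat()] matrix.
#' @param rule Axis retention rule.
#' @param k Number of axes for `rule = "first_k"`.
#' @param max_axes Optional hard cap on the number of retained axes
#'   (largest eigenvalues first); used by callers that must keep
#'   residual degrees of freedom in a constrained model.
#' @return An n x m numeric matrix of axis scores, rows labelled by
#'   specimen.
#' @export
explanatory_axes <- function(D, rule = c("positive", "first_k", "cum95"),
                             k = NULL, max_axes = NULL) {
  rule <- match.arg(rule)
  ord <- pcoa(D)
  m <- ncol(ord$coordinates)
  keep <- switch(rule,
    positive = seq_len(m),
    first_k = {
      if (is.null(k) || k < 1) abort("rule 'first_k' needs k >= 1")
      seq_len(min(k, m))
    },
    cum95 = {
      lam <- ord$values[ord$values > 0]
      share <- cumsum(lam) / sum(lam)
      seq_len(min(which(share >= 0.95 - 1e-12)))
    })
  if (m == 0 || length(keep) == 0) {
    abort("axis retention rule keeps no axes (no positive eigenvalues)")
  }
  if (!is.null(max_axes)) keep <- keep[seq_len(min(length(keep), max_axes))]
  ord$coordinates[, keep, drop = FALSE]
}
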