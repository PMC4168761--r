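#' Least-squares Procrustes superimposition
#'
#' Centers both configurations, then scales and rotates `Y` onto `X` to
#' minimise the sum of squared row-wise residuals. The rotation comes
#' from the singular value decomposition of `Y'X` over the full
#' orthogonal group, so reflections are allowed: principal-coordinate
#' axis signs are arbitrary and excluding reflections would make results
#' sign-dependent. Configurations with different column counts are
#' padded with zero columns to equal width.
#'
#' @param X Target configuration (n x k matrix, rows are specimens).
#' @param Y Configuration to transform (n x k' matrix, rows paired with
#'   `X` by position).
#' @return Object of class `procrustes_fit`: `rotation`, `scale`,
#'   `translation`, per-specimen squared `residuals`, and their sum
#'   `m2`.
#' @export
procrustes_superimpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("configurations must have equal row counts")
  if (nrow(X) < 2) abort("need at least 2 paired specimens")
  k <- max(ncol(X), ncol(Y), 1L)
  pad <- function(M) {
    if (ncol(M) < k) cbind(M, matrix(0, nrow(M), k - ncol(M))) else M
  }
  X <- pad(X); Y <- pad(Y)
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)
  ssY <- sum(Yc^2)
  if (ssY <= 0) {
    # degenerate Y: every point identical; best map sends Y to the centroid
    res <- rowSums(Xc^2)
    return(structure(list(rotation = diag(k), scale = 0,
                          translation = xbar, residuals = res,
                          m2 = sum(res)), class = "procrustes_fit"))
  }
  sv <- svd(crossprod(Yc, Xc))
  R <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / ssY
  Yrot <- s * Yc %*% R
  res <- rowSums((Xc - Yrot)^2)
  nm <- rownames(X) %||% rownames(Y)
  if (!is.null(nm)) names(res) <- nm
  structure(list(rotation = R, scale = s,
                 translation = as.numeric(xbar - s * crossprod(R, ybar)),
                 residuals = res, m2 = sum(res)),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("<procrustes_fit: %d specimens, m2 = %.6g, scale = %.4g>\n",
              length(x$residuals), x$m2, x$scale))
  invisible(x)
}

#' Procrustes test of co-phylogenetic congruence
#'
#' The Procrustes approach to co-phylogeny: both partners' distance
#' matrices are embedded by principal coordinates (positive axes, shared
#' implementation with the ordination module), the second partner's
#' configuration is superimposed onto the first's by least-squares
#' Procrustes (by convention the fungal ordination is rotated onto the
#' algal one), and the observed residual sum of squares `m2` is compared
#' with its distribution under random re-pairing: the row-to-row
#' association of `Y` is permuted `n_perm` times and `m2` recomputed.
#' The test is one-sided with small `m2` as evidence of congruence:
#' `p = (count(m2_perm <= m2_obs) + 1) / (n_perm + 1)`. The observed
#' pairing is not excluded from the null draws.
#'
#' @param algD First (target) partner's [as_distmat()]; the algal matrix
#'   in the standard direction.
#' @param funD Second partner's [as_distmat()], rotated onto the first;
#'   labels must match `algD` (one alga and one fungus per specimen).
#' @param n_perm Number of association randomisations (>= 1).
#' @param seed Integer seed.
#' @return Object of class `paco_result`: `m2`, `p`, `n_perm`,
#'   per-specimen squared `residuals` (named), and `null_m2`, the
#'   randomised statistics.
#' @export
paco_test <- function(algD, funD, n_perm = 10000, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  algD <- as_distmat(algD, tol = 1e-6)
  funD <- as_distmat(funD, tol = 1e-6)
  al <- align_specimens(algae = algD, fungi = funD)
  X <- pcoa(al$algae)$coordinates
  Y <- pcoa(al$fungi)$coordinates
  k <- max(ncol(X), ncol(Y), 1L)
  padk <- function(M) if (ncol(M) < k) cbind(M, matrix(0, nrow(M), k - ncol(M))) else M
  Xp <- padk(X); Yp <- padk(Y)
  fit <- procrustes_superimpose(Xp, Yp)
  n <- nrow(Xp)
  Xc <- sweep(Xp, 2, colMeans(Xp))
  Yc <- sweep(Yp, 2, colMeans(Yp))
  ssX <- sum(Xc^2); ssY <- sum(Yc^2)
  m2_of <- function(Yperm) {
    # least-squares minimum in closed form: m2 = ssX - (sum sv)^2 / ssY
    if (ssY <= 0) return(ssX)
    sv <- svd(crossprod(Yperm, Xc), nu = 0, nv = 0)
    ssX - sum(sv$d)^2 / ssY
  }
  draw <- function() {
    vapply(seq_len(n_perm), function(b) m2_of(Yc[sample.int(n), , drop = FALSE]),
           numeric(1))
  }
  null_m2 <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  p <- (sum(null_m2 <= fit$m2 + 1e-12) + 1) / (n_perm + 1)
  res <- fit$residuals
  names(res) <- rownames(al$algae)
  structure(list(m2 = fit$m2, p = p, n_perm = as.integer(n_perm),
                 residuals = res, null_m2 = null_m2,
                 ss_target = ssX,
                 fit = fit, labels = rownames(al$algae)),
            class = "paco_result")
}

#' @export
print.paco_result <- function(x, ...) {
  cat(sprintf("<paco_result: n = %d, m2 = %.6g, p = %s (%d randomisations)>\n",
              length(x$residuals), x$m2, format_pval(x$p, x$n_perm), x$n_perm))
  invisible(x)
}

#' @method tidy paco_result
#' @export
tidy.paco_result <- function(x, ...) {
  tibble::tibble(
    specimen_id = names(x$residuals),
    residual = unname(x$residuals),
    above_median = unname(x$residuals) > median(x$residuals))
}

#' @method glance paco_result
#' @export
glance.paco_result <- function(x, ...) {
  tibble::tibble(m2 = x$m2, p.value = x$p, n = length(x$residuals),
                 n_perm = x$n_perm,
                 m2_standardized = if (x$ss_target > 0) x$m2 / x$ss_target else NA_real_)
}

#' Group Procrustes residuals by a specimen trait
#'
#' Summarises per-specimen squared residuals by a categorical trait
#' (growth form, apothecia presence, ...): per-group count, mean and
#' median, plus each specimen's position relative to the overall median
#' residual. Specimens absent from `traits` are grouped as
#' `"unlabelled"`; a trait entry for an unknown specimen is an error.
#'
#' @param result A [paco_test()] result.
#' @param traits Named character vector (names are specimen ids), a
#'   tibble with columns `specimen_id` and `trait`, or `NULL`/empty for
#'   a single unlabelled group.
#' @return A list of class `trait_residuals`: `groups` (per-trait
#'   summary tibble), `specimens` (per-specimen tibble with trait and
#'   median flag) and `overall_median`.
#' @export
residuals_by_trait <- function(result, traits = NULL) {
  stopifnot(inherits(result, "paco_result"))
  ids <- names(result$residuals)
  if (is.data.frame(traits)) {
    traits <- stats::setNames(as.character(traits$trait), traits$specimen_id)
  }
  if (length(traits)) {
    unknown <- setdiff(names(traits), ids)
    if (length(unknown)) {
      abort(sprintf("trait given for unknown specimen(s): %s",
                    paste(head(unknown, 5), collapse = ", ")))
    }
  }
  lab <- rep("unlabelled", length(ids))
  names(lab) <- ids
  if (length(traits)) lab[names(traits)] <- as.character(traits)
  med <- median(result$residuals)
  specimens <- tibble::tibble(
    specimen_id = ids,
    trait = unname(lab),
    residual = unname(result$residuals),
    above_median = unname(result$residuals) > med)
  groups <- specimens %>%
    dplyr::group_by(.data$trait) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$residual),
                     median = median(.data$residual),
                     .groups = "drop")
  structure(list(groups = groups, specimens = specimens,
                 overall_median = med), class = "trait_residuals")
}

#' @export
print.trait_residuals <- function(x, ...) {
  cat(sprintf("<trait_residuals: overall median %.6g>\n", x$overall_median))
  print(x$groups)
  invisible(x)
}

# internal: render a permutation p-value the way results tables do
# (values below 10 / (n_perm + 1) print as a "<..." bound; exact values
# persist in the machine-readable output)
format_pval <- function(p, n_perm) {
  if (is.na(p)) return("NA")
  thr <- 10 / (n_perm + 1)
  if (p < thr) paste0("<", format(thr, digits = 2)) else sprintf("%.3f", p)
}
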