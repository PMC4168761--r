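#' Ezekiel-adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - m - 1)`, the multiple-regression
#' adjustment applied to canonical R-squared values in variance
#' partitioning.
#'
#' @param r2 Unadjusted fraction of variance explained.
#' @param n Number of specimens.
#' @param m Number of (linearly independent) predictors.
#' @return The adjusted value (may be negative).
#' @examples
#' adjusted_r2(0.5, n = 21, m = 5)
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (n <= m + 1) abort(sprintf("need n > m + 1 (n = %d, m = %d)", n, m))
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Distance-based redundancy analysis
#'
#' Embeds the response distance matrix by principal coordinates
#' (positive axes), projects the coordinates onto the column space of
#' the centered predictors, and reports the constrained fraction of
#' inertia `R2 = tr(Yhat' Yhat) / tr(Y' Y)` together with its Ezekiel
#' adjustment, a pseudo-F statistic, and a permutation p-value obtained
#' by permuting response rows. Collinear predictor columns are dropped
#' with a warning; a saturated model (`m >= n - 1`) is an error. The
#' p-value convention is `(count(F_perm >= F_obs) + 1) / (n_perm + 1)`.
#'
#' An empty predictor matrix (zero columns) is legal and gives
#' `R2 = 0` with no test; this is the no-predictor baseline used by
#' [variance_partition()].
#'
#' @param responseD Response [as_distmat()].
#' @param X Predictor matrix with rows labelled by specimen (e.g. from
#'   [explanatory_axes()] or a [mem_basis()]), or `NULL` for the empty
#'   model.
#' @param n_perm Number of row permutations for the test (0 to skip).
#' @param seed Integer seed for the permutations.
#' @return An object of class `dbrda_fit`: `r2`, `r2_adj`, `statistic`
#'   (pseudo-F), `p`, `m` (rank of predictors used), `n`, `n_perm`.
#' @export
dbrda <- function(responseD, X = NULL, n_perm = 999, seed = NULL) {
  responseD <- as_distmat(responseD, tol = 1e-6)
  n <- nrow(responseD)
  Y <- pcoa(responseD)$coordinates
  tot <- sum(Y^2)
  if (tot <= 0) abort("response matrix has no variation (all distances zero)")
  if (is.null(X) || NCOL(X) == 0) {
    return(structure(list(r2 = 0, r2_adj = 0, statistic = NA_real_,
                          p = NA_real_, m = 0L, n = n, n_perm = 0L),
                     class = "dbrda_fit"))
  }
  X <- as.matrix(X)
  if (!is.null(rownames(X))) {
    al <- align_specimens(response = responseD, predictors = X)
    X <- al$predictors
  } else if (nrow(X) != n) {
    abort("predictor rows do not match response specimens")
  }
  Q <- predictor_basis(X)
  m <- ncol(Q)
  if (m >= n - 1) {
    abort(sprintf("saturated model: %d predictors for %d specimens", m, n))
  }
  r2 <- sum(crossprod(Q, Y)^2) / tot
  stat <- (r2 / m) / ((1 - r2) / (n - 1 - m))
  p <- NA_real_
  if (n_perm >= 1) {
    r2p <- perm_r2(Y, Q, tot, n_perm, seed)
    p <- (sum(r2p >= r2 - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(r2 = r2, r2_adj = adjusted_r2(r2, n, m), statistic = stat,
                 p = p, m = m, n = n, n_perm = as.integer(n_perm)),
            class = "dbrda_fit")
}

# internal: orthonormal basis of the centered predictor column space;
# collinear columns dropped with a warning
predictor_basis <- function(X, quiet = FALSE) {
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  qrx <- qr(Xc)
  r <- qrx$rank
  if (r < ncol(Xc) && !quiet) {
    warn(sprintf("dropping %d collinear predictor column(s)", ncol(Xc) - r))
  }
  if (r == 0) abort("predictors have no variation")
  qr.Q(qrx)[, seq_len(r), drop = FALSE]
}

# internal: constrained-inertia fractions for n_perm row permutations of Y
perm_r2 <- function(Y, Q, tot, n_perm, seed = NULL) {
  do_perm <- function() {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(nrow(Y))
      sum(crossprod(Q, Y[idx, , drop = FALSE])^2) / tot
    }, numeric(1))
  }
  if (is.null(seed)) do_perm() else withr::with_seed(seed, do_perm())
}

#' @export
print.dbrda_fit <- function(x, ...) {
  cat(sprintf("<dbrda_fit: n = %d, m = %d>\n", x$n, x$m))
  cat(sprintf("  R2 = %.4f, adj R2 = %.4f, F = %s, p = %s (%d permutations)\n",
              x$r2, x$r2_adj,
              ifelse(is.na(x$statistic), "NA", sprintf("%.3f", x$statistic)),
              ifelse(is.na(x$p), "NA", format(x$p, digits = 4)), x$n_perm))
  invisible(x)
}

#' @method glance dbrda_fit
#' @export
glance.dbrda_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, r2_adj = x$r2_adj, statistic = x$statistic,
                 p.value = x$p, m = x$m, n = x$n, n_perm = x$n_perm)
}

#' Forward selection of spatial eigenvectors
#'
#' Greedy forward selection of Moran's eigenvector map variables against
#' a response distance matrix. At each step every remaining candidate is
#' tested by a permutation test of its partial pseudo-F (response rows
#' permuted, the already-selected set retained); the candidate with the
#' lowest p-value enters (ties broken by larger added R2, then lower
#' index), and selection stops when no candidate reaches `alpha`. An
#' empty selection is a legal result.
#'
#' @param responseD Response [as_distmat()].
#' @param basis A [mem_basis()] aligned to the response labels.
#' @param alpha Entry threshold in (0, 1] (0 forbids all entries).
#' @param n_perm Permutations per candidate test.
#' @param seed Integer seed.
#' @return A tibble of class `mem_selection` with one row per selected
#'   eigenvector in selection order: `step`, `mem`, `r2_added`,
#'   `r2_cum`, `statistic`, `p`.
#' @export
forward_select_mems <- function(responseD, basis, alpha = 0.05,
                                n_perm = 999, seed = NULL) {
  stopifnot(inherits(basis, "mem_basis"))
  responseD <- as_distmat(responseD, tol = 1e-6)
  al <- align_specimens(response = responseD, mem = basis$vectors)
  V <- al$mem
  n <- nrow(V)
  Y <- pcoa(al$response)$coordinates
  tot <- sum(Y^2)
  if (tot <= 0) abort("response matrix has no variation (all distances zero)")
  run <- function() {
    selected <- integer(0)
    rows <- list()
    r2_sel <- 0
    repeat {
      cand <- setdiff(seq_len(ncol(V)), selected)
      if (!length(cand) || length(selected) >= n - 3 || alpha <= 0) break
      perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
      Qs <- if (length(selected)) {
        predictor_basis(V[, selected, drop = FALSE], quiet = TRUE)
      } else NULL
      r2s_perm <- if (is.null(Qs)) {
        numeric(n_perm)
      } else {
        vapply(perms, function(idx)
          sum(crossprod(Qs, Y[idx, , drop = FALSE])^2) / tot, numeric(1))
      }
      stats <- purrr::map_dfr(cand, function(j) {
        Qf <- predictor_basis(V[, c(selected, j), drop = FALSE], quiet = TRUE)
        mf <- ncol(Qf)
        r2f <- sum(crossprod(Qf, Y)^2) / tot
        Fobs <- (r2f - r2_sel) / ((1 - r2f) / (n - 1 - mf))
        Fperm <- vapply(seq_len(n_perm), function(b) {
          Yp <- Y[perms[[b]], , drop = FALSE]
          r2fp <- sum(crossprod(Qf, Yp)^2) / tot
          (r2fp - r2s_perm[b]) / ((1 - r2fp) / (n - 1 - mf))
        }, numeric(1))
        tibble::tibble(
          mem = j, r2_added = r2f - r2_sel, r2_cum = r2f,
          statistic = Fobs,
          p = (sum(Fperm >= Fobs - 1e-12) + 1) / (n_perm + 1))
      })
      best <- stats[order(stats$p, -stats$r2_added, stats$mem), ][1, ]
      if (best$p > alpha) break
      selected <- c(selected, best$mem)
      r2_sel <- best$r2_cum
      rows[[length(rows) + 1L]] <- best
    }
    if (length(rows)) {
      out <- dplyr::bind_rows(rows)
      out$step <- seq_len(nrow(out))
      out[, c("step", "mem", "r2_added", "r2_cum", "statistic", "p")]
    } else {
      tibble::tibble(step = integer(0), mem = integer(0),
                     r2_added = numeric(0), r2_cum = numeric(0),
                     statistic = numeric(0), p = numeric(0))
    }
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("mem_selection", class(out))
  out
}

#' Variance partitioning of a response distance matrix
#'
#' Partitions the variation of the response into four adjusted-R2
#' fractions: `a` explained by the partner genetic predictors alone,
#' `b` shared between partner and space (spatially structured partner
#' variation), `c` purely spatial, and `d` unexplained. With
#' `A = adjR2(partner)`, `B = adjR2(space)` and `AB = adjR2(both)`:
#' `a = AB - B`, `b = A + B - AB`, `c = AB - A`, `d = 1 - AB`. The
#' fractions sum to 1; `a`, `b`, `c` may be slightly negative (an
#' adjusted-R2 artifact) and are reported raw, with clamped-at-zero
#' display values available from [tidy()]. When `spaceX` is empty the
#' partition reduces to `a = A`, `b = c = 0`, `d = 1 - A`.
#'
#' @param responseD Response [as_distmat()].
#' @param partnerX Partner predictor matrix (axes of the partner genetic
#'   distance matrix), or `NULL`/zero columns when the partner carries no
#'   variation.
#' @param spaceX Spatial predictor matrix (selected MEM columns), or
#'   `NULL` when no spatial variables are available or selected.
#' @return Object of class `varpart_fractions`: fractions `a`, `b`,
#'   `c`, `d`, plus the component fits (adjusted and unadjusted).
#' @export
variance_partition <- function(responseD, partnerX, spaceX = NULL) {
  responseD <- as_distmat(responseD, tol = 1e-6)
  has_partner <- !is.null(partnerX) && NCOL(partnerX) > 0
  has_space <- !is.null(spaceX) && NCOL(spaceX) > 0
  fit <- function(X) dbrda(responseD, X, n_perm = 0)
  fit_partner <- fit(if (has_partner) partnerX else NULL)
  A <- fit_partner$r2_adj
  if (!has_space) {
    out <- list(a = A, b = 0, c = 0, d = 1 - A,
                spatial = FALSE,
                partner_fit = fit_partner, space_fit = NULL, both_fit = NULL,
                a_raw = fit_partner$r2, b_raw = 0, c_raw = 0,
                d_raw = 1 - fit_partner$r2,
                labels = rownames(responseD))
    return(structure(out, class = "varpart_fractions"))
  }
  fit_space <- fit(spaceX)
  both <- if (has_partner) cbind(as.matrix(partnerX), as.matrix(spaceX)) else spaceX
  fit_both <- fit(both)
  B <- fit_space$r2_adj
  AB <- fit_both$r2_adj
  Au <- fit_partner$r2; Bu <- fit_space$r2; ABu <- fit_both$r2
  out <- list(
    a = AB - B, b = A + B - AB, c = AB - A, d = 1 - AB,
    spatial = TRUE,
    partner_fit = fit_partner, space_fit = fit_space, both_fit = fit_both,
    a_raw = ABu - Bu, b_raw = Au + Bu - ABu, c_raw = ABu - Au, d_raw = 1 - ABu,
    labels = rownames(responseD))
  structure(out, class = "varpart_fractions")
}

#' @export
print.varpart_fractions <- function(x, ...) {
  cat("<varpart_fractions>\n")
  cat(sprintf("  partner [a] = %.3f  shared [b] = %.3f  space [c] = %.3f  unexplained [d] = %.3f\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' @method tidy varpart_fractions
#' @export
tidy.varpart_fractions <- function(x, ...) {
  tibble::tibble(
    fraction = c("partner", "shared", "space", "unexplained"),
    value = c(x$a, x$b, x$c, x$d),
    value_clamped = pmax(c(x$a, x$b, x$c, x$d), 0),
    unadjusted = c(x$a_raw, x$b_raw, x$c_raw, x$d_raw))
}

#' @method glance varpart_fractions
#' @export
glance.varpart_fractions <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b, c = x$c, d = x$d,
    explained = x$a + x$b + x$c,
    n = length(x$labels),
    m_partner = if (is.null(x$partner_fit)) 0L else x$partner_fit$m,
    m_space = if (is.null(x$space_fit)) 0L else x$space_fit$m)
}
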