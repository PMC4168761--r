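#' Uncorrected p-distances from an alignment
#'
#' For each pair, the proportion of differing sites among the sites where
#' both sequences carry an unambiguous base (A, C, G or T). Gaps, `N` and
#' IUPAC ambiguity codes are treated as missing. With
#' `deletion = "pairwise"` (default) missing sites are excluded pair by
#' pair; with `"complete"` every column containing any missing state in
#' any sequence is dropped before comparison.
#'
#' @param aln A [dna_alignment()].
#' @param deletion `"pairwise"` or `"complete"` gap/ambiguity handling.
#' @return A [as_distmat()] of values in [0, 1], with attribute
#'   `n_sites`: the per-pair count of compared sites.
#' @examples
#' aln <- dna_alignment(c(a = "ACGT", b = "ACGA", c = "AC-A"))
#' p_distance(aln)
#' @export
p_distance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- aln_matrix(aln)
  valid <- matrix(m %in% c("A", "C", "G", "T"), nrow(m), ncol(m))
  if (deletion == "complete") {
    keep <- colSums(valid) == nrow(m)
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(m)
  ids <- rownames(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  nsites <- matrix(ncol(m), n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      nc <- sum(ok)
      if (nc == 0) {
        abort(sprintf("no comparable sites for pair ('%s', '%s')", ids[i], ids[j]))
      }
      d <- sum(m[i, ok] != m[j, ok]) / nc
      D[i, j] <- D[j, i] <- d
      nsites[i, j] <- nsites[j, i] <- nc
    }
  }
  out <- as_distmat(D)
  attr(out, "n_sites") <- nsites
  attr(out, "deletion") <- deletion
  out
}

#' Tamura-Nei (TN93) distances from an alignment
#'
#' Closed-form TN93 estimator distinguishing the two transition classes
#' (A<->G and C<->T) from transversions, with unequal base frequencies.
#' Base frequencies are estimated from the two sequences of each pair at
#' their compared sites by default (`frequencies = "pair"`), or from the
#' whole alignment (`"global"`). Missing-data handling follows
#' [p_distance()].
#'
#' When a pair is saturated (any logarithm argument is non-positive) the
#' distance is reported as `NA` and flagged in the logical
#' `inestimable` attribute rather than returned as a silent `NaN`.
#'
#' @inheritParams p_distance
#' @param frequencies Base-frequency estimation: per `"pair"` or
#'   `"global"` across the alignment.
#' @return A [as_distmat()] with attribute `inestimable` (logical
#'   matrix).
#' @export
tn93_distance <- function(aln, frequencies = c("pair", "global"),
                          deletion = c("pairwise", "complete")) {
  frequencies <- match.arg(frequencies)
  deletion <- match.arg(deletion)
  bases <- c("A", "C", "G", "T")
  m <- aln_matrix(aln)
  valid <- matrix(m %in% bases, nrow(m), ncol(m))
  if (deletion == "complete") {
    keep <- colSums(valid) == nrow(m)
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(m)
  ids <- rownames(m)
  gfreq <- NULL
  if (frequencies == "global") {
    tab <- table(factor(m[valid], levels = bases))
    gfreq <- as.numeric(tab) / sum(tab)
    names(gfreq) <- bases
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  flag <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) {
        abort(sprintf("no comparable sites for pair ('%s', '%s')", ids[i], ids[j]))
      }
      x <- m[i, ok]; y <- m[j, ok]
      nc <- length(x)
      g <- if (is.null(gfreq)) {
        tab <- table(factor(c(x, y), levels = bases))
        as.numeric(tab) / sum(tab)
      } else {
        unname(gfreq)
      }
      names(g) <- bases
      diff <- x != y
      ag <- (x %in% c("A", "G")) & (y %in% c("A", "G"))
      ct <- (x %in% c("C", "T")) & (y %in% c("C", "T"))
      P1 <- sum(diff & ag) / nc
      P2 <- sum(diff & ct) / nc
      Q <- sum(diff & !ag & !ct) / nc
      d <- tn93_formula(g, P1, P2, Q)
      if (is.na(d)) {
        flag[i, j] <- flag[j, i] <- TRUE
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  out <- as_distmat(D)
  attr(out, "inestimable") <- flag
  attr(out, "frequencies") <- frequencies
  out
}

# internal: TN93 closed form; NA when saturated (log argument <= 0) or
# when a required frequency class is empty but its difference class is not
tn93_formula <- function(g, P1, P2, Q) {
  gR <- g[["A"]] + g[["G"]]
  gY <- g[["C"]] + g[["T"]]
  if (P1 + P2 + Q == 0) return(0)
  if ((gR <= 0 && (P1 > 0 || Q > 0)) || (gY <= 0 && (P2 > 0 || Q > 0))) {
    return(NA_real_)
  }
  k1 <- if (gR > 0) 2 * g[["A"]] * g[["G"]] / gR else 0
  k2 <- if (gY > 0) 2 * g[["T"]] * g[["C"]] / gY else 0
  k3 <- 2 * (gR * gY -
               (if (gR > 0) g[["A"]] * g[["G"]] * gY / gR else 0) -
               (if (gY > 0) g[["T"]] * g[["C"]] * gR / gY else 0))
  terms <- 0
  if (k1 > 0) {
    w1 <- 1 - P1 / k1 - Q / (2 * gR)
    if (w1 <= 0) return(NA_real_)
    terms <- terms - k1 * log(w1)
  } else if (P1 > 0) return(NA_real_)
  if (k2 > 0) {
    w2 <- 1 - P2 / k2 - Q / (2 * gY)
    if (w2 <= 0) return(NA_real_)
    terms <- terms - k2 * log(w2)
  } else if (P2 > 0) return(NA_real_)
  if (k3 > 0) {
    w3 <- 1 - Q / (2 * gR * gY)
    if (w3 <= 0) return(NA_real_)
    terms <- terms - k3 * log(w3)
  } else if (Q > 0) return(NA_real_)
  unname(terms)
}

#' Great-circle geographic distances
#'
#' Haversine distances in meters on a sphere of radius 6,371,000 m. At
#' the spatial extents of typical specimen sets (up to ~1,300 km) the
#' sphere/ellipsoid difference is immaterial to the spatial
#' eigenfunction structure built downstream.
#'
#' @param coords Tibble/data frame with `specimen_id`, `lon`, `lat`
#'   (decimal degrees).
#' @return A [as_distmat()] of distances in meters.
#' @export
geographic_distance <- function(coords) {
  coords <- validate_coordinates(tibble::as_tibble(coords))
  xy <- cbind(coords$lon, coords$lat)
  D <- geosphere::distm(xy, xy,
                        fun = function(a, b) geosphere::distHaversine(a, b, r = 6371000))
  dimnames(D) <- list(coords$specimen_id, coords$specimen_id)
  as_distmat(D, tol = 1e-6)
}

#' Summary statistics of a distance matrix
#'
#' Mean, standard deviation and range over the off-diagonal
#' upper-triangle entries, the per-matrix summary used to characterise
#' genetic diversity and spatial extent (the maximum entry of a
#' geographic matrix).
#'
#' @param D A [as_distmat()] matrix.
#' @return A one-row tibble: `n`, `n_pairs`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_matrix <- function(D) {
  D <- as_distmat(D)
  if (nrow(D) < 2) abort("need at least 2 specimens to summarise")
  v <- upper_vals(D)
  tibble::tibble(
    n = nrow(D),
    n_pairs = length(v),
    mean = mean(v, na.rm = TRUE),
    sd = sd(v, na.rm = TRUE),
    min = min(v, na.rm = TRUE),
    max = max(v, na.rm = TRUE))
}
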