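#' Run the full congruence analysis
#'
#' Orchestrates the complete workflow in one or both dependent-matrix
#' directions: genetic distances (computed from alignments or taken as
#' supplied), geographic distances (from coordinates or supplied),
#' spatial eigenfunction basis, forward selection of spatial
#' eigenvectors against the response, adjusted-R2 variance partitioning
#' into partner/shared/space/unexplained fractions, and the Procrustes
#' congruence test with association randomisation. When no geographic
#' input is given the spatial stages are skipped and the partition
#' reduces to partner and unexplained fractions.
#'
#' Both directions share one spatial basis (space depends only on the
#' locations), so any difference in selected eigenvectors stems from the
#' response matrix alone. Every stochastic stage is seeded from
#' `config$seed` by fixed offsets; re-running with the same inputs and
#' configuration reproduces the report exactly.
#'
#' @param algae Algal input: a [dna_alignment()] or a [as_distmat()].
#' @param fungi Fungal input: a [dna_alignment()] or a [as_distmat()].
#' @param coords Optional specimen coordinates (tibble `specimen_id`,
#'   `lon`, `lat`).
#' @param geo_dist Optional precomputed geographic [as_distmat()]
#'   (meters); overrides `coords`.
#' @param config A [run_config()].
#' @return Object of class `congruence_report`; see [tidy()],
#'   [glance()], [autoplot()] and [write_report()].
#' @export
run_congruence_analysis <- function(algae, fungi, coords = NULL,
                                    geo_dist = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  to_dist <- function(x, what) {
    if (inherits(x, "dna_alignment")) {
      stage(paste0("distances (", what, ")"), {
        if (config$distance_model == "p") p_distance(x) else tn93_distance(x)
      })
    } else {
      stage(paste0("validate (", what, ")"), as_distmat(x, tol = 1e-6))
    }
  }
  algD <- to_dist(algae, "algae")
  funD <- to_dist(fungi, "fungi")
  geoD <- NULL
  if (!is.null(geo_dist)) {
    geoD <- stage("validate (geographic)", as_distmat(geo_dist, tol = 1e-6))
  } else if (!is.null(coords)) {
    geoD <- stage("geographic distances", geographic_distance(coords))
  }
  aligned <- if (is.null(geoD)) {
    stage("label matching", align_specimens(algae = algD, fungi = funD))
  } else {
    stage("label matching",
          align_specimens(algae = algD, fungi = funD, geographic = geoD))
  }
  algD <- aligned$algae
  funD <- aligned$fungi
  geoD <- aligned$geographic
  mem <- NULL
  if (!is.null(geoD)) {
    mem <- stage("spatial eigenfunctions",
                 mem_basis(geoD, truncation = config$mem_truncation))
  }
  directions <- switch(config$dependent,
                       both = c("algae", "fungi"),
                       algae = "algae", fungi = "fungi")
  run_direction <- function(dir_name, off) {
    respD <- if (dir_name == "algae") algD else funD
    partD <- if (dir_name == "algae") funD else algD
    selection <- NULL
    spaceX <- NULL
    if (!is.null(mem)) {
      selection <- stage(paste0("forward selection (", dir_name, "-dependent)"),
        forward_select_mems(respD, mem, alpha = config$forward_alpha,
                            n_perm = config$n_perm_select,
                            seed = stage_seed(config$seed, 10L + off)))
      if (nrow(selection)) {
        spaceX <- mem$vectors[, selection$mem, drop = FALSE]
      }
    }
    # the combined constrained model must keep residual degrees of
    # freedom: partner axes are capped (largest eigenvalues first) so
    # that m_partner + m_space <= n - 3
    n <- nrow(respD)
    cap <- max(1L, n - 3L - (if (is.null(spaceX)) 0L else ncol(spaceX)))
    partnerX <- stage(paste0("explanatory axes (", dir_name, "-dependent)"),
                      explanatory_axes(partD, rule = config$axis_rule,
                                       k = config$axis_k, max_axes = cap))
    vp <- stage(paste0("variance partitioning (", dir_name, "-dependent)"),
                variance_partition(respD, partnerX, spaceX))
    paco <- stage(paste0("procrustes test (", dir_name, "-dependent)"),
                  paco_test(respD, partD, n_perm = config$n_perm_paco,
                            seed = stage_seed(config$seed, 20L + off)))
    list(direction = dir_name, selection = selection, varpart = vp,
         paco = paco, n_spatial = if (is.null(mem)) 0L else ncol(mem$vectors))
  }
  results <- lapply(seq_along(directions), function(i) {
    run_direction(directions[i], i)
  })
  names(results) <- directions
  summaries <- dplyr::bind_rows(
    dplyr::mutate(summarize_matrix(algD), matrix = "algae", .before = 1),
    dplyr::mutate(summarize_matrix(funD), matrix = "fungi", .before = 1),
    if (!is.null(geoD)) {
      dplyr::mutate(summarize_matrix(geoD), matrix = "geographic", .before = 1)
    })
  structure(list(results = results, summaries = summaries,
                 mem = mem, config = config,
                 labels = rownames(algD)),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("<congruence_report: %d specimens, %s>\n",
              length(x$labels),
              if (is.null(x$mem)) "no spatial input"
              else sprintf("%d spatial eigenvectors (truncation %.6g m)",
                           ncol(x$mem$vectors), x$mem$truncation)))
  hdr <- sprintf("  %-16s %-22s %8s %8s %8s %8s %8s",
                 "Dependent", "Significant MEMs", "Partner", "Shared",
                 "Space", "Unexpl.", "P")
  cat(hdr, "\n")
  for (r in x$results) {
    vp <- r$varpart
    mems <- if (is.null(r$selection)) "-"
            else if (nrow(r$selection) == 0) "none"
            else paste(r$selection$mem, collapse = ", ")
    spatial <- !is.null(r$selection)
    cat(sprintf("  %-16s %-22s %8.2f %8s %8s %8.2f %8s\n",
                r$direction, mems, vp$a,
                if (spatial) sprintf("%.2f", vp$b) else "-",
                if (spatial) sprintf("%.2f", vp$c) else "-",
                vp$d, format_pval(r$paco$p, r$paco$n_perm)))
  }
  invisible(x)
}

#' @method tidy congruence_report
#' @export
tidy.congruence_report <- function(x, ...) {
  purrr::map_dfr(x$results, function(r) {
    tibble::tibble(
      dependent = r$direction,
      significant_mems = list(if (is.null(r$selection)) integer(0)
                              else r$selection$mem),
      partner = r$varpart$a,
      shared = if (is.null(r$selection)) NA_real_ else r$varpart$b,
      space = if (is.null(r$selection)) NA_real_ else r$varpart$c,
      unexplained = r$varpart$d,
      paco_m2 = r$paco$m2,
      p_paco = r$paco$p)
  })
}

#' @method glance congruence_report
#' @export
glance.congruence_report <- function(x, ...) {
  tibble::tibble(
    n = length(x$labels),
    n_directions = length(x$results),
    n_spatial_vectors = if (is.null(x$mem)) 0L else ncol(x$mem$vectors),
    mem_truncation = if (is.null(x$mem)) NA_real_ else x$mem$truncation,
    seed = x$config$seed)
}

#' Write a congruence report to TSV files
#'
#' Emits `report.tsv` (one row per direction, full precision),
#' `residuals.tsv` (per-specimen Procrustes residuals per direction, in
#' input order), `mems.tsv` (selected eigenvectors with their partial
#' statistics) and `provenance.txt` (configuration and seeds). All
#' tables carry a comment header recording configuration and seed.
#'
#' @param report A [run_congruence_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "congruence_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  hdr <- c(
    sprintf("seed=%d", cfg$seed),
    sprintf("distance_model=%s", cfg$distance_model),
    sprintf("forward_alpha=%g", cfg$forward_alpha),
    sprintf("n_perm_select=%d", cfg$n_perm_select),
    sprintf("n_perm_paco=%d", cfg$n_perm_paco),
    sprintf("axis_rule=%s", cfg$axis_rule),
    sprintf("mem_truncation=%s",
            if (is.null(report$mem)) "none"
            else format(report$mem$truncation, digits = 10)))
  write_tsv_commented <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    df <- as.data.frame(df)
    for (j in seq_along(df)) {
      if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 17)
    }
    write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  rep_tbl <- tidy(report)
  rep_tbl$significant_mems <- vapply(rep_tbl$significant_mems,
                                     paste, character(1), collapse = ",")
  write_tsv_commented(rep_tbl, file.path(dir, "report.tsv"))
  resid_tbl <- purrr::map_dfr(report$results, function(r) {
    dplyr::mutate(tidy(r$paco), dependent = r$direction, .before = 1)
  })
  write_tsv_commented(resid_tbl, file.path(dir, "residuals.tsv"))
  mem_tbl <- purrr::map_dfr(report$results, function(r) {
    if (is.null(r$selection) || nrow(r$selection) == 0) return(NULL)
    dplyr::mutate(tibble::as_tibble(r$selection),
                  dependent = r$direction, .before = 1)
  })
  if (nrow(mem_tbl) == 0) {
    mem_tbl <- tibble::tibble(dependent = character(0), step = integer(0),
                              mem = integer(0))
  }
  write_tsv_commented(mem_tbl, file.path(dir, "mems.tsv"))
  writeLines(hdr, file.path(dir, "provenance.txt"))
  invisible(dir)
}
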