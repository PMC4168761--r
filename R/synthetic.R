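#' Scenario for the co-phylogeny simulator
#'
#' Defines the generating conditions for a paired fungal/algal dataset
#' with known ground truth: a pure-birth fungal tree, an algal lineage
#' history driven by co-speciation versus horizontal acquisition,
#' Jukes-Cantor sequence evolution on both trees, and specimen placement
#' blending Brownian spatial signal with uniform scatter.
#'
#' Defaults describe a regionally sampled, strongly co-dispersing
#' symbiosis: 40 specimens, full co-speciation, no switching, 600-site
#' ITS-like sequences, 0.05 expected substitutions per site from root to
#' tip (pairwise p-distances mostly within 0 to 0.2), full spatial
#' signal inside a 100 km square.
#'
#' @param n_specimens Number of specimens (fungal tips), >= 4.
#' @param p_cospeciation Probability in [0, 1] that the algal lineage
#'   co-speciates at each fungal speciation; otherwise the new fungal
#'   daughter acquires an existing algal lineage uniformly at random.
#' @param switch_rate Per-lineage probability, applied at each fungal
#'   speciation event, of reassigning a fungal lineage to a uniformly
#'   chosen existing algal lineage (horizontal switching), >= 0.
#' @param seq_length Alignment length in sites.
#' @param subst_rate Expected substitutions per site across the tree
#'   depth (root to tip).
#' @param spatial_signal Blend weight sigma in [0, 1]: 0 places
#'   specimens uniformly at random, 1 places them by Brownian diffusion
#'   along the fungal tree.
#' @param bounding_box Width and height of the sampling window in
#'   meters.
#' @param seed Integer seed; every simulator output is a pure function
#'   of the scenario including this seed.
#' @return A list of class `cophylo_scenario`.
#' @export
cophylo_scenario <- function(n_specimens = 40, p_cospeciation = 1,
                             switch_rate = 0, seq_length = 600,
                             subst_rate = 0.05, spatial_signal = 1,
                             bounding_box = c(100000, 100000), seed = 1L) {
  if (n_specimens < 4) abort("n_specimens must be >= 4")
  if (p_cospeciation < 0 || p_cospeciation > 1) abort("p_cospeciation must lie in [0, 1]")
  if (switch_rate < 0 || switch_rate > 1) abort("switch_rate must lie in [0, 1]")
  if (spatial_signal < 0 || spatial_signal > 1) abort("spatial_signal must lie in [0, 1]")
  if (seq_length < 1 || subst_rate < 0) abort("invalid sequence parameters")
  if (length(bounding_box) != 2 || any(bounding_box <= 0)) {
    abort("bounding_box must be two positive extents in meters")
  }
  structure(list(
    n_specimens = as.integer(n_specimens),
    p_cospeciation = p_cospeciation,
    switch_rate = switch_rate,
    seq_length = as.integer(seq_length),
    subst_rate = subst_rate,
    spatial_signal = spatial_signal,
    bounding_box = as.numeric(bounding_box),
    seed = as.integer(seed)), class = "cophylo_scenario")
}

#' @export
print.cophylo_scenario <- function(x, ...) {
  cat("<cophylo_scenario>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-15s %s\n", nm, paste(x[[nm]], collapse = " x ")))
  }
  invisible(x)
}

#' Simulate a paired fungal/algal lineage history
#'
#' Grows the fungal tree by a pure-birth process (unit speciation rate
#' per lineage) to `n_specimens` tips. At each fungal speciation the
#' associated algal lineage co-speciates with probability
#' `p_cospeciation` (one daughter alga per daughter fungus); otherwise
#' the new fungal daughter attaches to an existing algal lineage chosen
#' uniformly. After each speciation every active fungal lineage switches
#' its algal association to a uniformly chosen existing lineage with
#' probability `switch_rate`. Algal lineages never go extinct.
#'
#' @param scenario A [cophylo_scenario()].
#' @return A list of class `cophylogeny_sim`: `fungal_tree` (an
#'   [ape::read.tree] style `phylo`, tips are specimen ids),
#'   `algal_tree` (`phylo` over distinct algal lineages `A1`, `A2`,
#'   ..., or `NULL` when only one lineage exists), `association` (tibble
#'   `specimen_id`, `algal_lineage`), `t_end` (tree depth in model time).
#' @export
simulate_cophylogeny <- function(scenario) {
  stopifnot(inherits(scenario, "cophylo_scenario"))
  withr::with_seed(scenario$seed, {
    n <- scenario$n_specimens
    f_parent <- NA_integer_
    f_birth <- 0
    f_split <- NA_real_
    assoc <- 1L
    n_alg <- 1L
    a_parent <- integer(0)  # algal split events: parent id
    a_child <- integer(0)   # new lineage id
    a_time <- numeric(0)
    active <- 1L
    t <- 0
    while (length(active) < n) {
      t <- t + rexp(1, rate = length(active))
      sp <- active[sample.int(length(active), 1L)]
      id1 <- length(f_parent) + 1L
      id2 <- id1 + 1L
      f_parent[c(id1, id2)] <- sp
      f_birth[c(id1, id2)] <- t
      f_split[c(id1, id2)] <- NA_real_
      f_split[sp] <- t
      a <- assoc[sp]
      if (runif(1) < scenario$p_cospeciation) {
        n_alg <- n_alg + 1L
        a_parent <- c(a_parent, a)
        a_child <- c(a_child, n_alg)
        a_time <- c(a_time, t)
        assoc[id1] <- a
        assoc[id2] <- n_alg
      } else {
        assoc[id1] <- a
        assoc[id2] <- sample.int(n_alg, 1L)
      }
      active <- c(active[active != sp], id1, id2)
      if (scenario$switch_rate > 0) {
        sw <- runif(length(active)) < scenario$switch_rate
        if (any(sw)) {
          assoc[active[sw]] <- sample.int(n_alg, sum(sw), replace = TRUE)
        }
      }
    }
    t_end <- t + rexp(1, rate = length(active))
    tips <- sort(active)
    specimen_ids <- sprintf("S%03d", seq_len(n))
    fungal_tree <- build_phylo(f_parent, f_birth, f_split, tips, t_end,
                               labels = specimen_ids)
    algal_tree <- if (n_alg > 1) {
      build_algal_tree(n_alg, a_parent, a_child, a_time, t_end)
    } else NULL
    association <- tibble::tibble(
      specimen_id = specimen_ids,
      algal_lineage = paste0("A", assoc[tips]))
    structure(list(fungal_tree = fungal_tree, algal_tree = algal_tree,
                   association = association, t_end = t_end,
                   scenario = scenario), class = "cophylogeny_sim")
  })
}

# internal: assemble a phylo object from birth-process lineage records.
# Lineage ids: every id either split (internal node) or is a tip; the
# root is lineage 1.
build_phylo <- function(parent, birth, split, tips, t_end, labels) {
  n <- length(tips)
  internal <- which(!is.na(split))
  internal <- internal[order(split[internal])]  # root (earliest split) first
  num <- integer(length(parent))
  num[tips] <- seq_len(n)
  num[internal] <- n + seq_along(internal)
  ids <- c(tips, internal[-1])  # every lineage with a parent edge
  edge <- cbind(num[parent[ids]], num[ids])
  end_time <- ifelse(is.na(split[ids]), t_end, split[ids])
  structure(list(edge = edge,
                 edge.length = end_time - birth[ids],
                 tip.label = labels,
                 Nnode = length(internal)), class = "phylo")
}

# internal: algal lineage tree from split events. A lineage persists
# through its splits (serial events), so each split becomes an internal
# node whose children are the continuing lineage segment and the new one.
build_algal_tree <- function(n_alg, a_parent, a_child, a_time, t_end) {
  ntip <- n_alg
  env <- new.env()
  env$edge_p <- integer(0)
  env$edge_c <- integer(0)
  env$edge_len <- numeric(0)
  env$next_internal <- ntip + 1L
  # events of each lineage, in time order
  ev <- split(data.frame(child = a_child, time = a_time),
              factor(a_parent, levels = seq_len(n_alg)))
  # returns node number of the subtree rooted where lineage `a` is at `from`
  descend <- function(a, from) {
    e <- ev[[a]]
    e <- e[e$time > from + 1e-12, , drop = FALSE]
    if (nrow(e) == 0) {
      return(list(node = a, time = t_end))
    }
    e <- e[order(e$time), , drop = FALSE]
    node <- env$next_internal
    env$next_internal <- node + 1L
    left <- descend(a, e$time[1])
    right <- descend(e$child[1], e$time[1])
    for (ch in list(left, right)) {
      env$edge_p <- c(env$edge_p, node)
      env$edge_c <- c(env$edge_c, ch$node)
      env$edge_len <- c(env$edge_len, ch$time - e$time[1])
    }
    list(node = node, time = e$time[1])
  }
  root <- descend(1L, -Inf)
  structure(list(edge = cbind(env$edge_p, env$edge_c),
                 edge.length = env$edge_len,
                 tip.label = paste0("A", seq_len(ntip)),
                 Nnode = ntip - 1L), class = "phylo")
}

#' Evolve sequences along a tree under Jukes-Cantor
#'
#' Site-independent Jukes-Cantor simulation from a uniform-random root
#' sequence. Branch lengths are rescaled so the maximum root-to-tip path
#' equals `subst_rate` expected substitutions per site; along a branch
#' of (rescaled) length `b` each site changes with probability
#' `(3/4)(1 - exp(-4 b / 3))`, uniformly to one of the other bases.
#'
#' @param tree A `phylo` with branch lengths.
#' @param subst_rate Expected substitutions per site, root to tip.
#' @param seq_length Number of sites.
#' @param seed Integer seed (optional).
#' @return A [dna_alignment()] named by the tree's tip labels.
#' @export
evolve_sequences <- function(tree, subst_rate, seq_length, seed = NULL) {
  run <- function() {
    bases <- c("A", "C", "G", "T")
    ntip <- length(tree$tip.label)
    depth <- max(ape::node.depth.edgelength(tree))
    scale <- if (depth > 0) subst_rate / depth else 0
    tree_o <- ape::reorder.phylo(tree, "cladewise")
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample.int(4L, seq_length, replace = TRUE)
    for (k in seq_len(nrow(tree_o$edge))) {
      par <- tree_o$edge[k, 1]
      chd <- tree_o$edge[k, 2]
      b <- tree_o$edge.length[k] * scale
      s <- seqs[[par]]
      p_change <- 0.75 * (1 - exp(-4 * b / 3))
      hit <- which(runif(seq_length) < p_change)
      if (length(hit)) {
        step <- sample.int(3L, length(hit), replace = TRUE)
        s[hit] <- (s[hit] - 1L + step) %% 4L + 1L
      }
      seqs[[chd]] <- s
    }
    out <- vapply(seq_len(ntip),
                  function(i) paste(bases[seqs[[i]]], collapse = ""),
                  character(1))
    dna_alignment(stats::setNames(out, tree$tip.label))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Place specimens in space with tunable phylogenetic signal
#'
#' Tip coordinates are a convex blend of a 2-D Brownian diffusion along
#' the fungal tree (rescaled to fill the bounding box) and uniform
#' random positions: `sigma = 1` gives fully tree-structured placement
#' (close relatives are spatial neighbours), `sigma = 0` random
#' placement. Meter offsets are converted to decimal degrees near the
#' equator so the haversine geographic distances reproduce the box
#' extents.
#'
#' @param tree Fungal `phylo` with branch lengths.
#' @param spatial_signal Blend weight sigma in [0, 1].
#' @param bounding_box Width/height of the window in meters.
#' @param seed Integer seed (optional).
#' @return Tibble `specimen_id`, `lon`, `lat`; all points inside the
#'   box.
#' @export
assign_locations <- function(tree, spatial_signal, bounding_box, seed = NULL) {
  run <- function() {
    ntip <- length(tree$tip.label)
    tree_o <- ape::reorder.phylo(tree, "cladewise")
    root <- ntip + 1L
    pos <- matrix(NA_real_, ntip + tree$Nnode, 2)
    pos[root, ] <- 0
    for (k in seq_len(nrow(tree_o$edge))) {
      par <- tree_o$edge[k, 1]
      chd <- tree_o$edge[k, 2]
      pos[chd, ] <- pos[par, ] + rnorm(2, sd = sqrt(max(tree_o$edge.length[k], 0)))
    }
    bm <- pos[seq_len(ntip), , drop = FALSE]
    for (d in 1:2) {
      rng <- range(bm[, d])
      bm[, d] <- if (diff(rng) > 0) {
        (bm[, d] - rng[1]) / diff(rng) * bounding_box[d]
      } else {
        rep(bounding_box[d] / 2, ntip)
      }
    }
    unif <- cbind(runif(ntip, 0, bounding_box[1]),
                  runif(ntip, 0, bounding_box[2]))
    xy <- spatial_signal * bm + (1 - spatial_signal) * unif
    meters_per_degree <- pi * 6371000 / 180
    tibble::tibble(specimen_id = tree$tip.label,
                   lon = xy[, 1] / meters_per_degree,
                   lat = xy[, 2] / meters_per_degree)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a complete synthetic paired dataset
#'
#' Composes [simulate_cophylogeny()], [evolve_sequences()] (fungal
#' sequences on the fungal tree; algal sequences on the algal lineage
#' tree, mapped to specimens through the association) and
#' [assign_locations()]. Deterministic: per-component seeds are derived
#' from the scenario seed by fixed offsets.
#'
#' @param scenario A [cophylo_scenario()].
#' @return A list of class `synthetic_dataset`: `algal` and `fungal`
#'   [dna_alignment()]s over specimens, `coords` tibble, `association`
#'   tibble, `sim` (the lineage history) and `scenario`.
#' @export
generate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "cophylo_scenario"))
  sim <- simulate_cophylogeny(scenario)
  fungal <- evolve_sequences(sim$fungal_tree, scenario$subst_rate,
                             scenario$seq_length,
                             seed = stage_seed(scenario$seed, 1001L))
  if (is.null(sim$algal_tree)) {
    one <- withr::with_seed(stage_seed(scenario$seed, 1002L), {
      paste(sample(c("A", "C", "G", "T"), scenario$seq_length, replace = TRUE),
            collapse = "")
    })
    lineage_seqs <- stats::setNames(one, "A1")
  } else {
    aln <- evolve_sequences(sim$algal_tree, scenario$subst_rate,
                            scenario$seq_length,
                            seed = stage_seed(scenario$seed, 1002L))
    lineage_seqs <- unclass(aln)
  }
  algal <- dna_alignment(stats::setNames(
    unname(lineage_seqs[sim$association$algal_lineage]),
    sim$association$specimen_id))
  coords <- assign_locations(sim$fungal_tree, scenario$spatial_signal,
                             scenario$bounding_box,
                             seed = stage_seed(scenario$seed, 1003L))
  structure(list(algal = algal, fungal = fungal, coords = coords,
                 association = sim$association, sim = sim,
                 scenario = scenario), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d specimens, %d distinct algal lineages, %d sites>\n",
              x$scenario$n_specimens,
              length(unique(x$association$algal_lineage)),
              x$scenario$seq_length))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `algal.fasta`, `fungal.fasta`, `coordinates.csv`,
#' `association.tsv` and `scenario.txt` (key=value provenance) in
#' formats guaranteed to round-trip through the package readers; output
#' is byte-identical for identical scenarios.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(dataset$algal, file.path(dir, "algal.fasta"))
  write_alignment(dataset$fungal, file.path(dir, "fungal.fasta"))
  write_coordinates(dataset$coords, file.path(dir, "coordinates.csv"))
  write.table(as.data.frame(dataset$association),
              file.path(dir, "association.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  sc <- dataset$scenario
  writeLines(sprintf("%s=%s", names(sc),
                     vapply(sc, function(v) paste(format(v, digits = 17), collapse = ","),
                            character(1))),
             file.path(dir, "scenario.txt"))
  invisible(dir)
}
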