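# shared builders for test fixtures; everything is generated in code

euclid_dist <- function(points) {
  if (is.null(rownames(points))) {
    rownames(points) <- sprintf("s%02d", seq_len(nrow(points)))
  }
  as_distmat(as.matrix(dist(points)))
}

random_planar <- function(n, seed = 1, scale = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(2 * n, 0, scale), n, 2)
    rownames(m) <- sprintf("s%02d", seq_len(n))
    m
  })
}

# cophenetic distances of an independent random coalescent tree,
# labels forced to a common specimen set
random_tree_dist <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rcoal(n)
    D <- ape::cophenetic.phylo(tr)
    ids <- sprintf("s%02d", seq_len(n))
    idx <- order(as.integer(sub("^t", "", rownames(D))))
    D <- D[idx, idx]
    dimnames(D) <- list(ids, ids)
    as_distmat(D / max(D))
  })
}

# regular transect locations, planar distances in meters
transect_dist <- function(n, spacing = 100) {
  pts <- cbind(seq(0, by = spacing, length.out = n), 0)
  rownames(pts) <- sprintf("s%02d", seq_len(n))
  euclid_dist(pts)
}

toy_alignment <- function() {
  dna_alignment(c(a = "ACGT", b = "ACGA", c = "AC-A"))
}

# random low-divergence alignment via the simulator
sim_alignment <- function(n = 8, seed = 1, subst_rate = 0.08) {
  generate_dataset(cophylo_scenario(n_specimens = n, subst_rate = subst_rate,
                                    seed = seed))$fungal
}

# character-matrix alignment to ape's DNAbin for oracle comparisons
as_dnabin <- function(aln) {
  m <- do.call(rbind, strsplit(tolower(unclass(aln)), ""))
  rownames(m) <- names(aln)
  ape::as.DNAbin(m)
}
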