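test_that("full co-speciation duplicates the fungal tree in the algal lineage", {
  sim <- simulate_cophylogeny(cophylo_scenario(n_specimens = 10, seed = 5))
  expect_equal(ape::Ntip(sim$fungal_tree), 10)
  expect_true(ape::is.ultrametric(sim$fungal_tree, tol = 1e-8))
  a <- sim$algal_tree
  expect_equal(ape::Ntip(a), 10)
  # relabel algal tips by their specimen and compare topologies
  map <- stats::setNames(sim$association$specimen_id, sim$association$algal_lineage)
  a$tip.label <- unname(map[a$tip.label])
  expect_true(ape::all.equal.phylo(sim$fungal_tree, a, use.edge.length = TRUE))
})

test_that("without co-speciation the algal side collapses to few lineages", {
  sim <- simulate_cophylogeny(cophylo_scenario(n_specimens = 30,
                                               p_cospeciation = 0, seed = 4))
  k <- length(unique(sim$association$algal_lineage))
  expect_lt(k, 30 / 2)
  expect_null(sim$algal_tree)  # a single lineage has no tree
})

test_that("algal lineage counts match a brute-force re-implementation", {
  # independent oracle for the attachment process at n = 8: one algal
  # split per co-speciating fungal speciation, uniform attachment
  # otherwise; the lineage count ignores waiting times entirely
  oracle_counts <- function(p_cosp, reps, seed) {
    withr::with_seed(seed, {
      vapply(seq_len(reps), function(b) {
        assoc <- 1L        # algal lineage per fungal lineage
        n_alg <- 1L
        while (length(assoc) < 8) {
          sp <- sample.int(length(assoc), 1)
          if (runif(1) < p_cosp) {
            n_alg <- n_alg + 1L
            assoc <- c(assoc[-sp], assoc[sp], n_alg)
          } else {
            assoc <- c(assoc[-sp], assoc[sp], sample.int(n_alg, 1))
          }
        }
        length(unique(assoc))
      }, numeric(1))
    })
  }
  mine <- vapply(1:2000, function(b) {
    sim <- simulate_cophylogeny(cophylo_scenario(
      n_specimens = 8, p_cospeciation = 0.5, seed = 10000 + b))
    length(unique(sim$association$algal_lineage))
  }, numeric(1))
  ref <- oracle_counts(0.5, 10000, seed = 77)
  expect_lt(abs(mean(mine) - mean(ref)), 3 * sqrt(var(ref) / 2000 + var(mine) / 2000) + 0.05)
  expect_lt(abs(sd(mine) - sd(ref)), 0.3)
})

test_that("the simulator is a pure function of its scenario", {
  sc <- cophylo_scenario(n_specimens = 12, p_cospeciation = 0.7,
                         switch_rate = 0.05, seed = 9)
  s1 <- simulate_cophylogeny(sc)
  s2 <- simulate_cophylogeny(sc)
  expect_identical(s1$fungal_tree, s2$fungal_tree)
  expect_identical(s1$association, s2$association)
  d1 <- generate_dataset(sc)
  d2 <- generate_dataset(sc)
  expect_identical(unclass(d1$algal), unclass(d2$algal))
  expect_identical(d1$coords, d2$coords)
})

test_that("written datasets are byte-identical across runs and round-trip", {
  sc <- cophylo_scenario(n_specimens = 8, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(sc), d1)
  write_dataset(generate_dataset(sc), d2)
  for (f in c("algal.fasta", "fungal.fasta", "coordinates.csv",
              "association.tsv", "scenario.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  aln <- read_alignment(file.path(d1, "fungal.fasta"))
  expect_equal(length(aln), 8)
  co <- read_coordinates(file.path(d1, "coordinates.csv"))
  expect_identical(co$specimen_id, names(aln))
})

test_that("sequence evolution obeys the Jukes-Cantor expectations", {
  # zero rate: identical sequences
  tr <- ape::rcoal(6)
  a0 <- evolve_sequences(tr, subst_rate = 0, seq_length = 100, seed = 1)
  expect_true(all(p_distance(a0) == 0))

  # two tips at a known path length: mean p-distance matches the closed form
  two <- ape::read.tree(text = "(a:0.1,b:0.1);")
  expected <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  L <- 500
  reps <- 200
  pbar <- mean(vapply(seq_len(reps), function(b) {
    aln <- evolve_sequences(two, subst_rate = 0.1, seq_length = L, seed = 500 + b)
    p_distance(aln)["a", "b"]
  }, numeric(1)))
  se <- sqrt(expected * (1 - expected) / L / reps)
  expect_lt(abs(pbar - expected), 3 * se + 1e-6)

  # saturation: enormous rates drive p toward 3/4
  sat <- evolve_sequences(two, subst_rate = 50, seq_length = 4000, seed = 3)
  expect_equal(unname(p_distance(sat)["a", "b"]), 0.75, tolerance = 0.03)
})

test_that("simulated divergences sit in the ITS-like range by default", {
  ds <- generate_dataset(cophylo_scenario(n_specimens = 25, seed = 31))
  for (aln in list(ds$algal, ds$fungal)) {
    s <- summarize_matrix(p_distance(aln))
    expect_gt(s$mean, 0.005)
    expect_lt(s$max, 0.25)
  }
})

test_that("spatial signal controls the geography-genetics correlation", {
  mantel_r <- function(sigma, seed) {
    sc <- cophylo_scenario(n_specimens = 40, spatial_signal = sigma, seed = seed)
    sim <- simulate_cophylogeny(sc)
    coords <- assign_locations(sim$fungal_tree, sigma, sc$bounding_box,
                               seed = seed + 1)
    g <- geographic_distance(coords)
    ph <- ape::cophenetic.phylo(sim$fungal_tree)[coords$specimen_id,
                                                 coords$specimen_id]
    cor(g[upper.tri(g)], ph[upper.tri(ph)])
  }
  r0 <- vapply(1:40, function(b) mantel_r(0, 600 + b), numeric(1))
  r1 <- vapply(1:40, function(b) mantel_r(1, 600 + b), numeric(1))
  expect_lt(abs(mean(r0)), 0.1)
  expect_gt(mean(r1 > 0), 0.95)

  # containment: every location stays inside the bounding box
  sc <- cophylo_scenario(n_specimens = 30, spatial_signal = 0.5, seed = 8)
  co <- generate_dataset(sc)$coords
  mpd <- pi * 6371000 / 180
  expect_true(all(co$lon >= 0 & co$lon <= sc$bounding_box[1] / mpd))
  expect_true(all(co$lat >= 0 & co$lat <= sc$bounding_box[2] / mpd))
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(cophylo_scenario(n_specimens = 3), "n_specimens")
  expect_error(cophylo_scenario(p_cospeciation = 1.2), "p_cospeciation")
  expect_error(cophylo_scenario(spatial_signal = -0.1), "spatial_signal")
  expect_error(cophylo_scenario(bounding_box = c(-1, 10)), "bounding_box")
})

test_that("standardized Procrustes lack-of-fit falls as co-speciation rises", {
  m2_std <- function(p_cosp, seed) {
    ds <- generate_dataset(cophylo_scenario(
      n_specimens = 25, p_cospeciation = p_cosp, seed = seed))
    funD <- p_distance(ds$fungal)
    algD <- p_distance(ds$algal)
    # fungal ordination as the target so the reference inertia never vanishes
    glance(paco_test(funD, algD, n_perm = 9, seed = seed))$m2_standardized
  }
  seeds <- 1:6
  m <- vapply(c(0, 0.5, 1), function(pc) {
    mean(vapply(seeds, function(s) m2_std(pc, 8000 + s), numeric(1)))
  }, numeric(1))
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3])
})
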