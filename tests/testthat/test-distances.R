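test_that("p-distance handles identity, substitutions and pairwise deletion", {
  aln <- toy_alignment()  # a: ACGT, b: ACGA, c: AC-A
  D <- p_distance(aln)
  expect_equal(unname(D["a", "a"]), 0)
  expect_equal(unname(D["a", "b"]), 0.25)        # 1 difference over 4 sites
  expect_equal(unname(D["a", "c"]), 1 / 3)       # gap removes one site pairwise
  expect_equal(unname(D["b", "c"]), 0)           # ACGA vs AC-A agree at 1,2,4
  expect_true(all(D >= 0 & D <= 1))

  # complete deletion drops the gapped column for every pair
  Dc <- p_distance(aln, deletion = "complete")
  expect_equal(unname(Dc["a", "b"]), 1 / 3)
})

test_that("a pair with no comparable sites is an error naming the pair", {
  aln <- dna_alignment(c(x = "AC--", y = "--GT", z = "ACGT"))
  expect_error(p_distance(aln), "'x', 'y'")
})

test_that("ambiguity codes and N are excluded as missing", {
  aln <- dna_alignment(c(a = "ACGT", b = "RCGN"))
  # compared sites: 2,3 only; identical there
  D <- p_distance(aln)
  expect_equal(unname(D["a", "b"]), 0)
  expect_equal(unname(attr(D, "n_sites")["a", "b"]), 2)
})

test_that("p-distance is permutation-equivariant", {
  aln <- sim_alignment(n = 6, seed = 21)
  D <- p_distance(aln)
  perm <- c(4, 1, 6, 2, 5, 3)
  aln2 <- dna_alignment(unclass(aln)[perm])
  D2 <- p_distance(aln2)
  expect_equal(unclass(D2), unclass(D)[perm, perm], ignore_attr = TRUE)
  expect_identical(rownames(D2), rownames(D)[perm])
})

test_that("p and TN93 distances agree with the reference implementation", {
  aln <- sim_alignment(n = 8, seed = 11)
  bin <- as_dnabin(aln)
  mine_p <- p_distance(aln)
  ref_p <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(unclass(mine_p), ref_p[rownames(mine_p), colnames(mine_p)],
               tolerance = 1e-12, ignore_attr = TRUE)

  mine_t <- tn93_distance(aln, frequencies = "global")
  ref_t <- as.matrix(ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE))
  expect_equal(unclass(mine_t), ref_t[rownames(mine_t), colnames(mine_t)],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("TN93 reduces to the Jukes-Cantor closed form under balanced counts", {
  # pair constructed so pooled base frequencies are exactly uniform and the
  # two transition classes and transversions are in JC proportion (Q = 4 P1)
  blocks <- rbind(
    c("A", "G"), c("G", "A"),          # A<->G transitions
    c("C", "T"), c("T", "C"),          # C<->T transitions
    c("A", "C"), c("C", "A"),          # transversions, all four kinds
    c("A", "T"), c("T", "A"),
    c("G", "C"), c("C", "G"),
    c("G", "T"), c("T", "G"))
  reps <- c(4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 4)
  s1 <- rep(blocks[, 1], reps)
  s2 <- rep(blocks[, 2], reps)
  ident <- rep(c("A", "C", "G", "T"), each = 12)
  aln <- dna_alignment(c(u = paste(c(s1, ident), collapse = ""),
                         v = paste(c(s2, ident), collapse = "")))
  p <- p_distance(aln)["u", "v"]
  expect_equal(unname(p), 0.5)
  jc <- -0.75 * log(1 - 4 * p / 3)
  for (freqs in c("pair", "global")) {
    d <- tn93_distance(aln, frequencies = freqs)["u", "v"]
    expect_equal(unname(d), unname(jc), tolerance = 1e-6)
  }
})

test_that("TN93 saturation is flagged inestimable, never a silent NaN", {
  # p = 0.75 with uniform frequencies pushes a log argument below zero
  aln <- dna_alignment(c(
    u = "ACGTACGTACGTACGT",
    v = "ACGTCGTACGTACGTA"))
  expect_equal(unname(p_distance(aln)["u", "v"]), 0.75)
  D <- tn93_distance(aln)
  expect_true(is.na(D["u", "v"]))
  expect_true(attr(D, "inestimable")["u", "v"])
  # identical sequences stay exactly zero and unflagged
  aln0 <- dna_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  D0 <- tn93_distance(aln0)
  expect_equal(unname(D0["a", "b"]), 0)
  expect_false(any(attr(D0, "inestimable")))
})

test_that("TN93 dominates the p-distance wherever both are defined", {
  for (seed in 1:3) {
    aln <- sim_alignment(n = 7, seed = seed, subst_rate = 0.12)
    p <- p_distance(aln)
    t93 <- tn93_distance(aln)
    ok <- !is.na(t93)
    expect_true(all(t93[ok] >= p[ok] - 1e-12))
  }
})

test_that("geographic distances are haversine on the 6371 km sphere", {
  co <- tibble::tibble(specimen_id = c("a", "b", "c"),
                       lon = c(0, 1, 0), lat = c(0, 0, 0))
  D <- geographic_distance(co)
  expect_equal(unname(D["a", "c"]), 0)
  # one degree of longitude at the equator: R * pi / 180
  expect_equal(unname(D["a", "b"]), 6371000 * pi / 180, tolerance = 1e-6)
  co2 <- tibble::tibble(specimen_id = sprintf("s%d", 1:6),
                        lon = runif(6, 165, 179), lat = runif(6, -47, -34))
  D2 <- geographic_distance(co2)
  expect_identical(unclass(D2), t(unclass(D2)))
})

test_that("matrix summaries use the off-diagonal upper triangle", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[upper.tri(m)] <- c(0.1, 0.2, 0.3)
  m <- m + t(m)
  s <- summarize_matrix(as_distmat(m))
  expect_equal(s$mean, 0.2)
  expect_equal(s$n_pairs, 3L)
  expect_equal(s$min, 0.1)
  expect_equal(s$max, 0.3)
  expect_equal(s$sd, sd(c(0.1, 0.2, 0.3)))

  z <- summarize_matrix(as_distmat(matrix(0, 3, 3,
    dimnames = list(letters[1:3], letters[1:3]))))
  expect_equal(z$mean, 0)
  expect_equal(z$sd, 0)
})
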