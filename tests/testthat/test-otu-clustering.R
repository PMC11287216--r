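test_that("QC filter applies strict completeness/contamination cutoffs", {
  mags <- make_mags(c("A", "B", "C", "D"),
                    completeness = c(49.9, 60, 60, 50),
                    contamination = c(5, 10, 9.9, 9.9))
  out <- qc_filter(mags)
  expect_identical(out$retained$mag_id, "C")
  expect_setequal(out$rejected$mag_id, c("A", "B", "D"))
  expect_error(qc_filter(mags, min_completeness = 120), "\\[0, 100\\]")
})

test_that("single-linkage chains merge OTUs; the threshold is strict", {
  mags <- make_mags(c("A", "B", "C"))
  chain <- make_ani(c("A", "B", "C"),
                    list(list("A", "B", 97), list("B", "C", 96),
                         list("A", "C", 94)))
  otus <- cluster_otus(chain, mags)
  expect_identical(nrow(otus), 1L)
  expect_setequal(otus$members[[1]], c("A", "B", "C"))

  apart <- make_ani(c("A", "B", "C"), base = 94)
  expect_identical(nrow(cluster_otus(apart, mags)), 3L)

  boundary <- make_ani(c("A", "B"), list(list("A", "B", 95.0)))
  expect_identical(nrow(cluster_otus(boundary, make_mags(c("A", "B")))), 2L)
  # just above the threshold links
  linked <- make_ani(c("A", "B"), list(list("A", "B", 95.1)))
  expect_identical(nrow(cluster_otus(linked, make_mags(c("A", "B")))), 1L)
})

test_that("a MAG missing from the ANI matrix is an input error", {
  mags <- make_mags(c("A", "B", "Z"))
  expect_error(cluster_otus(make_ani(c("A", "B")), mags), "Z")
})

test_that("clustering agrees with the transitive-closure oracle", {
  set.seed(2024)
  for (i in seq_len(60)) {
    n <- sample(2:12, 1)
    ani <- random_ani(n)
    otus <- cluster_otus(ani, make_mags(rownames(ani)))
    expect_identical(otus_partition(otus), oracle_partition(ani))
  }
})

test_that("the partition is invariant to input ordering", {
  set.seed(99)
  ani <- random_ani(10)
  mags <- make_mags(rownames(ani))
  base <- otus_partition(cluster_otus(ani, mags))
  for (i in 1:5) {
    perm <- sample(rownames(ani))
    shuffled <- ani[perm, perm]
    expect_identical(otus_partition(cluster_otus(shuffled,
                                                 mags[sample(nrow(mags)), ])),
                     base)
  }
})

test_that("raising the ANI threshold only refines the partition", {
  refines <- function(fine, coarse) {
    all(vapply(fine, function(f) {
      any(vapply(coarse, function(c) all(f %in% c), logical(1)))
    }, logical(1)))
  }
  set.seed(7)
  for (i in 1:20) {
    ani <- random_ani(9)
    mags <- make_mags(rownames(ani))
    p_lo <- otus_partition(cluster_otus(ani, mags, threshold_pct = 93))
    p_hi <- otus_partition(cluster_otus(ani, mags, threshold_pct = 97))
    expect_true(refines(p_hi, p_lo))
  }
})

test_that("asymmetric directions are combined per the chosen rule", {
  ani <- make_ani(c("A", "B"))
  ani["A", "B"] <- 96; ani["B", "A"] <- 93   # mean 94.5 < 95 < max 96
  mags <- make_mags(c("A", "B"))
  expect_identical(nrow(cluster_otus(ani, mags, symmetrize = "mean")), 2L)
  expect_identical(nrow(cluster_otus(ani, mags, symmetrize = "max")), 1L)
  expect_identical(nrow(cluster_otus(ani, mags, symmetrize = "min")), 2L)
  # a missing direction falls back to the present one
  ani["B", "A"] <- NA
  expect_identical(nrow(cluster_otus(ani, mags, symmetrize = "mean")), 1L)
})

test_that("representative selection follows the stated hierarchy", {
  mags <- make_mags(c("m1", "m2", "m3"),
                    completeness = c(90, 80, 90),
                    contamination = c(5, 1, 2),
                    abundance = c(1, 9, 3))
  expect_identical(select_representative(c("m1", "m2"), mags), "m1")
  # equal completeness: lower contamination wins
  expect_identical(select_representative(c("m1", "m3"), mags), "m3")
  # abundance breaks the remaining tie
  mags2 <- make_mags(c("a", "b"), completeness = 90, contamination = 2,
                     abundance = c(3, 8))
  expect_identical(select_representative(c("a", "b"), mags2), "b")
  # full tie: lexicographically smallest id
  mags3 <- make_mags(c("b", "a"), completeness = 90, contamination = 2,
                     abundance = 5)
  expect_identical(select_representative(c("b", "a"), mags3), "a")
  expect_error(select_representative(character(), mags), "no members")
})

test_that("OTU abundance sums member read fractions per depth", {
  mags <- make_mags(c("A", "B", "C"), depth = c(5, 5, 30),
                    abundance = c(3, 2.5, 4))
  ani <- make_ani(c("A", "B", "C"), list(list("A", "B", 98)))
  otus <- cluster_otus(ani, mags)
  ab <- otu_abundance(otus, mags)
  two <- otus$otu_id[vapply(otus$members, length, 1L) == 2]
  expect_equal(ab$abundance_pct[ab$otu_id == two & ab$depth_cm == 5], 5.5)
  expect_equal(ab$abundance_pct[ab$otu_id == two & ab$depth_cm == 30], 0)
  single <- otus$otu_id[vapply(otus$members, identical, TRUE, "C")]
  expect_equal(ab$abundance_pct[ab$otu_id == single & ab$depth_cm == 30], 4)
})
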