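test_that("patristic distances are path sums on the tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- phylo_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))

  star <- star_tree(2)
  expect_equal(phylo_distances(star)["t1", "t2"], 2)

  cherry <- ape::read.tree(text = "((A:0,B:0):1,C:2);")
  expect_equal(phylo_distances(cherry)["A", "B"], 0)

  expect_error(phylo_distances(ape::read.tree(text = "(A,B,C);")),
               "branch length")
})

test_that("phylogenetic correlation normalizes shared root-to-tip depth", {
  star <- star_tree(5)
  C <- phylo_correlation(star)
  expect_equal(diag(C), setNames(rep(1, 5), paste0("t", 1:5)))
  expect_true(all(abs(C[upper.tri(C)]) < 1e-12))

  # two tips sharing half of their root-to-tip depth
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C2 <- phylo_correlation(tr)
  expect_equal(C2["A", "B"], 0.5)
  expect_equal(C2["A", "C"], 0)

  twins <- ape::read.tree(text = "((A:0,B:0):1,C:2);")
  expect_equal(phylo_correlation(twins)["A", "B"], 1)

  zero <- ape::read.tree(text = "((A:0,B:1):0,C:2);")
  expect_error(phylo_correlation(zero), "zero root-to-tip")
})

test_that("PSV is 1 on a star, the mean off-diagonal otherwise, NA for singletons", {
  C <- phylo_correlation(star_tree(10))
  expect_equal(psv(C, paste0("t", 1:10)), 1)
  expect_true(is.na(psv(C, "t1")))
  expect_error(psv(C, c("t1", "nope")), "nope")

  Cc <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Cc) <- 1
  expect_equal(psv(Cc, letters[1:4]), 0.5)

  # PSV falls as a shared basal branch lengthens (total depth fixed)
  vals <- sapply(c(0.2, 0.5, 0.8), function(b) {
    tr <- ape::read.tree(text = sprintf("((A:%g,B:%g):%g,C:1);",
                                        1 - b, 1 - b, b))
    psv(phylo_correlation(tr), c("A", "B", "C"))
  })
  expect_true(all(diff(vals) < 0))
})

test_that("PSR scales PSV by richness and propagates NA", {
  expect_equal(psr(1, 10), 10)
  expect_equal(psr(0.5, 4), 2)
  expect_true(is.na(psr(NA_real_, 3)))
  # PSR <= S, equality iff PSV = 1
  C <- phylo_correlation(star_tree(6))
  expect_equal(psr(psv(C, paste0("t", 1:6)), 6), 6)
})

test_that("MPD equals the brute-force all-pairs mean", {
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mpd(c("a", "b"), D2), 3)
  D3 <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  expect_equal(mpd(letters[1:3], D3), 2)
  expect_true(is.na(mpd("a", D3)))

  set.seed(42)
  tr <- ape::rphylo(20, 1, 0)
  D <- phylo_distances(tr)
  for (i in 1:20) {
    sub <- sample(tr$tip.label, sample(2:15, 1L))
    expect_equal(mpd(sub, D), mpd_brute(sub, D), tolerance = 1e-12)
  }
})

test_that("observed PSV and MPD agree with picante on a random dataset", {
  set.seed(7)
  tr <- ape::rphylo(25, 1, 0)
  comm <- random_community(10, 25)
  colnames(comm) <- tr$tip.label
  C <- phylo_correlation(tr); D <- phylo_distances(tr)
  ours_psv <- sapply(seq_len(10), function(i)
    psv(C, colnames(comm)[comm[i, ] > 0]))
  ours_mpd <- sapply(seq_len(10), function(i)
    mpd(colnames(comm)[comm[i, ] > 0], D))
  pic_psv <- picante::psv(comm, tr)$PSVs
  pic_mpd <- picante::mpd((comm > 0) * 1, D)
  expect_equal(unname(ours_psv), unname(pic_psv), tolerance = 1e-10)
  expect_equal(unname(ours_mpd), unname(pic_mpd), tolerance = 1e-10)
})

test_that("independent swap exchanges checkerboards and preserves margins", {
  num <- function(x) matrix(as.numeric(x), nrow(x))
  m <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  out <- independent_swap(m, iterations = 1, seed = 1)
  # a 2x2 checkerboard has a single alternative state
  expect_true(identical(num(out), matrix(c(0, 1, 1, 0), 2)) ||
                identical(num(out), num(m)))
  out2 <- independent_swap(m, iterations = 500, seed = 2)
  expect_gt(attr(out2, "swaps"), 0)
  expect_equal(num(out2), matrix(c(0, 1, 1, 0), 2)[c(1, 2), ] *
                 (attr(out2, "swaps") %% 2) +
                 num(m) * (1 - attr(out2, "swaps") %% 2))

  ones <- matrix(1L, 3, 3, dimnames = list(paste0("p", 1:3), letters[1:3]))
  expect_warning(res <- independent_swap(ones, iterations = 50, seed = 1),
                 "no checkerboard")
  expect_equal(num(res), num(ones))

  set.seed(5)
  for (i in 1:20) {
    m <- (random_community(10, 20) > 0) * 1
    r <- independent_swap(m, iterations = 1000)
    expect_equal(unname(rowSums(r)), unname(rowSums(m)))
    expect_equal(unname(colSums(r)), unname(colSums(m)))
    expect_equal(sum(r), sum(m))
  }

  # reproducible under seed
  m <- (random_community(8, 12) > 0) * 1
  expect_identical(independent_swap(m, 200, seed = 9),
                   independent_swap(m, 200, seed = 9))
})

test_that("NRI is NA when the null is degenerate and ranks clustering correctly", {
  # every plot holds every species: no checkerboard, zero null sd
  tr <- ape::rphylo(6, 1, 0)
  m <- matrix(1, 4, 6, dimnames = list(paste0("p", 1:4), tr$tip.label))
  res <- nri(m, tr, n_rand = 19, seed = 1)
  expect_true(all(is.na(res$nri)))

  # one plot holding a tight clade vs one with scattered species
  set.seed(3)
  tr2 <- ape::rphylo(30, 1, 0)
  D <- phylo_distances(tr2)
  hc <- hclust(as.dist(D), method = "average")
  cl <- cutree(hc, k = 4)
  big <- as.integer(names(which.max(table(cl))))
  clade <- tr2$tip.label[cl == big][1:5]
  scattered <- tr2$tip.label[seq(1, 30, by = 6)][1:5]
  m2 <- matrix(0, 12, 30, dimnames = list(sprintf("p%02d", 1:12),
                                          tr2$tip.label))
  m2[1, clade] <- 1
  m2[2, scattered] <- 1
  for (k in 3:12) m2[k, sample(30, 5)] <- 1
  res2 <- nri(m2, tr2, n_rand = 199, seed = 11)
  expect_gt(res2$nri[1], res2$nri[2])

  # singleton plots give NA without disturbing others
  m2[3, ] <- 0; m2[3, 1] <- 1
  res3 <- nri(m2, tr2, n_rand = 49, seed = 2)
  expect_true(is.na(res3$nri[3]))
  expect_false(all(is.na(res3$nri)))
})

test_that("phylo_metrics stacks PSV/PSR/MPD/NRI consistently", {
  set.seed(13)
  tr <- ape::rphylo(15, 1, 0)
  comm <- (random_community(8, 15) > 0) * 2.5
  colnames(comm) <- tr$tip.label
  pm <- phylo_metrics(comm, tr, n_rand = 29, seed = 4)
  expect_named(pm, c("plot_id", "PSV", "PSR", "MPD", "NRI"))
  S <- rowSums(comm > 0)
  expect_equal(pm$PSR, unname(pm$PSV * S))
  expect_true(all(pm$PSR <= S + 1e-12, na.rm = TRUE))
  aud <- attr(pm, "audit")
  expect_equal(aud$n_rand, 29)
})
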