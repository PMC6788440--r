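test_that("pairwise partition matches hand-evaluated components", {
  ## identical sites: no dissimilarity
  ident <- rbind(s1 = c(TRUE, TRUE, FALSE), s2 = c(TRUE, TRUE, FALSE))
  p <- pairwisePartition(ident)
  expect_equal(p$sor[1, 2], 0)
  expect_equal(p$sim[1, 2], 0)
  expect_equal(p$sne[1, 2], 0)

  ## disjoint sites: pure turnover
  disj <- rbind(s1 = c(TRUE, TRUE, FALSE, FALSE),
                s2 = c(FALSE, FALSE, TRUE, TRUE))
  p <- pairwisePartition(disj)
  expect_equal(p$sor[1, 2], 1)
  expect_equal(p$sim[1, 2], 1)
  expect_equal(p$sne[1, 2], 0)

  ## {A,B,C} vs {A}: a=1, b=2, c=0 -> pure nestedness
  nest <- rbind(s1 = c(TRUE, TRUE, TRUE), s2 = c(TRUE, FALSE, FALSE))
  p <- pairwisePartition(nest)
  expect_equal(p$sim[1, 2], 0)
  expect_equal(p$sor[1, 2], 0.5)
  expect_equal(p$sne[1, 2], 0.5)

  ## a pair of empty sites is NA, never a silent zero
  withempty <- rbind(s1 = c(TRUE, TRUE), s2 = c(FALSE, FALSE),
                     s3 = c(FALSE, FALSE))
  p <- pairwisePartition(withempty)
  expect_true(is.na(p$sor[2, 3]))
  expect_false(is.na(p$sor[1, 2]))

  expect_error(pairwisePartition(rbind(s1 = c(TRUE, FALSE))), "two sites")
})

test_that("pairwise components agree with vegan and satisfy additivity/monotonicity", {
  skip_if_not_installed("vegan")
  set.seed(13)
  for (i in 1:20) {
    inc <- randomIncidence(sample(3:7, 1), sample(8:25, 1))
    if (any(rowSums(inc) == 0)) next
    p <- pairwisePartition(inc)
    ## independent implementations of the two base indices
    vs <- as.matrix(vegan::vegdist(inc, "bray", binary = TRUE))  # Sorensen
    vsim <- as.matrix(vegan::betadiver(inc, "sim"))
    expect_equal(unname(p$sor), unname(vs), tolerance = 1e-12)
    expect_equal(unname(p$sim), unname(vsim), tolerance = 1e-12)
    ## additivity to near machine precision
    expect_lt(max(abs(p$sor - (p$sim + p$sne)), na.rm = TRUE), 1e-12)
  }
  ## adding a species shared by both sites never increases sor
  set.seed(14)
  for (i in 1:20) {
    inc <- randomIncidence(2, 12)
    before <- pairwisePartition(inc)$sor[1, 2]
    after <- pairwisePartition(cbind(inc, new = c(TRUE, TRUE)))$sor[1, 2]
    if (is.na(before)) next
    expect_lte(after, before + 1e-12)
  }
})

test_that("multiple-site partition handles the canonical configurations", {
  ## all sites identical
  ident <- matrix(TRUE, 4, 5, dimnames = list(paste0("s", 1:4), NULL))
  m <- multisitePartition(ident)
  expect_equal(m@sor, 0)

  ## pairwise-disjoint sites
  disj <- rbind(s1 = c(T, T, F, F, F, F), s2 = c(F, F, T, T, F, F),
                s3 = c(F, F, F, F, T, T))
  m <- multisitePartition(disj)
  expect_equal(m@sor, 1)
  expect_equal(m@sim, 1)
  expect_equal(m@sne, 0)

  ## perfectly nested chain: all turnover vanishes
  chain <- rbind(s1 = c(T, T, T), s2 = c(T, T, F), s3 = c(T, F, F))
  m <- multisitePartition(chain)
  expect_equal(m@sim, 0)
  expect_equal(m@sor, m@sne)

  ## for two sites the multi-site and pairwise partitions coincide
  set.seed(5)
  for (i in 1:15) {
    inc <- randomIncidence(2, 15)
    if (any(rowSums(inc) == 0)) next
    m <- multisitePartition(inc)
    p <- pairwisePartition(inc)
    expect_equal(m@sor, p$sor[1, 2])
    expect_equal(m@sim, p$sim[1, 2])
    expect_equal(m@sne, p$sne[1, 2])
  }

  ## empty sites are excluded with a warning, not silently kept
  withempty <- rbind(s1 = c(T, T), s2 = c(F, F), s3 = c(T, F))
  expect_warning(m <- multisitePartition(withempty), "no species")
  expect_equal(length(m@sites), 2)
  expect_error(multisitePartition(rbind(s1 = c(TRUE, FALSE))), "two")
})

test_that("neighbor-joining recovers additive trees exactly", {
  ## three-point closed form
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- njTree(d3)
  expect_equal(sort(t3$edge.length), c(1, 2, 3))
  expect_equal(sort(t3$tip.label), c("A", "B", "C"))

  ## random additive matrices from 4-8 leaf trees: topology and lengths
  set.seed(21)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    d <- stats::cophenetic(tr)
    rec <- njTree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(rec$edge.length), sort(ape::unroot(tr)$edge.length),
                 tolerance = 1e-8)
    ## the recovered tree's path distances reproduce the input
    expect_equal(stats::cophenetic(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("neighbor-joining agrees with ape::nj on general dissimilarities", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.2, 1)
    d <- d + t(d)
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    mine <- suppressWarnings(njTree(d))
    theirs <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(mine, theirs), 0, ignore_attr = TRUE)
  }
})

test_that("neighbor-joining validates input and breaks ties by label order", {
  d <- matrix(c(0, 1, 1, 0), 2)
  expect_error(njTree(d), "three")
  d4 <- matrix(1, 4, 4); diag(d4) <- 0
  dimnames(d4) <- list(letters[1:4], letters[1:4])
  asym <- d4; asym[1, 2] <- 2
  expect_error(njTree(asym), "symmetric")
  negd <- d4; negd[1, 2] <- negd[2, 1] <- -1
  expect_error(njTree(negd), "non-negative")
  diagd <- d4; diag(diagd) <- c(0, 1, 0, 0)
  expect_error(njTree(diagd), "diagonal")
  nad <- d4; nad[1, 2] <- nad[2, 1] <- NA
  expect_error(njTree(nad), "NA")

  ## equidistant input: deterministic, label-ordered first join
  t1 <- njTree(d4)
  t2 <- njTree(d4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  first_cherry <- attr(t1, "rawNewick")
  expect_match(first_cherry, "\\(a:[0-9.]+,b:[0-9.]+\\)")
})

test_that("negative branch lengths are clamped with the raw tree retained", {
  d <- matrix(c(0, 0.010, 0.732, 0.251,
                0.010, 0, 0.616, 0.949,
                0.732, 0.616, 0, 0.949,
                0.251, 0.949, 0.949, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_warning(tr <- njTree(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
  expect_gt(attr(tr, "nNegative"), 0)
  expect_match(attr(tr, "rawNewick"), "-")
})

test_that("Newick output round-trips topology and branch lengths", {
  set.seed(8)
  tr <- ape::rtree(6)
  d <- stats::cophenetic(tr)
  mine <- njTree(d)
  txt <- writeNewick(mine)
  back <- ape::read.tree(text = txt)
  expect_equal(ape::dist.topo(mine, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(mine$edge.length),
               tolerance = 1e-8)
  ## file round-trip
  f <- tempfile(fileext = ".nwk")
  writeNewick(mine, f)
  expect_equal(ape::dist.topo(ape::read.tree(f), mine), 0,
               ignore_attr = TRUE)
  ## residual negative lengths are clamped on write, with a warning
  neg <- mine; neg$edge.length[1] <- -0.5
  expect_warning(txt2 <- writeNewick(neg), "clamped")
  expect_false(grepl("-", txt2))
})
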