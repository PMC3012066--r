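test_that("TN93 distances match the closed-form oracle and collapse to JC", {
  # identical sequences -> zero
  same <- as_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(unname(tn93_distance(same)[1, 2]), 0)
  # constructed pair with balanced base composition and known P1/P2/Q
  set.seed(31)
  L <- 2000
  s1 <- rep(c("A", "C", "G", "T"), each = L / 4)
  s2 <- s1
  idx <- sample(seq_len(L))
  agA <- idx[s1[idx] == "A"][1:50]; agG <- idx[s1[idx] == "G"][1:50]
  ctC <- idx[s1[idx] == "C"][1:30]; ctT <- idx[s1[idx] == "T"][1:30]
  tv1 <- setdiff(idx[s1[idx] == "A"], agA)[1:20]
  tv2 <- setdiff(idx[s1[idx] == "C"], ctC)[1:20]
  s2[agA] <- "G"; s2[agG] <- "A"; s2[ctC] <- "T"; s2[ctT] <- "C"
  s2[tv1] <- "C"; s2[tv2] <- "A"
  aln <- rbind(x = s1, y = s2)
  D <- tn93_distance(aln)
  expect_equal(unname(D["x", "y"]), oracle_tn93_pair(s1, s2), tolerance = 1e-6)
  # TN93 never below the raw mismatch proportion
  p <- mean(s1 != s2)
  expect_gte(D["x", "y"], p)
  # equal-frequency, equal-transition data approach the JC correction
  set.seed(13)
  t1 <- sample(c("A", "C", "G", "T"), 40000, replace = TRUE)
  t2 <- t1
  hit <- runif(40000) < 0.06
  t2[hit] <- vapply(t1[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  Dj <- tn93_distance(rbind(a = t1, b = t2))
  pj <- mean(t1 != t2)
  jc <- -3 / 4 * log(1 - 4 / 3 * pj)
  expect_equal(unname(Dj[1, 2]), jc, tolerance = 0.01)
})

test_that("saturated pairs get the configurable ceiling", {
  # maximally divergent pair: TN93 log argument non-positive
  s1 <- rep(c("A", "C"), 500)
  s2 <- rep(c("G", "T"), 500)
  expect_warning(D <- tn93_distance(rbind(a = s1, b = s2, c = s1)), "saturated")
  expect_equal(unname(D["a", "b"]), 5.0)
  expect_warning(D2 <- tn93_distance(rbind(a = s1, b = s2, c = s1), ceiling = 9),
                 "saturated")
  expect_equal(unname(D2["a", "b"]), 9)
})

test_that("NJ resolves the four-taxon additive case with known branch lengths", {
  D <- matrix(0.4, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                         c("A", "B", "C", "D")))
  diag(D) <- 0
  D["A", "B"] <- D["B", "A"] <- 0.2
  D["C", "D"] <- D["D", "C"] <- 0.3
  tr <- nj_tree(D)
  # path lengths reproduce D exactly (additivity)
  cd <- cophenetic(tr)[rownames(D), colnames(D)]
  expect_equal(cd, D, tolerance = 1e-10)
  # internal branch length 0.15
  internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
  expect_equal(internal, 0.15, tolerance = 1e-10)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
})

test_that("NJ reconstructs random additive trees exactly (property)", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    D <- cophenetic(tr0)
    tr <- nj_tree(D)
    expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D, tolerance = 1e-8)
  }
})

test_that("negative NJ branches are clamped to zero", {
  # a non-additive matrix known to induce a negative NJ branch
  D <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 1,
                9, 10, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 12   # distort
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic under a seed and bounded", {
  set.seed(123)
  aln <- two_clade_mosaic(L = 600, inter = 0.10, intra = 0.005, bp = 599,
                          n_clade = 2)[1:4, ]   # two clean 2-leaf clades
  t1 <- bootstrap_support(aln, B = 100, seed = 5)
  t2 <- bootstrap_support(aln, B = 100, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # deeply separated clades: maximal support for the split
  expect_true(all(sup >= 99))
  # B = 1: supports are 0 or 100
  tb1 <- bootstrap_support(aln, B = 1, seed = 2)
  s1 <- suppressWarnings(as.numeric(tb1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
  expect_error(bootstrap_support(aln, B = 0), "B must be")
})

test_that("midpoint rooting preserves path lengths and picks the longest path", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.15,(C:0.15,D:0.15):0.0);")
  rooted <- midpoint_root(tr)
  expect_true(ape::is.rooted(rooted))
  expect_equal(cophenetic(rooted)[c("A", "B", "C", "D"), c("A", "B", "C", "D")],
               cophenetic(tr)[c("A", "B", "C", "D"), c("A", "B", "C", "D")],
               tolerance = 1e-10)
  # root-to-deepest-leaves balanced: max depth halved
  depths <- ape::node.depth.edgelength(rooted)[1:4]
  expect_equal(max(depths), max(cophenetic(tr)) / 2, tolerance = 1e-10)
})

test_that("domain partitioning slices and validates intervals", {
  aln <- matrix(sample(c("A", "C"), 4 * 100, replace = TRUE), 4,
                dimnames = list(paste0("s", 1:4), NULL))
  part <- data.frame(name = c("five_prime", "three_prime"),
                     start = c(1, 41), end = c(40, 100))
  doms <- partition_by_domains(aln, part)
  expect_named(doms, c("five_prime", "three_prime"))
  expect_equal(sum(vapply(doms, ncol, integer(1))), 100)
  expect_equal(partition_by_domains(aln, part[0, ]), list())
  expect_error(partition_by_domains(aln, data.frame(name = "x", start = 50, end = 120)),
               "outside")
  expect_error(partition_by_domains(aln, data.frame(name = c("x", "y"),
                                                    start = c(1, 20),
                                                    end = c(30, 50))), "overlap")
  # BED-like partition files are 0-based half-open
  f <- tempfile()
  writeLines(c("five_prime\t0\t40", "three_prime\t40\t100"), f)
  p2 <- read_partition_tsv(f)
  expect_equal(p2$start, c(1, 41))
  expect_equal(p2$end, c(40, 100))
})

test_that("clade membership checks distinguish clades from paraphyletic sets", {
  tr <- ape::read.tree(text = "((A:1,B:1)90:1,(C:1,D:1)85:1);")
  expect_true(clade_by_label_check(tr, c("A", "B"))$is_clade)
  expect_equal(clade_by_label_check(tr, c("A", "B"))$support, 90)
  expect_false(clade_by_label_check(tr, c("A", "C"))$is_clade)
  expect_error(clade_by_label_check(tr, c("A", "Z")), "unknown label")
})

test_that("group-segregated domains pass the clade check only in the right region", {
  set.seed(21)
  aln <- two_clade_mosaic(L = 1200, inter = 0.05, intra = 0.002, bp = 600)
  # 3' region: R belongs with the B clade; 5' region: with the A clade
  left <- aln[, 1:600]; right <- aln[, 601:1200]
  t_left <- midpoint_root(nj_tree(tn93_distance(left)))
  t_right <- midpoint_root(nj_tree(tn93_distance(right)))
  expect_true(clade_by_label_check(t_left, c("A1", "A2", "A3", "R"))$is_clade)
  expect_true(clade_by_label_check(t_right, c("B1", "B2", "B3", "R"))$is_clade)
  expect_false(clade_by_label_check(t_right, c("A1", "A2", "A3", "R"))$is_clade)
})

test_that("the breakpoint scan localises a known recombination point", {
  set.seed(8)
  aln <- two_clade_mosaic(L = 1000, inter = 0.05, intra = 0.002, bp = 500)
  scan <- breakpoint_scan(aln, grouping1 = c("A1", "A2", "A3", "R"),
                          grouping2 = c("A1", "A2", "A3"),
                          n_perm = 199, seed = 99)
  expect_lt(abs(scan$breakpoint - 500), 26)
  expect_lt(scan$p_value, 0.05)
  # homogeneous alignment: no significant breakpoint
  hom <- aln[c("A1", "A2", "A3", "B1", "B2", "B3"), ]
  hom <- rbind(hom, R = aln["A1", ])   # non-mosaic "recombinant"
  scan0 <- breakpoint_scan(hom, grouping1 = c("A1", "A2", "A3", "R"),
                           grouping2 = c("A1", "A2", "A3"),
                           n_perm = 199, seed = 100)
  expect_true(is.na(scan0$breakpoint) || scan0$p_value > 0.05)
  # all informative sites on one side: returns the degenerate no-signal result
  one_sided <- aln[, 1:400]
  scan1 <- breakpoint_scan(one_sided, grouping1 = c("A1", "A2", "A3", "R"),
                           grouping2 = c("A1", "A2", "A3"), n_perm = 9)
  expect_true(is.na(scan1$breakpoint))
  expect_equal(scan1$p_value, 1)
  # no informative columns at all
  const <- matrix("A", 4, 50, dimnames = list(c("A1", "A2", "B1", "R"), NULL))
  expect_error(breakpoint_scan(const, c("A1", "A2", "R"), c("A1", "A2")),
               "no informative")
})
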