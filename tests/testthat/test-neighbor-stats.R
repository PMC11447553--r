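test_that("kNN geometry behaves on constructed configurations", {
  # 8 tails on a line: the end tail's 6 neighbors are the next 6
  line <- data.frame(tail_class = "FFA", x = 1:8, y = 0, z = 0)
  nb <- knn_tail_neighbors(line, box = c(100, 100))
  expect_identical(nb[[1]], 2:7)
  # hexagonal ring: the 6 nearest of the center are the ring
  ang <- seq(0, 300, by = 60) * pi / 180
  hex <- data.frame(tail_class = "FFA",
                    x = c(0, cos(ang), 3 * cos(ang)),
                    y = c(0, sin(ang), 3 * sin(ang)), z = 0)
  nbh <- knn_tail_neighbors(hex, box = c(100, 100))
  expect_setequal(nbh[[1]], 2:7)
  # CHOL queries return exactly 7 neighbors
  mix <- make_mixed_central_bilayer(100, seed = 1)
  nbm <- knn_tail_neighbors(mix, attr(mix, "box"))
  kk <- lengths(nbm)
  expect_true(all(kk[mix$tail_class == "CHOL"] == 7))
  expect_true(all(kk[mix$tail_class != "CHOL"] == 6))
  expect_error(knn_tail_neighbors(line[1:5, ], box = c(100, 100)),
               "at least 8 tails")
})

test_that("directed pair counting follows its stated conventions", {
  two <- data.frame(tail_class = c("CER_acyl_ext", "FFA"), x = c(0, 1),
                    y = 0, z = 0)
  nb <- knn_tail_neighbors(two, box = c(10, 10), k = 1, k_chol = 1)
  pc <- pair_counts(nb, two$tail_class)
  expect_equal(nrow(pc), 21)
  expect_equal(pc$raw[pc$tail_1 == "CER_acyl_ext" & pc$tail_2 == "FFA"], 2)
  expect_equal(sum(pc$raw), 2)
  # all one type, n tails, k = 6 -> count(T,T) = 6n
  one <- data.frame(tail_class = "FFA", x = runif(20, 0, 3),
                    y = runif(20, 0, 3), z = 0)
  nb1 <- knn_tail_neighbors(one, box = c(3, 3))
  pc1 <- pair_counts(nb1, one$tail_class)
  expect_equal(pc1$raw[pc1$tail_1 == "FFA" & pc1$tail_2 == "FFA"], 120)
})

test_that("fast kNN and pair counts equal the brute-force oracle", {
  for (n in c(30, 200)) {
    tl <- suppressWarnings(make_mixed_central_bilayer(n, seed = n))
    box <- attr(tl, "box")
    fast <- knn_tail_neighbors(tl, box)
    slow <- bf_knn(tl, box)
    expect_identical(fast, slow)
    expect_identical(pair_counts(fast, tl$tail_class),
                     pair_counts(slow, tl$tail_class))
  }
})

test_that("mixing-null weights follow the combinatorial construction", {
  null <- expected_pair_relative_probability(c(CER_acyl_ext = 2, FFA = 2))
  w <- setNames(null$weight, paste(null$tail_1, null$tail_2))
  expect_equal(unname(w["CER_acyl_ext CER_acyl_ext"]), 1)  # N(N-1)/2
  expect_equal(unname(w["CER_acyl_ext FFA"]), 4)           # Ni * Nj
  expect_equal(unname(w["FFA FFA"]), 1)
  expect_equal(null$rel_prob[null$tail_1 == "CER_acyl_ext" &
                               null$tail_2 == "FFA"], 4 / 6)
  # single type: all probability on the self pair
  n10 <- expected_pair_relative_probability(c(CHOL = 10))
  expect_equal(n10$rel_prob[n10$tail_1 == "CHOL" & n10$tail_2 == "CHOL"], 1)
  # two singletons: only the cross pair can form
  n11 <- expected_pair_relative_probability(c(CHOL = 1, FFA = 1))
  expect_equal(n11$rel_prob[n11$tail_1 == "CHOL" & n11$tail_2 == "FFA"], 1)
  # probabilities sum to 1 on random compositions
  set.seed(4)
  for (i in 1:10) {
    N <- setNames(rpois(6, 40) + 1, TAIL_CLASSES)
    expect_equal(sum(expected_pair_relative_probability(N)$rel_prob), 1,
                 tolerance = 1e-12)
  }
})

test_that("raw counts sum to 6 n_nonCHOL + 7 n_CHOL", {
  tl <- make_mixed_central_bilayer(300, seed = 5)
  pc <- pair_counts(knn_tail_neighbors(tl, attr(tl, "box")), tl$tail_class)
  nch <- sum(tl$tail_class == "CHOL")
  expect_equal(sum(pc$raw), 6 * (300 - nch) + 7 * nch)
})

test_that("segregated half-planes push like pairs above the mixed null", {
  set.seed(6)
  n <- 100
  x <- runif(n, 0, 5)
  tl <- data.frame(tail_class = ifelse(x < 2.5, "FFA", "CHOL"),
                   x = x, y = runif(n, 0, 5), z = 0)
  tab <- pair_analysis(tl, box = c(5, 5, 1))
  val <- function(a, b) tab$normalized[tab$tail_1 == a & tab$tail_2 == b]
  expect_gt(val("FFA", "FFA"), 1)
  expect_gt(val("CHOL", "CHOL"), 1)
  expect_lt(val("CHOL", "FFA"), 1)
})

test_that("an all-hairpin stack forces acyl-sphingosine adjacency", {
  sys <- make_multilayer(synthetic_spec(n_lipids = 400,
                                        fraction_extended = 0, seed = 13))
  tails <- central_bilayer_tails(sys$frames[[1]], sys$topology)
  tab <- pair_analysis(tails, box = sys$frames[[1]]$box)
  v <- tab$normalized[tab$tail_1 == "CER_acyl_hp" &
                        tab$tail_2 == "CER_sph_hp"]
  expect_gt(v, 1)
})

test_that("normalized counts are stable under periodic duplication", {
  tl <- make_mixed_central_bilayer(300, seed = 9)
  box <- attr(tl, "box")
  tab1 <- pair_analysis(tl, box)
  dup <- rbind(tl, transform(tl, x = x + box[1]))
  tab2 <- pair_analysis(dup, c(2 * box[1], box[2], box[3]))
  expect_lt(max(abs(tab1$normalized - tab2$normalized)), 0.05)
})

test_that("coordination numbers calibrate to one and agree with pair counts", {
  set.seed(11)
  vals <- replicate(10, {
    tl <- make_mixed_central_bilayer(400, seed = sample.int(1e6, 1))
    nb <- knn_tail_neighbors(tl, attr(tl, "box"))
    coordination_numbers(nb, tl$tail_class)$normalized
  })
  expect_true(all(abs(rowMeans(vals, na.rm = TRUE) - 1) < 0.1))

  # structured input: both statistics rank like pairs above unlike pairs
  set.seed(10)
  n <- 120
  x <- runif(n, 0, 5.5)
  tl <- data.frame(tail_class = ifelse(x < 2.75, "FFA", "CHOL"),
                   x = x, y = runif(n, 0, 5.5), z = 0)
  nb <- knn_tail_neighbors(tl, c(5.5, 5.5))
  tab <- pair_analysis(tl, c(5.5, 5.5, 1))
  cn <- coordination_numbers(nb, tl$tail_class)
  cn_val <- function(a, b) cn$normalized[cn$reference == a & cn$neighbor == b]
  tab_val <- function(a, b)
    tab$normalized[tab$tail_1 == a & tab$tail_2 == b]
  expect_equal(sign(cn_val("FFA", "FFA") - 1), sign(tab_val("FFA", "FFA") - 1))
  expect_equal(sign(cn_val("CHOL", "FFA") - 1),
               sign(tab_val("CHOL", "FFA") - 1))
  expect_equal(sign(cn_val("CHOL", "CHOL") - 1),
               sign(tab_val("CHOL", "CHOL") - 1))
})

test_that("replicate aggregation reports mean, sd and ascending order", {
  tabs <- lapply(1:4, function(s)
    pair_analysis(make_mixed_central_bilayer(200, seed = s)))
  agg <- aggregate_pair_tables(tabs)
  expect_equal(nrow(agg), 21)
  expect_false(is.unsorted(agg$normalized_count_mean))
  expect_true(all(agg$normalized_count_sd >= 0))
})
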