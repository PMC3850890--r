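test_that("pairwise coefficients match direct set arithmetic", {
  A <- 1:100; B <- 1:80      # B subset of A: under-segmentation of B
  co <- pair_coefficients(A, B)
  expect_equal(unname(co), c(0.8, 80 / 120, 0.8), tolerance = 1e-12)
  expect_gt(co[["c3"]], co[["c2"]])   # high c3, low c2 flags B under-segmented

  expect_equal(unname(pair_coefficients(1:10, 1:10)), c(1, 1, 1))
  expect_equal(unname(pair_coefficients(1:10, 11:20)), c(0, 0, 0))
  expect_error(pair_coefficients(integer(0), integer(0)), "empty")
})

test_that("coefficient identities hold on random voxel sets", {
  set.seed(20)
  dice <- function(A, B) 2 * length(intersect(A, B)) / (length(A) + length(B))
  for (rep in 1:50) {
    A <- sample(200, sample(5:150, 1))
    B <- sample(200, sample(5:150, 1))
    cab <- pair_coefficients(A, B); cba <- pair_coefficients(B, A)
    expect_identical(cab[["c1"]], cba[["c1"]])
    expect_equal(cab[["c2"]], cba[["c3"]], tolerance = 1e-12)
    expect_lte(cab[["c2"]], cab[["c1"]] + 1e-12)
    expect_lte(cab[["c3"]], cab[["c1"]] + 1e-12)
    expect_lte(cab[["c1"]], dice(A, B) + 1e-12)  # more conservative than Dice
  }
})

test_that("region matching is the optimal one-to-one assignment (brute-force oracle)", {
  set.seed(21)
  brute_best <- function(c1m) {
    na <- nrow(c1m); nb <- ncol(c1m)
    if (na <= nb) {
      perms <- combinat_perms(nb, na)
      best <- 0
      for (p in perms) best <- max(best, sum(c1m[cbind(seq_len(na), p)]))
    } else {
      perms <- combinat_perms(na, nb)
      best <- 0
      for (p in perms) best <- max(best, sum(c1m[cbind(p, seq_len(nb))]))
    }
    best
  }
  combinat_perms <- function(n, k) {
    # all ordered selections of k from n
    if (k == 0) return(list(integer(0)))
    out <- list()
    rec <- function(cur, remaining) {
      if (length(cur) == k) { out[[length(out) + 1]] <<- cur; return() }
      for (x in remaining) rec(c(cur, x), setdiff(remaining, x))
    }
    rec(integer(0), seq_len(n))
    out
  }
  for (rep in 1:60) {
    ka <- sample(2:5, 1); kb <- sample(2:5, 1)
    La <- random_labels(ka, seed = rep)
    Lb <- random_labels(kb, seed = rep + 1000)
    m <- match_regions(La, Lb)
    # recompute the same pairwise c1 matrix the matcher used
    ot <- memseg:::overlap_table(La, Lb)
    c1m <- matrix(0, length(ot$ids_a), length(ot$ids_b))
    for (i in seq_along(ot$ids_a)) for (j in seq_along(ot$ids_b)) {
      n <- ot$inter[i, j]
      if (n > 0) c1m[i, j] <- n / (ot$sz_a[i] + ot$sz_b[j] - n)
    }
    expect_equal(sum(m$pairs$c1), brute_best(c1m), tolerance = 1e-9)
  }
})

test_that("identical volumes match perfectly; overlapping regions map one-to-one", {
  L <- random_labels(4, seed = 7)
  m <- match_regions(L, L)
  expect_identical(nrow(m$pairs), 4L)
  expect_true(all(m$pairs$c1 == 1))
  # one region in A overlapping two in B is matched to exactly one
  La <- matrix(0L, 10, 10); La[2:9, 2:9] <- 1L
  Lb <- matrix(0L, 10, 10); Lb[2:9, 2:5] <- 1L; Lb[2:9, 6:9] <- 2L
  m2 <- match_regions(La, Lb)
  expect_identical(nrow(m2$pairs), 1L)
  expect_identical(length(m2$unmatched_b), 1L)
})

test_that("aggregation normalizes by the larger cell count", {
  pairs <- data.frame(c1 = rep(1, 3), c2 = rep(1, 3), c3 = rep(1, 3))
  expect_equal(unname(aggregate_coefficients(pairs, 3, 3)), c(1, 1, 1))
  expect_equal(aggregate_coefficients(pairs, 4, 3)[["C1"]], 0.75)
  empty <- data.frame(c1 = numeric(0), c2 = numeric(0), c3 = numeric(0))
  expect_equal(unname(aggregate_coefficients(empty, 2, 2)), c(0, 0, 0))
  expect_error(aggregate_coefficients(empty, 0, 0), "no cells")
})

test_that("inter-observer normalization adds the disagreement and caps at one", {
  expect_equal(normalize_interobserver(0.7080, 0.8238), 0.8842)
  expect_equal(normalize_interobserver(0.6772, 0.8238), 0.8534)
  expect_equal(normalize_interobserver(0.8238, 0.8238), 1.0000)
  expect_equal(normalize_interobserver(0.99, 0.5), 1)       # cap
  expect_error(normalize_interobserver(1.2, 0.5))
})

test_that("error counts distinguish fused, split, FP and FN", {
  L <- random_labels(4, seed = 8)
  expect_identical(unname(count_errors(L, L)), c(0L, 0L, 0L, 0L))

  # two reference cells merged into one auto region -> both falsely fused
  ref <- matrix(0L, 12, 12); ref[2:11, 2:6] <- 1L; ref[2:11, 7:11] <- 2L
  auto <- matrix(0L, 12, 12); auto[2:11, 2:11] <- 1L
  ce <- count_errors(auto, ref)
  expect_identical(ce[["falsely_fused"]], 2L)
  expect_identical(ce[["false_negative"]], 0L)

  # one reference cell cut in half by two auto regions -> one split event
  ce2 <- count_errors(ref, auto)   # roles swapped: auto has 2 regions, ref 1
  expect_identical(ce2[["falsely_split"]], 1L)

  # an auto region with no counterpart is a false positive
  auto_fp <- auto; auto_fp[1, 1] <- 0L; auto_fp[12, 12] <- 2L
  auto_fp2 <- matrix(0L, 12, 12); auto_fp2[2:11, 2:11] <- 1L; auto_fp2[1, 1] <- 2L
  ce3 <- count_errors(auto_fp2, ref)
  expect_identical(ce3[["false_positive"]], 1L)

  # a reference cell nobody covers is a false negative
  ref_fn <- ref; auto_empty <- matrix(0L, 12, 12); auto_empty[2:11, 2:6] <- 1L
  ce4 <- count_errors(auto_empty, ref_fn)
  expect_identical(ce4[["false_negative"]], 1L)
})

test_that("the full report combines matching, aggregation and normalization", {
  L <- random_labels(3, seed = 9)
  rep <- evaluate_segmentation(L, L, interobs = c(C1 = 0.8238, C2 = 0.8514, C3 = 0.9617))
  expect_equal(unname(rep$C), c(1, 1, 1))
  expect_equal(unname(rep$Cn), c(1, 1, 1))
  expect_identical(unname(rep$counts), c(0L, 0L, 0L, 0L))
})
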