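# Binding matrix construction, contrast statistics, candidate selection,
# band reporting and pyramidalization/correlation analysis.

toy_M <- function(E, codes = NULL) {
  k <- nrow(E)
  if (is.null(codes)) codes <- load_roster()$code[seq_len(k)]
  dimnames(E) <- list(codes, codes)
  binding_matrix(E, codes)
}

test_that("build_matrix takes the per-pair maximum and symmetrizes", {
  recs <- data.frame(
    group_x = c("HH-h", "HH-h", "HH-h", "NN-h"),
    group_y = c("NN-h", "NN-h", "HH-h", "NN-h"),
    pose_id = c("p1", "p2", "p1", "p1"),
    BE = c(3, 7, 1, 0))
  M <- build_matrix(recs)
  expect_equal(unname(M$E), matrix(c(1, 7, 7, 0), 2))
  expect_identical(M$pose["HH-h", "NN-h"], "p2")
  # records listed only as (Y, X) fill the same cell
  recs2 <- data.frame(group_x = c("HH-h", "NN-h", "NN-h"),
                      group_y = c("HH-h", "HH-h", "NN-h"),
                      pose_id = "p", BE = c(1, 7, 0))
  expect_equal(build_matrix(recs2)$E, M$E)
})

test_that("build_matrix applies the planarity filter and reports gaps", {
  recs <- data.frame(group_x = c("HH-h", "HH-h", "HH-h", "NN-h"),
                     group_y = c("NN-h", "NN-h", "HH-h", "NN-h"),
                     pose_id = c("p1", "p2", "p1", "p1"),
                     BE = c(3, 7, 1, 0),
                     planar = c(TRUE, FALSE, TRUE, TRUE))
  M <- build_matrix(recs)
  expect_equal(M$E["HH-h", "NN-h"], 3)  # the 7 kcal/mol pose was not planar
  expect_error(build_matrix(recs[1:2, ]), "no energy record")
})

test_that("matrix construction is invariant under roster permutation", {
  set.seed(41)
  codes <- c("HH-h", "NN-h", "HNH-hh")
  recs <- expand.grid(group_x = codes, group_y = codes,
                      stringsAsFactors = FALSE)
  recs <- recs[recs$group_x <= recs$group_y, ]
  recs$pose_id <- "p"
  recs$BE <- runif(nrow(recs), 0, 10)
  M1 <- build_matrix(recs, roster = codes)
  M2 <- build_matrix(recs, roster = rev(codes))
  expect_equal(M1$E, M2$E[codes, codes])
})

test_that("binary contrast follows its defining formula", {
  M <- toy_M(matrix(c(10, 15, 15, 4), 2), c("X-h", "Y-h"))
  expect_equal(contrast_binary(M, "X-h", "Y-h"), 15 - (10 + 4) / 2)
  expect_equal(contrast_binary(M, "X-h", "X-h"), 0)
  M0 <- toy_M(matrix(c(0, 20, 20, 0), 2), c("X-h", "Y-h"))
  expect_equal(contrast_binary(M0, "X-h", "Y-h"), 20)
  expect_error(contrast_binary(M0, "X-h", "Z-h"), "not in roster")
})

test_that("generalized contrast takes the strongest alternative, homo included", {
  E <- matrix(c(2, 20, 12,
                20, 3, 1,
                12, 1, 0), 3, byrow = TRUE)
  M <- toy_M(E, c("X-h", "Y-h", "Z-h"))
  expect_equal(contrast_generalized(M, "X-h", "Y-h", c("X-h", "Y-h")),
               20 - max(2, 3))
  expect_equal(contrast_generalized(M, "X-h", "Y-h"), 20 - 12)
  expect_error(contrast_generalized(M, "X-h", "Y-h", "X-h"), "context")
})

test_that("contrast identities and monotonicity hold on random matrices", {
  set.seed(42)
  for (rep in 1:20) {
    M <- rand_matrix(6)
    codes <- M$roster
    X <- codes[1]; Y <- codes[2]
    # binary (mean of homo) >= generalized with pair context (max of homo)
    expect_gte(contrast_binary(M, X, Y) + 1e-12,
               contrast_generalized(M, X, Y, c(X, Y)))
    # monotone nonincreasing in context size
    prev <- contrast_generalized(M, X, Y, c(X, Y))
    for (k in 3:length(codes)) {
      cur <- contrast_generalized(M, X, Y, codes[1:k])
      expect_lte(cur, prev + 1e-12)
      prev <- cur
    }
  }
})

test_that("candidate selection matches a brute-force filter and is sorted", {
  set.seed(43)
  M <- rand_matrix(8)
  cand <- select_candidates(M, threshold = 5)
  # brute force: loop all unordered pairs, keep contrast > 5
  want <- 0L
  for (i in 1:7) for (j in (i + 1):8) {
    X <- M$roster[i]; Y <- M$roster[j]
    if (M$E[X, Y] - (M$E[X, X] + M$E[Y, Y]) / 2 > 5) want <- want + 1L
  }
  expect_identical(nrow(cand), want)
  expect_true(all(diff(cand$E_XY) <= 0))
  expect_true(all(cand$E_C > 5))
  # threshold above every contrast empties the list
  expect_identical(nrow(select_candidates(M, threshold = 1e6)), 0L)
  # threshold 0 on an all-positive-contrast toy matrix keeps all hetero pairs
  Mpos <- toy_M(matrix(c(0, 8, 8, 0), 2), c("X-h", "Y-h"))
  expect_identical(nrow(select_candidates(Mpos, threshold = 0)), 1L)
})

test_that("pair annotations flag canonical and mixed pairs", {
  E <- matrix(0, 3, 3); E[1, 2] <- E[2, 1] <- 10; E[1, 3] <- E[3, 1] <- 9
  M <- toy_M(E, c("HH-h", "NN-h", "HNH-hh"))
  cand <- select_candidates(M, threshold = 1)
  dd_aa <- cand[cand$Y == "NN-h" | cand$X == "NN-h", ]
  expect_true(dd_aa$canonical)
  expect_false(dd_aa$mixed)
  dd_dad <- cand[cand$Y == "HNH-hh" | cand$X == "HNH-hh", ]
  expect_false(dd_dad$canonical)
  expect_true(dd_dad$mixed)
})

test_that("band report finds the per-band best pair and the maximum gap", {
  cand <- data.frame(X = c("A-h", "B-h", "C-h"), Y = c("D-h", "E-h", "F-h"),
                     E_XY = c(7, 9, 12), E_C = c(5, 8, 6))
  M <- toy_M(matrix(0, 2, 2), c("X-h", "Y-h"))
  rep1 <- band_report(M, cand, c(6, 10, 14))
  expect_equal(rep1$max_gap, 3)
  expect_identical(rep1$bands$X, c("B-h", "C-h"))  # best contrast in band 1
  # single candidate: one band populated, zero gap
  rep2 <- band_report(M, cand[1, ], c(6, 10))
  expect_equal(rep2$max_gap, 0)
  expect_identical(rep2$bands$X, "A-h")
})

test_that("matrix CSV round-trips in square and long form", {
  set.seed(44)
  M <- rand_matrix(5)
  sq <- temp_path("m.csv")
  write_matrix_csv(M, sq)
  M2 <- read_matrix_csv(sq)
  expect_equal(M2$E, M$E, tolerance = 1e-12)
  lg <- temp_path("long.csv")
  write_matrix_long(M, lg)
  df <- read.csv(lg)
  expect_identical(nrow(df), 15L)
})
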