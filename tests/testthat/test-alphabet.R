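# Alphabet mining over sliding energy windows, against the brute-force
# reference enumeration.

toy_alpha_M <- function(E, codes) {
  dimnames(E) <- list(codes, codes)
  binding_matrix(E, codes)
}

test_that("2L mining keeps in-window selective pairs and drops the rest", {
  codes <- c("HH-h", "NN-h")
  # E_XY = 15, homo pairs 0: in [10,20] with contrast 15 > 5
  M <- toy_alpha_M(matrix(c(0, 15, 15, 0), 2), codes)
  found <- find_2L(M, energy_window(10, 10))
  expect_length(found, 1)
  expect_identical(found[[1]]$letters, sort(codes))
  expect_equal(found[[1]]$E, 15)
  expect_equal(found[[1]]$contrast, 15)
  # all-zero matrix: nothing qualifies
  expect_length(find_2L(toy_alpha_M(matrix(0, 2, 2), codes),
                        energy_window(0, 10)), 0)
  # out-of-window pair is dropped
  expect_length(find_2L(M, energy_window(20, 10)), 0)
})

test_that("single-site letters are excluded by min_sites", {
  codes <- c("H-h", "N-h")   # one hydrogen-bond site each
  M <- toy_alpha_M(matrix(c(0, 15, 15, 0), 2), codes)
  expect_length(find_2L(M, energy_window(10, 10)), 0)
  expect_length(find_2L(M, energy_window(10, 10), min_sites = 1), 1)
})

test_that("window membership is a closed interval on both edges", {
  codes <- c("HH-h", "NN-h")
  for (e in c(10, 20)) {
    M <- toy_alpha_M(matrix(c(0, e, e, 0), 2), codes)
    expect_length(find_2L(M, energy_window(10, 10)), 1)
  }
  M <- toy_alpha_M(matrix(c(0, 20.001, 20.001, 0), 2), codes)
  expect_length(find_2L(M, energy_window(10, 10)), 0)
})

test_that("4L mining needs two disjoint selective pairs", {
  codes <- c("HH-h", "NN-h", "HNH-hh", "OHO-h")
  E <- matrix(0, 4, 4)
  E[1, 2] <- E[2, 1] <- 15          # pure pair
  E[3, 4] <- E[4, 3] <- 13          # mixed pair
  # weak cross-talk keeps four-letter contrasts above threshold
  E[1, 3] <- E[3, 1] <- 2; E[1, 4] <- E[4, 1] <- 1
  E[2, 3] <- E[3, 2] <- 1; E[2, 4] <- E[4, 2] <- 2
  M <- toy_alpha_M(E, codes)
  found <- find_4L(M, energy_window(10, 10))
  expect_length(found, 1)
  expect_identical(found[[1]]$letters, sort(codes))
  expect_equal(sort(found[[1]]$E), c(13, 15))
  # a single valid pair cannot form a 4L alphabet
  M2 <- toy_alpha_M(E[1:2, 1:2], codes[1:2])
  expect_length(find_4L(M2, energy_window(10, 10)), 0)
  # strong cross-talk to a third letter kills the alphabet
  E3 <- E; E3[1, 3] <- E3[3, 1] <- 9   # 13 - 9 = 4 < 5 within letters
  expect_length(find_4L(toy_alpha_M(E3, codes), energy_window(10, 10)), 0)
})

test_that("a 4L alphabet's pairs need not be individually valid 2L alphabets", {
  # pair-context contrast can exceed the 4-letter-context contrast only;
  # the reverse (valid in 4L context, invalid at pair context) cannot
  # happen, but a valid 2L pair can fail inside a 4L set - construct it
  codes <- c("HH-h", "NN-h", "HNH-hh", "OHO-h")
  E <- matrix(0, 4, 4)
  E[1, 2] <- E[2, 1] <- 15
  E[3, 4] <- E[4, 3] <- 13
  E[1, 3] <- E[3, 1] <- 9
  M <- toy_alpha_M(E, codes)
  in_w <- energy_window(10, 10)
  # both pairs are valid 2L alphabets on their own
  expect_length(find_2L(M, in_w), 2)
  # but no 4L alphabet survives the shared-context competition
  expect_length(find_4L(M, in_w), 0)
})

test_that("planted 6-group matrix yields exactly the planted 4L set", {
  set.seed(50)
  codes <- c("HH-h", "NN-h", "HNH-hh", "OHO-h", "HHH-h", "NNN-hhh")
  E <- matrix(runif(36, 0, 2), 6); E <- (E + t(E)) / 2
  E[1, 2] <- E[2, 1] <- 18
  E[3, 4] <- E[4, 3] <- 16
  M <- toy_alpha_M(E, codes)
  found <- find_4L(M, energy_window(10, 10))
  expect_length(found, 1)
  expect_identical(found[[1]]$letters, sort(codes[1:4]))
  # brute force agrees
  bf <- brute_force_alphabets(M, energy_window(10, 10), k = 4)
  expect_identical(alphabet_keys(found), alphabet_keys(bf))
})

test_that("fast mining equals brute force on random matrices", {
  set.seed(51)
  for (rep in 1:30) {
    M <- rand_matrix(sample(8:12, 1))
    w <- energy_window(runif(1, 0, 15), 10)
    for (k in c(2, 4)) {
      got <- alphabet_keys(find_alphabets(M, w, k = k))
      want <- alphabet_keys(brute_force_alphabets(M, w, k = k))
      expect_identical(got, want)
    }
  }
})

test_that("alphabet counts are monotone in threshold and min_sites", {
  set.seed(52)
  for (rep in 1:5) {
    M <- rand_matrix(10)
    w <- energy_window(5, 10)
    n_prev <- Inf
    for (thr in c(1, 3, 5, 8)) {
      n <- length(find_2L(M, w, threshold = thr))
      expect_lte(n, n_prev)
      n_prev <- n
    }
    expect_lte(length(find_2L(M, w, min_sites = 3)),
               length(find_2L(M, w, min_sites = 2)))
  }
})

test_that("alphabet letters are distinct and have enough sites", {
  set.seed(53)
  M <- rand_matrix(10)
  for (k in c(2, 4)) {
    for (a in find_alphabets(M, energy_window(5, 15), k = k)) {
      expect_identical(length(a$letters), as.integer(k))
      expect_identical(anyDuplicated(a$letters), 0L)
      for (l in a$letters) {
        expect_gte(length(as_site_pattern(l)$roles), 2)
      }
    }
  }
})

test_that("window scan is deterministic and counts per window", {
  codes <- c("HH-h", "NN-h", "HNH-hh", "OHO-h")
  E <- matrix(0, 4, 4)
  E[1, 2] <- E[2, 1] <- 12
  E[3, 4] <- E[4, 3] <- 22
  M <- toy_alpha_M(E, codes)
  sc1 <- scan_windows(M, window_spec(10, 5))
  sc2 <- scan_windows(M, window_spec(10, 5))
  expect_identical(sc1$windows, sc2$windows)
  # the 12 pair is counted in windows [5,15] and [10,20]
  expect_identical(sc1$windows$n_2L[sc1$windows$lower == 5], 1L)
  expect_identical(sc1$windows$n_2L[sc1$windows$lower == 10], 1L)
  expect_identical(sc1$windows$n_2L[sc1$windows$lower == 20], 1L)
  expect_identical(sum(sc1$windows$n_4L), 0L)
})

test_that("alphabets classify by pure/mixed pair composition", {
  mk <- function(pairs) {
    letters <- unlist(pairs)
    E <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
    structure(list(pairs = pairs, letters = sort(letters),
                   E = rep(10, length(pairs)),
                   contrast = rep(10, length(pairs)),
                   k = length(letters)), class = "alphabet")
  }
  expect_identical(
    classify_alphabet(mk(list(c("HH-hh-p", "NNN-hhh"),
                              c("HNH-hh", "OHO-h-p")))),
    "pure+mixed")
  expect_identical(
    classify_alphabet(mk(list(c("HH-h", "NN-h"), c("HHH-h", "NNN-hhh")))),
    "pure+pure")
  expect_identical(
    classify_alphabet(mk(list(c("HNH-hh", "OHO-h"), c("HHN-h", "NNH-h")))),
    "mixed+mixed")
  expect_identical(classify_alphabet(mk(list(c("HH-h", "NN-h")))), "pure")
})
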