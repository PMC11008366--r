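# Mining of molecular "alphabets": sets of mutually selective complementary
# pairs (2 letters = one pair, 4 letters = two disjoint pairs, ...) whose
# binding energies fall inside a sliding energy window and whose generalized
# contrast against every alternative inside the alphabet exceeds a threshold.

#' Energy window and sliding-window specification
#'
#' A window is a closed binding-energy interval `[lower, lower + width]`
#' kcal/mol. A window spec describes a sliding scan: windows of fixed width
#' advancing by a fixed step.
#'
#' @param lower lower edge in kcal/mol.
#' @param width window width in kcal/mol (default 10, must be > 0).
#' @param step scan step in kcal/mol (default 5, must be > 0).
#' @return `energy_window` / `window_spec` object.
#' @export
energy_window <- function(lower, width = 10) {
  stopifnot(is.numeric(lower), length(lower) == 1L, width > 0)
  structure(list(lower = lower, width = width, upper = lower + width),
            class = "energy_window")
}

#' @rdname energy_window
#' @export
window_spec <- function(width = 10, step = 5) {
  stopifnot(width > 0, step > 0)
  structure(list(width = width, step = step), class = "window_spec")
}

.in_window <- function(e, w) e >= w$lower & e <= w$upper

.n_sites_or_na <- function(code) {
  tryCatch(length(as_site_pattern(code)$roles), error = function(e) NA_integer_)
}

new_alphabet <- function(pairs, E, contrast) {
  letters <- sort(unique(unlist(pairs)))
  structure(list(pairs = pairs, letters = letters,
                 E = E, contrast = contrast, k = length(letters)),
            class = "alphabet")
}

#' @export
print.alphabet <- function(x, ...) {
  lab <- vapply(seq_along(x$pairs), function(i) {
    sprintf("%s:%s (E=%.2f, Ec=%.2f)", x$pairs[[i]][1], x$pairs[[i]][2],
            x$E[i], x$contrast[i])
  }, character(1))
  cat("<alphabet ", x$k, "L> ", paste(lab, collapse = "  "), "\n", sep = "")
  invisible(x)
}

# canonical identity of an alphabet = sorted "X|Y" pair keys
.alphabet_key <- function(pairs) {
  paste(sort(vapply(pairs, function(p) paste(sort(p), collapse = "|"),
                    character(1))), collapse = ";")
}

# Candidate hetero pairs inside the window with enough sites. Because the
# generalized contrast is monotone nonincreasing in context size, the
# pair-context contrast > threshold is a valid prefilter for any larger
# alphabet context.
.candidate_pairs <- function(M, w, threshold, min_sites) {
  n <- length(M$roster)
  ns <- vapply(M$roster, .n_sites_or_na, integer(1))
  keep <- is.na(ns) | ns >= min_sites
  out <- list()
  for (i in seq_len(n - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):n) {
      if (!keep[j]) next
      X <- M$roster[i]; Y <- M$roster[j]
      if (!.in_window(M$E[X, Y], w)) next
      if (contrast_generalized(M, X, Y, c(X, Y)) <= threshold) next
      out[[length(out) + 1L]] <- c(X, Y)
    }
  }
  out
}

#' Find k-letter alphabets in an energy window
#'
#' An alphabet is a set of `k/2` letter-disjoint hetero pairs such that every
#' pair's binding energy lies inside the closed window and every pair's
#' generalized contrast - with context equal to the alphabet's own letters -
#' strictly exceeds the threshold. Letters with fewer than `min_sites`
#' hydrogen-bonding sites are excluded (single-site groups cannot constrain
#' orientation). `find_2L()` and `find_4L()` are the common special cases.
#'
#' @param M a [binding_matrix].
#' @param w an [energy_window] (or numeric `c(lower, upper)`).
#' @param threshold generalized-contrast threshold in kcal/mol (default 5,
#'   strictly greater-than).
#' @param min_sites minimum hydrogen-bond sites per letter (default 2).
#'   Roster codes that do not parse as shorthand codes are not filtered.
#' @param k even number of letters (default 2).
#' @param context `"letters"` (default: contrasts judged inside the
#'   alphabet, the physical content of a k-letter system) or `"roster"`
#'   (contrasts against the whole roster).
#' @param require_all_in_window if `FALSE`, only one pair of a multi-pair
#'   alphabet must lie inside the window (the others may sit anywhere);
#'   default `TRUE`.
#' @return List of `alphabet` objects, deduplicated (pair order irrelevant).
#' @export
find_alphabets <- function(M, w, threshold = 5, min_sites = 2, k = 2,
                           context = c("letters", "roster"),
                           require_all_in_window = TRUE) {
  context <- match.arg(context)
  if (is.numeric(w) && length(w) == 2L) {
    w <- energy_window(w[1], w[2] - w[1])
  }
  stopifnot(inherits(w, "energy_window"), k %% 2 == 0, k >= 2)
  npairs <- k / 2
  cand <- .candidate_pairs(M, w, threshold, min_sites)
  if (!require_all_in_window && npairs > 1) {
    wide <- energy_window(min(M$E) - 1, diff(range(M$E)) + 2)
    extra <- .candidate_pairs(M, wide, threshold, min_sites)
    pool <- unique(c(lapply(cand, identity), lapply(extra, identity)))
  } else {
    pool <- cand
  }
  found <- list()
  seen <- character(0)

  check_set <- function(pairs) {
    letters <- unlist(pairs)
    ctx <- if (context == "letters") letters else M$roster
    E <- numeric(length(pairs))
    ec <- numeric(length(pairs))
    n_in <- 0L
    for (i in seq_along(pairs)) {
      X <- pairs[[i]][1]; Y <- pairs[[i]][2]
      E[i] <- M$E[X, Y]
      if (.in_window(E[i], w)) n_in <- n_in + 1L
      ec[i] <- contrast_generalized(M, X, Y, ctx)
      if (ec[i] <= threshold) return(NULL)
    }
    if (require_all_in_window && n_in < length(pairs)) return(NULL)
    if (!require_all_in_window && n_in < 1L) return(NULL)
    new_alphabet(pairs, E, ec)
  }

  recurse <- function(chosen, used, start) {
    if (length(chosen) == npairs) {
      key <- .alphabet_key(chosen)
      if (!(key %in% seen)) {
        a <- check_set(chosen)
        if (!is.null(a)) {
          seen <<- c(seen, key)
          found[[length(found) + 1L]] <<- a
        }
      }
      return(invisible(NULL))
    }
    if (start > length(pool)) return(invisible(NULL))
    for (idx in start:length(pool)) {
      p <- pool[[idx]]
      if (p[1] %in% used || p[2] %in% used) next
      recurse(c(chosen, list(p)), c(used, p), idx + 1L)
    }
    invisible(NULL)
  }
  if (length(pool) >= npairs) recurse(list(), character(0), 1L)
  found
}

#' @rdname find_alphabets
#' @export
find_2L <- function(M, w, threshold = 5, min_sites = 2, ...) {
  find_alphabets(M, w, threshold, min_sites, k = 2, ...)
}

#' @rdname find_alphabets
#' @export
find_4L <- function(M, w, threshold = 5, min_sites = 2, ...) {
  find_alphabets(M, w, threshold, min_sites, k = 4, ...)
}

#' Brute-force alphabet enumeration (reference implementation)
#'
#' Exhaustively enumerates all k-subsets of the roster and all perfect
#' matchings of each subset into pairs, applying the alphabet conditions to
#' each matching without any pruning. Serves as ground truth for
#' [find_alphabets()] in tests; practical up to rosters of a few dozen
#' groups.
#'
#' @inheritParams find_alphabets
#' @return List of `alphabet` objects.
#' @export
brute_force_alphabets <- function(M, w, threshold = 5, min_sites = 2, k = 2,
                                  context = c("letters", "roster"),
                                  require_all_in_window = TRUE) {
  context <- match.arg(context)
  if (is.numeric(w) && length(w) == 2L) {
    w <- energy_window(w[1], w[2] - w[1])
  }
  stopifnot(k %% 2 == 0, k >= 2, length(M$roster) <= 64)
  ns <- vapply(M$roster, .n_sites_or_na, integer(1))
  letters_ok <- M$roster[is.na(ns) | ns >= min_sites]
  if (length(letters_ok) < k) return(list())

  matchings <- function(letters) {
    if (length(letters) == 0L) return(list(list()))
    first <- letters[1]
    rest <- letters[-1]
    out <- list()
    for (p in seq_along(rest)) {
      sub <- matchings(rest[-p])
      for (s in sub) out[[length(out) + 1L]] <- c(list(c(first, rest[p])), s)
    }
    out
  }

  found <- list()
  seen <- character(0)
  for (subset in utils::combn(letters_ok, k, simplify = FALSE)) {
    for (pairs in matchings(subset)) {
      key <- .alphabet_key(pairs)
      if (key %in% seen) next
      ctx <- if (context == "letters") unlist(pairs) else M$roster
      ok <- TRUE
      E <- numeric(length(pairs)); ec <- numeric(length(pairs))
      n_in <- 0L
      for (i in seq_along(pairs)) {
        X <- pairs[[i]][1]; Y <- pairs[[i]][2]
        E[i] <- M$E[X, Y]
        if (.in_window(E[i], w)) n_in <- n_in + 1L
        ec[i] <- contrast_generalized(M, X, Y, ctx)
        if (ec[i] <= threshold) { ok <- FALSE; break }
      }
      if (ok && require_all_in_window && n_in < length(pairs)) ok <- FALSE
      if (ok && !require_all_in_window && n_in < 1L) ok <- FALSE
      if (ok) {
        seen <- c(seen, key)
        found[[length(found) + 1L]] <- new_alphabet(pairs, E, ec)
      }
    }
  }
  found
}

#' Sliding-window alphabet scan
#'
#' Generates windows covering the observed range of hetero binding energies
#' (lower edges from `step * floor(min(E) / step)` upward in increments of
#' `step`) and counts the alphabets of each requested size per window.
#'
#' @param M a [binding_matrix].
#' @param spec a [window_spec].
#' @param threshold generalized-contrast threshold (default 5).
#' @param k_values alphabet sizes to count (default `c(2, 4)`).
#' @param min_sites minimum sites per letter (default 2).
#' @param ... passed to [find_alphabets()].
#' @return Object of class `scan_result`: `windows` data frame (`lower`,
#'   `upper`, one count column `n_<k>L` per size) and `alphabets`, a list
#'   (per window) of lists (per k) of alphabets.
#' @export
scan_windows <- function(M, spec = window_spec(), threshold = 5,
                         k_values = c(2, 4), min_sites = 2, ...) {
  stopifnot(inherits(spec, "window_spec"))
  het <- M$E[upper.tri(M$E)]
  if (length(het) == 0L || all(is.na(het))) stop("matrix has no hetero pairs")
  lo <- spec$step * floor(min(het) / spec$step)
  lowers <- seq(lo, max(het), by = spec$step)
  windows <- data.frame(lower = lowers, upper = lowers + spec$width)
  alphabets <- vector("list", length(lowers))
  for (kv in k_values) windows[[sprintf("n_%dL", kv)]] <- 0L
  for (wi in seq_along(lowers)) {
    w <- energy_window(lowers[wi], spec$width)
    per_k <- list()
    for (kv in k_values) {
      found <- find_alphabets(M, w, threshold, min_sites, k = kv, ...)
      per_k[[sprintf("%dL", kv)]] <- found
      windows[[sprintf("n_%dL", kv)]][wi] <- length(found)
    }
    alphabets[[wi]] <- per_k
  }
  structure(list(windows = windows, alphabets = alphabets,
                 threshold = threshold, min_sites = min_sites),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> threshold ", x$threshold, " kcal/mol, min_sites ",
      x$min_sites, "\n", sep = "")
  print(x$windows)
  invisible(x)
}

#' Classify an alphabet by pair composition
#'
#' Each pair is labeled `"pure"` when both its patterns contain a single
#' role (e.g. DD...AA) and `"mixed"` when either contains both donors and
#' acceptors (e.g. DAD...ADA); the alphabet label is the sorted multiset of
#' pair labels, e.g. `"pure+mixed"`.
#'
#' @param a an `alphabet`.
#' @return Character label, `"pure"`/`"mixed"` joined with `+` (pure first).
#' @export
classify_alphabet <- function(a) {
  stopifnot(inherits(a, "alphabet"))
  lab <- vapply(a$pairs, function(p) {
    if (is_mixed(p[1]) || is_mixed(p[2])) "mixed" else "pure"
  }, character(1))
  paste(lab[order(match(lab, c("pure", "mixed")))], collapse = "+")
}

#' Serialize a scan result to JSON
#'
#' @param x a `scan_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_json <- function(x, path) {
  stopifnot(inherits(x, "scan_result"))
  payload <- list(
    threshold = x$threshold,
    min_sites = x$min_sites,
    windows = lapply(seq_len(nrow(x$windows)), function(i) {
      wk <- as.list(x$windows[i, ])
      wk$alphabets <- lapply(x$alphabets[[i]], function(per_k) {
        lapply(per_k, function(a) {
          list(pairs = a$pairs, E = a$E, contrast = a$contrast)
        })
      })
      wk
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
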