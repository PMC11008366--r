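# Shared generators and independent reference implementations ("oracles")
# used by the property-style tests. Oracles deliberately use a different
# algorithmic route than the package code they check.

# fresh temporary file path (cleaned with the session tempdir)
temp_path <- function(name) {
  file.path(tempfile("dir"), name) -> p
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}

# random site pattern with random acceptor flavors, under the caller's RNG
rand_pattern <- function(len = sample(1:3, 1)) {
  roles <- sample(c("D", "A"), len, replace = TRUE)
  flavors <- ifelse(roles == "D", "NH", sample(c("N", "O"), len, replace = TRUE))
  site_pattern(roles, flavors)
}

# Independent register-enumeration oracle: generate the full 2*(m+n-1)
# shift x flip grid with no dedup, materialize each configuration as an
# explicit two-row token table over the combined span, then remove
# duplicates by exhaustive pairwise comparison, where two configurations
# are the same physical object iff their token tables are equal as written
# or equal after rotating the whole complex 180 degrees in the plane
# (both rows reversed). Keeps the first representative in (flip, shift)
# order.
oracle_alignments <- function(x, y) {
  x <- as_site_pattern(x); y <- as_site_pattern(y)
  m <- length(x$roles); n <- length(y$roles)
  tok <- function(p, j) paste0(p$roles[j], ":", ifelse(is.na(p$flavors[j]),
                                                       "?", p$flavors[j]))
  configs <- list()
  for (flip in c(FALSE, TRUE)) {
    for (s in (1 - n):(m - 1)) {
      span <- min(1, s + 1):max(m, s + n)
      top <- sapply(span, function(r) if (r >= 1 && r <= m) tok(x, r) else ".")
      bot <- sapply(span, function(r) {
        j <- if (flip) r - s else n + 1 - (r - s)
        if (j >= 1 && j <= n) tok(y, j) else "."
      })
      configs[[length(configs) + 1]] <-
        list(flip = flip, shift = s, top = top, bot = bot)
    }
  }
  same <- function(a, b) {
    (identical(a$top, b$top) && identical(a$bot, b$bot)) ||
      (identical(a$top, rev(b$top)) && identical(a$bot, rev(b$bot)))
  }
  keep <- rep(TRUE, length(configs))
  for (i in seq_along(configs)) {
    if (!keep[i]) next
    for (j in seq_along(configs)) {
      if (j <= i) next
      if (keep[j] && same(configs[[i]], configs[[j]])) keep[j] <- FALSE
    }
  }
  configs[keep]
}

# brute-force pose selection: explicit filter, then scan for the maximum,
# then resolve ties by explicit sequential comparison
oracle_best_pose <- function(aligns, energies, ok) {
  idx <- which(ok)
  best <- NULL
  for (k in idx) {
    if (is.null(best)) { best <- k; next }
    a <- aligns[[k]]; b <- aligns[[best]]
    if (energies[k] > energies[best]) { best <- k; next }
    if (energies[k] < energies[best]) next
    if (a$n_contacts != b$n_contacts) {
      if (a$n_contacts < b$n_contacts) best <- k
      next
    }
    if (a$flip != b$flip) { if (!a$flip) best <- k; next }
    if (a$shift < b$shift) best <- k
  }
  best
}

# random symmetric binding matrix over k parseable codes
rand_matrix <- function(k, emax = 30) {
  pool <- load_roster()$code
  codes <- sample(pool, k)
  E <- matrix(stats::runif(k * k, -2, emax), k, k)
  E <- (E + t(E)) / 2
  dimnames(E) <- list(codes, codes)
  binding_matrix(E, codes)
}

alphabet_keys <- function(alphas) {
  sort(vapply(alphas, function(a) {
    paste(sort(vapply(a$pairs, function(p) paste(sort(p), collapse = "|"),
                      character(1))), collapse = ";")
  }, character(1)))
}
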