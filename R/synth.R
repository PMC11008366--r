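# Synthetic binding matrices: full surrogate scoring of a roster, with
# optional planted alphabets whose recovery is guaranteed by construction.

.as_roster_df <- function(roster) {
  if (is.character(roster)) {
    roster <- data.frame(code = roster, planarity = 1,
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(roster), "code" %in% names(roster))
  if (!"planarity" %in% names(roster)) roster$planarity <- 1
  roster
}

#' Synthesize a binding matrix with the surrogate scorer
#'
#' Scores every unordered roster pair (homo pairs included) by enumerating
#' all binding registers and keeping the best surrogate pose, then
#' optionally overwrites planted cells so that requested alphabets are
#' guaranteed to exist with a stated selectivity margin. Reproducible per
#' seed.
#'
#' Each planted alphabet is a list with elements `pairs` (list of code
#' pairs, letter-disjoint), `energies` (binding energy per pair, kcal/mol)
#' and `margin` (> 0): the planted pair cells are set to `energies` and
#' every other cell among the alphabet's letters (homo cells included) is
#' capped at `min(energies) - margin`, so each pair's generalized contrast
#' within the alphabet is at least `margin`. Conflicting plants (shared
#' letters with incompatible energies/caps) raise an error before any
#' generation.
#'
#' @param roster character vector of codes or data frame with `code` and
#'   `planarity` columns (e.g. from [load_roster()]).
#' @param params a [surrogate_params]; its `seed` drives the optional noise.
#' @param planted optional list of planted alphabets (see Details).
#' @param seed overrides `params$seed` when given.
#' @return A [binding_matrix] with source `"surrogate"`; planted cells carry
#'   pose tag `"planted"`.
#' @export
synth_matrix <- function(roster, params = surrogate_params(), planted = NULL,
                         seed = NULL) {
  roster <- .as_roster_df(roster)
  if (!is.null(seed)) params$seed <- as.integer(seed)
  codes <- roster$code
  n <- length(codes)

  plant_cells <- NULL
  if (!is.null(planted)) {
    plant_cells <- .validate_plants(planted, codes)
  }

  groups <- lapply(seq_len(n), function(i) {
    parse_code(codes[i], planarity = roster$planarity[i])
  })
  E <- matrix(0, n, n, dimnames = list(codes, codes))
  pose <- matrix(NA_character_, n, n, dimnames = list(codes, codes))
  align_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (j in i:n) {
      gi <- groups[[i]]; gj <- groups[[j]]
      key <- paste(class_label(gi$pattern),
                   paste(gi$pattern$flavors, collapse = ""),
                   class_label(gj$pattern),
                   paste(gj$pattern$flavors, collapse = ""), sep = "_")
      aligns <- align_cache[[key]]
      if (is.null(aligns)) {
        aligns <- enumerate_alignments(gi$pattern, gj$pattern)
        align_cache[[key]] <- aligns
      }
      e <- vapply(aligns,
                  function(a) surrogate_pair_energy(gi, gj, a, params),
                  numeric(1))
      best <- select_best_pose(aligns, e)
      E[i, j] <- E[j, i] <- attr(best, "energy")
      pose[i, j] <- pose[j, i] <- pose_id(best)
    }
  }

  if (!is.null(plant_cells)) {
    for (r in seq_len(nrow(plant_cells$set))) {
      X <- plant_cells$set$X[r]; Y <- plant_cells$set$Y[r]
      E[X, Y] <- E[Y, X] <- plant_cells$set$E[r]
      pose[X, Y] <- pose[Y, X] <- "planted"
    }
    for (r in seq_len(nrow(plant_cells$cap))) {
      X <- plant_cells$cap$X[r]; Y <- plant_cells$cap$Y[r]
      if (E[X, Y] > plant_cells$cap$cap[r]) {
        E[X, Y] <- E[Y, X] <- plant_cells$cap$cap[r]
        pose[X, Y] <- pose[Y, X] <- "planted"
      }
    }
  }
  binding_matrix(E, codes, pose, source = "surrogate")
}

# Validate planted alphabets and reduce them to cell assignments (set) and
# cell upper bounds (cap); errors on any conflict, before generation.
.validate_plants <- function(planted, codes) {
  set <- data.frame(X = character(0), Y = character(0), E = numeric(0))
  cap <- data.frame(X = character(0), Y = character(0), cap = numeric(0))
  ckey <- function(X, Y) paste(pmin(X, Y), pmax(X, Y), sep = "|")
  for (al in planted) {
    stopifnot(is.list(al), !is.null(al$pairs), !is.null(al$energies))
    margin <- if (is.null(al$margin)) 1 else al$margin
    if (margin <= 0) stop("planted alphabet margin must be > 0")
    letters <- unlist(al$pairs)
    if (anyDuplicated(letters)) {
      stop("planted alphabet pairs must be letter-disjoint")
    }
    if (!all(letters %in% codes)) {
      stop("planted letters not in roster: ",
           paste(setdiff(letters, codes), collapse = ", "))
    }
    if (length(al$energies) != length(al$pairs)) {
      stop("planted alphabet needs one energy per pair")
    }
    capval <- min(al$energies) - margin
    pk <- vapply(al$pairs, function(p) ckey(p[1], p[2]), character(1))
    for (i in seq_along(al$pairs)) {
      set <- rbind(set, data.frame(X = al$pairs[[i]][1],
                                   Y = al$pairs[[i]][2],
                                   E = al$energies[i]))
    }
    for (u in seq_along(letters)) {
      for (v in u:length(letters)) {
        if (ckey(letters[u], letters[v]) %in% pk) next
        cap <- rbind(cap, data.frame(X = letters[u], Y = letters[v],
                                     cap = capval))
      }
    }
  }
  sk <- ckey(set$X, set$Y)
  for (d in which(duplicated(sk))) {
    first <- match(sk[d], sk)
    if (set$E[first] != set$E[d]) {
      stop("conflicting planted energies for pair ", sk[d])
    }
  }
  # a planted pair must not be capped below its energy by another alphabet
  capk <- ckey(cap$X, cap$Y)
  hit <- match(sk, capk)
  bad <- which(!is.na(hit) & set$E > cap$cap[hit])
  if (length(bad) > 0L) {
    stop("infeasible planting: pair ", sk[bad[1]],
         " is planted at ", set$E[bad[1]], " but capped at ",
         cap$cap[hit[bad[1]]], " by another planted alphabet")
  }
  # keep the tightest cap per cell
  if (nrow(cap) > 0L) {
    ord <- order(capk, cap$cap)
    cap <- cap[ord, , drop = FALSE]
    cap <- cap[!duplicated(ckey(cap$X, cap$Y)), , drop = FALSE]
  }
  list(set = set[!duplicated(sk), , drop = FALSE], cap = cap)
}
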