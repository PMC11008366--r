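# Per-pose binding energies: definitions shared with quantum-chemistry
# ingestion, a built-in surrogate hydrogen-bond scorer, and best-pose
# selection.
#
# Sign convention throughout: binding energies are positive for bound
# complexes (energy released on association), matching the 7-23 kcal/mol
# range typical of doubly/triply hydrogen-bonded base pairs.

#' Binding energy from total energies
#'
#' `E_X + E_Y - E_complex`: the energy released when the relaxed isolated
#' monomers associate; positive for bound complexes.
#'
#' @param E_X,E_Y isolated monomer energies (kcal/mol).
#' @param E_complex total complex energy (kcal/mol).
#' @return Binding energy in kcal/mol.
#' @examples
#' binding_energy(-10, -12, -30)  # 8
#' @export
binding_energy <- function(E_X, E_Y, E_complex) {
  E_X + E_Y - E_complex
}

.req_field <- function(record, field, quantity) {
  v <- record[[field]]
  if (is.null(v) || length(v) != 1L || is.na(v)) {
    stop(quantity, " undefined: record lacks field '", field, "'")
  }
  as.numeric(v)
}

#' Counterpoise-corrected binding energies
#'
#' `be_relax()` subtracts the energies of the two independently optimized
#' monomers from the BSSE-corrected complex energy; `be_rigid()` subtracts
#' the in-complex (frozen-fragment) energies instead. `be_rigid >= be_relax`
#' whenever the in-complex fragment energies lie above the relaxed ones
#' (deformation costs energy).
#'
#' @param record an energy record: list or one-row data frame with fields
#'   `E_X_isolated`, `E_Y_isolated`, `E_complex_CP` (for `be_relax`) and
#'   `E_X_in_complex`, `E_Y_in_complex`, `E_complex_CP` (for `be_rigid`),
#'   all in kcal/mol.
#' @return Binding energy in kcal/mol. Missing required fields raise an
#'   explicit undefined-quantity error, never a silent zero.
#' @export
be_relax <- function(record) {
  binding_energy(.req_field(record, "E_X_isolated", "BE_relax"),
                 .req_field(record, "E_Y_isolated", "BE_relax"),
                 .req_field(record, "E_complex_CP", "BE_relax"))
}

#' @rdname be_relax
#' @export
be_rigid <- function(record) {
  binding_energy(.req_field(record, "E_X_in_complex", "BE_rigid"),
                 .req_field(record, "E_Y_in_complex", "BE_rigid"),
                 .req_field(record, "E_complex_CP", "BE_rigid"))
}

#' Surrogate scoring model parameters
#'
#' The surrogate stands in for semiempirical/DFT dimer energetics at desk
#' scale. Per facing contact: a donor-acceptor contact contributes the
#' primary strength of the acceptor flavor (`P_N` for pyridinic N, `P_O` for
#' keto O); a donor-donor contact contributes
#' `beta * (1 - min(planarity)) * P_N` - the amine-as-acceptor channel that
#' opens only for pyramidal amino groups; an acceptor-acceptor contact costs
#' `R_AA` (lone-pair repulsion). For each adjacent pair of contacted
#' registers, two diagonal secondary cross-terms of magnitude `S` are added,
#' attractive between unlike roles and repulsive between like roles
#' (Jorgensen-style secondary electrostatics). Optional Gaussian noise with
#' s.d. `sigma_noise` is seeded and reproducible.
#'
#' @param P_N primary D...N(pyridinic) strength, kcal/mol (default 6).
#' @param P_O primary D...O(keto) strength, kcal/mol (default 5).
#' @param S secondary cross-interaction magnitude, kcal/mol (default 1.5).
#' @param beta donor-as-acceptor factor in `[0, 1]` (default 0.6).
#' @param R_AA acceptor-acceptor contact penalty, kcal/mol (default 1).
#' @param sigma_noise Gaussian noise s.d., kcal/mol (default 0).
#' @param seed integer noise seed.
#' @return Object of class `surrogate_params`.
#' @export
surrogate_params <- function(P_N = 6, P_O = 5, S = 1.5, beta = 0.6,
                             R_AA = 1, sigma_noise = 0, seed = 1L) {
  stopifnot(P_N >= 0, P_O >= 0, S >= 0, R_AA >= 0, sigma_noise >= 0,
            beta >= 0, beta <= 1)
  structure(list(P_N = P_N, P_O = P_O, S = S, beta = beta, R_AA = R_AA,
                 sigma_noise = sigma_noise, seed = as.integer(seed)),
            class = "surrogate_params")
}

#' Surrogate binding energy of one pose
#'
#' Scores one register of two end groups with the surrogate hydrogen-bond
#' model (see [surrogate_params()]). Deterministic for `sigma_noise = 0`;
#' with noise, the perturbation is derived from the seed and the pair/pose
#' identity, so scores are reproducible and symmetric. The scorer satisfies
#' `E(x, y, a) == E(y, x, mirror_alignment(a))`.
#'
#' @param x,y [end_group] objects (codes are parsed with planarity 1).
#' @param a an alignment for the two patterns, from
#'   [enumerate_alignments()].
#' @param params a [surrogate_params] object.
#' @return Surrogate binding energy in kcal/mol (positive = bound).
#' @examples
#' x <- parse_code("HHH-hh"); y <- parse_code("NNN-hhh")
#' a <- enumerate_alignments(x, y)
#' max(sapply(a, function(al) surrogate_pair_energy(x, y, al)))  # 24
#' @export
surrogate_pair_energy <- function(x, y, a, params = surrogate_params()) {
  if (is.character(x)) x <- parse_code(x)
  if (is.character(y)) y <- parse_code(y)
  stopifnot(inherits(x, "end_group"), inherits(y, "end_group"),
            inherits(a, "alignment"))
  px <- x$pattern; py <- y$pattern
  if (a$m != length(px$roles) || a$n != length(py$roles)) {
    stop("alignment was enumerated for patterns of lengths ", a$m, "/", a$n,
         ", got ", length(px$roles), "/", length(py$roles))
  }
  pl <- min(x$planarity, y$planarity)
  prim_acc <- function(flavor) {
    if (identical(flavor, "O")) params$P_O else params$P_N
  }
  e <- 0
  cts <- a$contacts
  for (k in seq_len(nrow(cts))) {
    i <- cts[k, 1]; j <- cts[k, 2]
    rxy <- paste0(px$roles[i], py$roles[j])
    e <- e + switch(rxy,
                    DA = prim_acc(py$flavors[j]),
                    AD = prim_acc(px$flavors[i]),
                    DD = params$beta * (1 - pl) * params$P_N,
                    AA = -params$R_AA)
  }
  if (nrow(cts) > 1L) {
    for (k in seq_len(nrow(cts) - 1L)) {
      i1 <- cts[k, 1]; j1 <- cts[k, 2]
      i2 <- cts[k + 1L, 1]; j2 <- cts[k + 1L, 2]
      for (pair in list(c(i1, j2), c(i2, j1))) {
        like <- px$roles[pair[1]] == py$roles[pair[2]]
        e <- e + if (like) -params$S else params$S
      }
    }
  }
  if (params$sigma_noise > 0) {
    key <- paste(sort(c(x$code, y$code)), collapse = "|")
    key <- paste(key, paste(sort(c(class_label(px), class_label(py))),
                            collapse = "|"),
                 a$flip, a$n_contacts,
                 paste(sort(cts[, 1] + cts[, 2]), collapse = ","))
    e <- e + with_seed(str_seed(params$seed, key),
                      stats::rnorm(1, 0, params$sigma_noise))
  }
  e
}

#' Select the best binding pose
#'
#' Among poses passing the planarity predicate, returns the one with maximum
#' binding energy (equivalently minimum total energy). Ties are broken by
#' fewer contacts, then lowest (flip, shift).
#'
#' @param poses list of poses; each element is an alignment or a `pair_pose`
#'   (anything with an `$alignment`).
#' @param energies numeric vector of binding energies, one per pose.
#' @param planarity_ok predicate `function(pose) -> logical`; poses failing
#'   it are excluded. Default accepts every pose.
#' @return The selected pose, with attributes `energy` and `index` (position
#'   in the input). If no pose passes, an error of class `no_planar_pose`
#'   carrying the rejected poses is raised.
#' @export
select_best_pose <- function(poses, energies,
                             planarity_ok = function(pose) TRUE) {
  stopifnot(length(poses) == length(energies), length(poses) >= 1L)
  ok <- vapply(poses, function(p) isTRUE(planarity_ok(p)), logical(1))
  if (!any(ok)) {
    cond <- structure(class = c("no_planar_pose", "error", "condition"),
                      list(message = "no pose consistent with a planar geometry",
                           call = sys.call(), rejected = poses))
    stop(cond)
  }
  al <- function(p) if (inherits(p, "alignment")) p else p$alignment
  idx <- which(ok)
  key <- vapply(idx, function(k) {
    a <- al(poses[[k]])
    a$n_contacts * 1e4 + as.integer(a$flip) * 1e2 + (a$shift + 50)
  }, numeric(1))
  best <- idx[order(-energies[idx], key)][1]
  out <- poses[[best]]
  attr(out, "energy") <- unname(energies[best])
  attr(out, "index") <- best
  out
}

#' Best surrogate pose for a pair of end groups
#'
#' Convenience wrapper: enumerates all registers of the two groups, scores
#' each with the surrogate model, and selects the best pose.
#'
#' @inheritParams surrogate_pair_energy
#' @param params a [surrogate_params].
#' @return List with `energy`, `alignment`, and `energies` (all pose scores,
#'   named by pose id).
#' @export
surrogate_best_pose <- function(x, y, params = surrogate_params()) {
  if (is.character(x)) x <- parse_code(x)
  if (is.character(y)) y <- parse_code(y)
  aligns <- enumerate_alignments(x$pattern, y$pattern)
  e <- vapply(aligns, function(a) surrogate_pair_energy(x, y, a, params),
              numeric(1))
  names(e) <- vapply(aligns, pose_id, character(1))
  best <- select_best_pose(aligns, e)
  list(energy = attr(best, "energy"), alignment = best, energies = e)
}

# --- energy-table ingestion --------------------------------------------------

.ENERGY_REQUIRED <- c("group_x", "group_y", "pose_id", "E_complex",
                      "E_X_isolated", "E_Y_isolated")
.ENERGY_OPTIONAL <- c("E_complex_CP", "E_X_in_complex", "E_Y_in_complex")

#' Read a pairwise energy table exported from quantum-chemistry runs
#'
#' CSV with header; required columns `group_x`, `group_y`, `pose_id`,
#' `E_complex`, `E_X_isolated`, `E_Y_isolated`; optional counterpoise/rigid
#' columns `E_complex_CP`, `E_X_in_complex`, `E_Y_in_complex`. Units are
#' declared per file (`unit` argument) or per row (`unit` column accepting
#' `"kcal/mol"` or `"hartree"`); hartree values are converted with
#' 1 hartree = 627.509474 kcal/mol. Unknown columns are preserved.
#'
#' @param path CSV file path.
#' @param unit default unit when the table has no `unit` column.
#' @return Data frame of energy records in kcal/mol, with derived columns
#'   `BE` (plain binding energy), and `BE_relax`/`BE_rigid` where the
#'   counterpoise columns permit.
#' @export
read_energy_table <- function(path, unit = c("kcal/mol", "hartree")) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.ENERGY_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop("energy table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ecols <- intersect(c(.ENERGY_REQUIRED[-(1:3)], .ENERGY_OPTIONAL), names(df))
  for (cl in ecols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "")
    if (length(bad) > 0L) {
      stop("energy table ", path, ": non-numeric value '", df[[cl]][bad[1]],
           "' in column '", cl, "', row ", bad[1])
    }
    df[[cl]] <- v
  }
  rowunit <- if ("unit" %in% names(df)) df$unit else rep(unit, nrow(df))
  if (!all(rowunit %in% c("kcal/mol", "hartree"))) {
    stop("unknown unit value(s): ",
         paste(unique(setdiff(rowunit, c("kcal/mol", "hartree"))),
               collapse = ", "))
  }
  fac <- ifelse(rowunit == "hartree", HARTREE_KCAL, 1)
  for (cl in ecols) df[[cl]] <- df[[cl]] * fac
  if ("unit" %in% names(df)) df$unit <- "kcal/mol"

  key <- paste(df$group_x, df$group_y, df$pose_id, sep = "\r")
  dup <- which(duplicated(key))
  for (d in dup) {
    first <- match(key[d], key)
    same <- all(vapply(ecols, function(cl) {
      isTRUE(all.equal(df[[cl]][first], df[[cl]][d])) ||
        (is.na(df[[cl]][first]) && is.na(df[[cl]][d]))
    }, logical(1)))
    if (!same) {
      stop("energy table ", path, ": rows ", first, " and ", d,
           " duplicate pair/pose (", df$group_x[d], ", ", df$group_y[d],
           ", ", df$pose_id[d], ") with different energies")
    }
  }
  if (length(dup) > 0L) df <- df[-dup, , drop = FALSE]

  df$BE <- binding_energy(df$E_X_isolated, df$E_Y_isolated, df$E_complex)
  if ("E_complex_CP" %in% names(df)) {
    df$BE_relax <- binding_energy(df$E_X_isolated, df$E_Y_isolated,
                                  df$E_complex_CP)
    if (all(c("E_X_in_complex", "E_Y_in_complex") %in% names(df))) {
      df$BE_rigid <- binding_energy(df$E_X_in_complex, df$E_Y_in_complex,
                                    df$E_complex_CP)
    }
  }
  rownames(df) <- NULL
  df
}

#' Write an energy-record table to CSV
#'
#' Round-trip stable against [read_energy_table()] (energies are written in
#' kcal/mol). Derived `BE*` columns are recomputed on read and not written.
#'
#' @param records data frame of energy records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(records, path) {
  drop <- intersect(c("BE", "BE_relax", "BE_rigid"), names(records))
  out <- records[, setdiff(names(records), drop), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
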