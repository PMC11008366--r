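# Symmetric binding matrix of best-pose binding energies, selectivity
# contrast statistics, candidate selection and band reporting.

#' Construct a binding matrix
#'
#' A binding matrix holds the best-pose binding energy `E_XY` (kcal/mol,
#' positive = bound) for every unordered pair of roster codes, including the
#' homo pairs on the diagonal. Each cell is traceable to the pose it came
#' from (`pose` matrix) and to an energy-source tag.
#'
#' @param E numeric symmetric matrix with dimnames = roster codes.
#' @param roster character vector of codes (defaults to `rownames(E)`).
#' @param pose character matrix of per-cell pose ids (optional).
#' @param source energy-source tag, e.g. `"surrogate"` or a table path.
#' @return Object of class `binding_matrix`.
#' @export
binding_matrix <- function(E, roster = rownames(E), pose = NULL,
                           source = "unspecified") {
  E <- as.matrix(E)
  if (is.null(roster)) stop("roster codes required (dimnames of E)")
  stopifnot(nrow(E) == length(roster), ncol(E) == length(roster))
  dimnames(E) <- list(roster, roster)
  if (max(abs(E - t(E))) > 1e-9) stop("binding matrix must be symmetric")
  E <- (E + t(E)) / 2
  if (is.null(pose)) {
    pose <- matrix(NA_character_, nrow(E), ncol(E), dimnames = dimnames(E))
  }
  structure(list(roster = roster, E = E, pose = pose, source = source),
            class = "binding_matrix")
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat("<binding_matrix> ", length(x$roster), " groups (",
      length(x$roster) * (length(x$roster) + 1) / 2,
      " unordered cells), source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.binding_matrix <- function(x, ...) x$E

#' Build the binding matrix from per-pose energy records
#'
#' Every roster pair (including homo pairs) must have at least one record;
#' the cell value is the maximum binding energy over that pair's poses, after
#' the planarity filter. Records may list a pair in either order.
#'
#' @param records data frame with columns `group_x`, `group_y`, `pose_id`
#'   and the chosen energy column; an optional logical `planar` column
#'   filters poses inconsistent with a planar geometry.
#' @param energy_column which column holds the per-pose binding energy:
#'   `"BE"` (plain), `"BE_relax"` or `"BE_rigid"` (counterpoise-based), or
#'   any column name present in `records`.
#' @param roster codes to include; defaults to all codes in `records`.
#' @param source energy-source tag recorded on the matrix.
#' @return A [binding_matrix].
#' @export
build_matrix <- function(records, energy_column = "BE", roster = NULL,
                         source = energy_column) {
  stopifnot(is.data.frame(records))
  if (!energy_column %in% names(records)) {
    stop("records lack energy column '", energy_column, "'")
  }
  if ("planar" %in% names(records)) {
    records <- records[is.na(records$planar) | records$planar, , drop = FALSE]
  }
  if (is.null(roster)) {
    roster <- sort(unique(c(records$group_x, records$group_y)))
  }
  k <- length(roster)
  E <- matrix(NA_real_, k, k, dimnames = list(roster, roster))
  pose <- matrix(NA_character_, k, k, dimnames = list(roster, roster))
  xi <- match(records$group_x, roster)
  yi <- match(records$group_y, roster)
  keep <- !is.na(xi) & !is.na(yi) & !is.na(records[[energy_column]])
  for (r in which(keep)) {
    i <- xi[r]; j <- yi[r]
    e <- records[[energy_column]][r]
    if (is.na(E[i, j]) || e > E[i, j]) {
      E[i, j] <- E[j, i] <- e
      pose[i, j] <- pose[j, i] <- as.character(records$pose_id[r])
    }
  }
  if (anyNA(E)) {
    miss <- which(is.na(E) & upper.tri(E, diag = TRUE), arr.ind = TRUE)
    stop("no energy record for pair(s): ",
         paste(utils::head(paste0(roster[miss[, 1]], ":", roster[miss[, 2]]), 10),
               collapse = ", "),
         if (nrow(miss) > 10) sprintf(" (and %d more)", nrow(miss) - 10) else "")
  }
  binding_matrix(E, roster, pose, source)
}

.check_codes <- function(M, codes) {
  bad <- setdiff(codes, M$roster)
  if (length(bad) > 0L) {
    stop("code(s) not in roster: ", paste(bad, collapse = ", "))
  }
}

#' Binary binding-energy contrast
#'
#' `E_C = E_XY - (E_XX + E_YY) / 2`: how much the hetero pair is preferred
#' over the average of the two homo pairs. The primary figure of merit for
#' selecting a single complementary pair.
#'
#' @param M a [binding_matrix].
#' @param X,Y roster codes.
#' @return Contrast in kcal/mol (0 when `X == Y`).
#' @export
contrast_binary <- function(M, X, Y) {
  .check_codes(M, c(X, Y))
  M$E[X, Y] - (M$E[X, X] + M$E[Y, Y]) / 2
}

#' Generalized binding-energy contrast
#'
#' `E_C = E_XY - max_Z {E_XZ, E_YZ}` over all alternatives `Z` in a context
#' set: the margin by which X and Y prefer each other over every competing
#' interaction available in that context, homo pairs included. With context
#' `{X, Y}` this reduces to `E_XY - max(E_XX, E_YY)`; enlarging the context
#' can only decrease the result.
#'
#' @param M a [binding_matrix].
#' @param X,Y roster codes, both in `context`.
#' @param context character vector of codes forming the competing set.
#' @return Contrast in kcal/mol.
#' @export
contrast_generalized <- function(M, X, Y, context = M$roster) {
  context <- unique(context)
  .check_codes(M, c(X, Y, context))
  if (!all(c(X, Y) %in% context)) {
    stop("context must contain both X and Y")
  }
  alts <- c(M$E[X, setdiff(context, Y)], M$E[Y, setdiff(context, X)])
  if (length(alts) == 0L) {
    stop("context holds no alternative interaction for (", X, ", ", Y, ")")
  }
  M$E[X, Y] - max(alts)
}

#' Select selective candidate pairs
#'
#' All unordered hetero pairs whose contrast strictly exceeds the threshold,
#' sorted by binding energy `E_XY` descending. The binary contrast is the
#' default figure of merit for single-pair selection; the generalized
#' contrast (context = whole roster) is available for alphabet-style
#' screening.
#'
#' @param M a [binding_matrix].
#' @param threshold contrast threshold in kcal/mol (default 5); strictly
#'   greater-than.
#' @param contrast `"binary"` or `"generalized"`.
#' @return Data frame of pair summaries: `X`, `Y`, `E_XY`, `E_C`,
#'   `canonical`, `class_pair`, `mixed`.
#' @export
select_candidates <- function(M, threshold = 5,
                              contrast = c("binary", "generalized")) {
  contrast <- match.arg(contrast)
  n <- length(M$roster)
  rows <- list()
  # codes that do not parse (ad hoc toy labels) get NA pattern annotations
  pats <- lapply(M$roster, function(cd) {
    tryCatch(as_site_pattern(cd), error = function(e) NULL)
  })
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      X <- M$roster[i]; Y <- M$roster[j]
      ec <- if (contrast == "binary") contrast_binary(M, X, Y)
            else contrast_generalized(M, X, Y, M$roster)
      if (ec > threshold) {
        known <- !is.null(pats[[i]]) && !is.null(pats[[j]])
        rows[[length(rows) + 1L]] <- data.frame(
          X = X, Y = Y, E_XY = M$E[X, Y], E_C = ec,
          canonical = if (known) is_canonical_pair(pats[[i]], pats[[j]]) else NA,
          class_pair = if (known) {
            paste(class_label(pats[[i]]), class_label(pats[[j]]), sep = ":")
          } else NA_character_,
          mixed = if (known) is_mixed(pats[[i]]) || is_mixed(pats[[j]]) else NA,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(X = character(0), Y = character(0),
                      E_XY = numeric(0), E_C = numeric(0),
                      canonical = logical(0), class_pair = character(0),
                      mixed = logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$E_XY), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best candidate per binding-energy band
#'
#' Splits candidates into consecutive `E_XY` bands and reports, per band, the
#' candidate with maximum contrast, plus the maximum gap between consecutive
#' sorted binding energies of all candidates - the figure used to judge how
#' densely a selection spans an energy range.
#'
#' @param M a [binding_matrix] (used for provenance only).
#' @param candidates data frame from [select_candidates()].
#' @param band_edges increasing numeric vector of band edges in kcal/mol;
#'   band `k` is `[edge_k, edge_{k+1})`, the last band closed on both sides.
#' @return List with `bands` (data frame: band edges, best pair or `NA` if
#'   empty) and `max_gap`.
#' @export
band_report <- function(M, candidates, band_edges) {
  stopifnot(nrow(candidates) >= 1L, length(band_edges) >= 2L,
            !is.unsorted(band_edges, strictly = TRUE))
  e <- sort(candidates$E_XY)
  max_gap <- if (length(e) > 1L) max(diff(e)) else 0
  nb <- length(band_edges) - 1L
  bands <- data.frame(lower = band_edges[-length(band_edges)],
                      upper = band_edges[-1],
                      X = NA_character_, Y = NA_character_,
                      E_XY = NA_real_, E_C = NA_real_,
                      stringsAsFactors = FALSE)
  for (b in seq_len(nb)) {
    inb <- candidates$E_XY >= bands$lower[b] &
      (candidates$E_XY < bands$upper[b] |
         (b == nb & candidates$E_XY <= bands$upper[b]))
    if (any(inb)) {
      sub <- candidates[inb, , drop = FALSE]
      best <- sub[which.max(sub$E_C), ]
      bands$X[b] <- best$X; bands$Y[b] <- best$Y
      bands$E_XY[b] <- best$E_XY; bands$E_C[b] <- best$E_C
    }
  }
  list(bands = bands, max_gap = max_gap)
}

#' Correlate selectivity contrast with amine pyramidalization
#'
#' Pearson correlation between the binding-energy contrast and the mean
#' pyramidalization angle across pairs. Planar (conjugated) amino groups
#' cannot act as hydrogen-bond acceptors, so donor homo pairs stay near zero
#' and the contrast approaches the full hetero binding energy - a negative
#' correlation between angle and contrast is the expected signature.
#'
#' @param summaries data frame with numeric columns `E_C` and `angle`
#'   (degrees), one row per pair; at least 3 rows.
#' @return List (class `correlation_report`) with `n` and Pearson `r`.
#' @export
correlate_contrast_dihedral <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("E_C", "angle") %in% names(summaries)))
  if (nrow(summaries) < 3L) stop("need at least 3 pairs to correlate")
  if (stats::sd(summaries$E_C) == 0 || stats::sd(summaries$angle) == 0) {
    stop("correlation undefined: zero variance in contrast or angle")
  }
  r <- stats::cor(summaries$E_C, summaries$angle, method = "pearson")
  structure(list(n = nrow(summaries), r = r), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> n = ", x$n, ", Pearson r = ",
      format(x$r, digits = 4), "\n", sep = "")
  invisible(x)
}

# --- matrix I/O --------------------------------------------------------------

#' Read / write a binding matrix as CSV
#'
#' Square form: header row and first column carry the roster codes. Long
#' form: columns `X`, `Y`, `E`, `pose` (upper triangle incl. diagonal).
#'
#' @param M a [binding_matrix].
#' @param path CSV path.
#' @return `write_matrix_csv`/`write_matrix_long` return `path` invisibly;
#'   readers return a [binding_matrix].
#' @export
write_matrix_csv <- function(M, path) {
  df <- data.frame(code = M$roster, M$E, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  roster <- df[[1]]
  E <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(E), roster)) {
    stop("matrix CSV header codes do not match first-column codes")
  }
  binding_matrix(E, roster, source = path)
}

#' @rdname write_matrix_csv
#' @export
write_matrix_long <- function(M, path) {
  ut <- which(upper.tri(M$E, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(X = M$roster[ut[, 1]], Y = M$roster[ut[, 2]],
                   E = M$E[ut], pose = M$pose[ut])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
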