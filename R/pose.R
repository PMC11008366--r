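# Enumeration of binding registers ("poses") of two facing site patterns.
#
# Two end groups approach along the hydrogen-bond direction; their site rows
# face each other antiparallel. All distinct starting configurations are
# generated by shifting one pattern along the row and optionally flipping it
# in the binding plane. For two asymmetric three-site patterns this yields the
# classic 10 configurations: 4 with one facing contact, 4 with two, 2 with
# three.

.site_token <- function(pattern, j) {
  paste0(pattern$roles[j], ":",
         ifelse(is.na(pattern$flavors[j]), "?", pattern$flavors[j]))
}

# Physical-congruence signature of one register: the facing token sequence
# over the combined span, including dangling (uncontacted) sites. Canonical
# under 180-degree in-plane rotation of the whole dimer (both rows reversed),
# which makes flipped registers of palindromic patterns collapse onto their
# unflipped images.
.alignment_signature <- function(x, y, flip, shift, m, n) {
  rmin <- min(1L, shift + 1L)
  rmax <- max(m, shift + n)
  regs <- rmin:rmax
  xrow <- vapply(regs, function(r) {
    if (r >= 1L && r <= m) .site_token(x, r) else "."
  }, character(1))
  yrow <- vapply(regs, function(r) {
    j <- if (flip) r - shift else n + 1L - (r - shift)
    if (j >= 1L && j <= n) .site_token(y, j) else "."
  }, character(1))
  sig <- paste(paste(xrow, collapse = "|"), paste(yrow, collapse = "|"),
               sep = "//")
  rsig <- paste(paste(rev(xrow), collapse = "|"),
                paste(rev(yrow), collapse = "|"), sep = "//")
  if (sig <= rsig) sig else rsig
}

new_alignment <- function(flip, shift, contacts, m, n) {
  structure(list(flip = flip, shift = as.integer(shift),
                 contacts = contacts, n_contacts = nrow(contacts),
                 m = as.integer(m), n = as.integer(n)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> flip=", x$flip, " shift=", x$shift, " contacts=",
      paste(sprintf("(%d,%d)", x$contacts[, 1], x$contacts[, 2]),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Pose identifier string
#'
#' Compact `f<0|1>.s<shift>` label used as pose id in energy tables and
#' matrix provenance.
#'
#' @param a an alignment.
#' @return Character scalar.
#' @export
pose_id <- function(a) {
  sprintf("f%d.s%d", as.integer(a$flip), a$shift)
}

#' Enumerate all binding registers of two site patterns
#'
#' For each flip state of the second pattern, every shift with at least one
#' facing site-site contact is generated (`m + n - 1` shifts per flip state).
#' Registers that are physically congruent - identical facing configurations,
#' arising when either pattern is palindromic or both have a single site - are
#' deduplicated, keeping the unflipped representative. Output is ordered by
#' (flip, shift).
#'
#' With `flip = FALSE` the second pattern is read reversed (two molecules
#' facing each other); site `i` of the first pattern faces site
#' `n + 1 - (i - shift)` of the second, so the facing index `j` decrements as
#' `i` increments. `flip = TRUE` turns the second molecule over in the plane,
#' reading its pattern as written. Configurations with both molecules flipped
#' are rigid rotations of the whole complex and are not enumerated.
#'
#' @param x,y site patterns (anything [as_site_pattern()] accepts).
#' @return List of `alignment` objects, each with fields `flip`, `shift`,
#'   `contacts` (two-column integer matrix of facing indices `i`, `j`),
#'   `n_contacts`, `m`, `n`.
#' @examples
#' a <- enumerate_alignments("DDA", "AAD")
#' length(a)             # 10
#' contact_histogram(a)  # 4 / 4 / 2 poses with 1 / 2 / 3 contacts
#' @export
enumerate_alignments <- function(x, y) {
  x <- as_site_pattern(x)
  y <- as_site_pattern(y)
  m <- length(x$roles)
  n <- length(y$roles)
  if (m < 1L || n < 1L) stop("empty site pattern")
  out <- list()
  seen <- character(0)
  for (flip in c(FALSE, TRUE)) {
    for (s in (1L - n):(m - 1L)) {
      i <- max(1L, s + 1L):min(m, s + n)
      j <- if (flip) i - s else n + 1L - (i - s)
      sig <- .alignment_signature(x, y, flip, s, m, n)
      if (sig %in% seen) next
      seen <- c(seen, sig)
      contacts <- cbind(i = i, j = j)
      out[[length(out) + 1L]] <- new_alignment(flip, s, contacts, m, n)
    }
  }
  out
}

#' Contact-count histogram of a set of alignments
#'
#' @param alignments list of alignments (as from [enumerate_alignments()]).
#' @return Named integer vector, name = number of facing contacts,
#'   value = number of alignments with that count. Counts partition the input.
#' @export
contact_histogram <- function(alignments) {
  if (length(alignments) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  nc <- vapply(alignments, function(a) a$n_contacts, integer(1))
  tab <- table(nc)
  stats::setNames(as.integer(tab), names(tab))
}

#' Mirror an alignment to the swapped pair
#'
#' Returns the same physical register expressed for the pair `(y, x)` instead
#' of `(x, y)`: contacts are transposed and the shift re-expressed. Used to
#' state symmetry properties such as `E(x, y, a) == E(y, x, mirror(a))`.
#'
#' @param a an alignment between patterns of lengths `m` (first) and `n`
#'   (second).
#' @return An alignment between patterns of lengths `n` and `m`.
#' @export
mirror_alignment <- function(a) {
  contacts <- cbind(i = a$contacts[, 2], j = a$contacts[, 1])
  contacts <- contacts[order(contacts[, 1]), , drop = FALSE]
  shift <- if (a$flip) -a$shift else a$shift + a$n - a$m
  new_alignment(a$flip, shift, contacts, a$n, a$m)
}
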