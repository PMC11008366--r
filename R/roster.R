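# Packaged 64-group assay roster.
#
# The roster combines the end groups named in the screening study (HH-hh-p,
# OHO-h-p, NNN-hhh, ...), the five nucleobases mapped onto Watson-Crick-edge
# site patterns (a fixture convention, flagged in `label`), and
# programmatically generated filler codes that complete the class census
# (D, A, DA, DD, AA, DDD, AAA, DDA, DAD) up to exactly 64 entries.

# deterministic planarity rule for groups with amino donors: larger aromatic
# systems conjugate the nitrogen lone pair (more planar), additional amines
# compete for conjugation (more pyramidal); pure acceptors have no amines.
.planarity_rule <- function(code) {
  g <- parse_code(code)
  n_don <- sum(g$pattern$roles == "D")
  if (n_don == 0L) return(1)
  n_rings <- nchar(gsub("-", "", g$skeleton))
  min(1, max(0, 0.25 + 0.35 * n_rings - 0.25 * (n_don - 1)))
}

.NAMED_CODES <- c("HH-hh-p", "HH-pp", "HH-hh", "HH-hp", "HH-h_1", "HH-h_2",
                  "HHH-h", "HHH-hh", "HNH-hh", "OHO-h-p", "OHO-h_1",
                  "OHO-h_2", "NO-h-p", "NO-p", "NNN-hhh", "NNO-hh_1")

# nucleobase Watson-Crick edge patterns encoded as shorthand codes; these
# code assignments are fixture conventions of this package (synthetic
# stand-ins), not literature statements.
.NUCLEOBASE_CODES <- c(adenine = "NH-h-p", guanine = "OHH-h-p",
                       cytosine = "HNO-h", thymine = "OHO-h",
                       uracil = "OHO-h_0")

#' Load the packaged 64-group roster
#'
#' Deterministic: 16 study-named codes, 5 nucleobase stand-ins, and filler
#' codes generated class-by-class until the roster holds exactly 64 groups
#' covering every class of the assay (D, A, DA, DD, AA, DDD, AAA, DDA, DAD).
#' Per-group planarity follows a fixed rule: groups without amino donors are
#' fully planar; for donors, planarity grows with the aromatic-system size
#' and shrinks with the number of amines (see [toy_geometry()] for how the
#' value maps onto geometry).
#'
#' @return Data frame with 64 rows: `code`, `class` (role labels), `label`
#'   (`"named"`, nucleobase name, or `"filler"`), `planarity`.
#' @examples
#' r <- load_roster()
#' nrow(r)                 # 64
#' "HH-hh-p" %in% r$code   # TRUE
#' @export
load_roster <- function() {
  codes <- c(.NAMED_CODES, unname(.NUCLEOBASE_CODES))
  labels <- c(rep("named", length(.NAMED_CODES)), names(.NUCLEOBASE_CODES))

  classes <- c("D", "A", "DA", "DD", "AA", "DDD", "AAA", "DDA", "DAD")
  skeletons <- list(`1` = c("h", "p", "h-p"),
                    `2` = c("h", "p", "hh", "hp", "hh-p"),
                    `3` = c("h", "hh", "hp", "hhh", "hh-p"))
  acceptor_letters <- function(cls) {
    slots <- strsplit(cls, "")[[1]]
    opts <- lapply(slots, function(r) if (r == "D") "H" else c("N", "O"))
    grid <- expand.grid(opts, stringsAsFactors = FALSE)
    apply(grid, 1, paste, collapse = "")
  }
  for (cls in classes) {
    for (sk in skeletons[[as.character(nchar(cls))]]) {
      for (letters in acceptor_letters(cls)) {
        if (length(codes) >= 64L) break
        code <- paste0(letters, "-", sk)
        if (!code %in% codes) {
          codes <- c(codes, code)
          labels <- c(labels, "filler")
        }
      }
    }
  }
  stopifnot(length(codes) == 64L)
  data.frame(code = codes,
             class = vapply(codes, function(cd) class_label(parse_code(cd)),
                            character(1), USE.NAMES = FALSE),
             label = labels,
             planarity = vapply(codes, .planarity_rule, numeric(1),
                                USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}
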