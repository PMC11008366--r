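# End-group data model: shorthand codes, donor/acceptor site patterns,
# class labels and canonical (Watson-Crick-like) complementarity.
#
# A site is a hydrogen-bond donor (polarized N-H) or acceptor (pyridinic =N- or
# keto =O lone pair). An end group presents an ordered row of 1-3 such sites on
# a planar aromatic skeleton of hexagonal (h) and/or pentagonal (p) rings.
# Shorthand codes read sites-then-skeleton: "OHO-h-p" is acceptor, donor,
# acceptor on a fused hexagon-pentagon skeleton.

#' Construct a site pattern
#'
#' A site pattern is the ordered sequence of hydrogen-bond donor (`"D"`) and
#' acceptor (`"A"`) sites an end group presents. Acceptors carry a flavor
#' (pyridinic nitrogen `"N"` or keto oxygen `"O"`); donors are N-H hydrogens
#' (flavor `"NH"`). Flavors may be `NA` when only the role level is known
#' (e.g. for the role-complement of a pattern).
#'
#' @param roles character vector of `"D"`/`"A"`, length 1-3.
#' @param flavors character vector of `"NH"`, `"N"`, `"O"` or `NA`, recycled.
#' @return An object of class `site_pattern`.
#' @examples
#' site_pattern(c("D", "A", "D"))
#' @export
site_pattern <- function(roles, flavors = NA_character_) {
  roles <- as.character(roles)
  if (length(roles) < 1L || length(roles) > 3L) {
    stop("site pattern must have 1-3 sites, got ", length(roles))
  }
  if (!all(roles %in% c("D", "A"))) {
    stop("site roles must be 'D' or 'A'")
  }
  flavors <- rep_len(as.character(flavors), length(roles))
  ok <- is.na(flavors) |
    (roles == "D" & flavors == "NH") |
    (roles == "A" & flavors %in% c("N", "O"))
  if (!all(ok)) {
    stop("site flavor inconsistent with role: donors are 'NH', acceptors 'N' or 'O'")
  }
  structure(list(roles = roles, flavors = flavors), class = "site_pattern")
}

#' @export
print.site_pattern <- function(x, ...) {
  fl <- ifelse(is.na(x$flavors), "?", x$flavors)
  cat("<site_pattern> ", class_label(x), "  [", paste(fl, collapse = ","), "]\n",
      sep = "")
  invisible(x)
}

#' @export
length.site_pattern <- function(x) length(x$roles)

#' Class label of a site pattern
#'
#' Concatenation of the per-site role initials, e.g. `"DAD"` for a
#' donor-acceptor-donor pattern.
#'
#' @param pattern a [site_pattern] or [end_group].
#' @return Single character string.
#' @export
class_label <- function(pattern) {
  pattern <- as_site_pattern(pattern)
  paste(pattern$roles, collapse = "")
}

#' Is a site pattern palindromic?
#'
#' A pattern is palindromic when it equals its own reversal at role and flavor
#' level; flipping such an end group in the binding plane leaves it unchanged.
#'
#' @param pattern a [site_pattern] or [end_group].
#' @return Logical scalar.
#' @export
is_palindromic <- function(pattern) {
  pattern <- as_site_pattern(pattern)
  identical(pattern$roles, rev(pattern$roles)) &&
    identical(pattern$flavors, rev(pattern$flavors))
}

#' Coerce to a site pattern
#'
#' Accepts a [site_pattern], an [end_group], a shorthand code, or a role
#' string such as `"DDA"` (letters D/A, flavors left unspecified for
#' acceptors, `"NH"` for donors).
#'
#' @param x object to coerce.
#' @return A [site_pattern].
#' @export
as_site_pattern <- function(x) {
  if (inherits(x, "site_pattern")) return(x)
  if (inherits(x, "end_group")) return(x$pattern)
  if (is.character(x) && length(x) == 1L) {
    if (grepl("^[DA]{1,3}$", x)) {
      roles <- strsplit(x, "")[[1]]
      return(site_pattern(roles, ifelse(roles == "D", "NH", NA_character_)))
    }
    return(parse_code(x)$pattern)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a site pattern")
}

# letter <-> site maps for the shorthand codec
.letter_role <- c(H = "D", N = "A", O = "A")
.letter_flavor <- c(H = "NH", N = "N", O = "O")
.flavor_letter <- c(NH = "H", N = "N", O = "O")

#' Parse a shorthand end-group code
#'
#' Codes name the hydrogen-bonding sites with capital letters (`H` = N-H
#' donor, `N` = pyridinic-N acceptor, `O` = keto-O acceptor), then the
#' aromatic skeleton as `h` (hexagon) / `p` (pentagon) letters optionally
#' hyphen-separated, then an optional `_<digits>` isomer-variant suffix.
#' `"OHO-h-p"` is an acceptor-donor-acceptor group on a fused
#' hexagon-pentagon skeleton.
#'
#' @param code shorthand string, e.g. `"HNH-hh"`.
#' @param planarity amino-group planarity in `[0, 1]` (1 = fully planar);
#'   a surrogate-model parameter attached to the group.
#' @param geometry_ref optional handle (path or object) to an annotated
#'   monomer geometry.
#' @return An object of class `end_group` with fields `code`, `pattern`,
#'   `skeleton`, `variant`, `planarity`, `geometry_ref`.
#' @examples
#' g <- parse_code("HNH-hh")
#' class_label(g)   # "DAD"
#' @export
parse_code <- function(code, planarity = 1, geometry_ref = NULL) {
  stopifnot(is.character(code), length(code) == 1L)
  m <- regmatches(code, regexec(
    "^([A-Za-z]+)-([a-z-]+?)(_[0-9]+)?$", code, perl = TRUE))[[1]]
  if (length(m) == 0L) {
    stop("malformed end-group code '", code,
         "': expected SITES-SKELETON[_variant]")
  }
  sites <- m[2]
  skeleton <- m[3]
  variant <- if (is.na(m[4]) || m[4] == "") NA_character_ else m[4]
  site_letters <- strsplit(sites, "")[[1]]
  bad <- setdiff(site_letters, c("H", "N", "O"))
  if (length(bad) > 0L) {
    stop("malformed end-group code '", code, "': unknown site letter '",
         bad[1], "' (expected H, N or O)")
  }
  if (length(site_letters) > 3L) {
    stop("end-group code '", code, "' has ", length(site_letters),
         " site letters; at most 3 hydrogen-bond sites are supported")
  }
  if (!grepl("^[hp]+(-[hp]+)*$", skeleton)) {
    badchr <- regmatches(skeleton, regexpr("[^hp-]", skeleton))
    stop("malformed end-group code '", code, "': skeleton token '",
         skeleton, "'",
         if (length(badchr) > 0) paste0(" contains '", badchr, "'") else "",
         " (expected h/p letters, optionally hyphen-separated)")
  }
  if (!is.na(planarity) && (planarity < 0 || planarity > 1)) {
    stop("planarity must lie in [0, 1]")
  }
  pattern <- site_pattern(unname(.letter_role[site_letters]),
                          unname(.letter_flavor[site_letters]))
  structure(list(code = code,
                 pattern = pattern,
                 skeleton = skeleton,
                 variant = variant,
                 planarity = planarity,
                 geometry_ref = geometry_ref),
            class = "end_group")
}

#' Format an end group back to its shorthand code
#'
#' Exact inverse of [parse_code()], preserving internal skeleton hyphens and
#' the variant suffix.
#'
#' @param group an [end_group].
#' @return Shorthand code string.
#' @export
format_code <- function(group) {
  stopifnot(inherits(group, "end_group"))
  letters <- unname(.flavor_letter[group$pattern$flavors])
  if (anyNA(letters)) {
    stop("end group has flavor-unspecified sites; cannot format a code")
  }
  paste0(paste(letters, collapse = ""), "-", group$skeleton,
         if (is.na(group$variant)) "" else group$variant)
}

#' @export
print.end_group <- function(x, ...) {
  cat("<end_group> ", x$code, "  class ", class_label(x$pattern),
      "  planarity ", format(x$planarity), "\n", sep = "")
  invisible(x)
}

#' Role-level complement of a site pattern
#'
#' Swaps donor and acceptor at each site. Flavors of the result are
#' unspecified for acceptors (either pyridinic N or keto O would do) and
#' `"NH"` for donors. Applying the complement twice returns the original
#' role pattern.
#'
#' @param pattern a [site_pattern], [end_group], code, or role string.
#' @return A [site_pattern] with swapped roles.
#' @examples
#' class_label(complement("DDA"))   # "AAD"
#' @export
complement <- function(pattern) {
  pattern <- as_site_pattern(pattern)
  roles <- ifelse(pattern$roles == "D", "A", "D")
  site_pattern(roles, ifelse(roles == "D", "NH", NA_character_))
}

#' Canonical-pair test
#'
#' Two patterns form a canonical pair (by analogy with Watson-Crick base
#' pairs) when the role pattern of one equals the role complement of the
#' other, read in either direction. This reproduces the canonical classes
#' D...A, DA...AD, DD...AA, DDD...AAA, DDA...AAD and DAD...ADA, and rejects
#' noncanonical combinations such as DD...AAA.
#'
#' @param x,y patterns (anything [as_site_pattern()] accepts).
#' @return Logical scalar; symmetric in its arguments.
#' @examples
#' is_canonical_pair("DDA", "AAD")  # TRUE
#' is_canonical_pair("DD", "AAA")   # FALSE
#' @export
is_canonical_pair <- function(x, y) {
  rx <- as_site_pattern(x)$roles
  ry <- as_site_pattern(y)$roles
  if (length(rx) != length(ry)) return(FALSE)
  cx <- ifelse(rx == "D", "A", "D")
  identical(ry, cx) || identical(ry, rev(cx))
}

#' Does a pattern mix donor and acceptor roles?
#'
#' Pure patterns contain a single role (e.g. DD, AAA); mixed patterns contain
#' both (e.g. DAD, DDA). Mixed groups can form hydrogen-bonded homo pairs,
#' which limits their selectivity.
#'
#' @param pattern anything [as_site_pattern()] accepts.
#' @return Logical scalar.
#' @export
is_mixed <- function(pattern) {
  roles <- as_site_pattern(pattern)$roles
  ("D" %in% roles) && ("A" %in% roles)
}

#' Read an end-group roster file
#'
#' Plain-text (one code per line, `#` comments allowed) or CSV with a `code`
#' column and optional `planarity` and `geometry` columns.
#'
#' @param path file path.
#' @return A data frame with columns `code`, `planarity`, `geometry`.
#' @export
read_roster <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"code" %in% names(df)) stop("roster CSV lacks a 'code' column")
    if (!"planarity" %in% names(df)) df$planarity <- 1
    if (!"geometry" %in% names(df)) df$geometry <- NA_character_
  } else {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    df <- data.frame(code = lines, planarity = 1, geometry = NA_character_,
                     stringsAsFactors = FALSE)
  }
  for (cd in df$code) parse_code(cd)  # validate
  df[, c("code", "planarity", "geometry")]
}
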