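# Annotated monomer geometries, rigid construction of starting dimer
# geometries with a fixed hydrogen-bond gap, and amine pyramidalization.
#
# A monomer geometry carries plain XYZ-style coordinates plus a site
# annotation table: for each hydrogen-bonding site, its role, the heavy atom,
# the donor hydrogen (donors only) and the in-plane hydrogen-bond direction.
# Amino nitrogens are listed so pyramidalization can be evaluated.

#' Construct an annotated monomer geometry
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param sites data frame with one row per hydrogen-bonding site: columns
#'   `site` (1-based site index along the row), `role` (`"D"`/`"A"`),
#'   `flavor`, `heavy` (atom index of the site N/O), `hyd` (atom index of the
#'   donor H, `NA` for acceptors), `dir_x`, `dir_y`, `dir_z` (unit
#'   hydrogen-bond direction).
#' @param amine_n integer vector of amino-nitrogen atom indices (may be
#'   empty).
#' @return Object of class `monomer_geometry`.
#' @export
monomer_geometry <- function(symbols, coords, sites, amine_n = integer(0)) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) == length(symbols))
  need <- c("site", "role", "heavy", "dir_x", "dir_y", "dir_z")
  if (!all(need %in% names(sites))) {
    stop("site annotation lacks column(s): ",
         paste(setdiff(need, names(sites)), collapse = ", "))
  }
  if (!"hyd" %in% names(sites)) sites$hyd <- NA_integer_
  if (!"flavor" %in% names(sites)) sites$flavor <- NA_character_
  structure(list(symbols = symbols, coords = coords,
                 sites = sites[order(sites$site), , drop = FALSE],
                 amine_n = as.integer(amine_n)),
            class = "monomer_geometry")
}

#' @export
print.monomer_geometry <- function(x, ...) {
  cat("<monomer_geometry> ", length(x$symbols), " atoms, ",
      nrow(x$sites), " sites (", paste(x$sites$role, collapse = ""), ")\n",
      sep = "")
  invisible(x)
}

# Template layout constants shared by toy_geometry() and the exact-placement
# arithmetic in build_pose_geometry(): sites on a regular pitch along x, all
# hydrogen-bond directions +y.
.TOY_PITCH <- 3.0       # Angstrom between adjacent sites
.TOY_Y_HEAVY <- 0.6     # y of the site heavy atom
.TOY_NH <- 1.0          # N-H bond length

#' Build a toy planar monomer geometry for an end group
#'
#' Generates a schematic planar template: sites on a regular 3-Angstrom
#' pitch along x, hydrogen-bond directions along +y, each site backed by a
#' ring carbon. Donor sites are amino-like N-H with a second hydrogen whose
#' out-of-plane angle encodes the group's planarity parameter:
#' `(1 - planarity) * 54.7356` degrees, i.e. fully planar amines at
#' planarity 1 and ideally tetrahedral ones at planarity 0. The template
#' stands in for an optimized quantum-chemistry structure at desk scale; it
#' is not a chemically meaningful molecule.
#'
#' @param group an [end_group] (or code string; then planarity defaults to 1).
#' @return A [monomer_geometry].
#' @examples
#' g <- toy_geometry(parse_code("HH-hh", planarity = 1))
#' pyramidalization(g, g$amine_n)  # 0
#' @export
toy_geometry <- function(group) {
  if (is.character(group)) group <- parse_code(group)
  stopifnot(inherits(group, "end_group"))
  pat <- group$pattern
  theta <- (1 - group$planarity) * 54.7356 * pi / 180
  symbols <- character(0)
  coords <- NULL
  sites <- NULL
  amine_n <- integer(0)
  add <- function(sym, xyz) {
    symbols <<- c(symbols, sym)
    coords <<- rbind(coords, xyz)
    length(symbols)
  }
  for (k in seq_along(pat$roles)) {
    x0 <- (k - 1) * .TOY_PITCH
    role <- pat$roles[k]
    flavor <- pat$flavors[k]
    if (role == "D") {
      nN <- add("N", c(x0, .TOY_Y_HEAVY, 0))
      nH1 <- add("H", c(x0, .TOY_Y_HEAVY + .TOY_NH, 0))
      # second amino H: in-plane direction 108 deg from the bonding H,
      # lifted out of plane by theta
      u <- c(0.95, -0.31, 0)
      u <- u / sqrt(sum(u^2))
      h2 <- c(x0, .TOY_Y_HEAVY, 0) +
        .TOY_NH * (cos(theta) * u + sin(theta) * c(0, 0, 1))
      add("H", h2)
      cR <- add("C", c(x0 - 0.55, .TOY_Y_HEAVY - 1.25, 0))
      amine_n <- c(amine_n, nN)
      row <- data.frame(site = k, role = "D", flavor = flavor, heavy = nN,
                        hyd = nH1, dir_x = 0, dir_y = 1, dir_z = 0)
    } else {
      sym <- if (identical(flavor, "O")) "O" else "N"
      nA <- add(sym, c(x0, .TOY_Y_HEAVY, 0))
      cR <- add("C", c(x0 - 0.55, .TOY_Y_HEAVY - 1.25, 0))
      row <- data.frame(site = k, role = "A", flavor = flavor, heavy = nA,
                        hyd = NA_integer_, dir_x = 0, dir_y = 1, dir_z = 0)
    }
    sites <- rbind(sites, row)
  }
  rownames(coords) <- NULL
  monomer_geometry(symbols, coords, sites, amine_n)
}

.rot_z180 <- function(xyz) cbind(-xyz[, 1], -xyz[, 2], xyz[, 3])
.rot_x180 <- function(xyz) cbind(xyz[, 1], -xyz[, 2], -xyz[, 3])

#' Realize an alignment as a rigid 3D starting dimer
#'
#' Places the second monomer facing the first: for `flip = FALSE` it is
#' rotated 180 degrees in the binding plane (site order reversed along the
#' row), for `flip = TRUE` it is turned over through the plane. The rigid
#' translation is fixed by the first donor-acceptor contact so that the
#' donor-H to acceptor distance equals `gap` along the hydrogen-bond
#' direction; on regularly pitched templates every donor-acceptor contact is
#' then exact. Registers whose contacts are all donor-donor or
#' acceptor-acceptor are placed at `gap` between the facing H tips or
#' acceptor atoms. Poses bringing any two atoms of different monomers closer
#' than `collision_tol` are flagged (`collision = TRUE`), never dropped.
#'
#' @param x_geom,y_geom annotated [monomer_geometry] objects, planar within
#'   `planarity_tol` (heavy atoms).
#' @param a an alignment from [enumerate_alignments()] for the two site
#'   patterns.
#' @param gap target H...acceptor distance in Angstrom (default 2.0).
#' @param collision_tol minimum allowed intermonomer distance (default 1.0).
#' @param planarity_tol maximum heavy-atom out-of-plane deviation accepted on
#'   input (default 0.1).
#' @return Object of class `pair_pose`: combined `symbols`/`coords`, atom
#'   count `n_x` of the first monomer, the `alignment`, `gap`, a
#'   `contacts` data frame with achieved distances, and a `collision` flag.
#' @export
build_pose_geometry <- function(x_geom, y_geom, a, gap = 2.0,
                                collision_tol = 1.0, planarity_tol = 0.1) {
  stopifnot(inherits(x_geom, "monomer_geometry"),
            inherits(y_geom, "monomer_geometry"),
            inherits(a, "alignment"))
  for (g in list(x_geom, y_geom)) {
    hz <- g$coords[g$symbols != "H", 3]
    if (max(abs(hz - mean(hz))) > planarity_tol) {
      stop("monomer geometry is not planar within tolerance ", planarity_tol)
    }
  }
  if (nrow(x_geom$sites) < a$m || nrow(y_geom$sites) < a$n) {
    stop("site annotation missing: geometry annotates fewer sites than the ",
         "alignment requires")
  }
  ycoords <- if (a$flip) .rot_x180(y_geom$coords) else .rot_z180(y_geom$coords)
  ydir <- as.matrix(y_geom$sites[, c("dir_x", "dir_y", "dir_z")])
  ydir <- if (a$flip) .rot_x180(ydir) else .rot_z180(ydir)

  sx <- x_geom$sites
  sy <- y_geom$sites
  contacts <- a$contacts
  types <- character(nrow(contacts))
  for (k in seq_len(nrow(contacts))) {
    types[k] <- paste0(sx$role[contacts[k, 1]], sy$role[contacts[k, 2]])
  }
  # translation from the first hetero (D-A or A-D) contact if any
  kref <- match(TRUE, types %in% c("DA", "AD"))
  if (is.na(kref)) kref <- 1L
  i <- contacts[kref, 1]; j <- contacts[kref, 2]
  dirx <- as.numeric(sx[i, c("dir_x", "dir_y", "dir_z")])
  if (types[kref] == "DA") {
    hx <- x_geom$coords[sx$hyd[i], ]
    t <- hx + gap * dirx - ycoords[sy$heavy[j], ]
  } else if (types[kref] == "AD") {
    hy <- ycoords[sy$hyd[j], ]
    t <- x_geom$coords[sx$heavy[i], ] - hy - gap * ydir[j, ]
  } else if (types[kref] == "DD") {
    hx <- x_geom$coords[sx$hyd[i], ]
    hy <- ycoords[sy$hyd[j], ]
    t <- hx + gap * dirx - hy
  } else {
    t <- x_geom$coords[sx$heavy[i], ] + gap * dirx - ycoords[sy$heavy[j], ]
  }
  ycoords <- sweep(ycoords, 2, t, "+")

  dists <- numeric(nrow(contacts))
  for (k in seq_len(nrow(contacts))) {
    i <- contacts[k, 1]; j <- contacts[k, 2]
    p1 <- switch(types[k],
                 DA = x_geom$coords[sx$hyd[i], ],
                 AD = x_geom$coords[sx$heavy[i], ],
                 DD = x_geom$coords[sx$hyd[i], ],
                 AA = x_geom$coords[sx$heavy[i], ])
    p2 <- switch(types[k],
                 DA = ycoords[sy$heavy[j], ],
                 AD = ycoords[sy$hyd[j], ],
                 DD = ycoords[sy$hyd[j], ],
                 AA = ycoords[sy$heavy[j], ])
    dists[k] <- sqrt(sum((p1 - p2)^2))
  }
  cross <- as.matrix(stats::dist(rbind(x_geom$coords, ycoords)))
  nx <- nrow(x_geom$coords)
  inter <- cross[seq_len(nx), nx + seq_len(nrow(ycoords)), drop = FALSE]
  collision <- any(inter < collision_tol - 1e-9)

  structure(list(alignment = a, gap = gap,
                 symbols = c(x_geom$symbols, y_geom$symbols),
                 coords = rbind(x_geom$coords, ycoords),
                 n_x = nx,
                 amine_n = c(x_geom$amine_n, y_geom$amine_n + nx),
                 contacts = data.frame(i = contacts[, 1], j = contacts[, 2],
                                       type = types, distance = dists),
                 collision = collision),
            class = "pair_pose")
}

#' @export
print.pair_pose <- function(x, ...) {
  cat("<pair_pose> ", pose_id(x$alignment), "  ",
      nrow(x$contacts), " contact(s), gap ", x$gap,
      if (x$collision) "  [COLLISION]" else "", "\n", sep = "")
  invisible(x)
}

#' Amine pyramidalization angle
#'
#' For each listed nitrogen the three bonded substituents are resolved from
#' interatomic distances (cutoff 1.7 Angstrom; exactly three neighbors
#' required). With substituents ordered heavy atoms first (ring atom, then
#' hydrogens by index), the pyramidalization is the out-of-plane angle of the
#' N-to-third-substituent bond against the plane of (first substituent, N,
#' second substituent). A planar amine gives 0 degrees, an ideal tetrahedral
#' one 54.7356 degrees. The result is the mean over the listed nitrogens.
#'
#' @param geometry a [monomer_geometry], `pair_pose`, or any list with
#'   `symbols` and `coords`.
#' @param n_ids integer atom indices of the amino nitrogens.
#' @return Mean pyramidalization angle in degrees.
#' @examples
#' g <- toy_geometry(parse_code("H-h", planarity = 0))
#' pyramidalization(g, g$amine_n)  # 54.7356
#' @export
pyramidalization <- function(geometry, n_ids) {
  coords <- geometry$coords
  symbols <- geometry$symbols
  if (length(n_ids) == 0L) stop("no nitrogen atoms given")
  angles <- vapply(n_ids, function(nid) {
    d <- sqrt(colSums((t(coords) - coords[nid, ])^2))
    nb <- setdiff(which(d < 1.7 & d > 1e-8), nid)
    if (length(nb) != 3L) {
      stop("nitrogen atom ", nid, " has ", length(nb),
           " bonded neighbors; exactly 3 required")
    }
    heavy <- nb[symbols[nb] != "H"]
    hyd <- nb[symbols[nb] == "H"]
    nb <- c(sort(heavy), sort(hyd))
    b1 <- coords[nb[1], ] - coords[nid, ]
    b2 <- coords[nb[2], ] - coords[nid, ]
    b3 <- coords[nb[3], ] - coords[nid, ]
    nrm <- c(b1[2] * b2[3] - b1[3] * b2[2],
             b1[3] * b2[1] - b1[1] * b2[3],
             b1[1] * b2[2] - b1[2] * b2[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    asin(min(1, abs(sum(b3 * nrm)) / sqrt(sum(b3^2)))) * 180 / pi
  }, numeric(1))
  mean(angles)
}
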