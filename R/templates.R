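# Idealized planar nucleobase templates.
#
# Heavy-atom ring geometry follows mean small-molecule crystallographic bond
# lengths and angles for the DNA bases; hydrogens are placed in-plane on
# exterior bisectors (N-H 1.01 A, aromatic C-H 1.09 A, amino H-N-H split
# symmetrically about the C-N bond). Bases lie in the z = 0 plane; the C1'
# atom sits on the exterior bisector of the glycosidic nitrogen and O4' is
# placed off-plane so the glycosidic torsion chi takes a requested value.

RESIDUE_TYPES <- c("DA", "DG", "DC", "5mC", "DI", "2AP")

# which residues are purines / cytosine-like
is_purine_type <- function(type) type %in% c("DA", "DG", "DI", "2AP")
is_cytosine_type <- function(type) type %in% c("DC", "5mC")

ring_atom_names <- function(type) {
  if (is_purine_type(type)) c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

exocyclic_heavy_names <- function(type) {
  switch(type,
    DG = c("O6", "N2"),
    DA = "N6",
    DI = "O6",
    `2AP` = "N2",
    DC = c("O2", "N4"),
    `5mC` = c("O2", "N4", "C5M")
  )
}

glycosidic_atoms <- function(type) {
  if (is_purine_type(type)) c(n = "N9", ref = "C4") else c(n = "N1", ref = "C2")
}

# donor atom -> its hydrogens, per residue type
donor_table <- function(type) {
  switch(type,
    DG = list(N1 = "H1", N2 = c("H21", "H22")),
    DI = list(N1 = "H1"),
    DA = list(N6 = c("H61", "H62")),
    `2AP` = list(N2 = c("H21", "H22")),
    DC = list(N4 = c("H41", "H42")),
    `5mC` = list(N4 = c("H41", "H42"))
  )
}

acceptor_table <- function(type) {
  switch(type,
    DG = c("N3", "O6", "N7"),
    DI = c("N3", "O6", "N7"),
    DA = c("N1", "N3", "N7"),
    `2AP` = c("N1", "N3", "N7"),
    DC = c("O2", "N3"),
    `5mC` = c("O2", "N3")
  )
}

backbone_acceptors <- function() c("OP1", "OP2", "O5'", "O3'")

# ---- 2D ring construction -------------------------------------------------

# Walk a ring given consecutive bond lengths and interior angles.
# atoms[1] at origin, atoms[2] on +x; counter-clockwise walk.
ring_walk <- function(lengths, interior) {
  n <- length(lengths)
  pos <- matrix(0, n, 2)
  pos[2, ] <- c(lengths[1], 0)
  heading <- 0
  for (i in 3:n) {
    heading <- heading + (180 - interior[i - 1])
    pos[i, ] <- pos[i - 1, ] + lengths[i - 1] *
      c(cos(deg2rad(heading)), sin(deg2rad(heading)))
  }
  pos
}

# exterior-bisector direction at ring atom i (unit 2D vector away from centroid)
exo_dir <- function(ring, i, nb1, nb2) {
  a <- ring[i, ]
  d <- -(unitv2(ring[nb1, ] - a) + unitv2(ring[nb2, ] - a))
  unitv2(d)
}

unitv2 <- function(v) v / sqrt(sum(v^2))

# pyrimidine six-ring: N1 C2 N3 C4 C5 C6 (cytosine mean geometry)
pyrimidine_ring <- function() {
  lengths <- c(1.397, 1.353, 1.335, 1.425, 1.339, 1.367) # N1C2 C2N3 N3C4 C4C5 C5C6 C6N1
  interior <- c(120.3, 119.2, 119.9, 121.9, 117.4, 121.0) # at N1 C2 N3 C4 C5 C6
  ring <- ring_walk(lengths, interior)
  rownames(ring) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ring
}

# purine ring system: six-ring walk then five-ring closure
purine_ring <- function(type) {
  if (type %in% c("DG", "DI")) {
    lengths <- c(1.373, 1.323, 1.350, 1.379, 1.419, 1.391)
    interior <- c(125.1, 123.9, 111.9, 128.6, 118.8, 111.5)
    five <- list(C4C5N7 = 110.8, C5N7C8 = 104.3, N7C8N9 = 113.1,
                 lC5N7 = 1.388, lN7C8 = 1.305, lC8N9 = 1.374)
  } else { # DA, 2AP
    lengths <- c(1.339, 1.331, 1.344, 1.383, 1.406, 1.351)
    interior <- c(118.6, 129.3, 110.6, 126.8, 117.0, 117.7)
    five <- list(C4C5N7 = 110.7, C5N7C8 = 103.9, N7C8N9 = 113.8,
                 lC5N7 = 1.388, lN7C8 = 1.311, lC8N9 = 1.373)
  }
  six <- ring_walk(lengths, interior)
  rownames(six) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ctr <- colMeans(six)
  rot2 <- function(v, ang) {
    th <- deg2rad(ang)
    c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
  }
  place_off <- function(from, towards, bond, ang) {
    u <- unitv2(towards - from)
    list(p1 = from + bond * rot2(u, ang), p2 = from + bond * rot2(u, -ang))
  }
  # N7 off C5, exterior to the six-ring
  cand <- place_off(six["C5", ], six["C4", ], five$lC5N7, five$C4C5N7)
  N7 <- if (sum((cand$p1 - ctr)^2) > sum((cand$p2 - ctr)^2)) cand$p1 else cand$p2
  # C8 off N7 with interior angle C5-N7-C8; pick branch closing toward C4
  cand <- place_off(N7, six["C5", ], five$lN7C8, five$C5N7C8)
  pickC8 <- function(C8) {
    cand9 <- place_off(C8, N7, five$lC8N9, five$N7C8N9)
    d1 <- abs(sqrt(sum((cand9$p1 - six["C4", ])^2)) - 1.374)
    d2 <- abs(sqrt(sum((cand9$p2 - six["C4", ])^2)) - 1.374)
    if (d1 < d2) list(N9 = cand9$p1, err = d1) else list(N9 = cand9$p2, err = d2)
  }
  r1 <- pickC8(cand$p1); r2 <- pickC8(cand$p2)
  if (r1$err < r2$err) { C8 <- cand$p1; N9 <- r1$N9 } else { C8 <- cand$p2; N9 <- r2$N9 }
  ring <- rbind(six, N7 = N7, C8 = C8, N9 = N9)
  ring
}

# ---- full base templates --------------------------------------------------

#' Idealized planar base template
#'
#' Builds a planar idealized nucleobase (heavy atoms plus polar and aromatic
#' hydrogens) in the z = 0 plane, with the glycosidic \code{C1'} attached on
#' the exterior bisector of the glycosidic nitrogen and \code{O4'} placed so
#' that the glycosidic torsion chi (O4'-C1'-N9-C4 for purines,
#' O4'-C1'-N1-C2 for pyrimidines) equals \code{chi}.
#'
#' @param type residue type, one of \code{"DA"}, \code{"DG"}, \code{"DC"},
#'   \code{"5mC"}, \code{"DI"}, \code{"2AP"}.
#' @param chi glycosidic torsion in degrees; defaults to a mid-range anti
#'   value (240 for purines, 240 for pyrimidines).
#' @return data.frame with columns \code{name}, \code{element}, \code{x},
#'   \code{y}, \code{z}.
#' @examples
#' tc <- base_template("DC")
#' # reference interproton distance used for NOE calibration:
#' h5 <- unlist(tc[tc$name == "H5", c("x", "y", "z")])
#' h6 <- unlist(tc[tc$name == "H6", c("x", "y", "z")])
#' sqrt(sum((h5 - h6)^2))
#' @export
base_template <- function(type, chi = NULL) {
  type <- match.arg(type, RESIDUE_TYPES)
  if (is.null(chi)) chi <- 240
  NH <- 1.01; CH <- 1.09
  if (is_purine_type(type)) {
    ring <- purine_ring(type)
    idx <- function(nm) which(rownames(ring) == nm)
    nb <- list(N1 = c("C2", "C6"), C2 = c("N1", "N3"), N3 = c("C2", "C4"),
               C4 = c("N3", "C5"), C5 = c("C4", "C6"), C6 = c("C5", "N1"),
               N7 = c("C5", "C8"), C8 = c("N7", "N9"), N9 = c("C8", "C4"))
    # C4 and C5 are shared between rings; their "neighbours" for bisectors
    # are not needed (no exocyclic substituent there)
    exo <- list()
    add_exo <- function(at, attach, bond) {
      d <- exo_dir(ring, idx(attach), idx(nb[[attach]][1]), idx(nb[[attach]][2]))
      exo[[at]] <<- ring[attach, ] + bond * d
    }
    hyd <- list()
    add_h <- function(at, attach, bond) {
      d <- exo_dir(ring, idx(attach), idx(nb[[attach]][1]), idx(nb[[attach]][2]))
      hyd[[at]] <<- ring[attach, ] + bond * d
    }
    add_amino_h <- function(h1, h2, npos, cpos) {
      u <- unitv2(npos - cpos)
      rot2 <- function(v, ang) {
        th <- deg2rad(ang)
        c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
      }
      hyd[[h1]] <<- npos + NH * rot2(u, 60)
      hyd[[h2]] <<- npos + NH * rot2(u, -60)
    }
    if (type %in% c("DG", "DI")) {
      add_exo("O6", "C6", 1.237)
      add_h("H1", "N1", NH)
      add_h("H8", "C8", CH)
      if (type == "DG") {
        add_exo("N2", "C2", 1.341)
        add_amino_h("H21", "H22", exo$N2, ring["C2", ])
      } else {
        add_h("H2", "C2", CH)
      }
    } else { # DA / 2AP
      add_h("H8", "C8", CH)
      if (type == "DA") {
        add_exo("N6", "C6", 1.335)
        add_amino_h("H61", "H62", exo$N6, ring["C6", ])
        add_h("H2", "C2", CH)
      } else { # 2AP
        add_exo("N2", "C2", 1.341)
        add_amino_h("H21", "H22", exo$N2, ring["C2", ])
        add_h("H6", "C6", CH)
      }
    }
    gl <- "N9"; glref <- "C4"
    gl_nb <- nb$N9
  } else {
    ring <- pyrimidine_ring()
    idx <- function(nm) which(rownames(ring) == nm)
    nb <- list(N1 = c("C2", "C6"), C2 = c("N1", "N3"), N3 = c("C2", "C4"),
               C4 = c("N3", "C5"), C5 = c("C4", "C6"), C6 = c("C5", "N1"))
    exo <- list(); hyd <- list()
    d_at <- function(attach) exo_dir(ring, idx(attach), idx(nb[[attach]][1]), idx(nb[[attach]][2]))
    exo$O2 <- ring["C2", ] + 1.240 * d_at("C2")
    exo$N4 <- ring["C4", ] + 1.335 * d_at("C4")
    rot2 <- function(v, ang) {
      th <- deg2rad(ang)
      c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
    }
    u <- unitv2(exo$N4 - ring["C4", ])
    hyd$H41 <- exo$N4 + NH * rot2(u, 60)
    hyd$H42 <- exo$N4 + NH * rot2(u, -60)
    hyd$H6 <- ring["C6", ] + CH * d_at("C6")
    if (type == "DC") {
      hyd$H5 <- ring["C5", ] + CH * d_at("C5")
    } else { # 5mC
      exo$C5M <- ring["C5", ] + 1.500 * d_at("C5")
    }
    gl <- "N1"; glref <- "C2"
    gl_nb <- nb$N1
  }
  # glycosidic C1' on the exterior bisector of the glycosidic nitrogen
  c1p2 <- ring[gl, ] + 1.47 * exo_dir(ring, idx(gl), idx(gl_nb[1]), idx(gl_nb[2]))

  to3 <- function(p2) c(p2[1], p2[2], 0)
  nm <- c(rownames(ring), names(exo), names(hyd), "C1'")
  xyz <- rbind(cbind(ring, 0),
               if (length(exo)) cbind(do.call(rbind, exo), 0),
               if (length(hyd)) cbind(do.call(rbind, hyd), 0),
               matrix(c(c1p2, 0), 1, 3))
  rownames(xyz) <- nm
  # O4' via chi: torsion O4'-C1'-N(glyc)-C(ref)
  # place_atom's torsion sign convention is mirrored w.r.t. dihedral4
  o4p <- place_atom(a = xyz[glref, ], b = xyz[gl, ], c = xyz["C1'", ],
                    bond = 1.42, angle = 108, dih = -chi)
  xyz <- rbind(xyz, `O4'` = o4p)
  df <- data.frame(
    name = rownames(xyz),
    element = toupper(substr(rownames(xyz), 1, 1)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE, row.names = NULL
  )
  df$element[df$name == "C5M"] <- "C"
  df
}

#' Cytosine H5-H6 distance of the idealized template
#'
#' The fixed intra-cytosine H5-H6 interproton separation of the
#' standard-geometry template, used as the internal NOE calibration
#' reference distance.
#'
#' @return distance in Angstrom
#' @export
cytosine_reference_distance <- function() {
  tc <- base_template("DC")
  h5 <- unlist(tc[tc$name == "H5", c("x", "y", "z")])
  h6 <- unlist(tc[tc$name == "H6", c("x", "y", "z")])
  vnorm(h5 - h6)
}
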