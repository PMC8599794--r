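# Idealized tetramolecular model builder.
#
# The construct is two parallel-stranded homoduplexes (I and II, strands a
# and b each) whose cytosine tracts intercalate into a tetramolecular
# i-motif. Every base pair is assembled C2-symmetrically from the planar
# base templates; the pair planes are stacked along z with a fixed rise and
# twisted by a fixed angle per stack step, and duplex II is rotated 90 deg
# about the stack axis relative to duplex I (the two duplexes of an i-motif
# are close to orthogonal in projection).

# donor/acceptor edge and heavy-atom target distance per pairing geometry
pair_edge <- function(type, geometry) {
  pur <- is_purine_type(type)
  switch(geometry,
    SE = {
      if (!type %in% c("DG", "2AP"))
        stop("SE (sugar-edge N2H-N3) pairing requires an N2 amino group; ",
             type, " has none")
      list(donor = "N2", acceptor = "N3", target = 2.9)
    },
    HE = {
      if (type != "DA")
        stop("HE (Hoogsteen-edge N6H-N7) pairing requires adenine; got ", type)
      list(donor = "N6", acceptor = "N7", target = 2.9)
    },
    WCE = {
      if (type %in% c("DG", "DI")) list(donor = "N1", acceptor = "O6", target = 2.9)
      else if (type == "DA") list(donor = "N6", acceptor = "N1", target = 2.9)
      else stop("WCE pairing is defined for G/I (N1H-O6) and A (N6H-N1); got ", type)
    },
    CHplusC = {
      if (!is_cytosine_type(type))
        stop("CH+.C pairing requires cytosine or 5-methylcytosine; got ", type)
      list(donor = "N3", acceptor = "N3", target = 2.8)
    },
    none = {
      # place the two bases edge-to-edge but too far apart to hydrogen-bond
      if (pur) list(donor = "N1", acceptor = "N1", target = 4.3)
      else list(donor = "N3", acceptor = "N3", target = 4.3)
    },
    stop("unknown pairing geometry: ", geometry)
  )
}

# C2-symmetric homo base pair from a planar template.
# Strand b is the in-plane point reflection of strand a through
# p = (D + A + target * w) / 2, where D/A are the donor/acceptor positions
# and w is the donor's N-H direction (outward edge bisector when the donor
# carries no explicit hydrogen). This puts the partner's acceptor exactly
# `target` Angstrom from the donor along the N-H bond, so both symmetric
# hydrogen bonds are linear with the requested heavy-atom separation.
build_pair <- function(type, geometry, chi) {
  tmpl <- base_template(type, chi = chi)
  edge <- pair_edge(type, geometry)
  ring <- ring_atom_names(type)
  xy <- as.matrix(tmpl[, c("x", "y")])
  rownames(xy) <- tmpl$name
  ctr <- colMeans(xy[ring, , drop = FALSE])
  m <- (xy[edge$donor, ] + xy[edge$acceptor, ]) / 2
  u <- unitv2(m - ctr)
  dpos <- xy[edge$donor, ]
  hs <- intersect(unlist(donor_table(type)[edge$donor]), rownames(xy))
  w <- if (length(hs)) {
    dirs <- lapply(hs, function(h) unitv2(xy[h, ] - dpos))
    dirs[[which.max(vapply(dirs, function(d) sum(d * u), numeric(1)))]]
  } else {
    unitv2(dpos - ctr)
  }
  p <- (dpos + xy[edge$acceptor, ] + edge$target * w) / 2
  b <- tmpl
  b$x <- 2 * p[1] - tmpl$x
  b$y <- 2 * p[2] - tmpl$y
  # recentre the pair on the centroid of both bases' ring atoms, so that
  # consecutively stacked pairs of different types share the stack axis
  ra <- as.matrix(tmpl[tmpl$name %in% ring, c("x", "y")])
  rb <- as.matrix(b[b$name %in% ring, c("x", "y")])
  cen <- colMeans(rbind(ra, rb))
  tmpl$x <- tmpl$x - cen[1]; tmpl$y <- tmpl$y - cen[2]
  b$x <- b$x - cen[1]; b$y <- b$y - cen[2]
  list(a = tmpl, b = b, geometry = geometry)
}

#' Topology specification for the synthetic builder
#'
#' Describes a tetramolecular construct: a single cytosine/5-methylcytosine
#' tract at one terminus (the i-motif clip) attached to a purine block that
#' forms two parallel homoduplexes. The intercalation end class (3'E or
#' 5'E) determines, for a given sequence, whether the junction is extended
#' or compact: the topology is extended exactly when the tract cytosine
#' adjacent to the purine block occupies the outermost position of the
#' intercalated stack.
#'
#' @param sequence residue string 5'->3', e.g. \code{"CCCGAGA"} or a
#'   character vector of tokens over \{C, mC, G, A, I, aR\}.
#' @param end_class \code{"3'E"} or \code{"5'E"}: whether the outermost
#'   CH+.C pair of the stack is formed by the tract cytosines nearest the
#'   3' or the 5' terminus.
#' @param compactness \code{"extended"} or \code{"compact"}; if omitted the
#'   value implied by \code{sequence} and \code{end_class} is used. An
#'   explicitly requested value that is not geometrically constructible for
#'   the sequence raises an error.
#' @param purine_geometries optional named vector/list of pairing
#'   geometries (\code{"SE"}, \code{"HE"}, \code{"WCE"}, \code{"none"}) for
#'   purine positions, named by residue number. Defaults: the GA
#'   dinucleotide step closest to the tract gets SE (G) / HE (A); all other
#'   purines get WCE.
#' @param chi optional named vector of glycosidic torsions (degrees) per
#'   residue number; default 240 (anti) everywhere.
#' @return object of class \code{imclip_topology_spec}
#' @examples
#' topology_spec("CCCGAGA", "3'E")
#' topology_spec("AGAGCCC", "3'E", chi = c("4" = 60))  # syn G4
#' @export
topology_spec <- function(sequence, end_class = c("3'E", "5'E"),
                          compactness = NULL, purine_geometries = NULL,
                          chi = NULL) {
  end_class <- match.arg(end_class)
  types <- parse_sequence(sequence)
  n <- length(types)
  isc <- is_cytosine_type(types)
  if (!any(isc)) stop("sequence has no C/mC tract")
  r <- rle(isc)
  if (sum(r$values) != 1)
    stop("sequence must contain exactly one contiguous C/mC tract")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- which(r$values)
  tract <- starts[k]:ends[k]
  if (!(1 %in% tract || n %in% tract))
    stop("the C/mC tract must sit at the 5' or 3' terminus (it is internal)")
  if (length(tract) < 2)
    stop("the C/mC tract must have length >= 2 to define an intercalation end class")
  clip_end <- if (1 %in% tract) "5'" else "3'"
  purines <- setdiff(seq_len(n), tract)
  if (length(purines) && !all(is_purine_type(types[purines])))
    stop("non-purine residue outside the C/mC tract")
  if (!length(purines))
    stop("sequence has no purine block")

  # junction cytosine: tract residue adjacent to the purine block
  junction_c <- if (clip_end == "5'") max(tract) else min(tract)
  # extended iff the junction cytosine pair is outermost in the stack
  junction_is_outer <- (end_class == "3'E" && junction_c == max(tract)) ||
    (end_class == "5'E" && junction_c == min(tract))
  implied <- if (junction_is_outer) "extended" else "compact"
  if (is.null(compactness)) {
    compactness <- implied
  } else {
    compactness <- match.arg(compactness, c("extended", "compact"))
    if (compactness != implied)
      stop(sprintf(
        paste0("the %s %s combination is not constructible for this sequence: ",
               "with the tract at the %s end the junction cytosine C%d is %s ",
               "in the %s stack, which forces the %s topology"),
        end_class, compactness, clip_end, junction_c,
        if (junction_is_outer) "outermost" else "not outermost",
        end_class, implied))
  }

  # default purine pairing geometries
  geoms <- rep(NA_character_, n)
  if (length(purines)) {
    geoms[purines] <- "WCE"
    # GA dinucleotide (5'-G-A-3') closest to the tract
    ga <- purines[which(types[purines] == "DG")]
    ga <- ga[(ga + 1) %in% purines & types[pmin(ga + 1, n)] == "DA"]
    if (length(ga)) {
      dist_to_tract <- vapply(ga, function(i) min(abs(i - tract), abs(i + 1 - tract)),
                              numeric(1))
      g <- ga[which.min(dist_to_tract)]
      geoms[g] <- "SE"
      geoms[g + 1] <- "HE"
    }
  }
  if (!is.null(purine_geometries)) {
    pg <- unlist(purine_geometries)
    idx <- as.integer(names(pg))
    if (anyNA(idx) || !all(idx %in% purines))
      stop("purine_geometries must be named by purine residue numbers")
    geoms[idx] <- unname(pg)
  }
  bad <- which(!is.na(geoms) & !geoms %in% c("SE", "HE", "WCE", "none"))
  if (length(bad)) stop("unknown pairing geometry label: ", geoms[bad[1]])

  chis <- rep(240, n)
  if (!is.null(chi)) {
    ci <- as.integer(names(chi))
    if (anyNA(ci) || !all(ci %in% seq_len(n)))
      stop("chi must be named by residue numbers")
    chis[ci] <- unname(unlist(chi))
  }
  # validate pair construction feasibility early
  for (i in purines) pair_edge(types[i], geoms[i])

  structure(list(sequence = types, clip_end = clip_end, end_class = end_class,
                 compactness = compactness, tract = tract, purines = purines,
                 junction_c = junction_c, geometries = geoms, chi = chis),
            class = "imclip_topology_spec")
}

#' @export
print.imclip_topology_spec <- function(x, ...) {
  cat("TopologySpec:", paste(x$sequence, collapse = "-"),
      sprintf("(%s tract, %s %s)\n", x$clip_end, x$end_class, x$compactness))
  p <- x$purines
  cat("  purine geometries:",
      paste(sprintf("%s%d=%s", x$sequence[p], p, x$geometries[p]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Build an idealized tetramolecular model from a topology specification
#'
#' Assembles four chains (Ia, Ib, IIa, IIb). Each base pair is
#' C2-symmetric with donor-acceptor separations of 2.8--3.0 A; the
#' intercalated CH+.C stack uses alternating duplexes with a fixed
#' inter-plane rise, and the purine homoduplex stems extend beyond the
#' stack on both ends. Duplex II is rotated by \code{duplex_offset}
#' degrees about the stack axis.
#'
#' @param spec an \code{imclip_topology_spec} (or arguments forwarded to
#'   \code{\link{topology_spec}} when \code{spec} is a character sequence).
#' @param rise inter-plane rise in Angstrom between consecutive stacked
#'   pairs (default 3.1, typical of i-motif intercalation).
#' @param twist helical twist in degrees per stack step (default 15).
#' @param duplex_offset rotation of duplex II relative to duplex I about
#'   the stack axis, degrees (default 90).
#' @param ... forwarded to \code{\link{topology_spec}}.
#' @return a \code{\link{structure_model}} whose meta field records the
#'   spec and per-residue slot assignments.
#' @examples
#' m <- build_model(topology_spec("CCCGAGA", "3'E"))
#' m
#' @export
build_model <- function(spec, rise = 3.1, twist = 15, duplex_offset = 90, ...) {
  if (!inherits(spec, "imclip_topology_spec")) spec <- topology_spec(spec, ...)
  types <- spec$sequence
  n <- length(types)
  tract <- spec$tract
  m <- length(tract)
  # tract order 5'->3': j = 1..m maps to residue tract[j]
  a_bit <- if (spec$end_class == "3'E") 1L else 0L
  slot <- matrix(NA_real_, nrow = n, ncol = 2,
                 dimnames = list(NULL, c("I", "II")))
  for (j in seq_len(m)) {
    slot[tract[j], "I"] <- 2 * (j - 1) + a_bit
    slot[tract[j], "II"] <- 2 * (m - j) + (1 - a_bit)
  }
  # purine stems continue outward from each duplex's junction cytosine
  for (d in c("I", "II")) {
    js <- slot[spec$junction_c, d]
    dir <- if (js > (2 * m - 1) / 2) 1 else -1
    first <- if (dir > 0) 2 * m - 1 + 1 else -1
    walk <- if (spec$clip_end == "5'") (spec$junction_c + 1):n else (spec$junction_c - 1):1
    for (i in seq_along(walk)) slot[walk[i], d] <- first + dir * (i - 1)
  }

  atoms <- list()
  chain_of <- c(Ia = "A", Ib = "B", IIa = "C", IIb = "D")
  pair_slots <- list()
  for (d in c("I", "II")) {
    for (i in seq_len(n)) {
      geom <- if (i %in% tract) "CHplusC" else spec$geometries[i]
      pr <- build_pair(types[i], geom, chi = spec$chi[i])
      k <- slot[i, d]
      # negative sign: the stack descends along -z, so a right-handed
      # helix (positive twist measured along the stack direction) needs
      # clockwise rotation about +z per slot
      ang <- -k * twist + if (d == "II") duplex_offset else 0
      R <- rotmat_axis(c(0, 0, 1), ang)
      zoff <- -k * rise
      for (s in c("a", "b")) {
        df <- pr[[s]]
        xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
        xyz[, 3] <- xyz[, 3] + zoff
        lbl <- paste0(d, s)
        atoms[[length(atoms) + 1]] <- data.frame(
          chain = chain_of[[lbl]], duplex = d, strand = s, resno = i,
          resid = types[i], name = df$name, element = df$element,
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
          stringsAsFactors = FALSE)
      }
      pair_slots[[length(pair_slots) + 1]] <-
        data.frame(duplex = d, resno = i, geometry = geom, slot = k)
    }
  }
  at <- do.call(rbind, atoms)
  at <- at[order(match(at$chain, c("A", "B", "C", "D")), at$resno), ]
  rownames(at) <- NULL
  at <- add_schematic_backbone(at)
  structure_model(at, sequence = types,
                  meta = list(spec = spec, rise = rise, twist = twist,
                              duplex_offset = duplex_offset,
                              slots = do.call(rbind, pair_slots)))
}

# Schematic phosphate backbone: P midway between consecutive C1' atoms of a
# strand, pushed radially out from the stack axis, with OP1/OP2 and
# O5'/O3' placed at standard bond lengths. Purely connective - it gives the
# trajectory analyses backbone acceptors but carries no torsional realism.
add_schematic_backbone <- function(at) {
  out <- list(at)
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch & at$name == "C1'", ]
    sub <- sub[order(sub$resno), ]
    if (nrow(sub) < 2) next
    for (i in 2:nrow(sub)) {
      c1prev <- unlist(sub[i - 1, c("x", "y", "z")])
      c1cur <- unlist(sub[i, c("x", "y", "z")])
      mid <- (c1prev + c1cur) / 2
      radial <- c(mid[1], mid[2], 0)
      radial <- if (vnorm(radial) < 1e-6) c(1, 0, 0) else unitv(radial)
      P <- mid + 1.5 * radial
      OP1 <- P + 1.48 * radial
      OP2 <- P + 1.48 * c(0, 0, 1)
      O5p <- P + 1.60 * unitv(c1cur - P)
      O3p <- P + 1.60 * unitv(c1prev - P)
      tmplrow <- at[at$chain == ch & at$resno == sub$resno[i], ][1, ]
      mk <- function(name, p, resno) {
        r <- tmplrow
        r$resno <- resno
        r$resid <- at$resid[at$chain == ch & at$resno == resno][1]
        r$name <- name
        r$element <- substr(name, 1, 1)
        r$x <- p[1]; r$y <- p[2]; r$z <- p[3]
        r
      }
      out[[length(out) + 1]] <- rbind(
        mk("P", P, sub$resno[i]), mk("OP1", OP1, sub$resno[i]),
        mk("OP2", OP2, sub$resno[i]), mk("O5'", O5p, sub$resno[i]),
        mk("O3'", O3p, sub$resno[i - 1]))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chain, sort(unique(res$chain))), res$resno,
                   res$name != "P"), ]
  rownames(res) <- NULL
  res
}
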