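# Classification of base-pair geometry and i-motif intercalation topology
# from atomic coordinates.
#
# Purine-purine homo pairs are labelled by their hydrogen-bonded edge:
#   G.G mutual N2H-N3  -> SE  (sugar edge, tight)
#   G.G mutual N1H-O6  -> WCE (Watson-Crick edge, loose)
#   A.A mutual N6H-N7  -> HE  (Hoogsteen edge, tight)
#   A.A mutual N6H-N1  -> WCE (loose)
# Hemiprotonated C.C pairs are called from the heavy-atom N3...N3 distance
# (<= 3.0 A) with symmetric N4H-O2 support, since the shared proton is not
# resolvable from heavy atoms.

#' Detect hydrogen bonds in a structure
#'
#' Scans all donor (N-H) / acceptor pairs between residues and keeps those
#' with heavy-atom donor-acceptor distance <= \code{d_max} and
#' D-H...A angle >= \code{angle_min}. When a donor's hydrogens are absent
#' from the model they are inferred in the base plane from standard
#' geometry. The returned table is deduplicated and sorted by distance.
#'
#' @param model StructureModel
#' @param d_max heavy-atom distance cutoff in Angstrom (default 3.5)
#' @param angle_min minimum D-H...A angle in degrees (default 120)
#' @param include_backbone also consider backbone phosphate/sugar oxygens
#'   as acceptors (default TRUE)
#' @return data.frame with one row per hydrogen bond: donor and acceptor
#'   chain/resno/atom, heavy-atom distance and D-H...A angle.
#' @export
detect_hbonds <- function(model, d_max = 3.5, angle_min = 120,
                          include_backbone = TRUE) {
  at <- model$atoms
  res <- model_residues(model)
  donors <- list(); acceptors <- list()
  for (i in seq_len(nrow(res))) {
    ty <- res$resid[i]
    if (!ty %in% RESIDUE_TYPES) next
    sel <- at$chain == res$chain[i] & at$resno == res$resno[i]
    have <- at$name[sel]
    need <- ring_atom_names(ty)
    if (!all(need %in% have)) {
      warning(sprintf("residue %s/%d (%s) is missing heavy atoms; skipped",
                      res$chain[i], res$resno[i], ty))
      next
    }
    dt <- donor_table(ty)
    for (dn in names(dt)) {
      if (!dn %in% have) next
      dxyz <- atom_xyz(model, res$chain[i], res$resno[i], dn)
      hs <- dt[[dn]]
      hxyz <- lapply(hs[hs %in% have], function(h)
        atom_xyz(model, res$chain[i], res$resno[i], h))
      if (!length(hxyz))
        hxyz <- infer_donor_hydrogens(model, res$chain[i], res$resno[i], dn, ty)
      donors[[length(donors) + 1]] <- list(
        chain = res$chain[i], resno = res$resno[i], atom = dn,
        xyz = dxyz, h = hxyz)
    }
    acc <- acceptor_table(ty)
    if (include_backbone) acc <- c(acc, intersect(backbone_acceptors(), have))
    for (an in intersect(acc, have)) {
      acceptors[[length(acceptors) + 1]] <- list(
        chain = res$chain[i], resno = res$resno[i], atom = an,
        xyz = atom_xyz(model, res$chain[i], res$resno[i], an))
    }
  }
  rows <- list()
  for (d in donors) {
    for (a in acceptors) {
      if (d$chain == a$chain && d$resno == a$resno) next
      dist <- vnorm(d$xyz - a$xyz)
      if (dist > d_max) next
      ang <- max(vapply(d$h, function(h) angle3(d$xyz, h, a$xyz), numeric(1)))
      if (ang < angle_min) next
      rows[[length(rows) + 1]] <- data.frame(
        donor_chain = d$chain, donor_resno = d$resno, donor_atom = d$atom,
        acceptor_chain = a$chain, acceptor_resno = a$resno,
        acceptor_atom = a$atom, distance = dist, angle = ang,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_atom = character(0), acceptor_chain = character(0),
                      acceptor_resno = integer(0), acceptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0)))
  hb <- do.call(rbind, rows)
  hb <- unique(hb)
  hb[order(hb$distance), , drop = FALSE]
}

# In-plane inference of missing donor hydrogens from the base heavy atoms:
# amino H's symmetric about the C-N bond, ring N-H on the exterior bisector.
infer_donor_hydrogens <- function(model, chain, resno, donor, type) {
  ring <- ring_atom_names(type)
  rxyz <- residue_xyz(model, chain, resno, ring)
  pl <- ls_plane(rxyz)
  d <- atom_xyz(model, chain, resno, donor)
  attach <- switch(donor, N2 = "C2", N6 = "C6", N4 = "C4", N1 = NA, N3 = NA, NA)
  NH <- 1.01
  if (!is.na(attach)) {
    cpos <- atom_xyz(model, chain, resno, attach)
    u <- unitv(d - cpos)
    lapply(c(60, -60), function(ang) {
      R <- rotmat_axis(pl$normal, ang)
      as.vector(d + NH * (R %*% u))
    })
  } else {
    # ring N-H: exterior bisector from the two ring neighbours
    nb <- switch(donor,
                 N1 = if (is_purine_type(type)) c("C2", "C6") else c("C2", "C6"),
                 N3 = c("C2", "C4"))
    n1 <- atom_xyz(model, chain, resno, nb[1])
    n2 <- atom_xyz(model, chain, resno, nb[2])
    dir <- -(unitv(n1 - d) + unitv(n2 - d))
    list(d + NH * unitv(dir))
  }
}

#' Glycosidic torsion and conformer of a residue
#'
#' chi is the O4'-C1'-N9-C4 torsion for purines and O4'-C1'-N1-C2 for
#' pyrimidines, reported in [0, 360). Conformers: syn 25--95 deg for all
#' bases; anti 170--310 deg for pyrimidines and 200--280 deg for purines;
#' anything else is \code{"other"}.
#'
#' @param model StructureModel
#' @param chain chain id
#' @param resno residue number
#' @return list with \code{chi} (degrees) and \code{conformer}
#' @export
chi_torsion <- function(model, chain, resno) {
  ty <- residue_type(model, chain, resno)
  ga <- glycosidic_atoms(ty)
  p <- lapply(c("O4'", "C1'", ga[["n"]], ga[["ref"]]), function(nm)
    atom_xyz(model, chain, resno, nm))
  chi <- dihedral4(p[[1]], p[[2]], p[[3]], p[[4]]) %% 360
  conf <- if (chi >= 25 && chi <= 95) "syn"
  else if (is_purine_type(ty) && chi >= 200 && chi <= 280) "anti"
  else if (!is_purine_type(ty) && chi >= 170 && chi <= 310) "anti"
  else "other"
  list(chi = chi, conformer = conf)
}

# hydrogen bonds between a specific residue pair (either direction)
hbonds_between <- function(hbonds, c1, r1, c2, r2) {
  sel <- (hbonds$donor_chain == c1 & hbonds$donor_resno == r1 &
            hbonds$acceptor_chain == c2 & hbonds$acceptor_resno == r2) |
    (hbonds$donor_chain == c2 & hbonds$donor_resno == r2 &
       hbonds$acceptor_chain == c1 & hbonds$acceptor_resno == r1)
  hbonds[sel & !hbonds$acceptor_atom %in% backbone_acceptors(), , drop = FALSE]
}

has_mutual <- function(hb, c1, r1, c2, r2, donor, acceptor) {
  f <- any(hb$donor_chain == c1 & hb$donor_resno == r1 & hb$donor_atom == donor &
             hb$acceptor_chain == c2 & hb$acceptor_resno == r2 &
             hb$acceptor_atom == acceptor)
  b <- any(hb$donor_chain == c2 & hb$donor_resno == r2 & hb$donor_atom == donor &
             hb$acceptor_chain == c1 & hb$acceptor_resno == r1 &
             hb$acceptor_atom == acceptor)
  f && b
}

#' Classify the pairing geometry of a residue pair
#'
#' @param model StructureModel
#' @param res1,res2 lists with \code{chain} and \code{resno} (or vectors
#'   \code{c(chain, resno)}).
#' @param hbonds optional precomputed table from \code{\link{detect_hbonds}}
#' @return object of class \code{imclip_base_pair} with fields
#'   \code{geometry} (SE/HE/WCE/CHplusC/unpaired), \code{tightness},
#'   \code{c2_symmetric}, \code{hbonds} and a \code{note} for cases that
#'   are recognized but deliberately not classified (e.g. G.A mismatches).
#' @export
classify_base_pair <- function(model, res1, res2, hbonds = NULL) {
  as_ref <- function(r) if (is.list(r)) r else list(chain = r[[1]], resno = as.integer(r[[2]]))
  r1 <- as_ref(res1); r2 <- as_ref(res2)
  if (is.null(hbonds)) hbonds <- detect_hbonds(model)
  t1 <- residue_type(model, r1$chain, r1$resno)
  t2 <- residue_type(model, r2$chain, r2$resno)
  hb <- hbonds_between(hbonds, r1$chain, r1$resno, r2$chain, r2$resno)
  mk <- function(geometry, tightness, note = NA_character_) {
    c2sym <- FALSE
    if (nrow(hb) >= 2) {
      # mirror symmetry: forward and backward H-bond length sets agree
      fwd <- sort(hb$distance[hb$donor_chain == r1$chain & hb$donor_resno == r1$resno])
      bwd <- sort(hb$distance[hb$donor_chain == r2$chain & hb$donor_resno == r2$resno])
      c2sym <- length(fwd) == length(bwd) && length(fwd) > 0 &&
        all(abs(fwd - bwd) <= 0.3)
    }
    structure(list(res1 = r1, res2 = r2, types = c(t1, t2), hbonds = hb,
                   geometry = geometry, tightness = tightness,
                   c2_symmetric = c2sym, note = note),
              class = "imclip_base_pair")
  }
  pur1 <- is_purine_type(t1); pur2 <- is_purine_type(t2)
  if (pur1 && pur2 && t1 != t2)
    return(mk("unpaired", NA_character_,
              note = "hetero purine pair (e.g. G.A mismatch): not classified"))
  cc <- function(...) has_mutual(hb, r1$chain, r1$resno, r2$chain, r2$resno, ...)
  if (t1 %in% c("DG", "DI") && t2 == t1) {
    if (t1 == "DG" && cc("N2", "N3")) return(mk("SE", "tight"))
    if (cc("N1", "O6")) return(mk("WCE", "loose"))
  }
  if (t1 == "DA" && t2 == "DA") {
    if (cc("N6", "N7")) return(mk("HE", "tight"))
    if (cc("N6", "N1")) return(mk("WCE", "loose"))
  }
  if (is_cytosine_type(t1) && is_cytosine_type(t2)) {
    n3a <- atom_xyz(model, r1$chain, r1$resno, "N3")
    n3b <- atom_xyz(model, r2$chain, r2$resno, "N3")
    if (vnorm(n3a - n3b) <= 3.0 && cc("N4", "O2"))
      return(mk("CHplusC", "tight"))
  }
  mk("unpaired", NA_character_)
}

#' @export
print.imclip_base_pair <- function(x, ...) {
  cat(sprintf("BasePair %s%d.%s%d [%s]: %s%s, %d H-bond(s)%s\n",
              x$res1$chain, x$res1$resno, x$res2$chain, x$res2$resno,
              paste(x$types, collapse = "."), x$geometry,
              if (!is.na(x$tightness)) paste0(" (", x$tightness, ")") else "",
              nrow(x$hbonds),
              if (x$c2_symmetric) ", C2-symmetric" else ""))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# base-pair helper: plane normal and centroid from both residues' ring atoms
pair_plane <- function(model, pair) {
  xyz <- rbind(
    residue_xyz(model, pair$res1$chain, pair$res1$resno,
                ring_atom_names(pair$types[1])),
    residue_xyz(model, pair$res2$chain, pair$res2$resno,
                ring_atom_names(pair$types[2])))
  ls_plane(xyz)
}

#' Find and classify all base pairs in a model
#'
#' Enumerates inter-chain residue pairs with at least two base-base
#' hydrogen bonds (or an N3...N3 contact for cytosines), classifies each
#' and greedily keeps the best non-overlapping set (each residue in at
#' most one pair).
#'
#' @param model StructureModel
#' @param hbonds optional precomputed hydrogen-bond table
#' @return list of \code{imclip_base_pair} objects
#' @export
find_base_pairs <- function(model, hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(model)
  res <- model_residues(model)
  cand <- list()
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (j <= i) next
      if (res$chain[i] == res$chain[j]) next
      bp <- classify_base_pair(model,
                               list(chain = res$chain[i], resno = res$resno[i]),
                               list(chain = res$chain[j], resno = res$resno[j]),
                               hbonds = hbonds)
      if (bp$geometry != "unpaired") cand[[length(cand) + 1]] <- bp
    }
  }
  if (!length(cand)) return(list())
  # greedy by number of H-bonds then by shortest mean distance
  score <- vapply(cand, function(b) nrow(b$hbonds) * 100 - mean(b$hbonds$distance),
                  numeric(1))
  used <- character(0)
  out <- list()
  for (k in order(-score)) {
    b <- cand[[k]]
    id1 <- paste(b$res1$chain, b$res1$resno)
    id2 <- paste(b$res2$chain, b$res2$resno)
    if (id1 %in% used || id2 %in% used) next
    used <- c(used, id1, id2)
    out[[length(out) + 1]] <- b
  }
  out
}

#' Classify the i-motif intercalation topology of a tetramolecular model
#'
#' Orders the hemiprotonated CH+.C pairs along the mean base-pair normal,
#' checks that duplex membership alternates along the stack (a condition
#' of valid intercalation), and calls the end class -- 3'E when the
#' outermost pair is formed by the tract cytosines nearest the 3' terminus
#' of their strands, 5'E when nearest the 5' terminus -- and the
#' compactness of the duplex/i-motif junction: extended when the purine
#' pair at the junction stacks directly on a CH+.C pair of the same
#' duplex, compact when a CH+.C pair of the orthogonal duplex is
#' intercalated between them.
#'
#' @param model StructureModel
#' @param hbonds optional precomputed hydrogen-bond table
#' @return object of class \code{imclip_topology} with fields
#'   \code{stack} (ordered pair table), \code{end_class},
#'   \code{compactness}, \code{junction}.
#' @export
classify_topology <- function(model, hbonds = NULL) {
  pairs <- find_base_pairs(model, hbonds = hbonds)
  is_cc <- vapply(pairs, function(p) p$geometry == "CHplusC", logical(1))
  cc <- pairs[is_cc]
  if (length(cc) < 2)
    stop("need at least two CH+.C pairs to classify an i-motif topology (found ",
         length(cc), ")")
  planes <- lapply(pairs, function(p) pair_plane(model, p))
  cc_planes <- planes[is_cc]
  # sign-align normals and average over CH+.C pairs
  ref <- cc_planes[[1]]$normal
  axis <- Reduce(`+`, lapply(cc_planes, function(p)
    if (sum(p$normal * ref) < 0) -p$normal else p$normal))
  axis <- unitv(axis)
  proj <- vapply(planes, function(p) sum(p$center * axis), numeric(1))
  duplex_of <- function(p) {
    d <- unique(c(model$atoms$duplex[model$atoms$chain == p$res1$chain],
                  model$atoms$duplex[model$atoms$chain == p$res2$chain]))
    if (length(d) == 1) d else NA_character_
  }
  pd <- data.frame(
    idx = seq_along(pairs),
    geometry = vapply(pairs, function(p) p$geometry, character(1)),
    duplex = vapply(pairs, duplex_of, character(1)),
    resno = vapply(pairs, function(p) p$res1$resno, numeric(1)),
    proj = proj)
  ccd <- pd[pd$geometry == "CHplusC", , drop = FALSE]
  ccd <- ccd[order(ccd$proj), , drop = FALSE]
  if (any(ccd$duplex[-1] == ccd$duplex[-nrow(ccd)]))
    stop("invalid intercalation: two consecutive CH+.C pairs of the stack ",
         "belong to the same duplex")
  # tract = run of cytosine-type residues (indices shared by all strands)
  types <- model$sequence
  if (is.null(types)) {
    rr <- model_residues(model)
    rr <- rr[rr$chain == rr$chain[1], ]
    types <- rr$resid[order(rr$resno)]
  }
  tract <- which(is_cytosine_type(types))
  outer_res <- c(ccd$resno[1], ccd$resno[nrow(ccd)])
  call_end <- function(r) {
    if (r == max(tract)) "3'E" else if (r == min(tract)) "5'E" else NA_character_
  }
  ends <- vapply(outer_res, call_end, character(1))
  if (anyNA(ends) || length(unique(ends)) != 1)
    stop("outermost CH+.C pairs do not give a consistent end class")
  end_class <- ends[1]
  # junction: purine pair closest to the CH+.C stack, per side
  pu <- pd[pd$geometry != "CHplusC", , drop = FALSE]
  compact_calls <- character(0)
  junction_desc <- character(0)
  if (nrow(pu)) {
    lo <- min(ccd$proj); hi <- max(ccd$proj)
    for (side in c("low", "high")) {
      out_pu <- pu[if (side == "low") pu$proj < lo else pu$proj > hi, , drop = FALSE]
      if (!nrow(out_pu)) next
      jp <- out_pu[which.min(abs(out_pu$proj - if (side == "low") lo else hi)), ]
      # nearest stacked neighbour on the core side of the junction purine
      others <- pd[pd$idx != jp$idx &
                     (if (side == "low") pd$proj > jp$proj else pd$proj < jp$proj),
                   , drop = FALSE]
      if (!nrow(others)) next
      nb <- others[which.min(abs(others$proj - jp$proj)), ]
      if (nb$geometry == "CHplusC") {
        compact_calls <- c(compact_calls,
                           if (nb$duplex == jp$duplex) "extended" else "compact")
        junction_desc <- c(junction_desc, sprintf(
          "purine bp %s%d (duplex %s) <-> nearest stacked bp C%d of duplex %s",
          types[jp$resno], jp$resno, jp$duplex, nb$resno, nb$duplex))
      }
    }
  }
  if (!length(compact_calls))
    stop("no purine pair adjacent to the CH+.C stack; compactness undefined")
  if (length(unique(compact_calls)) != 1)
    stop("the two junctions disagree on compactness (",
         paste(compact_calls, collapse = ", "), ")")
  structure(list(stack = ccd[, c("duplex", "resno", "proj")],
                 end_class = end_class,
                 compactness = compact_calls[1],
                 junction = junction_desc,
                 pairs = pairs),
            class = "imclip_topology")
}

#' @export
print.imclip_topology <- function(x, ...) {
  cat(sprintf("i-motif topology: %s %s\n", x$end_class, x$compactness))
  cat("  CH+.C stack (axis order):",
      paste(sprintf("C%d(%s)", x$stack$resno, x$stack$duplex), collapse = " | "),
      "\n")
  for (j in x$junction) cat("  junction:", j, "\n")
  invisible(x)
}
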