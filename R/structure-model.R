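# StructureModel: the package's atomic-coordinate container.
#
# Atoms live in a flat data.frame; chains carry duplex (I/II) and strand
# (a/b) labels, residues are numbered 1..n from the 5' terminus of each
# strand, matching the superscript convention used for these constructs.

#' Construct a StructureModel
#'
#' @param atoms data.frame with columns \code{chain}, \code{duplex},
#'   \code{strand}, \code{resno}, \code{resid}, \code{name}, \code{element},
#'   \code{x}, \code{y}, \code{z}.
#' @param sequence character vector of residue types (5' to 3'), one entry
#'   per residue of a single strand (all four strands share it).
#' @param meta list of builder metadata (may be empty).
#' @return object of class \code{imclip_model}
#' @export
structure_model <- function(atoms, sequence = NULL, meta = list()) {
  need <- c("chain", "duplex", "strand", "resno", "resid", "name",
            "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  structure(list(atoms = atoms, sequence = sequence, meta = meta),
            class = "imclip_model")
}

#' @export
print.imclip_model <- function(x, ...) {
  ch <- unique(x$atoms[, c("chain", "duplex", "strand")])
  cat("StructureModel:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chains\n")
  if (!is.null(x$sequence))
    cat("  sequence (5'->3'):", paste(x$sequence, collapse = "-"), "\n")
  for (i in seq_len(nrow(ch)))
    cat("  chain ", ch$chain[i], " -> duplex ", ch$duplex[i],
        ", strand ", ch$strand[i], "\n", sep = "")
  invisible(x)
}

#' Coordinates of one atom
#'
#' @param model StructureModel
#' @param chain chain id
#' @param resno residue number (1-based from 5')
#' @param name atom name
#' @return numeric xyz vector of length 3
#' @export
atom_xyz <- function(model, chain, resno, name) {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & a$name == name)
  if (length(i) != 1)
    stop(sprintf("atom %s/%s/%s matched %d records", chain, resno, name, length(i)))
  unlist(a[i, c("x", "y", "z")], use.names = FALSE)
}

#' Coordinate matrix for a residue (optionally a subset of atom names)
#' @noRd
residue_xyz <- function(model, chain, resno, names = NULL) {
  a <- model$atoms
  sel <- a$chain == chain & a$resno == resno
  if (!is.null(names)) sel <- sel & a$name %in% names
  m <- as.matrix(a[sel, c("x", "y", "z")])
  rownames(m) <- a$name[sel]
  m
}

#' Residue type lookup
#' @noRd
residue_type <- function(model, chain, resno) {
  a <- model$atoms
  t <- unique(a$resid[a$chain == chain & a$resno == resno])
  if (length(t) != 1) stop("residue not found: ", chain, "/", resno)
  t
}

#' All residues of a model as a data.frame (chain, duplex, strand, resno, resid)
#' @export
model_residues <- function(model) {
  unique(model$atoms[, c("chain", "duplex", "strand", "resno", "resid")])
}

#' Apply a rigid motion (rotation matrix + translation) to a model
#'
#' @param model StructureModel
#' @param R 3x3 rotation matrix
#' @param t translation vector (length 3)
#' @return transformed StructureModel
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, -t)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# parse a sequence given as character vector of tokens or compact string
# ("CCCGAGA", "GAGACCmC"; multi-letter tokens mC and aR)
parse_sequence <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1 && !sequence %in% c("mC", "aR")) {
    toks <- character(0)
    s <- sequence
    while (nchar(s)) {
      two <- substr(s, 1, 2)
      if (two %in% c("mC", "aR")) {
        toks <- c(toks, two); s <- substr(s, 3, nchar(s))
      } else {
        toks <- c(toks, substr(s, 1, 1)); s <- substr(s, 2, nchar(s))
      }
    }
    sequence <- toks
  }
  map <- c(C = "DC", mC = "5mC", G = "DG", A = "DA", I = "DI", aR = "2AP")
  if (!all(sequence %in% c(names(map), RESIDUE_TYPES)))
    stop("unknown residue token(s): ",
         paste(setdiff(sequence, c(names(map), RESIDUE_TYPES)), collapse = ", "))
  ifelse(sequence %in% names(map), unname(map[sequence]), sequence)
}
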