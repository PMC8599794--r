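# Structure file I/O. Reading goes through bio3d (PDB and mmCIF,
# multi-model aware); the multi-model PDB writer is local since bio3d
# writes single models only.

resid_to_pdb <- c(DA = "DA", DG = "DG", DC = "DC", `5mC` = "5CM",
                  DI = "DI", `2AP` = "2AP")
pdb_to_resid <- stats::setNames(names(resid_to_pdb), resid_to_pdb)

#' Write one model or a trajectory as (multi-model) PDB
#'
#' @param x StructureModel, list of StructureModels, or
#'   \code{imclip_trajectory}
#' @param path output file
#' @return the path, invisibly
#' @export
write_structure <- function(x, path) {
  models <- if (inherits(x, "imclip_model")) list(x)
  else if (inherits(x, "imclip_trajectory"))
    lapply(seq_len(n_frames(x)), function(i) frame_model(x, i))
  else x
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (mi in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", mi), con)
    at <- models[[mi]]$atoms
    resname <- unname(resid_to_pdb[at$resid])
    resname[is.na(resname)] <- at$resid[is.na(resname)]
    name4 <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
                    sprintf(" %-3s", at$name))
    lines <- sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), name4, resname, at$chain, at$resno,
      at$x, at$y, at$z, 1.00, 0.00, at$element)
    writeLines(lines, con)
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a structure file (PDB or mmCIF, multi-model aware)
#'
#' Chains are mapped to duplex/strand labels (Ia, Ib, IIa, IIb) in file
#' order by default, or via \code{chain_map}. Files whose chain count is
#' not four are still read, with duplex/strand labels left NA and a
#' warning (per-chain analyses remain possible).
#'
#' @param path file path
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}
#' @param chain_map optional data.frame with columns \code{chain},
#'   \code{duplex}, \code{strand}
#' @return a single StructureModel, or a list of them (class
#'   \code{imclip_model_set}) for multi-model files
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chain_map = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE)
    else bio3d::read.cif(path),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  resid <- unname(pdb_to_resid[a$resid])
  resid[is.na(resid)] <- a$resid[is.na(resid)]
  chains <- unique(a$chain)
  if (is.null(chain_map)) {
    if (length(chains) == 4) {
      chain_map <- data.frame(chain = chains,
                              duplex = c("I", "I", "II", "II"),
                              strand = c("a", "b", "a", "b"))
    } else {
      warning("expected 4 chains for a tetramolecular model, found ",
              length(chains), "; duplex/strand labels left NA")
      chain_map <- data.frame(chain = chains, duplex = NA_character_,
                              strand = NA_character_)
    }
  }
  dup <- chain_map$duplex[match(a$chain, chain_map$chain)]
  str <- chain_map$strand[match(a$chain, chain_map$chain)]
  base <- data.frame(chain = a$chain, duplex = dup, strand = str,
                     resno = a$resno, resid = resid, name = a$elety,
                     element = ifelse(is.na(a$elesy) | a$elesy == "",
                                      toupper(substr(a$elety, 1, 1)), a$elesy),
                     x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || nmod <= 1) return(structure_model(base))
  models <- lapply(seq_len(nmod), function(i) {
    xyz <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    b <- base
    b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
    structure_model(b)
  })
  class(models) <- c("imclip_model_set", "list")
  models
}

#' @export
print.imclip_model_set <- function(x, ...) {
  cat("Model set with", length(x), "models\n")
  print(x[[1]])
  invisible(x)
}

#' Convert a list of models (equal atom sets) to a trajectory
#'
#' @param models list of StructureModels
#' @param timestep ps between consecutive models
#' @return \code{\link{trajectory}}
#' @export
as_trajectory <- function(models, timestep = 100) {
  na <- nrow(models[[1]]$atoms)
  coords <- array(NA_real_, dim = c(na, 3, length(models)))
  for (i in seq_along(models)) {
    if (nrow(models[[i]]$atoms) != na) stop("atom-count mismatch between models")
    coords[, , i] <- as.matrix(models[[i]]$atoms[, c("x", "y", "z")])
  }
  trajectory(models[[1]], coords, seq_along(models) * timestep)
}

#' Write / read NOE buildup tables as CSV
#'
#' Long-format CSV with columns \code{peak_id}, \code{chain1},
#' \code{resno1}, \code{atom1}, \code{chain2}, \code{resno2},
#' \code{atom2}, \code{tau_ms}, \code{volume}, \code{flags}.
#'
#' @param buildups list of \code{\link{noe_buildup}} objects
#' @param path file path
#' @export
write_noe_csv <- function(buildups, path) {
  rows <- lapply(buildups, function(b) {
    data.frame(peak_id = b$peak_id,
               chain1 = b$atom1$chain, resno1 = b$atom1$resno,
               atom1 = b$atom1$name,
               chain2 = b$atom2$chain, resno2 = b$atom2$resno,
               atom2 = b$atom2$name,
               tau_ms = b$volumes$tau_ms, volume = b$volumes$volume,
               flags = paste(b$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_noe_csv
#' @return \code{read_noe_csv}: list of \code{\link{noe_buildup}} objects
#' @export
read_noe_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$flags[is.na(df$flags)] <- ""
  out <- lapply(split(df, df$peak_id), function(g) {
    noe_buildup(g$peak_id[1],
                list(chain = g$chain1[1], resno = g$resno1[1], name = g$atom1[1]),
                list(chain = g$chain2[1], resno = g$resno2[1], name = g$atom2[1]),
                g$tau_ms, g$volume,
                flags = if (nzchar(g$flags[1])) strsplit(g$flags[1], ";")[[1]]
                else character(0))
  })
  unname(out[order(vapply(out, function(b) b$peak_id, character(1)))])
}
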