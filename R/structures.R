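#' Construct a C-alpha structure
#'
#' A minimal per-residue coordinate container: one C-alpha bead per residue,
#' 1-based residue numbering preserved from the source. Consecutive C-alpha
#' distances are checked against physical bounds (2.0-5.0 Angstrom) unless
#' the structure is flagged synthetic.
#'
#' @param data Data frame with columns `residue`, `x`, `y`, `z` (Angstrom).
#' @param synthetic Skip the physical bond-length check (toy geometries).
#' @param ss_mask Optional logical vector, one per residue, marking residues
#'   inside secondary-structure elements.
#' @return A `calpha_structure` tibble.
#' @export
calpha_structure <- function(data, synthetic = FALSE, ss_mask = NULL) {
  data <- as_tibble(data)
  stopifnot(all(c("residue", "x", "y", "z") %in% names(data)))
  xyz <- as.matrix(data[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort_invalid("coordinates must be finite")
  if (!synthetic && nrow(data) > 1) {
    consec <- which(diff(data$residue) == 1L)
    if (length(consec)) {
      d <- sqrt(rowSums((xyz[consec + 1L, , drop = FALSE] -
                           xyz[consec, , drop = FALSE])^2))
      if (any(d < 2 | d > 5)) {
        abort_invalid(
          "consecutive C-alpha distance outside 2-5 Angstrom (min %.2f, max %.2f); pass synthetic = TRUE for toy geometries",
          min(d), max(d))
      }
    }
  }
  if (!is.null(ss_mask)) {
    stopifnot(length(ss_mask) == nrow(data))
    attr(data, "ss_mask") <- as.logical(ss_mask)
  }
  attr(data, "synthetic") <- synthetic
  class(data) <- c("calpha_structure", class(data))
  data
}

coords_matrix <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts the C-alpha trace of one model and chain (first model, first
#' chain, altloc A by default). Residue numbering is preserved as written;
#' gaps in numbering are recorded in the `gaps` attribute, not renumbered.
#' Insertion codes are rejected.
#'
#' @param path PDB file path.
#' @param chain Chain identifier; default first chain present.
#' @param model Model number (multi-model files), default 1.
#' @return A `calpha_structure` tibble.
#' @export
read_calpha_pdb <- function(path, chain = NULL, model = 1) {
  if (!file.exists(path)) abort_invalid("file not found: %s", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$elety == "CA" & at$type == "ATOM"
  if (!is.null(at$alt)) keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) abort_invalid("no C-alpha atoms in %s", path)
  if (any(!is.na(at$insert) & at$insert != "")) {
    abort_invalid("insertion codes present in %s; renumber before use", path)
  }
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) abort_invalid("chain %s has no C-alpha atoms", chain)
  if (model > 1) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    idx <- which(keep)[pdb$atom$chain[keep] == chain]
    at$x <- xyz[idx, 1]; at$y <- xyz[idx, 2]; at$z <- xyz[idx, 3]
  }
  out <- calpha_structure(tibble(residue = as.integer(at$resno),
                                 x = at$x, y = at$y, z = at$z),
                          synthetic = TRUE)
  attr(out, "synthetic") <- FALSE
  attr(out, "chain") <- chain
  attr(out, "resid") <- at$resid
  gaps <- which(diff(out$residue) > 1L)
  attr(out, "gaps") <- if (length(gaps)) {
    tibble(after_residue = out$residue[gaps],
           missing = out$residue[gaps + 1L] - out$residue[gaps] - 1L)
  } else NULL
  out
}

#' Write a C-alpha structure as a single-chain PDB file
#'
#' One CA atom per residue, chain A, occupancy 1. Round-trips through
#' [read_calpha_pdb()].
#'
#' @param structure A `calpha_structure`.
#' @param path Output path.
#' @param resid Residue names (default GLY).
#' @return `path`, invisibly.
#' @export
write_calpha_pdb <- function(structure, path, resid = "GLY") {
  n <- nrow(structure)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords_matrix(structure))),
    resno = structure$residue,
    resid = rep(resid, length.out = n),
    chain = rep("A", n),
    elety = rep("CA", n))
  invisible(path)
}
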