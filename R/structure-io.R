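# PDB-backed structure model. Parsing/writing of coordinate records is
# delegated to bio3d; this layer adds the altloc/hydrogen/water policies,
# REMARK 2 resolution handling, and the accessors the pipeline needs.

.water_names <- c("HOH", "WAT", "DOD")
.ion_names <- c("NA", "SOD")
.backbone_atoms <- c("N", "CA", "C", "O")

.aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

#' Construct a structure model
#'
#' Low-level constructor around a per-atom table. Most users obtain models
#' from [read_pdb()] or the fixture generators rather than calling this
#' directly.
#'
#' @param atoms Data frame with columns `type` (ATOM/HETATM), `eleno`,
#'   `elety` (atom name), `resid` (3-letter residue name), `chain`, `resno`,
#'   `insert`, `x`, `y`, `z`, `o` (occupancy), `b` (B-factor, A^2), `elesy`
#'   (element symbol).
#' @param entry_id Identifier for the structure (e.g. a PDB id).
#' @param resolution Crystallographic resolution in Angstrom, or `NA`.
#' @param metadata Free-form named list.
#' @return An object of class `aquahom_structure`.
#' @export
structure_model <- function(atoms, entry_id = "unknown", resolution = NA_real_,
                            metadata = list()) {
  need <- c("type", "eleno", "elety", "resid", "chain", "resno",
            "insert", "x", "y", "z", "o", "b", "elesy")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  if (any(atoms$b < 0, na.rm = TRUE)) stop("negative B-factor in atom table")
  if (!is.na(resolution) && resolution <= 0)
    stop("resolution must be positive when present")
  rownames(atoms) <- NULL
  structure(list(entry_id = entry_id, atoms = atoms,
                 resolution = resolution, metadata = metadata),
            class = "aquahom_structure")
}

#' @export
print.aquahom_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<aquahom_structure> %s: %d atoms, %d protein residues, %d waters",
              x$entry_id, nrow(a), nrow(unique(.protein_rows(x)[, c("chain", "resno", "insert")])),
              nrow(water_oxygens(x))))
  if (!is.na(x$resolution)) cat(sprintf(", %.2f A", x$resolution))
  cat("\n")
  invisible(x)
}

.is_water_resid <- function(resid) resid %in% .water_names

.is_protein_resid <- function(resid) {
  !.is_water_resid(resid) & suppressWarnings(bio3d::aa321(resid)) != "X"
}

.protein_rows <- function(model, chain = NULL) {
  a <- model$atoms
  sel <- .is_protein_resid(a$resid)
  if (!is.null(chain)) sel <- sel & a$chain == chain
  a[sel, , drop = FALSE]
}

#' Per-atom views of a structure model
#'
#' `protein_atoms()` returns the heavy atoms of standard (or recognised
#' modified) amino-acid residues; `water_oxygens()` one oxygen row per water
#' (HOH/WAT/DOD); `hetero_atoms()` everything else (ligands, ions);
#' `heavy_atom_coords()` the coordinates of every atom in the model as a
#' matrix, the occupied-space set used for clash checks.
#'
#' @param model An `aquahom_structure`.
#' @param chain Optional chain to restrict to.
#' @return A data frame of atom rows, or for `heavy_atom_coords()` a numeric
#'   matrix with columns x, y, z.
#' @export
protein_atoms <- function(model, chain = NULL) .protein_rows(model, chain)

#' @rdname protein_atoms
#' @export
water_oxygens <- function(model) {
  a <- model$atoms
  a[.is_water_resid(a$resid) & substr(a$elety, 1, 1) == "O", , drop = FALSE]
}

#' @rdname protein_atoms
#' @export
hetero_atoms <- function(model) {
  a <- model$atoms
  a[!.is_water_resid(a$resid) & !.is_protein_resid(a$resid), , drop = FALSE]
}

#' @rdname protein_atoms
#' @export
heavy_atom_coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

.coords <- function(df) {
  m <- as.matrix(df[, c("x", "y", "z"), drop = FALSE])
  dimnames(m) <- NULL
  m
}

.parse_resolution <- function(lines) {
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rem)) return(NA_real_)
  m <- regmatches(rem[1], regexpr("[0-9]+\\.[0-9]+", rem[1]))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

# Altloc policy: one conformer per (chain, resno, insert, resid, elety);
# highest occupancy wins, ties resolved toward blank/'A'.
.resolve_altlocs <- function(a) {
  key <- paste(a$chain, a$resno, a$insert, a$resid, a$elety, sep = "\r")
  if (!anyDuplicated(key)) return(a)
  alt <- ifelse(is.na(a$alt) | a$alt == "", "A", a$alt)
  occ <- ifelse(is.na(a$o), 1, a$o)
  ord <- order(key, -occ, alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  a[order(a$eleno), , drop = FALSE]
}

#' Read a PDB file into a structure model
#'
#' Hydrogens are dropped, waters are reduced to their oxygen atom, and
#' alternate locations are collapsed to the highest-occupancy conformer
#' (ties broken toward altloc 'A'). Resolution is taken from the REMARK 2
#' header when present. Residue names HOH, WAT and DOD are recognised as
#' water.
#'
#' @param path Path to a PDB file containing at least one ATOM/HETATM record.
#' @param model_index Which MODEL to use in a multi-model file (default 1).
#' @param entry_id Identifier to attach; defaults to the file name stem.
#' @return An `aquahom_structure`.
#' @export
read_pdb <- function(path, model_index = 1L, entry_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    stop("no ATOM/HETATM records in ", path)
  multi <- model_index > 1L || sum(grepl("^MODEL ", lines)) > 1L
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = multi, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (multi) {
    if (is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1) {
      if (model_index > nrow(pdb$xyz))
        stop("model_index ", model_index, " but file has ",
             nrow(pdb$xyz), " models")
      xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    } else if (model_index > 1L) {
      stop("model_index ", model_index, " but file has 1 model")
    }
  }
  # bio3d reads the sodium residue/atom name "NA" as missing; restore it.
  a$resid[is.na(a$resid)] <- "NA"
  a$elety[is.na(a$elety)] <- "NA"
  a$elesy[is.na(a$elesy) | a$elesy == ""] <-
    toupper(substr(a$elety[is.na(a$elesy) | a$elesy == ""], 1, 1))
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  a$insert[is.na(a$insert)] <- ""
  a <- .resolve_altlocs(a)
  a <- a[!(a$elesy %in% c("H", "D")), , drop = FALSE]
  # waters: keep the oxygen only
  wat <- .is_water_resid(a$resid)
  a <- a[!wat | substr(a$elety, 1, 1) == "O", , drop = FALSE]
  if (!nrow(a)) stop("no heavy atoms retained from ", path)
  keep <- c("type", "eleno", "elety", "resid", "chain", "resno",
            "insert", "x", "y", "z", "o", "b", "elesy")
  a <- a[, keep]
  if (is.null(entry_id)) entry_id <- sub("\\.(pdb|ent)$", "", basename(path))
  structure_model(a, entry_id = entry_id,
                  resolution = .parse_resolution(lines))
}

#' Write a structure model to a PDB file
#'
#' Emits standard fixed-width PDB v3.3 records via bio3d, prefixed with a
#' REMARK 2 resolution line when the model carries one. Waters are written
#' as HETATM HOH; sodium as HETATM NA.
#'
#' @param model An `aquahom_structure` with at least one atom.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  if (!nrow(a)) stop("empty model")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(.coords(a))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = a$insert,
                   o = a$o, b = a$b, elesy = a$elesy)
  header <- character()
  if (!is.na(model$resolution))
    header <- c(header, sprintf("REMARK   2 RESOLUTION.  %6.2f ANGSTROMS.",
                                model$resolution))
  if (!is.null(model$metadata$seed))
    header <- c(header, sprintf("REMARK  99 GENERATOR SEED %d",
                                as.integer(model$metadata$seed)))
  if (length(header)) {
    body <- readLines(path, warn = FALSE)
    writeLines(c(header, body), path)
  }
  invisible(path)
}

.chain_residues <- function(model, chain_id) {
  p <- .protein_rows(model, chain_id)
  if (!nrow(p)) {
    avail <- unique(.protein_rows(model)$chain)
    stop("chain '", chain_id, "' has no protein residues; available: ",
         if (length(avail)) paste(avail, collapse = ", ") else "<none>")
  }
  key <- paste(p$resno, p$insert, sep = "\r")
  first <- !duplicated(key)
  res <- p[first, c("resno", "insert", "resid")]
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract the one-letter amino-acid sequence of a chain
#'
#' Residues are emitted in residue-number order; gaps in the author
#' numbering do not insert characters. Modified residues with a known parent
#' (e.g. MSE) map to the parent letter, unknown residues to 'X'. The residue
#' numbers backing each sequence position are attached as attribute
#' `"resno"`.
#'
#' @param model An `aquahom_structure`.
#' @param chain_id Chain label.
#' @return Character scalar; attribute `resno` gives the author residue
#'   number of each position.
#' @export
extract_sequence <- function(model, chain_id) {
  res <- .chain_residues(model, chain_id)
  letters1 <- suppressWarnings(bio3d::aa321(res$resid))
  seq <- paste(letters1, collapse = "")
  attr(seq, "resno") <- res$resno
  seq
}

#' Strip a structure for reference-database curation
#'
#' Keeps the protein residues of one chain, hetero residues whose names are
#' in `ligand_names` (retained ligands), and waters that sit closer to the
#' kept chain than to any removed chain. Auxiliary/fusion chains and all
#' other hetero groups are removed.
#'
#' @param model An `aquahom_structure`.
#' @param keep_chain Chain label of the receptor chain to keep.
#' @param ligand_names Character vector of hetero residue names to retain.
#' @return A stripped `aquahom_structure`.
#' @export
strip_for_curation <- function(model, keep_chain, ligand_names = character()) {
  .chain_residues(model, keep_chain)  # errors if chain absent
  a <- model$atoms
  prot <- .is_protein_resid(a$resid)
  wat <- .is_water_resid(a$resid)
  keep_prot <- prot & a$chain == keep_chain
  keep_lig <- !prot & !wat & a$resid %in% ligand_names
  # water ownership is decided between protein chains: a water stays iff it
  # is at least as close to the kept chain as to any removed protein chain
  removed <- prot & a$chain != keep_chain
  keep_wat <- wat & substr(a$elety, 1, 1) == "O"
  if (any(keep_wat) && any(removed)) {
    wxyz <- .coords(a[keep_wat, ])
    kept_xyz <- .coords(a[keep_prot, ])
    rem_xyz <- .coords(a[removed, ])
    d_keep <- .min_dist_each(wxyz, kept_xyz)
    d_rem <- .min_dist_each(wxyz, rem_xyz)
    keep_wat[keep_wat] <- d_keep <= d_rem
  }
  out <- a[keep_prot | keep_lig | keep_wat, , drop = FALSE]
  structure_model(out, entry_id = model$entry_id,
                  resolution = model$resolution, metadata = model$metadata)
}

# min distance from each row of `pts` to the set `ref` (both n x 3)
.min_dist_each <- function(pts, ref) {
  if (!nrow(ref)) return(rep(Inf, nrow(pts)))
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (ref[, 1] - pts[i, 1])^2 + (ref[, 2] - pts[i, 2])^2 +
      (ref[, 3] - pts[i, 3])^2
    sqrt(min(d2))
  }, numeric(1))
}
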