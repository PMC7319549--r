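# Reference database of curated internal waters. Waters from template
# structures pass two filters before storage: crystallographic order
# (B-factor <= 45 A^2; strictly greater is discarded) and burial, measured
# by circular variance of the directions to surrounding protein heavy atoms
# (internal iff CV >= 0.6 within 10 A).

DB_SCHEMA_VERSION <- 1L

#' Circular variance of neighbour directions around a water oxygen
#'
#' Computes `1 - ||sum(u)|| / N` where `u` are unit vectors from the oxygen
#' to each neighbour atom within `radius` (coincident atoms are skipped).
#' Values near 1 mean the point is surrounded (buried); values near 0 mean
#' all neighbours lie to one side (exposed). With no neighbours in range the
#' value is 0 (treated as external) with a warning.
#'
#' @param water_oxygen Numeric length-3 position (Angstrom).
#' @param neighbor_atoms Numeric matrix (n x 3) of candidate neighbour
#'   positions; typically protein heavy atoms.
#' @param radius Inclusion radius in Angstrom (default 10).
#' @return Numeric scalar in `[0, 1]`.
#' @export
#' @examples
#' circular_variance(c(0, 0, 0), rbind(c(3, 0, 0)))        # 0: one-sided
#' circular_variance(c(0, 0, 0), rbind(c(5, 0, 0), c(0, 5, 0)))  # 1 - sqrt(2)/2
circular_variance <- function(water_oxygen, neighbor_atoms, radius = 10) {
  stopifnot(radius > 0, length(water_oxygen) == 3)
  if (is.null(neighbor_atoms) || !NROW(neighbor_atoms)) {
    warning("no neighbour atoms within radius; circular variance set to 0")
    return(0)
  }
  nb <- matrix(as.numeric(neighbor_atoms), ncol = 3)
  dv <- sweep(nb, 2, as.numeric(water_oxygen))
  d <- sqrt(rowSums(dv^2))
  sel <- d > 0 & d <= radius
  if (!any(sel)) {
    warning("no neighbour atoms within radius; circular variance set to 0")
    return(0)
  }
  u <- dv[sel, , drop = FALSE] / d[sel]
  1 - sqrt(sum(colSums(u)^2)) / nrow(u)
}

#' Classify a water as internal or external
#'
#' A water is internal iff its circular variance over the surrounding
#' protein heavy atoms is at least `cv_threshold`. External waters are
#' incompatible with a membrane environment outside the crystal lattice and
#' are excluded from the reference database.
#'
#' @param water Numeric length-3 oxygen position, or a 1-row atom data frame
#'   with x/y/z columns.
#' @param protein_atoms Matrix (n x 3) of protein heavy-atom positions.
#' @param radius Neighbourhood radius in Angstrom (default 10).
#' @param cv_threshold Internal/external threshold (default 0.6).
#' @return `"internal"` or `"external"`, with the CV value in attribute
#'   `"cv"`.
#' @export
classify_water <- function(water, protein_atoms, radius = 10,
                           cv_threshold = 0.6) {
  if (is.data.frame(water)) water <- as.numeric(water[1, c("x", "y", "z")])
  cv <- suppressWarnings(circular_variance(water, protein_atoms, radius))
  out <- if (cv >= cv_threshold) "internal" else "external"
  attr(out, "cv") <- cv
  out
}

.parse_res250 <- function(res_250) {
  if (is.null(res_250) || (length(res_250) == 1 && is.na(res_250))) return(NULL)
  if (is.character(res_250)) {
    parts <- strsplit(res_250, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("res_250 must be 'chain:resno', got ", res_250)
    return(list(chain = parts[1], resno = as.integer(parts[2])))
  }
  res_250
}

#' Build a reference-database entry from a curated structure
#'
#' Applies the two water filters (B-factor, then circular variance) and
#' records the surviving internal waters, any sodium ions (flagged when
#' within 6 A of the position-2.50 residue), the chain sequence, and the
#' backbone atoms needed later for superposition.
#'
#' @param model An `aquahom_structure`, already stripped via
#'   [strip_for_curation()].
#' @param receptor_name Receptor identity label.
#' @param state Functional state: `"active"`, `"inactive"` or `"unknown"`.
#' @param res_250 Optional locator of the Ballesteros-Weinstein 2.50 residue,
#'   `"chain:resno"` or `list(chain=, resno=)`.
#' @param chain_id Receptor chain; defaults to the first protein chain.
#' @param resolution Resolution override (Angstrom); defaults to the model's.
#' @param bfactor_max Discard waters with B-factor strictly above this
#'   (default 45 A^2).
#' @param cv_threshold,cv_radius Circular-variance filter parameters
#'   (defaults 0.6 and 10 A).
#' @return A `template_entry` object.
#' @export
build_template_entry <- function(model, receptor_name = model$entry_id,
                                 state = "unknown", res_250 = NULL,
                                 chain_id = NULL, resolution = NULL,
                                 bfactor_max = 45, cv_threshold = 0.6,
                                 cv_radius = 10) {
  prot <- protein_atoms(model)
  if (!nrow(prot)) stop("no protein residues in model ", model$entry_id)
  if (is.null(chain_id)) chain_id <- prot$chain[1]
  seq <- extract_sequence(model, chain_id)
  pxyz <- .coords(prot)

  wat <- water_oxygens(model)
  wat <- wat[wat$b <= bfactor_max, , drop = FALSE]
  waters <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                       b = numeric(0), cv = numeric(0))
  if (nrow(wat)) {
    cv <- vapply(seq_len(nrow(wat)), function(i)
      suppressWarnings(circular_variance(as.numeric(wat[i, c("x", "y", "z")]),
                                         pxyz, cv_radius)),
      numeric(1))
    keep <- cv >= cv_threshold
    waters <- data.frame(x = wat$x[keep], y = wat$y[keep], z = wat$z[keep],
                         b = wat$b[keep], cv = cv[keep])
    waters <- waters[order(waters$b), , drop = FALSE]
    rownames(waters) <- NULL
  }

  res_250 <- .parse_res250(res_250)
  het <- hetero_atoms(model)
  ionrows <- het[het$resid %in% .ion_names | het$elesy == "NA", , drop = FALSE]
  ions <- data.frame(element = character(0), x = numeric(0), y = numeric(0),
                     z = numeric(0), near_250 = logical(0))
  if (nrow(ionrows)) {
    near <- rep(FALSE, nrow(ionrows))
    if (!is.null(res_250)) {
      a <- model$atoms
      ref <- a[a$chain == res_250$chain & a$resno == res_250$resno &
                 .is_protein_resid(a$resid), , drop = FALSE]
      if (nrow(ref))
        near <- .min_dist_each(.coords(ionrows), .coords(ref)) <= 6
    }
    ions <- data.frame(element = "NA", x = ionrows$x, y = ionrows$y,
                       z = ionrows$z, near_250 = near)
  }

  bb <- prot[prot$chain == chain_id & prot$elety %in% .backbone_atoms,
             c("resno", "elety", "resid", "x", "y", "z")]
  rownames(bb) <- NULL
  resol <- if (!is.null(resolution)) resolution else model$resolution
  structure(list(entry_id = model$entry_id, chain_id = chain_id,
                 receptor_name = receptor_name,
                 sequence = as.character(seq),
                 seq_resno = attr(seq, "resno"),
                 state = state, resolution = resol,
                 waters = waters, ions = ions,
                 res_250 = res_250, backbone = bb),
            class = "template_entry")
}

#' @export
print.template_entry <- function(x, ...) {
  cat(sprintf("<template_entry> %s/%s (%s, %s, %.2f A): %d internal waters, %d ions\n",
              x$entry_id, x$chain_id, x$receptor_name, x$state,
              ifelse(is.na(x$resolution), NA, x$resolution),
              nrow(x$waters), nrow(x$ions)))
  invisible(x)
}

#' Assemble a reference database from template entries
#'
#' @param entries List of `template_entry` objects; `(entry_id, chain_id)`
#'   pairs must be unique.
#' @param provenance Named list recording the build cutoffs.
#' @return A `reference_db` object.
#' @export
reference_db <- function(entries, provenance = list(bfactor_max = 45,
                                                    cv_threshold = 0.6,
                                                    cv_radius = 10)) {
  keys <- vapply(entries, function(e) paste(e$entry_id, e$chain_id), "")
  if (anyDuplicated(keys))
    stop("duplicate (entry_id, chain_id): ",
         paste(keys[duplicated(keys)], collapse = ", "))
  structure(list(entries = entries, schema_version = DB_SCHEMA_VERSION,
                 provenance = provenance),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  nw <- sum(vapply(x$entries, function(e) nrow(e$waters), 0L))
  cat(sprintf("<reference_db> schema %d: %d entries, %d internal waters\n",
              x$schema_version, length(x$entries), nw))
  invisible(x)
}

#' Build a reference database from structures and sidecar metadata
#'
#' Convenience wrapper: each model is stripped to its receptor chain and
#' converted with [build_template_entry()]. The metadata table mirrors the
#' sidecar TSV consumed by the command-line front end.
#'
#' @param models List of `aquahom_structure` objects (or PDB file paths).
#' @param metadata Data frame with columns `entry_id`, `chain`,
#'   `receptor_name`, `state`, `resolution`, `res_250` (may be `NA`), one
#'   row per model, matched by `entry_id`.
#' @param ligand_names Hetero residue names to retain during stripping.
#' @inheritParams build_template_entry
#' @return A `reference_db`.
#' @export
build_reference_db <- function(models, metadata, ligand_names = character(),
                               bfactor_max = 45, cv_threshold = 0.6,
                               cv_radius = 10) {
  entries <- lapply(models, function(m) {
    if (is.character(m)) m <- read_pdb(m)
    row <- metadata[metadata$entry_id == m$entry_id, , drop = FALSE]
    if (!nrow(row)) stop("no metadata row for entry ", m$entry_id)
    row <- row[1, ]
    # sodium ions ride through curation so near-2.50 ions can be recorded
    stripped <- strip_for_curation(m, row$chain, union(ligand_names, .ion_names))
    build_template_entry(stripped, receptor_name = row$receptor_name,
                         state = row$state,
                         res_250 = if ("res_250" %in% names(row)) row$res_250 else NULL,
                         chain_id = row$chain, resolution = row$resolution,
                         bfactor_max = bfactor_max,
                         cv_threshold = cv_threshold, cv_radius = cv_radius)
  })
  reference_db(entries, provenance = list(bfactor_max = bfactor_max,
                                          cv_threshold = cv_threshold,
                                          cv_radius = cv_radius))
}

.entry_to_list <- function(e) unclass(e)

.df_from_json <- function(x, template) {
  if (is.data.frame(x) && nrow(x)) {
    for (nm in names(template)) {
      x[[nm]] <- switch(class(template[[nm]])[1],
                        numeric = as.numeric(x[[nm]]),
                        integer = as.integer(x[[nm]]),
                        logical = as.logical(x[[nm]]),
                        as.character(x[[nm]]))
    }
    return(x[, names(template), drop = FALSE])
  }
  template
}

.list_to_entry <- function(l) {
  wt <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                   b = numeric(0), cv = numeric(0))
  it <- data.frame(element = character(0), x = numeric(0), y = numeric(0),
                   z = numeric(0), near_250 = logical(0))
  bt <- data.frame(resno = integer(0), elety = character(0),
                   resid = character(0), x = numeric(0), y = numeric(0),
                   z = numeric(0))
  l$waters <- .df_from_json(l$waters, wt)
  l$ions <- .df_from_json(l$ions, it)
  l$backbone <- .df_from_json(l$backbone, bt)
  l$seq_resno <- as.integer(unlist(l$seq_resno))
  if (!is.null(l$res_250) && length(l$res_250))
    l$res_250 <- list(chain = l$res_250$chain,
                      resno = as.integer(l$res_250$resno))
  else l$res_250 <- NULL
  l$resolution <- if (is.null(l$resolution)) NA_real_ else as.numeric(l$resolution)
  structure(l, class = "template_entry")
}

#' Persist / load a reference database (JSON-lines)
#'
#' The on-disk format is one JSON object per line: a header carrying
#' `schema_version` and the build provenance, then one template entry per
#' line. The round trip is lossless at full double precision.
#'
#' @param db A `reference_db`.
#' @param path File path (conventionally `.jsonl`).
#' @return `save_water_db()` returns `path` invisibly; `load_water_db()` the
#'   restored `reference_db`.
#' @export
save_water_db <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  header <- jsonlite::toJSON(list(schema_version = db$schema_version,
                                  provenance = db$provenance),
                             auto_unbox = TRUE, digits = NA, null = "null")
  lines <- vapply(db$entries, function(e)
    as.character(jsonlite::toJSON(.entry_to_list(e), auto_unbox = TRUE,
                                  digits = NA, null = "null")), "")
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' @rdname save_water_db
#' @export
load_water_db <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty database file: ", path)
  header <- jsonlite::fromJSON(lines[1])
  if (is.null(header$schema_version) ||
      header$schema_version != DB_SCHEMA_VERSION)
    stop("unsupported schema_version ",
         if (is.null(header$schema_version)) "<missing>" else header$schema_version,
         " in ", path, " (expected ", DB_SCHEMA_VERSION, ")")
  entries <- lapply(lines[-1][nzchar(lines[-1])], function(ln)
    .list_to_entry(jsonlite::fromJSON(ln)))
  reference_db(entries, provenance = header$provenance)
}
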