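# Deterministic generator of synthetic homolog families: alpha-helical
# bundles built at ideal backbone geometry (phi = -57, psi = -47), arranged
# around a central pore, with waters planted on the pore axis (internal)
# and outside the bundle surface (external). Families share the ancestor's
# scaffold with controlled sequence identity, backbone jitter, and a random
# whole-member rigid motion, providing ground truth for every stage of the
# pipeline.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Specification of a synthetic homolog family
#'
#' @param seed Integer seed; the generators are fully deterministic given
#'   the spec.
#' @param n_helices Helices in the bundle (default 7, the transmembrane
#'   bundle of the target receptor family).
#' @param helix_length Residues per helix (default 30).
#' @param family_size Members in [generate_family()] (default 6).
#' @param target_identity Percent sequence identity of each member to the
#'   ancestor (default 90).
#' @param n_cavity_waters Waters planted in the central pore (default 8).
#' @param n_surface_waters Waters planted outside the bundle (default 4).
#' @param n_conserved How many cavity waters are conserved across the
#'   family (default: all of them).
#' @param coordinate_noise Per-coordinate Gaussian backbone jitter between
#'   family members, in Angstrom (default 0.3).
#' @param bfactor_range Uniform B-factor range for planted waters
#'   (default 10-40 A^2, inside the curation filter).
#' @param plant_sodium Plant a sodium ion near the designated position-2.50
#'   residue in each member (default `TRUE`).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_helices = 7L, helix_length = 30L,
                         family_size = 6L, target_identity = 90,
                         n_cavity_waters = 8L, n_surface_waters = 4L,
                         n_conserved = n_cavity_waters,
                         coordinate_noise = 0.3,
                         bfactor_range = c(10, 40), plant_sodium = TRUE) {
  stopifnot(target_identity > 0, target_identity <= 100,
            n_cavity_waters >= 0, n_surface_waters >= 0,
            n_conserved >= 0, n_conserved <= n_cavity_waters,
            coordinate_noise >= 0, n_helices >= 2, helix_length >= 5,
            length(bfactor_range) == 2, bfactor_range[1] <= bfactor_range[2])
  structure(list(seed = as.integer(seed), n_helices = as.integer(n_helices),
                 helix_length = as.integer(helix_length),
                 family_size = as.integer(family_size),
                 target_identity = target_identity,
                 n_cavity_waters = as.integer(n_cavity_waters),
                 n_surface_waters = as.integer(n_surface_waters),
                 n_conserved = as.integer(n_conserved),
                 coordinate_noise = coordinate_noise,
                 bfactor_range = bfactor_range,
                 plant_sodium = isTRUE(plant_sodium)),
            class = "fixture_spec")
}

# --- ideal backbone geometry ------------------------------------------------

.place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180; tor <- torsion_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  nxbc <- c(n[2] * bc[3] - n[3] * bc[2],
            n[3] * bc[1] - n[1] * bc[3],
            n[1] * bc[2] - n[2] * bc[1])
  m <- cbind(bc, nxbc, n)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + as.numeric(m %*% d)
}

# Backbone of an ideal alpha-helix of L residues: N, CA, C, O per residue.
.ideal_helix <- function(L, phi = -57, psi = -47, omega = 180) {
  N <- matrix(0, L, 3); CA <- matrix(0, L, 3)
  C <- matrix(0, L, 3); O <- matrix(0, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(111.2 * pi / 180), sin(111.2 * pi / 180), 0)
  for (i in 2:L) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi)
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, omega)
    C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
  }
  for (i in 1:L) O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
  # align the helix axis (principal component of CA) with +z, centred
  cac <- sweep(CA, 2, colMeans(CA))
  ax <- svd(cac)$v[, 1]
  if (sum(ax * (CA[L, ] - CA[1, ])) < 0) ax <- -ax
  z <- c(0, 0, 1)
  v <- c(ax[2] * z[3] - ax[3] * z[2], ax[3] * z[1] - ax[1] * z[3],
         ax[1] * z[2] - ax[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(ax * z)
  R <- if (s < 1e-12) diag(3) * sign(cth) else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  ctr <- colMeans(CA)
  tf <- function(m) sweep(m, 2, ctr) %*% t(R)
  list(N = tf(N), CA = tf(CA), C = tf(C), O = tf(O))
}

.rotz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
.rotx180 <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3, byrow = TRUE)

.random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic helix-bundle structure
#'
#' Builds `n_helices` ideal alpha-helices (backbone N, CA, C, O at standard
#' geometry; rise about 1.5 A per residue, about 100 degrees per residue),
#' arranged antiparallel on a circle wide enough to enclose a central pore,
#' as a single chain A with a random (seeded) sequence. Deterministic for a
#' fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @param entry_id Identifier for the model.
#' @return An `aquahom_structure` with `metadata` fields `seed`,
#'   `bundle_radius`, `z_range`.
#' @export
generate_bundle <- function(spec, entry_id = "SYN00") {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_helices; L <- spec$helix_length
    sequence <- sample(.aa20, n * L, replace = TRUE)
    helix <- .ideal_helix(L)
    Rc <- max(8.6 / (2 * sin(pi / n)), 8.5)
    rows <- list()
    for (h in seq_len(n)) {
      theta <- 360 * (h - 1) / n
      Rz <- .rotz(theta + 25 * h)  # vary azimuthal phase per helix
      flip <- if (h %% 2 == 0) .rotx180 else diag(3)
      shift <- c(Rc * cos(theta * pi / 180), Rc * sin(theta * pi / 180), 0)
      for (i in seq_len(L)) {
        resno <- (h - 1) * L + i
        for (at in c("N", "CA", "C", "O")) {
          p <- as.numeric(helix[[at]][i, ] %*% t(flip) %*% t(Rz)) + shift
          rows[[length(rows) + 1L]] <- c(resno, p)
          names(rows)[length(rows)] <- at
        }
      }
    }
    m <- do.call(rbind, rows)
    elety <- names(rows)
    resno <- as.integer(m[, 1])
    atoms <- data.frame(type = "ATOM", eleno = seq_len(nrow(m)),
                        elety = elety,
                        resid = bio3d::aa123(sequence[resno]),
                        chain = "A", resno = resno, insert = "",
                        x = m[, 2], y = m[, 3], z = m[, 4], o = 1, b = 20,
                        elesy = toupper(substr(elety, 1, 1)))
    # helices must not overlap
    hx <- (resno - 1) %/% L
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    for (h in seq_len(n - 1)) {
      a <- xyz[hx == h - 1, , drop = FALSE]
      b <- xyz[hx == h, , drop = FALSE]
      if (min(.min_dist_each(a, b)) < 2.2) stop("helices overlap")
    }
    structure_model(atoms, entry_id = entry_id,
                    metadata = list(seed = spec$seed, bundle_radius = Rc,
                                    z_range = range(atoms$z)))
  })
}

#' Plant internal (pore) and external (surface) waters into a bundle
#'
#' Cavity waters go on the pore axis, pairwise at least 2.8 A apart and at
#' least 2.6 A from the protein; surface waters at least 4 A outside the
#' bundle. The generator verifies its own labels against the circular
#' variance classifier with a safety margin (internal CV >= 0.7, external
#' <= 0.5), retrying placement a bounded number of times.
#'
#' @param model A bundle from [generate_bundle()].
#' @param spec The [fixture_spec()].
#' @return The model with waters appended (chain A, residue numbers from
#'   1001) and `metadata$water_truth`, a data frame with `resno`, `label`,
#'   `x`, `y`, `z`.
#' @export
plant_waters <- function(model, spec) {
  .with_seed(spec$seed + 7919L, {
    prot <- .coords(protein_atoms(model))
    zr <- model$metadata$z_range
    # stay clear of the bundle ends, where the pore opens and CV drops
    margin <- min(7, (zr[2] - zr[1]) / 4)
    zmin <- zr[1] + margin; zmax <- zr[2] - margin
    n_cav <- spec$n_cavity_waters
    if (n_cav > 0 && (zmax - zmin) < (n_cav - 1) * 3.0)
      stop("cavity too small for ", n_cav, " waters")
    truth <- list()
    wxyz <- list()
    if (n_cav > 0) {
      zs <- seq(zmin, zmax, length.out = max(n_cav, 2))[seq_len(n_cav)]
      for (k in seq_len(n_cav)) {
        placed <- FALSE
        for (attempt in 1:20) {
          pos <- c(runif(2, -0.8, 0.8), zs[k] + runif(1, -0.3, 0.3))
          others <- do.call(rbind, wxyz)
          ok_sep <- is.null(others) ||
            min(.min_dist_each(matrix(pos, 1), others)) >= 2.8
          ok_prot <- min(.min_dist_each(matrix(pos, 1), prot)) >= 2.6
          cv <- suppressWarnings(circular_variance(pos, prot, 10))
          if (ok_sep && ok_prot && cv >= 0.7) { placed <- TRUE; break }
        }
        if (!placed) stop("could not place cavity water ", k,
                          " with CV margin; cavity too small")
        wxyz[[length(wxyz) + 1L]] <- pos
        truth[[length(truth) + 1L]] <- "internal"
      }
    }
    if (spec$n_surface_waters > 0) {
      rad <- max(sqrt(prot[, 1]^2 + prot[, 2]^2)) + 4.5
      for (k in seq_len(spec$n_surface_waters)) {
        placed <- FALSE
        for (attempt in 1:20) {
          th <- runif(1, 0, 2 * pi)
          pos <- c(rad * cos(th), rad * sin(th),
                   runif(1, zmin, zmax))
          others <- do.call(rbind, wxyz)
          ok_sep <- is.null(others) ||
            min(.min_dist_each(matrix(pos, 1), others)) >= 2.8
          ok_dist <- min(.min_dist_each(matrix(pos, 1), prot)) >= 4.0
          cv <- suppressWarnings(circular_variance(pos, prot, 10))
          if (ok_sep && ok_dist && cv <= 0.5) { placed <- TRUE; break }
        }
        if (!placed) stop("could not place surface water ", k,
                          " with CV margin")
        wxyz[[length(wxyz) + 1L]] <- pos
        truth[[length(truth) + 1L]] <- "external"
      }
    }
    n <- length(wxyz)
    out <- model
    if (n) {
      m <- do.call(rbind, wxyz)
      b <- runif(n, spec$bfactor_range[1], spec$bfactor_range[2])
      add <- data.frame(type = "HETATM",
                        eleno = max(out$atoms$eleno) + seq_len(n),
                        elety = "O", resid = "HOH", chain = "A",
                        resno = 1000L + seq_len(n), insert = "",
                        x = m[, 1], y = m[, 2], z = m[, 3], o = 1, b = b,
                        elesy = "O")
      out$atoms <- rbind(out$atoms, add)
      out$metadata$water_truth <- data.frame(resno = 1000L + seq_len(n),
                                             label = unlist(truth),
                                             x = m[, 1], y = m[, 2],
                                             z = m[, 3])
    } else {
      out$metadata$water_truth <- data.frame(resno = integer(0),
                                             label = character(0),
                                             x = numeric(0), y = numeric(0),
                                             z = numeric(0))
    }
    out
  })
}

.mutate_sequence <- function(sequence, target_identity) {
  L <- length(sequence)
  n_mut <- round((1 - target_identity / 100) * L)
  if (n_mut > L) stop("identity target unreachable")
  if (n_mut == 0) return(sequence)
  pos <- sample(L, n_mut)
  for (p in pos) sequence[p] <- sample(setdiff(.aa20, sequence[p]), 1)
  sequence
}

#' Generate a synthetic homolog family with conserved-water ground truth
#'
#' The ancestor bundle (with planted waters) is mutated to the target
#' sequence identity per member, its backbone jittered by
#' `coordinate_noise` (per-coordinate Gaussian), and a random whole-member
#' rigid motion applied so superposition is non-trivial. The first
#' `n_conserved` cavity waters are copied (jittered) into every member;
#' remaining cavity waters are displaced per member; surface waters are
#' jittered. Each member optionally carries a sodium ion near its
#' designated position-2.50 residue. Water B-factors are resampled per
#' member. Fully deterministic for a fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @return List with `ancestor` (the planted ancestor model), `members` (a
#'   list of `list(model, metadata, motion, conserved_truth)` where
#'   `conserved_truth` holds the conserved-water positions in the member
#'   frame and `motion` the applied rigid transform), `metadata` (combined
#'   sidecar table), and `spec`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), spec$family_size >= 2)
  anc <- plant_waters(generate_bundle(spec, entry_id = "ANC00"), spec)
  truth <- anc$metadata$water_truth
  cav <- truth[truth$label == "internal", , drop = FALSE]
  sur <- truth[truth$label == "external", , drop = FALSE]
  n_cons <- min(spec$n_conserved, nrow(cav))
  anc_seq <- suppressWarnings(bio3d::aa321(
    .chain_residues(anc, "A")$resid))
  res250 <- spec$helix_length + spec$helix_length %/% 2L
  members <- list()
  meta_rows <- list()
  .with_seed(spec$seed + 104729L, {
    for (i in seq_len(spec$family_size)) {
      id <- sprintf("SYN%02d", i)
      m <- anc
      m$entry_id <- id
      prot_sel <- .is_protein_resid(m$atoms$resid)
      # sequence: mutate to target identity (coordinates are backbone-only)
      seq_i <- .mutate_sequence(anc_seq, spec$target_identity)
      m$atoms$resid[prot_sel] <- bio3d::aa123(seq_i[m$atoms$resno[prot_sel]])
      # backbone jitter
      nz <- sum(prot_sel)
      m$atoms$x[prot_sel] <- m$atoms$x[prot_sel] + rnorm(nz, 0, spec$coordinate_noise)
      m$atoms$y[prot_sel] <- m$atoms$y[prot_sel] + rnorm(nz, 0, spec$coordinate_noise)
      m$atoms$z[prot_sel] <- m$atoms$z[prot_sel] + rnorm(nz, 0, spec$coordinate_noise)
      # waters: conserved jittered in place, member-specific displaced
      wat_sel <- which(.is_water_resid(m$atoms$resid))
      wresno <- m$atoms$resno[wat_sel]
      jit <- function(n) rnorm(n, 0, spec$coordinate_noise)
      for (k in seq_along(wat_sel)) {
        rn <- wresno[k]
        row <- wat_sel[k]
        if (rn %in% cav$resno && match(rn, cav$resno) > n_cons) {
          # member-specific pore water: push along the axis
          m$atoms$z[row] <- m$atoms$z[row] + runif(1, -1.2, 1.2)
          m$atoms$x[row] <- m$atoms$x[row] + runif(1, -0.6, 0.6)
          m$atoms$y[row] <- m$atoms$y[row] + runif(1, -0.6, 0.6)
        } else {
          m$atoms$x[row] <- m$atoms$x[row] + jit(1)
          m$atoms$y[row] <- m$atoms$y[row] + jit(1)
          m$atoms$z[row] <- m$atoms$z[row] + jit(1)
        }
      }
      m$atoms$b[wat_sel] <- runif(length(wat_sel), spec$bfactor_range[1],
                                  spec$bfactor_range[2])
      # sodium near the designated 2.50 residue
      if (spec$plant_sodium) {
        ca <- m$atoms[m$atoms$resno == res250 & m$atoms$elety == "CA", ]
        axis_pt <- c(0, 0, ca$z[1])
        dir <- axis_pt - c(ca$x[1], ca$y[1], ca$z[1])
        dir <- dir / sqrt(sum(dir^2))
        pos <- c(ca$x[1], ca$y[1], ca$z[1]) + 5 * dir
        ion <- data.frame(type = "HETATM", eleno = max(m$atoms$eleno) + 1L,
                          elety = "NA", resid = "NA", chain = "A",
                          resno = 2001L, insert = "",
                          x = pos[1], y = pos[2], z = pos[3], o = 1, b = 15,
                          elesy = "NA")
        m$atoms <- rbind(m$atoms, ion)
      }
      # whole-member rigid motion
      R <- .random_rotation()
      tr <- runif(3, -20, 20)
      xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
      xyz <- sweep(xyz, 2, tr, "+")
      m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
      m$resolution <- round(runif(1, 1.9, 2.7), 2)
      m$metadata$seed <- spec$seed
      m$metadata$water_truth <- NULL
      cons_rows <- match(cav$resno[seq_len(n_cons)], m$atoms$resno[wat_sel])
      cons_xyz <- xyz[wat_sel[cons_rows], , drop = FALSE]
      state <- if (i %% 2 == 1) "inactive" else "active"
      meta_rows[[i]] <- data.frame(entry_id = id, chain = "A",
                                   receptor_name = sprintf("RCPT%d_SYN", i),
                                   state = state,
                                   resolution = m$resolution,
                                   res_250 = sprintf("A:%d", res250))
      members[[i]] <- list(model = m, metadata = meta_rows[[i]],
                           motion = list(rotation = R, translation = tr),
                           conserved_truth = cons_xyz)
    }
  })
  list(ancestor = anc, members = members,
       metadata = do.call(rbind, meta_rows), spec = spec)
}

#' Build a reference database from a synthetic family
#'
#' Convenience wrapper over [build_reference_db()] for the output of
#' [generate_family()].
#'
#' @param family Output of [generate_family()].
#' @inheritParams build_reference_db
#' @return A `reference_db`.
#' @export
family_reference_db <- function(family, bfactor_max = 45, cv_threshold = 0.6,
                                cv_radius = 10) {
  build_reference_db(lapply(family$members, `[[`, "model"), family$metadata,
                     bfactor_max = bfactor_max, cv_threshold = cv_threshold,
                     cv_radius = cv_radius)
}
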