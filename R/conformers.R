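# Synthetic conformer generation: rebuild Cartesian coordinates from template
# internal coordinates with chosen rotatable dihedrals, emulating the in-class
# conformational heterogeneity of flexible fragments (all in-class variation
# is rotation about dihedral angles on a fixed covalent graph).

# Evaluate the RNG-dependent expression with a locally seeded, restored RNG.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct a fragment object
#'
#' @param label Class code (3- or 6-letter).
#' @param atom_names Character vector of atom names.
#' @param elements Character vector of element symbols.
#' @param coords Numeric n x 3 coordinate matrix (Angstrom).
#' @param res Integer residue slot per atom (1 or 2).
#' @param source_id Free-text provenance tag.
#' @param complete Logical: TRUE once hydrogens/termini have been built.
#' @return An object of class `fragment`.
#' @export
fragment <- function(label, atom_names, elements, coords, res = 1L,
                     source_id = "", complete = TRUE) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(atom_names),
            length(elements) == length(atom_names))
  if (!all(is.finite(coords))) stop("fragment: non-finite coordinates")
  structure(list(label = toupper(label), atom_names = as.character(atom_names),
                 elements = as.character(elements),
                 res = rep_len(as.integer(res), length(atom_names)),
                 coords = unname(coords), source_id = source_id,
                 n_residues = if (nchar(label) == 6) 2L else 1L,
                 complete = isTRUE(complete)),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment %s: %d atoms%s%s>\n", x$label, nrow(x$coords),
              if (x$complete) "" else " (heavy-only)",
              if (nzchar(x$source_id)) paste0(" from ", x$source_id) else ""))
  invisible(x)
}

#' Validate fragment invariants
#'
#' Checks atom count against the class template (for completed fragments),
#' coordinate finiteness and a 0.5 A minimum inter-atomic separation.
#'
#' @param frag A `fragment`.
#' @return TRUE invisibly; stops with a message on violation.
#' @export
validate_fragment <- function(frag) {
  stopifnot(inherits(frag, "fragment"))
  if (!all(is.finite(frag$coords))) stop("non-finite coordinates")
  if (frag$complete && nrow(frag$coords) != atom_count(frag$label))
    stop(sprintf("atom count %d does not match template count %d for %s",
                 nrow(frag$coords), atom_count(frag$label), frag$label))
  if (nrow(frag$coords) > 1) {
    dmin <- min(stats::dist(frag$coords))
    if (dmin < 0.5)
      stop(sprintf("atoms closer than 0.5 A (min %.3f)", dmin))
  }
  invisible(TRUE)
}

.template_for_label <- function(label) {
  label <- toupper(label)
  if (nchar(label) == 6)
    dipeptide_template(substr(label, 1, 3), substr(label, 4, 6))
  else get_template(label)
}

# Dihedral variable names a caller must (or may) assign for a template.
#' Names of the rotatable dihedrals of a class
#' @param label 3- or 6-letter class code.
#' @return Character vector of dihedral names (psi/phi/chi style).
#' @export
rotatable_dihedral_names <- function(label) {
  tpl <- .template_for_label(label)
  vars <- unique(stats::na.omit(tpl$atoms$var))
  setdiff(vars, names(.PRO_RING))
}

# Build Cartesian coordinates from the template Z-matrix.
.build_coords <- function(tpl, dihedrals) {
  at <- tpl$atoms
  need <- setdiff(unique(at$var[!is.na(at$var) & at$var != "NA"]),
                  names(.PRO_RING))
  miss <- setdiff(need, names(dihedrals))
  if (length(miss))
    stop("missing dihedral assignment(s): ", paste(miss, collapse = ", "))
  vals <- c(as.list(dihedrals), as.list(.PRO_RING))
  n <- nrow(at)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (is.na(at$ip[i])) {                        # root
      xyz[i, ] <- c(0, 0, 0)
    } else if (is.na(at$ia[i])) {                 # second atom
      xyz[i, ] <- xyz[at$ip[i], ] + c(at$r[i], 0, 0)
    } else {
      p1 <- xyz[at$ip[i], ]; p2 <- xyz[at$ia[i], ]
      if (is.na(at$id[i])) {                      # third atom: arbitrary plane
        p3 <- p2 + c(0, 0, 1)
        phi <- 0
      } else {
        p3 <- xyz[at$id[i], ]
        phi <- if (!is.na(at$var[i]) && at$var[i] != "NA")
          vals[[at$var[i]]] + at$off[i] else at$dih[i]
      }
      xyz[i, ] <- place_atom(p1, p2, p3, at$r[i], at$th[i], phi)
    }
  }
  xyz
}

#' Build one conformer from a template and dihedral assignment
#'
#' Reconstructs Cartesian coordinates with the template's ideal bond lengths
#' and angles and the requested rotatable dihedrals, then applies a steric
#' clash check (no non-bonded atom pair closer than `clash_tol`).
#'
#' @param template A `residue_template`.
#' @param dihedrals Named numeric vector/list of dihedral angles (degrees)
#'   covering `rotatable_dihedral_names()` of the class.
#' @param source_id Provenance tag stored on the fragment.
#' @param clash_tol Minimum allowed non-bonded distance (default 1.0 A).
#' @return A completed `fragment`.
#' @export
build_conformer <- function(template, dihedrals, source_id = "synthetic",
                            clash_tol = 1.0) {
  stopifnot(inherits(template, "residue_template"))
  xyz <- .build_coords(template, dihedrals)
  # non-bonded clash check: exclude 1-2 and 1-3 pairs
  n <- nrow(xyz)
  adj <- matrix(FALSE, n, n)
  adj[template$bonds] <- TRUE
  adj <- adj | t(adj)
  near <- adj %*% adj > 0          # 1-3 (and 1-2 via diagonal paths)
  excl <- adj | near | diag(TRUE, n)
  D <- as.matrix(stats::dist(xyz))
  viol <- D < clash_tol & !excl
  if (any(viol)) {
    ij <- which(viol, arr.ind = TRUE)[1, ]
    stop(sprintf("steric clash: %s-%s at %.2f A",
                 template$atoms$name[ij[1]], template$atoms$name[ij[2]],
                 D[ij[1], ij[2]]), call. = FALSE)
  }
  fragment(template$code, template$atoms$name, template$atoms$elem, xyz,
           res = template$atoms$res, source_id = source_id, complete = TRUE)
}

#' Read a named rotatable dihedral back from fragment coordinates
#' @param frag A completed `fragment`.
#' @param name Dihedral name as in `rotatable_dihedral_names()`.
#' @return Angle in degrees.
#' @export
measure_dihedral <- function(frag, name) {
  tpl <- .template_for_label(frag$label)
  tu <- tpl$rotatable_dihedrals[[name]]
  if (is.null(tu)) stop("unknown dihedral: ", name)
  key_f <- .atom_key(frag$atom_names, frag$res)
  ii <- match(.atom_key(tu[, 1], as.integer(tu[, 2])), key_f)
  if (anyNA(ii)) stop("fragment lacks atoms for dihedral ", name)
  torsion_angle(frag$coords[ii[1], ], frag$coords[ii[2], ],
                frag$coords[ii[3], ], frag$coords[ii[4], ])
}

#' Specification of a synthetic conformer ensemble
#'
#' @param label Class code (3- or 6-letter).
#' @param n_conformers Number of conformers (>= 1).
#' @param seed Integer RNG seed.
#' @param mode `"uniform_dihedrals"` (every rotatable sampled over its full
#'   plausible range) or `"k_modes"` (dihedrals drawn around per-mode centers,
#'   giving clusterable multi-modal ensembles).
#' @param n_modes,spread For `k_modes`: number of modes and Gaussian spread
#'   (degrees) around each mode's dihedral centers.
#' @param centers Optional list (length `n_modes`) of named center vectors;
#'   drawn at random (from the ensemble seed) when omitted.
#' @return An object of class `conformer_spec`.
#' @export
conformer_spec <- function(label, n_conformers, seed = 1L,
                           mode = c("uniform_dihedrals", "k_modes"),
                           n_modes = 2L, spread = 10, centers = NULL) {
  mode <- match.arg(mode)
  if (n_conformers < 1) stop("n_conformers must be >= 1")
  if (spread < 0) stop("spread must be >= 0")
  structure(list(label = toupper(label), n_conformers = as.integer(n_conformers),
                 seed = as.integer(seed), mode = mode,
                 n_modes = as.integer(n_modes), spread = spread,
                 centers = centers),
            class = "conformer_spec")
}

# Sampling ranges: backbone psi/phi over broad plausible ranges (limits
# clashes), side-chain chi over the full circle.
.sample_dihedrals <- function(vars) {
  out <- numeric(length(vars)); names(out) <- vars
  for (v in vars) {
    out[[v]] <- if (grepl("^phi", v)) stats::runif(1, -160, -40)
    else if (grepl("^psi", v)) stats::runif(1, -180, 180)
    else stats::runif(1, -180, 180)
  }
  out
}

#' Generate a synthetic conformer ensemble for one class
#'
#' Conformers share the template's exact bond lengths and angles and differ
#' only in rotatable dihedrals. Clashing samples are redrawn (up to 100
#' retries each). Deterministic given the spec seed.
#'
#' @param spec A `conformer_spec`.
#' @return List of completed `fragment` objects.
#' @export
generate_class_ensemble <- function(spec) {
  stopifnot(inherits(spec, "conformer_spec"))
  tpl <- .template_for_label(spec$label)
  vars <- rotatable_dihedral_names(spec$label)
  .with_seed(spec$seed, {
    centers <- spec$centers
    if (spec$mode == "k_modes" && is.null(centers)) {
      # draw mode centers that themselves build clash-free, so that spread
      # noise around them cannot exhaust the retry budget
      centers <- lapply(seq_len(spec$n_modes), function(m) {
        for (try in seq_len(50)) {
          ctr <- .sample_dihedrals(vars)
          ok <- tryCatch({ build_conformer(tpl, ctr); TRUE },
                         error = function(e) FALSE)
          if (ok) return(ctr)
        }
        stop("could not find a clash-free mode center for ", spec$label)
      })
    }
    out <- vector("list", spec$n_conformers)
    for (k in seq_len(spec$n_conformers)) {
      frag <- NULL
      for (try in seq_len(100)) {
        dih <- if (spec$mode == "uniform_dihedrals") .sample_dihedrals(vars)
        else {
          m <- ((k - 1) %% spec$n_modes) + 1L
          ctr <- centers[[m]]
          v <- stats::rnorm(length(vars), unlist(ctr)[vars], spec$spread)
          names(v) <- vars
          v
        }
        frag <- tryCatch(
          build_conformer(tpl, dih,
                          source_id = sprintf("%s/synth%04d", spec$label, k)),
          error = function(e) NULL)
        if (!is.null(frag)) break
      }
      if (is.null(frag))
        stop("unresolvable steric clash after 100 retries for ", spec$label)
      out[[k]] <- frag
    }
    out
  })
}

#' Generate a balanced synthetic dataset store
#'
#' Builds `n_per_class` conformers for every requested class and writes their
#' raw coordinates (heterogeneous collection `"coord"`), labels and template
#' topology into an HDF5 store ready for featurization/splitting/training.
#'
#' @param classes Character vector of 3- or 6-letter class codes.
#' @param n_per_class Conformers per class.
#' @param seed Integer seed; per-class streams are derived from it.
#' @param path Output HDF5 file path.
#' @param mode,n_modes,spread Passed to [conformer_spec()].
#' @return A `fragment_store` handle (see [open_store()]).
#' @export
generate_dataset <- function(classes, n_per_class, seed = 1L,
                             path = tempfile(fileext = ".h5"),
                             mode = "uniform_dihedrals", n_modes = 2L,
                             spread = 10) {
  classes <- toupper(classes)
  if (!length(classes)) stop("no classes requested")
  frags <- list()
  for (ci in seq_along(classes)) {
    sp <- conformer_spec(classes[ci], n_per_class,
                         seed = (seed * 131L + ci) %% .Machine$integer.max,
                         mode = mode, n_modes = n_modes, spread = spread)
    frags <- c(frags, generate_class_ensemble(sp))
  }
  store <- create_store(path)
  write_fragments(store, frags)
  store
}
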