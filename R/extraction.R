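# Harvesting single-residue and dipeptide fragments from PDB structures and
# normalizing them to the completed template form (hydrogens and terminal
# atoms rebuilt from template internal coordinates anchored on the observed
# heavy atoms; heavy-atom coordinates are never modified).

.ATOM_ALIASES <- list(ILE = c(CD = "CD1"))
.TERMINAL_O_ALIASES <- c(OT1 = "O", O1 = "O", OT2 = "OXT", O2 = "OXT")

#' Parse a PDB structure
#'
#' Reads PDB-format content (a file path or raw text) into a simple model:
#' chains in file order, each a list of residues with their atom records.
#' Alternate locations are resolved by keeping the blank/"A" location (ties
#' broken by the highest occupancy); hydrogens are retained here and
#' discarded later during completion.
#'
#' @param pdb Path to a PDB file, or a character string/vector of PDB text.
#' @return An object of class `structure_model`: list of chains, each a list
#'   of residue records (`resid`, `resno`, `insert`, `atoms` data frame with
#'   name/elem/x/y/z).
#' @export
parse_structure <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || !file.exists(pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1) pdb else strsplit(pdb, "\n")[[1]], path)
    on.exit(unlink(path))
  }
  pd <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                 error = function(e)
                   stop("unreadable PDB input: ", conditionMessage(e),
                        call. = FALSE))
  at <- pd$atom[pd$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in input", call. = FALSE)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc resolution per (chain, residue, atom name)
  keykey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  pref <- ifelse(at$alt == "", 0L, ifelse(at$alt == "A", 1L, 2L))
  ord <- order(match(keykey, unique(keykey)), pref, -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "|")), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "|"),
                       unique(keykey <- paste(at$chain, at$resno, at$insert,
                                              sep = "|")))), , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[0-9']", "", at$elety[bad]), 1, 1)
  elem <- toupper(elem)
  chains <- list()
  for (ch in unique(at$chain)) {
    rows <- at[at$chain == ch, , drop = FALSE]
    rkey <- paste(rows$resno, rows$insert, sep = "|")
    residues <- lapply(unique(rkey), function(k) {
      rr <- rows[rkey == k, , drop = FALSE]
      nm <- rr$elety
      # canonical atom-name aliases
      al <- .ATOM_ALIASES[[rr$resid[1]]]
      if (!is.null(al)) {
        hit <- nm %in% names(al)
        nm[hit] <- al[nm[hit]]
      }
      hit <- nm %in% names(.TERMINAL_O_ALIASES)
      nm[hit] <- .TERMINAL_O_ALIASES[nm[hit]]
      list(resid = rr$resid[1], resno = rr$resno[1], insert = rr$insert[1],
           atoms = data.frame(name = nm,
                              elem = elem[match(rownames(rr), rownames(at))],
                              x = rr$x, y = rr$y, z = rr$z,
                              stringsAsFactors = FALSE))
    })
    chains[[as.character(ch)]] <- residues
  }
  structure(list(chains = chains), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model: %d chain(s), %d residues>\n",
              length(x$chains), sum(lengths(x$chains))))
  invisible(x)
}

# Heavy-atom completeness check against the template; returns NULL if the
# residue cannot provide the required heavy set, else the matched atom table.
.match_heavy <- function(res_atoms, code, slot, tpl) {
  ta <- tpl$atoms
  req <- ta$name[ta$heavy & ta$res == slot]
  opt <- intersect("OXT", req)
  req <- setdiff(req, opt)
  have <- res_atoms[res_atoms$elem != "H", , drop = FALSE]
  have <- have[!duplicated(have$name), , drop = FALSE]
  extra <- setdiff(have$name, c(req, opt))
  missing <- setdiff(req, have$name)
  if (length(missing) || length(extra))
    return(list(ok = FALSE, missing = missing, extra = extra))
  list(ok = TRUE, atoms = have[have$name %in% c(req, opt), , drop = FALSE])
}

.raw_fragment <- function(label, parts, source_id) {
  nm <- unlist(lapply(parts, function(p) p$atoms$name))
  el <- unlist(lapply(parts, function(p) p$atoms$elem))
  rs <- unlist(lapply(seq_along(parts),
                      function(i) rep(i, nrow(parts[[i]]$atoms))))
  co <- do.call(rbind, lapply(parts, function(p)
    as.matrix(p$atoms[, c("x", "y", "z")])))
  fragment(label, nm, el, co, res = rs, source_id = source_id,
           complete = FALSE)
}

#' Extract single-residue fragments from a parsed model
#'
#' One heavy-atom fragment per standard residue whose backbone and side-chain
#' heavy atoms are all present; non-standard or incomplete residues are
#' skipped and counted (attribute `"skipped"`).
#'
#' @param model A `structure_model`.
#' @param source_id Provenance prefix for the fragments.
#' @return List of heavy-only `fragment` objects (pass to
#'   [complete_fragment()]).
#' @export
extract_single_fragments <- function(model, source_id = "pdb") {
  stopifnot(inherits(model, "structure_model"))
  out <- list()
  skipped <- 0L
  for (ch in names(model$chains)) {
    for (res in model$chains[[ch]]) {
      if (!res$resid %in% .AA3) { skipped <- skipped + 1L; next }
      tpl <- get_template(res$resid)
      m <- .match_heavy(res$atoms, res$resid, 1L, tpl)
      if (!m$ok) { skipped <- skipped + 1L; next }
      out[[length(out) + 1L]] <- .raw_fragment(
        res$resid, list(list(atoms = m$atoms)),
        sprintf("%s/%s%d%s", source_id, ch, res$resno, res$insert))
    }
  }
  attr(out, "skipped") <- skipped
  out
}

# Covalent continuity: peptide C(i)-N(i+1) bond length criterion.
.peptide_continuous <- function(res1, res2, max_cn = 1.7) {
  c1 <- res1$atoms[res1$atoms$name == "C", c("x", "y", "z")]
  n2 <- res2$atoms[res2$atoms$name == "N", c("x", "y", "z")]
  if (nrow(c1) != 1 || nrow(n2) != 1) return(FALSE)
  sqrt(sum((as.numeric(c1) - as.numeric(n2))^2)) <= max_cn
}

#' Extract consecutive dipeptide fragments from a parsed model
#'
#' One heavy-atom fragment per residue pair that is consecutive in a chain
#' and covalently continuous (peptide C-N distance <= `max_cn`); the label is
#' the 6-letter concatenation in N-to-C order. Chain breaks terminate
#' pairing.
#'
#' @param model A `structure_model`.
#' @param max_cn Peptide-bond distance criterion (default 1.7 A).
#' @param source_id Provenance prefix.
#' @return List of heavy-only `fragment` objects; attribute `"skipped"`
#'   counts rejected pairs.
#' @export
extract_dual_fragments <- function(model, max_cn = 1.7, source_id = "pdb") {
  stopifnot(inherits(model, "structure_model"))
  out <- list()
  skipped <- 0L
  for (ch in names(model$chains)) {
    rs <- model$chains[[ch]]
    if (length(rs) < 2) next
    for (i in seq_len(length(rs) - 1L)) {
      r1 <- rs[[i]]; r2 <- rs[[i + 1L]]
      if (!r1$resid %in% .AA3 || !r2$resid %in% .AA3) { skipped <- skipped + 1L; next }
      if (!.peptide_continuous(r1, r2, max_cn)) { skipped <- skipped + 1L; next }
      label <- paste0(r1$resid, r2$resid)
      tpl <- dipeptide_template(r1$resid, r2$resid)
      m1 <- .match_heavy(r1$atoms, r1$resid, 1L, tpl)
      m2 <- .match_heavy(r2$atoms, r2$resid, 2L, tpl)
      if (!m1$ok || !m2$ok) { skipped <- skipped + 1L; next }
      out[[length(out) + 1L]] <- .raw_fragment(
        label, list(list(atoms = m1$atoms), list(atoms = m2$atoms)),
        sprintf("%s/%s%d%s+", source_id, ch, r1$resno, r1$insert))
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Complete a heavy-atom fragment to its template form
#'
#' Adds hydrogens and missing terminal atoms by evaluating the template
#' internal coordinates anchored on the observed heavy atoms. Heavy-atom
#' coordinates pass through bit-identically; input hydrogens are discarded
#' and rebuilt. Idempotent on already-complete fragments.
#'
#' @param raw A `fragment` (heavy atoms, or already completed).
#' @return A completed `fragment` in template atom order.
#' @export
complete_fragment <- function(raw) {
  stopifnot(inherits(raw, "fragment"))
  tpl <- .template_for_label(raw$label)
  ta <- tpl$atoms
  keep <- raw$elements != "H"
  key_raw <- .atom_key(raw$atom_names[keep], raw$res[keep])
  key_tpl <- .atom_key(ta$name, ta$res)
  heavy_req <- key_tpl[ta$heavy & !(ta$name == "OXT")]
  missing <- setdiff(heavy_req, key_raw)
  extra <- setdiff(key_raw, key_tpl[ta$heavy])
  if (length(missing) || length(extra))
    stop(sprintf("heavy-atom mismatch for %s:%s%s", raw$label,
                 if (length(missing)) paste0(" missing ", paste(missing, collapse = ",")) else "",
                 if (length(extra)) paste0(" extra ", paste(extra, collapse = ","))  else ""),
         call. = FALSE)
  xyz <- matrix(NA_real_, nrow(ta), 3)
  hit <- match(key_tpl, key_raw)
  src <- which(!is.na(hit))
  xyz[src, ] <- raw$coords[keep, , drop = FALSE][hit[src], , drop = FALSE]
  for (i in which(is.na(hit))) {
    ip <- ta$ip[i]; ia <- ta$ia[i]; id <- ta$id[i]
    p3 <- if (is.na(id)) xyz[ia, ] + c(0, 0, 1) else xyz[id, ]
    phi <- if (is.na(id)) 0
    else if (!is.na(ta$var[i]) && ta$var[i] != "NA") {
      if (ta$var[i] %in% names(.PRO_RING)) .PRO_RING[[ta$var[i]]] + ta$off[i]
      else stop("cannot rebuild atom ", ta$name[i],
                " without observed anchors", call. = FALSE)
    } else ta$dih[i]
    xyz[i, ] <- place_atom(xyz[ip, ], xyz[ia, ], p3, ta$r[i], ta$th[i], phi)
  }
  fragment(raw$label, ta$name, ta$elem, xyz, res = ta$res,
           source_id = raw$source_id, complete = TRUE)
}

#' Write a fragment as PDB-format text
#'
#' Minimal ATOM-record writer (one chain, sequential residue numbers), mainly
#' for interoperability checks and round-trip tests.
#'
#' @param frag A `fragment`.
#' @param path Optional output file; when `NULL` the text is returned.
#' @param chain Chain identifier.
#' @param resno_start First residue number.
#' @param heavy_only Drop hydrogens on output.
#' @return Character vector of PDB lines (invisibly if written to `path`).
#' @export
write_fragment_pdb <- function(frag, path = NULL, chain = "A",
                               resno_start = 1L, heavy_only = FALSE) {
  stopifnot(inherits(frag, "fragment"))
  codes <- if (frag$n_residues == 2L)
    c(substr(frag$label, 1, 3), substr(frag$label, 4, 6)) else frag$label
  sel <- if (heavy_only) frag$elements != "H" else rep(TRUE, length(frag$elements))
  idx <- which(sel)
  lines <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    nm <- frag$atom_names[i]
    nm4 <- if (nchar(nm) < 4) paste0(" ", formatC(nm, width = -3)) else nm
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            k, nm4, codes[frag$res[i]], chain,
            resno_start + frag$res[i] - 1L,
            frag$coords[i, 1], frag$coords[i, 2], frag$coords[i, 3],
            frag$elements[i])
  }, "")
  lines <- c(lines, "END")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
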