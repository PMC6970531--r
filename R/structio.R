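## structio: coordinate I/O, residue-range selections, built-in domain table

#' Construct an atom model
#'
#' An `atom_model` wraps an atom table (one row per atom, in file order) with
#' its provenance. The columns follow the conventions of crystallographic
#' atom records: `chain`, `resno` (author numbering), `insert` (insertion
#' code or `NA`), `resid` (3-letter residue name), `elety` (atom name),
#' `elesy` (element symbol), `x`, `y`, `z` (Cartesian coordinates,
#' Angstrom), `o` (occupancy), `alt` (alternate-location id or `NA`).
#'
#' @param atoms data.frame with at least the columns listed above.
#' @param source_id file name or accession the model came from.
#' @param model_number model number within the source file.
#' @return An object of class `atom_model`.
#' @export
atom_model <- function(atoms, source_id = "", model_number = 1L) {
  needed <- c("chain", "resno", "insert", "resid", "elety", "elesy",
              "x", "y", "z", "o", "alt")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stopf("atom table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("atom coordinates contain non-finite values")
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 source_id = as.character(source_id),
                 model_number = as.integer(model_number)),
            class = "atom_model")
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("<atom_model> %d atoms, %d chain(s) [%s], source: %s (model %d)\n",
              n_atoms(x), length(unique(x$atoms$chain)),
              paste(sort(unique(x$atoms$chain)), collapse = ","),
              if (nzchar(x$source_id)) x$source_id else "<in memory>",
              x$model_number))
  invisible(x)
}

#' Number of atoms in a model
#' @param model an `atom_model`.
#' @return integer count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Coordinate matrix of a model
#' @param model an `atom_model`.
#' @return N x 3 numeric matrix (Angstrom).
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Replace the coordinates of a model
#' @param model an `atom_model`.
#' @param xyz N x 3 matrix.
#' @return the modified model.
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == n_atoms(model), ncol(xyz) == 3)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

## resolve alternate locations: keep highest occupancy, ties -> first seen
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert),
               atoms$elety, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ## order by key then decreasing occupancy then file order; keep first per key
  ord <- order(key, -atoms$o, seq_len(nrow(atoms)))
  keep_rows <- ord[!duplicated(key[ord])]
  atoms[sort(keep_rows), , drop = FALSE]
}

#' Read an atomic coordinate file
#'
#' Reads PDB (v3.3) or mmCIF/PDBx files via the bio3d parsers. Hetero atoms
#' (metals, nucleic acids, ligands) are retained. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by file order).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension;
#'   `.cif`/`.mmcif` are mmCIF, anything else PDB).
#' @param model_number which model to return from a multi-model file.
#' @return An [atom_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model_number = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif")
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE,
                                       rm.alt = FALSE))
    else
      bio3d::read.pdb(path, multi = model_number > 1L, verbose = FALSE,
                      rm.alt = FALSE),
    error = function(e) stopf("could not parse %s file '%s': %s",
                              format, path, conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stopf("empty model in '%s'", path)
  if (model_number > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_number)
      stopf("'%s' has no model %d", path, model_number)
    xyz <- matrix(pdb$xyz[model_number, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at <- at[, c("chain", "resno", "insert", "resid", "elety", "elesy",
               "x", "y", "z", "o", "alt")]
  at$o[is.na(at$o)] <- 1
  at <- resolve_altloc(at)
  atom_model(at, source_id = basename(path), model_number = model_number)
}

#' Write a model to a PDB file
#'
#' @param model an [atom_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  if (nrow(at) == 0L) stopf("refusing to write an empty model")
  is_het <- !(at$resid %in% bio3d::aa.table$aa3) &
    !(at$resid %in% c("DA", "DC", "DG", "DT", "A", "C", "G", "U"))
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path,
    type = ifelse(is_het, "HETATM", "ATOM"),
    xyz = as.vector(t(coords(model))),
    resno = at$resno, resid = at$resid, chain = at$chain,
    insert = ifelse(is.na(at$insert), "", at$insert),
    elety = at$elety, elesy = at$elesy,
    alt = ifelse(is.na(at$alt), "", at$alt),
    o = at$o, b = rep(0, nrow(at))))
  invisible(path)
}

## ---- selections -------------------------------------------------------

normalize_ranges <- function(rng) {
  ## rng: 2-column matrix of inclusive [start, end]; merge overlapping/adjacent
  if (nrow(rng) == 0L) return(rng)
  rng <- rng[order(rng[, 1], rng[, 2]), , drop = FALSE]
  out <- rng[1, , drop = FALSE]
  if (nrow(rng) > 1L) for (i in 2:nrow(rng)) {
    last <- nrow(out)
    if (rng[i, 1] <= out[last, 2] + 1L) {
      out[last, 2] <- max(out[last, 2], rng[i, 2])
    } else out <- rbind(out, rng[i, , drop = FALSE])
  }
  out
}

new_selection <- function(terms, atom_name = NULL) {
  ## terms: named list chain -> 2-col integer matrix of ranges
  for (ch in names(terms)) {
    rng <- terms[[ch]]
    if (any(rng[, 1] > rng[, 2]))
      stopf("selection range with start > end on chain %s", ch)
    terms[[ch]] <- normalize_ranges(rng)
  }
  terms <- terms[order(names(terms))]
  structure(list(terms = terms, atom_name = atom_name), class = "selection")
}

#' Parse a residue-range selection expression
#'
#' Grammar: `CHAIN:RANGE(,RANGE)*` with chains separated by `;`, where
#' `RANGE` is `N` or `N-M` (author numbering, inclusive on both ends), with
#' an optional trailing `@NAME` atom-name filter, e.g.
#' `"C:787-931,1135-1150,1216-1317"` or `"A:1-100@CA"`. Ranges are
#' normalized: sorted, merged, non-overlapping.
#'
#' @param text selection expression.
#' @return A `selection` object.
#' @export
parse_selection <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("[[:space:]]", "", text)
  atom_name <- NULL
  if (grepl("@", txt, fixed = TRUE)) {
    parts <- strsplit(txt, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[2]))
      stopf("malformed atom-name filter in '%s'", text)
    atom_name <- parts[2]
    txt <- parts[1]
  }
  if (!nzchar(txt)) stopf("empty selection expression")
  terms <- list()
  for (chunk in strsplit(txt, ";", fixed = TRUE)[[1]]) {
    if (!grepl(":", chunk, fixed = TRUE))
      stopf("expected CHAIN:RANGES, got '%s'", chunk)
    cp <- regmatches(chunk, regexpr(":", chunk, fixed = TRUE), invert = TRUE)[[1]]
    chain <- cp[1]; rngtxt <- cp[2]
    if (!nzchar(chain)) stopf("missing chain id in '%s'", chunk)
    rows <- lapply(strsplit(rngtxt, ",", fixed = TRUE)[[1]], function(r) {
      if (grepl("^-?[0-9]+$", r)) {
        n <- as.integer(r); c(n, n)
      } else if (grepl("^(-?[0-9]+)-(-?[0-9]+)$", r)) {
        m <- regmatches(r, regexec("^(-?[0-9]+)-(-?[0-9]+)$", r))[[1]]
        a <- as.integer(m[2]); b <- as.integer(m[3])
        if (a > b) stopf("range start %d > end %d in '%s'", a, b, r)
        c(a, b)
      } else stopf("malformed range token '%s' in '%s'", r, text)
    })
    rng <- do.call(rbind, rows)
    terms[[chain]] <- if (is.null(terms[[chain]])) rng else rbind(terms[[chain]], rng)
  }
  new_selection(terms, atom_name)
}

#' @export
print.selection <- function(x, ...) {
  cat("<selection>", selection_to_text(x), "\n")
  invisible(x)
}

#' Render a selection back to its text form
#' @param sel a `selection`.
#' @return character scalar in [parse_selection()] grammar.
#' @export
selection_to_text <- function(sel) {
  chunks <- vapply(names(sel$terms), function(ch) {
    rng <- sel$terms[[ch]]
    rr <- apply(rng, 1, function(r)
      if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "-", r[2]))
    paste0(ch, ":", paste(rr, collapse = ","))
  }, character(1))
  out <- paste(chunks, collapse = ";")
  if (!is.null(sel$atom_name)) out <- paste0(out, "@", sel$atom_name)
  out
}

#' Row indices of a model matched by a selection
#' @param model an [atom_model()].
#' @param sel a `selection`, or `NULL` to match everything.
#' @return integer vector of row indices into `model$atoms`.
#' @export
selection_indices <- function(model, sel) {
  at <- model$atoms
  if (is.null(sel)) return(seq_len(nrow(at)))
  hit <- rep(FALSE, nrow(at))
  for (ch in names(sel$terms)) {
    rng <- sel$terms[[ch]]
    on_chain <- !is.na(at$chain) & at$chain == ch
    for (i in seq_len(nrow(rng)))
      hit <- hit | (on_chain & at$resno >= rng[i, 1] & at$resno <= rng[i, 2])
  }
  if (!is.null(sel$atom_name)) hit <- hit & at$elety == sel$atom_name
  which(hit)
}

#' Apply a selection to a model
#'
#' Returns the sub-model of atoms matching the selection's chains, residue
#' ranges and optional atom-name filter, preserving atom order. An empty
#' result is legal; it is flagged by the `empty` attribute.
#'
#' @param model an [atom_model()].
#' @param sel a `selection` (see [parse_selection()]), or `NULL` for all atoms.
#' @return An [atom_model()] with attribute `empty = TRUE` if no atom matched.
#' @export
apply_selection <- function(model, sel) {
  idx <- selection_indices(model, sel)
  sub <- atom_model(model$atoms[idx, , drop = FALSE],
                    source_id = model$source_id,
                    model_number = model$model_number)
  attr(sub, "empty") <- length(idx) == 0L
  sub
}

#' Union of two selections
#' @param a,b `selection` objects sharing the same atom-name filter.
#' @return merged `selection`.
#' @export
selection_union <- function(a, b) {
  if (!identical(a$atom_name, b$atom_name))
    stopf("cannot union selections with different atom-name filters")
  terms <- a$terms
  for (ch in names(b$terms))
    terms[[ch]] <- if (is.null(terms[[ch]])) b$terms[[ch]] else
      rbind(terms[[ch]], b$terms[[ch]])
  new_selection(terms, a$atom_name)
}

## ---- built-in domain definitions --------------------------------------

#' Built-in RNAP domain definitions
#'
#' Translates the canonical E. coli RNAP mobile-module boundaries into
#' concrete chain selections. Shipped entries (author numbering):
#' \describe{
#'   \item{clamp}{beta 1319-1342; beta' 1-342, 1318-1344; sigma70 92-137,
#'     353-449 (the clamp here includes sigma70 region 2).}
#'   \item{shelf}{beta' 787-931, 1135-1150, 1216-1317 (includes the jaw).}
#'   \item{si3}{beta' 948-1126, the lineage-specific insertion in the
#'     trigger loop (two SBHM folds).}
#'   \item{si1}{beta 225-343, the lineage-specific insertion in the beta
#'     lobe.}
#'   \item{bridge_helix}{beta' 770-805, a window bracketing the kink
#'     residue L788. The window width is a package choice; override via
#'     your own selection if needed.}
#'   \item{blobe_si1}{beta 151-453. The beta-lobe boundaries are not a
#'     standard published range; this default (lobe plus the Si1 insertion)
#'     is a package choice and rotations measured with it should not be
#'     presented as exact.}
#' }
#'
#' @param chain_map named character vector mapping subunit names to chain
#'   ids; required names: `beta`, `beta_prime`, `sigma70`.
#' @return A named list of class `domain_definitions`; each entry holds
#'   `selection` and a `provenance` note.
#' @export
builtin_domains <- function(chain_map) {
  chain_map <- unlist(chain_map)
  need <- c("beta", "beta_prime", "sigma70")
  miss <- setdiff(need, names(chain_map))
  if (length(miss))
    stopf("chain_map must name chains for: %s (missing %s)",
          paste(need, collapse = ", "), paste(miss, collapse = ", "))
  b <- chain_map[["beta"]]; bp <- chain_map[["beta_prime"]]
  s <- chain_map[["sigma70"]]
  def <- function(txt, why) list(selection = parse_selection(txt), provenance = why)
  structure(list(
    clamp = def(sprintf("%s:1319-1342;%s:1-342,1318-1344;%s:92-137,353-449", b, bp, s),
                "clamp incl. sigma70 region 2: beta 1319-1342; beta' 1-342, 1318-1344; sigma70 92-137, 353-449"),
    shelf = def(sprintf("%s:787-931,1135-1150,1216-1317", bp),
                "beta' shelf module (incl. jaw): beta' 787-931/1135-1150/1216-1317"),
    si3 = def(sprintf("%s:948-1126", bp),
              "Si3 lineage-specific insertion in the trigger loop: beta' 948-1126"),
    si1 = def(sprintf("%s:225-343", b),
              "Si1 lineage-specific insertion in the beta lobe: beta 225-343"),
    bridge_helix = def(sprintf("%s:770-805", bp),
                       "bridge helix window around kink residue beta' L788 (package-chosen width)"),
    blobe_si1 = def(sprintf("%s:151-453", b),
                    "beta lobe plus Si1; lobe boundaries are a package default, not a published range")
  ), class = "domain_definitions")
}

#' @export
print.domain_definitions <- function(x, ...) {
  cat("<domain_definitions>\n")
  for (nm in names(x))
    cat(sprintf("  %-13s %s\n", nm, selection_to_text(x[[nm]]$selection)))
  invisible(x)
}

#' Write domain definitions to a plain-text config
#' @param domains a `domain_definitions` object.
#' @param path output path. One line per domain:
#'   `name<TAB>selection<TAB>provenance`.
#' @return `path`, invisibly.
#' @export
write_domain_config <- function(domains, path) {
  lines <- vapply(names(domains), function(nm)
    paste(nm, selection_to_text(domains[[nm]]$selection),
          domains[[nm]]$provenance, sep = "\t"), character(1))
  writeLines(c("# domain\tselection\tprovenance", lines), path)
  invisible(path)
}

#' Read domain definitions from a plain-text config
#' @param path file written by [write_domain_config()].
#' @return a `domain_definitions` object.
#' @export
read_domain_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stopf("malformed domain config line: '%s'", ln)
    out[[f[1]]] <- list(selection = parse_selection(f[2]),
                        provenance = if (length(f) >= 3L) f[3] else "")
  }
  structure(out, class = "domain_definitions")
}
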