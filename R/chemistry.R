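#' Parse a SMILES string into a chemical structure
#'
#' Parses a SMILES string with the OpenBabel backend (via ChemmineOB) and
#' builds an annotated heavy-atom molecular graph used by the descriptor and
#' fingerprint machinery. The canonical SMILES recorded in the result is the
#' backend's canonical form and is stable across runs, so two SMILES spellings
#' of the same molecule yield identical structures.
#'
#' Aromaticity and canonicalization conventions are those of OpenBabel; the
#' backend name and canonical form are kept in the object so that every
#' downstream report can trace how the structure was standardized.
#'
#' @param smiles a single SMILES string.
#' @param id identifier carried into reports; defaults to the input SMILES.
#' @return an object of class `qsar_chem`: a list with elements `id`,
#'   `smiles`, `canonical_smiles`, `atoms` (data frame: `element`, `aromatic`,
#'   `in_ring`, `n_rings`, `implicit_h`), `bonds` (data frame: `a1`, `a2`,
#'   `order`, `aromatic`, `in_ring`), `n_heavy`, `adjacency` (list of integer
#'   vectors), and `props` (backend-computed molecular weight, TPSA, H-bond
#'   donor and acceptor counts).
#' @export
#' @examples
#' \dontrun{
#' benzene <- parse_smiles("c1ccccc1")
#' benzene$n_heavy  # 6
#' }
parse_smiles <- function(smiles, id = smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("'smiles' must be a single non-empty string", call. = FALSE)

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) NULL)
  can <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = smiles)),
    error = function(e) "")
  can <- sub("[ \t\r\n].*$", "", can)
  if (is.null(sdf) || !nzchar(can))
    stop(sprintf("unparsable SMILES for '%s': \"%s\"", id, smiles),
         call. = FALSE)

  # ChemmineR rejects bond-less (single heavy atom) SDFs; fall back to
  # reading the backend's V2000 text directly for those
  degenerate <- !isTRUE(tryCatch(ChemmineR::validSDF(sdf)[1],
                                 error = function(e) FALSE))
  if (degenerate) {
    v2k <- .read_v2000(ChemmineOB::convertFormat("SMI", "SDF",
                                                 source = smiles))
    elements <- v2k$elements
    bb <- v2k$bonds
  } else {
    mol <- sdf[[1]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    elements <- sub("_.*$", "", rownames(ab))
  }

  if (!is.matrix(bb)) bb <- matrix(bb, ncol = max(3L, length(bb)))
  bonds <- if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  bonds <- bonds[bonds$a1 >= 1L & bonds$a2 >= 1L & bonds$order >= 1L, ,
                 drop = FALSE]

  # ring perception + aromatic flags on the full-atom graph
  ringinfo <- if (degenerate) list(RINGS = list(), AROMATIC = logical())
  else tryCatch(
    ChemmineR::rings(mol, type = "all", arom = TRUE),
    error = function(e) list(RINGS = list(), AROMATIC = logical()))
  ring_atom_idx <- integer(); arom_atom_idx <- integer()
  n_ring_membership <- integer(length(elements))
  ringlist <- ringinfo$RINGS
  for (k in seq_along(ringlist)) {
    idx <- as.integer(sub("^.*_", "", ringlist[[k]]))
    ring_atom_idx <- union(ring_atom_idx, idx)
    n_ring_membership[idx] <- n_ring_membership[idx] + 1L
    if (isTRUE(ringinfo$AROMATIC[[k]])) arom_atom_idx <- union(arom_atom_idx, idx)
  }

  # drop hydrogens (incl. isotopes written explicitly): descriptors and
  # fingerprints operate on the heavy-atom graph
  heavy <- which(elements != "H")
  remap <- integer(length(elements)); remap[heavy] <- seq_along(heavy)

  atoms <- data.frame(
    element = elements[heavy],
    aromatic = heavy %in% arom_atom_idx,
    in_ring = heavy %in% ring_atom_idx,
    n_rings = n_ring_membership[heavy],
    stringsAsFactors = FALSE)

  keep <- bonds$a1 %in% heavy & bonds$a2 %in% heavy
  bonds <- bonds[keep, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  bonds$aromatic <- atoms$aromatic[bonds$a1] & atoms$aromatic[bonds$a2] &
    (atoms$in_ring[bonds$a1] & atoms$in_ring[bonds$a2])
  ring_bond <- logical(nrow(bonds))
  for (k in seq_along(ringlist)) {
    idx <- remap[as.integer(sub("^.*_", "", ringlist[[k]]))]
    ring_bond <- ring_bond | (bonds$a1 %in% idx & bonds$a2 %in% idx)
  }
  bonds$in_ring <- ring_bond
  rownames(bonds) <- NULL

  rings_heavy <- list()
  rings_aromatic <- logical()
  for (k in seq_along(ringlist)) {
    idx <- as.integer(sub("^.*_", "", ringlist[[k]]))
    if (all(idx %in% heavy)) {
      rings_heavy[[length(rings_heavy) + 1L]] <- remap[idx]
      rings_aromatic <- c(rings_aromatic, isTRUE(ringinfo$AROMATIC[[k]]))
    }
  }

  n <- nrow(atoms)
  adjacency <- rep(list(integer()), n)
  for (b in seq_len(nrow(bonds))) {
    adjacency[[bonds$a1[b]]] <- c(adjacency[[bonds$a1[b]]], bonds$a2[b])
    adjacency[[bonds$a2[b]]] <- c(adjacency[[bonds$a2[b]]], bonds$a1[b])
  }

  atoms$implicit_h <- .implicit_h(atoms, bonds)

  props <- tryCatch({
    p <- if (degenerate)
      ChemmineOB::prop_OB(ChemmineOB::forEachMol(
        "SDF", ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
        identity))
    else ChemmineR::propOB(sdf)
    list(mw = as.numeric(p$MW), tpsa = as.numeric(p$TPSA),
         hbd = as.numeric(p$HBD), hba = as.numeric(p$HBA1))
  }, error = function(e) list(mw = NA_real_, tpsa = NA_real_,
                              hbd = NA_real_, hba = NA_real_))

  structure(list(id = id, smiles = smiles, canonical_smiles = can,
                 atoms = atoms, bonds = bonds, n_heavy = n,
                 adjacency = adjacency, props = props,
                 rings = rings_heavy, rings_aromatic = rings_aromatic,
                 backend = "OpenBabel/ChemmineOB"),
            class = "qsar_chem")
}

# minimal V2000 molblock reader; used only when the main SDF reader rejects
# a bond-less molecule
.read_v2000 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  elements <- vapply(seq_len(natoms), function(i)
    trimws(substr(lines[4 + i], 32, 34)), character(1))
  bonds <- if (nbonds > 0) {
    t(vapply(seq_len(nbonds), function(i) {
      ln <- lines[4 + natoms + i]
      c(as.integer(substr(ln, 1, 3)), as.integer(substr(ln, 4, 6)),
        as.integer(substr(ln, 7, 9)))
    }, integer(3)))
  } else matrix(integer(), 0, 3)
  list(elements = elements, bonds = bonds)
}

# implicit hydrogen counts from default valences; aromatic bonds count 1.5
# and the total is rounded down.  Formal charges are not modelled.
.implicit_h <- function(atoms, bonds) {
  default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                       F = 1, Cl = 1, Br = 1, I = 1, B = 3, Si = 4)
  bsum <- numeric(nrow(atoms))
  for (b in seq_len(nrow(bonds))) {
    o <- if (bonds$aromatic[b]) 1.5 else bonds$order[b]
    bsum[bonds$a1[b]] <- bsum[bonds$a1[b]] + o
    bsum[bonds$a2[b]] <- bsum[bonds$a2[b]] + o
  }
  dv <- default_valence[atoms$element]
  dv[is.na(dv)] <- 0
  pmax(0L, as.integer(floor(dv - bsum + 1e-9)))
}

#' @export
print.qsar_chem <- function(x, ...) {
  cat("Chemical structure:", x$id, "\n")
  cat("  SMILES:          ", x$smiles, "\n")
  cat("  canonical SMILES:", x$canonical_smiles, "\n")
  cat("  heavy atoms:", x$n_heavy, " bonds:", nrow(x$bonds), "\n")
  invisible(x)
}

#' Read a SMILES (.smi) file
#'
#' One `SMILES<whitespace>ID` record per line; lines starting with `#` and
#' blank lines are ignored. Records whose SMILES does not parse are returned
#' with a diagnostic instead of aborting the whole file.
#'
#' @param path path to the .smi file.
#' @return a list with `chemicals` (list of [parse_smiles()] structures) and
#'   `failures` (data frame of `id`, `smiles`, `error`).
#' @export
read_smi_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  chems <- list()
  fails <- data.frame(id = character(), smiles = character(),
                      error = character(), stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[ \t]+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) >= 2) paste(parts[-1], collapse = " ")
          else sprintf("chem%03d", i)
    res <- tryCatch(parse_smiles(smi, id = id), error = function(e) e)
    if (inherits(res, "error")) {
      fails <- rbind(fails, data.frame(id = id, smiles = smi,
                                       error = conditionMessage(res),
                                       stringsAsFactors = FALSE))
    } else chems[[id]] <- res
  }
  list(chemicals = chems, failures = fails)
}

#' Read a CSV table of externally supplied descriptor values
#'
#' The table must have a header row whose first column is the chemical id;
#' remaining columns are descriptor names. Values are parsed as doubles
#' (exponent notation included). A missing cell is an error naming its row
#' and column, since silent missing descriptor values would poison every
#' downstream leverage computation.
#'
#' @param path path to a UTF-8 CSV file.
#' @return a data frame, one row per chemical (ids as `id` column and row
#'   names), descriptor columns numeric, with attribute `provenance =
#'   "supplied"`.
#' @export
read_descriptor_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(tab) < 2L)
    stop("descriptor table needs an id column plus at least one descriptor",
         call. = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicated chemical ids in descriptor table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (j in 2:ncol(tab)) {
    raw <- trimws(tab[[j]])
    bad <- which(!nzchar(raw) | is.na(raw))
    if (length(bad))
      stop(sprintf("missing descriptor value at row '%s', column '%s'",
                   ids[bad[1]], names(tab)[j]), call. = FALSE)
    val <- suppressWarnings(as.numeric(raw))
    nn <- which(is.na(val))
    if (length(nn))
      stop(sprintf("non-numeric descriptor value '%s' at row '%s', column '%s'",
                   raw[nn[1]], ids[nn[1]], names(tab)[j]), call. = FALSE)
    out[[names(tab)[j]]] <- val
  }
  rownames(out) <- ids
  attr(out, "provenance") <- "supplied"
  out
}
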