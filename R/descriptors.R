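#' Built-in molecular descriptors
#'
#' The package computes a small, exactly specified descriptor set; models
#' needing anything else supply values through a descriptor table (see
#' [read_descriptor_table()]). Definitions:
#'
#' * `molecular_weight` — average molecular weight including implicit
#'   hydrogens (backend value, g/mol).
#' * `heavy_atom_count` — number of non-hydrogen atoms.
#' * `ring_count` — cyclomatic number of the heavy-atom graph
#'   (bonds − atoms + connected components), i.e. the size of a smallest
#'   set of smallest rings.
#' * `h_bond_donors`, `h_bond_acceptors` — backend (OpenBabel) donor and
#'   acceptor counts.
#' * `rotatable_bonds` — acyclic single bonds between two heavy atoms that
#'   each have at least one further heavy neighbor (terminal bonds are not
#'   rotatable; ring bonds never are).
#' * `wiener_index` — sum of topological shortest-path distances over all
#'   unordered heavy-atom pairs, summed per connected component.
#' * `tpsa` — Ertl topological polar surface area (backend value, Å²).
#'
#' @return `descriptor_names()` returns the character vector of available
#'   computed-descriptor names.
#' @export
descriptor_names <- function() {
  c("molecular_weight", "heavy_atom_count", "ring_count",
    "h_bond_donors", "h_bond_acceptors", "rotatable_bonds",
    "wiener_index", "tpsa")
}

#' Compute descriptor values for a chemical structure
#'
#' @param structure a `qsar_chem` object from [parse_smiles()].
#' @param specs character vector of descriptor names (see
#'   [descriptor_names()]), or a descriptor-spec data frame as stored in a
#'   fitted model, in which case only entries with `source == "computed"`
#'   are evaluated (others are returned as `NA` for the caller to fill from
#'   a supplied table).
#' @return named numeric vector aligned to `specs`, with a `provenance`
#'   attribute (`"computed"` or `"supplied"` per value).
#' @export
compute_descriptors <- function(structure, specs) {
  stopifnot(inherits(structure, "qsar_chem"))
  if (is.data.frame(specs)) {
    nm <- specs$name; src <- specs$source
  } else {
    nm <- as.character(specs); src <- rep("computed", length(nm))
  }
  unknown <- setdiff(nm[src == "computed"], descriptor_names())
  if (length(unknown))
    stop("unknown computed descriptor(s): ",
         paste(unknown, collapse = ", "),
         "; available: ", paste(descriptor_names(), collapse = ", "),
         call. = FALSE)
  vals <- vapply(seq_along(nm), function(i) {
    if (src[i] != "computed") return(NA_real_)
    .descriptor_value(structure, nm[i])
  }, numeric(1))
  names(vals) <- nm
  attr(vals, "provenance") <- ifelse(src == "computed", "computed", "supplied")
  vals
}

.descriptor_value <- function(mol, name) {
  switch(name,
    molecular_weight = mol$props$mw,
    heavy_atom_count = as.numeric(mol$n_heavy),
    ring_count = .ring_count(mol),
    h_bond_donors = mol$props$hbd,
    h_bond_acceptors = mol$props$hba,
    rotatable_bonds = .rotatable_bonds(mol),
    wiener_index = .wiener_index(mol$adjacency),
    tpsa = mol$props$tpsa,
    stop("unknown descriptor: ", name, call. = FALSE))
}

.ring_count <- function(mol) {
  n <- mol$n_heavy
  if (n == 0L) return(0)
  comp <- .components(mol$adjacency)
  nrow(mol$bonds) - n + max(comp)
}

.rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(0)
  deg <- lengths(mol$adjacency)
  sum(b$order == 1L & !b$in_ring & !b$aromatic &
        deg[b$a1] >= 2L & deg[b$a2] >= 2L)
}

# BFS all-pairs shortest paths; unreachable pairs (across components)
# contribute nothing
.wiener_index <- function(adjacency) {
  n <- length(adjacency)
  if (n < 2L) return(0)
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in adjacency[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; nxt <- c(nxt, w)
      }
      frontier <- nxt
    }
    total <- total + sum(dist, na.rm = TRUE)
  }
  total / 2
}

.components <- function(adjacency) {
  n <- length(adjacency)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v]) next
      comp[v] <- cur
      stack <- c(stack, adjacency[[v]][comp[adjacency[[v]]] == 0L])
    }
  }
  comp
}
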