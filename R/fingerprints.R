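#' Molecular fingerprints
#'
#' Three documented fingerprint kinds are provided behind a single interface,
#' so that the similarity and neighbor machinery is independent of the
#' fingerprint definition:
#'
#' * `hashed_path` — all simple linear paths of 1–7 heavy atoms; each path is
#'   labelled by its element symbols (lower-case when aromatic) and bond
#'   symbols, read in the lexicographically smaller direction, and hashed
#'   onto 1024 bits.
#' * `smarts_keys` — a shipped dictionary of ~55 structural keys (elements,
#'   functional groups, ring topology), each documented with its
#'   SMARTS-equivalent notation and matched on the annotated heavy-atom
#'   graph; binary (key present/absent).
#' * `smarts_keys_count` — the same dictionary with occurrence counts.
#'
#' These kinds are this package's own, exactly reproducible definitions, not
#' reimplementations of any published fingerprint; external fingerprints can
#' be plugged in by constructing a `qsar_fingerprint` object directly with
#' [make_fingerprint()].
#'
#' @param structure a `qsar_chem` object from [parse_smiles()].
#' @param kind one of `"hashed_path"`, `"smarts_keys"`, `"smarts_keys_count"`.
#' @return object of class `qsar_fingerprint`: list with `kind`, `length`,
#'   `on` (sorted 0-based indices of set bits) and, for the count kind,
#'   `counts` (positive integers aligned to `on`).
#' @export
compute_fingerprint <- function(structure,
                                kind = c("hashed_path", "smarts_keys",
                                         "smarts_keys_count")) {
  stopifnot(inherits(structure, "qsar_chem"))
  kind <- match.arg(kind)
  if (kind == "hashed_path") {
    bits <- .hashed_path_bits(structure)
    return(make_fingerprint(kind, 1024L, bits))
  }
  counts <- .structural_key_counts(structure)
  on <- which(counts > 0L) - 1L
  if (kind == "smarts_keys")
    make_fingerprint(kind, length(counts), on)
  else
    make_fingerprint(kind, length(counts), on, counts = counts[counts > 0L])
}

#' Construct a fingerprint object directly
#'
#' Adapter point for external fingerprints: any binary or count fingerprint
#' can be wrapped for use with [fingerprint_similarity()] and
#' [find_neighbors()].
#'
#' @param kind fingerprint kind label (free text for external kinds).
#' @param length total number of bit positions.
#' @param on 0-based indices of set bits.
#' @param counts optional positive counts aligned to `on`; presence marks a
#'   count fingerprint.
#' @return a `qsar_fingerprint` object.
#' @export
make_fingerprint <- function(kind, length, on, counts = NULL) {
  on <- as.integer(on)
  if (any(on < 0L) || any(on >= length))
    stop("bit indices must lie in [0, length)", call. = FALSE)
  o <- order(on)
  on <- on[o]
  if (anyDuplicated(on)) stop("duplicated bit indices", call. = FALSE)
  if (!is.null(counts)) {
    counts <- as.integer(counts)[o]
    if (length(counts) != length(on) || any(counts <= 0L))
      stop("counts must be positive and aligned to 'on'", call. = FALSE)
  }
  structure(list(kind = kind, length = as.integer(length), on = on,
                 counts = counts), class = "qsar_fingerprint")
}

#' @export
print.qsar_fingerprint <- function(x, ...) {
  cat(sprintf("Fingerprint [%s], %d/%d bits set%s\n", x$kind,
              length(x$on), x$length,
              if (is.null(x$counts)) "" else " (counts)"))
  invisible(x)
}

# ---- hashed linear paths --------------------------------------------------

.hashed_path_bits <- function(mol, max_atoms = 7L, nbits = 1024L) {
  n <- mol$n_heavy
  if (n == 0L) return(integer())
  el <- mol$atoms$element
  sym <- ifelse(mol$atoms$aromatic, tolower(el), el)
  # bond symbol lookup
  bsym <- matrix("", n, n)
  for (b in seq_len(nrow(mol$bonds))) {
    s <- if (mol$bonds$aromatic[b]) "~" else
      switch(mol$bonds$order[b], "-", "=", "#", "$")
    bsym[mol$bonds$a1[b], mol$bonds$a2[b]] <- s
    bsym[mol$bonds$a2[b], mol$bonds$a1[b]] <- s
  }
  labels <- character(0)
  # depth-first enumeration of simple paths; a path and its reverse are the
  # same feature, so paths of >1 atom are kept only from the end with the
  # smaller index
  walk <- function(path) {
    if (length(path) > 1L && path[1] < path[length(path)]) {
      fwd <- .path_label(path, sym, bsym)
      rev_ <- .path_label(rev(path), sym, bsym)
      labels[[length(labels) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    }
    if (length(path) == max_atoms) return(invisible())
    for (w in mol$adjacency[[path[length(path)]]])
      if (!(w %in% path)) walk(c(path, w))
  }
  for (s in seq_len(n)) {
    labels[[length(labels) + 1L]] <- sym[s]
    walk(s)
  }
  unique(vapply(unique(labels), .string_hash, integer(1), nbits = nbits,
                USE.NAMES = FALSE))
}

.path_label <- function(path, sym, bsym) {
  out <- sym[path[1]]
  for (i in seq_along(path)[-1])
    out <- paste0(out, bsym[path[i - 1L], path[i]], sym[path[i]])
  out
}

# deterministic polynomial rolling hash over UTF-8 bytes
.string_hash <- function(s, nbits) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% nbits)
}

# ---- structural key dictionary -------------------------------------------

#' Structural key dictionary
#'
#' @return data frame with key `name` and its SMARTS-equivalent `pattern`
#'   notation, in bit order.
#' @export
structural_keys <- function() {
  data.frame(name = .key_table$name, pattern = .key_table$pattern,
             stringsAsFactors = FALSE)
}

.key_table <- local({
  keys <- list(
    c("carbon",            "[#6]"),
    c("aromatic_carbon",   "c"),
    c("nitrogen",          "[#7]"),
    c("aromatic_nitrogen", "n"),
    c("oxygen",            "[#8]"),
    c("aromatic_oxygen",   "o"),
    c("sulfur",            "[#16]"),
    c("aromatic_sulfur",   "s"),
    c("phosphorus",        "[#15]"),
    c("fluorine",          "[F]"),
    c("chlorine",          "[Cl]"),
    c("bromine",           "[Br]"),
    c("iodine",            "[I]"),
    c("halogen",           "[F,Cl,Br,I]"),
    c("double_bond",       "*=*"),
    c("triple_bond",       "*#*"),
    c("aromatic_bond",     "*:*"),
    c("hydroxyl",          "[OX2H]"),
    c("alcohol",           "[CX4][OX2H]"),
    c("phenol",            "c[OX2H]"),
    c("carbonyl",          "[CX3]=[OX1]"),
    c("aldehyde",          "[CX3H1]=O"),
    c("ketone",            "[#6][CX3](=O)[#6]"),
    c("carboxylic_acid",   "[CX3](=O)[OX2H]"),
    c("ester",             "[CX3](=O)[OX2][#6]"),
    c("amide",             "[CX3](=O)[NX3]"),
    c("ether",             "[OD2]([#6])[#6]"),
    c("primary_amine",     "[NX3H2][#6]"),
    c("secondary_amine",   "[NX3H1]([#6])[#6]"),
    c("tertiary_amine",    "[NX3H0]([#6])([#6])[#6]"),
    c("aniline_nitrogen",  "[NX3]c"),
    c("nitrile",           "[CX2]#[NX1]"),
    c("nitro",             "[NX3](=O)[O]"),
    c("imine",             "[CX3]=[NX2]"),
    c("thiol",             "[SX2H]"),
    c("thioether",         "[SX2]([#6])[#6]"),
    c("sulfonyl",          "[SX4](=O)=O"),
    c("alkene",            "[CX3]=[CX3]"),
    c("alkyne",            "[CX2]#[CX2]"),
    c("ring_atom",         "[R]"),
    c("ring_bond",         "[R]@[R]"),
    c("aromatic_ring",     "a1aaaaa1-like (any aromatic ring)"),
    c("aliphatic_ring",    "any non-aromatic ring"),
    c("ring_size3",        "*1**1"),
    c("ring_size4",        "*1***1"),
    c("ring_size5",        "*1****1"),
    c("ring_size6",        "*1*****1"),
    c("ring_size7plus",    "ring of 7 or 8 atoms"),
    c("fused_ring_atom",   "[R2]"),
    c("branch_atom",       "[D3,D4]"),
    c("quaternary_carbon", "[CX4]([#6])([#6])([#6])[#6]"),
    c("methyl",            "[CH3][#6]"),
    c("aryl_halide",       "c[F,Cl,Br,I]"),
    c("hetero_hetero_bond","[N,O,S]~[N,O,S]"),
    c("carbon_chain4",     "C-C-C-C acyclic backbone present")
  )
  list(name = vapply(keys, `[`, "", 1L), pattern = vapply(keys, `[`, "", 2L))
})

.structural_key_counts <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  el <- a$element; arom <- a$aromatic; nh <- a$implicit_h
  deg <- lengths(mol$adjacency)
  n <- mol$n_heavy
  # neighbor helpers
  nbr <- mol$adjacency
  dbl_to <- function(i, elem) {          # neighbors double-bonded to atom i
    hit <- b[(b$a1 == i | b$a2 == i) & b$order == 2L & !b$aromatic, , drop = FALSE]
    j <- ifelse(hit$a1 == i, hit$a2, hit$a1)
    j[el[j] %in% elem]
  }
  sgl_to <- function(i, elem) {
    hit <- b[(b$a1 == i | b$a2 == i) & b$order == 1L & !b$aromatic, , drop = FALSE]
    j <- ifelse(hit$a1 == i, hit$a2, hit$a1)
    j[el[j] %in% elem]
  }
  is_sp3C <- el == "C" & !arom &
    vapply(seq_len(n), function(i) length(dbl_to(i, unique(el))) == 0L &&
             length(.triple_partners(b, i)) == 0L, logical(1))

  carbonyl_C <- which(el == "C" & !arom &
                        vapply(seq_len(n), function(i)
                          length(dbl_to(i, "O")) > 0L, logical(1)))

  ringsz <- lengths(mol$rings)
  cnt <- integer(length(.key_table$name))
  names(cnt) <- .key_table$name

  cnt["carbon"] <- sum(el == "C")
  cnt["aromatic_carbon"] <- sum(el == "C" & arom)
  cnt["nitrogen"] <- sum(el == "N")
  cnt["aromatic_nitrogen"] <- sum(el == "N" & arom)
  cnt["oxygen"] <- sum(el == "O")
  cnt["aromatic_oxygen"] <- sum(el == "O" & arom)
  cnt["sulfur"] <- sum(el == "S")
  cnt["aromatic_sulfur"] <- sum(el == "S" & arom)
  cnt["phosphorus"] <- sum(el == "P")
  cnt["fluorine"] <- sum(el == "F")
  cnt["chlorine"] <- sum(el == "Cl")
  cnt["bromine"] <- sum(el == "Br")
  cnt["iodine"] <- sum(el == "I")
  cnt["halogen"] <- sum(el %in% c("F", "Cl", "Br", "I"))
  cnt["double_bond"] <- sum(b$order == 2L & !b$aromatic)
  cnt["triple_bond"] <- sum(b$order == 3L)
  cnt["aromatic_bond"] <- sum(b$aromatic)

  hydroxyl <- which(el == "O" & !arom & nh >= 1L)
  cnt["hydroxyl"] <- length(hydroxyl)
  cnt["alcohol"] <- sum(vapply(hydroxyl, function(i)
    any(is_sp3C[nbr[[i]]]), logical(1)))
  cnt["phenol"] <- sum(vapply(hydroxyl, function(i)
    any(el[nbr[[i]]] == "C" & arom[nbr[[i]]]), logical(1)))
  cnt["carbonyl"] <- length(carbonyl_C)
  cnt["aldehyde"] <- sum(nh[carbonyl_C] >= 1L)
  cnt["ketone"] <- sum(vapply(carbonyl_C, function(i)
    sum(el[nbr[[i]]] == "C") == 2L &&
      length(sgl_to(i, c("O", "N", "S"))) == 0L && nh[i] == 0L, logical(1)))
  cnt["carboxylic_acid"] <- sum(vapply(carbonyl_C, function(i)
    any(nh[sgl_to(i, "O")] >= 1L), logical(1)))
  cnt["ester"] <- sum(vapply(carbonyl_C, function(i) {
    os <- sgl_to(i, "O")
    any(vapply(os, function(o) nh[o] == 0L &&
                 length(setdiff(nbr[[o]], i)) >= 1L &&
                 any(el[setdiff(nbr[[o]], i)] == "C"), logical(1)))
  }, logical(1)))
  cnt["amide"] <- sum(vapply(carbonyl_C, function(i)
    length(sgl_to(i, "N")) > 0L, logical(1)))
  cnt["ether"] <- sum(el == "O" & !arom & nh == 0L & deg == 2L &
                        vapply(seq_len(n), function(i)
                          all(el[nbr[[i]]] == "C"), logical(1)))
  amineN <- el == "N" & !arom &
    vapply(seq_len(n), function(i) length(dbl_to(i, unique(el))) == 0L &&
             length(.triple_partners(b, i)) == 0L, logical(1))
  cnt["primary_amine"] <- sum(amineN & nh >= 2L & deg == 1L &
                                vapply(seq_len(n), function(i)
                                  any(el[nbr[[i]]] == "C"), logical(1)))
  cnt["secondary_amine"] <- sum(amineN & nh == 1L & deg == 2L)
  cnt["tertiary_amine"] <- sum(amineN & nh == 0L & deg == 3L)
  cnt["aniline_nitrogen"] <- sum(el == "N" & !arom &
                                   vapply(seq_len(n), function(i)
                                     any(arom[nbr[[i]]] &
                                           el[nbr[[i]]] == "C"), logical(1)))
  cnt["nitrile"] <- sum(el == "C" & vapply(seq_len(n), function(i)
    any(el[.triple_partners(b, i)] == "N"), logical(1)))
  cnt["nitro"] <- sum(el == "N" & vapply(seq_len(n), function(i)
    length(dbl_to(i, "O")) >= 1L && sum(el[nbr[[i]]] == "O") >= 2L,
    logical(1)))
  cnt["imine"] <- sum(el == "C" & !arom & vapply(seq_len(n), function(i)
    any(!arom[dbl_to(i, "N")]), logical(1)))
  cnt["thiol"] <- sum(el == "S" & !arom & nh >= 1L)
  cnt["thioether"] <- sum(el == "S" & !arom & nh == 0L & deg == 2L &
                            vapply(seq_len(n), function(i)
                              all(el[nbr[[i]]] == "C"), logical(1)))
  cnt["sulfonyl"] <- sum(el == "S" & vapply(seq_len(n), function(i)
    length(dbl_to(i, "O")) >= 2L, logical(1)))
  cnt["alkene"] <- sum(b$order == 2L & !b$aromatic &
                         el[b$a1] == "C" & el[b$a2] == "C")
  cnt["alkyne"] <- sum(b$order == 3L & el[b$a1] == "C" & el[b$a2] == "C")
  cnt["ring_atom"] <- sum(a$in_ring)
  cnt["ring_bond"] <- sum(b$in_ring)
  small <- ringsz <= 8L
  cnt["aromatic_ring"] <- sum(mol$rings_aromatic & small)
  cnt["aliphatic_ring"] <- sum(!mol$rings_aromatic & small)
  cnt["ring_size3"] <- sum(ringsz == 3L)
  cnt["ring_size4"] <- sum(ringsz == 4L)
  cnt["ring_size5"] <- sum(ringsz == 5L)
  cnt["ring_size6"] <- sum(ringsz == 6L)
  cnt["ring_size7plus"] <- sum(ringsz %in% 7:8)
  cnt["fused_ring_atom"] <- sum(a$n_rings >= 2L)
  cnt["branch_atom"] <- sum(deg >= 3L)
  cnt["quaternary_carbon"] <- sum(el == "C" & deg == 4L &
                                    vapply(seq_len(n), function(i)
                                      sum(el[nbr[[i]]] == "C") == 4L,
                                      logical(1)))
  cnt["methyl"] <- sum(el == "C" & !arom & deg == 1L & nh == 3L &
                         vapply(seq_len(n), function(i)
                           any(el[nbr[[i]]] == "C"), logical(1)))
  cnt["aryl_halide"] <- sum(el %in% c("F", "Cl", "Br", "I") &
                              vapply(seq_len(n), function(i)
                                any(arom[nbr[[i]]]), logical(1)))
  cnt["hetero_hetero_bond"] <- sum(el[b$a1] %in% c("N", "O", "S") &
                                     el[b$a2] %in% c("N", "O", "S"))
  cnt["carbon_chain4"] <- as.integer(.longest_carbon_path(mol) >= 4L)
  cnt
}

.triple_partners <- function(b, i) {
  hit <- b[(b$a1 == i | b$a2 == i) & b$order == 3L, , drop = FALSE]
  ifelse(hit$a1 == i, hit$a2, hit$a1)
}

.longest_carbon_path <- function(mol, cap = 8L) {
  cidx <- which(mol$atoms$element == "C" & !mol$atoms$aromatic)
  if (!length(cidx)) return(0L)
  best <- 0L
  walk <- function(path) {
    best <<- max(best, length(path))
    if (length(path) >= cap) return(invisible())
    for (w in mol$adjacency[[path[length(path)]]])
      if (w %in% cidx && !(w %in% path)) walk(c(path, w))
  }
  for (s in cidx) walk(s)
  best
}
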