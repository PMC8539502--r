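# SMILES parsing and chemical perception.
#
# Chemistry (valence model, kekulisation) is delegated to OpenBabel through
# ChemmineOB; ring enumeration and aromaticity perception to ChemmineR::rings().
# The V2000 connection table returned by OpenBabel is read by a small extractor
# here because ChemmineR's SDF reader rejects bond-free molecules (e.g. methane)
# and single atoms are legitimate inputs for this package.

# Old-style V2000 atom-block charge codes (field 37-39): 1..7 -> +3..-3, 4 = radical.
.charge_codes <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                   `5` = -1L, `6` = -2L, `7` = -3L)

# Default valences used to derive implicit hydrogen counts from the kekulised
# bond order sum. Charge shifts the allowed valence for the usual organic set.
.default_valence <- c(H = 1L, C = 4L, N = 3L, O = 2L, S = 2L, F = 1L,
                      Cl = 1L, Br = 1L, I = 1L, P = 3L)

#' Lexical validity check for a SMILES string
#'
#' OpenBabel silently repairs some malformed SMILES (an unmatched `(` parses as
#' if it were absent), so syntactic defects are caught here before any
#' conversion: the string must be non-empty, parentheses and brackets must be
#' balanced, and every ring-closure label must appear an even number of times.
#'
#' @param smiles character scalar.
#' @return `TRUE` if syntactically plausible, otherwise a character scalar
#'   describing the defect.
#' @keywords internal
smiles_syntax_check <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return("empty or non-character SMILES")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  alphabet <- c(LETTERS, letters, 0:9,
                strsplit("[]()=#$+-./\\@%:*", "", fixed = TRUE)[[1]])
  if (!all(chars %in% alphabet)) {
    return("contains characters outside the SMILES alphabet")
  }
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) return("unmatched ')'")
  }
  if (depth != 0L) return("unmatched '('")
  bdepth <- cumsum((chars == "[") - (chars == "]"))
  if (any(bdepth > 1L) || any(bdepth < 0L) || bdepth[length(bdepth)] != 0L) {
    return("unbalanced brackets")
  }
  # ring-closure labels: single digits (or %nn) outside brackets must pair up
  outside <- chars
  outside[bdepth > 0L | chars == "]"] <- " "
  stripped <- paste(outside, collapse = "")
  labels <- c(
    sub("%", "", regmatches(stripped, gregexpr("%[0-9]{2}", stripped))[[1]]),
    regmatches(gsub("%[0-9]{2}", "", stripped),
               gregexpr("[0-9]", gsub("%[0-9]{2}", "", stripped)))[[1]]
  )
  if (length(labels)) {
    counts <- table(labels)
    if (any(counts %% 2L != 0L)) return("unclosed ring bond")
  }
  TRUE
}

# Split concatenated SDF text into per-molecule records.
.split_sdf_records <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  if (!length(ends)) return(list())
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(function(s, e) lines[s:(e - 1L)], starts, ends)
}

# Read one V2000 connection table: elements, charges, bonds.
.read_ctab <- function(lines) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) return(NULL)
  atom_lines <- lines[4 + seq_len(na)]
  element <- trimws(substr(atom_lines, 32, 34))
  charge <- unname(.charge_codes[as.character(as.integer(substr(atom_lines, 37, 39)))])
  charge[is.na(charge)] <- 0L
  if (nb > 0L) {
    bond_lines <- lines[4 + na + seq_len(nb)]
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    order <- as.integer(substr(bond_lines, 7, 9))
  } else {
    a1 <- a2 <- order <- integer(0)
  }
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0L, na)  # M CHG supersedes all atom-block charge fields
    for (ln in chg_lines) {
      fields <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      nent <- fields[1]
      for (k in seq_len(nent)) {
        charge[fields[2 * k]] <- fields[2 * k + 1]
      }
    }
  }
  list(element = element, charge = charge,
       bonds = data.frame(a1 = a1, a2 = a2, order = order))
}

# Ring perception: bridge detection (igraph) gives exact ring membership;
# ChemmineR::rings() enumerates rings up to `upper` atoms and flags aromaticity.
.perceive_rings <- function(element, bonds, charge, upper = 12L) {
  n <- length(element)
  nb <- nrow(bonds)
  atom_in_ring <- rep(FALSE, n)
  bond_in_ring <- rep(FALSE, max(nb, 0L))
  ring_size <- rep(0L, n)
  atom_aromatic <- rep(FALSE, n)
  bond_aromatic <- rep(FALSE, max(nb, 0L))
  if (nb >= 3L) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    bridge_ids <- igraph::bridges(g)
    bond_in_ring <- !(seq_len(nb) %in% as.integer(bridge_ids))
    atom_in_ring[unique(c(bonds$a1[bond_in_ring], bonds$a2[bond_in_ring]))] <- TRUE
    if (any(bond_in_ring)) {
      sdf <- .as_chemminer_sdf(element, bonds, charge)
      rr <- tryCatch(
        ChemmineR::rings(sdf, upper = upper, type = "all", arom = FALSE,
                         inner = FALSE),
        error = function(e) NULL)
      if (!is.null(rr) && length(rr)) {
        ring_size[atom_in_ring] <- upper  # in a ring, size only bounded below
        bkey <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
        for (i in seq_along(rr)) {
          members <- as.integer(sub("^.*_", "", rr[[i]]))
          len <- length(members)
          ring_size[members] <- pmin(ring_size[members], len)
          if (.ring_is_aromatic(members, element, charge, bonds)) {
            atom_aromatic[members] <- TRUE
            cyc <- cbind(members, members[c(2:len, 1L)])
            key <- paste(pmin(cyc[, 1], cyc[, 2]), pmax(cyc[, 1], cyc[, 2]))
            bond_aromatic[bkey %in% key] <- TRUE
          }
        }
      }
    }
  }
  list(atom_in_ring = atom_in_ring, bond_in_ring = bond_in_ring,
       ring_size = ring_size, atom_aromatic = atom_aromatic,
       bond_aromatic = bond_aromatic)
}

# Simplified Hueckel aromaticity over one enumerated ring (kekulised orders):
# each ring atom must be pi-capable, contributing 1 electron for a double bond
# inside the ring, 0 for an exocyclic double/triple bond or a carbocation,
# 2 for a heteroatom lone pair or carbanion; a saturated carbon disqualifies
# the ring. Aromatic iff the electron count satisfies 4n + 2.
.ring_is_aromatic <- function(members, element, charge, bonds) {
  len <- length(members)
  if (len < 3L) return(FALSE)
  nxt <- members[c(2:len, 1L)]
  ring_pairs <- paste(pmin(members, nxt), pmax(members, nxt))
  bond_key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
  electrons <- 0L
  for (a in members) {
    inc <- which(bonds$a1 == a | bonds$a2 == a)
    in_ring_double <- any(bonds$order[inc] == 2L & bond_key[inc] %in% ring_pairs)
    exo_multiple <- any(bonds$order[inc] >= 2L & !(bond_key[inc] %in% ring_pairs))
    if (in_ring_double) {
      electrons <- electrons + 1L
    } else if (exo_multiple) {
      # sp2 but its pi electrons point out of the ring
    } else if (element[a] %in% c("N", "O", "S", "P") && charge[a] >= 0L) {
      electrons <- electrons + 2L
    } else if (charge[a] < 0L) {
      electrons <- electrons + 2L
    } else if (charge[a] > 0L) {
      # empty p orbital, contributes nothing
    } else {
      return(FALSE)  # saturated carbon breaks conjugation
    }
  }
  electrons > 2L && (electrons - 2L) %% 4L == 0L
}

# Minimal SDF S4 object, enough for ChemmineR::rings(); the atom-block keeps
# the old-style charge code in column 5 as real connection tables do.
.as_chemminer_sdf <- function(element, bonds, charge = integer(length(element))) {
  n <- length(element)
  code <- integer(n)
  code[charge != 0L] <- match(charge[charge != 0L], c(3L, 2L, 1L, NA, -1L, -2L, -3L))
  code[is.na(code)] <- 0L
  ab <- matrix(0, n, 6, dimnames = list(paste(element, seq_len(n), sep = "_"),
                                        c("C1", "C2", "C3", "C5", "C6", "C7")))
  ab[, 5] <- code
  bb <- cbind(C1 = bonds$a1, C2 = bonds$a2, C3 = bonds$order,
              C4 = 0, C5 = 0, C6 = 0, C7 = 0)
  rownames(bb) <- seq_len(nrow(bonds))
  methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
               header = c(Molecule_Name = "mol", Source = "", Comment = "",
                          Counts_Line = ""),
               atomblock = ab, bondblock = bb, datablock = character(0))
}

.implicit_h <- function(element, charge, kek_order_sum) {
  val <- .default_valence[element]
  val[is.na(val)] <- 4L
  adj <- ifelse(element %in% c("N", "P", "O", "S"), charge, -abs(charge))
  pmax(0L, as.integer(val + adj - kek_order_sum))
}

.build_molecule <- function(smiles, ctab, neutralize = FALSE) {
  n <- length(ctab$element)
  bonds <- ctab$bonds
  charge <- ctab$charge
  perception <- .perceive_rings(ctab$element, bonds, ctab$charge)
  order_chr <- as.character(bonds$order)
  order_chr[perception$bond_aromatic] <- "ar"
  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  kek_sum <- vapply(seq_len(n), function(i) {
    sum(bonds$order[bonds$a1 == i | bonds$a2 == i])
  }, numeric(1))
  neutralized <- 0L
  if (neutralize) {
    h <- .implicit_h(ctab$element, charge, kek_sum)
    # protonation-state fixes only: anions gain H, cations with an H lose one;
    # charges without an available H shift (e.g. quaternary N+) are kept.
    fixable <- (charge < 0L) | (charge > 0L & h > 0L)
    neutralized <- sum(fixable & charge != 0L)
    charge[fixable] <- 0L
  }
  atoms <- data.frame(
    element = ctab$element,
    charge = charge,
    aromatic = perception$atom_aromatic,
    in_ring = perception$atom_in_ring,
    ring_size = perception$ring_size,
    degree = deg,
    h_count = .implicit_h(ctab$element, charge, kek_sum),
    stringsAsFactors = FALSE
  )
  bonds_out <- data.frame(
    a1 = bonds$a1, a2 = bonds$a2,
    order = order_chr,
    kek_order = bonds$order,
    aromatic = perception$bond_aromatic,
    in_ring = perception$bond_in_ring,
    stringsAsFactors = FALSE
  )
  structure(list(smiles = smiles, atoms = atoms, bonds = bonds_out,
                 neutralized = neutralized),
            class = "molecule")
}

#' Parse SMILES strings into perceived molecules
#'
#' Converts each SMILES to a heavy-atom molecular structure with aromaticity,
#' ring membership, smallest-ring sizes, formal charges, degrees and implicit
#' hydrogen counts perceived. Hydrogens stay implicit.
#'
#' @param smiles character vector of SMILES strings.
#' @param neutralize logical; if `TRUE`, protonation-state formal charges are
#'   removed (anions gain an implicit hydrogen, protonated cations lose one;
#'   non-neutralisable charges such as quaternary ammonium are kept).
#' @param on_error `"stop"` (default) raises an error naming the offending
#'   input; `"drop"` skips it with a warning and returns the rest.
#' @return a list of `molecule` objects, one per successfully parsed input,
#'   named by input position.
#' @examples
#' mols <- parse_molecules(c("CC", "c1ccccc1"))
#' mols[[2]]$atoms$ring_size
#' @export
parse_molecules <- function(smiles, neutralize = FALSE,
                            on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  ok <- rep(TRUE, length(smiles))
  for (i in seq_along(smiles)) {
    chk <- smiles_syntax_check(smiles[i])
    if (!isTRUE(chk)) {
      msg <- sprintf("cannot parse SMILES '%s': %s", smiles[i], chk)
      if (on_error == "stop") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      ok[i] <- FALSE
    }
  }
  idx <- which(ok)
  out <- vector("list", length(smiles))
  if (length(idx)) {
    src <- paste0(paste(smiles[idx], idx, sep = "\t"), "\n", collapse = "")
    text <- ChemmineOB::convertFormat("SMI", "SDF", source = src)
    recs <- .split_sdf_records(text)
    titles <- vapply(recs, function(r) trimws(r[1]), character(1))
    for (j in seq_along(recs)) {
      i <- suppressWarnings(as.integer(titles[j]))
      if (is.na(i)) next
      ctab <- .read_ctab(recs[[j]])
      if (is.null(ctab)) next
      out[[i]] <- .build_molecule(smiles[i], ctab, neutralize = neutralize)
    }
    failed <- idx[vapply(out[idx], is.null, logical(1))]
    for (i in failed) {
      msg <- sprintf("cannot parse SMILES '%s': rejected by structure perception",
                     smiles[i])
      if (on_error == "stop") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
  }
  names(out) <- as.character(seq_along(smiles))
  out[!vapply(out, is.null, logical(1))]
}

#' Parse a single SMILES string
#'
#' @inheritParams parse_molecules
#' @param smiles a single SMILES string.
#' @return a `molecule` object: a list with `atoms` (element, charge, aromatic,
#'   in_ring, ring_size with 0 meaning acyclic, degree, h_count) and `bonds`
#'   (endpoints, order in `{"1","2","3","ar"}`, kekulised order, flags).
#' @export
parse_molecule <- function(smiles, neutralize = FALSE) {
  parse_molecules(smiles[1], neutralize = neutralize, on_error = "stop")[[1]]
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d heavy atoms, %d bonds, %d ring atoms\n",
              x$smiles, nrow(x$atoms), nrow(x$bonds), sum(x$atoms$in_ring)))
  invisible(x)
}

#' Number of heavy atoms / bonds in a molecule
#' @param mol a `molecule`.
#' @return integer count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(mol) nrow(mol$bonds)
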