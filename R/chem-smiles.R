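# SMILES <-> internal molecular graph, plus OpenBabel-backed canonicalization.
#
# Internal representation ("mol"): a list with
#   elem    character, element symbol per atom (explicit H atoms allowed)
#   charge  integer formal charge per atom
#   arom    logical, atom is aromatic
#   hcount  integer, *implicit* hydrogen count per atom (0 once H are explicit)
#   chiral  integer, 0 = none, 1 = anticlockwise ("@"), 2 = clockwise ("@@"),
#           parity expressed relative to neighbours taken in increasing atom
#           index order (implicit hydrogens, if any, occupy the tail)
#   bond_i, bond_j, bond_type  parallel vectors; type 1/2/3 = single/double/
#           triple, 4 = aromatic
# Atom indices are 1-based internally; the tensor encoding is 0-based at the
# interface where the spec requires it.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")

# default valence sets for implicit-H completion (neutral atoms)
.default_valence <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L
)

new_mol <- function() {
  list(elem = character(), charge = integer(), arom = logical(),
       hcount = integer(), chiral = integer(),
       bond_i = integer(), bond_j = integer(), bond_type = integer())
}

mol_n_atoms <- function(mol) length(mol$elem)
mol_n_bonds <- function(mol) length(mol$bond_i)

#' @keywords internal
mol_add_atom <- function(mol, elem, charge = 0L, arom = FALSE,
                         hcount = 0L, chiral = 0L) {
  mol$elem <- c(mol$elem, elem)
  mol$charge <- c(mol$charge, as.integer(charge))
  mol$arom <- c(mol$arom, arom)
  mol$hcount <- c(mol$hcount, as.integer(hcount))
  mol$chiral <- c(mol$chiral, as.integer(chiral))
  mol
}

mol_add_bond <- function(mol, i, j, type) {
  mol$bond_i <- c(mol$bond_i, as.integer(i))
  mol$bond_j <- c(mol$bond_j, as.integer(j))
  mol$bond_type <- c(mol$bond_type, as.integer(type))
  mol
}

# neighbour list: for each atom, integer vector of (nbr, bond index)
mol_adjlist <- function(mol) {
  n <- mol_n_atoms(mol)
  adj <- vector("list", n)
  for (b in seq_len(mol_n_bonds(mol))) {
    i <- mol$bond_i[b]; j <- mol$bond_j[b]
    adj[[i]] <- rbind(adj[[i]], c(j, b))
    adj[[j]] <- rbind(adj[[j]], c(i, b))
  }
  adj
}

.parity_of_permutation <- function(perm) {
  # 0 even, 1 odd
  n <- length(perm); visited <- logical(n); swaps <- 0L
  for (s in seq_len(n)) {
    if (visited[s]) next
    len <- 0L; k <- s
    while (!visited[k]) { visited[k] <- TRUE; k <- perm[k]; len <- len + 1L }
    swaps <- swaps + (len - 1L)
  }
  swaps %% 2L
}

# parity (0/1) of the permutation taking sort(x) to x
.tuple_parity <- function(x) {
  .parity_of_permutation(order(x))
}

## ---------------------------------------------------------------------------
## Tokenizer + parser
## ---------------------------------------------------------------------------

.smiles_tokens <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  toks <- list(); i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      jend <- i
      while (jend <= n && chars[jend] != "]") jend <- jend + 1L
      if (jend > n) stop("smiles parse: unterminated bracket atom")
      toks[[length(toks) + 1L]] <- list(kind = "atom",
                                        text = paste(chars[i:jend], collapse = ""))
      i <- jend + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      toks[[length(toks) + 1L]] <- list(kind = "atom", text = paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s")) {
      toks[[length(toks) + 1L]] <- list(kind = "atom", text = ch)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      toks[[length(toks) + 1L]] <- list(kind = "bond", text = ch)
      i <- i + 1L
    } else if (ch == "(" || ch == ")") {
      toks[[length(toks) + 1L]] <- list(kind = ch, text = ch)
      i <- i + 1L
    } else if (ch == ".") {
      toks[[length(toks) + 1L]] <- list(kind = "dot", text = ".")
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      toks[[length(toks) + 1L]] <- list(kind = "ring", text = ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("smiles parse: bad %% ring closure")
      toks[[length(toks) + 1L]] <- list(kind = "ring",
                                        text = paste(chars[(i + 1L):(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch == " " || ch == "\t") {
      break  # title/whitespace terminates the SMILES proper
    } else {
      stop(sprintf("smiles parse: unexpected character '%s'", ch))
    }
  }
  toks
}

.parse_bracket_atom <- function(text) {
  body <- sub("^\\[", "", sub("\\]$", "", text))
  m <- regmatches(body, regexec(
    "^([0-9]+)?([A-Za-z][a-z]?|\\*)(@@|@)?(H[0-9]*)?((?:\\+[0-9]*|-[0-9]*|\\++|-+))?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0) stop(sprintf("smiles parse: bad bracket atom [%s]", body))
  sym <- m[3]
  arom <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  elem <- if (arom) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10)) else sym
  chiral <- switch(m[4], "@" = 1L, "@@" = 2L, 0L)
  h <- m[5]
  hcount <- if (h == "") 0L else if (h == "H") 1L else as.integer(substr(h, 2, 10))
  chg <- m[6]
  charge <- 0L
  if (chg != "") {
    if (grepl("^[+-]+$", chg)) {
      charge <- nchar(chg) * (if (substr(chg, 1, 1) == "+") 1L else -1L)
    } else {
      sign <- if (substr(chg, 1, 1) == "+") 1L else -1L
      num <- substr(chg, 2, 10)
      charge <- sign * (if (num == "") 1L else as.integer(num))
    }
  }
  list(elem = elem, arom = arom, chiral = chiral, hcount = hcount,
       charge = charge, bracket = TRUE)
}

.parse_atom_token <- function(text) {
  if (startsWith(text, "[")) return(.parse_bracket_atom(text))
  arom <- text %in% c("b", "c", "n", "o", "p", "s")
  elem <- if (arom) toupper(text) else text
  list(elem = elem, arom = arom, chiral = 0L, hcount = NA_integer_,
       charge = 0L, bracket = FALSE)
}

#' Parse a SMILES string into the internal molecular graph
#'
#' Supports the organic subset, bracket atoms with charge, explicit hydrogen
#' counts and tetrahedral chirality tags, branches, ring closures (including
#' `%nn`), aromatic lowercase notation and dot-separated fragments.
#' Double-bond (E/Z) stereo markers are read but discarded. Tetrahedral parity
#' is converted from SMILES writing order to the package convention (neighbours
#' in increasing atom index order, implicit hydrogens at the tail).
#'
#' @param s SMILES string.
#' @return internal mol list.
#' @keywords internal
smiles_to_mol <- function(s) {
  toks <- .smiles_tokens(s)
  mol <- new_mol()
  bracket <- logical()      # per atom: was it a bracket atom?
  nbr_order <- list()       # per atom: neighbours in SMILES order (0 = implicit H slot)
  smi_chiral <- integer()   # chirality tag as written
  prev <- 0L                # current attachment atom (0 = none)
  stack <- integer()
  pending_bond <- ""        # bond symbol seen since last atom
  ring_open <- list()       # ring number -> list(atom, bond, slot)
  consume_bond <- function() { b <- pending_bond; pending_bond <<- ""; b }

  bond_type_between <- function(sym, a1, a2) {
    if (sym == "-") return(1L)
    if (sym == "=") return(2L)
    if (sym == "#") return(3L)
    if (sym == ":") return(4L)
    if (sym %in% c("/", "\\")) return(1L)   # E/Z carrier; geometry dropped
    # unspecified: aromatic iff both atoms aromatic (bridges demoted later)
    if (mol$arom[a1] && mol$arom[a2]) 4L else 1L
  }

  for (tk in toks) {
    if (tk$kind == "atom") {
      at <- .parse_atom_token(tk$text)
      mol <- mol_add_atom(mol, at$elem, at$charge, at$arom,
                          if (is.na(at$hcount)) 0L else at$hcount, 0L)
      idx <- mol_n_atoms(mol)
      bracket[idx] <- at$bracket
      smi_chiral[idx] <- at$chiral
      nbr_order[[idx]] <- integer()
      if (at$bracket && at$hcount > 0L) {
        # implicit H slot: first if the atom opens the SMILES, else right
        # after the preceding atom (OpenSMILES convention)
        nbr_order[[idx]] <- rep(0L, at$hcount)
      }
      if (prev > 0L) {
        sym <- consume_bond()
        bt <- bond_type_between(sym, prev, idx)
        mol <- mol_add_bond(mol, prev, idx, bt)
        nbr_order[[prev]] <- c(nbr_order[[prev]], idx)
        # preceding atom comes first in the neighbour ordering
        nbr_order[[idx]] <- c(prev, nbr_order[[idx]])
      } else {
        pending_bond <- ""
      }
      prev <- idx
    } else if (tk$kind == "bond") {
      pending_bond <- tk$text
    } else if (tk$kind == "(") {
      stack <- c(stack, prev)
    } else if (tk$kind == ")") {
      if (length(stack) == 0L) stop("smiles parse: unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tk$kind == "dot") {
      prev <- 0L; pending_bond <- ""
    } else if (tk$kind == "ring") {
      num <- tk$text
      if (is.null(ring_open[[num]])) {
        ring_open[[num]] <- list(atom = prev, bond = consume_bond(),
                                 slot = length(nbr_order[[prev]]) + 1L)
        # reserve the slot now; fill the partner in when the ring closes
        nbr_order[[prev]] <- c(nbr_order[[prev]], NA_integer_)
      } else {
        op <- ring_open[[num]]
        ring_open[[num]] <- NULL
        sym <- consume_bond()
        if (sym == "" && op$bond != "") sym <- op$bond
        bt <- bond_type_between(sym, op$atom, prev)
        mol <- mol_add_bond(mol, op$atom, prev, bt)
        nbr_order[[op$atom]][op$slot] <- prev
        nbr_order[[prev]] <- c(nbr_order[[prev]], op$atom)
      }
    }
  }
  if (length(ring_open) > 0L) stop("smiles parse: unclosed ring bond")
  if (length(stack) > 0L) stop("smiles parse: unbalanced '('")

  mol <- .demote_nonring_aromatic_bonds(mol)
  mol <- .assign_implicit_h(mol, bracket)
  mol <- .convert_parity_from_smiles(mol, smi_chiral, nbr_order)
  mol
}

# a bond written as "aromatic by default" between two aromatic atoms but not
# lying in any cycle (e.g. the biphenyl link) is a single bond
.demote_nonring_aromatic_bonds <- function(mol) {
  ar <- which(mol$bond_type == 4L)
  if (length(ar) == 0L) return(mol)
  ring <- .bond_in_ring(mol)
  mol$bond_type[ar[!ring[ar]]] <- 1L
  mol
}

.assign_implicit_h <- function(mol, bracket) {
  n <- mol_n_atoms(mol)
  if (n == 0L) return(mol)
  consum <- numeric(n)
  for (b in seq_len(mol_n_bonds(mol))) {
    o <- if (mol$bond_type[b] == 4L) 1L else mol$bond_type[b]
    consum[mol$bond_i[b]] <- consum[mol$bond_i[b]] + o
    consum[mol$bond_j[b]] <- consum[mol$bond_j[b]] + o
  }
  for (a in seq_len(n)) {
    if (bracket[a]) next    # bracket atoms carry explicit H counts
    dv <- .default_valence[[mol$elem[a]]]
    if (is.null(dv)) { mol$hcount[a] <- 0L; next }
    if (mol$arom[a]) {
      mol$hcount[a] <- max(0L, dv[1] - as.integer(consum[a]) - 1L)
    } else {
      fit <- dv[dv >= consum[a]]
      mol$hcount[a] <- if (length(fit) == 0L) 0L else as.integer(fit[1] - consum[a])
    }
  }
  mol
}

.convert_parity_from_smiles <- function(mol, smi_chiral, nbr_order) {
  for (a in which(smi_chiral > 0L)) {
    tup <- nbr_order[[a]]
    if (anyNA(tup)) next
    nh <- sum(tup == 0L)
    if (length(tup) != 4L || nh > 1L) next  # not a resolvable tetrahedral centre
    # implicit H sorts to the tail: model it as an index beyond every atom
    tup[tup == 0L] <- mol_n_atoms(mol) + 1L + a
    flip <- .tuple_parity(tup)
    p <- smi_chiral[a]
    mol$chiral[a] <- if (flip == 1L) (3L - p) else p
  }
  mol
}

## ---------------------------------------------------------------------------
## Writer
## ---------------------------------------------------------------------------

#' Write the internal molecular graph as SMILES
#'
#' Atoms are emitted fully bracketed (explicit hydrogen counts and charges),
#' which keeps the writer independent of implicit-valence rules; the result is
#' meant to be fed to the canonicalizer, not shown to users. Terminal explicit
#' hydrogen atoms are collapsed into the hydrogen count of their heavy
#' neighbour. Tetrahedral parity is converted from the package convention to
#' the written neighbour order.
#'
#' @param mol internal mol list.
#' @return SMILES string (fragments joined by '.').
#' @keywords internal
mol_to_smiles <- function(mol) {
  n <- mol_n_atoms(mol)
  if (n == 0L) return("")
  adj <- mol_adjlist(mol)
  # collapse plain terminal H atoms (single bond, no charge, bonded to heavy)
  collapse <- logical(n)
  hc <- mol$hcount
  h_of <- vector("list", n)
  for (a in seq_len(n)) {
    if (mol$elem[a] != "H" || mol$charge[a] != 0L) next
    nb <- adj[[a]]
    if (is.null(nb) || nrow(nb) != 1L) next
    b <- nb[1, 2]
    heavy <- nb[1, 1]
    if (mol$bond_type[b] == 1L && mol$elem[heavy] != "H") {
      collapse[a] <- TRUE
      hc[heavy] <- hc[heavy] + 1L
      h_of[[heavy]] <- c(h_of[[heavy]], a)
    }
  }

  visited <- logical(n)
  ring_digit <- 0L
  ring_of_bond <- list()  # bond index -> digit
  out <- character(0)

  # pre-compute ring-closure (back-edge) bonds via DFS over kept atoms
  atom_written_nbrs <- vector("list", n)  # neighbour ids in written order

  bond_sym <- function(b, a1, a2) {
    bt <- mol$bond_type[b]
    if (bt == 2L) return("=")
    if (bt == 3L) return("#")
    if (bt == 4L) return("")                 # aromatic atoms, default bond
    if (mol$arom[a1] && mol$arom[a2]) return("-")  # single between aromatics
    ""
  }

  atom_token <- function(a) {
    sym <- mol$elem[a]
    if (mol$arom[a]) sym <- tolower(sym)
    chi <- ""
    if (mol$chiral[a] > 0L) {
      tup <- atom_written_nbrs[[a]]
      if (length(tup) == 4L) {
        flip <- .tuple_parity(tup)
        p <- mol$chiral[a]
        if (flip == 1L) p <- 3L - p
        chi <- if (p == 1L) "@" else "@@"
      }
    }
    hstr <- if (hc[a] == 0L) "" else if (hc[a] == 1L) "H" else paste0("H", hc[a])
    chg <- mol$charge[a]
    cstr <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
            else if (chg > 0L) paste0("+", chg) else paste0("-", abs(chg))
    paste0("[", sym, chi, hstr, cstr, "]")
  }

  # iterative DFS writing one fragment
  write_fragment <- function(root) {
    frag <- character(0)
    # first pass: discover spanning tree + back edges, record written order
    tree_children <- vector("list", n)
    tree_bonds <- vector("list", n)
    back_edges <- vector("list", n)   # per atom: bonds closing rings at it
    seen_bond <- logical(mol_n_bonds(mol))
    visited[root] <<- TRUE
    dfs <- function(a, frombond) {
      nb <- adj[[a]]
      if (!is.null(nb)) {
        ord <- nb[order(nb[, 1]), , drop = FALSE]
        for (k in seq_len(nrow(ord))) {
          j <- ord[k, 1]; b <- ord[k, 2]
          if (collapse[j] || b == frombond || seen_bond[b]) next
          if (visited[j]) {
            seen_bond[b] <<- TRUE
            back_edges[[a]] <<- c(back_edges[[a]], b)
          } else {
            seen_bond[b] <<- TRUE
            visited[j] <<- TRUE
            tree_children[[a]] <<- c(tree_children[[a]], j)
            tree_bonds[[a]] <<- c(tree_bonds[[a]], b)
            dfs(j, b)
          }
        }
      }
    }
    dfs(root, 0L)

    # assign ring digits: a back edge gets a digit at both end atoms
    digit_at <- vector("list", n)
    for (a in seq_len(n)) {
      for (b in back_edges[[a]]) {
        ring_digit <<- ring_digit + 1L
        d <- ring_digit
        other <- if (mol$bond_i[b] == a) mol$bond_j[b] else mol$bond_i[b]
        digit_at[[a]] <- rbind(digit_at[[a]], c(d, b, other))
        digit_at[[other]] <- rbind(digit_at[[other]], c(d, b, a))
      }
    }

    # second pass: emit text; written neighbour order for chirality is
    # (from atom, collapsed Hs, ring-closure partners, tree children)
    emit <- function(a, from) {
      tup <- integer()
      if (from > 0L) tup <- from
      tup <- c(tup, h_of[[a]])
      if (mol$hcount[a] > 0L)           # implicit H: sorts to the tail
        tup <- c(tup, rep(n + 1L + a, mol$hcount[a]))
      dg <- digit_at[[a]]
      ringtxt <- ""
      if (!is.null(dg)) {
        dg <- dg[order(dg[, 1]), , drop = FALSE]
        for (k in seq_len(nrow(dg))) {
          b <- dg[k, 2]
          other <- dg[k, 3]
          tup <- c(tup, other)
          dtxt <- if (dg[k, 1] > 9L) paste0("%", dg[k, 1]) else as.character(dg[k, 1])
          ringtxt <- paste0(ringtxt, bond_sym(b, a, other), dtxt)
        }
      }
      kids <- tree_children[[a]]
      tup <- c(tup, kids)
      atom_written_nbrs[[a]] <<- tup
      txt <- paste0(atom_token(a), ringtxt)
      if (length(kids) > 0L) {
        parts <- character(length(kids))
        for (k in seq_along(kids)) {
          j <- kids[k]
          b <- tree_bonds[[a]][k]
          sub <- emit(j, a)
          parts[k] <- paste0(bond_sym(b, a, j), sub)
        }
        if (length(parts) > 1L) {
          txt <- paste0(txt,
                        paste0(vapply(parts[-length(parts)],
                                      function(p) paste0("(", p, ")"), ""),
                               collapse = ""),
                        parts[length(parts)])
        } else {
          txt <- paste0(txt, parts)
        }
      }
      txt
    }
    emit(root, 0L)
  }

  frags <- character(0)
  for (root in seq_len(n)) {
    if (visited[root] || collapse[root]) next
    frags <- c(frags, write_fragment(root))
  }
  paste(frags, collapse = ".")
}

## ---------------------------------------------------------------------------
## Explicit hydrogens
## ---------------------------------------------------------------------------

#' Make implicit hydrogens explicit atoms
#'
#' New H atoms are appended after the existing atoms, in order of their heavy
#' atom. Appending keeps tetrahedral parity in the package convention valid:
#' the implicit-H slot was already modelled at the tail of the sorted order.
#' @keywords internal
mol_expand_h <- function(mol) {
  n <- mol_n_atoms(mol)
  for (a in seq_len(n)) {
    k <- mol$hcount[a]
    if (k > 0L) {
      for (q in seq_len(k)) {
        mol <- mol_add_atom(mol, "H", 0L, FALSE, 0L, 0L)
        mol <- mol_add_bond(mol, a, mol_n_atoms(mol), 1L)
      }
      mol$hcount[a] <- 0L
    }
  }
  mol
}

## ---------------------------------------------------------------------------
## OpenBabel wrappers
## ---------------------------------------------------------------------------

.ob_convert <- function(from, to, text, opts = NULL) {
  if (is.null(opts)) {
    ChemmineOB::convertFormat(from, to, text)
  } else {
    ChemmineOB::convertFormat(from, to, text, options = opts)
  }
}

.strip_stereo_smiles <- function(s) {
  gsub("[@/\\\\]", "", s)
}

#' Canonical SMILES
#'
#' Deterministic canonical form via OpenBabel. With `use_stereo = FALSE` all
#' tetrahedral and double-bond stereo descriptors are removed before
#' canonicalization, so enantiomers map to the same string.
#'
#' @param smiles character vector of SMILES.
#' @param use_stereo logical; keep stereochemistry in the canonical form.
#' @return character vector of canonical SMILES; `NA` where parsing failed.
#' @examples
#' canonicalize(c("C(C)O", "CCO"))   # identical strings
#' @export
canonicalize <- function(smiles, use_stereo = TRUE) {
  if (length(smiles) == 0L) return(character(0))
  inp <- if (use_stereo) smiles else .strip_stereo_smiles(smiles)
  out <- rep(NA_character_, length(smiles))
  res <- suppressWarnings(.ob_convert("SMI", "CAN", paste0(inp, collapse = "\n")))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- sub("[ \t].*$", "", lines)
  lines <- lines[lines != ""]
  if (length(lines) == length(smiles)) {
    out <- lines
  } else {
    # at least one failure aborted the batch: fall back to per-molecule calls
    for (k in seq_along(smiles)) {
      r <- suppressWarnings(.ob_convert("SMI", "CAN", inp[k]))
      r <- sub("[ \t].*$", "", strsplit(r, "\n", fixed = TRUE)[[1]][1])
      if (!is.na(r) && nzchar(r)) out[k] <- r
    }
  }
  out
}

#' Substructure match counts via SMARTS
#'
#' @param smiles character vector of molecules.
#' @param smarts single SMARTS (or SMILES used as substructure) query.
#' @return integer vector of match counts (`NA` for unparseable molecules).
#' @keywords internal
smarts_match_count <- function(smiles, smarts) {
  if (length(smiles) == 0L) return(integer(0))
  out <- rep(NA_integer_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  mols <- tryCatch(suppressWarnings(
    ChemmineOB::forEachMol("SMILES", paste0(smiles[ok], collapse = "\n"),
                           identity)),
    error = function(e) NULL)
  if (length(mols) == sum(ok)) {
    cnt <- suppressWarnings(
      ChemmineOB::smartsSearch_OB(mols, smarts, uniqueMatches = FALSE))
    out[ok] <- as.integer(cnt)
  } else {
    for (k in which(ok)) {
      m <- tryCatch(suppressWarnings(
        ChemmineOB::forEachMol("SMILES", smiles[k], identity)), error = function(e) NULL)
      if (length(m) == 1L) {
        out[k] <- as.integer(suppressWarnings(
          ChemmineOB::smartsSearch_OB(m, smarts, uniqueMatches = FALSE)))
      }
    }
  }
  out
}

#' Molecular descriptors from OpenBabel
#' @keywords internal
ob_descriptors <- function(smiles) {
  mols <- suppressWarnings(
    ChemmineOB::forEachMol("SMILES", paste0(smiles, collapse = "\n"), identity))
  suppressWarnings(ChemmineOB::prop_OB(mols))
}

#' Write molecules to an SDF file
#'
#' Converts SMILES to MDL SDF via OpenBabel and writes them to `path`.
#' @param smiles character vector.
#' @param path output file.
#' @param titles optional molecule titles.
#' @return invisibly, the path.
#' @export
write_sdf <- function(smiles, path, titles = NULL) {
  inp <- if (is.null(titles)) smiles else paste0(smiles, "\t", titles)
  sdf <- suppressWarnings(.ob_convert("SMI", "SDF", paste0(inp, collapse = "\n")))
  writeLines(sdf, path)
  invisible(path)
}
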