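# Graph perception on the internal mol representation: ring membership,
# smallest set of smallest rings, kekulization of the aromatic subsystem,
# chemical sanitization (the validity authority for decoded graphs),
# stereocentre detection and Morgan-style circular environments.

## ---------------------------------------------------------------------------
## Connectivity and rings
## ---------------------------------------------------------------------------

#' Connected components over atoms
#' @return integer component label per atom (1-based)
#' @keywords internal
mol_components <- function(mol) {
  n <- mol_n_atoms(mol)
  comp <- integer(n)
  if (n == 0L) return(comp)
  adj <- mol_adjlist(mol)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue) > 0L) {
      a <- queue[1]; queue <- queue[-1]
      nb <- adj[[a]]
      if (!is.null(nb)) {
        for (j in nb[, 1]) if (comp[j] == 0L) { comp[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  comp
}

# TRUE for bonds lying on at least one cycle (= non-bridge edges),
# found by DFS bridge detection
.bond_in_ring <- function(mol) {
  n <- mol_n_atoms(mol)
  m <- mol_n_bonds(mol)
  inring <- rep(FALSE, m)
  if (m == 0L) return(inring)
  adj <- mol_adjlist(mol)
  disc <- integer(n); low <- integer(n); timer <- 0L
  # iterative DFS to avoid recursion limits
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(a = root, pe = 0L, k = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      a <- fr$a
      nb <- adj[[a]]
      if (!is.null(nb) && fr$k <= nrow(nb)) {
        j <- nb[fr$k, 1]; b <- nb[fr$k, 2]
        stack[[length(stack)]]$k <- fr$k + 1L
        if (b == fr$pe) next
        if (disc[j] != 0L) {
          low[a] <- min(low[a], disc[j])
          inring[b] <- TRUE   # back edge is always on a cycle
        } else {
          timer <- timer + 1L; disc[j] <- low[j] <- timer
          stack[[length(stack) + 1L]] <- list(a = j, pe = b, k = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0L) {
          pa <- stack[[length(stack)]]$a
          pe <- fr$pe
          low[pa] <- min(low[pa], low[a])
          if (low[a] > disc[pa]) {
            # bridge: stays FALSE
          } else if (pe != 0L) {
            inring[pe] <- TRUE
          }
        }
      }
    }
  }
  inring
}

#' Smallest set of smallest rings (SSSR)
#'
#' Greedy minimum cycle basis: for every ring bond, the shortest cycle through
#' it is found by BFS; candidate cycles are added shortest-first while linearly
#' independent over GF(2) in bond space. Returns a list of atom-index vectors.
#' @keywords internal
mol_sssr <- function(mol) {
  n <- mol_n_atoms(mol)
  m <- mol_n_bonds(mol)
  comp <- mol_components(mol)
  n_cycles <- m - n + length(unique(comp[seq_len(n)]))
  if (m == 0L || n_cycles <= 0L) return(list())
  adj <- mol_adjlist(mol)

  shortest_cycle_through <- function(b) {
    # BFS from bond_i to bond_j avoiding bond b
    src <- mol$bond_i[b]; dst <- mol$bond_j[b]
    prev <- integer(n); prevb <- integer(n); seen <- logical(n)
    seen[src] <- TRUE; queue <- src
    while (length(queue) > 0L) {
      a <- queue[1]; queue <- queue[-1]
      if (a == dst) break
      nb <- adj[[a]]
      if (is.null(nb)) next
      for (k in seq_len(nrow(nb))) {
        j <- nb[k, 1]; e <- nb[k, 2]
        if (e == b || seen[j]) next
        seen[j] <- TRUE; prev[j] <- a; prevb[j] <- e
        queue <- c(queue, j)
      }
    }
    if (!seen[dst]) return(NULL)
    path <- dst; bonds <- integer(0)
    while (path[1] != src) {
      bonds <- c(prevb[path[1]], bonds)
      path <- c(prev[path[1]], path)
    }
    list(atoms = path, bonds = c(bonds, b))
  }

  cand <- list()
  for (b in seq_len(m)) {
    cyc <- shortest_cycle_through(b)
    if (!is.null(cyc)) cand[[length(cand) + 1L]] <- cyc
  }
  if (length(cand) == 0L) return(list())
  cand <- cand[order(vapply(cand, function(c) length(c$bonds), 0L))]

  basis <- matrix(FALSE, nrow = 0, ncol = m)
  rings <- list()
  for (cyc in cand) {
    v <- rep(FALSE, m); v[cyc$bonds] <- TRUE
    # GF(2) reduction against current basis
    w <- v
    for (r in seq_len(nrow(basis))) {
      pivot <- which(basis[r, ])[1]
      if (w[pivot]) w <- xor(w, basis[r, ])
    }
    if (any(w)) {
      basis <- rbind(basis, w)
      rings[[length(rings) + 1L]] <- cyc$atoms
      if (length(rings) == n_cycles) break
    }
  }
  rings
}

## ---------------------------------------------------------------------------
## Kekulization
## ---------------------------------------------------------------------------

# Aromatic atoms that must receive exactly one double bond within the aromatic
# subsystem. Returns NA when the atom cannot take part in aromaticity at all.
.needs_double <- function(elem, charge, arom_deg, other_valence) {
  # other_valence: bond-order sum of non-aromatic bonds + explicit/implicit H
  if (elem == "C") {
    if (charge == 0L)  return(arom_deg + other_valence == 3)
    if (abs(charge) == 1L) return(FALSE)   # tropylium / cyclopentadienyl: lone pair or empty
    return(NA)
  }
  if (elem == "N" || elem == "P") {
    if (charge == 0L) return(arom_deg + other_valence == 2)   # pyridine-type
    if (charge == 1L) return(arom_deg + other_valence == 3)   # pyridinium-type
    if (charge == -1L) return(FALSE)
    return(NA)
  }
  if (elem == "O" || elem == "S") {
    if (charge == 0L) return(FALSE)                            # furan/thiophene-type
    if (charge == 1L) return(arom_deg + other_valence == 2)
    return(NA)
  }
  if (elem == "B") return(FALSE)
  NA
}

#' Kekulize the aromatic subsystem
#'
#' Finds an assignment of alternating double bonds over the aromatic bonds
#' (a perfect matching on the atoms that require one double bond) by
#' backtracking. Returns the bond type vector with aromatic bonds replaced by
#' 1/2, or NULL if no Kekule structure exists.
#' @keywords internal
mol_kekulize <- function(mol) {
  bt <- mol$bond_type
  ar_bonds <- which(bt == 4L)
  if (length(ar_bonds) == 0L) return(bt)
  n <- mol_n_atoms(mol)
  arom_deg <- integer(n)
  other_val <- as.numeric(mol$hcount)
  for (b in seq_len(mol_n_bonds(mol))) {
    i <- mol$bond_i[b]; j <- mol$bond_j[b]
    if (bt[b] == 4L) {
      arom_deg[i] <- arom_deg[i] + 1L; arom_deg[j] <- arom_deg[j] + 1L
    } else {
      other_val[i] <- other_val[i] + bt[b]; other_val[j] <- other_val[j] + bt[b]
    }
  }
  ar_atoms <- sort(unique(c(mol$bond_i[ar_bonds], mol$bond_j[ar_bonds])))
  need <- rep(FALSE, n)
  for (a in ar_atoms) {
    nd <- .needs_double(mol$elem[a], mol$charge[a], arom_deg[a], other_val[a])
    if (is.na(nd)) return(NULL)
    need[a] <- nd
  }
  # matching by backtracking over aromatic bonds
  adj_ar <- vector("list", n)
  for (b in ar_bonds) {
    adj_ar[[mol$bond_i[b]]] <- c(adj_ar[[mol$bond_i[b]]], b)
    adj_ar[[mol$bond_j[b]]] <- c(adj_ar[[mol$bond_j[b]]], b)
  }
  assigned <- rep(1L, length(bt))    # aromatic bonds default to single
  matched <- rep(FALSE, n)

  todo <- ar_atoms[need[ar_atoms]]
  if (length(todo) %% 2L == 1L) return(NULL)

  bt2 <- bt
  solve <- function(pos) {
    while (pos <= length(todo) && matched[todo[pos]]) pos <- pos + 1L
    if (pos > length(todo)) return(TRUE)
    a <- todo[pos]
    for (b in adj_ar[[a]]) {
      other <- if (mol$bond_i[b] == a) mol$bond_j[b] else mol$bond_i[b]
      if (!need[other] || matched[other]) next
      matched[a] <<- TRUE; matched[other] <<- TRUE
      bt2[b] <<- 2L
      if (solve(pos + 1L)) return(TRUE)
      matched[a] <<- FALSE; matched[other] <<- FALSE
      bt2[b] <<- 1L
    }
    FALSE
  }
  bt2[ar_bonds] <- 1L
  if (!solve(1L)) return(NULL)
  bt2
}

## ---------------------------------------------------------------------------
## Sanitization
## ---------------------------------------------------------------------------

# allowed valence sets by element and formal charge
.allowed_valence <- function(elem, charge) {
  key <- paste0(elem, charge)
  tab <- list(
    "C0" = 4L,  "C1" = 3L,  "C-1" = 3L,
    "N0" = c(3L, 5L), "N1" = 4L, "N-1" = 2L,
    "O0" = 2L,  "O1" = 3L,  "O-1" = 1L,
    "S0" = c(2L, 4L, 6L), "S1" = c(3L, 5L), "S-1" = 1L,
    "P0" = c(3L, 5L), "P1" = 4L,
    "B0" = 3L,
    "H0" = 1L,
    "F0" = 1L,  "F-1" = 0L,
    "Cl0" = 1L, "Cl-1" = 0L,
    "Br0" = 1L, "Br-1" = 0L,
    "I0" = 1L,  "I-1" = 0L
  )
  tab[[key]]
}

#' Chemical sanitization of an internal mol
#'
#' The validity authority for decoded graphs. Checks, in order: aromatic bonds
#' only between aromatizable elements and lying in rings of the aromatic
#' subsystem; a Kekule structure exists; every atom's bond-order sum (after
#' kekulization, including explicit hydrogens) does not exceed an allowed
#' valence for its element and formal charge. Under-filled valences of
#' organic-subset atoms are completed with implicit hydrogens (mirroring
#' standard toolkit behaviour); explicit H atoms must have exactly one single
#' bond.
#'
#' @param mol internal mol.
#' @return list(ok, reason, mol) where mol has `hcount` filled and kekulized
#'   bond orders stored in `kekule_type`; reason is one of
#'   "empty", "aromaticity", "kekulize", "valence" when not ok.
#' @keywords internal
mol_sanitize <- function(mol) {
  n <- mol_n_atoms(mol)
  if (n == 0L) return(list(ok = FALSE, reason = "empty", mol = mol))

  # aromatic flags must be consistent: an atom is aromatic iff it has
  # aromatic bonds; aromatic bonds must lie in rings
  ar_bonds <- which(mol$bond_type == 4L)
  if (length(ar_bonds) > 0L) {
    inring <- .bond_in_ring(mol)
    if (!all(inring[ar_bonds]))
      return(list(ok = FALSE, reason = "aromaticity", mol = mol))
    ends <- unique(c(mol$bond_i[ar_bonds], mol$bond_j[ar_bonds]))
    if (!all(mol$elem[ends] %in% AROMATIC_OK))
      return(list(ok = FALSE, reason = "aromaticity", mol = mol))
    deg_ar <- integer(n)
    for (b in ar_bonds) {
      deg_ar[mol$bond_i[b]] <- deg_ar[mol$bond_i[b]] + 1L
      deg_ar[mol$bond_j[b]] <- deg_ar[mol$bond_j[b]] + 1L
    }
    if (any(deg_ar[ends] < 2L) || any(deg_ar > 3L))
      return(list(ok = FALSE, reason = "aromaticity", mol = mol))
    mol$arom <- deg_ar > 0L
  } else {
    mol$arom <- rep(FALSE, n)
  }

  kek <- mol_kekulize(mol)
  if (is.null(kek)) return(list(ok = FALSE, reason = "kekulize", mol = mol))

  valsum <- as.numeric(mol$hcount)
  degree <- integer(n)
  for (b in seq_len(mol_n_bonds(mol))) {
    i <- mol$bond_i[b]; j <- mol$bond_j[b]
    valsum[i] <- valsum[i] + kek[b]; valsum[j] <- valsum[j] + kek[b]
    degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
  }

  for (a in seq_len(n)) {
    av <- .allowed_valence(mol$elem[a], mol$charge[a])
    if (is.null(av)) return(list(ok = FALSE, reason = "valence", mol = mol))
    if (mol$elem[a] == "H") {
      # one single bond, or none (a bare [H] radical, which standard
      # sanitization accepts); more than one bond is a valence error
      if (valsum[a] > 1L)
        return(list(ok = FALSE, reason = "valence", mol = mol))
      next
    }
    fit <- av[av >= valsum[a]]
    if (length(fit) == 0L)
      return(list(ok = FALSE, reason = "valence", mol = mol))
    if (mol$arom[a] && valsum[a] > min(fit)) { } # aromatic atoms already complete
    mol$hcount[a] <- mol$hcount[a] + as.integer(fit[1] - valsum[a])
  }
  mol$kekule_type <- kek
  list(ok = TRUE, reason = NA_character_, mol = mol)
}

## ---------------------------------------------------------------------------
## Stereocentres, spiro / bridgehead atoms
## ---------------------------------------------------------------------------

# Canonical atom classes by iterative neighbourhood refinement (Morgan-like).
.atom_classes <- function(mol) {
  n <- mol_n_atoms(mol)
  adj <- mol_adjlist(mol)
  lab <- paste(mol$elem, mol$charge, mol$arom, mol$hcount, sep = "|")
  cls <- as.integer(factor(lab))
  for (it in seq_len(n)) {
    sig <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      if (is.null(nb)) return(paste0(cls[a], "!"))
      paste0(cls[a], "!", paste(sort(paste0(mol$bond_type[nb[, 2]], ":",
                                            cls[nb[, 1]])), collapse = ","))
    }, "")
    new_cls <- as.integer(factor(sig))
    if (length(unique(new_cls)) == length(unique(cls))) break
    cls <- new_cls
  }
  cls
}

#' Count potential tetrahedral stereocentres (assigned or not)
#'
#' A non-aromatic C (or N+, P) atom with four substituents counting implicit
#' hydrogens, whose substituent branches fall in four distinct canonical
#' classes. Branch identity is judged by iterative neighbourhood refinement;
#' equivalent to counting centres a CIP-style perception would flag, for
#' molecules without stereo-dependent symmetry.
#' @keywords internal
mol_count_stereocentres <- function(mol) {
  n <- mol_n_atoms(mol)
  if (n == 0L) return(0L)
  adj <- mol_adjlist(mol)
  cls <- .atom_classes(mol)
  cnt <- 0L
  for (a in seq_len(n)) {
    if (mol$arom[a]) next
    if (!(mol$elem[a] %in% c("C", "P") ||
          (mol$elem[a] == "N" && mol$charge[a] == 1L))) next
    nb <- adj[[a]]
    nheavy <- if (is.null(nb)) 0L else nrow(nb)
    if (nheavy + mol$hcount[a] != 4L) next
    if (!is.null(nb) && any(mol$bond_type[nb[, 2]] != 1L)) next
    subcls <- if (is.null(nb)) integer(0) else cls[nb[, 1]]
    # implicit hydrogens form one extra class; two implicit H => duplicate
    if (mol$hcount[a] >= 2L) next
    hclass <- if (mol$hcount[a] == 1L) -1L else NULL
    allcls <- c(subcls, hclass)
    if (length(allcls) == 4L && length(unique(allcls)) == 4L) cnt <- cnt + 1L
  }
  cnt
}

#' Spiro atoms, bridgehead atoms and macrocycles from the SSSR
#' @return list(n_spiro, n_bridgehead, n_macrocycles)
#' @keywords internal
mol_ring_complexity <- function(mol) {
  rings <- mol_sssr(mol)
  n_macro <- sum(vapply(rings, length, 0L) > 8L)
  n_spiro <- 0L; n_bridge <- 0L
  if (length(rings) >= 2L) {
    spiro_atoms <- integer(0); bridge_atoms <- integer(0)
    for (r1 in seq_len(length(rings) - 1L)) {
      for (r2 in (r1 + 1L):length(rings)) {
        shared <- intersect(rings[[r1]], rings[[r2]])
        if (length(shared) == 1L) {
          spiro_atoms <- c(spiro_atoms, shared)
        } else if (length(shared) >= 3L) {
          # rings sharing >= 2 bonds: terminal shared atoms are bridgeheads
          deg_in_shared <- vapply(shared, function(a) {
            sum(vapply(shared, function(b) {
              any((mol$bond_i == a & mol$bond_j == b) |
                  (mol$bond_j == a & mol$bond_i == b))
            }, TRUE))
          }, 0L)
          bridge_atoms <- c(bridge_atoms, shared[deg_in_shared == 1L])
        }
      }
    }
    n_spiro <- length(unique(spiro_atoms))
    n_bridge <- length(unique(bridge_atoms))
  }
  list(n_spiro = n_spiro, n_bridgehead = n_bridge, n_macrocycles = n_macro)
}

## ---------------------------------------------------------------------------
## Morgan-style circular environments
## ---------------------------------------------------------------------------

#' Circular atom environments with counts, Morgan-fingerprint style
#'
#' Heavy-atom environments of radius 0..radius over the hydrogen-suppressed
#' graph. Radius-0 environments are always emitted once per atom. For radius
#' >= 1 an environment is emitted only if its bond set is non-empty and has
#' not been produced before (layers processed in radius order, atoms in index
#' order) -- the deduplication used by count-based circular fingerprints.
#'
#' @param mol internal mol (implicit or explicit H; H atoms are suppressed).
#' @param radius maximum radius.
#' @return data.frame(sig, atom, radius) of retained environments; `sig` is a
#'   canonical signature string of the environment.
#' @keywords internal
mol_morgan_envs <- function(mol, radius = 2L) {
  # suppress explicit hydrogens into hcount
  heavy <- which(mol$elem != "H")
  if (length(heavy) < mol_n_atoms(mol)) {
    mol <- mol_suppress_h(mol)
    heavy <- seq_len(mol_n_atoms(mol))
  }
  n <- mol_n_atoms(mol)
  if (n == 0L)
    return(data.frame(sig = character(), atom = integer(), radius = integer()))
  adj <- mol_adjlist(mol)
  deg <- vapply(seq_len(n), function(a) if (is.null(adj[[a]])) 0L else nrow(adj[[a]]), 0L)
  inring <- rep(FALSE, n)
  br <- .bond_in_ring(mol)
  for (b in which(br)) { inring[mol$bond_i[b]] <- TRUE; inring[mol$bond_j[b]] <- TRUE }

  sig0 <- paste0(mol$elem, ";", mol$charge, ";", mol$hcount, ";", deg, ";",
                 as.integer(mol$arom), ";", as.integer(inring))
  sigs <- list(sig0)
  for (r in seq_len(radius)) {
    prev <- sigs[[r]]
    cur <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      if (is.null(nb)) return(paste0("(", prev[a], ")"))
      parts <- sort(paste0(mol$bond_type[nb[, 2]], "~", prev[nb[, 1]]))
      paste0("(", prev[a], ")[", paste(parts, collapse = "|"), "]")
    }, "")
    sigs[[r + 1L]] <- cur
  }

  # bond set of environment (a, r): bonds whose nearer endpoint is < r away
  dmat <- .mol_distances(mol, adj)
  env_bonds <- function(a, r) {
    if (r == 0L) return(integer(0))
    keep <- which(pmin(dmat[a, mol$bond_i], dmat[a, mol$bond_j]) < r)
    sort(keep)
  }

  out_sig <- character(0); out_atom <- integer(0); out_rad <- integer(0)
  seen <- character(0)
  for (a in seq_len(n)) {
    out_sig <- c(out_sig, sigs[[1L]][a]); out_atom <- c(out_atom, a)
    out_rad <- c(out_rad, 0L)
  }
  for (r in seq_len(radius)) {
    for (a in seq_len(n)) {
      eb <- env_bonds(a, r)
      if (length(eb) == 0L) next
      key <- paste(eb, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out_sig <- c(out_sig, sigs[[r + 1L]][a])
      out_atom <- c(out_atom, a)
      out_rad <- c(out_rad, r)
    }
  }
  data.frame(sig = out_sig, atom = out_atom, radius = out_rad,
             stringsAsFactors = FALSE)
}

.mol_distances <- function(mol, adj = NULL) {
  n <- mol_n_atoms(mol)
  if (is.null(adj)) adj <- mol_adjlist(mol)
  dmat <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dmat[s, s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      a <- queue[1]; queue <- queue[-1]
      nb <- adj[[a]]
      if (is.null(nb)) next
      for (j in nb[, 1]) {
        if (is.infinite(dmat[s, j])) { dmat[s, j] <- dmat[s, a] + 1; queue <- c(queue, j) }
      }
    }
  }
  dmat
}

#' Collapse explicit hydrogen atoms into hydrogen counts
#' @keywords internal
mol_suppress_h <- function(mol) {
  n <- mol_n_atoms(mol)
  adj <- mol_adjlist(mol)
  drop <- logical(n)
  for (a in seq_len(n)) {
    if (mol$elem[a] != "H" || mol$charge[a] != 0L) next
    nb <- adj[[a]]
    if (is.null(nb) || nrow(nb) != 1L) next
    heavy <- nb[1, 1]
    if (mol$elem[heavy] == "H" || mol$bond_type[nb[1, 2]] != 1L) next
    drop[a] <- TRUE
    mol$hcount[heavy] <- mol$hcount[heavy] + 1L
    if (mol$chiral[heavy] > 0L) {
      # parity convention puts implicit H at the tail of the sorted order;
      # moving the explicit H there flips parity when the move is odd
      nbh <- sort(adj[[heavy]][, 1])
      k <- match(a, nbh)
      if (!is.na(k) && (length(nbh) - k) %% 2L == 1L)
        mol$chiral[heavy] <- 3L - mol$chiral[heavy]
    }
  }
  if (!any(drop)) return(mol)
  keep <- which(!drop)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  kb <- !(drop[mol$bond_i] | drop[mol$bond_j])
  list(elem = mol$elem[keep], charge = mol$charge[keep], arom = mol$arom[keep],
       hcount = mol$hcount[keep], chiral = mol$chiral[keep],
       bond_i = remap[mol$bond_i[kb]], bond_j = remap[mol$bond_j[kb]],
       bond_type = mol$bond_type[kb])
}
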